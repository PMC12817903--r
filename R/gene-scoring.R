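# Collapse feature-level statistics to gene-level chemical-gene (CG) scores:
# insertion-site aggregation for the Tn library, median-of-perfect-spacer LFC
# with Stouffer-combined significance for CRISPRi, and partial-knockdown
# scoring of essential genes via qualifying mismatch guides.

# Map insertion sites to (possibly clipped) gene bodies. Coordinates are
# stored 1-based inclusive and converted to 0-based half-open internally.
# Sites outside every gene are dropped; a site inside several overlapping
# genes is matched to each (reported via a message).
assign_sites_to_genes <- function(sites, genes, clip_frac = 0.05) {
  if (clip_frac < 0 || clip_frac >= 0.5) abort("`clip_frac` must lie in [0, 0.5).")
  g <- genes %>%
    dplyr::mutate(
      len = .data$end - .data$start + 1L,
      clip = floor(clip_frac * .data$len),
      lo0 = (.data$start - 1L) + .data$clip,        # 0-based half-open [lo0, hi0)
      hi0 = .data$end - .data$clip) %>%
    dplyr::filter(.data$hi0 > .data$lo0)
  s <- sites %>% dplyr::mutate(pos0 = .data$pos - 1L)
  hits <- dplyr::inner_join(
    s, g,
    by = dplyr::join_by(replicon, between(pos0, lo0, hi0)),
    relationship = "many-to-many") %>%
    dplyr::filter(.data$pos0 < .data$hi0) %>%       # between() is closed; make hi0 exclusive
    dplyr::select("site_id", "gene_id")
  if (anyDuplicated(hits$site_id)) {
    inform("some sites fall in overlapping genes and are counted in each.")
  }
  hits
}

#' Aggregate insertion-site counts to genes
#'
#' Sums site-level counts over the unique insertion sites falling inside each
#' gene body after removing the first and last `clip_frac` of its length.
#' Sites outside every clipped gene body are dropped; genes without sites get
#' a row of zeros. The number of contributing sites per gene is attached as
#' attribute `"n_sites"`.
#'
#' @param counts Site-level count table (tibble, `feature_id` + samples).
#' @param sites Tibble (`site_id`, `replicon`, `pos`), 1-based positions.
#' @param genes Gene model tibble (`gene_id`, `replicon`, `start`, `end`),
#'   1-based inclusive.
#' @param clip_frac Fraction clipped from each gene end (default 0.05).
#' @return Gene-level count table (tibble, `feature_id` = gene id + samples).
#' @export
tn_gene_aggregate <- function(counts, sites, genes, clip_frac = 0.05) {
  m <- count_matrix(counts)
  sites <- sites %>% dplyr::filter(.data$site_id %in% rownames(m))
  hits <- assign_sites_to_genes(sites, genes, clip_frac)
  agg <- matrix(0, nrow = nrow(genes), ncol = ncol(m),
                dimnames = list(genes$gene_id, colnames(m)))
  if (nrow(hits)) {
    sub <- m[hits$site_id, , drop = FALSE]
    for (j in seq_len(ncol(m))) {
      agg[, j] <- tapply(sub[, j], factor(hits$gene_id, levels = genes$gene_id),
                         sum, default = 0)
    }
  }
  out <- dplyr::bind_cols(tibble(feature_id = genes$gene_id), as_tibble(agg))
  n_sites <- table(factor(hits$gene_id, levels = genes$gene_id))
  attr(out, "n_sites") <- setNames(as.integer(n_sites), genes$gene_id)
  out
}

#' Stouffer's combined p-value
#'
#' Combines k p-values by summing their upper-tail normal quantiles:
#' `z_i = qnorm(1 - p_i)`, combined `z = sum(w_i z_i) / sqrt(sum(w_i^2))`,
#' returning `1 - pnorm(z)`. Inputs are clipped to `[1e-15, 1 - 1e-15]`
#' before the transform.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; must be non-empty (zeros
#'   are handled by the clipping).
#' @param weights Optional positive weights (default equal).
#' @return A single combined p-value.
#' @examples
#' stouffer(c(0.05, 0.05))
#' @export
stouffer <- function(p, weights = NULL) {
  if (length(p) == 0) abort("`p` must contain at least one value.")
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("`p` values must lie in [0, 1].")
  w <- weights %||% rep(1, length(p))
  if (length(w) != length(p) || any(w <= 0)) abort("`weights` must be positive, one per p-value.")
  z <- qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15))
  1 - pnorm(sum(w * z) / sqrt(sum(w^2)))
}

#' Gene-level CRISPRi chemical-gene scores
#'
#' The CG score of a gene is the median LFC of its perfect-match spacers; the
#' gene-level FDR combines those spacers' q-values with [stouffer()]. Mismatch
#' and non-targeting spacers are excluded; genes without any scored
#' perfect-match spacer yield no row.
#'
#' @param spacer_stats Feature statistics from [nb_lfc_test()] on spacer
#'   counts (`feature_id`, `lfc`, `p`, `q`).
#' @param guides Guide annotation tibble (`spacer_id`, `gene_id`, `class`).
#' @param condition Condition label stored in the output.
#' @param library Library label (default `"CRISPRi"`).
#' @return A gene-score tibble (`gene_id`, `condition`, `library`, `cg_score`,
#'   `gene_fdr`, `n_features`).
#' @export
crispri_gene_scores <- function(spacer_stats, guides,
                                condition = NA_character_,
                                library = "CRISPRi") {
  perfect <- guides %>%
    dplyr::filter(.data$class == "perfect", !is.na(.data$gene_id))
  joined <- spacer_stats %>%
    dplyr::inner_join(perfect, by = c(feature_id = "spacer_id"))
  if (nrow(joined) == 0) {
    return(tibble(gene_id = character(), condition = character(),
                  library = character(), cg_score = numeric(),
                  gene_fdr = numeric(), n_features = integer()))
  }
  joined %>%
    dplyr::summarise(
      cg_score = median(.data$lfc),
      gene_fdr = stouffer(.data$q),
      n_features = dplyr::n(),
      .by = "gene_id") %>%
    dplyr::mutate(condition = condition, library = library,
                  .after = "gene_id") %>%
    dplyr::arrange(.data$gene_id)
}

#' Gene-level Tn chemical-gene scores
#'
#' Wraps gene-level test results (from [nb_lfc_test()] on
#' [tn_gene_aggregate()] output) into the common gene-score shape. Genes with
#' no insertion sites are dropped (they cannot be assessed by the Tn library).
#'
#' @param gene_stats Feature statistics over gene-level counts.
#' @param n_sites Named vector of insertion sites per gene, as attached by
#'   [tn_gene_aggregate()].
#' @inheritParams crispri_gene_scores
#' @return A gene-score tibble with the same columns as
#'   [crispri_gene_scores()].
#' @export
tn_gene_scores <- function(gene_stats, n_sites,
                           condition = NA_character_, library = "Tn") {
  gene_stats %>%
    dplyr::mutate(n_features = as.integer(n_sites[.data$feature_id])) %>%
    dplyr::filter(.data$n_features >= 1L) %>%
    dplyr::transmute(
      gene_id = .data$feature_id, condition = condition, library = library,
      cg_score = .data$lfc, gene_fdr = .data$q, n_features = .data$n_features) %>%
    dplyr::arrange(.data$gene_id)
}

#' Partial-knockdown CG scores from mismatch guides
#'
#' For genes whose full knockdown is lethal, chemical phenotypes can still be
#' read out from mismatched spacers that cause only a partial fitness defect
#' under induction alone. A mismatch spacer qualifies when its induction LFC
#' (induced final vs uninduced initial timepoint) lies within `lfc_window`
#' and its induction FDR is at most `fdr_max`; the gene's partial-knockdown
#' CG score is the median chemical LFC of its qualifying spacers. Genes with
#' no qualifying spacer yield no row.
#'
#' @param chemical_stats Spacer statistics for treated vs control.
#' @param induction_stats Spacer statistics for induced vs uninduced samples.
#' @param guides Guide annotation tibble.
#' @param lfc_window Closed induction-LFC window (default `c(-4, -1)`).
#' @param fdr_max Induction FDR gate (default 0.05).
#' @param condition Condition label stored in the output.
#' @return A tibble (`gene_id`, `condition`, `cg_score`, `n_features`).
#' @export
mismatch_partial_scores <- function(chemical_stats, induction_stats, guides,
                                    lfc_window = c(-4, -1), fdr_max = 0.05,
                                    condition = NA_character_) {
  stopifnot(length(lfc_window) == 2, lfc_window[1] <= lfc_window[2])
  mm <- guides %>%
    dplyr::filter(.data$class == "mismatch", !is.na(.data$gene_id))
  qualifying <- induction_stats %>%
    dplyr::inner_join(mm, by = c(feature_id = "spacer_id")) %>%
    dplyr::filter(.data$lfc >= lfc_window[1], .data$lfc <= lfc_window[2],
                  .data$q <= fdr_max) %>%
    dplyr::select("feature_id", "gene_id")
  chemical_stats %>%
    dplyr::inner_join(qualifying, by = "feature_id") %>%
    dplyr::summarise(cg_score = median(.data$lfc), n_features = dplyr::n(),
                     .by = "gene_id") %>%
    dplyr::mutate(condition = condition, .after = "gene_id") %>%
    dplyr::arrange(.data$gene_id)
}
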