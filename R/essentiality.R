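# Essential-gene calling in each library, and transfer of an LFC cutoff
# between studies via linear regression.

#' Call essential genes from transposon insertion density
#'
#' A gene is essential when it carries significantly fewer unique insertion
#' sites than expected from the genome-wide insertion density. A site
#' qualifies when its summed reads over the supplied (control) samples reach
#' `min_hits`; the genome-wide density `d` is the number of qualifying sites
#' inside clipped gene bodies divided by the total clipped gene length. For a
#' gene with `k` qualifying sites in a clipped body of length `L`, the
#' depletion p-value is the one-sided binomial tail `P[Binom(L, d) <= k]`, and
#' the call requires `p < alpha` together with a density metric below
#' `density_cutoff`.
#'
#' Two density metrics are reported: `hits_per_bp = k / L` and the
#' density-normalized `norm_hits_per_bp = (k / L) / d` (the fraction of the
#' expected density the gene attains). The call uses the normalized metric by
#' default; set `use_normalized_metric = FALSE` to gate on the raw one.
#'
#' @inheritParams tn_gene_aggregate
#' @param control_samples Sample columns to use (untreated/control only);
#'   default all sample columns in `counts`.
#' @param min_hits Minimum summed reads for a site to count as hit (default 5).
#' @param alpha Significance level (default 0.05).
#' @param density_cutoff Density gate (default 0.025).
#' @param use_normalized_metric Gate on the density-normalized metric
#'   (default `TRUE`).
#' @return A tibble (`gene_id`, `library`, `n_sites`, `clipped_length`,
#'   `hits_per_bp`, `norm_hits_per_bp`, `p_value`, `essential`).
#' @export
tn_essentiality <- function(counts, sites, genes,
                            control_samples = NULL,
                            min_hits = 5, clip_frac = 0.05,
                            alpha = 0.05, density_cutoff = 0.025,
                            use_normalized_metric = TRUE) {
  m <- count_matrix(counts)
  control_samples <- control_samples %||% colnames(m)
  missing <- setdiff(control_samples, colnames(m))
  if (length(missing)) {
    abort(paste0("sample(s) not in count table: ", paste(missing, collapse = ", ")))
  }
  reads <- rowSums(m[, control_samples, drop = FALSE])
  qualifying <- sites %>%
    dplyr::filter(.data$site_id %in% names(reads)[reads >= min_hits])

  g <- genes %>%
    dplyr::mutate(
      len = .data$end - .data$start + 1L,
      clipped_length = .data$len - 2L * floor(clip_frac * .data$len))
  hits <- assign_sites_to_genes(qualifying, genes, clip_frac)
  k <- table(factor(hits$gene_id, levels = genes$gene_id))
  k <- setNames(as.integer(k), genes$gene_id)
  total_len <- sum(g$clipped_length)
  d <- sum(k) / total_len
  if (d == 0) abort("genome-wide insertion density is zero; cannot assess essentiality.")

  res <- g %>%
    dplyr::transmute(
      gene_id = .data$gene_id,
      library = "Tn",
      n_sites = unname(k[.data$gene_id]),
      clipped_length = .data$clipped_length,
      hits_per_bp = .data$n_sites / .data$clipped_length,
      norm_hits_per_bp = .data$hits_per_bp / d,
      p_value = pbinom(.data$n_sites, .data$clipped_length, d))
  metric <- if (use_normalized_metric) res$norm_hits_per_bp else res$hits_per_bp
  res$essential <- res$p_value < alpha & metric < density_cutoff
  attr(res, "genome_density") <- d
  res
}

#' Call essential genes from CRISPRi induction depletion
#'
#' A gene is essential when its gene-level significance is at most `alpha` and
#' its median perfect-spacer LFC in the induced final timepoint (vs the
#' uninduced initial timepoint) is at most `lfc_cutoff` (both gates inclusive).
#'
#' @param gene_scores Gene-score tibble from [crispri_gene_scores()] on the
#'   induced-vs-uninduced comparison.
#' @param lfc_cutoff Median-LFC gate (default -5.1).
#' @param alpha Gene-level FDR gate (default 0.05).
#' @return A tibble (`gene_id`, `library`, `median_lfc`, `gene_fdr`,
#'   `essential`).
#' @export
crispri_essentiality <- function(gene_scores, lfc_cutoff = -5.1, alpha = 0.05) {
  gene_scores %>%
    dplyr::transmute(
      gene_id = .data$gene_id,
      library = "CRISPRi",
      median_lfc = .data$cg_score,
      gene_fdr = .data$gene_fdr,
      essential = .data$gene_fdr <= alpha & .data$cg_score <= lfc_cutoff)
}

#' Transfer an LFC cutoff between studies by linear regression
#'
#' Fits ordinary least squares of the current study's per-gene LFCs on a
#' reference study's LFCs for the same genes, then maps the reference study's
#' cutoff through the fitted line, rounding to one decimal. With the published
#' relationship `y = 1.567x - 0.373` a reference cutoff of -3 maps to -5.1.
#'
#' @param paired_lfcs Data frame with columns `reference_lfc` (x) and
#'   `current_lfc` (y), one row per shared gene; needs at least two distinct
#'   `reference_lfc` values.
#' @param reference_cutoff Cutoff on the reference scale (default -3).
#' @return A `cutoff_transfer` object with elements `slope`, `intercept`,
#'   `reference_cutoff`, `mapped_cutoff`, `n` and the underlying `fit`;
#'   supports [tidy()] and [glance()].
#' @examples
#' d <- tibble::tibble(reference_lfc = -5:2,
#'                     current_lfc = 1.567 * (-5:2) - 0.373)
#' transfer_cutoff(d, reference_cutoff = -3)$mapped_cutoff
#' @export
transfer_cutoff <- function(paired_lfcs, reference_cutoff = -3) {
  if (!all(c("reference_lfc", "current_lfc") %in% names(paired_lfcs))) {
    abort("`paired_lfcs` needs columns `reference_lfc` and `current_lfc`.")
  }
  x <- paired_lfcs$reference_lfc
  if (length(unique(x)) < 2) abort("need at least two distinct reference LFC values.")
  fit <- lm(current_lfc ~ reference_lfc, data = paired_lfcs)
  slope <- unname(coef(fit)[["reference_lfc"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  structure(list(
    slope = slope,
    intercept = intercept,
    reference_cutoff = reference_cutoff,
    mapped_cutoff = round(slope * reference_cutoff + intercept, 1),
    n = nrow(paired_lfcs),
    fit = fit
  ), class = "cutoff_transfer")
}

#' @export
print.cutoff_transfer <- function(x, ...) {
  cat("<cutoff_transfer>\n")
  cat(sprintf("  y = %.3f x %+.3f  (n = %d genes)\n", x$slope, x$intercept, x$n))
  cat(sprintf("  reference cutoff %.2f -> mapped cutoff %.1f\n",
              x$reference_cutoff, x$mapped_cutoff))
  invisible(x)
}

#' @rdname transfer_cutoff
#' @param x A `cutoff_transfer` object.
#' @param ... Unused.
#' @method tidy cutoff_transfer
#' @export
tidy.cutoff_transfer <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname transfer_cutoff
#' @method glance cutoff_transfer
#' @export
glance.cutoff_transfer <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = summary(x$fit)$r.squared, n = x$n,
         reference_cutoff = x$reference_cutoff, mapped_cutoff = x$mapped_cutoff)
}
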