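# Cross-library validation: quantile normalization of CG scores, ROC/AUC
# cutoff sweeps using one library as ground truth for the other, dual-gate hit
# calling, concordance tallies, and Ward clustering of the score matrix.

#' Quantile-normalize score columns
#'
#' Classic quantile normalization: within each column, the rank-k value is
#' replaced by the mean of all columns' rank-k values, so every column ends up
#' with an identical value multiset; ties within a column receive the mean of
#' their would-be normalized values. Missing entries are an error — restrict
#' the input to genes scored in every column first.
#'
#' @param scores Data frame: id column first, then one numeric score column
#'   per library (>= 2 columns).
#' @return A tibble of the same shape with normalized columns.
#' @examples
#' quantile_normalize(tibble::tibble(gene = c("a", "b", "c"),
#'                                   tn = c(1, 2, 3), crispri = c(4, 5, 6)))
#' @export
quantile_normalize <- function(scores) {
  m <- split_id_matrix(scores, "scores")
  if (ncol(m) < 2) abort("need at least two score columns to normalize.")
  if (anyNA(m)) {
    abort("`scores` contains missing entries; intersect to genes scored in every column first.")
  }
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  dplyr::bind_cols(scores[, 1, drop = FALSE], as_tibble(norm))
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from mid-ranks. With a
#' single-class label vector the AUC is undefined and `NA` is returned (so
#' sweeps can flag rather than fail).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or 0/1) vector; `TRUE` marks positives.
#' @return The AUC in \[0, 1\], or `NA_real_` when undefined.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("`scores` and `labels` must have equal length.")
  if (anyNA(scores) || anyNA(labels)) abort("`scores`/`labels` must not contain NA.")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Sweep CG score cutoffs with cross-library ROC
#'
#' For each cutoff `c`, genes in the ground-truth library passing the score
#' gate (`truth_score >= c` for the beneficial direction, `<= -c` for the
#' detrimental direction) *and* `truth_fdr <= fdr_max` are the positives; all
#' other shared genes are negatives. The other library's score (negated in
#' the detrimental direction) then classifies those labels and its AUC is
#' recorded alongside the number of positives. AUC is `NA` where either class
#' is empty.
#'
#' @param scores Data frame with columns `truth_score`, `truth_fdr`,
#'   `classifier_score`, one row per shared gene (x condition).
#' @param direction `"detrimental"`, `"beneficial"`, or both (default).
#' @param cutoffs Non-empty non-negative cutoff grid (default 0 to 8 by 0.25).
#' @param fdr_max FDR gate on the ground-truth library (default 0.05).
#' @return A `sweep_result` tibble (`direction`, `cutoff`, `n_hits`, `auc`,
#'   `auc_defined`).
#' @export
cutoff_sweep <- function(scores,
                         direction = c("detrimental", "beneficial"),
                         cutoffs = seq(0, 8, by = 0.25),
                         fdr_max = 0.05) {
  need <- c("truth_score", "truth_fdr", "classifier_score")
  if (!all(need %in% names(scores))) {
    abort("`scores` needs columns truth_score, truth_fdr, classifier_score.")
  }
  if (length(cutoffs) == 0) abort("`cutoffs` must be non-empty.")
  direction <- match.arg(direction, several.ok = TRUE)
  out <- tidyr::expand_grid(direction = direction, cutoff = sort(cutoffs)) %>%
    dplyr::mutate(purrr::map2_dfr(.data$direction, .data$cutoff, function(dir, cc) {
      pos <- if (dir == "beneficial") {
        scores$truth_score >= cc
      } else {
        scores$truth_score <= -cc
      }
      pos <- pos & scores$truth_fdr <= fdr_max
      clf <- if (dir == "beneficial") scores$classifier_score else -scores$classifier_score
      tibble(n_hits = sum(pos), auc = roc_auc(clf, pos))
    })) %>%
    dplyr::mutate(auc_defined = !is.na(.data$auc))
  class(out) <- c("sweep_result", class(out))
  out
}

#' Call cross-validated hits
#'
#' Per gene and condition, a library's phenotype is significant when
#' `|cg_score| >= cutoff` and `gene_fdr <= alpha`. The category is `"both"`
#' when both libraries are significant (with the same effect sign when
#' `require_same_sign = TRUE`; discordant-sign pairs become `"discordant"`),
#' `"tn_only"`/`"crispri_only"` when one is, `"none"` otherwise. Genes scored
#' in only one library are flagged via `in_both_libraries` and categorized on
#' the available library.
#'
#' @param tn_scores,crispri_scores Gene-score tibbles (`gene_id`, `condition`,
#'   `cg_score`, `gene_fdr`), scores on the normalized scale used for the
#'   sweep.
#' @param cutoff Absolute CG score gate (default 4).
#' @param alpha FDR gate (default 0.05).
#' @param require_same_sign Demand concordant effect direction for `"both"`
#'   (default `TRUE`).
#' @return A `hit_calls` tibble: per gene x condition scores, FDRs,
#'   significance flags, `in_both_libraries` and `category`.
#' @export
call_hits <- function(tn_scores, crispri_scores, cutoff = 4, alpha = 0.05,
                      require_same_sign = TRUE) {
  pick <- function(x, prefix) {
    x %>% dplyr::select("gene_id", "condition",
                        "{prefix}_cg_score" := "cg_score",
                        "{prefix}_fdr" := "gene_fdr")
  }
  out <- dplyr::full_join(pick(tn_scores, "tn"), pick(crispri_scores, "crispri"),
                          by = c("gene_id", "condition")) %>%
    dplyr::mutate(
      tn_significant = !is.na(.data$tn_cg_score) &
        abs(.data$tn_cg_score) >= cutoff & .data$tn_fdr <= alpha,
      crispri_significant = !is.na(.data$crispri_cg_score) &
        abs(.data$crispri_cg_score) >= cutoff & .data$crispri_fdr <= alpha,
      in_both_libraries = !is.na(.data$tn_cg_score) & !is.na(.data$crispri_cg_score),
      concordant = .data$tn_significant & .data$crispri_significant &
        (!require_same_sign |
           sign(.data$tn_cg_score) == sign(.data$crispri_cg_score)),
      category = dplyr::case_when(
        concordant ~ "both",
        tn_significant & crispri_significant ~ "discordant",
        tn_significant ~ "tn_only",
        crispri_significant ~ "crispri_only",
        .default = "none")) %>%
    dplyr::select(-"concordant") %>%
    dplyr::arrange(.data$condition, .data$gene_id)
  class(out) <- c("hit_calls", class(out))
  out
}

#' Gene-level concordance tallies
#'
#' Counts genes significant in at least one condition, categorized once per
#' gene: `both` if both libraries called it (same condition) anywhere;
#' `discordant` if they called it with opposite signs and never concordantly;
#' `mixed` if each library called it but never in the same condition;
#' otherwise `tn_only` / `crispri_only`. `union` is the total number of genes
#' significant anywhere and equals the sum of the other counts.
#'
#' @param hits A [call_hits()] tibble.
#' @return A one-row tibble (`both`, `tn_only`, `crispri_only`, `discordant`,
#'   `mixed`, `union`).
#' @export
concordance_summary <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble(both = 0L, tn_only = 0L, crispri_only = 0L,
                  discordant = 0L, mixed = 0L, union = 0L))
  }
  per_gene <- hits %>%
    dplyr::summarise(
      tn_any = any(.data$tn_significant),
      ci_any = any(.data$crispri_significant),
      both_any = any(.data$category == "both"),
      disc_any = any(.data$category == "discordant"),
      .by = "gene_id") %>%
    dplyr::mutate(category = dplyr::case_when(
      both_any ~ "both",
      disc_any ~ "discordant",
      tn_any & ci_any ~ "mixed",
      tn_any ~ "tn_only",
      ci_any ~ "crispri_only",
      .default = "none"))
  n_of <- function(x) sum(per_gene$category == x)
  tibble(both = n_of("both"), tn_only = n_of("tn_only"),
         crispri_only = n_of("crispri_only"), discordant = n_of("discordant"),
         mixed = n_of("mixed"),
         union = sum(per_gene$category != "none"))
}

#' Ward hierarchical clustering of a score matrix
#'
#' Agglomerative Ward linkage (minimum within-cluster variance increase) on
#' Euclidean geometry, via [stats::hclust()] with `method = "ward.D2"`; merge
#' heights are non-decreasing and equal `sqrt(2 * delta-ESS)`.
#'
#' @param scores Data frame: id column first, then numeric columns (one per
#'   condition x library); >= 2 rows, no missing values.
#' @return An [stats::hclust] tree labelled by the id column.
#' @seealso [dendro_newick()] for a text serialization.
#' @export
ward_linkage <- function(scores) {
  m <- split_id_matrix(scores, "scores")
  if (nrow(m) < 2) abort("need at least two rows to cluster.")
  if (anyNA(m)) abort("`scores` contains missing values; impute or drop upstream.")
  hclust(dist(m), method = "ward.D2")
}

#' Serialize an hclust tree to Newick text
#'
#' Branch lengths are differences of merge heights (leaf branches span from
#' height zero to their first merge).
#'
#' @param hc An [stats::hclust] object.
#' @param digits Branch-length digits.
#' @return A single Newick string terminated by `;`.
#' @export
dendro_newick <- function(hc, digits = 4) {
  stopifnot(inherits(hc, "hclust"))
  lab <- hc$labels %||% as.character(seq_along(hc$order))
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%s", lab[-i], format(round(parent_h, digits)))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s",
              node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
              format(round(parent_h - h, digits)))
    }
  }
  n <- nrow(hc$merge)
  sprintf("(%s,%s);", node(hc$merge[n, 1], hc$height[n]),
          node(hc$merge[n, 2], hc$height[n]))
}
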