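# Proteome-response stage: left-censored imputation, per-protein Welch tests
# with a dual significance gate, the envelope-localization rule, and Fisher
# enrichment of envelope proteins among responders.

#' Impute left-censored missing intensities
#'
#' Missing entries are drawn per sample from a Gaussian shifted into the
#' sample's low-intensity tail: mean `sample mean - shift * sample sd`, sd
#' `width * sample sd` (computed from the observed values). This is the usual
#' convention for label-free proteomics where low-abundance proteins drop
#' below the detection limit. A complete table is returned unchanged.
#'
#' @param intensities Tibble: `protein_id` column then one log2-intensity
#'   column per sample; `NA` marks missing values.
#' @param seed Optional integer seed; imputation is deterministic given it.
#' @param shift,width Down-shift and width of the imputation distribution in
#'   units of the sample sd (defaults 1.8 and 0.3).
#' @param min_obs Minimum observed values per sample needed to estimate its
#'   moments (default 10); fewer is an error.
#' @return The completed tibble.
#' @export
impute_missing <- function(intensities, seed = NULL, shift = 1.8, width = 0.3,
                           min_obs = 10) {
  m <- split_id_matrix(intensities, "intensities")
  if (any(!is.finite(m) & !is.na(m))) abort("intensities must be finite where present.")
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < min_obs)) {
    abort(sprintf("sample(s) with fewer than %d observed values: %s", min_obs,
                  paste(colnames(m)[n_obs < min_obs], collapse = ", ")))
  }
  if (!anyNA(m)) return(as_tibble(intensities))
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (!any(miss)) next
      mu <- mean(m[!miss, j])
      sdv <- sd(m[!miss, j])
      m[miss, j] <- rnorm(sum(miss), mu - shift * sdv, width * sdv)
    }
    dplyr::bind_cols(intensities[, 1, drop = FALSE], as_tibble(m))
  })
}

#' Per-protein differential abundance (Welch test)
#'
#' Log2 fold change is the treated-minus-control group mean difference of log2
#' intensities; p-values come from a two-sided unequal-variance (Welch) t test
#' and are BH-adjusted. A protein is significant when `q < alpha` and
#' `|lfc| > lfc_cutoff` (both strict, matching the FDR < 0.05, |LFC| > 1
#' convention).
#'
#' @param intensities Complete intensity tibble (impute first).
#' @param treated,control Sample column names (>= 2 each).
#' @param lfc_cutoff Absolute LFC gate (default 1).
#' @param alpha FDR gate (default 0.05).
#' @return A `protein_diff_stats` tibble (`protein_id`, `lfc`, `p`, `q`,
#'   `significant`).
#' @export
protein_diff <- function(intensities, treated, control,
                         lfc_cutoff = 1, alpha = 0.05) {
  m <- split_id_matrix(intensities, "intensities")
  if (anyNA(m)) abort("intensities contain missing values; run impute_missing() first.")
  missing <- setdiff(c(treated, control), colnames(m))
  if (length(missing)) {
    abort(paste0("sample(s) not in intensity table: ", paste(missing, collapse = ", ")))
  }
  n1 <- length(treated); n2 <- length(control)
  if (n1 < 2 || n2 < 2) abort("need at least two replicates per group.")
  x1 <- m[, treated, drop = FALSE]; x2 <- m[, control, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  tstat <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  lfc <- unname(lfc); p <- unname(p)
  q <- bh_adjust(p)
  out <- tibble(protein_id = rownames(m), lfc = lfc, p = p, q = q,
                significant = q < alpha & abs(lfc) > lfc_cutoff)
  class(out) <- c("protein_diff_stats", class(out))
  out
}

#' Classify protein localization
#'
#' A protein is an envelope protein when its signal-peptide likelihood exceeds
#' `likelihood_cutoff` (strictly) or it has at least one predicted
#' transmembrane segment; all other proteins are cytoplasmic.
#'
#' @param predictions Data frame with columns `signal_likelihood` (in
#'   \[0, 1\]) and `n_tm_segments` (>= 0), typically one row per protein.
#' @param likelihood_cutoff Signal-peptide likelihood gate (default 0.9,
#'   strict greater-than).
#' @return The input tibble with a `label` column
#'   (`"envelope"`/`"cytoplasmic"`) appended.
#' @examples
#' classify_localization(tibble::tibble(protein_id = c("a", "b", "c"),
#'                                      signal_likelihood = c(0.95, 0.5, 0.90),
#'                                      n_tm_segments = c(0, 3, 0)))
#' @export
classify_localization <- function(predictions, likelihood_cutoff = 0.9) {
  need <- c("signal_likelihood", "n_tm_segments")
  if (!all(need %in% names(predictions))) {
    abort("`predictions` needs columns signal_likelihood and n_tm_segments.")
  }
  sl <- predictions$signal_likelihood
  tm <- predictions$n_tm_segments
  if (anyNA(sl) || any(sl < 0 | sl > 1)) abort("`signal_likelihood` must lie in [0, 1].")
  if (anyNA(tm) || any(tm < 0)) abort("`n_tm_segments` must be >= 0.")
  predictions %>%
    dplyr::mutate(label = dplyr::if_else(
      sl > likelihood_cutoff | tm >= 1, "envelope", "cytoplasmic"))
}

#' Envelope fraction of a protein set
#'
#' Percentage of envelope-labelled proteins in a subset, rounded to two
#' decimals (e.g. 544 envelope proteins of 1,852 give 29.37).
#'
#' @param localization Tibble with `protein_id` and `label` columns.
#' @param proteins Optional character vector restricting to a subset (must be
#'   contained in the table); default all proteins.
#' @return A single percentage rounded to 2 decimals.
#' @export
envelope_fraction <- function(localization, proteins = NULL) {
  if (!all(c("protein_id", "label") %in% names(localization))) {
    abort("`localization` needs columns protein_id and label.")
  }
  lab <- setNames(localization$label, localization$protein_id)
  proteins <- proteins %||% localization$protein_id
  if (length(proteins) == 0) abort("`proteins` must be non-empty.")
  unknown <- setdiff(proteins, names(lab))
  if (length(unknown)) abort("`proteins` contains ids absent from the localization table.")
  round(100 * mean(lab[proteins] == "envelope"), 2)
}

#' Fisher enrichment of envelope proteins among responders
#'
#' Builds the 2x2 table (responsive vs background-minus-responsive) x
#' (envelope vs cytoplasmic) and tests association with a two-sided Fisher
#' exact test. The odds ratio is the sample cross-product ratio with a
#' Haldane correction of 0.5 added to every cell when any cell is zero. With
#' a degenerate margin the p-value is 1 and the odds ratio undefined (`NA`).
#'
#' @param localization Tibble with `protein_id` and `label`.
#' @param responsive Character vector of responsive protein ids.
#' @param background Character vector of background ids (default: all proteins
#'   in the table); must contain `responsive`.
#' @return An `enrichment_result` with elements `table` (2x2 matrix),
#'   `odds_ratio`, `p_value`, `haldane`; supports [tidy()].
#' @export
envelope_enrichment <- function(localization, responsive, background = NULL) {
  background <- background %||% localization$protein_id
  if (!all(responsive %in% background)) abort("`responsive` must be a subset of `background`.")
  lab <- setNames(localization$label, localization$protein_id)
  unknown <- setdiff(background, names(lab))
  if (length(unknown)) abort("`background` contains ids absent from the localization table.")
  rest <- setdiff(background, responsive)
  tab <- matrix(c(
    sum(lab[responsive] == "envelope"), sum(lab[responsive] == "cytoplasmic"),
    sum(lab[rest] == "envelope"), sum(lab[rest] == "cytoplasmic")),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("responsive", "non_responsive"),
                    c("envelope", "cytoplasmic")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    p <- 1; or <- NA_real_; haldane <- FALSE
  } else {
    p <- fisher.test(tab)$p.value
    haldane <- any(tab == 0)
    tt <- if (haldane) tab + 0.5 else tab
    or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  }
  structure(list(table = tab, odds_ratio = or, p_value = p, haldane = haldane),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$table)
  cat(sprintf("  odds ratio %.3g%s, Fisher p = %.4g\n", x$odds_ratio,
              if (x$haldane) " (Haldane-corrected)" else "", x$p_value))
  invisible(x)
}

#' @rdname envelope_enrichment
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(estimate = x$odds_ratio, p.value = x$p_value,
         n_responsive = sum(x$table[1, ]), n_background = sum(x$table),
         haldane = x$haldane)
}
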