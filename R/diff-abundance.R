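# Count normalization and per-feature differential abundance between treated
# and untreated samples: median-of-ratios size factors, method-of-moments
# common dispersion, and a negative-binomial conditional exact-style test.

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment. Thin wrapper over [stats::p.adjust()] that rejects
#' missing or out-of-range input instead of propagating it.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(is.nan(p))) abort("`p` must not contain NA/NaN.")
  if (any(p < 0 | p > 1)) abort("`p` values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the ratio
#' of that sample's count to the feature's geometric mean over samples, using
#' only features nonzero in every sample; factors are then rescaled so their
#' geometric mean is 1. If no feature is nonzero in all samples the factors
#' fall back to total-count ratios (with a warning).
#'
#' @param counts Count table: tibble with a `feature_id` column followed by one
#'   column per sample (non-negative integers).
#' @return A tibble (`sample_id`, `size_factor`).
#' @examples
#' counts <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                          s1 = c(2, 4, 8), s2 = c(4, 8, 16))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  if (any(colSums(m) == 0)) abort("a sample has all-zero counts; cannot normalize.")
  full <- rowSums(m > 0) == ncol(m)
  if (!any(full)) {
    warn("no feature is nonzero in all samples; falling back to total-count size factors.")
    f <- colSums(m)
  } else {
    mm <- m[full, , drop = FALSE]
    geo <- exp(rowMeans(log(mm)))
    f <- apply(mm / geo, 2, median)
  }
  f <- f / geometric_mean(f)
  tibble(sample_id = colnames(m), size_factor = unname(f))
}

#' Method-of-moments common dispersion
#'
#' Pools normalized within-group residual variance across all features and
#' replicate groups to estimate a single negative-binomial overdispersion
#' `phi` under the variance model `m + phi * m^2`; the estimate is truncated
#' at zero. Groups with fewer than two samples contribute nothing; with no
#' replication anywhere the function warns and returns 0.
#'
#' @inheritParams size_factors
#' @param groups Group label per sample column (vector aligned with the sample
#'   columns, or named by sample id); `NA` samples are ignored.
#' @param factors Size factors as returned by [size_factors()] (default) or a
#'   named vector.
#' @return A single number, `phi >= 0`.
#' @export
common_dispersion <- function(counts, groups, factors = NULL) {
  m <- count_matrix(counts)
  ids <- colnames(m)
  if (!is.null(names(groups))) groups <- groups[ids]
  if (length(groups) != ncol(m)) {
    abort("`groups` must provide one label per sample column.")
  }
  s <- factor_vector(factors %||% size_factors(counts), ids)
  y <- sweep(m, 2, s, "/")
  num <- 0; den <- 0; any_rep <- FALSE
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(!is.na(groups) & groups == g)
    n <- length(idx)
    if (n < 2) next
    any_rep <- TRUE
    yg <- y[, idx, drop = FALSE]
    mg <- rowMeans(yg)
    ss <- rowSums((yg - mg)^2) / (n - 1)
    cbar <- mean(1 / s[idx])
    keep <- mg > 0
    num <- num + sum(ss[keep] - mg[keep] * cbar)
    den <- den + sum(mg[keep]^2)
  }
  if (!any_rep) {
    warn("no group has >= 2 replicates; returning dispersion 0.")
    return(0)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# Two-sided conditional p-value for the treated group sum kt out of total n.
# At phi = 0 this is the binomial conditional test; at phi > 0 the conditional
# distribution is beta-binomial with total precision (n_t + n_c)/phi and mean
# n * prob (exact when size factors are equal within groups). Two-sided by
# doubling the smaller tail, capped at 1.
cond_pvalues <- function(kt, n, prob, phi, n_treated, n_control) {
  p <- rep(1, length(kt))
  pos <- which(n > 0)
  if (!length(pos)) return(p)
  if (phi <= 0) {
    lo <- pbinom(kt[pos], n[pos], prob)
    hi <- pbinom(kt[pos] - 1, n[pos], prob, lower.tail = FALSE)
    p[pos] <- pmin(1, 2 * pmin(lo, hi))
    return(p)
  }
  cc <- (n_treated + n_control) / phi
  a <- cc * prob
  b <- cc * (1 - prob)
  for (i in pos) {
    ni <- n[i]
    k <- seq_len(ni)
    lr <- log((ni - k + 1) / k) + log((k - 1 + a) / (ni - k + b))
    l <- c(0, cumsum(lr))
    l <- l - max(l)
    pr <- exp(l)
    pr <- pr / sum(pr)
    cdf <- cumsum(pr)
    ki <- kt[i]
    lo <- cdf[ki + 1]
    hi <- if (ki == 0) 1 else 1 - cdf[ki]
    p[i] <- min(1, 2 * min(lo, hi))
  }
  p
}

#' Negative-binomial conditional exact-style test
#'
#' Per-feature differential abundance between a treated and a control sample
#' group. The log2 fold change is computed on pseudocounted normalized group
#' sums; the p-value conditions on the feature's total count: at `phi = 0` the
#' treated sum is binomial given the total, and at `phi > 0` it follows the
#' beta-binomial conditional distribution implied by the common-dispersion
#' negative-binomial model. Two-sided p-values double the smaller tail.
#' Features with zero counts in both groups get `lfc = 0`, `p = 1`.
#'
#' With unequal group sizes each group's normalized sum is rescaled by
#' `mean(group sizes) / group size` so the reported LFC carries no group-size
#' offset (a no-op for balanced designs).
#'
#' @inheritParams size_factors
#' @param treated,control Character vectors of sample column names.
#' @param factors Size factors ([size_factors()] output or named vector);
#'   computed from `counts` when `NULL`.
#' @param phi Common dispersion; estimated with [common_dispersion()] over the
#'   treated/control grouping when `NULL`.
#' @param pseudocount Pseudocount added to each normalized group sum for the
#'   LFC (keeps complete-dropout features finite).
#' @return A tibble (`feature_id`, `lfc`, `p`, `q`) with `q` from
#'   [bh_adjust()].
#' @examples
#' counts <- tibble::tibble(feature_id = paste0("f", 1:3),
#'                          t1 = c(0, 30, 10), t2 = c(0, 35, 12),
#'                          c1 = c(50, 30, 11), c2 = c(50, 28, 9))
#' nb_lfc_test(counts, treated = c("t1", "t2"), control = c("c1", "c2"))
#' @export
nb_lfc_test <- function(counts, treated, control,
                        factors = NULL, phi = NULL, pseudocount = 0.5) {
  m <- count_matrix(counts)
  if (!length(treated) || !length(control)) {
    abort("both `treated` and `control` must name at least one sample.")
  }
  missing <- setdiff(c(treated, control), colnames(m))
  if (length(missing)) {
    abort(paste0("sample(s) not in count table: ", paste(missing, collapse = ", ")))
  }
  sub <- m[, c(treated, control), drop = FALSE]
  sub_counts <- dplyr::bind_cols(
    tibble(feature_id = rownames(m)), as_tibble(sub))
  factors <- factors %||% size_factors(sub_counts)
  s <- factor_vector(factors, c(treated, control))
  if (is.null(phi)) {
    grp <- setNames(c(rep("treated", length(treated)), rep("control", length(control))),
                    c(treated, control))
    phi <- common_dispersion(sub_counts, grp, factors = s)
  }
  if (phi < 0) abort("`phi` must be >= 0.")

  st <- s[treated]; sc <- s[control]
  yt <- sweep(m[, treated, drop = FALSE], 2, st, "/")
  yc <- sweep(m[, control, drop = FALSE], 2, sc, "/")
  balance <- mean(c(length(treated), length(control)))
  sum_t <- rowSums(yt) * balance / length(treated)
  sum_c <- rowSums(yc) * balance / length(control)
  lfc <- log2((sum_t + pseudocount) / (sum_c + pseudocount))

  kt <- rowSums(m[, treated, drop = FALSE])
  kc <- rowSums(m[, control, drop = FALSE])
  n <- kt + kc
  prob <- sum(st) / (sum(st) + sum(sc))
  p <- cond_pvalues(kt, n, prob, phi, length(treated), length(control))
  lfc[n == 0] <- 0
  tibble(feature_id = rownames(m), lfc = unname(lfc), p = unname(p),
         q = bh_adjust(unname(p)))
}
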