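# Proteome-response stage: imputation, Welch testing with the dual gate,
# localization rule, envelope fractions and Fisher enrichment.

test_that("impute_missing draws from the left-shifted distribution deterministically", {
  set.seed(19)
  complete <- dplyr::bind_cols(
    tibble::tibble(protein_id = sprintf("p%03d", 1:200)),
    tibble::as_tibble(matrix(rnorm(200 * 3, 25, 2), ncol = 3,
                             dimnames = list(NULL, c("s1", "s2", "s3")))))
  expect_equal(impute_missing(complete, seed = 1), complete)

  holey <- complete
  miss_idx <- sample(200, 80)
  holey$s1[miss_idx] <- NA
  imp1 <- impute_missing(holey, seed = 7)
  imp2 <- impute_missing(holey, seed = 7)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1$s1))
  # untouched entries and samples preserved
  expect_equal(imp1$s1[-miss_idx], holey$s1[-miss_idx])
  expect_equal(imp1$s2, holey$s2)
  # imputed values sit in the low tail: below the observed 25th percentile
  expect_lt(mean(imp1$s1[miss_idx]), quantile(holey$s1, 0.25, na.rm = TRUE))

  few <- tibble::tibble(protein_id = sprintf("p%d", 1:5),
                        s1 = c(1, 2, NA, 4, 5))
  expect_error(impute_missing(few), "fewer than")
})

test_that("protein_diff applies the Welch test and the dual significance gate", {
  ids <- sprintf("p%03d", 1:3)
  x <- tibble::tibble(protein_id = ids,
                      t1 = c(10, 13.0, 10.5), t2 = c(10, 13.1, 10.4),
                      t3 = c(10, 12.9, 10.6),
                      c1 = c(10, 10.0, 10.0), c2 = c(10, 10.1, 9.9),
                      c3 = c(10, 9.9, 10.1))
  st <- protein_diff(x, paste0("t", 1:3), paste0("c", 1:3))
  # identical groups: lfc 0, not significant (zero variance, equal means)
  expect_equal(st$lfc[1], 0)
  expect_equal(st$p[1], 1)
  expect_false(st$significant[1])
  # planted 3-log2 shift at sd ~0.1: significant
  expect_true(st$significant[2])
  # small shift: tiny q but |lfc| <= 1 fails the effect-size gate
  expect_lt(st$q[3], 0.05)
  expect_false(st$significant[3])

  # Welch p matches stats::t.test
  ref <- t.test(unlist(x[2, 2:4]), unlist(x[2, 5:7]))
  expect_equal(st$p[2], ref$p.value, tolerance = 1e-12)
})

test_that("protein_diff null data yield an (almost) empty significant set", {
  set.seed(20)
  n <- 2000
  x <- dplyr::bind_cols(
    tibble::tibble(protein_id = sprintf("p%04d", 1:n)),
    tibble::as_tibble(matrix(rnorm(n * 6, 25, 0.4), ncol = 6,
                             dimnames = list(NULL, c(paste0("t", 1:3),
                                                     paste0("c", 1:3))))))
  st <- protein_diff(x, paste0("t", 1:3), paste0("c", 1:3))
  expect_lte(sum(st$significant), 2)
})

test_that("protein_diff recovers planted shifts at realistic noise", {
  planted <- tibble::tibble(protein_id = sprintf("p%05d", 1:15), lfc = 3)
  sim <- simulate_proteome(n_proteins = 600, missing_rate = 0.05,
                           planted_lfc = planted, noise_sd = 0.2, seed = 23)
  filled <- impute_missing(sim$intensities, seed = 24)
  st <- protein_diff(filled,
                     sim$design$sample_id[sim$design$treatment == "treated"],
                     sim$design$sample_id[sim$design$treatment == "control"])
  found <- st$protein_id[st$significant]
  expect_gte(mean(planted$protein_id %in% found), 0.9)
  expect_lte(sum(!(found %in% planted$protein_id)), 3)
})

test_that("classify_localization implements the strict-likelihood/TM rule", {
  d <- tibble::tibble(protein_id = c("a", "b", "c", "d"),
                      signal_likelihood = c(0.95, 0.5, 0.90, 0.1),
                      n_tm_segments = c(0, 3, 0, 0))
  lab <- classify_localization(d)$label
  expect_equal(lab, c("envelope", "envelope", "cytoplasmic", "cytoplasmic"))
  expect_error(classify_localization(dplyr::mutate(d, signal_likelihood = 1.2)),
               "0, 1")
  # partition: every protein is exactly one of the two classes
  expect_true(all(lab %in% c("envelope", "cytoplasmic")))
})

test_that("envelope_fraction reproduces the printed percentages", {
  mk_loc <- function(n_env, n_tot) tibble::tibble(
    protein_id = sprintf("p%04d", seq_len(n_tot)),
    label = rep(c("envelope", "cytoplasmic"), c(n_env, n_tot - n_env)))
  expect_equal(envelope_fraction(mk_loc(544, 1852)), 29.37)
  expect_equal(envelope_fraction(mk_loc(466, 1622)), 28.73)
  expect_equal(envelope_fraction(mk_loc(0, 50)), 0)

  loc <- mk_loc(30, 100)
  cyto <- 100 - 30
  expect_equal(envelope_fraction(loc) +
                 round(100 * cyto / 100, 2), 100, tolerance = 0.01)
  expect_error(envelope_fraction(loc, proteins = "nope"), "absent")
  expect_error(envelope_fraction(loc, proteins = character()), "non-empty")
})

test_that("envelope_enrichment matches hypergeometric enumeration", {
  loc <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:20),
    label = rep(c("envelope", "cytoplasmic"), each = 10))
  # perfectly separated 2x2 table [[10,0],[0,10]]
  res <- envelope_enrichment(loc, responsive = sprintf("p%02d", 1:10))
  expect_equal(res$table, matrix(c(10, 0, 0, 10), 2, byrow = TRUE,
                                 dimnames = dimnames(res$table)))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(res$p_value, fisher_enumeration(res$table), tolerance = 1e-10)
  expect_true(res$haldane)

  # equal proportions: no association
  res2 <- envelope_enrichment(loc, responsive = c("p01", "p02", "p11", "p12"))
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p_value, 1)

  # random tables with n <= 30: implementation == enumeration oracle
  set.seed(25)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    labs <- sample(c("envelope", "cytoplasmic"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    loc_i <- tibble::tibble(protein_id = sprintf("q%02d", 1:n), label = labs)
    resp <- sample(loc_i$protein_id, sample(1:(n - 1), 1))
    res_i <- envelope_enrichment(loc_i, responsive = resp)
    if (any(rowSums(res_i$table) == 0) || any(colSums(res_i$table) == 0)) {
      expect_equal(res_i$p_value, 1)
    } else {
      expect_equal(res_i$p_value, fisher_enumeration(res_i$table),
                   tolerance = 1e-9)
    }
  }
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  loc <- tibble::tibble(protein_id = sprintf("p%02d", 1:24),
                        label = rep(c("envelope", "cytoplasmic"), c(9, 15)))
  resp <- c(sprintf("p%02d", 1:6), sprintf("p%02d", 10:12))
  res <- envelope_enrichment(loc, responsive = resp)
  swapped <- res$table[2:1, 2:1]
  expect_equal(fisher.test(swapped)$p.value, res$p_value, tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(td$p.value, res$p_value)
})
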