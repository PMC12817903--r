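# Synthetic data generator: planted truth, count simulation, determinism and
# the negative-binomial mean-variance contract.

test_that("generate_truth plants exact class counts and validates fractions", {
  design <- screen_design(n_genes = 1000, conditions = "cond_a")
  truth <- generate_truth(design, essential_frac = 0.1, beneficial_frac = 0.02,
                          detrimental_frac = 0.03, fp_frac = 0, seed = 3)
  expect_equal(sum(truth$effect_class == "beneficial"), 20)
  expect_equal(sum(truth$effect_class == "detrimental"), 30)
  expect_equal(length(unique(truth$gene_id[truth$essential])), 100)

  # degenerate case: everything neutral, nothing essential
  none <- generate_truth(design, essential_frac = 0, beneficial_frac = 0,
                         detrimental_frac = 0, fp_frac = 0, seed = 1)
  expect_true(all(none$effect_class == "neutral"))
  expect_true(all(none$effect == 0))
  expect_false(any(none$essential))

  expect_error(generate_truth(design, beneficial_frac = 1.2), "fractions")
  expect_error(generate_truth(design, beneficial_frac = 0.6, detrimental_frac = 0.6),
               "at most 1")
})

test_that("truth table satisfies its class/sign/shared invariants", {
  design <- screen_design(n_genes = 300)
  truth <- generate_truth(design, fp_frac = 0.04, seed = 5)
  expect_equal(nrow(truth), 300 * length(design$conditions))
  expect_true(all((truth$effect == 0) == (truth$effect_class == "neutral")))
  expect_true(all(sign(truth$effect[truth$effect_class == "beneficial"]) == 1))
  expect_true(all(sign(truth$effect[truth$effect_class == "detrimental"]) == -1))
  # essential genes never carry chemical effects; false positives are tagged
  expect_true(all(truth$effect[truth$essential] == 0))
  expect_true(all(is.na(truth$fp_library) == truth$shared_in_both_libraries))
  expect_true(all(truth$fp_library[!truth$shared_in_both_libraries] %in% c("tn", "crispri")))
})

test_that("simulators are deterministic in the seed and differ across seeds", {
  design <- screen_design(n_genes = 40, n_nontargeting = 40,
                          reads_per_sample = 1e5, conditions = "c1")
  truth <- generate_truth(design, seed = 9)
  expect_identical(generate_truth(design, seed = 9), truth)
  expect_false(identical(generate_truth(design, seed = 10), truth))

  tn1 <- simulate_tn_counts(truth, design, seed = 2)
  tn2 <- simulate_tn_counts(truth, design, seed = 2)
  expect_identical(tn1, tn2)
  ci1 <- simulate_crispri_counts(truth, design, seed = 2)
  ci2 <- simulate_crispri_counts(truth, design, seed = 2)
  expect_identical(ci1, ci2)
  expect_false(identical(simulate_tn_counts(truth, design, seed = 3)$counts,
                         tn1$counts))
})

test_that("essential genes get no insertion sites in their clipped bodies", {
  scr <- small_screen(seed = 21)
  ess <- unique(scr$truth$gene_id[scr$truth$essential])
  gene_counts <- tn_gene_aggregate(scr$tn$counts, scr$tn$sites, scr$tn$genes,
                                   clip_frac = 0.05)
  n_sites <- attr(gene_counts, "n_sites")
  expect_true(all(n_sites[ess] == 0))
  expect_true(all(n_sites[setdiff(names(n_sites), ess)] > 0))
})

test_that("zero sequencing depth yields an all-zero count table", {
  design <- screen_design(n_genes = 20, reads_per_sample = 0,
                          n_nontargeting = 10, conditions = "c1")
  truth <- generate_truth(design, seed = 1)
  tn <- simulate_tn_counts(truth, design, seed = 1)
  expect_true(all(as.matrix(tn$counts[-1]) == 0))
  ci <- simulate_crispri_counts(truth, design, seed = 1)
  expect_true(all(as.matrix(ci$counts[-1]) == 0))
})

test_that("with no effects and phi = 0 per-gene treated/control ratios are near 1", {
  design <- screen_design(n_genes = 100, nb_dispersion = 0, abundance_sd = 0,
                          reads_per_sample = 5e5, conditions = "c1")
  truth <- generate_truth(design, essential_frac = 0, beneficial_frac = 0,
                          detrimental_frac = 0, fp_frac = 0, seed = 4)
  tn <- simulate_tn_counts(truth, design, seed = 4)
  gc <- tn_gene_aggregate(tn$counts, tn$sites, tn$genes)
  m <- as.matrix(gc[-1])
  trt <- tn$samples$sample_id[tn$samples$role == "treated"]
  ctl <- tn$samples$sample_id[tn$samples$role == "control"]
  ratio <- rowSums(m[, trt, drop = FALSE]) / rowSums(m[, ctl, drop = FALSE])
  # thousands of Poisson reads per gene: ratios concentrate tightly around 1
  expect_lt(max(abs(ratio - 1)), 0.15)
  expect_lt(abs(mean(ratio) - 1), 0.02)
})

test_that("CRISPRi guide classes behave by construction", {
  scr <- small_screen(seed = 31)
  guides <- scr$ci$guides
  expect_true(all(is.na(guides$gene_id[guides$class == "nontargeting"])))
  expect_true(all(!is.na(guides$gene_id[guides$class != "nontargeting"])))
  expect_true(all(guides$relative_activity[guides$class == "perfect"] == 1))

  # strong depletion of essential-gene perfect guides after induction
  counts <- scr$ci$counts
  t0 <- scr$ci$samples$sample_id[scr$ci$samples$role == "T0_uninduced"]
  t2 <- scr$ci$samples$sample_id[scr$ci$samples$role == "T2_induced"]
  ess <- unique(scr$truth$gene_id[scr$truth$essential])
  pg <- guides$spacer_id[guides$class == "perfect" & guides$gene_id %in% ess]
  m <- as.matrix(counts[-1]); rownames(m) <- counts$feature_id
  lfc <- log2((rowSums(m[pg, t2, drop = FALSE]) + 0.5) /
              (rowSums(m[pg, t0, drop = FALSE]) + 0.5))
  expect_lt(median(lfc), -5)
  # non-targeting guides are untouched by induction
  nt <- guides$spacer_id[guides$class == "nontargeting"]
  lfc_nt <- log2((rowSums(m[nt, t2, drop = FALSE]) + 0.5) /
                 (rowSums(m[nt, t0, drop = FALSE]) + 0.5))
  expect_lt(abs(median(lfc_nt)), 0.2)
})

test_that("sub-library read mass follows the 8:1:6 mix", {
  scr <- small_screen(seed = 41)
  m <- as.matrix(scr$ci$counts[-1])
  cls <- scr$ci$guides$class
  mass <- tapply(rowSums(m), cls, sum)
  frac <- mass / sum(mass)
  expect_equal(as.numeric(frac[c("perfect", "nontargeting", "mismatch")]),
               c(8, 1, 6) / 15, tolerance = 0.05)
})

test_that("counts obey the negative-binomial mean-variance relation", {
  # phi = 0: variance/mean -> 1; phi = 0.2: moment estimator recovers phi
  design0 <- screen_design(n_genes = 100, nb_dispersion = 0, abundance_sd = 0,
                           reads_per_sample = 2e5, conditions = "c1",
                           n_replicates = 8)
  truth0 <- generate_truth(design0, essential_frac = 0, beneficial_frac = 0,
                           detrimental_frac = 0, fp_frac = 0, seed = 6)
  tn0 <- simulate_tn_counts(truth0, design0, seed = 6)
  m0 <- as.matrix(tn0$counts[-1])
  ctl <- tn0$samples$sample_id[tn0$samples$role == "control"]
  y <- m0[, ctl]
  vm <- apply(y, 1, var) / rowMeans(y)
  expect_equal(mean(vm), 1, tolerance = 0.05)

  design2 <- screen_design(n_genes = 500, nb_dispersion = 0.2, abundance_sd = 0,
                           reads_per_sample = 5e6, conditions = "c1",
                           n_replicates = 6, n_nontargeting = 0,
                           mismatch_series = NULL, guides_per_gene = 10)
  truth2 <- generate_truth(design2, essential_frac = 0, beneficial_frac = 0,
                           detrimental_frac = 0, fp_frac = 0, seed = 7)
  ci2 <- simulate_crispri_counts(truth2, design2, seed = 7)
  grp <- setNames(ci2$samples$role, ci2$samples$sample_id)
  phi_hat <- common_dispersion(ci2$counts, grp)
  expect_equal(phi_hat, 0.2, tolerance = 0.2)
})

test_that("proteome simulator censors on the left and respects planted shifts", {
  sim0 <- simulate_proteome(n_proteins = 200, missing_rate = 0, seed = 2)
  expect_false(anyNA(as.matrix(sim0$intensities[-1])))

  planted <- tibble::tibble(protein_id = sprintf("p%05d", 1:10), lfc = 3)
  sim <- simulate_proteome(n_proteins = 2000, missing_rate = 0.15,
                           planted_lfc = planted, seed = 2)
  m <- as.matrix(sim$intensities[-1])
  expect_equal(mean(is.na(m)), 0.15, tolerance = 0.03)
  # left-censoring: the observed mean of rows with missing values is lower
  has_na <- rowSums(is.na(m)) > 0
  expect_lt(mean(m[has_na, ], na.rm = TRUE), mean(m[!has_na, ]))
  expect_identical(sim, simulate_proteome(n_proteins = 2000, missing_rate = 0.15,
                                          planted_lfc = planted, seed = 2))
  expect_error(simulate_proteome(n_proteins = 10, missing_rate = 1), "missing_rate")
})
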