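# Cross-library validation: quantile normalization, ROC/AUC, cutoff sweeps,
# hit calling, concordance and Ward clustering.

test_that("quantile_normalize matches the order-statistic mean by hand", {
  x <- tibble::tibble(gene = c("a", "b", "c"), tn = c(1, 2, 3), ci = c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(qn$tn, c(2.5, 3.5, 4.5))
  expect_equal(qn$ci, c(2.5, 3.5, 4.5))

  same <- tibble::tibble(gene = c("a", "b"), tn = c(7, 1), ci = c(7, 1))
  expect_equal(quantile_normalize(same), same)

  expect_error(quantile_normalize(tibble::tibble(g = "a", x = 1)), "two")
  expect_error(quantile_normalize(tibble::tibble(g = c("a", "b"),
                                                 x = c(1, NA), y = c(2, 3))),
               "missing")
})

test_that("quantile_normalize equalizes all column quantiles", {
  set.seed(12)
  x <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                      tn = rnorm(200, 0, 2), ci = rt(200, df = 3) + 1)
  qn <- quantile_normalize(x)
  expect_equal(sort(qn$tn), sort(qn$ci))
  expect_equal(mean(qn$tn), mean(qn$ci))
  expect_equal(quantile(qn$tn, c(0.1, 0.5, 0.9)),
               quantile(qn$ci, c(0.1, 0.5, 0.9)))
})

test_that("roc_auc equals brute-force pairwise enumeration", {
  expect_equal(roc_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_true(is.na(roc_auc(1:4, rep(TRUE, 4))))

  set.seed(14)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    scores <- sample(c(rnorm(n), round(rnorm(n), 0)), n)  # allow ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    expect_equal(roc_auc(scores, labels), auc_brute_force(scores, labels))
  }
})

test_that("roc_auc agrees with pROC and negation flips it", {
  set.seed(15)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (sum(labels) > 0 && sum(!labels) > 0) {
    expect_equal(roc_auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))))
    expect_equal(roc_auc(-scores, labels), 1 - roc_auc(scores, labels))
  }
})

test_that("cutoff_sweep reproduces the 4-gene worked case and its gates", {
  d <- tibble::tibble(truth_score = c(6, 5, 1, 0), truth_fdr = 0.01,
                      classifier_score = c(5, 2, 3, 0))
  sw <- cutoff_sweep(d, direction = "beneficial", cutoffs = 4)
  expect_equal(sw$n_hits, 2L)   # positives: scores 6 and 5
  expect_equal(sw$auc, 0.75)    # pairs won 3 of 4

  # classifier identical to truth: perfect AUC wherever defined
  d2 <- tibble::tibble(truth_score = c(6, 5, 1, 0), truth_fdr = 0.01,
                       classifier_score = c(6, 5, 1, 0))
  sw2 <- cutoff_sweep(d2, direction = "beneficial", cutoffs = c(2, 4))
  expect_equal(sw2$auc, c(1, 1))

  # FDR gate removes would-be positives
  d3 <- dplyr::mutate(d, truth_fdr = c(0.01, 0.2, 0.01, 0.01))
  sw3 <- cutoff_sweep(d3, direction = "beneficial", cutoffs = 4)
  expect_equal(sw3$n_hits, 1L)

  expect_error(cutoff_sweep(d, cutoffs = numeric()), "non-empty")
})

test_that("cutoff_sweep n_hits is monotone non-increasing in the cutoff", {
  set.seed(16)
  d <- tibble::tibble(truth_score = rnorm(300, 0, 3),
                      truth_fdr = runif(300),
                      classifier_score = rnorm(300, 0, 3))
  for (dir in c("beneficial", "detrimental")) {
    sw <- cutoff_sweep(d, direction = dir, cutoffs = seq(0, 8, 0.25))
    expect_true(all(diff(sw$n_hits) <= 0))
    expect_true(all(sw$auc[sw$auc_defined] >= 0 & sw$auc[sw$auc_defined] <= 1))
    expect_true(all(is.na(sw$auc[!sw$auc_defined])))
  }
})

test_that("call_hits applies inclusive dual gates and sign agreement", {
  mk <- function(score, fdr, lib) {
    tibble::tibble(gene_id = sprintf("g%d", seq_along(score)), condition = "c1",
                   library = lib, cg_score = score, gene_fdr = fdr)
  }
  tn <- mk(c(5.0, 4.0, 5.0, 4.5, -4.5), c(0.01, 0.05, 0.2, 0.01, 0.01), "Tn")
  ci <- mk(c(4.2, 1.0, 4.2, -4.2, -4.2), c(0.02, 0.5, 0.02, 0.01, 0.01), "CRISPRi")
  hits <- call_hits(tn, ci)
  expect_equal(hits$category[hits$gene_id == "g1"], "both")
  expect_equal(hits$category[hits$gene_id == "g2"], "tn_only")   # boundary 4.0/0.05 passes
  expect_equal(hits$category[hits$gene_id == "g3"], "crispri_only")  # tn fails FDR gate
  expect_equal(hits$category[hits$gene_id == "g4"], "discordant")
  expect_equal(hits$category[hits$gene_id == "g5"], "both")      # concordant negative

  # without the sign requirement g4 becomes both
  hits2 <- call_hits(tn, ci, require_same_sign = FALSE)
  expect_equal(hits2$category[hits2$gene_id == "g4"], "both")

  # a gene missing in one library is flagged and judged on the other
  hits3 <- call_hits(mk(5, 0.01, "Tn"),
                     mk(c(5, 4.4), c(0.01, 0.01), "CRISPRi")[2, ])
  expect_false(any(hits3$in_both_libraries))
})

test_that("hit sets nest across cutoffs", {
  scr_seed <- 81
  set.seed(scr_seed)
  n <- 400
  true_eff <- c(runif(20, 4, 6), -runif(20, 4, 6), rep(0, n - 40))
  mk_lib <- function(noise) {
    tibble::tibble(gene_id = sprintf("g%03d", 1:n), condition = "c1",
                   library = "x",
                   cg_score = true_eff + rnorm(n, 0, noise),
                   gene_fdr = ifelse(true_eff != 0, 0.001, runif(n)))
  }
  tn <- mk_lib(0.4); ci <- mk_lib(0.5)
  h4 <- call_hits(tn, ci, cutoff = 4)
  h3 <- call_hits(tn, ci, cutoff = 3)
  sig4 <- h4$gene_id[h4$category != "none"]
  sig3 <- h3$gene_id[h3$category != "none"]
  expect_true(all(sig4 %in% sig3))
  both4 <- h4$gene_id[h4$category == "both"]
  both3 <- h3$gene_id[h3$category == "both"]
  expect_true(all(both4 %in% both3))
})

test_that("concordance_summary partitions the union of significant genes", {
  expect_equal(concordance_summary(call_hits(
    tibble::tibble(gene_id = character(), condition = character(),
                   library = character(), cg_score = numeric(),
                   gene_fdr = numeric()),
    tibble::tibble(gene_id = character(), condition = character(),
                   library = character(), cg_score = numeric(),
                   gene_fdr = numeric())))$union, 0L)

  set.seed(17)
  n <- 300
  mk <- function() tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:n), 2),
    condition = rep(c("c1", "c2"), each = n),
    library = "x",
    cg_score = sample(c(0, 4.5, -4.5), 2 * n, replace = TRUE,
                      prob = c(0.8, 0.1, 0.1)),
    gene_fdr = sample(c(0.01, 0.5), 2 * n, replace = TRUE))
  hits <- call_hits(mk(), mk())
  cs <- concordance_summary(hits)
  expect_equal(cs$union,
               cs$both + cs$tn_only + cs$crispri_only + cs$discordant + cs$mixed)
  expect_equal(cs$union,
               length(unique(hits$gene_id[hits$tn_significant |
                                            hits$crispri_significant])))
})

test_that("ward_linkage agrees with exhaustive minimum-variance agglomeration", {
  dup <- tibble::tibble(id = c("a", "b", "c"),
                        x = c(0, 0, 10), y = c(0, 0, 10))
  hc <- ward_linkage(dup)
  expect_equal(hc$height[1], 0)              # duplicate pair merges first
  expect_setequal(hclust_merge_sets(hc)[[1]], c(1, 2))

  set.seed(18)
  for (i in 1:8) {
    n <- sample(3:6, 1)
    m <- matrix(rnorm(n * 3), nrow = n)
    scores <- dplyr::bind_cols(tibble::tibble(id = sprintf("r%d", 1:n)),
                               tibble::as_tibble(m, .name_repair = "minimal"))
    hc <- ward_linkage(scores)
    oracle <- ward_brute_force(m)
    expect_equal(hclust_merge_sets(hc), oracle$merges)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    expect_true(all(diff(hc$height) >= -1e-12))
  }

  expect_error(ward_linkage(dup[1, ]), "two rows")
  expect_error(ward_linkage(tibble::tibble(id = c("a", "b"), x = c(1, NA))),
               "missing")
})

test_that("dendro_newick serializes a labelled tree", {
  scores <- tibble::tibble(id = c("a", "b", "c"),
                           x = c(0, 0.1, 5), y = c(0, 0.1, 5))
  nwk <- dendro_newick(ward_linkage(scores))
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(sapply(c("a", "b", "c"), grepl, nwk)))
})
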