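# Independent brute-force oracles used to verify the fast implementations.

# AUC by exhaustive pairwise comparison of positives against negatives.
auc_brute_force <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- outer(pos, neg, ">")
  ties <- outer(pos, neg, "==")
  mean(wins + 0.5 * ties)
}

# Two-sided Fisher exact p by enumerating the conditional hypergeometric
# distribution of the top-left cell given the margins.
fisher_enumeration <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(ks, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exhaustive greedy Ward agglomeration: at each step merge the pair of
# clusters with the smallest increase in total within-cluster sum of squares.
# Returns the sequence of merged member sets and heights sqrt(2 * delta-ESS).
ward_brute_force <- function(m) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    x <- m[rows, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, sqrt(2 * best_d))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Member sets produced at each merge of an hclust tree.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  members <- function(i) if (i < 0) -i else sets[[i]]
  for (k in seq_len(nrow(hc$merge))) {
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# Small deterministic screen used by several unit tests (fast: ~1 s).
small_screen <- function(seed = 101, n_genes = 150, conditions = "ferulic_acid") {
  design <- screen_design(
    n_genes = n_genes, n_nontargeting = 150,
    reads_per_sample = n_genes * 1000 * 0.01 * 500,
    conditions = conditions)
  truth <- generate_truth(design, seed = seed)
  list(design = design, truth = truth,
       tn = simulate_tn_counts(truth, design, seed = seed + 1),
       ci = simulate_crispri_counts(truth, design, seed = seed + 2))
}

as_counts <- function(m, prefix = "f") {
  dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("%s%04d", prefix, seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = "minimal"))
}
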