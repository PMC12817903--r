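# Synthetic paired-screen generator: paired Tn and CRISPRi count tables plus a
# proteome intensity table, all with planted ground truth, so that every
# downstream stage of the pipeline has a known answer to be tested against.

#' Describe a paired Tn/CRISPRi screen design
#'
#' Collects every knob of the synthetic screen in one validated object: gene
#' layout, transposon insertion-site density, guide complement (perfect-match,
#' graded mismatch series, non-targeting), sub-library read weights, sequencing
#' depth, negative-binomial overdispersion and replication.
#'
#' Genes are laid out non-overlapping with uniform length on a single circular
#' replicon; the genome length is `n_genes * (gene_length + gene_gap)`.
#' Sub-library read weights follow the 8:1:6 perfect : non-targeting : mismatch
#' mixing ratio used when pooling such libraries.
#'
#' @param n_genes Number of genes.
#' @param gene_length,gene_gap Gene body length and intergenic gap (bp).
#' @param tn_site_density Expected transposon insertion sites per bp.
#' @param guides_per_gene Perfect-match spacers designed per gene.
#' @param mismatch_series Data frame with columns `relative_activity` (in
#'   \[0, 1\], knockdown activity relative to a perfect-match spacer) and
#'   `count` (spacers per gene at that activity).
#' @param n_nontargeting Number of non-targeting control spacers.
#' @param sublibrary_mix Positive read-abundance weights for the perfect,
#'   non-targeting and mismatch spacer classes (total reads split in these
#'   proportions between the classes).
#' @param reads_per_sample Expected total read count per sample.
#' @param nb_dispersion Negative-binomial overdispersion phi >= 0
#'   (variance = m + phi * m^2).
#' @param n_replicates Replicates per sample role.
#' @param conditions Character vector of chemical condition labels.
#' @param abundance_sd Log-normal sd of per-feature baseline abundance.
#' @param library_effect_sd Sd (log2 units) of the library-specific
#'   perturbation added to each planted nonzero effect: a knockout and a
#'   knockdown of the same gene rarely show exactly the same effect size, so
#'   each library realizes the shared effect with independent Gaussian noise.
#' @return A `screen_design` list.
#' @examples
#' design <- screen_design(n_genes = 50, reads_per_sample = 1e5)
#' design$genome_length
#' @export
screen_design <- function(n_genes = 1000,
                          gene_length = 900,
                          gene_gap = 100,
                          tn_site_density = 0.01,
                          guides_per_gene = 3,
                          mismatch_series = tibble(
                            relative_activity = c(0.125, 0.25, 0.5),
                            count = c(2L, 2L, 2L)),
                          n_nontargeting = 1000,
                          sublibrary_mix = c(perfect = 8, nontargeting = 1, mismatch = 6),
                          reads_per_sample = 5e6,
                          nb_dispersion = 0.05,
                          n_replicates = 2,
                          conditions = c("ferulic_acid", "p_coumaric_acid"),
                          abundance_sd = 0.3,
                          library_effect_sd = 0.25) {
  stopifnot(is.data.frame(mismatch_series) || is.null(mismatch_series))
  if (is.null(mismatch_series)) {
    mismatch_series <- tibble(relative_activity = numeric(), count = integer())
  }
  if (n_genes < 1 || gene_length < 1 || gene_gap < 0) {
    abort("gene layout parameters must be positive.")
  }
  if (tn_site_density < 0 || reads_per_sample < 0 || n_nontargeting < 0 ||
      guides_per_gene < 1 || n_replicates < 1) {
    abort("design counts must be non-negative (guides_per_gene, n_replicates >= 1).")
  }
  if (nb_dispersion < 0) abort("`nb_dispersion` (phi) must be >= 0.")
  if (length(sublibrary_mix) != 3 || any(sublibrary_mix <= 0)) {
    abort("`sublibrary_mix` must be three positive weights (perfect, nontargeting, mismatch).")
  }
  if (nrow(mismatch_series) &&
      (any(mismatch_series$relative_activity < 0) ||
       any(mismatch_series$relative_activity > 1))) {
    abort("mismatch `relative_activity` must lie in [0, 1].")
  }
  if (nrow(mismatch_series) && any(mismatch_series$count < 0)) {
    abort("mismatch `count` must be >= 0.")
  }
  if (length(conditions) < 1) abort("at least one condition is required.")
  names(sublibrary_mix) <- c("perfect", "nontargeting", "mismatch")
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    gene_gap = as.integer(gene_gap),
    genome_length = as.integer(n_genes) * (as.integer(gene_length) + as.integer(gene_gap)),
    tn_site_density = tn_site_density,
    guides_per_gene = as.integer(guides_per_gene),
    mismatch_series = as_tibble(mismatch_series),
    n_nontargeting = as.integer(n_nontargeting),
    sublibrary_mix = sublibrary_mix,
    reads_per_sample = reads_per_sample,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    conditions = as.character(conditions),
    abundance_sd = abundance_sd,
    library_effect_sd = library_effect_sd
  ), class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n")
  cat(sprintf("  %d genes on a %s bp circular replicon\n",
              x$n_genes, format(x$genome_length, big.mark = ",")))
  cat(sprintf("  Tn site density %.4g /bp; %d perfect guides/gene; %d mismatch guides/gene; %d non-targeting\n",
              x$tn_site_density, x$guides_per_gene,
              sum(x$mismatch_series$count), x$n_nontargeting))
  cat(sprintf("  %s reads/sample, phi = %.3g, %d replicates, conditions: %s\n",
              format(x$reads_per_sample, big.mark = ","), x$nb_dispersion,
              x$n_replicates, paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Plant ground truth for a synthetic screen
#'
#' Assigns essential genes and, per condition, conditionally beneficial and
#' detrimental chemical-gene effects. A configurable fraction of otherwise
#' neutral genes receives a library-specific false-positive effect (planted in
#' exactly one of the two libraries) to exercise the cross-validation stage.
#' Essential genes are never assigned chemical effects; their induction
#' depletion is drawn around -6 log2 units so that a -5.1 call threshold is
#' exceeded with margin.
#'
#' @param design A [screen_design()].
#' @param essential_frac,beneficial_frac,detrimental_frac Fractions of genes
#'   that are essential / carry a positive / negative chemical effect per
#'   condition. Class counts are `round(frac * n_genes)` exactly.
#' @param fp_frac Fraction of genes given a single-library false-positive
#'   effect per condition (split evenly between the libraries).
#' @param effect_range Magnitude range (log2) for planted effects.
#' @param essential_lfc_mean,essential_lfc_sd Distribution of the induction
#'   depletion LFC for essential genes.
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @return A `truth_table` tibble with one row per gene x condition:
#'   `gene_id`, `essential`, `essential_lfc`, `condition`, `effect`,
#'   `effect_class`, `shared_in_both_libraries`, `fp_library`.
#' @examples
#' truth <- generate_truth(screen_design(n_genes = 100), seed = 1)
#' dplyr::count(truth, effect_class)
#' @export
generate_truth <- function(design,
                           essential_frac = 0.10,
                           beneficial_frac = 0.02,
                           detrimental_frac = 0.02,
                           fp_frac = 0.02,
                           effect_range = c(4, 6),
                           essential_lfc_mean = -6,
                           essential_lfc_sd = 0.3,
                           seed = NULL) {
  stopifnot(inherits(design, "screen_design"))
  fr <- c(essential_frac, beneficial_frac, detrimental_frac, fp_frac)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    abort("fractions must lie in [0, 1].")
  }
  if (beneficial_frac + detrimental_frac + fp_frac > 1) {
    abort("non-neutral fractions must sum to at most 1.")
  }
  n <- design$n_genes
  n_ess <- round(essential_frac * n)
  n_ben <- round(beneficial_frac * n)
  n_det <- round(detrimental_frac * n)
  n_fp <- round(fp_frac * n)
  if (n_ben + n_det + n_fp > n - n_ess) {
    abort("not enough non-essential genes for the requested effect fractions.")
  }
  gene_ids <- sprintf("g%05d", seq_len(n))

  with_seed(seed, {
    essential_ids <- sort(sample(gene_ids, n_ess))
    ess_lfc <- setNames(rep(NA_real_, n), gene_ids)
    ess_lfc[essential_ids] <- rnorm(n_ess, essential_lfc_mean, essential_lfc_sd)
    nonessential <- setdiff(gene_ids, essential_ids)

    per_condition <- purrr::map(design$conditions, function(cond) {
      chosen <- sample(nonessential, n_ben + n_det + n_fp)
      ben <- chosen[seq_len(n_ben)]
      det <- chosen[n_ben + seq_len(n_det)]
      fp <- chosen[n_ben + n_det + seq_len(n_fp)]
      fp_lib <- rep(c("tn", "crispri"), length.out = length(fp))
      mag <- function(k) runif(k, effect_range[1], effect_range[2])
      tibble(
        gene_id = gene_ids,
        condition = cond,
        effect = 0,
        effect_class = "neutral",
        shared_in_both_libraries = TRUE,
        fp_library = NA_character_
      ) %>%
        dplyr::rows_update(
          tibble(gene_id = ben, effect = mag(n_ben),
                 effect_class = "beneficial"),
          by = "gene_id", unmatched = "ignore") %>%
        dplyr::rows_update(
          tibble(gene_id = det, effect = -mag(n_det),
                 effect_class = "detrimental"),
          by = "gene_id", unmatched = "ignore") %>%
        dplyr::rows_update(
          tibble(gene_id = fp,
                 effect = mag(length(fp)) * sample(c(-1, 1), length(fp), replace = TRUE),
                 shared_in_both_libraries = FALSE,
                 fp_library = fp_lib),
          by = "gene_id", unmatched = "ignore") %>%
        dplyr::mutate(effect_class = dplyr::if_else(
          .data$effect == 0, "neutral",
          dplyr::if_else(.data$effect > 0, "beneficial", "detrimental")))
    })

    out <- dplyr::bind_rows(per_condition) %>%
      dplyr::mutate(
        essential = .data$gene_id %in% essential_ids,
        essential_lfc = unname(ess_lfc[.data$gene_id]),
        .after = "gene_id") %>%
      dplyr::arrange(.data$condition, .data$gene_id)
    class(out) <- c("truth_table", class(out))
    out
  })
}

# Gene model implied by a screen design: uniform non-overlapping genes on one
# circular replicon, 1-based inclusive coordinates.
design_gene_model <- function(design) {
  n <- design$n_genes
  pitch <- design$gene_length + design$gene_gap
  tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    replicon = "chr1",
    start = (seq_len(n) - 1L) * pitch + 1L,
    end = (seq_len(n) - 1L) * pitch + design$gene_length,
    strand = "+"
  )
}

# Draw counts with mean `mu` and variance mu + phi mu^2.
draw_counts <- function(mu, phi) {
  n <- length(mu)
  if (phi == 0) return(rpois(n, lambda = mu))
  rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate transposon insertion-site counts
#'
#' Places unique insertion sites uniformly along the replicon, removes sites
#' falling inside the clipped body of planted essential genes (an essential
#' disruption yields no viable mutant), assigns each site a log-normal baseline
#' abundance, and draws negative-binomial counts for untreated control samples
#' and chemical-treated samples. The expected count of a site inside gene *g*
#' in a treated sample is its control expectation times `2^effect(g)` for
#' effects planted in the Tn library.
#'
#' @param truth A [generate_truth()] table.
#' @param design The matching [screen_design()].
#' @param clip_frac Fraction of each gene body clipped from both ends when
#'   deciding which sites an essential gene excludes (matches the clipping used
#'   downstream during aggregation and essentiality calling).
#' @param seed Optional integer seed.
#' @return A list with `counts` (site x sample tibble), `sites`
#'   (site_id, replicon, pos), `genes` (gene model) and `samples`
#'   (sample sheet: sample_id, condition, replicate, role).
#' @export
simulate_tn_counts <- function(truth, design, clip_frac = 0.05, seed = NULL) {
  stopifnot(inherits(design, "screen_design"))
  if (design$genome_length < design$n_genes * design$gene_length) {
    abort("genome too short for the requested gene layout.")
  }
  genes <- design_gene_model(design)
  ess <- truth %>%
    dplyr::distinct(.data$gene_id, .data$essential) %>%
    dplyr::filter(.data$essential)

  with_seed(seed, {
    n_sites <- round(design$genome_length * design$tn_site_density)
    pos <- sort(sample.int(design$genome_length, n_sites))
    sites <- tibble(
      site_id = sprintf("site_%08d", pos),
      replicon = "chr1",
      pos = pos)

    # drop sites inside clipped bodies of essential genes
    ess_genes <- genes %>% dplyr::semi_join(ess, by = "gene_id")
    if (nrow(ess_genes)) {
      hits <- assign_sites_to_genes(sites, ess_genes, clip_frac)
      sites <- sites %>% dplyr::anti_join(hits, by = "site_id")
    }

    # per-condition planted effect of the gene each site sits in (full body);
    # the shared effect is realized with library-specific noise
    site_gene <- assign_sites_to_genes(sites, genes, clip_frac = 0)
    tn_truth <- truth %>%
      dplyr::filter(is.na(.data$fp_library) | .data$fp_library == "tn") %>%
      dplyr::mutate(effect = .data$effect + dplyr::if_else(
        .data$effect != 0,
        rnorm(dplyr::n(), 0, design$library_effect_sd), 0))
    site_effects <- site_gene %>%
      dplyr::inner_join(tn_truth, by = "gene_id",
                        relationship = "many-to-many") %>%
      dplyr::select("site_id", "condition", "effect")

    w <- stats::rlnorm(nrow(sites), 0, design$abundance_sd)
    mu0 <- design$reads_per_sample * w / sum(w)
    names(mu0) <- sites$site_id

    samples <- dplyr::bind_rows(
      tibble(sample_id = sprintf("tn_control_%d", seq_len(design$n_replicates)),
             condition = "none", replicate = seq_len(design$n_replicates),
             role = "control"),
      purrr::map_dfr(design$conditions, function(cond) {
        tibble(sample_id = sprintf("tn_%s_%d", cond, seq_len(design$n_replicates)),
               condition = cond, replicate = seq_len(design$n_replicates),
               role = "treated")
      }))

    counts <- tibble(feature_id = sites$site_id)
    for (i in seq_len(nrow(samples))) {
      mu <- mu0
      if (samples$role[i] == "treated") {
        eff <- site_effects %>% dplyr::filter(.data$condition == samples$condition[i])
        if (nrow(eff)) {
          idx <- match(eff$site_id, sites$site_id)
          mu[idx] <- mu[idx] * 2^eff$effect
        }
      }
      counts[[samples$sample_id[i]]] <- draw_counts(mu, design$nb_dispersion)
    }
    list(counts = counts, sites = sites, genes = genes, samples = samples)
  })
}

#' Simulate CRISPRi spacer counts
#'
#' Builds the guide complement (perfect-match, mismatch series, non-targeting),
#' splits the expected reads between the spacer classes by the sub-library mix
#' weights, and draws counts for uninduced-initial (`T0_uninduced`) and
#' induced-final (`T2_induced`) samples plus chemical treated/control samples
#' (both induced). A spacer of relative activity *a* targeting gene *g*
#' carries `a * essential_lfc(g)` induction depletion and `a * effect(g)`
#' chemical effect; non-targeting spacers carry no effect.
#'
#' @inheritParams simulate_tn_counts
#' @return A list with `counts` (spacer x sample tibble), `guides`
#'   (spacer_id, gene_id, class, relative_activity) and `samples`.
#' @export
simulate_crispri_counts <- function(truth, design, seed = NULL) {
  stopifnot(inherits(design, "screen_design"))
  gene_ids <- sprintf("g%05d", seq_len(design$n_genes))

  perfect <- tidyr::expand_grid(gene_id = gene_ids,
                                k = seq_len(design$guides_per_gene)) %>%
    dplyr::mutate(spacer_id = sprintf("%s_p%d", .data$gene_id, .data$k),
                  class = "perfect", relative_activity = 1) %>%
    dplyr::select("spacer_id", "gene_id", "class", "relative_activity")
  mism <- tibble(spacer_id = character(), gene_id = character(),
                 class = character(), relative_activity = numeric())
  ms <- design$mismatch_series
  if (nrow(ms) && sum(ms$count) > 0) {
    per_gene <- tibble(
      relative_activity = rep(ms$relative_activity, ms$count),
      k = seq_len(sum(ms$count)))
    mism <- tidyr::expand_grid(gene_id = gene_ids, per_gene) %>%
      dplyr::mutate(spacer_id = sprintf("%s_m%d", .data$gene_id, .data$k),
                    class = "mismatch") %>%
      dplyr::select("spacer_id", "gene_id", "class", "relative_activity")
  }
  nt <- tibble(
    spacer_id = sprintf("nt_%05d", seq_len(design$n_nontargeting)),
    gene_id = NA_character_, class = "nontargeting", relative_activity = 0)
  guides <- dplyr::bind_rows(perfect, mism, nt)

  ess_lfc <- truth %>%
    dplyr::distinct(.data$gene_id, .data$essential, .data$essential_lfc)
  ci_truth <- truth %>%
    dplyr::filter(is.na(.data$fp_library) | .data$fp_library == "crispri")

  with_seed(seed, {
    # shared planted effects are realized with library-specific noise
    ci_truth <- ci_truth %>%
      dplyr::mutate(effect = .data$effect + dplyr::if_else(
        .data$effect != 0,
        rnorm(dplyr::n(), 0, design$library_effect_sd), 0))
    mix <- design$sublibrary_mix / sum(design$sublibrary_mix)
    class_n <- table(factor(guides$class, c("perfect", "nontargeting", "mismatch")))
    w_class <- c(perfect = unname(mix["perfect"] / max(class_n[["perfect"]], 1)),
                 nontargeting = unname(mix["nontargeting"] / max(class_n[["nontargeting"]], 1)),
                 mismatch = unname(mix["mismatch"] / max(class_n[["mismatch"]], 1)))
    w <- w_class[guides$class] * stats::rlnorm(nrow(guides), 0, design$abundance_sd)
    mu0 <- design$reads_per_sample * w / sum(w)

    depl <- guides %>%
      dplyr::left_join(ess_lfc, by = "gene_id") %>%
      dplyr::mutate(depletion = dplyr::if_else(
        !is.na(.data$essential) & .data$essential,
        .data$relative_activity * .data$essential_lfc, 0)) %>%
      dplyr::pull("depletion")
    depl[is.na(depl)] <- 0

    samples <- dplyr::bind_rows(
      tibble(sample_id = sprintf("ci_T0_%d", seq_len(design$n_replicates)),
             condition = "induction", replicate = seq_len(design$n_replicates),
             role = "T0_uninduced"),
      tibble(sample_id = sprintf("ci_T2_%d", seq_len(design$n_replicates)),
             condition = "induction", replicate = seq_len(design$n_replicates),
             role = "T2_induced"),
      purrr::map_dfr(design$conditions, function(cond) {
        dplyr::bind_rows(
          tibble(sample_id = sprintf("ci_%s_ctrl_%d", cond, seq_len(design$n_replicates)),
                 condition = cond, replicate = seq_len(design$n_replicates),
                 role = "control"),
          tibble(sample_id = sprintf("ci_%s_%d", cond, seq_len(design$n_replicates)),
                 condition = cond, replicate = seq_len(design$n_replicates),
                 role = "treated"))
      }))

    chem_effect <- function(cond) {
      eff <- ci_truth %>% dplyr::filter(.data$condition == cond)
      e <- eff$effect[match(guides$gene_id, eff$gene_id)]
      e[is.na(e)] <- 0
      guides$relative_activity * e
    }

    counts <- tibble(feature_id = guides$spacer_id)
    for (i in seq_len(nrow(samples))) {
      role <- samples$role[i]
      mu <- switch(role,
        T0_uninduced = mu0,
        T2_induced = mu0 * 2^depl,
        control = mu0 * 2^depl,
        treated = mu0 * 2^(depl + chem_effect(samples$condition[i])))
      counts[[samples$sample_id[i]]] <- draw_counts(mu, design$nb_dispersion)
    }
    list(counts = counts, guides = guides, samples = samples)
  })
}

#' Simulate a label-free proteome intensity table
#'
#' Log2 protein intensities are Gaussian around per-protein baselines; treated
#' samples are shifted by planted log2 fold changes; missingness is
#' left-censored (probability of a missing value increases as the latent
#' intensity decreases), calibrated so the overall missing fraction matches
#' `missing_rate`.
#'
#' @param n_proteins,n_replicates Numbers of proteins and replicates per group.
#' @param missing_rate Overall fraction of missing entries, in \[0, 1).
#' @param planted_lfc Optional data frame (`protein_id`, `lfc`) of true
#'   treated-vs-control log2 fold changes; unlisted proteins get 0.
#' @param baseline_mean,baseline_sd Distribution of per-protein baselines.
#' @param noise_sd Replicate noise sd (log2 units).
#' @param seed Optional integer seed.
#' @return A list with `intensities` (protein x sample tibble, `NA` = missing)
#'   and `design` (sample_id, treatment, timepoint).
#' @export
simulate_proteome <- function(n_proteins = 1800,
                              n_replicates = 3,
                              missing_rate = 0.1,
                              planted_lfc = NULL,
                              baseline_mean = 25,
                              baseline_sd = 2,
                              noise_sd = 0.3,
                              seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must lie in [0, 1).")
  if (n_proteins < 1 || n_replicates < 1) abort("sizes must be positive.")
  ids <- sprintf("p%05d", seq_len(n_proteins))
  lfc <- setNames(rep(0, n_proteins), ids)
  if (!is.null(planted_lfc)) {
    unknown <- setdiff(planted_lfc$protein_id, ids)
    if (length(unknown)) abort("`planted_lfc` names proteins outside the table.")
    lfc[planted_lfc$protein_id] <- planted_lfc$lfc
  }
  design <- dplyr::bind_rows(
    tibble(sample_id = sprintf("prot_control_%d", seq_len(n_replicates)),
           treatment = "control", timepoint = "post"),
    tibble(sample_id = sprintf("prot_treated_%d", seq_len(n_replicates)),
           treatment = "treated", timepoint = "post"))

  with_seed(seed, {
    base <- rnorm(n_proteins, baseline_mean, baseline_sd)
    m <- sapply(seq_len(nrow(design)), function(i) {
      shift <- if (design$treatment[i] == "treated") lfc else 0
      base + shift + rnorm(n_proteins, 0, noise_sd)
    })
    colnames(m) <- design$sample_id
    if (missing_rate > 0) {
      x <- as.vector(m)
      raw <- plogis((quantile(x, missing_rate) - x) / 0.8)
      p <- pmin(1, raw * missing_rate / mean(raw))
      m[runif(length(x)) < p] <- NA_real_
    }
    list(intensities = dplyr::bind_cols(tibble(protein_id = ids), as_tibble(m)),
         design = design)
  })
}
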