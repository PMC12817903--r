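# Orchestration: validated configuration, input validation, and the
# end-to-end synthetic screen pipeline
# (simulate -> differential abundance -> gene scoring -> essentiality ->
#  cross-validation -> proteome response).

#' Pipeline configuration
#'
#' Bundles the screen design with every stage's thresholds. Unknown keys in
#' any section are rejected. All thresholds default to the values used
#' throughout the package: hit gate `|CG| >= 4` & FDR <= 0.05, CRISPRi
#' essentiality `median LFC <= -5.1` & FDR <= 0.05, Tn essentiality
#' `min_hits = 5`, `clip_frac = 0.05`, `alpha = 0.05`,
#' `density_cutoff = 0.025`, mismatch partial-knockdown window `[-4, -1]`,
#' proteomics gates `q < 0.05` & `|LFC| > 1`.
#'
#' @param design A [screen_design()].
#' @param truth Named list overriding [generate_truth()] arguments
#'   (`essential_frac`, `beneficial_frac`, `detrimental_frac`, `fp_frac`,
#'   `effect_range`, `essential_lfc_mean`, `essential_lfc_sd`).
#' @param scoring Named list: `clip_frac`, `pseudocount`.
#' @param essentiality Named list: `min_hits`, `clip_frac`, `alpha`,
#'   `density_cutoff`, `lfc_cutoff`.
#' @param crossval Named list: `cutoff`, `alpha`, `cutoffs` (sweep grid),
#'   `require_same_sign`.
#' @param mismatch Named list: `lfc_window`, `fdr_max`.
#' @param proteome Named list (or `NULL` to skip the stage): `n_proteins`,
#'   `n_replicates`, `missing_rate`, `n_responsive`, `lfc`,
#'   `envelope_rate`, `responsive_envelope_rate`, `lfc_cutoff`, `alpha`.
#' @param seed Root integer seed; each stage draws from a named substream.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(design = screen_design(),
                            truth = list(),
                            scoring = list(),
                            essentiality = list(),
                            crossval = list(),
                            mismatch = list(),
                            proteome = list(),
                            seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  merge_section <- function(defaults, given, name) {
    if (is.null(given)) return(NULL)
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      abort(sprintf("unknown key(s) in config section '%s': %s",
                    name, paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    design = design,
    truth = merge_section(list(
      essential_frac = 0.10, beneficial_frac = 0.02, detrimental_frac = 0.02,
      fp_frac = 0.02, effect_range = c(4, 6),
      essential_lfc_mean = -6, essential_lfc_sd = 0.3), truth, "truth"),
    scoring = merge_section(list(
      clip_frac = 0.05, pseudocount = 0.5), scoring, "scoring"),
    essentiality = merge_section(list(
      min_hits = 5, clip_frac = 0.05, alpha = 0.05,
      density_cutoff = 0.025, lfc_cutoff = -5.1), essentiality, "essentiality"),
    crossval = merge_section(list(
      cutoff = 4, alpha = 0.05, cutoffs = seq(0, 8, by = 0.25),
      require_same_sign = TRUE), crossval, "crossval"),
    mismatch = merge_section(list(
      lfc_window = c(-4, -1), fdr_max = 0.05), mismatch, "mismatch"),
    proteome = merge_section(list(
      n_proteins = 400, n_replicates = 3, missing_rate = 0.08,
      n_responsive = 25, lfc = 3, envelope_rate = 0.29,
      responsive_envelope_rate = 0.55, lfc_cutoff = 1, alpha = 0.05),
      proteome, "proteome"),
    seed = as.integer(seed))
  es <- cfg$essentiality; cv <- cfg$crossval
  if (es$alpha <= 0 || es$alpha > 1 || cv$alpha <= 0 || cv$alpha > 1) {
    abort("alpha thresholds must lie in (0, 1].")
  }
  if (cv$cutoff < 0 || es$density_cutoff <= 0 || es$min_hits < 0) {
    abort("cutoffs must be non-negative.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a `design` section (arguments to [screen_design()])
#' plus any section accepted by [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design_args <- y$design %||% list()
  if (!is.null(design_args$mismatch_series)) {
    design_args$mismatch_series <- as_tibble(design_args$mismatch_series)
  }
  if (!is.null(design_args$sublibrary_mix)) {
    design_args$sublibrary_mix <- unlist(design_args$sublibrary_mix)
  }
  y$design <- NULL
  unknown <- setdiff(names(y), c("truth", "scoring", "essentiality", "crossval",
                                 "mismatch", "proteome", "seed"))
  if (length(unknown)) {
    abort(paste0("unknown top-level config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, c(list(design = do.call(screen_design, design_args)), y))
}

#' Validate pipeline input tables
#'
#' Checks table dialects, id cross-references (guides to genes, sites to gene
#' replicons), metadata coverage and count non-negativity, distinguishing
#' fatal problems from warnings.
#'
#' @param counts Count table (tibble).
#' @param samples Sample sheet (tibble) or `NULL`.
#' @param guides Guide annotation or `NULL`.
#' @param genes Gene model or `NULL`.
#' @param sites Insertion-site table or `NULL`.
#' @return A tibble (`severity` in `warning`/`fatal`, `message`), zero rows
#'   when everything validates; attribute `"ok"` is `TRUE` when no fatal
#'   issue was found.
#' @export
validate_inputs <- function(counts, samples = NULL, guides = NULL,
                            genes = NULL, sites = NULL) {
  issues <- list()
  note <- function(severity, message) {
    issues[[length(issues) + 1L]] <<- tibble(severity = severity, message = message)
  }
  m <- tryCatch(count_matrix(counts), error = function(e) {
    note("fatal", conditionMessage(e)); NULL
  })
  if (!is.null(m) && !is.null(samples)) {
    missing <- setdiff(colnames(m), samples$sample_id)
    if (length(missing)) {
      note("fatal", paste0("sample(s) without metadata: ", paste(missing, collapse = ", ")))
    }
    bad_role <- setdiff(unique(samples$role),
                        c("treated", "control", "T0_uninduced", "T2_induced"))
    if (length(bad_role)) {
      note("fatal", paste0("unknown sample role(s): ", paste(bad_role, collapse = ", ")))
    }
  }
  if (!is.null(guides)) {
    nt_with_gene <- guides$class == "nontargeting" & !is.na(guides$gene_id)
    if (any(nt_with_gene)) note("fatal", "non-targeting guide(s) reference a gene.")
    tg_without <- guides$class != "nontargeting" & is.na(guides$gene_id)
    if (any(tg_without)) note("fatal", "targeting guide(s) lack a gene id.")
    if (!is.null(genes)) {
      unknown <- setdiff(guides$gene_id[!is.na(guides$gene_id)], genes$gene_id)
      if (length(unknown)) {
        note("fatal", paste0("guide(s) reference unknown gene(s): ",
                             paste(head(unknown, 5), collapse = ", ")))
      }
    }
    if (!is.null(m)) {
      unmatched <- setdiff(rownames(m), guides$spacer_id)
      if (length(unmatched)) {
        note("warning", sprintf("%d count feature(s) missing from the guide annotation.",
                                length(unmatched)))
      }
    }
  }
  if (!is.null(sites) && !is.null(genes)) {
    off <- setdiff(unique(sites$replicon), unique(genes$replicon))
    if (length(off)) {
      note("fatal", paste0("site replicon(s) absent from the gene model: ",
                           paste(off, collapse = ", ")))
    }
    if (any(sites$pos < 1)) note("fatal", "site position(s) below 1.")
  }
  out <- if (length(issues)) dplyr::bind_rows(issues) else {
    tibble(severity = character(), message = character())
  }
  attr(out, "ok") <- !any(out$severity == "fatal")
  out
}

#' Compare cross-validated hits with planted truth
#'
#' Positives are gene x condition pairs carrying a planted effect shared by
#' both libraries; a pair is predicted when its hit category is `"both"`.
#'
#' @param hits A [call_hits()] tibble.
#' @param truth A [generate_truth()] table.
#' @return A one-row tibble (`tp`, `fp`, `fn`, `precision`, `recall`).
#' @export
hit_performance <- function(hits, truth) {
  pos <- truth %>%
    dplyr::filter(.data$effect_class != "neutral", .data$shared_in_both_libraries) %>%
    dplyr::mutate(key = paste(.data$gene_id, .data$condition))
  pred <- hits %>%
    dplyr::filter(.data$category == "both") %>%
    dplyr::mutate(key = paste(.data$gene_id, .data$condition))
  tp <- sum(pred$key %in% pos$key)
  fp <- nrow(pred) - tp
  fn <- nrow(pos) - tp
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (nrow(pred)) tp / nrow(pred) else NA_real_,
         recall = if (nrow(pos)) tp / nrow(pos) else NA_real_)
}

#' Run the full synthetic screen pipeline
#'
#' Executes, in order: ground-truth generation, Tn and CRISPRi count
#' simulation, per-feature differential abundance, gene scoring (including
#' mismatch partial-knockdown scores), essentiality calling in both libraries,
#' per-condition quantile normalization over shared non-essential genes,
#' cutoff sweeps with each library as ground truth, dual-gate hit calling,
#' concordance tallies, Ward clustering of hit-gene scores, and (optionally)
#' the proteome-response stage. The run is idempotent given the config
#' (including its seed).
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every intermediate table is
#'   written as TSV and the run manifest as JSON.
#' @return A `screen_result` list: `truth`, `tn`, `crispri`, `tn_scores`,
#'   `crispri_scores`, `induction_scores`, `mismatch_scores`, `essentiality`,
#'   `normalized`, `sweeps`, `hits`, `concordance`, `dendrogram`, `proteome`,
#'   `performance`, `manifest`.
#' @export
run_screen_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  seed <- config$seed
  inform(sprintf("stage truth: planting ground truth (seed %d)", seed))
  truth <- do.call(generate_truth, c(list(design = design),
                                     config$truth,
                                     list(seed = derive_seed(seed, 1))))

  inform("stage simulate: drawing Tn and CRISPRi counts")
  tn <- simulate_tn_counts(truth, design, clip_frac = config$scoring$clip_frac,
                           seed = derive_seed(seed, 2))
  ci <- simulate_crispri_counts(truth, design, seed = derive_seed(seed, 3))

  inform("stage diffabund/score: per-feature tests and gene scores")
  ctrl_tn <- tn$samples$sample_id[tn$samples$role == "control"]
  gene_counts <- tn_gene_aggregate(tn$counts, tn$sites, tn$genes,
                                   clip_frac = config$scoring$clip_frac)
  n_sites <- attr(gene_counts, "n_sites")
  tn_scores <- purrr::map_dfr(design$conditions, function(cond) {
    trt <- tn$samples$sample_id[tn$samples$condition == cond &
                                  tn$samples$role == "treated"]
    stats <- nb_lfc_test(gene_counts, treated = trt, control = ctrl_tn,
                         pseudocount = config$scoring$pseudocount)
    tn_gene_scores(stats, n_sites, condition = cond)
  })

  t0 <- ci$samples$sample_id[ci$samples$role == "T0_uninduced"]
  t2 <- ci$samples$sample_id[ci$samples$role == "T2_induced"]
  induction_stats <- nb_lfc_test(ci$counts, treated = t2, control = t0,
                                 pseudocount = config$scoring$pseudocount)
  induction_scores <- crispri_gene_scores(induction_stats, ci$guides,
                                          condition = "induction")
  ci_by_cond <- purrr::map(setNames(design$conditions, design$conditions),
                           function(cond) {
    trt <- ci$samples$sample_id[ci$samples$condition == cond &
                                  ci$samples$role == "treated"]
    ctl <- ci$samples$sample_id[ci$samples$condition == cond &
                                  ci$samples$role == "control"]
    nb_lfc_test(ci$counts, treated = trt, control = ctl,
                pseudocount = config$scoring$pseudocount)
  })
  crispri_scores <- purrr::imap_dfr(ci_by_cond, function(stats, cond) {
    crispri_gene_scores(stats, ci$guides, condition = cond)
  })
  mismatch_scores <- purrr::imap_dfr(ci_by_cond, function(stats, cond) {
    mismatch_partial_scores(stats, induction_stats, ci$guides,
                            lfc_window = config$mismatch$lfc_window,
                            fdr_max = config$mismatch$fdr_max,
                            condition = cond)
  })

  inform(sprintf(
    "stage essential: Tn gate p < %.3g & norm hits/bp < %.3g; CRISPRi gate FDR <= %.3g & LFC <= %.2f",
    config$essentiality$alpha, config$essentiality$density_cutoff,
    config$essentiality$alpha, config$essentiality$lfc_cutoff))
  ess <- config$essentiality
  tn_ess <- tn_essentiality(tn$counts, tn$sites, tn$genes,
                            control_samples = ctrl_tn,
                            min_hits = ess$min_hits, clip_frac = ess$clip_frac,
                            alpha = ess$alpha, density_cutoff = ess$density_cutoff)
  ci_ess <- crispri_essentiality(induction_scores,
                                 lfc_cutoff = ess$lfc_cutoff, alpha = ess$alpha)
  essential_union <- union(tn_ess$gene_id[tn_ess$essential],
                           ci_ess$gene_id[ci_ess$essential])

  inform(sprintf(
    "stage crossval: hit gate |CG| >= %.2f & FDR <= %.3g over %d-point sweep grid",
    config$crossval$cutoff, config$crossval$alpha, length(config$crossval$cutoffs)))
  per_cond <- purrr::map(setNames(design$conditions, design$conditions),
                         function(cond) {
    tn_c <- tn_scores %>% dplyr::filter(.data$condition == cond,
                                        !(.data$gene_id %in% essential_union))
    ci_c <- crispri_scores %>% dplyr::filter(.data$condition == cond,
                                             !(.data$gene_id %in% essential_union))
    shared <- dplyr::inner_join(
      tn_c %>% dplyr::select("gene_id", tn = "cg_score", tn_fdr = "gene_fdr"),
      ci_c %>% dplyr::select("gene_id", crispri = "cg_score", crispri_fdr = "gene_fdr"),
      by = "gene_id")
    if (nrow(shared) < 2) return(NULL)
    norm <- quantile_normalize(shared %>% dplyr::select("gene_id", "tn", "crispri"))
    shared %>%
      dplyr::mutate(tn = norm$tn, crispri = norm$crispri, condition = cond)
  })
  normalized <- dplyr::bind_rows(per_cond)

  sweep_input <- function(truth_library) {
    if (truth_library == "Tn") {
      normalized %>% dplyr::transmute(truth_score = .data$tn,
                                      truth_fdr = .data$tn_fdr,
                                      classifier_score = .data$crispri)
    } else {
      normalized %>% dplyr::transmute(truth_score = .data$crispri,
                                      truth_fdr = .data$crispri_fdr,
                                      classifier_score = .data$tn)
    }
  }
  sweeps <- purrr::map_dfr(c("Tn", "CRISPRi"), function(lib) {
    cutoff_sweep(sweep_input(lib), cutoffs = config$crossval$cutoffs,
                 fdr_max = config$crossval$alpha) %>%
      dplyr::mutate(truth_library = lib, .before = 1)
  })
  class(sweeps) <- c("sweep_result", class(tibble()))

  norm_scores <- function(lib_col, fdr_col, lib) {
    normalized %>%
      dplyr::transmute(gene_id = .data$gene_id, condition = .data$condition,
                       library = lib, cg_score = .data[[lib_col]],
                       gene_fdr = .data[[fdr_col]])
  }
  hits <- call_hits(norm_scores("tn", "tn_fdr", "Tn"),
                    norm_scores("crispri", "crispri_fdr", "CRISPRi"),
                    cutoff = config$crossval$cutoff,
                    alpha = config$crossval$alpha,
                    require_same_sign = config$crossval$require_same_sign)
  concordance <- concordance_summary(hits)
  performance <- hit_performance(hits, truth)

  hit_genes <- hits %>%
    dplyr::filter(.data$category != "none") %>%
    dplyr::pull("gene_id") %>% unique()
  dendrogram <- NULL
  if (length(hit_genes) >= 2) {
    wide <- normalized %>%
      dplyr::filter(.data$gene_id %in% hit_genes) %>%
      tidyr::pivot_wider(id_cols = "gene_id", names_from = "condition",
                         values_from = c("tn", "crispri"), values_fill = 0)
    dendrogram <- ward_linkage(wide)
  }

  proteome <- NULL
  if (!is.null(config$proteome)) {
    inform("stage proteome: simulated ferulic-acid response")
    proteome <- run_proteome_stage(config$proteome, seed = derive_seed(seed, 4))
  }

  manifest <- list(
    package = "dualscreen",
    version = as.character(utils::packageVersion("dualscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = rlang::hash(unclass(config)))

  result <- structure(list(
    config = config, truth = truth, tn = tn, crispri = ci,
    tn_scores = tn_scores, crispri_scores = crispri_scores,
    induction_scores = induction_scores, mismatch_scores = mismatch_scores,
    essentiality = list(tn = tn_ess, crispri = ci_ess, union = essential_union),
    normalized = normalized, sweeps = sweeps, hits = hits,
    concordance = concordance, dendrogram = dendrogram,
    proteome = proteome, performance = performance, manifest = manifest
  ), class = "screen_result")

  if (!is.null(outdir)) write_result_bundle(result, outdir)
  result
}

# Synthetic proteome stage: plant responsive proteins with an envelope bias,
# impute, test, classify and run the enrichment.
run_proteome_stage <- function(p, seed) {
  ids <- sprintf("p%05d", seq_len(p$n_proteins))
  with_seed(seed, {
    responsive <- sample(ids, p$n_responsive)
    planted <- tibble(protein_id = responsive,
                      lfc = p$lfc * sample(c(-1, 1), p$n_responsive, replace = TRUE))
    envelope_p <- ifelse(ids %in% responsive,
                         p$responsive_envelope_rate, p$envelope_rate)
    is_env <- runif(p$n_proteins) < envelope_p
    localization <- tibble(
      protein_id = ids,
      signal_likelihood = ifelse(is_env, runif(p$n_proteins, 0.905, 1),
                                 runif(p$n_proteins, 0, 0.9)),
      n_tm_segments = ifelse(is_env & runif(p$n_proteins) < 0.5,
                             sample(1:6, p$n_proteins, replace = TRUE), 0L)) %>%
      classify_localization()
    sim <- simulate_proteome(
      n_proteins = p$n_proteins, n_replicates = p$n_replicates,
      missing_rate = p$missing_rate, planted_lfc = planted,
      seed = derive_seed(seed, 11))
    complete <- impute_missing(sim$intensities, seed = derive_seed(seed, 12))
    treated <- sim$design$sample_id[sim$design$treatment == "treated"]
    control <- sim$design$sample_id[sim$design$treatment == "control"]
    stats <- protein_diff(complete, treated, control,
                          lfc_cutoff = p$lfc_cutoff, alpha = p$alpha)
    enrich <- envelope_enrichment(localization,
                                  responsive = stats$protein_id[stats$significant])
    list(planted = planted, localization = localization,
         intensities = sim$intensities, stats = stats,
         envelope_fraction = envelope_fraction(localization),
         enrichment = enrich)
  })
}

write_result_bundle <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      readr::write_tsv(x, file.path(outdir, paste0(name, ".tsv")))
    }
  }
  w(result$truth, "truth")
  w(result$tn_scores, "tn_gene_scores")
  w(result$crispri_scores, "crispri_gene_scores")
  w(result$induction_scores, "induction_gene_scores")
  w(result$mismatch_scores, "mismatch_partial_scores")
  w(result$essentiality$tn, "tn_essentiality")
  w(result$essentiality$crispri, "crispri_essentiality")
  w(result$normalized, "normalized_scores")
  w(result$sweeps, "cutoff_sweeps")
  w(result$hits, "hit_calls")
  w(result$concordance, "concordance")
  w(result$performance, "hit_performance")
  if (!is.null(result$dendrogram)) {
    writeLines(dendro_newick(result$dendrogram),
               file.path(outdir, "dendrogram.nwk"))
    merge_tab <- tibble(
      step = seq_len(nrow(result$dendrogram$merge)),
      left = result$dendrogram$merge[, 1],
      right = result$dendrogram$merge[, 2],
      height = result$dendrogram$height)
    readr::write_tsv(merge_tab, file.path(outdir, "dendrogram_merges.tsv"))
  }
  if (!is.null(result$proteome)) {
    w(result$proteome$stats, "protein_diff")
    w(result$proteome$localization, "protein_localization")
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  %d genes, conditions: %s\n", x$config$design$n_genes,
              paste(x$config$design$conditions, collapse = ", ")))
  cat(sprintf("  essential: %d (Tn), %d (CRISPRi), union %d\n",
              sum(x$essentiality$tn$essential),
              sum(x$essentiality$crispri$essential),
              length(x$essentiality$union)))
  cat(sprintf("  hits: both %d | tn_only %d | crispri_only %d | union %d\n",
              x$concordance$both, x$concordance$tn_only,
              x$concordance$crispri_only, x$concordance$union))
  cat(sprintf("  cross-validated precision %.3f, recall %.3f\n",
              x$performance$precision, x$performance$recall))
  invisible(x)
}

#' @rdname run_screen_pipeline
#' @param x A `screen_result`.
#' @param ... Unused.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_genes = x$config$design$n_genes,
           n_conditions = length(x$config$design$conditions),
           tn_essential = sum(x$essentiality$tn$essential),
           crispri_essential = sum(x$essentiality$crispri$essential)),
    x$concordance,
    x$performance %>% dplyr::select("precision", "recall"))
}
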