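# TSV dialects for count tables, sample sheets, guide annotations and result
# tables, plus GFF3/BED interval I/O via rtracklayer.

#' Read and write the package's TSV dialects
#'
#' Count tables are TSV with a `feature_id` first column and one column per
#' sample. Sample sheets carry `sample_id`, `condition`, `replicate`, `role`
#' (`treated`, `control`, `T0_uninduced` or `T2_induced`). Guide annotations
#' carry `spacer_id`, `gene_id` (`NA` for non-targeting), `class`
#' (`perfect`/`mismatch`/`nontargeting`) and `relative_activity`. Gene-score,
#' truth, and generic result tables round-trip as plain TSV.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return tibbles; writers return `x` invisibly.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  count_matrix(x)  # validates
  x
}

#' @rdname screen_io
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname screen_io
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "condition", "replicate", "role")
  if (!all(need %in% names(x))) {
    abort("sample sheet needs columns sample_id, condition, replicate, role.")
  }
  x
}

#' @rdname screen_io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname screen_io
#' @export
read_guide_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(gene_id = readr::col_character()))
  need <- c("spacer_id", "gene_id", "class")
  if (!all(need %in% names(x))) {
    abort("guide annotation needs columns spacer_id, gene_id, class.")
  }
  bad <- setdiff(unique(x$class), c("perfect", "mismatch", "nontargeting"))
  if (length(bad)) abort(paste0("unknown guide class: ", paste(bad, collapse = ", ")))
  x
}

#' @rdname screen_io
#' @export
write_guide_annotation <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname screen_io
#' @export
read_result_table <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' @rdname screen_io
#' @export
write_result_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand %||% "*",
    gene_id = genes$gene_id)
}

#' Gene-model and insertion-site interval I/O
#'
#' Gene models are stored 1-based inclusive, matching GFF3; BED output is
#' 0-based half-open (the conversion is handled by rtracklayer). Insertion
#' sites are written as 1-bp features.
#'
#' @param path File path (`.gff3` or `.bed`).
#' @param genes Gene model tibble (`gene_id`, `replicon`, `start`, `end`,
#'   `strand`).
#' @param sites Site tibble (`site_id`, `replicon`, `pos`).
#' @return `read_gene_model()` returns a gene-model tibble; writers return
#'   their input invisibly.
#' @name interval_io
NULL

#' @rdname interval_io
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  id <- if (!is.null(md$gene_id)) md$gene_id
        else if (!is.null(md$ID)) md$ID
        else if (!is.null(md$name)) md$name
        else as.character(seq_along(gr))
  tibble(
    gene_id = as.character(id),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname interval_io
#' @export
write_gene_model_gff3 <- function(genes, path) {
  gr <- genes_to_granges(genes)
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(genes)
}

#' @rdname interval_io
#' @export
write_sites_gff3 <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$replicon,
    ranges = IRanges::IRanges(start = sites$pos, width = 1),
    site_id = sites$site_id)
  S4Vectors::mcols(gr)$ID <- sites$site_id
  S4Vectors::mcols(gr)$type <- "insertion_site"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(sites)
}

#' @rdname interval_io
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$replicon,
    ranges = IRanges::IRanges(start = sites$pos, width = 1))
  names(gr) <- sites$site_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(sites)
}
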