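# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Named substreams derived from one root seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009L + as.numeric(offset)) %% 2147483647)
}

# Wide count tibble (feature_id + one column per sample) -> integer matrix.
count_matrix <- function(counts, id_col = 1L) {
  if (!is.data.frame(counts) || ncol(counts) < 2L) {
    abort("`counts` must be a data frame with an id column plus sample columns.")
  }
  ids <- as.character(counts[[id_col]])
  if (anyDuplicated(ids)) abort("feature ids must be unique.")
  m <- as.matrix(counts[, -id_col, drop = FALSE])
  if (!is.numeric(m)) abort("count columns must be numeric.")
  if (anyNA(m)) abort("count table contains missing values.")
  if (any(m < 0)) abort("count table contains negative entries.")
  rownames(m) <- ids
  m
}

# Accept a size-factor tibble (sample_id, size_factor) or a named vector and
# return a vector aligned to `sample_ids`.
factor_vector <- function(factors, sample_ids) {
  if (is.data.frame(factors)) {
    f <- setNames(factors$size_factor, factors$sample_id)
  } else {
    f <- factors
  }
  if (is.null(names(f))) {
    if (length(f) != length(sample_ids)) {
      abort("unnamed size factors must match the number of samples.")
    }
    names(f) <- sample_ids
  }
  missing <- setdiff(sample_ids, names(f))
  if (length(missing)) {
    abort(paste0("no size factor for sample(s): ", paste(missing, collapse = ", ")))
  }
  f <- f[sample_ids]
  if (any(!is.finite(f)) || any(f <= 0)) abort("size factors must be positive and finite.")
  f
}

geometric_mean <- function(x) exp(mean(log(x)))

# First column of a score frame is the row id; the rest must be numeric.
split_id_matrix <- function(x, what = "scores") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("`%s` must be a data frame with an id column plus value columns.", what))
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1L]])
  m
}
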