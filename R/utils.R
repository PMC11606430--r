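# Internal validation helpers shared across modules.

stop_bad_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "droughtjac_error")
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_bad_arg("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assert_proportion <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    stop_bad_arg("`%s` must be a single number in [%g, %g]", name, lo, hi)
  }
  as.numeric(x)
}

# names of the metabolite (non-metadata) columns of an abundance table
metabolite_columns <- function(matrix) {
  setdiff(names(matrix), META_COLS)
}

assert_metabolite_matrix <- function(matrix, arg = "matrix") {
  if (!is.data.frame(matrix)) {
    stop_bad_arg("`%s` must be a data frame of observations x metabolites", arg)
  }
  missing_meta <- setdiff(META_COLS, names(matrix))
  if (length(missing_meta) > 0L) {
    stop_bad_arg(
      "`%s` is missing metadata column(s): %s", arg,
      paste(missing_meta, collapse = ", ")
    )
  }
  mets <- metabolite_columns(matrix)
  if (length(mets) == 0L) {
    stop_bad_arg("`%s` has no metabolite columns", arg)
  }
  keys <- do.call(paste, c(matrix[META_COLS], sep = "\r"))
  if (anyDuplicated(keys)) {
    stop_bad_arg(
      "`%s` has duplicated (genotype, replicate, condition, time_point) keys", arg
    )
  }
  invisible(matrix)
}

# symmetrize a numerically-almost-symmetric matrix
symmetrize <- function(M) (M + t(M)) / 2

max_abs <- function(M) if (length(M)) max(abs(M)) else 0

is_hurwitz <- function(J, tol = 0) {
  all(Re(eigen(J, only.values = TRUE)$values) < -tol)
}
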