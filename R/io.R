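# Strict readers/writers for the three tabular inputs. Parsing is strict
# by design: a malformed numeric cell aborts the read instead of being
# coerced to NA, because silent NAs propagate into covariance estimates
# invisibly.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_strict <- function(path, col_types) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  # readr warns about parsing issues; we turn them into errors below, so
  # the advisory warning is redundant noise
  out <- withCallingHandlers(
    readr::read_delim(path, delim = delim_for(path), col_types = col_types,
                      show_col_types = FALSE, progress = FALSE, lazy = FALSE),
    warning = function(w) {
      if (grepl("parsing issues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    p <- probs[1, ]
    stop_bad_arg(
      "malformed value in %s at row %d, column %d (expected %s, got %s)%s",
      path, p$row, p$col, p$expected, p$actual,
      if (nrow(probs) > 1L) sprintf("; %d further problem(s)", nrow(probs) - 1L) else ""
    )
  }
  out
}

#' Read a wide abundance table
#'
#' Expects a TSV (or `.csv`) with header: metadata columns `genotype`,
#' `replicate`, `condition`, `time_point`, then one numeric column per
#' metabolite. Condition labels are normalized case-insensitively to
#' `WW`/`DS`; anything else errors. Duplicate observation keys and
#' non-numeric abundance cells error rather than being coerced.
#'
#' @param path File path.
#' @return A validated abundance tibble.
#' @export
read_abundance_table <- function(path) {
  header <- names(readr::read_delim(path, delim = delim_for(path), n_max = 0,
                                    show_col_types = FALSE, progress = FALSE))
  missing_meta <- setdiff(META_COLS, header)
  if (length(missing_meta) > 0L) {
    stop_bad_arg("%s is missing required column(s): %s", path,
                 paste(missing_meta, collapse = ", "))
  }
  ct <- do.call(readr::cols, c(
    list(.default = readr::col_double(),
         genotype = readr::col_character(),
         replicate = readr::col_integer(),
         condition = readr::col_character(),
         time_point = readr::col_integer())
  ))
  out <- read_strict(path, ct)
  cond <- toupper(out$condition)
  bad <- setdiff(unique(cond), c("WW", "DS"))
  if (length(bad) > 0L) {
    stop_bad_arg("unknown condition label(s) in %s: %s (expected WW or DS)",
                 path, paste(bad, collapse = ", "))
  }
  out$condition <- cond
  out <- out[, c(META_COLS, setdiff(header, META_COLS))]
  assert_metabolite_matrix(out)
  out
}

#' Write an abundance table
#'
#' @param matrix Abundance tibble.
#' @param path Destination path (TSV, or `.csv` for comma-separated).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(matrix, path) {
  assert_metabolite_matrix(matrix)
  readr::write_delim(matrix, path, delim = delim_for(path))
  invisible(path)
}

#' Read a phenotype (yield) table
#'
#' Expects columns `genotype`, `Yp`, `Ys` (header required): per-genotype
#' mean trait values under well-watered and drought conditions.
#'
#' @param path File path.
#' @return A validated yield tibble.
#' @export
read_phenotype_table <- function(path) {
  header <- names(readr::read_delim(path, delim = delim_for(path), n_max = 0,
                                    show_col_types = FALSE, progress = FALSE))
  missing_cols <- setdiff(c("genotype", "Yp", "Ys"), header)
  if (length(missing_cols) > 0L) {
    stop_bad_arg("%s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  out <- read_strict(path, readr::cols(genotype = readr::col_character(),
                                       Yp = readr::col_double(),
                                       Ys = readr::col_double(),
                                       .default = readr::col_guess()))
  validate_yield_table(out, arg = path)
  out
}

#' Read a directed network edge list
#'
#' Expects columns `source`, `target` with metabolite names matching the
#' abundance table's columns (that match is checked when the pipeline is
#' assembled, not here). Self-edges are accepted and noted; the Jacobian
#' diagonal is always allowed regardless.
#'
#' @param path File path.
#' @return A [metabolic_network()].
#' @export
read_network <- function(path) {
  header <- names(readr::read_delim(path, delim = delim_for(path), n_max = 0,
                                    show_col_types = FALSE, progress = FALSE))
  missing_cols <- setdiff(c("source", "target"), header)
  if (length(missing_cols) > 0L) {
    stop_bad_arg("%s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  out <- read_strict(path, readr::cols(source = readr::col_character(),
                                       target = readr::col_character(),
                                       .default = readr::col_guess()))
  n_self <- sum(out$source == out$target)
  if (n_self > 0L) {
    rlang::inform(sprintf("%d self-edge(s) in %s (diagonal entries are always allowed)",
                          n_self, path))
  }
  metabolic_network(out)
}

#' Read a flat key-value pipeline configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values are coerced: `true`/`false` to logical, numbers to
#' numeric, comma-separated lists to character vectors. Keys must be valid
#' [pipeline_config()] arguments.
#'
#' @param path File path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_bad_arg("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad) > 0L) {
    stop_bad_arg("unparseable config line: %s", bad[1])
  }
  vals <- lapply(kv, function(m) coerce_config_value(trimws(m[3])))
  names(vals) <- vapply(kv, `[`, "", 2L)
  do.call(pipeline_config, vals)
}

coerce_config_value <- function(v) {
  if (grepl(",", v, fixed = TRUE)) {
    return(trimws(strsplit(v, ",", fixed = TRUE)[[1]]))
  }
  if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}
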