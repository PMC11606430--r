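#' Log-transform an abundance table
#'
#' Element-wise logarithm of the metabolite columns, leaving metadata
#' untouched. Relative GC-MS abundances are strictly positive, so
#' non-positive values indicate an upstream problem: by default they raise
#' an error naming the metabolite and the offending observation. The
#' `"offset"` policy instead adds half of the smallest positive value of
#' that metabolite before logging (a standard pseudo-count for
#' peak-area data).
#'
#' @param matrix Abundance table: metadata columns `genotype`, `replicate`,
#'   `condition`, `time_point`, then one numeric column per metabolite.
#' @param base Logarithm base: `"e"` (default), `"10"` or `"2"`. Pearson
#'   correlation downstream is invariant to the base.
#' @param nonpositive_policy `"error"` (default) or `"offset"`.
#' @return The table with metabolite columns on log scale.
#' @export
log_transform <- function(matrix, base = c("e", "10", "2"),
                          nonpositive_policy = c("error", "offset")) {
  base <- match.arg(base)
  nonpositive_policy <- match.arg(nonpositive_policy)
  assert_metabolite_matrix(matrix)
  logb <- switch(base, e = exp(1), "10" = 10, "2" = 2)
  mets <- metabolite_columns(matrix)
  out <- matrix
  for (m in mets) {
    v <- out[[m]]
    if (!is.numeric(v)) stop_bad_arg("metabolite column `%s` is not numeric", m)
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0L) {
      if (nonpositive_policy == "error") {
        stop_bad_arg(
          "non-positive abundance for metabolite `%s` at observation %d (genotype %s); use nonpositive_policy = \"offset\" to add a pseudo-count",
          m, bad[1], as.character(matrix$genotype[bad[1]])
        )
      }
      pos <- v[!is.na(v) & v > 0]
      if (length(pos) == 0L) {
        stop_bad_arg("metabolite `%s` has no positive values to derive an offset from", m)
      }
      v <- v + min(pos) / 2
    }
    out[[m]] <- log(v, base = logb)
  }
  out
}

#' Per-metabolite Pearson correlation with SSI
#'
#' Screens every metabolite of a log-scale abundance table for linear
#' association with the genotype-level stress susceptibility index.
#' Observations are filtered to one condition and harvest time point, and
#' each replicate observation is paired with its genotype's SSI, so with
#' 36 genotypes x 3 replicates the correlations use n = 108 pairs. For
#' each metabolite the Pearson r, the t statistic `t = r*sqrt(n-2) /
#' sqrt(1-r^2)`, its two-sided p-value (t distribution, n-2 df), the
#' Benjamini-Hochberg adjusted q-value across the metabolite family, and
#' the variance explained `r_squared = r^2` are reported.
#'
#' Zero-variance metabolites cannot be correlated: their rows are flagged
#' `undefined = TRUE`, carry `NA` statistics, and are excluded from the BH
#' family (with a warning).
#'
#' @param matrix Log-scale abundance table (see [log_transform()]).
#' @param ssi An `ssi_result` from [compute_ssi()], or any data frame with
#'   `genotype` and `SSI` columns covering every genotype in the slice.
#' @param condition Condition to analyse, `"DS"` (default) or `"WW"`.
#' @param time_point Harvest time point to analyse; default `2`, the
#'   mid-pod-filling stage where the drought response peaks.
#' @param alpha Significance level for the `significant` flag on the raw
#'   p-value; default 0.05.
#' @return A tibble of class `correlation_table`, one row per metabolite,
#'   sorted by decreasing `|r|`: `metabolite`, `r`, `n`, `t_stat`, `p`,
#'   `q`, `r_squared`, `significant`, `undefined`.
#' @export
correlate_to_ssi <- function(matrix, ssi, condition = "DS", time_point = 2,
                             alpha = 0.05) {
  assert_metabolite_matrix(matrix)
  if (!is.data.frame(ssi) || !all(c("genotype", "SSI") %in% names(ssi))) {
    stop_bad_arg("`ssi` must have columns genotype and SSI (see compute_ssi())")
  }
  slice <- matrix[matrix$condition == condition &
                    matrix$time_point == time_point, , drop = FALSE]
  if (nrow(slice) < 3L) {
    stop_bad_arg(
      "fewer than 3 observations for condition %s, time point %s",
      condition, as.character(time_point)
    )
  }
  missing_g <- setdiff(unique(slice$genotype), ssi$genotype)
  if (length(missing_g) > 0L) {
    stop_bad_arg("no SSI value for genotype(s): %s", paste(missing_g, collapse = ", "))
  }
  ssi_obs <- ssi$SSI[match(slice$genotype, ssi$genotype)]

  mets <- metabolite_columns(slice)
  rows <- purrr::map(mets, function(m) {
    v <- slice[[m]]
    keep <- !is.na(v) & !is.na(ssi_obs)
    n <- sum(keep)
    if (n < 3L || sd(v[keep]) == 0 || sd(ssi_obs[keep]) == 0) {
      return(tibble::tibble(metabolite = m, r = NA_real_, n = n,
                            t_stat = NA_real_, p = NA_real_,
                            r_squared = NA_real_, undefined = TRUE))
    }
    ct <- stats::cor.test(v[keep], ssi_obs[keep], method = "pearson")
    r <- unname(ct$estimate)
    tibble::tibble(metabolite = m, r = r, n = n,
                   t_stat = unname(ct$statistic), p = ct$p.value,
                   r_squared = r^2, undefined = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$undefined)) {
    rlang::warn(sprintf(
      "%d zero-variance or under-observed metabolite(s) excluded from the BH family: %s",
      sum(out$undefined), paste(out$metabolite[out$undefined], collapse = ", ")
    ))
  }
  out$q <- NA_real_
  out$q[!out$undefined] <- stats::p.adjust(out$p[!out$undefined], method = "BH")
  out$significant <- !out$undefined & out$p < alpha
  out <- out[order(-abs(out$r), out$metabolite, na.last = TRUE), ]
  out <- out[, c("metabolite", "r", "n", "t_stat", "p", "q", "r_squared",
                 "significant", "undefined")]
  structure(out, condition = condition, time_point = time_point,
            alpha = alpha,
            class = c("correlation_table", class(out)))
}

#' Bar chart of metabolite-SSI correlations
#'
#' @param object A `correlation_table` from [correlate_to_ssi()].
#' @param top Number of strongest-|r| metabolites to show; default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_table <- function(object, top = 20, ...) {
  d <- object[!object$undefined, , drop = FALSE]
  d <- head(d[order(-abs(d$r)), ], top)
  d$metabolite <- factor(d$metabolite, levels = rev(d$metabolite))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$metabolite,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "Pearson r with SSI", y = NULL,
                  fill = sprintf("p < %.3g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
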