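#' Group covariance of log metabolite abundances
#'
#' Unbiased (n-1) sample covariance over all genotype-by-replicate
#' observations of a group slice of a log-scale abundance table. This is
#' the `C` fed to the inverse Lyapunov solver; with typical designs
#' (more metabolites than observations per group) it is singular, which
#' the solver handles via its minimum-norm path.
#'
#' @param matrix Log-scale abundance table (see [log_transform()]).
#' @param genotypes Optional character vector restricting the group; by
#'   default all genotypes in the slice.
#' @param condition,time_point Analysis slice; defaults `"DS"`, `2`.
#' @param metabolites Optional character vector selecting (and ordering)
#'   the metabolite subset; default all metabolite columns. Metabolites
#'   with any missing value in the slice are dropped with a warning.
#' @return Symmetric covariance matrix with metabolite dimnames and an
#'   `n_samples` attribute.
#' @export
estimate_covariance <- function(matrix, genotypes = NULL, condition = "DS",
                                time_point = 2, metabolites = NULL) {
  assert_metabolite_matrix(matrix)
  slice <- matrix[matrix$condition == condition &
                    matrix$time_point == time_point, , drop = FALSE]
  if (!is.null(genotypes)) {
    slice <- slice[slice$genotype %in% genotypes, , drop = FALSE]
  }
  if (nrow(slice) < 2L) {
    stop_bad_arg("fewer than 2 observations in the requested slice; cannot estimate covariance")
  }
  mets <- metabolites %||% metabolite_columns(slice)
  missing_m <- setdiff(mets, metabolite_columns(slice))
  if (length(missing_m) > 0L) {
    stop_bad_arg("metabolite(s) not in table: %s", paste(missing_m, collapse = ", "))
  }
  X <- as.matrix(slice[, mets, drop = FALSE])
  has_na <- colSums(is.na(X)) > 0L
  if (any(has_na)) {
    rlang::warn(sprintf("excluding %d metabolite(s) with missing values: %s",
                        sum(has_na), paste(mets[has_na], collapse = ", ")))
    X <- X[, !has_na, drop = FALSE]
  }
  if (ncol(X) == 0L) stop_bad_arg("no metabolites left after missing-value exclusion")
  C <- stats::cov(X)
  C <- symmetrize(C)
  attr(C, "n_samples") <- nrow(X)
  C
}

#' Differential Jacobian between two genotype groups
#'
#' Entry-wise comparison of two Monte-Carlo Jacobian estimates on the same
#' network mask: for every masked entry,
#' `dJ = ln(|J1| / |J2|)`, the log-ratio of entry magnitudes. Positive
#' values indicate a larger reaction elasticity (faster flux response) in
#' group 1, negative in group 2. Because the log-ratio of magnitudes is
#' undefined when an entry vanishes, entries where either magnitude falls
#' below `epsilon_factor` times the median masked-entry magnitude are
#' flagged `undefined` (this symmetric rule keeps the antisymmetry
#' `dJ(swap) = -dJ` exact, flags included). The log-ratio also ignores
#' sign changes, so `sign_concordant` records whether the two entries
#' agree in sign, and `mode` labels concordant entries as `"activating"`
#' (shared sign positive) or `"inhibiting"` (negative).
#'
#' @param J1,J2 `jacobian_estimate` objects from [monte_carlo_jacobian()]
#'   with identical masks and variable ordering.
#' @param group_names Length-2 character naming the groups; default
#'   `c("group1", "group2")`.
#' @param epsilon_factor Relative magnitude floor for defined log-ratios;
#'   default `1e-9`.
#' @return A tibble of class `differential_jacobian`, one row per masked
#'   entry: `source`, `target`, `j1`, `j2`, `dJ`, `sign_concordant`,
#'   `mode`, `dominant_group`, `undefined`.
#' @export
differential_jacobian <- function(J1, J2,
                                  group_names = c("group1", "group2"),
                                  epsilon_factor = 1e-9) {
  if (!inherits(J1, "jacobian_estimate") || !inherits(J2, "jacobian_estimate")) {
    stop_bad_arg("`J1` and `J2` must be jacobian_estimate objects")
  }
  if (!identical(dim(J1$mask), dim(J2$mask)) || !all(J1$mask == J2$mask) ||
      !identical(rownames(J1$median), rownames(J2$median))) {
    stop_bad_arg("`J1` and `J2` have different masks or variable orderings")
  }
  if (length(group_names) != 2L) stop_bad_arg("`group_names` must have length 2")
  mask <- J1$mask
  free <- which(mask)
  n <- nrow(mask)
  vn <- rownames(J1$median) %||% paste0("V", seq_len(n))
  a <- J1$median[free]
  b <- J2$median[free]
  eps <- epsilon_factor * median(abs(c(a, b)))
  undefined <- abs(a) < eps | abs(b) < eps
  dJ <- ifelse(undefined, NA_real_, log(abs(a) / abs(b)))
  concordant <- ifelse(undefined, NA, sign(a) == sign(b))
  mode <- dplyr::case_when(
    is.na(concordant) | !concordant ~ NA_character_,
    sign(a) > 0 ~ "activating",
    .default = "inhibiting"
  )
  dominant <- dplyr::case_when(
    is.na(dJ) ~ NA_character_,
    dJ > 0 ~ group_names[1],
    dJ < 0 ~ group_names[2],
    .default = "none"
  )
  out <- tibble::tibble(
    target = vn[((free - 1L) %% n) + 1L],
    source = vn[((free - 1L) %/% n) + 1L],
    j1 = a, j2 = b, dJ = dJ,
    sign_concordant = concordant, mode = mode,
    dominant_group = dominant, undefined = undefined
  )
  structure(out, group_names = group_names,
            class = c("differential_jacobian", class(out)))
}

#' Report network edges with differential flux above a threshold
#'
#' Filters a differential Jacobian to the defined entries with
#' `|dJ| >= threshold` and returns the tidy table behind a circular
#' differential-flux diagram: which reactions respond faster in which
#' group, and whether the shared elasticity sign marks them activating or
#' inhibiting.
#'
#' @param diff A `differential_jacobian`.
#' @param threshold Non-negative cut-off on `|dJ|` (log-ratio units);
#'   default 0 (report everything defined).
#' @return Tibble sorted by decreasing `|dJ|`: `source`, `target`,
#'   `dominant_group`, `mode`, `dJ`.
#' @export
classify_edges <- function(diff, threshold = 0) {
  if (!inherits(diff, "differential_jacobian")) {
    stop_bad_arg("`diff` must come from differential_jacobian()")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop_bad_arg("`threshold` must be a single non-negative number")
  }
  d <- diff[!diff$undefined & abs(diff$dJ) >= threshold, , drop = FALSE]
  d <- d[order(-abs(d$dJ)), c("source", "target", "dominant_group", "mode", "dJ")]
  tibble::as_tibble(d)
}

#' Tile plot of differential Jacobian entries
#'
#' @param object A `differential_jacobian`.
#' @param ... Unused.
#' @return A ggplot object: source x target tiles coloured by `dJ`
#'   (positive = dominant in group 1), crossed where signs are discordant.
#' @exportS3Method ggplot2::autoplot
autoplot.differential_jacobian <- function(object, ...) {
  gn <- attr(object, "group_names")
  d <- object[!object$undefined, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$target,
                                  fill = .data$dJ)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = d[!d$sign_concordant, , drop = FALSE],
                        shape = 4, size = 2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "source metabolite", y = "target metabolite",
                  fill = sprintf("ln |J(%s)| - ln |J(%s)|", gn[1], gn[2])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
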