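#' Stress intensity of a genotype panel
#'
#' Stress intensity quantifies the panel-level relative loss of the trait
#' under stress: `SI = 1 - MYs/MYp`, where `MYp` and `MYs` are the grand
#' means of the trait (here 100-seed weight) over all genotypes under
#' well-watered (WW) and drought (DS) conditions.
#'
#' @param table Data frame with columns `genotype`, `Yp` (mean trait value
#'   per genotype under WW, must be > 0) and `Ys` (mean trait value under
#'   DS, >= 0).
#' @return A single number, the stress intensity `SI` in (0, 1].
#' @examples
#' panel <- tibble::tibble(genotype = c("A", "B", "C"),
#'                         Yp = c(20, 30, 50), Ys = c(10, 27, 40))
#' stress_intensity(panel)  # 0.23
#' @export
stress_intensity <- function(table) {
  validate_yield_table(table)
  si <- 1 - mean(table$Ys) / mean(table$Yp)
  if (si <= 0) {
    stop_bad_arg(
      "no net stress in panel: mean Ys (%.4g) >= mean Yp (%.4g), SI = %.4g <= 0; SSI is undefined",
      mean(table$Ys), mean(table$Yp), si
    )
  }
  si
}

validate_yield_table <- function(table, arg = "table") {
  if (!is.data.frame(table) || !all(c("genotype", "Yp", "Ys") %in% names(table))) {
    stop_bad_arg("`%s` must have columns genotype, Yp, Ys", arg)
  }
  if (nrow(table) < 1L) stop_bad_arg("`%s` has no genotypes", arg)
  if (anyDuplicated(table$genotype)) {
    stop_bad_arg("`%s` has duplicated genotype identifiers", arg)
  }
  bad <- table$genotype[!is.finite(table$Yp) | table$Yp <= 0]
  if (length(bad) > 0L) {
    stop_bad_arg("non-positive Yp for genotype(s): %s", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(table$Ys) | table$Ys < 0)) {
    stop_bad_arg("`%s` has negative or non-finite Ys values", arg)
  }
  invisible(table)
}

#' Stress susceptibility index per genotype
#'
#' Computes the Fischer-Maurer stress susceptibility index for every
#' genotype in a yield panel:
#' `SSI_i = (1 - Ys_i / Yp_i) / SI`, with `SI = 1 - MYs/MYp` the panel
#' stress intensity. `SSI < 1` marks genotypes losing less than the panel
#' average under stress (drought tolerant), `SSI > 1` more than average
#' (susceptible). The `Yp`-weighted mean of SSI over the panel is exactly 1
#' by construction.
#'
#' @inheritParams stress_intensity
#' @return A tibble of class `ssi_result` with columns `genotype`, `Yp`,
#'   `Ys`, `SSI` and `tolerance` (`"tolerant"` if `SSI <= 1` else
#'   `"susceptible"`), carrying the panel summaries `SI`, `MYp`, `MYs` as
#'   attributes (retrieve with [glance()]).
#' @examples
#' panel <- tibble::tibble(genotype = c("A", "B", "C"),
#'                         Yp = c(20, 30, 50), Ys = c(10, 27, 40))
#' compute_ssi(panel)
#' @seealso [classify_quadrants()], [stress_intensity()]
#' @export
compute_ssi <- function(table) {
  si <- stress_intensity(table)
  out <- tibble::as_tibble(table[c("genotype", "Yp", "Ys")])
  out$SSI <- (1 - out$Ys / out$Yp) / si
  out$tolerance <- ifelse(out$SSI <= 1, "tolerant", "susceptible")
  structure(
    out,
    SI = si,
    MYp = mean(table$Yp),
    MYs = mean(table$Ys),
    class = c("ssi_result", class(out))
  )
}

#' @exportS3Method generics::glance
glance.ssi_result <- function(x, ...) {
  tibble::tibble(
    n_genotypes = nrow(x),
    SI = attr(x, "SI"),
    MYp = attr(x, "MYp"),
    MYs = attr(x, "MYs"),
    ssi_min = min(x$SSI),
    ssi_max = max(x$SSI)
  )
}

#' Tolerance/production quadrant classification
#'
#' Places each genotype in the SSI-versus-stressed-trait biplot and assigns
#' one of four quadrants: Q1 tolerant and high-yielding (`SSI <=
#' ssi_threshold`, `Ys >=` trait threshold), Q2 tolerant but low-yielding,
#' Q3 susceptible and low-yielding, Q4 susceptible but high-yielding. A
#' genotype exactly at the SSI threshold falls on the tolerant side; one
#' exactly at the trait threshold on the high-yield side.
#'
#' @param ssi An `ssi_result` from [compute_ssi()] (or any data frame with
#'   `genotype`, `Ys` and `SSI` columns).
#' @param ssi_threshold SSI split between tolerant and susceptible;
#'   default 1 (the panel-average loss).
#' @param trait_threshold_policy How to split the stressed trait axis:
#'   `"median"` (default) or `"mean"` of `Ys` over genotypes, or
#'   `"explicit"` with `trait_threshold` supplied.
#' @param trait_threshold Numeric threshold on `Ys`, required when
#'   `trait_threshold_policy = "explicit"`.
#' @return A tibble of class `quadrant_assignment`: `genotype`, `SSI`,
#'   `Ys`, `quadrant` (factor Q1-Q4), plus the thresholds used as columns
#'   `ssi_threshold` and `trait_threshold`.
#' @examples
#' panel <- tibble::tibble(genotype = paste0("G", 1:4),
#'                         Yp = c(30, 28, 25, 27), Ys = c(28, 20, 12, 25))
#' classify_quadrants(compute_ssi(panel))
#' @export
classify_quadrants <- function(ssi,
                               ssi_threshold = 1.0,
                               trait_threshold_policy = c("median", "mean", "explicit"),
                               trait_threshold = NULL) {
  trait_threshold_policy <- match.arg(trait_threshold_policy)
  if (!is.data.frame(ssi) || !all(c("genotype", "Ys", "SSI") %in% names(ssi))) {
    stop_bad_arg("`ssi` must have columns genotype, Ys, SSI (see compute_ssi())")
  }
  trait_thr <- switch(trait_threshold_policy,
    median = stats::median(ssi$Ys),
    mean = mean(ssi$Ys),
    explicit = {
      if (is.null(trait_threshold) || !is.numeric(trait_threshold)) {
        stop_bad_arg("trait_threshold_policy = \"explicit\" requires a numeric `trait_threshold`")
      }
      trait_threshold
    }
  )
  tolerant <- ssi$SSI <= ssi_threshold
  high <- ssi$Ys >= trait_thr
  quadrant <- dplyr::case_when(
    tolerant & high ~ "Q1",
    tolerant & !high ~ "Q2",
    !tolerant & !high ~ "Q3",
    .default = "Q4"
  )
  out <- tibble::tibble(
    genotype = ssi$genotype,
    SSI = ssi$SSI,
    Ys = ssi$Ys,
    quadrant = factor(quadrant, levels = c("Q1", "Q2", "Q3", "Q4")),
    ssi_threshold = ssi_threshold,
    trait_threshold = trait_thr
  )
  class(out) <- c("quadrant_assignment", class(out))
  out
}

#' Biplot of SSI versus stressed-trait value
#'
#' @param object A `quadrant_assignment` from [classify_quadrants()].
#' @param ... Unused.
#' @return A ggplot object: genotypes as labelled points, threshold lines,
#'   quadrant colouring.
#' @exportS3Method ggplot2::autoplot
autoplot.quadrant_assignment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$SSI, y = .data$Ys,
                                       colour = .data$quadrant)) +
    ggplot2::geom_vline(xintercept = object$ssi_threshold[1], linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$trait_threshold[1], linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype),
                       vjust = -0.7, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Stress susceptibility index (SSI)",
                  y = "Trait under drought (Ys)",
                  colour = "Quadrant") +
    ggplot2::theme_minimal()
}
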