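#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' list. Inputs may be given as file paths (read with the strict readers)
#' or as in-memory data frames.
#'
#' @param abundance Abundance table or path (see [read_abundance_table()]).
#' @param phenotype Yield table or path (see [read_phenotype_table()]).
#' @param network Edge list, [metabolic_network()], or path.
#' @param out_dir Optional output directory; when given, every result
#'   table is written there as TSV plus a JSON run manifest.
#' @param condition,time_point Analysis slice; defaults `"DS"`, `2` (the
#'   drought arm at the mid-pod-filling harvest).
#' @param group1,group2 Genotype groups to contrast in the Jacobian stage:
#'   either a quadrant label (`"Q1"`..`"Q4"`, resolved from the in-run
#'   quadrant classification) or an explicit character vector of genotype
#'   names. Defaults `"Q1"` vs `"Q3"` (tolerant/high-yield vs
#'   susceptible/low-yield).
#' @param n_iter,seed,noise_mode,epsilon_factor,shrinkage Monte-Carlo
#'   Jacobian settings (see [monte_carlo_jacobian()] and
#'   [differential_jacobian()]). `seed` is mandatory.
#' @param metabolites Optional metabolite subset (and ordering) for the
#'   covariance/Jacobian stage; default all metabolite columns.
#' @param log_base,nonpositive_policy Passed to [log_transform()].
#' @param alpha Significance level of the correlation screen.
#' @param ssi_threshold,trait_threshold_policy,trait_threshold Passed to
#'   [classify_quadrants()].
#' @param edge_threshold `|dJ|` cut-off of the final edge report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance, phenotype, network, out_dir = NULL,
                            condition = "DS", time_point = 2,
                            group1 = "Q1", group2 = "Q3",
                            n_iter = 10000, seed, noise_mode = "half_normal",
                            epsilon_factor = 1e-9, shrinkage = 0,
                            metabolites = NULL,
                            log_base = "e", nonpositive_policy = "error",
                            alpha = 0.05,
                            ssi_threshold = 1.0,
                            trait_threshold_policy = "median",
                            trait_threshold = NULL,
                            edge_threshold = 0) {
  if (missing(seed)) stop_bad_arg("`seed` is mandatory: every stochastic stage must be reproducible")
  config <- list(
    abundance = abundance, phenotype = phenotype, network = network,
    out_dir = out_dir, condition = condition, time_point = time_point,
    group1 = group1, group2 = group2,
    n_iter = assert_count(n_iter, "n_iter"),
    seed = assert_count(seed, "seed", min = 0L),
    noise_mode = match.arg(noise_mode, c("half_normal", "normal")),
    epsilon_factor = epsilon_factor,
    shrinkage = assert_proportion(shrinkage, "shrinkage"),
    metabolites = metabolites,
    log_base = match.arg(as.character(log_base), c("e", "10", "2")),
    nonpositive_policy = match.arg(nonpositive_policy, c("error", "offset")),
    alpha = assert_proportion(alpha, "alpha"),
    ssi_threshold = ssi_threshold,
    trait_threshold_policy = match.arg(trait_threshold_policy,
                                       c("median", "mean", "explicit")),
    trait_threshold = trait_threshold,
    edge_threshold = edge_threshold
  )
  structure(config, class = "pipeline_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

resolve_group <- function(spec, quadrants, which_group) {
  if (is.character(spec) && length(spec) == 1L && spec %in% c("Q1", "Q2", "Q3", "Q4")) {
    g <- quadrants$genotype[quadrants$quadrant == spec]
    if (length(g) < 2L) {
      stop_bad_arg("group too small for covariance: quadrant %s has %d genotype(s)",
                   spec, length(g))
    }
    return(as.character(g))
  }
  g <- as.character(spec)
  if (length(g) < 2L) {
    stop_bad_arg("group too small for covariance: %s has %d genotype(s)",
                 which_group, length(g))
  }
  g
}

#' Run the end-to-end drought-tolerance analysis
#'
#' Executes every stage in order: SSI computation, quadrant
#' classification, log transformation, the metabolite-SSI correlation
#' screen, per-group covariance estimation, Monte-Carlo Jacobian
#' inference for both genotype groups (shared seed and noise draws, so
#' the groups differ only through their covariances), the differential
#' Jacobian, and the thresholded edge report. When `out_dir` is set,
#' every result is written as TSV alongside a JSON run manifest
#' (configuration echo, package version, per-stage dimensions, seeds and
#' collected warnings); re-running an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `drought_pipeline`: `ssi`, `quadrants`,
#'   `correlations`, `group1`/`group2` (genotype sets),
#'   `jacobian1`/`jacobian2`, `differential`, `edges`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_bad_arg("`config` must come from pipeline_config()")
  }
  warnings_log <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  abundance <- resolve_input(config$abundance, read_abundance_table)
  phenotype <- resolve_input(config$phenotype, read_phenotype_table)
  network <- resolve_input(config$network, read_network)
  assert_metabolite_matrix(abundance, "abundance")
  if (!is.data.frame(network) || !all(c("source", "target") %in% names(network))) {
    stop_bad_arg("`network` must be an edge list with columns source, target")
  }

  slice_n <- sum(abundance$condition == config$condition &
                   abundance$time_point == config$time_point)
  if (slice_n == 0L) {
    stop_bad_arg("no observations for condition %s at time point %s",
                 config$condition, as.character(config$time_point))
  }

  mets <- config$metabolites %||% metabolite_columns(abundance)
  unmatched <- setdiff(unique(c(network$source, network$target)), mets)
  if (length(unmatched) > 0L) {
    stop_bad_arg("network node(s) not present among abundance metabolites: %s",
                 paste(unmatched, collapse = ", "))
  }

  ssi <- compute_ssi(phenotype)
  quadrants <- classify_quadrants(
    ssi, ssi_threshold = config$ssi_threshold,
    trait_threshold_policy = config$trait_threshold_policy,
    trait_threshold = config$trait_threshold
  )
  logm <- log_transform(abundance, base = config$log_base,
                        nonpositive_policy = config$nonpositive_policy)
  correlations <- collect(correlate_to_ssi(
    logm, ssi, condition = config$condition, time_point = config$time_point,
    alpha = config$alpha
  ))

  g1 <- resolve_group(config$group1, quadrants, "group1")
  g2 <- resolve_group(config$group2, quadrants, "group2")
  mask <- collect(jacobian_mask(network, nodes = mets))
  C1 <- collect(estimate_covariance(logm, genotypes = g1,
                                    condition = config$condition,
                                    time_point = config$time_point,
                                    metabolites = mets))
  C2 <- collect(estimate_covariance(logm, genotypes = g2,
                                    condition = config$condition,
                                    time_point = config$time_point,
                                    metabolites = mets))
  J1 <- monte_carlo_jacobian(C1, mask, n_iter = config$n_iter,
                             seed = config$seed,
                             noise_mode = config$noise_mode,
                             shrinkage = config$shrinkage)
  J2 <- monte_carlo_jacobian(C2, mask, n_iter = config$n_iter,
                             seed = config$seed,
                             noise_mode = config$noise_mode,
                             shrinkage = config$shrinkage)
  group_names <- c(
    if (is.character(config$group1) && length(config$group1) == 1L) config$group1 else "group1",
    if (is.character(config$group2) && length(config$group2) == 1L) config$group2 else "group2"
  )
  if (anyDuplicated(group_names)) group_names <- c("group1", "group2")
  differential <- differential_jacobian(J1, J2, group_names = group_names,
                                        epsilon_factor = config$epsilon_factor)
  edges <- classify_edges(differential, threshold = config$edge_threshold)

  manifest <- list(
    package_version = as.character(utils::packageVersion("droughtjac")),
    condition = config$condition, time_point = config$time_point,
    seed = config$seed, n_iter = config$n_iter,
    noise_mode = config$noise_mode, shrinkage = config$shrinkage,
    log_base = config$log_base, alpha = config$alpha,
    ssi_threshold = config$ssi_threshold,
    trait_threshold_policy = config$trait_threshold_policy,
    edge_threshold = config$edge_threshold,
    stages = list(
      n_observations = nrow(abundance),
      n_slice_observations = slice_n,
      n_metabolites = length(mets),
      n_genotypes = nrow(ssi),
      n_group1 = length(g1), n_group2 = length(g2),
      n_network_edges = nrow(network),
      n_mask_free = sum(mask),
      rank_deficiency_group1 = J1$rank_deficiency,
      rank_deficiency_group2 = J2$rank_deficiency,
      n_correlations = nrow(correlations),
      n_edges_reported = nrow(edges)
    ),
    groups = stats::setNames(list(g1, g2), group_names),
    warnings = warnings_log
  )

  result <- structure(
    list(ssi = ssi, quadrants = quadrants, correlations = correlations,
         group1 = g1, group2 = g2, jacobian1 = J1, jacobian2 = J2,
         differential = differential, edges = edges, manifest = manifest),
    class = "drought_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, name))
  }
  w(result$ssi, "ssi.tsv")
  w(result$quadrants, "quadrants.tsv")
  w(result$correlations, "correlations.tsv")
  w(tidy(result$jacobian1), "jacobian_group1.tsv")
  w(tidy(result$jacobian2), "jacobian_group2.tsv")
  w(result$differential, "differential_jacobian.tsv")
  w(result$edges, "differential_edges.tsv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.drought_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "drought-tolerance pipeline run (seed %d)\n  %d genotypes, %d metabolites, slice %s/t%s (%d obs)\n  groups: %s (n=%d) vs %s (n=%d); %d free Jacobian entries\n  %d differential edges reported\n",
    m$seed, m$stages$n_genotypes, m$stages$n_metabolites, m$condition,
    as.character(m$time_point), m$stages$n_slice_observations,
    names(m$groups)[1], m$stages$n_group1, names(m$groups)[2],
    m$stages$n_group2, m$stages$n_mask_free, m$stages$n_edges_reported
  ))
  invisible(x)
}
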