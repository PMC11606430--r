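# Seeded generators for every input the pipeline consumes, each with a
# known ground truth so parameter recovery can be asserted: stable
# Jacobians on toy networks (with their exact stationary covariance),
# stationary log-normal abundance draws, yield panels with planted
# tolerant/susceptible classes, and metabolite columns with a planted
# correlation to SSI.

#' Generate a toy metabolic network with a known stable Jacobian
#'
#' Builds a directed network on nodes `M1..Mn` (chain, ring, or
#' Erdos-Renyi random), draws a ground-truth Jacobian supported on the
#' network mask, and computes its exact stationary covariance by the
#' forward Lyapunov solve. Off-diagonal entries get magnitudes uniform in
#' `[0.3, 1]` with random signs; each diagonal entry is set negative with
#' magnitude exceeding its row's off-diagonal absolute sum (strict
#' diagonal dominance), which places all Gershgorin discs in the left
#' half-plane and so guarantees a Hurwitz matrix. Fluctuation intensities
#' `D` are uniform in `[0.5, 1.5]`.
#'
#' @param n_nodes Number of metabolites (>= 1).
#' @param topology `"chain"` (M1 -> M2 -> ...), `"ring"` (chain plus
#'   Mn -> M1) or `"random"`.
#' @param edge_prob Edge probability for `topology = "random"`; ignored
#'   otherwise.
#' @param seed Integer seed.
#' @return A list of class `ground_truth_system`: `network`
#'   ([metabolic_network()]), `mask`, `J_true`, `D_true` (diagonal
#'   matrix), `C_true`.
#' @examples
#' sys <- make_toy_network(4, "ring", seed = 1)
#' max(Re(eigen(sys$J_true)$values)) < 0
#' @export
make_toy_network <- function(n_nodes, topology = c("chain", "ring", "random"),
                             edge_prob = 0.3, seed = 1) {
  n_nodes <- assert_count(n_nodes, "n_nodes")
  topology <- match.arg(topology)
  edge_prob <- assert_proportion(edge_prob, "edge_prob")
  seed <- assert_count(seed, "seed", min = 0L)
  nodes <- paste0("M", seq_len(n_nodes))

  withr::with_seed(seed, {
    edges <- switch(topology,
      chain = if (n_nodes > 1L) {
        tibble::tibble(source = nodes[-n_nodes], target = nodes[-1L])
      } else {
        tibble::tibble(source = character(), target = character())
      },
      ring = if (n_nodes > 1L) {
        tibble::tibble(source = nodes, target = nodes[c(2:n_nodes, 1L)])
      } else {
        tibble::tibble(source = character(), target = character())
      },
      random = {
        pairs <- expand.grid(source = nodes, target = nodes,
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
        keep <- runif(nrow(pairs)) < edge_prob
        tibble::as_tibble(pairs[keep, , drop = FALSE])
      }
    )
    network <- metabolic_network(edges, nodes = nodes)
    mask <- suppressWarnings(jacobian_mask(network, nodes = nodes))

    J <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
    off <- which(mask & !diag(TRUE, n_nodes))
    if (length(off) > 0L) {
      J[off] <- runif(length(off), 0.3, 1) * sample(c(-1, 1), length(off),
                                                    replace = TRUE)
    }
    diag(J) <- 0
    diag(J) <- -(rowSums(abs(J)) + runif(n_nodes, 0.5, 1.5))
    D <- diag(runif(n_nodes, 0.5, 1.5), n_nodes)
    dimnames(D) <- list(nodes, nodes)

    structure(
      list(network = network, mask = mask, J_true = J, D_true = D,
           C_true = forward_lyapunov(J, D)),
      class = "ground_truth_system"
    )
  })
}

#' Simulate stationary metabolite abundances from a ground-truth system
#'
#' Draws independent samples of the stationary state of the system's
#' Ornstein-Uhlenbeck dynamics: multivariate normal with mean zero and
#' covariance `C_true` on the log scale, exponentiated element-wise to
#' positive abundances. The pipeline's log transform therefore exactly
#' recovers the Gaussian layer, and the sample covariance of the log
#' abundances converges to `C_true`.
#'
#' @param system A `ground_truth_system` from [make_toy_network()].
#' @param n_samples Number of observations (>= 2).
#' @param seed Integer seed.
#' @param genotype,condition,time_point Metadata values stamped on the
#'   generated observations (a single synthetic group by default).
#' @return An abundance tibble: metadata columns plus one positive column
#'   per network node.
#' @export
simulate_abundances <- function(system, n_samples, seed = 1,
                                genotype = "SYN", condition = "DS",
                                time_point = 2) {
  if (!inherits(system, "ground_truth_system")) {
    stop_bad_arg("`system` must come from make_toy_network()")
  }
  n_samples <- assert_count(n_samples, "n_samples", min = 2L)
  seed <- assert_count(seed, "seed", min = 0L)
  C <- unclass(system$C_true)
  attr(C, "n_samples") <- NULL
  ev <- eigen(symmetrize(C), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_bad_arg("unstable system: C_true is not positive definite")
  }
  X <- withr::with_seed(seed, {
    MASS::mvrnorm(n_samples, mu = rep(0, nrow(C)), Sigma = C)
  })
  X <- matrix(X, nrow = n_samples)
  colnames(X) <- rownames(C)
  dplyr::bind_cols(
    tibble::tibble(genotype = genotype, replicate = seq_len(n_samples),
                   condition = condition, time_point = time_point),
    tibble::as_tibble(exp(X))
  )
}

#' Specification of a synthetic genotype yield panel
#'
#' Bundles the design of a two-class (tolerant/susceptible) yield panel:
#' how many genotypes and replicates, what fraction is tolerant, the mean
#' relative yield loss of each class under drought, and the coefficient of
#' variation of multiplicative noise on the stressed yield.
#'
#' @param n_genotypes Number of genotypes; default 36.
#' @param n_replicates Replicates per genotype (>= 1); default 3.
#' @param tolerant_fraction Fraction of genotypes in the tolerant class;
#'   default 0.5.
#' @param loss_tolerant,loss_susceptible Mean relative loss of the trait
#'   under drought for each class, in `[0, 1)` with
#'   `loss_tolerant < loss_susceptible`; defaults 0.1 and 0.5.
#' @param cv_noise Coefficient of variation of the multiplicative noise on
#'   `Ys`; default 0.05.
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_genotypes = 36, n_replicates = 3,
                       tolerant_fraction = 0.5, loss_tolerant = 0.1,
                       loss_susceptible = 0.5, cv_noise = 0.05, seed = 1) {
  spec <- list(
    n_genotypes = assert_count(n_genotypes, "n_genotypes"),
    n_replicates = assert_count(n_replicates, "n_replicates"),
    tolerant_fraction = assert_proportion(tolerant_fraction, "tolerant_fraction"),
    loss_tolerant = assert_proportion(loss_tolerant, "loss_tolerant"),
    loss_susceptible = assert_proportion(loss_susceptible, "loss_susceptible"),
    cv_noise = assert_proportion(cv_noise, "cv_noise", hi = Inf),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (spec$loss_tolerant >= spec$loss_susceptible) {
    stop_bad_arg("loss_tolerant must be smaller than loss_susceptible")
  }
  if (spec$loss_susceptible >= 1) {
    stop_bad_arg("class losses must be < 1")
  }
  structure(spec, class = "panel_spec")
}

#' Generate a yield panel with planted tolerance classes
#'
#' Draws per-genotype well-watered 100-seed weights `Yp` from a log-normal
#' baseline (median 25 g, typical for desi chickpea), assigns each
#' genotype a tolerance class, and sets the drought value
#' `Ys = Yp * (1 - class loss) * noise` with multiplicative Gaussian noise
#' of the requested coefficient of variation (truncated above zero). With
#' `cv_noise = 0` the construction is exact, so tolerant genotypes have
#' `Ys/Yp = 1 - loss_tolerant` precisely.
#'
#' @param spec A [panel_spec()].
#' @return A tibble: `genotype` (`G1..Gn`), `Yp`, `Ys`, `class`
#'   (planted label, for recovery tests).
#' @export
generate_yield_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) stop_bad_arg("`spec` must come from panel_spec()")
  n <- spec$n_genotypes
  n_tol <- round(n * spec$tolerant_fraction)
  if (n_tol == 0L || n_tol == n) {
    rlang::warn("tolerant_fraction rounds to an empty class; proceeding with a one-class panel")
  }
  withr::with_seed(spec$seed, {
    cls <- sample(rep(c("tolerant", "susceptible"), c(n_tol, n - n_tol)))
    Yp <- rlnorm(n, meanlog = log(25), sdlog = 0.2)
    loss <- ifelse(cls == "tolerant", spec$loss_tolerant, spec$loss_susceptible)
    noise <- if (spec$cv_noise > 0) pmax(1 + rnorm(n, 0, spec$cv_noise), 0.05) else 1
    tibble::tibble(
      genotype = paste0("G", seq_len(n)),
      Yp = Yp,
      Ys = Yp * (1 - loss) * noise,
      class = cls
    )
  })
}

#' Generate a metabolome with a planted correlation to SSI
#'
#' Constructs an abundance table whose first metabolite has a planted
#' population Pearson correlation `rho` between its log value and the
#' genotype SSI: per observation,
#' `log x = rho * z + sqrt(1 - rho^2) * eps`, where `z` is the genotype's
#' standardized SSI (replicates inherit their genotype's value) and `eps`
#' is standard normal. Optional filler metabolites are uncorrelated
#' log-normal noise, giving the correlation screen a null background.
#'
#' @param ssi An `ssi_result` (or data frame with `genotype` and `SSI`),
#'   >= 3 genotypes, non-constant SSI.
#' @param rho Target correlation in `[-1, 1]`.
#' @param n_replicates Replicates per genotype.
#' @param seed Integer seed.
#' @param n_filler Number of uncorrelated filler metabolites; default 0.
#' @param condition,time_point Metadata stamped on the observations.
#' @return An abundance tibble with metabolite columns `met_ssi` and
#'   `filler1..fillerK`.
#' @export
generate_ssi_correlated_metabolome <- function(ssi, rho, n_replicates = 3,
                                               seed = 1, n_filler = 0,
                                               condition = "DS", time_point = 2) {
  if (!is.data.frame(ssi) || !all(c("genotype", "SSI") %in% names(ssi))) {
    stop_bad_arg("`ssi` must have columns genotype and SSI")
  }
  if (nrow(ssi) < 3L) stop_bad_arg("need at least 3 genotypes")
  if (abs(rho) > 1) stop_bad_arg("`rho` must be in [-1, 1]")
  n_replicates <- assert_count(n_replicates, "n_replicates")
  n_filler <- assert_count(n_filler, "n_filler", min = 0L)
  seed <- assert_count(seed, "seed", min = 0L)
  if (sd(ssi$SSI) == 0) stop_bad_arg("degenerate phenotype: SSI is constant across genotypes")

  z <- as.numeric(scale(ssi$SSI))
  obs <- tidyr::expand_grid(genotype = ssi$genotype,
                            replicate = seq_len(n_replicates))
  zobs <- z[match(obs$genotype, ssi$genotype)]
  n_obs <- nrow(obs)
  withr::with_seed(seed, {
    eps <- rnorm(n_obs)
    logx <- rho * zobs + sqrt(1 - rho^2) * eps
    out <- dplyr::bind_cols(
      tibble::tibble(genotype = obs$genotype, replicate = obs$replicate,
                     condition = condition, time_point = time_point),
      tibble::tibble(met_ssi = exp(logx))
    )
    if (n_filler > 0L) {
      fill <- matrix(exp(rnorm(n_obs * n_filler)), n_obs, n_filler,
                     dimnames = list(NULL, paste0("filler", seq_len(n_filler))))
      out <- dplyr::bind_cols(out, tibble::as_tibble(fill))
    }
    out
  })
}
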