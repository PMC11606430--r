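test_that("generated systems satisfy the Lyapunov identity and are Hurwitz", {
  cases <- expand.grid(n = c(1, 3, 6, 10), topo = c("chain", "ring", "random"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    sys <- make_toy_network(cases$n[i], cases$topo[i], edge_prob = 0.3,
                            seed = 100 + i)
    resid <- sys$J_true %*% sys$C_true + sys$C_true %*% t(sys$J_true) +
      2 * sys$D_true
    expect_lt(max(abs(resid)), 1e-10)
    expect_lt(max(Re(eigen(sys$J_true, only.values = TRUE)$values)), 0)
    # entries confined to mask + diagonal
    expect_true(all(sys$J_true[!sys$mask] == 0))
  }
})

test_that("a one-node system solves the scalar Lyapunov relation", {
  sys <- make_toy_network(1, "chain", seed = 5)
  a <- -sys$J_true[1, 1]
  expect_gt(a, 0)
  expect_equal(sys$C_true[1, 1], sys$D_true[1, 1] / a)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(make_toy_network(5, "random", 0.4, seed = 9),
                   make_toy_network(5, "random", 0.4, seed = 9))
  sys <- make_toy_network(4, "ring", seed = 2)
  expect_identical(simulate_abundances(sys, 20, seed = 3),
                   simulate_abundances(sys, 20, seed = 3))
  spec <- panel_spec(seed = 4)
  expect_identical(generate_yield_panel(spec), generate_yield_panel(spec))
  ssi <- compute_ssi(generate_yield_panel(spec))
  expect_identical(
    generate_ssi_correlated_metabolome(ssi, 0.5, seed = 6),
    generate_ssi_correlated_metabolome(ssi, 0.5, seed = 6)
  )
})

test_that("random-topology systems at moderate edge density stay stable", {
  sys <- make_toy_network(6, "random", edge_prob = 0.3, seed = 7)
  expect_lt(max(Re(eigen(sys$J_true, only.values = TRUE)$values)), 0)
})

test_that("sample covariance of simulated log abundances converges to C_true", {
  sys <- identity_system(4)
  for (n in c(1e3, 1e5)) {
    ab <- simulate_abundances(sys, n, seed = 8)
    X <- log(as.matrix(ab[, paste0("M", 1:4)]))
    Chat <- stats::cov(X)
    # sampling error of a covariance entry is ~ sqrt(2/n) at unit variance
    expect_lt(max(abs(Chat - diag(4))), 5 * sqrt(2 / n))
  }
  # absolute check at large n
  ab <- simulate_abundances(sys, 1e5, seed = 8)
  Chat <- stats::cov(log(as.matrix(ab[, paste0("M", 1:4)])))
  expect_lt(max(abs(Chat - diag(4))), 0.05)
})

test_that("simulate_abundances validates its inputs", {
  sys <- make_toy_network(3, "chain", seed = 1)
  expect_error(simulate_abundances(sys, 1), "n_samples")
  ab <- simulate_abundances(sys, 2, seed = 1)
  expect_equal(nrow(ab), 2)
  expect_true(all(as.matrix(ab[, paste0("M", 1:3)]) > 0))
  broken <- sys
  broken$C_true <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3,
                          dimnames = dimnames(sys$C_true))  # indefinite
  expect_error(simulate_abundances(broken, 10, seed = 1), "unstable system")
})

test_that("noiseless yield panels reproduce class losses exactly", {
  spec <- panel_spec(n_genotypes = 10, tolerant_fraction = 0.5,
                     loss_tolerant = 0.1, loss_susceptible = 0.5,
                     cv_noise = 0, seed = 3)
  panel <- generate_yield_panel(spec)
  tol <- panel$class == "tolerant"
  expect_equal(panel$Ys[tol] / panel$Yp[tol], rep(0.9, sum(tol)))
  expect_equal(panel$Ys[!tol] / panel$Yp[!tol], rep(0.5, sum(!tol)))
})

test_that("degenerate panel fractions warn but proceed", {
  spec <- panel_spec(n_genotypes = 5, tolerant_fraction = 0.01,
                     loss_tolerant = 0.1, loss_susceptible = 0.5, seed = 2)
  expect_warning(panel <- generate_yield_panel(spec), "one-class")
  expect_equal(nrow(panel), 5)
})

test_that("a planted SSI-correlated metabolome has the designed correlation", {
  ssi <- compute_ssi(generate_yield_panel(panel_spec(seed = 10)))
  # rho = 1: noise weight zero, correlation exactly 1 on the log scale
  met <- generate_ssi_correlated_metabolome(ssi, rho = 1, n_replicates = 3,
                                            seed = 1)
  z <- ssi$SSI[match(met$genotype, ssi$genotype)]
  expect_equal(cor(log(met$met_ssi), z), 1)
  # rho = 0.5: Monte-Carlo mean of the sample correlation over 200 seeds
  rs <- vapply(1:200, function(s) {
    m <- generate_ssi_correlated_metabolome(ssi, rho = 0.5, n_replicates = 3,
                                            seed = s)
    cor(log(m$met_ssi), ssi$SSI[match(m$genotype, ssi$genotype)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.05)
  # rho = 0: the null |r| distribution at n = 108 concentrates near zero
  # (sampling sd ~ 1/sqrt(107) ~ 0.097); check its 90th percentile
  r0 <- vapply(201:300, function(s) {
    m <- generate_ssi_correlated_metabolome(ssi, rho = 0, n_replicates = 3,
                                            seed = s)
    cor(log(m$met_ssi), ssi$SSI[match(m$genotype, ssi$genotype)])
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)
  expect_lt(quantile(abs(r0), 0.9), 0.2)
})

test_that("SSI-correlated generator rejects degenerate phenotypes", {
  flat <- tibble::tibble(genotype = c("A", "B", "C"), SSI = c(1, 1, 1))
  expect_error(generate_ssi_correlated_metabolome(flat, 0.5), "degenerate phenotype")
  two <- tibble::tibble(genotype = c("A", "B"), SSI = c(0.5, 1.5))
  expect_error(generate_ssi_correlated_metabolome(two, 0.5), "3 genotypes")
})
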