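test_that("noise matrices are strictly diagonal and reproducible", {
  D <- withr::with_seed(1, draw_noise_matrix(6))
  expect_true(all(D[upper.tri(D) | lower.tri(D)] == 0))
  expect_true(all(diag(D) >= 0))
  expect_identical(withr::with_seed(2, draw_noise_matrix(4)),
                   withr::with_seed(2, draw_noise_matrix(4)))
  Dn <- withr::with_seed(3, draw_noise_matrix(4, mode = "normal"))
  expect_identical(abs(diag(Dn)),
                   diag(withr::with_seed(3, draw_noise_matrix(4))))
})

test_that("half-normal diagonal entries have the analytic mean sqrt(2/pi)", {
  d <- withr::with_seed(5, replicate(200, diag(draw_noise_matrix(500))))
  expect_lt(abs(mean(d) - sqrt(2 / pi)), 0.01)
})

test_that("a single-iteration ensemble equals one explicit solve", {
  sys <- make_toy_network(5, "ring", seed = 6)
  est <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 1, seed = 77)
  D1 <- withr::with_seed(77, draw_noise_matrix(5))
  sol <- solve_inverse_jacobian(sys$C_true, D1, sys$mask)
  expect_equal(est$median, sol$J, tolerance = 1e-12)
  expect_equal(est$iqr, 0 * sol$J, ignore_attr = TRUE)
})

test_that("the vectorized ensemble equals a literal per-iteration loop", {
  sys <- make_toy_network(4, "random", edge_prob = 0.5, seed = 8)
  n_iter <- 50
  est <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = n_iter, seed = 9)
  draws <- withr::with_seed(9, {
    Z <- abs(matrix(rnorm(4 * n_iter), 4, n_iter))
    lapply(seq_len(n_iter), function(i) {
      solve_inverse_jacobian(sys$C_true, diag(Z[, i], 4), sys$mask)$J
    })
  })
  free <- which(sys$mask)
  med_oracle <- apply(vapply(draws, function(J) J[free],
                             numeric(length(free))), 1L, median)
  expect_equal(est$median[free], med_oracle, tolerance = 1e-10)
})

test_that("seeded ensembles are identical and seeds matter", {
  sys <- make_toy_network(4, "chain", seed = 3)
  e1 <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 100, seed = 11)
  e2 <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 100, seed = 11)
  expect_identical(e1$median, e2$median)
  expect_identical(e1$iqr, e2$iqr)
  e3 <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 100, seed = 12)
  expect_false(identical(e1$median, e3$median))
})

test_that("scaling the covariance by alpha scales median estimates by 1/alpha", {
  sys <- make_toy_network(4, "random", edge_prob = 0.5, seed = 14)
  alpha <- 3.7
  e1 <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 200, seed = 15)
  e2 <- monte_carlo_jacobian(alpha * sys$C_true, sys$mask, n_iter = 200, seed = 15)
  expect_equal(e2$median, e1$median / alpha, tolerance = 1e-8)
})

test_that("group covariance matches the two-pass textbook formula", {
  m <- tibble::tibble(genotype = c("A", "A", "B"), replicate = c(1L, 2L, 1L),
                      condition = "DS", time_point = 2L,
                      x = c(1, 2, 4), y = c(0, 1, -1))
  C <- estimate_covariance(m)
  two_pass <- function(a, b) sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1)
  expect_equal(C["x", "y"], two_pass(c(1, 2, 4), c(0, 1, -1)))
  expect_equal(C["x", "x"], two_pass(c(1, 2, 4), c(1, 2, 4)))
  expect_equal(attr(C, "n_samples"), 3L)
  # duplicated variable: rank-1 block with all four entries equal
  m2 <- dplyr::mutate(m, y = x)
  C2 <- estimate_covariance(m2)
  expect_equal(max(C2) - min(C2), 0)
})

test_that("covariance estimation converges to C_true on simulated data", {
  sys <- make_toy_network(4, "ring", seed = 19)
  ab <- simulate_abundances(sys, 1e5, seed = 20)
  C <- estimate_covariance(log_transform(ab))
  expect_lt(max(abs(C - sys$C_true)) / max(abs(sys$C_true)), 0.05)
})

test_that("covariance slice validation: too few observations, missing values", {
  m <- tibble::tibble(genotype = "A", replicate = 1L, condition = "DS",
                      time_point = 2L, x = 1, y = 2)
  expect_error(estimate_covariance(m), "fewer than 2")
  m3 <- tibble::tibble(genotype = c("A", "A", "B"), replicate = c(1L, 2L, 1L),
                       condition = "DS", time_point = 2L,
                       x = c(1, 2, 4), y = c(0, NA, -1))
  expect_warning(C <- estimate_covariance(m3), "y")
  expect_equal(colnames(C), "x")
})

test_that("differential Jacobian recovers hand-computed log-ratios and antisymmetry", {
  sys <- make_toy_network(4, "ring", seed = 22)
  e1 <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 50, seed = 23)
  # identical groups: all dJ exactly 0 and concordant
  d0 <- differential_jacobian(e1, e1)
  expect_true(all(d0$dJ[!d0$undefined] == 0))
  expect_true(all(d0$sign_concordant[!d0$undefined]))
  # doubling every entry of group 1: dJ = ln 2 everywhere defined
  e2 <- e1
  e2$median <- 2 * e1$median
  d2 <- differential_jacobian(e2, e1, group_names = c("hi", "lo"))
  expect_equal(d2$dJ[!d2$undefined],
               rep(log(2), sum(!d2$undefined)))
  expect_true(all(d2$dominant_group[!d2$undefined] == "hi"))
  # swapping groups negates every entry, flags included
  d21 <- differential_jacobian(e1, e2)
  expect_equal(d21$dJ, -d2$dJ)
  expect_identical(d21$undefined, d2$undefined)
  # opposite signs are reported as discordant, not as a complex log
  e3 <- e1
  e3$median <- -e1$median
  d3 <- differential_jacobian(e3, e1)
  expect_true(all(!d3$sign_concordant[!d3$undefined]))
  expect_true(all(is.na(d3$mode[!d3$undefined])))
  expect_error(differential_jacobian(e1, monte_carlo_jacobian(
    sys$C_true[1:3, 1:3], sys$mask[1:3, 1:3], n_iter = 10, seed = 1
  )), "mask")
})

test_that("the entry pair (2, 1) gives dJ = ln 2 toward group 1", {
  est <- function(v) {
    m <- matrix(v, 1, 1, dimnames = list("M1", "M1"))
    structure(list(median = m, iqr = 0 * m,
                   mask = matrix(TRUE, 1, 1, dimnames = dimnames(m)),
                   n_iter = 1L, seed = 1L),
              class = "jacobian_estimate")
  }
  d <- differential_jacobian(est(2), est(1), group_names = c("Q1", "Q3"))
  expect_equal(d$dJ, log(2))
  expect_equal(d$dominant_group, "Q1")
})

test_that("edge classification reports exactly the edges above threshold", {
  ps <- planted_differential_system(seed = 42)
  e1 <- monte_carlo_jacobian(ps$C1, ps$mask, n_iter = 200, seed = 5)
  e2 <- monte_carlo_jacobian(ps$C2, ps$mask, n_iter = 200, seed = 5)
  d <- differential_jacobian(e1, e2, group_names = c("Q1", "Q3"))
  all_edges <- classify_edges(d, threshold = 0)
  expect_equal(nrow(all_edges), sum(!d$undefined))
  expect_equal(nrow(classify_edges(d, threshold = max(abs(d$dJ), na.rm = TRUE) + 1)), 0)
  expect_error(classify_edges(d, threshold = -1), "non-negative")
})

test_that("planted differential edges dominate the report near ln 2", {
  ps <- planted_differential_system(seed = 42)
  e1 <- monte_carlo_jacobian(ps$C1, ps$mask, n_iter = 200, seed = 5)
  e2 <- monte_carlo_jacobian(ps$C2, ps$mask, n_iter = 200, seed = 5)
  d <- differential_jacobian(e1, e2, group_names = c("Q1", "Q3"))
  n <- nrow(ps$mask)
  planted_keys <- paste(((ps$planted - 1) %% n) + 1, ((ps$planted - 1) %/% n) + 1)
  d_keys <- paste(match(d$target, rownames(ps$C1)), match(d$source, rownames(ps$C1)))
  on_planted <- d$dJ[match(planted_keys, d_keys)]
  # the headline sign-recovery property: >= k - 1 of the k planted edges
  expect_gte(sum(on_planted > 0, na.rm = TRUE), 2)
  # and near-ln-2 threshold keeps mostly the planted edges at the top
  top <- classify_edges(d, threshold = log(2) * 0.8)
  expect_gte(sum(paste(match(top$target, rownames(ps$C1)),
                       match(top$source, rownames(ps$C1))) %in% planted_keys), 2)
})
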