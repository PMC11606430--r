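# Core inverse-modelling machinery: the Lyapunov equation
#   J C + C J' = -2 D
# links the Jacobian J of a linearized stochastic metabolic system to the
# stationary covariance C of (log) metabolite levels and the diagonal
# fluctuation matrix D. The forward direction (J, D -> C) powers the
# simulator and the test oracle; the inverse direction (C, D -> J), under
# a network sparsity constraint, is the estimator.

#' Stationary covariance of a stable linear stochastic system
#'
#' Solves the forward Lyapunov equation `J C + C J' = -2 D` for the unique
#' stationary covariance `C`, given a Hurwitz Jacobian `J` (all eigenvalue
#' real parts negative) and a diagonal fluctuation matrix `D`. This is the
#' covariance of the stationary Ornstein-Uhlenbeck process
#' `dx = J x dt + sqrt(2 D) dW`.
#'
#' @param J Square numeric matrix, Hurwitz.
#' @param D Diagonal non-negative matrix (or a vector of diagonal
#'   entries) of fluctuation intensities.
#' @return Symmetric positive semi-definite matrix `C` with the dimnames
#'   of `J`.
#' @examples
#' forward_lyapunov(-diag(2), diag(2))  # identity
#' @export
forward_lyapunov <- function(J, D) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (ncol(J) != n) stop_bad_arg("`J` must be square")
  if (is.vector(D) || (is.matrix(D) && length(D) == 1 && n == 1)) D <- diag(as.numeric(D), n)
  D <- as.matrix(D)
  if (!all(dim(D) == n)) stop_bad_arg("`D` must match the dimension of `J`")
  if (!is_hurwitz(J)) {
    stop_bad_arg("no stationary covariance: `J` has an eigenvalue with non-negative real part")
  }
  # vec(J C + C J') = (I (x) J + J (x) I) vec(C)
  A <- diag(n) %x% J + J %x% diag(n)
  C <- matrix(solve(A, -2 * as.vector(D)), n, n)
  C <- symmetrize(C)
  dimnames(C) <- dimnames(J)
  attr(C, "n_samples") <- NA_integer_
  C
}

#' Draw a random diagonal noise matrix
#'
#' The inverse Lyapunov estimator averages over arbitrary fluctuation
#' matrices: each draw is diagonal with off-diagonal entries exactly zero.
#' By default the diagonal entries are absolute values of standard-normal
#' draws (half-normal), so they are valid non-negative fluctuation
#' intensities; `mode = "normal"` keeps the signed draws for literal
#' replication of signed-normal protocols (note that with signed draws the
#' solutions for `+D` and `-D` are negatives of each other, so their
#' Monte-Carlo median collapses towards zero).
#'
#' @param n Dimension (number of metabolites).
#' @param mode `"half_normal"` (default) or `"normal"`.
#' @return An `n x n` diagonal matrix.
#' @export
draw_noise_matrix <- function(n, mode = c("half_normal", "normal")) {
  n <- assert_count(n, "n")
  mode <- match.arg(mode)
  z <- rnorm(n)
  if (mode == "half_normal") z <- abs(z)
  diag(z, n)
}

# Assemble the least-squares system of the masked inverse Lyapunov
# problem. Unknowns are the masked entries of J (column-major order of
# which(mask)); one equation per unordered pair (p <= q):
#   sum_k J[p,k] C[k,q] + sum_k J[q,k] C[k,p] = -2 D[p,q].
# Returns the design matrix plus the (p, q) index of every equation.
lyapunov_design <- function(C, mask) {
  n <- nrow(C)
  free <- which(mask)
  ui <- ((free - 1L) %% n) + 1L   # row of each unknown
  uj <- ((free - 1L) %/% n) + 1L  # column of each unknown
  pq <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  neq <- nrow(pq)
  A <- matrix(0, neq, length(free))
  for (e in seq_len(neq)) {
    p <- pq[e, 1L]; q <- pq[e, 2L]
    A[e, ] <- (ui == p) * C[cbind(uj, rep(q, length(uj)))] +
      (ui == q) * C[cbind(uj, rep(p, length(uj)))]
  }
  list(A = A, free = free, ui = ui, uj = uj, p = pq[, 1L], q = pq[, 2L])
}

# Minimum-norm least-squares via SVD, reporting the numerical rank.
svd_min_norm <- function(A, tol_factor = max(dim(A))) {
  sv <- svd(A)
  tol <- tol_factor * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  pinv <- if (rank == 0L) {
    matrix(0, ncol(A), nrow(A))
  } else {
    sv$v[, seq_len(rank), drop = FALSE] %*%
      (t(sv$u[, seq_len(rank), drop = FALSE]) / sv$d[seq_len(rank)])
  }
  list(pinv = pinv, rank = rank)
}

#' Solve the inverse Lyapunov problem for a masked Jacobian
#'
#' Given a covariance matrix `C` of log abundances, a diagonal noise
#' matrix `D` and a structural mask of allowed Jacobian entries, solves
#' `J C + C J' = -2 D` for `J` in the least-squares sense over the free
#' (masked) entries: `n(n+1)/2` equations (one per unordered index pair)
#' in `sum(mask)` unknowns. When the system is rank-deficient — the usual
#' case when `C` is estimated from fewer samples than variables — the
#' minimum-norm solution is returned and the number of unresolved degrees
#' of freedom is reported.
#'
#' @param C Symmetric covariance matrix (possibly singular).
#' @param D Diagonal noise matrix (or vector of diagonal entries).
#' @param mask Logical square matrix from [jacobian_mask()]; diagonal must
#'   be `TRUE`. Default: all entries free.
#' @return A list of class `jacobian_solution`: `J` (zero off-mask),
#'   `residual_norm` (Frobenius norm of `J C + C J' + 2 D`),
#'   `rank_deficiency` (free entries minus numerical rank), `rank`.
#' @examples
#' solve_inverse_jacobian(matrix(0.5), matrix(1))  # J = -2
#' @export
solve_inverse_jacobian <- function(C, D, mask = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (ncol(C) != n) stop_bad_arg("`C` must be square")
  if (max_abs(C - t(C)) > 1e-8 * max(1, max_abs(C))) {
    stop_bad_arg("`C` must be symmetric")
  }
  if (all(C == 0)) stop_bad_arg("degenerate covariance: `C` is identically zero")
  if (is.vector(D) || (n == 1 && length(D) == 1)) D <- diag(as.numeric(D), n)
  D <- as.matrix(D)
  if (!all(dim(D) == n)) stop_bad_arg("`D` must match the dimension of `C`")
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  mask <- validate_mask(mask, n)

  des <- lyapunov_design(C, mask)
  sol <- svd_min_norm(des$A)
  b <- -2 * D[cbind(des$p, des$q)]
  x <- drop(sol$pinv %*% b)
  J <- matrix(0, n, n)
  if (!is.null(rownames(C))) dimnames(J) <- list(rownames(C), rownames(C))
  J[des$free] <- x
  structure(
    list(
      J = J,
      residual_norm = sqrt(sum((J %*% C + C %*% t(J) + 2 * D)^2)),
      rank = sol$rank,
      rank_deficiency = length(des$free) - sol$rank
    ),
    class = "jacobian_solution"
  )
}

validate_mask <- function(mask, n) {
  if (!is.matrix(mask) || !is.logical(mask) || !all(dim(mask) == n)) {
    stop_bad_arg("`mask` must be a logical %d x %d matrix", n, n)
  }
  if (!all(diag(mask))) stop_bad_arg("`mask` diagonal must be all TRUE")
  mask
}

#' Monte-Carlo median Jacobian estimate
#'
#' The inverse Lyapunov solution depends on the arbitrary fluctuation
#' matrix `D`. Following the data-driven protocol, the calculation is
#' repeated `n_iter` times with freshly drawn random diagonal noise
#' matrices and the entry-wise median over draws is taken as the final
#' Jacobian estimate; the entry-wise interquartile range quantifies the
#' spread. Because the least-squares map is linear in `D`, the repeated
#' solves share one design-matrix pseudoinverse, so `n_iter = 10^4` on a
#' ~50-metabolite network costs seconds, and results are bit-reproducible
#' from `seed`.
#'
#' @inheritParams solve_inverse_jacobian
#' @param n_iter Number of noise-matrix draws; default `10000`.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param noise_mode Passed to [draw_noise_matrix()].
#' @param shrinkage Optional diagonal shrinkage intensity `lambda` in
#'   `[0, 1]` applied to `C` as `(1-lambda) C + lambda mean(diag(C)) I`
#'   before solving; default 0 (off).
#' @param max_fail_frac Iterations yielding non-finite solutions are
#'   dropped; the run errors if their fraction exceeds this (default 1%).
#' @return A list of class `jacobian_estimate`: `median` and `iqr`
#'   matrices (zero off-mask), `mask`, `n_iter`, `seed`, `noise_mode`,
#'   `rank`, `rank_deficiency`, `residual_norm` (median over iterations of
#'   the per-iteration least-squares residual), `n_failed`.
#' @export
monte_carlo_jacobian <- function(C, mask = NULL, n_iter = 10000, seed,
                                 noise_mode = c("half_normal", "normal"),
                                 shrinkage = 0, max_fail_frac = 0.01) {
  n_iter <- assert_count(n_iter, "n_iter")
  noise_mode <- match.arg(noise_mode)
  if (missing(seed)) stop_bad_arg("`seed` is required for a reproducible estimate")
  seed <- assert_count(seed, "seed", min = 0L)
  shrinkage <- assert_proportion(shrinkage, "shrinkage")
  C <- as.matrix(C)
  n <- nrow(C)
  if (all(C == 0)) stop_bad_arg("degenerate covariance: `C` is identically zero")
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  mask <- validate_mask(mask, n)
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(n)
  }

  des <- lyapunov_design(C, mask)
  sol <- svd_min_norm(des$A)
  # RHS is nonzero only on the n diagonal equations (p == q); one column
  # of draws per iteration, identical RNG stream to calling
  # draw_noise_matrix() n_iter times in sequence.
  diag_eq <- which(des$p == des$q)
  Z <- withr::with_seed(seed, {
    draws <- matrix(rnorm(n * n_iter), nrow = n, ncol = n_iter)
    if (noise_mode == "half_normal") abs(draws) else draws
  })
  Jdraws <- sol$pinv[, diag_eq, drop = FALSE] %*% (-2 * Z)  # m x n_iter

  ok <- apply(is.finite(Jdraws), 2L, all)
  n_failed <- sum(!ok)
  if (n_failed > max_fail_frac * n_iter) {
    stop_bad_arg("%d of %d Monte-Carlo iterations failed (limit %.1f%%)",
                 n_failed, n_iter, 100 * max_fail_frac)
  }
  Jok <- Jdraws[, ok, drop = FALSE]
  med <- apply(Jok, 1L, median)
  iqr <- apply(Jok, 1L, function(v) diff(quantile(v, c(0.25, 0.75), names = FALSE)))

  # per-iteration least-squares residual norms, summarized by their median
  B <- matrix(0, length(des$p), ncol(Jok))
  B[diag_eq, ] <- -2 * Z[, ok, drop = FALSE]
  res <- sqrt(colSums((des$A %*% Jok - B)^2))

  vnames <- rownames(C) %||% paste0("V", seq_len(n))
  Jmed <- matrix(0, n, n, dimnames = list(vnames, vnames))
  Jiqr <- Jmed
  Jmed[des$free] <- med
  Jiqr[des$free] <- iqr
  structure(
    list(
      median = Jmed, iqr = Jiqr, mask = mask,
      n_iter = n_iter, seed = seed, noise_mode = noise_mode,
      shrinkage = shrinkage, rank = sol$rank,
      rank_deficiency = sum(mask) - sol$rank,
      residual_norm = median(res), n_failed = n_failed
    ),
    class = "jacobian_estimate"
  )
}

#' @export
print.jacobian_estimate <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo Jacobian estimate: %d variables, %d free entries\n  n_iter = %d (%d failed), seed = %d, noise = %s\n  rank deficiency = %d, median residual = %.4g\n",
    nrow(x$median), sum(x$mask), x$n_iter, x$n_failed, x$seed,
    x$noise_mode, x$rank_deficiency, x$residual_norm
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.jacobian_estimate <- function(x, ...) {
  free <- which(x$mask)
  n <- nrow(x$mask)
  vn <- rownames(x$median)
  tibble::tibble(
    target = vn[((free - 1L) %% n) + 1L],
    source = vn[((free - 1L) %/% n) + 1L],
    estimate = x$median[free],
    iqr = x$iqr[free]
  )
}

#' @exportS3Method generics::glance
glance.jacobian_estimate <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$median), n_free = sum(x$mask),
    n_iter = x$n_iter, n_failed = x$n_failed,
    rank = x$rank, rank_deficiency = x$rank_deficiency,
    residual_norm = x$residual_norm
  )
}
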