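# Shared fixtures, all built in code.

# the worked 3-genotype panel: SI = 0.23, SSI = (2.1739..., 0.4348..., 0.8696...)
toy_panel <- function() {
  tibble::tibble(genotype = c("A", "B", "C"),
                 Yp = c(20, 30, 50), Ys = c(10, 27, 40))
}

# a hand-built ground-truth system with C_true = I (J = -I, D = I)
identity_system <- function(n = 4) {
  nodes <- paste0("M", seq_len(n))
  eye <- diag(n)
  dimnames(eye) <- list(nodes, nodes)
  structure(
    list(
      network = metabolic_network(
        tibble::tibble(source = character(), target = character()),
        nodes = nodes
      ),
      mask = eye > 0, J_true = -eye, D_true = eye, C_true = eye
    ),
    class = "ground_truth_system"
  )
}

# Two groups sharing a 6-node ring mask and D = I; k off-diagonal edges of
# group 2 are halved, planting dJ = ln(2) > 0 (group 1 dominant) on them.
planted_differential_system <- function(seed = 42, k = 3) {
  sys <- make_toy_network(6, "ring", seed = seed)
  mask <- sys$mask
  off <- which(mask & !diag(TRUE, 6))
  stopifnot(length(off) >= k)
  planted <- off[seq_len(k)]
  J1 <- sys$J_true
  J2 <- J1
  J2[planted] <- J1[planted] / 2
  D <- diag(6)
  list(
    mask = mask, J1 = J1, J2 = J2, D = D,
    C1 = forward_lyapunov(J1, D), C2 = forward_lyapunov(J2, D),
    planted = planted
  )
}

# abundance table for a genotype panel where every genotype's observations
# come from the same ground-truth system (n_reps each)
panel_abundances <- function(system, genotypes, n_reps = 3, base_seed = 1000) {
  purrr::map_dfr(seq_along(genotypes), function(i) {
    simulate_abundances(system, n_reps, seed = base_seed + i,
                        genotype = genotypes[i])
  })
}
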