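# Independent brute-force oracles used to validate the package's solvers.
# These are deliberately written as plain nested bisection loops, separate
# from the package implementation, so solver and oracle can disagree.

# Equilibrium oracle: outer bisection on E_free in [0, E_total], inner on
# T_free in [0, T_total]; R_free eliminated through its conservation law.
oracle_equilibrium <- function(R_total, T_total, E_total, K1, K2, K3, K4,
                               iters = 100) {
  r_of <- function(t, e) R_total / (1 + t / K1 + e / K4 + t * e / (K1 * K2))
  t_residual <- function(t, e) {
    r <- r_of(t, e)
    t + r * t / K1 + r * t * e / (K1 * K2) - T_total
  }
  e_residual <- function(e) {
    lo <- 0; hi <- T_total
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (t_residual(mid, e) > 0) hi <- mid else lo <- mid
    }
    t <- (lo + hi) / 2
    r <- r_of(t, e)
    e + r * e / K4 + r * t * e / (K1 * K2) - E_total
  }
  lo <- 0; hi <- E_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (e_residual(mid) > 0) hi <- mid else lo <- mid
  }
  e <- (lo + hi) / 2
  lo <- 0; hi <- T_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (t_residual(mid, e) > 0) hi <- mid else lo <- mid
  }
  t <- (lo + hi) / 2
  r <- r_of(t, e)
  list(R_free = r, T_free = t, E_free = e,
       RT = r * t / K1, RE = r * e / K4, RTE = r * t * e / (K1 * K2))
}

# Textbook quadratic-root solution of a single A + B = AB reaction.
oracle_two_species <- function(A, B, K) {
  s <- A + B + K
  (s - sqrt(s^2 - 4 * A * B)) / 2
}

# Generators for synthetic fit inputs.
langmuir_curve <- function(A, K, x) {
  data.frame(free_ligand = x, response = A * x / (K + x))
}
hill_curve <- function(A, K, n, x) {
  data.frame(free_ligand = x, response = A * x^n / (K^n + x^n))
}
lseq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

expect_state_close <- function(state, oracle, tol = 1e-8) {
  for (sp in c("R_free", "T_free", "E_free", "RT", "RE", "RTE")) {
    scale <- max(abs(oracle[[sp]]), 1e-6)
    expect_lt(abs(state[[sp]] - oracle[[sp]]) / scale, tol)
  }
}
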