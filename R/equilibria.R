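#' Dissociation constants of the 43S PIC / eIF3 binding cycle
#'
#' The three-component network couples the 40S ribosomal subunit (with eIF1 and
#' eIF1A; denoted R), the eIF2--GTP--Met-tRNAi ternary complex (T) and eIF3 (E)
#' through four reversible binding steps:
#'
#' \describe{
#'   \item{K1}{T + R = RT, dissociation constant of TC binding the free 43S
#'     (no eIF3) complex, nM.}
#'   \item{K2}{E + RT = RTE, dissociation constant of eIF3 binding the 43S PIC,
#'     nM.}
#'   \item{K3}{T + RE = RTE, dissociation constant of TC binding the
#'     40S-eIF3 complex, nM.}
#'   \item{K4}{E + R = RE, dissociation constant of eIF3 binding the free 40S
#'     subunit, nM.}
#' }
#'
#' The four steps form a closed thermodynamic cycle, so only three constants are
#' independent: `K1 * K2 == K3 * K4`. `K4` is never taken as a free input; it is
#' either derived with [derive_fourth_constant()] (when omitted) or checked
#' against cycle closure to a relative tolerance of 1e-9 (when supplied).
#'
#' @param K1,K2,K3 Dissociation constants in nM; strictly positive and finite.
#' @param K4 Optional fourth constant in nM. If `NULL` (default) it is derived
#'   from cycle closure; if given, it must satisfy closure to 1e-9 relative.
#' @return An object of class `"equilibrium_constants"`: a named list with
#'   elements `K1`, `K2`, `K3`, `K4`.
#' @examples
#' equilibrium_constants(K1 = 104, K2 = 38, K3 = 15)
#' @export
equilibrium_constants <- function(K1, K2, K3, K4 = NULL) {
  ks <- c(K1 = K1, K2 = K2, K3 = K3)
  if (!all(is.finite(ks)) || any(ks <= 0)) {
    stop("invalid constant: K1, K2, K3 must be strictly positive and finite",
         call. = FALSE)
  }
  K4_closed <- derive_fourth_constant(K1, K2, K3)
  if (is.null(K4)) {
    K4 <- K4_closed
  } else {
    if (!is.finite(K4) || K4 <= 0) {
      stop("invalid constant: K4 must be strictly positive and finite",
           call. = FALSE)
    }
    if (abs(K4 - K4_closed) > 1e-9 * K4_closed) {
      stop(sprintf(
        "cycle closure violated: K1*K2 = %.10g but K3*K4 = %.10g",
        K1 * K2, K3 * K4), call. = FALSE)
    }
  }
  structure(list(K1 = K1, K2 = K2, K3 = K3, K4 = K4),
            class = "equilibrium_constants")
}

#' Derive the fourth constant of the binding cycle
#'
#' Closure of the thermodynamic cycle requires `K1 * K2 == K3 * K4`; the
#' affinity of eIF3 for the free 40S subunit is therefore fully determined by
#' the other three constants: `K4 = K1 * K2 / K3`.
#'
#' @inheritParams equilibrium_constants
#' @return `K4` in nM.
#' @examples
#' derive_fourth_constant(104, 38, 15) # 263.47 nM
#' @export
derive_fourth_constant <- function(K1, K2, K3) {
  ks <- c(K1, K2, K3)
  if (length(ks) != 3 || !all(is.finite(ks)) || any(ks <= 0)) {
    stop("invalid constant: K1, K2, K3 must be strictly positive and finite",
         call. = FALSE)
  }
  K1 * K2 / K3
}

#' Total concentrations in a binding reaction
#'
#' @param R_total Total 40S (as 40S-eIF1-eIF1A) concentration, nM.
#' @param T_total Total ternary-complex concentration, nM.
#' @param E_total Total eIF3 concentration, nM.
#' @return An object of class `"mixture_totals"`.
#' @export
mixture_totals <- function(R_total, T_total, E_total) {
  tot <- c(R_total = R_total, T_total = T_total, E_total = E_total)
  if (!all(is.finite(tot)) || any(tot < 0)) {
    stop("totals must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(tot), class = "mixture_totals")
}

# Bound complex of a single two-species reaction A + B = AB with dissociation
# constant K: the admissible root of AB^2 - (A + B + K) AB + A B = 0 in
# [0, min(A, B)].  Written in the numerically stable form that avoids
# cancellation when K is large.
two_species_complex <- function(A_total, B_total, K) {
  if (A_total == 0 || B_total == 0) return(0)
  s <- A_total + B_total + K
  disc <- s * s - 4 * A_total * B_total
  # 2ab / (s + sqrt(disc)) equals the small quadratic root without subtraction
  2 * A_total * B_total / (s + sqrt(disc))
}

# Residuals of the T and E conservation laws at free concentrations (t, e),
# with R_free eliminated exactly through its own conservation law.
conservation_residuals <- function(t, e, totals, k) {
  r <- totals$R_total / (1 + t / k$K1 + e / k$K4 + t * e / (k$K1 * k$K2))
  fT <- t * (1 + r / k$K1 + r * e / (k$K1 * k$K2)) - totals$T_total
  fE <- e * (1 + r / k$K4 + r * t / (k$K1 * k$K2)) - totals$E_total
  list(fT = fT, fE = fE, r = r)
}

# Nested bisection on the same residuals: outer on E_free in [0, E_total],
# inner on T_free in [0, T_total].  Each residual is monotone increasing in its
# own free variable so the brackets are guaranteed.  Used as the fallback when
# Newton stalls; slower but unconditionally convergent.
solve_equilibrium_bisect <- function(totals, k, tol = 1e-12, max_iter = 200) {
  inner_t <- function(e) {
    lo <- 0; hi <- totals$T_total
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      if (conservation_residuals(mid, e, totals, k)$fT > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= tol * totals$T_total) break
    }
    (lo + hi) / 2
  }
  lo <- 0; hi <- totals$E_total
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (conservation_residuals(inner_t(mid), mid, totals, k)$fE > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= tol * totals$E_total) break
  }
  e <- (lo + hi) / 2
  t <- inner_t(e)
  c(t = t, e = e)
}

#' Solve the coupled three-component binding equilibrium
#'
#' Computes the unique physically admissible equilibrium of the
#' R/T/E network (all species non-negative, conservation of each component,
#' all four mass-action relations satisfied) for given totals and dissociation
#' constants. Free R is eliminated analytically through its conservation law,
#' leaving a two-variable root problem in (`T_free`, `E_free`) solved by damped
#' Newton iteration; if Newton fails to reach tolerance within the iteration
#' budget the solver falls back to nested bisection, which is guaranteed to
#' converge because each conservation residual is monotone in its own free
#' variable. Mixtures with a zero total collapse analytically to at most one
#' two-species reaction and bypass the general solver.
#'
#' @param totals A [mixture_totals()] object (or list with `R_total`,
#'   `T_total`, `E_total` in nM).
#' @param constants An [equilibrium_constants()] object.
#' @param tol Relative residual tolerance on every conservation law and
#'   mass-action relation (default 1e-10, far below measurement noise).
#' @param max_iter Iteration cap for Newton and for each bisection loop.
#' @return An object of class `"species_state"`: named list with free species
#'   `R_free`, `T_free`, `E_free` and complexes `RT`, `RE`, `RTE` (all nM),
#'   carrying the totals and constants as attributes.
#' @examples
#' k <- equilibrium_constants(104, 38, 15)
#' solve_equilibrium(mixture_totals(30, 2, 100), k)
#' @export
solve_equilibrium <- function(totals, constants, tol = 1e-10, max_iter = 200) {
  if (!inherits(constants, "equilibrium_constants")) {
    constants <- do.call(equilibrium_constants, as.list(constants)[c("K1", "K2", "K3")])
  }
  if (!inherits(totals, "mixture_totals")) {
    totals <- mixture_totals(totals$R_total, totals$T_total, totals$E_total)
  }
  k <- constants

  # degenerate mixtures: collapse the network analytically
  if (totals$R_total == 0) {
    return(new_species_state(totals$R_total, totals$T_total, totals$E_total,
                             0, 0, 0, totals, k))
  }
  if (totals$T_total == 0) {
    RE <- two_species_complex(totals$R_total, totals$E_total, k$K4)
    return(new_species_state(totals$R_total - RE, 0, totals$E_total - RE,
                             0, RE, 0, totals, k))
  }
  if (totals$E_total == 0) {
    RT <- two_species_complex(totals$R_total, totals$T_total, k$K1)
    return(new_species_state(totals$R_total - RT, totals$T_total - RT, 0,
                             RT, 0, 0, totals, k))
  }

  scale_T <- totals$T_total
  scale_E <- totals$E_total
  ok <- function(res) {
    abs(res$fT) <= tol * scale_T && abs(res$fE) <= tol * scale_E
  }

  # damped Newton on (t, e) with a finite-difference Jacobian
  t <- totals$T_total / 2
  e <- totals$E_total / 2
  res <- conservation_residuals(t, e, totals, k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (ok(res)) { converged <- TRUE; break }
    ht <- max(t, totals$T_total) * 1e-7 + 1e-300
    he <- max(e, totals$E_total) * 1e-7 + 1e-300
    rt <- conservation_residuals(t + ht, e, totals, k)
    re <- conservation_residuals(t, e + he, totals, k)
    J <- matrix(c((rt$fT - res$fT) / ht, (re$fT - res$fT) / he,
                  (rt$fE - res$fE) / ht, (re$fE - res$fE) / he),
                2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, -c(res$fT, res$fE)), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lambda <- 1
    norm0 <- abs(res$fT) / scale_T + abs(res$fE) / scale_E
    improved <- FALSE
    for (half in 1:30) {
      t_new <- min(max(t + lambda * step[1], 0), totals$T_total)
      e_new <- min(max(e + lambda * step[2], 0), totals$E_total)
      res_new <- conservation_residuals(t_new, e_new, totals, k)
      if (abs(res_new$fT) / scale_T + abs(res_new$fE) / scale_E < norm0) {
        t <- t_new; e <- e_new; res <- res_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }

  if (!converged) {
    fe <- solve_equilibrium_bisect(totals, k, tol = 1e-14, max_iter = max_iter)
    t <- fe[["t"]]; e <- fe[["e"]]
    res <- conservation_residuals(t, e, totals, k)
    if (!ok(res)) {
      stop(sprintf(
        paste0("equilibrium solver failed to converge: residuals fT = %.3e, ",
               "fE = %.3e exceed tolerance %.1e"),
        res$fT, res$fE, tol), call. = FALSE)
    }
  }

  r <- res$r
  RT <- r * t / k$K1
  RE <- r * e / k$K4
  RTE <- r * t * e / (k$K1 * k$K2)
  new_species_state(r, t, e, RT, RE, RTE, totals, k)
}

new_species_state <- function(R_free, T_free, E_free, RT, RE, RTE,
                              totals, constants) {
  structure(
    list(R_free = max(R_free, 0), T_free = max(T_free, 0),
         E_free = max(E_free, 0), RT = max(RT, 0), RE = max(RE, 0),
         RTE = max(RTE, 0)),
    totals = totals, constants = constants, class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat("Equilibrium species state (nM):\n")
  print(round(unlist(unclass(x)), 6))
  invisible(x)
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat("Binding-cycle dissociation constants (nM):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Band fractions of the radiolabelled tracer
#'
#' Converts an equilibrium species state into the three band fractions a native
#' gel resolves when the ternary complex carries the radiolabel: free tracer,
#' tracer in 43S PICs (RT) and tracer in 43S-eIF3 complexes (RTE). Fractions
#' are relative to total tracer and sum to 1 by conservation.
#'
#' @param state A `"species_state"` from [solve_equilibrium()].
#' @return Named numeric vector `c(frac_free, frac_43S, frac_43S_eIF3)`.
#' @export
band_fractions <- function(state) {
  stopifnot(inherits(state, "species_state"))
  T_total <- attr(state, "totals")$T_total
  if (T_total <= 0) {
    stop("band fractions undefined: T_total is zero (no labelled tracer)",
         call. = FALSE)
  }
  c(frac_free = state$T_free / T_total,
    frac_43S = state$RT / T_total,
    frac_43S_eIF3 = state$RTE / T_total)
}
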