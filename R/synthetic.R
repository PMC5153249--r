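#' Measurement-noise model for simulated gel quantifications
#'
#' Band fractions from phosphorimager quantification carry approximately
#' Gaussian error at the intensities of these assays. The generator adds
#' independent Gaussian noise of standard deviation `sigma` to each band
#' fraction, clips to [0, 1], and renormalizes the lane to its pre-noise total
#' so the lane still behaves like a quantified gel lane. The default
#' `sigma = 0.02` gives replicate SEMs on the scale of the error bars typical
#' of these experiments.
#'
#' @param sigma Standard deviation of the additive noise on each fraction
#'   (>= 0).
#' @param seed Integer master seed; every replicate draws from a substream
#'   derived deterministically from it, so generation is bit-reproducible.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0.02, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# deterministic substream seed for replicate i (kept inside 32-bit range)
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483587L)
}

noisy_fractions <- function(fr, sigma) {
  if (sigma == 0) return(fr)
  total <- sum(fr)
  f <- pmin(pmax(fr + stats::rnorm(length(fr), 0, sigma), 0), 1)
  s <- sum(f)
  if (s > 0) f <- f * total / s
  pmin(f, 1)
}

#' Design of a simulated gel-shift titration
#'
#' Captures everything needed to generate a titration: which species is
#' titrated and over what grid, the fixed totals, the true dissociation
#' constants, and the replicate count. Defaults follow the standard assay
#' layouts: eIF3 titrated from 30 to 500 nM into 30 nM 40S and 2 nM tracer
#' TC; 40S titrated from 10 to 320 nM (two-fold steps) against 1 nM tracer.
#'
#' @param titrant `"eIF3"` or `"40S"`.
#' @param grid Titrant totals, nM, strictly increasing. `NULL` picks the
#'   default grid for the titrant.
#' @param constants True [equilibrium_constants()].
#' @param R_total,T_total,E_total Fixed totals, nM (the titrated one is
#'   ignored).
#' @param n_replicates Number of replicates (>= 1; standard designs use >= 2).
#' @return An object of class `"titration_design"`.
#' @export
titration_design <- function(titrant = c("eIF3", "40S"), grid = NULL,
                             constants,
                             R_total = 30, T_total = 2, E_total = 0,
                             n_replicates = 2L) {
  titrant <- match.arg(titrant)
  if (is.null(grid)) {
    grid <- if (titrant == "eIF3") {
      round(exp(seq(log(30), log(500), length.out = 7)))
    } else {
      c(10, 20, 40, 80, 160, 320)
    }
  }
  if (length(grid) == 0) stop("titration grid is empty", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (!inherits(constants, "equilibrium_constants")) {
    stop("constants must be an equilibrium_constants object", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(titrant = titrant, grid = grid, constants = constants,
                 R_total = R_total, T_total = T_total, E_total = E_total,
                 n_replicates = as.integer(n_replicates)),
            class = "titration_design")
}

#' Simulate a replicate-structured gel-shift titration
#'
#' For every lane the coupled equilibrium is solved exactly at the design's
#' true constants, band fractions are computed, and measurement noise is
#' added. Replicates differ only by their noise substream. The result is a
#' table in the same schema the readers consume, carrying the design as the
#' `"truth"` attribute for later recovery scoring.
#'
#' @param design A [titration_design()].
#' @param noise A [noise_model()].
#' @return Data frame with columns `replicate_id`, `titrant`,
#'   `titrant_total_nM`, `frac_free`, `frac_43S`, `frac_43S_eIF3`.
#' @export
simulate_titration <- function(design, noise = noise_model()) {
  stopifnot(inherits(design, "titration_design"), inherits(noise, "noise_model"))
  noiseless <- t(vapply(design$grid, function(x) {
    totals <- if (design$titrant == "eIF3") {
      mixture_totals(design$R_total, design$T_total, x)
    } else {
      mixture_totals(x, design$T_total, design$E_total)
    }
    band_fractions(solve_equilibrium(totals, design$constants))
  }, numeric(3)))

  reps <- lapply(seq_len(design$n_replicates), function(i) {
    set.seed(substream_seed(noise$seed, i))
    fr <- t(apply(noiseless, 1, noisy_fractions, sigma = noise$sigma))
    data.frame(replicate_id = sprintf("rep%d", i),
               titrant = design$titrant,
               titrant_total_nM = design$grid,
               frac_free = fr[, 1], frac_43S = fr[, 2],
               frac_43S_eIF3 = fr[, 3])
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  attr(out, "truth") <- design
  out
}

#' Design of a simulated recruitment time course
#'
#' @param A True endpoint (amplitude) in [0, 1].
#' @param k True observed rate constant, min^-1 (> 0: a zero rate is not a
#'   recruitment process and is rejected).
#' @param time_grid Sampling times in minutes, strictly increasing; default 8
#'   log-spaced points from 0.5 to 60 min. Designs for slow reactions should
#'   extend toward 120 min.
#' @param n_replicates Replicate count (>= 1).
#' @param mRNA_label,condition Metadata tags carried into the table.
#' @return An object of class `"timecourse_design"`.
#' @export
timecourse_design <- function(A, k, time_grid = NULL, n_replicates = 2L,
                              mRNA_label = "", condition = "") {
  if (is.null(time_grid)) {
    time_grid <- exp(seq(log(0.5), log(60), length.out = 8))
  }
  if (A < 0 || A > 1) stop("amplitude A must lie in [0, 1]", call. = FALSE)
  if (k <= 0) {
    stop("rate constant must be > 0: k = 0 is not a recruitment process",
         call. = FALSE)
  }
  if (length(time_grid) == 0) stop("time grid is empty", call. = FALSE)
  if (any(time_grid < 0) || any(diff(time_grid) <= 0)) {
    stop("time grid must be >= 0 and strictly increasing", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(A = A, k = k, time_grid = time_grid,
                 n_replicates = as.integer(n_replicates),
                 mRNA_label = mRNA_label, condition = condition),
            class = "timecourse_design")
}

#' Simulate replicate recruitment time courses
#'
#' Generates `y(t) = A * (1 - exp(-k t))` on the design's time grid and adds
#' truncated Gaussian noise per point, per replicate.
#'
#' @param design A [timecourse_design()].
#' @param noise A [noise_model()].
#' @return Data frame in the time-course table schema, with the design as the
#'   `"truth"` attribute.
#' @export
simulate_timecourse <- function(design, noise = noise_model()) {
  stopifnot(inherits(design, "timecourse_design"), inherits(noise, "noise_model"))
  y_true <- design$A * (1 - exp(-design$k * design$time_grid))
  reps <- lapply(seq_len(design$n_replicates), function(i) {
    set.seed(substream_seed(noise$seed, i))
    y <- pmin(pmax(y_true + stats::rnorm(length(y_true), 0, noise$sigma), 0), 1)
    data.frame(replicate_id = sprintf("rep%d", i),
               condition = design$condition,
               mRNA_label = design$mRNA_label,
               time_min = design$time_grid,
               frac_recruited = y)
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  attr(out, "truth") <- design
  out
}

#' Simulate a panel of named conditions
#'
#' Emulates the variant-panel structure of the assays: one eIF3 titration
#' dataset per named condition (wild-type factor plus variants), each with its
#' own true constants, plus a manifest of the true parameters for recovery
#' scoring. Condition names must be unique.
#'
#' @param conditions Data frame with columns `condition`, `K1`, `K2`, `K3`
#'   (nM, true values per condition).
#' @param noise A [noise_model()]; condition index is folded into the seed so
#'   conditions get distinct noise streams.
#' @param grid,R_total,T_total,n_replicates Passed to [titration_design()].
#' @return List with `tables` (named list of titration tables) and `manifest`
#'   (named list of true parameters).
#' @export
variant_panel <- function(conditions, noise = noise_model(), grid = NULL,
                          R_total = 30, T_total = 2, n_replicates = 2L) {
  stopifnot(is.data.frame(conditions),
            all(c("condition", "K1", "K2", "K3") %in% names(conditions)))
  if (nrow(conditions) == 0) stop("empty condition panel", call. = FALSE)
  if (anyDuplicated(conditions$condition)) {
    stop("condition names must be unique", call. = FALSE)
  }
  tables <- list()
  manifest <- list()
  for (i in seq_len(nrow(conditions))) {
    row <- conditions[i, ]
    k <- equilibrium_constants(row$K1, row$K2, row$K3)
    des <- titration_design("eIF3", grid = grid, constants = k,
                            R_total = R_total, T_total = T_total,
                            n_replicates = n_replicates)
    nm <- noise_model(noise$sigma, substream_seed(noise$seed, 100000 + i))
    tables[[row$condition]] <- simulate_titration(des, nm)
    manifest[[row$condition]] <- list(K1 = row$K1, K2 = row$K2, K3 = row$K3,
                                      K4 = k$K4, R_total = R_total,
                                      T_total = T_total,
                                      n_replicates = n_replicates,
                                      sigma = noise$sigma)
  }
  list(tables = tables, manifest = manifest)
}

#' Write or read a panel manifest of true parameters
#'
#' @param manifest Named list of per-condition true parameters.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
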