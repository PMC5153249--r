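#' Fit a Langmuir (hyperbolic) binding isotherm
#'
#' Least-squares fit of `response = A * x / (K + x)` to a binding curve. The
#' amplitude is free in [0, 1.05] rather than fixed at one, because the
#' endpoint of complex formation is itself condition-dependent and reported.
#' `K` is bounded in `[min(x)/10, max(x)*10]`; an estimate pinned at either
#' bound is not a measurement and is returned as a fit failure, as is optimizer
#' non-convergence. Fitting uses deterministic multi-start (five
#' Levenberg-Marquardt starts with K log-spaced across the x range) to avoid
#' local minima.
#'
#' @param curve A `"corrected_curve"` or data frame with columns `free_ligand`
#'   (or `x`) and `response` (or `y`).
#' @return An object of class `"isotherm_fit"`: list with `model`, `K_app`,
#'   `amplitude`, `hill_n`, `rss`, `n_points`, `failed`, `reason`, `censored`,
#'   `censor_limit`.
#' @examples
#' x <- c(10, 30, 100, 300, 1000)
#' fit_langmuir(data.frame(free_ligand = x, response = 0.8 * x / (100 + x)))
#' @export
fit_langmuir <- function(curve) {
  fit_isotherm(curve, model = "langmuir")
}

#' Fit a Hill binding isotherm
#'
#' Least-squares fit of `response = A * x^n / (K^n + x^n)` in the
#' half-saturation parameterization, so `K_app` is reported directly in nM.
#' The Hill coefficient is constrained to [0.5, 6]. With `n = 1` the model
#' reduces exactly to the Langmuir isotherm. Apparently cooperative curves
#' that defeat the hyperbolic fit are still fit well by this form.
#'
#' @inheritParams fit_langmuir
#' @return An `"isotherm_fit"`; see [fit_langmuir()].
#' @export
fit_hill <- function(curve) {
  fit_isotherm(curve, model = "hill")
}

curve_xy <- function(curve) {
  d <- as.data.frame(curve)
  x <- if ("free_ligand" %in% names(d)) d$free_ligand else d$x
  y <- if ("response" %in% names(d)) d$response else d$y
  if (is.null(x) || is.null(y)) {
    stop("curve must have columns free_ligand/response (or x/y)", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  data.frame(x = x[keep], y = y[keep])
}

failed_fit <- function(model, n_points, reason) {
  structure(list(model = model, K_app = NA_real_, amplitude = NA_real_,
                 hill_n = NA_real_, rss = NA_real_, n_points = n_points,
                 failed = TRUE, reason = reason,
                 censored = FALSE, censor_limit = NA_real_),
            class = "isotherm_fit")
}

fit_isotherm <- function(curve, model = c("langmuir", "hill"),
                         n_starts = 5L, fix_hill_n = NULL) {
  model <- match.arg(model)
  d <- curve_xy(curve)
  n <- nrow(d)
  if (n < 4) {
    stop("isotherm fitting needs at least 4 points", call. = FALSE)
  }
  xr <- range(d$x[d$x > 0])
  if (xr[2] / max(xr[1], .Machine$double.eps) < 4) {
    stop("isotherm fitting needs x spanning at least a 4-fold range",
         call. = FALSE)
  }
  K_lo <- xr[1] / 10
  K_hi <- xr[2] * 10
  A0 <- min(max(max(d$y), 0.05), 1.05)

  if (model == "langmuir") {
    form <- y ~ A * x / (K + x)
    lower <- c(A = 0, K = K_lo)
    upper <- c(A = 1.05, K = K_hi)
    make_start <- function(K0) list(A = A0, K = K0)
  } else {
    n_fixed <- !is.null(fix_hill_n)
    if (n_fixed) {
      form <- substitute(y ~ A * x^nh / (K^nh + x^nh),
                         list(nh = fix_hill_n))
      form <- stats::as.formula(form)
      lower <- c(A = 0, K = K_lo)
      upper <- c(A = 1.05, K = K_hi)
      make_start <- function(K0) list(A = A0, K = K0)
    } else {
      form <- y ~ A * x^nh / (K^nh + x^nh)
      lower <- c(A = 0, K = K_lo, nh = 0.5)
      upper <- c(A = 1.05, K = K_hi, nh = 6)
      make_start <- function(K0) list(A = A0, K = K0, nh = 1.5)
    }
  }

  starts <- exp(seq(log(xr[1]), log(xr[2]), length.out = n_starts))
  best <- NULL
  for (K0 in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = d, start = make_start(K0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(failed_fit(model, n, "optimizer did not converge from any start"))
  }
  p <- stats::coef(best$fit)
  K <- p[["K"]]
  # an estimate pinned at either K bound is unidentifiable, not a measurement
  if (K <= K_lo * (1 + 1e-6) || K >= K_hi * (1 - 1e-6)) {
    return(failed_fit(model, n, sprintf(
      "K estimate at parameter bound (%.3g nM): unidentifiable", K)))
  }
  hill_n <- if (model == "langmuir") 1
            else if (!is.null(fix_hill_n)) fix_hill_n
            else p[["nh"]]
  structure(list(model = model, K_app = K, amplitude = p[["A"]],
                 hill_n = hill_n, rss = best$rss, n_points = n,
                 failed = FALSE, reason = NA_character_,
                 censored = FALSE, censor_limit = NA_real_),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<%s isotherm fit: FAILED (%s)>\n", x$model, x$reason))
  } else {
    kd <- if (x$censored) {
      sprintf("%.3g nM (<= %g nM: at assay resolution)", x$K_app, x$censor_limit)
    } else {
      sprintf("%.4g nM", x$K_app)
    }
    cat(sprintf("<%s isotherm fit: K_app = %s, A = %.3f, n = %.2f, rss = %.3g>\n",
                x$model, kd, x$amplitude, x$hill_n, x$rss))
  }
  invisible(x)
}

# small-sample corrected information criterion from a least-squares fit;
# k counts the fitted parameters plus the residual variance
aicc_from_rss <- function(rss, n, n_par) {
  k <- n_par + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

#' Compare Langmuir and Hill fits of the same curve
#'
#' Fits both isotherms and selects between them with the small-sample
#' corrected information criterion (AICc) computed from residual sums of
#' squares (2 vs 3 fitted parameters). A failed Langmuir fit auto-selects the
#' Hill model; if both fail the comparison itself is reported as failed.
#'
#' @inheritParams fit_langmuir
#' @return List with `preferred` (`"langmuir"`, `"hill"`, or `NA` on total
#'   failure), the two `"isotherm_fit"` objects and their AICc values.
#' @export
compare_isotherms <- function(curve) {
  fl <- fit_langmuir(curve)
  fh <- fit_hill(curve)
  aic_l <- if (!fl$failed) aicc_from_rss(fl$rss, fl$n_points, 2) else Inf
  aic_h <- if (!fh$failed) aicc_from_rss(fh$rss, fh$n_points, 3) else Inf
  preferred <- if (fl$failed && fh$failed) NA_character_
               else if (fl$failed) "hill"
               else if (fh$failed) "langmuir"
               else if (aic_h < aic_l) "hill" else "langmuir"
  list(preferred = preferred, langmuir = fl, hill = fh,
       aicc_langmuir = aic_l, aicc_hill = aic_h,
       failed = is.na(preferred))
}

#' Censor apparent affinities below assay resolution
#'
#' When the fitted apparent dissociation constant is at or below the
#' concentration of the limiting binding partner (the 40S subunits, 30 nM in
#' the standard design), the titration is essentially stoichiometric and the
#' fit reports an upper limit, not a point estimate. Such values are flagged
#' `censored` with the limit recorded; the numerical value is retained.
#'
#' @param fit An `"isotherm_fit"` that succeeded.
#' @param limiting_40S Concentration of the limiting species, nM.
#' @return The fit with `censored`/`censor_limit` set.
#' @export
censor_apparent_kd <- function(fit, limiting_40S) {
  stopifnot(inherits(fit, "isotherm_fit"))
  if (fit$failed) stop("cannot censor a failed fit", call. = FALSE)
  fit$censored <- fit$K_app <= limiting_40S
  fit$censor_limit <- if (fit$censored) limiting_40S else NA_real_
  fit
}

#' Aggregate per-replicate fitted parameters
#'
#' Experiments are fit individually and the per-replicate parameter estimates
#' summarized as mean and standard error of the mean (sample SD / sqrt(n));
#' curves are never pooled into a single fit. With a single replicate the SEM
#' is undefined and reported as `NA`.
#'
#' @param values Numeric vector of per-replicate estimates (length >= 1).
#' @return An object of class `"replicate_summary"`: list with `mean`, `sem`,
#'   `n`.
#' @examples
#' aggregate_replicates(c(12, 18)) # mean 15, sem 3
#' @export
aggregate_replicates <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("no replicate values to aggregate", call. = FALSE)
  sem <- if (n == 1) NA_real_ else stats::sd(values) / sqrt(n)
  structure(list(mean = mean(values), sem = sem, n = n),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  sem <- if (is.na(x$sem)) "NA (single replicate)" else sprintf("%.4g", x$sem)
  cat(sprintf("mean %.4g +/- %s (SEM), n = %d\n", x$mean, sem, x$n))
  invisible(x)
}
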