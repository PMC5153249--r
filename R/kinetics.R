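#' An mRNA-recruitment time course
#'
#' One replicate of a recruitment experiment: the fraction of labelled mRNA in
#' the 48S band at each quenched time point. Times are minutes, start at or
#' after zero, and must be strictly increasing; rate fitting requires at least
#' five points.
#'
#' @param time_min Numeric vector of times, min.
#' @param frac_recruited Fractions in [0, 1], same length.
#' @param replicate_id Replicate identifier.
#' @param mRNA_label Free-text mRNA identity (e.g. `"RPL41A"`, `"mid-AUG"`).
#' @param condition Free-text condition tag (factor variant, temperature, ...).
#' @return An object of class `"time_course"`.
#' @export
time_course <- function(time_min, frac_recruited, replicate_id = "rep1",
                        mRNA_label = "", condition = "") {
  stopifnot(length(time_min) == length(frac_recruited))
  if (any(time_min < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(frac_recruited < 0 | frac_recruited > 1)) {
    stop("frac_recruited must lie in [0, 1]", call. = FALSE)
  }
  structure(list(points = data.frame(t = time_min, y = frac_recruited),
                 replicate_id = replicate_id, mRNA_label = mRNA_label,
                 condition = condition),
            class = "time_course")
}

failed_kinetic_fit <- function(reason) {
  structure(list(k_obs = NA_real_, endpoint = NA_real_, rss = NA_real_,
                 rate_resolved = FALSE, failed = TRUE, reason = reason),
            class = "kinetic_fit")
}

#' Fit a single-exponential recruitment time course
#'
#' Least-squares fit of `y(t) = A * (1 - exp(-k * t))` to a recruitment time
#' course. The intercept is fixed at zero because reactions are initiated by
#' simultaneous addition of mRNA and ATP; there is no burst term. The
#' amplitude is bounded in [0, 1.05] and `k` is found by deterministic
#' multi-start Levenberg-Marquardt (rate starts log-spaced between
#' `0.05 / t_max` and `10 / t_min`).
#'
#' A reaction essentially complete by the first quenched sample carries no
#' rate information: when the fitted curve at the earliest time point already
#' exceeds 90 percent of the fitted amplitude, the fit is returned with
#' `rate_resolved = FALSE` (the endpoint is still meaningful) so that a rate
#' faster than the time resolution of the assay is never reported as a point
#' estimate. Flat-zero data are a fit failure.
#'
#' @param tc A [time_course()] with at least 5 points.
#' @return An object of class `"kinetic_fit"`: list with `k_obs` (min^-1),
#'   `endpoint`, `rss`, `rate_resolved`, `failed`, `reason`.
#' @examples
#' t <- c(1, 2, 4, 8, 16, 32, 64)
#' fit_single_exponential(time_course(t, 0.85 * (1 - exp(-0.27 * t))))
#' @export
fit_single_exponential <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc$points
  if (nrow(d) < 5) {
    stop("rate fitting needs at least 5 time points", call. = FALSE)
  }
  if (all(abs(d$y) < 1e-9)) {
    return(failed_kinetic_fit("flat-zero time course: no recruitment signal"))
  }
  t_pos <- d$t[d$t > 0]
  k_starts <- exp(seq(log(0.05 / max(t_pos)), log(10 / min(t_pos)),
                      length.out = 6))
  A0 <- min(max(max(d$y), 0.05), 1.05)
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A * (1 - exp(-k * t)), data = d,
        start = list(A = A0, k = k0),
        lower = c(A = 0, k = 1e-8), upper = c(A = 1.05, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(failed_kinetic_fit("optimizer did not converge from any start"))
  }
  p <- stats::coef(best$fit)
  A <- p[["A"]]; k <- p[["k"]]
  if (A <= 0) return(failed_kinetic_fit("zero fitted amplitude"))
  t1 <- min(d$t[d$t > 0])
  saturated_by_first <- A * (1 - exp(-k * t1)) >= 0.9 * A
  structure(list(k_obs = k, endpoint = A, rss = best$rss,
                 rate_resolved = !saturated_by_first,
                 failed = FALSE, reason = NA_character_),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<kinetic fit: FAILED (%s)>\n", x$reason))
  } else if (!x$rate_resolved) {
    cat(sprintf(
      "<kinetic fit: rate faster than assay time resolution; endpoint = %.3f>\n",
      x$endpoint))
  } else {
    cat(sprintf("<kinetic fit: k_obs = %.4g min^-1, endpoint = %.3f, rss = %.3g>\n",
                x$k_obs, x$endpoint, x$rss))
  }
  invisible(x)
}

#' Extent of recruitment at reaction completion
#'
#' For endpoint-only designs each replicate contributes a single terminal
#' measurement taken after the reaction has proceeded to completion; the
#' extents are summarized as mean and SEM across replicates with no kinetic
#' model.
#'
#' @param endpoint_fractions Numeric vector, one terminal fraction per
#'   replicate.
#' @return A `"replicate_summary"` (see [aggregate_replicates()]).
#' @examples
#' extent_at_completion(c(0.29, 0.27)) # 0.28 +/- 0.01
#' @export
extent_at_completion <- function(endpoint_fractions) {
  if (length(endpoint_fractions) == 0) {
    stop("no endpoint measurements", call. = FALSE)
  }
  if (any(endpoint_fractions < 0 | endpoint_fractions > 1)) {
    stop("endpoint fractions must lie in [0, 1]", call. = FALSE)
  }
  aggregate_replicates(endpoint_fractions)
}

#' Fold-change between two observed rate constants
#'
#' @param fit_a,fit_b `"kinetic_fit"` objects with resolved rates.
#' @return `k_obs(a) / k_obs(b)`.
#' @export
rate_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "kinetic_fit"), inherits(fit_b, "kinetic_fit"))
  if (fit_a$failed || fit_b$failed ||
      !fit_a$rate_resolved || !fit_b$rate_resolved) {
    stop(paste("rate ratio requires two resolved rates; for an unresolved",
               "rate report a bound on the fold change instead"),
         call. = FALSE)
  }
  fit_a$k_obs / fit_b$k_obs
}

# ---- delimited-table interface --------------------------------------------

timecourse_columns <- c("replicate_id", "condition", "mRNA_label",
                        "time_min", "frac_recruited")

#' Read and write time-course tables
#'
#' Time-course tables are delimited text with a mandatory header and columns
#' `replicate_id`, `condition`, `mRNA_label`, `time_min`, `frac_recruited`.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` infers from the header line.
#' @export
read_timecourse_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(timecourse_columns, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("malformed time-course table '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' @rdname read_timecourse_table
#' @param tab Data frame in the time-course table schema.
#' @export
write_timecourse_table <- function(tab, path, sep = ",") {
  stopifnot(all(timecourse_columns %in% names(tab)))
  utils::write.table(tab[timecourse_columns], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a time-course table into per-replicate time courses
#'
#' @param tab Data frame in the time-course table schema.
#' @return List of `"time_course"` objects, one per (condition, mRNA_label,
#'   replicate_id) combination.
#' @export
split_timecourses <- function(tab) {
  stopifnot(all(timecourse_columns %in% names(tab)))
  key <- interaction(tab$condition, tab$mRNA_label, tab$replicate_id,
                     drop = TRUE)
  lapply(split(tab, key), function(d) {
    d <- d[order(d$time_min), ]
    time_course(d$time_min, d$frac_recruited,
                replicate_id = as.character(d$replicate_id[1]),
                mRNA_label = as.character(d$mRNA_label[1]),
                condition = as.character(d$condition[1]))
  })
}
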