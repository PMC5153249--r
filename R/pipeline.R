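#' Configuration of a pipeline run
#'
#' A single declarative object holds everything a run needs; every threshold
#' has a documented default and nothing else is hard-coded in the runners.
#' Configurations can be written to and read from YAML or JSON with
#' [read_run_config()].
#'
#' @param mode One of `"simulate"`, `"fit-eif3"`, `"fit-tc"`, `"fit-kinetics"`,
#'   `"recover"`.
#' @param inputs Named list (by condition) of input tables: file paths or
#'   in-memory data frames in the module schemas.
#' @param out_dir Output directory for result tables and logs; `NULL` keeps
#'   results in memory only.
#' @param K3_map Named list/vector: the measured TC:40S-eIF3 dissociation
#'   constant (nM) per condition, required by the free-eIF3 correction.
#' @param censor_limit Concentration of the limiting 40S subunits, nM;
#'   affinities at or below it are reported as upper limits (default 30).
#' @param fixed_totals List with `R_total` and `T_total` (nM) of the
#'   non-titrated species in eIF3 titrations.
#' @param panel Condition panel data frame for `"simulate"` mode (see
#'   [variant_panel()]).
#' @param sigma,seed Noise level and master seed for simulation modes.
#' @param tolerance Relative tolerance used by `"recover"` mode (default
#'   0.15).
#' @param manifest Manifest path or list for `"recover"` mode.
#' @param format `"csv"` or `"tsv"` for written tables.
#' @param model Isotherm policy for `"fit-eif3"`: `"compare"` (default) fits
#'   both isotherms and selects by AICc; `"hill"` or `"langmuir"` forces one
#'   model.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(mode = c("simulate", "fit-eif3", "fit-tc",
                                "fit-kinetics", "recover"),
                       inputs = list(), out_dir = NULL, K3_map = NULL,
                       censor_limit = 30,
                       fixed_totals = list(R_total = 30, T_total = 2),
                       panel = NULL, sigma = 0.02, seed = 1L,
                       tolerance = 0.15, manifest = NULL,
                       format = c("csv", "tsv"),
                       model = c("compare", "hill", "langmuir")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  model <- match.arg(model)
  for (inp in inputs) {
    if (is.character(inp) && !file.exists(inp)) {
      stop("input file not found: ", inp, call. = FALSE)
    }
  }
  if (mode == "fit-eif3" && length(inputs) && is.null(K3_map)) {
    stop("fit-eif3 mode requires a K3_map", call. = FALSE)
  }
  if (mode == "simulate" && is.null(panel)) {
    stop("simulate mode requires a condition panel", call. = FALSE)
  }
  if (mode == "recover" && is.null(manifest)) {
    stop("recover mode requires a manifest of true parameters", call. = FALSE)
  }
  structure(list(mode = mode, inputs = inputs, out_dir = out_dir,
                 K3_map = K3_map, censor_limit = censor_limit,
                 fixed_totals = fixed_totals, panel = panel, sigma = sigma,
                 seed = as.integer(seed), tolerance = tolerance,
                 manifest = manifest, format = format, model = model),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  if (!is.null(raw$panel)) raw$panel <- as.data.frame(raw$panel)
  do.call(run_config, raw)
}

resolve_table <- function(inp, reader) {
  if (is.character(inp)) reader(inp) else as.data.frame(inp)
}

config_sep <- function(config) if (config$format == "tsv") "\t" else ","

write_result_table <- function(tab, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- config$format
  utils::write.table(tab, file.path(config$out_dir, paste0(name, ".", ext)),
                     sep = config_sep(config), row.names = FALSE, quote = FALSE)
}

write_run_log <- function(log_lines, decisions, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(log_lines, file.path(config$out_dir, paste0(name, ".log")))
  jsonlite::write_json(decisions,
                       file.path(config$out_dir, paste0(name, "_decisions.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Fit eIF3 titrations across conditions
#'
#' The full affinity pipeline for eIF3 titrations: per replicate, apply the
#' free-eIF3 correction, fit both the Langmuir and Hill isotherms, select a
#' model by small-sample information criterion, and censor affinities at or
#' below the 40S concentration; then aggregate per-replicate apparent K_D
#' values into mean and SEM per condition. Every flag, failed fit and model
#' choice is recorded in the run log, and every summary value is traceable to
#' rows of the per-replicate detail table.
#'
#' @param config A [run_config()] with mode `"fit-eif3"`.
#' @return List with `summary` and `detail` data frames, `log` (character)
#'   and `decisions` (list).
#' @export
run_fit_eif3 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  detail <- list(); summary <- list(); log_lines <- character(); decisions <- list()
  for (cond in names(config$inputs)) {
    tab <- resolve_table(config$inputs[[cond]], read_titration_table)
    K3 <- config$K3_map[[cond]]
    if (is.null(K3)) stop("no K3 for condition ", cond, call. = FALSE)
    exps <- split_titrations(tab, config$fixed_totals, K3_assumed = K3)
    for (exp in exps) {
      curve <- withCallingHandlers(
        correct_titration(exp),
        warning = function(w) {
          log_lines <<- c(log_lines, sprintf("[%s/%s] %s", cond,
                                             exp$replicate_id, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (any(curve$flagged)) {
        decisions <- c(decisions, list(list(
          condition = cond, replicate = exp$replicate_id,
          event = "negative free-eIF3 floored",
          lanes = which(curve$flagged))))
      }
      if (config$model == "compare") {
        cmp <- compare_isotherms(curve)
        chosen <- if (cmp$failed) NULL else cmp[[cmp$preferred]]
        choice_note <- if (cmp$failed) NULL else sprintf(
          "model = %s (AICc %.2f vs %.2f)", cmp$preferred,
          cmp$aicc_langmuir, cmp$aicc_hill)
      } else {
        one <- if (config$model == "hill") fit_hill(curve)
               else fit_langmuir(curve)
        chosen <- if (one$failed) NULL else one
        choice_note <- sprintf("model = %s (forced)", config$model)
      }
      if (is.null(chosen)) {
        log_lines <- c(log_lines, sprintf(
          "[%s/%s] isotherm fit(s) failed; replicate excluded from summary",
          cond, exp$replicate_id))
        detail[[length(detail) + 1]] <- data.frame(
          condition = cond, replicate_id = exp$replicate_id,
          model = NA_character_, K_app_nM = NA_real_, hill_n = NA_real_,
          amplitude = NA_real_, rss = NA_real_, censored = NA, failed = TRUE)
        next
      }
      fit <- censor_apparent_kd(chosen, config$censor_limit)
      log_lines <- c(log_lines, sprintf(
        "[%s/%s] %s, K_app = %.3g nM%s",
        cond, exp$replicate_id, choice_note, fit$K_app,
        if (fit$censored) sprintf(" (censored: <= %g nM)", fit$censor_limit) else ""))
      detail[[length(detail) + 1]] <- data.frame(
        condition = cond, replicate_id = exp$replicate_id,
        model = fit$model, K_app_nM = fit$K_app, hill_n = fit$hill_n,
        amplitude = fit$amplitude, rss = fit$rss, censored = fit$censored,
        failed = FALSE)
    }
    cond_rows <- do.call(rbind, detail)
    cond_rows <- cond_rows[cond_rows$condition == cond & !cond_rows$failed, ,
                           drop = FALSE]
    if (nrow(cond_rows)) {
      agg <- aggregate_replicates(cond_rows$K_app_nM)
      model_pick <- names(sort(table(cond_rows$model), decreasing = TRUE))[1]
      summary[[length(summary) + 1]] <- data.frame(
        condition = cond, model = model_pick,
        mean_nM = agg$mean, sem_nM = agg$sem, n_replicates = agg$n,
        censored = any(cond_rows$censored),
        censor_limit_nM = if (any(cond_rows$censored)) config$censor_limit
                          else NA_real_)
    }
  }
  detail <- do.call(rbind, detail)
  summary <- do.call(rbind, summary)
  write_result_table(detail, config, "eif3_fits_detail")
  write_result_table(summary, config, "eif3_fits_summary")
  write_run_log(log_lines, decisions, config, "fit_eif3")
  list(summary = summary, detail = detail, log = log_lines,
       decisions = decisions)
}

#' Fit ternary-complex 40S titrations across conditions
#'
#' Per replicate, build the fraction-TC-bound curve in total-40S coordinates
#' and fit the Langmuir isotherm (amplitude free, reported as the recruitment
#' endpoint); aggregate K_D and endpoint per condition.
#'
#' @param config A [run_config()] with mode `"fit-tc"`.
#' @return List with `summary`, `detail`, `log`.
#' @export
run_fit_tc <- function(config) {
  stopifnot(inherits(config, "run_config"))
  detail <- list(); summary <- list(); log_lines <- character()
  for (cond in names(config$inputs)) {
    tab <- resolve_table(config$inputs[[cond]], read_titration_table)
    exps <- split_titrations(tab, config$fixed_totals)
    for (exp in exps) {
      fit <- fit_langmuir(tc_binding_curve(exp))
      if (fit$failed) {
        log_lines <- c(log_lines, sprintf("[%s/%s] Langmuir fit failed: %s",
                                          cond, exp$replicate_id, fit$reason))
      }
      detail[[length(detail) + 1]] <- data.frame(
        condition = cond, replicate_id = exp$replicate_id,
        K_app_nM = fit$K_app, amplitude = fit$amplitude, rss = fit$rss,
        failed = fit$failed)
    }
    cond_rows <- do.call(rbind, detail)
    cond_rows <- cond_rows[cond_rows$condition == cond & !cond_rows$failed, ,
                           drop = FALSE]
    if (nrow(cond_rows)) {
      aggK <- aggregate_replicates(cond_rows$K_app_nM)
      aggA <- aggregate_replicates(cond_rows$amplitude)
      summary[[length(summary) + 1]] <- data.frame(
        condition = cond, mean_KD_nM = aggK$mean, sem_KD_nM = aggK$sem,
        mean_endpoint = aggA$mean, sem_endpoint = aggA$sem,
        n_replicates = aggK$n)
    }
  }
  detail <- do.call(rbind, detail)
  summary <- do.call(rbind, summary)
  write_result_table(detail, config, "tc_fits_detail")
  write_result_table(summary, config, "tc_fits_summary")
  write_run_log(log_lines, list(), config, "fit_tc")
  list(summary = summary, detail = detail, log = log_lines)
}

#' Fit recruitment time courses across conditions
#'
#' Per replicate, fit the single-exponential recruitment law; aggregate
#' observed rate constants (resolved rates only) and endpoints per
#' (condition, mRNA) group.
#'
#' @param config A [run_config()] with mode `"fit-kinetics"`.
#' @return List with `summary`, `detail`, `log`.
#' @export
run_fit_kinetics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  detail <- list(); log_lines <- character()
  for (cond in names(config$inputs)) {
    tab <- resolve_table(config$inputs[[cond]], read_timecourse_table)
    for (tc in split_timecourses(tab)) {
      fit <- fit_single_exponential(tc)
      if (fit$failed) {
        log_lines <- c(log_lines, sprintf("[%s/%s/%s] kinetic fit failed: %s",
                                          cond, tc$mRNA_label,
                                          tc$replicate_id, fit$reason))
      } else if (!fit$rate_resolved) {
        log_lines <- c(log_lines, sprintf(
          "[%s/%s/%s] rate faster than assay time resolution; endpoint only",
          cond, tc$mRNA_label, tc$replicate_id))
      }
      detail[[length(detail) + 1]] <- data.frame(
        condition = cond, mRNA_label = tc$mRNA_label,
        replicate_id = tc$replicate_id, k_obs_per_min = fit$k_obs,
        endpoint = fit$endpoint, rate_resolved = fit$rate_resolved,
        failed = fit$failed)
    }
  }
  detail <- do.call(rbind, detail)
  groups <- unique(detail[c("condition", "mRNA_label")])
  summary <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    rows <- detail[detail$condition == groups$condition[i] &
                   detail$mRNA_label == groups$mRNA_label[i] &
                   !detail$failed, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    resolved <- rows[rows$rate_resolved, , drop = FALSE]
    aggA <- aggregate_replicates(rows$endpoint)
    if (nrow(resolved)) {
      aggk <- aggregate_replicates(resolved$k_obs_per_min)
      data.frame(condition = groups$condition[i],
                 mRNA_label = groups$mRNA_label[i],
                 mean_k_per_min = aggk$mean, sem_k_per_min = aggk$sem,
                 mean_endpoint = aggA$mean, sem_endpoint = aggA$sem,
                 n_replicates = aggA$n, rate_resolved = TRUE)
    } else {
      data.frame(condition = groups$condition[i],
                 mRNA_label = groups$mRNA_label[i],
                 mean_k_per_min = NA_real_, sem_k_per_min = NA_real_,
                 mean_endpoint = aggA$mean, sem_endpoint = aggA$sem,
                 n_replicates = aggA$n, rate_resolved = FALSE)
    }
  }))
  write_result_table(detail, config, "kinetics_fits_detail")
  write_result_table(summary, config, "kinetics_fits_summary")
  write_run_log(log_lines, list(), config, "fit_kinetics")
  list(summary = summary, detail = detail, log = log_lines)
}

#' Simulate a full variant panel to disk or memory
#'
#' @param config A [run_config()] with mode `"simulate"` and a `panel`.
#' @return The [variant_panel()] bundle; tables and manifest are written when
#'   `out_dir` is set.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- variant_panel(config$panel,
                          noise = noise_model(config$sigma, config$seed),
                          R_total = config$fixed_totals$R_total,
                          T_total = config$fixed_totals$T_total)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in names(bundle$tables)) {
      write_titration_table(
        bundle$tables[[cond]],
        file.path(config$out_dir, paste0(cond, ".", config$format)),
        sep = config_sep(config))
    }
    write_manifest(bundle$manifest, file.path(config$out_dir, "manifest.json"))
  }
  bundle
}

#' Score parameter recovery of a simulated bundle
#'
#' Runs the eIF3 affinity pipeline on a simulated bundle and compares the
#' recovered apparent K_D per condition against the true eIF3:PIC dissociation
#' constant in the manifest. A condition passes when its relative error is
#' within the configured tolerance, or when the truth lies at or below the
#' censor limit and the pipeline correctly reported the value as censored (an
#' upper limit cannot be scored as a point estimate).
#'
#' @param config A [run_config()] with mode `"recover"`: `inputs` are the
#'   simulated tables (per condition) and `manifest` the true parameters.
#' @return List with `report` data frame (true vs recovered, relative error,
#'   pass/fail) and logical `pass` (all conditions passed).
#' @export
run_recover <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- if (is.character(config$manifest)) read_manifest(config$manifest)
              else config$manifest
  missing_conds <- setdiff(names(config$inputs), names(manifest))
  if (length(missing_conds)) {
    stop("manifest/bundle mismatch: no true parameters for ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  }
  K3_map <- lapply(manifest[names(config$inputs)], `[[`, "K3")
  fit_cfg <- run_config("fit-eif3", inputs = config$inputs,
                        out_dir = config$out_dir, K3_map = K3_map,
                        censor_limit = config$censor_limit,
                        fixed_totals = config$fixed_totals,
                        format = config$format)
  res <- run_fit_eif3(fit_cfg)
  report <- do.call(rbind, lapply(seq_len(nrow(res$summary)), function(i) {
    row <- res$summary[i, ]
    true_K2 <- manifest[[row$condition]]$K2
    rel_err <- abs(row$mean_nM - true_K2) / true_K2
    censor_ok <- isTRUE(row$censored) && true_K2 <= config$censor_limit
    data.frame(condition = row$condition, true_K2_nM = true_K2,
               recovered_nM = row$mean_nM, rel_error = rel_err,
               censored = row$censored,
               pass = censor_ok || rel_err <= config$tolerance)
  }))
  write_result_table(report, config, "recovery_report")
  list(report = report, pass = all(report$pass))
}
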