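#' A replicate-structured gel-shift titration
#'
#' Bundles the quantified lanes of one titration replicate: the total
#' concentration of the titrated species (eIF3 or 40S) per lane and the three
#' band fractions of the radiolabelled tracer. Band quantification never sums
#' exactly to one, so lane fractions must sum to within [0.95, 1.05].
#'
#' @param lanes A data frame with columns `titrant_total_nM`, `frac_free`,
#'   `frac_43S`, `frac_43S_eIF3`; `titrant_total_nM` strictly increasing.
#' @param titrant `"eIF3"` or `"40S"`.
#' @param fixed_totals Named list/vector of the totals held fixed (nM): for an
#'   eIF3 titration, `R_total` and `T_total`; for a 40S titration, `T_total`
#'   and (optionally) `E_total`.
#' @param K3_assumed The measured dissociation constant of TC for the 40S-eIF3
#'   complex, nM; required to correct eIF3 titrations. The value is
#'   variant-specific and is therefore an input per experiment, not a constant.
#' @param replicate_id Identifier for the replicate.
#' @return An object of class `"titration_experiment"`.
#' @export
titration_experiment <- function(lanes, titrant = c("eIF3", "40S"),
                                 fixed_totals, K3_assumed = NULL,
                                 replicate_id = "rep1") {
  titrant <- match.arg(titrant)
  needed <- c("titrant_total_nM", "frac_free", "frac_43S", "frac_43S_eIF3")
  if (!all(needed %in% names(lanes))) {
    stop("lanes must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  lanes <- as.data.frame(lanes)[needed]
  fr <- as.matrix(lanes[c("frac_free", "frac_43S", "frac_43S_eIF3")])
  if (any(fr < 0 | fr > 1)) {
    stop("band fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(fr)
  if (any(sums < 0.95 | sums > 1.05)) {
    stop(sprintf(
      "lane fractions must sum to within [0.95, 1.05]; worst lane sums to %.3f",
      sums[which.max(abs(sums - 1))]), call. = FALSE)
  }
  if (any(diff(lanes$titrant_total_nM) <= 0)) {
    stop("titrant_total_nM must be strictly increasing across lanes",
         call. = FALSE)
  }
  fixed_totals <- as.list(fixed_totals)
  structure(list(lanes = lanes, titrant = titrant,
                 fixed_totals = fixed_totals,
                 K3_assumed = K3_assumed, replicate_id = replicate_id),
            class = "titration_experiment")
}

#' Free eIF3 in a single titration lane
#'
#' At low 40S concentrations a large population of free 40S subunits competes
#' for eIF3, so the total eIF3 in a lane overstates the free concentration that
#' sets the occupancy of the PIC. All tracer-containing species are resolved on
#' the gel, so the eIF3-containing species can be reconstructed: the 43S-eIF3
#' complex is measured directly (`RTE = frac_43S_eIF3 * T_total`), and the
#' unobservable 40S-eIF3 complex follows from the mass-action relation of TC
#' binding to 40S-eIF3, `RE = K3 * RTE / T_free`. Free eIF3 is then the total
#' minus both complexes.
#'
#' With noisy fractions the subtraction can go (slightly) negative; the value
#' is floored at zero and flagged rather than dropped.
#'
#' @param frac_free,frac_43S_eIF3 Band fractions of the lane.
#' @param T_total Total tracer TC, nM.
#' @param E_total Total eIF3 in the lane, nM.
#' @param K3 Dissociation constant of TC for 40S-eIF3, nM (> 0).
#' @return List with `E_free`, `RE`, `RTE` (nM) and logical `floored`.
#' @export
free_eif3_in_lane <- function(frac_free, frac_43S_eIF3, T_total, E_total, K3) {
  frac_free <- as.numeric(frac_free)
  frac_43S_eIF3 <- as.numeric(frac_43S_eIF3)
  if (K3 <= 0) stop("K3 must be > 0", call. = FALSE)
  if (frac_free <= 0) {
    stop(paste("frac_free is zero: free eIF3 is not computable for this lane;",
               "exclude it from the corrected curve"), call. = FALSE)
  }
  RTE <- frac_43S_eIF3 * T_total
  T_free <- frac_free * T_total
  RE <- K3 * RTE / T_free
  E_free <- E_total - RTE - RE
  floored <- E_free < 0
  if (floored) {
    warning(sprintf(
      "computed free eIF3 is negative (%.3g nM) at E_total = %.3g nM; floored to 0",
      E_free, E_total), call. = FALSE)
    E_free <- 0
  }
  list(E_free = E_free, RE = RE, RTE = RTE, floored = floored)
}

#' Free-ligand corrected eIF3 binding curve
#'
#' Applies [free_eif3_in_lane()] to every lane of an eIF3 titration, producing
#' the curve of PIC-bound eIF3 fraction against *free* eIF3 on which the
#' eIF3:PIC dissociation constant is fit. Lanes where the correction had to be
#' floored at zero are flagged, not dropped.
#'
#' @param exp A [titration_experiment()] with `titrant = "eIF3"` and
#'   `K3_assumed` set.
#' @return An object of class `"corrected_curve"`: a data frame with columns
#'   `free_ligand` (nM), `response` and `flagged`, with attribute
#'   `response_def = "frac_43S_eIF3"`.
#' @export
correct_titration <- function(exp) {
  stopifnot(inherits(exp, "titration_experiment"))
  if (exp$titrant != "eIF3") {
    stop("correct_titration applies to eIF3 titrations; use tc_binding_curve ",
         "for 40S titrations", call. = FALSE)
  }
  if (is.null(exp$K3_assumed)) {
    stop("K3_assumed must be set on the experiment to correct an eIF3 titration",
         call. = FALSE)
  }
  T_total <- exp$fixed_totals$T_total
  n <- nrow(exp$lanes)
  out <- data.frame(free_ligand = numeric(n), response = numeric(n),
                    flagged = logical(n))
  for (i in seq_len(n)) {
    lane <- exp$lanes[i, ]
    cor <- free_eif3_in_lane(lane$frac_free, lane$frac_43S_eIF3,
                             T_total, lane$titrant_total_nM, exp$K3_assumed)
    out$free_ligand[i] <- cor$E_free
    out$response[i] <- lane$frac_43S_eIF3
    out$flagged[i] <- cor$floored
  }
  structure(out, response_def = "frac_43S_eIF3",
            replicate_id = exp$replicate_id, class = c("corrected_curve", "data.frame"))
}

#' Ternary-complex binding curve from a 40S titration
#'
#' For 40S titrations the tracer TC is held at 1--2 nM, at least five-fold
#' below the smallest dissociation constant measured, so depletion of the
#' titrant is negligible and total 40S stands in for free 40S. The response is
#' the total fraction of tracer in any PIC band
#' (`frac_43S + frac_43S_eIF3`).
#'
#' @param exp A [titration_experiment()] with `titrant = "40S"`.
#' @return A `"corrected_curve"` with `free_ligand` = total 40S (nM) and
#'   attribute `response_def = "frac_TC_bound"`.
#' @export
tc_binding_curve <- function(exp) {
  stopifnot(inherits(exp, "titration_experiment"))
  if (exp$titrant != "40S") {
    stop("tc_binding_curve applies to 40S titrations", call. = FALSE)
  }
  out <- data.frame(
    free_ligand = exp$lanes$titrant_total_nM,
    response = exp$lanes$frac_43S + exp$lanes$frac_43S_eIF3,
    flagged = FALSE)
  structure(out, response_def = "frac_TC_bound",
            replicate_id = exp$replicate_id, class = c("corrected_curve", "data.frame"))
}

# ---- delimited-table interface --------------------------------------------

titration_columns <- c("replicate_id", "titrant", "titrant_total_nM",
                       "frac_free", "frac_43S", "frac_43S_eIF3")

#' Read and write titration tables
#'
#' Titration tables are delimited text (comma or tab, inferred from the file
#' or set with `sep`) with a mandatory header row and columns `replicate_id`,
#' `titrant`, `titrant_total_nM`, `frac_free`, `frac_43S`, `frac_43S_eIF3`.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` infers from the header line.
#' @return `read_titration_table()` returns a data frame;
#'   `write_titration_table()` returns `path` invisibly.
#' @export
read_titration_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(titration_columns, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("malformed titration table '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' @rdname read_titration_table
#' @param tab Data frame in the titration table schema.
#' @export
write_titration_table <- function(tab, path, sep = ",") {
  stopifnot(all(titration_columns %in% names(tab)))
  utils::write.table(tab[titration_columns], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a titration table into per-replicate experiments
#'
#' @param tab Data frame in the titration table schema.
#' @param fixed_totals,K3_assumed Passed to [titration_experiment()].
#' @return Named list of `"titration_experiment"` objects, one per
#'   `replicate_id`.
#' @export
split_titrations <- function(tab, fixed_totals, K3_assumed = NULL) {
  stopifnot(all(titration_columns %in% names(tab)))
  lapply(split(tab, tab$replicate_id), function(d) {
    d <- d[order(d$titrant_total_nM), ]
    titration_experiment(
      d[c("titrant_total_nM", "frac_free", "frac_43S", "frac_43S_eIF3")],
      titrant = unique(d$titrant),
      fixed_totals = fixed_totals,
      K3_assumed = K3_assumed,
      replicate_id = as.character(d$replicate_id[1]))
  })
}
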