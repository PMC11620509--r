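#' Read and validate a long-format dosing/observation dataset
#'
#' Expects the column contract of [generate_study_dataset()].  Validation
#' failures are reported with the offending row numbers.  Clinical flow
#' units stay as stored (`QBLOOD` mL/min, `QEFF` mL/h); they are converted
#' to L/h where the model consumes them.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV", "MATRIX",
                "LLOQ", "WT", "AGE", "EGFR", "CKRT", "DIURESIS", "FILT",
                "QBLOOD", "QEFF", "UVOL", "HCT")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("dataset missing columns: ", paste(miss, collapse = ", "))
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      stop("dataset validation failed: ", msg, " (rows ",
           paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) ", ..." else "", ")")
  }
  obs <- d$EVID == 0
  bad(obs & !(d$MATRIX %in% .matrix_levels), "unknown MATRIX label")
  bad(obs & d$MDV == 1 & !is.na(d$DV), "DV present with MDV = 1")
  bad(d$EVID == 1 & (is.na(d$AMT) | d$AMT <= 0), "dose row with missing or negative AMT")
  bad(d$EVID == 1 & (is.na(d$RATE) | d$RATE <= 0), "dose row with missing or non-positive RATE")
  bad(obs & d$MDV == 0 & (is.na(d$DV) | d$DV < 0), "observation with missing or negative DV")
  bad(d$CKRT == 1 & is.na(d$QEFF), "CKRT row missing QEFF")
  bad(d$CKRT == 1 & is.na(d$QBLOOD), "CKRT row missing QBLOOD")
  bad(d$CKRT == 1 & is.na(d$FILT), "CKRT row missing FILT")
  bad(obs & d$MATRIX %in% "urine" & (is.na(d$UVOL) | d$UVOL <= 0),
      "urine record with missing or non-positive UVOL")
  d
}

#' Write a dataset to CSV
#'
#' @param data long-format data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.default_config <- function() {
  list(seed = 1L,
       out_dir = ".",
       parameters = list(),
       design = list(n_ckrt = 7, n_nonckrt = 9, weight_group = "mixed",
                     missingness_rate = 0),
       pta = list(
         n = 1000,
         mics = .default_mics,
         thresholds = c(45, 65),
         regimens = list(
           std_q8h = list(dose_per_kg = 40, infusion_duration = 0.5,
                          interval = 8),
           ckrt_adjusted = list(dose_per_kg = 40, infusion_duration = 0.5,
                                interval = 8, switch_at_dose = 4,
                                switch_interval = 12),
           extended_4h = list(dose_per_kg = 40, infusion_duration = 4,
                              interval = 8),
           ci_60 = list(dose_per_kg = 60, infusion_duration = 24,
                        interval = 24),
           ci_120 = list(dose_per_kg = 120, infusion_duration = 24,
                         interval = 24))))
}

#' Read a run configuration
#'
#' YAML configuration with keys `seed`, `out_dir`, `parameters` (overrides
#' for [population_parameters()]), `design` (arguments of
#' [cohort_design()]) and `pta` (`n`, `mics`, `thresholds`, `regimens` as
#' argument lists of [regimen()]).  Missing keys take package defaults; the
#' resolved configuration round-trips losslessly and is written next to the
#' outputs of every CLI run.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return the resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}

.config_pop <- function(cfg) {
  do.call(population_parameters, cfg$parameters)
}

.config_regimens <- function(cfg) {
  lapply(cfg$pta$regimens, function(a) do.call(regimen, c(a, list(horizon = 48))))
}

#' Table-style text report of a fit
#'
#' @param fit a [pk_fit()] result.
#' @return character vector of report lines.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "pedmero_fit"))
  fmt <- function(nm) {
    e <- fit$estimates[[nm]]
    r <- fit$rse_pct[[nm]]
    if (is.null(e) || is.na(e)) return("--")
    sprintf("%.3g (%s)", e, if (is.finite(r)) sprintf("%.0f", r) else "NA")
  }
  have <- function(nm) nm %in% names(fit$estimates)
  cv <- function(re) {
    o <- fit$omega2[[re]]
    if (is.null(o) || is.na(o)) "--" else sprintf("%.0f", 100 * sqrt(exp(o) - 1))
  }
  lines <- c(
    "Population pharmacokinetic parameter estimates",
    sprintf("  Patients: %d   Observations: %d   OFV: %.2f",
            length(fit$patients), fit$n_obs, fit$ofv),
    "  Parameter              Estimate (RSE%)   IPV CV% [shrinkage %]")
  row <- function(lab, nm, re = NULL) {
    sprintf("  %-22s %-17s %s", lab, fmt(nm),
            if (!is.null(re) && re %in% names(fit$omega2))
              sprintf("%s [%.0f]", cv(re), fit$shrinkage_pct[[re]]) else "")
  }
  if (have("theta_clr")) lines <- c(lines, row("CLR (L/h)", "theta_clr", "CLR"))
  if (have("t50_CLR_AGE")) lines <- c(lines, row("  T50 age (months)", "t50_CLR_AGE"))
  if (have("theta_clr_ckrt")) lines <- c(lines, row("CLR, CKRT+diuresis", "theta_clr_ckrt"))
  if (have("theta_clckrt")) lines <- c(lines, row("CLCKRT (L/h)", "theta_clckrt"))
  if (have("fac_CLCKRT_FILT_low")) lines <- c(lines, row("  FILT low", "fac_CLCKRT_FILT_low"))
  if (have("fac_CLCKRT_FILT_high")) lines <- c(lines, row("  FILT high", "fac_CLCKRT_FILT_high"))
  lines <- c(lines, row("CLM (L/h)", "theta_clm", "CLM"),
             row("V1 (L per 10 kg)", "theta_v1", "V1"))
  if (have("theta_cld")) lines <- c(lines, row("CLD (L/h)", "theta_cld"))
  if (have("theta_v2")) lines <- c(lines, row("V2 (L)", "theta_v2"))
  for (cl in names(fit$sigma_log))
    lines <- c(lines, sprintf("  sigma %-16s %.3g", cl, fit$sigma_log[[cl]]))
  lines
}
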