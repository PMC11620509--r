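#' Synthetic-cohort study design
#'
#' Describes the trial-design emulator: counts of CKRT and non-CKRT patients,
#' weight group, the nominal sparse sampling schedule relative to the
#' monitored dose, the number of preceding doses, assay LOQ and an optional
#' unstructured missingness rate.  The defaults reproduce the study design:
#' 16 patients (7 CKRT), 40 mg/kg q8h 30-min infusions with the CKRT interval
#' switched to q12h at the fourth dose, sampling at 0, 0.5, 2, 4, 6, 8 h
#' after the start of the fourth dose, LOQ 0.5 mg/L.  The 0.5 h
#' (end-of-infusion) point extends the nominal trough/2/4/6/8-h schedule so
#' that each patient contributes six samples per matrix.
#'
#' @param n_ckrt,n_nonckrt patient counts.
#' @param weight_group `"3-10"`, `"10-30"`, `"30-60"` (kg) or `"mixed"`.
#' @param sampling_times h relative to the monitored dose, within its interval.
#' @param doses_before_sampling doses given before the monitored dose.
#' @param loq assay lower limit of quantification, mg/L.
#' @param missingness_rate fraction of scheduled records dropped at random.
#' @param seed integer seed driving all generation randomness.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_ckrt = 7, n_nonckrt = 9, weight_group = "mixed",
                          sampling_times = c(0, 0.5, 2, 4, 6, 8),
                          doses_before_sampling = 3, loq = 0.5,
                          missingness_rate = 0, seed = 2024L) {
  weight_group <- match.arg(weight_group, c("mixed", "3-10", "10-30", "30-60"))
  stopifnot(n_ckrt >= 0, n_nonckrt >= 0, loq > 0,
            missingness_rate >= 0, missingness_rate < 1,
            all(sampling_times >= 0), all(sampling_times <= 8))
  structure(list(n_ckrt = n_ckrt, n_nonckrt = n_nonckrt,
                 weight_group = weight_group,
                 sampling_times = sort(sampling_times),
                 doses_before_sampling = doses_before_sampling,
                 loq = loq, missingness_rate = missingness_rate,
                 seed = as.integer(seed)), class = "cohort_design")
}

.weight_bounds <- function(group) {
  switch(group, "3-10" = c(3, 10), "10-30" = c(10, 30), "30-60" = c(30, 60),
         stop("unknown weight group: ", group))
}

.group_of_weight <- function(w) {
  ifelse(w < 10, "3-10", ifelse(w < 30, "10-30", "30-60"))
}

# Weight-conditional age sampler: log-linear growth-curve-style median with
# lognormal scatter, calibrated so the median (weight, age) pairs bracket the
# cohort medians (non-CKRT 7.5 kg / 8 mo, CKRT 20 kg / 48 mo).
.age_from_weight <- function(weight) {
  b <- log(48 / 8) / log(20 / 7.5)
  a <- log(8) - b * log(7.5)
  age <- exp(a + b * log(weight) + rnorm(length(weight), 0, 0.45))
  pmin(pmax(age, 1), 216)
}

#' Draw one virtual patient
#'
#' Samples covariates, circuit settings and individual random effects for a
#' virtual patient of the study population.  Weight is uniform within its
#' group (log-uniform over 3-60 kg for `"mixed"`); age follows a
#' weight-conditional growth-curve-style distribution; eGFR (non-CKRT) is
#' uniform within the group's assigned range (60-120 for the two lower
#' weight groups, 120-130 mL/min/1.73 m2 for 30-60 kg, independent of
#' weight); the filter surface follows the weight-group mapping (low 0.2 m2 /
#' medium 0.6 m2 / high 1.2 m2); blood flow and per-kg effluent flow are
#' drawn from the observed clinical ranges.  Draws with
#' `cl_ckrt >= phi_plasma_corr` (which would imply a negative postfilter
#' concentration) are rejected and redrawn.  Uses the current RNG stream:
#' callers seed via `set.seed()` or a [cohort_design()] seed.
#'
#' @param weight_group `"3-10"`, `"10-30"`, `"30-60"` or `"mixed"`.
#' @param ckrt logical.
#' @param pop a [population_parameters()] object (its `omega2` drives the
#'   random effects; set to 0 for typical-value patients).
#' @param diuresis optional logical override for CKRT patients (default:
#'   Bernoulli with the cohort's 3/7 diuresis frequency).
#' @return a list of class `virtual_patient` with elements `cov`
#'   ([patient_covariates()]), `circ` ([filter_circuit()] or `NULL`), `eta`
#'   (named vector) and `ip` ([individual_parameters()]).
#' @export
sample_virtual_patient <- function(weight_group, ckrt, pop, diuresis = NULL) {
  stopifnot(inherits(pop, "pop_parameters"))
  for (attempt in 1:100) {
    weight <- if (weight_group == "mixed") {
      exp(runif(1, log(3), log(60)))
    } else {
      bb <- .weight_bounds(weight_group)
      runif(1, bb[1], bb[2])
    }
    age <- .age_from_weight(weight)
    grp <- .group_of_weight(weight)
    hct <- runif(1, 0.25, 0.40)
    if (!ckrt) {
      rng <- if (grp == "30-60") c(120, 130) else c(60, 120)
      egfr <- runif(1, rng[1], rng[2])
      cov <- patient_covariates(weight, age, egfr = egfr, ckrt = FALSE,
                                hematocrit = hct,
                                urine_output_rate = runif(1, 14, 125))
      circ <- NULL
    } else {
      diu <- if (is.null(diuresis)) runif(1) < 3 / 7 else diuresis
      cov <- patient_covariates(weight, age, ckrt = TRUE, diuresis = diu,
                                hematocrit = hct,
                                urine_output_rate =
                                  if (diu) runif(1, 1.25, 15.4) else NA_real_)
      surf <- c("3-10" = "low", "10-30" = "medium", "30-60" = "high")[[grp]]
      eff_pars <- list(low = c(44, 8), medium = c(60, 4), high = c(46, 12))[[surf]]
      eff_kg <- max(10, rnorm(1, eff_pars[1], eff_pars[2]))
      circ <- filter_circuit(surf,
                             blood_flow_ml_min = runif(1, 40, 100),
                             effluent_flow_ml_h = eff_kg * weight,
                             bpr = 1 - hct)
    }
    eff_names <- names(pop$omega2)
    eta <- setNames(rnorm(length(eff_names), 0, sqrt(pop$omega2)), eff_names)
    ip <- individual_parameters(cov, pop, circ, eta)
    if (is.null(attr(ip, "invalid_flow")))
      return(structure(list(cov = cov, circ = circ, eta = eta, ip = ip),
                       class = "virtual_patient"))
  }
  stop("could not draw a valid patient (cl_ckrt < phi_plasma_corr) in 100 tries")
}

#' Generate a synthetic sparse multi-matrix study dataset
#'
#' Emulates the trial design: every patient receives 40 mg/kg as 30-min
#' infusions every 8 h; in CKRT patients the interval switches to 12 h at the
#' fourth dose.  Sampling starts at the dose following
#' `doses_before_sampling` doses.  Each CKRT patient contributes prefilter,
#' postfilter and effluent concentrations at the six nominal times
#' (18 scheduled records); each non-CKRT patient contributes six plasma
#' samples and six urine collections (12 records).  Urine collections span
#' consecutive sampling times, the first starting at the previous dose;
#' `U_Vol = urine_output_rate x interval length`.  Observations are the model
#' predictions perturbed by lognormal residual error with the matrix class's
#' log-scale SD; records below the LOQ are flagged and (by default) dropped;
#' unstructured missingness is applied after flagging.
#'
#' @param design a [cohort_design()].
#' @param pop a [population_parameters()] providing the ground truth.
#' @param dose_per_kg dose, mg/kg (default 40).
#' @param lloq_action `"drop"` (default) or `"flag"` (keep flagged rows).
#' @return a list with `data` (long-format data.frame; see Details), `truth`
#'   (per-patient data.frame of covariates, true etas and true individual
#'   parameters) and `predictions` (noiseless predictions of all scheduled
#'   records).
#' @details The dataset columns are `ID`, `TIME` (h since first dose), `EVID`
#'   (1 dose / 0 observation), `AMT` (mg), `RATE` (mg/h), `DV` (mg/L), `MDV`,
#'   `MATRIX`, `LLOQ` (below-LOQ flag), `WT`, `AGE`, `EGFR`, `CKRT`,
#'   `DIURESIS`, `FILT`, `QBLOOD` (mL/min), `QEFF` (mL/h), `UVOL` (mL),
#'   `HCT`.  With the design seed fixed, generation is byte-identical across
#'   runs.
#' @examples
#' ds <- generate_study_dataset(cohort_design(n_ckrt = 1, n_nonckrt = 0,
#'                                            seed = 1))
#' sum(ds$data$EVID == 0)  # 18 scheduled records per CKRT patient
#' @export
generate_study_dataset <- function(design, pop = population_parameters(),
                                   dose_per_kg = 40,
                                   lloq_action = c("drop", "flag")) {
  stopifnot(inherits(design, "cohort_design"))
  lloq_action <- match.arg(lloq_action)
  set.seed(design$seed)
  n <- design$n_ckrt + design$n_nonckrt
  cols <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV", "MATRIX",
            "LLOQ", "WT", "AGE", "EGFR", "CKRT", "DIURESIS", "FILT",
            "QBLOOD", "QEFF", "UVOL", "HCT")
  if (n == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(list(data = empty, truth = NULL, predictions = NULL))
  }
  is_ckrt <- rep(c(TRUE, FALSE), c(design$n_ckrt, design$n_nonckrt))
  rows <- list(); truth <- list(); preds <- list()
  for (i in seq_len(n)) {
    vp <- sample_virtual_patient(design$weight_group, is_ckrt[i], pop)
    cov <- vp$cov; circ <- vp$circ; ip <- vp$ip
    reg <- if (is_ckrt[i])
      regimen(dose_per_kg, 0.5, 8, switch_at_dose = 4, switch_interval = 12,
              horizon = 40)
    else regimen(dose_per_kg, 0.5, 8, horizon = 40)
    ev <- dose_events(reg, cov$weight)
    t_mon <- ev$time[design$doses_before_sampling + 1]
    obs_t <- t_mon + design$sampling_times
    base <- data.frame(
      ID = i, WT = cov$weight, AGE = cov$age, EGFR = cov$egfr,
      CKRT = as.integer(is_ckrt[i]),
      DIURESIS = as.integer(isTRUE(cov$diuresis)),
      FILT = if (is_ckrt[i]) circ$surface else NA_character_,
      QBLOOD = if (is_ckrt[i]) circ$phi_blood / 0.06 else NA_real_,
      QEFF = if (is_ckrt[i]) circ$phi_effluent * 1000 else NA_real_,
      HCT = cov$hematocrit)
    dose_rows <- cbind(data.frame(TIME = ev$time, EVID = 1, AMT = ev$amt,
                                  RATE = ev$rate, DV = NA_real_, MDV = 1,
                                  MATRIX = NA_character_, LLOQ = 0,
                                  UVOL = NA_real_), base)
    if (is_ckrt[i]) {
      st <- simulate_amounts(ip, times = obs_t, events = ev)
      pr <- predict_concentrations(st, ip, circ = circ)
      pr <- pr[pr$matrix %in% c("prefilter", "postfilter", "effluent"), ]
      uvol <- rep(NA_real_, nrow(pr))
    } else {
      t_prev <- max(ev$time[ev$time < obs_t[1]])
      u_start <- c(t_prev, obs_t[-length(obs_t)])
      grid <- sort(unique(c(obs_t, u_start)))
      st <- simulate_amounts(ip, times = grid, events = ev)
      uv <- data.frame(t_start = u_start, t_end = obs_t,
                       u_vol = cov$urine_output_rate * (obs_t - u_start))
      pr <- predict_concentrations(st, ip, urine = uv)
      pr <- pr[pr$matrix == "plasma" & pr$time %in% obs_t |
                 pr$matrix == "urine", ]
      uvol <- ifelse(pr$matrix == "urine",
                     uv$u_vol[match(pr$time, uv$t_end)], NA_real_)
    }
    sig <- pop$sigma_log[residual_class(pr$matrix)]
    dv <- pr$conc * exp(rnorm(nrow(pr), 0, sig))
    obs_rows <- cbind(data.frame(TIME = pr$time, EVID = 0, AMT = NA_real_,
                                 RATE = NA_real_, DV = dv, MDV = 0,
                                 MATRIX = pr$matrix,
                                 LLOQ = as.integer(dv < design$loq),
                                 UVOL = uvol), base)
    rows[[i]] <- rbind(dose_rows, obs_rows)
    truth[[i]] <- cbind(data.frame(ID = i), base[1, setdiff(names(base), "ID")],
                        as.data.frame(as.list(setNames(
                          vp$eta, paste0("ETA_", names(vp$eta))))),
                        data.frame(CL_RENAL = ip$cl_renal, CL_M = ip$cl_m,
                                   CL_CKRT = ip$cl_ckrt, V1 = ip$v1,
                                   V2 = ip$v2, CL_D = ip$cl_d))
    preds[[i]] <- data.frame(ID = i, TIME = pr$time, MATRIX = pr$matrix,
                             PRED_TRUE = pr$conc)
  }
  data <- do.call(rbind, rows)
  ord <- order(data$ID, data$TIME, -data$EVID)
  data <- data[ord, cols]
  if (lloq_action == "drop")
    data <- data[!(data$EVID == 0 & data$LLOQ == 1), ]
  if (design$missingness_rate > 0) {
    drop <- data$EVID == 0 &
      runif(nrow(data)) < design$missingness_rate
    data <- data[!drop, ]
  }
  rownames(data) <- NULL
  list(data = data, truth = do.call(rbind, truth),
       predictions = do.call(rbind, preds))
}
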