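#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, random-effect variances and residual
#' log-scale standard deviations of the meropenem model.  The defaults are the
#' final covariate-model estimates for critically ill children with and
#' without continuous kidney replacement therapy (CKRT): renal clearance
#' scales linearly with eGFR (reference 95 mL/min/1.73 m2) and matures with
#' postnatal age through a hyperbolic (Emax-type) function; CKRT patients with
#' residual diuresis have a constant renal clearance and anuric patients none;
#' extracorporeal clearance is proportional to a filter-surface factor; the
#' central volume scales linearly with weight (reference 10 kg).
#'
#' @param theta_clr typical renal clearance at eGFR 95 and full maturation, L/h.
#' @param theta_50 postnatal age at half-mature renal clearance, months.
#' @param hill Hill exponent of the maturation function (dimensionless).
#' @param theta_clr_ckrt renal clearance of CKRT patients with diuresis, L/h.
#' @param theta_clckrt extracorporeal (hemofilter) clearance at the
#'   medium-surface reference, L/h.
#' @param filt_factors named numeric, multiplicative filter-surface factors for
#'   `low` (0.2 m2), `medium` (0.6 m2, reference = 1) and `high` (1.2 m2).
#' @param theta_clm non-renal (metabolic) clearance, L/h.
#' @param theta_v1 central volume of distribution at the 10-kg reference, L.
#' @param theta_cld inter-compartmental (distribution) clearance, L/h.
#' @param theta_v2 peripheral volume of distribution, L.
#' @param omega2 named numeric, variances of the lognormal random effects on
#'   `CLR`, `CLM` and `V1` (optionally `CLCKRT`).
#' @param sigma_log named numeric, additive log-scale residual SDs per
#'   residual class (`plasma_prefilter`, `postfilter`, `effluent`, `urine`),
#'   in log(mg/L).
#' @param egfr_ref,wgt_ref covariate reference values (population medians).
#'
#' @return an object of class `pop_parameters`.
#' @examples
#' pop <- population_parameters()
#' pop$theta_clr       # 5.5 L/h at eGFR 95 and full maturation
#' @export
population_parameters <- function(theta_clr = 5.5,
                                  theta_50 = 15.6,
                                  hill = 1,
                                  theta_clr_ckrt = 0.96,
                                  theta_clckrt = 1.26,
                                  filt_factors = c(low = 0.27, medium = 1, high = 1.5),
                                  theta_clm = 0.91,
                                  theta_v1 = 4.75,
                                  theta_cld = 0.28,
                                  theta_v2 = 10.7,
                                  omega2 = c(CLR = log(1 + 0.30^2),
                                             CLM = log(1 + 0.86^2),
                                             V1 = log(1 + 0.48^2)),
                                  sigma_log = c(plasma_prefilter = 0.38,
                                                postfilter = 0.38,
                                                effluent = 0.37,
                                                urine = 0.86),
                                  egfr_ref = 95,
                                  wgt_ref = 10) {
  thetas <- c(theta_clr = theta_clr, theta_50 = theta_50, hill = hill,
              theta_clr_ckrt = theta_clr_ckrt, theta_clckrt = theta_clckrt,
              theta_clm = theta_clm, theta_v1 = theta_v1,
              theta_cld = theta_cld, theta_v2 = theta_v2)
  if (any(!is.finite(thetas)) || any(thetas <= 0))
    stop("all fixed-effect parameters must be finite and positive")
  if (!all(c("low", "medium", "high") %in% names(filt_factors)))
    stop("filt_factors must name 'low', 'medium' and 'high'")
  if (abs(filt_factors[["medium"]] - 1) > 1e-12)
    stop("filt_factors['medium'] is the reference and must equal 1")
  if (any(omega2 < 0)) stop("omega2 variances must be >= 0")
  if (!all(names(sigma_log) %in% .residual_classes))
    stop("unknown residual class in sigma_log")
  structure(list(theta_clr = theta_clr, theta_50 = theta_50, hill = hill,
                 theta_clr_ckrt = theta_clr_ckrt, theta_clckrt = theta_clckrt,
                 filt_factors = filt_factors, theta_clm = theta_clm,
                 theta_v1 = theta_v1, theta_cld = theta_cld,
                 theta_v2 = theta_v2, omega2 = omega2, sigma_log = sigma_log,
                 egfr_ref = egfr_ref, wgt_ref = wgt_ref),
            class = "pop_parameters")
}

#' @export
print.pop_parameters <- function(x, ...) {
  cat("Population PK parameters (meropenem, paediatric ICU +/- CKRT)\n")
  cat(sprintf("  CLR:   %.3g L/h x (eGFR/%g) x AGE^h/(AGE^h + %.3g^h), h = %g\n",
              x$theta_clr, x$egfr_ref, x$theta_50, x$hill))
  cat(sprintf("  CLR (CKRT + diuresis): %.3g L/h; anuric: 0\n", x$theta_clr_ckrt))
  cat(sprintf("  CLCKRT: %.3g L/h x FILT (low %.3g / medium 1 / high %.3g)\n",
              x$theta_clckrt, x$filt_factors[["low"]], x$filt_factors[["high"]]))
  cat(sprintf("  CLM: %.3g L/h   V1: %.3g L x (WGT/%g)   CLD: %.3g L/h   V2: %.3g L\n",
              x$theta_clm, x$theta_v1, x$wgt_ref, x$theta_cld, x$theta_v2))
  cat("  omega2:", paste(sprintf("%s=%.3g", names(x$omega2), x$omega2),
                         collapse = " "), "\n")
  cat("  sigma (log):", paste(sprintf("%s=%.2g", names(x$sigma_log), x$sigma_log),
                              collapse = " "), "\n")
  invisible(x)
}

#' Patient covariates
#'
#' @param weight body weight, kg (> 0).
#' @param age postnatal age, months (>= 0).
#' @param egfr estimated glomerular filtration rate, mL/min/1.73 m2; required
#'   for non-CKRT patients (it does not enter the model under CKRT).
#' @param ckrt logical, is the patient on continuous kidney replacement
#'   therapy?
#' @param diuresis logical, residual diuresis; only meaningful when
#'   `ckrt = TRUE` (non-CKRT patients always produce urine).
#' @param hematocrit haematocrit as a fraction (0-1); used to derive the
#'   blood-to-plasma ratio of the circuit.
#' @param urine_output_rate urine output, mL/h; required for urine-matrix
#'   predictions (non-CKRT, or CKRT with diuresis).
#' @return an object of class `patient_covariates`.
#' @export
patient_covariates <- function(weight, age, egfr = NA_real_, ckrt = FALSE,
                               diuresis = NA, hematocrit = 0.3,
                               urine_output_rate = NA_real_) {
  stopifnot(is.numeric(weight), weight > 0, is.numeric(age), age >= 0)
  if (!ckrt && (is.na(egfr) || egfr <= 0))
    stop("a positive eGFR is required for a non-CKRT patient")
  if (!ckrt && !is.na(diuresis))
    stop("diuresis is only defined for CKRT patients")
  if (ckrt && is.na(diuresis))
    stop("diuresis status (TRUE/FALSE) is required for a CKRT patient")
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be a fraction in (0, 1)")
  structure(list(weight = weight, age = age, egfr = egfr, ckrt = ckrt,
                 diuresis = if (ckrt) diuresis else TRUE,
                 hematocrit = hematocrit,
                 urine_output_rate = urine_output_rate),
            class = "patient_covariates")
}

#' Hemofilter circuit description
#'
#' Clinical units are converted on ingestion: blood flow mL/min -> L/h,
#' effluent flow mL/h -> L/h.  The corrected plasma flow is
#' `phi_plasma_corr = phi_blood x BPR`, where BPR is the blood-to-plasma
#' concentration ratio; red-cell partitioning of meropenem is negligible, so
#' the default BPR is `1 - hematocrit`.
#'
#' @param surface filter surface category: `"low"` (0.2 m2), `"medium"`
#'   (0.6 m2) or `"high"` (1.2 m2).
#' @param blood_flow_ml_min blood flow in mL/min.
#' @param effluent_flow_ml_h total effluent flow in mL/h.
#' @param bpr blood-to-plasma concentration ratio in (0, 1].
#' @return an object of class `filter_circuit` with flows in L/h.
#' @examples
#' filter_circuit("medium", blood_flow_ml_min = 70, effluent_flow_ml_h = 1200,
#'                bpr = 0.65)
#' @export
filter_circuit <- function(surface, blood_flow_ml_min, effluent_flow_ml_h,
                           bpr = 0.65) {
  surface <- match.arg(surface, c("low", "medium", "high"))
  phi_blood <- blood_flow_ml_min * 60 / 1000   # mL/min -> L/h
  phi_effluent <- effluent_flow_ml_h / 1000    # mL/h  -> L/h
  if (phi_blood <= 0 || phi_effluent <= 0) stop("circuit flows must be > 0")
  if (bpr <= 0 || bpr > 1) stop("bpr must be in (0, 1]")
  structure(list(surface = surface,
                 surface_m2 = c(low = 0.2, medium = 0.6, high = 1.2)[[surface]],
                 phi_blood = phi_blood,
                 phi_effluent = phi_effluent,
                 bpr = bpr,
                 phi_plasma_corr = phi_blood * bpr),
            class = "filter_circuit")
}

#' Individual pharmacokinetic parameters from the covariate model
#'
#' Applies the final covariate model to one patient.  For a non-CKRT patient
#' the renal clearance is
#' `theta_clr * (eGFR/95) * AGE^h / (AGE^h + theta_50^h) * exp(eta_CLR)`;
#' a CKRT patient with diuresis has constant renal clearance
#' `theta_clr_ckrt * exp(eta_CLR)` and an anuric CKRT patient none.
#' Extracorporeal clearance is `theta_clckrt * filt_factor[surface]` with no
#' random effect in the final model.  `V1` scales linearly with weight.
#'
#' @param cov a [patient_covariates()] object.
#' @param pop a [population_parameters()] object.
#' @param circ a [filter_circuit()] object; required iff `cov$ckrt`.
#' @param eta named numeric vector of random effects (`CLR`, `CLM`, `V1`,
#'   optionally `CLCKRT`); defaults to all zero (typical patient).
#' @return an object of class `individual_parameters` with elements
#'   `cl_renal`, `cl_m`, `cl_ckrt`, `v1`, `v2`, `cl_d` (all L or L/h) and the
#'   derived `cl_total`.
#' @examples
#' pop <- population_parameters()
#' cov <- patient_covariates(weight = 10, age = 42, egfr = 95)
#' ip <- individual_parameters(cov, pop)
#' ip$cl_renal  # 5.5 * 42/(42 + 15.6) = 4.010 L/h
#' ip$cl_total  # 4.920 L/h
#' @export
individual_parameters <- function(cov, pop, circ = NULL,
                                  eta = c(CLR = 0, CLM = 0, V1 = 0)) {
  stopifnot(inherits(cov, "patient_covariates"),
            inherits(pop, "pop_parameters"))
  if (cov$ckrt && is.null(circ))
    stop("a filter_circuit is required for a CKRT patient")
  if (!cov$ckrt && !is.null(circ))
    stop("a filter_circuit was supplied for a non-CKRT patient")
  e <- function(nm) if (nm %in% names(eta)) exp(eta[[nm]]) else 1
  if (!cov$ckrt) {
    h <- pop$hill
    mat <- cov$age^h / (cov$age^h + pop$theta_50^h)
    cl_renal <- pop$theta_clr * (cov$egfr / pop$egfr_ref) * mat * e("CLR")
    cl_ckrt <- 0
  } else if (isTRUE(cov$diuresis)) {
    cl_renal <- pop$theta_clr_ckrt * e("CLR")
    cl_ckrt <- pop$theta_clckrt * pop$filt_factors[[circ$surface]] * e("CLCKRT")
  } else {
    cl_renal <- 0
    cl_ckrt <- pop$theta_clckrt * pop$filt_factors[[circ$surface]] * e("CLCKRT")
  }
  ip <- structure(list(
    cl_renal = cl_renal,
    cl_m = pop$theta_clm * e("CLM"),
    cl_ckrt = cl_ckrt,
    v1 = pop$theta_v1 * (cov$weight / pop$wgt_ref) * e("V1"),
    v2 = pop$theta_v2,
    cl_d = pop$theta_cld), class = "individual_parameters")
  ip$cl_total <- ip$cl_renal + ip$cl_m + ip$cl_ckrt
  if (!is.null(circ) && ip$cl_ckrt >= circ$phi_plasma_corr)
    attr(ip, "invalid_flow") <- TRUE
  ip
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf(paste0("Individual PK parameters: CLR %.3g, CLM %.3g, ",
                     "CLCKRT %.3g, total CL %.3g L/h; V1 %.3g L, V2 %.3g L, ",
                     "CLD %.3g L/h\n"),
              x$cl_renal, x$cl_m, x$cl_ckrt, x$cl_total, x$v1, x$v2, x$cl_d))
  invisible(x)
}

#' Clearance partition of a typical patient
#'
#' Convenience summary of the share each elimination route contributes to the
#' total clearance, in percent.
#'
#' @inheritParams individual_parameters
#' @return named numeric: `renal`, `metabolic`, `extracorporeal` percentages.
#' @examples
#' pop <- population_parameters()
#' cov <- patient_covariates(weight = 20, age = 48, ckrt = TRUE, diuresis = TRUE)
#' circ <- filter_circuit("medium", 70, 1200)
#' clearance_shares(cov, pop, circ)["extracorporeal"]  # ~40%
#' @export
clearance_shares <- function(cov, pop, circ = NULL,
                             eta = c(CLR = 0, CLM = 0, V1 = 0)) {
  ip <- individual_parameters(cov, pop, circ, eta)
  100 * c(renal = ip$cl_renal, metabolic = ip$cl_m,
          extracorporeal = ip$cl_ckrt) / ip$cl_total
}
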