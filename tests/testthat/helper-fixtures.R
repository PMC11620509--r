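# shared fixtures: built in code, deterministic

table4_pop <- function(...) population_parameters(...)

# population with (numerically) no interindividual variability / noise
degenerate_pop <- function(sigma = 1e-6) {
  population_parameters(
    omega2 = c(CLR = 1e-12, CLM = 1e-12, V1 = 1e-12),
    sigma_log = c(plasma_prefilter = sigma, postfilter = sigma,
                  effluent = sigma, urine = sigma))
}

typical_nonckrt <- function(pop = table4_pop(), weight = 10, age = 42,
                            egfr = 95) {
  individual_parameters(patient_covariates(weight, age, egfr), pop)
}

# hand-built individual parameters for solver edge cases
raw_ip <- function(cl_renal = 0, cl_m = 0, cl_ckrt = 0, v1 = 1, v2 = 0,
                   cl_d = 0) {
  ip <- structure(list(cl_renal = cl_renal, cl_m = cl_m, cl_ckrt = cl_ckrt,
                       v1 = v1, v2 = v2, cl_d = cl_d),
                  class = "individual_parameters")
  ip$cl_total <- cl_renal + cl_m + cl_ckrt
  ip
}

# random positive parameter/regimen draws for solver property tests
random_solver_case <- function() {
  ip <- raw_ip(cl_renal = exp(runif(1, -2, 2)),
               cl_m = exp(runif(1, -2, 1)),
               cl_ckrt = if (runif(1) < 0.5) exp(runif(1, -3, 0.5)) else 0,
               v1 = exp(runif(1, 0, 3)),
               v2 = exp(runif(1, 0.5, 3.5)),
               cl_d = exp(runif(1, -3, 1)))
  reg <- regimen(dose_per_kg = runif(1, 10, 120),
                 infusion_duration = runif(1, 0.25, 4),
                 interval = sample(c(6, 8, 12, 24), 1),
                 horizon = 48)
  list(ip = ip, reg = reg, weight = runif(1, 3, 60))
}

# single-patient dataset built by hand (long format)
one_patient_data <- function(dose_amt = 100, dose_rate = 1e7, obs_time = 1e-3,
                             dv, matrix = "plasma", wt = 10, age = 42,
                             egfr = 95) {
  data.frame(
    ID = 1, TIME = c(0, obs_time), EVID = c(1, 0),
    AMT = c(dose_amt, NA), RATE = c(dose_rate, NA),
    DV = c(NA, dv), MDV = c(1, 0), MATRIX = c(NA, matrix), LLOQ = 0,
    WT = wt, AGE = age, EGFR = egfr, CKRT = 0, DIURESIS = NA,
    FILT = NA, QBLOOD = NA, QEFF = NA, UVOL = NA, HCT = 0.3)
}

jittered_inits <- function(pop, seed) {
  set.seed(seed)
  j <- function(x) x * runif(length(x), 0.5, 1.5)
  population_parameters(
    theta_clr = j(pop$theta_clr), theta_50 = j(pop$theta_50),
    theta_clr_ckrt = j(pop$theta_clr_ckrt),
    theta_clckrt = j(pop$theta_clckrt),
    filt_factors = c(low = unname(j(pop$filt_factors[["low"]])), medium = 1,
                     high = unname(j(pop$filt_factors[["high"]]))),
    theta_clm = j(pop$theta_clm), theta_v1 = j(pop$theta_v1),
    theta_cld = j(pop$theta_cld), theta_v2 = j(pop$theta_v2),
    omega2 = pop$omega2 * runif(length(pop$omega2), 0.6, 1.6),
    sigma_log = pop$sigma_log * runif(length(pop$sigma_log), 0.7, 1.4))
}

# non-CKRT-only model spec used for SCM and compact estimation tests
nonckrt_spec <- function(with_egfr = TRUE) {
  terms <- list(
    list(param = "CLR", cov = "AGE", form = "emax", ref = NA),
    list(param = "V1", cov = "WT", form = "ratio", ref = 10))
  if (with_egfr)
    terms <- c(list(list(param = "CLR", cov = "EGFR", form = "ratio",
                         ref = 95)), terms)
  model_spec("2-cpt", covariate_terms = terms,
             random_effects = c("CLR", "CLM", "V1"))
}
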