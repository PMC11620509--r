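test_that("a single fixed-effects observation gives the closed-form normal -2LL", {
  spec <- model_spec("1-cpt", random_effects = character(0))
  params <- list(theta_clr = 0.8, theta_clm = 0.4, theta_v1 = 5,
                 omega2 = numeric(0), sigma_log = c(plasma_prefilter = 0.25))
  dat <- one_patient_data(dose_amt = 100, obs_time = 2, dv = 7.3)
  ll <- neg2_loglik(spec, params, dat)
  # oracle: simulate the prediction, apply the log-normal density directly
  ip <- raw_ip(cl_renal = 0.8, cl_m = 0.4, v1 = 5)
  ev <- data.frame(time = 0, amt = 100, rate = 1e7, duration = 1e-5)
  pred <- simulate_amounts(ip, times = 2, events = ev)$a_central / 5
  expected <- log(2 * pi * 0.25^2) + (log(7.3) - log(pred))^2 / 0.25^2
  expect_equal(ll, expected, tolerance = 1e-8)
})

test_that("doubling sigma on zero-residual data adds 2 n log 2 to the -2LL", {
  spec <- model_spec("1-cpt", random_effects = character(0))
  ip <- raw_ip(cl_renal = 0.8, cl_m = 0.4, v1 = 5)
  ev <- data.frame(time = 0, amt = 100, rate = 1e7, duration = 1e-5)
  tt <- c(1, 2, 4, 6)
  pred <- simulate_amounts(ip, times = tt, events = ev)$a_central / 5
  dat <- do.call(rbind, lapply(seq_along(tt), function(i)
    one_patient_data(obs_time = tt[i], dv = pred[i])))
  dat$ID <- 1; dat <- dat[!duplicated(paste(dat$TIME, dat$EVID)), ]
  params <- list(theta_clr = 0.8, theta_clm = 0.4, theta_v1 = 5,
                 omega2 = numeric(0), sigma_log = c(plasma_prefilter = 0.2))
  params2 <- modifyList(params, list(sigma_log = c(plasma_prefilter = 0.4)))
  d <- neg2_loglik(spec, params2, dat) - neg2_loglik(spec, params, dat)
  expect_equal(d, 2 * length(tt) * log(2), tolerance = 1e-8)
})

test_that("the Laplace marginal is exact in the log-linear (conjugate) case", {
  # near-instant bolus observed immediately: log C = log(D/theta_v1) - eta_V1,
  # so the marginal of log DV is N(log(D/theta_v1), sigma^2 + omega^2)
  spec <- model_spec("1-cpt", random_effects = "V1")
  sigma <- 0.2; omega2 <- 0.09; D <- 100; v1 <- 5; dv <- 25
  params <- list(theta_clr = 1e-9, theta_clm = 1e-9, theta_v1 = v1,
                 omega2 = c(V1 = omega2),
                 sigma_log = c(plasma_prefilter = sigma))
  dat <- one_patient_data(dose_amt = D, obs_time = 1e-3, dv = dv)
  ll <- neg2_loglik(spec, params, dat)
  s2 <- sigma^2 + omega2
  expected <- log(2 * pi * s2) + (log(dv) - log(D / v1))^2 / s2
  expect_equal(ll, expected, tolerance = 1e-5)
})

test_that("noise-free data identify the fixed effects", {
  pop0 <- population_parameters(
    omega2 = c(CLR = 1e-12, CLM = 1e-12, V1 = 1e-12),
    sigma_log = c(plasma_prefilter = 1e-4, postfilter = 1e-4,
                  effluent = 1e-4, urine = 1e-4))
  ds <- generate_study_dataset(cohort_design(n_ckrt = 0, n_nonckrt = 6,
                                             seed = 81), pop0,
                               lloq_action = "flag")
  inits <- population_parameters(
    theta_clr = 5.5 * 1.15, theta_clm = 0.91 * 0.9, theta_v1 = 4.75 * 1.1,
    theta_cld = 0.28 * 1.1, theta_v2 = 10.7 * 0.9,
    omega2 = c(CLR = 1e-6, CLM = 1e-6, V1 = 1e-6),
    sigma_log = c(plasma_prefilter = 1e-4, postfilter = 1e-4,
                  effluent = 1e-4, urine = 1e-4))
  fit <- pk_fit(nonckrt_spec(), ds$data, inits = inits, compute_se = FALSE,
                control = list(iter.max = 3000, eval.max = 10000,
                               rel.tol = 1e-10))
  for (nm in c("theta_clr", "theta_clm", "theta_v1", "theta_cld", "theta_v2"))
    expect_equal(fit$estimates[[nm]],
                 unclass(pop0)[[nm]], tolerance = 5e-3, label = nm)
})

test_that("the optimizer never worsens the initial objective", {
  pop <- table4_pop()
  ds <- generate_study_dataset(cohort_design(n_ckrt = 2, n_nonckrt = 4,
                                             seed = 91), pop)
  fit <- pk_fit(final_model_spec(), ds$data,
                inits = jittered_inits(pop, 1), compute_se = FALSE)
  expect_lte(fit$ofv, fit$ofv_init)
})

test_that("fits are equivariant to rescaling doses and concentrations", {
  pop <- table4_pop()
  ds <- generate_study_dataset(cohort_design(n_ckrt = 0, n_nonckrt = 12,
                                             seed = 95), pop)
  f1 <- pk_fit(nonckrt_spec(), ds$data, inits = pop, compute_se = FALSE)
  scaled <- ds$data
  scaled$AMT <- scaled$AMT * 10; scaled$RATE <- scaled$RATE * 10
  scaled$DV <- scaled$DV * 10
  f2 <- pk_fit(nonckrt_spec(), scaled, inits = pop, compute_se = FALSE)
  # the sparse design leaves CLD/V2 on a flat ridge, so the comparison
  # covers the identifiable parameters and the objective value
  for (nm in c("theta_clr", "theta_v1", "sigma_plasma_prefilter",
               "sigma_urine"))
    expect_equal(f2$estimates[[nm]], f1$estimates[[nm]], tolerance = 0.05,
                 label = nm)
  expect_lt(abs(f2$ofv - f1$ofv), 0.5)
})

test_that("objective-function comparison uses the stated thresholds", {
  cmp <- compare_models(full = 100, reduced = 104, df = 1)
  expect_true(cmp$significant_05)
  expect_false(cmp$significant_01)
  expect_equal(cmp$threshold_05, 3.84)
  expect_equal(cmp$threshold_01, 6.61)
  cmp0 <- compare_models(full = 100, reduced = 100, df = 1)
  expect_false(cmp0$significant_05)
  cmp2 <- compare_models(full = 100, reduced = 110, df = 2)
  expect_equal(cmp2$threshold_05, qchisq(0.95, 2), tolerance = 1e-6)
  expect_equal(cmp2$threshold_01, qchisq(0.99, 2), tolerance = 1e-6)
  expect_equal(round(cmp2$threshold_05, 2), 5.99)
  expect_equal(round(cmp2$threshold_01, 2), 9.21)
  expect_error(compare_models(full = 100, reduced = 104), "df")
})

test_that("non-nested comparisons are rejected", {
  pop <- table4_pop()
  ds <- generate_study_dataset(cohort_design(n_ckrt = 0, n_nonckrt = 4,
                                             seed = 99), pop)
  fa <- pk_fit(model_spec("2-cpt", covariate_terms = list(
    list(param = "CLR", cov = "EGFR", form = "power", ref = 95))),
    ds$data, inits = pop, compute_se = FALSE,
    control = list(iter.max = 5))
  fb <- pk_fit(model_spec("2-cpt", covariate_terms = list(
    list(param = "CLM", cov = "WT", form = "power", ref = 10))),
    ds$data, inits = pop, compute_se = FALSE,
    control = list(iter.max = 5))
  expect_error(compare_models(fa, fb), "nested")
})

test_that("an empty candidate set leaves the base model unchanged", {
  pop <- table4_pop()
  ds <- generate_study_dataset(cohort_design(n_ckrt = 0, n_nonckrt = 4,
                                             seed = 103), pop)
  res <- scm(nonckrt_spec(), list(), ds$data, inits = pop)
  expect_identical(res$spec, nonckrt_spec())
  expect_equal(nrow(res$trail), 0)
})
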