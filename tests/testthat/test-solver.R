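test_that("one-compartment bolus decays with the closed-form half-life", {
  # only metabolic elimination, no distribution: A1(t) = D exp(-(clm/v1) t)
  ip <- raw_ip(cl_m = 0.9, v1 = 4.5)
  D <- 200
  thalf <- ip$v1 * log(2) / ip$cl_m
  ev <- data.frame(time = 0, amt = D, rate = D / 1e-6, duration = 1e-6)
  st <- simulate_amounts(ip, times = c(thalf, 2 * thalf), events = ev)
  expect_equal(st$a_central, c(D / 2, D / 4), tolerance = 1e-5)
})

test_that("mass balance and solver-backend agreement hold over random draws", {
  set.seed(42)
  worst_rel <- 0
  for (k in 1:100) {
    cs <- random_solver_case()
    times <- sort(c(0.25, runif(8, 0, 48), 47.9))
    stc <- simulate_amounts(cs$ip, cs$reg, times, cs$weight)
    dose_total <- max(stc$infused_cum)
    imbalance <- stc$infused_cum -
      rowSums(stc[, c("a_central", "a_peripheral", "a_urine_cum",
                      "a_ckrt_cum", "a_metabolized_cum")])
    expect_lt(max(abs(imbalance)), 1e-6 * dose_total)
    sto <- simulate_amounts(cs$ip, cs$reg, times, cs$weight, engine = "ode")
    rel <- abs(stc$a_central - sto$a_central) /
      pmax(abs(sto$a_central), 1e-6 * dose_total)
    worst_rel <- max(worst_rel, max(rel))
  }
  expect_lt(worst_rel, 1e-6)
})

test_that("continuous infusion converges to the steady-state closed form", {
  # typical 10-kg non-CKRT patient, 120 mg/kg over 24 h: Css = R/CL
  ip <- typical_nonckrt()
  R <- 120 * 10 / 24
  expect_equal(R / ip$cl_total, 10.16, tolerance = 1e-3)
  st <- simulate_amounts(ip, regimen(120, 24, 24, horizon = 480),
                         times = c(400, 479), weight = 10)
  css_sim <- st$a_central[2] / ip$v1
  expect_equal(css_sim, R / ip$cl_total, tolerance = 0.005)
})

test_that("an observation at a dose time is evaluated pre-dose (trough)", {
  ip <- typical_nonckrt()
  st <- simulate_amounts(ip, regimen(40, 0.5, 8), times = c(7.999, 8, 8.25),
                         weight = 10)
  expect_equal(st$a_central[2], st$a_central[1], tolerance = 1e-3)
  expect_gt(st$a_central[3], 5 * st$a_central[2])  # next infusion running
})

test_that("hemofilter observation equations follow the flow partition", {
  pop <- table4_pop()
  circ <- filter_circuit("low", blood_flow_ml_min = 70,
                         effluent_flow_ml_h = 2000, bpr = 0.65)
  cov <- patient_covariates(5, 6, ckrt = TRUE, diuresis = TRUE)
  ip <- individual_parameters(cov, pop, circ)
  st <- simulate_amounts(ip, regimen(40, 0.5, 8), times = c(1, 4, 7, 12),
                         weight = 5)
  pr <- predict_concentrations(st, ip, circ = circ)
  wide <- split(pr, pr$matrix)
  # post/pre ratio constant in time, equal to 1 - cl_ckrt/phi_pl_corr
  ratio <- wide$postfilter$conc / wide$prefilter$conc
  expect_equal(ratio, rep(1 - ip$cl_ckrt / circ$phi_plasma_corr, 4),
               tolerance = 1e-12)
  # effluent mass-flow identity: phi_effl * C_effl = cl_ckrt * C_pre
  expect_equal(circ$phi_effluent * wide$effluent$conc,
               ip$cl_ckrt * wide$prefilter$conc, tolerance = 1e-12)
})

test_that("filter equations reproduce worked single-point values", {
  # C_pre = 10 mg/L, cl_ckrt = 1.26 L/h, phi_blood = 4.2 L/h, BPR = 0.65
  ip <- raw_ip(cl_ckrt = 1.26, cl_m = 0.5, v1 = 10)
  circ <- filter_circuit("medium", blood_flow_ml_min = 70,
                         effluent_flow_ml_h = 2000, bpr = 0.65)
  expect_equal(circ$phi_blood, 4.2)
  expect_equal(circ$phi_plasma_corr, 2.73)
  st <- structure(data.frame(time = 1, a_central = 100, a_peripheral = 0,
                             a_urine_cum = 0, a_ckrt_cum = 0,
                             a_metabolized_cum = 0, infused_cum = 100),
                  class = c("system_state", "data.frame"))
  pr <- predict_concentrations(st, ip, circ = circ)
  expect_equal(pr$conc[pr$matrix == "postfilter"], 10 * (1 - 1.26 / 2.73),
               tolerance = 1e-12)
  expect_equal(pr$conc[pr$matrix == "effluent"], 1.26 * 10 / 2,
               tolerance = 1e-12)
  # null case: no extracorporeal clearance
  ip0 <- raw_ip(cl_m = 0.5, v1 = 10)
  pr0 <- predict_concentrations(st, ip0, circ = circ)
  expect_equal(pr0$conc[pr0$matrix == "postfilter"],
               pr0$conc[pr0$matrix == "prefilter"])
  expect_equal(pr0$conc[pr0$matrix == "effluent"], 0)
})

test_that("urine concentration is the excreted amount over collected volume", {
  ip <- raw_ip(cl_renal = 2, v1 = 8)
  ev <- data.frame(time = 0, amt = 100, rate = 200, duration = 0.5)
  st <- simulate_amounts(ip, times = c(1, 3), events = ev)
  delta <- st$a_urine_cum[2] - st$a_urine_cum[1]
  pr <- predict_concentrations(st, ip,
                               urine = data.frame(t_start = 1, t_end = 3,
                                                  u_vol = 40))
  expect_equal(pr$conc[pr$matrix == "urine"], delta / 0.040, tolerance = 1e-12)
  # worked numbers: 8 mg collected in 40 mL is 200 mg/L
  expect_equal(8 / (40 / 1000), 200)
  expect_error(predict_concentrations(
    st, ip, urine = data.frame(t_start = 1, t_end = 3, u_vol = 0)), "volume")
})

test_that("impossible flow combinations are rejected", {
  ip <- raw_ip(cl_ckrt = 3, cl_m = 0.5, v1 = 10)  # exceeds phi_pl_corr
  circ <- filter_circuit("medium", 70, 2000, bpr = 0.65)
  st <- simulate_amounts(ip, regimen(40, 0.5, 8), times = c(1, 2), weight = 10)
  expect_error(predict_concentrations(st, ip, circ = circ), "phi_plasma_corr")
  expect_error(simulate_amounts(raw_ip(cl_m = Inf, v1 = 1),
                                regimen(40), times = 1, weight = 10), "finite")
})
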