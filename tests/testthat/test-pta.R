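test_that("steady-state continuous infusion attains low MICs fully", {
  ip <- typical_nonckrt()  # CL = 4.920 L/h
  prof <- concentration_profile(ip, regimen(120, 24, 24, horizon = 480),
                                weight = 10)
  css <- 120 * 10 / 24 / ip$cl_total
  expect_equal(css, 10.16, tolerance = 1e-3)
  expect_equal(percent_time_above_mic(prof, 2, c(400, 480)), 100)
  expect_equal(percent_time_above_mic(prof, 20, c(400, 480)), 0)
})

test_that("an MIC above the whole profile gives zero attainment", {
  ip <- typical_nonckrt()
  prof <- concentration_profile(ip, regimen(40, 0.5, 8), weight = 10)
  expect_equal(percent_time_above_mic(prof, 1e5, c(0, 48)), 0)
})

test_that("mono-exponential decay crosses the MIC at the logarithmic time", {
  # C0 = 8, MIC = 2: time above is exactly two half-lives
  ip <- raw_ip(cl_m = 1, v1 = 10)  # t1/2 = 10 log 2
  D <- 80  # C0 = 8 mg/L
  ev <- data.frame(time = 0, amt = D, rate = D / 1e-6, duration = 1e-6)
  prof_long <- concentration_profile(ip, events = ev, horizon = 60)
  thalf <- 10 * log(2)
  window <- c(0, 60)
  ta <- percent_time_above_mic(prof_long, 2, window)
  expect_equal(ta, 100 * 2 * thalf / 60, tolerance = 1e-6)
  # brute-force grid oracle at 1e-4 h resolution
  grid <- seq(0, 60, by = 1e-4)
  brute <- 100 * mean(profile_conc(prof_long, grid) > 2)
  expect_equal(ta, brute, tolerance = 1e-3)
})

test_that("attainment is invariant to how finely anyone grids time", {
  ip <- typical_nonckrt()
  prof <- concentration_profile(ip, regimen(40, 0.5, 8), weight = 10)
  ta <- percent_time_above_mic(prof, 4, c(24, 32))
  brute <- 100 * mean(profile_conc(prof, seq(24, 32, by = 1e-4)) > 4)
  expect_equal(ta, brute, tolerance = 0.02)
})

test_that("simulated %TA is monotone in MIC and certain at negligible MIC", {
  pop <- table4_pop()
  res <- simulate_pta(pop, list(std = regimen(40, 0.5, 8)),
                      groups = data.frame(weight_group = c("3-10", "10-30"),
                                          ckrt = c(FALSE, TRUE)),
                      mics = c(0.001, .default_mics), n = 50, seed = 5)
  for (key in split(res$pta, paste(res$pta$weight_group, res$pta$ckrt))) {
    expect_true(all(diff(key$mean_ta) <= 1e-9))
    expect_equal(key$mean_ta[key$mic == 0.001], 100)
  }
})

test_that("degenerate variance makes all simulated patients identical", {
  pop0 <- population_parameters(omega2 = c(CLR = 0, CLM = 0, V1 = 0))
  set.seed(61)
  vps <- replicate(20, {
    v <- sample_virtual_patient("10-30", FALSE, pop0)
    v$ip$cl_m  # no covariates on CLM: typical for everyone
  })
  expect_equal(max(vps) - min(vps), 0)
})

test_that("mean %TA grows with dose at fixed interval and duration", {
  pop <- table4_pop()
  g <- data.frame(weight_group = "10-30", ckrt = FALSE)
  lo <- simulate_pta(pop, list(d = regimen(20, 0.5, 8)), groups = g,
                     mics = c(2, 8), n = 150, seed = 9)
  hi <- simulate_pta(pop, list(d = regimen(80, 0.5, 8)), groups = g,
                     mics = c(2, 8), n = 150, seed = 9)
  expect_true(all(hi$pta$mean_ta >= lo$pta$mean_ta))
})

test_that("PTA runs are reproducible byte-for-byte under one seed", {
  pop <- table4_pop()
  g <- data.frame(weight_group = "3-10", ckrt = TRUE)
  a <- simulate_pta(pop, list(d = regimen(40, 0.5, 8)), groups = g,
                    mics = c(1, 4), n = 40, seed = 77)
  b <- simulate_pta(pop, list(d = regimen(40, 0.5, 8)), groups = g,
                    mics = c(1, 4), n = 40, seed = 77)
  expect_identical(a, b)
})

test_that("toxicity bands summarise trough exceedance with set semantics", {
  pop <- table4_pop()
  g <- data.frame(weight_group = "30-60", ckrt = TRUE)
  res <- simulate_pta(pop, list(ci60 = regimen(60, 24, 24)), groups = g,
                      mics = 2, n = 60, seed = 13)
  t1 <- toxicity_bands(res, thresholds = c(45, 65))
  t2 <- toxicity_bands(res, thresholds = c(65, 45))
  expect_identical(t1, t2)
  # a threshold above every simulated concentration: zero exceedance
  t3 <- toxicity_bands(res, thresholds = 1e6)
  expect_equal(t3$frac_troughs_above, 0)
  expect_false(any(t3$band_crosses))
})

test_that("a typical anuric low-filter infant's steady state is the closed form", {
  # 5 kg anuric CKRT patient on a low-surface filter, 120 mg/kg per 24 h:
  # Css = R / (CLM + CLCKRT) = 25 / 1.2502 = 20.0 mg/L, below the 45 mg/L line
  pop <- table4_pop()
  circ <- filter_circuit("low", 70, 1500)
  cov <- patient_covariates(5, 6, ckrt = TRUE, diuresis = FALSE)
  ip <- individual_parameters(cov, pop, circ)
  expect_equal(ip$cl_total, 0.91 + 0.3402, tolerance = 1e-12)
  prof <- concentration_profile(ip, regimen(120, 24, 24, horizon = 720),
                                weight = 5)
  css <- profile_conc(prof, 719)
  expect_equal(css, (120 * 5 / 24) / (0.91 + 0.3402), tolerance = 0.005)
  expect_equal(css, 20.0, tolerance = 0.01)
  expect_lt(css, 45)
})
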