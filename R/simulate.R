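#' Dosing regimen specification
#'
#' Doses are expressed per kg of body weight and realised at simulation time
#' for a given patient.  A schedule switch (e.g. the CKRT renal adjustment
#' from q8h to q12h at the fourth dose) changes the inter-dose interval from a
#' given dose index onwards.  A continuous infusion is a regimen whose
#' infusion duration equals its interval.
#'
#' @param dose_per_kg dose per administration, mg/kg.
#' @param infusion_duration infusion duration, h (0.5 for the standard 30-min
#'   infusion; equal to `interval` for a continuous infusion).
#' @param interval inter-dose interval, h.
#' @param loading_dose_per_kg optional loading bolus at t = 0, mg/kg
#'   (administered as a 1-minute infusion).
#' @param switch_at_dose optional dose index (1-based) from which
#'   `switch_interval` applies.
#' @param switch_interval new interval from `switch_at_dose` onwards, h.
#' @param horizon simulated horizon, h (>= 48 for day-2 metrics).
#' @return an object of class `regimen_spec`.
#' @examples
#' # CKRT protocol: 40 mg/kg q8h, switched to q12h at the 4th dose
#' regimen(40, 0.5, 8, switch_at_dose = 4, switch_interval = 12)
#' # continuous infusion, 60 mg/kg per 24 h
#' regimen(60, 24, 24)
#' @export
regimen <- function(dose_per_kg, infusion_duration = 0.5, interval = 8,
                    loading_dose_per_kg = NULL, switch_at_dose = NULL,
                    switch_interval = NULL, horizon = 48) {
  stopifnot(dose_per_kg > 0, infusion_duration > 0, interval > 0)
  if (infusion_duration > interval)
    stop("infusion_duration must not exceed the dosing interval")
  if (!is.null(switch_at_dose) && is.null(switch_interval))
    stop("switch_interval required with switch_at_dose")
  structure(list(dose_per_kg = dose_per_kg,
                 infusion_duration = infusion_duration,
                 interval = interval,
                 loading_dose_per_kg = loading_dose_per_kg,
                 switch_at_dose = switch_at_dose,
                 switch_interval = switch_interval,
                 horizon = horizon), class = "regimen_spec")
}

#' Realise a regimen as dose events for one patient
#'
#' @param reg a [regimen()] object.
#' @param weight body weight, kg.
#' @return data.frame with columns `time` (h), `amt` (mg), `rate` (mg/h),
#'   `duration` (h).
#' @export
dose_events <- function(reg, weight) {
  stopifnot(inherits(reg, "regimen_spec"), weight > 0)
  times <- numeric(0)
  t <- 0
  i <- 1L
  repeat {
    if (t >= reg$horizon) break
    times <- c(times, t)
    iv <- if (!is.null(reg$switch_at_dose) && i >= reg$switch_at_dose)
      reg$switch_interval else reg$interval
    t <- t + iv
    i <- i + 1L
  }
  amt <- reg$dose_per_kg * weight
  ev <- data.frame(time = times, amt = amt,
                   rate = amt / reg$infusion_duration,
                   duration = reg$infusion_duration)
  if (!is.null(reg$loading_dose_per_kg)) {
    lamt <- reg$loading_dose_per_kg * weight
    ev <- rbind(data.frame(time = 0, amt = lamt, rate = lamt * 60,
                           duration = 1 / 60), ev)
  }
  ev
}

# Piecewise-constant infusion-rate segments covering [0, horizon] from dose
# events; overlapping infusions add.
.build_segments <- function(events, horizon) {
  if (nrow(events) == 0)
    return(matrix(c(0, horizon, 0), nrow = 1,
                  dimnames = list(NULL, c("t0", "t1", "rate"))))
  bounds <- sort(unique(c(0, events$time, pmin(events$time + events$duration,
                                               horizon), horizon)))
  bounds <- bounds[bounds <= horizon + 1e-12]
  n <- length(bounds) - 1L
  seg <- cbind(t0 = bounds[-length(bounds)], t1 = bounds[-1], rate = 0)
  for (k in seq_len(nrow(events))) {
    on <- seg[, "t0"] >= events$time[k] - 1e-12 &
      seg[, "t1"] <= events$time[k] + events$duration[k] + 1e-12
    seg[on, "rate"] <- seg[on, "rate"] + events$rate[k]
  }
  seg
}

.ip_vector <- function(ip) {
  c(ip$cl_renal, ip$cl_m, ip$cl_ckrt, ip$v1, ip$v2, ip$cl_d)
}

#' Simulate compartment and cumulative-elimination amounts
#'
#' Solves the two-compartment disposition system
#' \deqn{dA_1/dt = (CL_D/V_2) A_2 - (CL_D/V_1) A_1 -
#'   (CL_R + CL_{CKRT} + CL_M)/V_1 \, A_1 + R(t)}
#' \deqn{dA_2/dt = (CL_D/V_1) A_1 - (CL_D/V_2) A_2}
#' with cumulative urine, extracorporeal and metabolic elimination ledgers,
#' under piecewise-constant zero-order input into the central compartment.
#' Two interchangeable backends are provided: the default closed-form
#' piecewise solution (matrix exponential per constant-rate segment) and
#' adaptive numeric integration (`deSolve::lsoda`); they agree to a relative
#' tolerance of 1e-6 and serve as mutual oracles.
#'
#' @param ip an [individual_parameters()] object.
#' @param reg a [regimen()] object, realised for `weight`; alternatively pass
#'   `events` directly.
#' @param times strictly increasing output time grid, h, starting at >= 0.
#' @param weight body weight, kg (to realise mg/kg doses).
#' @param engine `"closed"` (default) or `"ode"`.
#' @param events optional data.frame of dose events (`time`, `amt`, `rate`,
#'   `duration`) overriding `reg`.
#' @return data.frame with `time` and columns `a_central`, `a_peripheral`,
#'   `a_urine_cum`, `a_ckrt_cum`, `a_metabolized_cum`, `infused_cum` (mg).
#'   An observation time equal to a dose time is evaluated just before the
#'   dose (trough convention).
#' @examples
#' pop <- population_parameters()
#' cov <- patient_covariates(weight = 10, age = 42, egfr = 95)
#' ip <- individual_parameters(cov, pop)
#' st <- simulate_amounts(ip, regimen(40), times = 0:48, weight = 10)
#' max(abs(st$infused_cum - rowSums(st[, 2:6])))  # mass balance ~ 0
#' @export
simulate_amounts <- function(ip, reg = NULL, times, weight = NULL,
                             engine = c("closed", "ode"), events = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(ip, "individual_parameters"))
  p <- .ip_vector(ip)
  if (any(!is.finite(p)) || any(p < 0))
    stop("individual parameters must be finite and non-negative")
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("times must be strictly increasing and non-negative")
  if (is.null(events)) {
    if (is.null(reg) || is.null(weight))
      stop("either events or (reg, weight) must be supplied")
    if (any(dose_events(reg, weight)$duration <= 0))
      stop("infusion durations must be positive")
    events <- dose_events(reg, weight)
  }
  horizon <- max(times, if (nrow(events)) max(events$time + events$duration) else 0)
  seg <- .build_segments(events, horizon)
  if (engine == "closed") {
    m <- cpp_profile(p, seg, times)
  } else {
    m <- .ode_profile(p, seg, times)
  }
  out <- data.frame(time = times, a_central = m[, 1], a_peripheral = m[, 2],
                    a_urine_cum = m[, 3], a_ckrt_cum = m[, 4],
                    a_metabolized_cum = m[, 5], infused_cum = m[, 6])
  class(out) <- c("system_state", class(out))
  out
}

# numeric backend: lsoda within each constant-rate segment
.ode_profile <- function(p, seg, times) {
  clr <- p[1]; clm <- p[2]; clckrt <- p[3]; v1 <- p[4]; v2 <- p[5]; cld <- p[6]
  two <- cld > 0 && v2 > 0
  k12 <- if (two) cld / v1 else 0
  k21 <- if (two) cld / v2 else 0
  k10 <- (clr + clm + clckrt) / v1
  deriv <- function(t, y, parms) {
    r <- parms
    list(c(k21 * y[2] - (k10 + k12) * y[1] + r,
           k12 * y[1] - k21 * y[2],
           clr / v1 * y[1],
           clckrt / v1 * y[1],
           clm / v1 * y[1],
           r))
  }
  out <- matrix(0, length(times), 6)
  state <- rep(0, 6)
  done <- times <= seg[1, "t0"] + 1e-15
  for (i in seq_len(nrow(seg))) {
    t0 <- seg[i, "t0"]; t1 <- seg[i, "t1"]; rate <- seg[i, "rate"]
    inside <- !done & times <= t1 + 1e-12
    tv <- sort(unique(c(t0, times[inside], t1)))
    if (length(tv) > 1) {
      sol <- deSolve::lsoda(state, tv, deriv, parms = rate,
                            rtol = 1e-11, atol = 1e-11)
      if (any(inside))
        out[inside, ] <- sol[match(times[inside], sol[, 1]), -1, drop = FALSE]
      state <- as.numeric(sol[nrow(sol), -1])
    }
    done <- done | inside
  }
  if (any(!done)) { # free decay past the last segment
    tend <- seg[nrow(seg), "t1"]
    tv <- sort(unique(c(tend, times[!done])))
    sol <- deSolve::lsoda(state, tv, deriv, parms = 0,
                          rtol = 1e-11, atol = 1e-11)
    out[!done, ] <- sol[match(times[!done], sol[, 1]), -1, drop = FALSE]
  }
  out
}

#' Predict matrix-labelled concentrations from a simulated trajectory
#'
#' Plasma and prefilter concentrations are `A1/V1`.  Across the hemofilter,
#' `C_post = C_pre * (1 - CL_CKRT / phi_pl_corr)` and
#' `C_effl = CL_CKRT * C_pre / phi_effl`, where `phi_pl_corr = phi_blood * BPR`
#' is the corrected plasma flow.  Urine concentration over a collection
#' interval is the urinary amount excreted during the interval divided by the
#' collected volume (mg / L; `u_vol` is given in mL).
#'
#' @param state a trajectory from [simulate_amounts()].
#' @param ip the matching [individual_parameters()].
#' @param circ a [filter_circuit()]; required for postfilter/effluent output.
#' @param urine optional data.frame of collection intervals with columns
#'   `t_start`, `t_end` (h) and `u_vol` (mL); times must be on the state grid.
#' @return data.frame `time`, `matrix`, `conc` (mg/L); urine rows are reported
#'   at `t_end`.
#' @export
predict_concentrations <- function(state, ip, circ = NULL, urine = NULL) {
  stopifnot(inherits(state, "system_state"),
            inherits(ip, "individual_parameters"))
  cp <- state$a_central / ip$v1
  out <- data.frame(time = state$time, matrix = "plasma", conc = cp)
  if (!is.null(circ)) {
    if (ip$cl_ckrt >= circ$phi_plasma_corr)
      stop("invalid parameter/flow combination: cl_ckrt >= phi_plasma_corr ",
           "would give a negative postfilter concentration")
    out <- rbind(out,
      data.frame(time = state$time, matrix = "prefilter", conc = cp),
      data.frame(time = state$time, matrix = "postfilter",
                 conc = cp * (1 - ip$cl_ckrt / circ$phi_plasma_corr)),
      data.frame(time = state$time, matrix = "effluent",
                 conc = ip$cl_ckrt * cp / circ$phi_effluent))
  }
  if (!is.null(urine)) {
    stopifnot(all(c("t_start", "t_end", "u_vol") %in% names(urine)))
    if (any(urine$t_end <= urine$t_start)) stop("urine t_end must exceed t_start")
    if (any(urine$u_vol <= 0)) stop("urine collection volume must be > 0")
    a_at <- function(t) {
      i <- match(TRUE, abs(state$time - t) < 1e-9)
      if (is.na(i)) stop("urine interval endpoint ", t, " not on the state grid")
      state$a_urine_cum[i]
    }
    conc <- vapply(seq_len(nrow(urine)), function(k) {
      (a_at(urine$t_end[k]) - a_at(urine$t_start[k])) / (urine$u_vol[k] / 1000)
    }, numeric(1))
    out <- rbind(out, data.frame(time = urine$t_end, matrix = "urine",
                                 conc = conc))
  }
  out
}
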