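# log-scale predictions for one prepared patient at a given eta
.predict_patient_log <- function(spec, sp, pat, eta) {
  typ <- .typical_params(spec, sp$th, pat)
  if (length(eta)) {
    emap <- c(CLR = 1L, CLM = 2L, CLCKRT = 3L, V1 = 4L)[names(eta)]
    typ[emap] <- typ[emap] * exp(eta)
  }
  st <- cpp_profile(typ, pat$segments, pat$ev_times)
  a1 <- st[pat$obs_idx + 1L, 1]
  v1 <- typ[4]; clckrt <- typ[3]
  conc <- numeric(length(a1))
  for (i in seq_along(a1)) {
    conc[i] <- switch(as.character(pat$obs_type[i]),
      "0" = a1[i] / v1,
      "1" = a1[i] / v1 * (1 - clckrt / pat$phi_pl),
      "2" = clckrt * (a1[i] / v1) / pat$phi_eff,
      "3" = (st[pat$obs_idx[i] + 1L, 3] -
               if (pat$obs_idx0[i] >= 0) st[pat$obs_idx0[i] + 1L, 3] else 0) /
        pat$obs_uvol[i])
  }
  log(pmax(conc, 1e-12))
}

#' Goodness-of-fit tables
#'
#' Computes, for every usable record, the typical population prediction
#' (`PRED`, at eta = 0), the individual prediction at the empirical Bayes
#' estimates (`IPRED`), the individual weighted residual on the log scale
#' (`IWRES`, matching the additive log-scale error model) and conditional
#' weighted residuals (`CWRES`) from the linearised conditional covariance.
#'
#' @param fit a [pk_fit()] result.
#' @return data.frame with columns `ID`, `TIME`, `MATRIX`, `DV`, `PRED`,
#'   `IPRED`, `IWRES`, `CWRES` (concentrations in mg/L; residuals
#'   dimensionless).
#' @export
gof_tables <- function(fit) {
  stopifnot(inherits(fit, "pedmero_fit"))
  spec <- fit$spec
  sp <- list(th = fit$theta, omega2 = fit$omega2, sigma = fit$sigma_log)
  k <- length(spec$random_effects)
  Om <- diag(fit$omega2, k)
  out <- list()
  for (i in seq_along(fit$patients)) {
    pat <- fit$patients[[i]]
    eta0 <- setNames(rep(0, k), spec$random_effects)
    etah <- setNames(fit$eta[i, ], spec$random_effects)
    lp0 <- .predict_patient_log(spec, sp, pat, eta0)
    lph <- .predict_patient_log(spec, sp, pat, etah)
    sig <- sp$sigma[pat$obs_class]
    y <- pat$obs_y
    iwres <- (y - lph) / sig
    J <- matrix(0, length(y), k)
    h <- 1e-4
    for (c in seq_len(k)) {
      ep <- etah; ep[c] <- ep[c] + h
      em <- etah; em[c] <- em[c] - h
      J[, c] <- (.predict_patient_log(spec, sp, pat, ep) -
                   .predict_patient_log(spec, sp, pat, em)) / (2 * h)
    }
    Ey <- lph - J %*% etah
    Cov <- J %*% Om %*% t(J) + diag(sig^2, length(y))
    L <- chol(Cov)
    cwres <- backsolve(L, y - Ey, transpose = TRUE)
    mat <- .matrix_levels[match(pat$obs_type, c(0, 1, 2, 3))]
    mat[pat$obs_type == 0] <- ifelse(pat$obs_class[pat$obs_type == 0] ==
                                       "plasma_prefilter" & pat$ckrt,
                                     "prefilter", "plasma")
    out[[i]] <- data.frame(ID = pat$id, TIME = pat$ev_times[pat$obs_idx + 1L],
                           MATRIX = mat, DV = exp(y), PRED = exp(lp0),
                           IPRED = exp(lph), IWRES = iwres,
                           CWRES = as.numeric(cwres))
  }
  do.call(rbind, out)
}

# simulate one replicate of the observation vector for every patient
.simulate_replicate <- function(spec, sp, pats) {
  k <- length(spec$random_effects)
  lapply(pats, function(pat) {
    eta <- setNames(rnorm(k, 0, sqrt(sp$omega2)), spec$random_effects)
    lp <- .predict_patient_log(spec, sp, pat, eta)
    lp + rnorm(length(lp), 0, sp$sigma[pat$obs_class])
  })
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_replicates` datasets with the fitted parameters under the
#' original design, prediction-corrects observations and simulations by the
#' ratio of the bin-median typical prediction to the record's typical
#' prediction, and summarises the 5th/50th/95th percentiles per time bin and
#' matrix class together with their simulated 90% confidence bands.
#'
#' @param fit a [pk_fit()] result.
#' @param n_replicates number of simulated study replicates.
#' @param bins optional numeric vector of bin edges for observation times;
#'   default is one bin per nominal sampling time.
#' @param correct set `FALSE` for a plain (uncorrected) VPC.
#' @return list of class `vpc_result` with `summary` (data.frame: `matrix_class`,
#'   `bin`, `stat`, `observed`, `sim_lo`, `sim_med`, `sim_hi`, `n_obs`) and
#'   `n_replicates`.  Empty bins are reported with `n_obs = 0`, never merged.
#' @export
pcvpc <- function(fit, n_replicates = 1000, bins = NULL, correct = TRUE) {
  stopifnot(inherits(fit, "pedmero_fit"), n_replicates >= 1)
  spec <- fit$spec
  sp <- list(th = fit$theta, omega2 = fit$omega2, sigma = fit$sigma_log)
  pats <- fit$patients
  k <- length(spec$random_effects)
  eta0 <- setNames(rep(0, k), spec$random_effects)
  times <- unlist(lapply(pats, function(p) p$ev_times[p$obs_idx + 1L]))
  classes <- unlist(lapply(pats, function(p) p$obs_class))
  lpred <- unlist(lapply(pats, function(p)
    .predict_patient_log(spec, sp, p, eta0)))
  yobs <- unlist(lapply(pats, function(p) p$obs_y))
  if (is.null(bins)) {
    ut <- sort(unique(round(times, 6)))
    bin_id <- match(round(times, 6), ut)
    bin_lab <- ut
  } else {
    bin_id <- findInterval(times, bins, all.inside = TRUE)
    bin_lab <- (bins[-length(bins)] + bins[-1]) / 2
  }
  # prediction correction factor per record (log scale)
  corr <- rep(0, length(times))
  if (correct) {
    for (cl in unique(classes)) for (b in unique(bin_id)) {
      ix <- classes == cl & bin_id == b
      if (any(ix)) corr[ix] <- median(lpred[ix]) - lpred[ix]
    }
  }
  pc_obs <- yobs + corr
  probs <- c(0.05, 0.50, 0.95)
  cells <- expand.grid(matrix_class = sort(unique(classes)),
                       bin = seq_along(bin_lab), stringsAsFactors = FALSE)
  sim_q <- array(NA_real_, c(nrow(cells), 3, n_replicates))
  for (r in seq_len(n_replicates)) {
    ysim <- unlist(.simulate_replicate(spec, sp, pats)) + corr
    for (ci in seq_len(nrow(cells))) {
      ix <- classes == cells$matrix_class[ci] & bin_id == cells$bin[ci]
      if (any(ix)) sim_q[ci, , r] <- quantile(ysim[ix], probs, names = FALSE)
    }
  }
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    ix <- classes == cells$matrix_class[ci] & bin_id == cells$bin[ci]
    obs_q <- if (any(ix)) quantile(pc_obs[ix], probs, names = FALSE)
    else rep(NA_real_, 3)
    for (s in 1:3) {
      sq <- sim_q[ci, s, ]
      rows[[length(rows) + 1]] <- data.frame(
        matrix_class = cells$matrix_class[ci],
        bin = bin_lab[cells$bin[ci]],
        stat = c("p5", "p50", "p95")[s],
        observed = exp(obs_q[s]),
        sim_lo = exp(quantile(sq, 0.05, names = FALSE, na.rm = TRUE)),
        sim_med = exp(median(sq, na.rm = TRUE)),
        sim_hi = exp(quantile(sq, 0.95, names = FALSE, na.rm = TRUE)),
        n_obs = sum(ix))
    }
  }
  res <- do.call(rbind, rows)
  if (any(res$n_obs == 0))
    message("empty bins present; reported with n_obs = 0")
  structure(list(summary = res, n_replicates = n_replicates),
            class = "vpc_result")
}

# multivariate normal helpers on the transformed parameter scale
.rmvn <- function(n, mean, V) {
  L <- chol(V)
  sweep(matrix(rnorm(n * length(mean)), n) %*% L, 2, mean, "+")
}
.dmvn_log <- function(x, mean, V) {
  L <- chol(V)
  z <- backsolve(L, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * length(mean) * log(2 * pi)
}

#' Sampling-importance-resampling parameter uncertainty
#'
#' Draws `n_samples` parameter vectors from a multivariate normal proposal
#' centred at the estimates with an inflated Hessian covariance, weights them
#' by the likelihood ratio to the proposal density, and resamples
#' `n_resamples` vectors without replacement to obtain percentile confidence
#' intervals.  If the effective sample size of the weights falls below
#' `n_resamples`, the proposal is inflated and redrawn once, with a warning.
#'
#' @param fit a [pk_fit()] result.
#' @param n_samples proposal draws (default 1000).
#' @param n_resamples resampled vectors (default 500; must not exceed
#'   `n_samples`).
#' @param inflation proposal covariance inflation factor.
#' @return data.frame `parameter`, `estimate`, `ci_lo`, `ci_hi` (natural
#'   scale, 95% percentile interval), plus attribute `ess`.
#' @export
sir_uncertainty <- function(fit, n_samples = 1000, n_resamples = 500,
                            inflation = 1.5) {
  stopifnot(inherits(fit, "pedmero_fit"))
  if (n_resamples > n_samples)
    stop("n_resamples must not exceed n_samples")
  table <- fit$par_table; spec <- fit$spec; pats <- fit$patients
  warm <- new.env(); warm$eta <- vector("list", length(pats))
  obj <- function(pt) as.numeric(.n2ll_total(pt, table, spec, pats, warm))
  H <- optimHess(fit$par_opt, obj)
  V <- 2 * solve((H + t(H)) / 2)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8)
  V <- ev$vectors %*% diag(ev$values, length(ev$values)) %*% t(ev$vectors)
  draw <- function(infl) {
    Vp <- infl * V
    X <- .rmvn(n_samples, fit$par_opt, Vp)
    n2 <- apply(X, 1, obj)
    lw <- -0.5 * (n2 - fit$ofv) - .dmvn_log(X, fit$par_opt, Vp)
    lw <- lw - max(lw[is.finite(lw)])
    w <- ifelse(is.finite(lw), exp(lw), 0)
    list(X = X, w = w, ess = sum(w)^2 / sum(w^2))
  }
  d <- draw(inflation)
  if (d$ess < n_resamples) {
    warning("effective sample size ", round(d$ess),
            " below n_resamples; inflating proposal and redrawing")
    d <- draw(inflation * 2)
  }
  # weighted resampling without replacement
  idx <- integer(0); w <- d$w
  for (j in seq_len(n_resamples)) {
    pick <- sample.int(length(w), 1, prob = pmax(w, 1e-300))
    idx <- c(idx, pick); w[pick] <- 0
  }
  R <- d$X[idx, , drop = FALSE]
  nat <- t(apply(R, 1, function(pt) .unpack_vec(pt, table)))
  ci <- t(apply(nat, 2, quantile, c(0.025, 0.975), names = FALSE))
  out <- data.frame(parameter = table$name,
                    estimate = as.numeric(fit$estimates),
                    ci_lo = ci[, 1], ci_hi = ci[, 2])
  attr(out, "ess") <- d$ess
  out
}
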