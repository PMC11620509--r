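#' Model specification for mixed-effects estimation
#'
#' Describes the structural variant, the multiplicative covariate terms on
#' the typical parameters, the random-effect set and the residual classes.
#' Covariate terms are given as a list of `list(param, cov, form, ref)` where
#' `param` is one of `CLR`, `CLM`, `CLCKRT`, `V1`, `CLD`, `V2`; `cov` names a
#' dataset column (`WT`, `AGE`, `EGFR`, `FILT`, ...); and `form` is one of
#' \describe{
#'   \item{`ratio`}{fixed linear scaling `x/ref` (no estimated parameter) —
#'     the final model's eGFR/95 and WGT/10 terms;}
#'   \item{`linear`}{`1 + beta (x - ref)` with estimated slope;}
#'   \item{`power`}{`(x/ref)^beta` with estimated exponent;}
#'   \item{`emax`}{maturation `x^h/(x^h + t50^h)` with estimated `t50`
#'     (Hill exponent `h` fixed at 1 unless `estimate_hill`);}
#'   \item{`factor`}{categorical multipliers, reference level fixed at 1.}
#' }
#' Continuous covariates should be referenced at the population median
#' (`ref`); if `ref` is `NA` the median of the dataset is used at fit time.
#' CKRT patients always follow the structural renal split (constant renal
#' clearance under diuresis, zero under anuria) and terms on `CLR` apply to
#' non-CKRT patients only.
#'
#' @param structure `"2-cpt"` or `"1-cpt"`.
#' @param covariate_terms list of term lists (see above).
#' @param random_effects subset of `c("CLR", "CLM", "CLCKRT", "V1")`.
#' @param estimate_hill estimate the Hill exponent of `emax` terms?
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(structure = c("2-cpt", "1-cpt"),
                       covariate_terms = list(),
                       random_effects = c("CLR", "CLM", "V1"),
                       estimate_hill = FALSE) {
  structure <- match.arg(structure)
  stopifnot(all(random_effects %in% c("CLR", "CLM", "CLCKRT", "V1")))
  for (tm in covariate_terms) {
    stopifnot(all(c("param", "cov", "form") %in% names(tm)),
              tm$param %in% c("CLR", "CLM", "CLCKRT", "V1", "CLD", "V2"),
              tm$form %in% c("ratio", "linear", "power", "emax", "factor"))
  }
  base::structure(list(structure = structure,
                       covariate_terms = covariate_terms,
                       random_effects = random_effects,
                       estimate_hill = estimate_hill),
                  class = "model_spec")
}

#' The final covariate model specification
#'
#' Two compartments; renal clearance scaled by eGFR (reference 95) and an
#' age-maturation function; central volume proportional to weight
#' (reference 10 kg); extracorporeal clearance scaled by a filter-surface
#' factor; lognormal random effects on `CLR`, `CLM` and `V1`.
#' @return a [model_spec()].
#' @export
final_model_spec <- function() {
  model_spec("2-cpt",
             covariate_terms = list(
               list(param = "CLR", cov = "EGFR", form = "ratio", ref = 95),
               list(param = "CLR", cov = "AGE", form = "emax", ref = NA),
               list(param = "V1", cov = "WT", form = "ratio", ref = 10),
               list(param = "CLCKRT", cov = "FILT", form = "factor", ref = "medium")),
             random_effects = c("CLR", "CLM", "V1"))
}

#' Base (covariate-free) model specification
#'
#' Starting point for stepwise covariate modelling: two compartments, no
#' covariate terms beyond the structural CKRT renal split.
#' @inheritParams model_spec
#' @return a [model_spec()].
#' @export
base_model_spec <- function(structure = "2-cpt",
                            random_effects = c("CLR", "CLM", "V1")) {
  model_spec(structure, covariate_terms = list(),
             random_effects = random_effects)
}

.term_id <- function(tm) paste(tm$param, tm$cov, tm$form, sep = "_")

# names of estimated parameters contributed by a covariate term
.term_par_names <- function(tm, spec, levels = NULL) {
  switch(tm$form,
         ratio = character(0),
         linear = paste0("beta_", .term_id(tm)),
         power = paste0("beta_", .term_id(tm)),
         emax = c(paste0("t50_", tm$param, "_", tm$cov),
                  if (spec$estimate_hill) paste0("hill_", tm$param, "_", tm$cov)),
         factor = paste0("fac_", tm$param, "_", tm$cov, "_",
                         setdiff(levels, tm$ref)))
}

# ---- dataset preparation ---------------------------------------------------

# Split a long-format dataset into per-patient structures consumed by the
# C++ Laplace objective.  Urine interval starts are derived: the first urine
# record's collection starts at the latest dose before it, later ones at the
# previous urine record.
.prepare_patients <- function(data) {
  stopifnot(all(c("ID", "TIME", "EVID", "DV", "MDV", "MATRIX") %in% names(data)))
  type_code <- c(plasma = 0L, prefilter = 0L, postfilter = 1L,
                 effluent = 2L, urine = 3L)
  lapply(split(data, data$ID), function(d) {
    d <- d[order(d$TIME, -d$EVID), ]
    doses <- d[d$EVID == 1, ]
    # usage is governed by MDV; the LLOQ column is an informational flag
    # (datasets generated with lloq_action = "drop" already exclude them)
    obs <- d[d$EVID == 0 & d$MDV == 0, ]
    if (nrow(obs) == 0) return(NULL)
    if (any(obs$DV <= 0)) stop("observations must be positive for log transform")
    events <- data.frame(time = doses$TIME, amt = doses$AMT,
                         rate = doses$RATE, duration = doses$AMT / doses$RATE)
    obs <- obs[order(obs$TIME, match(obs$MATRIX, .matrix_levels)), ]
    tstart <- rep(NA_real_, nrow(obs))
    iu <- which(obs$MATRIX == "urine")
    if (length(iu)) {
      ut <- obs$TIME[iu]
      tstart[iu] <- c(max(events$time[events$time < ut[1]]), ut[-length(ut)])
    }
    ev_times <- sort(unique(c(obs$TIME, tstart[!is.na(tstart)])))
    ckrt <- d$CKRT[1] == 1
    hct <- if ("HCT" %in% names(d)) d$HCT[1] else 0.3
    list(id = d$ID[1],
         events = events,
         ev_times = ev_times,
         obs_idx = match(obs$TIME, ev_times) - 1L,
         obs_idx0 = ifelse(is.na(tstart), -1L, match(tstart, ev_times) - 1L),
         obs_type = type_code[obs$MATRIX],
         obs_class = residual_class(obs$MATRIX),
         obs_y = log(obs$DV),
         obs_uvol = ifelse(is.na(obs$UVOL), 1, obs$UVOL / 1000),
         segments = .build_segments(events,
                                    max(ev_times, events$time + events$duration)),
         wt = d$WT[1], age = d$AGE[1], egfr = d$EGFR[1],
         ckrt = ckrt,
         diuresis = if (ckrt) d$DIURESIS[1] == 1 else TRUE,
         filt = if (ckrt) d$FILT[1] else NA_character_,
         phi_pl = if (ckrt) d$QBLOOD[1] * 0.06 * (1 - hct) else 1,
         phi_eff = if (ckrt) d$QEFF[1] / 1000 else 1)
  })
}

# covariate value for a term, given a prepared patient
.cov_value <- function(pat, covname) {
  switch(covname,
         WT = pat$wt, AGE = pat$age, EGFR = pat$egfr, FILT = pat$filt,
         stop("unknown covariate: ", covname))
}

# multiplicative covariate factor of one term for one patient
.term_factor <- function(tm, th, pat, spec) {
  x <- .cov_value(pat, tm$cov)
  switch(tm$form,
         ratio = x / tm$ref,
         linear = max(1e-6, 1 + th[[paste0("beta_", .term_id(tm))]] * (x - tm$ref)),
         power = (x / tm$ref)^th[[paste0("beta_", .term_id(tm))]],
         emax = {
           t50 <- th[[paste0("t50_", tm$param, "_", tm$cov)]]
           h <- if (spec$estimate_hill)
             th[[paste0("hill_", tm$param, "_", tm$cov)]] else 1
           x^h / (x^h + t50^h)
         },
         factor = {
           if (is.na(x)) 1
           else if (x == tm$ref) 1
           else th[[paste0("fac_", tm$param, "_", tm$cov, "_", x)]]
         })
}

# typical structural parameters (clr, clm, clckrt, v1, v2, cld) per patient
.typical_params <- function(spec, th, pat) {
  fac <- c(CLR = 1, CLM = 1, CLCKRT = 1, V1 = 1, CLD = 1, V2 = 1)
  for (tm in spec$covariate_terms)
    fac[[tm$param]] <- fac[[tm$param]] * .term_factor(tm, th, pat, spec)
  clr <- if (!pat$ckrt) th$theta_clr * fac[["CLR"]]
  else if (pat$diuresis) th$theta_clr_ckrt else 0
  clckrt <- if (pat$ckrt) th$theta_clckrt * fac[["CLCKRT"]] else 0
  two <- spec$structure == "2-cpt"
  c(clr, th$theta_clm * fac[["CLM"]], clckrt, th$theta_v1 * fac[["V1"]],
    if (two) th$theta_v2 * fac[["V2"]] else 0,
    if (two) th$theta_cld * fac[["CLD"]] else 0)
}

# ---- parameter packing -----------------------------------------------------

# Build the estimated-parameter table for a spec and dataset: names, scale
# ("log" or "id"), and initial values on the natural scale.
.par_table <- function(spec, pats, inits) {
  any_ckrt <- any(vapply(pats, function(p) p$ckrt, logical(1)))
  any_diu_ckrt <- any(vapply(pats, function(p) p$ckrt && p$diuresis, logical(1)))
  any_nonckrt <- any(vapply(pats, function(p) !p$ckrt, logical(1)))
  classes <- sort(unique(unlist(lapply(pats, function(p) p$obs_class))))
  nm <- character(0); sc <- character(0); iv <- numeric(0)
  add <- function(n, s, v) {
    nm <<- c(nm, n); sc <<- c(sc, rep(s, length(n))); iv <<- c(iv, v)
  }
  if (any_nonckrt) add("theta_clr", "log", inits$theta_clr)
  if (any_diu_ckrt) add("theta_clr_ckrt", "log", inits$theta_clr_ckrt)
  if (any_ckrt) add("theta_clckrt", "log", inits$theta_clckrt)
  add("theta_clm", "log", inits$theta_clm)
  add("theta_v1", "log", inits$theta_v1)
  if (spec$structure == "2-cpt") {
    add("theta_cld", "log", inits$theta_cld)
    add("theta_v2", "log", inits$theta_v2)
  }
  for (tm in spec$covariate_terms) {
    if (tm$form %in% c("linear", "power")) {
      add(.term_par_names(tm, spec), "id",
          inits[[.term_par_names(tm, spec)]] %||% 0.1)
    } else if (tm$form == "emax") {
      pn <- .term_par_names(tm, spec)
      add(pn[1], "log", inits[[pn[1]]] %||% inits$theta_50 %||% 15)
      if (spec$estimate_hill) add(pn[2], "log", inits[[pn[2]]] %||% 1)
    } else if (tm$form == "factor") {
      levs <- sort(unique(stats::na.omit(
        vapply(pats, function(p) as.character(.cov_value(p, tm$cov)),
               character(1)))))
      for (lv in setdiff(levs, tm$ref)) {
        pn <- paste0("fac_", tm$param, "_", tm$cov, "_", lv)
        add(pn, "log", inits[[pn]] %||%
              inits$filt_factors[[lv]] %||% 1)
      }
    }
  }
  for (re in spec$random_effects)
    add(paste0("omega2_", re), "log",
        max(inits$omega2[[re]] %||% 0.1, 1e-4))
  for (cl in classes)
    add(paste0("sigma_", cl), "log", inits$sigma_log[[cl]] %||% 0.3)
  data.frame(name = nm, scale = sc, init = iv, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# turn a fit into an inits list so child models start at the parent optimum
.fit_to_inits <- function(fit) {
  sp <- .split_params(fit$estimates, fit$spec)
  c(sp$th, list(omega2 = sp$omega2, sigma_log = sp$sigma))
}

.pack <- function(values, table) {
  out <- values
  i <- table$scale == "log"
  out[i] <- log(values[i])
  out
}
.unpack_vec <- function(pt, table) {
  v <- ifelse(table$scale == "log", exp(pt), pt)
  names(v) <- table$name
  v
}

# Split a natural-scale named vector into the pieces used by the objective.
.split_params <- function(v, spec) {
  th <- as.list(v[!grepl("^(omega2_|sigma_)", names(v))])
  names(th) <- sub("^", "", names(th))
  omega2 <- v[grepl("^omega2_", names(v))]
  names(omega2) <- sub("omega2_", "", names(omega2))
  omega2 <- omega2[spec$random_effects]
  sigma <- v[grepl("^sigma_", names(v))]
  names(sigma) <- sub("sigma_", "", names(sigma))
  list(th = th, omega2 = omega2, sigma = sigma)
}

# ---- likelihood ------------------------------------------------------------

# total Laplace -2LL over patients; warm (environment) caches per-patient
# empirical-Bayes modes across calls
.n2ll_total <- function(pt, table, spec, pats, warm = NULL, want_eta = FALSE) {
  v <- .unpack_vec(pt, table)
  sp <- .split_params(v, spec)
  k <- length(spec$random_effects)
  omega_inv <- diag(1 / sp$omega2, k)
  log_det_omega <- sum(log(sp$omega2))
  eta_map <- c(CLR = 0L, CLM = 1L, CLCKRT = 2L, V1 = 3L)[spec$random_effects]
  total <- 0
  etas <- matrix(0, length(pats), k,
                 dimnames = list(names(pats), spec$random_effects))
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    typ <- .typical_params(spec, sp$th, p)
    if (any(!is.finite(typ))) return(1e10)
    sig2 <- sp$sigma[p$obs_class]^2
    eta0 <- if (!is.null(warm) && !is.null(warm$eta[[i]])) warm$eta[[i]]
    else rep(0, k)
    r <- cpp_laplace_patient(typ, unname(eta_map), omega_inv, log_det_omega,
                             p$segments, p$ev_times, p$obs_idx, p$obs_idx0,
                             unname(p$obs_type), p$obs_y, unname(sig2),
                             p$obs_uvol, p$phi_pl, p$phi_eff, eta0)
    if (!is.null(warm)) warm$eta[[i]] <- r$eta
    if (want_eta && k > 0) etas[i, ] <- r$eta
    total <- total + r$n2ll
  }
  if (want_eta) attr(total, "etas") <- etas
  total
}

#' Approximate -2 log-likelihood of a model on a dataset
#'
#' Marginal likelihood over the random effects approximated by a Laplace
#' expansion around the per-patient empirical Bayes modes (Gauss-Newton
#' Hessian), matching a first-order-conditional-with-interaction analysis in
#' intent; absolute values are implementation-specific, so model comparison
#' must use OFV *differences*.  The observation model is
#' `log(DV) ~ N(log(pred), sigma_matrix^2)` with a separate residual SD per
#' matrix class.
#'
#' @param spec a [model_spec()].
#' @param params named list with entries `theta_*` (see
#'   [population_parameters()] naming), `omega2` (named by random effect) and
#'   `sigma_log` (named by residual class); a [population_parameters()]
#'   object is also accepted.
#' @param data long-format dataset (see [generate_study_dataset()]).
#' @return the approximate -2LL (lower is better).
#' @export
neg2_loglik <- function(spec, params, data) {
  pats <- Filter(Negate(is.null), .prepare_patients(data))
  inits <- .params_to_inits(params)
  table <- .par_table(spec, pats, inits)
  pt <- .pack(table$init, table)
  as.numeric(.n2ll_total(pt, table, spec, pats))
}

.params_to_inits <- function(params) {
  if (inherits(params, "pop_parameters")) {
    out <- unclass(params)
  } else out <- params
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit the population model by Laplace approximation
#'
#' Minimises the approximate -2LL over log-parameterised fixed effects,
#' random-effect variances and residual SDs with `nlminb`.  Standard errors
#' come from the numerical Hessian at the optimum; shrinkage per random
#' effect is `100 (1 - SD(EBE)/omega)`.
#'
#' @inheritParams neg2_loglik
#' @param inits initial values (list or [population_parameters()]); defaults
#'   to [population_parameters()].
#' @param control passed to [stats::nlminb()].
#' @param compute_se compute the Hessian-based standard errors (slower)?
#' @param optimize set `FALSE` to evaluate at `inits` without optimising
#'   (useful for diagnostics at known parameters).
#' @return an object of class `pedmero_fit` with elements `estimates`
#'   (named natural-scale vector), `theta`, `omega2`, `sigma_log`, `ofv`,
#'   `se`, `rse_pct`, `eta` (per-patient EBEs), `shrinkage_pct`,
#'   `convergence`, `spec` and the prepared data.
#' @export
pk_fit <- function(spec, data, inits = population_parameters(),
                   control = list(iter.max = 500, eval.max = 2000, rel.tol = 1e-8),
                   compute_se = TRUE, optimize = TRUE) {
  pats <- Filter(Negate(is.null), .prepare_patients(data))
  if (length(pats) == 0) stop("no usable observations in the dataset")
  inits <- .params_to_inits(inits)
  table <- .par_table(spec, pats, inits)
  warm <- new.env(); warm$eta <- vector("list", length(pats))
  obj <- function(pt) as.numeric(.n2ll_total(pt, table, spec, pats, warm))
  pt0 <- .pack(table$init, table)
  ofv0 <- obj(pt0)
  if (!is.finite(ofv0) || ofv0 >= 1e10)
    stop("initial values give a non-finite objective")
  lower <- ifelse(table$scale == "log", -12, -50)
  upper <- ifelse(table$scale == "log", 12, 50)
  opt <- if (optimize) {
    o <- nlminb(pt0, obj, control = control, lower = lower, upper = upper)
    # a stalled line search ("false convergence") often clears on restart
    if (o$convergence != 0) {
      o2 <- nlminb(o$par, obj, control = control, lower = lower,
                   upper = upper)
      if (o2$objective <= o$objective) o <- o2
    }
    o
  } else list(par = pt0, convergence = 0L, message = "evaluated at inits")
  est <- .unpack_vec(opt$par, table)
  sp <- .split_params(est, spec)
  n2 <- .n2ll_total(opt$par, table, spec, pats, warm, want_eta = TRUE)
  etas <- attr(n2, "etas")
  se <- rse <- setNames(rep(NA_real_, nrow(table)), table$name)
  if (compute_se) {
    H <- try(optimHess(opt$par, obj), silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(2 * solve(H), silent = TRUE)  # objective is -2LL
      if (!inherits(V, "try-error")) {
        sd_t <- sqrt(pmax(diag(V), 0))
        # delta method back to the natural scale for log-parameterised entries
        se <- setNames(ifelse(table$scale == "log", est * sd_t, sd_t),
                       table$name)
        rse <- 100 * se / abs(est)
      }
    }
  }
  shr <- setNames(rep(NA_real_, length(spec$random_effects)),
                  spec$random_effects)
  if (length(pats) > 1)
    for (re in spec$random_effects)
      shr[re] <- 100 * (1 - sd(etas[, re]) / sqrt(sp$omega2[[re]]))
  structure(list(estimates = est, theta = sp$th, omega2 = sp$omega2,
                 sigma_log = sp$sigma, ofv = as.numeric(n2),
                 ofv_init = ofv0, se = se, rse_pct = rse,
                 eta = etas, shrinkage_pct = shr,
                 convergence = opt$convergence, message = opt$message,
                 n_obs = sum(vapply(pats, function(p) length(p$obs_y), 0L)),
                 par_table = table, par_opt = opt$par,
                 spec = spec, patients = pats),
            class = "pedmero_fit")
}

#' @export
print.pedmero_fit <- function(x, ...) {
  cat("Population PK fit (Laplace):", length(x$patients), "patients,",
      x$n_obs, "observations\n")
  cat(sprintf("  OFV = %.3f (convergence code %d)\n", x$ofv, x$convergence))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    `RSE%` = round(x$rse_pct, 1), check.names = FALSE)
  print(tab)
  if (length(x$shrinkage_pct))
    cat("  shrinkage (%):",
        paste(sprintf("%s=%.0f", names(x$shrinkage_pct), x$shrinkage_pct),
              collapse = " "), "\n")
  invisible(x)
}

#' Compare two nested fits by objective-function difference
#'
#' A drop of 3.84 / 6.61 points in the objective function for one additional
#' parameter is significant at the 5% / 1% level; for more parameters the
#' matching chi-square quantiles are used.
#'
#' @param full,reduced `pedmero_fit` objects (or numeric OFVs, with `df`).
#' @param df number of additional parameters in `full`; inferred from fit
#'   objects when possible.
#' @return list with `delta_ofv`, `df`, `threshold_05`, `threshold_01`,
#'   `significant_05`, `significant_01`, `p_value`.
#' @export
compare_models <- function(full, reduced, df = NULL) {
  ofv_f <- if (inherits(full, "pedmero_fit")) full$ofv else full
  ofv_r <- if (inherits(reduced, "pedmero_fit")) reduced$ofv else reduced
  if (is.null(df)) {
    if (!inherits(full, "pedmero_fit") || !inherits(reduced, "pedmero_fit"))
      stop("df must be given when OFVs are passed as numbers")
    nf <- full$par_table$name; nr <- reduced$par_table$name
    if (!all(nr %in% nf))
      stop("models are not nested: reduced model has parameters absent ",
           "from the full model")
    df <- length(setdiff(nf, nr))
  }
  if (df < 1) stop("df must be >= 1")
  d <- ofv_r - ofv_f
  th05 <- if (df == 1) 3.84 else qchisq(0.95, df)
  th01 <- if (df == 1) 6.61 else qchisq(0.99, df)
  list(delta_ofv = d, df = df, threshold_05 = th05, threshold_01 = th01,
       significant_05 = d > th05, significant_01 = d > th01,
       p_value = stats::pchisq(max(d, 0), df, lower.tail = FALSE))
}

#' Stepwise covariate modelling
#'
#' Greedy forward selection (admit the candidate with the largest
#' objective-function drop if it exceeds the 5% chi-square threshold)
#' followed by backward deletion (remove each retained term unless its loss
#' exceeds the 1% threshold).  Ties are resolved by larger drop, then fewer
#' added parameters, then lexicographic term id, so the audit trail is
#' deterministic.  Highly collinear candidate pairs (|r| > 0.95 across
#' patients) are flagged with a warning, not dropped.
#'
#' @param base_spec the starting [model_spec()].
#' @param candidates list of covariate term lists (as in [model_spec()]).
#' @param data long-format dataset.
#' @param inits initial values forwarded to [pk_fit()].
#' @param forward_alpha,backward_alpha significance levels (defaults 0.05
#'   and 0.01).
#' @param control optimizer control for the stepwise fits; the default is
#'   looser than [pk_fit()]'s since admission decisions only need the
#'   objective to ~0.1 points.
#' @return list with `spec` (selected model), `fit` (its fit), and `trail`
#'   (data.frame logging every tested step).
#' @export
scm <- function(base_spec, candidates, data,
                inits = population_parameters(),
                forward_alpha = 0.05, backward_alpha = 0.01,
                control = list(iter.max = 400, eval.max = 1600,
                               rel.tol = 1e-7)) {
  if (length(candidates) == 0) {
    fit <- pk_fit(base_spec, data, inits, compute_se = FALSE,
                  control = control)
    return(list(spec = base_spec, fit = fit,
                trail = data.frame(phase = character(0), term = character(0),
                                   delta_ofv = numeric(0), df = integer(0),
                                   action = character(0))))
  }
  .flag_collinear(candidates, data)
  fit0 <- pk_fit(base_spec, data, inits, compute_se = FALSE,
                 control = control)
  current <- base_spec; cur_fit <- fit0
  remaining <- candidates
  trail <- list()
  repeat {  # forward
    if (length(remaining) == 0) break
    res <- lapply(remaining, function(tm) {
      sp <- current
      sp$covariate_terms <- c(sp$covariate_terms, list(tm))
      f <- try(pk_fit(sp, data, inits, compute_se = FALSE,
                      control = control), silent = TRUE)
      if (inherits(f, "try-error")) return(NULL)
      df <- length(setdiff(f$par_table$name, cur_fit$par_table$name))
      list(tm = tm, fit = f, d = cur_fit$ofv - f$ofv, df = max(df, 1L))
    })
    res <- Filter(Negate(is.null), res)
    if (length(res) == 0) break
    ids <- vapply(res, function(r) .term_id(r$tm), character(1))
    dvs <- vapply(res, function(r) r$d, numeric(1))
    dfs <- vapply(res, function(r) r$df, numeric(1))
    for (k in seq_along(res))
      trail[[length(trail) + 1]] <- data.frame(
        phase = "forward", term = ids[k], delta_ofv = dvs[k], df = dfs[k],
        action = "tested")
    ord <- order(-dvs, dfs, ids)
    best <- res[[ord[1]]]
    thr <- qchisq(1 - forward_alpha, best$df)
    if (best$df == 1) thr <- 3.84
    if (best$d > thr) {
      # before admitting, make sure the gain is not a stalled parent fit:
      # refit the current model warm-started from the candidate's estimates
      re <- try(pk_fit(current, data, .fit_to_inits(best$fit),
                       compute_se = FALSE, control = control), silent = TRUE)
      if (!inherits(re, "try-error") && re$ofv < cur_fit$ofv - 1e-8) {
        cur_fit <- re
        best$d <- cur_fit$ofv - best$fit$ofv
      }
    }
    if (best$d > thr) {
      current$covariate_terms <- c(current$covariate_terms, list(best$tm))
      cur_fit <- best$fit
      remaining <- remaining[vapply(remaining, .term_id, character(1)) !=
                               .term_id(best$tm)]
      trail[[length(trail) + 1]] <- data.frame(
        phase = "forward", term = .term_id(best$tm), delta_ofv = best$d,
        df = best$df, action = "added")
    } else break
  }
  added_ids <- setdiff(vapply(current$covariate_terms, .term_id, character(1)),
                       vapply(base_spec$covariate_terms, .term_id, character(1)))
  base_sig <- paste(sort(vapply(base_spec$covariate_terms, .term_id,
                                character(1))), collapse = "|")
  for (id in added_ids) {  # backward
    keep <- vapply(current$covariate_terms, .term_id, character(1)) != id
    sp <- current; sp$covariate_terms <- current$covariate_terms[keep]
    sig <- paste(sort(vapply(sp$covariate_terms, .term_id, character(1))),
                 collapse = "|")
    f <- if (sig == base_sig) fit0
    else pk_fit(sp, data, inits, compute_se = FALSE, control = control)
    df <- max(length(setdiff(cur_fit$par_table$name, f$par_table$name)), 1L)
    loss <- f$ofv - cur_fit$ofv
    thr <- if (df == 1) 6.61 else qchisq(1 - backward_alpha, df)
    if (loss > thr && sig != base_sig) {
      # about to keep the term: rule out a stalled reduced fit
      re <- try(pk_fit(sp, data, .fit_to_inits(cur_fit), compute_se = FALSE,
                       control = control), silent = TRUE)
      if (!inherits(re, "try-error") && re$ofv < f$ofv) {
        f <- re
        loss <- f$ofv - cur_fit$ofv
      }
    }
    drop_it <- loss <= thr
    trail[[length(trail) + 1]] <- data.frame(
      phase = "backward", term = id, delta_ofv = loss, df = df,
      action = if (drop_it) "removed" else "kept")
    if (drop_it) { current <- sp; cur_fit <- f }
  }
  list(spec = current, fit = cur_fit, trail = do.call(rbind, trail))
}

.flag_collinear <- function(candidates, data) {
  cont <- unique(unlist(lapply(candidates, function(tm)
    if (tm$form != "factor") tm$cov)))
  cont <- intersect(cont, names(data))
  if (length(cont) < 2) return(invisible())
  first <- data[!duplicated(data$ID), cont, drop = FALSE]
  cc <- suppressWarnings(stats::cor(first, use = "pairwise.complete.obs"))
  cc[!upper.tri(cc)] <- 0
  bad <- which(abs(cc) > 0.95, arr.ind = TRUE)
  for (k in seq_len(nrow(bad)))
    warning("candidate covariates ", cont[bad[k, 1]], " and ",
            cont[bad[k, 2]], " are highly collinear (|r| > 0.95)",
            call. = FALSE)
  invisible()
}
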