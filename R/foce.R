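# FOCE-I estimation. Outer optimization runs on an unconstrained transformed
# scale: log for positive structural parameters, GvHD factors and variances,
# raw scale for covariate exponents, log-Cholesky for the Omega block.
# Objective values follow the NONMEM convention: -2*log-likelihood without
# the n*log(2*pi) constant, applied consistently everywhere (so the Omega->0
# limit equals the naive-pooled -2LL under the same convention).

THETA_NAMES <- c("cl", "vc", "q", "vp")
COEF_NAMES <- c("wt_on_cl", "wt_on_vc", "alb_on_cl", "age_on_cl",
                "lym_on_cl", "gvhd_liver_on_cl", "gvhd_skin_on_cl",
                "gvhd_gut_on_cl")
LOG_COEFS <- c("gvhd_liver_on_cl", "gvhd_skin_on_cl", "gvhd_gut_on_cl")

default_estimate <- function() {
  c(THETA_NAMES, "wt_on_cl", "wt_on_vc", "alb_on_cl", "age_on_cl",
    "omega", "omega_iov_cl", "sigma2_prop")
}

# transformed parameter vector <-> pk_params
pars_to_vec <- function(params, est) {
  v <- c()
  for (nm in intersect(THETA_NAMES, est))
    v[paste0("log_", nm)] <- log(params$theta[[nm]])
  for (nm in intersect(COEF_NAMES, est))
    v[nm] <- if (nm %in% LOG_COEFS) log(params$coeffs[[nm]]) else
      params$coeffs[[nm]]
  if ("vmax" %in% est) v["log_vmax"] <- log(params$vmax)
  if ("km" %in% est) v["log_km"] <- log(params$km)
  if ("omega" %in% est) {
    L <- t(chol(params$omega))
    v["om_l11"] <- log(L[1, 1]); v["om_l21"] <- L[2, 1]
    v["om_l22"] <- log(L[2, 2]); v["om_l31"] <- L[3, 1]
    v["om_l32"] <- L[3, 2]; v["om_l33"] <- log(L[3, 3])
  }
  if ("omega_iov_cl" %in% est)
    v["log_omega_iov"] <- log(params$omega_iov_cl)
  if ("sigma2_prop" %in% est)
    v["log_sigma2_prop"] <- log(params$sigma2_prop)
  if ("sigma2_add" %in% est)
    v["log_sigma2_add"] <- log(params$sigma2_add)
  v
}

vec_to_pars <- function(v, template, est) {
  p <- template
  for (nm in intersect(THETA_NAMES, est))
    p$theta[[nm]] <- exp(v[[paste0("log_", nm)]])
  for (nm in intersect(COEF_NAMES, est))
    p$coeffs[[nm]] <- if (nm %in% LOG_COEFS) exp(v[[nm]]) else v[[nm]]
  if ("vmax" %in% est) p$vmax <- exp(v[["log_vmax"]])
  if ("km" %in% est) p$km <- exp(v[["log_km"]])
  if ("omega" %in% est) {
    L <- matrix(0, 3, 3)
    L[1, 1] <- exp(v[["om_l11"]]); L[2, 1] <- v[["om_l21"]]
    L[2, 2] <- exp(v[["om_l22"]]); L[3, 1] <- v[["om_l31"]]
    L[3, 2] <- v[["om_l32"]]; L[3, 3] <- exp(v[["om_l33"]])
    p$omega <- L %*% t(L)
    dimnames(p$omega) <- dimnames(template$omega)
  }
  if ("omega_iov_cl" %in% est)
    p$omega_iov_cl <- exp(v[["log_omega_iov"]])
  if ("sigma2_prop" %in% est)
    p$sigma2_prop <- exp(v[["log_sigma2_prop"]])
  if ("sigma2_add" %in% est)
    p$sigma2_add <- exp(v[["log_sigma2_add"]])
  p
}

# one evaluation of the FOCE-I objective on assembled fit data
foce_eval <- function(fd, params, b_init = NULL) {
  typ <- fd_typical(fd, params)
  if (is.null(b_init)) b_init <- vector("list", fd$nsub)
  .foce_all_cpp(as.integer(fd$sub_seg_off), fd$seg_t0, fd$seg_rate,
                typ$cl0, typ$vc0, typ$q0, typ$vp0,
                as.integer(fd$seg_occ), as.integer(fd$sub_obs_off),
                fd$obs_t, as.integer(fd$obs_seg), fd$y,
                as.integer(fd$sub_nocc), params$omega, params$omega_iov_cl,
                params$sigma2_prop, params$sigma2_add, b_init)
}

#' FOCE-I objective function value
#'
#' Evaluates the first-order-conditional-estimation-with-interaction
#' approximation to -2 log-likelihood of an event-record dataset under a
#' population model: per subject the joint conditional mode of (eta, kappa)
#' is located, the model is linearized around it, and the marginal normal
#' likelihood is evaluated with the residual variance taken at the
#' conditional estimates (the "interaction" part). The additive constant
#' n*log(2*pi) is omitted (NONMEM convention).
#'
#' @param data Event-record dataset (BLQ rows already excluded, see
#'   [apply_exclusions()]).
#' @param params A [pk_params()] object.
#' @return The objective function value, with attributes `ofv_i`
#'   (per-subject contributions) and `converged` (per-subject inner
#'   convergence flags). Inner failures are flagged, never silently dropped.
#' @export
foce_objective <- function(data, params) {
  fd <- build_fitdata(data)
  if (sum(fd$sub_obs_off[fd$nsub + 1]) < 1)
    stop("dataset has no usable observations")
  res <- foce_eval(fd, params)
  structure(res$ofv, ofv_i = res$ofv_i, converged = res$converged)
}

#' Empirical Bayes estimates and shrinkage
#'
#' Conditional modes of the subject-level random effects eta (CL, Vc, Vp)
#' and occasion-level kappa (CL) given the data and a set of population
#' parameters, with eta-shrinkage per random effect on the standard
#' deviation scale, `100*(1 - SD(EBE)/omega)`. A subject with no
#' observations keeps the prior mode 0. Random effects with zero population
#' variance have undefined shrinkage (`NA`).
#'
#' @inheritParams foce_objective
#' @return List with `eta` (matrix subjects x 3), `kappa` (per-subject
#'   vectors indexed by dosing occasion; occasions without observations are
#'   0), `shrinkage` (named percentage vector: `cl`, `vc`, `vp`, `iov_cl`),
#'   `ipred` (individual predictions at the modes) and `ofv`.
#' @export
empirical_bayes <- function(data, params) {
  fd <- build_fitdata(data)
  res <- foce_eval(fd, params)
  extract_ebes(fd, params, res)
}

extract_ebes <- function(fd, params, res) {
  eta <- matrix(0, fd$nsub, 3, dimnames = list(fd$ids, c("cl", "vc", "vp")))
  kappa <- vector("list", fd$nsub)
  for (i in seq_len(fd$nsub)) {
    b <- res$b[[i]]
    kap <- rep(0, fd$sub_ndose[i])
    if (!is.null(b)) {
      eta[i, ] <- b[1:3]
      klev <- fd$kappa_levels[[i]]
      if (length(klev)) kap[klev] <- b[3 + seq_along(klev)]
    }
    kappa[[i]] <- kap
  }
  shr <- c(cl = NA_real_, vc = NA_real_, vp = NA_real_, iov_cl = NA_real_)
  ov <- diag(params$omega)
  for (k in 1:3) if (ov[k] > 0)
    shr[k] <- 100 * (1 - sd(eta[, k]) / sqrt(ov[k]))
  allk <- unlist(lapply(seq_len(fd$nsub), function(i) {
    klev <- fd$kappa_levels[[i]]
    if (length(klev)) kappa[[i]][klev] else numeric(0)
  }))
  if (params$omega_iov_cl > 0 && length(allk) > 1)
    shr["iov_cl"] <- 100 * (1 - sd(allk) / sqrt(params$omega_iov_cl))
  ipred <- numeric(length(fd$obs_t))
  for (i in seq_len(fd$nsub)) {
    o <- seq.int(fd$sub_obs_off[i] + 1, length.out = diff(fd$sub_obs_off)[i])
    if (length(o) && !is.null(res$ipred[[i]])) ipred[o] <- res$ipred[[i]]
  }
  list(eta = eta, kappa = kappa, shrinkage = shr, ipred = ipred,
       ofv = res$ofv)
}

#' Fit the population PK model by FOCE-I
#'
#' Maximum-likelihood estimation of the two-compartment population model by
#' first-order conditional estimation with interaction. The outer problem is
#' solved by quasi-Newton optimization on an unconstrained transformed scale
#' (log for positive parameters, log-Cholesky factor for the Omega block),
#' which enforces positivity and positive semi-definiteness by construction;
#' per-subject conditional modes are located by a damped Gauss-Newton inner
#' optimization and carried as warm starts between outer iterations.
#'
#' @param data Event-record dataset with BLQ rows already excluded (see
#'   [apply_exclusions()]).
#' @param start Initial [pk_params()]; also supplies the values of all
#'   parameters that are not estimated (e.g. the fixed allometric exponents
#'   0.75 on Q and 1 on Vp, which are never estimated).
#' @param estimate Character vector naming the estimated components: any of
#'   `"cl"`, `"vc"`, `"q"`, `"vp"`, the covariate coefficients
#'   (`"wt_on_cl"`, `"wt_on_vc"`, `"alb_on_cl"`, `"age_on_cl"`,
#'   `"lym_on_cl"`, `"gvhd_*_on_cl"`), `"omega"` (the full 3x3 block),
#'   `"omega_iov_cl"`, `"sigma2_prop"`, `"sigma2_add"`. Defaults to the
#'   final-model structure: structural parameters, weight exponents on CL
#'   and Vc, albumin and age exponents on CL, Omega block, IOV and
#'   proportional error.
#' @param compute_se Compute standard errors from a finite-difference
#'   Hessian of the objective at the optimum (adds roughly `p^2` objective
#'   evaluations).
#' @param control Passed to [nlminb()]; defaults
#'   `list(rel.tol = 1e-7, iter.max = 400, eval.max = 1600)`.
#' @return An object of class `"pkfit"`; see [summary.pkfit()],
#'   [coef.pkfit()], [predict.pkfit()], [residuals.pkfit()],
#'   [simulate.pkfit()], [plot.pkfit()].
#' @export
pk_foce_fit <- function(data, start = pk_params(),
                        estimate = default_estimate(),
                        compute_se = FALSE, control = list()) {
  stopifnot(inherits(start, "pk_params"))
  bad <- setdiff(estimate, c(THETA_NAMES, COEF_NAMES, "omega",
                             "omega_iov_cl", "sigma2_prop", "sigma2_add"))
  if (length(bad)) stop("unknown estimate components: ",
                        paste(bad, collapse = ", "))
  fd <- build_fitdata(data)
  v0 <- pars_to_vec(start, estimate)
  n_obs <- length(fd$obs_t)
  n_fixef <- sum(names(v0) %in% c(paste0("log_", THETA_NAMES), COEF_NAMES))
  if (n_obs < n_fixef)
    stop("fewer observations (", n_obs, ") than estimated fixed effects (",
         n_fixef, ")")

  warm <- new.env(parent = emptyenv())
  warm$b <- vector("list", fd$nsub)
  warm$last_v <- NULL; warm$last_f <- NULL
  obj <- function(v) {
    names(v) <- names(v0)
    p <- try(vec_to_pars(v, start, estimate), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    res <- try(foce_eval(fd, p, warm$b), silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$ofv)) return(1e10)
    warm$b <- res$b
    warm$last_v <- v; warm$last_f <- res$ofv
    res$ofv
  }
  # forward-difference gradient with a step large enough to dominate the
  # small warm-start noise of the inner optimization (the PORT default step
  # is too small for a conditionally-optimized objective)
  grad_h <- 1e-4
  grad <- function(v) {
    f0 <- if (!is.null(warm$last_v) && isTRUE(all.equal(v, warm$last_v,
                                                        tolerance = 0)))
      warm$last_f else obj(v)
    vapply(seq_along(v), function(k) {
      vk <- v; vk[k] <- vk[k] + grad_h
      (obj(vk) - f0) / grad_h
    }, numeric(1))
  }
  ctrl <- modifyList(list(rel.tol = 1e-7, iter.max = 400, eval.max = 1600),
                     control)
  opt <- nlminb(v0, obj, grad, control = ctrl)
  if (opt$convergence != 0) {  # one restart from the incumbent
    opt2 <- nlminb(opt$par, obj, grad, control = ctrl)
    if (is.finite(opt2$objective) && opt2$objective <= opt$objective)
      opt2$iterations <- opt$iterations + opt2$iterations
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  vhat <- setNames(opt$par, names(v0))
  p_hat <- vec_to_pars(vhat, start, estimate)
  final <- foce_eval(fd, p_hat, warm$b)
  eb <- extract_ebes(fd, p_hat, final)
  n_par <- length(vhat)
  ofv <- final$ofv
  fit <- structure(list(
    params = p_hat, estimate = estimate, vec = vhat, start = start,
    ofv = ofv, aic = ofv + 2 * n_par, n_par = n_par,
    n_obs = n_obs, n_sub = fd$nsub,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       inner_ok = all(final$converged)),
    eta = eb$eta, kappa = eb$kappa, shrinkage = eb$shrinkage,
    ipred = eb$ipred, pred = fd_pred(fd, p_hat),
    fd = fd, vcov_t = NULL, se_table = NULL), class = "pkfit")
  if (compute_se) fit <- add_standard_errors(fit, obj)
  fit
}

# finite-difference Hessian -> covariance of estimates; natural-scale SE and
# RSE% by the delta method (log-scale parameters: SE = estimate * SE_log)
add_standard_errors <- function(fit, obj) {
  vhat <- fit$vec
  H <- try(optimHess(vhat, obj,
                     control = list(ndeps = rep(1e-4, length(vhat)))),
           silent = TRUE)
  cov_t <- NULL
  if (!inherits(H, "try-error")) {
    H <- (H + t(H)) / 2
    cov_t <- try(2 * solve(H), silent = TRUE)
    if (inherits(cov_t, "try-error") || any(diag(cov_t) < 0)) cov_t <- NULL
  }
  if (is.null(cov_t)) {
    warning("Hessian singular or indefinite; covariance of estimates ",
            "unavailable, confidence intervals suppressed")
    fit$vcov_t <- NULL
    return(fit)
  }
  dimnames(cov_t) <- list(names(vhat), names(vhat))
  fit$vcov_t <- cov_t
  nat <- natural_estimates(fit)
  se_t <- sqrt(diag(cov_t))
  log_scale <- is_log_scale(names(vhat))
  se_nat <- ifelse(log_scale, abs(nat$value) * se_t, se_t)
  fit$se_table <- data.frame(parameter = nat$parameter, estimate = nat$value,
                             se = se_nat,
                             rse_percent = 100 * se_nat / abs(nat$value),
                             log_scale = log_scale)
  fit
}

# transformed-scale parameters estimated on the log scale (positive theta,
# variances, GvHD factors, Omega-Cholesky diagonal)
is_log_scale <- function(nm) {
  grepl("^log_", nm) | nm %in% LOG_COEFS |
    nm %in% c("om_l11", "om_l22", "om_l33")
}

# natural-scale values of the estimated (transformed) parameter vector;
# Omega entries are reported as Cholesky-factor elements
natural_estimates <- function(fit) {
  v <- fit$vec
  nm <- names(v)
  val <- ifelse(is_log_scale(nm), exp(v), v)
  par <- sub("^log_", "", nm)
  data.frame(parameter = par, value = unname(val))
}
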