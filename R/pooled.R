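# Naive-pooled (no-random-effects) maximum-likelihood fitting. Used for
# structural-model screening, in particular the comparison of linear against
# parallel linear + Michaelis-Menten elimination, where the saturable
# pathway's parameters are typically poorly identified and a random-effects
# fit is not warranted until a structural form is chosen.

fd_pred_mm <- function(fd, params, rtol = 1e-8, atol = 1e-10) {
  typ <- fd_typical(fd, params)
  out <- numeric(length(fd$obs_t))
  for (i in seq_len(fd$nsub)) {
    s <- (fd$sub_seg_off[i] + 1):fd$sub_seg_off[i + 1]
    o <- seq.int(fd$sub_obs_off[i] + 1, length.out = diff(fd$sub_obs_off)[i])
    if (!length(o)) next
    out[o] <- .profile_mm_cpp(fd$seg_t0[s], fd$seg_rate[s], typ$cl0[s],
                              typ$vc0[s], typ$q0[s], typ$vp0[s],
                              params$vmax, params$km, fd$obs_t[o],
                              fd$obs_seg[o], rtol, atol)
  }
  out
}

#' Naive-pooled fit of the structural model
#'
#' Maximum-likelihood fit treating all observations as coming from one
#' typical subject (all random effects fixed at zero), for either the linear
#' two-compartment model or the variant with parallel Michaelis-Menten
#' elimination. Intended for structural screening and AIC comparison via
#' [compare_models()]; population variability is estimated with
#' [pk_foce_fit()] once the structural form is chosen.
#'
#' @param data Event-record dataset (BLQ-excluded).
#' @param start Initial [pk_params()]; for `model = "mm"` it must carry
#'   `vmax` and `km`.
#' @param estimate Estimated components: structural names, covariate
#'   coefficients, `"sigma2_prop"`, `"sigma2_add"`, and for the MM variant
#'   `"vmax"`, `"km"`.
#' @param model `"linear"` or `"mm"`.
#' @param control Passed to [nlminb()].
#' @return A list of class `"pkfit_pooled"` with `params`, `ofv`, `aic`,
#'   `n_par`, `n_obs`, `convergence`; usable with [compare_models()].
#' @export
pk_pooled_fit <- function(data, start = pk_params(),
                          estimate = c("cl", "vc", "q", "vp", "sigma2_prop"),
                          model = c("linear", "mm"), control = list()) {
  model <- match.arg(model)
  allowed <- c(THETA_NAMES, COEF_NAMES, "sigma2_prop", "sigma2_add",
               "vmax", "km")
  bad <- setdiff(estimate, allowed)
  if (length(bad)) stop("unknown estimate components for a pooled fit: ",
                        paste(bad, collapse = ", "))
  if (model == "linear" && any(c("vmax", "km") %in% estimate))
    stop("vmax/km can only be estimated with model = 'mm'")
  if (model == "mm" && is.null(start$vmax))
    stop("model = 'mm' needs start values for vmax and km")
  fd <- build_fitdata(data)
  v0 <- pars_to_vec(start, estimate)
  obj <- function(v) {
    names(v) <- names(v0)
    p <- try(vec_to_pars(v, start, estimate), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    f <- try(if (model == "mm") fd_pred_mm(fd, p) else fd_pred(fd, p),
             silent = TRUE)
    if (inherits(f, "try-error") || any(!is.finite(f))) return(1e10)
    vv <- pmax(p$sigma2_prop * f^2 + p$sigma2_add, 1e-12)
    sum(log(vv) + (fd$y - f)^2 / vv)
  }
  ctrl <- modifyList(list(rel.tol = 1e-9, iter.max = 500, eval.max = 2000),
                     control)
  opt <- nlminb(v0, obj, control = ctrl)
  vhat <- setNames(opt$par, names(v0))
  p_hat <- vec_to_pars(vhat, start, estimate)
  structure(list(params = p_hat, model = model, vec = vhat,
                 ofv = opt$objective, aic = opt$objective + 2 * length(vhat),
                 n_par = length(vhat), n_obs = length(fd$obs_t),
                 n_sub = fd$nsub,
                 convergence = list(code = opt$convergence,
                                    message = opt$message)),
            class = "pkfit_pooled")
}

#' @export
print.pkfit_pooled <- function(x, ...) {
  cat(sprintf("Naive-pooled %s structural fit: %d obs, %d parameters, OFV %.3f, AIC %.3f\n",
              x$model, x$n_obs, x$n_par, x$ofv, x$aic))
  th <- x$params$theta
  cat(sprintf("  CL %.4g, Vc %.4g, Q %.4g, Vp %.4g", th["cl"], th["vc"],
              th["q"], th["vp"]))
  if (x$model == "mm")
    cat(sprintf(", Vmax %.4g mg/day, Km %.4g ug/mL", x$params$vmax,
                x$params$km))
  cat("\n")
  invisible(x)
}
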