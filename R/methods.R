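# S3 methods for "pkfit" objects.

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK model fit (FOCE-I)\n")
  cat(sprintf("  %d subjects, %d observations, %d estimated parameters\n",
              x$n_sub, x$n_obs, x$n_par))
  cat(sprintf("  OFV %.3f   AIC %.3f   (outer convergence code %d%s)\n",
              x$ofv, x$aic, x$convergence$code,
              if (x$convergence$inner_ok) "" else "; inner failures flagged"))
  th <- x$params$theta
  cat(sprintf("  CL %.4g L/day, Vc %.4g L, Q %.4g L/day, Vp %.4g L (reference patient)\n",
              th["cl"], th["vc"], th["q"], th["vp"]))
  invisible(x)
}

#' Coefficients of a fitted population PK model
#'
#' @param object A `"pkfit"` object.
#' @param ... Unused.
#' @return Named vector of the estimated parameters on the natural scale
#'   (structural values, covariate coefficients, Omega Cholesky entries,
#'   variances).
#' @export
coef.pkfit <- function(object, ...) {
  nat <- natural_estimates(object)
  setNames(nat$value, nat$parameter)
}

#' @export
vcov.pkfit <- function(object, ...) {
  if (is.null(object$vcov_t))
    stop("covariance of estimates unavailable; refit with compute_se = TRUE")
  object$vcov_t
}

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' Summarize a fitted population PK model
#'
#' Renders a parameter report in the layout customary for population PK
#' papers: structural estimates with 95% CI and RSE%, variance components
#' with CV% (`100*sqrt(exp(omega2)-1)` for log-normal IIV/IOV,
#' `100*sqrt(sigma2)` for proportional error), correlations of the Omega
#' block, and eta/kappa shrinkage on the SD scale.
#'
#' @param object A `"pkfit"` object.
#' @param ci_scale `"lognormal"` for CIs of positive parameters on the log
#'   scale (`theta*exp(±1.96*RSE/100)`), `"symmetric"` for `±1.96*SE`.
#' @param ... Unused.
#' @return An object of class `"summary.pkfit"` (list of report tables).
#' @export
summary.pkfit <- function(object, ci_scale = c("lognormal", "symmetric"),
                          ...) {
  ci_scale <- match.arg(ci_scale)
  p <- object$params
  th <- data.frame(parameter = c("CL", "Vc", "Q", "Vp"),
                   estimate = unname(p$theta[THETA_NAMES]),
                   units = c("L/day", "L", "L/day", "L"))
  th$lower <- th$upper <- th$rse <- NA_real_
  if (!is.null(object$se_table)) {
    st <- object$se_table
    for (k in seq_len(4)) {
      row <- match(THETA_NAMES[k], st$parameter)
      if (!is.na(row)) {
        th$rse[k] <- st$rse_percent[row]
        ci <- if (ci_scale == "lognormal")
          ci95_lognormal(th$estimate[k], st$rse_percent[row]) else
            ci95_symmetric(th$estimate[k], st$se[row])
        th$lower[k] <- ci[1]; th$upper[k] <- ci[2]
      }
    }
  }
  om <- p$omega
  iiv <- data.frame(
    parameter = c("IIV CL", "IIV Vc", "IIV Vp", "IOV CL", "Proportional"),
    estimate = c(diag(om), p$omega_iov_cl, p$sigma2_prop),
    cv_percent = c(cv_percent(diag(om)[1]), cv_percent(diag(om)[2]),
                   cv_percent(diag(om)[3]), cv_percent(p$omega_iov_cl),
                   cv_percent(p$sigma2_prop, type = "proportional")),
    shrinkage = c(object$shrinkage[c("cl", "vc", "vp", "iov_cl")], NA))
  corr <- data.frame(
    pair = c("CL-Vc", "CL-Vp", "Vc-Vp"),
    covariance = c(om[1, 2], om[1, 3], om[2, 3]),
    correlation = c(corr_from_cov(om[1, 2], om[1, 1], om[2, 2]),
                    corr_from_cov(om[1, 3], om[1, 1], om[3, 3]),
                    corr_from_cov(om[2, 3], om[2, 2], om[3, 3])))
  cf <- p$coeffs
  covariate <- data.frame(
    parameter = c("weight on CL", "weight on Vc", "weight on Q (fixed)",
                  "weight on Vp (fixed)", "albumin on CL", "age on CL",
                  "lymphocytes on CL", "GvHD liver on CL",
                  "GvHD skin on CL", "GvHD gut on CL"),
    estimate = unname(unlist(cf)))
  structure(list(fit = object, structural = th, covariate = covariate,
                 random = iiv, correlation = corr, ci_scale = ci_scale),
            class = "summary.pkfit")
}

#' @export
print.summary.pkfit <- function(x, digits = 3, ...) {
  f <- x$fit
  cat("Population PK model: two-compartment, linear elimination, FOCE-I\n")
  cat(sprintf("%d subjects, %d observations; OFV %.3f, AIC %.3f\n\n",
              f$n_sub, f$n_obs, f$ofv, f$aic))
  cat("Structural parameters (reference patient):\n")
  st <- x$structural
  for (k in seq_len(nrow(st)))
    cat(sprintf("  %-3s %9.4g %-6s %s RSE%% %s\n", st$parameter[k],
                st$estimate[k], st$units[k],
                if (is.na(st$lower[k])) "CI n/a       " else
                  sprintf("%.3g-%.3g", st$lower[k], st$upper[k]),
                if (is.na(st$rse[k])) "n/a" else sprintf("%.3g", st$rse[k])))
  cat("\nCovariate coefficients:\n")
  for (k in seq_len(nrow(x$covariate)))
    cat(sprintf("  %-22s %8.4g\n", x$covariate$parameter[k],
                x$covariate$estimate[k]))
  cat("\nRandom effects:\n")
  rd <- x$random
  for (k in seq_len(nrow(rd)))
    cat(sprintf("  %-13s %8.4g  [CV%% = %.1f]  shrinkage %s\n",
                rd$parameter[k], rd$estimate[k], rd$cv_percent[k],
                if (is.na(rd$shrinkage[k])) "-" else
                  sprintf("%.1f%%", rd$shrinkage[k])))
  cat("\nOmega correlations:\n")
  for (k in seq_len(nrow(x$correlation)))
    cat(sprintf("  %-6s cov %9.4g  [Corr = %.3f]\n", x$correlation$pair[k],
                x$correlation$covariance[k], x$correlation$correlation[k]))
  invisible(x)
}

#' Predictions from a fitted population PK model
#'
#' @param object A `"pkfit"` object.
#' @param newdata Optional event-record dataset; defaults to the fitting
#'   data. Individual predictions require `newdata` to contain only subjects
#'   present in the fit.
#' @param type `"population"` (all random effects zero) or `"individual"`
#'   (empirical Bayes modes).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations, one per observation
#'   row of the dataset (in `ID`/`TIME` order).
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("population", "individual"), ...) {
  type <- match.arg(type)
  fd <- if (is.null(newdata)) object$fd else build_fitdata(newdata)
  if (type == "population") return(fd_pred(fd, object$params))
  idx <- match(fd$ids, object$fd$ids)
  if (anyNA(idx))
    stop("individual predictions need subjects present in the fit")
  fd_ipred(fd, object$params, object$eta[idx, , drop = FALSE],
           object$kappa[idx])
}

#' Residuals of a fitted population PK model
#'
#' @param object A `"pkfit"` object.
#' @param type `"individual"` (observation minus individual prediction) or
#'   `"population"`; `weighted = TRUE` scales by the residual SD at the
#'   prediction (proportional + additive error model).
#' @param weighted Scale residuals by the model residual SD.
#' @param ... Unused.
#' @return Numeric vector, one value per fitted observation.
#' @export
residuals.pkfit <- function(object, type = c("individual", "population"),
                            weighted = FALSE, ...) {
  type <- match.arg(type)
  f <- if (type == "individual") object$ipred else object$pred
  r <- object$fd$y - f
  if (weighted) {
    v <- object$params$sigma2_prop * f^2 + object$params$sigma2_add
    r <- r / sqrt(pmax(v, 1e-12))
  }
  r
}

#' Simulate datasets from a fitted population PK model
#'
#' Draws replicate observation vectors on the design of the fitting dataset
#' (same subjects, doses, times and covariates) with new random effects and
#' residual noise at the estimated parameters.
#'
#' @param object A `"pkfit"` object.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix of simulated concentrations, observations in rows (in the
#'   order of the fitted observations), replicates in columns.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  sim_replicates(object$fd, object$params, nsim, seed)
}

#' Goodness-of-fit plots for a fitted population PK model
#'
#' Observed versus population and individual predictions, and weighted
#' residuals versus time and versus population predictions.
#'
#' @param x A `"pkfit"` object.
#' @param which Subset of the four panels to draw.
#' @param ... Unused.
#' @export
plot.pkfit <- function(x, which = 1:4, ...) {
  op <- par(mfrow = c(length(which) > 2, 2) + c(1, 0), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  y <- x$fd$y
  if (1 %in% which) {
    plot(x$pred, y, xlab = "Population prediction (ug/mL)",
         ylab = "Observed (ug/mL)", main = "Observed vs PRED", pch = 16,
         col = adjustcolor("black", 0.4))
    abline(0, 1, col = "grey50")
  }
  if (2 %in% which) {
    plot(x$ipred, y, xlab = "Individual prediction (ug/mL)",
         ylab = "Observed (ug/mL)", main = "Observed vs IPRED", pch = 16,
         col = adjustcolor("black", 0.4))
    abline(0, 1, col = "grey50")
  }
  wres <- residuals(x, type = "population", weighted = TRUE)
  if (3 %in% which) {
    plot(x$fd$obs_t, wres, xlab = "Time after first dose (days)",
         ylab = "Weighted residual", main = "Residuals vs time", pch = 16,
         col = adjustcolor("black", 0.4))
    abline(h = 0, col = "grey50")
  }
  if (4 %in% which) {
    plot(x$pred, wres, xlab = "Population prediction (ug/mL)",
         ylab = "Weighted residual", main = "Residuals vs PRED", pch = 16,
         col = adjustcolor("black", 0.4))
    abline(h = 0, col = "grey50")
  }
  invisible(x)
}
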