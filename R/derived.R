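# Derived reporting statistics: exact closed-form transforms used in the
# parameter tables.

#' Coefficient of variation of a variance estimate
#'
#' For log-normal inter-individual or inter-occasion variability,
#' `CV% = 100*sqrt(exp(omega2) - 1)`; for a proportional residual error
#' variance, `CV% = 100*sqrt(sigma2)`.
#'
#' @param variance Variance estimate, `>= 0`.
#' @param type `"lognormal"` (IIV/IOV) or `"proportional"` (residual).
#' @return CV in percent.
#' @examples
#' cv_percent(0.0827)                      # 29.4
#' cv_percent(0.0241, "proportional")      # 15.5
#' @export
cv_percent <- function(variance, type = c("lognormal", "proportional")) {
  type <- match.arg(type)
  if (any(variance < 0)) stop("variance must be non-negative")
  if (type == "lognormal") 100 * sqrt(exp(variance) - 1) else
    100 * sqrt(variance)
}

#' Correlation from a covariance and two variances
#'
#' @param cov_ij Covariance.
#' @param var_i,var_j Strictly positive variances.
#' @return `cov_ij / sqrt(var_i * var_j)`; values outside `[-1, 1]`
#'   (inconsistent inputs, e.g. from rounded table entries) raise an error.
#' @examples
#' corr_from_cov(0.0272, 0.0323, 0.179)    # 0.358
#' @export
corr_from_cov <- function(cov_ij, var_i, var_j) {
  if (var_i <= 0 || var_j <= 0) stop("variances must be strictly positive")
  r <- cov_ij / sqrt(var_i * var_j)
  if (abs(r) > 1 + 1e-12)
    stop("inconsistent inputs: |correlation| > 1 (", format(r), ")")
  min(max(r, -1), 1)
}

#' 95% confidence intervals for a positive estimate
#'
#' `ci95_lognormal()` places the interval on the log scale,
#' `theta*exp(±1.96*RSE/100)`, appropriate for strictly positive structural
#' parameters; `ci95_symmetric()` is the plain `estimate ± 1.96*SE` used for
#' variance components.
#'
#' @param estimate Estimate (`> 0` for the log-normal form).
#' @param rse_percent Relative standard error in percent (`> 0`).
#' @param se Standard error (symmetric form).
#' @return Length-2 vector `(lower, upper)`.
#' @examples
#' ci95_lognormal(0.148, 4.49)   # 0.136 - 0.162
#' @export
ci95_lognormal <- function(estimate, rse_percent) {
  if (estimate <= 0) stop("estimate must be strictly positive")
  if (rse_percent <= 0) stop("rse_percent must be strictly positive")
  estimate * exp(c(-1, 1) * 1.96 * rse_percent / 100)
}

#' @rdname ci95_lognormal
#' @export
ci95_symmetric <- function(estimate, se) {
  if (se < 0) stop("se must be non-negative")
  estimate + c(-1, 1) * 1.96 * se
}

#' Compare two fitted models by AIC
#'
#' Returns the preferred of two fits of the same dataset: the lower AIC
#' wins, but when the difference is below `tie` units the model with fewer
#' estimated parameters is preferred (parsimony).
#'
#' @param fit_a,fit_b `"pkfit"` objects (or lists with elements `aic`,
#'   `n_par`, `n_obs`) fitted to the same dataset.
#' @param labels Length-2 character labels for the report.
#' @param tie AIC difference below which the fits are treated as equivalent.
#' @return List with `preferred` (label), `delta_aic`
#'   (`AIC[a] - AIC[b]`) and `reason` (`"aic"` or `"parsimony"`).
#' @export
compare_models <- function(fit_a, fit_b, labels = c("A", "B"), tie = 2) {
  if (!is.null(fit_a$n_obs) && !is.null(fit_b$n_obs) &&
      fit_a$n_obs != fit_b$n_obs)
    stop("fits are not on identical datasets")
  d <- fit_a$aic - fit_b$aic
  if (abs(d) < tie) {
    pref <- if (fit_a$n_par <= fit_b$n_par) labels[1] else labels[2]
    reason <- "parsimony"
  } else {
    pref <- if (d < 0) labels[1] else labels[2]
    reason <- "aic"
  }
  list(preferred = pref, delta_aic = d, reason = reason)
}
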