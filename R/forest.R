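# Covariate forest-plot inference: uncertainty distribution of relative
# clearance at perturbed covariate values, normalized to the reference CL.

CL_DRAW_NAMES <- c("log_cl", "wt_on_cl", "alb_on_cl", "age_on_cl",
                   "lym_on_cl", "gvhd_liver_on_cl", "gvhd_skin_on_cl",
                   "gvhd_gut_on_cl")

#' Parameter uncertainty draws for clearance inference
#'
#' Samples the clearance-related parameter vector (log CL and the covariate
#' coefficients acting on CL) from a multivariate normal uncertainty
#' distribution on the estimation scale. The covariance may come from a fit
#' (`vcov` = the transformed-scale covariance of estimates, e.g.
#' `fit$vcov_t`), from a named diagonal of squared standard errors, or be
#' zero (`vcov = NULL`), in which case every draw equals the point estimate
#' and all intervals collapse.
#'
#' @param params A [pk_params()] object (point estimates).
#' @param vcov `NULL`, a named covariance matrix on the transformed scale
#'   (rows/columns named as in a `pkfit` vector: `log_cl`, `wt_on_cl`,
#'   `alb_on_cl`, ...), or a named vector of squared standard errors.
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return Object of class `"cl_draws"`: matrix of draws (one column per
#'   clearance-related parameter) with the reference covariates attached.
#' @export
uncertainty_draws <- function(params, vcov = NULL, n_draws = 10000,
                              seed = 1) {
  stopifnot(inherits(params, "pk_params"), n_draws >= 1)
  cf <- params$coeffs
  mu <- c(log_cl = log(params$theta[["cl"]]),
          wt_on_cl = cf$wt_on_cl, alb_on_cl = cf$alb_on_cl,
          age_on_cl = cf$age_on_cl, lym_on_cl = cf$lym_on_cl,
          gvhd_liver_on_cl = log(cf$gvhd_liver_on_cl),
          gvhd_skin_on_cl = log(cf$gvhd_skin_on_cl),
          gvhd_gut_on_cl = log(cf$gvhd_gut_on_cl))
  V <- matrix(0, length(mu), length(mu), dimnames = list(names(mu), names(mu)))
  if (!is.null(vcov)) {
    if (is.matrix(vcov)) {
      shared <- intersect(rownames(vcov), names(mu))
      V[shared, shared] <- vcov[shared, shared]
    } else {
      shared <- intersect(names(vcov), names(mu))
      diag(V)[match(shared, names(mu))] <- vcov[shared]
    }
  }
  set.seed(seed)
  draws <- matrix(rep(mu, each = n_draws), n_draws,
                  dimnames = list(NULL, names(mu)))
  if (max(abs(V)) > 0) {
    ev <- eigen(V, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    A <- ev$vectors %*% diag(sqrt(ev$values), nrow(V))
    draws <- draws + matrix(rnorm(n_draws * length(mu)), n_draws) %*% t(A)
    colnames(draws) <- names(mu)
  }
  structure(list(draws = draws, ref = params$ref, n_draws = n_draws,
                 seed = seed),
            class = "cl_draws")
}

#' Reference clearance from uncertainty draws
#'
#' The median over draws of the clearance evaluated at the reference
#' covariates; with zero covariance this is exactly the point estimate.
#'
#' @param draws A [uncertainty_draws()] object.
#' @return Scalar reference CL (L/day).
#' @export
reference_cl <- function(draws) {
  stopifnot(inherits(draws, "cl_draws"))
  median(exp(draws$draws[, "log_cl"]))
}

cl_coef_column <- c(weight = "wt_on_cl", albumin = "alb_on_cl",
                    age = "age_on_cl", lymphocytes = "lym_on_cl",
                    gvhd_liver = "gvhd_liver_on_cl",
                    gvhd_skin = "gvhd_skin_on_cl",
                    gvhd_gut = "gvhd_gut_on_cl")

#' Relative clearance at a perturbed covariate value
#'
#' Evaluates, per uncertainty draw, the clearance of a patient identical to
#' the reference except for one covariate fixed at `value` (univariate
#' perturbation), normalized by the reference CL (the median of the draw
#' distribution at reference covariates). Continuous covariates act through
#' their power-law term `(value/ref)^coef`; GvHD indicators through the
#' on-off factor.
#'
#' @param draws A [uncertainty_draws()] object.
#' @param covariate One of `"weight"`, `"albumin"`, `"age"`,
#'   `"lymphocytes"`, `"gvhd_liver"`, `"gvhd_skin"`, `"gvhd_gut"`.
#' @param value Perturbed covariate value (`> 0` for continuous covariates,
#'   0/1 for indicators).
#' @param level Confidence level of the interval (default 90%, the level
#'   used for covariate inference; 95% is also common for forest displays).
#' @return One-row data frame: `covariate`, `value`, `median`, `lower`,
#'   `upper`.
#' @export
relative_cl <- function(draws, covariate, value, level = 0.90) {
  stopifnot(inherits(draws, "cl_draws"))
  col <- cl_coef_column[covariate]
  if (is.na(col)) stop("unknown covariate: ", covariate)
  cont <- covariate %in% c("weight", "albumin", "age", "lymphocytes")
  if (cont && value <= 0)
    stop("continuous covariate values must be strictly positive")
  if (!cont && !value %in% c(0, 1))
    stop("GvHD indicator values must be 0 or 1")
  d <- draws$draws
  ref <- draws$ref[[covariate]]
  term <- if (cont) (value / ref)^d[, col] else exp(d[, col])^value
  rel <- exp(d[, "log_cl"]) * term / reference_cl(draws)
  a <- (1 - level) / 2
  data.frame(covariate = covariate, value = value,
             median = median(rel),
             lower = unname(quantile(rel, a)),
             upper = unname(quantile(rel, 1 - a)))
}

#' Relative steady-state exposure implied by a relative clearance
#'
#' For a linear model, steady-state exposure over a dosing interval is
#' `AUCss = Dose/CL`, so relative AUCss is the reciprocal of relative CL.
#'
#' @param relative_cl_value Relative clearance (`> 0`), e.g. the `median`
#'   column of [relative_cl()].
#' @return Relative AUCss.
#' @examples
#' aucss_change(0.833)   # about +20% exposure
#' @export
aucss_change <- function(relative_cl_value) {
  if (any(relative_cl_value <= 0)) stop("relative CL must be positive")
  1 / relative_cl_value
}

#' Observed covariate percentiles from a dataset
#'
#' The 5th/10th/25th/50th/75th/90th/95th percentiles of the observed values
#' of body weight, age, albumin and lymphocyte count on the observation rows
#' of an event-record dataset (time-varying covariates contribute all their
#' observed values).
#'
#' @param data Event-record dataset.
#' @param probs Percentile levels.
#' @return Data frame `covariate`, `percentile`, `value`.
#' @export
covariate_percentiles <- function(data,
                                  probs = c(0.05, 0.1, 0.25, 0.5, 0.75,
                                            0.9, 0.95)) {
  obs <- data[data$EVID == 0, , drop = FALSE]
  cols <- c(weight = "WT", albumin = "ALB", age = "AGE", lymphocytes = "LYM")
  do.call(rbind, lapply(names(cols), function(cv) {
    data.frame(covariate = cv, percentile = probs,
               value = unname(quantile(obs[[cols[cv]]], probs)))
  }))
}

#' Covariate forest table for relative clearance
#'
#' One row per covariate and observed percentile (plus the reference row),
#' each giving the median and confidence interval of relative CL under
#' parameter uncertainty. Rows whose interval lies entirely outside the
#' ±25% reference band are flagged as potentially clinically important.
#'
#' @param draws A [uncertainty_draws()] object.
#' @param percentiles Data frame from [covariate_percentiles()] (columns
#'   `covariate`, `percentile`, `value`).
#' @param level Confidence level (default 90%).
#' @return Object of class `"pk_forest"`: data frame `covariate`, `percentile`,
#'   `value`, `median`, `lower`, `upper`, `potentially_important`; has a
#'   `plot()` method drawing the forest with the ±25% shaded band.
#' @export
forest_table <- function(draws, percentiles, level = 0.90) {
  stopifnot(inherits(draws, "cl_draws"),
            all(c("covariate", "value") %in% names(percentiles)))
  ref_row <- relative_cl(draws, "weight", draws$ref[["weight"]], level)
  ref_row$covariate <- "reference"
  ref_row$percentile <- NA_real_
  rows <- lapply(seq_len(nrow(percentiles)), function(k) {
    r <- relative_cl(draws, percentiles$covariate[k],
                     percentiles$value[k], level)
    r$percentile <- percentiles$percentile[k]
    r
  })
  out <- rbind(ref_row, do.call(rbind, rows))
  out <- out[, c("covariate", "percentile", "value", "median", "lower",
                 "upper")]
  out$potentially_important <- out$lower > 1.25 | out$upper < 0.75
  structure(out, class = c("pk_forest", "data.frame"), level = level)
}

#' @export
plot.pk_forest <- function(x, ...) {
  n <- nrow(x)
  ypos <- rev(seq_len(n))
  xlim <- range(0.5, 1.5, x$lower, x$upper)
  op <- par(mar = c(4, 12, 2, 1))
  on.exit(par(op))
  plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
       xlab = "Relative CL", ylab = "",
       main = sprintf("Covariate effects on clearance (%d%% CI)",
                      round(100 * attr(x, "level"))))
  rect(0.75, 0.25, 1.25, n + 0.75, col = adjustcolor("grey70", 0.3),
       border = NA)
  abline(v = 1, col = "grey40")
  segments(x$lower, ypos, x$upper, ypos, lwd = 2, col = "steelblue4")
  points(x$median, ypos, pch = 16, col = "steelblue4")
  labs <- ifelse(is.na(x$percentile), "reference",
                 sprintf("%s %.3g (p%g)", x$covariate, x$value,
                         100 * x$percentile))
  axis(2, at = ypos, labels = labs, las = 1, cex.axis = 0.7)
  invisible(x)
}
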