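# Simulation-based model evaluation: prediction-corrected VPC and NPDE.

# quantile-based bins of time after most recent dose; nominal sampling times
# are snapped together (1e-6 day) so tied design times stay in one bin, and
# designs with few distinct times get one bin per time. Bins with fewer than
# min_n observations are merged into their left neighbour.
vpc_bins <- function(tad, bins, min_n = 3) {
  tad <- round(tad, 6)
  u <- sort(unique(tad))
  if (length(u) <= bins) {
    idx <- match(tad, u)
  } else {
    br <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
    idx <- findInterval(tad, br, rightmost.closed = TRUE, all.inside = TRUE)
    idx <- match(idx, sort(unique(idx)))
  }
  repeat {
    cnt <- tabulate(idx, nbins = max(idx))
    small <- which(cnt > 0 & cnt < min_n)
    if (!length(small)) break
    k <- small[1]
    tgt <- if (k > 1) k - 1L else k + 1L
    idx[idx == k] <- tgt
    idx <- match(idx, sort(unique(idx)))  # re-number contiguously
    message("VPC: merged a bin with fewer than ", min_n,
            " observations into its neighbour")
  }
  idx
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_rep` replicates of the dataset under the model, bins
#' observations by time after the most recent dose, prediction-corrects
#' observed and simulated values within each bin (value times bin-median
#' population prediction over the observation's own population prediction),
#' and summarizes the 5th/50th/95th percentiles of the observed data against
#' the 95% confidence bands of the same percentiles across replicates.
#'
#' @param data Event-record dataset (BLQ-excluded fitting set).
#' @param params Population parameters ([pk_params()] or `fit$params`).
#' @param n_rep Number of Monte Carlo replicates (>= 2; 500 in routine use).
#' @param bins Number of quantile bins of time after most recent dose.
#' @param seed Integer seed.
#' @return Object of class `"pk_vpc"`: a data frame with one row per bin
#'   (median time, n, observed percentiles, simulated 95% CI of each
#'   percentile) plus attributes; has a `plot()` method.
#' @export
pc_vpc <- function(data, params, n_rep = 500, bins = 8, seed = 1) {
  if (n_rep < 2) stop("n_rep must be at least 2")
  fd <- build_fitdata(data)
  pred <- fd_pred(fd, params)
  use <- pred > 0
  if (!all(use))
    message("VPC: dropping ", sum(!use),
            " pre-dose observations with zero population prediction")
  tad <- fd$tad[use]
  idx <- vpc_bins(tad, bins)
  nb <- max(idx)
  corr <- vapply(seq_len(nb), function(b) median(pred[use][idx == b]),
                 numeric(1))[idx] / pred[use]
  pc_obs <- fd$y[use] * corr

  probs <- c(0.05, 0.5, 0.95)
  obs_q <- t(vapply(seq_len(nb), function(b)
    quantile(pc_obs[idx == b], probs, names = FALSE), numeric(3)))

  sims <- sim_replicates(fd, params, n_rep, seed)[use, , drop = FALSE]
  sim_q <- array(NA_real_, c(nb, 3, n_rep))
  for (r in seq_len(n_rep)) {
    pc <- sims[, r] * corr
    for (b in seq_len(nb))
      sim_q[b, , r] <- quantile(pc[idx == b], probs, names = FALSE)
  }
  lo <- apply(sim_q, 1:2, quantile, probs = 0.025)
  hi <- apply(sim_q, 1:2, quantile, probs = 0.975)
  md <- apply(sim_q, 1:2, median)

  out <- data.frame(
    bin = seq_len(nb),
    tad_median = vapply(seq_len(nb), function(b) median(tad[idx == b]),
                        numeric(1)),
    n = tabulate(idx, nb),
    obs_p5 = obs_q[, 1], obs_p50 = obs_q[, 2], obs_p95 = obs_q[, 3],
    sim_p5_lo = lo[, 1], sim_p5_md = md[, 1], sim_p5_hi = hi[, 1],
    sim_p50_lo = lo[, 2], sim_p50_md = md[, 2], sim_p50_hi = hi[, 2],
    sim_p95_lo = lo[, 3], sim_p95_md = md[, 3], sim_p95_hi = hi[, 3])
  structure(out, class = c("pk_vpc", "data.frame"),
            n_rep = n_rep, seed = seed)
}

#' @export
plot.pk_vpc <- function(x, log = "y", ...) {
  tt <- x$tad_median
  ylim <- range(x$obs_p5, x$obs_p95, x$sim_p5_lo, x$sim_p95_hi)
  if (log == "y") ylim[1] <- max(ylim[1], 1e-3)
  plot(tt, x$obs_p50, type = "n", log = log, ylim = ylim,
       xlab = "Time after most recent dose (days)",
       ylab = "Prediction-corrected concentration (ug/mL)",
       main = "Prediction-corrected VPC")
  band <- function(lo, hi, col)
    polygon(c(tt, rev(tt)), c(lo, rev(hi)), border = NA,
            col = adjustcolor(col, 0.3))
  band(x$sim_p5_lo, x$sim_p5_hi, "grey40")
  band(x$sim_p95_lo, x$sim_p95_hi, "grey40")
  band(x$sim_p50_lo, x$sim_p50_hi, "steelblue")
  lines(tt, x$obs_p50, lwd = 2)
  lines(tt, x$obs_p5, lty = 2, lwd = 2)
  lines(tt, x$obs_p95, lty = 2, lwd = 2)
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' Per subject, simulates `n_rep` replicate observation vectors under the
#' model, decorrelates the observed and simulated vectors with the inverse
#' Cholesky factor of the simulated covariance, and transforms the rank of
#' each decorrelated observation among its simulated counterparts through
#' the standard normal quantile function using the mid-rank rule
#' `(k + 0.5)/(n_rep + 1)`. Under the true model the NPDE are standard
#' normal with mean 0 and variance 1.
#'
#' @inheritParams pc_vpc
#' @param n_rep Number of replicates (>= 100).
#' @return Object of class `"pk_npde"`: list with `npde` (per observation),
#'   `mean`, `var`, `shapiro_p` (normality test on up to 5000 values),
#'   `id`, `time`, `pred`.
#' @export
npde <- function(data, params, n_rep = 500, seed = 1) {
  if (n_rep < 100) stop("n_rep must be at least 100")
  fd <- build_fitdata(data)
  sims <- sim_replicates(fd, params, n_rep, seed)
  val <- numeric(length(fd$y))
  ridge_used <- FALSE
  for (i in seq_len(fd$nsub)) {
    o <- seq.int(fd$sub_obs_off[i] + 1, length.out = diff(fd$sub_obs_off)[i])
    if (!length(o)) next
    Y <- sims[o, , drop = FALSE]
    m <- rowMeans(Y)
    V <- tcrossprod(Y - m) / (n_rep - 1)
    L <- tryCatch(t(chol(V)), error = function(e) NULL)
    if (is.null(L)) {
      ridge_used <- TRUE
      V <- V + diag(1e-8 * mean(diag(V)) + 1e-12, nrow(V))
      L <- t(chol(V))
    }
    ystar <- forwardsolve(L, fd$y[o] - m)
    Ystar <- forwardsolve(L, Y - m)
    k <- rowSums(Ystar < ystar)
    val[o] <- qnorm((k + 0.5) / (n_rep + 1))
  }
  if (ridge_used)
    warning("singular simulated covariance ridge-regularized for some subjects")
  sh <- if (length(val) >= 3)
    shapiro.test(if (length(val) > 5000) sample(val, 5000) else val)$p.value
  else NA_real_
  structure(list(npde = val, mean = mean(val), var = var(val),
                 shapiro_p = sh, id = fd$obs_id, time = fd$obs_t,
                 pred = fd_pred(fd, params), n_rep = n_rep, seed = seed),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d replicates): mean %.3f, variance %.3f\n",
              length(x$npde), x$n_rep, x$mean, x$var))
  cat(sprintf("Shapiro-Wilk normality p = %.3g (reference: N(0,1))\n",
              x$shapiro_p))
  invisible(x)
}

#' @export
plot.pk_npde <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$time, x$npde, pch = 16, col = adjustcolor("black", 0.4),
       xlab = "Time after first dose (days)", ylab = "NPDE",
       main = "NPDE vs time")
  abline(h = c(-1.96, 0, 1.96), lty = c(2, 1, 2), col = "grey50")
  plot(x$pred, x$npde, pch = 16, col = adjustcolor("black", 0.4),
       xlab = "Population prediction (ug/mL)", ylab = "NPDE",
       main = "NPDE vs PRED")
  abline(h = c(-1.96, 0, 1.96), lty = c(2, 1, 2), col = "grey50")
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Emits per-observation and per-subject diagnostic tables from a fitted
#' model: observed values with population and individual predictions,
#' raw and weighted residuals, time after dose and covariates (ready for
#' scatter/LOESS display), and empirical Bayes eta estimates against
#' subject-level covariates (including GvHD involvement) for post hoc
#' covariate exploration.
#'
#' @param data The fitted (BLQ-excluded) event-record dataset.
#' @param fit A `"pkfit"` object.
#' @return List with `observations` and `ebe` data frames.
#' @export
gof_tables <- function(data, fit) {
  fd <- fit$fd
  rows <- fd$data[fd$obs_row, , drop = FALSE]
  v <- fit$params$sigma2_prop * fit$ipred^2 + fit$params$sigma2_add
  obs <- data.frame(
    ID = fd$obs_id, TIME = fd$obs_t, TAD = fd$tad, OCC = fd$occ,
    DV = fd$y, PRED = fit$pred, IPRED = fit$ipred,
    RES = fd$y - fit$pred, IRES = fd$y - fit$ipred,
    IWRES = (fd$y - fit$ipred) / sqrt(pmax(v, 1e-12)),
    rows[, intersect(c(COV_COLS, "SEX", "RACE", "STUDY"), names(rows)),
         drop = FALSE])
  base <- fd$data[!duplicated(fd$data$ID), , drop = FALSE]
  base <- base[match(fd$ids, base$ID), , drop = FALSE]
  sub <- fd$data[fd$data$EVID == 0, , drop = FALSE]
  gv <- aggregate(sub[, c("GVHDL", "GVHDS", "GVHDI")],
                  by = list(ID = sub$ID), FUN = max)
  gv <- gv[match(fd$ids, gv$ID), , drop = FALSE]
  ebe <- data.frame(
    ID = fd$ids,
    eta_cl = fit$eta[, 1], eta_vc = fit$eta[, 2], eta_vp = fit$eta[, 3],
    WT = base$WT, ALB = base$ALB, AGE = base$AGE, LYM = base$LYM,
    GVHD_LIVER = gv$GVHDL, GVHD_SKIN = gv$GVHDS, GVHD_GUT = gv$GVHDI,
    SEX = base$SEX, STUDY = base$STUDY)
  list(observations = obs, ebe = ebe)
}
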