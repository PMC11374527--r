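# Internal assembly of an event-record table into the flattened
# segment/observation arrays consumed by the compiled kernels. Covariates on
# the table rows are interpolated with NOCB; segments break at dose starts,
# infusion ends and covariate-change times, and observations are evaluated
# inside their segment (an observation exactly at a dose time sees the
# pre-dose state). The same assembly backs simulation, FOCE estimation,
# predictions and diagnostics, so their time-varying-covariate semantics are
# identical by construction.

build_fitdata <- function(data) {
  req <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", COV_COLS)
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("dataset is missing columns: ",
                         paste(miss, collapse = ", "))
  data <- data[order(data$ID, data$TIME, data$EVID), , drop = FALSE]
  data$.ROW <- seq_len(nrow(data))
  ids <- unique(data$ID)
  nsub <- length(ids)

  seg_t0 <- seg_rate <- numeric(0)
  seg_cov <- vector("list", nsub)
  seg_occ <- seg_dose <- integer(0)
  sub_seg_off <- sub_obs_off <- integer(nsub + 1)
  obs_t <- y <- tad <- numeric(0)
  obs_seg <- occ_lab <- integer(0)
  obs_row <- integer(0)
  sub_nocc <- sub_ndose <- integer(nsub)
  kappa_levels <- vector("list", nsub)

  for (i in seq_len(nsub)) {
    rows <- data[data$ID == ids[i], , drop = FALSE]
    dr <- rows[rows$EVID == 1, , drop = FALSE]
    orows <- rows[rows$EVID == 0, , drop = FALSE]
    if (nrow(dr) == 0) stop("subject ", ids[i], " has no dose record")
    if (any(is.na(dr$AMT)) || any(dr$AMT <= 0) ||
        any(is.na(dr$RATE)) || any(dr$RATE <= 0))
      stop("dose rows of subject ", ids[i], " need AMT > 0 and RATE > 0")
    doses <- data.frame(time = dr$TIME, amt = dr$AMT,
                        duration = dr$AMT / dr$RATE)

    # per-subject covariate series from the table rows (first row at a time)
    keep <- !duplicated(rows$TIME)
    ctimes <- rows$TIME[keep]
    cvals <- rows[keep, COV_COLS, drop = FALSE]
    chg <- ctimes[c(TRUE, rowSums(abs(as.matrix(cvals[-1, , drop = FALSE]) -
                     as.matrix(cvals[-nrow(cvals), , drop = FALSE]))) > 0)]

    ot <- orows$TIME
    if (length(ot) == 0) ot <- max(doses$time)  # segments still needed
    seg <- build_segments(doses, knots = chg, t = ot)
    nseg <- length(seg$t0)
    scv <- as.data.frame(lapply(cvals, function(v)
      nocb_interpolate(ctimes, v, seg$mid)))
    names(scv) <- COV_COLS

    lab <- assign_occasions(doses$time, orows$TIME)
    klev <- attr(lab, "kappa_levels")
    slab <- findInterval(seg$mid, doses$time)
    socc <- match(slab, klev) - 1L
    socc[is.na(socc)] <- -1L

    sub_seg_off[i + 1] <- sub_seg_off[i] + nseg
    sub_obs_off[i + 1] <- sub_obs_off[i] + nrow(orows)
    seg_t0 <- c(seg_t0, seg$t0)
    seg_rate <- c(seg_rate, seg$rate)
    seg_cov[[i]] <- scv
    seg_occ <- c(seg_occ, socc)
    seg_dose <- c(seg_dose, slab - 1L)
    obs_t <- c(obs_t, orows$TIME)
    obs_seg <- c(obs_seg, if (nrow(orows)) findInterval(orows$TIME, seg$t0) - 1L)
    y <- c(y, orows$DV)
    occ_lab <- c(occ_lab, as.integer(lab))
    # time after most recent *strictly prior* dose: a trough drawn at the
    # dosing instant carries the elapsed interval, not zero (the
    # prior-or-equal convention applies to occasion labels only)
    lab_tad <- findInterval(orows$TIME, doses$time, left.open = TRUE)
    tad <- c(tad, ifelse(lab_tad > 0,
                         orows$TIME - doses$time[pmax(lab_tad, 1)],
                         orows$TIME))
    obs_row <- c(obs_row, orows$.ROW)
    sub_nocc[i] <- length(klev)
    sub_ndose[i] <- nrow(doses)
    kappa_levels[[i]] <- klev
  }
  cov <- do.call(rbind, seg_cov)
  list(nsub = nsub, ids = ids,
       sub_seg_off = sub_seg_off, seg_t0 = seg_t0, seg_rate = seg_rate,
       seg_cov = cov, seg_occ = seg_occ, seg_dose = seg_dose,
       sub_obs_off = sub_obs_off, obs_t = obs_t, obs_seg = obs_seg, y = y,
       occ = occ_lab, tad = tad, obs_row = obs_row,
       sub_nocc = sub_nocc, sub_ndose = sub_ndose,
       kappa_levels = kappa_levels,
       obs_id = rep(ids, diff(sub_obs_off)), data = data)
}

# covariate-adjusted typical parameter values per segment
fd_typical <- function(fd, params) {
  th <- params$theta; cf <- params$coeffs; rf <- params$ref
  cv <- fd$seg_cov
  wt <- cv$WT / rf[["weight"]]
  list(cl0 = th[["cl"]] * wt^cf$wt_on_cl *
         (cv$ALB / rf[["albumin"]])^cf$alb_on_cl *
         (cv$AGE / rf[["age"]])^cf$age_on_cl *
         (cv$LYM / rf[["lymphocytes"]])^cf$lym_on_cl *
         cf$gvhd_liver_on_cl^cv$GVHDL *
         cf$gvhd_skin_on_cl^cv$GVHDS *
         cf$gvhd_gut_on_cl^cv$GVHDI,
       vc0 = th[["vc"]] * wt^cf$wt_on_vc,
       q0 = th[["q"]] * wt^cf$wt_on_q,
       vp0 = th[["vp"]] * wt^cf$wt_on_vp)
}

# population predictions (all random effects at zero)
fd_pred <- function(fd, params, typ = fd_typical(fd, params)) {
  out <- numeric(length(fd$obs_t))
  for (i in seq_len(fd$nsub)) {
    s <- (fd$sub_seg_off[i] + 1):fd$sub_seg_off[i + 1]
    o <- seq.int(fd$sub_obs_off[i] + 1, length.out = diff(fd$sub_obs_off)[i])
    if (!length(o)) next
    out[o] <- .profile_piecewise_cpp(fd$seg_t0[s], fd$seg_rate[s],
                                     typ$cl0[s], typ$vc0[s], typ$q0[s],
                                     typ$vp0[s], fd$obs_t[o], fd$obs_seg[o])
  }
  out
}

# individual predictions for given random effects: eta = nsub x 3 matrix,
# kappa = list of per-dose-occasion vectors (length sub_ndose[i]) or NULL
fd_ipred <- function(fd, params, eta, kappa = NULL,
                     typ = fd_typical(fd, params)) {
  out <- numeric(length(fd$obs_t))
  for (i in seq_len(fd$nsub)) {
    s <- (fd$sub_seg_off[i] + 1):fd$sub_seg_off[i + 1]
    o <- seq.int(fd$sub_obs_off[i] + 1, length.out = diff(fd$sub_obs_off)[i])
    if (!length(o)) next
    kap <- if (is.null(kappa)) rep(0, fd$sub_ndose[i]) else kappa[[i]]
    kseg <- ifelse(fd$seg_dose[s] >= 0, kap[fd$seg_dose[s] + 1L], 0)
    out[o] <- .profile_piecewise_cpp(
      fd$seg_t0[s], fd$seg_rate[s],
      typ$cl0[s] * exp(eta[i, 1] + kseg),
      typ$vc0[s] * exp(eta[i, 2]), typ$q0[s],
      typ$vp0[s] * exp(eta[i, 3]),
      fd$obs_t[o], fd$obs_seg[o])
  }
  out
}

# simulate n_rep replicate observation vectors under params; returns a
# matrix (total observations x n_rep). Draws eta ~ MVN(0, Omega) per subject,
# kappa ~ N(0, omega_iov) per dosing occasion, proportional (+ additive)
# residual noise.
sim_replicates <- function(fd, params, n_rep, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  typ <- fd_typical(fd, params)
  om <- params$omega
  L <- if (max(abs(om)) > 0) t(chol(om + 1e-12 * diag(3))) else
    matrix(0, 3, 3)
  sdk <- sqrt(params$omega_iov_cl)
  sp <- sqrt(params$sigma2_prop); sa <- sqrt(params$sigma2_add)
  nobs <- length(fd$obs_t)
  out <- matrix(NA_real_, nobs, n_rep)
  for (r in seq_len(n_rep)) {
    eta <- t(L %*% matrix(rnorm(3 * fd$nsub), 3))
    kappa <- lapply(fd$sub_ndose, function(nd) rnorm(nd, 0, sdk))
    f <- fd_ipred(fd, params, eta, kappa, typ)
    out[, r] <- f * (1 + rnorm(nobs, 0, sp)) +
      (if (sa > 0) rnorm(nobs, 0, sa) else 0)
  }
  out
}
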