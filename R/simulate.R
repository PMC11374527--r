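#' Simulate a synthetic PK trial
#'
#' Forward-simulates concentrations for a generated population under a
#' population model: per subject a random effect vector eta ~ MVN(0, Omega),
#' per dosing occasion kappa ~ N(0, omega_iov), concentrations from the
#' two-compartment infusion model with time-varying covariates, and residual
#' noise `DV = f*(1 + e_prop) + e_add`. Observations below the lower limit
#' of quantification are flagged (`BLQ = 1`) but kept in the table; use
#' [apply_exclusions()] to remove them before fitting.
#'
#' @param population A [generate_population()] result.
#' @param params True model parameters ([pk_params()]).
#' @param seed Integer seed.
#' @return A `data.frame` (class `"pk_trial"`) in NONMEM-dialect event-record
#'   form: `ID`, `TIME` (days after first dose), `DAY` (transplant calendar
#'   day, `TIME - 1`), `AMT` (mg), `RATE` (mg/day), `EVID` (1 dose, 0
#'   observation), `MDV`, `DV` (ug/mL), `BLQ`, `OCC`, covariates `WT`,
#'   `ALB`, `AGE`, `LYM`, `GVHDL`, `GVHDS`, `GVHDI`, `SEX`, `RACE`, `STUDY`.
#'   The LLOQ is attached as attribute `lloq`.
#' @examples
#' pop <- generate_population(population_spec(n_1015 = 1, n_3035 = 2), seed = 1)
#' trial <- simulate_trial(pop, pk_params(), seed = 2)
#' head(trial)
#' @export
simulate_trial <- function(population, params, seed = 1) {
  stopifnot(inherits(population, "pk_population"),
            inherits(params, "pk_params"))
  ev <- eigen(params$omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("omega must be positive semi-definite")

  rows <- lapply(population, function(s) {
    if (nrow(s$doses) < 1) stop("subject ", s$id, " has no dose")
    lab <- assign_occasions(s$doses$time, s$obs_times)
    dn <- nrow(s$doses); on <- length(s$obs_times)
    d <- data.frame(
      ID = s$id,
      TIME = c(s$doses$time, s$obs_times),
      AMT = c(s$doses$amt, rep(NA_real_, on)),
      RATE = c(s$doses$amt / s$doses$duration, rep(NA_real_, on)),
      EVID = c(rep(1L, dn), rep(0L, on)),
      MDV = c(rep(1L, dn), rep(0L, on)),
      DV = NA_real_,
      BLQ = c(rep(NA_integer_, dn), rep(0L, on)),
      OCC = c(seq_len(dn), as.integer(lab)))
    cv <- subject_covariates_at(s, d$TIME)
    d <- cbind(d, cv)
    d$SEX <- s$sex; d$RACE <- s$race; d$STUDY <- s$study
    d
  })
  data <- do.call(rbind, rows)
  data <- data[order(data$ID, data$TIME, data$EVID), , drop = FALSE]
  data$DAY <- data$TIME - 1

  set.seed(seed)
  fd <- build_fitdata(data)
  typ <- fd_typical(fd, params)
  om <- params$omega
  L <- if (max(abs(om)) > 0) t(chol(om + 1e-12 * diag(3))) else matrix(0, 3, 3)
  eta <- t(L %*% matrix(rnorm(3 * fd$nsub), 3))
  kappa <- lapply(fd$sub_ndose, function(nd)
    rnorm(nd, 0, sqrt(params$omega_iov_cl)))
  f <- fd_ipred(fd, params, eta, kappa, typ)
  nobs <- length(f)
  dv <- f * (1 + rnorm(nobs, 0, sqrt(params$sigma2_prop))) +
    (if (params$sigma2_add > 0) rnorm(nobs, 0, sqrt(params$sigma2_add)) else 0)

  lloq <- population[[1]]$lloq
  out <- fd$data
  out$DV[fd$obs_row] <- dv
  out$BLQ[fd$obs_row] <- as.integer(dv < lloq)
  out$.ROW <- NULL
  rownames(out) <- NULL
  cols <- c("ID", "TIME", "DAY", "AMT", "RATE", "EVID", "MDV", "DV", "BLQ",
            "OCC", COV_COLS, "SEX", "RACE", "STUDY")
  out <- out[, cols]
  attr(out, "lloq") <- lloq
  attr(out, "seed") <- seed
  class(out) <- c("pk_trial", "data.frame")
  out
}
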