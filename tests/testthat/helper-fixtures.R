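# Shared fixtures, generated in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# small mixed-design trial with the published parameters as truth
small_trial <- function() {
  if (is.null(.fixtures$small)) {
    pop <- generate_population(population_spec(n_1015 = 3, n_3035 = 9),
                               seed = 101)
    trial <- simulate_trial(pop, pk_params(), seed = 102)
    .fixtures$small <- apply_exclusions(trial)
  }
  .fixtures$small
}

# identical-subject trial: degenerate covariate distributions so every
# subject shares the same design, weights and labs
uniform_population <- function(n = 12, seed = 501) {
  generate_population(population_spec(
    n_1015 = 0, n_3035 = n, age_sd = 1e-9,
    wt_quantiles = c(p10 = 75, p50 = 75, p90 = 75),
    alb_sd = 1e-9, alb_dip = 0, lym_cv = 1e-9,
    gvhd_incidence = c(liver = 0, skin = 0, gut = 0),
    wt_noise = 0, alb_noise = 0, lym_noise = 0), seed = seed)
}

# random positive two-compartment parameter/dose draws
random_pk_case <- function() {
  list(cl = runif(1, 0.05, 0.6), vc = runif(1, 1, 8),
       q = runif(1, 0.05, 2), vp = runif(1, 1, 10),
       dose = runif(1, 50, 500), dur = runif(1, 1 / 48, 0.5))
}

# one-subject event table at reference covariates
one_subject_table <- function(obs_times, dv, dose_amt = 300,
                              dose_time = 0, dur = 1 / 48) {
  n <- length(obs_times)
  d <- data.frame(
    ID = 1L,
    TIME = c(dose_time, obs_times),
    AMT = c(dose_amt, rep(NA_real_, n)),
    RATE = c(dose_amt / dur, rep(NA_real_, n)),
    EVID = c(1L, rep(0L, n)), MDV = c(1L, rep(0L, n)),
    DV = c(NA_real_, dv), BLQ = c(NA_integer_, rep(0L, n)),
    OCC = 1L, WT = 75, ALB = 4, AGE = 53, LYM = 0.1,
    GVHDL = 0L, GVHDS = 0L, GVHDI = 0L,
    SEX = "M", RACE = "white", STUDY = "VEDO-3035")
  d[order(d$TIME, d$EVID), ]
}
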