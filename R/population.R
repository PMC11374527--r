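# Synthetic subject generation: covariate distributions parameterized from
# the pooled-population summaries, with time-varying weight, albumin and
# lymphocyte trajectories and GvHD onset flags.

# fractional albumin dip: 0 at t = 0, deepest (= depth) near day 7,
# essentially resolved by day 60
albumin_dip_factor <- function(t, depth) {
  s <- pmax(t, 0) / 7
  1 - depth * s * exp(1 - s)
}

# lymphocyte depletion after conditioning with recovery over ~3 months
lymphocyte_factor <- function(t) {
  ifelse(t < 2, 1, 0.1 + 0.9 * (1 - exp(-(t - 2) / 45)))
}

#' Generate a synthetic study population
#'
#' Draws subjects for both study designs from the distributions in a
#' [population_spec()]: sex, race, age (truncated normal), baseline weight
#' (log-normal solved from the 10th/50th/90th percentiles), baseline albumin
#' and lymphocytes, dose allocation, covariate trajectories sampled at each
#' design's measurement visits, and GvHD onset times (exponential, truncated
#' to the study window; a flag stays 1 after onset). Output is reproducible
#' for a given `seed`.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed for the random draws.
#' @return An object of class `"pk_population"`: a list of subject records,
#'   each a list with `id`, `study`, `doses` (data frame `time`, `amt`,
#'   `duration`), `obs_times`, `cov` (data frame `time`, `weight`, `albumin`,
#'   `lymphocytes`), `gvhd_onset` (named vector, `Inf` = never), `age`,
#'   `sex`, `race`, `lloq`.
#' @examples
#' pop <- generate_population(population_spec(n_1015 = 2, n_3035 = 3), seed = 1)
#' length(pop)
#' @export
generate_population <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  designs <- list(vedo1015_design(), vedo3035_design())
  n_by <- c(spec$n_1015, spec$n_3035)
  # two-piece log-normal weight: matches all three printed deciles
  # (p10/p50/p90) exactly, accommodating their asymmetry on the log scale
  wq <- spec$wt_quantiles
  wt_meanlog <- log(wq[[2]])
  wt_sd_lo <- (log(wq[[2]]) - log(wq[[1]])) / qnorm(0.9)
  wt_sd_hi <- (log(wq[[3]]) - log(wq[[2]])) / qnorm(0.9)

  subjects <- list()
  id <- 0L
  for (d in seq_along(designs)) {
    des <- designs[[d]]
    if (n_by[d] == 0) next
    # dose-amount allocation with exact arm counts (e.g. 3 of 24 on 75 mg),
    # shuffled across subjects
    counts <- diff(c(0, round(cumsum(des$dose_fractions) * n_by[d])))
    amts <- rep(des$dose_amounts, counts)
    amts <- amts[sample.int(length(amts))]
    for (i in seq_len(n_by[d])) {
      id <- id + 1L
      sex <- if (runif(1) < spec$frac_male) "M" else "F"
      race <- sample(names(spec$race_probs), 1, prob = spec$race_probs)
      age <- 0
      while (age < spec$age_range[1] || age > spec$age_range[2])
        age <- rnorm(1, spec$age_mean, spec$age_sd)
      z <- rnorm(1)
      wt0 <- exp(wt_meanlog + z * (if (z < 0) wt_sd_lo else wt_sd_hi))
      alb0 <- max(rnorm(1, spec$alb_mean, spec$alb_sd), 1.5)
      lym0 <- exp(rnorm(1, log(spec$lym_mean) - 0.5 * spec$lym_cv^2,
                        spec$lym_cv))
      ct <- des$cov_times
      cov <- data.frame(
        time = ct,
        weight = wt0 * exp(rnorm(length(ct), 0, spec$wt_noise)),
        albumin = pmax(alb0 * albumin_dip_factor(ct, spec$alb_dip) *
                         exp(rnorm(length(ct), 0, spec$alb_noise)), 1.0),
        lymphocytes = pmax(lym0 * lymphocyte_factor(ct) *
                             exp(rnorm(length(ct), 0, spec$lym_noise)), 0.01))
      onset <- vapply(spec$gvhd_incidence, function(p) {
        if (runif(1) < p) {
          o <- 1 + rexp(1, 1 / spec$gvhd_onset_mean)  # post-transplant
          while (o > des$window) o <- 1 + rexp(1, 1 / spec$gvhd_onset_mean)
          o
        } else Inf
      }, numeric(1))
      names(onset) <- c("liver", "skin", "gut")
      subjects[[id]] <- list(
        id = id, study = des$label,
        doses = data.frame(time = des$dose_days, amt = amts[i],
                           duration = des$duration),
        obs_times = des$sample_times,
        cov = cov, gvhd_onset = onset,
        age = age, sex = sex, race = race, lloq = des$lloq)
    }
  }
  structure(subjects, class = "pk_population")
}

#' @export
print.pk_population <- function(x, ...) {
  st <- table(vapply(x, `[[`, "", "study"))
  cat(sprintf("Synthetic PK population: %d subjects (%s)\n", length(x),
              paste(sprintf("%s n=%d", names(st), st), collapse = ", ")))
  invisible(x)
}

# covariate vector of one subject at given times (NOCB for labs, onset
# thresholds for GvHD flags)
subject_covariates_at <- function(subj, times) {
  data.frame(
    WT = nocb_interpolate(subj$cov$time, subj$cov$weight, times),
    ALB = nocb_interpolate(subj$cov$time, subj$cov$albumin, times),
    AGE = rep(subj$age, length(times)),
    LYM = nocb_interpolate(subj$cov$time, subj$cov$lymphocytes, times),
    GVHDL = as.integer(times >= subj$gvhd_onset["liver"]),
    GVHDS = as.integer(times >= subj$gvhd_onset["skin"]),
    GVHDI = as.integer(times >= subj$gvhd_onset["gut"]))
}
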