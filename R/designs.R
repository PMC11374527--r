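# Study designs of the two source trials. TIME is days after the first dose;
# the transplant calendar day is TIME - 1 (first dose on Day -1, transplant
# on Day 0 of the calendar).

#' Study designs for the two vedolizumab GvHD-prophylaxis trials
#'
#' `vedo1015_design()` is the phase 1b dose-finding study: 75 mg (3 of 24
#' patients) or 300 mg given as 30-min IV infusions on calendar Days -1, +13
#' and +42, with rich sampling (pre-dose and 0.5, 2, 12, 24 h post-dose on
#' the first two dosing days; pre-dose and 0.5, 1, 2 h on the third; single
#' samples on 14 non-dosing days up to Day +100).
#'
#' `vedo3035_design()` is the phase 3 study: 300 mg infusions on calendar
#' Days -1, +13, +41, +69, +97, +125 and +153, with trough-style sampling
#' (pre-dose trough and end-of-infusion sample on dosing days, plus Day +180
#' and the end-of-treatment visit).
#'
#' @param eot_day Calendar day of the end-of-treatment visit (phase 3).
#' @return An object of class `"study_design"`: a list with `label`,
#'   `dose_days` (TIME of infusion starts), `dose_amounts` (mg) and
#'   `dose_fractions` (allocation), `duration` (infusion length, days),
#'   `sample_times` (TIME of PK samples), `cov_times` (TIME of covariate
#'   measurements), `lloq` (ug/mL) and `window` (study span, days).
#' @examples
#' vedo3035_design()$dose_days
#' @export
vedo1015_design <- function() {
  dose_days <- c(0, 14, 43)              # calendar days -1, +13, +42
  h <- 1 / 24
  samples <- sort(unique(c(
    0, 0 + c(0.5, 2, 12, 24) * h,        # Day -1: pre-dose + serial
    14, 14 + c(0.5, 2, 12, 24) * h,      # Day +13
    43, 43 + c(0.5, 1, 2) * h,           # Day +42
    c(3, 5, 7, 9, 11, 16, 18, 20, 22, 26, 30, 36, 40, 100) + 1)))
  structure(list(label = "VEDO-1015",
                 dose_days = dose_days,
                 dose_amounts = c(75, 300),
                 dose_fractions = c(3, 21) / 24,
                 duration = INFUSION_30MIN,
                 sample_times = samples,
                 cov_times = c(dose_days, 101),
                 lloq = 0.2,
                 window = 120),
            class = "study_design")
}

#' @rdname vedo1015_design
#' @export
vedo3035_design <- function(eot_day = 194) {
  dose_days <- c(0, 14, 42, 70, 98, 126, 154)  # Days -1, +13, ..., +153
  eoi <- dose_days + INFUSION_30MIN            # end-of-infusion samples
  troughs <- dose_days[-1]                     # pre-dose troughs (2nd dose on)
  samples <- sort(unique(c(eoi, troughs, 181, eot_day + 1)))
  structure(list(label = "VEDO-3035",
                 dose_days = dose_days,
                 dose_amounts = 300,
                 dose_fractions = 1,
                 duration = INFUSION_30MIN,
                 sample_times = samples,
                 cov_times = c(dose_days, 181),
                 lloq = 0.2,
                 window = eot_day + 1,
                 eot_day = eot_day),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design %s: %d doses (%s mg) on days %s\n", x$label,
              length(x$dose_days),
              paste(x$dose_amounts, collapse = "/"),
              paste(x$dose_days, collapse = ", ")))
  cat(sprintf("  %d PK samples per subject, LLOQ %.2g ug/mL\n",
              length(x$sample_times), x$lloq))
  invisible(x)
}

#' Population specification for the synthetic-trial generator
#'
#' Distributional summaries of the pooled analysis population used to draw
#' synthetic subjects: 57% male; age 18-72 years with mean 50.8; baseline
#' body weight two-piece log-normal matching the 10th/50th/90th percentiles
#' 51/75/105 kg exactly (separate log-scale spreads below and above the
#' median accommodate their asymmetry);
#' baseline albumin mean 3.97 g/dL; baseline absolute lymphocyte count mean
#' 0.426 K/uL; cumulative GvHD incidences 3.1% (liver), 32.1% (skin), 8.8%
#' (intestine).
#'
#' Covariate trajectories: weight carries small multiplicative measurement
#' noise; albumin shows a transient post-transplant dip (default 20% deep,
#' peaking around day 7 and resolved by about day 60); lymphocytes fall
#' after conditioning and recover over ~3 months. GvHD onset times are
#' exponential (truncated to the study window), and flags stay 1 after onset.
#'
#' @param n_1015,n_3035 Number of subjects on each study design.
#' @param frac_male Fraction of male subjects.
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated).
#' @param wt_quantiles Baseline weight 10th/50th/90th percentiles (kg).
#' @param alb_mean,alb_sd Baseline albumin distribution (g/dL).
#' @param alb_dip Fractional depth of the post-transplant albumin dip.
#' @param lym_mean,lym_cv Baseline lymphocyte log-normal mean (K/uL) and CV.
#' @param gvhd_incidence Named cumulative incidences (liver, skin, gut).
#' @param gvhd_onset_mean Mean of the exponential GvHD onset time (days).
#' @param wt_noise,alb_noise,lym_noise Multiplicative log-scale measurement
#'   noise SDs of the covariate trajectories.
#' @param race_probs Named race allocation probabilities.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(n_1015 = 24, n_3035 = 169,
                            frac_male = 0.57,
                            age_mean = 50.8, age_sd = 12,
                            age_range = c(18, 72),
                            wt_quantiles = c(p10 = 51, p50 = 75, p90 = 105),
                            alb_mean = 3.97, alb_sd = 0.35,
                            alb_dip = 0.20,
                            lym_mean = 0.426, lym_cv = 0.8,
                            gvhd_incidence = c(liver = 0.031, skin = 0.321,
                                               gut = 0.088),
                            gvhd_onset_mean = 30,
                            wt_noise = 0.015, alb_noise = 0.03,
                            lym_noise = 0.25,
                            race_probs = c(white = 0.741, asian = 0.155,
                                           black = 0.021, other = 0.083)) {
  if (n_1015 + n_3035 < 1) stop("at least one subject required")
  if (frac_male < 0 || frac_male > 1) stop("frac_male must be in [0, 1]")
  if (any(gvhd_incidence < 0 | gvhd_incidence > 1))
    stop("gvhd_incidence values must be in [0, 1]")
  if (is.unsorted(wt_quantiles)) stop("weight quantiles must be monotone")
  if (alb_dip < 0 || alb_dip >= 1) stop("alb_dip must be in [0, 1)")
  structure(list(n_1015 = n_1015, n_3035 = n_3035, frac_male = frac_male,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 wt_quantiles = wt_quantiles, alb_mean = alb_mean,
                 alb_sd = alb_sd, alb_dip = alb_dip, lym_mean = lym_mean,
                 lym_cv = lym_cv, gvhd_incidence = gvhd_incidence,
                 gvhd_onset_mean = gvhd_onset_mean, wt_noise = wt_noise,
                 alb_noise = alb_noise, lym_noise = lym_noise,
                 race_probs = race_probs / sum(race_probs)),
            class = "population_spec")
}
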