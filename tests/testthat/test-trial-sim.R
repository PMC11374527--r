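# Synthetic-trial generator: determinism, distributional targets, noise
# structure, design features, LLOQ accounting.

test_that("generation and simulation are reproducible given the seed", {
  spec <- population_spec(n_1015 = 2, n_3035 = 4)
  p1 <- generate_population(spec, seed = 77)
  p2 <- generate_population(spec, seed = 77)
  expect_identical(p1, p2)
  t1 <- simulate_trial(p1, pk_params(), seed = 78)
  t2 <- simulate_trial(p2, pk_params(), seed = 78)
  expect_identical(t1, t2)
  t3 <- simulate_trial(p1, pk_params(), seed = 79)
  expect_false(identical(t1$DV, t3$DV))
})

test_that("population summaries converge to the specification", {
  pop <- generate_population(population_spec(n_1015 = 0, n_3035 = 10000),
                             seed = 88)
  sex <- vapply(pop, `[[`, "", "sex")
  expect_lt(abs(mean(sex == "M") - 0.57), 0.02)
  wt0 <- vapply(pop, function(s) s$cov$weight[1], numeric(1))
  qs <- quantile(wt0, c(0.1, 0.5, 0.9))
  expect_lt(abs(qs[1] - 51), 3)
  expect_lt(abs(qs[2] - 75), 3)
  expect_lt(abs(qs[3] - 105), 3)
  alb0 <- vapply(pop, function(s) s$cov$albumin[1], numeric(1))
  expect_lt(abs(mean(alb0) - 3.97), 0.05)
  age <- vapply(pop, `[[`, 0, "age")
  expect_true(all(age >= 18 & age <= 72))
  expect_lt(abs(mean(age) - 50.8), 1.5)
  gv <- t(vapply(pop, function(s) is.finite(s$gvhd_onset), logical(3)))
  expect_lt(abs(mean(gv[, "liver"]) - 0.031), 0.01)
  expect_lt(abs(mean(gv[, "skin"]) - 0.321), 0.02)
  expect_lt(abs(mean(gv[, "gut"]) - 0.088), 0.015)
  expect_error(population_spec(frac_male = 1.4), "frac_male")
})

test_that("noise-free simulation equals the deterministic population prediction", {
  pop <- generate_population(population_spec(n_1015 = 2, n_3035 = 3),
                             seed = 91)
  p0 <- pk_params(omega = matrix(0, 3, 3), omega_iov_cl = 0,
                  sigma2_prop = 0, sigma2_add = 0)
  trial <- simulate_trial(pop, p0, seed = 92)
  fd <- vedopk:::build_fitdata(trial)
  pred <- vedopk:::fd_pred(fd, p0)
  expect_equal(fd$y, pred, tolerance = 1e-12)
  expect_equal(trial$DV[trial$EVID == 0], pred, tolerance = 1e-12)
})

test_that("full design emits the published visit structure and LLOQ accounting", {
  pop <- generate_population(population_spec(), seed = 201)
  trial <- simulate_trial(pop, pk_params(), seed = 202)
  # a phase 3 subject: samples on all 7 dosing days plus Day 180 and EOT
  s35 <- trial[trial$STUDY == "VEDO-3035" & trial$ID == trial$ID[
    which(trial$STUDY == "VEDO-3035")[1]], ]
  doses <- s35$TIME[s35$EVID == 1]
  expect_equal(doses, c(0, 14, 42, 70, 98, 126, 154))
  obs_t <- s35$TIME[s35$EVID == 0]
  expect_true(all(vapply(doses, function(d)
    any(obs_t >= d & obs_t < d + 1), logical(1))))
  expect_true(181 %in% obs_t)          # Day +180
  expect_true(195 %in% obs_t)          # end-of-treatment visit
  # phase 1b: 75 mg allocation and rich sampling
  s15 <- trial[trial$STUDY == "VEDO-1015", ]
  expect_setequal(unique(s15$AMT[s15$EVID == 1]), c(75, 300))
  expect_gt(sum(s15$EVID == 0) / length(unique(s15$ID)), 20)

  # BLQ regression fixture: fraction recorded from this fixed-seed run
  ex <- apply_exclusions(trial)
  expect_equal(ex$n_obs, 3207)
  expect_equal(ex$blq_fraction, 0.00748362956, tolerance = 1e-8)
  expect_lt(ex$blq_fraction, 0.03)     # of order 1%
  expect_gt(ex$blq_fraction, 0.001)
})

test_that("between-subject spread of exposures grows with the CL variance", {
  pop <- uniform_population(n = 40, seed = 93)
  cvs <- vapply(c(0.01, 0.0827, 0.3), function(w) {
    p <- pk_params(omega = diag(c(w, 1e-8, 1e-8)), omega_iov_cl = 0,
                   sigma2_prop = 1e-8)
    trial <- simulate_trial(pop, p, seed = 94)
    # trough concentrations at the last dosing day reflect cumulative CL
    tr <- trial[trial$EVID == 0 & trial$TIME == 154, "DV"]
    sd(tr) / mean(tr)
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("proportional residual noise is centred on the model prediction", {
  pop <- generate_population(population_spec(n_1015 = 0, n_3035 = 60),
                             seed = 95)
  p <- pk_params()
  trial <- simulate_trial(pop, p, seed = 96)
  # regenerate the noiseless individual profiles with the same seed draws
  p0 <- pk_params(sigma2_prop = 0)
  t0 <- simulate_trial(pop, p0, seed = 96)
  ratio <- trial$DV[trial$EVID == 0] / t0$DV[t0$EVID == 0]
  keep <- is.finite(ratio)
  n <- sum(keep)
  expect_lt(abs(mean(ratio[keep]) - 1),
            3 * sqrt(p$sigma2_prop) / sqrt(n))
})
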