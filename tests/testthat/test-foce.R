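# FOCE-I objective and estimation: degenerate limits, quadrature oracle,
# recovery, empirical Bayes and shrinkage behaviour.

test_that("Omega -> 0 objective equals the naive-pooled -2LL", {
  dat <- small_trial()$retained
  p0 <- pk_params(omega = matrix(0, 3, 3), omega_iov_cl = 0)
  ofv <- foce_objective(dat, p0)
  fd <- vedopk:::build_fitdata(dat)
  f <- vedopk:::fd_pred(fd, p0)
  v <- p0$sigma2_prop * f^2
  naive <- sum(log(v) + (fd$y - f)^2 / v)
  expect_equal(as.numeric(ofv), naive, tolerance = 1e-6)
  expect_true(all(attr(ofv, "converged")))
})

test_that("single-observation objective matches the numerically integrated marginal", {
  # additive-error, one subject, one observation; exact marginal by
  # quadrature over the CL random effect
  y <- 30
  dat <- one_subject_table(obs_times = 7, dv = y)
  s2a <- 4
  marginal_m2ll <- function(w) {
    f_eta <- function(eta) vapply(eta, function(e)
      conc_2cmt_linear(7, data.frame(time = 0, amt = 300),
                       list(cl = 0.148 * exp(e), vc = 3.12, q = 0.5,
                            vp = 3.95)), numeric(1))
    L <- 8 * sqrt(w)   # the prior confines the posterior to +/- 8 SD
    lik <- integrate(function(eta)
      dnorm(y, f_eta(eta), sqrt(s2a)) * dnorm(eta, 0, sqrt(w)),
      -L, L, rel.tol = 1e-12)$value
    -2 * log(lik) - log(2 * pi)  # same constant convention as the objective
  }
  # the conditional approximation converges to the exact marginal as the
  # random-effect variance shrinks (error is O(omega^2) here), and stays
  # within the method class at the published variance
  err <- vapply(c(1e-6, 1e-4, 0.0827), function(w) {
    p <- pk_params(omega = diag(c(w, 0, 0)), omega_iov_cl = 0,
                   sigma2_prop = 0, sigma2_add = s2a)
    abs(as.numeric(foce_objective(dat, p)) - marginal_m2ll(w))
  }, numeric(1))
  expect_lt(err[1], 1e-4)
  expect_lt(err[2], 1e-2)
  expect_lt(err[1], 0.1 * err[2])        # vanishing approximation error
  expect_lt(err[3] / marginal_m2ll(0.0827), 0.02)
})

test_that("inflating the residual variance away from the truth raises the objective", {
  dat <- small_trial()$retained
  truth <- pk_params()
  bigger <- pk_params(sigma2_prop = 2 * truth$sigma2_prop)
  expect_lt(as.numeric(foce_objective(dat, truth)),
            as.numeric(foce_objective(dat, bigger)))
})

test_that("structural parameters are recovered exactly without random effects", {
  truth <- pk_params(omega = matrix(0, 3, 3), omega_iov_cl = 0,
                     sigma2_prop = 1e-6)
  pop <- generate_population(population_spec(n_1015 = 4, n_3035 = 8),
                             seed = 21)
  dat <- apply_exclusions(simulate_trial(pop, truth, seed = 22))$retained
  start <- pk_params(cl = 0.2, vc = 4, q = 0.4, vp = 3,
                     omega = matrix(0, 3, 3), omega_iov_cl = 0,
                     sigma2_prop = 1e-6)
  fit <- pk_foce_fit(dat, start, estimate = c("cl", "vc", "q", "vp"))
  expect_lt(max(abs(fit$params$theta - truth$theta) / truth$theta), 0.01)
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_par)       # AIC identity
  expect_lte(fit$ofv, as.numeric(foce_objective(dat, start)))
})

test_that("refits from different starting values agree", {
  pop <- generate_population(population_spec(n_1015 = 2, n_3035 = 10),
                             seed = 31)
  dat <- apply_exclusions(simulate_trial(pop, pk_params(), seed = 32))$retained
  est <- c("cl", "vc", "q", "vp", "omega", "sigma2_prop")
  s1 <- pk_params(cl = 0.12, vc = 2.6, q = 0.6, vp = 4.8,
                  omega = diag(c(0.15, 0.05, 0.1)), sigma2_prop = 0.05)
  s2 <- pk_params(cl = 0.19, vc = 3.8, q = 0.35, vp = 3.1,
                  omega = diag(c(0.04, 0.02, 0.3)), sigma2_prop = 0.012)
  f1 <- pk_foce_fit(dat, s1, estimate = est)
  f2 <- pk_foce_fit(dat, s2, estimate = est)
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
})

test_that("empirical Bayes estimates shrink as information decreases", {
  # a subject with no observations keeps the prior mode
  tab <- one_subject_table(obs_times = c(1, 7), dv = c(80, 35))
  dose_only <- tab[tab$EVID == 1, ]
  dose_only$ID <- 2L
  eb <- empirical_bayes(rbind(tab, dose_only), pk_params())
  expect_equal(unname(eb$eta[2, ]), c(0, 0, 0))
  expect_false(all(eb$eta[1, ] == 0))

  # rich sampling keeps CL shrinkage small
  pop <- generate_population(population_spec(n_1015 = 25, n_3035 = 0),
                             seed = 41)
  rich <- apply_exclusions(simulate_trial(pop, pk_params(), seed = 42))$retained
  eb_rich <- empirical_bayes(rich, pk_params())
  expect_lt(eb_rich$shrinkage["cl"], 20)
  expect_length(eb_rich$kappa[[1]], 3)   # one kappa per dosing occasion

  # one observation per subject shrinks far more than twelve
  pop2 <- generate_population(population_spec(n_1015 = 0, n_3035 = 40),
                              seed = 43)
  full <- apply_exclusions(simulate_trial(pop2, pk_params(), seed = 44))$retained
  obs_rows <- which(full$EVID == 0)
  first_obs <- obs_rows[!duplicated(full$ID[obs_rows])]
  one_obs <- full[sort(c(which(full$EVID == 1), first_obs)), ]
  sh1 <- empirical_bayes(one_obs, pk_params())$shrinkage["cl"]
  sh12 <- empirical_bayes(full, pk_params())$shrinkage["cl"]
  expect_gt(sh1, sh12)

  # EBE distribution under the true model is centred near zero
  ebf <- empirical_bayes(full, pk_params())
  n <- nrow(ebf$eta)
  for (k in 1:3)
    expect_lt(abs(mean(ebf$eta[, k])), 2 * sd(ebf$eta[, k]) / sqrt(n) + 0.02)
})

test_that("fit reports standard errors and a publication-style summary", {
  truth <- pk_params(omega = diag(c(0.08, 0.03, 0.18)), omega_iov_cl = 0,
                     sigma2_prop = 0.02)
  pop <- generate_population(population_spec(n_1015 = 3, n_3035 = 12),
                             seed = 51)
  dat <- apply_exclusions(simulate_trial(pop, truth, seed = 52))$retained
  fit <- pk_foce_fit(dat, truth, estimate = c("cl", "vc", "q", "vp",
                                              "sigma2_prop"),
                     compute_se = TRUE)
  expect_false(is.null(fit$vcov_t))
  st <- fit$se_table
  expect_true(all(c("estimate", "se", "rse_percent") %in% names(st)))
  expect_true(all(st$se[st$parameter %in% c("cl", "vc")] > 0))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.pkfit")
  expect_false(anyNA(sm$structural$lower[1:2]))
  out <- capture.output(print(sm))
  expect_true(any(grepl("CV%", out)))
  expect_true(any(grepl("Corr", out)))
  # logLik/AIC accessors agree with the stored objective
  expect_equal(AIC(fit), fit$ofv + 2 * fit$n_par)
  # predictions and residuals line up with the fitted data
  expect_length(predict(fit), fit$n_obs)
  expect_equal(predict(fit, type = "individual"), fit$ipred)
  expect_equal(residuals(fit, type = "individual"),
               fit$fd$y - fit$ipred)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_obs, 3))
})
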