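# Simulation-based diagnostics: pcVPC, NPDE, goodness-of-fit tables.

test_that("prediction correction is the identity when predictions agree within a bin", {
  # identical subjects observed at a single time point: one bin, equal PRED
  pop <- uniform_population(n = 15, seed = 511)
  trial <- simulate_trial(pop, pk_params(), seed = 512)
  one_t <- trial[trial$EVID == 1 | abs(trial$TIME - (14 + 1 / 48)) < 1e-9, ]
  v <- pc_vpc(one_t, pk_params(), n_rep = 50, bins = 1, seed = 513)
  dv <- one_t$DV[one_t$EVID == 0]
  expect_equal(v$obs_p50, median(dv), tolerance = 1e-9)
  expect_equal(v$obs_p5, unname(quantile(dv, 0.05)), tolerance = 1e-9)
})

test_that("VPC bands are ordered, partition the data and widen with CL variance", {
  pop <- generate_population(population_spec(n_1015 = 5, n_3035 = 25),
                             seed = 521)
  widths <- vapply(c(0.02, 0.0827, 0.25), function(w) {
    p <- pk_params(omega = matrix(c(w, 0, 0, 0, 0.0323, 0.0272,
                                    0, 0.0272, 0.179), 3, 3))
    trial <- simulate_trial(pop, p, seed = 522)
    dat <- apply_exclusions(trial)$retained
    v <- pc_vpc(dat, p, n_rep = 120, bins = 6, seed = 523)
    expect_true(all(v$sim_p5_lo <= v$sim_p5_hi))
    expect_true(all(v$sim_p50_lo <= v$sim_p50_hi))
    expect_true(all(v$sim_p95_lo <= v$sim_p95_hi))
    expect_equal(sum(v$n), sum(dat$EVID == 0) -
                   sum(vedopk:::fd_pred(vedopk:::build_fitdata(dat), p) <= 0))
    # spread between the outer percentile bands tracks the IIV magnitude
    mean(v$sim_p95_md / v$sim_p5_md)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("NPDE is invariant to row order and stable across seeds", {
  dat <- small_trial()$retained
  p <- pk_params()
  n1 <- npde(dat, p, n_rep = 300, seed = 531)
  perm <- dat[sample(nrow(dat)), ]
  n2 <- npde(perm, p, n_rep = 300, seed = 531)
  expect_equal(n1$npde, n2$npde)   # assembly re-sorts by ID and TIME
  n3 <- npde(dat, p, n_rep = 400, seed = 532)
  n4 <- npde(dat, p, n_rep = 400, seed = 533)
  expect_gt(cor(n3$npde, n4$npde), 0.95)
  expect_true(all(is.finite(n1$npde)))
})

test_that("goodness-of-fit tables expose predictions, residuals and EBE covariates", {
  # noise-free data reproduce the individual predictions exactly
  pop <- generate_population(population_spec(n_1015 = 2, n_3035 = 6),
                             seed = 541)
  p0 <- pk_params(sigma2_prop = 0)
  trial0 <- simulate_trial(pop, p0, seed = 542)
  dat0 <- apply_exclusions(trial0)$retained
  fit0 <- pk_foce_fit(dat0, p0, estimate = "cl",
                      control = list(iter.max = 1, eval.max = 3))
  g0 <- gof_tables(dat0, fit0)
  expect_lt(max(abs(g0$observations$DV - g0$observations$IPRED) /
                  g0$observations$DV), 1e-4)

  dat <- small_trial()$retained
  fit <- pk_foce_fit(dat, pk_params(), estimate = c("cl", "vc"),
                     control = list(iter.max = 2, eval.max = 8))
  g <- gof_tables(dat, fit)
  expect_setequal(
    intersect(c("ID", "TIME", "TAD", "DV", "PRED", "IPRED", "RES", "IRES",
                "IWRES", "WT", "ALB", "AGE", "LYM", "GVHDL", "GVHDS",
                "GVHDI"), names(g$observations)),
    c("ID", "TIME", "TAD", "DV", "PRED", "IPRED", "RES", "IRES", "IWRES",
      "WT", "ALB", "AGE", "LYM", "GVHDL", "GVHDS", "GVHDI"))
  expect_equal(nrow(g$observations), sum(dat$EVID == 0))
  expect_true(all(c("eta_cl", "GVHD_SKIN", "GVHD_LIVER") %in% names(g$ebe)))
})

test_that("EBEs show no GvHD association when the simulated effect is null", {
  pop <- generate_population(population_spec(n_1015 = 0, n_3035 = 150),
                             seed = 551)
  trial <- simulate_trial(pop, pk_params(), seed = 552)  # GvHD factors all 1
  dat <- apply_exclusions(trial)$retained
  eb <- empirical_bayes(dat, pk_params())
  fd <- vedopk:::build_fitdata(dat)
  skin <- vapply(seq_along(fd$ids), function(i) {
    rows <- fd$data[fd$data$ID == fd$ids[i] & fd$data$EVID == 0, "GVHDS"]
    max(rows)
  }, numeric(1))
  e <- eb$eta[, "cl"]
  n1 <- sum(skin == 1); n0 <- sum(skin == 0)
  diff <- mean(e[skin == 1]) - mean(e[skin == 0])
  pooled_se <- sd(e) * sqrt(1 / n1 + 1 / n0)
  expect_lt(abs(diff), 3 * pooled_se)
})
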