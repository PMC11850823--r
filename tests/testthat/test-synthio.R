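test_that("default cohorts have the design's group structure, deterministically", {
  coh <- generate_cohort(cohort_config(seed = 42))
  expect_equal(sum(coh$subjects$group == "drinker"), 17)
  expect_equal(sum(coh$subjects$group == "control"), 11)
  expect_equal(sum(coh$subjects$voltammetry & coh$subjects$group == "drinker"), 8)
  expect_equal(sum(coh$subjects$voltammetry & coh$subjects$group == "control"), 8)

  # fixed seed => bit-identical cohorts; different seed => different truth
  coh2 <- generate_cohort(cohort_config(seed = 42))
  expect_identical(coh$truth, coh2$truth)
  coh3 <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(coh$truth$true_vmax, coh3$truth$true_vmax))

  # truth respects its physical ranges
  expect_true(all(coh$truth$true_dap > 0))
  expect_true(all(coh$truth$true_vmax > 0))
  expect_true(all(coh$truth$true_inhibition_300nM >= 0 &
                    coh$truth$true_inhibition_300nM <= 1))
  expect_true(all(coh$truth$true_disinhibition >= 0 &
                    coh$truth$true_disinhibition <= 1))
  expect_true(all(coh$truth$sig_top >= coh$truth$sig_bottom))
  expect_true(all(coh$truth$lifetime_intake_gkg[coh$truth$group == "control"] == 0))
})

test_that("config validation reports offending fields by name", {
  expect_error(cohort_config(n_drinkers = 1), "n_drinkers")
  expect_error(cohort_config(n_voltammetry_per_group = 12), "exceeds")
  expect_error(cohort_config(coupling = list(a_priori_dopamine =
    c(control = 0, drinker = 1.2))), "coupling")
  expect_error(cohort_config(kor_params = list(
    control = c(i300 = 1.4, i1000 = 0.5, sd = 0.1),
    drinker = c(i300 = 0.4, i1000 = 0.6, sd = 0.1))), "kor_params")
  expect_error(cohort_config(noise = c(trace_sd = -1, expression_sd = 0.5,
                                       bac_sd = 15)), "noise")
})

test_that("group parameter distributions follow the configured means", {
  # identical group means: two-sample t on true_vmax is non-significant in
  # most seeded replicates (Monte-Carlo under the null)
  eq <- list(control = c(mean = 2.5, sd = 0.6), drinker = c(mean = 2.5, sd = 0.6))
  rejections <- vapply(1:100, function(s) {
    coh <- generate_cohort(cohort_config(n_drinkers = 1000, n_controls = 1000,
                                         n_voltammetry_per_group = 8, seed = s,
                                         vmax_params = eq))
    t.test(true_vmax ~ group, data = coh$truth)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.94)

  # +1 SD shift in the drinker mean dominates at n = 1000 per group
  up <- list(control = c(mean = 2.5, sd = 0.6), drinker = c(mean = 3.1, sd = 0.6))
  coh <- generate_cohort(cohort_config(n_drinkers = 1000, n_controls = 1000,
                                       n_voltammetry_per_group = 8, seed = 7,
                                       vmax_params = up))
  m <- tapply(coh$truth$true_vmax, coh$truth$group, mean)
  expect_gt(m["drinker"], m["control"])
})

test_that("copula coupling hits the target Spearman correlation", {
  panel <- gene_panel("a_priori_dopamine")
  big <- function(seed) generate_cohort(cohort_config(
    n_drinkers = 5000, n_controls = 5000, n_voltammetry_per_group = 8,
    seed = seed))

  # rho = 1: comonotone, expression rank order equals the measure's
  coh8 <- generate_cohort(cohort_config(seed = 3))
  ex1 <- generate_expression(coh8, panel, coupling = c(control = 1, drinker = 1))
  idx <- coh8$truth$group == "drinker"
  expect_identical(unname(rank(ex1["SLC6A3", idx])),
                   rank(coh8$truth$true_vmax[idx]))

  # rho = 0 and rho = 0.8: empirical Spearman within +/- 0.03 at n = 5000
  coh <- big(11)
  for (rho in c(0, 0.8)) {
    ex <- generate_expression(coh, panel,
                              coupling = c(control = rho, drinker = rho),
                              seed = 99)
    idx <- coh$truth$group == "drinker"
    emp <- cor(ex["SLC6A3", idx], coh$truth$true_vmax[idx], method = "spearman")
    expect_lt(abs(emp - rho), 0.03)
  }

  expect_error(generate_expression(coh8, panel,
                                   coupling = c(control = 0, drinker = 2)),
               "\\[-1, 1\\]")
})

test_that("count generation is NB with mean exp(latent) x library size", {
  coh <- generate_cohort(cohort_config(seed = 5))
  n <- nrow(coh$truth)

  # degenerate mean: latent -Inf gives all-zero counts
  exprInf <- matrix(-Inf, 1, n, dimnames = list("dead", coh$truth$subject_id))
  expect_true(all(generate_counts(exprInf, 1e5, 0.1, seed = 1) == 0))

  # dispersion 0 is Poisson: sample variance tracks the mean over 10,000 draws
  expr1 <- matrix(log(50), 1, n, dimnames = list("g", coh$truth$subject_id))
  draws <- vapply(1:400, function(s)
    as.numeric(generate_counts(expr1, 1, 0, seed = s)), numeric(n))
  expect_equal(var(as.vector(draws)), mean(draws), tolerance = 0.05)

  # doubling one sample's library size doubles its expected counts
  libs <- rep(1e4, n); libs[3] <- 2e4
  expr2 <- matrix(log(1e-2), 200, n,
                  dimnames = list(sprintf("g%03d", 1:200), coh$truth$subject_id))
  cnt <- generate_counts(expr2, libs, dispersion = 0.02, seed = 9)
  expect_equal(mean(cnt[, 3]) / mean(cnt[, -3]), 2, tolerance = 0.05)

  expect_error(generate_counts(expr2, c(-1, rep(1e4, n - 1))), "positive")
  expect_error(generate_counts(expr2, 1e4, dispersion = -0.1), "dispersion")
})

test_that("drinking records are linear in intake with configured noise", {
  coh <- generate_cohort(cohort_config(seed = 13))

  # residual_sd = 0: BAC is an exact line in intake
  d0 <- generate_drinking(coh, residual_sd = 0)$drinking
  dr <- d0[d0$group == "drinker", ]
  expect_equal(cor(dr$intake_gkg, dr$bac_mgdl), 1, tolerance = 1e-12)

  # controls have zero intake and zero BAC
  ct <- d0[d0$group == "control", ]
  expect_true(all(ct$intake_gkg == 0) && all(ct$bac_mgdl == 0))

  # OLS on 10,000 generated pairs recovers the configured slope within 2%
  bigcfg <- cohort_config(n_drinkers = 1000, n_controls = 2,
                          n_voltammetry_per_group = 2, seed = 17)
  db <- generate_drinking(generate_cohort(bigcfg), slope_mgdl_per_gkg = 55,
                          intercept = 0, residual_sd = 15)$drinking
  db <- db[db$group == "drinker", ]
  expect_equal(nrow(db), 10000)
  slope <- coef(lm(bac_mgdl ~ intake_gkg, data = db))[2]
  expect_lt(abs(slope - 55) / 55, 0.02)
})

test_that("session traces embody the configured condition effects", {
  cfg <- cohort_config(n_drinkers = 2, n_controls = 2,
                       n_voltammetry_per_group = 2, seed = 23,
                       noise = c(trace_sd = 0, expression_sd = 0.5, bac_sd = 15))
  coh <- generate_cohort(cfg)
  coh$truth$true_inhibition_1uM[1] <- 0.4
  coh$truth$true_disinhibition[1] <- 0.2
  sid <- coh$truth$subject_id[1]
  tr <- coh$truth[1, ]
  ses <- generate_fscv_session(coh, sid)

  # noiseless baseline equals the forward model with the subject truth
  ref <- simulate_trace(stim_protocol(1, amplitude_uA = 350), tr$true_dap,
                        tr$true_vmax)
  expect_equal(ses$traces$baseline$values, ref$values, tolerance = 1e-12)

  # agonist at 1 uM with inhibition 0.4: trace equals the model at 0.6 x dap
  ref_ag <- simulate_trace(stim_protocol(1, amplitude_uA = 350),
                           0.6 * tr$true_dap, tr$true_vmax)
  expect_equal(ses$traces$agonist_1uM$values, ref_ag$values, tolerance = 1e-12)

  # antagonist at the highest frequency: release scaled by 1.2
  ref_post <- simulate_trace(stim_protocol(5, frequency_hz = 100, onset_s = 1),
                             1.2 * tr$true_dap, tr$true_vmax, duration_s = 12)
  expect_equal(ses$traces$freq_post_100$values, ref_post$values,
               tolerance = 1e-12)
  # ... and at the lowest frequency the pre/post traces coincide (w = 0)
  expect_equal(ses$traces$freq_post_005$values, ses$traces$freq_pre_005$values,
               tolerance = 1e-12)

  # io condition follows the subject's sigmoid truth
  amp <- 400
  dap_400 <- tr$sig_bottom + (tr$sig_top - tr$sig_bottom) /
    (1 + exp((tr$sig_ea50 - amp) / tr$sig_steepness))
  ref_io <- simulate_trace(stim_protocol(1, amplitude_uA = amp), dap_400,
                           tr$true_vmax)
  expect_equal(ses$traces$io_0400$values, ref_io$values, tolerance = 1e-12)

  # guards: unknown condition, non-voltammetry subject, negative values never
  expect_error(generate_fscv_session(coh, sid, conditions = "banana"),
               "unknown condition")
  noisy <- generate_fscv_session(coh, sid, noise_sd = 0.5, seed = 2)
  expect_true(all(vapply(noisy$traces, function(t) all(t$values >= 0),
                         logical(1))))
})

test_that("sessions and expression are reproducible under a fixed seed", {
  cfg <- cohort_config(n_drinkers = 3, n_controls = 3,
                       n_voltammetry_per_group = 2, seed = 99)
  coh <- generate_cohort(cfg)
  s1 <- generate_fscv_session(coh, "c01")
  s2 <- generate_fscv_session(coh, "c01")
  expect_identical(lapply(s1$traces, `[[`, "values"),
                   lapply(s2$traces, `[[`, "values"))
  e1 <- generate_expression(coh, gene_panel("kor_system"))
  e2 <- generate_expression(coh, gene_panel("kor_system"))
  expect_identical(e1, e2)
})
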