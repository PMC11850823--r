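test_that("correlate matches the textbook Pearson formula and its t-based p", {
  # perfect linearity
  r1 <- correlate(1:6, 2 * (1:6) + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_equal(r1$slope, 2, tolerance = 1e-12)
  r2 <- correlate(1:5, -(1:5))
  expect_equal(r2$r, -1, tolerance = 1e-12)

  # 5-point fixture against the hand formula
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- correlate(x, y)
  expect_equal(res$r, pearson_hand(x, y), tolerance = 1e-12)
  expect_equal(res$p, pearson_p_hand(pearson_hand(x, y), 5), tolerance = 1e-12)
  expect_equal(res$slope, cov(x, y) / var(x), tolerance = 1e-14)
  expect_equal(res$n, 5)

  # more hand fixtures, 4 to 6 points
  set.seed(31)
  for (n in 4:6) {
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(correlate(a, b)$r, pearson_hand(a, b), tolerance = 1e-12)
  }

  expect_error(correlate(1:2, 2:3), "at least 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("slope-set tests use the exact df formulas and pooled-variance t", {
  a <- c(1, 2, 3, 4); b <- c(0, 0, 1, 1)
  out <- slope_set_tests(b, a)
  expect_equal(out$two_sample$df, 6)       # n1 + n2 - 2
  expect_equal(out$control$df, 3)          # n - 1
  expect_equal(out$drinker$df, 3)
  expect_equal(out$two_sample$t, pooled_t_hand(a, b), tolerance = 1e-12)
  expect_equal(out$drinker$t, one_sample_t_hand(a), tolerance = 1e-12)

  # 8 slopes per group reproduce the design's df of 14 and 7
  set.seed(8)
  s1 <- rnorm(8); s2 <- rnorm(8, 1)
  out8 <- slope_set_tests(s1, s2)
  expect_equal(out8$two_sample$df, 14)
  expect_equal(out8$control$df, 7)

  expect_error(slope_set_tests(rep(0, 4), a), "zero variance")
})

test_that("within-group ranking is ascending with average ties", {
  expect_equal(rank_within_group(c(3.2, 1.1, 7.8)), c(2, 1, 3))
  expect_equal(rank_within_group(c(1, 1, 2)), c(1.5, 1.5, 3))
  # idempotent on permutations
  expect_equal(rank_within_group(c(2, 1, 3)), c(2, 1, 3))
  expect_error(rank_within_group(1), "at least 2")
})

test_that("rank pooling conserves the subject x gene x measure count", {
  # 4 genes x 2 measures x 8 subjects = 64 pairs per group
  d <- toy_sync_data(n = 8, genes = paste0("g", 1:4))
  tab <- pool_ranks(d$ft, d$ex, measures = c("release", "vmax"),
                    group = "control")
  expect_equal(nrow(tab), 64)
  expect_identical(attr(tab, "group"), "control")

  # 2 genes x 1 measure x 3 subjects = 6 rows
  d3 <- toy_sync_data(n = 3, genes = c("g1", "g2"))
  expect_equal(nrow(pool_ranks(d3$ft, d3$ex, measures = "release",
                               group = "drinker")), 6)

  # row count equals an independent nested-loop enumeration on random panels
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(3:9, 1); ng <- sample(1:5, 1); nm <- sample(1:2, 1)
    d <- toy_sync_data(n = n, genes = paste0("g", seq_len(ng)), seed = rep)
    ms <- c("release", "vmax")[seq_len(nm)]
    brute <- 0L
    for (g in seq_len(ng)) for (m in seq_len(nm))
      for (s in seq_len(n)) brute <- brute + 1L
    expect_equal(nrow(pool_ranks(d$ft, d$ex, measures = ms, group = "control")),
                 brute)
  }

  # within each gene the expression ranks are a permutation of 1..n
  ranks <- tab$rank_expression[tab$gene == "g2" & tab$measure == "vmax"]
  expect_equal(sort(ranks), 1:8)

  expect_error(pool_ranks(d$ft, d$ex, measures = "missing", group = "control"),
               "measure")
  expect_error(pool_ranks(d$ft, d$ex, genes = "nope", measures = "release",
                          group = "control"), "gene")
})

test_that("missing subject values are dropped pairwise with re-ranking", {
  d <- toy_sync_data(n = 6, genes = c("g1", "g2"))
  d$ex["g1", "c02"] <- NA
  expect_warning(tab <- pool_ranks(d$ft, d$ex, measures = c("release", "vmax"),
                                   group = "control"), "missing")
  # only g1's pairs lose that subject (2 measures x 1 subject)
  expect_equal(nrow(tab), 6 * 2 * 2 - 2)
  g1 <- tab[tab$gene == "g1" & tab$measure == "release", ]
  expect_equal(sort(g1$rank_expression), 1:5)   # re-ranked within 5 subjects
  expect_false("c02" %in% g1$subject_id)
})

test_that("pooled Spearman equals Pearson on ranks and flags comonotone data", {
  d <- toy_sync_data(n = 8, genes = paste0("g", 1:4), seed = 4)
  tab <- pool_ranks(d$ft, d$ex, measures = c("release", "vmax"),
                    group = "drinker")
  res <- pooled_spearman(tab)
  # definitional identity: Spearman on pooled raw ranks = Pearson on ranks
  expect_equal(res$pooled_r,
               cor(tab$rank_function, tab$rank_expression, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(res$pooled_r, cor(tab$rank_function, tab$rank_expression),
               tolerance = 1e-14)
  expect_equal(res$n_pairs, 64)

  # comonotone: every gene's expression ranks equal the paired function ranks
  ft <- d$ft
  ex <- d$ex
  for (g in rownames(ex)) ex[g, ] <- ft$release[match(colnames(ex),
                                                      ft$subject_id)]
  tab1 <- pool_ranks(ft, ex, measures = "release", group = "control")
  expect_equal(pooled_spearman(tab1)$pooled_r, 1, tolerance = 1e-12)

  expect_error(pooled_spearman(tab[1:2, ]), "at least 3")
})

test_that("the pooled correlation is centred near zero under independence", {
  # expression generated independently of function: mean pooled r over seeded
  # simulations is ~0 (Monte-Carlo under independence)
  rs <- vapply(1:300, function(s) {
    d <- toy_sync_data(n = 8, genes = paste0("g", 1:4), seed = s)
    tab <- pool_ranks(d$ft, d$ex, measures = c("release", "vmax"),
                      group = "control")
    pooled_spearman(tab)$pooled_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02 + 2 * sd(rs) / sqrt(length(rs)))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the subject permutation test is valid, monotone-invariant, bounded", {
  # perfect coupling: no permutation except identity-equivalents reaches
  # |r| = 1, so p attains its minimum 1/(B+1)
  d <- toy_sync_data(n = 8, genes = paste0("g", 1:4), seed = 2)
  ft <- d$ft; ex <- d$ex
  for (g in rownames(ex)) ex[g, ] <- ft$release[match(colnames(ex),
                                                      ft$subject_id)]
  tab <- pool_ranks(ft, ex, measures = "release", group = "control")
  res <- subject_permutation_test(tab, B = 999, seed = 10)
  expect_lte(res$permutation_p, 3 / 1000)
  expect_gte(res$permutation_p, 1 / 1000)

  # p is invariant under monotone transformation of all expression values
  # (rank-based statistic)
  d2 <- toy_sync_data(n = 8, genes = paste0("g", 1:4), seed = 6)
  t_raw <- pool_ranks(d2$ft, d2$ex, measures = c("release", "vmax"),
                      group = "drinker")
  t_mono <- pool_ranks(d2$ft, exp(3 * d2$ex + 1),
                       measures = c("release", "vmax"), group = "drinker")
  p_raw <- subject_permutation_test(t_raw, B = 300, seed = 5)$permutation_p
  p_mono <- subject_permutation_test(t_mono, B = 300, seed = 5)$permutation_p
  expect_identical(p_raw, p_mono)

  # bounds: p in [1/(B+1), 1]
  expect_gte(p_raw, 1 / 301)
  expect_lte(p_raw, 1)

  # coarse-n warning
  d4 <- toy_sync_data(n = 4, genes = c("g1", "g2"), seed = 3)
  t4 <- pool_ranks(d4$ft, d4$ex, measures = "release", group = "control")
  expect_warning(subject_permutation_test(t4, B = 100, seed = 1), "coarse")
})

test_that("permutation p-values are near-uniform under the independence null", {
  # KS-distance check on 500 seeded independence simulations. The p-values
  # live on the discrete 1/(B+1) grid with occasional ties at the observed
  # statistic, so the distance is compared against the alpha = 0.01 critical
  # value directly rather than through ks.test's tie-sensitive p-value.
  ps <- vapply(1:500, function(s) {
    d <- toy_sync_data(n = 8, genes = paste0("g", 1:4), seed = 20000 + s)
    tab <- pool_ranks(d$ft, d$ex, measures = c("release", "vmax"),
                      group = "control")
    subject_permutation_test(tab, B = 200, seed = 50000 + s)$permutation_p
  }, numeric(1))
  x <- sort(ps); n <- length(x)
  D <- max(pmax(abs(seq_len(n) / n - x), abs((seq_len(n) - 1) / n - x)))
  expect_lt(D, 1.628 / sqrt(n))            # KS critical value at alpha = 0.01
  expect_gt(mean(ps <= 0.05), 0.02)
  expect_lt(mean(ps <= 0.05), 0.08)
})

test_that("group contrasts report CIs, slope tests and the reversal flag", {
  cfg <- cohort_config(seed = 55,
                       coupling = list(a_priori_dopamine =
                                         c(control = 0.85, drinker = -0.85),
                                       a_posteriori_control =
                                         c(control = 0, drinker = 0),
                                       kor_system = c(control = 0, drinker = 0),
                                       dynorphin = c(control = 0, drinker = 0)))
  coh <- generate_cohort(cfg)
  expr <- generate_expression(coh, gene_panel("a_priori_dopamine"))
  ft <- truth_function_table(coh)
  ctr <- synchrony(ft, expr, "a_priori_dopamine", B = 300, n_boot = 200,
                   seed = 9)
  expect_s3_class(ctr, "synchrony_contrast")
  expect_gt(ctr$control$pooled_r, 0)
  expect_lt(ctr$drinker$pooled_r, 0)
  expect_true(is.numeric(ctr$ci_control) && length(ctr$ci_control) == 2)
  expect_equal(ctr$slope_tests$two_sample$df, 14)
  expect_equal(ctr$difference,
               ctr$drinker$pooled_r - ctr$control$pooled_r, tolerance = 1e-12)
  expect_output(print(ctr), "reversal")

  # identical groups: near-zero contrast, no reversal
  d <- toy_sync_data(n = 8, genes = paste0("g", 1:4), seed = 77)
  ft2 <- d$ft
  ft2$release <- rep(ft2$release[1:8], 2)   # same values in both groups
  ft2$vmax <- rep(ft2$vmax[1:8], 2)
  ex2 <- d$ex[, 1:8][, rep(1:8, 2)]
  colnames(ex2) <- ft2$subject_id
  sym <- synchrony(ft2, ex2, paste0("g", 1:4), measures = c("release", "vmax"),
                   B = 200, n_boot = 100, seed = 3)
  expect_equal(sym$difference, 0, tolerance = 1e-12)
  expect_false(sym$reversal)

  # mismatched panels error
  expect_error(synchrony_contrast(ctr$control, sym$drinker), "different")
})

test_that("zero permutations fall back to the nominal p with a warning", {
  coh <- generate_cohort(cohort_config(seed = 60))
  expr <- generate_expression(coh, gene_panel("a_priori_dopamine"))
  ft <- truth_function_table(coh)
  w <- capture_warnings(res <- synchrony(ft, expr, "a_priori_dopamine", B = 0,
                                         n_boot = 50, seed = 1))
  expect_true(any(grepl("nominal", w)))
  expect_null(res$control$permutation_p)
  expect_true(is.numeric(res$control$nominal_p))
})
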