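#' Within-group correlation between a functional measure and expression
#'
#' Correlates one functional measure (x) with one gene's expression (y)
#' within a single group, reporting the correlation coefficient, its
#' two-tailed p-value, and the ordinary least-squares slope of expression on
#' function (expression is the ordinate throughout, so slopes are in
#' expression units per function unit).
#'
#' @param x Functional measure values (one per subject).
#' @param y Expression values (same subjects).
#' @param method `"pearson"` (continuous variables) or `"spearman"`.
#' @return A one-row data frame: `method, r, p, n, slope`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  data.frame(method = method, r = unname(ct$estimate), p = ct$p.value,
             n = length(x), slope = stats::cov(x, y) / stats::var(x))
}

#' One- and two-sample tests on sets of regression slopes
#'
#' Each group contributes one slope per gene x measure correlation. The mean
#' slope of each group is tested against zero with a one-sample t-test
#' (df = n - 1), and the groups are compared with an unpaired pooled-variance
#' t-test (df = n1 + n2 - 2; 8 + 8 slopes give the design's df of 14).
#'
#' @param slopes_controls,slopes_drinkers Numeric slope sets (>= 2 each, with
#'   nonzero variance).
#' @return A list with per-group one-sample results (`mean`, `t`, `df`, `p`)
#'   and the `two_sample` comparison (`t`, `df`, `p`).
#' @export
slope_set_tests <- function(slopes_controls, slopes_drinkers) {
  one <- function(s, label) {
    if (length(s) < 2L)
      stop("need at least 2 slopes in ", label, call. = FALSE)
    if (stats::sd(s) == 0)
      stop("zero variance in the ", label, " slope set; t-test undefined",
           call. = FALSE)
    tt <- t.test(s, mu = 0)
    list(mean = mean(s), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  }
  ctl <- one(slopes_controls, "control slopes")
  drk <- one(slopes_drinkers, "drinker slopes")
  tt2 <- t.test(slopes_drinkers, slopes_controls, var.equal = TRUE)
  list(control = ctl, drinker = drk,
       two_sample = list(t = unname(tt2$statistic),
                         df = unname(tt2$parameter), p = tt2$p.value,
                         mean_difference = mean(slopes_drinkers) -
                           mean(slopes_controls)))
}

#' Rank subjects within a group
#'
#' Ascending ranks 1..n (lowest value gets rank 1), with ties receiving
#' average ranks — for 8 subjects this is the "value from 1 to 8" assignment.
#'
#' @param values Numeric vector (n >= 2).
#' @return Numeric ranks.
#' @export
rank_within_group <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("ranking needs at least 2 values", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Pool rank pairs across a panel's gene x measure grid
#'
#' For one group, every subject x gene x measure combination contributes one
#' (rank-function, rank-expression) pair, letting all the panel's
#' correlations (e.g. 4 genes x 2 measures x 8 subjects = 64 pairs) be
#' analysed in a single rank-rank coordinate plane. Ranks are computed within
#' the group, separately for each variable. Subjects missing a value are
#' dropped for the affected gene x measure only, with ranks recomputed
#' within the reduced set (pairwise deletion).
#'
#' @param function_table Data frame with `subject_id`, `group` and one column
#'   per functional measure.
#' @param expression Genes x subjects matrix (latent or normalized values;
#'   column names are subject ids).
#' @param genes Genes to pool (default: all rows of `expression`).
#' @param measures Functional measure column names to pool.
#' @param group Group to analyse (`"control"` or `"drinker"`).
#' @return A `pooled_rank_table` data frame
#'   (`subject_id, gene, measure, rank_function, rank_expression`) with the
#'   group and subject count as attributes.
#' @export
pool_ranks <- function(function_table, expression, genes = rownames(expression),
                       measures, group) {
  stopifnot(is.data.frame(function_table), is.matrix(expression))
  if (!all(c("subject_id", "group") %in% names(function_table)))
    stop("'function_table' needs subject_id and group columns", call. = FALSE)
  missing_m <- setdiff(measures, names(function_table))
  if (length(missing_m))
    stop("measure(s) not in the function table: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  missing_g <- setdiff(genes, rownames(expression))
  if (length(missing_g))
    stop("gene(s) not in the expression matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  ft <- function_table[function_table$group == group, , drop = FALSE]
  if (nrow(ft) < 2L)
    stop("fewer than 2 subjects in group '", group, "'", call. = FALSE)
  if (!all(ft$subject_id %in% colnames(expression)))
    stop("expression matrix is missing subjects of group '", group, "'",
         call. = FALSE)
  ex <- expression[, ft$subject_id, drop = FALSE]

  out <- list(); dropped <- 0L
  for (g in genes) for (m in measures) {
    xv <- ft[[m]]; yv <- ex[g, ]
    ok <- is.finite(xv) & is.finite(yv)
    dropped <- dropped + sum(!ok)
    if (sum(ok) < 2L) next
    out[[paste(g, m)]] <- data.frame(
      subject_id = ft$subject_id[ok], gene = g, measure = m,
      rank_function = rank_within_group(xv[ok]),
      rank_expression = rank_within_group(yv[ok]))
  }
  if (dropped > 0L)
    warning(dropped, " subject value(s) missing; affected gene x measure ",
            "pairs were re-ranked within the reduced set", call. = FALSE)
  tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(tab, "group") <- group
  attr(tab, "n_subjects") <- nrow(ft)
  class(tab) <- c("pooled_rank_table", "data.frame")
  tab
}

# Nominal two-tailed p for a Spearman correlation via the t approximation.
spearman_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), n - 2)
}

#' Pooled Spearman correlation over a rank table
#'
#' The synchrony statistic: the Spearman correlation of the pooled
#' (rank-function, rank-expression) pairs, equal by construction to the
#' Pearson correlation of the ranks. The nominal two-tailed p-value treats
#' the pairs as independent, which they are not (each subject contributes to
#' every gene x measure pair); see [subject_permutation_test()] for a
#' dependence-aware p-value.
#'
#' @param table A `pooled_rank_table`.
#' @return A `synchrony_result`: list with `group`, `pooled_r`, `nominal_p`,
#'   `n_pairs` and the input table.
#' @export
pooled_spearman <- function(table) {
  stopifnot(inherits(table, "pooled_rank_table"))
  if (nrow(table) < 3L) stop("need at least 3 pooled rows", call. = FALSE)
  x <- table$rank_function; y <- table$rank_expression
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant ranks; pooled correlation undefined", call. = FALSE)
  r <- cor(x, y)
  structure(list(group = attr(table, "group"), pooled_r = r,
                 nominal_p = spearman_p(r, nrow(table)),
                 n_pairs = nrow(table), table = table),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("Pooled synchrony (%s): Spearman r = %.3f over %d pairs, nominal p = %.3g",
              x$group %||% "?", x$pooled_r, x$n_pairs, x$nominal_p))
  if (!is.null(x$permutation_p))
    cat(sprintf(", permutation p = %.3g (B = %d)", x$permutation_p, x$B))
  cat("\n")
  invisible(x)
}

#' Subject-level permutation test for the pooled synchrony correlation
#'
#' The pooled pairs share subjects, so the nominal Spearman p-value
#' overstates the evidence. This test permutes subject labels of the
#' functional measures within the group — keeping each subject's expression
#' vector intact — recomputes the pooled correlation each time, and reports
#' \deqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (B + 1).}
#'
#' @param table A complete `pooled_rank_table` (no missing subjects).
#' @param B Number of permutations (>= 100).
#' @param seed Seed for the permutation stream.
#' @return The `synchrony_result` for the table, augmented with
#'   `permutation_p` and `B`.
#' @export
subject_permutation_test <- function(table, B = 1000, seed = NULL) {
  stopifnot(inherits(table, "pooled_rank_table"))
  B <- check_count(B, "B", lower = 100L)
  res <- pooled_spearman(table)
  subjects <- sort(unique(table$subject_id))
  n <- length(subjects)
  if (n < 5L)
    warning("only ", n, " subjects; the permutation null is very coarse",
            call. = FALSE)
  genes <- unique(table$gene); measures <- unique(table$measure)
  if (nrow(table) != n * length(genes) * length(measures))
    stop("permutation test requires a complete pooled table ",
         "(every subject present in every gene x measure pair)", call. = FALSE)
  # subject x measure function ranks and subject x gene expression ranks
  Rf <- matrix(NA_real_, n, length(measures),
               dimnames = list(subjects, measures))
  Re <- matrix(NA_real_, n, length(genes), dimnames = list(subjects, genes))
  for (m in measures) {
    rows <- table$measure == m & table$gene == genes[1]
    Rf[table$subject_id[rows], m] <- table$rank_function[rows]
  }
  for (g in genes) {
    rows <- table$gene == g & table$measure == measures[1]
    Re[table$subject_id[rows], g] <- table$rank_expression[rows]
  }
  pairs <- expand.grid(gene = genes, measure = measures,
                       stringsAsFactors = FALSE)
  y <- as.vector(Re[, pairs$gene])
  r_obs <- res$pooled_r
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      x <- as.vector(Rf[perm, pairs$measure])
      if (abs(cor(x, y)) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
    }
    res$permutation_p <- (1 + exceed) / (B + 1)
    res$B <- B
    res
  })
}

# Full per-group synchrony analysis used by synchrony() and the pipeline.
synchrony_group <- function(function_table, expression, genes, measures,
                            group, B = 1000, seed = NULL) {
  ft <- function_table[function_table$group == group, , drop = FALSE]
  ex <- expression[, ft$subject_id, drop = FALSE]
  cors <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(measures, function(m) {
      cbind(data.frame(gene = g, measure = m, group = group),
            correlate(ft[[m]], ex[g, ]))
    }))
  }))
  tab <- pool_ranks(function_table, expression, genes, measures, group)
  res <- if (is.null(B) || B == 0) {
    warning("zero permutations requested; reporting the nominal p only",
            call. = FALSE)
    pooled_spearman(tab)
  } else {
    subject_permutation_test(tab, B = B, seed = seed)
  }
  res$correlations <- cors
  res$slopes <- cors$slope
  res$raw <- list(func = ft[, measures, drop = FALSE], expr = ex,
                  genes = genes, measures = measures)
  res
}

# Bootstrap percentile CI of the pooled correlation, resampling subjects.
bootstrap_pooled_r <- function(raw, n_boot = 1000, seed = NULL,
                               level = 0.95) {
  n <- nrow(raw$func)
  with_seed(seed, {
    rs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      xr <- apply(raw$func[idx, , drop = FALSE], 2, rank)
      yr <- apply(t(raw$expr[, idx, drop = FALSE]), 2, rank)
      pairs <- expand.grid(g = raw$genes, m = raw$measures,
                           stringsAsFactors = FALSE)
      suppressWarnings(cor(as.vector(xr[, pairs$m]), as.vector(yr[, pairs$g])))
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  })
}

#' Contrast the synchrony of two groups
#'
#' Reports each group's pooled correlation with a subject-level bootstrap
#' confidence interval, the slope-set tests, the between-group difference in
#' pooled correlation, and a sign-reversal flag (raised when the pooled
#' correlations have opposite signs and both permutation p-values are below
#' `alpha`).
#'
#' @param result_controls,result_drinkers `synchrony_result` objects from
#'   [subject_permutation_test()] run on the same panel and measures (as
#'   produced by [synchrony()]).
#' @param alpha Significance level for the reversal flag (default 0.05).
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed Seed for the bootstrap.
#' @return A `synchrony_contrast` list.
#' @export
synchrony_contrast <- function(result_controls, result_drinkers, alpha = 0.05,
                               n_boot = 1000, seed = NULL) {
  stopifnot(inherits(result_controls, "synchrony_result"),
            inherits(result_drinkers, "synchrony_result"))
  rc <- result_controls; rd <- result_drinkers
  if (!identical(sort(unique(rc$table$gene)), sort(unique(rd$table$gene))) ||
      !identical(sort(unique(rc$table$measure)), sort(unique(rd$table$measure))))
    stop("the two groups were analysed on different panels or measures",
         call. = FALSE)
  ci_c <- ci_d <- NULL
  if (!is.null(rc$raw)) ci_c <- bootstrap_pooled_r(rc$raw, n_boot,
                                                   child_seed(seed %||% 0, "bc"))
  if (!is.null(rd$raw)) ci_d <- bootstrap_pooled_r(rd$raw, n_boot,
                                                   child_seed(seed %||% 0, "bd"))
  slopes <- if (!is.null(rc$slopes) && !is.null(rd$slopes))
    slope_set_tests(rc$slopes, rd$slopes) else NULL
  pp_c <- rc$permutation_p %||% rc$nominal_p
  pp_d <- rd$permutation_p %||% rd$nominal_p
  reversal <- sign(rc$pooled_r) != sign(rd$pooled_r) &&
    pp_c < alpha && pp_d < alpha
  structure(list(control = rc, drinker = rd, ci_control = ci_c,
                 ci_drinker = ci_d, slope_tests = slopes,
                 difference = rd$pooled_r - rc$pooled_r,
                 reversal = reversal, alpha = alpha),
            class = "synchrony_contrast")
}

#' @export
print.synchrony_contrast <- function(x, ...) {
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" [%.3f, %.3f]", ci[1], ci[2])
  cat("Transcript-function synchrony contrast\n")
  cat(sprintf("  control: pooled r = %.3f%s, permutation p = %.3g\n",
              x$control$pooled_r, fmt_ci(x$ci_control),
              x$control$permutation_p %||% NA))
  cat(sprintf("  drinker: pooled r = %.3f%s, permutation p = %.3g\n",
              x$drinker$pooled_r, fmt_ci(x$ci_drinker),
              x$drinker$permutation_p %||% NA))
  cat(sprintf("  difference (drinker - control) = %.3f; sign reversal: %s\n",
              x$difference, x$reversal))
  if (!is.null(x$slope_tests))
    cat(sprintf("  slope sets: two-sample t(%d) = %.3f, p = %.3g\n",
                x$slope_tests$two_sample$df, x$slope_tests$two_sample$t,
                x$slope_tests$two_sample$p))
  invisible(x)
}

#' Fit the full two-group synchrony analysis
#'
#' Runs the whole procedure for both groups on one panel: within-group
#' Pearson correlations and regression slopes for every gene x measure pair,
#' within-group ranking and pooling into a single rank-rank plane, the
#' pooled Spearman correlation with nominal and subject-permutation
#' p-values, and the between-group contrast with bootstrap CIs, slope-set
#' tests and the sign-reversal flag.
#'
#' @param function_table Data frame with `subject_id`, `group` and one column
#'   per measure.
#' @param expression Genes x subjects matrix.
#' @param panel A [gene_panel()] (or name), or a character vector of gene ids.
#' @param measures Measures to analyse (defaults to the panel's).
#' @param B Permutations per group (0 skips the permutation test).
#' @param n_boot Bootstrap replicates for the contrast CIs.
#' @param seed Seed.
#' @param alpha Significance level for the reversal flag.
#' @return A `synchrony_contrast` (contains both groups' results).
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' expr <- generate_expression(coh, gene_panel("a_priori_dopamine"))
#' ft <- truth_function_table(coh)
#' synchrony(ft, expr, "a_priori_dopamine", B = 200, seed = 1)
#' @export
synchrony <- function(function_table, expression, panel,
                      measures = NULL, B = 1000, n_boot = 1000, seed = NULL,
                      alpha = 0.05) {
  if (is.character(panel) && length(panel) == 1L &&
      panel %in% c("a_priori_dopamine", "a_posteriori_control", "kor_system",
                   "dynorphin"))
    panel <- gene_panel(panel)
  genes <- if (inherits(panel, "gene_panel")) panel$symbol else panel
  measures <- measures %||%
    (if (inherits(panel, "gene_panel")) panel_measures(panel) else
       stop("'measures' must be given for a plain gene list", call. = FALSE))
  rc <- synchrony_group(function_table, expression, genes, measures,
                        "control", B = B, seed = child_seed(seed %||% 0, "pc"))
  rd <- synchrony_group(function_table, expression, genes, measures,
                        "drinker", B = B, seed = child_seed(seed %||% 0, "pd"))
  synchrony_contrast(rc, rd, alpha = alpha, n_boot = n_boot, seed = seed)
}

#' Functional measure table from cohort ground truth
#'
#' Convenience accessor assembling the per-subject functional measures
#' (release, `V_max`, KOR potency/efficacy percentages, frequency-AUC change)
#' directly from the generator's ground truth, for analyses that bypass the
#' trace-fitting stages.
#'
#' @param cohort An `fscv_cohort`.
#' @param voltammetry_only Restrict to the voltammetry subset (default TRUE).
#' @return A data frame usable as a `function_table`.
#' @export
truth_function_table <- function(cohort, voltammetry_only = TRUE) {
  stopifnot(inherits(cohort, "fscv_cohort"))
  tr <- cohort$truth
  if (voltammetry_only) tr <- tr[tr$voltammetry, , drop = FALSE]
  data.frame(subject_id = tr$subject_id, group = tr$group,
             release = tr$true_dap, vmax = tr$true_vmax,
             potency_300nM = 100 * tr$true_inhibition_300nM,
             efficacy_1uM = 100 * tr$true_inhibition_1uM,
             delta_auc_percent = 100 * tr$true_disinhibition,
             row.names = NULL)
}
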