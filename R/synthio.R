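#' Configuration for a synthetic cohort
#'
#' Defines the study conditions emulated by the generator: group sizes (17
#' drinkers, 11 controls, of which 8 + 8 carry voltammetry recordings),
#' per-group distributions of the functional ground truth, the rank
#' correlation ("coupling") between each transcript panel and its paired
#' functional measures, and noise levels. No distributional
#' forms or variances are published for these functional measures, so the
#' default means/SDs
#' are illustrative values typical of ex vivo accumbens FSCV; they are not
#' estimates of the primate data.
#'
#' @param n_drinkers,n_controls Group sizes (defaults 17 and 11).
#' @param n_voltammetry_per_group Subjects per group with FSCV recordings
#'   (default 8); must not exceed either group size.
#' @param seed Integer seed; a fixed seed makes the cohort bit-identical.
#' @param vmax_params Per-group `c(mean, sd)` of maximal uptake rate (uM/s).
#' @param release_params Per-group list: `dap = c(mean, sd)` of baseline
#'   per-pulse release (uM) and `sigmoid = c(bottom, top, ea50, steepness)`
#'   input-output truth with subject-level SDs `sigmoid_sd = c(top, ea50,
#'   steepness)`.
#' @param kor_params Per-group `c(i300, i1000, sd)`: mean inhibition fraction
#'   at 300 nM and 1 uM agonist, and their subject SD.
#' @param dynorphin_params Per-group `c(mean, sd)` frequency-dependent
#'   disinhibition fraction after KOR blockade.
#' @param coupling Per-panel named vector `c(control =, drinker =)` of target
#'   Spearman rank correlations between gene expression and the gene's paired
#'   functional measure.
#' @param measure_cor Latent correlation between the two measures of a panel
#'   within a subject (release vs `V_max`; potency vs efficacy). Both scale
#'   with terminal density, so they are positively correlated by default.
#' @param noise `c(trace_sd, expression_sd, bac_sd)`: additive trace noise SD
#'   (uM), latent expression SD (natural-log scale), BAC residual SD (mg/dL).
#' @param drinking `c(slope, intercept, intake_mean, intake_sd, lifetime_mean,
#'   lifetime_sd, n_bac_samples)`: BAC (mg/dL) vs same-day intake (g/kg) line,
#'   intake distribution, lifetime intake distribution (g/kg).
#' @param n_background_genes Uncoupled background genes added to the count
#'   matrix (global null between groups).
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(
    n_drinkers = 17, n_controls = 11, n_voltammetry_per_group = 8, seed = 1,
    vmax_params = list(control = c(mean = 2.5, sd = 0.6),
                       drinker = c(mean = 3.0, sd = 0.6)),
    release_params = list(
      control = list(dap = c(mean = 1.0, sd = 0.25),
                     sigmoid = c(bottom = 0.05, top = 2.0, ea50 = 316.4,
                                 steepness = 80),
                     sigmoid_sd = c(top = 0.3, ea50 = 25, steepness = 10)),
      drinker = list(dap = c(mean = 0.9, sd = 0.25),
                     sigmoid = c(bottom = 0.05, top = 1.6, ea50 = 315.9,
                                 steepness = 80),
                     sigmoid_sd = c(top = 0.3, ea50 = 25, steepness = 10))),
    kor_params = list(control = c(i300 = 0.25, i1000 = 0.55, sd = 0.08),
                      drinker = c(i300 = 0.40, i1000 = 0.60, sd = 0.08)),
    dynorphin_params = list(control = c(mean = 0.15, sd = 0.08),
                            drinker = c(mean = 0.30, sd = 0.08)),
    coupling = list(a_priori_dopamine = c(control = 0.0, drinker = 0.8),
                    a_posteriori_control = c(control = 0.0, drinker = 0.0),
                    kor_system = c(control = 0.8, drinker = -0.8),
                    dynorphin = c(control = 0.0, drinker = 0.0)),
    measure_cor = 0.7,
    noise = c(trace_sd = 0.02, expression_sd = 0.5, bac_sd = 15),
    drinking = c(slope = 55, intercept = 0, intake_mean = 3.0, intake_sd = 1.0,
                 lifetime_mean = 1100, lifetime_sd = 250, n_bac_samples = 10),
    n_background_genes = 0) {

  n_drinkers <- check_count(n_drinkers, "n_drinkers", lower = 2L)
  n_controls <- check_count(n_controls, "n_controls", lower = 2L)
  n_voltammetry_per_group <- check_count(n_voltammetry_per_group,
                                         "n_voltammetry_per_group", lower = 2L)
  if (n_voltammetry_per_group > min(n_drinkers, n_controls))
    stop("'n_voltammetry_per_group' exceeds a group size", call. = FALSE)
  check_scalar(seed, "seed")
  check_scalar(measure_cor, "measure_cor", lower = 0, upper = 1)
  n_background_genes <- check_count(n_background_genes, "n_background_genes",
                                    lower = 0L)

  for (g in c("control", "drinker")) {
    if (vmax_params[[g]]["sd"] < 0)
      stop("'vmax_params$", g, "' sd must be >= 0", call. = FALSE)
    sig <- release_params[[g]]$sigmoid
    if (sig["top"] < sig["bottom"])
      stop("'release_params$", g, "$sigmoid' needs top >= bottom", call. = FALSE)
    if (any(c(release_params[[g]]$dap["sd"], release_params[[g]]$sigmoid_sd,
              kor_params[[g]]["sd"], dynorphin_params[[g]]["sd"]) < 0))
      stop("all SDs in '", g, "' parameters must be >= 0", call. = FALSE)
    if (any(kor_params[[g]][c("i300", "i1000")] < 0 |
            kor_params[[g]][c("i300", "i1000")] > 1))
      stop("'kor_params$", g, "' inhibition fractions must lie in [0, 1]",
           call. = FALSE)
  }
  for (p in names(coupling))
    if (any(abs(coupling[[p]]) > 1))
      stop("'coupling$", p, "' must lie in [-1, 1]", call. = FALSE)
  if (any(noise < 0)) stop("'noise' SDs must be >= 0", call. = FALSE)
  if (drinking["n_bac_samples"] < 1)
    stop("'drinking' n_bac_samples must be >= 1", call. = FALSE)

  structure(list(n_drinkers = n_drinkers, n_controls = n_controls,
                 n_voltammetry_per_group = n_voltammetry_per_group,
                 seed = as.integer(seed), vmax_params = vmax_params,
                 release_params = release_params, kor_params = kor_params,
                 dynorphin_params = dynorphin_params, coupling = coupling,
                 measure_cor = measure_cor, noise = noise, drinking = drinking,
                 n_background_genes = n_background_genes),
            class = "cohort_config")
}

# measure name -> latent z column in the truth table
measure_latent <- c(release = "z_release", vmax = "z_vmax",
                    potency_300nM = "z_i300", efficacy_1uM = "z_i1000",
                    delta_auc_percent = "z_dyn")


#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject functional ground truth (per-pulse release, `V_max`,
#' input-output sigmoid, KOR inhibition fractions, disinhibition fraction,
#' lifetime intake) from the per-group distributions in the config. Within a
#' subject, paired measures share a latent "terminal function" factor with
#' correlation `measure_cor`; the underlying standard-normal scores are kept
#' in the truth table so expression can be coupled to them by a Gaussian
#' copula. The first `n_voltammetry_per_group` subjects of each group form
#' the voltammetry subset.
#'
#' @param config A [cohort_config()].
#' @return An `fscv_cohort`: list with `config`, `subjects` (id, group,
#'   voltammetry flag) and `truth` (one row per subject).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(child_seed(config$seed, "cohort"), {
    groups <- c(rep("control", config$n_controls),
                rep("drinker", config$n_drinkers))
    ids <- c(sprintf("c%02d", seq_len(config$n_controls)),
             sprintf("d%02d", seq_len(config$n_drinkers)))
    n <- length(ids)
    a <- sqrt(config$measure_cor)
    b <- sqrt(1 - config$measure_cor)

    z_fun <- rnorm(n); z_kor <- rnorm(n)
    z_release <- a * z_fun + b * rnorm(n)
    z_vmax <- a * z_fun + b * rnorm(n)
    z_i300 <- a * z_kor + b * rnorm(n)
    z_i1000 <- a * z_kor + b * rnorm(n)
    z_dyn <- rnorm(n)

    g <- function(field) vapply(groups, function(gr) field(gr), numeric(1))
    rp <- config$release_params; kp <- config$kor_params
    vp <- config$vmax_params; dp <- config$dynorphin_params

    true_dap <- pmax(0.05, g(function(gr) rp[[gr]]$dap["mean"]) +
                       g(function(gr) rp[[gr]]$dap["sd"]) * z_release)
    true_vmax <- pmax(0.1, g(function(gr) vp[[gr]]["mean"]) +
                        g(function(gr) vp[[gr]]["sd"]) * z_vmax)
    sig_bottom <- g(function(gr) rp[[gr]]$sigmoid["bottom"])
    sig_top <- pmax(sig_bottom + 0.1,
                    g(function(gr) rp[[gr]]$sigmoid["top"]) +
                      g(function(gr) rp[[gr]]$sigmoid_sd["top"]) * z_release)
    sig_ea50 <- pmax(25, g(function(gr) rp[[gr]]$sigmoid["ea50"]) +
                       g(function(gr) rp[[gr]]$sigmoid_sd["ea50"]) * rnorm(n))
    sig_steep <- pmax(20, g(function(gr) rp[[gr]]$sigmoid["steepness"]) +
                        g(function(gr) rp[[gr]]$sigmoid_sd["steepness"]) * rnorm(n))
    i300 <- pmin(1, pmax(0, g(function(gr) kp[[gr]]["i300"]) +
                           g(function(gr) kp[[gr]]["sd"]) * z_i300))
    i1000 <- pmin(1, pmax(0, g(function(gr) kp[[gr]]["i1000"]) +
                            g(function(gr) kp[[gr]]["sd"]) * z_i1000))
    disinh <- pmin(1, pmax(0, g(function(gr) dp[[gr]]["mean"]) +
                             g(function(gr) dp[[gr]]["sd"]) * z_dyn))
    lifetime <- ifelse(groups == "drinker",
                       pmax(50, rnorm(n, config$drinking["lifetime_mean"],
                                      config$drinking["lifetime_sd"])), 0)

    volt <- stats::ave(seq_len(n), groups, FUN = seq_along) <=
      config$n_voltammetry_per_group
    truth <- data.frame(subject_id = ids, group = groups, voltammetry = volt,
                        true_dap = true_dap, true_vmax = true_vmax,
                        sig_bottom = sig_bottom, sig_top = sig_top,
                        sig_ea50 = sig_ea50, sig_steepness = sig_steep,
                        true_inhibition_300nM = i300,
                        true_inhibition_1uM = i1000,
                        true_disinhibition = disinh,
                        lifetime_intake_gkg = lifetime,
                        z_release = z_release, z_vmax = z_vmax,
                        z_i300 = z_i300, z_i1000 = z_i1000, z_dyn = z_dyn,
                        z_fun = z_fun, z_kor = z_kor,
                        row.names = NULL)
    structure(list(config = config,
                   subjects = truth[, c("subject_id", "group", "voltammetry")],
                   truth = truth),
              class = "fscv_cohort")
  })
}

#' @export
print.fscv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d drinkers + %d controls (%d + %d with voltammetry), seed %d\n",
              x$config$n_drinkers, x$config$n_controls,
              sum(x$subjects$voltammetry & x$subjects$group == "drinker"),
              sum(x$subjects$voltammetry & x$subjects$group == "control"),
              x$config$seed))
  invisible(x)
}

#' Generate panel gene expression coupled to functional truth
#'
#' Latent (natural-log abundance) expression for each panel gene, coupled
#' within each group to the subject's paired functional measure at a target
#' Spearman correlation via a Gaussian copula: the latent Pearson correlation
#' is \eqn{r = 2 \sin(\pi \rho / 6)}, so the empirical Spearman correlation
#' converges to \eqn{\rho} as the group grows. Because the panel's measures
#' share a latent terminal-function factor (see `measure_cor`), a gene
#' coupled to one measure also tracks the panel's other measure at about
#' `measure_cor` times the coupling. Coupling (and ranking downstream) is
#' strictly within-group.
#'
#' @param cohort An `fscv_cohort`.
#' @param panel A [gene_panel()] (or panel name).
#' @param coupling Named vector `c(control =, drinker =)` of target Spearman
#'   rho; defaults to the cohort config entry for the panel.
#' @param seed Seed for the gene-level noise (default derived from the cohort
#'   seed).
#' @param gene_mean_log Mean latent log-abundance per gene (recycled).
#' @return An `expression_matrix`: genes x subjects latent values with the
#'   panel stored as an attribute.
#' @export
generate_expression <- function(cohort, panel, coupling = NULL, seed = NULL,
                                gene_mean_log = log(1e-4)) {
  stopifnot(inherits(cohort, "fscv_cohort"))
  if (is.character(panel)) panel <- gene_panel(panel)
  stopifnot(inherits(panel, "gene_panel"))
  pname <- attr(panel, "panel")
  coupling <- coupling %||% cohort$config$coupling[[pname]]
  if (is.null(coupling))
    stop("no coupling configured for panel '", pname, "'", call. = FALSE)
  if (any(abs(coupling) > 1))
    stop("coupling rho must lie in [-1, 1]", call. = FALSE)
  if (!all(c("control", "drinker") %in% names(coupling)))
    stop("coupling needs named entries for 'control' and 'drinker'", call. = FALSE)
  bad <- !panel$paired_measure %in% names(measure_latent)
  if (any(bad))
    stop("unknown paired measure for gene(s): ",
         paste(panel$symbol[bad], collapse = ", "), call. = FALSE)
  seed <- seed %||% child_seed(cohort$config$seed, paste0("expr_", pname))
  tr <- cohort$truth
  n <- nrow(tr)
  sdlat <- unname(cohort$config$noise["expression_sd"])
  means <- rep_len(gene_mean_log, nrow(panel))

  with_seed(seed, {
    mat <- matrix(NA_real_, nrow(panel), n,
                  dimnames = list(panel$symbol, tr$subject_id))
    for (gi in seq_len(nrow(panel))) {
      zc <- tr[[measure_latent[panel$paired_measure[gi]]]]
      for (gr in c("control", "drinker")) {
        idx <- tr$group == gr
        rho <- unname(coupling[gr])
        r <- 2 * sin(pi * rho / 6)
        x <- r * zc[idx] + sqrt(1 - r^2) * rnorm(sum(idx))
        mat[gi, idx] <- means[gi] + sdlat * x
      }
    }
    attr(mat, "panel") <- pname
    attr(mat, "paired_measure") <- setNames(panel$paired_measure, panel$symbol)
    class(mat) <- c("expression_matrix", class(mat))
    mat
  })
}

#' Generate uncoupled background gene expression (global null)
#'
#' Background genes share their latent mean across groups, so any
#' differential-expression screen on them is under the global null.
#'
#' @param cohort An `fscv_cohort`.
#' @param n_genes Number of background genes.
#' @param mean_log_range Range of per-gene mean latent log-abundance.
#' @param sd Latent SD (defaults to the config expression noise).
#' @param seed Seed (default derived from the cohort seed).
#' @return Genes x subjects latent matrix (gene ids `bg0001`...).
#' @export
generate_background_expression <- function(cohort, n_genes = NULL,
                                           mean_log_range = log(c(1e-6, 1e-3)),
                                           sd = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "fscv_cohort"))
  n_genes <- check_count(n_genes %||% cohort$config$n_background_genes,
                         "n_genes", lower = 1L)
  sd <- sd %||% unname(cohort$config$noise["expression_sd"])
  seed <- seed %||% child_seed(cohort$config$seed, "background")
  ids <- cohort$truth$subject_id
  with_seed(seed, {
    gm <- runif(n_genes, mean_log_range[1], mean_log_range[2])
    mat <- gm + matrix(rnorm(n_genes * length(ids), sd = sd), n_genes)
    dimnames(mat) <- list(sprintf("bg%04d", seq_len(n_genes)), ids)
    mat
  })
}

#' Generate negative-binomial read counts from latent expression
#'
#' Counts are drawn with mean `exp(latent) * library_size`; `dispersion` is
#' the NB dispersion (variance `mu + dispersion * mu^2`), with `dispersion =
#' 0` giving Poisson counts.
#'
#' @param expr Genes x samples latent (natural-log abundance) matrix.
#' @param library_sizes Per-sample library size (> 0, recycled).
#' @param dispersion NB dispersion (>= 0).
#' @param seed Seed.
#' @return Integer genes x samples count matrix.
#' @export
generate_counts <- function(expr, library_sizes = 5e5, dispersion = 0.05,
                            seed = NULL) {
  stopifnot(is.matrix(expr))
  library_sizes <- rep_len(library_sizes, ncol(expr))
  if (any(library_sizes <= 0))
    stop("library sizes must be positive", call. = FALSE)
  check_scalar(dispersion, "dispersion", lower = 0)
  mu <- sweep(exp(expr), 2, library_sizes, "*")
  with_seed(seed, {
    cnt <- if (dispersion == 0) rpois(length(mu), mu)
           else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    out <- matrix(as.integer(cnt), nrow(expr), dimnames = dimnames(expr))
    out
  })
}

#' Generate drinking records with BAC linearly related to intake
#'
#' For each drinker, daily intakes are drawn around the configured mean and
#' blood alcohol concentration follows `intercept + slope * intake` plus
#' Gaussian residual noise, truncated at 0. Controls receive zero intake and
#' zero BAC.
#'
#' @param cohort An `fscv_cohort`.
#' @param slope_mgdl_per_gkg,intercept,residual_sd BAC line parameters;
#'   defaults from the config.
#' @param seed Seed.
#' @return The cohort with a `drinking` data frame added
#'   (`subject_id, group, day, intake_gkg, bac_mgdl`).
#' @export
generate_drinking <- function(cohort, slope_mgdl_per_gkg = NULL,
                              intercept = NULL, residual_sd = NULL,
                              seed = NULL) {
  stopifnot(inherits(cohort, "fscv_cohort"))
  dk <- cohort$config$drinking
  slope <- slope_mgdl_per_gkg %||% unname(dk["slope"])
  intercept <- intercept %||% unname(dk["intercept"])
  residual_sd <- residual_sd %||% unname(cohort$config$noise["bac_sd"])
  check_scalar(residual_sd, "residual_sd", lower = 0)
  seed <- seed %||% child_seed(cohort$config$seed, "drinking")
  ndays <- as.integer(dk["n_bac_samples"])
  tr <- cohort$truth
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(tr)), function(i) {
      if (tr$group[i] == "drinker") {
        intake <- pmax(0.1, rnorm(ndays, dk["intake_mean"], dk["intake_sd"]))
        bac <- pmax(0, intercept + slope * intake +
                      rnorm(ndays, sd = residual_sd))
      } else {
        intake <- rep(0, ndays); bac <- rep(0, ndays)
      }
      data.frame(subject_id = tr$subject_id[i], group = tr$group[i],
                 day = seq_len(ndays), intake_gkg = intake, bac_mgdl = bac)
    })
    cohort$drinking <- do.call(rbind, rows)
    cohort
  })
}

# Subject-level sigmoid evaluated at amperage I (per-pulse release truth).
subject_sigmoid <- function(truth_row, I) {
  truth_row$sig_bottom + (truth_row$sig_top - truth_row$sig_bottom) /
    (1 + exp((truth_row$sig_ea50 - I) / truth_row$sig_steepness))
}

#' Simulate an FSCV recording session for one subject
#'
#' Emits noiseless-model traces for the requested experimental conditions,
#' with the condition's configured effect applied multiplicatively to the
#' subject's per-pulse release truth, plus additive Gaussian noise floored at
#' zero:
#' \describe{
#'   \item{baseline}{single pulse, 350 uA, release = `true_dap`.}
#'   \item{io}{single pulses across ascending amperages; release follows the
#'     subject's input-output sigmoid truth.}
#'   \item{agonist_300nM / agonist_1uM}{single pulse with release scaled by
#'     `1 - true_inhibition` at that (cumulative) agonist concentration.}
#'   \item{frequency_pre / frequency_post}{5-pulse trains at each frequency;
#'     post-antagonist release is scaled by `1 + true_disinhibition * w(f)`
#'     with `w` ramping linearly from 0 at the lowest to 1 at the highest
#'     frequency.}
#' }
#'
#' @param cohort An `fscv_cohort`.
#' @param subject_id Subject to record from (must be in the voltammetry
#'   subset).
#' @param conditions Subset of the condition labels above.
#' @param noise_sd Additive trace noise SD in uM (default from the config).
#' @param seed Seed.
#' @param io_amplitudes Amperage grid for the `io` condition (uA).
#' @param frequencies Frequency grid for the train conditions (Hz).
#' @return An `fscv_session`: list with `subject_id` and a named list
#'   `traces`; each trace carries `condition` and (where relevant)
#'   `amplitude_uA` / `frequency_hz` attributes.
#' @export
generate_fscv_session <- function(cohort, subject_id,
                                  conditions = c("baseline", "io",
                                                 "agonist_300nM", "agonist_1uM",
                                                 "frequency_pre",
                                                 "frequency_post"),
                                  noise_sd = NULL, seed = NULL,
                                  io_amplitudes = c(50, 100, 200, 300, 400,
                                                    500, 600, 750, 900),
                                  frequencies = c(5, 10, 20, 40, 60, 100)) {
  stopifnot(inherits(cohort, "fscv_cohort"))
  known <- c("baseline", "io", "agonist_300nM", "agonist_1uM",
             "frequency_pre", "frequency_post")
  bad <- setdiff(conditions, known)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  i <- match(subject_id, cohort$truth$subject_id)
  if (is.na(i)) stop("unknown subject: ", subject_id, call. = FALSE)
  tr <- cohort$truth[i, ]
  if (!tr$voltammetry)
    stop("subject ", subject_id, " is not in the voltammetry subset",
         call. = FALSE)
  noise_sd <- noise_sd %||% unname(cohort$config$noise["trace_sd"])
  check_scalar(noise_sd, "noise_sd", lower = 0)
  seed <- seed %||% child_seed(cohort$config$seed, paste0("fscv_", subject_id))

  km <- 0.160
  single <- function(amp) stim_protocol(1, amplitude_uA = amp)
  train <- function(f) stim_protocol(5, frequency_hz = f, onset_s = 1)
  wf <- (frequencies - min(frequencies)) / diff(range(frequencies))

  with_seed(seed, {
    traces <- list()
    add <- function(label, trace, condition, ...) {
      extra <- list(...)
      attr(trace, "condition") <- condition
      for (nm in names(extra)) attr(trace, nm) <- extra[[nm]]
      if (noise_sd > 0)
        trace$values <- pmax(0, trace$values +
                               rnorm(length(trace$values), sd = noise_sd))
      traces[[label]] <<- trace
    }
    for (cond in conditions) {
      switch(cond,
        baseline = add("baseline",
                       simulate_trace(single(350), tr$true_dap, tr$true_vmax, km),
                       "baseline"),
        io = for (amp in io_amplitudes)
          add(sprintf("io_%04d", amp),
              simulate_trace(single(amp), subject_sigmoid(tr, amp),
                             tr$true_vmax, km),
              "io", amplitude_uA = amp),
        agonist_300nM = add("agonist_300nM",
                            simulate_trace(single(350),
                                           tr$true_dap * (1 - tr$true_inhibition_300nM),
                                           tr$true_vmax, km),
                            "agonist_300nM"),
        agonist_1uM = add("agonist_1uM",
                          simulate_trace(single(350),
                                         tr$true_dap * (1 - tr$true_inhibition_1uM),
                                         tr$true_vmax, km),
                          "agonist_1uM"),
        frequency_pre = for (k in seq_along(frequencies))
          add(sprintf("freq_pre_%03d", frequencies[k]),
              simulate_trace(train(frequencies[k]), tr$true_dap, tr$true_vmax,
                             km, duration_s = 12),
              "frequency_pre", frequency_hz = frequencies[k]),
        frequency_post = for (k in seq_along(frequencies))
          add(sprintf("freq_post_%03d", frequencies[k]),
              simulate_trace(train(frequencies[k]),
                             tr$true_dap * (1 + tr$true_disinhibition * wf[k]),
                             tr$true_vmax, km, duration_s = 12),
              "frequency_post", frequency_hz = frequencies[k]))
    }
    structure(list(subject_id = subject_id, traces = traces),
              class = "fscv_session")
  })
}

#' @export
print.fscv_session <- function(x, ...) {
  conds <- vapply(x$traces, attr, "", "condition")
  cat(sprintf("FSCV session for %s: %d traces (%s)\n", x$subject_id,
              length(x$traces),
              paste(sprintf("%s x%d", names(table(conds)), table(conds)),
                    collapse = ", ")))
  invisible(x)
}
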