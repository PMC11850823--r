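#' Pipeline run configuration
#'
#' Bundles the cohort configuration with the analysis parameters of every
#' downstream stage. Can be read from / written to JSON (or YAML if the
#' `yaml` package is available) via [read_run_config()].
#'
#' @param cohort A [cohort_config()].
#' @param km_um Fixed Michaelis constant for kinetic fitting (uM).
#' @param filter `c(min_count, min_samples)` for [filter_low_expression()].
#' @param fdr_alpha BH significance threshold for the DE screen.
#' @param panels Panels analysed for synchrony, in priority order (a gene
#'   appearing in several panels takes its generator pairing from the first).
#' @param permutations Permutations per group for the synchrony test.
#' @param n_boot Bootstrap replicates for contrast CIs.
#' @param library_size,dispersion Count-generation parameters.
#' @param io_amplitudes,frequencies Stimulation grids.
#' @param seed Run seed; defaults to the cohort seed.
#' @return A `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), km_um = 0.160,
                       filter = c(min_count = 5, min_samples = 3),
                       fdr_alpha = 0.05,
                       panels = c("a_priori_dopamine", "kor_system"),
                       permutations = 200, n_boot = 200,
                       library_size = 5e5, dispersion = 0.05,
                       io_amplitudes = c(50, 100, 200, 300, 400, 500, 600,
                                         750, 900),
                       frequencies = c(5, 10, 20, 40, 60, 100),
                       seed = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  check_scalar(km_um, "km_um", lower = 0, strict_lower = TRUE)
  check_scalar(fdr_alpha, "fdr_alpha", lower = 0, upper = 1)
  permutations <- check_count(permutations, "permutations", lower = 0L)
  structure(list(cohort = cohort, km_um = km_um, filter = filter,
                 fdr_alpha = fdr_alpha, panels = panels,
                 permutations = permutations, n_boot = n_boot,
                 library_size = library_size, dispersion = dispersion,
                 io_amplitudes = io_amplitudes, frequencies = frequencies,
                 seed = as.integer(seed %||% cohort$seed)),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' The file mirrors [run_config()] field-for-field; absent fields fall back
#' to the defaults. Format is chosen by extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  coh_args <- raw$cohort %||% list()
  cohort <- do.call(cohort_config, coh_args)
  args <- raw[setdiff(names(raw), "cohort")]
  do.call(run_config, c(list(cohort = cohort), args))
}

# Cheap FNV-1a hash of the serialized config, for output provenance headers.
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 2166136261
  for (ch in s) h <- (bitwXor(as.integer(h %% 2^31), ch) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Derive per-subject scalar functional metrics from one recording session.
session_metrics <- function(session, km, frequencies) {
  tr <- session$traces
  cond <- vapply(tr, attr, "", "condition")
  base_fit <- fit_kinetics(tr[[which(cond == "baseline")[1]]], km = km)
  base_peak <- peak_release(tr[[which(cond == "baseline")[1]]])

  io_idx <- which(cond == "io")
  sig <- NULL
  if (length(io_idx) >= 5L) {
    amps <- vapply(tr[io_idx], attr, numeric(1), "amplitude_uA")
    peaks <- vapply(tr[io_idx], peak_release, numeric(1))
    sig <- fit_io_sigmoid(amps, peaks)
  }

  kor <- NULL
  if (any(cond == "agonist_300nM") && any(cond == "agonist_1uM")) {
    kor <- kor_sensitivity_metrics(
      base_peak,
      vapply(tr[cond == "agonist_300nM"], peak_release, numeric(1)),
      vapply(tr[cond == "agonist_1uM"], peak_release, numeric(1)))
  }

  freq <- function(which_cond, cc) {
    idx <- which(cond == which_cond)
    if (!length(idx)) return(NULL)
    f <- vapply(tr[idx], attr, numeric(1), "frequency_hz")
    p <- vapply(tr[idx], peak_release, numeric(1))
    o <- order(f)
    normalize_frequency_series(f[o], p[o], base_peak, condition = cc)
  }
  pre <- freq("frequency_pre", "pre"); post <- freq("frequency_post", "post")
  auc_pre <- if (!is.null(pre)) auc_frequency(pre) else NA_real_
  auc_post <- if (!is.null(post)) auc_frequency(post) else NA_real_

  data.frame(
    subject_id = session$subject_id,
    release = unname(coef(base_fit)["dap"]),
    vmax = unname(coef(base_fit)["vmax"]),
    ea50 = if (!is.null(sig)) unname(coef(sig)["ea50"]) else NA_real_,
    top = if (!is.null(sig)) unname(coef(sig)["top"]) else NA_real_,
    bottom = if (!is.null(sig)) unname(coef(sig)["bottom"]) else NA_real_,
    span = if (!is.null(sig)) span(sig) else NA_real_,
    potency_300nM = if (!is.null(kor)) kor$potency_300nM else NA_real_,
    efficacy_1uM = if (!is.null(kor)) kor$efficacy_1uM else NA_real_,
    auc_pre = auc_pre, auc_post = auc_post,
    delta_auc_percent = if (is.finite(auc_pre) && auc_pre > 0 &&
                            is.finite(auc_post))
      disinhibition_auc_change(auc_pre, auc_post) else NA_real_)
}

# mean +/- SEM summary used in the run report
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> kinetic fitting -> terminal metrics -> expression ->
#' synchrony in order, entirely from the run configuration, and returns a
#' machine-readable report. Identical config and seed give identical results
#' (and byte-identical output files). If `out_dir` is given, every stage's
#' table is written there (CSV/TSV with a provenance header carrying the seed
#' and config hash; JSON for summaries and ground truth).
#'
#' @param config A [run_config()] (or a path to a JSON/YAML config file).
#' @param out_dir Optional output directory.
#' @param write_traces Also write each trace as CSV + JSON sidecar (default
#'   FALSE; traces are bulky).
#' @return A `run_report` list: stage row counts, config echo, per-group
#'   mean +/- SEM summaries of each functional measure, DE/PCA summaries,
#'   and per-panel synchrony summaries.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         write_traces = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  report <- list(seed = config$seed, config_hash = config_hash(config))
  tryCatch({
    cohort <- generate_cohort(config$cohort)
    cohort <- generate_drinking(cohort)

    # expression: panel genes (first panel listing a gene wins) + background
    panel_expr <- list(); seen <- character()
    for (p in config$panels) {
      pe <- generate_expression(cohort, gene_panel(p))
      keep <- setdiff(rownames(pe), seen)
      panel_expr[[p]] <- pe[keep, , drop = FALSE]
      seen <- c(seen, keep)
    }
    expr <- do.call(rbind, c(lapply(panel_expr, unclass), list(deparse.level = 0)))
    rownames(expr) <- unlist(lapply(panel_expr, rownames), use.names = FALSE)
    if (config$cohort$n_background_genes > 0)
      expr <- rbind(expr, generate_background_expression(cohort))

    stage <- "counts"
    counts <- generate_counts(expr, config$library_size, config$dispersion,
                              seed = child_seed(config$seed, "counts"))

    stage <- "fscv"
    volt <- cohort$subjects$subject_id[cohort$subjects$voltammetry]
    sessions <- lapply(volt, function(s)
      generate_fscv_session(cohort, s, io_amplitudes = config$io_amplitudes,
                            frequencies = config$frequencies))
    names(sessions) <- volt

    stage <- "metrics"
    metrics <- do.call(rbind, lapply(sessions, session_metrics,
                                     km = config$km_um,
                                     frequencies = config$frequencies))
    metrics <- merge(cohort$subjects[, c("subject_id", "group")], metrics,
                     by = "subject_id", sort = TRUE)

    stage <- "expression"
    filtered <- filter_low_expression(counts, config$filter["min_count"],
                                      config$filter["min_samples"])
    sf <- size_factors(filtered)
    norm <- normalize_log(filtered, sf)
    de <- de_screen(norm, cohort$subjects$group)
    pca <- pca_scores(norm, k = min(2L, ncol(norm) - 1L))

    stage <- "synchrony"
    sync <- list()
    for (p in config$panels) {
      pan <- gene_panel(p)
      if (!all(pan$symbol %in% rownames(norm))) {
        warning("panel '", p, "' genes missing after filtering; skipped",
                call. = FALSE)
        next
      }
      sync[[p]] <- synchrony(metrics, norm[, volt, drop = FALSE], pan,
                             B = config$permutations, n_boot = config$n_boot,
                             seed = child_seed(config$seed, paste0("sync_", p)))
    }

    stage <- "report"
    grp_summary <- lapply(split(metrics, metrics$group), function(df)
      lapply(df[, !(names(df) %in% c("subject_id", "group")), drop = FALSE],
             mean_sem))
    sync_summary <- lapply(sync, function(s) list(
      control = list(pooled_r = s$control$pooled_r,
                     nominal_p = s$control$nominal_p,
                     permutation_p = s$control$permutation_p,
                     n_pairs = s$control$n_pairs),
      drinker = list(pooled_r = s$drinker$pooled_r,
                     nominal_p = s$drinker$nominal_p,
                     permutation_p = s$drinker$permutation_p,
                     n_pairs = s$drinker$n_pairs),
      difference = s$difference, reversal = s$reversal,
      slope_two_sample = s$slope_tests$two_sample))
    report$stages <- list(
      subjects = nrow(cohort$subjects), drinking_rows = nrow(cohort$drinking),
      genes_simulated = nrow(counts), genes_retained = nrow(filtered),
      traces = sum(vapply(sessions, function(s) length(s$traces), 0L)),
      metrics_rows = nrow(metrics),
      de_significant = sum(de$padj < config$fdr_alpha),
      pooled_pairs = lapply(sync, function(s)
        list(control = s$control$n_pairs, drinker = s$drinker$n_pairs)))
    report$group_summary <- grp_summary
    report$synchrony <- sync_summary
    report$config <- unclass_recursive(config)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      hdr <- sprintf("# seed=%d config_hash=%s", config$seed,
                     report$config_hash)
      write_with_header(cohort$subjects, file.path(out_dir, "subjects.csv"), hdr)
      write_with_header(cohort$drinking, file.path(out_dir, "drinking.csv"), hdr)
      write_with_header(metrics, file.path(out_dir, "metrics.csv"), hdr)
      write_with_header(de, file.path(out_dir, "de_results.csv"), hdr)
      write_with_header(
        data.frame(subject_id = rownames(pca), pca, row.names = NULL),
        file.path(out_dir, "pca_scores.csv"), hdr)
      for (nm in c("counts", "expr", "norm")) {
        obj <- switch(nm, counts = counts, expr = expr, norm = norm)
        f <- file.path(out_dir, switch(nm, counts = "counts.tsv",
                                       expr = "expression.tsv",
                                       norm = "normalized.tsv"))
        con <- file(f, "w"); writeLines(hdr, con)
        utils::write.table(data.frame(gene_id = rownames(obj),
                                      as.data.frame(unclass(obj)[, , drop = FALSE])),
                           con, sep = "\t", row.names = FALSE, quote = FALSE)
        close(con)
      }
      cors <- do.call(rbind, lapply(names(sync), function(p)
        cbind(panel = p, rbind(sync[[p]]$control$correlations,
                               sync[[p]]$drinker$correlations))))
      if (!is.null(cors))
        write_with_header(cors, file.path(out_dir, "correlations.csv"), hdr)
      pooled <- do.call(rbind, lapply(names(sync), function(p)
        cbind(panel = p,
              rbind(cbind(group = "control",
                          as.data.frame(sync[[p]]$control$table)),
                    cbind(group = "drinker",
                          as.data.frame(sync[[p]]$drinker$table))))))
      if (!is.null(pooled))
        write_with_header(pooled, file.path(out_dir, "pooled_rank_table.csv"),
                          hdr)
      jsonlite::write_json(sync_summary,
                           file.path(out_dir, "synchrony_summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
      if (write_traces) {
        tdir <- file.path(out_dir, "traces")
        dir.create(tdir, showWarnings = FALSE)
        for (s in sessions) for (lbl in names(s$traces))
          write_trace(s$traces[[lbl]],
                      file.path(tdir, sprintf("%s_%s.csv", s$subject_id, lbl)))
      }
    }
    structure(report, class = "run_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  %d subjects, %d genes simulated (%d retained), %d traces\n",
              x$stages$subjects, x$stages$genes_simulated,
              x$stages$genes_retained, x$stages$traces))
  cat(sprintf("  DE screen: %d gene(s) BH-significant\n",
              x$stages$de_significant))
  for (p in names(x$synchrony)) {
    s <- x$synchrony[[p]]
    cat(sprintf("  synchrony [%s]: control r = %.3f, drinker r = %.3f, reversal %s\n",
                p, s$control$pooled_r, s$drinker$pooled_r, s$reversal))
  }
  invisible(x)
}

#' Generate the small bundled test fixture cohort
#'
#' A reduced cohort (4 + 4 subjects, all with voltammetry; 4 panel + 46
#' background genes; 5-amplitude I/O grid and 3-frequency trains) written to
#' `out_dir` by the full pipeline. Small enough to run in seconds; used by
#' the test suite.
#'
#' @param out_dir Output directory.
#' @param seed Seed.
#' @param write_traces Write individual trace files too (default TRUE).
#' @return The `run_report`, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1, write_traces = TRUE) {
  cfg <- fixture_config(seed)
  rep <- run_pipeline(cfg, out_dir = out_dir, write_traces = write_traces)
  invisible(rep)
}

# the fixture-scale run configuration
fixture_config <- function(seed = 1) {
  run_config(
    cohort = cohort_config(n_drinkers = 4, n_controls = 4,
                           n_voltammetry_per_group = 4, seed = seed,
                           n_background_genes = 46),
    panels = "a_priori_dopamine",
    permutations = 100, n_boot = 100,
    io_amplitudes = c(50, 150, 300, 500, 900),
    frequencies = c(5, 20, 100),
    seed = seed)
}
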