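#' Named transcript panels and their paired functional measures
#'
#' Three small panels of midbrain transcripts analysed against nucleus
#' accumbens terminal function:
#' \describe{
#'   \item{a_priori_dopamine}{`DRD2`, `OPRK1`, `SLC6A3` (DAT), `SLC18A2`
#'     (VMAT2) — dopamine autoreceptor/transporter genes, analysed against
#'     evoked release and `V_max`.}
#'   \item{a_posteriori_control}{`DRD1`, `DRD5`, `SLC17A6` (VGLUT2),
#'     `SLC32A1` (VGAT) — a size-matched control panel (2 GPCRs, 2 solute
#'     carriers) not expected to track terminal function.}
#'   \item{kor_system}{`OPRK1`, `PDYN`, `ARRB1`, `ARRB2` — kappa opioid
#'     receptor system genes, analysed against agonist potency (300 nM) and
#'     efficacy (1 uM).}
#'   \item{dynorphin}{`OPRK1`, `PDYN` against the percent change in
#'     frequency-curve AUC after KOR blockade.}
#' }
#' The `paired_measure` column records which functional measure each gene's
#' expression is coupled to in the synthetic generator.
#'
#' @param name Panel name.
#' @return A data frame with columns `symbol`, `paired_measure` and a
#'   `panel` attribute; class `gene_panel`.
#' @export
gene_panel <- function(name = c("a_priori_dopamine", "a_posteriori_control",
                                "kor_system", "dynorphin")) {
  name <- match.arg(name)
  def <- switch(name,
    a_priori_dopamine = data.frame(
      symbol = c("DRD2", "OPRK1", "SLC6A3", "SLC18A2"),
      paired_measure = c("release", "release", "vmax", "vmax")),
    a_posteriori_control = data.frame(
      symbol = c("DRD1", "DRD5", "SLC17A6", "SLC32A1"),
      paired_measure = c("release", "release", "vmax", "vmax")),
    kor_system = data.frame(
      symbol = c("OPRK1", "PDYN", "ARRB1", "ARRB2"),
      paired_measure = c("potency_300nM", "potency_300nM",
                         "efficacy_1uM", "efficacy_1uM")),
    dynorphin = data.frame(
      symbol = c("OPRK1", "PDYN"),
      paired_measure = c("delta_auc_percent", "delta_auc_percent")))
  attr(def, "panel") <- name
  class(def) <- c("gene_panel", "data.frame")
  def
}

#' Default measures analysed with a panel
#'
#' @param panel A `gene_panel` or panel name.
#' @return Character vector of functional measure names.
#' @export
panel_measures <- function(panel) {
  name <- if (inherits(panel, "gene_panel")) attr(panel, "panel") else panel
  switch(name,
         a_priori_dopamine = c("release", "vmax"),
         a_posteriori_control = c("release", "vmax"),
         kor_system = c("potency_300nM", "efficacy_1uM"),
         dynorphin = "delta_auc_percent",
         stop("unknown panel: ", name, call. = FALSE))
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("count matrix needs unique gene ids as rownames", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("count matrix needs unique sample ids as colnames", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(counts)
}

#' Filter lowly expressed genes
#'
#' Keeps genes with a count of at least `min_count` in at least `min_samples`
#' samples; everything else is dropped. Gene order is preserved and the
#' filter is idempotent.
#'
#' @param counts Integer gene x sample matrix.
#' @param min_count Minimum count (default 5).
#' @param min_samples Minimum number of samples reaching it (default 3).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_count = 5, min_samples = 3) {
  check_counts(counts)
  check_scalar(min_count, "min_count", lower = 0)
  min_samples <- check_count(min_samples, "min_samples", lower = 1L)
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!any(keep))
    warning("no genes pass the expression filter", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of each sample's count divided by the gene's
#' geometric mean across samples. Factors are rescaled so the median sample
#' has factor 1 (size factors are defined only up to a common scalar).
#'
#' @param counts Integer gene x sample matrix.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  check_counts(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has positive counts in every sample; size factors undefined",
         call. = FALSE)
  lc <- log(counts[all_pos, , drop = FALSE])
  log_geo <- rowMeans(lc)
  raw <- apply(lc, 2, function(x) exp(median(x - log_geo)))
  raw / median(raw)
}

#' Log-scale normalization of counts
#'
#' The working normalized value is `log2(count / size_factor + 1)` — a simple
#' log-like transform that removes library-size effects. It is a declared
#' stand-in ("vst_standin") for a full variance-stabilizing transform, which
#' is deliberately out of scope here.
#'
#' @param counts Integer gene x sample matrix.
#' @param factors Positive per-sample size factors (default computed from
#'   `counts`).
#' @return A `normalized_matrix`: numeric matrix of the same shape, with the
#'   factors stored in the `size_factors` attribute.
#' @export
normalize_log <- function(counts, factors = size_factors(counts)) {
  check_counts(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0))
    stop("'factors' must be one positive value per sample", call. = FALSE)
  out <- log2(sweep(counts, 2, factors, "/") + 1)
  attr(out, "size_factors") <- factors
  class(out) <- c("normalized_matrix", class(out))
  out
}

#' Per-gene differential expression screen with BH correction
#'
#' Welch's two-sample t-test per gene on normalized values, with the log2
#' fold change taken as the difference of group means (the normalized scale
#' is log2). P-values are Benjamini-Hochberg adjusted across all retained
#' genes. Genes with zero variance in both groups are flagged and assigned
#' p = 1. This screen exists to test the global-null behaviour of the FDR
#' step, not to re-implement a count-model test.
#'
#' @param norm Normalized gene x sample matrix.
#' @param groups Factor or character vector of two group labels, one per
#'   sample. The log2 fold change is `level2 - level1` of `factor(groups)`.
#' @return A data frame (`de_result`) with columns `gene`, `log2fc`,
#'   `pvalue`, `padj`, `zero_variance`.
#' @export
de_screen <- function(norm, groups) {
  stopifnot(is.matrix(norm))
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels", call. = FALSE)
  if (length(groups) != ncol(norm))
    stop("one group label per sample is required", call. = FALSE)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2L || n2 < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)

  x1 <- norm[, groups == levels(groups)[1], drop = FALSE]
  x2 <- norm[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zerovar <- se2 == 0
  p[zerovar] <- 1
  out <- data.frame(gene = rownames(norm), log2fc = m2 - m1, pvalue = p,
                    padj = p.adjust(p, method = "BH"),
                    zero_variance = zerovar, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Principal-component scores of samples
#'
#' Samples are embedded on the top `k` principal axes of the gene-centered
#' normalized matrix (no scaling), as used to check for global group
#' segregation.
#'
#' @param norm Normalized gene x sample matrix.
#' @param k Number of components (default 2).
#' @return A sample x k matrix of scores with a `variance` attribute holding
#'   the per-component variances (non-increasing).
#' @export
pca_scores <- function(norm, k = 2) {
  stopifnot(is.matrix(norm))
  k <- check_count(k, "k", lower = 1L)
  if (ncol(norm) < k + 1L)
    stop(sprintf("need at least %d samples for %d components", k + 1L, k),
         call. = FALSE)
  pc <- prcomp(t(norm), center = TRUE, scale. = FALSE)
  if (k > ncol(pc$x))
    stop("k exceeds the rank of the data", call. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "variance") <- pc$sdev[seq_len(k)]^2
  scores
}

#' Per-sample expression ratio of two genes
#'
#' Elementwise ratio of two genes' normalized values, e.g. the dynorphin
#' ligand-to-receptor ratio `PDYN / OPRK1`. Samples where the denominator is
#' zero are returned as `NA` and flagged.
#'
#' @param norm Normalized gene x sample matrix.
#' @param gene_a Numerator gene id (default `"PDYN"`).
#' @param gene_b Denominator gene id (default `"OPRK1"`).
#' @return Named numeric vector of ratios with attribute `flagged` naming
#'   samples with a zero denominator.
#' @export
expression_ratio <- function(norm, gene_a = "PDYN", gene_b = "OPRK1") {
  stopifnot(is.matrix(norm))
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(norm))
      stop("gene not present in the matrix: ", g, call. = FALSE)
  a <- norm[gene_a, ]; b <- norm[gene_b, ]
  bad <- b == 0
  out <- ifelse(bad, NA_real_, a / b)
  names(out) <- colnames(norm)
  attr(out, "flagged") <- colnames(norm)[bad]
  if (any(bad))
    warning(sum(bad), " sample(s) have zero denominator expression; returned NA",
            call. = FALSE)
  out
}
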