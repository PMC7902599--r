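#' Construct an expression study
#'
#' Bundles a locus-by-sample raw count matrix with its sample sheet.
#'
#' @param counts non-negative integer matrix, rownames = locus ids,
#'   colnames = sample ids.
#' @param samples data frame with columns `sample`, `dataset`, `condition`
#'   (levels `control`, `HS`), `replicate`, `library_size`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(counts, samples) {
  counts <- as.matrix(counts)
  need <- c("sample", "dataset", "condition", "replicate", "library_size")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(colnames(counts)) ||
      !identical(sort(colnames(counts)), sort(as.character(samples$sample))))
    stop("count matrix columns must match sample sheet 'sample' ids")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(samples$library_size <= 0)) stop("library sizes must be positive")
  if (any(colSums(counts) > samples$library_size))
    stop("column sum exceeds declared library size")
  tab <- table(samples$dataset, samples$condition)
  if (any(tab == 0))
    stop("every dataset needs >= 1 replicate per condition")
  structure(list(counts = counts, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$counts), "loci x", ncol(x$counts),
      "samples;", length(unique(x$samples$dataset)), "dataset(s)\n")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' RPM = count / library_size * 1e6, with the library size taken from the
#' sample sheet (total sequenced reads), not the column sum.
#'
#' @param study an `expression_study`.
#' @return numeric matrix of RPM values, same dimensions as the counts.
#' @export
rpm_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  sweep(study$counts, 2, study$samples$library_size, "/") * 1e6
}

#' Drop loci with uniformly low counts
#'
#' A locus is kept iff at least one sample has `min_count` or more reads.
#'
#' @param study an `expression_study`.
#' @param min_count threshold (default 10).
#' @return The filtered `expression_study`.
#' @export
filter_low_counts <- function(study, min_count = 10) {
  stopifnot(inherits(study, "expression_study"))
  keep <- apply(study$counts, 1, max) >= min_count
  study$counts <- study$counts[keep, , drop = FALSE]
  study
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over loci (restricted to
#' loci with all-positive counts) of the ratio of the count to the locus
#' geometric mean across samples.
#'
#' @param counts non-negative count matrix (loci x samples).
#' @return named numeric vector of positive size factors.
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no locus with all-positive counts; consider a pseudo-reference ",
         "(e.g. adding a pseudo-count) before computing size factors")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  names(sf) <- colnames(counts)
  sf
}

# Per-locus method-of-moments NB dispersion shared across the two
# conditions, computed on size-factor-normalized counts. NA when both
# condition variances are undefined.
.mom_dispersion <- function(x1, x2) {
  m1 <- mean(x1); m2 <- mean(x2)
  n1 <- length(x1); n2 <- length(x2)
  num <- 0; den <- 0
  if (n1 > 1) { num <- num + (n1 - 1) * (stats::var(x1) - m1)
                den <- den + (n1 - 1) * m1^2 }
  if (n2 > 1) { num <- num + (n2 - 1) * (stats::var(x2) - m2)
                den <- den + (n2 - 1) * m2^2 }
  if (den <= 0) return(NA_real_)
  num / den
}

#' Negative-binomial Wald test for HS versus control
#'
#' A self-contained NB Wald test on median-of-ratios-normalized counts.
#' Per locus, a dispersion shared across conditions is estimated by the
#' method of moments; because per-locus moment estimates are very noisy at
#' typical replicate numbers, each estimate is moderated by flooring it at
#' the cohort median dispersion (and at `1e-8`), a simplified analogue of
#' the shrinkage used by established DE packages. The log2 fold change is
#' computed from normalized condition means with a pseudo-count of 1/2, its
#' standard error by the delta method from the NB variance, and a two-sided
#' normal p-value is reported with Benjamini-Hochberg adjustment over the
#' tested loci. No LFC shrinkage, outlier refitting, or independent
#' filtering is performed.
#'
#' Loci with all-zero counts in both conditions get NA statistics and are
#' excluded from the multiple-testing adjustment.
#'
#' @param study an `expression_study` (typically one dataset, already
#'   filtered with [filter_low_counts]).
#' @param dataset optional dataset name to subset the study to.
#' @param condition_ref,condition_alt condition labels (default `control`
#'   vs `HS`).
#' @param moderate logical; floor per-locus dispersions at the cohort
#'   median (default TRUE).
#' @return data frame with columns `locus`, `base_mean`, `lfc`, `se`,
#'   `stat`, `p`, `padj`, `mean_norm_ref`, `mean_norm_alt`.
#' @export
nb_wald_test <- function(study, dataset = NULL, condition_ref = "control",
                         condition_alt = "HS", moderate = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  samples <- study$samples
  counts <- study$counts
  if (!is.null(dataset)) {
    sel <- samples$dataset == dataset
    if (!any(sel)) stop("no samples for dataset: ", dataset)
    samples <- samples[sel, , drop = FALSE]
    counts <- counts[, sel, drop = FALSE]
  }
  g1 <- samples$condition == condition_ref
  g2 <- samples$condition == condition_alt
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("need >= 2 replicates per condition for dispersion estimation")
  sf <- median_ratio_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(g2)
  alpha <- vapply(seq_len(nrow(norm)), function(i)
    .mom_dispersion(norm[i, g1], norm[i, g2]), numeric(1))
  defined <- m1 + m2 > 0
  if (moderate) {
    amed <- stats::median(alpha[defined], na.rm = TRUE)
    if (!is.finite(amed)) amed <- 0
    alpha <- pmax(alpha, amed, na.rm = FALSE)
  }
  alpha <- pmax(alpha, 1e-8)
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  se2 <- ((m1 + alpha * m1^2) / (n1 * (m1 + 0.5)^2) +
          (m2 + alpha * m2^2) / (n2 * (m2 + 0.5)^2)) / log(2)^2
  se <- sqrt(se2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  lfc[!defined] <- NA_real_
  se[!defined] <- NA_real_
  stat[!defined] <- NA_real_
  p[!defined] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[defined] <- stats::p.adjust(p[defined], method = "BH")
  data.frame(locus = rownames(counts),
             base_mean = (m1 + m2) / 2,
             lfc = lfc, se = se, stat = stat, p = p, padj = padj,
             mean_norm_ref = m1, mean_norm_alt = m2,
             row.names = NULL)
}

#' Differential-expression flag
#'
#' DEX iff |log2 fold change| >= `lfc_min` and adjusted p < `padj_max`.
#'
#' @param de result of [nb_wald_test].
#' @param lfc_min,padj_max thresholds (defaults 1 and 0.05).
#' @return logical vector (FALSE for loci with NA statistics).
#' @export
call_dex <- function(de, lfc_min = 1, padj_max = 0.05) {
  flag <- abs(de$lfc) >= lfc_min & de$padj < padj_max
  flag[is.na(flag)] <- FALSE
  flag
}

#' Per-dataset condition-mean RPM
#'
#' @param study an `expression_study`.
#' @return data frame `locus`, `dataset`, `condition`, `mean_rpm`
#'   (arithmetic mean over replicates).
#' @export
condition_mean_rpm <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  rpm <- rpm_normalize(study)
  key <- interaction(study$samples$dataset, study$samples$condition,
                     drop = TRUE, sep = "\r")
  means <- sapply(levels(key), function(k)
    rowMeans(rpm[, key == k, drop = FALSE]))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- do.call(rbind, lapply(seq_along(parts), function(j)
    data.frame(locus = rownames(rpm),
               dataset = parts[[j]][1], condition = parts[[j]][2],
               mean_rpm = means[, j], row.names = NULL)))
  out
}

#' Expression-threshold specificity calls
#'
#' Per dataset and locus the condition-mean RPM drives: `pex` (pollen
#' expressed) iff the mean RPM exceeds `rpm_pex` in at least one condition
#' of a pollen dataset; `hpex` iff it exceeds `rpm_hpex`; `present` iff it
#' reaches `rpm_present` in at least one condition. `psx` (pollen specific)
#' iff the locus is PEX in at least one pollen dataset and its mean RPM is
#' below `rpm_sporo_max` in every condition of every sporophytic dataset.
#'
#' @param mean_rpm data frame from [condition_mean_rpm] (possibly several
#'   studies row-bound).
#' @param dataset_types named character vector mapping dataset name to
#'   `"pollen"` or `"sporophytic"`.
#' @param rpm_pex,rpm_hpex,rpm_present thresholds (1, 10, 0.05).
#' @param rpm_sporo_max sporophytic-silence cutoff for the PSX call
#'   (default 1 RPM, the published rule); kept separate from `rpm_pex` so
#'   that tightening the PEX threshold can only shrink the PSX set.
#' @return list with `per_dataset` (locus, dataset, expressed, pex, hpex,
#'   present) and `per_locus` (locus, pex, hpex, psx).
#' @export
call_specificity <- function(mean_rpm, dataset_types, rpm_pex = 1,
                             rpm_hpex = 10, rpm_present = 0.05,
                             rpm_sporo_max = 1) {
  stopifnot(all(mean_rpm$dataset %in% names(dataset_types)),
            all(dataset_types %in% c("pollen", "sporophytic")))
  agg <- function(thr, op = `>`)
    stats::aggregate(op(mean_rpm$mean_rpm, thr),
                     by = list(locus = mean_rpm$locus,
                               dataset = mean_rpm$dataset), FUN = any)
  ex <- agg(rpm_pex)
  hp <- agg(rpm_hpex)
  pr <- agg(rpm_present, op = `>=`)
  per_dataset <- data.frame(
    locus = ex$locus, dataset = ex$dataset,
    expressed = ex$x,
    pex = ex$x & dataset_types[ex$dataset] == "pollen",
    hpex = hp$x & dataset_types[ex$dataset] == "pollen",
    present = pr$x, row.names = NULL)
  loci <- unique(per_dataset$locus)
  pex_any <- tapply(per_dataset$pex, per_dataset$locus, any)[loci]
  hpex_any <- tapply(per_dataset$hpex, per_dataset$locus, any)[loci]
  sporo <- mean_rpm[dataset_types[mean_rpm$dataset] == "sporophytic", ]
  if (nrow(sporo)) {
    low <- tapply(sporo$mean_rpm < rpm_sporo_max, sporo$locus, all)
    sporo_low <- as.logical(low[loci])
    sporo_low[is.na(sporo_low)] <- TRUE
  } else sporo_low <- rep(TRUE, length(loci))
  per_locus <- data.frame(locus = loci,
                          pex = as.logical(pex_any),
                          hpex = as.logical(hpex_any),
                          psx = as.logical(pex_any) & sporo_low,
                          row.names = NULL)
  list(per_dataset = per_dataset, per_locus = per_locus)
}
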