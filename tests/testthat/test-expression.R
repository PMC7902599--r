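make_study <- function(counts, nrep = 3, lib = NULL, dataset = "D1") {
  n <- ncol(counts)
  if (is.null(lib)) lib <- rep(1e6, n)
  cond <- rep(c("control", "HS"), each = n / 2)
  snames <- sprintf("%s_%s_r%d", dataset, cond, rep(seq_len(n / 2), 2))
  colnames(counts) <- snames
  expression_study(counts, data.frame(
    sample = snames, dataset = dataset, condition = cond,
    replicate = rep(seq_len(n / 2), 2), library_size = lib))
}

test_that("RPM normalization scales by declared library size", {
  counts <- matrix(c(500, 0, 1000, 250), 2,
                   dimnames = list(c("a", "b"), NULL))
  st <- make_study(cbind(counts, counts), lib = rep(c(1e6, 2e6), 2))
  rpm <- rpm_normalize(st)
  expect_equal(rpm["a", 1], 500)
  expect_equal(rpm["b", 1], 0)
  expect_equal(rpm["a", 2], 500)  # doubled count, doubled library
  # doubling everything leaves RPM unchanged
  st2 <- make_study(cbind(counts, counts) * 2, lib = rep(c(2e6, 4e6), 2))
  expect_equal(rpm_normalize(st2), rpm_normalize(st))
  expect_error(make_study(cbind(counts, counts), lib = c(0, 1e6, 1e6, 1e6)),
               "positive")
})

test_that("low-count filter keeps a locus iff any sample reaches 10", {
  counts <- rbind(all9 = rep(9, 6), one10 = c(0, 0, 0, 0, 0, 10))
  st <- make_study(counts)
  kept <- filter_low_counts(st)
  expect_equal(rownames(kept$counts), "one10")
  empty <- make_study(counts[0, , drop = FALSE])
  expect_equal(nrow(filter_low_counts(empty)$counts), 0L)
})

test_that("median-of-ratios size factors match hand arithmetic", {
  c1 <- c(10, 100, 40, 7)
  m <- cbind(s1 = c1, s2 = c1)
  expect_equal(unname(median_ratio_size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c1, s2 = 2 * c1)
  expect_equal(unname(median_ratio_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))
  # invariant to locus order
  p <- sample(nrow(m2))
  expect_equal(median_ratio_size_factors(m2[p, ]),
               median_ratio_size_factors(m2))
  expect_error(median_ratio_size_factors(cbind(c(0, 5), c(3, 0))),
               "pseudo-reference")
})

test_that("scaling one sample's counts scales its relative factor", {
  set.seed(105)
  m <- matrix(rnbinom(500 * 4, mu = 100, size = 10), 500)
  sf <- median_ratio_size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  sf2 <- median_ratio_size_factors(m2)
  # factors are defined relative to the per-row geometric-mean reference,
  # which absorbs c^(1/n); the invariant is on between-sample ratios
  expect_equal((sf2[2] / sf2[1]) / (sf[2] / sf[1]), 3, tolerance = 0.02)
  expect_equal(sf2[3] / sf2[1], sf[3] / sf[1], tolerance = 0.02)
  expect_equal(sf2[4] / sf2[1], sf[4] / sf[1], tolerance = 0.02)
})

test_that("degenerate inputs of the Wald test behave as specified", {
  counts <- rbind(flat = rep(50, 6), zero = rep(0, 6),
                  live = rep(c(120, 80, 100), 2))
  st <- make_study(counts)
  de <- nb_wald_test(st)
  expect_equal(de$lfc[de$locus == "flat"], 0)
  expect_gt(de$p[de$locus == "flat"], 0.99)
  expect_true(is.na(de$lfc[de$locus == "zero"]))
  expect_true(is.na(de$padj[de$locus == "zero"]))  # excluded from BH
  # BH: padj >= p, monotone in p rank
  ok <- !is.na(de$p)
  expect_true(all(de$padj[ok] >= de$p[ok] - 1e-12))
  expect_error(nb_wald_test(make_study(counts[, c(1, 4), drop = FALSE],
                                       nrep = 1)),
               "replicates")
})

test_that("DEX rule applies both thresholds with the documented boundaries", {
  de <- data.frame(lfc = c(1, 0.99, -3, 2), padj = c(0.049, 0.001, 0.2, 0.05))
  expect_equal(call_dex(de), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("specificity thresholds separate PEX, hPEX and PSX", {
  mean_rpm <- rbind(
    data.frame(locus = "A", dataset = "MP", condition = c("control", "HS"),
               mean_rpm = c(1.2, 0.8)),
    data.frame(locus = "A", dataset = "CL", condition = c("control", "HS"),
               mean_rpm = c(0, 0)),
    data.frame(locus = "B", dataset = "MP", condition = c("control", "HS"),
               mean_rpm = c(15, 2)),
    data.frame(locus = "B", dataset = "CL", condition = c("control", "HS"),
               mean_rpm = c(0.2, 0.01)),
    data.frame(locus = "C", dataset = "MP", condition = c("control", "HS"),
               mean_rpm = c(30, 25)),
    data.frame(locus = "C", dataset = "CL", condition = c("control", "HS"),
               mean_rpm = c(5, 4)))
  sp <- call_specificity(mean_rpm, c(MP = "pollen", CL = "sporophytic"))
  pl <- sp$per_locus
  expect_true(pl$pex[pl$locus == "A"])
  expect_true(pl$psx[pl$locus == "A"])   # leaf silent
  expect_true(pl$hpex[pl$locus == "B"])
  expect_true(pl$psx[pl$locus == "B"])   # leaf < 1 RPM in both conditions
  expect_true(pl$pex[pl$locus == "C"])
  expect_false(pl$psx[pl$locus == "C"])  # leaf-expressed
  pd <- sp$per_dataset
  expect_true(pd$present[pd$locus == "B" & pd$dataset == "CL"])
  expect_false(pd$present[pd$locus == "A" & pd$dataset == "CL"])
})

test_that("strong planted effects are recovered with high sensitivity and low FDR", {
  set.seed(106)
  n <- 2000; nde <- 200; nrep <- 3
  base <- 200
  lfc <- rep(0, n)
  lfc[seq_len(nde)] <- sample(c(-3, 3), nde, replace = TRUE)
  mu_hs <- base * 2^lfc
  counts <- cbind(
    matrix(rnbinom(n * nrep, mu = base, size = 1 / 0.05), n),
    matrix(rnbinom(n * nrep, mu = mu_hs, size = 1 / 0.05), n))
  rownames(counts) <- sprintf("L%04d", seq_len(n))
  st <- make_study(counts)
  de <- nb_wald_test(st)
  dex <- call_dex(de)
  sens <- mean(dex[seq_len(nde)])
  fdr <- sum(dex[-seq_len(nde)]) / max(1, sum(dex))
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("Wald results track an established NB DE implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(107)
  n <- 300; nrep <- 3
  lfc <- c(rep(0, 250), sample(c(-2, 2), 50, replace = TRUE))
  base <- exp(runif(n, log(20), log(500)))
  counts <- cbind(
    matrix(rnbinom(n * nrep, mu = base, size = 1 / 0.05), n),
    matrix(rnbinom(n * nrep, mu = base * 2^lfc, size = 1 / 0.05), n))
  rownames(counts) <- sprintf("L%03d", seq_len(n))
  st <- make_study(counts)
  de <- nb_wald_test(st)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      st$counts, data.frame(condition = factor(st$samples$condition,
                                               c("control", "HS"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  expect_gt(cor(de$lfc, res$log2FoldChange, use = "complete.obs"), 0.95)
  # decisions agree on the vast majority of loci at the published rule
  dex_pkg <- call_dex(de)
  dex_ref <- !is.na(res$padj) & res$padj < 0.05 &
    abs(res$log2FoldChange) >= 1
  expect_gt(mean(dex_pkg == dex_ref), 0.93)
})
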