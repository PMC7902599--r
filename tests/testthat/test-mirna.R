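rc <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("expectation penalties follow the published scheme", {
  set.seed(109)
  mir <- random_dna(21)
  site <- rc(mir)
  expect_equal(score_alignment(mir, site)$expectation, 0)

  # G:U wobble at miRNA position 5 (inside the 2-13 seed): 0.5 x 2
  mir_gu <- mir
  substr(mir_gu, 5, 5) <- "G"
  site_gu <- rc(mir_gu)
  j <- 21 - 5 + 1
  substr(site_gu, j, j) <- "T"  # G:U pair instead of G:C
  expect_equal(score_alignment(mir_gu, site_gu)$expectation, 1.0)

  # mismatch at position 20 (outside the seed): 1.0, undoubled
  site_mm <- rc(mir)
  j <- 21 - 20 + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b20 <- substr(mir, 20, 20)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(comp[[b20]], if (b20 == "G") "T", if (b20 == "T") "G"))
  substr(site_mm, j, j) <- bad[1]
  expect_equal(score_alignment(mir, site_mm)$expectation, 1.0)

  # same mismatch at position 10 doubles and flips the mode call
  site_c <- rc(mir)
  j <- 21 - 10 + 1
  b10 <- substr(mir, 10, 10)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(comp[[b10]], if (b10 == "G") "T", if (b10 == "T") "G"))
  substr(site_c, j, j) <- bad[1]
  expect_equal(score_alignment(mir, site_c)$expectation, 2.0)
})

test_that("U and T are interchangeable and short miRNAs are rejected", {
  mir <- "UGACCUAGGCAAUCCAUGUAC"
  tgt <- paste0(random_dna(30), rc(chartr("U", "T", mir)), random_dna(30))
  hits <- find_mirna_targets(c(m1 = mir), c(L1 = tgt))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$mode, "cleavage")
  expect_error(find_mirna_targets(c(bad = "ACGUACGUACGU"), c(L = tgt)),
               "15 nt")
})

test_that("central mismatches call translational inhibition", {
  set.seed(110)
  mir <- random_dna(21)
  site <- rc(mir)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  j <- 21 - 10 + 1
  b10 <- substr(mir, 10, 10)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(comp[[b10]], if (b10 == "G") "T", if (b10 == "T") "G"))
  substr(site, j, j) <- bad[1]
  tgt <- paste0(random_dna(40), site, random_dna(40))
  hits <- find_mirna_targets(c(m = mir), c(L = tgt))
  expect_equal(hits$mode, "translational_inhibition")
  expect_equal(hits$expectation, 2)
})

test_that("window scan equals the exhaustive ungapped oracle", {
  set.seed(111)
  for (rep in 1:50) {
    m <- sample(15:24, 1)
    mir <- random_dna(m)
    tgt <- random_dna(sample(60:200, 1))
    if (runif(1) < 0.5) {
      pos <- sample(nchar(tgt) - m, 1)
      s <- rc(mir)
      for (k in sample(m, sample(0:2, 1)))
        substr(s, k, k) <- sample(c("A", "C", "G", "T"), 1)
      substr(tgt, pos, pos + m - 1) <- s
    }
    want <- oracle_mirna_best(mir, tgt)
    hits <- find_mirna_targets(c(m = mir), c(L = tgt),
                               expectation_max = 1e9, allow_gap = FALSE)
    expect_equal(hits$expectation, want$expectation)
    expect_equal(hits$start, want$start)
  }
})

test_that("lowering the expectation cutoff never adds hits", {
  set.seed(112)
  mirs <- stats::setNames(vapply(1:4, function(i) random_dna(21),
                                 character(1)),
                          paste0("m", 1:4))
  tgts <- stats::setNames(vapply(1:6, function(i) random_dna(300),
                                 character(1)),
                          paste0("L", 1:6))
  tgts[1] <- paste0(substr(tgts[1], 1, 50), rc(mirs[1]),
                    substr(tgts[1], 72, 300))
  cuts <- c(0, 1, 2, 3, 5, 10)
  sizes <- vapply(cuts, function(cc)
    nrow(find_mirna_targets(mirs, tgts, expectation_max = cc)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("single-bulge alignments are scored with the gap penalty", {
  set.seed(113)
  mir <- random_dna(21)
  site <- rc(mir)
  # bulge one target base between the pairs of miRNA positions 16/17,
  # outside the seed: gap penalty 2
  j <- 21 - 16 + 1
  site_b <- paste0(substr(site, 1, j), "A", substr(site, j + 1, 21))
  got <- score_alignment(mir, site_b)
  expect_lte(got$expectation, 2)
  tgt <- paste0(random_dna(30), site_b, random_dna(30))
  hits <- find_mirna_targets(c(m = mir), c(L = tgt), expectation_max = 3)
  expect_equal(nrow(hits), 1L)
  expect_lte(hits$expectation, 2)
})
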