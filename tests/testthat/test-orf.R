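test_that("hand-checked ORFs are reported correctly", {
  o <- find_orfs("ATGAAATAA", "forward")
  expect_equal(nrow(o), 1L)
  expect_equal(o$peptide_length, 2L)
  expect_equal(o$start, 1L)
  expect_equal(o$end, 9L)
  # span identity: end - start + 1 = 3 * (peptide + 1)
  expect_equal(o$end - o$start + 1L, 3L * (o$peptide_length + 1L))

  expect_equal(nrow(find_orfs("CCCCCCCCC", "forward")), 0L)
  expect_equal(nrow(find_orfs("", "both")), 0L)
  # an open-ended ATG run without an in-frame stop is not an ORF
  expect_equal(nrow(find_orfs("ATGAAAAAAAAA", "forward")), 0L)
  # N codons never act as start or stop
  expect_equal(nrow(find_orfs("ATGNAATAA", "forward")), 1L)
  expect_equal(find_orfs("ATGNAATAA", "forward")$peptide_length, 2L)
  expect_error(find_orfs("ATGXAA"), "A/C/G/T/N")
})

test_that("reverse-strand ORFs are found in both-strand mode", {
  fwd <- "ATGAAATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_equal(nrow(find_orfs(rc, "forward")), 0L)
  o <- find_orfs(rc, "both")
  expect_equal(nrow(o), 1L)
  expect_equal(o$strand, "-")
  expect_equal(o$peptide_length, 2L)
})

test_that("longest ORF per start chain: nested ATGs collapse to the first", {
  # ATG atg aaa TAA: inner ATG shares the stop; only the outer is reported
  o <- find_orfs("ATGATGAAATAA", "forward")
  o0 <- o[o$frame == 0, ]
  expect_equal(nrow(o0), 1L)
  expect_equal(o0$start, 1L)
  expect_equal(o0$peptide_length, 3L)
})

test_that("ORF finder matches the naive six-frame oracle on random sequences", {
  set.seed(103)
  for (rep in 1:60) {
    s <- random_dna(sample(60:600, 1))
    got <- find_orfs(s, "both")
    want <- oracle_orfs(s)
    ord <- function(d) d[order(d$strand, d$frame, d$start), , drop = FALSE]
    got <- ord(got); want <- ord(want)
    expect_equal(got$strand, want$strand)
    for (col in c("frame", "start", "end", "peptide_length"))
      expect_equal(as.numeric(got[[col]]), as.numeric(want[[col]]))
  }
})

test_that("biotype rules compose as published", {
  # short: strictly under 200 nt; exactly 200 nt is long (tie -> lncRNA)
  expect_equal(as.character(classify_biotype(180, 0, 1000, FALSE)), "short")
  expect_equal(as.character(classify_biotype(200, 0, 1000, TRUE)), "lncRNA")
  expect_equal(as.character(classify_biotype(800, 120, 1000, FALSE)),
               "orf_coding")
  expect_equal(as.character(classify_biotype(800, 100, 100, TRUE)),
               "orf_coding")
  expect_equal(as.character(classify_biotype(800, 99, 600, FALSE)),
               "lincRNA")
  # boundary: exactly 500 bp away qualifies ("500 or more bp away")
  expect_equal(as.character(classify_biotype(800, 99, 500, FALSE)),
               "lincRNA")
  expect_equal(as.character(classify_biotype(800, 99, 499, FALSE)),
               "lncRNA")
  expect_equal(as.character(classify_biotype(800, 99, 600, TRUE)),
               "lncRNA")
  expect_error(classify_biotype(800, 10, NA, FALSE), "distance_to_gene")
})

test_that("classification is a total partition over a cohort", {
  set.seed(104)
  n <- 200
  cls <- classify_biotype(sample(100:2000, n, TRUE), sample(0:150, n, TRUE),
                          sample(0:1500, n, TRUE), sample(c(TRUE, FALSE),
                                                          n, TRUE))
  expect_false(any(is.na(cls)))
  expect_equal(sum(table(cls)), n)
})

test_that("homology bins respect the E-value filter and identity edges", {
  hits <- data.frame(
    qseqid = c("L1", "L2", "L3", "L4", "L4"),
    sseqid = "P",
    pident = c(98.5, 80, 96.5, 55, 99),
    evalue = c(1e-20, 1e-6, 1e-9, 1e-30, 1e-3))
  out <- parse_homology_table(hits, queries = c("L1", "L2", "L3", "L4", "L5"))
  bin <- stats::setNames(as.character(out$bin), out$query)
  expect_equal(bin[["L1"]], "full")
  expect_equal(bin[["L2"]], "none")    # E = 1e-6 fails the 1e-7 cutoff
  expect_equal(bin[["L3"]], "partial") # 96.5 sits below the 97 edge
  # best hit for L4 is the E=1e-30 row; its 99%-identity row fails E
  expect_equal(bin[["L4"]], "partial")
  expect_equal(bin[["L5"]], "none")
  expect_equal(out$best_identity[out$query == "L4"], 55)
})

test_that("malformed homology rows raise an error naming the line", {
  hits <- data.frame(qseqid = c("a", "b"), sseqid = "P",
                     pident = c("90", "oops"), evalue = c("1e-9", "1e-9"))
  expect_error(parse_homology_table(hits), "line.*2")
  expect_error(parse_homology_table(data.frame(qseqid = "a")), "missing")
})
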