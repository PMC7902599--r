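test_that("exonic overlap chains define loci", {
  ex <- data.frame(
    tcons_id = c("A", "B", "C", "D"),
    chrom = "chr1",
    start = c(100, 150, 280, 5000),
    end = c(200, 300, 400, 5100),
    strand = "+")
  g <- group_into_loci(ex)
  ids <- tapply(g$xloc_id, g$tcons_id, unique)
  # A-B overlap directly; B-C overlap; A and C do not, but chain merges all
  expect_equal(ids[["A"]], ids[["B"]])
  expect_equal(ids[["B"]], ids[["C"]])
  expect_false(ids[["A"]] == ids[["D"]])
})

test_that("loci never span chromosomes and ids follow leftmost order", {
  ex <- data.frame(
    tcons_id = c("A", "B"),
    chrom = c("chr2", "chr1"),
    start = c(100, 100), end = c(200, 200), strand = "+")
  g <- group_into_loci(ex)
  expect_equal(length(unique(g$xloc_id)), 2L)
  # chr1 transcript gets the first id
  expect_equal(g$xloc_id[g$tcons_id == "B"], "XLOC_000001")
})

test_that("strand is consulted only when both strands are known", {
  ex <- data.frame(
    tcons_id = c("P", "M", "U"),
    chrom = "chr1",
    start = c(100, 150, 180), end = c(200, 260, 320),
    strand = c("+", "-", "*"))
  g <- group_into_loci(ex)
  ids <- tapply(g$xloc_id, g$tcons_id, unique)
  # + and - never merge directly, but the unknown-strand transcript
  # bridges whatever it overlaps
  expect_equal(ids[["M"]], ids[["U"]])
  ex2 <- ex[ex$tcons_id != "U", ]
  g2 <- group_into_loci(ex2)
  ids2 <- tapply(g2$xloc_id, g2$tcons_id, unique)
  expect_false(ids2[["P"]] == ids2[["M"]])
})

test_that("grouping matches a connected-components oracle and is idempotent", {
  set.seed(101)
  for (rep in 1:25) {
    ex <- random_exon_table(sample(4:10, 1))
    g <- group_into_loci(ex)
    comp <- oracle_components(ex)
    got <- tapply(g$xloc_id, g$tcons_id, unique)[names(comp)]
    # same partition: co-membership must agree pairwise
    for (i in seq_along(comp)) for (j in seq_along(comp))
      expect_equal(got[i] == got[j], comp[i] == comp[j])
    g2 <- group_into_loci(g)
    expect_identical(g2$xloc_id, g$xloc_id)
  }
})

test_that("novelty classification follows the two-reference rule", {
  tair <- annotation_set(data.frame(chrom = "chr1", start = 1000, end = 2000,
                                    biotype = "protein_coding"))
  araport <- annotation_set(data.frame(
    chrom = "chr1", start = c(1000, 5000), end = c(2000, 6000),
    biotype = c("protein_coding", "other_gene")))
  ex <- data.frame(
    tcons_id = c("T1", "T2", "T3"), chrom = "chr1",
    start = c(2000, 5500, 9000),   # T1: 1-bp overlap with the TAIR gene
    end = c(2400, 5800, 9400),
    strand = "+", xloc_id = c("X1", "X2", "X3"))
  nov <- classify_novelty(ex, tair, araport)
  expect_equal(as.character(nov$novelty[match(c("X1", "X2", "X3"),
                                              nov$xloc_id)]),
               c("known", "recent", "novel"))
})

test_that("gene distance is the gap between spans, zero on overlap", {
  genes <- annotation_set(data.frame(chrom = "chr1", start = 1701, end = 1900,
                                     biotype = "protein_coding"))
  ex <- data.frame(tcons_id = "T", chrom = "chr1", start = 1001, end = 1200,
                   strand = "+", xloc_id = "X")
  expect_equal(distance_to_nearest_gene(ex, genes)$distance_to_gene, 500)
  ex$end <- 1800
  expect_equal(distance_to_nearest_gene(ex, genes)$distance_to_gene, 0)
  empty <- annotation_set(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), biotype = character()))
  expect_warning(d <- distance_to_nearest_gene(ex, empty), "undefined")
  expect_true(is.na(d$distance_to_gene))
})

test_that("gene distance equals a linear-scan oracle on random instances", {
  set.seed(102)
  for (rep in 1:40) {
    ng <- sample(1:15, 1)
    gs <- sample(1:20000, ng)
    ge <- gs + sample(50:500, ng, replace = TRUE)
    genes <- annotation_set(data.frame(chrom = "chr1", start = gs, end = ge,
                                       biotype = "protein_coding"))
    ls <- sample(1:20000, 1); le <- ls + sample(50:800, 1)
    ex <- data.frame(tcons_id = "T", chrom = "chr1", start = ls, end = le,
                     strand = "+", xloc_id = "X")
    expect_equal(distance_to_nearest_gene(ex, genes)$distance_to_gene,
                 oracle_min_gap(ls, le, gs, ge))
  }
})

test_that("TE overlap is exonic: intronic TEs do not count", {
  # two exons with an intron 201..799
  ex <- data.frame(tcons_id = "T", chrom = "chr1",
                   start = c(100, 800), end = c(200, 900),
                   strand = "+", xloc_id = "X")
  te_intron <- annotation_set(data.frame(chrom = "chr1", start = 300,
                                         end = 700, biotype = "TE"))
  te_edge <- annotation_set(data.frame(chrom = "chr1", start = 200,
                                       end = 350, biotype = "TE"))
  none <- annotation_set(data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), biotype = character()))
  expect_false(te_overlap(ex, te_intron)$te_overlap)
  expect_true(te_overlap(ex, te_edge)$te_overlap)   # 1-bp exon-edge overlap
  expect_false(te_overlap(ex, none)$te_overlap)
})

test_that("spliced sequences respect exon order and strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTTACGTACGT"))
  ex <- data.frame(tcons_id = c("T", "T"), chrom = "chr1",
                   start = c(1, 10), end = c(3, 12), strand = "+")
  expect_equal(as.character(spliced_sequences(ex, genome)[["T"]]), "AAATTT")
  ex$strand <- "-"
  expect_equal(as.character(spliced_sequences(ex, genome)[["T"]]), "AAATTT")
  ex2 <- data.frame(tcons_id = "S", chrom = "chr1", start = 4, end = 9,
                    strand = "-")
  expect_equal(as.character(spliced_sequences(ex2, genome)[["S"]]),
               "CCCGGG")
})

test_that("exon tables are validated", {
  bad <- data.frame(tcons_id = "T", chrom = "chr1", start = 10, end = 5,
                    strand = "+")
  expect_error(group_into_loci(bad), "start > end")
  mixed <- data.frame(tcons_id = "T", chrom = "chr1",
                      start = c(1, 10), end = c(5, 20),
                      strand = c("+", "-"))
  expect_error(group_into_loci(mixed), "mixed strands")
})
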