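test_that("configuration invariants are enforced", {
  expect_error(sim_config(class_mix = c(short = 0.5, lncRNA = 0.4,
                                        lincRNA = 0.2, orf_coding = 0.1)),
               "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(planted_lfc = Inf), "finite")
  expect_error(sim_config(de_fraction = 1.2), "fractions")
})

test_that("identical configurations give byte-identical output files", {
  cfg <- sim_config(seed = 21, n_novel_loci = 25, n_reference_genes = 40,
                    n_te = 25, n_chromosomes = 2, chrom_length = 8e5)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_xloc_sim(simulate_xloc_study(cfg), d1)
  write_xloc_sim(simulate_xloc_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every transcript maps to exactly one ground-truth locus", {
  sim <- small_sim()
  tx <- unique(sim$exons[, c("tcons_id", "xloc_id")])
  expect_false(any(duplicated(tx$tcons_id)))
  expect_true(all(tx$xloc_id %in% sim$truth$xloc_id))
  expect_false(any(duplicated(sim$truth$xloc_id)))
})

test_that("generated features respect genome bounds and placement rules", {
  sim <- small_sim()
  chrl <- Biostrings::width(sim$genome)
  names(chrl) <- names(sim$genome)
  g <- sim$tair_like
  expect_true(all(GenomicRanges::start(g) >= 1))
  expect_true(all(GenomicRanges::end(g) <=
                  chrl[as.character(GenomicRanges::seqnames(g))]))
  expect_true(all(sim$exons$end <= chrl[sim$exons$chrom]))
  # planted lincRNAs sit >= 500 bp from genes and clear of TEs
  d <- distance_to_nearest_gene(sim$exons, sim$tair_like)
  te <- te_overlap(sim$exons, sim$te_set)
  linc <- sim$truth$xloc_id[sim$truth$class == "lincRNA"]
  expect_true(all(d$distance_to_gene[d$xloc_id %in% linc] >= 500))
  expect_false(any(te$te_overlap[te$xloc_id %in% linc]))
  # planted non-linc lncRNAs violate at least one criterion
  lnc <- sim$truth$xloc_id[sim$truth$class == "lncRNA"]
  viol <- d$distance_to_gene[match(lnc, d$xloc_id)] < 500 |
    te$te_overlap[match(lnc, te$xloc_id)]
  expect_true(all(viol))
})

test_that("planted ORFs and lengths agree with an independent ORF scan", {
  sim <- small_sim()
  tl <- transcript_lengths(sim$exons)
  tl <- tl[order(tl$xloc_id, -tl$spliced_length, tl$tcons_id), ]
  rep_tx <- tl[!duplicated(tl$xloc_id), ]
  seqs <- spliced_sequences(
    sim$exons[sim$exons$tcons_id %in% rep_tx$tcons_id, ], sim$genome)
  for (cls in c("orf_coding", "short")) {
    ids <- sim$truth$xloc_id[sim$truth$class == cls]
    ids <- sample(ids, min(6, length(ids)))
    for (x in ids) {
      tid <- rep_tx$tcons_id[rep_tx$xloc_id == x]
      s <- as.character(seqs[[tid]])
      o <- oracle_orfs(s)
      if (cls == "orf_coding") {
        expect_equal(max(o$peptide_length),
                     sim$truth$peptide[sim$truth$xloc_id == x])
      } else {
        expect_lte(nchar(s), 199)
      }
    }
  }
})

test_that("a degenerate class mix forces every transcript short", {
  cfg <- sim_config(seed = 5, n_novel_loci = 15, n_reference_genes = 20,
                    n_te = 10, n_chromosomes = 1, chrom_length = 6e5,
                    class_mix = c(short = 1, lncRNA = 0, lincRNA = 0,
                                  orf_coding = 0),
                    mirna_target_fraction = 0)
  gen <- generate_genome_and_annotation(cfg)
  tx <- generate_novel_transcripts(cfg, gen)
  tl <- transcript_lengths(tx$exons)
  expect_true(all(tl$spliced_length <= 199))
})

test_that("zero TEs means no TE-overlap ground truth", {
  cfg <- sim_config(seed = 6, n_novel_loci = 15, n_reference_genes = 20,
                    n_te = 0, n_chromosomes = 1, chrom_length = 6e5,
                    class_mix = c(short = 0, lncRNA = 0.5, lincRNA = 0.3,
                                  orf_coding = 0.2))
  gen <- generate_genome_and_annotation(cfg)
  tx <- generate_novel_transcripts(cfg, gen)
  ov <- te_overlap(tx$exons, gen$te_set)
  lnc <- tx$truth$xloc_id[tx$truth$class == "lncRNA"]
  # without TEs the only lincRNA violation left is gene proximity
  d <- distance_to_nearest_gene(tx$exons, gen$tair_like)
  expect_true(all(d$distance_to_gene[match(lnc, d$xloc_id)] < 500))
  expect_false(any(ov$te_overlap))
})

test_that("an undersized genome raises a sizing error", {
  cfg <- sim_config(seed = 7, n_novel_loci = 200, n_reference_genes = 200,
                    n_chromosomes = 1, chrom_length = 1e5)
  expect_error(generate_genome_and_annotation(cfg), "too short")
})

test_that("requested multi-isoform loci appear in the GTF", {
  sim <- small_sim()
  tx <- unique(sim$exons[, c("tcons_id", "xloc_id")])
  n_multi <- sum(table(tx$xloc_id) >= 2)
  want <- round(sim$config$multi_isoform_fraction *
                sim$config$n_novel_loci)
  expect_equal(n_multi, want)
  expect_equal(sum(sim$truth$multi_isoform), want)
})

test_that("null fold changes give near-zero empirical mean LFC", {
  cfg <- sim_config(seed = 31, n_novel_loci = 40, n_reference_genes = 50,
                    n_te = 30, n_chromosomes = 2, chrom_length = 1e6,
                    de_fraction = 0)
  gen <- generate_genome_and_annotation(cfg)
  tx <- generate_novel_transcripts(cfg, gen)
  cnt <- generate_counts(cfg, tx$truth)
  st <- cnt$studies$MP_HS
  rpm <- rpm_normalize(st)
  ctrl <- rowMeans(rpm[, st$samples$condition == "control"])
  hs <- rowMeans(rpm[, st$samples$condition == "HS"])
  lfc <- log2((hs + 0.5) / (ctrl + 0.5))
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("pollen-specific loci are silent in the sporophytic dataset", {
  sim <- small_sim()
  st <- sim$studies$CL_HS
  rpm <- rpm_normalize(st)
  psx <- sim$truth$xloc_id[sim$truth$psx]
  expect_true(all(rpm[psx, ] < 1))
})

test_that("homology tables encode the planted strata", {
  sim <- small_sim()
  lin <- read_lineages(sim$homology$lineages)
  focal <- lin[["Arabidopsis thaliana"]]
  hits <- sim$homology$hits
  pass <- hits[hits$evalue <= 1e-5 &
               hits$subject_taxon != "Arabidopsis thaliana", ]
  for (x in sim$truth$xloc_id) {
    stratum <- sim$truth$stratum[sim$truth$xloc_id == x]
    hx <- pass[pass$query == x, ]
    if (stratum == "Arabidopsis thaliana") {
      expect_equal(nrow(hx), 0L)
    } else {
      expect_gt(nrow(hx), 0L)
      lcas <- vapply(hx$subject_taxon, function(tx)
        lca_node(lin[[tx]], focal)$node, character(1))
      expect_true(all(lcas == stratum))
    }
  }
})
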