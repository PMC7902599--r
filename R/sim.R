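#' @title Synthetic pollen-XLOC study generator
#'
#' @description Generates every input of the characterization pipeline with
#' known ground truth: a random genome with non-overlapping reference genes
#' and transposable elements, novel intergenic loci of planted biotype
#' classes and novelty status, negative-binomial count matrices for several
#' RNA-seq datasets (three pollen, one leaf; control vs heat stress, three
#' replicates each) with planted fold changes and pollen-specific
#' expression, ribosome P-site tracks with planted 3-nt periodicity,
#' homology hit tables with planted phylostrata, and mature miRNAs with
#' planted target sites.
#'
#' All generators draw from a single pseudo-random stream seeded once from
#' the configuration, in a fixed order (layout and classes, genome bases,
#' transcript sequences and planted sites, counts per dataset, P-site
#' tracks, homology tables, protein-hit tables), so outputs are reproducible
#' and adding later stages never perturbs earlier ones.
#'
#' @name synthetic-data
NULL

.default_datasets <- function() {
  data.frame(
    dataset = c("MP_HS", "MP_HotCold", "GP_HS", "CL_HS"),
    type = c("pollen", "pollen", "pollen", "sporophytic"),
    library_size = c(63.7e6, 30.7e6, 101.6e6, 60.7e6),
    stranded = c(FALSE, FALSE, TRUE, FALSE),
    has_rpf = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

.default_lineages <- function() {
  root <- "cellular organisms;Eukaryota;Viridiplantae;Streptophyta;Spermatophyta;Magnoliopsida"
  eud <- paste0(root, ";Eudicotyledons")
  bra <- paste0(eud, ";Brassicales;Brassicaceae")
  cam <- paste0(bra, ";Camelineae")
  data.frame(
    taxon = c("Arabidopsis thaliana", "Arabidopsis lyrata",
              "Arabidopsis halleri", "Capsella rubella", "Camelina sativa",
              "Brassica rapa", "Eutrema salsugineum",
              "Tarenaya hassleriana", "Carica papaya",
              "Solanum lycopersicum", "Vitis vinifera",
              "Oryza sativa", "Zea mays"),
    lineage = c(
      paste0(cam, ";Arabidopsis;Arabidopsis thaliana"),
      paste0(cam, ";Arabidopsis;Arabidopsis lyrata"),
      paste0(cam, ";Arabidopsis;Arabidopsis halleri"),
      paste0(cam, ";Capsella;Capsella rubella"),
      paste0(cam, ";Camelina;Camelina sativa"),
      paste0(bra, ";Brassiceae;Brassica;Brassica rapa"),
      paste0(bra, ";Eutremeae;Eutrema;Eutrema salsugineum"),
      paste0(eud, ";Brassicales;Cleomaceae;Tarenaya;Tarenaya hassleriana"),
      paste0(eud, ";Brassicales;Caricaceae;Carica;Carica papaya"),
      paste0(eud, ";Solanales;Solanum;Solanum lycopersicum"),
      paste0(eud, ";Vitales;Vitis;Vitis vinifera"),
      paste0(root, ";Liliopsida;Oryza;Oryza sativa"),
      paste0(root, ";Liliopsida;Zea;Zea mays")),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the study design that motivates the package: a cohort
#' of 312 intergenic loci with the published class mix (3 short, 248
#' lncRNA, 38 lincRNA, 29 ORF-coding), 246/312 recently annotated, 41
#' multi-isoform loci, four RNA-seq datasets (MP_HS, MP_HotCold, GP_HS
#' pollen and CL_HS cauline leaf; control vs HS, 3 replicates, library
#' sizes 63.7/30.7/101.6/60.7 million reads), 230/312 pollen-specific loci
#' and 61/312 expressed in germinating pollen. Library sizes are jittered
#' +/- 10 percent across replicates so size factors differ from 1.
#'
#' @param seed integer seed for the single pseudo-random stream.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_reference_genes,n_te numbers of reference protein-coding genes
#'   and transposable elements.
#' @param n_novel_loci number of planted intergenic loci.
#' @param class_mix named proportions over short/lncRNA/lincRNA/orf_coding
#'   (must sum to 1).
#' @param recent_fraction fraction of loci annotated in the updated
#'   ("Araport11-like") reference.
#' @param multi_isoform_fraction fraction of loci with >= 2 isoforms.
#' @param datasets data frame describing the RNA-seq datasets (columns
#'   `dataset`, `type`, `library_size`, `stranded`, `has_rpf`).
#' @param replicates_per_condition replicates per condition (default 3).
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param de_fraction per-pollen-dataset fraction of expressed loci given a
#'   planted fold change under HS.
#' @param planted_lfc planted |log2 fold change| for DE loci.
#' @param psx_fraction fraction of loci that are pollen-specific.
#' @param gp_expressed_fraction fraction expressed in germinating pollen.
#' @param rpm_range range of planted baseline pollen RPM (log-uniform).
#' @param boundary_margin multiplicative guard band kept around the RPM
#'   decision thresholds (1 and 10) when drawing planted means, so planted
#'   truth is well-separated from the calls.
#' @param psite_signal_rate,psite_noise_rate mean P-site counts per
#'   in-frame / off-frame position.
#' @param translated_fraction fraction of ORF-coding, GP-expressed loci
#'   that are planted as translated.
#' @param rpf_library_size total reads of the RPF libraries.
#' @param n_mirna,mirna_length,mirna_target_fraction,ti_fraction mature
#'   miRNA count and length, fraction of loci given a target site, and
#'   fraction of sites in translational-inhibition mode.
#' @param stratum_weights named weights over focal-lineage nodes for
#'   planted phylostrata.
#' @param protein_hit_fraction fraction of loci with a planted protein
#'   homology hit (blastx-style table).
#' @param unknown_strand_fraction fraction of non-coding loci whose
#'   transcripts carry no strand information.
#' @param lineages lineage table (`taxon`, `lineage`) used for homology
#'   simulation; the last field of the first row's lineage is the focal
#'   species.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4, chrom_length = 1.6e6,
                       n_reference_genes = 400, n_te = 250,
                       n_novel_loci = 312,
                       class_mix = c(short = 3, lncRNA = 248,
                                     lincRNA = 38, orf_coding = 29) / 318,
                       recent_fraction = 246 / 312,
                       multi_isoform_fraction = 41 / 312,
                       datasets = .default_datasets(),
                       replicates_per_condition = 3,
                       nb_dispersion = 0.05,
                       de_fraction = 0.15,
                       planted_lfc = 2,
                       psx_fraction = 230 / 312,
                       gp_expressed_fraction = 61 / 312,
                       rpm_range = c(4, 400),
                       boundary_margin = 1.4,
                       psite_signal_rate = 4,
                       psite_noise_rate = 0.002,
                       translated_fraction = 0.6,
                       rpf_library_size = 2e7,
                       n_mirna = 20, mirna_length = 21,
                       mirna_target_fraction = 50 / 312,
                       ti_fraction = 0.2,
                       stratum_weights = c("Arabidopsis thaliana" = 180,
                                           "Arabidopsis" = 68,
                                           "Camelineae" = 15,
                                           "Brassicaceae" = 38,
                                           "Brassicales" = 2,
                                           "Eudicotyledons" = 5,
                                           "Magnoliopsida" = 4),
                       protein_hit_fraction = 116 / 312,
                       unknown_strand_fraction = 0.2,
                       lineages = .default_lineages()) {
  cfg <- as.list(environment())
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!setequal(names(class_mix),
                c("short", "lncRNA", "lincRNA", "orf_coding")))
    stop("class_mix needs names short/lncRNA/lincRNA/orf_coding")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (!is.finite(planted_lfc)) stop("planted_lfc must be finite")
  counts <- c(n_chromosomes, chrom_length, n_reference_genes, n_te,
              n_novel_loci, replicates_per_condition, n_mirna)
  if (any(counts < 0)) stop("counts must be non-negative")
  fr <- c(recent_fraction, multi_isoform_fraction, de_fraction,
          psx_fraction, gp_expressed_fraction, mirna_target_fraction,
          ti_fraction, protein_hit_fraction, unknown_strand_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  focal <- utils::tail(strsplit(lineages$lineage[1], ";")[[1]], 1)
  focal_nodes <- trimws(strsplit(
    lineages$lineage[lineages$taxon == focal], ";")[[1]])
  if (!all(names(stratum_weights) %in% focal_nodes))
    stop("stratum_weights names must be nodes of the focal lineage")
  cfg$focal_taxon <- focal
  structure(cfg, class = "sim_config")
}

#' Noiseless configuration preset
#'
#' The noiseless preset keeps the default study design but makes every
#' stochastic call deterministic in practice: near-Poisson counts
#' (dispersion 1e-6), zero off-frame P-site noise and a strong in-frame
#' signal. Planted expression means are kept away from the decision
#' thresholds by the default guard band, so ground-truth recovery is exact.
#'
#' @param n_novel_loci cohort size (default 500).
#' @param seed seed.
#' @param ... further overrides passed to [sim_config].
#' @return A `sim_config`.
#' @export
sim_config_noiseless <- function(n_novel_loci = 500, seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_novel_loci = n_novel_loci,
                   n_chromosomes = 6, chrom_length = 1.6e6,
                   nb_dispersion = 1e-6, psite_noise_rate = 0,
                   psite_signal_rate = 6)
  do.call(sim_config, utils::modifyList(defaults, args))
}

.alloc_counts <- function(n, prop) {
  # largest-remainder allocation of n among classes
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(prop))
}

.rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.split_len <- function(total, k, min_part = 60) {
  if (k == 1) return(total)
  if (total < k * min_part) stop("length too short to split")
  extra <- total - k * min_part
  cuts <- sort(sample.int(extra + 1, k - 1, replace = TRUE) - 1)
  parts <- diff(c(0, cuts, extra))
  parts + min_part
}

# ---- layout -----------------------------------------------------------

.sim_layout <- function(config) {
  cls_n <- .alloc_counts(config$n_novel_loci, config$class_mix)
  classes <- sample(rep(names(cls_n), cls_n))
  n_loci <- config$n_novel_loci
  violation <- rep(NA_character_, n_loci)
  is_lnc <- classes == "lncRNA"
  violation[is_lnc] <- sample(c("near_gene", "te"), sum(is_lnc),
                              replace = TRUE)
  # TE-overlap violations cannot exceed the TE budget
  te_viol <- which(!is.na(violation) & violation == "te")
  if (length(te_viol) > config$n_te)
    violation[te_viol[seq_len(length(te_viol) - config$n_te) +
                      config$n_te]] <- "near_gene"
  n_exons <- sample(1:3, n_loci, replace = TRUE, prob = c(0.55, 0.3, 0.15))
  # spliced structure per locus
  spliced <- integer(n_loci)
  pep <- rep(NA_integer_, n_loci)
  utr5 <- rep(NA_integer_, n_loci)
  for (i in seq_len(n_loci)) {
    spliced[i] <- switch(classes[i],
      short = sample(130:199, 1),
      orf_coding = {
        pep[i] <- sample(100:300, 1)
        utr5[i] <- sample(30:150, 1)
        3L * (pep[i] + 1L) + utr5[i] + sample(60:300, 1)
      },
      sample(420:1500, 1))
    if (classes[i] == "short") n_exons[i] <- 1L
  }
  exon_parts <- lapply(seq_len(n_loci), function(i)
    .split_len(spliced[i], n_exons[i]))
  intron_parts <- lapply(seq_len(n_loci), function(i)
    if (n_exons[i] > 1) sample(80:400, n_exons[i] - 1, replace = TRUE)
    else integer(0))
  locus_span <- vapply(seq_len(n_loci), function(i)
    sum(exon_parts[[i]]) + sum(intron_parts[[i]]), numeric(1))
  strand <- sample(c("+", "-"), n_loci, replace = TRUE)
  strand_known <- rep(TRUE, n_loci)
  noncod <- which(classes != "orf_coding")
  nunk <- round(config$unknown_strand_fraction * length(noncod))
  if (nunk > 0)
    strand_known[sample(noncod, nunk)] <- FALSE

  gene_len <- sample(800:3000, config$n_reference_genes, replace = TRUE)
  near <- which(!is.na(violation) & violation == "near_gene")
  if (length(near) > config$n_reference_genes)
    stop("not enough reference genes to anchor near-gene lncRNA loci")
  partner <- if (length(near)) sample(config$n_reference_genes, length(near))
             else integer(0)
  n_te_planted <- sum(!is.na(violation) & violation == "te")
  n_te_free <- max(0L, config$n_te - n_te_planted)
  te_len_free <- if (n_te_free) sample(150:800, n_te_free, replace = TRUE)
                 else integer(0)

  # blocks: paired (gene, near locus), single gene, single locus, free TE
  blocks <- list()
  for (k in seq_along(near))
    blocks[[length(blocks) + 1L]] <- list(type = "pair", gene = partner[k],
                                          locus = near[k])
  for (g in setdiff(seq_len(config$n_reference_genes), partner))
    blocks[[length(blocks) + 1L]] <- list(type = "gene", gene = g)
  for (l in setdiff(seq_len(n_loci), near))
    blocks[[length(blocks) + 1L]] <- list(type = "locus", locus = l)
  for (t in seq_len(n_te_free))
    blocks[[length(blocks) + 1L]] <- list(type = "te", te = t)
  blocks <- blocks[sample(length(blocks))]

  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  margin <- 1000
  gene_pos <- matrix(NA_real_, config$n_reference_genes, 2)
  gene_chrom <- character(config$n_reference_genes)
  locus_start <- rep(NA_real_, n_loci)
  locus_chrom <- character(n_loci)
  te_rows <- list()
  ci <- 1L
  cursor <- margin
  prev_linc <- FALSE
  place <- function(span) {
    # returns start coordinate, advancing chromosomes as needed
    while (cursor + span > config$chrom_length - margin) {
      ci <<- ci + 1L
      if (ci > config$n_chromosomes)
        stop("chromosomes too short to place the requested features; ",
             "increase chrom_length or n_chromosomes")
      cursor <<- margin
      prev_linc <<- FALSE
    }
    s <- cursor
    cursor <<- cursor + span
    s
  }
  gap_before <- function(linc) {
    g <- sample(200:800, 1)
    if (linc || prev_linc) g <- max(g, 600)
    g
  }
  for (b in blocks) {
    if (b$type == "pair") {
      inner <- sample(80:400, 1)
      span <- gene_len[b$gene] + inner + locus_span[b$locus]
      g <- gap_before(FALSE)
      s <- place(g + span) + g
      gene_pos[b$gene, ] <- c(s, s + gene_len[b$gene] - 1)
      gene_chrom[b$gene] <- chrom_names[ci]
      ls <- s + gene_len[b$gene] + inner
      locus_start[b$locus] <- ls
      locus_chrom[b$locus] <- chrom_names[ci]
      prev_linc <- FALSE
    } else if (b$type == "gene") {
      g <- gap_before(FALSE)
      s <- place(g + gene_len[b$gene]) + g
      gene_pos[b$gene, ] <- c(s, s + gene_len[b$gene] - 1)
      gene_chrom[b$gene] <- chrom_names[ci]
      prev_linc <- FALSE
    } else if (b$type == "locus") {
      linc <- classes[b$locus] == "lincRNA"
      g <- gap_before(linc)
      s <- place(g + locus_span[b$locus]) + g
      locus_start[b$locus] <- s
      locus_chrom[b$locus] <- chrom_names[ci]
      prev_linc <- linc
    } else {
      g <- gap_before(FALSE)
      s <- place(g + te_len_free[b$te]) + g
      te_rows[[length(te_rows) + 1L]] <-
        data.frame(chrom = chrom_names[ci], start = s,
                   end = s + te_len_free[b$te] - 1)
      prev_linc <- FALSE
    }
  }

  # exon coordinates per locus (primary isoform)
  exon_list <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    starts <- locus_start[i] +
      cumsum(c(0, utils::head(exon_parts[[i]], -1) + intron_parts[[i]]))
    exon_list[[i]] <- data.frame(start = starts,
                                 end = starts + exon_parts[[i]] - 1)
  }
  # TEs overlapping the planted 'te' lncRNA loci
  for (i in which(!is.na(violation) & violation == "te")) {
    e <- exon_list[[i]]
    j <- sample(nrow(e), 1)
    ov <- sample(30:min(100, e$end[j] - e$start[j] + 1), 1)
    te_start <- e$end[j] - ov + 1
    te_end <- e$end[j] + sample(50:150, 1)
    te_rows[[length(te_rows) + 1L]] <-
      data.frame(chrom = locus_chrom[i], start = te_start, end = te_end)
  }
  te <- if (length(te_rows)) do.call(rbind, te_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric())

  loci <- data.frame(locus = seq_len(n_loci), chrom = locus_chrom,
                     start = locus_start,
                     end = locus_start + locus_span - 1,
                     strand = strand, strand_known = strand_known,
                     class = classes, violation = violation,
                     spliced_length = spliced, n_exons = n_exons,
                     peptide = pep, utr5 = utr5)
  genes <- data.frame(gene = seq_len(config$n_reference_genes),
                      chrom = gene_chrom,
                      start = gene_pos[, 1], end = gene_pos[, 2],
                      strand = sample(c("+", "-"),
                                      config$n_reference_genes, TRUE))
  list(chrom_names = chrom_names, loci = loci, genes = genes, te = te,
       exon_list = exon_list)
}

# ---- genome + annotation ---------------------------------------------

#' Generate the genome and reference annotations
#'
#' Places non-overlapping reference protein-coding genes, transposable
#' elements (both intergenic and overlapping the planted TE-class loci) and
#' the footprints of the novel loci on random chromosome sequences. Seeds
#' the simulation stream; the remaining generators continue it.
#'
#' @param config a [sim_config].
#' @return list with `genome` (`DNAStringSet`), `tair_like` and
#'   `araport_like` annotation `GRanges`, `te_set` (`GRanges`), and the
#'   internal `layout` consumed by [generate_novel_transcripts].
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- .sim_layout(config)
  genome <- Biostrings::DNAStringSet(vapply(layout$chrom_names, function(cn)
    paste(.rand_dna(config$chrom_length), collapse = ""), character(1)))
  names(genome) <- layout$chrom_names
  g <- layout$genes
  tair_like <- annotation_set(data.frame(
    chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
    biotype = "protein_coding",
    feature_id = sprintf("AT_GENE_%04d", g$gene)))
  # recent loci become annotated (non-coding/unknown) genes in the
  # updated reference
  n_recent <- round(config$recent_fraction * nrow(layout$loci))
  recent <- sort(sample(nrow(layout$loci), n_recent))
  layout$loci$novelty <- ifelse(seq_len(nrow(layout$loci)) %in% recent,
                                "recent", "novel")
  l <- layout$loci[recent, , drop = FALSE]
  araport_extra <- if (nrow(l)) data.frame(
    chrom = l$chrom, start = pmax(1, l$start - 25), end = l$end + 25,
    strand = "*", biotype = "other_gene",
    feature_id = sprintf("ARAPORT_NEW_%04d", l$locus)) else NULL
  araport_like <- annotation_set(rbind(
    data.frame(chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, biotype = "protein_coding",
               feature_id = sprintf("AT_GENE_%04d", g$gene)),
    araport_extra))
  te <- layout$te
  te_set <- annotation_set(data.frame(
    chrom = te$chrom, start = te$start, end = te$end,
    strand = rep("*", nrow(te)),
    biotype = rep("TE", nrow(te)),
    feature_id = sprintf("TE_%04d", seq_len(nrow(te)))))
  list(genome = genome, tair_like = tair_like, araport_like = araport_like,
       te_set = te_set, layout = layout)
}

# ---- transcripts ------------------------------------------------------

.stop_codons <- c("TAA", "TAG", "TGA")

.rand_codons <- function(n) {
  all_cod <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               c("A", "C", "G", "T")), 1, paste,
                   collapse = "")
  ok <- setdiff(all_cod, .stop_codons)
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# construct a target site from a miRNA: perfect reverse complement for
# cleavage mode, one central mismatch (miRNA position 10) for
# translational-inhibition mode
.plant_site <- function(mirna, mode) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mirna)))
  if (mode == "cleavage") return(list(site = rc, expectation = 0))
  m <- nchar(mirna)
  pos10 <- substr(mirna, 10, 10)
  forbidden <- c(.complement[[pos10]],
                 if (pos10 == "G") "T" else if (pos10 == "T") "G")
  repl <- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1)
  j <- m - 10 + 1
  site <- rc
  substr(site, j, j) <- repl
  list(site = site, expectation = 2)  # mismatch inside the seed span
}

#' Generate novel transcripts, their sequences and planted miRNA sites
#'
#' Writes class-consistent spliced sequences into the genome: ORF-coding
#' loci receive an explicit ATG...stop ORF of the planted peptide length
#' (and no competing ORF at or above 100 aa); non-coding loci are
#' regenerated until no ORF of 100 aa or more exists on either strand;
#' short loci are at most 199 nt. A fraction of loci receive a second
#' (truncated) isoform sharing exons with the primary one, and a fraction
#' receive a planted miRNA target site.
#'
#' @param config a [sim_config].
#' @param gen result of [generate_genome_and_annotation].
#' @return list with `genome` (updated), `exons` (exon table with
#'   `xloc_id`/`tcons_id` assigned by leftmost coordinate), `mirnas`
#'   (named vector), `truth` (per-locus data frame) and `truth_mirna`.
#' @export
generate_novel_transcripts <- function(config, gen) {
  layout <- gen$layout
  loci <- layout$loci
  n_loci <- nrow(loci)
  genome_chars <- lapply(as.character(gen$genome), function(s)
    strsplit(s, "")[[1]])

  # deterministic ids by leftmost coordinate
  ord <- order(loci$chrom, loci$start)
  xloc_id <- character(n_loci)
  xloc_id[ord] <- sprintf("XLOC_%06d", seq_len(n_loci))
  loci$xloc_id <- xloc_id

  # mature miRNAs and target assignment
  mirnas <- stats::setNames(
    vapply(seq_len(config$n_mirna), function(i)
      paste(.rand_dna(config$mirna_length), collapse = ""), character(1)),
    sprintf("ath-simR%03d", seq_len(config$n_mirna)))
  eligible <- which(loci$strand_known &
                    loci$spliced_length >= config$mirna_length + 40 &
                    loci$class != "short")
  n_targets <- min(length(eligible),
                   round(config$mirna_target_fraction * n_loci))
  target_loci <- if (n_targets && config$n_mirna > 0)
    sample(eligible, n_targets) else integer(0)
  target_mirna <- if (n_targets)
    sample(config$n_mirna, n_targets, replace = TRUE) else integer(0)
  target_mode <- if (n_targets)
    sample(c("cleavage", "translational_inhibition"), n_targets,
           replace = TRUE,
           prob = c(1 - config$ti_fraction, config$ti_fraction))
    else character(0)

  truth_mirna <- list()
  orf_start <- rep(NA_integer_, n_loci)  # on the spliced transcript
  m <- config$mirna_length

  for (i in seq_len(n_loci)) {
    len <- loci$spliced_length[i]
    ti <- match(i, target_loci)
    pos <- NA_integer_
    planted <- NULL
    for (attempt in 1:100) {
      if (loci$class[i] == "orf_coding") {
        p <- loci$peptide[i]
        u5 <- loci$utr5[i]
        u3 <- len - u5 - 3 * (p + 1)
        seqs <- paste0(paste(.rand_dna(u5), collapse = ""),
                       "ATG", .rand_codons(p - 1),
                       sample(.stop_codons, 1),
                       paste(.rand_dna(u3), collapse = ""))
        orf_start[i] <- u5 + 1L
      } else {
        seqs <- paste(.rand_dna(len), collapse = "")
      }
      if (!is.na(ti)) {
        planted <- .plant_site(mirnas[[target_mirna[ti]]], target_mode[ti])
        lo <- if (loci$class[i] == "orf_coding")
          len - (len - (loci$utr5[i] + 3 * (loci$peptide[i] + 1))) + 1
          else 10L
        hi <- len - m - 5L
        if (hi < lo) { pos <- NA } else pos <- sample(lo:hi, 1)
        if (!is.na(pos)) substr(seqs, pos, pos + m - 1) <- planted$site
      }
      orfs <- find_orfs(seqs, "both")
      big <- orfs[orfs$peptide_length >= 100, , drop = FALSE]
      ok <- if (loci$class[i] == "orf_coding") {
        nrow(big) == 1 && big$strand == "+" && big$start == orf_start[i] &&
          big$peptide_length == loci$peptide[i]
      } else nrow(big) == 0
      if (ok) break
      if (attempt == 100) stop("failed to construct class-consistent ",
                               "sequence for locus ", i)
    }
    if (!is.na(ti) && !is.na(pos)) {
      truth_mirna[[length(truth_mirna) + 1L]] <- data.frame(
        xloc_id = loci$xloc_id[i], mirna = names(mirnas)[target_mirna[ti]],
        mode = target_mode[ti], expectation = planted$expectation,
        site_start = pos)
    }
    # splat the spliced sequence into the genome across the exons
    ex <- layout$exon_list[[i]]
    sp <- if (loci$strand[i] == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
      else seqs
    chars <- strsplit(sp, "")[[1]]
    off <- 0L
    cv <- genome_chars[[loci$chrom[i]]]
    for (j in seq_len(nrow(ex))) {
      w <- ex$end[j] - ex$start[j] + 1
      cv[ex$start[j]:ex$end[j]] <- chars[(off + 1):(off + w)]
      off <- off + w
    }
    genome_chars[[loci$chrom[i]]] <- cv
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- names(gen$genome)

  # exon table: primary isoform per locus plus truncated second isoforms
  n_multi <- round(config$multi_isoform_fraction * n_loci)
  multi <- if (n_multi) sample(n_loci, n_multi) else integer(0)
  rows <- list()
  tcount <- 0L
  tcons_of <- function() { tcount <<- tcount + 1L
                           sprintf("TCONS_%08d", tcount) }
  for (i in order(loci$chrom, loci$start)) {
    ex <- layout$exon_list[[i]]
    strand_out <- if (loci$strand_known[i]) loci$strand[i] else "*"
    tid <- tcons_of()
    rows[[length(rows) + 1L]] <- data.frame(
      tcons_id = tid, xloc_id = loci$xloc_id[i], chrom = loci$chrom[i],
      start = ex$start, end = ex$end, strand = strand_out)
    if (i %in% multi) {
      k <- sample(nrow(ex), 1)
      ex2 <- ex[seq_len(k), , drop = FALSE]
      w <- ex2$end[k] - ex2$start[k] + 1
      trim <- sample.int(max(1, floor(w * 0.4)), 1) - 1L
      ex2$end[k] <- ex2$end[k] - trim
      tid2 <- tcons_of()
      rows[[length(rows) + 1L]] <- data.frame(
        tcons_id = tid2, xloc_id = loci$xloc_id[i], chrom = loci$chrom[i],
        start = ex2$start, end = ex2$end, strand = strand_out)
    }
  }
  exons <- do.call(rbind, rows)

  truth <- data.frame(
    xloc_id = loci$xloc_id, class = loci$class,
    novelty = loci$novelty,
    te_overlap = !is.na(loci$violation) & loci$violation == "te",
    strand = ifelse(loci$strand_known, loci$strand, "*"),
    spliced_length = loci$spliced_length,
    peptide = loci$peptide,
    orf_start = orf_start,
    multi_isoform = seq_len(n_loci) %in% multi)
  truth <- truth[order(truth$xloc_id), ]
  rownames(truth) <- NULL
  truth_mirna <- if (length(truth_mirna)) do.call(rbind, truth_mirna) else
    data.frame(xloc_id = character(), mirna = character(),
               mode = character(), expectation = numeric(),
               site_start = integer())
  list(genome = genome, exons = exons, mirnas = mirnas, truth = truth,
       truth_mirna = truth_mirna)
}

# ---- counts -----------------------------------------------------------

# log-uniform draw avoiding guard bands around the PEX/hPEX thresholds
.draw_rpm <- function(n, lo, hi, margin) {
  bands <- rbind(c(1 / margin, 1 * margin), c(10 / margin, 10 * margin))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- exp(stats::runif(1, log(lo), log(hi)))
      if (!any(x >= bands[, 1] & x <= bands[, 2])) break
    }
    out[i] <- x
  }
  out
}

#' Generate per-dataset count matrices with planted effects
#'
#' Counts follow a negative-binomial model: the planted per-locus RPM and
#' each sample's (jittered) library size give the mean; HS samples of DE
#' loci have the mean shifted by the planted log2 fold change;
#' pollen-specific loci get near-zero means in sporophytic datasets, and
#' loci not expressed in germinating pollen get near-zero means there.
#'
#' @param config a [sim_config].
#' @param truth per-locus truth table from [generate_novel_transcripts].
#' @return list with `studies` (named list of [expression_study]) and
#'   `truth` (the input extended with planted expression/DE columns).
#' @export
generate_counts <- function(config, truth) {
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  n <- nrow(truth)
  margin <- config$boundary_margin
  ds <- config$datasets
  psx <- seq_len(n) %in% sample(n, round(config$psx_fraction * n))
  gp_expr <- seq_len(n) %in% sample(n, round(config$gp_expressed_fraction * n))
  truth$psx <- psx
  studies <- list()
  nrep <- config$replicates_per_condition
  for (d in seq_len(nrow(ds))) {
    dname <- ds$dataset[d]
    pollen <- ds$type[d] == "pollen"
    germinating <- pollen & ds$has_rpf[d]
    if (!pollen) {
      base <- ifelse(psx, 0.002, .draw_rpm(n, 2, 50, margin))
      expressed <- !psx
    } else if (germinating) {
      base <- ifelse(gp_expr, .draw_rpm(n, 2, 80, margin), 0.005)
      expressed <- gp_expr
    } else {
      base <- .draw_rpm(n, config$rpm_range[1], config$rpm_range[2], margin)
      expressed <- rep(TRUE, n)
    }
    de <- rep(FALSE, n)
    lfc <- rep(0, n)
    if (pollen && config$de_fraction > 0) {
      cand <- which(expressed)
      sel <- cand[stats::runif(length(cand)) < config$de_fraction]
      de[sel] <- TRUE
      lfc[sel] <- sample(c(-1, 1), length(sel), TRUE) * config$planted_lfc
      # keep both condition means outside the guard bands
      for (i in sel) {
        tries <- 0
        while (any(abs(log(base[i] * 2^lfc[i]) - log(c(1, 10))) <
                   log(margin)) && tries < 50) {
          base[i] <- .draw_rpm(1, max(config$rpm_range[1], 2),
                               config$rpm_range[2], margin)
          tries <- tries + 1
        }
      }
    }
    mean_hs <- base * 2^lfc
    libs <- round(ds$library_size[d] *
                  stats::runif(2 * nrep, 0.9, 1.1))
    cond <- rep(c("control", "HS"), each = nrep)
    snames <- sprintf("%s_%s_rep%d", dname, cond, rep(seq_len(nrep), 2))
    mu <- cbind(matrix(rep(base, nrep), n),
                matrix(rep(mean_hs, nrep), n))
    mu <- sweep(mu, 2, libs / 1e6, "*")
    counts <- matrix(stats::rnbinom(n * 2 * nrep, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     n, dimnames = list(truth$xloc_id, snames))
    samples <- data.frame(sample = snames, dataset = dname,
                          condition = cond,
                          replicate = rep(seq_len(nrep), 2),
                          library_size = libs,
                          type = ds$type[d])
    studies[[dname]] <- expression_study(counts, samples)
    truth[[paste0("rpm_control_", dname)]] <- base
    truth[[paste0("rpm_hs_", dname)]] <- mean_hs
    truth[[paste0("expressed_", dname)]] <- expressed
    truth[[paste0("pex_", dname)]] <-
      pollen & (base > 1 | mean_hs > 1)
    truth[[paste0("hpex_", dname)]] <-
      pollen & (base > 10 | mean_hs > 10)
    truth[[paste0("de_", dname)]] <- de
    truth[[paste0("lfc_", dname)]] <- lfc
  }
  truth$gp_expressed <- gp_expr
  list(studies = studies, truth = truth)
}

# ---- P-site tracks ----------------------------------------------------

#' Generate ribosome P-site tracks with planted periodicity
#'
#' Translated loci (a planted subset of the ORF-coding loci expressed in
#' the RPF-bearing dataset) draw Poisson counts at the signal rate on the
#' in-frame codon positions of their planted ORF and at the noise rate
#' elsewhere; ribosome-associated but untranslated loci get a few isolated
#' pile-up positions; all other expressed loci get sub-threshold RPF
#' abundance.
#'
#' @param config a [sim_config].
#' @param truth truth table from [generate_counts].
#' @param exons exon table (to map loci to their primary transcript).
#' @return list with `tracks` (data frame `transcript`, `condition`,
#'   `position`, `count`), `meta` (per transcript and condition:
#'   `total_rpf_reads`, `library_total_reads`), `anchors` and `truth`
#'   (extended with `translated`).
#' @export
generate_psite_tracks <- function(config, truth, exons) {
  margin <- config$boundary_margin
  tl <- transcript_lengths(exons)
  # primary transcript per locus: the longest
  tl <- tl[order(tl$xloc_id, -tl$spliced_length, tl$tcons_id), ]
  primary <- tl[!duplicated(tl$xloc_id), ]
  m <- match(truth$xloc_id, primary$xloc_id)
  truth$primary_tcons <- primary$tcons_id[m]

  cand <- which(truth$class == "orf_coding" & truth$gp_expressed)
  translated <- rep(FALSE, nrow(truth))
  translated[cand] <- stats::runif(length(cand)) < config$translated_fraction
  truth$translated <- translated

  conds <- c("control", "HS")
  tracks <- list(); meta <- list()
  anchors <- integer(0)
  for (i in which(truth$gp_expressed)) {
    tid <- truth$primary_tcons[i]
    len <- truth$spliced_length[i]
    if (translated[i]) {
      rpm <- .draw_rpm(1, 2, 20, margin)
    } else if (truth$class[i] == "orf_coding" ||
               stats::runif(1) < 0.3) {
      # ribosome-associated but not translated
      rpm <- .draw_rpm(1, 2, 10, margin)
    } else {
      rpm <- stats::runif(1, 0.05, 1 / margin)
    }
    peaks <- if (!translated[i]) sample(len, sample(2:4, 1)) else integer(0)
    for (cn in conds) {
      if (translated[i]) {
        orf0 <- truth$orf_start[i]
        inpos <- orf0 + 3 * (0:(truth$peptide[i] - 1))
        counts <- rep(0L, len)
        counts[inpos] <- stats::rpois(length(inpos),
                                      config$psite_signal_rate)
        if (config$psite_noise_rate > 0) {
          off <- setdiff(seq_len(len), inpos)
          counts[off] <- stats::rpois(length(off), config$psite_noise_rate)
        }
      } else {
        # the same few pause positions in both conditions
        counts <- rep(0L, len)
        counts[peaks] <- stats::rpois(length(peaks), 8) + 1L
        if (config$psite_noise_rate > 0) {
          rest <- setdiff(seq_len(len), peaks)
          counts[rest] <- stats::rpois(length(rest),
                                       config$psite_noise_rate)
        }
      }
      nz <- which(counts > 0)
      if (length(nz))
        tracks[[length(tracks) + 1L]] <- data.frame(
          transcript = tid, condition = cn, position = nz,
          count = counts[nz])
      meta[[length(meta) + 1L]] <- data.frame(
        transcript = tid, condition = cn,
        total_rpf_reads = round(rpm * config$rpf_library_size / 1e6),
        library_total_reads = config$rpf_library_size)
    }
    anchors[tid] <- 1L
  }
  tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(transcript = character(), condition = character(),
               position = integer(), count = integer())
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(transcript = character(), condition = character(),
               total_rpf_reads = numeric(), library_total_reads = numeric())
  list(tracks = tracks, meta = meta, anchors = anchors, truth = truth)
}

# ---- homology ---------------------------------------------------------

#' Generate homology hit and lineage tables with planted phylostrata
#'
#' Each locus is planted a phylostratum (a node of the focal lineage).
#' Passing hits (E <= 1e-5) come only from taxa whose lowest common
#' ancestor with the focal species is exactly the planted node;
#' species-specific loci receive no passing hit. Decoy rows exercise the
#' E-value filter (E > 1e-5, possibly from older taxa) and the
#' self-species exclusion.
#'
#' @param config a [sim_config].
#' @param truth truth table.
#' @return list with `hits` (query, subject_taxon, pident, evalue),
#'   `lineages` (taxon, lineage) and `truth` extended with `stratum`.
#' @export
generate_homology_tables <- function(config, truth) {
  lineages <- config$lineages
  lin <- read_lineages(lineages)
  focal <- config$focal_taxon
  focal_lin <- lin[[focal]]
  depth_of <- vapply(names(lin), function(tx)
    lca_node(lin[[tx]], focal_lin)$depth, integer(1))
  node_depth <- stats::setNames(seq_along(focal_lin), focal_lin)
  w <- config$stratum_weights
  strata <- sample(names(w), nrow(truth), replace = TRUE,
                   prob = w / sum(w))
  truth$stratum <- strata
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    q <- truth$xloc_id[i]
    d <- node_depth[[strata[i]]]
    if (strata[i] != focal) {
      taxa <- names(depth_of)[depth_of == d & names(depth_of) != focal]
      nh <- sample(1:3, 1)
      for (tx in sample(taxa, nh, replace = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, subject_taxon = tx,
          pident = round(stats::runif(1, 70, 100), 1),
          evalue = 10^-stats::runif(1, 6, 50))
    }
    if (stats::runif(1) < 0.3) {
      # decoy failing the E-value filter, possibly from an older node
      older <- names(depth_of)[depth_of <= d & names(depth_of) != focal]
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, subject_taxon = sample(older, 1),
        pident = round(stats::runif(1, 60, 90), 1),
        evalue = 10^-stats::runif(1, 1, 4.7))
    }
    if (stats::runif(1) < 0.2) {
      # self hit, excluded upstream of the LCA rule
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, subject_taxon = focal, pident = 100,
        evalue = 1e-60)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), subject_taxon = character(),
               pident = numeric(), evalue = numeric())
  list(hits = hits, lineages = lineages, truth = truth)
}

#' Generate a protein-homology (blastx-style) table with planted bins
#'
#' @param config a [sim_config].
#' @param truth truth table.
#' @return list with `hits` (qseqid, sseqid, pident, evalue) and `truth`
#'   extended with `protein_bin`.
#' @export
generate_blastx_table <- function(config, truth) {
  n <- nrow(truth)
  has <- stats::runif(n) < config$protein_hit_fraction
  bin <- rep("none", n)
  bin[has] <- sample(c("full", "partial"), sum(has), TRUE,
                     prob = c(0.4, 0.6))
  rows <- list()
  for (i in seq_len(n)) {
    q <- truth$xloc_id[i]
    if (bin[i] == "full") {
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = q, sseqid = sprintf("SIMPROT%04d", i),
        pident = round(stats::runif(1, 97, 100), 1),
        evalue = 10^-stats::runif(1, 8, 60))
    } else if (bin[i] == "partial") {
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = q, sseqid = sprintf("SIMPROT%04d", i),
        pident = round(stats::runif(1, 50, 96.5), 1),
        evalue = 10^-stats::runif(1, 8, 60))
    } else if (stats::runif(1) < 0.2) {
      # decoy failing the E-value cutoff or the identity floor
      if (stats::runif(1) < 0.5)
        rows[[length(rows) + 1L]] <- data.frame(
          qseqid = q, sseqid = sprintf("SIMJUNK%04d", i),
          pident = round(stats::runif(1, 55, 90), 1),
          evalue = 10^-stats::runif(1, 2, 6.5))
      else
        rows[[length(rows) + 1L]] <- data.frame(
          qseqid = q, sseqid = sprintf("SIMJUNK%04d", i),
          pident = round(stats::runif(1, 20, 49), 1),
          evalue = 10^-stats::runif(1, 8, 30))
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qseqid = character(), sseqid = character(),
               pident = numeric(), evalue = numeric())
  truth$protein_bin <- bin
  list(hits = hits, truth = truth)
}

# ---- master -----------------------------------------------------------

#' Simulate a complete pollen-XLOC study
#'
#' Runs all generators in their fixed order and bundles every pipeline
#' input together with the ground truth.
#'
#' @param config a [sim_config].
#' @return An object of class `xloc_sim`: list with `genome`, `tair_like`,
#'   `araport_like`, `te_set`, `exons`, `studies`, `psite` (tracks, meta,
#'   anchors), `homology` (hits, lineages), `blastx`, `mirnas`, `truth`,
#'   `truth_mirna`, `config`.
#' @export
simulate_xloc_study <- function(config = sim_config()) {
  gen <- generate_genome_and_annotation(config)
  tx <- generate_novel_transcripts(config, gen)
  cnt <- generate_counts(config, tx$truth)
  ps <- generate_psite_tracks(config, cnt$truth, tx$exons)
  hom <- generate_homology_tables(config, ps$truth)
  bx <- generate_blastx_table(config, hom$truth)
  structure(list(
    genome = tx$genome, tair_like = gen$tair_like,
    araport_like = gen$araport_like, te_set = gen$te_set,
    exons = tx$exons, studies = cnt$studies,
    psite = list(tracks = ps$tracks, meta = ps$meta, anchors = ps$anchors),
    homology = list(hits = hom$hits, lineages = hom$lineages),
    blastx = bx$hits, mirnas = tx$mirnas,
    truth = bx$truth, truth_mirna = tx$truth_mirna,
    config = config), class = "xloc_sim")
}

#' @export
print.xloc_sim <- function(x, ...) {
  cat("xloc_sim:", nrow(x$truth), "loci,",
      length(unique(x$exons$tcons_id)), "transcripts,",
      length(x$studies), "datasets\n")
  invisible(x)
}
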