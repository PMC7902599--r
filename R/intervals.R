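#' @title Genomic interval model and locus-level interval operations
#'
#' @description Transcript models are represented as an exon table with one
#' row per exon: columns `tcons_id`, `chrom`, `start`, `end`, `strand` and
#' (once assigned) `xloc_id`. Coordinates are 1-based closed throughout, the
#' IRanges/GenomicRanges convention; GTF/GFF3 files use the same convention
#' so no conversion happens at I/O. Strand is one of `"+"`, `"-"` or `"*"`
#' (unknown, as in non-strand-specific libraries).
#'
#' @name intervals
NULL

.check_exons <- function(exons) {
  need <- c("tcons_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop("exon table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(exons$start > exons$end))
    stop("exon with start > end")
  if (!all(exons$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  bad <- tapply(exons$strand, exons$tcons_id, function(s) length(unique(s)) > 1)
  if (any(bad))
    stop("transcript(s) with mixed strands: ",
         paste(names(bad)[bad], collapse = ", "))
  invisible(exons)
}

#' Convert an exon table to a GRanges
#'
#' @param exons exon data frame (see [intervals]).
#' @return A `GRanges` with metadata column `tcons_id` (and `xloc_id` when
#'   present).
#' @export
exons_to_granges <- function(exons) {
  .check_exons(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand)
  S4Vectors::mcols(gr)$tcons_id <- exons$tcons_id
  if (!is.null(exons$xloc_id))
    S4Vectors::mcols(gr)$xloc_id <- exons$xloc_id
  gr
}

#' Build an annotation set
#'
#' A thin wrapper around `GRanges` carrying a `biotype` metadata column with
#' values in `protein_coding`, `other_gene`, `TE`.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `strand`
#'   (optional, defaults `"*"`), `biotype`, and optionally `feature_id`; or a
#'   `GRanges` that already has a `biotype` column.
#' @return A `GRanges` with a `biotype` metadata column.
#' @export
annotation_set <- function(df) {
  if (methods::is(df, "GRanges")) {
    if (is.null(S4Vectors::mcols(df)$biotype))
      stop("GRanges annotation needs a 'biotype' metadata column")
    return(df)
  }
  if (is.null(df$strand)) df$strand <- rep("*", nrow(df))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$biotype <- df$biotype
  if (!is.null(df$feature_id))
    S4Vectors::mcols(gr)$feature_id <- df$feature_id
  gr
}

.biotype_subset <- function(annot, biotypes) {
  annot[S4Vectors::mcols(annot)$biotype %in% biotypes]
}

#' Group transcripts into loci by chained exonic overlap
#'
#' Two transcripts belong to the same locus iff they are connected by a
#' chain of pairwise exonic overlaps (>= 1 bp) on the same chromosome, the
#' cuffmerge locus semantics. Strand is only consulted when both transcripts
#' have a known strand: a `+` and a `-` transcript never merge, while a `*`
#' transcript merges with either. Locus identifiers are assigned
#' deterministically by leftmost genomic coordinate (`XLOC_000001`, ...).
#'
#' @param exons exon data frame (see [intervals]).
#' @param id_prefix prefix for generated locus ids.
#' @return The exon table with an `xloc_id` column added (input `xloc_id`,
#'   if any, is replaced).
#' @export
group_into_loci <- function(exons, id_prefix = "XLOC_") {
  .check_exons(exons)
  tids <- unique(exons$tcons_id)
  n <- length(tids)
  gr <- exons_to_granges(exons)
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  s1 <- as.character(BiocGenerics::strand(gr))[qi]
  s2 <- as.character(BiocGenerics::strand(gr))[si]
  keep <- !(s1 != "*" & s2 != "*" & s1 != s2)
  t1 <- match(S4Vectors::mcols(gr)$tcons_id[qi][keep], tids)
  t2 <- match(S4Vectors::mcols(gr)$tcons_id[si][keep], tids)

  # union-find over transcripts
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(t1)) {
    a <- find(t1[k]); b <- find(t2[k])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))

  # order components by leftmost (chrom, start)
  tx_chrom <- exons$chrom[match(tids, exons$tcons_id)]
  tx_start <- vapply(tids, function(t) min(exons$start[exons$tcons_id == t]),
                     numeric(1))
  comp_ids <- unique(comp)
  comp_chrom <- vapply(comp_ids, function(cidx)
    min(tx_chrom[comp == cidx]), character(1))
  comp_start <- vapply(comp_ids, function(cidx)
    min(tx_start[comp == cidx]), numeric(1))
  ord <- order(comp_chrom, comp_start)
  rank <- match(comp, comp_ids[ord])
  xloc <- sprintf("%s%06d", id_prefix, rank)
  exons$xloc_id <- xloc[match(exons$tcons_id, tids)]
  exons
}

.locus_exon_granges <- function(exons) {
  gr <- exons_to_granges(exons)
  S4Vectors::split(gr, exons$xloc_id)
}

#' Classify locus novelty against two reference annotations
#'
#' A locus with any exonic overlap (>= 1 bp, strand-blind) with a gene of
#' the primary reference ("TAIR10-like") is `known` and would be excluded
#' from an XLOC cohort; otherwise overlap with a gene of the updated
#' reference ("Araport11-like") makes it `recent`; otherwise it is `novel`.
#' Reference genes are taken at gene-body resolution.
#'
#' @param exons exon table with `xloc_id` assigned.
#' @param tair_like,araport_like annotation `GRanges` (see
#'   [annotation_set]); `TE` features are ignored here.
#' @return data frame with columns `xloc_id`, `novelty`
#'   (factor known/recent/novel).
#' @export
classify_novelty <- function(exons, tair_like, araport_like) {
  stopifnot(!is.null(exons$xloc_id))
  by_locus <- .locus_exon_granges(exons)
  ids <- names(by_locus)
  ov <- function(ref) {
    genes <- .biotype_subset(ref, c("protein_coding", "other_gene"))
    hits <- GenomicRanges::findOverlaps(by_locus, genes, ignore.strand = TRUE)
    ids %in% ids[unique(S4Vectors::queryHits(hits))]
  }
  in_tair <- ov(tair_like)
  in_araport <- ov(araport_like)
  novelty <- ifelse(in_tair, "known", ifelse(in_araport, "recent", "novel"))
  data.frame(xloc_id = ids,
             novelty = factor(novelty, levels = c("known", "recent", "novel")),
             row.names = NULL)
}

#' Distance from each locus to its nearest protein-coding gene
#'
#' Returns 0 for any overlap, otherwise the number of bases strictly between
#' the locus span and the nearest gene body, matching the "500 or more bp
#' away" lincRNA criterion. Strand is ignored.
#'
#' @param exons exon table with `xloc_id`.
#' @param genes annotation `GRanges`; only `protein_coding` features are
#'   used.
#' @return data frame `xloc_id`, `distance_to_gene` (NA when the annotation
#'   holds no protein-coding gene, with a warning).
#' @export
distance_to_nearest_gene <- function(exons, genes) {
  stopifnot(!is.null(exons$xloc_id))
  pc <- .biotype_subset(genes, "protein_coding")
  ids <- sort(unique(exons$xloc_id))
  if (length(pc) == 0L) {
    warning("no protein-coding gene in annotation; distances undefined")
    return(data.frame(xloc_id = ids, distance_to_gene = NA_real_))
  }
  span <- unlist(range(.locus_exon_granges(exons), ignore.strand = TRUE))
  d <- vapply(seq_along(span), function(i) {
    dd <- suppressWarnings(
      GenomicRanges::distance(span[i], pc, ignore.strand = TRUE))
    dd <- dd[!is.na(dd)]
    if (!length(dd)) NA_real_ else as.numeric(min(dd))
  }, numeric(1))
  data.frame(xloc_id = names(span), distance_to_gene = d,
             row.names = NULL)[match(ids, names(span)), , drop = FALSE]
}

#' Exonic transposable-element overlap per locus
#'
#' TRUE iff any exon of the locus shares >= 1 bp with a TE feature.
#' Intron-only TEs do not count. Strand is ignored.
#'
#' @param exons exon table with `xloc_id`.
#' @param te_set annotation `GRanges`; only `TE` features are used.
#' @return data frame `xloc_id`, `te_overlap` (logical).
#' @export
te_overlap <- function(exons, te_set) {
  stopifnot(!is.null(exons$xloc_id))
  te <- .biotype_subset(te_set, "TE")
  by_locus <- .locus_exon_granges(exons)
  ids <- names(by_locus)
  if (length(te) == 0L)
    return(data.frame(xloc_id = ids, te_overlap = FALSE))
  hits <- GenomicRanges::findOverlaps(by_locus, te, ignore.strand = TRUE)
  data.frame(xloc_id = ids,
             te_overlap = ids %in% ids[unique(S4Vectors::queryHits(hits))],
             row.names = NULL)
}

#' Spliced transcript lengths
#'
#' @param exons exon table.
#' @return data frame `tcons_id`, `xloc_id` (if present), `chrom`, `strand`,
#'   `n_exons`, `spliced_length`.
#' @export
transcript_lengths <- function(exons) {
  .check_exons(exons)
  len <- exons$end - exons$start + 1
  agg <- stats::aggregate(len, by = list(tcons_id = exons$tcons_id), FUN = sum)
  names(agg)[2] <- "spliced_length"
  first <- exons[!duplicated(exons$tcons_id), ]
  agg$chrom <- first$chrom[match(agg$tcons_id, first$tcons_id)]
  agg$strand <- first$strand[match(agg$tcons_id, first$tcons_id)]
  ne <- table(exons$tcons_id)
  agg$n_exons <- as.integer(ne[agg$tcons_id])
  if (!is.null(exons$xloc_id))
    agg$xloc_id <- exons$xloc_id[match(agg$tcons_id, exons$tcons_id)]
  agg
}

#' Extract spliced transcript sequences from a genome
#'
#' Exons are concatenated in genomic order; minus-strand transcripts are
#' reverse-complemented. Unknown-strand transcripts return the plus-strand
#' sequence.
#'
#' @param exons exon table.
#' @param genome a named `DNAStringSet` of chromosome sequences.
#' @return A named `DNAStringSet`, one sequence per transcript.
#' @export
spliced_sequences <- function(exons, genome) {
  .check_exons(exons)
  exons <- exons[order(exons$tcons_id, exons$start), ]
  tids <- unique(exons$tcons_id)
  out <- vector("list", length(tids))
  for (i in seq_along(tids)) {
    e <- exons[exons$tcons_id == tids[i], ]
    chrom <- e$chrom[1]
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    parts <- lapply(seq_len(nrow(e)), function(j)
      Biostrings::subseq(genome[[chrom]], e$start[j], e$end[j]))
    seqc <- do.call(Biostrings::xscat, parts)
    if (e$strand[1] == "-") seqc <- Biostrings::reverseComplement(seqc)
    out[[i]] <- seqc
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- tids
  res
}
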