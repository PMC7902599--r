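#' @title File interfaces
#'
#' @description The simulated study (and any real study shaped like it) is
#' exchanged on disk as plain-text standard formats: genome FASTA,
#' reference/TE annotations as GFF3, transcript models as GTF with
#' cuffmerge-style `gene_id "XLOC_..."` / `transcript_id "TCONS_..."`
#' attributes, counts and sample sheet as TSV, homology hits and lineages
#' as TSV, mature miRNAs as FASTA, P-site tracks as TSV and the ground
#' truth as JSON.
#'
#' @name io
NULL

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write transcript models as GTF
#'
#' @param exons exon table with `xloc_id` and `tcons_id`.
#' @param path output path.
#' @export
write_transcripts_gtf <- function(exons, path) {
  gr <- exons_to_granges(exons)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "pollenxloc"
  S4Vectors::mcols(gr)$gene_id <- exons$xloc_id
  S4Vectors::mcols(gr)$transcript_id <- exons$tcons_id
  S4Vectors::mcols(gr)$tcons_id <- NULL
  S4Vectors::mcols(gr)$xloc_id <- NULL
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Exon rows are kept; `gene_id`/`transcript_id` attributes map to
#' `xloc_id`/`tcons_id`.
#'
#' @param path GTF path.
#' @return exon data frame (see [intervals]).
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  data.frame(
    tcons_id = S4Vectors::mcols(gr)$transcript_id,
    xloc_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    row.names = NULL)
}

#' Write an annotation set as GFF3
#'
#' @param annot annotation `GRanges` (see [annotation_set]).
#' @param path output path.
#' @export
write_annotation_gff3 <- function(annot, path) {
  gr <- annot
  S4Vectors::mcols(gr)$type <- ifelse(
    S4Vectors::mcols(gr)$biotype == "TE", "transposable_element", "gene")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation set from GFF3
#'
#' The `biotype` attribute is used when present; otherwise features typed
#' `transposable_element` become `TE` and everything else
#' `protein_coding`.
#'
#' @param path GFF3 path.
#' @return annotation `GRanges`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  biotype <- if ("biotype" %in% names(mc)) as.character(mc$biotype)
    else ifelse(as.character(mc$type) == "transposable_element",
                "TE", "protein_coding")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(biotype = biotype)
  gr
}

#' Write a simulated study to a directory
#'
#' @param sim an `xloc_sim` from [simulate_xloc_study].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_xloc_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "xloc_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_annotation_gff3(sim$tair_like, p("tair_like.gff3"))
  write_annotation_gff3(sim$araport_like, p("araport_like.gff3"))
  write_annotation_gff3(sim$te_set, p("te.gff3"))
  write_transcripts_gtf(sim$exons, p("transcripts.gtf"))
  samples <- do.call(rbind, lapply(sim$studies, function(s) s$samples))
  rownames(samples) <- NULL
  .write_tsv(samples, p("samples.tsv"))
  for (d in names(sim$studies)) {
    cm <- as.data.frame(sim$studies[[d]]$counts)
    cm <- cbind(locus = rownames(cm), cm)
    .write_tsv(cm, p(sprintf("counts_%s.tsv", d)))
  }
  .write_tsv(sim$psite$tracks, p("psite_tracks.tsv"))
  .write_tsv(sim$psite$meta, p("psite_meta.tsv"))
  .write_tsv(sim$homology$hits, p("homology_hits.tsv"))
  .write_tsv(sim$homology$lineages, p("lineages.tsv"))
  .write_tsv(sim$blastx, p("blastx_hits.tsv"))
  mir <- Biostrings::DNAStringSet(sim$mirnas)
  Biostrings::writeXStringSet(mir, p("mirnas.fa"))
  jsonlite::write_json(
    list(truth = sim$truth, truth_mirna = sim$truth_mirna),
    p("ground_truth.json"), dataframe = "rows", digits = NA, na = "null")
  invisible(dir)
}

#' Read pipeline inputs from a directory
#'
#' Reads back the file layout written by [write_xloc_sim] into the same
#' in-memory shape (minus the ground truth, which [read_ground_truth]
#' loads separately).
#'
#' @param dir input directory.
#' @return list with the same input slots as an `xloc_sim`.
#' @export
read_xloc_inputs <- function(dir) {
  p <- function(...) file.path(dir, ...)
  for (f in c("genome.fa", "transcripts.gtf", "samples.tsv"))
    if (!file.exists(p(f))) stop("missing input file: ", p(f))
  genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  samples <- .read_tsv(p("samples.tsv"))
  studies <- list()
  for (d in unique(samples$dataset)) {
    cm <- .read_tsv(p(sprintf("counts_%s.tsv", d)))
    counts <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts) <- cm$locus
    studies[[d]] <- expression_study(
      counts, samples[samples$dataset == d, , drop = FALSE])
  }
  list(genome = genome,
       tair_like = read_annotation_gff3(p("tair_like.gff3")),
       araport_like = read_annotation_gff3(p("araport_like.gff3")),
       te_set = read_annotation_gff3(p("te.gff3")),
       exons = read_transcripts_gtf(p("transcripts.gtf")),
       studies = studies,
       psite = list(tracks = .read_tsv(p("psite_tracks.tsv")),
                    meta = .read_tsv(p("psite_meta.tsv"))),
       homology = list(hits = .read_tsv(p("homology_hits.tsv")),
                       lineages = .read_tsv(p("lineages.tsv"))),
       blastx = .read_tsv(p("blastx_hits.tsv")),
       mirnas = {
         m <- Biostrings::readDNAStringSet(p("mirnas.fa"))
         stats::setNames(as.character(m), sub("\\s.*$", "", names(m)))
       })
}

#' Read the ground truth written by [write_xloc_sim]
#'
#' @param dir input directory.
#' @return list with `truth` and `truth_mirna` data frames.
#' @export
read_ground_truth <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
}
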