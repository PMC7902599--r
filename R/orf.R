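#' Find open reading frames in a spliced transcript sequence
#'
#' Scans the three forward frames (and the three reverse-complement frames
#' when `strand_mode = "both"`, the appropriate mode for transcripts from
#' non-strand-specific libraries) for ATG...stop spans. An ORF requires both
#' an ATG start and an in-frame stop (TAA/TAG/TGA) inside the sequence;
#' open-ended runs are not reported. Within one start chain (several ATGs
#' sharing a stop) only the longest ORF, i.e. the first ATG, is reported.
#' Codons containing N never match start or stop. `peptide_length` counts
#' codons from ATG up to but excluding the stop.
#'
#' Coordinates are 1-based positions on the scanned strand's sequence (for
#' `strand = "-"` rows, positions refer to the reverse complement); `end` is
#' the last base of the stop codon, so `end - start + 1 == 3 *
#' (peptide_length + 1)`.
#'
#' @param seq character scalar or `DNAString` over A/C/G/T/N.
#' @param strand_mode `"both"` or `"forward"`.
#' @return data frame with columns `strand`, `frame` (0/1/2), `start`,
#'   `end`, `peptide_length`, ordered by decreasing `peptide_length`.
#' @export
find_orfs <- function(seq, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  seq <- toupper(as.character(seq))
  if (!nzchar(seq))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      peptide_length = integer()))
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over A/C/G/T/N")
  scan1 <- function(s, strand) {
    n <- nchar(s)
    res <- list()
    for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < 2) next
      starts <- f + 1 + 3 * (0:(ncod - 1))
      cods <- substring(s, starts, starts + 2)
      is_start <- cods == "ATG"
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_  # codon index of first ATG since last stop
      for (k in seq_len(ncod)) {
        if (is_stop[k]) {
          if (!is.na(open)) {
            res[[length(res) + 1L]] <- data.frame(
              strand = strand, frame = f,
              start = starts[open], end = starts[k] + 2L,
              peptide_length = k - open)
            open <- NA_integer_
          }
        } else if (is_start[k] && is.na(open)) {
          open <- k
        }
      }
    }
    res
  }
  res <- scan1(seq, "+")
  if (strand_mode == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    res <- c(res, scan1(rc, "-"))
  }
  if (!length(res))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      peptide_length = integer()))
  out <- do.call(rbind, res)
  out[order(-out$peptide_length, out$strand, out$start), , drop = FALSE]
}

#' Longest ORF length (in amino acids) of a sequence
#'
#' @inheritParams find_orfs
#' @return Integer; 0 when no ORF is found.
#' @export
longest_orf_aa <- function(seq, strand_mode = c("both", "forward")) {
  orfs <- find_orfs(seq, strand_mode)
  if (!nrow(orfs)) 0L else max(orfs$peptide_length)
}

#' Biotype classification of transcripts or loci
#'
#' Applies the class rules: spliced length below `short_max_nt` gives
#' `short` (a transcript of exactly `short_max_nt` nucleotides is *long*;
#' the tie goes to lncRNA); otherwise a longest ORF of at least `orf_min_aa`
#' amino acids gives `orf_coding`; otherwise the transcript is a lncRNA,
#' sub-classified `lincRNA` when it lies at least `linc_min_distance` bp
#' from the nearest protein-coding gene and has no exonic TE overlap.
#'
#' @param spliced_length integer vector of spliced lengths (nt).
#' @param longest_orf_aa integer vector, longest ORF per entry (aa).
#' @param distance_to_gene numeric vector, bp to nearest protein-coding
#'   gene; may be NA only for entries that do not reach the lncRNA branch.
#' @param te_flag logical vector, exonic TE overlap.
#' @param short_max_nt,orf_min_aa,linc_min_distance thresholds (defaults
#'   200 nt, 100 aa, 500 bp).
#' @return factor with levels `short`, `orf_coding`, `lncRNA`, `lincRNA`
#'   (a partition: lincRNAs are not double-counted as lncRNA).
#' @export
classify_biotype <- function(spliced_length, longest_orf_aa,
                             distance_to_gene, te_flag,
                             short_max_nt = 200, orf_min_aa = 100,
                             linc_min_distance = 500) {
  n <- length(spliced_length)
  stopifnot(length(longest_orf_aa) == n, length(distance_to_gene) == n,
            length(te_flag) == n)
  cls <- character(n)
  cls[spliced_length < short_max_nt] <- "short"
  orf <- cls == "" & longest_orf_aa >= orf_min_aa
  cls[orf] <- "orf_coding"
  lnc <- cls == ""
  if (any(lnc & is.na(distance_to_gene)))
    stop("distance_to_gene is required (non-NA) for lncRNA classification")
  linc <- lnc & distance_to_gene >= linc_min_distance & !te_flag
  cls[linc] <- "lincRNA"
  cls[lnc & !linc] <- "lncRNA"
  factor(cls, levels = c("short", "orf_coding", "lncRNA", "lincRNA"))
}

#' Parse a tabular protein-homology table into per-query bins
#'
#' Consumes blastx-style tabular hits (`qseqid sseqid pident evalue`, extra
#' columns ignored). Rows failing the E-value cutoff are dropped before
#' binning; the best remaining hit per query is chosen by lowest E-value,
#' ties broken by highest identity. Bins: identity >= 97 is `full`,
#' 50 <= identity < 97 is `partial` (the published 50-96% / >= 97% bins,
#' with the 96-97 gap closed at 97), below 50 is `none`.
#'
#' @param hits data frame or path to a TSV with columns `qseqid`, `sseqid`,
#'   `pident`, `evalue`.
#' @param queries optional character vector of query ids to report even when
#'   they have no (passing) hit.
#' @param evalue_max E-value cutoff (default 1e-7).
#' @return data frame `query`, `bin` (factor none/partial/full),
#'   `best_identity`, `best_evalue` (NA when no passing hit).
#' @export
parse_homology_table <- function(hits, queries = NULL, evalue_max = 1e-7) {
  if (is.character(hits) && length(hits) == 1L)
    hits <- utils::read.delim(hits, header = TRUE, stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "pident", "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("homology table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(hits$pident))) |
               !is.finite(suppressWarnings(as.numeric(hits$evalue))))
  if (length(bad))
    stop("malformed homology row(s) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  hits$pident <- as.numeric(hits$pident)
  hits$evalue <- as.numeric(hits$evalue)
  if (is.null(queries)) queries <- unique(hits$qseqid)
  pass <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  out <- data.frame(query = queries,
                    bin = factor("none", levels = c("none", "partial", "full")),
                    best_identity = NA_real_, best_evalue = NA_real_,
                    row.names = NULL)
  if (nrow(pass)) {
    ord <- order(pass$qseqid, pass$evalue, -pass$pident)
    best <- pass[ord, ][!duplicated(pass$qseqid[ord]), ]
    m <- match(out$query, best$qseqid)
    hit <- !is.na(m)
    out$best_identity[hit] <- best$pident[m[hit]]
    out$best_evalue[hit] <- best$evalue[m[hit]]
    id <- out$best_identity[hit]
    out$bin[hit] <- ifelse(id >= 97, "full", ifelse(id >= 50, "partial", "none"))
  }
  out
}
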