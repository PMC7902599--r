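#' Assign ribosome P-sites from footprint 5' ends
#'
#' Each ribosome-protected-fragment read is converted to a P-site position
#' by adding a read-length-specific offset to its 5' end. Reads whose
#' length is absent from the offset table are dropped and counted.
#'
#' @param reads data frame with columns `pos5` (1-based transcript
#'   coordinate of the read 5' end) and `length`.
#' @param offsets data frame with columns `read_length`, `offset`.
#' @param transcript_length optional; P-sites beyond it are dropped too.
#' @return list with `track` (data frame `position`, `count`, positions
#'   with zero counts omitted) and `n_dropped`.
#' @export
assign_psites <- function(reads, offsets, transcript_length = NULL) {
  stopifnot(all(c("pos5", "length") %in% names(reads)),
            all(c("read_length", "offset") %in% names(offsets)))
  m <- match(reads$length, offsets$read_length)
  dropped <- sum(is.na(m))
  pos <- reads$pos5[!is.na(m)] + offsets$offset[m[!is.na(m)]]
  if (!is.null(transcript_length)) {
    out <- pos < 1 | pos > transcript_length
    dropped <- dropped + sum(out)
    pos <- pos[!out]
  }
  if (!length(pos))
    return(list(track = data.frame(position = integer(), count = integer()),
                n_dropped = dropped))
  tab <- table(pos)
  list(track = data.frame(position = as.integer(names(tab)),
                          count = as.integer(tab), row.names = NULL),
       n_dropped = dropped)
}

#' Periodic-footprint P-site counts per reading frame
#'
#' A transcript position is a PF P-site when its count reaches
#' `pf_min_count`. Each PF position is assigned to frame
#' `(position - anchor) mod 3` and the number of PF *positions* (not reads)
#' per frame is returned.
#'
#' @param track data frame `position`, `count`.
#' @param anchor transcript position defining frame 0 (default 1, the
#'   transcript 5' end; use the ORF start when one is annotated).
#' @param pf_min_count minimum count for a position to qualify (default 1).
#' @return named integer vector `c(F0, F1, F2)`.
#' @export
pf_frame_counts <- function(track, anchor = 1L, pf_min_count = 1L) {
  pf <- track$position[track$count >= pf_min_count]
  fr <- (pf - anchor) %% 3
  out <- vapply(0:2, function(f) sum(fr == f), integer(1))
  names(out) <- c("F0", "F1", "F2")
  out
}

#' Exact binomial enrichment test for frame periodicity
#'
#' Tests whether the dominant frame holds more PF P-sites than expected
#' under a uniform 1/3 distribution: p = min(1, 3 * P(X >= max count)) with
#' X ~ Binomial(total, 1/3); the factor 3 adjusts for selecting the maximal
#' frame. Returns NA (no signal) when there are no PF positions.
#'
#' @param frames integer vector of three per-frame PF counts.
#' @return p-value, or NA when all counts are zero.
#' @export
periodicity_test <- function(frames) {
  stopifnot(length(frames) == 3)
  n <- sum(frames)
  if (n == 0) return(NA_real_)
  k <- max(frames)
  min(1, 3 * stats::pbinom(k - 1, n, 1 / 3, lower.tail = FALSE))
}

#' Translation-likelihood calls from P-site tracks
#'
#' A transcript is *considered* when its RPF abundance reaches
#' `rpf_rpm_min` RPM in at least one condition; it is called *translated*
#' when, in addition, its maximal per-frame PF P-site count reaches
#' `min_pf`. Transcripts with two or more frames at `min_pf` or above are
#' flagged `multi_frame` (the signature of retained introns or
#' frame-shifted reading). Tracks from several conditions of the same
#' transcript are pooled position-wise before frame counting.
#'
#' @param tracks data frame with columns `transcript`, `position`, `count`
#'   (optionally `condition`; conditions are pooled for frame counts).
#' @param rpf_meta data frame with columns `transcript`, `condition`,
#'   `total_rpf_reads`, `library_total_reads`.
#' @param anchors optional named vector of frame anchors per transcript
#'   (default 1 = transcript 5' end).
#' @param min_pf minimum same-frame PF P-sites (default 5).
#' @param rpf_rpm_min RPF RPM threshold (default 1).
#' @param pf_min_count count threshold defining a PF position (default 1).
#' @return data frame `transcript`, `rpf_rpm_max` plus one `rpf_rpm_<cond>`
#'   column per condition, `F0`, `F1`, `F2`, `dominant_frame`,
#'   `periodicity_p`, `considered`, `translated`, `multi_frame`.
#' @export
call_translation <- function(tracks, rpf_meta, anchors = NULL, min_pf = 5,
                             rpf_rpm_min = 1, pf_min_count = 1L) {
  stopifnot(all(c("transcript", "position", "count") %in% names(tracks)),
            all(c("transcript", "condition", "total_rpf_reads",
                  "library_total_reads") %in% names(rpf_meta)))
  rpf_meta$rpm <- rpf_meta$total_rpf_reads / rpf_meta$library_total_reads * 1e6
  conds <- unique(rpf_meta$condition)
  tids <- unique(rpf_meta$transcript)
  rpm_mat <- sapply(conds, function(cn) {
    v <- rpf_meta$rpm[rpf_meta$condition == cn][
      match(tids, rpf_meta$transcript[rpf_meta$condition == cn])]
    v[is.na(v)] <- 0
    v
  })
  rpm_mat <- matrix(rpm_mat, nrow = length(tids),
                    dimnames = list(tids, conds))
  out <- data.frame(transcript = tids,
                    rpf_rpm_max = apply(rpm_mat, 1, max), row.names = NULL)
  for (cn in conds) out[[paste0("rpf_rpm_", cn)]] <- rpm_mat[, cn]
  fr <- matrix(0L, length(tids), 3, dimnames = list(tids, c("F0", "F1", "F2")))
  pval <- rep(NA_real_, length(tids))
  for (i in seq_along(tids)) {
    tr <- tracks[tracks$transcript == tids[i], , drop = FALSE]
    if (nrow(tr)) {
      pooled <- stats::aggregate(tr$count, by = list(position = tr$position),
                                 FUN = sum)
      names(pooled)[2] <- "count"
      anchor <- if (!is.null(anchors) && tids[i] %in% names(anchors))
        anchors[[tids[i]]] else 1L
      fr[i, ] <- pf_frame_counts(pooled, anchor = anchor,
                                 pf_min_count = pf_min_count)
      pval[i] <- periodicity_test(fr[i, ])
    }
  }
  out$F0 <- fr[, 1]; out$F1 <- fr[, 2]; out$F2 <- fr[, 3]
  out$dominant_frame <- c("F0", "F1", "F2")[max.col(fr, ties.method = "first")]
  out$dominant_frame[rowSums(fr) == 0] <- NA_character_
  out$periodicity_p <- pval
  out$considered <- out$rpf_rpm_max >= rpf_rpm_min
  out$translated <- out$considered & apply(fr, 1, max) >= min_pf
  out$multi_frame <- rowSums(fr >= min_pf) >= 2
  out
}
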