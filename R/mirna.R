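#' @title Plant miRNA target-site scoring
#'
#' @description Target sites are scored with an expectation penalty in the
#' style of the plant target-prediction tools: each aligned miRNA/target
#' position contributes 0 for a Watson-Crick match, 0.5 for a G:U wobble,
#' 1.0 for a mismatch and 2.0 for a gap, and the contribution is doubled
#' when the miRNA position (counted from its 5' end) falls in the seed span
#' 2-13. A hit is reported when the summed expectation does not exceed the
#' cutoff (3 by default). The predicted regulation mode is
#' `translational_inhibition` when any non-match state occurs at the
#' central miRNA positions 9-11 (the cleavage site), `cleavage` otherwise.
#'
#' @name mirna
NULL

.mirna_pen_params <- function() {
  list(mismatch = 1, gu = 0.5, gap = 2, seed = c(2L, 13L), seed_mult = 2)
}

.norm_rna <- function(x) chartr("Uu", "Tt", toupper(as.character(x)))

# penalty of pairing miRNA base a with target base b (antiparallel duplex)
.pair_pen_lookup <- function() {
  p <- .mirna_pen_params()
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pen <- matrix(p$mismatch, 4, 4, dimnames = list(bases, bases))
  for (a in bases) pen[a, comp[a]] <- 0
  pen["G", "T"] <- p$gu  # G:U wobble
  pen["T", "G"] <- p$gu
  pen
}

.state_lookup <- function() {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  st <- matrix("mismatch", 4, 4, dimnames = list(bases, bases))
  for (a in bases) st[a, comp[a]] <- "match"
  st["G", "T"] <- "GU"
  st["T", "G"] <- "GU"
  st
}

.seed_factor <- function(pos) {
  p <- .mirna_pen_params()
  ifelse(pos >= p$seed[1] & pos <= p$seed[2], p$seed_mult, 1)
}

#' Score one miRNA / target-site alignment
#'
#' The target site is given 5'->3' and must be the miRNA length, one base
#' shorter (one miRNA base bulged out) or one base longer (one target base
#' bulged out); the best gap placement is chosen. miRNA position 1 is its
#' 5' end and pairs with the 3' end of the site.
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param site target site sequence 5'->3'.
#' @return list with `expectation`, `states` (character vector along miRNA
#'   positions 1..m with values match/GU/mismatch, plus attribute-free
#'   `gap_pos` = the miRNA position charged for a gap, NA when ungapped).
#' @export
score_alignment <- function(mirna, site) {
  p <- .mirna_pen_params()
  mir <- strsplit(.norm_rna(mirna), "")[[1]]
  tgt <- strsplit(.norm_rna(site), "")[[1]]
  m <- length(mir); L <- length(tgt)
  if (any(!mir %in% c("A", "C", "G", "T")) || any(!tgt %in% c("A", "C", "G", "T")))
    stop("sequences must be over the A/C/G/U/T alphabet")
  pen <- .pair_pen_lookup(); stl <- .state_lookup()
  sf <- .seed_factor(seq_len(m))
  score_pairing <- function(tidx, gap_pos) {
    # tidx[i] = target index paired with miRNA position i (length m)
    pp <- vapply(seq_len(m), function(i) pen[mir[i], tgt[tidx[i]]], numeric(1))
    st <- vapply(seq_len(m), function(i) stl[mir[i], tgt[tidx[i]]], character(1))
    e <- sum(pp * sf)
    if (!is.na(gap_pos))
      e <- e + p$gap * .seed_factor(gap_pos)
    list(expectation = e, states = st, gap_pos = gap_pos)
  }
  if (L == m) {
    return(score_pairing(rev(seq_len(m)), NA_integer_))
  } else if (L == m + 1) {
    # one target base bulged between miRNA positions g and g+1
    best <- NULL
    for (g in seq_len(m - 1)) {
      tidx <- ifelse(seq_len(m) <= g, m - seq_len(m) + 2L, m - seq_len(m) + 1L)
      cand <- score_pairing(tidx, g + 1L)
      if (is.null(best) || cand$expectation < best$expectation) best <- cand
    }
    return(best)
  } else if (L == m - 1) {
    # one miRNA base (position g) bulged out
    best <- NULL
    for (g in seq_len(m)) {
      ii <- setdiff(seq_len(m), g)
      tidx <- integer(m)
      tidx[ii] <- ifelse(ii > g, m - ii, m - ii - 1L) + 1L
      pp <- vapply(ii, function(i) pen[mir[i], tgt[tidx[i]]], numeric(1))
      st <- rep("gap", m)
      st[ii] <- vapply(ii, function(i) stl[mir[i], tgt[tidx[i]]], character(1))
      e <- sum(pp * .seed_factor(ii)) + p$gap * .seed_factor(g)
      cand <- list(expectation = e, states = st, gap_pos = g)
      if (is.null(best) || cand$expectation < best$expectation) best <- cand
    }
    return(best)
  }
  stop("site length must be within one base of the miRNA length")
}

# penalty rows P[i, t] for miRNA position i against every target position
.penalty_rows <- function(mir, tgt) {
  pen <- .pair_pen_lookup()
  sf <- .seed_factor(seq_along(mir))
  lapply(seq_along(mir), function(i) unname(pen[mir[i], tgt]) * sf[i])
}

# best site of one miRNA in one sequence; returns NULL when nothing scores
# at or below emax
.scan_one <- function(mir, tgt, emax, allow_gap = TRUE) {
  p <- .mirna_pen_params()
  m <- length(mir); L <- length(tgt)
  best <- NULL
  upd <- function(score, s, type, len) {
    if (score <= emax &&
        (is.null(best) || score < best$score ||
         (score == best$score && s < best$s)))
      best <<- list(score = score, s = s, type = type, len = len)
  }
  if (L < m) return(NULL)
  P <- .penalty_rows(mir, tgt)
  nu <- L - m + 1
  U <- numeric(nu)
  for (i in seq_len(m)) U <- U + P[[i]][(m - i + 1):(L - i + 1)]
  s_best <- which.min(U)
  upd(U[s_best], s_best, "ungapped", m)
  if (allow_gap && L >= m + 1) {
    # target bulge: windows of length m + 1
    ns <- L - m
    S <- numeric(ns)  # sum over i > g of P[i, s + m - i]
    for (i in seq_len(m)) S <- S + P[[i]][(m - i + 1):(L - i)]
    R <- numeric(ns)  # sum over i <= g of P[i, s + m - i + 1]
    Tb <- rep(Inf, ns)
    gb <- integer(ns)
    for (g in seq_len(m - 1)) {
      S <- S - P[[g]][(m - g + 1):(L - g)]
      R <- R + P[[g]][(m - g + 2):(L - g + 1)]
      tot <- S + R + p$gap * .seed_factor(g + 1L)
      better <- tot < Tb
      Tb[better] <- tot[better]
      gb[better] <- g
    }
    s_best <- which.min(Tb)
    upd(Tb[s_best], s_best, "target_bulge", m + 1L)
  }
  if (allow_gap && L >= m - 1 && m >= 2) {
    # miRNA bulge: windows of length m - 1
    ns <- L - m + 2
    S <- numeric(ns)  # sum over i > g of P[i, s + m - i]
    for (i in seq_len(m)) {
      if (i == 1) next  # i ranges g+1..m with g >= 1
      S <- S + P[[i]][(m - i + 1):(L - i + 2)]
    }
    R <- numeric(ns)  # sum over i < g of P[i, s + m - i - 1]
    Mb <- rep(Inf, ns)
    for (g in seq_len(m)) {
      if (g > 1) {
        gm <- g - 1L
        R <- R + P[[gm]][(m - gm):(L - gm + 1)]
        S <- S - P[[g]][(m - g + 1):(L - g + 2)]
      }
      tot <- S + R + p$gap * .seed_factor(g)
      better <- tot < Mb
      Mb[better] <- tot[better]
    }
    s_best <- which.min(Mb)
    upd(Mb[s_best], s_best, "mirna_bulge", m - 1L)
  }
  best
}

#' Find miRNA target sites in locus sequences
#'
#' Scans every (miRNA, sequence) pair for its best-scoring site using the
#' expectation scheme of [score_alignment]; the search covers all ungapped
#' windows plus all windows with a single one-base bulge on either strand
#' of the duplex. Only the best site per pair is reported, and only when
#' its expectation is at or below `expectation_max`; score ties are broken
#' by the 5'-most site. T and U are equivalent.
#'
#' @param mirnas named character vector (or `DNAStringSet`/`RNAStringSet`)
#'   of mature miRNA sequences, 5'->3'; each must be at least 15 nt.
#' @param sequences named character vector (or `DNAStringSet`) of target
#'   (transcript or locus) sequences.
#' @param expectation_max report threshold (default 3).
#' @param allow_gap also search single-bulge alignments (default TRUE).
#' @return data frame `mirna`, `locus`, `start`, `end` (site coordinates on
#'   the target, 1-based), `expectation`, `mode` (`cleavage` /
#'   `translational_inhibition`), `alignment` (string along miRNA positions
#'   5'->3': `=` match, `o` G:U, `x` mismatch, `-` bulged miRNA base).
#' @export
find_mirna_targets <- function(mirnas, sequences, expectation_max = 3,
                               allow_gap = TRUE) {
  mnames <- names(mirnas); snames <- names(sequences)
  if (is.null(mnames) || is.null(snames))
    stop("mirnas and sequences must be named")
  mirnas <- stats::setNames(.norm_rna(as.character(mirnas)), mnames)
  sequences <- stats::setNames(.norm_rna(as.character(sequences)), snames)
  short <- nchar(mirnas) < 15
  if (any(short))
    stop("miRNA(s) shorter than 15 nt: ",
         paste(names(mirnas)[short], collapse = ", "))
  res <- list()
  for (mi in names(mirnas)) {
    mir <- strsplit(mirnas[[mi]], "")[[1]]
    for (si in names(sequences)) {
      tgt <- strsplit(sequences[[si]], "")[[1]]
      hit <- .scan_one(mir, tgt, expectation_max, allow_gap)
      if (is.null(hit)) next
      site <- substr(sequences[[si]], hit$s, hit$s + hit$len - 1L)
      aln <- score_alignment(mirnas[[mi]], site)
      states <- aln$states
      sym <- c(match = "=", GU = "o", mismatch = "x", gap = "-")
      central <- states[9:min(11, length(states))]
      mode <- if (any(central != "match")) "translational_inhibition" else "cleavage"
      res[[length(res) + 1L]] <- data.frame(
        mirna = mi, locus = si,
        start = hit$s, end = hit$s + hit$len - 1L,
        expectation = aln$expectation, mode = mode,
        alignment = paste(sym[states], collapse = ""),
        row.names = NULL)
    }
  }
  if (!length(res))
    return(data.frame(mirna = character(), locus = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), mode = character(),
                      alignment = character()))
  do.call(rbind, res)
}
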