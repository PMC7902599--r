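# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# minimum gap between [s1,e1] and the nearest of a set of intervals
# (1-based closed); 0 on overlap
oracle_min_gap <- function(s1, e1, starts, ends) {
  if (!length(starts)) return(NA_real_)
  gaps <- numeric(length(starts))
  for (i in seq_along(starts)) {
    if (e1 >= starts[i] && s1 <= ends[i]) gaps[i] <- 0
    else if (e1 < starts[i]) gaps[i] <- starts[i] - e1 - 1
    else gaps[i] <- s1 - ends[i] - 1
  }
  min(gaps)
}

# naive six-frame ORF scan: every ATG..stop span, longest per start chain
oracle_orfs <- function(seq) {
  seq <- toupper(seq)
  revcomp <- function(s) {
    m <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(m[strsplit(s, "")[[1]]]), collapse = "")
  }
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    for (f in 0:2) {
      i <- f + 1
      open <- NA
      while (i + 2 <= n) {
        cod <- substr(s, i, i + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(open)) {
            out[[length(out) + 1]] <- data.frame(
              strand = strand, frame = f, start = open, end = i + 2,
              peptide_length = (i - open) / 3)
            open <- NA
          }
        } else if (cod == "ATG" && is.na(open)) open <- i
        i <- i + 3
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      peptide_length = integer()))
  do.call(rbind, out)
}

# connected components of transcripts by pairwise exonic overlap
oracle_components <- function(exons) {
  tids <- unique(exons$tcons_id)
  n <- length(tids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    ei <- exons[exons$tcons_id == tids[i], ]
    ej <- exons[exons$tcons_id == tids[j], ]
    if (ei$chrom[1] != ej$chrom[1]) next
    si <- ei$strand[1]; sj <- ej$strand[1]
    if (si != "*" && sj != "*" && si != sj) next
    ov <- FALSE
    for (a in seq_len(nrow(ei))) for (b in seq_len(nrow(ej)))
      if (ei$start[a] <= ej$end[b] && ej$start[b] <= ei$end[a]) ov <- TRUE
    adj[i, j] <- adj[j, i] <- ov
  }
  comp <- rep(NA_integer_, n)
  cc <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cc <- cc + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  stats::setNames(comp, tids)
}

# ungapped miRNA expectation of the best window (gap-free oracle)
oracle_mirna_best <- function(mirna, target) {
  norm <- function(x) chartr("Uu", "Tt", toupper(x))
  mir <- strsplit(norm(mirna), "")[[1]]
  tgt <- strsplit(norm(target), "")[[1]]
  m <- length(mir); L <- length(tgt)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pen1 <- function(a, b) {
    if (comp[[a]] == b) 0
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) 0.5
    else 1
  }
  best <- Inf; best_s <- NA
  if (L >= m) for (s in 1:(L - m + 1)) {
    e <- 0
    for (i in 1:m) {
      p <- pen1(mir[i], tgt[s + m - i])
      if (i >= 2 && i <= 13) p <- 2 * p
      e <- e + p
    }
    if (e < best) { best <- e; best_s <- s }
  }
  list(expectation = best, start = best_s)
}

# frame tally of PF positions by brute mod-3
oracle_frames <- function(positions, counts, anchor, min_count = 1) {
  pf <- positions[counts >= min_count]
  f <- integer(3)
  for (p in pf) f[((p - anchor) %% 3) + 1] <- f[((p - anchor) %% 3) + 1] + 1
  f
}

random_exon_table <- function(n_tx, chroms = c("chr1", "chr2"),
                              max_pos = 5000) {
  rows <- list()
  for (i in seq_len(n_tx)) {
    ne <- sample(1:3, 1)
    st <- sort(sample(seq_len(max_pos), ne))
    w <- sample(20:120, ne, replace = TRUE)
    ex <- data.frame(start = st, end = st + w)
    # enforce disjoint, ordered exons
    if (ne > 1) for (j in 2:ne)
      if (ex$start[j] <= ex$end[j - 1]) ex$start[j] <- ex$end[j - 1] + 10
    ex$end <- pmax(ex$end, ex$start + 5)
    rows[[i]] <- data.frame(tcons_id = sprintf("T%03d", i),
                            chrom = sample(chroms, 1),
                            start = ex$start, end = ex$end,
                            strand = sample(c("+", "-", "*"), 1))
  }
  do.call(rbind, rows)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
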