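#' Pipeline run configuration
#'
#' One place for every numeric threshold of the characterization: the
#' low-count filter, the RPM thresholds for expressed / highly expressed /
#' present calls, the DEX rule, the lincRNA distance, the ORF and length
#' class bounds, the two E-value cutoffs (nucleotide homology for
#' phylostrata; protein homology for smORF evidence), the miRNA
#' expectation cutoff and the translation-call thresholds.
#'
#' @param min_count low-count filter (default 10).
#' @param rpm_pex,rpm_hpex,rpm_present RPM thresholds (1, 10, 0.05).
#' @param rpm_sporo_max sporophytic-silence cutoff for the PSX call (1).
#' @param lfc_min,padj_max DEX rule (1, 0.05).
#' @param linc_distance minimum gene distance for lincRNA (500 bp).
#' @param orf_min_aa,short_max_nt class bounds (100 aa, 200 nt).
#' @param evalue_phylo,evalue_blastx E-value cutoffs (1e-5, 1e-7).
#' @param expectation_max miRNA expectation cutoff (3).
#' @param min_pf,rpf_rpm_min,pf_min_count translation-call thresholds
#'   (5 PF P-sites, 1 RPM, count >= 1 defines a PF position).
#' @return list of class `run_config`.
#' @export
run_config <- function(min_count = 10, rpm_pex = 1, rpm_hpex = 10,
                       rpm_present = 0.05, rpm_sporo_max = 1,
                       lfc_min = 1, padj_max = 0.05,
                       linc_distance = 500, orf_min_aa = 100,
                       short_max_nt = 200, evalue_phylo = 1e-5,
                       evalue_blastx = 1e-7, expectation_max = 3,
                       min_pf = 5, rpf_rpm_min = 1, pf_min_count = 1) {
  cfg <- as.list(environment())
  if (any(unlist(cfg) <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "run_config")
}

.resolve_inputs <- function(inputs) {
  if (inherits(inputs, "xloc_sim")) return(inputs)
  if (is.character(inputs) && length(inputs) == 1L)
    return(read_xloc_inputs(inputs))
  if (is.list(inputs)) return(inputs)
  stop("inputs must be an xloc_sim, an input list, or a directory path")
}

#' Run the full XLOC characterization pipeline
#'
#' Groups the transcript models into loci, classifies novelty against the
#' two reference annotations, assigns biotypes from spliced length, ORF
#' content, gene distance and TE overlap, computes RPM/threshold calls and
#' NB Wald differential expression per dataset, assigns phylostrata, bins
#' protein homology, scans for miRNA target sites, and calls translation
#' likelihood from P-site tracks. Deterministic given inputs and
#' configuration.
#'
#' @param inputs an `xloc_sim`, the list returned by [read_xloc_inputs],
#'   or a directory path.
#' @param config a [run_config].
#' @return list of class `xloc_run` with `records` (one row per locus),
#'   `summary` (partition counts and DEX overlaps), and the per-stage
#'   tables (`de`, `specificity`, `phylostrata`, `mirna_hits`,
#'   `translation`).
#' @export
run_pipeline <- function(inputs, config = run_config()) {
  inputs <- .resolve_inputs(inputs)
  stopifnot(inherits(config, "run_config"))

  # --- loci ---------------------------------------------------------
  exons <- group_into_loci(inputs$exons)
  tl <- transcript_lengths(exons)
  dup <- any(duplicated(unique(exons[, c("tcons_id", "xloc_id")])$tcons_id))
  if (dup) stop("transcript id collision across loci")
  loci <- sort(unique(exons$xloc_id))
  nov <- classify_novelty(exons, inputs$tair_like, inputs$araport_like)
  dist <- distance_to_nearest_gene(exons, inputs$tair_like)
  te <- te_overlap(exons, inputs$te_set)

  # --- biotype (locus class = longest representative transcript) ----
  tl <- tl[order(tl$xloc_id, -tl$spliced_length, tl$tcons_id), ]
  rep_tx <- tl[!duplicated(tl$xloc_id), ]
  seqs <- spliced_sequences(
    exons[exons$tcons_id %in% rep_tx$tcons_id, , drop = FALSE],
    inputs$genome)
  orf_aa <- integer(nrow(rep_tx))
  orf_start <- rep(NA_integer_, nrow(rep_tx))
  for (i in seq_len(nrow(rep_tx))) {
    mode <- if (rep_tx$strand[i] == "*") "both" else "forward"
    orfs <- find_orfs(seqs[[rep_tx$tcons_id[i]]], mode)
    if (nrow(orfs)) {
      orf_aa[i] <- orfs$peptide_length[1]
      if (orfs$strand[1] == "+") orf_start[i] <- orfs$start[1]
    }
  }
  rec <- data.frame(xloc_id = rep_tx$xloc_id,
                    representative_tcons = rep_tx$tcons_id,
                    spliced_length = rep_tx$spliced_length,
                    longest_orf_aa = orf_aa, row.names = NULL)
  rec <- rec[match(loci, rec$xloc_id), ]
  rec$n_isoforms <- as.integer(table(unique(
    exons[, c("tcons_id", "xloc_id")])$xloc_id)[loci])
  rec$novelty <- nov$novelty[match(loci, nov$xloc_id)]
  rec$distance_to_gene <- dist$distance_to_gene[match(loci, dist$xloc_id)]
  rec$te_overlap <- te$te_overlap[match(loci, te$xloc_id)]
  rec$class <- classify_biotype(rec$spliced_length, rec$longest_orf_aa,
                                rec$distance_to_gene, rec$te_overlap,
                                short_max_nt = config$short_max_nt,
                                orf_min_aa = config$orf_min_aa,
                                linc_min_distance = config$linc_distance)

  # --- expression ---------------------------------------------------
  dataset_types <- character(0)
  mean_rpm <- list(); de_tables <- list()
  for (d in names(inputs$studies)) {
    study <- inputs$studies[[d]]
    ty <- if ("type" %in% names(study$samples)) study$samples$type[1]
          else "pollen"
    dataset_types[d] <- ty
    mean_rpm[[d]] <- condition_mean_rpm(study)
    filt <- filter_low_counts(study, min_count = config$min_count)
    de <- nb_wald_test(filt, dataset = d)
    de$dex <- call_dex(de, lfc_min = config$lfc_min,
                       padj_max = config$padj_max)
    de_tables[[d]] <- de
  }
  mean_rpm <- do.call(rbind, mean_rpm)
  spec <- call_specificity(mean_rpm, dataset_types,
                           rpm_pex = config$rpm_pex,
                           rpm_hpex = config$rpm_hpex,
                           rpm_present = config$rpm_present,
                           rpm_sporo_max = config$rpm_sporo_max)
  m <- match(loci, spec$per_locus$locus)
  rec$pex <- spec$per_locus$pex[m]
  rec$hpex <- spec$per_locus$hpex[m]
  rec$psx <- spec$per_locus$psx[m]
  for (d in names(de_tables)) {
    pd <- spec$per_dataset[spec$per_dataset$dataset == d, ]
    md <- match(loci, pd$locus)
    rec[[paste0("expressed_", d)]] <- pd$expressed[md]
    rec[[paste0("pex_", d)]] <- pd$pex[md]
    rec[[paste0("hpex_", d)]] <- pd$hpex[md]
    de <- de_tables[[d]]
    mde <- match(loci, de$locus)
    rec[[paste0("lfc_", d)]] <- de$lfc[mde]
    rec[[paste0("padj_", d)]] <- de$padj[mde]
    dx <- de$dex[mde]
    dx[is.na(dx)] <- FALSE
    rec[[paste0("dex_", d)]] <- dx
  }

  # --- phylostrata --------------------------------------------------
  # convention: the first row of the lineage table is the focal species
  lineages <- read_lineages(inputs$homology$lineages)
  focal <- names(lineages)[1]
  phylo <- assign_phylostrata(inputs$homology$hits, lineages, focal,
                              loci = loci,
                              evalue_max = config$evalue_phylo)
  mp <- match(loci, phylo$locus)
  rec$stratum <- phylo$stratum[mp]
  rec$n_homology_hits <- phylo$n_hits[mp]

  # --- protein homology bins ----------------------------------------
  hom <- parse_homology_table(inputs$blastx, queries = loci,
                              evalue_max = config$evalue_blastx)
  rec$protein_bin <- hom$bin[match(loci, hom$query)]

  # --- miRNA targets ------------------------------------------------
  mirna_hits <- find_mirna_targets(
    inputs$mirnas, stats::setNames(as.character(seqs), names(seqs)),
    expectation_max = config$expectation_max)
  if (nrow(mirna_hits)) {
    mirna_hits$locus <- rep_tx$xloc_id[
      match(mirna_hits$locus, rep_tx$tcons_id)]
    nh <- table(mirna_hits$locus)
    rec$n_mirna_hits <- as.integer(nh[loci])
    rec$n_mirna_hits[is.na(rec$n_mirna_hits)] <- 0L
  } else rec$n_mirna_hits <- 0L

  # --- translation --------------------------------------------------
  if (!is.null(inputs$psite) && nrow(inputs$psite$meta)) {
    tcalls <- call_translation(inputs$psite$tracks, inputs$psite$meta,
                               min_pf = config$min_pf,
                               rpf_rpm_min = config$rpf_rpm_min,
                               pf_min_count = config$pf_min_count)
    tcalls$xloc_id <- exons$xloc_id[match(tcalls$transcript, exons$tcons_id)]
    # locus-level: best transcript by maximal PF count
    tcalls$max_pf <- pmax(tcalls$F0, tcalls$F1, tcalls$F2)
    tc <- tcalls[order(tcalls$xloc_id, -tcalls$max_pf), ]
    tc_loc <- tc[!duplicated(tc$xloc_id), ]
    cons <- tapply(tcalls$considered, tcalls$xloc_id, any)
    trans <- tapply(tcalls$translated, tcalls$xloc_id, any)
    mt <- match(loci, tc_loc$xloc_id)
    rec$rpf_considered <- as.logical(cons[loci])
    rec$rpf_considered[is.na(rec$rpf_considered)] <- FALSE
    rec$translated <- as.logical(trans[loci])
    rec$translated[is.na(rec$translated)] <- FALSE
    rec$dominant_frame <- tc_loc$dominant_frame[mt]
    rec$multi_frame <- tc_loc$multi_frame[mt]
    rec$multi_frame[is.na(rec$multi_frame)] <- FALSE
  } else {
    tcalls <- NULL
    rec$rpf_considered <- FALSE
    rec$translated <- FALSE
    rec$dominant_frame <- NA_character_
    rec$multi_frame <- FALSE
  }

  summary <- xloc_summary(rec, dataset_types)
  structure(list(records = rec, summary = summary, de = de_tables,
                 specificity = spec, phylostrata = phylo,
                 mirna_hits = mirna_hits, translation = tcalls,
                 dataset_types = dataset_types, config = config),
            class = "xloc_run")
}

#' @export
print.xloc_run <- function(x, ...) {
  s <- x$summary
  cat("xloc_run:", s$n_xloc, "loci (", s$novelty["novel"], "novel /",
      s$novelty["recent"], "recent );",
      "classes:", paste(names(s$class), s$class, collapse = ", "), "\n")
  invisible(x)
}

#' Partition and funnel summary of a record table
#'
#' @param records record table from [run_pipeline].
#' @param dataset_types named vector mapping dataset to pollen /
#'   sporophytic.
#' @return list of headline counts (cohort size, novelty and class
#'   partitions, per-dataset PEX/hPEX/DEX, PSX, strata histogram,
#'   translation funnel and DEX overlap regions).
#' @export
xloc_summary <- function(records, dataset_types) {
  dex_cols <- grep("^dex_", names(records), value = TRUE)
  dex_sets <- lapply(dex_cols, function(cn)
    records$xloc_id[records[[cn]]])
  names(dex_sets) <- sub("^dex_", "", dex_cols)
  pollen <- names(dataset_types)[dataset_types == "pollen"]
  list(n_xloc = nrow(records),
       n_multi_isoform = sum(records$n_isoforms >= 2),
       novelty = table(records$novelty),
       class = table(records$class),
       n_lncRNA_total = sum(records$class %in% c("lncRNA", "lincRNA")),
       pex = vapply(pollen, function(d)
         sum(records[[paste0("pex_", d)]]), integer(1)),
       hpex = vapply(pollen, function(d)
         sum(records[[paste0("hpex_", d)]]), integer(1)),
       dex = vapply(names(dex_sets), function(d)
         length(dex_sets[[d]]), integer(1)),
       n_psx = sum(records$psx),
       strata = table(records$stratum),
       n_rpf_considered = sum(records$rpf_considered),
       n_translated = sum(records$translated),
       dex_overlaps = summarize_overlaps(dex_sets[
         intersect(names(dex_sets), pollen)]))
}

#' Exclusive region counts of k sets (Venn regions)
#'
#' @param sets named list of character vectors.
#' @return data frame `region` (set names joined by `&`), `count`
#'   (elements belonging to exactly those sets); all `2^k - 1` regions are
#'   reported and their counts sum to the union size.
#' @export
summarize_overlaps <- function(sets) {
  k <- length(sets)
  if (k == 0)
    return(data.frame(region = character(), count = integer()))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  region <- apply(combos, 1, function(sel)
    paste(names(sets)[as.logical(sel)], collapse = "&"))
  count <- apply(combos, 1, function(sel)
    sum(apply(memb, 1, function(r) all(r == as.logical(sel)))))
  if (!length(universe)) count <- rep(0L, nrow(combos))
  data.frame(region = region, count = as.integer(count), row.names = NULL)
}

#' Recount headline cohort numbers from a per-locus characterization table
#'
#' Applies the package's classification and threshold rules to the columns
#' of an XLOC record table (such as one assembled from supplementary
#' per-locus tables) and reports the resulting counts. When the raw
#' ingredient columns (`spliced_length`, `longest_orf_aa`,
#' `distance_to_gene`, `te_overlap`) are present the biotype partition is
#' recomputed from them; likewise DEX flags are recomputed from
#' `lfc_<dataset>` / `padj_<dataset>` columns. A `schema` can map the
#' table's actual column names onto the canonical ones.
#'
#' @param tab data frame (or TSV path) with one row per locus.
#' @param schema optional named character vector, canonical name ->
#'   column name in `tab`.
#' @param config a [run_config] supplying the thresholds.
#' @return named numeric vector of counts (all zero for an empty table).
#' @export
recount_from_supplementary <- function(tab, schema = NULL,
                                       config = run_config()) {
  if (is.character(tab) && length(tab) == 1L) tab <- .read_tsv(tab)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(tab))
    if (length(miss))
      stop("schema refers to missing column(s): ",
           paste(miss, collapse = ", "))
    for (canon in names(schema)) {
      names(tab)[names(tab) == schema[[canon]]] <- canon
    }
  }
  if (!"xloc_id" %in% names(tab))
    stop("required column missing: xloc_id")
  out <- c(n_xloc = length(unique(tab$xloc_id)))
  if (nrow(tab) == 0) {
    out <- c(out, n_multi_isoform = 0, n_novel = 0, n_recent = 0,
             n_short = 0, n_orf_coding = 0, n_lncRNA = 0, n_lincRNA = 0,
             n_lncRNA_total = 0, n_psx = 0, n_translated = 0)
    return(out)
  }
  if ("n_isoforms" %in% names(tab))
    out["n_multi_isoform"] <- sum(tab$n_isoforms >= 2)
  if ("novelty" %in% names(tab)) {
    out["n_novel"] <- sum(tab$novelty == "novel")
    out["n_recent"] <- sum(tab$novelty == "recent")
  }
  cls <- NULL
  raw <- c("spliced_length", "longest_orf_aa", "distance_to_gene",
           "te_overlap")
  if (all(raw %in% names(tab))) {
    cls <- classify_biotype(tab$spliced_length, tab$longest_orf_aa,
                            tab$distance_to_gene, tab$te_overlap,
                            short_max_nt = config$short_max_nt,
                            orf_min_aa = config$orf_min_aa,
                            linc_min_distance = config$linc_distance)
  } else if ("class" %in% names(tab)) cls <- tab$class
  if (!is.null(cls)) {
    out["n_short"] <- sum(cls == "short")
    out["n_orf_coding"] <- sum(cls == "orf_coding")
    out["n_lncRNA"] <- sum(cls == "lncRNA")
    out["n_lincRNA"] <- sum(cls == "lincRNA")
    out["n_lncRNA_total"] <- sum(cls %in% c("lncRNA", "lincRNA"))
  }
  for (cn in grep("^pex_", names(tab), value = TRUE))
    out[paste0("n_", cn)] <- sum(tab[[cn]], na.rm = TRUE)
  for (cn in grep("^hpex_", names(tab), value = TRUE))
    out[paste0("n_", cn)] <- sum(tab[[cn]], na.rm = TRUE)
  lfc_cols <- grep("^lfc_", names(tab), value = TRUE)
  for (cn in lfc_cols) {
    d <- sub("^lfc_", "", cn)
    pc <- paste0("padj_", d)
    if (pc %in% names(tab)) {
      dex <- abs(tab[[cn]]) >= config$lfc_min & tab[[pc]] < config$padj_max
      out[paste0("n_dex_", d)] <- sum(dex, na.rm = TRUE)
    }
  }
  if ("psx" %in% names(tab)) out["n_psx"] <- sum(tab$psx, na.rm = TRUE)
  if ("stratum" %in% names(tab)) {
    st <- table(tab$stratum)
    out[paste0("n_stratum_", gsub("[^A-Za-z0-9]+", "_", names(st)))] <-
      as.integer(st)
  }
  if ("rpf_considered" %in% names(tab))
    out["n_rpf_considered"] <- sum(tab$rpf_considered, na.rm = TRUE)
  if ("translated" %in% names(tab))
    out["n_translated"] <- sum(tab$translated, na.rm = TRUE)
  out
}
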