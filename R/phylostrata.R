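#' Read a taxon lineage table
#'
#' @param x data frame with columns `taxon` and `lineage`
#'   (semicolon-joined, root to tip), or a path to such a TSV.
#' @return named list of character vectors (root-to-tip node names).
#' @export
read_lineages <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.delim(x, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("taxon", "lineage") %in% names(x)))
    stop("lineage table needs columns 'taxon' and 'lineage'")
  lin <- strsplit(x$lineage, ";", fixed = TRUE)
  lin <- lapply(lin, trimws)
  names(lin) <- x$taxon
  if (any(lengths(lin) == 0)) stop("empty lineage entry")
  lin
}

#' Lowest common ancestor of two root-to-tip lineages
#'
#' Lineages are compared positionally from the root; the deepest node at
#' which they still agree is returned. The lineage file is authoritative:
#' no taxonomy reconciliation is attempted.
#'
#' @param hit_lineage,focal_lineage character vectors, root to tip.
#' @return list with `node` (name) and `depth` (1-based index in
#'   `focal_lineage`).
#' @export
lca_node <- function(hit_lineage, focal_lineage) {
  k <- min(length(hit_lineage), length(focal_lineage))
  same <- hit_lineage[seq_len(k)] == focal_lineage[seq_len(k)]
  if (!same[1])
    stop("lineages share no root node")
  d <- if (all(same)) k else which(!same)[1] - 1L
  list(node = focal_lineage[d], depth = d)
}

#' Assign phylostrata to loci from a homology hit table
#'
#' Hits to the focal species itself are excluded (emulating a search run
#' that omits self-matches), then hits failing the E-value cutoff are
#' dropped. Each remaining hit is mapped to the lowest common ancestor of
#' its subject taxon's lineage with the focal lineage; the locus stratum is
#' the root-most such node (the oldest phylogenetic node at which a homolog
#' is detected). Loci with no passing hit are assigned the focal species
#' stratum (species-specific).
#'
#' @param hits data frame with columns `query`, `subject_taxon`, `pident`,
#'   `evalue` (or a path to such a TSV).
#' @param lineages named list from [read_lineages]; must cover every
#'   subject taxon.
#' @param focal_taxon name of the focal species (must be in `lineages`).
#' @param loci optional character vector of locus ids to report even
#'   without hits.
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return data frame `locus`, `stratum`, `stratum_depth` (1 = root-most
#'   node of the focal lineage), `n_hits` (passing hits).
#' @export
assign_phylostrata <- function(hits, lineages, focal_taxon, loci = NULL,
                               evalue_max = 1e-5) {
  if (is.character(hits) && length(hits) == 1L)
    hits <- utils::read.delim(hits, header = TRUE, stringsAsFactors = FALSE)
  need <- c("query", "subject_taxon", "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  if (!focal_taxon %in% names(lineages))
    stop("focal taxon missing from lineage table: ", focal_taxon)
  focal <- lineages[[focal_taxon]]
  hits <- hits[hits$subject_taxon != focal_taxon, , drop = FALSE]
  unknown <- setdiff(unique(hits$subject_taxon), names(lineages))
  if (length(unknown))
    stop("subject taxa missing from lineage table: ",
         paste(unknown, collapse = ", "))
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (is.null(loci)) loci <- unique(hits$query)
  taxa <- unique(hits$subject_taxon)
  depth_by_taxon <- vapply(taxa, function(tx)
    lca_node(lineages[[tx]], focal)$depth, integer(1))
  hit_depth <- depth_by_taxon[hits$subject_taxon]
  out <- data.frame(locus = loci,
                    stratum = focal[length(focal)],
                    stratum_depth = length(focal),
                    n_hits = 0L, row.names = NULL)
  if (nrow(hits)) {
    mind <- tapply(hit_depth, hits$query, min)
    nh <- table(hits$query)
    m <- match(out$locus, names(mind))
    has <- !is.na(m)
    out$stratum_depth[has] <- as.integer(mind[m[has]])
    out$stratum[has] <- focal[out$stratum_depth[has]]
    out$n_hits[has] <- as.integer(nh[names(mind)[m[has]]])
  }
  out
}
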