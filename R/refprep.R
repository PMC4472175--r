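# Minimal (m-CDS) and singleton (s-CDS) mapping references: paralog groups
# are connected components of the all-vs-all protein homology graph at an
# E-value cutoff calibrated on known paralog pairs.

#' E-value cutoff from known paralog pairs
#'
#' Returns the nearest-rank 95th percentile (by default) of the E-values of
#' known paralog pairs, i.e. a cutoff at least as large (as permissive) as
#' 95\% of known-paralog E-values.
#'
#' @param known_paralog_evalues numeric vector of non-negative E-values.
#' @param percentile percentile in (0, 100]; default 95.
#' @return a single E-value cutoff.
#' @export
select_evalue_cutoff <- function(known_paralog_evalues, percentile = 95) {
  x <- known_paralog_evalues
  if (length(x) == 0L) stop("empty E-value list")
  if (any(x < 0)) stop("E-values must be non-negative")
  s <- sort(x)
  s[ceiling(percentile / 100 * length(s))]
}

#' Read BLAST tabular ("outfmt 6"-style) homology hits
#'
#' Expects at least columns qseqid, sseqid, ..., evalue, bitscore; only the
#' first, second, second-to-last and last columns are used.
#'
#' @param path TSV path.
#' @return \code{data.table} with query_id, subject_id, evalue, bitscore.
#' @export
read_homology_hits <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  nc <- ncol(x)
  if (nc < 4L) stop("homology hit table needs >= 4 columns")
  out <- x[, c(1L, 2L, nc - 1L, nc), with = FALSE]
  data.table::setnames(out, c("query_id", "subject_id", "evalue", "bitscore"))
  out
}

#' Group paralogs as connected components of the homology graph
#'
#' Self-hits are removed; a pair of genes is connected when the smaller of
#' its two directional E-values is at most \code{cutoff}; paralog groups are
#' the connected components, genes without a qualifying edge forming
#' singleton groups.
#'
#' @param hits data.frame with query_id, subject_id, evalue (e.g. from
#'   \code{\link{read_homology_hits}}).
#' @param cutoff E-value cutoff (see \code{\link{select_evalue_cutoff}}).
#' @param gene_ids the full gene universe; hits must reference only these.
#' @return named list of member-id character vectors (names are the group
#'   representatives' ids once \code{\link{build_reference}} assigns them;
#'   here names are arbitrary \code{grp...} labels).
#' @export
build_paralog_groups <- function(hits, cutoff, gene_ids) {
  hits <- data.table::as.data.table(hits)
  bad <- setdiff(unique(c(hits$query_id, hits$subject_id)), gene_ids)
  if (length(bad) > 0L)
    stop("hits reference genes absent from the CDS set: ",
         paste(head(bad, 5L), collapse = ", "))
  hits <- hits[query_id != subject_id]
  # undirected pair key; min over the two directions
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  pr <- data.table::data.table(a = a, b = b, evalue = hits$evalue)
  pr <- pr[, .(evalue = min(evalue)), by = .(a, b)]
  pr <- pr[evalue <= cutoff]
  g <- igraph::graph_from_data_frame(pr[, .(a, b)], directed = FALSE,
                                     vertices = data.frame(name = gene_ids))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  names(groups) <- sprintf("grp%05d", seq_along(groups))
  lapply(groups, sort)
}

#' Build the m-CDS or s-CDS mapping reference
#'
#' m-CDS keeps one representative per paralog group — the longest member,
#' ties broken by lexicographically smallest gene id. s-CDS keeps only
#' singleton groups, so s-CDS is a subset of m-CDS.
#'
#' @param groups named list of member-id vectors (from
#'   \code{\link{build_paralog_groups}}).
#' @param cds_set named \code{DNAStringSet}; members must partition its names.
#'   Sequences whose length is not a multiple of 3 are dropped with a warning
#'   before grouping-based selection.
#' @param mode \code{"m-cds"} or \code{"s-cds"}.
#' @return \code{DNAStringSet} of representative sequences.
#' @export
build_reference <- function(groups, cds_set, mode = c("m-cds", "s-cds")) {
  mode <- match.arg(mode)
  if (length(groups) == 0L) stop("empty group set")
  cds_set <- drop_frameshifted(cds_set)
  groups <- Filter(length, lapply(groups, intersect, names(cds_set)))
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, names(cds_set)))
    stop("groups must partition the CDS set")
  if (mode == "s-cds") groups <- groups[lengths(groups) == 1L]
  reps <- vapply(groups, function(m) {
    w <- Biostrings::width(cds_set[m])
    cand <- m[w == max(w)]
    sort(cand)[1L]
  }, character(1))
  cds_set[sort(unname(reps))]
}

# Drop CDS whose length is not a multiple of 3 (codon machinery downstream
# requires a clean frame).
drop_frameshifted <- function(cds_set) {
  bad <- Biostrings::width(cds_set) %% 3L != 0L
  if (any(bad)) {
    warning(sum(bad), " CDS dropped: length not divisible by 3 (",
            paste(head(names(cds_set)[bad], 3L), collapse = ", "), " ...)")
    cds_set <- cds_set[!bad]
  }
  cds_set
}
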