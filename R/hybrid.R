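# Lineage marker sites and allele-of-origin classification. A marker site
# is a reference position where every species of group 1 shares one
# consensus base and every species of group 2 shares a different consensus
# base; a query sample's reads are then classified at each marker site:
#   both alleles   - each marker base supported by >= 40% of mapped reads;
#   group-k allele - that marker base supported by >= 90% of mapped reads;
#   uncertain      - neither rule fires (including sites dominated by a base
#                    that is neither marker, flagged 'neither_base', and
#                    zero-coverage sites, flagged 'no_coverage').
# The both-alleles rule is tested first: 0.4 + 0.4 <= 1 < 0.9 + 0.4, so the
# two single-allele rules can never fire together with it.

#' Define lineage marker sites from derived sequences
#'
#' @param derived_list named list of \code{cs_derived} objects (one per
#'   species).
#' @param group1,group2 character vectors of species labels (names of
#'   \code{derived_list}).
#' @param exclude species to leave out of both groups (e.g. the suspected
#'   hybrid's parents), default none.
#' @return \code{data.table} of class \code{cs_markers}: gene_id, position
#'   (1-based), group1_base, group2_base.
#' @export
define_marker_sites <- function(derived_list, group1, group2,
                                exclude = character(0)) {
  group1 <- setdiff(group1, exclude)
  group2 <- setdiff(group2, exclude)
  if (length(group1) == 0L || length(group2) == 0L)
    stop("a species group is empty after exclusions")
  missing <- setdiff(c(group1, group2), names(derived_list))
  if (length(missing) > 0L)
    stop("species not in derived_list: ", paste(missing, collapse = ", "))
  genes <- sort(Reduce(intersect, lapply(derived_list[c(group1, group2)], names)))
  out <- list()
  for (g in genes) {
    m1 <- do.call(rbind, lapply(derived_list[group1], function(d)
      strsplit(d[[g]]$seq, "", fixed = TRUE)[[1]]))
    m2 <- do.call(rbind, lapply(derived_list[group2], function(d)
      strsplit(d[[g]]$seq, "", fixed = TRUE)[[1]]))
    cs1 <- apply(matrix(m1 %in% DNA_BASES, nrow = nrow(m1)), 2L, all)
    cs2 <- apply(matrix(m2 %in% DNA_BASES, nrow = nrow(m2)), 2L, all)
    same1 <- apply(m1, 2L, function(col) length(unique(col)) == 1L)
    same2 <- apply(m2, 2L, function(col) length(unique(col)) == 1L)
    b1 <- m1[1L, ]
    b2 <- m2[1L, ]
    hit <- cs1 & cs2 & same1 & same2 & b1 != b2
    if (any(hit))
      out[[g]] <- data.table::data.table(gene_id = g, position = which(hit),
                                         group1_base = b1[hit],
                                         group2_base = b2[hit])
  }
  res <- if (length(out) == 0L)
    data.table::data.table(gene_id = character(0), position = integer(0),
                           group1_base = character(0),
                           group2_base = character(0))
  else data.table::rbindlist(out)
  data.table::setattr(res, "class", c("cs_markers", class(res)))
  res
}

#' Classify a query pileup column at one marker site
#'
#' Fractions are computed over the total mapped-read depth at the site,
#' including reads reporting neither marker base.
#'
#' @param counts A/C/G/T counts of the query at the site (named or in that
#'   order).
#' @param group1_base,group2_base the two marker bases (distinct).
#' @param pure_min single-allele threshold; default 0.90.
#' @param hybrid_min both-alleles threshold; default 0.40.
#' @return list: category ("group1_allele", "group2_allele", "both_alleles",
#'   "uncertain"), dominant ("group1", "group2" or "none"; defined only for
#'   both_alleles, exact tie -> "none"), depth, frac1, frac2, flag ("" or
#'   "no_coverage"/"neither_base").
#' @export
classify_marker_site <- function(counts, group1_base, group2_base,
                                 pure_min = 0.90, hybrid_min = 0.40) {
  if (group1_base == group2_base) stop("marker bases must differ")
  if (!is.null(names(counts))) counts <- counts[DNA_BASES]
  depth <- sum(counts)
  if (depth == 0L)
    return(list(category = "uncertain", dominant = "none", depth = 0L,
                frac1 = NA_real_, frac2 = NA_real_, flag = "no_coverage"))
  f1 <- counts[[match(group1_base, DNA_BASES)]] / depth
  f2 <- counts[[match(group2_base, DNA_BASES)]] / depth
  eps <- 1e-9
  if (f1 >= hybrid_min - eps && f2 >= hybrid_min - eps) {
    dom <- if (abs(f1 - f2) < eps) "none" else if (f1 > f2) "group1" else "group2"
    list(category = "both_alleles", dominant = dom, depth = depth,
         frac1 = f1, frac2 = f2, flag = "")
  } else if (f1 >= pure_min - eps) {
    list(category = "group1_allele", dominant = "none", depth = depth,
         frac1 = f1, frac2 = f2, flag = "")
  } else if (f2 >= pure_min - eps) {
    list(category = "group2_allele", dominant = "none", depth = depth,
         frac1 = f1, frac2 = f2, flag = "")
  } else {
    list(category = "uncertain", dominant = "none", depth = depth,
         frac1 = f1, frac2 = f2,
         flag = if (f1 + f2 < 0.5) "neither_base" else "")
  }
}

#' Classify a query sample at every marker site
#'
#' @param query_pileup \code{cs_pileup} of the query sample (same reference
#'   as the marker definition).
#' @param markers \code{cs_markers} from \code{\link{define_marker_sites}}.
#' @inheritParams classify_marker_site
#' @return \code{data.table}: marker columns plus category, dominant, depth,
#'   frac1, frac2, flag.
#' @export
classify_marker_sites <- function(query_pileup, markers, pure_min = 0.90,
                                  hybrid_min = 0.40) {
  if (nrow(markers) == 0L) stop("no marker sites")
  res <- lapply(seq_len(nrow(markers)), function(i) {
    g <- markers$gene_id[i]
    if (is.null(query_pileup[[g]]))
      stop("query pileup lacks gene ", g)
    cl <- classify_marker_site(query_pileup[[g]][, markers$position[i]],
                               markers$group1_base[i], markers$group2_base[i],
                               pure_min, hybrid_min)
    data.table::data.table(gene_id = g, position = markers$position[i],
                           group1_base = markers$group1_base[i],
                           group2_base = markers$group2_base[i],
                           category = cl$category, dominant = cl$dominant,
                           depth = cl$depth, frac1 = cl$frac1,
                           frac2 = cl$frac2, flag = cl$flag)
  })
  data.table::rbindlist(res)
}

#' Summarize marker-site classifications
#'
#' Category counts and proportions over all classified sites, with the
#' both-alleles category split by dominant marker.
#'
#' @param classifications output of \code{\link{classify_marker_sites}}.
#' @return list: counts (named integer), proportions (named numeric, sums to
#'   1), both_dominant_split (named numeric over group1/group2/none; sums to
#'   the both_alleles proportion), n_sites.
#' @export
summarize_marker_profile <- function(classifications) {
  if (nrow(classifications) == 0L) stop("no classifications")
  cats <- c("group1_allele", "group2_allele", "both_alleles", "uncertain")
  counts <- vapply(cats, function(k) sum(classifications$category == k),
                   integer(1))
  n <- nrow(classifications)
  props <- counts / n
  both <- classifications[classifications$category == "both_alleles", ]
  split <- vapply(c("group1", "group2", "none"),
                  function(k) sum(both$dominant == k), integer(1)) / n
  list(counts = counts, proportions = props, both_dominant_split = split,
       n_sites = n)
}
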