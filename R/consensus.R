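# Per-site nucleotide counts (pileup) from filtered alignments, and the
# three-way CS/AS/UNS site classification that turns a pileup into a derived
# sequence per sample:
#   CS (consensus, upper case): depth >= min_depth and the majority base
#       carries >= min_agree of the mapped reads;
#   UNS (uncovered, '-'): zero mapped reads;
#   AS (ambiguous, lower case): covered but failing the CS rule.
# Internally pileup matrices are indexed 1-based (R convention); exported
# tables report 1-based positions, alignment inputs carry 0-based PSL-style
# intervals.

#' Build per-gene pileups from alignments
#'
#' Counts A/C/G/T calls per reference position from the aligned read
#' segments; 'N's contribute nothing. Alignments should already be filtered
#' at the calibrated score cutoff.
#'
#' @param alignments \code{cs_alignments} with non-NA \code{bases}.
#' @param reference named \code{DNAStringSet}/character vector the alignments
#'   refer to.
#' @return object of class \code{cs_pileup}: named list (per gene) of 4 x L
#'   integer matrices with rows A, C, G, T. Genes without alignments get
#'   all-zero matrices.
#' @export
build_pileup <- function(alignments, reference) {
  ref <- as.character(reference)
  ids <- names(ref)
  lens <- nchar(ref)
  pil <- lapply(seq_along(ref), function(i)
    matrix(0L, nrow = 4L, ncol = lens[i],
           dimnames = list(DNA_BASES, NULL)))
  names(pil) <- ids
  a <- alignments[!is.na(alignments$bases) & nchar(alignments$bases) > 0L, ]
  if (nrow(a) > 0L) {
    bad <- setdiff(unique(a$target_id), ids)
    if (length(bad) > 0L)
      stop("alignment to gene absent from the reference: ", bad[1L])
    seg_len <- a$t_end - a$t_start
    gidx <- rep(match(a$target_id, ids), seg_len)
    pos1 <- unlist(lapply(seq_len(nrow(a)),
                          function(i) seq.int(a$t_start[i] + 1L, a$t_end[i])))
    base <- strsplit(paste(a$bases, collapse = ""), "", fixed = TRUE)[[1]]
    bidx <- match(base, DNA_BASES)          # N and others -> NA, dropped
    keep <- !is.na(bidx)
    dt <- data.table::data.table(g = gidx[keep], b = bidx[keep],
                                 p = pos1[keep])
    cnt <- as.data.frame(dt[, .N, by = .(g, b, p)])
    for (gg in unique(cnt$g)) {
      sub <- cnt[cnt$g == gg, ]
      pil[[gg]][cbind(sub$b, sub$p)] <- pil[[gg]][cbind(sub$b, sub$p)] + sub$N
    }
  }
  structure(pil, class = "cs_pileup")
}

#' Classify one pileup column as CS, AS or UNS
#'
#' @param counts integer vector of A, C, G, T counts (named or in that
#'   order).
#' @param min_depth minimum depth for a consensus call; default 10.
#' @param min_agree minimum majority-base fraction for a consensus call;
#'   default 0.80. Both thresholds are inclusive.
#' @return list: category ("CS"/"AS"/"UNS"), symbol (upper-case base,
#'   lower-case base, or "-"), depth, agreement_fraction (NA for UNS). Ties
#'   for the majority base resolve to the alphabetically first tied base.
#' @export
classify_site <- function(counts, min_depth = 10L, min_agree = 0.80) {
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(names(counts))) counts <- counts[DNA_BASES]
  depth <- sum(counts)
  if (depth == 0L)
    return(list(category = "UNS", symbol = "-", depth = 0L,
                agreement_fraction = NA_real_))
  top <- which.max(counts)                  # first maximum = alphabetical tie-break
  agree <- counts[[top]] / depth
  if (depth >= min_depth && counts[[top]] >= min_agree * depth - 1e-9)
    list(category = "CS", symbol = DNA_BASES[top], depth = depth,
         agreement_fraction = agree)
  else
    list(category = "AS", symbol = tolower(DNA_BASES[top]), depth = depth,
         agreement_fraction = agree)
}

# Vectorized site classification over a 4 x L count matrix -> symbol vector.
classify_columns <- function(m, min_depth = 10L, min_agree = 0.80) {
  depth <- colSums(m)
  top <- max.col(t(m), ties.method = "first")
  maxc <- m[cbind(top, seq_len(ncol(m)))]
  sym <- ifelse(depth == 0L, "-",
         ifelse(depth >= min_depth & maxc >= min_agree * depth - 1e-9,
                DNA_BASES[top], tolower(DNA_BASES[top])))
  sym
}

#' Derive the CS/AS/UNS sequence of one gene
#'
#' @param gene_pileup 4 x L count matrix (one element of
#'   \code{\link{build_pileup}}).
#' @param min_depth,min_agree consensus thresholds (see
#'   \code{\link{classify_site}}).
#' @param min_cs_cover minimum fraction of positions that must be CS for the
#'   gene to be retained; default 0.10.
#' @return list: seq (mixed-case/'-' string), cs_cover, retained.
#' @export
derive_sequence <- function(gene_pileup, min_depth = 10L, min_agree = 0.80,
                            min_cs_cover = 0.10) {
  sym <- classify_columns(gene_pileup, min_depth, min_agree)
  is_cs <- sym %in% DNA_BASES
  cs_cover <- mean(is_cs)
  list(seq = chars_to_string(sym), cs_cover = cs_cover,
       retained = cs_cover >= min_cs_cover - 1e-9)
}

#' Derive sequences for every gene of a sample
#'
#' @param pileup \code{cs_pileup}.
#' @param sample sample label.
#' @inheritParams derive_sequence
#' @return object of class \code{cs_derived}: named list (per gene) of
#'   \code{\link{derive_sequence}} results, with attribute \code{sample}.
#' @export
derive_sequences <- function(pileup, sample = "sample", min_depth = 10L,
                             min_agree = 0.80, min_cs_cover = 0.10) {
  out <- lapply(pileup, derive_sequence, min_depth = min_depth,
                min_agree = min_agree, min_cs_cover = min_cs_cover)
  structure(out, class = "cs_derived", sample = sample)
}

#' Pool pileups of several libraries of one species
#'
#' Per-position counts are element-wise sums; site classification is then
#' re-applied to the pooled counts, so sites too shallow in any one library
#' can still reach consensus depth in the pool.
#'
#' @param pileups list of \code{cs_pileup} objects over the same reference.
#' @return pooled \code{cs_pileup}.
#' @export
pool_pileups <- function(pileups) {
  stopifnot(length(pileups) >= 1L)
  ids <- names(pileups[[1]])
  for (p in pileups)
    if (!identical(names(p), ids) ||
        !identical(lengths0(p), lengths0(pileups[[1]])))
      stop("pileups were built against different references")
  out <- pileups[[1]]
  for (p in pileups[-1L])
    for (g in ids) out[[g]] <- out[[g]] + p[[g]]
  structure(out, class = "cs_pileup")
}

lengths0 <- function(p) vapply(p, ncol, integer(1))

#' Cross-library consistency of consensus calls
#'
#' For each gene, over positions that are CS in both derived sequences, the
#' fraction with identical consensus base; genes with no jointly-CS position
#' are reported as NA and excluded from the mean.
#'
#' @param derived_a,derived_b \code{cs_derived} objects over the same
#'   reference.
#' @return list: per_gene (data.frame gene, n_joint_cs, frac_identical),
#'   mean_identical (mean over genes with >= 1 jointly-CS position).
#' @export
consistency_report <- function(derived_a, derived_b) {
  genes <- names(derived_a)
  if (!identical(genes, names(derived_b)))
    stop("derived sequences cover different gene sets")
  res <- lapply(genes, function(g) {
    a <- strsplit(derived_a[[g]]$seq, "", fixed = TRUE)[[1]]
    b <- strsplit(derived_b[[g]]$seq, "", fixed = TRUE)[[1]]
    joint <- a %in% DNA_BASES & b %in% DNA_BASES
    n <- sum(joint)
    data.frame(gene = g, n_joint_cs = n,
               frac_identical = if (n == 0L) NA_real_ else mean(a[joint] == b[joint]))
  })
  per_gene <- do.call(rbind, res)
  list(per_gene = per_gene,
       mean_identical = mean(per_gene$frac_identical, na.rm = TRUE))
}

#' Write derived sequences as mixed-case FASTA
#' @param derived \code{cs_derived}. @param path output path.
#' @param retained_only write only genes passing the coverage filter?
#' @return \code{path}, invisibly.
#' @export
write_derived_fasta <- function(derived, path, retained_only = FALSE) {
  keep <- if (retained_only) vapply(derived, `[[`, logical(1), "retained")
          else rep(TRUE, length(derived))
  seqs <- vapply(derived[keep], `[[`, character(1), "seq")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read a mixed-case derived-sequence FASTA back as a cs_derived object
#'
#' Consensus coverage and the retention flag are recomputed from the
#' symbols.
#'
#' @param path FASTA path written by \code{\link{write_derived_fasta}}.
#' @param sample sample label.
#' @param min_cs_cover retention threshold; default 0.10.
#' @return \code{cs_derived} object.
#' @export
read_derived_fasta <- function(path, sample = basename(path),
                               min_cs_cover = 0.10) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
  out <- lapply(seqs, function(s) {
    cs <- mean(strsplit(s, "", fixed = TRUE)[[1]] %in% DNA_BASES)
    list(seq = s, cs_cover = cs, retained = cs >= min_cs_cover - 1e-9)
  })
  names(out) <- ids
  structure(out, class = "cs_derived", sample = sample)
}

#' Export a pileup as a per-site TSV
#'
#' Columns: gene, pos (1-based), A, C, G, T, depth, call.
#' @param pileup \code{cs_pileup}. @param path output path.
#' @param min_depth,min_agree consensus thresholds.
#' @return \code{path}, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path, min_depth = 10L, min_agree = 0.80) {
  rows <- lapply(names(pileup), function(g) {
    m <- pileup[[g]]
    data.frame(gene = g, pos = seq_len(ncol(m)), A = m["A", ], C = m["C", ],
               G = m["G", ], T = m["T", ], depth = colSums(m),
               call = classify_columns(m, min_depth, min_agree))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
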