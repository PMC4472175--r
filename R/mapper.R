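# Translated (protein-space) read mapping against a CDS reference, and
# decoy-based calibration of the mapping score cutoff.
#
# The mapper is a deliberately simple seeded translated aligner: exact 7-aa
# seed words shared between a read frame and a target frame propose
# diagonals, and each (read, target, diagonal) candidate is rescored in
# nucleotide space as the maximal ungapped segment under +1 match / -1
# mismatch. Targets are indexed in their three forward frames; reads are
# searched in all six frames, so reverse-strand placements come from the
# reverse-complemented read. Real and decoy references receive identical
# treatment, which is what the FDR calibration requires. External BLAT
# alignments can be ingested instead via read_psl().

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

# Integer-encode all w-mer amino-acid windows of a protein character vector.
# Returns data.table(seq_idx, aa_start (1-based), code); windows containing
# a stop, X, or a sequence boundary are dropped.
protein_words <- function(prots, w) {
  lens <- nchar(prots)
  concat <- paste(prots, collapse = "")
  ints <- utf8ToInt(concat)
  map <- rep(NA_integer_, 128L)
  map[utf8ToInt(paste(AA_LETTERS, collapse = ""))] <- seq_along(AA_LETTERS)
  aa <- map[ints]
  bad <- is.na(aa)
  aa[bad] <- 0L
  k <- w
  # windowed positional encode: code at end position i covers [i-k+1, i]
  codes <- as.numeric(stats::filter(aa, 25^(0:(k - 1)), sides = 1))
  nbad <- as.numeric(stats::filter(as.numeric(bad), rep(1, k), sides = 1))
  ends <- seq_along(aa)
  starts <- ends - k + 1L
  bounds_end <- cumsum(lens)
  bounds_start <- c(1L, head(bounds_end, -1L) + 1L)
  seq_of <- findInterval(ends, bounds_start)
  ok <- starts >= bounds_start[seq_of] & !is.na(codes) & nbad == 0
  data.table::data.table(
    seq_idx = seq_of[ok],
    aa_start = (starts - bounds_start[seq_of] + 1L)[ok],
    code = codes[ok])
}

translate_frames <- function(seqs_chr) {
  # list of 3 character vectors: protein translation of forward frames 0,1,2
  lapply(0:2, function(off) {
    sub <- substr(seqs_chr, off + 1L, nchar(seqs_chr))
    sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
    empty <- nchar(sub) < 3L
    sub[empty] <- ""
    out <- character(length(sub))
    if (any(!empty))
      out[!empty] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(sub[!empty]), if.fuzzy.codon = "X"))
    out
  })
}

#' Build a protein-space seed index over a reference
#'
#' Indexes exact \code{word_aa}-mer amino-acid words of the three forward
#' frames of every reference sequence.
#'
#' @param reference named \code{DNAStringSet} or character vector of CDS.
#' @param word_aa seed word length in amino acids (default 7).
#' @return an object of class \code{cs_seed_index}.
#' @export
seed_index <- function(reference, word_aa = 7L) {
  seqs <- as.character(reference)
  ids <- names(seqs) %||% sprintf("t%05d", seq_along(seqs))
  frames <- translate_frames(seqs)
  tabs <- lapply(0:2, function(off) {
    wt <- protein_words(frames[[off + 1L]], word_aa)
    wt[, t_nt := off + 3L * (aa_start - 1L)]   # 0-based nt offset on target
    wt[, aa_start := NULL]
    wt
  })
  tab <- data.table::rbindlist(tabs)
  data.table::setkey(tab, code)
  structure(list(words = tab, target_ids = ids, targets = unname(seqs),
                 word_aa = as.integer(word_aa)),
            class = "cs_seed_index")
}

#' Map reads to a reference in protein space
#'
#' Seeds exact amino-acid words between the six read frames and the indexed
#' target frames, collapses seeds to (read, strand, target, diagonal)
#' candidates, rescans each diagonal in nucleotide space (+1 match, -1
#' mismatch, ungapped) and keeps the best-scoring placement per read.
#' Alignments scoring below \code{min_score} are discarded; a read whose
#' best score is tied across different targets is discarded as ambiguous.
#'
#' @param reads named character vector of read sequences (A/C/G/T/N).
#' @param reference named \code{DNAStringSet}/character vector of CDS, or a
#'   prebuilt \code{\link{seed_index}}.
#' @param min_score score floor; default 18.
#' @param word_aa seed word size (amino acids) when \code{reference} is not
#'   already an index.
#' @return \code{data.table} with one row per mapped read: read_id,
#'   target_id, strand, score, t_start/t_end (0-based half-open nt interval
#'   on the target), r_start (0-based on the strand-oriented read), matches,
#'   mismatches, bases (aligned read segment, target-forward orientation),
#'   q_size, t_size. Class \code{cs_alignments}.
#' @export
translated_map <- function(reads, reference, min_score = 18L, word_aa = 7L) {
  if (any(grepl("[^ACGTN]", reads)))
    stop("reads must contain only A, C, G, T, N")
  idx <- if (inherits(reference, "cs_seed_index")) reference
         else seed_index(reference, word_aa)
  w <- idx$word_aa
  if (any(nchar(reads) < 3L * w))
    stop("reads shorter than one seed word (", 3L * w, " nt) are not mappable")
  read_ids <- names(reads) %||% sprintf("r%07d", seq_along(reads))
  oriented <- list(`+` = unname(reads), `-` = revcomp_chr(unname(reads)))
  cand_list <- list()
  for (st in c("+", "-")) {
    frames <- translate_frames(oriented[[st]])
    for (off in 0:2) {
      wt <- protein_words(frames[[off + 1L]], w)
      if (nrow(wt) == 0L) next
      wt[, r_nt := off + 3L * (aa_start - 1L)]
      hits <- idx$words[wt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits) == 0L) next
      cand_list[[length(cand_list) + 1L]] <- data.table::data.table(
        read = hits$i.seq_idx, strand = st, target = hits$seq_idx,
        diag_nt = hits$t_nt - hits$r_nt)
    }
  }
  if (length(cand_list) == 0L) return(empty_alignments())
  cand <- unique(data.table::rbindlist(cand_list))
  ror <- ifelse(cand$strand == "+", 0L, length(reads)) + cand$read
  all_oriented <- c(oriented[["+"]], oriented[["-"]])
  sc <- rescore_diagonals(all_oriented, ror, idx$targets, cand$target,
                          cand$diag_nt)
  cand <- cbind(cand, data.table::as.data.table(sc))
  cand <- cand[score >= min_score]
  if (nrow(cand) == 0L) return(empty_alignments())
  # best placement per read; ties across distinct targets -> ambiguous
  cand[, best := score == max(score), by = read]
  top <- cand[best == TRUE]
  amb <- top[, .(n_targets = data.table::uniqueN(target)), by = read]
  keep <- amb[n_targets == 1L, read]
  top <- top[read %in% keep]
  data.table::setorder(top, read, strand, diag_nt)
  top <- top[!duplicated(read)]
  out <- data.table::data.table(
    read_id = read_ids[top$read],
    target_id = idx$target_ids[top$target],
    strand = top$strand,
    score = top$score,
    t_start = top$t_start, t_end = top$t_end, r_start = top$r_start,
    matches = top$matches, mismatches = top$mismatches,
    bases = substr(all_oriented[ifelse(top$strand == "+", 0L, length(reads)) + top$read],
                   top$r_start + 1L, top$r_start + (top$t_end - top$t_start)),
    q_size = nchar(reads)[top$read],
    t_size = nchar(idx$targets)[top$target])
  data.table::setattr(out, "class", c("cs_alignments", class(out)))
  out
}

empty_alignments <- function() {
  out <- data.table::data.table(
    read_id = character(0), target_id = character(0), strand = character(0),
    score = integer(0), t_start = integer(0), t_end = integer(0),
    r_start = integer(0), matches = integer(0), mismatches = integer(0),
    bases = character(0), q_size = integer(0), t_size = integer(0))
  data.table::setattr(out, "class", c("cs_alignments", class(out)))
  out
}

#' Choose the mapping score cutoff from a decoy
#'
#' Scans integer cutoffs and returns the smallest cutoff \code{c} at which
#' the decoy-based FDR estimate — (decoy reads with score >= c) / (real reads
#' with score >= c) — falls below \code{fdr_max}, requiring that at least one
#' real read passes. The realized ratio is reported as \code{q}.
#'
#' @param real_alignments,decoy_alignments \code{cs_alignments} tables (or
#'   numeric score vectors) from mapping the same reads against the real and
#'   the shuffled reference.
#' @param fdr_max maximum tolerated FDR; default 0.01 (1\%).
#' @return list of class \code{cs_cutoff}: cutoff, realized_fdr,
#'   n_real_passing, n_decoy_passing.
#' @export
choose_score_cutoff <- function(real_alignments, decoy_alignments,
                                fdr_max = 0.01) {
  real <- if (is.numeric(real_alignments)) real_alignments else real_alignments$score
  decoy <- if (is.numeric(decoy_alignments)) decoy_alignments else decoy_alignments$score
  if (length(real) == 0L) stop("no real alignments: cannot calibrate a cutoff")
  lo <- min(c(real, decoy))
  for (c_try in seq(lo, max(real))) {
    n_real <- sum(real >= c_try)
    if (n_real == 0L) break
    n_decoy <- sum(decoy >= c_try)
    q <- n_decoy / n_real
    if (q < fdr_max) {
      return(structure(list(cutoff = c_try, realized_fdr = q,
                            n_real_passing = n_real,
                            n_decoy_passing = n_decoy),
                       class = "cs_cutoff"))
    }
  }
  stop("no score cutoff achieves FDR < ", fdr_max,
       " while passing at least one real read")
}

#' Pairing statistics of a mapped paired-end library
#'
#' Fraction 1: mapped reads whose mate is also mapped, over all mapped
#' reads. Fraction 2: pairs with both mates mapped that hit the same target,
#' over all such pairs (0, flagged, when no pair has both mates mapped).
#'
#' @param alignments \code{cs_alignments}; read ids must end in \code{/1} or
#'   \code{/2}.
#' @return list: frac_mate_mapped, frac_same_target, n_mapped, n_pairs_mapped,
#'   undefined_same_target (flag).
#' @export
pair_stats <- function(alignments) {
  if (nrow(alignments) == 0L) stop("no alignments")
  mt <- sub("^.*/", "", alignments$read_id)
  if (!all(mt %in% c("1", "2")))
    stop("pair_stats requires paired read ids ending in /1 or /2")
  dt <- data.table::data.table(base_id = sub("/[12]$", "", alignments$read_id),
                               mate = mt, target = alignments$target_id)
  pairs <- dt[, .(n = .N, same = data.table::uniqueN(target) == 1L), by = base_id]
  n_mapped <- nrow(dt)
  both <- pairs[pairs$n == 2L]
  frac1 <- if (n_mapped == 0L) 0 else 2L * nrow(both) / n_mapped
  undef <- nrow(both) == 0L
  frac2 <- if (undef) 0 else mean(both$same)
  list(frac_mate_mapped = frac1, frac_same_target = frac2,
       n_mapped = n_mapped, n_pairs_mapped = nrow(both),
       undefined_same_target = undef)
}
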