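# 21-column PSL (BLAT) reading and writing. Target coordinates are 0-based
# half-open per the PSL specification; the alignment score is recomputed as
# matches + repMatches - misMatches - qNumInsert - tNumInsert.

PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
              "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
              "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read BLAT alignments from a PSL file
#'
#' Accepts headerless PSL as well as files with the standard
#' \code{psLayout} 5-line header. Scores are recomputed as
#' matches + repMatches - misMatches - qNumInsert - tNumInsert.
#'
#' @param path PSL path.
#' @param reads optional named character vector of read sequences; when
#'   given, aligned base strings are reconstructed for single-block rows so
#'   the result can feed \code{\link{build_pileup}}.
#' @return \code{cs_alignments} table (see \code{\link{translated_map}}).
#' @export
read_psl <- function(path, reads = NULL) {
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^psLayout", lines[1L]))
    lines <- lines[-seq_len(5L)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 21L))
    stop("malformed PSL: expected 21 columns, found ", ncols[ncols != 21L][1L],
         " on line ", which(ncols != 21L)[1L])
  m <- do.call(rbind, fields)
  colnames(m) <- PSL_COLS
  num <- function(col) as.integer(m[, col])
  if (any(num("tEnd") > num("tSize")))
    stop("malformed PSL: tEnd exceeds tSize")
  score <- num("matches") + num("repMatches") - num("misMatches") -
    num("qNumInsert") - num("tNumInsert")
  bases <- rep(NA_character_, nrow(m))
  if (!is.null(reads)) {
    one_block <- num("blockCount") == 1L
    for (i in which(one_block)) {
      rseq <- reads[[m[i, "qName"]]]
      if (is.null(rseq)) next
      if (m[i, "strand"] %in% c("-", "--", "-+"))
        rseq <- revcomp_chr(rseq)
      qs <- as.integer(strsplit(m[i, "qStarts"], ",")[[1]][1L])
      bl <- as.integer(strsplit(m[i, "blockSizes"], ",")[[1]][1L])
      bases[i] <- substr(rseq, qs + 1L, qs + bl)
    }
  }
  out <- data.table::data.table(
    read_id = m[, "qName"], target_id = m[, "tName"],
    strand = substr(m[, "strand"], 1L, 1L), score = score,
    t_start = num("tStart"), t_end = num("tEnd"), r_start = num("qStart"),
    matches = num("matches") + num("repMatches"),
    mismatches = num("misMatches"),
    bases = bases, q_size = num("qSize"), t_size = num("tSize"))
  data.table::setattr(out, "class", c("cs_alignments", class(out)))
  out
}

#' Write alignments as 21-column PSL
#'
#' Internal alignments are ungapped single blocks; insert counts are zero.
#'
#' @param alignments \code{cs_alignments}.
#' @param path output path.
#' @param header write the \code{psLayout} header? default FALSE.
#' @return \code{path}, invisibly.
#' @export
write_psl <- function(alignments, path, header = FALSE) {
  a <- alignments
  blen <- a$t_end - a$t_start
  rows <- data.frame(
    matches = a$matches, misMatches = a$mismatches, repMatches = 0L,
    nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L,
    tBaseInsert = 0L, strand = a$strand, qName = a$read_id, qSize = a$q_size,
    qStart = a$r_start, qEnd = a$r_start + blen, tName = a$target_id,
    tSize = a$t_size, tStart = a$t_start, tEnd = a$t_end, blockCount = 1L,
    blockSizes = paste0(blen, ","), qStarts = paste0(a$r_start, ","),
    tStarts = paste0(a$t_start, ","))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("psLayout version 3", "",
                 paste(PSL_COLS, collapse = "\t"), "",
                 paste(rep("-", 60), collapse = "")), con)
  }
  write.table(rows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
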