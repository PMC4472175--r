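# Consensus-codon supermatrix: a reference codon enters the matrix iff all
# three of its positions are CS in every sample and the gene passes the
# coverage filter in every sample. Because every derived sequence is laid
# out on the same reference coordinates, concatenation needs no multiple
# sequence alignment. Columns are ordered by (gene id, codon index), and the
# codon position (1/2/3) of every column is kept as the partition map.

#' Build the consensus-codon supermatrix
#'
#' @param derived_list named list of \code{cs_derived} objects, one per
#'   sample/taxon (names become the taxa labels).
#' @param require_retained genes must pass the 10\% coverage filter in every
#'   sample (default TRUE).
#' @return object of class \code{cs_matrix}: list with \code{taxa},
#'   \code{mat} (taxa x L character matrix, upper case), \code{provenance}
#'   (data.frame gene, codon: 1-based codon index on the gene), and
#'   \code{partition} (integer vector of codon positions 1/2/3 per column).
#' @export
build_cs_matrix <- function(derived_list, require_retained = TRUE) {
  if (length(derived_list) < 2L) stop("need at least 2 samples")
  taxa <- names(derived_list)
  genes <- sort(Reduce(intersect, lapply(derived_list, names)))
  if (require_retained) {
    keep <- vapply(genes, function(g)
      all(vapply(derived_list, function(d) d[[g]]$retained, logical(1))),
      logical(1))
    genes <- genes[keep]
  }
  blocks <- list()
  prov <- list()
  for (g in genes) {
    rows <- lapply(derived_list, function(d)
      strsplit(d[[g]]$seq, "", fixed = TRUE)[[1]])
    L <- length(rows[[1]])
    if (any(lengths(rows) != L)) stop("derived lengths differ for gene ", g)
    chm <- do.call(rbind, rows)
    is_cs <- matrix(chm %in% DNA_BASES, nrow = nrow(chm))
    all_cs <- apply(is_cs, 2L, all)
    n_codon <- L %/% 3L
    codon_ok <- vapply(seq_len(n_codon), function(j)
      all(all_cs[(3L * j - 2L):(3L * j)]), logical(1))
    if (!any(codon_ok)) next
    cols <- as.vector(vapply(which(codon_ok), function(j)
      (3L * j - 2L):(3L * j), integer(3)))
    blocks[[g]] <- chm[, cols, drop = FALSE]
    prov[[g]] <- data.frame(gene = g, codon = which(codon_ok))
  }
  if (length(blocks) == 0L)
    stop("zero retained codons: no codon is CS in all samples for any ",
         "retained gene (", length(genes), " candidate genes)")
  mat <- do.call(cbind, blocks)
  rownames(mat) <- taxa
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  structure(list(taxa = taxa, mat = mat, provenance = provenance,
                 partition = rep(1:3, times = ncol(mat) %/% 3L)),
            class = "cs_matrix")
}

#' @export
print.cs_matrix <- function(x, ...) {
  cat("cs_matrix:", length(x$taxa), "taxa x", ncol(x$mat), "sites (",
      nrow(x$provenance), "codons from", length(unique(x$provenance$gene)),
      "genes )\n")
  invisible(x)
}

#' Extract the single-codon-position submatrix
#'
#' @param matrix a \code{cs_matrix}.
#' @param position codon position, 1, 2 or 3.
#' @return a \code{cs_matrix} containing only columns at that codon
#'   position (partition map all equal to \code{position}).
#' @export
codon_position_submatrix <- function(matrix, position) {
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  keep <- matrix$partition == position
  structure(list(taxa = matrix$taxa,
                 mat = matrix$mat[, keep, drop = FALSE],
                 provenance = matrix$provenance,
                 partition = matrix$partition[keep]),
            class = "cs_matrix")
}

sanitize_labels <- function(labels) {
  clean <- gsub("[^A-Za-z0-9_.|-]", "_", labels)
  if (!identical(clean, labels))
    message("taxon labels sanitized for output: ",
            paste(labels[clean != labels], "->", clean[clean != labels],
                  collapse = ", "))
  make.unique(clean, sep = "_")
}

#' Write the supermatrix in standard alignment formats
#'
#' Supported formats: relaxed PHYLIP (header "ntaxa nchar"), FASTA, NEXUS
#' (DATA block, plus a SETS block when \code{partition_style = "nexus-sets"}).
#' \code{partition_style = "raxml"} additionally writes a RAxML-style
#' partition file ("DNA, codon1 = 1-L\\3" ...) next to the matrix. Taxon
#' labels with characters illegal for the format are sanitized with a
#' message. Output is byte-stable for fixed input.
#'
#' @param matrix \code{cs_matrix}.
#' @param path output path.
#' @param format "relaxed-phylip", "fasta" or "nexus".
#' @param partition_style "none", "raxml" or "nexus-sets".
#' @param partition_path path for the RAxML partition file; default
#'   \code{paste0(path, ".partitions")}.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(matrix, path,
                         format = c("relaxed-phylip", "fasta", "nexus"),
                         partition_style = c("none", "raxml", "nexus-sets"),
                         partition_path = NULL) {
  format <- match.arg(format)
  partition_style <- match.arg(partition_style)
  mat <- matrix$mat
  L <- ncol(mat)
  labels <- sanitize_labels(rownames(mat))
  seqs <- apply(mat, 1L, paste, collapse = "")
  lines <- switch(format,
    "relaxed-phylip" = c(paste(nrow(mat), L),
                         paste(labels, seqs)),
    "fasta" = paste0(">", labels, "\n", seqs),
    "nexus" = {
      body <- c("#NEXUS", "BEGIN DATA;",
                sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), L),
                "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX",
                paste0("    ", labels, "  ", seqs), "  ;", "END;")
      if (partition_style == "nexus-sets")
        body <- c(body, "BEGIN SETS;",
                  sprintf("  CHARSET codon%d = %d-%d\\3;", 1:3, 1:3, L),
                  "END;")
      body
    })
  writeLines(lines, path)
  if (partition_style == "raxml") {
    pp <- partition_path %||% paste0(path, ".partitions")
    writeLines(sprintf("DNA, codon%d = %d-%d\\3", 1:3, 1:3, L), pp)
  }
  invisible(path)
}

#' Read a FASTA alignment back as a cs_matrix (no provenance)
#'
#' Round-trip companion of \code{\link{write_matrix}}; provenance and the
#' gene map are not recoverable from flat alignments, the partition map is
#' re-derived from column position.
#'
#' @param path FASTA path.
#' @return \code{cs_matrix} with empty provenance.
#' @export
read_matrix_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  chm <- do.call(rbind, strsplit(as.character(x), "", fixed = TRUE))
  rownames(chm) <- names(x)
  structure(list(taxa = names(x), mat = chm,
                 provenance = data.frame(gene = character(0),
                                         codon = integer(0)),
                 partition = rep_len(1:3, ncol(chm))),
            class = "cs_matrix")
}

#' Export the column provenance map
#'
#' One row per matrix column: column index (1-based), gene, codon index on
#' the gene (1-based), codon position (1/2/3).
#'
#' @param matrix \code{cs_matrix}. @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_provenance_tsv <- function(matrix, path) {
  df <- data.frame(column = seq_len(ncol(matrix$mat)),
                   gene = rep(matrix$provenance$gene, each = 3L),
                   codon = rep(matrix$provenance$codon, each = 3L),
                   codon_position = matrix$partition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
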