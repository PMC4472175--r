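# Shared low-level helpers. Nucleotides are handled as plain character
# vectors internally; Biostrings objects appear only at IO boundaries.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split a DNAStringSet / character vector into a list of character vectors.
seq_chars <- function(x) {
  strsplit(as.character(x), "", fixed = TRUE)
}

chars_to_string <- function(x) paste(x, collapse = "")

revcomp_chr <- function(x) {
  # reverse-complement of a character vector of sequences
  vapply(x, function(s) {
    chars_to_string(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]))
  }, character(1), USE.NAMES = FALSE)
}

# Replace each selected position with a uniformly drawn *different* base.
substitute_bases <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  cur <- chars[idx]
  pick <- sample.int(3L, length(idx), replace = TRUE)
  new <- vapply(seq_along(idx), function(i) setdiff(DNA_BASES, cur[i])[pick[i]],
                character(1))
  chars[idx] <- new
  chars
}

# In-frame stop-codon positions (1-based codon indices) of a character vector.
inframe_stops <- function(chars) {
  n <- length(chars)
  stopifnot(n %% 3L == 0L)
  cod <- paste0(chars[seq(1L, n, 3L)], chars[seq(2L, n, 3L)], chars[seq(3L, n, 3L)])
  which(cod %in% STOP_CODONS)
}

as_dna_stringset <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(unlist(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
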