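# k-let-preserving sequence shuffle (Euler-path shuffle on the (k-1)-mer
# De Bruijn multigraph). The decoy reference built this way has exactly the
# same k-mer multiset as the original for the chosen k (and hence for every
# smaller k), which is what makes the decoy a fair null for mapping-FDR
# estimation.

#' Shuffle sequences preserving the k-mer multiset
#'
#' Each sequence is rewritten as a uniformly random Eulerian path on its
#' (k-1)-mer De Bruijn multigraph (random arborescence via Wilson's
#' algorithm, last-exit edge rule), so the multiset of k-mers — and of all
#' shorter words — is exactly conserved while longer-range structure is
#' randomized.
#'
#' @param x \code{DNAStringSet} or character vector of sequences.
#' @param k word length to preserve; default 6 (hexamers).
#' @param seed integer seed; decoys are reproducible for a fixed seed.
#' @return same type as \code{x}, with names suffixed \code{"_shuffled"} when
#'   names are present.
#' @export
shuffle_klet <- function(x, k = 6L, seed = 1L) {
  was_xs <- methods::is(x, "XStringSet")
  seqs <- as.character(x)
  if (any(nchar(seqs) < k)) stop("all sequences must have length >= k")
  out <- with_seed(seed, vapply(seqs, shuffle_klet_one, character(1), k = k,
                                USE.NAMES = FALSE))
  if (!is.null(names(x))) names(out) <- paste0(names(x), "_shuffled")
  if (was_xs) Biostrings::DNAStringSet(out) else out
}

shuffle_klet_one <- function(s, k) {
  n <- nchar(s)
  if (n == k) return(s)                       # single arrangement
  m <- n - k + 2L                             # number of (k-1)-mer positions
  keys <- substring(s, 1:m, (1:m) + k - 2L)
  uk <- unique(keys)
  vid <- match(keys, uk)                      # vertex id per position
  if (length(uk) == 1L) return(s)             # homopolymer-like: unique path
  root <- vid[m]
  # out-edge target lists: edge at position i goes vid[i] -> vid[i+1]
  edge_from <- vid[-m]
  edge_to <- vid[-1L]
  out_edges <- split(edge_to, edge_from)      # names are vertex ids as chars
  outs <- vector("list", length(uk))
  outs[as.integer(names(out_edges))] <- out_edges
  # Wilson's algorithm: random arborescence oriented toward the root
  in_tree <- logical(length(uk))
  in_tree[root] <- TRUE
  nxt <- integer(length(uk))
  for (v in seq_along(uk)) {
    u <- v
    while (!in_tree[u]) {
      cand <- outs[[u]]
      nxt[u] <- cand[sample.int(length(cand), 1L)]
      u <- nxt[u]
    }
    u <- v
    while (!in_tree[u]) {
      in_tree[u] <- TRUE
      u <- nxt[u]
    }
  }
  # order each vertex's out-edges randomly, with the arborescence edge last
  for (v in seq_along(uk)) {
    e <- outs[[v]]
    if (is.null(e)) next
    if (v == root) {
      outs[[v]] <- e[sample.int(length(e))]
    } else {
      last <- which(e == nxt[v])[1L]
      rest <- e[-last]
      outs[[v]] <- c(rest[sample.int(length(rest))], e[last])
    }
  }
  # walk the Eulerian path from the first vertex
  ptr <- integer(length(uk))
  visited <- integer(m - 1L)
  cur <- vid[1L]
  for (step in seq_len(m - 1L)) {
    ptr[cur] <- ptr[cur] + 1L
    cur <- outs[[cur]][ptr[cur]]
    visited[step] <- cur
  }
  paste0(uk[vid[1L]],
         chars_to_string(substring(uk[visited], k - 1L, k - 1L)))
}

#' k-mer count vector of a set of sequences
#'
#' Counts words within each sequence (never across sequence boundaries) and
#' sums over the set. Used as the independent check that a decoy conserves
#' the k-mer multiset.
#'
#' @param x \code{DNAStringSet} or character vector.
#' @param k word length.
#' @return named integer vector of counts over observed k-mers.
#' @export
kmer_counts <- function(x, k) {
  seqs <- as.character(x)
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }))
  table_to_named_int(table(words))
}

table_to_named_int <- function(tb) {
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

#' Do two sequence sets have identical k-mer count vectors?
#' @param a,b sequence sets. @param k word length.
#' @return logical.
#' @export
same_kmer_spectrum <- function(a, b, k) {
  ca <- kmer_counts(a, k)
  cb <- kmer_counts(b, k)
  length(ca) == length(cb) && setequal(names(ca), names(cb)) &&
    all(ca[names(cb)] == cb)
}
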