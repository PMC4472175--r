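# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal method available (enumeration,
# direct rule transcription, exhaustive scans) and share no code with the
# package implementations they check.

# k-mer counts by direct window extraction into an environment counter.
oracle_kmer_counts <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (s in as.character(seqs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      env[[w]] <- (if (is.null(env[[w]])) 0L else env[[w]]) + 1L
    }
  }
  out <- unlist(as.list(env))
  out[order(names(out))]
}

# Literal transcription of the three-way site rule.
oracle_classify <- function(counts, min_depth = 10, min_agree = 0.80) {
  counts <- as.numeric(counts)
  depth <- sum(counts)
  if (depth == 0) return("-")
  mx <- max(counts)
  base <- c("A", "C", "G", "T")[which(counts == mx)[1L]]
  if (depth >= min_depth && isTRUE(mx / depth >= min_agree - 1e-12))
    base else tolower(base)
}

# Literal transcription of the 90%/40% marker rules (both-alleles first).
oracle_marker <- function(counts, b1, b2, pure_min = 0.90, hybrid_min = 0.40) {
  depth <- sum(counts)
  if (depth == 0) return("uncertain")
  f1 <- counts[match(b1, c("A", "C", "G", "T"))] / depth
  f2 <- counts[match(b2, c("A", "C", "G", "T"))] / depth
  ge <- function(a, b) isTRUE(a >= b - 1e-12)
  if (ge(f1, hybrid_min) && ge(f2, hybrid_min)) "both_alleles"
  else if (ge(f1, pure_min)) "group1_allele"
  else if (ge(f2, pure_min)) "group2_allele"
  else "uncertain"
}

# Transitive closure of qualifying pairs by repeated set expansion.
oracle_groups <- function(pairs_a, pairs_b, gene_ids) {
  groups <- as.list(gene_ids)
  find <- function(groups, id) which(vapply(groups, function(g) id %in% g,
                                            logical(1)))
  for (i in seq_along(pairs_a)) {
    ga <- find(groups, pairs_a[i])
    gb <- find(groups, pairs_b[i])
    if (ga != gb) {
      groups[[ga]] <- union(groups[[ga]], groups[[gb]])
      groups[[gb]] <- NULL
    }
  }
  unname(lapply(groups, sort))
}

same_partition <- function(a, b) {
  norm <- function(g) {
    g <- lapply(g, sort)
    g[order(vapply(g, `[`, character(1), 1L))]
  }
  identical(norm(unname(a)), norm(unname(b)))
}

# Best ungapped local alignment of a read to one target by exhaustive
# diagonal scan on both strands, +1 match / -1 mismatch.
oracle_best_alignment <- function(read, target) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                          collapse = "")
  best <- 0L
  for (r in c(read, rc(read))) {
    rv <- strsplit(r, "")[[1]]
    tv <- strsplit(target, "")[[1]]
    for (d in seq(-length(rv) + 1L, length(tv) - 1L)) {
      ps <- max(1L, 1L - d):min(length(rv), length(tv) - d)
      sc <- ifelse(rv[ps] == tv[ps + d] & rv[ps] != "N", 1L, -1L)
      cur <- 0L
      for (x in sc) {
        cur <- max(0L, cur + x)
        best <- max(best, cur)
      }
    }
  }
  best
}

# Bipartitions of an unrooted tree by cutting each internal edge (BFS on the
# edge list), returned as a set of canonical split strings.
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  edges <- tree$edge
  n_tip <- length(tips)
  adj <- lapply(seq_len(max(edges)), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  splits <- character(0)
  internal <- edges[edges[, 2] > n_tip, , drop = FALSE]
  for (e in seq_len(nrow(internal))) {
    a <- internal[e, 1]; b <- internal[e, 2]
    seen <- b
    queue <- b
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == b && w == a) next        # do not cross the cut edge
        if (!(w %in% seen)) {
          seen <- c(seen, w); queue <- c(queue, w)
        }
      }
    }
    side <- sort(tips[seen[seen <= n_tip]])
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    other <- sort(setdiff(tips, side))
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    splits <- c(splits, canon)
  }
  unique(splits)
}

oracle_rf <- function(ta, tb) {
  sa <- oracle_splits(ta)
  sb <- oracle_splits(tb)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# Hamming distance by an independent byte-level scan.
oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Small shared end-to-end fixture: reference, species, derived sequences.
make_pipeline_fixture <- function(n_genes = 8L, gene_length = 150L,
                                  tree = "((A:0.02,B:0.02):0.04,(C:0.02,D:0.02):0.04);",
                                  mean_depth = 40, error_rate = 0, seed = 7L) {
  cfg <- sim_config(n_genes = n_genes, gene_length_nt = gene_length,
                    tree = tree, mean_depth = mean_depth,
                    read_length_nt = 60L, error_rate = error_rate, seed = seed)
  ref <- simulate_reference(cfg)
  sp <- evolve_along_tree(ref, tree, seed = seed + 1L)
  idx <- seed_index(ref$sequences)
  pils <- list(); derived <- list()
  for (s in names(sp)) {
    cfg_s <- sim_config(n_genes = n_genes, gene_length_nt = gene_length,
                        mean_depth = mean_depth, read_length_nt = 60L,
                        error_rate = error_rate,
                        seed = seed + 10L + match(s, names(sp)))
    rds <- simulate_reads(sp[[s]], cfg_s, species = s)
    aln <- translated_map(rds$reads, idx)
    pils[[s]] <- build_pileup(aln, ref$sequences)
    derived[[s]] <- derive_sequences(pils[[s]], s)
  }
  list(cfg = cfg, ref = ref, species = sp, idx = idx, pileups = pils,
       derived = derived, tree = tree)
}
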