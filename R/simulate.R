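# Synthetic-data generator: reference CDS sets, sequences evolved along a
# known tree, sequencing reads (optionally paired, optionally from a hybrid
# with two haplotypes), all with recorded ground truth.

#' Simulation configuration
#'
#' Bundles and validates the knobs of the read simulator. Branch lengths of
#' \code{tree} are expected substitutions per site; \code{error_rate} is the
#' per-base sequencing error probability; \code{mean_depth} is the target
#' read coverage per reference site.
#'
#' @param n_genes number of reference genes.
#' @param gene_length_nt gene length in nucleotides; must be a multiple of 3.
#' @param tree a rooted tree with branch lengths, as an \code{ape} \code{phylo}
#'   object or a Newick string. May be \code{NULL} when only reads from the
#'   reference itself are needed.
#' @param substitution_model substitution model identifier; only \code{"JC69"}
#'   (Jukes–Cantor) is implemented.
#' @param read_length_nt read length in nucleotides.
#' @param mean_depth expected per-site read coverage (reads/site).
#' @param error_rate per-base substitution error probability, in [0, 0.25).
#' @param paired simulate paired-end fragments?
#' @param insert_size fragment length for paired-end mode (nt).
#' @param seed integer seed; every simulator operation re-derives its
#'   randomness from it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 20L, gene_length_nt = 300L, tree = NULL,
                       substitution_model = "JC69", read_length_nt = 80L,
                       mean_depth = 20, error_rate = 0.01, paired = FALSE,
                       insert_size = 200L, seed = 1L) {
  if (gene_length_nt %% 3L != 0L)
    stop("gene_length_nt must be divisible by 3")
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(tree)) {
    tree <- as_phylo(tree)
    if (any(tree$edge.length < 0)) stop("all branch lengths must be >= 0")
  }
  if (!identical(substitution_model, "JC69"))
    stop("unknown substitution model: ", substitution_model)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_nt = as.integer(gene_length_nt), tree = tree,
                 substitution_model = substitution_model,
                 read_length_nt = as.integer(read_length_nt),
                 mean_depth = mean_depth, error_rate = error_rate,
                 paired = isTRUE(paired), insert_size = as.integer(insert_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  ape::read.tree(text = tree)
}

random_cds <- function(length_nt) {
  n_codon <- length_nt %/% 3L
  nonstop <- setdiff(
    apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste, collapse = ""),
    STOP_CODONS)
  paste(c("ATG", sample(nonstop, n_codon - 1L, replace = TRUE)), collapse = "")
}

#' Simulate a reference CDS set, optionally with paralog families
#'
#' Generates \code{n_genes} frame-clean coding sequences (each starts with
#' ATG and contains no in-frame stop codon). With \code{paralogs}, the first
#' \code{n_families} genes act as family ancestors and additional diverged
#' copies are appended, emulating the paralog structure that the minimal
#' reference (m-CDS) construction collapses.
#'
#' @param config a \code{\link{sim_config}}.
#' @param paralogs \code{NULL}, or a list with elements \code{n_families},
#'   \code{copies_per_family} (extra copies per ancestor, default 1) and
#'   \code{divergence} (per-site substitution fraction of each copy).
#' @return a list with \code{sequences} (a named \code{DNAStringSet}) and
#'   \code{ground_truth} (a list with \code{paralog_groups}, a named list of
#'   member id vectors).
#' @export
simulate_reference <- function(config, paralogs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_genes), function(i)
      random_cds(config$gene_length_nt), character(1))
    names(seqs) <- sprintf("g%04d", seq_len(config$n_genes))
    groups <- as.list(names(seqs))
    names(groups) <- names(seqs)
    if (!is.null(paralogs)) {
      nf <- paralogs$n_families
      cpf <- paralogs$copies_per_family %||% 1L
      div <- paralogs$divergence
      stopifnot(nf <= config$n_genes, div >= 0, div < 0.75)
      for (f in seq_len(nf)) {
        anc <- names(seqs)[f]
        for (cc in seq_len(cpf)) {
          id <- sprintf("%s_p%d", anc, cc)
          chars <- strsplit(seqs[[anc]], "", fixed = TRUE)[[1]]
          idx <- which(runif(length(chars)) < div)
          idx <- idx[idx > 3L]            # keep the start codon intact
          chars <- substitute_bases(chars, idx)
          chars <- resample_stops(chars, idx)
          seqs[id] <- chars_to_string(chars)
          groups[[anc]] <- c(groups[[anc]], id)
        }
      }
    }
    list(sequences = Biostrings::DNAStringSet(seqs),
         ground_truth = list(paralog_groups = groups))
  })
}

# Redraw substituted bases inside any codon that mutation turned into a stop,
# until the frame is clean again. Only codons containing a substituted
# position can have become stops, so this terminates.
resample_stops <- function(chars, mutated_idx) {
  if (length(mutated_idx) == 0L) return(chars)
  mut_codon <- unique((mutated_idx - 1L) %/% 3L + 1L)
  repeat {
    bad <- intersect(inframe_stops(chars), mut_codon)
    if (length(bad) == 0L) return(chars)
    redo <- mutated_idx[((mutated_idx - 1L) %/% 3L + 1L) %in% bad]
    chars <- substitute_bases(chars, redo)
  }
}

# Jukes-Cantor mutation of one sequence along a branch of length b
# (expected substitutions/site): a site differs from its parent with
# probability (3/4)(1 - exp(-4b/3)) and then takes one of the other three
# bases uniformly.
mutate_jc <- function(chars, b) {
  if (b == 0) return(chars)
  p <- 0.75 * (1 - exp(-4 * b / 3))
  idx <- which(runif(length(chars)) < p)
  chars2 <- substitute_bases(chars, idx)
  resample_stops(chars2, idx)
}

#' Evolve a reference along a tree
#'
#' Places the reference at the root and applies independent per-site
#' Jukes–Cantor substitution along every branch, keeping reading frames free
#' of stop codons (a codon mutated into a stop is redrawn). Returns one full
#' set of gene sequences per leaf.
#'
#' @param reference named \code{DNAStringSet} (or result of
#'   \code{\link{simulate_reference}}).
#' @param tree \code{phylo} or Newick string; branch lengths in expected
#'   substitutions/site.
#' @param model substitution model identifier; only \code{"JC69"}.
#' @param seed integer seed.
#' @return named list: leaf label -> named \code{DNAStringSet} of gene
#'   sequences.
#' @export
evolve_along_tree <- function(reference, tree, model = "JC69", seed = 1L) {
  if (is.list(reference) && !is.null(reference$sequences))
    reference <- reference$sequences
  if (!identical(model, "JC69")) stop("unknown substitution model: ", model)
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree must have finite branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tree leaves must be uniquely labelled")
  lens <- Biostrings::width(reference)
  gene_ids <- names(reference)
  root_chars <- strsplit(paste(as.character(reference), collapse = ""), "",
                         fixed = TRUE)[[1]]
  bounds <- cumsum(lens)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- root_chars
    # parents precede children in cladewise edge order from the root
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    elens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    out <- list()
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; child <- edges[e, 2L]
      node_seq[[child]] <- mutate_jc(node_seq[[par]], elens[e])
      if (child <= ntip) {
        s <- node_seq[[child]]
        genes <- substring(chars_to_string(s), c(1L, head(bounds, -1L) + 1L), bounds)
        names(genes) <- gene_ids
        out[[tree$tip.label[child]]] <- Biostrings::DNAStringSet(genes)
      }
    }
    out[tree$tip.label]
  })
}

#' Combine two parental gene sets into a hybrid with two haplotypes
#'
#' The hybrid carries both parental haplotypes; during read simulation each
#' fragment is drawn from one haplotype with probability 1/2, emulating
#' balanced biparental expression.
#'
#' @param parent_a,parent_b named \code{DNAStringSet}s over the same gene set.
#' @param label species label for the hybrid.
#' @return an object of class \code{cs_hybrid}.
#' @export
make_hybrid <- function(parent_a, parent_b, label = "hybrid") {
  if (!identical(sort(names(parent_a)), sort(names(parent_b))))
    stop("parents must share the same gene set")
  structure(list(hap1 = parent_a, hap2 = parent_b[names(parent_a)],
                 label = label), class = "cs_hybrid")
}

#' Simulate RNA-Seq reads from one species
#'
#' Draws reads (or paired fragments) uniformly along each gene, at an
#' expected count of \code{mean_depth * gene_length / read_length} reads per
#' gene (Poisson), applies uniform per-base substitution errors at
#' \code{error_rate}, and records the true origin of every read.
#'
#' @param species_sequences a named \code{DNAStringSet} (one haplotype) or a
#'   \code{\link{make_hybrid}} object (two haplotypes sampled 1:1).
#' @param config a \code{\link{sim_config}}; \code{paired}, \code{insert_size},
#'   \code{read_length_nt}, \code{mean_depth}, \code{error_rate} and
#'   \code{seed} are used.
#' @param species species label recorded in the ground truth (defaults to the
#'   hybrid's label or \code{"sample"}).
#' @return list with \code{reads} (named character vector of read sequences;
#'   paired mode appends \code{/1}), \code{reads2} (mates, \code{/2}, or
#'   \code{NULL}), and \code{ground_truth} (a \code{data.table} with columns
#'   read_id, species, gene, start, strand, haplotype).
#' @export
simulate_reads <- function(species_sequences, config, species = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(species_sequences, "cs_hybrid")) {
    haps <- list(as.character(species_sequences$hap1),
                 as.character(species_sequences$hap2))
    species <- species %||% species_sequences$label
  } else {
    if (is.list(species_sequences) && !is.null(species_sequences$sequences))
      species_sequences <- species_sequences$sequences
    haps <- list(as.character(species_sequences))
    species <- species %||% "sample"
  }
  if (length(haps[[1]]) == 0L) stop("empty input sequences")
  rl <- config$read_length_nt
  lens <- nchar(haps[[1]])
  if (any(rl > lens)) stop("read_length_nt exceeds a gene length")
  if (config$paired && any(config$insert_size > lens))
    stop("insert_size exceeds a gene length")
  gene_ids <- names(haps[[1]])
  with_seed(config$seed, {
    recs <- vector("list", length(gene_ids))
    for (gi in seq_along(gene_ids)) {
      L <- lens[gi]
      n_reads <- rpois(1L, config$mean_depth * L / rl)
      n_frag <- if (config$paired) ceiling(n_reads / 2) else n_reads
      if (n_frag == 0L) next
      hap <- sample.int(length(haps), n_frag, replace = TRUE)
      strand <- sample(c("+", "-"), n_frag, replace = TRUE)
      span <- if (config$paired) config$insert_size else rl
      start <- sample.int(L - span + 1L, n_frag, replace = TRUE)
      src <- vapply(hap, function(h) haps[[h]][[gene_ids[gi]]], character(1))
      frag <- substr(src, start, start + span - 1L)
      frag[strand == "-"] <- revcomp_chr(frag[strand == "-"])
      if (config$paired) {
        r1 <- substr(frag, 1L, rl)
        r2 <- revcomp_chr(substr(frag, span - rl + 1L, span))
      } else {
        r1 <- frag
        r2 <- NULL
      }
      recs[[gi]] <- data.table::data.table(
        gene = gene_ids[gi], start = start, strand = strand,
        haplotype = hap, r1 = r1, r2 = if (is.null(r2)) NA_character_ else r2)
    }
    gt <- data.table::rbindlist(recs)
    if (nrow(gt) == 0L) stop("no reads simulated; increase mean_depth")
    gt[, read_id := sprintf("%s_r%06d", species, seq_len(.N))]
    gt[, species := species]
    r1 <- apply_seq_errors(gt$r1, config$error_rate)
    if (config$paired) {
      r2 <- apply_seq_errors(gt$r2, config$error_rate)
      names(r1) <- paste0(gt$read_id, "/1")
      names(r2) <- paste0(gt$read_id, "/2")
    } else {
      r2 <- NULL
      names(r1) <- gt$read_id
    }
    list(reads = r1, reads2 = r2,
         ground_truth = gt[, .(read_id, species, gene, start, strand, haplotype)])
  })
}

# Uniform per-base substitution errors applied across a read set at once.
apply_seq_errors <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  all_chars <- strsplit(paste(reads, collapse = ""), "", fixed = TRUE)[[1]]
  idx <- which(runif(length(all_chars)) < error_rate)
  all_chars <- substitute_bases(all_chars, idx)
  bounds <- cumsum(lens)
  out <- substring(chars_to_string(all_chars), c(1L, head(bounds, -1L) + 1L), bounds)
  names(out) <- names(reads)
  out
}

#' Write simulated reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @param quality_char constant quality character (default \code{"I"}, Q40).
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality_char, n), character(1)))
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
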