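mk_der <- function(seqs, sample = "s") {
  genes <- lapply(seqs, function(s) list(seq = s, cs_cover = 1, retained = TRUE))
  structure(genes, class = "cs_derived", sample = sample)
}

test_that("marker sites require within-group consensus and between-group difference", {
  # all species identical: zero markers
  d <- list(a1 = mk_der(list(g = "ACGT")), a2 = mk_der(list(g = "ACGT")),
            b1 = mk_der(list(g = "ACGT")), b2 = mk_der(list(g = "ACGT")))
  mk0 <- define_marker_sites(d, c("a1", "a2"), c("b1", "b2"))
  expect_identical(nrow(mk0), 0L)
  # one diagnostic site: group1 C, group2 T
  d2 <- list(a1 = mk_der(list(g = "ACGT")), a2 = mk_der(list(g = "ACGT")),
             b1 = mk_der(list(g = "ATGT")), b2 = mk_der(list(g = "ATGT")))
  mk1 <- define_marker_sites(d2, c("a1", "a2"), c("b1", "b2"))
  expect_identical(nrow(mk1), 1L)
  expect_identical(mk1$position, 2L)
  expect_identical(mk1$group1_base, "C")
  expect_identical(mk1$group2_base, "T")
  # AS/UNS in any member skips the site; exclusions apply
  d3 <- d2
  d3$a2 <- mk_der(list(g = "AcGT"))
  expect_identical(nrow(define_marker_sites(d3, c("a1", "a2"), c("b1", "b2"))), 0L)
  expect_identical(nrow(define_marker_sites(d3, c("a1", "a2"), c("b1", "b2"),
                                            exclude = "a2")), 1L)
  expect_error(define_marker_sites(d2, "a1", "b1", exclude = c("a1", "b1")),
               "empty")
})

test_that("marker sets match a ground-truth scan under simulated divergence", {
  fix <- make_pipeline_fixture(n_genes = 10L, gene_length = 150L,
                               tree = "((A:0.02,B:0.02):0.05,(C:0.02,D:0.02):0.05);",
                               mean_depth = 50, seed = 43L)
  mk <- define_marker_sites(fix$derived, c("A", "B"), c("C", "D"))
  expect_gt(nrow(mk), 0L)
  # brute-force re-scan over derived strings
  want <- 0L
  for (g in names(fix$derived$A)) {
    ca <- lapply(c("A", "B"), function(s) strsplit(fix$derived[[s]][[g]]$seq, "")[[1]])
    cb <- lapply(c("C", "D"), function(s) strsplit(fix$derived[[s]][[g]]$seq, "")[[1]])
    for (p in seq_along(ca[[1]])) {
      v1 <- c(ca[[1]][p], ca[[2]][p]); v2 <- c(cb[[1]][p], cb[[2]][p])
      if (all(c(v1, v2) %in% c("A", "C", "G", "T")) &&
          length(unique(v1)) == 1L && length(unique(v2)) == 1L &&
          v1[1] != v2[1]) want <- want + 1L
    }
  }
  expect_identical(nrow(mk), want)
  # markers agree with the true species sequences at CS-covered sites
  for (i in head(seq_len(nrow(mk)), 20L)) {
    tA <- substr(as.character(fix$species$A[[mk$gene_id[i]]]), mk$position[i],
                 mk$position[i])
    expect_identical(mk$group1_base[i], tA)
  }
})

test_that("allele classification reproduces worked fractions and thresholds", {
  got <- classify_marker_site(c(A = 0, C = 58, G = 0, T = 42), "C", "T")
  expect_identical(got$category, "both_alleles")
  expect_identical(got$dominant, "group1")
  expect_identical(classify_marker_site(c(A = 0, C = 0, G = 5, T = 95),
                                        "C", "T")$category, "group2_allele")
  expect_identical(classify_marker_site(c(A = 0, C = 85, G = 0, T = 15),
                                        "C", "T")$category, "uncertain")
  expect_identical(classify_marker_site(c(A = 0, C = 0, G = 0, T = 0),
                                        "C", "T")$flag, "no_coverage")
  expect_identical(classify_marker_site(c(A = 100, C = 1, G = 0, T = 1),
                                        "C", "T")$flag, "neither_base")
  expect_error(classify_marker_site(c(A = 1, C = 0, G = 0, T = 0), "C", "C"),
               "must differ")
  # exact 50/50 tie: both alleles, no dominant
  tie <- classify_marker_site(c(A = 0, C = 50, G = 0, T = 50), "C", "T")
  expect_identical(tie$dominant, "none")
})

test_that("classification equals the literal rule on exhaustive count grids", {
  for (depth in c(1:25)) {
    for (c1 in 0:depth) {
      for (oth in 0:(depth - c1)) {
        counts <- c(A = oth, C = c1, G = 0, T = depth - c1 - oth)
        got <- classify_marker_site(counts, "C", "T")$category
        expect_identical(got, oracle_marker(counts, "C", "T"),
                         info = paste(counts, collapse = ","))
      }
    }
  }
  # scaling invariance
  set.seed(44)
  for (i in 1:30) {
    counts <- c(A = sample(0:9, 1), C = sample(0:30, 1), G = 0,
                T = sample(0:30, 1))
    if (sum(counts) == 0) counts["C"] <- 1
    base <- classify_marker_site(counts, "C", "T")$category
    expect_identical(classify_marker_site(counts * 5L, "C", "T")$category, base)
  }
})

test_that("profiles sum to one and split the both-alleles category", {
  cls <- data.table::data.table(
    category = c(rep("group2_allele", 4), rep("both_alleles", 4), "uncertain"),
    dominant = c(rep("none", 4), "group1", "group1", "group2", "none", "none"))
  s <- summarize_marker_profile(cls)
  expect_equal(sum(s$proportions), 1)
  expect_equal(unname(s$proportions["both_alleles"]), 4 / 9)
  expect_equal(sum(s$both_dominant_split),
               unname(s$proportions["both_alleles"]))
  expect_error(summarize_marker_profile(cls[0]), "no classifications")
  # all one category
  one <- data.table::data.table(category = rep("group2_allele", 5),
                                dominant = "none")
  expect_equal(unname(summarize_marker_profile(one)$proportions),
               c(0, 1, 0, 0))
})

test_that("a 1:1 hybrid is separated from pure species by the both-alleles rate", {
  fix <- make_pipeline_fixture(n_genes = 10L, gene_length = 150L,
                               tree = "((A:0.02,B:0.02):0.05,(C:0.02,D:0.02):0.05);",
                               mean_depth = 60, seed = 45L)
  mk <- define_marker_sites(fix$derived, c("A", "B"), c("C", "D"))
  hyb <- make_hybrid(fix$species$A, fix$species$C, "H")
  cfg_h <- sim_config(n_genes = 10L, gene_length_nt = 150L, mean_depth = 60,
                      read_length_nt = 60L, error_rate = 0, seed = 46L)
  rds <- simulate_reads(hyb, cfg_h)
  pil_h <- build_pileup(translated_map(rds$reads, fix$idx), fix$ref$sequences)
  prof_h <- summarize_marker_profile(classify_marker_sites(pil_h, mk))
  prof_a <- summarize_marker_profile(classify_marker_sites(fix$pileups$A, mk))
  expect_gt(prof_h$proportions["both_alleles"], 0.5)
  expect_lt(prof_a$proportions["both_alleles"], 0.05)
  # dominant split of the hybrid is balanced (binomial tolerance)
  split <- prof_h$both_dominant_split
  expect_lt(abs(split["group1"] - split["group2"]),
            4 * sqrt(0.25 / prof_h$n_sites) + 0.1)
})
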