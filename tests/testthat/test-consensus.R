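test_that("site classification reproduces the worked examples and thresholds", {
  expect_identical(classify_site(c(A = 8, C = 0, G = 0, T = 2))$symbol, "A")
  expect_identical(classify_site(c(A = 0, C = 0, G = 0, T = 0))$symbol, "-")
  expect_identical(classify_site(c(A = 8, C = 0, G = 0, T = 4))$symbol, "a")
  expect_identical(classify_site(c(A = 9, C = 0, G = 0, T = 0))$symbol, "a")
  expect_identical(classify_site(c(A = 10, C = 0, G = 0, T = 0))$symbol, "A")
  # tie on the majority base resolves alphabetically, lower case
  expect_identical(classify_site(c(A = 5, C = 0, G = 0, T = 5))$symbol, "a")
  expect_identical(classify_site(c(A = 0, C = 6, G = 6, T = 0))$symbol, "c")
  expect_error(classify_site(c(A = -1, C = 0, G = 0, T = 0)), "negative")
})

test_that("classification equals the literal rule on exhaustive two-base columns", {
  for (depth in 0:30) {
    for (n_major in 0:depth) {
      counts <- c(A = n_major, C = 0, G = 0, T = depth - n_major)
      got <- classify_site(counts)$symbol
      expect_identical(got, oracle_classify(counts),
                       info = sprintf("depth=%d major=%d", depth, n_major))
    }
  }
  # scale invariance above the depth threshold
  set.seed(31)
  for (i in 1:50) {
    counts <- c(A = sample(0:20, 1), C = sample(0:20, 1),
                G = sample(0:20, 1), T = sample(0:20, 1))
    if (sum(counts) < 10) counts <- counts + 10L
    s1 <- classify_site(counts)$symbol
    for (m in c(2L, 7L)) expect_identical(classify_site(counts * m)$symbol, s1)
  }
})

test_that("pileups equal a brute-force recount of aligned bases", {
  cfg <- sim_config(n_genes = 3L, gene_length_nt = 150L, mean_depth = 25,
                    read_length_nt = 60L, error_rate = 0.01, seed = 32L)
  ref <- simulate_reference(cfg)
  rds <- simulate_reads(ref$sequences, cfg, species = "S")
  aln <- translated_map(rds$reads, ref$sequences)
  pil <- build_pileup(aln, ref$sequences)
  for (g in names(pil)) {
    m <- matrix(0L, 4, 150, dimnames = list(c("A", "C", "G", "T"), NULL))
    rows <- aln[aln$target_id == g, ]
    for (i in seq_len(nrow(rows))) {
      b <- strsplit(rows$bases[i], "")[[1]]
      p <- seq.int(rows$t_start[i] + 1L, rows$t_end[i])
      for (j in seq_along(p)) {
        bi <- match(b[j], c("A", "C", "G", "T"))
        if (!is.na(bi)) m[bi, p[j]] <- m[bi, p[j]] + 1L
      }
    }
    expect_identical(pil[[g]], m)
  }
  expect_error(
    build_pileup(data.table::data.table(target_id = "nope", bases = "A",
                                        t_start = 0L, t_end = 1L),
                 ref$sequences), "absent")
})

test_that("gene retention applies the 10% consensus-coverage rule", {
  mk <- function(n_cs) {
    m <- matrix(0L, 4, 300, dimnames = list(c("A", "C", "G", "T"), NULL))
    if (n_cs > 0) m[1, seq_len(n_cs)] <- 10L
    m
  }
  d45 <- derive_sequence(mk(45))
  expect_equal(d45$cs_cover, 0.15)
  expect_true(d45$retained)
  d29 <- derive_sequence(mk(29))
  expect_false(d29$retained)
  d30 <- derive_sequence(mk(30))   # exactly 10%: retained ("at least")
  expect_true(d30$retained)
})

test_that("pooling sums counts and can rescue shallow concordant sites", {
  m6 <- matrix(0L, 4, 30, dimnames = list(c("A", "C", "G", "T"), NULL))
  m6[2, ] <- 6L                      # C at depth 6 everywhere: AS alone
  p1 <- structure(list(g1 = m6), class = "cs_pileup")
  p2 <- structure(list(g1 = m6), class = "cs_pileup")
  expect_identical(pool_pileups(list(p1)), p1)
  pooled <- pool_pileups(list(p1, p2))
  expect_identical(pooled$g1, m6 + m6)
  expect_identical(derive_sequence(p1$g1)$seq, strrep("c", 30))
  expect_identical(derive_sequence(pooled$g1)$seq, strrep("C", 30))
  # mixed references are rejected
  p3 <- structure(list(g2 = m6), class = "cs_pileup")
  expect_error(pool_pileups(list(p1, p3)), "different references")
  # pooled counts equal recount over concatenated alignment sets
  cfg <- sim_config(n_genes = 2L, gene_length_nt = 150L, mean_depth = 10,
                    read_length_nt = 60L, error_rate = 0, seed = 33L)
  ref <- simulate_reference(cfg)
  r1 <- simulate_reads(ref$sequences, cfg, species = "L1")
  cfg2 <- sim_config(n_genes = 2L, gene_length_nt = 150L, mean_depth = 10,
                     read_length_nt = 60L, error_rate = 0, seed = 34L)
  r2 <- simulate_reads(ref$sequences, cfg2, species = "L2")
  a1 <- translated_map(r1$reads, ref$sequences)
  a2 <- translated_map(r2$reads, ref$sequences)
  pooled2 <- pool_pileups(list(build_pileup(a1, ref$sequences),
                               build_pileup(a2, ref$sequences)))
  joint <- build_pileup(rbind(a1, a2), ref$sequences)
  expect_identical(unclass(pooled2), unclass(joint))
})

test_that("cross-library consistency is 1 for replicates, ~1-p for sisters", {
  fix <- make_pipeline_fixture(n_genes = 20L, gene_length = 300L,
                               tree = "(A:0.025,B:0.025);", mean_depth = 40,
                               seed = 35L)
  # same library twice: identical
  self <- consistency_report(fix$derived$A, fix$derived$A)
  expect_identical(self$mean_identical, 1)
  # sister species at JC path 0.05: identical-CS fraction near 1 - p_obs
  rep_ab <- consistency_report(fix$derived$A, fix$derived$B)
  p_exp <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  expect_lt(abs(rep_ab$mean_identical - (1 - p_exp)), 0.02)
  # disjoint consensus coverage: undefined, excluded from the mean
  da <- structure(list(g = list(seq = "AC--", cs_cover = 0.5, retained = TRUE)),
                  class = "cs_derived")
  db <- structure(list(g = list(seq = "--GT", cs_cover = 0.5, retained = TRUE)),
                  class = "cs_derived")
  rep0 <- consistency_report(da, db)
  expect_true(is.na(rep0$per_gene$frac_identical[1]))
  expect_true(is.nan(rep0$mean_identical))
})

test_that("error-free deep coverage reproduces the true sequence at every CS", {
  fix <- make_pipeline_fixture(n_genes = 6L, gene_length = 150L,
                               tree = "(A:0.02,B:0.02);", mean_depth = 60,
                               seed = 36L)
  for (s in c("A", "B")) {
    truth <- as.character(fix$species[[s]])
    for (g in names(truth)) {
      d <- strsplit(fix$derived[[s]][[g]]$seq, "")[[1]]
      t <- strsplit(truth[[g]], "")[[1]]
      cs <- d %in% c("A", "C", "G", "T")
      expect_gt(mean(cs), 0.5)
      expect_identical(sum(d[cs] != t[cs]), 0L)
    }
  }
})
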