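test_that("enumerate_words collapses strand pairs and matches the naive oracle", {
  one <- enumerate_words("ACGTAC", 6L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$word, min("ACGTAC", "GTACGT"))
  expect_equal(one$seq_hits, 1L)
  expect_equal(one$total_hits, 1L)  # one locus, counted once
  # random subset vs the all-offsets counting oracle
  seqs <- random_dna(10, 400, seed = 17)
  got <- enumerate_words(seqs, 6L)
  ora <- oracle_word_counts(seqs, 6L)
  expect_setequal(got$word, names(ora$total))
  expect_equal(got$total_hits[match(names(ora$total), got$word)],
               unname(ora$total))
  expect_equal(got$seq_hits[match(names(ora$seq_hits), got$word)],
               unname(ora$seq_hits))
  expect_error(enumerate_words("ACG", 6L), "exceeds")
})

test_that("palindromes count once per locus and N windows are skipped", {
  pal <- enumerate_words("GAATTC", 6L)  # EcoRI site, self-complementary
  expect_equal(pal$total_hits, 1L)
  withN <- enumerate_words(c("ACGTNACGTA"), 6L)
  expect_true(all(!grepl("N", withN$word)))
  expect_equal(sum(withN$total_hits), 0L)  # every 6-window spans the N
})

test_that("mismatch-tolerant counting grows monotonically", {
  seqs <- c("AAACGTCAAA", "TTTCGTCTTT")
  w0 <- enumerate_words(seqs, 6L, max_mismatches = 0L)
  w1 <- enumerate_words(seqs, 6L, max_mismatches = 1L)
  shared <- intersect(w0$word, w1$word)
  expect_true(all(w1$seq_hits[match(shared, w1$word)] >=
                    w0$seq_hits[match(shared, w0$word)]))
  # direct check: ACGTCA at 1 mismatch hits CGTCTT's neighbourhood too
  target <- promens:::canonicalize_words("AACGTC")
  expect_gte(w1$seq_hits[w1$word == target], w0$seq_hits[w0$word == target])
})

test_that("word_significance follows the binomial tail closed form", {
  bg <- uniform_background()
  expect_equal(word_significance("ACGTCA", 0L, bg, 10L, 1000L), 1.0)
  # force p1 = 0.5 via a single-position region: word prob both strands
  # = 2 * 0.25^6; choose region_length = width so n_pos = 1
  p_word <- 2 * 0.25^6
  p <- word_significance("ACGTCA", 10L, bg, 10L, 6L)
  expect_equal(p, p_word^10, tolerance = 1e-12)
  # general case equals pbinom on a manually computed p1
  L <- 200L
  p1 <- 1 - (1 - p_word)^(L - 6L + 1L)
  expect_equal(word_significance("ACGTCA", 3L, bg, 10L, L),
               pbinom(2, 10, p1, lower.tail = FALSE), tolerance = 1e-12)
  # palindrome: only one strand contributes
  p_pal <- 1 - (1 - 0.25^6)^(L - 5L)
  expect_equal(word_significance("GAATTC", 1L, bg, 5L, L),
               pbinom(0, 5, p_pal, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("word_significance agrees with Monte-Carlo subset simulation", {
  bg <- uniform_background()
  word <- "ACGTCA"
  L <- 100L; n_sub <- 8L
  p_an <- word_significance(word, 2L, bg, n_sub, L)
  set.seed(51)
  n_mc <- 20000L
  rc <- revcomp(word)
  hits <- replicate(n_mc, {
    seqs <- vapply(seq_len(n_sub), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    }, character(1))
    sum(grepl(word, seqs, fixed = TRUE) | grepl(rc, seqs, fixed = TRUE)) >= 2L
  })
  p_mc <- mean(hits)
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(p_an - p_mc), 3 * se + 1e-4)
})

test_that("benjamini_hochberg equals an explicit-sort step-up oracle", {
  expect_equal(benjamini_hochberg(0.01), 0.01)
  expect_equal(benjamini_hochberg(c(0.001, 0.02, 0.9)),
               c(0.003, 0.03, 0.9))
  set.seed(23)
  p <- runif(100)^2
  q <- benjamini_hochberg(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone along sorted p
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("seed_qvalue recovers a planted word and respects its gate", {
  bg <- uniform_background()
  regs <- sample_background_sequences(bg, 10, 500, seed = 41)
  planted <- plant_motifs(regs, planted_motif_spec("ACGTCAGT", prevalence = 1,
                                                   seed = 6))
  cfg <- engine_config("seed_qvalue", width_range = c(6, 8))
  motifs <- discover_motifs(planted$regions, bg, cfg)
  expect_gte(length(motifs), 1L)
  expect_true(all(vapply(motifs, `[[`, 0, "score") <= 0.05))
  top <- motifs[[1]]$consensus
  expect_equal(promens:::canonicalize_words(top),
               promens:::canonicalize_words("ACGTCAGT"))
})

test_that("ranked_topk returns at most top_k; em_refine applies its score gate", {
  bg <- uniform_background()
  regs <- sample_background_sequences(bg, 10, 400, seed = 43)
  planted <- plant_motifs(regs, planted_motif_spec("TTGACCGA", prevalence = 1,
                                                   seed = 2))
  tk <- discover_motifs(planted$regions, bg,
                        engine_config("ranked_topk", top_k = 5))
  expect_lte(length(tk), 5L)
  expect_equal(promens:::canonicalize_words(tk[[1]]$consensus),
               promens:::canonicalize_words("TTGACCGA"))
  em <- discover_motifs(planted$regions, bg,
                        engine_config("em_refine", width_range = c(6, 8)))
  expect_gte(length(em), 1L)
  expect_true(all(vapply(em, `[[`, 0, "score") <= 0.001))
  best_mm <- min(vapply(em, function(m) {
    consensus_mismatch(m$consensus, "TTGACCGA")
  }, integer(1)))
  expect_lte(best_mm, 1L)
})

test_that("discovery is invariant to reverse-complementing the input", {
  bg <- uniform_background()
  regs <- sample_background_sequences(bg, 8, 300, seed = 47)
  planted <- plant_motifs(regs, planted_motif_spec("ACGTCAGT", prevalence = 1,
                                                   seed = 9))
  cfg <- engine_config("seed_qvalue", width_range = c(8, 8))
  fwd <- discover_motifs(planted$regions$seq, bg, cfg)
  rev <- discover_motifs(revcomp(planted$regions$seq), bg, cfg)
  expect_equal(vapply(fwd, `[[`, "", "consensus"),
               vapply(rev, `[[`, "", "consensus"))
  expect_equal(vapply(fwd, `[[`, 0, "score"),
               vapply(rev, `[[`, 0, "score"), tolerance = 1e-12)
})

test_that("null subsets rarely yield discoveries at q <= 0.05", {
  bg <- uniform_background()
  set.seed(61)
  n_runs <- 60L
  found <- vapply(seq_len(n_runs), function(i) {
    seqs <- sample_background_sequences(bg, 10, 1000, seed = 6000 + i)$seq
    length(discover_motifs(seqs, bg,
                           engine_config("seed_qvalue",
                                         width_range = c(6, 8)))) > 0L
  }, logical(1))
  expect_lte(mean(found), 0.10)
})
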