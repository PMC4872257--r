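test_that("scan_regions reports exact planted loci on both strands", {
  bg <- uniform_background()
  base <- strrep("A", 100)
  m <- motif_from_word("CCGGTACG", leak = 0.001)
  fwd <- base; substr(fwd, 41, 48) <- "CCGGTACG"
  rev <- base; substr(rev, 41, 48) <- revcomp("CCGGTACG")
  regs <- promens:::as_regions(c(fwd, rev), gene_ids = c("gf", "gr"))
  inst <- scan_regions(m, regs, bg, score_fraction = 1.0)
  instf <- inst[inst$gene_id == "gf", ]
  instr <- inst[inst$gene_id == "gr", ]
  expect_equal(nrow(instf), 1L)
  expect_equal(instf$offset, 40L - 100L)
  expect_equal(instf$strand, "+")
  expect_equal(instf$matched_word, "CCGGTACG")
  expect_equal(nrow(instr), 1L)
  expect_equal(instr$offset, instf$offset)  # same locus, other strand
  expect_equal(instr$strand, "-")
  expect_equal(instr$matched_word, "CCGGTACG")
})

test_that("scan_regions equals the naive per-position oracle on random input", {
  bg <- uniform_background()
  regs <- sample_background_sequences(bg, 50, 120, seed = 55)
  m <- random_pwm_motif(6, seed = 21)
  got <- scan_regions(m, regs, bg, score_fraction = 0.85)
  ora <- oracle_scan(m, regs, rep(0.25, 4), 0.85)
  key <- function(df) sort(paste(df$gene_id, df$offset, df$strand))
  expect_equal(key(got), key(ora))
  expect_equal(sort(got$score), sort(ora$score), tolerance = 1e-9)
  # threshold monotonicity: raising the fraction never adds instances
  lower <- scan_regions(m, regs, bg, score_fraction = 0.75)
  expect_gte(nrow(lower), nrow(got))
  expect_true(all(key(got) %in% key(lower)))
})

test_that("scanning with the reverse-complement motif flips strands only", {
  bg <- uniform_background()
  regs <- sample_background_sequences(bg, 20, 150, seed = 56)
  m <- random_pwm_motif(7, seed = 23)
  a <- scan_regions(m, regs, bg, score_fraction = 0.8)
  b <- scan_regions(reverse_complement(m), regs, bg, score_fraction = 0.8)
  flip <- function(s) ifelse(s == "+", "-", "+")
  expect_equal(sort(paste(a$gene_id, a$offset, a$strand)),
               sort(paste(b$gene_id, b$offset, flip(b$strand))))
})

test_that("tally_instances counts completely and flags identical layouts", {
  genes <- c("g1", "g2", "g3")
  motifs <- c("m1", "m2")
  empty <- tally_instances(
    data.frame(motif_id = character(0), gene_id = character(0),
               offset = integer(0), strand = character(0),
               matched_word = character(0), score = numeric(0)),
    motifs, genes)
  expect_true(all(empty$counts == 0L))
  inst <- data.frame(
    motif_id = c("m1", "m1", "m1", "m2", "m2"),
    gene_id = c("g1", "g1", "g2", "g1", "g2"),
    offset = c(-10L, -30L, -10L, -50L, -50L),
    strand = c("+", "+", "+", "-", "-"),
    matched_word = "ACGTCA", score = 1, stringsAsFactors = FALSE)
  tal <- tally_instances(inst, motifs, genes)
  expect_equal(unname(tal$totals), c(3L, 2L))
  expect_equal(unname(rowSums(tal$counts)), unname(tal$totals))
  expect_equal(tal$counts["m1", "g1"], 2L)
  expect_equal(tal$counts["m2", "g3"], 0L)
  # random instance set vs a group-and-count oracle
  set.seed(77)
  rnd <- data.frame(
    motif_id = sample(motifs, 50, TRUE), gene_id = sample(genes, 50, TRUE),
    offset = sample(-100:-6, 50, TRUE), strand = sample(c("+", "-"), 50, TRUE),
    matched_word = "ACGTCA", score = 1, stringsAsFactors = FALSE)
  tal2 <- tally_instances(rnd, motifs, genes)
  ora <- tapply(rep(1L, 50), rnd$motif_id, sum)
  expect_equal(unname(tal2$totals[names(ora)]), as.vector(ora))
  # identical layout flag (tandem-duplicate class)
  dup <- rbind(inst,
               data.frame(motif_id = c("m1", "m1", "m2"), gene_id = "g3",
                          offset = c(-10L, -30L, -50L), strand = c("+", "+", "-"),
                          matched_word = "ACGTCA", score = 1))
  tal3 <- tally_instances(dup, motifs, genes)
  expect_equal(tal3$identical_layouts, list(c("g1", "g3")))
  expect_error(tally_instances(inst, "m1", genes), "unknown motif")
})

test_that("match_database ranks by mismatches with the printed worked pair", {
  db <- data.frame(id = c("S1F", "DEC1", "DEC2"),
                   consensus = c("TACCAT", "GGGGGG", "TACCAC"),
                   keywords = c("plastid repression", "", ""),
                   stringsAsFactors = FALSE)
  res <- match_database("TACCAC", db, top_n = 3)
  expect_equal(res$database_id[1], "DEC2")  # exact copy ranks first
  expect_equal(res$mismatches[1], 0L)
  s1f <- res[res$database_id == "S1F", ]
  expect_equal(s1f$mismatches, 1L)
  expect_equal(s1f$overlap, 6L)
  # full ranking equals an all-offsets brute-force oracle on a fixture db
  fx <- make_database_fixture(list("ACGTCAGT", "TTGACC"), n_decoys = 48,
                              mutation_rate = 0.2, seed = 31)
  q <- random_pwm_motif(7, seed = 41)
  got <- match_database(q, fx$database, top_n = nrow(fx$database))
  ora_mm <- vapply(fx$database$consensus, function(cons) {
    consensus_align(q$consensus, cons)$mismatches
  }, integer(1))
  ora_order <- order(ora_mm, fx$database$id)
  expect_equal(got$database_id, fx$database$id[ora_order])
  expect_equal(got$mismatches, unname(ora_mm[ora_order]))
})

test_that("export_map emits right-anchored BED-like records that round-trip", {
  bg <- uniform_background()
  regs <- sample_background_sequences(bg, 4, 1000, seed = 60)
  planted <- plant_motifs(regs[1:3, ],
                          planted_motif_spec("CCGGTACG", prevalence = 1,
                                             seed = 13))
  all_regs <- rbind(planted$regions, regs[4, ])
  m <- motif_from_word("CCGGTACG", leak = 0.001)
  inst <- scan_regions(m, all_regs, bg, score_fraction = 1.0,
                       motif_id = "mot1")
  out <- export_map(inst, all_regs, dir = tempfile())
  # instance at tss offset -w maps to [L-w, L)
  expect_equal(out$bed$start, 1000L + inst$offset[match(
    paste(out$bed$gene_id, out$bed$start),
    paste(inst$gene_id, 1000L + inst$offset))])
  expect_true(all(out$bed$end - out$bed$start == 8L))
  # gene with no instances keeps an empty track in the layout
  expect_true("sim_0004" %in% names(out$layout))
  expect_length(out$layout[["sim_0004"]], 0L)
  # round trip through the instance file
  dir <- tempfile()
  export_map(inst, all_regs, dir = dir)
  back <- read_instances(file.path(dir, "instances.bed"), all_regs)
  key <- function(df) {
    o <- order(df$gene_id, df$offset, df$strand)
    df <- df[o, c("motif_id", "gene_id", "offset", "strand", "matched_word")]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(back), key(inst))
})

test_that("coordinate arithmetic places a TSS-abutting instance at [L-w, L)", {
  regs <- promens:::as_regions(paste0(strrep("A", 994), "CCGGTA"),
                               gene_ids = "g1")
  inst <- data.frame(motif_id = "m", gene_id = "g1", offset = -6L,
                     strand = "+", matched_word = "CCGGTA", score = 1,
                     stringsAsFactors = FALSE)
  bed <- export_map(inst, regs)$bed
  expect_equal(c(bed$start, bed$end), c(994L, 1000L))
})
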