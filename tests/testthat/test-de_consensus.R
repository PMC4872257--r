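make_cell <- function(genes, sig_up = character(0), sig_down = character(0)) {
  data.frame(gene_id = genes,
             log2fc = ifelse(genes %in% sig_up, 2,
                             ifelse(genes %in% sig_down, -2, 0.1)),
             p = rep(0.5, length(genes)),
             q = ifelse(genes %in% c(sig_up, sig_down), 0.01, 0.5),
             significant = genes %in% c(sig_up, sig_down),
             stringsAsFactors = FALSE)
}

grid_names <- function(cultivars, timepoints) {
  g <- expand.grid(cultivar = cultivars, timepoint = timepoints,
                   stringsAsFactors = FALSE)
  paste(g$cultivar, g$timepoint, sep = "|")
}

test_that("consensus requires significance with one direction in every cell", {
  genes <- sprintf("g%02d", 1:10)
  nm <- grid_names(c("a", "b", "c"), c("t1", "t2"))
  tabs <- stats::setNames(lapply(nm, function(x) {
    make_cell(genes, sig_up = c("g01", "g02"), sig_down = "g03")
  }), nm)
  res <- consensus_gene_lists(tabs)
  expect_equal(res$over_expressed, c("g01", "g02"))
  expect_equal(res$under_expressed, "g03")
  expect_length(intersect(res$over_expressed, res$under_expressed), 0L)
  # a gene significant only at one timepoint moves to the per-timepoint tally
  tabs2 <- tabs
  for (x in nm[grepl("t2$", nm)]) {
    tabs2[[x]] <- make_cell(genes, sig_up = "g02", sig_down = "g03")
  }
  res2 <- consensus_gene_lists(tabs2)
  expect_equal(res2$over_expressed, "g02")
  tp <- res2$timepoint_only
  expect_equal(tp$n_over[tp$timepoint == "t1"], 1L)  # g01
  # all-empty tables
  nilnm <- grid_names("a", "t1")
  nil <- stats::setNames(list(make_cell(character(0))), nilnm)
  res3 <- consensus_gene_lists(nil)
  expect_length(res3$over_expressed, 0L)
  expect_length(res3$under_expressed, 0L)
})

test_that("consensus equals a brute-force set-intersection oracle on random grids", {
  set.seed(19)
  for (rep in 1:20) {
    genes <- sprintf("g%03d", 1:40)
    nm <- grid_names(c("a", "b"), c("t1", "t2"))
    tabs <- stats::setNames(lapply(nm, function(x) {
      up <- sample(genes, sample(0:8, 1))
      down <- sample(setdiff(genes, up), sample(0:8, 1))
      make_cell(genes, up, down)
    }), nm)
    res <- consensus_gene_lists(tabs)
    # oracle: intersect (gene, sign) significance sets across cells
    sig_sets <- lapply(tabs, function(t) {
      list(up = t$gene_id[t$significant & t$log2fc > 0],
           down = t$gene_id[t$significant & t$log2fc < 0])
    })
    expect_equal(res$over_expressed,
                 sort(Reduce(intersect, lapply(sig_sets, `[[`, "up"))))
    expect_equal(res$under_expressed,
                 sort(Reduce(intersect, lapply(sig_sets, `[[`, "down"))))
  }
})

test_that("genes absent from one table count as non-significant, not errors", {
  genes <- sprintf("g%02d", 1:5)
  nm <- grid_names(c("a", "b"), "t1")
  t1 <- make_cell(genes, sig_up = "g01")
  t2 <- make_cell(genes[-1], sig_up = character(0))  # g01 missing here
  res <- consensus_gene_lists(stats::setNames(list(t1, t2), nm))
  expect_length(res$over_expressed, 0L)
  # adding a non-significant gene everywhere changes nothing
  t1b <- rbind(t1, make_cell("g99"))
  t2b <- rbind(t2, make_cell("g99"))
  res_b <- consensus_gene_lists(stats::setNames(list(t1b, t2b), nm))
  expect_equal(res_b$over_expressed, res$over_expressed)
  expect_equal(res_b$under_expressed, res$under_expressed)
})

test_that("load_de_tables validates the grid and the rows", {
  dir <- tempfile(); dir.create(dir)
  good <- file.path(dir, "good.diff")
  utils::write.table(
    data.frame(gene_id = c("g1", "g2"), `log2(fold_change)` = c(1, -1),
               p_value = c(0.01, 0.5), q_value = c(0.02, 0.6),
               significant = c("yes", "no"), check.names = FALSE),
    good, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(cultivar = "a", timepoint = "t1", path = good,
                         stringsAsFactors = FALSE)
  tabs <- load_de_tables(manifest)
  expect_equal(tabs[["a|t1"]]$significant, c(TRUE, FALSE))
  # missing grid cell
  m2 <- rbind(manifest, data.frame(cultivar = "b", timepoint = "t2", path = good))
  expect_error(load_de_tables(m2), "missing DE table")
  # non-numeric q names the line
  bad <- file.path(dir, "bad.diff")
  writeLines(c("gene_id\tlog2(fold_change)\tp_value\tq_value\tsignificant",
               "g1\t1.0\t0.1\toops\tno"), bad)
  expect_error(load_de_tables(data.frame(cultivar = "a", timepoint = "t1",
                                         path = bad)), "line 2")
  # duplicate gene
  dup <- file.path(dir, "dup.diff")
  writeLines(c("gene_id\tlog2(fold_change)\tp_value\tq_value\tsignificant",
               "g1\t1\t0.1\t0.2\tno", "g1\t1\t0.1\t0.2\tno"), dup)
  expect_error(load_de_tables(data.frame(cultivar = "a", timepoint = "t1",
                                         path = dup)), "duplicate gene")
  # empty file warns
  empty <- file.path(dir, "empty.diff")
  writeLines("gene_id\tlog2(fold_change)\tp_value\tq_value\tsignificant", empty)
  expect_warning(load_de_tables(data.frame(cultivar = "a", timepoint = "t1",
                                           path = empty)), "empty")
})

test_that("housekeeping normalisation equalises geometric means", {
  counts <- matrix(c(10, 20, 100, 10, 20, 100, 20, 40, 200), nrow = 3,
                   dimnames = list(c("hk1", "hk2", "x"), c("s1", "s2", "s3")))
  # identical housekeeping counts across s1/s2 -> factors equal there
  norm <- normalize_by_housekeeping(counts, c("hk1", "hk2"))
  f <- attr(norm, "factors")
  expect_equal(f[["s1"]], f[["s2"]])
  expect_equal(f[["s3"]], f[["s1"]] / 2)  # doubled sample halves its factor
  gm <- exp(colMeans(log(norm[c("hk1", "hk2"), ])))
  expect_equal(unname(gm), rep(gm[[1]], 3))
  # random matrix vs explicit product/root oracle
  set.seed(30)
  m <- matrix(stats::rlnorm(60), nrow = 10,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  hk <- c("g1", "g2", "g3")
  got <- normalize_by_housekeeping(m, hk)
  gms <- apply(m[hk, ], 2, function(col) prod(col)^(1 / length(col)))
  expected <- sweep(m, 2, mean(gms) / gms, "*")
  expect_equal(got, expected, ignore_attr = TRUE, tolerance = 1e-12)
  m_bad <- m; m_bad["g1", 2] <- 0
  expect_error(normalize_by_housekeeping(m_bad, hk), "g1.*s2")
})

test_that("rank_correlation matches rank-then-Pearson with ties", {
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(rank_correlation(x, x^3 + 2), 1.0)
  expect_equal(rank_correlation(x, -x), -1.0)
  y <- c(2, 7, 1, 8, 2, 8)  # ties in both vectors
  expect_equal(rank_correlation(x, y), oracle_spearman(x, y),
               tolerance = 1e-12)
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})
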