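# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (explicit loops, direct arithmetic) so they share no
# code path with the package.

# An exactly uniform order-1 background (each base frequency 0.25).
uniform_background <- function() {
  build_background(strrep("ACGT", 2500L), max_order = 1L)
}

random_dna <- function(n, length, seed) {
  with_seed <- function(s, e) { set.seed(s); e }
  with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1)))
}

random_pwm_motif <- function(width, seed) {
  set.seed(seed)
  mat <- matrix(stats::rgamma(4 * width, 1), 4, width)
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  motif(mat)
}

# --- oracles ---------------------------------------------------------------

# Naive sliding-window k-mer frequencies (single strand, N-free windows).
oracle_kmer_freq <- function(seqs, k) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      word <- substr(s, i, i + k - 1L)
      if (grepl("N", word, fixed = TRUE)) next
      counts[[word]] <- (counts[[word]] %||% 0) + 1
    }
  }
  v <- unlist(as.list(counts))
  v / sum(v)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Explicit-sort step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1L):1L) {
    if (m < 2L) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1L])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Rank-then-Pearson Spearman with average ranks for ties.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exhaustive offset/orientation motif distance (double loop, no shared code
# with align_motifs).
oracle_motif_distance <- function(a, b, min_overlap = 4L) {
  ma <- a$matrix
  best <- Inf
  for (orient in 1:2) {
    mb <- if (orient == 1L) b$matrix else {
      m <- b$matrix[c("T", "G", "C", "A"), ncol(b$matrix):1, drop = FALSE]
      rownames(m) <- c("A", "C", "G", "T"); m
    }
    wa <- ncol(ma); wb <- ncol(mb)
    for (off in (-(wb - min_overlap)):(wa - min_overlap)) {
      tot <- 0; n_ov <- 0L
      for (i in seq_len(wa)) {
        j <- i - off
        if (j >= 1L && j <= wb) {
          tot <- tot + sqrt(sum((ma[, i] - mb[, j])^2))
          n_ov <- n_ov + 1L
        }
      }
      if (n_ov >= min_overlap) best <- min(best, tot / n_ov)
    }
  }
  best
}

# Exhaustive k-medoids optimum: minimum assignment cost over all possible
# medoid sets.
oracle_kmedoids_optimum <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# Naive per-position, per-strand log-odds scan.
oracle_scan <- function(motif, regions, bg0, score_fraction) {
  w <- motif$width
  lo <- log2(pmax(motif$matrix, 1e-9)) - log2(matrix(bg0, 4, w))
  thr <- score_fraction * sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (r in seq_len(nrow(regions))) {
    s <- regions$seq[r]; L <- nchar(s)
    for (pos in seq_len(max(L - w + 1L, 0L))) {
      word <- substr(s, pos, pos + w - 1L)
      if (grepl("N", word, fixed = TRUE)) next
      ch <- strsplit(word, "")[[1]]
      sc_f <- 0; sc_r <- 0
      for (j in seq_len(w)) {
        sc_f <- sc_f + lo[ch[j], j]
        sc_r <- sc_r + lo[comp[ch[w - j + 1L]], j]
      }
      if (sc_f >= thr) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = regions$gene_id[r], offset = pos - 1L - L, strand = "+",
          score = sc_f, stringsAsFactors = FALSE)
      }
      if (sc_r >= thr) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = regions$gene_id[r], offset = pos - 1L - L, strand = "-",
          score = sc_r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), offset = integer(0),
               strand = character(0), score = numeric(0))
}

# Naive all-offsets word counting (both strands, canonical collapsing).
oracle_word_counts <- function(seqs, width) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc1 <- function(word) {
    paste(rev(comp[strsplit(word, "")[[1]]]), collapse = "")
  }
  total <- new.env(parent = emptyenv())
  seqhit <- new.env(parent = emptyenv())
  for (s in seqs) {
    seen <- character(0)
    for (i in seq_len(nchar(s) - width + 1L)) {
      word <- substr(s, i, i + width - 1L)
      if (grepl("N", word, fixed = TRUE)) next
      canon <- min(word, rc1(word))
      total[[canon]] <- (total[[canon]] %||% 0L) + 1L
      seen <- union(seen, canon)
    }
    for (w in seen) seqhit[[w]] <- (seqhit[[w]] %||% 0L) + 1L
  }
  list(total = unlist(as.list(total)), seq_hits = unlist(as.list(seqhit)))
}

# Tiny two-contig genome + GFF3 fixture written to tempfiles.
write_tiny_reference <- function(dir = tempfile("ref")) {
  dir.create(dir)
  set.seed(11)
  c1 <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  c2 <- "ACGTACGTAC"
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1 test contig", c1, ">chr2", tolower(c2)), fa)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t1400\t.\t+\t.\tID=geneA",
    "chr1\ttest\tgene\t100\t300\t.\t-\t.\tID=geneB",
    "chr2\ttest\tgene\t4\t8\t.\t-\t.\tID=geneC"), gff)
  list(fasta = fa, gff = gff, chr1 = c1, chr2 = c2)
}
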