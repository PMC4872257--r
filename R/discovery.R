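# De novo motif discovery on one promoter subset: word enumeration with
# reverse-complement canonicalisation, over-representation significance
# against the Markov background, Benjamini-Hochberg control, and three
# engines playing the classic seed-and-gate / rank-top-k / EM-refinement
# roles with their traditional gating thresholds (q <= 0.05, top 5,
# e-value-like score <= 0.001).

#' Engine configuration for de novo discovery
#'
#' @param engine one of `"seed_qvalue"` (all words passing BH q <= `q_max`),
#'   `"ranked_topk"` (the `top_k` best words by p-value), `"em_refine"`
#'   (EM-refined PWMs from seed words, gated on a background-corrected
#'   score <= `score_max`).
#' @param width_range integer `c(w_min, w_max)`; `w_min` must be >= 6, the
#'   conventional minimum motif length.
#' @param max_mismatches mismatches allowed when counting a word's
#'   occurrences (default 0).
#' @param q_max seed_qvalue significance gate (default 0.05).
#' @param score_max em_refine score gate (default 0.001).
#' @param top_k ranked_topk result count (default 5).
#' @param both_strands search forward and reverse-complement strands
#'   (default TRUE).
#' @param pseudocount PWM smoothing for instance-built motifs (default 0.1).
#' @return list of class `engine_config`.
#' @export
engine_config <- function(engine = c("seed_qvalue", "ranked_topk", "em_refine"),
                          width_range = c(6L, 8L), max_mismatches = 0L,
                          q_max = 0.05, score_max = 0.001, top_k = 5L,
                          both_strands = TRUE, pseudocount = 0.1) {
  engine <- match.arg(engine)
  width_range <- as.integer(width_range)
  if (length(width_range) == 1L) width_range <- rep(width_range, 2L)
  if (width_range[1] < 6L) {
    stop_fmt("minimum motif width is 6 (got %d)", width_range[1])
  }
  if (width_range[2] < width_range[1]) stop_fmt("invalid width_range")
  if (q_max <= 0 || score_max <= 0 || top_k < 1L) {
    stop_fmt("thresholds must be positive")
  }
  structure(list(engine = engine, width_range = width_range,
                 max_mismatches = as.integer(max_mismatches),
                 q_max = q_max, score_max = score_max,
                 top_k = as.integer(top_k), both_strands = both_strands,
                 pseudocount = pseudocount),
            class = "engine_config")
}

# Per-sequence canonical windows. Returns, per sequence, the canonical
# (lexicographically smaller of word / revcomp) form of every N-free
# window, plus the forward window and its reverse complement (needed to
# recover oriented instances). The reverse complement of window i is read
# from the reverse-complemented sequence at the mirrored position, avoiding
# per-window string reversal.
canonical_windows <- function(seqs, width, both_strands = TRUE,
                              rcseqs = NULL) {
  if (both_strands && is.null(rcseqs)) rcseqs <- revcomp(seqs)
  lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    fw <- str_windows(s, width)
    if (length(fw) == 0L) return(NULL)
    ok <- !grepl("N", fw, fixed = TRUE)
    if (both_strands) {
      rc <- rev(str_windows(rcseqs[[i]], width))
      canon <- pmin(fw, rc)
    } else {
      rc <- fw
      canon <- fw
    }
    list(fw = fw[ok], rc = rc[ok], canon = canon[ok],
         pos = which(ok))  # 1-based window start
  })
}

#' Enumerate candidate words in a promoter subset
#'
#' Every `width`-word occurring in the subset (or, when `max_mismatches`
#' > 0, whose mismatch neighbourhood occurs) is listed with the number of
#' subset sequences containing a match (`seq_hits`) and the total number of
#' matching loci (`total_hits`). A word and its reverse complement are
#' collapsed to one canonical entry (the lexicographically smaller of the
#' pair); a palindromic word's forward and reverse match at the same locus
#' counts once. Windows containing N are skipped.
#'
#' @param subset `upstream_regions` data.frame or character vector.
#' @param width word length.
#' @param max_mismatches allowed mismatches per match (default 0).
#' @param both_strands match on both strands (default TRUE).
#' @return data.frame: word, width, seq_hits, total_hits.
#' @export
enumerate_words <- function(subset, width, max_mismatches = 0L,
                            both_strands = TRUE, rcseqs = NULL) {
  seqs <- unname(region_sequences(subset))
  if (any(nchar(seqs) < width)) {
    stop_fmt("width %d exceeds the shortest region length (%d)",
             width, min(nchar(seqs)))
  }
  wins <- canonical_windows(seqs, width, both_strands, rcseqs = rcseqs)
  wins <- Filter(Negate(is.null), wins)
  all_canon <- unlist(lapply(wins, `[[`, "canon"), use.names = FALSE)
  if (length(all_canon) == 0L) {
    return(data.frame(word = character(0), width = integer(0),
                      seq_hits = integer(0), total_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (max_mismatches == 0L) {
    words <- unique(all_canon)
    total <- tabulate(match(all_canon, words), length(words))
    per_seq <- lapply(wins, function(w) unique(w$canon))
    seq_hits <- tabulate(match(unlist(per_seq, use.names = FALSE), words),
                         length(words))
    return(data.frame(word = words, width = width, seq_hits = seq_hits,
                      total_hits = total, stringsAsFactors = FALSE))
  }
  # mismatch-tolerant path: candidate set = observed words plus their
  # Hamming-<=m neighbourhoods, counted against every window. Quadratic in
  # candidates x windows; intended for small inputs.
  observed <- unique(all_canon)
  cands <- observed
  for (m in seq_len(max_mismatches)) {
    cands <- unique(unlist(lapply(cands, hamming_neighbors)))
  }
  cands <- sort(unique(canonicalize_words(cands)))
  cmat <- word_matrix(cands)
  counts <- lapply(wins, function(w) {
    fwm <- word_matrix(w$fw)
    rcm <- word_matrix(w$rc)
    hits_per_cand_locus <- count_mismatch_hits(cmat, fwm, rcm, max_mismatches,
                                               both_strands)
    hits_per_cand_locus
  })
  total <- Reduce(`+`, lapply(counts, function(x) x$total))
  seq_hits <- Reduce(`+`, lapply(counts, function(x) as.integer(x$total > 0L)))
  keep <- total > 0L
  data.frame(word = cands[keep], width = width,
             seq_hits = seq_hits[keep], total_hits = total[keep],
             stringsAsFactors = FALSE)
}

# All Hamming-distance-1 neighbours of a word (including the word itself).
hamming_neighbors <- function(word) {
  bases <- strsplit(word, "", fixed = TRUE)[[1]]
  out <- c(word)
  for (j in seq_along(bases)) {
    for (b in setdiff(DNA_BASES, bases[j])) {
      v <- bases; v[j] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

canonicalize_words <- function(words) pmin(words, revcomp(words))

# words -> n x w character matrix
word_matrix <- function(words) {
  if (length(words) == 0L) return(matrix(character(0), 0, 0))
  matrix(unlist(strsplit(words, "", fixed = TRUE), use.names = FALSE),
         nrow = length(words), byrow = TRUE)
}

# For each candidate row of cmat, count loci (columns of fwm/rcm rows)
# within max_mm mismatches on either strand (a locus counts once).
count_mismatch_hits <- function(cmat, fwm, rcm, max_mm, both_strands) {
  n_loci <- nrow(fwm)
  n_cand <- nrow(cmat)
  total <- integer(n_cand)
  for (i in seq_len(n_cand)) {
    mm_f <- rowSums(fwm != matrix(cmat[i, ], n_loci, ncol(cmat), byrow = TRUE))
    hit <- mm_f <= max_mm
    if (both_strands) {
      mm_r <- rowSums(rcm != matrix(cmat[i, ], n_loci, ncol(cmat), byrow = TRUE))
      hit <- hit | (mm_r <= max_mm)
    }
    total[i] <- sum(hit)
  }
  list(total = total)
}

#' Over-representation p-value for candidate words
#'
#' Under the background, the probability that a single position matches the
#' word on either strand is `p_word = P(word) + P(revcomp(word))` (a
#' palindrome counts once); the per-sequence match probability is
#' `p1 = 1 - (1 - p_word)^(L - w + 1)` (independence approximation), and
#' the p-value is the binomial upper tail
#' `P(X >= seq_hits | n = subset_size, p1)`.
#'
#' @param word character vector of canonical words.
#' @param seq_hits observed number of subset sequences with a match.
#' @param background a `background_model`.
#' @param subset_size number of sequences in the subset.
#' @param region_length representative region length L.
#' @param both_strands match probability over both strands (default TRUE).
#' @return numeric vector of p-values in [0, 1].
#' @export
word_significance <- function(word, seq_hits, background, subset_size,
                              region_length, both_strands = TRUE) {
  if (length(word) == 0L) return(numeric(0))
  pw <- word_probability(background, word)
  if (both_strands) {
    rc <- revcomp(word)
    pal <- rc == word
    pw <- pw + ifelse(pal, 0, word_probability(background, rc))
  }
  w <- nchar(word)
  n_pos <- pmax(region_length - w + 1L, 1L)
  p1 <- 1 - (1 - pmin(pw, 1))^n_pos
  zero <- p1 == 0 & seq_hits > 0
  if (any(zero)) {
    warn_fmt("%d word(s) with background probability 0 but observed hits; p-value 0",
             sum(zero))
  }
  p <- stats::pbinom(seq_hits - 1L, subset_size, p1, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in input
#' order (delegates to `stats::p.adjust`).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Oriented instance words of `word` in the subset (for PWM building with
# mismatches): minus-strand matches are reverse-complemented into the
# word's orientation.
word_instance_words <- function(wins, word, max_mm, both_strands) {
  if (max_mm == 0L) return(NULL)  # caller uses the word itself
  rc_word <- revcomp(word)
  out <- character(0)
  for (w in wins) {
    fwm <- word_matrix(w$fw)
    tgt <- strsplit(word, "", fixed = TRUE)[[1]]
    mm_f <- rowSums(fwm != matrix(tgt, nrow(fwm), length(tgt), byrow = TRUE))
    hit_f <- mm_f <= max_mm
    out <- c(out, w$fw[hit_f])
    if (both_strands && rc_word != word) {
      mm_r <- rowSums(fwm != matrix(strsplit(rc_word, "", fixed = TRUE)[[1]],
                                    nrow(fwm), length(tgt), byrow = TRUE))
      hit_r <- mm_r <= max_mm & !hit_f
      out <- c(out, revcomp(w$fw[hit_r]))
    }
  }
  out
}

#' Discover motifs in one promoter subset
#'
#' Enumerates candidate words over the configured width range, computes
#' over-representation p-values against the background, applies
#' Benjamini-Hochberg correction across all candidates of the run, and
#' gates per the engine: `seed_qvalue` returns a PWM for every word with
#' q <= `q_max` (built from its matching instances); `ranked_topk` returns
#' the `top_k` best words by p-value (ties broken by information content,
#' then consensus); `em_refine` seeds EM refinement from the best words and
#' returns motifs whose background-corrected score is <= `score_max`.
#'
#' @param subset `upstream_regions` data.frame or character vector (the
#'   promoter subset).
#' @param background a `background_model`.
#' @param config an [engine_config()].
#' @return list of `motif` objects (possibly empty), ordered by
#'   significance.
#' @export
discover_motifs <- function(subset, background, config = engine_config()) {
  seqs <- unname(region_sequences(subset))
  if (length(seqs) == 0L) stop_fmt("empty subset")
  rcseqs <- if (config$both_strands) revcomp(seqs) else NULL
  cand <- do.call(rbind, lapply(config$width_range[1]:config$width_range[2],
                                function(w) {
    enumerate_words(seqs, w, max_mismatches = config$max_mismatches,
                    both_strands = config$both_strands, rcseqs = rcseqs)
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(list())
  L <- round(mean(nchar(seqs)))
  cand$p <- word_significance(cand$word, cand$seq_hits, background,
                              subset_size = length(seqs), region_length = L,
                              both_strands = config$both_strands)
  cand$q <- benjamini_hochberg(cand$p)

  build_word_motif <- function(word, n_instances, score) {
    inst <- if (config$max_mismatches > 0L) {
      wins <- canonical_windows(seqs, nchar(word), config$both_strands)
      word_instance_words(Filter(Negate(is.null), wins), word,
                          config$max_mismatches, config$both_strands)
    } else {
      rep(word, n_instances)
    }
    pwm_from_instances(inst, pseudocount = config$pseudocount,
                       source = config$engine, score = score)
  }

  if (config$engine == "seed_qvalue") {
    hits <- cand[cand$q <= config$q_max, , drop = FALSE]
    if (nrow(hits) == 0L) return(list())
    motifs <- lapply(seq_len(nrow(hits)), function(i) {
      build_word_motif(hits$word[i], hits$total_hits[i], hits$q[i])
    })
    ord <- order(hits$q,
                 -vapply(motifs, information_content, numeric(1)),
                 vapply(motifs, `[[`, "", "consensus"))
    return(motifs[ord])
  }

  if (config$engine == "ranked_topk") {
    # rank by p; resolve ties by information content (desc) then consensus
    pool <- cand[order(cand$p), , drop = FALSE]
    pool <- utils::head(pool, max(config$top_k * 4L, 20L))
    motifs <- lapply(seq_len(nrow(pool)), function(i) {
      build_word_motif(pool$word[i], pool$total_hits[i], pool$p[i])
    })
    ord <- order(pool$p,
                 -vapply(motifs, information_content, numeric(1)),
                 vapply(motifs, `[[`, "", "consensus"))
    return(motifs[ord][seq_len(min(config$top_k, length(motifs)))])
  }

  # em_refine: EM-polish PWMs seeded from the best candidate words; score a
  # refined motif by the binomial tail of its consensus word multiplied by
  # the number of seeds tried (an e-value-like correction).
  seeds <- cand[order(cand$p), , drop = FALSE]
  seeds <- utils::head(seeds, 20L)
  refined <- list()
  seen <- character(0)
  for (i in seq_len(nrow(seeds))) {
    m <- em_refine_motif(seqs, seeds$word[i], background,
                         pseudocount = config$pseudocount)
    cons_word <- paste(DNA_BASES[apply(m$matrix, 2, which.max)],
                       collapse = "")  # score via the top-base word
    canon <- canonicalize_words(cons_word)
    if (canon %in% seen) next
    seen <- c(seen, canon)
    hits <- enumerate_words(seqs, nchar(canon),
                            both_strands = config$both_strands)
    sh <- hits$seq_hits[match(canon, hits$word)]
    if (is.na(sh)) sh <- 0L
    p <- word_significance(canon, sh, background, length(seqs), L,
                           both_strands = config$both_strands)
    score <- min(1, p * nrow(seeds))
    if (score <= config$score_max) {
      m$score <- score
      refined[[length(refined) + 1L]] <- m
    }
  }
  if (length(refined) == 0L) return(list())
  refined[order(vapply(refined, `[[`, 0, "score"),
                -vapply(refined, information_content, numeric(1)),
                vapply(refined, `[[`, "", "consensus"))]
}

# ZOOPS-style EM refinement of a PWM seeded from one word. At most
# `max_iter` iterations or until the log likelihood-ratio improves by less
# than `tol`. Deterministic given its inputs.
em_refine_motif <- function(seqs, seed_word, background, max_iter = 20L,
                            tol = 1e-4, gamma = 0.5, pseudocount = 0.1) {
  w <- nchar(seed_word)
  bg0 <- background$freq[[1]][DNA_BASES]
  bg0[is.na(bg0)] <- 1e-9
  codes <- lapply(seqs, function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)  # N -> NA
  })
  mat <- motif_from_word(seed_word, leak = 0.05)$matrix
  loglr_old <- -Inf
  for (iter in seq_len(max_iter)) {
    num <- matrix(pseudocount, 4L, w)
    loglr <- 0
    lw <- log(mat) - log(matrix(bg0, 4L, w))
    for (code in codes) {
      L <- length(code)
      n_pos <- L - w + 1L
      if (n_pos < 1L) next
      lr <- numeric(n_pos); lr_rc <- numeric(n_pos)
      lw_rc <- lw[4:1, w:1, drop = FALSE]
      for (j in seq_len(w)) {
        b <- code[j:(j + n_pos - 1L)]
        contrib <- lw[cbind(b, j)]; contrib[is.na(contrib)] <- -Inf
        lr <- lr + contrib
        contrib_rc <- lw_rc[cbind(b, j)]; contrib_rc[is.na(contrib_rc)] <- -Inf
        lr_rc <- lr_rc + contrib_rc
      }
      rat <- c(exp(lr), exp(lr_rc))
      prior <- gamma / (2 * n_pos)
      denom <- (1 - gamma) + prior * sum(rat)
      z <- prior * rat / denom
      loglr <- loglr + log(denom / (1 - gamma) + 1e-300)
      # accumulate expected counts
      zf <- z[seq_len(n_pos)]; zr <- z[n_pos + seq_len(n_pos)]
      for (j in seq_len(w)) {
        b <- code[j:(j + n_pos - 1L)]
        ok <- !is.na(b)
        if (any(ok)) {
          num[, j] <- num[, j] + tabulate_weighted(b[ok], zf[ok])
        }
      }
      # reverse-strand sites: column j of the site reads the complement of
      # sequence position (window start + w - j)
      for (j in seq_len(w)) {
        b <- code[(w - j + 1L):(w - j + n_pos)]
        ok <- !is.na(b)
        if (any(ok)) {
          num[, j] <- num[, j] + tabulate_weighted(5L - b[ok], zr[ok])
        }
      }
    }
    mat_new <- sweep(num, 2, colSums(num), "/")
    if (abs(loglr - loglr_old) < tol) { mat <- mat_new; break }
    mat <- mat_new
    loglr_old <- loglr
  }
  motif(mat, source = "em_refine", provenance = sprintf("seed:%s", seed_word))
}

tabulate_weighted <- function(bins, w) {
  out <- numeric(4)
  for (b in unique(bins)) out[b] <- sum(w[bins == b])
  out
}
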