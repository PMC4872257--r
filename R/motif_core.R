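# Motif data model and algebra: position weight matrices with IUPAC
# consensus, reverse complement, information content, and an inter-motif
# distance with offset/orientation search (the metric behind clustering).

#' Construct a motif object
#'
#' A motif is a 4 x width column-stochastic position weight matrix (rows
#' A, C, G, T) together with its IUPAC consensus, the discovery engine it
#' came from, the engine-native significance score, and free-form
#' provenance (subset id, cluster id).
#'
#' @param matrix numeric 4 x width matrix; rows are taken as A, C, G, T
#'   (rownames, if present, must match). Every column must sum to 1.
#' @param source label of the producing engine ("" for constructed motifs).
#' @param score engine-native significance (q-value, e-value-like score, or
#'   rank); `NA` when not applicable.
#' @param provenance free-form origin tag.
#' @param strong,pair consensus thresholds passed to [consensus_string()].
#' @return an object of class `motif`.
#' @export
motif <- function(matrix, source = "", score = NA_real_, provenance = "",
                  strong = 0.7, pair = 0.8) {
  mat <- as.matrix(matrix)
  if (nrow(mat) != 4L) stop_fmt("motif matrix must have 4 rows (A,C,G,T), got %d", nrow(mat))
  if (!is.null(rownames(mat)) && !identical(rownames(mat), DNA_BASES)) {
    if (!setequal(rownames(mat), DNA_BASES)) {
      stop_fmt("motif matrix rownames must be A,C,G,T")
    }
    mat <- mat[DNA_BASES, , drop = FALSE]
  }
  rownames(mat) <- DNA_BASES
  if (any(mat < 0)) stop_fmt("motif matrix entries must be non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) {
    stop_fmt("motif matrix columns must sum to 1 (max deviation %.3g)",
             max(abs(cs - 1)))
  }
  m <- structure(
    list(matrix = mat, width = ncol(mat),
         consensus = consensus_string_matrix(mat, strong = strong, pair = pair),
         source = source, score = score, provenance = provenance),
    class = "motif")
  m
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s  width=%d  source=%s  score=%s\n",
              x$consensus, x$width,
              if (nzchar(x$source)) x$source else "-",
              format(x$score, digits = 3)))
  invisible(x)
}

is_motif <- function(x) inherits(x, "motif")

as_motif_matrix <- function(x) {
  if (is_motif(x)) x$matrix else {
    m <- as.matrix(x)
    rownames(m) <- DNA_BASES
    m
  }
}

#' Build a PWM motif from aligned instance words
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param words character vector of equal-length words over A,C,G,T.
#' @param pseudocount non-negative smoothing constant added per base
#'   (default 0.1).
#' @param ... passed to [motif()] (source, score, provenance).
#' @return a `motif`.
#' @export
pwm_from_instances <- function(words, pseudocount = 0.1, ...) {
  if (length(words) == 0L) stop_fmt("pwm_from_instances: empty word list")
  w <- unique(nchar(words))
  if (length(w) != 1L) stop_fmt("pwm_from_instances: ragged word widths (%s)",
                                paste(w, collapse = ", "))
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  bad <- grepl("[^ACGT]", words)
  if (any(bad)) stop_fmt("words must be over A,C,G,T: %s", words[bad][1])
  n <- length(words)
  counts <- vapply(seq_len(w), function(j) {
    b <- substring(words, j, j)
    tabulate(match(b, DNA_BASES), 4L)
  }, numeric(4))
  counts <- matrix(counts, nrow = 4L)
  mat <- (counts + pseudocount) / (n + 4 * pseudocount)
  motif(mat, ...)
}

# Column-wise consensus of a bare 4 x w matrix (internal; motif() calls it
# before the object exists).
consensus_string_matrix <- function(mat, strong = 0.7, pair = 0.8) {
  pair_code <- c(AC = "m", AG = "r", AT = "w", CG = "s", CT = "y", GT = "k")
  out <- vapply(seq_len(ncol(mat)), function(j) {
    p <- mat[, j]
    o <- order(p, decreasing = TRUE)
    if (p[o[1]] >= strong) return(DNA_BASES[o[1]])
    if (p[o[1]] + p[o[2]] >= pair) {
      key <- paste(sort(DNA_BASES[o[1:2]]), collapse = "")
      return(pair_code[[key]])
    }
    "."
  }, character(1))
  paste(out, collapse = "")
}

#' IUPAC consensus of a motif
#'
#' Per column: the top base (uppercase) if its probability reaches `strong`;
#' otherwise a lowercase two-base IUPAC code if the top two sum to at least
#' `pair`; otherwise `.`.
#'
#' @param motif a `motif` (or bare 4 x width matrix).
#' @param strong single-base threshold (default 0.7).
#' @param pair two-base threshold on the top-two sum (default 0.8).
#' @return IUPAC string of length `width`.
#' @export
consensus_string <- function(motif, strong = 0.7, pair = 0.8) {
  consensus_string_matrix(as_motif_matrix(motif), strong = strong, pair = pair)
}

#' Reverse complement of a motif
#'
#' Columns are reversed and bases complemented (A<->T, C<->G); the consensus
#' is recomputed.
#'
#' @param motif a `motif`.
#' @return a `motif` on the opposite strand.
#' @export
reverse_complement <- function(motif) {
  mat <- as_motif_matrix(motif)
  rc <- mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(rc) <- DNA_BASES
  if (is_motif(motif)) {
    motif(rc, source = motif$source, score = motif$score,
          provenance = motif$provenance)
  } else {
    motif(rc)
  }
}

#' Information content of a motif (bits)
#'
#' Sum over columns of `2 + sum_b p_b log2 p_b`, with `0 log 0 := 0`.
#'
#' @param motif a `motif` or 4 x width matrix.
#' @return total information content in bits.
#' @export
information_content <- function(motif) {
  mat <- as_motif_matrix(motif)
  pl <- ifelse(mat > 0, mat * log2(mat), 0)
  sum(2 + colSums(pl))
}

# Enumerate ungapped alignments of b (or revcomp(b)) against a; returns the
# best (distance, offset, rc). Offset is the position of b's first column
# relative to a's first column. Distance is the mean per-overlapping-column
# Euclidean distance between column distributions.
align_motifs <- function(a, b, min_overlap = 4L) {
  ma <- as_motif_matrix(a); mb0 <- as_motif_matrix(b)
  wa <- ncol(ma); wb <- ncol(mb0)
  if (wa < min_overlap || wb < min_overlap) {
    stop_fmt("motif widths (%d, %d) below min_overlap %d", wa, wb, min_overlap)
  }
  mb_rc <- mb0[c(4, 3, 2, 1), rev(seq_len(wb)), drop = FALSE]
  best <- list(distance = Inf, offset = 0L, rc = FALSE)
  for (rc in c(FALSE, TRUE)) {
    mb <- if (rc) mb_rc else mb0
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      ib <- ia - off
      d2 <- colSums((ma[, ia, drop = FALSE] - mb[, ib, drop = FALSE])^2)
      d <- mean(sqrt(d2))
      if (d < best$distance - 1e-12) {
        best <- list(distance = d, offset = as.integer(off), rc = rc)
      }
    }
  }
  best
}

#' Distance between two motifs
#'
#' Minimum over all ungapped offsets with at least `min_overlap` overlapping
#' columns, and over `b` versus its reverse complement, of the mean
#' per-overlapping-column Euclidean distance between column distributions.
#' Symmetric and non-negative; zero iff some offset/orientation aligns all
#' overlapping columns identically.
#'
#' @param a,b motifs.
#' @param min_overlap minimum number of overlapping columns (default 4).
#' @return non-negative distance.
#' @export
motif_distance <- function(a, b, min_overlap = 4L) {
  align_motifs(a, b, min_overlap = min_overlap)$distance
}

# Pairwise distance matrix over a list of motifs.
motif_distance_matrix <- function(motifs, min_overlap = 4L) {
  n <- length(motifs)
  d <- matrix(0, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- motif_distance(motifs[[i]], motifs[[j]],
                                             min_overlap = min_overlap)
      }
    }
  }
  d
}

#' Point-mass motif from a plain word
#'
#' Convenience constructor: each column puts probability
#' `1 - 3 * leak` on the word's base and `leak` elsewhere.
#'
#' @param word string over A,C,G,T.
#' @param leak per-other-base probability (default 0 gives point-mass columns).
#' @param ... passed to [motif()].
#' @return a `motif`.
#' @export
motif_from_word <- function(word, leak = 0, ...) {
  bases <- strsplit(toupper(word), "", fixed = TRUE)[[1]]
  if (!all(bases %in% DNA_BASES)) stop_fmt("word must be over A,C,G,T: %s", word)
  mat <- matrix(leak, 4L, length(bases), dimnames = list(DNA_BASES, NULL))
  mat[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 1 - 3 * leak
  motif(mat, ...)
}

# --- IUPAC consensus comparison -------------------------------------------

# 4-bit base-set encoding of every accepted consensus character.
iupac_bits <- local({
  codes <- names(IUPAC_SETS)
  bits <- vapply(IUPAC_SETS, function(s) {
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[s])
  }, integer(1))
  names(bits) <- codes
  bits
})

iupac_encode <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  b <- iupac_bits[ch]
  if (anyNA(b)) stop_fmt("invalid IUPAC character '%s' in \"%s\"",
                         ch[which(is.na(b))[1]], s)
  unname(b)
}

#' Best ungapped IUPAC consensus alignment
#'
#' Compares two IUPAC consensus strings over all ungapped offsets with at
#' least `min_overlap` overlapping positions and both orientations of `b`.
#' Two positions are compatible when their base sets intersect (`.`/`n`
#' match anything). Returns the alignment minimising the number of
#' incompatible positions; ties prefer the larger overlap, then the smaller
#' absolute offset.
#'
#' @param a,b IUPAC strings.
#' @param min_overlap minimum overlapping positions (default 4).
#' @return list with `mismatches`, `offset` (of b's first position relative
#'   to a's), `orientation` ("+" or "-"), and `overlap`.
#' @export
consensus_align <- function(a, b, min_overlap = 4L) {
  ea <- iupac_encode(a)
  wa <- length(ea); wb <- nchar(b)
  if (wa < min_overlap || wb < min_overlap) {
    stop_fmt("consensus widths (%d, %d) below min_overlap %d", wa, wb, min_overlap)
  }
  best <- NULL
  for (orient in c("+", "-")) {
    eb <- iupac_encode(if (orient == "+") b else revcomp(b))
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      mm <- sum(bitwAnd(ea[ia], eb[ia - off]) == 0L)
      cand <- list(mismatches = mm, offset = as.integer(off),
                   orientation = orient, overlap = length(ia))
      if (is.null(best) ||
          mm < best$mismatches ||
          (mm == best$mismatches && cand$overlap > best$overlap) ||
          (mm == best$mismatches && cand$overlap == best$overlap &&
           abs(cand$offset) < abs(best$offset))) {
        best <- cand
      }
    }
  }
  best
}

#' Minimal mismatch count between two IUPAC consensi
#'
#' Shorthand for `consensus_align(a, b, ...)$mismatches`.
#' @inheritParams consensus_align
#' @return integer mismatch count of the best alignment.
#' @export
consensus_mismatch <- function(a, b, min_overlap = 4L) {
  consensus_align(a, b, min_overlap = min_overlap)$mismatches
}

# --- MEME minimal format ---------------------------------------------------

#' Write motifs in MEME minimal motif format
#'
#' @param motifs list of `motif` objects.
#' @param path output file.
#' @param background optional background model supplying 0-order base
#'   frequencies for the header (uniform when absent).
#' @export
write_meme <- function(motifs, path, background = NULL) {
  bg <- if (is.null(background)) {
    stats::setNames(rep(0.25, 4), DNA_BASES)
  } else {
    background$freq[[1]][DNA_BASES]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    nm <- if (nzchar(m$provenance)) m$provenance else sprintf("motif_%d", i)
    writeLines(sprintf("MOTIF %s %s", nm, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= %s",
      m$width, format(m$score %||% 0)), con)
    writeLines(apply(m$matrix, 2, function(p) {
      sprintf("%.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal motif format
#'
#' @param path file written by [write_meme()] (or any minimal-format file
#'   with letter-probability matrices over ACGT).
#' @return list of `motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    hdr <- strsplit(sub("^MOTIF ", "", lines[s]), "\\s+")[[1]]
    lpm <- grep("^letter-probability matrix:", lines)
    lpm <- lpm[lpm > s][1]
    w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", lines[lpm]))
    rows <- lines[(lpm + 1L):(lpm + w)]
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
    mat <- t(mat)  # 4 x w
    mat <- sweep(mat, 2, colSums(mat), "/")
    motif(mat, provenance = hdr[1])
  })
}
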