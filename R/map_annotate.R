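# Mapping cluster-average motifs back onto upstream regions (both strands,
# TSS-relative coordinates with the TSS at the right end of each region),
# tallying instances per motif and gene, and annotating discovered motifs
# against an IUPAC consensus motif database.

#' Scan regions with a motif
#'
#' Per position and strand, scores the window by the log2-odds of the motif
#' versus the order-0 background; positions scoring at least
#' `score_fraction` of the motif's maximum achievable score are reported.
#' Windows containing N are skipped; a (gene, offset, strand) locus is
#' never reported twice. Offsets are TSS-relative and negative: the TSS
#' sits at the right end of each region, so a width-w instance ending at
#' the TSS has offset `-w`.
#'
#' @param motif a `motif`.
#' @param regions `upstream_regions` data.frame.
#' @param background a `background_model` (supplies order-0 base
#'   frequencies).
#' @param score_fraction fraction of the maximum log-odds score required
#'   (default 0.85).
#' @param motif_id label used in the output (default the motif consensus).
#' @return data.frame of instances: motif_id, gene_id, offset, strand,
#'   matched_word, score.
#' @export
scan_regions <- function(motif, regions, background, score_fraction = 0.85,
                         motif_id = NULL) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  motif_id <- motif_id %||% motif$consensus
  w <- motif$width
  bg0 <- background$freq[[1]][DNA_BASES]
  bg0[is.na(bg0) | bg0 <= 0] <- 1e-9
  floor_p <- 1e-9  # zero PWM entries score as a large negative, not -Inf
  lo_f <- log2(pmax(motif$matrix, floor_p)) - log2(matrix(bg0, 4L, w))
  lo_r <- lo_f[4:1, w:1, drop = FALSE]
  max_score <- sum(apply(lo_f, 2, max))
  thr <- score_fraction * max_score
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$seq[i]
    L <- nchar(s)
    if (L < w) next
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
    n_pos <- L - w + 1L
    sc_f <- numeric(n_pos); sc_r <- numeric(n_pos)
    for (j in seq_len(w)) {
      b <- code[j:(j + n_pos - 1L)]
      cf <- lo_f[cbind(b, j)]; cr <- lo_r[cbind(b, j)]
      sc_f <- sc_f + cf  # NA propagates for windows containing N
      sc_r <- sc_r + cr
    }
    hit_f <- which(!is.na(sc_f) & sc_f >= thr)
    hit_r <- which(!is.na(sc_r) & sc_r >= thr)
    if (length(hit_f) + length(hit_r) == 0L) next
    word_at <- function(p) substring(s, p, p + w - 1L)
    df <- rbind(
      if (length(hit_f)) data.frame(
        motif_id = motif_id, gene_id = regions$gene_id[i],
        offset = hit_f - 1L - L, strand = "+",
        matched_word = word_at(hit_f), score = sc_f[hit_f],
        stringsAsFactors = FALSE),
      if (length(hit_r)) data.frame(
        motif_id = motif_id, gene_id = regions$gene_id[i],
        offset = hit_r - 1L - L, strand = "-",
        matched_word = revcomp(word_at(hit_r)), score = sc_r[hit_r],
        stringsAsFactors = FALSE))
    out[[i]] <- df
  }
  res <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(res)) {
    res <- data.frame(motif_id = character(0), gene_id = character(0),
                      offset = integer(0), strand = character(0),
                      matched_word = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res[!duplicated(res[c("motif_id", "gene_id", "offset", "strand")]), ,
      drop = FALSE]
}

#' Tally motif instances per motif and gene
#'
#' Builds the complete motif x gene count table (zero cells included),
#' per-motif totals, and flags groups of genes with identical per-motif
#' instance layouts (same motifs at the same offsets and strands —
#' typically tandem duplicates).
#'
#' @param instances data.frame from [scan_regions()] (rows may cover
#'   several motifs).
#' @param motifs character vector of all motif ids to tabulate.
#' @param genes character vector of all gene ids to tabulate.
#' @return list: `counts` (matrix motif x gene), `totals` (named vector),
#'   `identical_layouts` (list of gene-id groups sharing a non-empty
#'   layout).
#' @export
tally_instances <- function(instances, motifs, genes) {
  bad_m <- setdiff(instances$motif_id, motifs)
  if (length(bad_m)) stop_fmt("instance references unknown motif %s", bad_m[1])
  bad_g <- setdiff(instances$gene_id, genes)
  if (length(bad_g)) stop_fmt("instance references unknown gene %s", bad_g[1])
  counts <- matrix(0L, length(motifs), length(genes),
                   dimnames = list(motifs, genes))
  if (nrow(instances)) {
    tab <- table(factor(instances$motif_id, levels = motifs),
                 factor(instances$gene_id, levels = genes))
    counts[] <- as.integer(tab)
  }
  totals <- rowSums(counts)
  layouts <- vapply(genes, function(g) {
    rows <- instances[instances$gene_id == g, , drop = FALSE]
    if (nrow(rows) == 0L) return("")
    rows <- rows[order(rows$motif_id, rows$offset, rows$strand), ]
    paste(sprintf("%s@%d%s", rows$motif_id, rows$offset, rows$strand),
          collapse = ";")
  }, character(1))
  nonempty <- layouts[nzchar(layouts)]
  groups <- split(names(nonempty), nonempty)
  identical_layouts <- unname(Filter(function(g) length(g) > 1L, groups))
  list(counts = counts, totals = totals,
       identical_layouts = identical_layouts)
}

#' Match a discovered motif against a consensus database
#'
#' The query consensus is compared with every database consensus over all
#' ungapped offsets with overlap >= `min_overlap` and both orientations;
#' the mismatch count of a pair is the minimal number of incompatible
#' positions (IUPAC codes are compatible when their base sets intersect;
#' `.` matches anything). Results are ranked by mismatches, ties by
#' database id.
#'
#' @param query a `motif` or IUPAC consensus string.
#' @param database data.frame with columns id, consensus (and optionally
#'   keywords), e.g. from [read_motif_database()].
#' @param top_n number of results returned (default 5).
#' @param min_overlap minimum aligned positions (default 4).
#' @return data.frame: query_motif_id, database_id, mismatches,
#'   best_offset, orientation, overlap, keywords, rank.
#' @export
match_database <- function(query, database, top_n = 5L, min_overlap = 4L) {
  if (nrow(database) == 0L) stop_fmt("empty motif database")
  qcons <- if (is_motif(query)) query$consensus else query
  res <- lapply(seq_len(nrow(database)), function(i) {
    al <- consensus_align(qcons, database$consensus[i],
                          min_overlap = min_overlap)
    data.frame(query_motif_id = qcons, database_id = database$id[i],
               mismatches = al$mismatches, best_offset = al$offset,
               orientation = al$orientation, overlap = al$overlap,
               keywords = database$keywords[i] %||% "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$mismatches, res$database_id), , drop = FALSE]
  res <- utils::head(res, top_n)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Export instance maps
#'
#' Per gene, instances sorted by offset with the TSS at the right end
#' (offset 0), emitted as BED-like records (region-relative 0-based
#' half-open coordinates with a strand column) plus a JSON layout; genes
#' without instances get an empty track.
#'
#' @param instances data.frame of instances (as from [scan_regions()]).
#' @param regions `upstream_regions` covering the instance genes.
#' @param dir optional output directory; when given, writes
#'   `instances.bed` and `layout.json` there.
#' @return list with `bed` (data.frame: gene_id, start, end, motif_id,
#'   score, strand) and `layout` (named per-gene list of instance
#'   records).
#' @export
export_map <- function(instances, regions, dir = NULL) {
  L <- stats::setNames(regions$length, regions$gene_id)
  width <- nchar(instances$matched_word)
  bed <- data.frame(
    gene_id = instances$gene_id,
    start = as.integer(L[instances$gene_id] + instances$offset),
    end = as.integer(L[instances$gene_id] + instances$offset + width),
    motif_id = instances$motif_id,
    score = round(instances$score, 4),
    strand = instances$strand,
    stringsAsFactors = FALSE)
  bed <- bed[order(bed$gene_id, bed$start, bed$strand, bed$motif_id), ,
             drop = FALSE]
  rownames(bed) <- NULL
  layout <- lapply(stats::setNames(regions$gene_id, regions$gene_id),
                   function(g) {
    rows <- instances[instances$gene_id == g, , drop = FALSE]
    rows <- rows[order(rows$offset), , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) {
      list(motif = rows$motif_id[i], offset = rows$offset[i],
           strand = rows$strand[i], word = rows$matched_word[i],
           score = rows$score[i])
    })
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(bed, file.path(dir, "instances.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    jsonlite::write_json(layout, file.path(dir, "layout.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(bed = bed, layout = layout)
}

#' Read a BED-like instance file back into an instance table
#'
#' Inverse of the `instances.bed` export: reconstructs TSS-relative
#' offsets from the region lengths.
#'
#' @param path BED-like file written by [export_map()].
#' @param regions the same `upstream_regions` used at export time.
#' @return instance data.frame (motif_id, gene_id, offset, strand,
#'   matched_word, score); matched words are re-derived from the region
#'   sequences.
#' @export
read_instances <- function(path, regions) {
  bed <- utils::read.delim(path, stringsAsFactors = FALSE)
  L <- stats::setNames(regions$length, regions$gene_id)
  seqs <- stats::setNames(regions$seq, regions$gene_id)
  word <- substring(seqs[bed$gene_id], bed$start + 1L, bed$end)
  word <- ifelse(bed$strand == "-", revcomp(word), word)
  data.frame(motif_id = bed$motif_id, gene_id = bed$gene_id,
             offset = as.integer(bed$start - L[bed$gene_id]),
             strand = bed$strand, matched_word = unname(word),
             score = bed$score, stringsAsFactors = FALSE)
}
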