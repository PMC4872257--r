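# Genome and annotation input, upstream flanking-region extraction, and the
# genome-wide background word-frequency model.
#
# Coordinate convention: 0-based half-open internally. GFF3 (1-based closed)
# is converted on read: for a "+" gene the TSS is `start - 1`, for a "-"
# gene `end - 1` — in both cases the 0-based coordinate of the first
# transcribed base.

#' Load a genome and its gene annotation
#'
#' Reads a multi-record FASTA genome (via Biostrings) and a GFF3 annotation
#' (via rtracklayer), keeping `gene`-type features. Sequences are
#' uppercased. Strand and TSS are resolved per gene.
#'
#' @param genome_source path to a FASTA file.
#' @param annotation_source path to a GFF3 file containing gene features.
#' @return list with `contigs` (named character vector of uppercase
#'   sequences) and `annotations` (data.frame: gene_id, contig_id, strand,
#'   tss — 0-based coordinate of the first transcribed base).
#' @export
load_reference <- function(genome_source, annotation_source) {
  dss <- Biostrings::readDNAStringSet(genome_source)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids)) {
    stop_fmt("duplicate contig id in FASTA: %s", ids[duplicated(ids)][1])
  }
  contigs <- toupper(as.character(dss))
  names(contigs) <- ids

  gff <- as.data.frame(rtracklayer::import(annotation_source, format = "gff3"))
  gff <- gff[gff$type == "gene", , drop = FALSE]
  gene_id <- gff$ID %||% gff$Name
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(gff)))
  gene_id <- as.character(gene_id)
  strand <- as.character(gff$strand)

  undir <- !(strand %in% c("+", "-"))
  if (any(undir)) {
    stop_fmt("gene %s has no strand ('.') in the annotation", gene_id[undir][1])
  }
  contig_id <- as.character(gff$seqnames)
  unknown <- !(contig_id %in% names(contigs))
  if (any(unknown)) {
    stop_fmt("gene %s references contig %s absent from the genome FASTA",
             gene_id[unknown][1], contig_id[unknown][1])
  }
  if (anyDuplicated(gene_id)) {
    stop_fmt("duplicate gene id in annotation: %s", gene_id[duplicated(gene_id)][1])
  }
  tss <- ifelse(strand == "+", gff$start - 1L, gff$end - 1L)
  len <- nchar(contigs)[contig_id]
  bad <- tss < 0L | tss >= len
  if (any(bad)) {
    stop_fmt("gene %s has TSS outside its contig", gene_id[bad][1])
  }
  list(contigs = contigs,
       annotations = data.frame(gene_id = gene_id, contig_id = contig_id,
                                strand = strand, tss = as.integer(tss),
                                stringsAsFactors = FALSE))
}

#' Extract upstream flanking regions
#'
#' For every annotated gene, takes up to `flank_length` bases immediately 5'
#' of the TSS on the gene's strand. The returned sequence reads 5'->3' on
#' the gene's strand, so its last base abuts the TSS; the base at the TSS
#' itself is never included. Regions truncated by a contig edge keep their
#' true (shorter) length; zero-length or sub-`min_length` regions are
#' omitted with a warning.
#'
#' @param contigs named character vector of contig sequences (uppercase).
#' @param annotations data.frame as returned by [load_reference()].
#' @param flank_length maximum region length in bp (default 1000, the
#'   standard analysis window).
#' @param min_length shortest truncated region retained (default 1).
#' @return data.frame of class `upstream_regions`: gene_id, contig_id,
#'   strand, start, end (0-based half-open genomic interval), length, seq.
#' @export
extract_upstream <- function(contigs, annotations, flank_length = 1000L,
                             min_length = 1L) {
  if (flank_length < 1L) stop_fmt("flank_length must be >= 1")
  ann <- annotations
  L <- nchar(contigs)[ann$contig_id]
  plus <- ann$strand == "+"
  start <- ifelse(plus, pmax(0L, ann$tss - flank_length), ann$tss + 1L)
  end <- ifelse(plus, ann$tss, pmin(L, ann$tss + 1L + flank_length))
  len <- end - start
  keep <- len >= max(1L, min_length)
  dropped <- ann$gene_id[!keep]
  if (length(dropped)) {
    warn_fmt("omitting %d region(s) shorter than %d bp (e.g. %s)",
             length(dropped), max(1L, min_length), dropped[1])
  }
  trunc <- keep & len < flank_length
  if (any(trunc)) {
    message(sprintf("%d region(s) truncated at contig edges (< %d bp)",
                    sum(trunc), flank_length))
  }
  ann <- ann[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]; len <- len[keep]
  seq <- substring(contigs[ann$contig_id], start + 1L, end)
  minus <- ann$strand == "-"
  if (any(minus)) seq[minus] <- revcomp(seq[minus])
  out <- data.frame(gene_id = ann$gene_id, contig_id = ann$contig_id,
                    strand = ann$strand, start = as.integer(start),
                    end = as.integer(end), length = as.integer(len),
                    seq = unname(seq), stringsAsFactors = FALSE)
  class(out) <- c("upstream_regions", "data.frame")
  rownames(out) <- NULL
  out
}

# Regions can also be handed around as bare character vectors of sequence;
# this coerces either representation.
region_sequences <- function(regions) {
  if (is.character(regions)) return(regions)
  if (is.data.frame(regions)) {
    s <- regions$seq
    names(s) <- regions$gene_id
    return(s)
  }
  stop_fmt("regions must be an upstream_regions data.frame or character vector")
}

# Wrap bare sequences as an upstream_regions data.frame with synthetic ids.
as_regions <- function(seqs, gene_ids = NULL) {
  if (is.data.frame(seqs)) return(seqs)
  ids <- gene_ids %||% names(seqs) %||% sprintf("g%04d", seq_along(seqs))
  out <- data.frame(gene_id = ids, contig_id = ids, strand = "+",
                    start = 0L, end = nchar(seqs),
                    length = nchar(seqs), seq = unname(seqs),
                    stringsAsFactors = FALSE)
  class(out) <- c("upstream_regions", "data.frame")
  out
}

#' Build a background word-frequency model
#'
#' Counts every k-window (k = 1..`max_order`) not containing `N`, pooled
#' over all regions on the given strand only, and normalises to
#' frequencies. The model doubles as the null for over-representation
#' statistics and as the emission model of the synthetic promoter
#' generator (an order-(K-1) Markov chain).
#'
#' @param regions `upstream_regions` data.frame or character vector.
#' @param max_order largest word length K tracked (default 3).
#' @return object of class `background_model`: list with `freq` (per-k named
#'   frequency vectors), `max_order`, `n_regions`, `total_positions`.
#' @export
build_background <- function(regions, max_order = 3L) {
  seqs <- region_sequences(regions)
  if (length(seqs) == 0L) stop_fmt("build_background: no regions")
  if (max_order < 1L) stop_fmt("max_order must be >= 1")
  freq <- vector("list", max_order)
  totals <- integer(max_order)
  for (k in seq_len(max_order)) {
    words <- unlist(lapply(seqs, str_windows, w = k), use.names = FALSE)
    if (length(words) == 0L) {
      stop_fmt("all regions shorter than word length %d", k)
    }
    words <- words[!grepl("N", words, fixed = TRUE)]
    if (length(words) == 0L) {
      stop_fmt("no N-free windows of length %d", k)
    }
    u <- sort(unique(words))
    cnt <- tabulate(match(words, u), length(u))
    freq[[k]] <- stats::setNames(cnt / sum(cnt), u)
    totals[k] <- length(words)
  }
  structure(list(freq = freq, max_order = as.integer(max_order),
                 n_regions = length(seqs),
                 total_positions = totals,
                 cache = new.env(parent = emptyenv())),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> order %d, %d regions, %s positions at k=1\n",
              x$max_order, x$n_regions, format(x$total_positions[1], big.mark = ",")))
  invisible(x)
}

#' Probability of words under the background model
#'
#' Words no longer than the model order are looked up directly; longer words
#' use the order-(K-1) Markov chain factorisation
#' `P(w) = P(w[1..K]) * prod_j P(w[j] | w[j-K+1..j-1])`. Words containing
#' k-grams never observed in the background get probability 0.
#'
#' @param background a `background_model`.
#' @param words character vector of equal-width words over A,C,G,T.
#' @return numeric vector of probabilities.
#' @export
word_probability <- function(background, words) {
  if (length(words) == 0L) return(numeric(0))
  w <- unique(nchar(words))
  if (length(w) != 1L) {
    out <- numeric(length(words))
    for (g in split(seq_along(words), nchar(words))) {
      out[g] <- word_probability(background, words[g])
    }
    return(out)
  }
  K <- min(background$max_order, w)
  fK <- background$freq[[K]]
  look <- function(tab, keys) {
    p <- unname(tab[keys]); p[is.na(p)] <- 0; p
  }
  p <- look(fK, substring(words, 1L, K))
  if (w > K) {
    fKm1 <- if (K > 1L) background$freq[[K - 1L]] else NULL
    for (j in (K + 1L):w) {
      gram <- substring(words, j - K + 1L, j)
      num <- look(fK, gram)
      if (K > 1L) {
        den <- look(fKm1, substring(words, j - K + 1L, j - 1L))
        step <- ifelse(den > 0, num / den, 0)
      } else {
        step <- num
      }
      p <- p * step
    }
  }
  p
}

# --- serialization ---------------------------------------------------------

#' Write regions as FASTA
#'
#' Headers follow `gene_id|contig|strand|start-end`.
#' @param regions `upstream_regions` data.frame.
#' @param path output FASTA path.
#' @export
write_regions_fasta <- function(regions, path) {
  hdr <- sprintf("%s|%s|%s|%d-%d", regions$gene_id, regions$contig_id,
                 regions$strand, regions$start, regions$end)
  dss <- Biostrings::DNAStringSet(regions$seq)
  names(dss) <- hdr
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read regions written by [write_regions_fasta()]
#' @param path FASTA path.
#' @return `upstream_regions` data.frame.
#' @export
read_regions_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(dss), "|", fixed = TRUE)
  iv <- strsplit(vapply(parts, `[`, "", 4L), "-", fixed = TRUE)
  seqs <- as.character(dss)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    contig_id = vapply(parts, `[`, "", 2L),
                    strand = vapply(parts, `[`, "", 3L),
                    start = as.integer(vapply(iv, `[`, "", 1L)),
                    end = as.integer(vapply(iv, `[`, "", 2L)),
                    length = nchar(seqs), seq = unname(seqs),
                    stringsAsFactors = FALSE)
  class(out) <- c("upstream_regions", "data.frame")
  out
}

#' Serialize a background model
#'
#' One two-column tab-delimited table (word, frequency) per order, plus a
#' JSON sidecar with totals.
#'
#' @param background a `background_model`.
#' @param dir output directory (created if needed).
#' @export
write_background <- function(background, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(background$max_order)) {
    f <- background$freq[[k]]
    utils::write.table(
      data.frame(word = names(f), frequency = unname(f)),
      file.path(dir, sprintf("background_k%d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(max_order = background$max_order, n_regions = background$n_regions,
         total_positions = background$total_positions),
    file.path(dir, "background.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a background model written by [write_background()]
#' @param dir directory holding the per-order tables and JSON sidecar.
#' @return a `background_model`.
#' @export
read_background <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "background.json"),
                              simplifyVector = TRUE)
  freq <- lapply(seq_len(meta$max_order), function(k) {
    tab <- utils::read.delim(file.path(dir, sprintf("background_k%d.tsv", k)),
                             stringsAsFactors = FALSE)
    stats::setNames(tab$frequency, tab$word)
  })
  structure(list(freq = freq, max_order = as.integer(meta$max_order),
                 n_regions = meta$n_regions,
                 total_positions = meta$total_positions,
                 cache = new.env(parent = emptyenv())),
            class = "background_model")
}
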