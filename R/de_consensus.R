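# Cross-condition differential-expression screening: load the per-cultivar,
# per-timepoint tables, intersect them into consistent over-/under-expressed
# gene lists, tally timepoint-specific genes, and provide the
# housekeeping-normalisation and rank-correlation validation computations.

#' Column mapping for CuffDiff-style DE tables
#'
#' Defaults follow the `gene_exp.diff` layout; override any entry for other
#' tabular formats.
#'
#' @param gene_id,log2fc,p,q,significant source column names. `significant`
#'   may be `NA` if the table has no significance flag.
#' @return named character vector used by [load_de_tables()].
#' @export
de_columns <- function(gene_id = "gene_id", log2fc = "log2(fold_change)",
                       p = "p_value", q = "q_value",
                       significant = "significant") {
  c(gene_id = gene_id, log2fc = log2fc, p = p, q = q,
    significant = significant)
}

parse_de_table <- function(path, columns, cell_label) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warn_fmt("DE table %s (%s) is empty", path, cell_label)
    return(data.frame(gene_id = character(0), log2fc = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  need <- columns[c("gene_id", "log2fc", "p", "q")]
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols)) {
    stop_fmt("DE table %s lacks column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[columns[[col]]]]))
    bad <- which(is.na(v) & !is.na(raw[[columns[[col]]]]) &
                   raw[[columns[[col]]]] != "NA")
    if (length(bad)) {
      stop_fmt("DE table %s: non-numeric %s at line %d", path, col,
               bad[1] + 1L)  # +1 for the header line
    }
    v
  }
  out <- data.frame(gene_id = as.character(raw[[columns[["gene_id"]]]]),
                    log2fc = num("log2fc"), p = num("p"), q = num("q"),
                    stringsAsFactors = FALSE)
  sig_col <- columns[["significant"]]
  out$significant <- if (!is.na(sig_col) && sig_col %in% names(raw)) {
    raw[[sig_col]] %in% c("yes", "TRUE", "True", "true", "1")
  } else {
    NA
  }
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    stop_fmt("DE table %s: duplicate gene %s", path, out$gene_id[dup][1])
  }
  out
}

#' Load a grid of DE tables
#'
#' @param manifest data.frame with columns `cultivar`, `timepoint`, `path`;
#'   every (cultivar, timepoint) cell of the grid must be present exactly
#'   once.
#' @param columns column mapping from [de_columns()].
#' @return named list of parsed tables (names `"cultivar|timepoint"`), with
#'   attributes `cultivars` and `timepoints`.
#' @export
load_de_tables <- function(manifest, columns = de_columns()) {
  stopifnot(all(c("cultivar", "timepoint", "path") %in% names(manifest)))
  cultivars <- unique(manifest$cultivar)
  timepoints <- unique(manifest$timepoint)
  want <- expand.grid(cultivar = cultivars, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  key <- paste(manifest$cultivar, manifest$timepoint, sep = "|")
  wkey <- paste(want$cultivar, want$timepoint, sep = "|")
  missing_cells <- setdiff(wkey, key)
  if (length(missing_cells)) {
    stop_fmt("missing DE table(s) for grid cell(s): %s",
             paste(missing_cells, collapse = ", "))
  }
  if (anyDuplicated(key)) {
    stop_fmt("duplicate DE table for cell %s", key[duplicated(key)][1])
  }
  tables <- lapply(seq_len(nrow(manifest)), function(i) {
    parse_de_table(manifest$path[i], columns, key[i])
  })
  names(tables) <- key
  attr(tables, "cultivars") <- cultivars
  attr(tables, "timepoints") <- timepoints
  tables
}

de_cell_meta <- function(tables) {
  parts <- strsplit(names(tables), "|", fixed = TRUE)
  data.frame(cultivar = vapply(parts, `[`, "", 1L),
             timepoint = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Consensus differential-expression gene lists across a condition grid
#'
#' A gene is over-expressed iff it is significant with positive log2 fold
#' change in every (cultivar, timepoint) cell, under-expressed iff
#' significant and negative everywhere. Significance honours the table's
#' flag when present, otherwise `q <= alpha`. Genes significant (with a
#' consistent direction) in all cultivars at exactly one timepoint are
#' tallied per timepoint and direction. Genes absent from a table are
#' treated as non-significant there.
#'
#' @param tables named list from [load_de_tables()] or
#'   [simulate_de_tables()] (names `"cultivar|timepoint"`).
#' @param alpha significance threshold on q (default 0.05), used when a
#'   table carries no significance flag.
#' @param require_direction require the same fold-change sign in every
#'   cell (default TRUE); when FALSE, genes significant everywhere are
#'   assigned by the sign of their mean log2 fold change.
#' @return list of class `consensus_result`: `over_expressed`,
#'   `under_expressed` (lexicographically sorted), and `timepoint_only`
#'   (data.frame timepoint, n_over, n_under).
#' @export
consensus_gene_lists <- function(tables, alpha = 0.05,
                                 require_direction = TRUE) {
  if (length(tables) == 0L) stop_fmt("empty DE table grid")
  meta <- de_cell_meta(tables)
  universe <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  if (length(universe) == 0L) {
    return(structure(list(
      over_expressed = character(0), under_expressed = character(0),
      timepoint_only = data.frame(timepoint = unique(meta$timepoint),
                                  n_over = 0L, n_under = 0L,
                                  stringsAsFactors = FALSE)),
      class = "consensus_result"))
  }
  n_cells <- length(tables)
  # status per gene x cell: +1 significant-up, -1 significant-down, 0 not
  status <- matrix(0L, length(universe), n_cells,
                   dimnames = list(universe, names(tables)))
  for (j in seq_len(n_cells)) {
    t <- tables[[j]]
    sig <- if (length(t$significant) && !all(is.na(t$significant))) {
      t$significant
    } else {
      t$q <= alpha
    }
    sig[is.na(sig)] <- FALSE
    idx <- match(t$gene_id, universe)
    status[idx[sig], j] <- ifelse(t$log2fc[sig] > 0, 1L, -1L)
  }
  if (require_direction) {
    over <- universe[rowSums(status == 1L) == n_cells]
    under <- universe[rowSums(status == -1L) == n_cells]
  } else {
    all_sig <- rowSums(status != 0L) == n_cells
    net <- rowSums(status)
    over <- universe[all_sig & net > 0]
    under <- universe[all_sig & net < 0]
  }
  consensus <- c(over, under)

  timepoints <- unique(meta$timepoint)
  tp_counts <- data.frame(timepoint = timepoints, n_over = 0L, n_under = 0L,
                          stringsAsFactors = FALSE)
  # per timepoint: genes significant with a consistent sign in all cultivars
  tp_dir <- sapply(timepoints, function(tp) {
    cols <- which(meta$timepoint == tp)
    up <- rowSums(status[, cols, drop = FALSE] == 1L) == length(cols)
    down <- rowSums(status[, cols, drop = FALSE] == -1L) == length(cols)
    ifelse(up, 1L, ifelse(down, -1L, 0L))
  })
  tp_dir <- matrix(tp_dir, ncol = length(timepoints),
                   dimnames = list(universe, timepoints))
  one_tp <- rowSums(tp_dir != 0L) == 1L & !(universe %in% consensus)
  for (i in seq_along(timepoints)) {
    here <- one_tp & tp_dir[, i] != 0L
    tp_counts$n_over[i] <- sum(tp_dir[here, i] == 1L)
    tp_counts$n_under[i] <- sum(tp_dir[here, i] == -1L)
  }
  structure(list(over_expressed = over, under_expressed = under,
                 timepoint_only = tp_counts),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d over-expressed, %d under-expressed\n",
              length(x$over_expressed), length(x$under_expressed)))
  for (i in seq_len(nrow(x$timepoint_only))) {
    cat(sprintf("  %s only: %d over, %d under\n",
                x$timepoint_only$timepoint[i], x$timepoint_only$n_over[i],
                x$timepoint_only$n_under[i]))
  }
  invisible(x)
}

#' Write consensus gene lists and summary
#'
#' Two one-column text lists plus a JSON summary of the per-timepoint-only
#' counts.
#' @param result a `consensus_result`.
#' @param dir output directory.
#' @export
write_consensus <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(result$over_expressed, file.path(dir, "over_expressed.txt"))
  writeLines(result$under_expressed, file.path(dir, "under_expressed.txt"))
  jsonlite::write_json(
    list(n_over = length(result$over_expressed),
         n_under = length(result$under_expressed),
         timepoint_only = result$timepoint_only),
    file.path(dir, "consensus_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Normalise a count matrix by housekeeping-gene geometric means
#'
#' Each sample's scaling factor is the grand arithmetic mean of the
#' per-sample housekeeping geometric means divided by that sample's own
#' housekeeping geometric mean; after scaling, the housekeeping geometric
#' mean is equal across samples.
#'
#' @param counts numeric matrix, genes x samples, with rownames.
#' @param housekeeping_ids one or more rownames used as the reference set;
#'   their counts must all be positive.
#' @return normalised matrix of the same shape, with the per-sample factors
#'   in attribute `"factors"`.
#' @export
normalize_by_housekeeping <- function(counts, housekeeping_ids) {
  if (length(housekeeping_ids) < 1L) stop_fmt("need >= 1 housekeeping gene")
  missing_hk <- setdiff(housekeeping_ids, rownames(counts))
  if (length(missing_hk)) {
    stop_fmt("housekeeping gene %s absent from the count matrix", missing_hk[1])
  }
  hk <- counts[housekeeping_ids, , drop = FALSE]
  bad <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_fmt("non-positive housekeeping count for gene %s in sample %s",
             rownames(hk)[bad[1, 1]],
             colnames(counts)[bad[1, 2]] %||% as.character(bad[1, 2]))
  }
  gm <- exp(colMeans(log(hk)))
  factors <- mean(gm) / gm
  out <- sweep(counts, 2, factors, "*")
  attr(out, "factors") <- factors
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to compare two
#' expression-measurement platforms over the same gene set.
#'
#' @param x,y numeric vectors of equal length (>= 3), no NAs.
#' @return correlation in [-1, 1].
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("x and y must have equal length")
  if (length(x) < 3L) stop_fmt("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_fmt("NA values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_fmt("rank correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}
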