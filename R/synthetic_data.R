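# Synthetic inputs with known ground truth: background-derived promoters,
# planted motif instances, differential-expression table grids, and
# perturbed motif databases. Every generator is seed-deterministic and
# returns the ground truth needed to score the downstream stages.

#' Sample promoter sequences from a background model
#'
#' Sequences are drawn from the model as an order-(K-1) Markov chain: the
#' first K-1 bases from the (K-1)-gram frequencies, each subsequent base
#' from the conditional K-gram distribution given the preceding context.
#'
#' @param model a `background_model`.
#' @param n number of sequences.
#' @param length length of each sequence in bp.
#' @param seed integer RNG seed.
#' @param gene_ids optional ids (default `sim_0001`, ...).
#' @return `upstream_regions` data.frame of synthetic promoters.
#' @export
sample_background_sequences <- function(model, n, length, seed = 1L,
                                        gene_ids = NULL) {
  if (n <= 0L || length <= 0L) stop_fmt("n and length must be positive")
  K <- model$max_order
  with_seed(seed, {
    seqs <- if (K == 1L) {
      f <- model$freq[[1]]
      vapply(seq_len(n), function(i) {
        paste(sample(names(f), length, replace = TRUE, prob = f), collapse = "")
      }, character(1))
    } else {
      fK <- model$freq[[K]]
      ctx_of <- substring(names(fK), 1L, K - 1L)
      last_of <- substring(names(fK), K, K)
      by_ctx <- split(seq_along(fK), ctx_of)
      fKm1 <- model$freq[[K - 1L]]
      vapply(seq_len(n), function(i) {
        out <- character(length)
        init <- sample(names(fKm1), 1L, prob = fKm1)
        start <- strsplit(init, "", fixed = TRUE)[[1]]
        m <- min(length, K - 1L)
        out[seq_len(m)] <- start[seq_len(m)]
        if (length > K - 1L) {
          for (j in K:length) {
            ctx <- paste(out[(j - K + 1L):(j - 1L)], collapse = "")
            idx <- by_ctx[[ctx]]
            if (is.null(idx)) {  # context never observed: restart from 1-grams
              out[j] <- sample(names(model$freq[[1]]), 1L,
                               prob = model$freq[[1]])
            } else {
              out[j] <- sample(last_of[idx], 1L, prob = fK[idx])
            }
          }
        }
        paste(out, collapse = "")
      }, character(1))
    }
    as_regions(seqs, gene_ids = gene_ids %||% sprintf("sim_%04d", seq_len(n)))
  })
}

#' Specification of a planted motif
#'
#' @param motif a `motif` or IUPAC-free word (converted to a point-mass PWM).
#' @param prevalence fraction of sequences receiving at least one instance.
#' @param instances_per_sequence instances per selected sequence (default 1).
#' @param strand_probability probability an instance is planted on the
#'   reverse strand (default 0.5; reverse-strand instances are written as
#'   the reverse complement of the sampled word).
#' @param seed integer RNG seed.
#' @return list of class `planted_motif_spec`.
#' @export
planted_motif_spec <- function(motif, prevalence, instances_per_sequence = 1L,
                               strand_probability = 0.5, seed = 1L) {
  if (is.character(motif)) motif <- motif_from_word(motif)
  stopifnot(prevalence >= 0, prevalence <= 1, instances_per_sequence >= 1L,
            strand_probability >= 0, strand_probability <= 1)
  structure(list(motif = motif, prevalence = prevalence,
                 instances_per_sequence = as.integer(instances_per_sequence),
                 strand_probability = strand_probability, seed = seed),
            class = "planted_motif_spec")
}

# Sample one word column-wise from a PWM.
sample_pwm_word <- function(mat) {
  paste(apply(mat, 2, function(p) sample(DNA_BASES, 1L, prob = p)),
        collapse = "")
}

#' Plant motif instances into background promoters
#'
#' `ceiling(prevalence * n)` regions are selected without replacement; each
#' receives `instances_per_sequence` words sampled column-wise from the
#' motif, written over the background (region length unchanged) at
#' uniformly chosen non-overlapping offsets. Reverse-strand instances write
#' the reverse complement of the sampled word.
#'
#' @param regions `upstream_regions` data.frame.
#' @param spec a [planted_motif_spec()].
#' @return list with `regions` (modified) and `truth` (data.frame: gene_id,
#'   offset — 0-based region-relative start, tss_offset — TSS-relative,
#'   strand, word).
#' @export
plant_motifs <- function(regions, spec) {
  stopifnot(inherits(spec, "planted_motif_spec"))
  w <- spec$motif$width
  n <- nrow(regions)
  if (any(regions$length < w)) stop_fmt("motif width %d exceeds a region length", w)
  n_sel <- ceiling(spec$prevalence * n)
  with_seed(spec$seed, {
    sel <- if (n_sel > 0L) sort(sample.int(n, n_sel)) else integer(0)
    truth <- list()
    seqs <- regions$seq
    for (i in sel) {
      L <- regions$length[i]
      taken <- integer(0)  # occupied positions
      for (r in seq_len(spec$instances_per_sequence)) {
        valid <- setdiff(seq_len(L - w + 1L),
                         unlist(lapply(taken, function(s) (s - w + 1L):(s + w - 1L))))
        if (length(valid) == 0L) {
          stop_fmt("cannot fit %d non-overlapping instances of width %d in %s",
                   spec$instances_per_sequence, w, regions$gene_id[i])
        }
        pos <- if (length(valid) == 1L) valid else sample(valid, 1L)
        word <- sample_pwm_word(spec$motif$matrix)
        minus <- stats::runif(1) < spec$strand_probability
        written <- if (minus) revcomp(word) else word
        substr(seqs[i], pos, pos + w - 1L) <- written
        taken <- c(taken, pos)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = regions$gene_id[i], offset = pos - 1L,
          tss_offset = (pos - 1L) - L,
          strand = if (minus) "-" else "+", word = word,
          stringsAsFactors = FALSE)
      }
    }
    regions$seq <- seqs
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), offset = integer(0),
                 tss_offset = integer(0), strand = character(0),
                 word = character(0), stringsAsFactors = FALSE)
    list(regions = regions, truth = truth)
  })
}

#' Specification of a simulated differential-expression grid
#'
#' Defines the cultivar x timepoint design, the gene universe, and which
#' genes are consistently responsive (all cells), timepoint-specific
#' (significant at one timepoint in all cultivars), or null.
#'
#' @param cultivars,timepoints condition labels.
#' @param n_genes size of the gene universe.
#' @param consistent_up,consistent_down gene ids significant with the given
#'   sign in every cell.
#' @param timepoint_specific named character vector: gene id -> "up@tp" or
#'   "down@tp" (tp a timepoint label), or an empty vector.
#' @param alpha significance threshold on q (default 0.05).
#' @param effect_size mean |log2 fold change| of responsive genes (default 2).
#' @param noise_sd sd of log2 fold changes (default 0.4 responsive,
#'   also used scaled for null genes).
#' @param seed integer RNG seed.
#' @param gene_ids optional explicit universe (default `gene_0001`, ...).
#' @return list of class `de_simulation_spec`.
#' @export
de_simulation_spec <- function(cultivars = c("cvA", "cvB", "cvC"),
                               timepoints = c("t1", "t2"),
                               n_genes = 200L,
                               consistent_up = character(0),
                               consistent_down = character(0),
                               timepoint_specific = character(0),
                               alpha = 0.05, effect_size = 2, noise_sd = 0.4,
                               seed = 1L, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("gene_%04d", seq_len(n_genes))
  if (n_genes < length(consistent_up) + length(consistent_down) +
      length(timepoint_specific)) {
    stop_fmt("n_genes (%d) smaller than the designated gene lists", n_genes)
  }
  if (length(intersect(consistent_up, consistent_down))) {
    stop_fmt("consistent_up and consistent_down overlap")
  }
  desig <- c(consistent_up, consistent_down, names(timepoint_specific))
  if (!all(desig %in% gene_ids)) {
    stop_fmt("designated gene %s not in the gene universe",
             setdiff(desig, gene_ids)[1])
  }
  if (length(timepoint_specific)) {
    tp <- sub("^.*@", "", timepoint_specific)
    dir <- sub("@.*$", "", timepoint_specific)
    if (!all(tp %in% timepoints) || !all(dir %in% c("up", "down"))) {
      stop_fmt("timepoint_specific entries must look like 'up@t1' / 'down@t2'")
    }
  }
  structure(list(cultivars = cultivars, timepoints = timepoints,
                 n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 consistent_up = consistent_up,
                 consistent_down = consistent_down,
                 timepoint_specific = timepoint_specific,
                 alpha = alpha, effect_size = effect_size,
                 noise_sd = noise_sd, seed = seed),
            class = "de_simulation_spec")
}

#' Simulate a grid of differential-expression tables
#'
#' One table per (cultivar, timepoint) cell. Consistently responsive genes
#' get `q < alpha` with the designated sign in every cell;
#' timepoint-specific genes only in their timepoint (all cultivars); all
#' other genes draw small symmetric log2 fold changes with `q` uniform
#' above alpha.
#'
#' @param spec a [de_simulation_spec()].
#' @return named list of data.frames (names `"cultivar|timepoint"`), each
#'   with columns gene_id, log2fc, p, q, significant.
#' @export
simulate_de_tables <- function(spec) {
  stopifnot(inherits(spec, "de_simulation_spec"))
  with_seed(spec$seed, {
    cells <- expand.grid(cultivar = spec$cultivars, timepoint = spec$timepoints,
                         stringsAsFactors = FALSE)
    sp_tp <- sub("^.*@", "", spec$timepoint_specific)
    sp_dir <- sub("@.*$", "", spec$timepoint_specific)
    names(sp_tp) <- names(sp_dir) <- names(spec$timepoint_specific)
    out <- vector("list", nrow(cells))
    names(out) <- paste(cells$cultivar, cells$timepoint, sep = "|")
    for (i in seq_len(nrow(cells))) {
      tp <- cells$timepoint[i]
      g <- spec$gene_ids
      sign <- numeric(length(g))
      sign[g %in% spec$consistent_up] <- 1
      sign[g %in% spec$consistent_down] <- -1
      sp_here <- names(sp_tp)[sp_tp == tp]
      sign[g %in% sp_here] <- ifelse(sp_dir[g[g %in% sp_here]] == "up", 1, -1)
      sig <- sign != 0
      log2fc <- stats::rnorm(length(g), 0, spec$noise_sd / 2)
      log2fc[sig] <- sign[sig] *
        abs(stats::rnorm(sum(sig), spec$effect_size, spec$noise_sd))
      q <- stats::runif(length(g), spec$alpha, 1)
      q[sig] <- stats::runif(sum(sig), 0, spec$alpha * 0.9)
      p <- q * stats::runif(length(g))
      out[[i]] <- data.frame(gene_id = g, log2fc = log2fc, p = p, q = q,
                             significant = sig, stringsAsFactors = FALSE)
    }
    out
  })
}

#' Write simulated DE tables as CuffDiff-style flat files
#'
#' @param tables output of [simulate_de_tables()].
#' @param dir output directory.
#' @return data.frame manifest (cultivar, timepoint, path) accepted by
#'   [load_de_tables()].
#' @export
write_de_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- strsplit(names(tables), "|", fixed = TRUE)
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    df <- data.frame(
      test_id = t$gene_id, gene_id = t$gene_id, gene = t$gene_id,
      locus = "-", sample_1 = "control", sample_2 = "treated",
      status = "OK", value_1 = 1, value_2 = 2 ^ t$log2fc,
      `log2.fold_change.` = t$log2fc, test_stat = 0,
      p_value = t$p, q_value = t$q,
      significant = ifelse(t$significant, "yes", "no"),
      check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[names(df) == "log2.fold_change."] <- "log2(fold_change)"
    paths[i] <- file.path(dir, sprintf("%s_%s.diff", keys[[i]][1], keys[[i]][2]))
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  data.frame(cultivar = vapply(keys, `[`, "", 1L),
             timepoint = vapply(keys, `[`, "", 2L),
             path = paths, stringsAsFactors = FALSE)
}

#' Build a perturbed motif-database fixture
#'
#' For every true motif the database receives one variant of its consensus
#' with each position substituted independently with probability
#' `mutation_rate` (at least one substitution forced when the rate is
#' positive, emulating database entries one nucleotide away from a
#' discovered motif), plus `n_decoys` random same-width-range decoys.
#'
#' @param true_motifs list of `motif` objects (or plain words).
#' @param n_decoys number of random decoy entries.
#' @param mutation_rate per-position substitution probability.
#' @param seed integer RNG seed.
#' @return list with `database` (data.frame: id, consensus, keywords) and
#'   `truth` (data.frame: database_id, true_consensus, hamming).
#' @export
make_database_fixture <- function(true_motifs, n_decoys = 10L,
                                  mutation_rate = 0.15, seed = 1L) {
  if (n_decoys < 0L) stop_fmt("n_decoys must be >= 0")
  cons <- vapply(true_motifs, function(m) {
    if (is.character(m)) toupper(m) else m$consensus
  }, character(1))
  with_seed(seed, {
    variants <- character(length(cons))
    dists <- integer(length(cons))
    for (i in seq_along(cons)) {
      bases <- strsplit(cons[i], "", fixed = TRUE)[[1]]
      flip <- stats::runif(length(bases)) < mutation_rate
      if (mutation_rate > 0 && !any(flip)) {
        flip[sample.int(length(bases), 1L)] <- TRUE
      }
      for (j in which(flip)) {
        pool <- setdiff(DNA_BASES, toupper(bases[j]))
        bases[j] <- sample(pool, 1L)
      }
      variants[i] <- paste(bases, collapse = "")
      dists[i] <- sum(flip)
    }
    widths <- nchar(cons)
    decoys <- vapply(seq_len(n_decoys), function(i) {
      w <- if (length(widths) == 1L) widths else sample(widths, 1L)
      paste(sample(DNA_BASES, w, replace = TRUE), collapse = "")
    }, character(1))
    db <- data.frame(
      id = c(sprintf("DBTRUE%03d", seq_along(variants)),
             if (n_decoys > 0L) sprintf("DBDECOY%03d", seq_len(n_decoys))),
      consensus = c(variants, decoys),
      keywords = c(rep("perturbed true motif", length(variants)),
                   rep("random decoy", n_decoys)),
      stringsAsFactors = FALSE)
    truth <- data.frame(database_id = db$id[seq_along(variants)],
                        true_consensus = cons, hamming = dists,
                        stringsAsFactors = FALSE)
    list(database = db, truth = truth)
  })
}

#' Write / read a flat-file motif database
#'
#' Tab-delimited with columns id, consensus, keywords (PLACE-style
#' consensus strings; keywords semicolon-separated free text).
#'
#' @param database data.frame with id, consensus, keywords.
#' @param path file path.
#' @export
write_motif_database <- function(database, path) {
  utils::write.table(database, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_motif_database
#' @export
read_motif_database <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "consensus")
  if (!all(need %in% names(db))) {
    stop_fmt("motif database must have columns id and consensus")
  }
  if (is.null(db$keywords)) db$keywords <- ""
  if (any(!nzchar(db$consensus))) stop_fmt("empty consensus in motif database")
  db
}
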