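# Subsample-ensemble driver and redundancy resolution. Discovery is run on
# many small random promoter subsets (classically 5000 subsets of 10),
# which raises the chance of catching motifs present in only a fraction of
# the promoters; the pooled motifs are then de-duplicated by k-medoids
# clustering and each cluster is represented by its average PWM.

#' Draw random promoter subsets
#'
#' Each subset is drawn uniformly without replacement within itself;
#' subsets are drawn independently of one another, so a gene may appear in
#' many subsets.
#'
#' @param gene_ids pool of gene ids.
#' @param n_subsets number of subsets (default 5000).
#' @param subset_size genes per subset (default 10).
#' @param seed integer RNG seed.
#' @return list of class `subset_collection`: `subsets` (list of id
#'   vectors), `n_subsets`, `subset_size`, `seed`.
#' @export
make_subsets <- function(gene_ids, n_subsets = 5000L, subset_size = 10L,
                         seed = 1L) {
  if (subset_size > length(gene_ids)) {
    stop_fmt("subset_size (%d) exceeds the gene pool (%d)",
             subset_size, length(gene_ids))
  }
  subsets <- with_seed(seed, {
    lapply(seq_len(n_subsets), function(i) sample(gene_ids, subset_size))
  })
  structure(list(subsets = subsets, n_subsets = as.integer(n_subsets),
                 subset_size = as.integer(subset_size), seed = seed),
            class = "subset_collection")
}

#' Run discovery engines over a subset collection
#'
#' Concatenates every engine's significant motifs over every subset, each
#' tagged with its subset index, engine, and rank; output order is
#' deterministic (subset index, engine, rank).
#'
#' @param regions `upstream_regions` data.frame covering every subset id.
#' @param collection a [make_subsets()] collection.
#' @param background a `background_model`.
#' @param configs list of [engine_config()]s (a single config is accepted).
#' @return list of `motif` objects.
#' @export
run_ensemble <- function(regions, collection, background,
                         configs = list(engine_config())) {
  if (inherits(configs, "engine_config")) configs <- list(configs)
  missing_ids <- setdiff(unique(unlist(collection$subsets)), regions$gene_id)
  if (length(missing_ids)) {
    stop_fmt("no upstream region for subset gene %s", missing_ids[1])
  }
  seq_by_gene <- stats::setNames(regions$seq, regions$gene_id)
  out <- list()
  for (si in seq_along(collection$subsets)) {
    seqs <- unname(seq_by_gene[collection$subsets[[si]]])
    for (cfg in configs) {
      motifs <- discover_motifs(seqs, background, cfg)
      for (ri in seq_along(motifs)) {
        m <- motifs[[ri]]
        m$provenance <- sprintf("subset%d/%s/rank%d", si, cfg$engine, ri)
        out[[length(out) + 1L]] <- m
      }
    }
  }
  out
}

# Total cost of assigning every point to its nearest medoid.
kmedoids_cost <- function(d, medoids) {
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}

# Voronoi-style alternation from one initial medoid set. Stops when the
# assignment cost no longer strictly decreases (the medoid set itself can
# oscillate between equal-cost choices when members are duplicated, e.g.
# identical motifs rediscovered across subsets), with an iteration cap as
# a safety net.
kmedoids_once <- function(d, medoids, max_iter = 100L) {
  n <- nrow(d)
  cost_of <- function(meds) {
    assign <- meds[apply(d[, meds, drop = FALSE], 1, which.min)]
    assign[meds] <- meds  # a medoid anchors its own cluster even under ties
    list(assign = assign, cost = sum(d[cbind(seq_len(n), assign)]))
  }
  medoids <- sort(unique(medoids))
  state <- cost_of(medoids)
  for (iter in seq_len(max_iter)) {
    new_medoids <- sort(unique(vapply(unique(state$assign), function(m) {
      members <- which(state$assign == m)
      members[which.min(colSums(d[members, members, drop = FALSE]))]
    }, integer(1))))
    new_state <- cost_of(new_medoids)
    if (new_state$cost < state$cost - 1e-12) {
      medoids <- new_medoids
      state <- new_state
    } else break
  }
  list(medoids = medoids, assign = state$assign, cost = state$cost)
}

mean_silhouette <- function(d, assign) {
  sil <- cluster::silhouette(as.integer(factor(assign)), dmatrix = d)
  if (length(sil) == 1L && is.na(sil)) return(NA_real_)
  mean(sil[, "sil_width"])
}

#' Cluster motifs by k-medoids
#'
#' PAM-style alternation under [motif_distance()]: assign every motif to
#' its nearest medoid, update each medoid to the member minimising the
#' within-cluster cost, repeat until the cost stops changing; the best of
#' `restarts` seeded initialisations is kept. `k = "auto"` sweeps
#' 2..min(20, n-1) and picks the k maximising the mean silhouette width
#' (ties towards the smaller k). `restarts = "exhaustive"` refines from
#' every possible initial medoid set (small n only).
#'
#' @param motifs list of `motif` objects (>= 2 for a meaningful clustering).
#' @param k number of clusters, or `"auto"`.
#' @param restarts number of seeded initialisations (default 10), or
#'   `"exhaustive"`.
#' @param seed integer RNG seed for the initialisations.
#' @param min_overlap passed to [motif_distance()].
#' @return list of `motif_cluster` objects: `members` (motifs), `medoid`
#'   (index into members), `average` (cluster-average motif),
#'   `total_within_cost`.
#' @export
cluster_motifs_kmedoids <- function(motifs, k = "auto", restarts = 10L,
                                    seed = 1L, min_overlap = 4L) {
  n <- length(motifs)
  if (n < 1L) stop_fmt("no motifs to cluster")
  make_cluster <- function(members_idx, medoid_idx, d) {
    members <- motifs[members_idx]
    list(members = members,
         medoid = match(medoid_idx, members_idx),
         average = average_cluster(members,
                                   medoid = match(medoid_idx, members_idx),
                                   min_overlap = min_overlap),
         total_within_cost = sum(d[members_idx, medoid_idx]))
  }
  d <- motif_distance_matrix(motifs, min_overlap = min_overlap)
  if (n == 1L) {
    return(list(structure(make_cluster(1L, 1L, d), class = "motif_cluster")))
  }
  if (is.numeric(k) && k >= n) {
    warn_fmt("k (%d) >= number of motifs (%d): each motif its own cluster",
             k, n)
    return(lapply(seq_len(n), function(i) {
      structure(make_cluster(i, i, d), class = "motif_cluster")
    }))
  }
  run_k <- function(k) {
    if (identical(restarts, "exhaustive")) {
      inits <- utils::combn(n, k, simplify = FALSE)
    } else {
      seeds <- derive_seeds(seed, restarts)
      inits <- lapply(seeds, function(s) with_seed(s, sort(sample.int(n, k))))
    }
    best <- NULL
    for (init in inits) {
      fit <- kmedoids_once(d, init)
      if (is.null(best) || fit$cost < best$cost - 1e-12) best <- fit
    }
    best
  }
  if (identical(k, "auto")) {
    if (max(d) < 1e-9) {
      fit <- run_k(1L)
    } else if (n == 2L) {
      fit <- run_k(2L)
    } else {
      ks <- 2:min(20L, n - 1L)
      fits <- lapply(ks, run_k)
      sils <- vapply(seq_along(ks), function(i) {
        if (length(unique(fits[[i]]$assign)) < 2L) return(-Inf)
        mean_silhouette(d, fits[[i]]$assign)
      }, numeric(1))
      fit <- fits[[which.max(sils)]]
    }
  } else {
    fit <- run_k(as.integer(k))
  }
  lapply(sort(unique(fit$assign)), function(m) {
    structure(make_cluster(which(fit$assign == m), m, d),
              class = "motif_cluster")
  })
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat(sprintf("<motif_cluster> %d member(s), medoid %s, average %s, cost %.4g\n",
              length(x$members), x$members[[x$medoid]]$consensus,
              x$average$consensus, x$total_within_cost))
  invisible(x)
}

#' Average motif of a cluster
#'
#' Each member is aligned to the medoid at its best offset/orientation (per
#' [motif_distance()]); columns are averaged position-wise over the members
#' covering that position; positions covered by fewer than half the members
#' are trimmed; columns are renormalised and the consensus recomputed.
#'
#' @param members list of `motif` objects (>= 1).
#' @param medoid index of the alignment anchor within `members` (default:
#'   the member minimising the summed distance to the others).
#' @param min_overlap passed to the alignment search.
#' @return the cluster-average `motif`.
#' @export
average_cluster <- function(members, medoid = NULL, min_overlap = 4L) {
  n <- length(members)
  if (n < 1L) stop_fmt("average_cluster: empty cluster")
  if (is.null(medoid)) {
    d <- motif_distance_matrix(members, min_overlap = min_overlap)
    medoid <- which.min(rowSums(d))
  }
  anchor <- members[[medoid]]
  offs <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == medoid) {
      offs[[i]] <- list(mat = members[[i]]$matrix, offset = 0L)
    } else {
      al <- align_motifs(anchor, members[[i]], min_overlap = min_overlap)
      mat <- members[[i]]$matrix
      if (al$rc) mat <- mat[4:1, rev(seq_len(ncol(mat))), drop = FALSE]
      offs[[i]] <- list(mat = mat, offset = al$offset)
    }
  }
  lo <- min(vapply(offs, `[[`, 0L, "offset"))
  hi <- max(vapply(offs, function(o) o$offset + ncol(o$mat) - 1L, 0L))
  width <- hi - lo + 1L
  acc <- matrix(0, 4L, width)
  cov <- integer(width)
  for (o in offs) {
    idx <- (o$offset - lo + 1L):(o$offset - lo + ncol(o$mat))
    acc[, idx] <- acc[, idx] + o$mat
    cov[idx] <- cov[idx] + 1L
  }
  keep <- cov >= n / 2
  # guard: never trim to nothing (can only happen for degenerate overlaps)
  if (!any(keep)) keep <- cov == max(cov)
  avg <- acc[, keep, drop = FALSE] /
    matrix(cov[keep], 4L, sum(keep), byrow = TRUE)
  avg <- sweep(avg, 2, colSums(avg), "/")
  rownames(avg) <- DNA_BASES
  motif(avg, source = "cluster_average",
        provenance = sprintf("average_of_%d", n))
}

#' Tab-delimited cluster report
#'
#' One row per cluster: id, member count, medoid consensus, average
#' consensus, total within-cluster cost.
#'
#' @param clusters list of `motif_cluster`s from [cluster_motifs_kmedoids()].
#' @param path optional output file; when given, the table is written there.
#' @return the report data.frame (invisibly when written).
#' @export
cluster_report <- function(clusters, path = NULL) {
  df <- data.frame(
    cluster_id = sprintf("cluster_%02d", seq_along(clusters)),
    n_members = vapply(clusters, function(c) length(c$members), integer(1)),
    medoid_consensus = vapply(clusters, function(c)
      c$members[[c$medoid]]$consensus, character(1)),
    average_consensus = vapply(clusters, function(c)
      c$average$consensus, character(1)),
    total_within_cost = vapply(clusters, `[[`, 0, "total_within_cost"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
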