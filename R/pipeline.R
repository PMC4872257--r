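# Configuration and the end-to-end driver: DE consensus -> upstream region
# extraction -> background -> ensemble discovery (run separately for the
# over- and under-expressed lists) -> k-medoids clustering -> cluster
# averages -> genome-wide remapping -> database annotation. Every stage's
# output is serialized into the run directory and a JSON manifest records
# seeds and parameters.

pipeline_defaults <- function() {
  list(
    genome = NULL, annotation = NULL, de_manifest = NULL, database = NULL,
    flank_length = 1000L, min_region_length = 1L,
    background_order = 3L,
    alpha = 0.05,
    n_subsets = 5000L, subset_size = 10L,
    engines = list(list(engine = "seed_qvalue", width_min = 6L,
                        width_max = 8L)),
    k = "auto", restarts = 10L,
    score_fraction = 0.85, top_n_matches = 5L,
    seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML document (path or literal text), injects defaults, rejects
#' unknown keys, and range-checks every numeric parameter. An empty
#' document yields the all-defaults configuration (1000 bp flank, 5000
#' subsets of 10, q-gated engine over widths 6-8, silhouette-chosen k).
#'
#' @param source path to a YAML file, a YAML string, or a named list.
#' @return list of class `pipeline_config`.
#' @export
validate_config <- function(source = list()) {
  cfg <- if (is.list(source)) {
    source
  } else if (file.exists(source)) {
    yaml::read_yaml(source) %||% list()
  } else {
    yaml::yaml.load(source) %||% list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, cfg)
  chk <- function(key, ok) {
    if (!ok) stop_fmt("configuration key %s out of range (got %s)", key,
                      paste(format(out[[key]]), collapse = ","))
  }
  chk("flank_length", is.numeric(out$flank_length) && out$flank_length >= 1)
  chk("background_order", is.numeric(out$background_order) &&
        out$background_order >= 1)
  chk("alpha", is.numeric(out$alpha) && out$alpha > 0 && out$alpha < 1)
  chk("n_subsets", is.numeric(out$n_subsets) && out$n_subsets >= 1)
  chk("subset_size", is.numeric(out$subset_size) && out$subset_size >= 2)
  chk("score_fraction", is.numeric(out$score_fraction) &&
        out$score_fraction > 0 && out$score_fraction <= 1)
  chk("restarts", identical(out$restarts, "exhaustive") ||
        (is.numeric(out$restarts) && out$restarts >= 1))
  chk("k", identical(out$k, "auto") || (is.numeric(out$k) && out$k >= 1))
  chk("seed", is.numeric(out$seed) && out$seed == round(out$seed))
  for (key in c("flank_length", "min_region_length", "background_order",
                "n_subsets", "subset_size", "seed")) {
    out[[key]] <- as.integer(out[[key]])
  }
  structure(out, class = c("pipeline_config", "list"))
}

#' Serialize a pipeline configuration to YAML
#'
#' Round-trips through [validate_config()] unchanged.
#' @param config a `pipeline_config`.
#' @param path optional output file.
#' @return YAML string (invisibly when written to `path`).
#' @export
write_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

config_engines <- function(config) {
  lapply(config$engines, function(e) {
    engine_config(engine = e$engine %||% "seed_qvalue",
                  width_range = c(e$width_min %||% 6L, e$width_max %||% 8L),
                  max_mismatches = e$max_mismatches %||% 0L,
                  q_max = e$q_max %||% 0.05,
                  score_max = e$score_max %||% 0.001,
                  top_k = e$top_k %||% 5L)
  })
}

#' Run the full discovery pipeline
#'
#' Executes DE consensus, upstream-region extraction, background-model
#' construction, subsample-ensemble discovery (independently for the
#' over- and under-expressed lists — the two lists are never pooled),
#' k-medoids clustering with cluster averaging, remapping of the cluster
#' averages onto the responsive promoters, and database annotation. All
#' artifacts are written under `output_dir`; a `manifest.json` records
#' parameters and per-stage counts. Fails loudly naming the stage; partial
#' outputs are retained.
#'
#' @param config a `pipeline_config` from [validate_config()].
#' @param output_dir run directory (created).
#' @return list of in-memory results: `consensus`, `regions`, `background`,
#'   and per direction (`over`, `under`) the pooled `motifs`, `clusters`,
#'   `instances`, `tally`, and database `matches`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 8L)
  manifest <- list(parameters = unclass(config), counts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  de <- stage("de_consensus", {
    tables <- load_de_tables(utils::read.delim(config$de_manifest,
                                               stringsAsFactors = FALSE))
    res <- consensus_gene_lists(tables, alpha = config$alpha)
    write_consensus(res, file.path(output_dir, "consensus"))
    res
  })
  manifest$counts$over_expressed <- length(de$over_expressed)
  manifest$counts$under_expressed <- length(de$under_expressed)

  ref <- stage("genome_io", load_reference(config$genome, config$annotation))
  all_regions <- stage("extract_upstream", {
    r <- extract_upstream(ref$contigs, ref$annotations,
                          flank_length = config$flank_length,
                          min_length = config$min_region_length)
    write_regions_fasta(r, file.path(output_dir, "upstream_regions.fasta"))
    r
  })
  manifest$counts$regions <- nrow(all_regions)

  background <- stage("background", {
    b <- build_background(all_regions, max_order = config$background_order)
    write_background(b, file.path(output_dir, "background"))
    b
  })

  engines <- config_engines(config)
  database <- if (!is.null(config$database)) {
    read_motif_database(config$database)
  } else NULL

  results <- list(consensus = de, regions = all_regions,
                  background = background)
  directions <- list(over = de$over_expressed, under = de$under_expressed)
  for (dname in names(directions)) {
    genes <- directions[[dname]]
    ddir <- file.path(output_dir, dname)
    dir.create(ddir, showWarnings = FALSE)
    if (length(genes) < config$subset_size) {
      stop_fmt(paste0("pipeline stage 'ensemble/%s' failed: gene list (%d) ",
                      "smaller than subset_size (%d)"),
               dname, length(genes), config$subset_size)
    }
    regions <- all_regions[all_regions$gene_id %in% genes, , drop = FALSE]
    dseed <- seeds[match(dname, names(directions))]
    collection <- make_subsets(genes, n_subsets = config$n_subsets,
                               subset_size = config$subset_size, seed = dseed)
    motifs <- stage(paste0("ensemble/", dname),
                    run_ensemble(regions, collection, background, engines))
    manifest$counts[[paste0(dname, "_motifs")]] <- length(motifs)
    write_meme(motifs, file.path(ddir, "pooled_motifs.meme"), background)
    if (length(motifs) == 0L) {
      results[[dname]] <- list(motifs = motifs, clusters = list(),
                               instances = NULL, tally = NULL, matches = NULL)
      next
    }
    clusters <- stage(paste0("cluster/", dname),
                      cluster_motifs_kmedoids(motifs, k = config$k,
                                              restarts = config$restarts,
                                              seed = seeds[3L]))
    cluster_report(clusters, file.path(ddir, "clusters.tsv"))
    averages <- lapply(clusters, `[[`, "average")
    write_meme(averages, file.path(ddir, "cluster_averages.meme"), background)
    manifest$counts[[paste0(dname, "_clusters")]] <- length(clusters)

    instances <- stage(paste0("map/", dname), {
      do.call(rbind, lapply(seq_along(averages), function(i) {
        scan_regions(averages[[i]], regions, background,
                     score_fraction = config$score_fraction,
                     motif_id = sprintf("cluster_%02d", i))
      }))
    })
    tally <- tally_instances(instances,
                             sprintf("cluster_%02d", seq_along(averages)),
                             regions$gene_id)
    export_map(instances, regions, dir = ddir)
    utils::write.table(
      data.frame(motif_id = names(tally$totals), total = tally$totals),
      file.path(ddir, "instance_totals.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts[[paste0(dname, "_instances")]] <- nrow(instances)

    matches <- if (!is.null(database)) {
      stage(paste0("annotate/", dname), {
        do.call(rbind, lapply(seq_along(averages), function(i) {
          m <- match_database(averages[[i]], database,
                              top_n = config$top_n_matches)
          m$query_motif_id <- sprintf("cluster_%02d", i)
          m
        }))
      })
    } else NULL
    if (!is.null(matches)) {
      utils::write.table(matches, file.path(ddir, "database_matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results[[dname]] <- list(motifs = motifs, clusters = clusters,
                             instances = instances, tally = tally,
                             matches = matches)
  }
  manifest$seed_derivation <- seeds
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
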