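#' End-to-end run configuration
#'
#' Bundles the per-stage parameters of the full workflow: cluster the
#' repertoire, rank clusters by frequency and by enrichment, progress the
#' union of the top-k of both rankings (deduplicated, mirroring the dual
#' frequency/enrichment selection route), then per progressed cluster
#' train a generative model, sample new sequences, rank the combined pool
#' by NLL, profile developability and nominate candidates.
#'
#' @param input Path to a repertoire table, a repertoire tibble, or
#'   `NULL` to simulate from `simulation`.
#' @param simulation A [simulation_config()] used when `input` is `NULL`.
#' @param output_dir Run directory for stage outputs and the manifest.
#' @param seed Global seed; per-cluster model seeds are derived from it.
#' @param cluster_threshold CDR3 identity threshold.
#' @param sel_round,base_round Selected and baseline rounds for
#'   enrichment (`NULL` sel_round = last round present).
#' @param residue_base_round Baseline round for per-residue enrichment
#'   matrices (`NULL` = the round before `sel_round`).
#' @param top_k_frequency,top_k_enrichment Clusters progressed from each
#'   ranking.
#' @param generative A [generative_config()].
#' @param selection A [selection_config()]; empty descriptor cutoffs are
#'   filled from the reference as mean + 1 SD for the cutoff-bearing
#'   descriptors.
#' @param reference `"repertoire"` (descriptor stats over the NGS
#'   sequences of the progressed clusters), a path to a CSV with
#'   `descriptor`, `mean`, `sd` columns, or a [reference_stats()] object.
#' @param profile_top_n Number of top-ranked pool sequences carried into
#'   developability profiling and selection per cluster.
#' @param min_cluster_size Minimum unique sequences with reads in the
#'   selected round for a progressed cluster to enter the generative
#'   stage; smaller clusters are skipped (recorded in the manifest).
#' @param write_matrices Write per-cluster positional matrices.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, simulation = simulation_config(),
                       output_dir = tempfile("vhh_run_"), seed = 1L,
                       cluster_threshold = 0.5, sel_round = NULL,
                       base_round = 0L, residue_base_round = NULL,
                       top_k_frequency = 5L, top_k_enrichment = 5L,
                       generative = generative_config(),
                       selection = selection_config(),
                       reference = "repertoire", profile_top_n = 500L,
                       min_cluster_size = 25L, write_matrices = TRUE) {
  structure(list(
    input = input, simulation = simulation, output_dir = output_dir,
    seed = as.integer(seed), cluster_threshold = cluster_threshold,
    sel_round = sel_round, base_round = as.integer(base_round),
    residue_base_round = residue_base_round,
    top_k_frequency = as.integer(top_k_frequency),
    top_k_enrichment = as.integer(top_k_enrichment),
    generative = generative, selection = selection,
    reference = reference, profile_top_n = as.integer(profile_top_n),
    min_cluster_size = as.integer(min_cluster_size),
    write_matrices = write_matrices
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()]; `generative`,
#' `selection` and `simulation` blocks are passed to their constructors.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("generative", "selection", "simulation"))]
  if (!is.null(y$generative)) {
    args$generative <- do.call(generative_config, y$generative)
  }
  if (!is.null(y$selection)) {
    sel <- y$selection
    if (!is.null(sel$descriptor_cutoffs)) {
      sel$descriptor_cutoffs <- unlist(sel$descriptor_cutoffs)
    }
    args$selection <- do.call(selection_config, sel)
  }
  if (!is.null(y$simulation)) {
    args$simulation <- do.call(simulation_config, y$simulation)
  }
  do.call(run_config, args)
}

stage_path <- function(dir, name) file.path(dir, name)

#' Run the full discovery workflow
#'
#' Executes simulate/read, cluster, enrich, and per-cluster
#' train/sample/score/profile/select stages in order, writing each
#' stage's tabular output plus a JSON manifest (parameters, seeds,
#' package version, per-file MD5 checksums) sufficient to reproduce the
#' run. With `resume = TRUE`, stages whose outputs already exist in
#' `output_dir` are reloaded instead of recomputed, so deleted
#' downstream outputs are regenerated reproducibly. A stage failure is
#' recorded in the manifest and downstream stages are skipped.
#'
#' @param config A [run_config()].
#' @param resume Reuse existing stage outputs.
#' @return A `vhh_run` list: `repertoire`, `clusters`, `rankings`,
#'   `progressed`, `pools`, `selections`, `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config = run_config(), resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vhhmine")),
    seed = config$seed,
    parameters = list(
      cluster_threshold = config$cluster_threshold,
      base_round = config$base_round,
      top_k_frequency = config$top_k_frequency,
      top_k_enrichment = config$top_k_enrichment,
      generative = unclass(config$generative),
      selection = lapply(unclass(config$selection), function(v)
        if (is.null(v)) NA else v)
    ),
    stages = list()
  )
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res))
      failed <<- TRUE
      return(NULL)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  # stage 1: input
  rep_path <- stage_path(config$output_dir, "repertoire.csv")
  repertoire <- run_stage("input", function() {
    if (resume && file.exists(rep_path)) return(read_repertoire(rep_path))
    x <- if (is.data.frame(config$input)) {
      as_repertoire(config$input)
    } else if (is.character(config$input)) {
      read_repertoire(config$input)
    } else {
      simulate_repertoire(config$simulation)$repertoire
    }
    write_repertoire(x, rep_path)
    x
  })

  sel_round <- config$sel_round
  if (is.null(sel_round) && !is.null(repertoire)) {
    sel_round <- max(repertoire_rounds(repertoire)$round)
  }

  # stage 2: clustering
  clusters <- run_stage("cluster", function() {
    cl <- cluster_by_cdr3(repertoire, config$cluster_threshold)
    readr::write_csv(as_tibble(cl)[, c("seq_id", "cluster_id")],
                     stage_path(config$output_dir, "assignments.csv"))
    readr::write_csv(cluster_summary(cl),
                     stage_path(config$output_dir, "cluster_summary.csv"))
    cl
  })

  # stage 3: enrichment ranking and cluster progression
  rankings <- run_stage("enrich", function() {
    by_ef <- rank_clusters(clusters, "enrichment", sel_round,
                           config$base_round)
    by_freq <- rank_clusters(clusters, "frequency", sel_round)
    readr::write_csv(by_ef, stage_path(config$output_dir, "enrichment.csv"))
    readr::write_csv(by_freq, stage_path(config$output_dir, "frequency.csv"))
    list(enrichment = by_ef, frequency = by_freq)
  })
  progressed <- run_stage("progress_clusters", function() {
    ids <- union(
      utils::head(rankings$frequency$cluster_id, config$top_k_frequency),
      utils::head(rankings$enrichment$cluster_id, config$top_k_enrichment)
    )
    readr::write_csv(tibble(cluster_id = ids),
                     stage_path(config$output_dir, "progressed_clusters.csv"))
    ids
  })

  # stage 4: per-residue matrices for progressed clusters
  run_stage("residue_matrices", function() {
    if (!config$write_matrices) return(invisible(NULL))
    rbase <- config$residue_base_round
    if (is.null(rbase)) rbase <- max(sel_round - 1, 0)
    mdir <- stage_path(config$output_dir, "matrices")
    dir.create(mdir, showWarnings = FALSE)
    for (k in progressed) {
      members <- as_tibble(clusters) %>% filter(.data$cluster_id == k)
      for (region in c("cdr1", "cdr2", "cdr3")) {
        fr <- positional_frequency(members, sel_round, region)
        utils::write.csv(unclass(fr),
                         file.path(mdir, sprintf("cluster%d_%s_frequency.csv",
                                                 k, region)), row.names = FALSE)
        en <- tryCatch(
          positional_enrichment(members, sel_round, rbase, region = region),
          error = function(e) NULL)
        if (!is.null(en)) {
          utils::write.csv(unclass(en),
                           file.path(mdir, sprintf("cluster%d_%s_enrichment.csv",
                                                   k, region)),
                           row.names = FALSE)
        }
      }
    }
    invisible(NULL)
  })

  # stage 5: generative modelling and pool ranking per cluster
  pools <- run_stage("generative", function() {
    out <- list()
    skipped <- integer(0)
    for (k in progressed) {
      members_all <- as_tibble(clusters) %>% filter(.data$cluster_id == k)
      n_train_k <- sum(members_all[[sprintf("count_r%d", sel_round)]] > 0)
      if (n_train_k < max(config$min_cluster_size, config$generative$cv_folds)) {
        skipped <- c(skipped, k)
        next
      }
      pool_path <- stage_path(config$output_dir, sprintf("pool_cluster%d.csv", k))
      if (resume && file.exists(pool_path)) {
        out[[as.character(k)]] <- readr::read_csv(pool_path,
                                                  show_col_types = FALSE)
        next
      }
      members <- as_tibble(clusters) %>% filter(.data$cluster_id == k)
      gcfg <- config$generative
      gcfg$seed <- config$seed * 131L + as.integer(k)
      model <- train_generative_model(members, gcfg, round = sel_round)
      save_generative_model(
        model, stage_path(config$output_dir, sprintf("model_cluster%d.rds", k)))
      set.seed(gcfg$seed + 7L)
      sampled <- sample_sequences(model)
      pool <- rank_pool(members, sampled, model)
      pool$cluster_id <- k
      readr::write_csv(pool, pool_path)
      out[[as.character(k)]] <- pool
    }
    attr(out, "skipped_clusters") <- skipped
    out
  })

  # stage 6: developability profiling (top of each ranked pool) + reference
  profiled <- run_stage("develop", function() {
    out <- list()
    for (k in names(pools)) {
      top <- utils::head(pools[[k]], config$profile_top_n)
      prof <- assess_developability(top)
      readr::write_csv(prof, stage_path(config$output_dir,
                                        sprintf("profiled_cluster%s.csv", k)))
      out[[k]] <- prof
    }
    out
  })
  reference <- run_stage("reference", function() {
    if (inherits(config$reference, "reference_stats")) return(config$reference)
    if (is.character(config$reference) && config$reference != "repertoire") {
      return(reference_stats(readr::read_csv(config$reference,
                                             show_col_types = FALSE)))
    }
    if (length(profiled) == 0) return(NULL)
    # descriptor stats over the NGS members of the progressed clusters
    ngs <- bind_rows(profiled)[, c("source", "pI", "cdr_hydropathy",
                                   "cdr_positive_charge")]
    ngs <- ngs %>% filter(.data$source == "ngs")
    reference_stats(ngs[, c("pI", "cdr_hydropathy", "cdr_positive_charge")])
  })

  # stage 7: candidate selection per cluster
  selections <- run_stage("select", function() {
    out <- list()
    log_lines <- character(0)
    for (k in names(profiled)) {
      prof <- profiled[[k]]
      scfg <- config$selection
      if (length(scfg$descriptor_cutoffs) == 0 && !is.null(reference)) {
        cuts <- vapply(lit_descriptors(), function(d) {
          r <- reference[reference$descriptor == d, ]
          r$mean + r$sd
        }, numeric(1))
        scfg$descriptor_cutoffs <- cuts
      }
      if (!is.null(reference)) {
        for (d in intersect(lit_descriptors(), reference$descriptor)) {
          r <- reference[reference$descriptor == d, ]
          prof[[paste0("light_", d)]] <- traffic_light(prof[[d]], r$mean, r$sd)
        }
      }
      rep_k <- select_candidates(prof, scfg)
      out[[k]] <- rep_k
      sel_tab <- tidy(rep_k)
      sel_tab$cluster_id <- as.integer(k)
      readr::write_csv(sel_tab, stage_path(config$output_dir,
                                           sprintf("selection_cluster%s.csv", k)))
      g <- glance(rep_k)
      log_lines <- c(log_lines, sprintf(
        "cluster %s: %d selected (%d ngs, %d sampled), %d excluded",
        k, g$n_selected, g$n_ngs, g$n_sampled, g$n_excluded))
    }
    writeLines(log_lines, stage_path(config$output_dir, "selection_log.txt"))
    out
  })

  manifest$skipped_clusters <- attr(pools, "skipped_clusters")
  # manifest with checksums over all tabular outputs
  files <- sort(list.files(config$output_dir, recursive = TRUE,
                           pattern = "\\.(csv|txt)$"))
  manifest$checksums <- as.list(tools::md5sum(
    file.path(config$output_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest,
                       stage_path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(
    repertoire = repertoire, clusters = clusters, rankings = rankings,
    progressed = progressed, pools = pools, selections = selections,
    manifest = manifest, output_dir = config$output_dir
  ), class = "vhh_run")
}

#' @export
print.vhh_run <- function(x, ...) {
  ok <- vapply(x$manifest$stages, function(s) s$status, character(1))
  cat(sprintf("<vhh_run> %s\n", x$output_dir))
  cat(paste(sprintf("  %s: %s", names(ok), ok), collapse = "\n"), "\n")
  invisible(x)
}
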