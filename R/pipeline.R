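## End-to-end orchestration: load (or simulate) a dataset, then run
## occurrence filtering, DMM metacommunity typing, biomarker discovery,
## dysbiosis indexing, reporter enrichment, capacity profiling, differential
## networks, growth rates and cohort statistics, writing per-stage TSVs and
## a manifest. A single global seed derives per-stage substreams, so
## toggling one stage never shifts another stage's randomness.

default_pipeline_params <- function() {
  list(occurrence_min_rate = 0.05,
       k_min = 1L, k_max = 7L, n_restarts = 5L,
       lefse_alpha = 0.05, lda_threshold = 2, n_boot = 30L,
       reporter_background = 1000L,
       network_iterations = 20L, network_nulls = 200L,
       edge_threshold = 0.3, p_threshold = 0.01,
       min_mean_coverage = 5, smooth_window_frac = 0.1,
       permanova_permutations = 999L)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("run config: seed is mandatory")
  if (is.null(config$outdir)) stop("run config: outdir is mandatory")
  config$params <- utils::modifyList(default_pipeline_params(),
                                     config$params %||% list())
  config$stages <- config$stages %||% list()
  config
}

stage_enabled <- function(config, stage) {
  !identical(config$stages[[stage]], FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (cluster -> biomarkers ->
#' dysbiosis index -> reporter enrichment -> capacity -> networks -> growth
#' -> cohort statistics), writing each stage's outputs to `outdir` and a
#' manifest (`manifest.json`) recording files, parameters, the seed and md5
#' hashes. Re-running with the same configuration reproduces all stochastic
#' outputs bit-identically.
#'
#' @param config A list, or path to a YAML/JSON file, with elements:
#'   `seed` and `outdir` (mandatory); either `cohort` (an in-memory
#'   [simulate_cohort()] result) or `paths` (named list: `counts`,
#'   `metadata`, optional `annotation`, `ko_table`, `pathway_map`,
#'   `gene_table`, `gene_map`, `coverage`); optional `params` overriding
#'   stage parameters; optional `stages` (named flags to disable stages).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  seed <- as.integer(cfg$seed)
  outdir <- cfg$outdir
  prm <- cfg$params

  # fail-fast validation before any stage runs
  if (is.null(cfg$cohort)) {
    if (is.null(cfg$paths) || is.null(cfg$paths$counts) || is.null(cfg$paths$metadata)) {
      stop("run config: needs either 'cohort' or paths$counts + paths$metadata")
    }
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) stop("run config: input file not found: ", p)
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, params = prm, stages = list())
  emit <- function(stage, name, obj) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write_abundance_table(obj, path)
    manifest$stages[[stage]]$outputs <<- c(manifest$stages[[stage]]$outputs, path)
    path
  }
  run_stage <- function(stage, fun) {
    manifest$stages[[stage]] <<- list(outputs = character())
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## load
  dat <- run_stage("load", function() {
    if (!is.null(cfg$cohort)) {
      ch <- cfg$cohort
      list(counts = ch$counts, metadata = ch$metadata,
           annotation = ch$annotation, ko_table = ch$ko_table,
           pathway_map = ch$pathway_map, gene_table = ch$gene_table,
           gene_map = ch$gene_map, coverage = ch$coverage)
    } else {
      ds <- load_dataset(cfg$paths$counts, cfg$paths$metadata,
                         cfg$paths$annotation)
      extra <- list(ko_table = NULL, pathway_map = NULL, gene_table = NULL,
                    gene_map = NULL, coverage = NULL)
      if (!is.null(cfg$paths$ko_table)) {
        extra$ko_table <- read_abundance_table(cfg$paths$ko_table, mode = "relative")
      }
      if (!is.null(cfg$paths$pathway_map)) {
        extra$pathway_map <- read_tsv_checked(cfg$paths$pathway_map)
      }
      if (!is.null(cfg$paths$gene_table)) {
        gt <- read_tsv_checked(cfg$paths$gene_table)
        m <- as.matrix(gt[, -1L, drop = FALSE])
        rownames(m) <- gt[[1L]]
        extra$gene_table <- m
      }
      if (!is.null(cfg$paths$gene_map)) {
        extra$gene_map <- read_tsv_checked(cfg$paths$gene_map)
      }
      if (!is.null(cfg$paths$coverage)) {
        extra$coverage <- read_tsv_checked(cfg$paths$coverage)
      }
      c(list(counts = ds$abundance, metadata = ds$metadata,
             annotation = ds$annotation), extra)
    }
  })
  counts <- filter_by_occurrence(dat$counts, prm$occurrence_min_rate)
  rel <- to_relative(counts)
  meta <- dat$metadata
  disease <- stats::setNames(meta$disease_status, meta$sample_id)

  ## cluster
  labels <- NULL
  scheme <- NULL
  if (stage_enabled(cfg, "cluster")) {
    sel <- run_stage("cluster", function() {
      select_k(counts, k_min = prm$k_min, k_max = prm$k_max,
               n_restarts = prm$n_restarts, seed = derive_seed(seed, "cluster"))
    })
    labels <- assign_metacommunities(sel$models[[paste0("K", sel$best_K)]], counts)
    emit("cluster", "model_selection", sel$curve)
    emit("cluster", "metacommunity_labels",
         data.frame(sample_id = names(labels),
                    metacommunity = LETTERS[labels],
                    stringsAsFactors = FALSE))
    scheme <- default_scheme(meta, labels)
  }

  ## biomarkers
  biomarkers <- NULL
  if (stage_enabled(cfg, "biomarkers") && !is.null(scheme)) {
    biomarkers <- run_stage("biomarkers", function() {
      discover_biomarkers(rel, scheme, alpha = prm$lefse_alpha,
                          lda_threshold = prm$lda_threshold,
                          n_boot = prm$n_boot,
                          seed = derive_seed(seed, "biomarkers"))
    })
    emit("biomarkers", "biomarkers", as.data.frame(biomarkers))
  }

  ## dysbiosis index
  if (stage_enabled(cfg, "mdindex") && !is.null(biomarkers) && nrow(biomarkers)) {
    md <- run_stage("mdindex", function() {
      grp_disease <- vapply(scheme$groups, function(ids) {
        mean(disease[ids] == "CD")
      }, numeric(1L))
      cd_groups <- names(grp_disease)[grp_disease > 0.5]
      ct_groups <- names(grp_disease)[grp_disease <= 0.5]
      sets <- derive_md_sets(biomarkers, cd_groups, ct_groups)
      md_index(rel, sets$up_set, sets$down_set)
    })
    emit("mdindex", "md_index", md)
  }

  ## reporter enrichment (CT vs CD)
  if (stage_enabled(cfg, "reporter") && !is.null(dat$ko_table) &&
      !is.null(dat$pathway_map)) {
    rep_scores <- run_stage("reporter", function() {
      ks <- ko_zscores(dat$ko_table,
                       names(disease)[disease == "CT"],
                       names(disease)[disease == "CD"])
      reporter_scores(ks, dat$pathway_map,
                      n_background = prm$reporter_background,
                      seed = derive_seed(seed, "reporter"))
    })
    emit("reporter", "reporter_scores", rep_scores)
  }

  ## capacity profiling
  if (stage_enabled(cfg, "capacity") && !is.null(dat$annotation)) {
    cap <- run_stage("capacity", function() {
      classes <- classify_lps(dat$annotation)
      prof <- class_abundances(rel, classes)
      if (!is.null(dat$gene_table) && !is.null(dat$gene_map)) {
        sc <- scfa_capacity(dat$gene_table, dat$gene_map)
        prof <- merge(prof, sc, by = "sample_id", sort = FALSE)
      }
      prof
    })
    emit("capacity", "capacity_profile", cap)
    cmp <- run_stage("capacity_tests", function() {
      m <- as.matrix(cap[, setdiff(names(cap), c("sample_id", "no_mass")),
                         drop = FALSE])
      rownames(m) <- cap$sample_id
      wilcoxon_bh(m, names(disease)[disease == "CT"],
                  names(disease)[disease == "CD"])
    })
    emit("capacity_tests", "capacity_comparison", cmp)
  }

  ## networks: typical control vs typical case metacommunity
  if (stage_enabled(cfg, "network") && !is.null(labels)) {
    nets <- run_stage("network", function() {
      feat <- if (!is.null(biomarkers) && nrow(biomarkers) >= 8L) {
        biomarkers$feature_id
      } else {
        colnames(counts$values)[order(-colMeans(rel$values))][seq_len(
          min(20L, ncol(counts$values)))]
      }
      grp_disease <- vapply(split(names(labels), labels), function(ids)
        mean(disease[ids] == "CD"), numeric(1L))
      ct_comp <- as.integer(names(which.min(grp_disease)))
      cd_comp <- as.integer(names(which.max(grp_disease)))
      g_ct <- names(labels)[labels == ct_comp & disease[names(labels)] == "CT"]
      g_cd <- names(labels)[labels == cd_comp & disease[names(labels)] == "CD"]
      build_one <- function(ids, tag) {
        sub <- abundance_table(counts$values[ids, feat, drop = FALSE],
                               mode = "counts")
        res <- sparcc_correlations(sub, n_iterations = prm$network_iterations,
                                   seed = derive_seed(seed, paste0("net-", tag)))
        p <- sparcc_pvalues(sub, res, n_null = prm$network_nulls,
                            seed = derive_seed(seed, paste0("netp-", tag)))
        build_network(res, p, edge_threshold = prm$edge_threshold,
                      p_threshold = prm$p_threshold)
      }
      list(ct = build_one(g_ct, "ct"), cd = build_one(g_cd, "cd"))
    })
    emit("network", "network_ct_edges", nets$ct$edges)
    emit("network", "network_cd_edges", nets$cd$edges)
    diff <- compare_networks(nets$ct, nets$cd)
    emit("network", "network_diff",
         data.frame(measure = c("lost", "gained", "shared", "strong_lost",
                                "strong_gained"),
                    count = c(nrow(diff$edges_lost), nrow(diff$edges_gained),
                              nrow(diff$edges_shared), diff$n_strong_lost,
                              diff$n_strong_gained)))
  }

  ## growth rates
  if (stage_enabled(cfg, "growth") && !is.null(dat$coverage)) {
    gr <- run_stage("growth", function() {
      estimate_ptr_table(dat$coverage,
                         min_mean_coverage = prm$min_mean_coverage,
                         smooth_window_frac = prm$smooth_window_frac)
    })
    emit("growth", "growth_rates", gr)
  }

  ## cohort statistics
  if (stage_enabled(cfg, "stats")) {
    st <- run_stage("stats", function() {
      shan <- apply(rel$values, 1L, shannon_index)
      gc <- apply(counts$values, 1L, gene_count)
      D <- distance_matrix(rel, "bray_curtis")
      pv <- permanova(D, disease[rownames(rel$values)],
                      n_permutations = prm$permanova_permutations,
                      seed = derive_seed(seed, "permanova"))
      out <- list(per_sample = data.frame(
        sample_id = rownames(rel$values), shannon = shan, gene_count = gc,
        stringsAsFactors = FALSE),
        permanova = data.frame(term = "disease_status", pseudo_F = pv$pseudo_F,
                               p = pv$p, n_permutations = pv$n_permutations))
      if (!is.null(labels)) {
        out$fisher <- fisher_association(LETTERS[labels],
                                         disease[names(labels)])
      }
      out
    })
    emit("stats", "alpha_diversity", st$per_sample)
    emit("stats", "permanova", st$permanova)
    if (!is.null(st$fisher)) emit("stats", "metacommunity_association", st$fisher)
  }

  ## manifest with content hashes
  all_files <- unlist(lapply(manifest$stages, `[[`, "outputs"), use.names = FALSE)
  manifest$hashes <- as.list(tools::md5sum(all_files))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_msg("pipeline complete: ", length(all_files), " outputs in ", outdir)
  invisible(manifest)
}
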