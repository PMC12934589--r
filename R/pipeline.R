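#' Pipeline run configuration
#'
#' Assembles and defaults every knob of the end-to-end analysis. Defaults are
#' sized for a paired cohort of a few dozen patients on one CPU.
#'
#' @param counts_path,metadata_path,taxonomy_path Input TSV paths.
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param ranks Taxonomic ranks analysed for diversity/DA (the topic model
#'   uses `topic_rank`).
#' @param min_reads Pair-retention read-depth threshold (strict `>`).
#' @param q_threshold Significance threshold used throughout.
#' @param contaminants Character vector of contaminant taxon ids.
#' @param sweep_transforms,sweep_metrics Ordination sweep grids.
#' @param topic_rank Rank for topic modeling.
#' @param k_grid Topic-number grid.
#' @param s_grid Scaling-factor grid.
#' @param lda_iterations,lda_burn_in,lda_thin Gibbs schedule.
#' @param n_mc Monte-Carlo instances for the resampling DA engine.
#' @param n_folds Cross-validation folds.
#' @param num_trees Trees per random forest.
#' @param pathway_map_path Optional item-to-pathway TSV enabling the
#'   over-representation stage (items = taxa at `topic_rank`).
#' @param seed Global seed; per-stage seeds are derived from it by stage
#'   name.
#' @return List of class `run_config`.
#' @export
run_config <- function(counts_path, metadata_path, taxonomy_path,
                       out_dir,
                       ranks = c("phylum", "genus", "species"),
                       min_reads = 1000, q_threshold = 0.05,
                       contaminants = character(),
                       sweep_transforms = c("tss", "clr"),
                       sweep_metrics = c("bray_curtis", "jaccard", "euclidean"),
                       topic_rank = "genus",
                       k_grid = 2:8,
                       s_grid = c(100L, 1000L),
                       lda_iterations = 800L, lda_burn_in = 400L,
                       lda_thin = 20L,
                       n_mc = 64L, n_folds = 4L, num_trees = 300L,
                       pathway_map_path = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every invariant and returns all violations at once.
#'
#' @param cfg A [run_config()].
#' @return Character vector of problems (length 0 when the config is valid).
#' @export
validate_config <- function(cfg) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(length(cfg$ranks) > 0 &&
        all(cfg$ranks %in% c("phylum", "genus", "species", "asv")),
      "ranks must be a non-empty subset of phylum/genus/species/asv")
  chk(is.numeric(cfg$min_reads) && cfg$min_reads >= 0, "min_reads must be >= 0")
  chk(cfg$q_threshold > 0 && cfg$q_threshold < 1, "q_threshold must lie in (0, 1)")
  chk(length(cfg$k_grid) > 0 && all(cfg$k_grid >= 2), "k_grid must be non-empty with K >= 2")
  chk(length(cfg$s_grid) > 0 && all(cfg$s_grid >= 10), "s_grid must be non-empty with S >= 10")
  chk(length(cfg$sweep_transforms) > 0, "sweep_transforms must be non-empty")
  chk(length(cfg$sweep_metrics) > 0, "sweep_metrics must be non-empty")
  chk(cfg$lda_iterations > cfg$lda_burn_in, "lda_iterations must exceed lda_burn_in")
  chk(cfg$lda_thin >= 1 &&
        cfg$lda_thin <= cfg$lda_iterations - cfg$lda_burn_in,
      "lda_thin must fit at least one recorded sweep")
  chk(cfg$n_folds >= 2, "n_folds must be >= 2")
  chk(cfg$n_mc >= 1, "n_mc must be >= 1")
  problems
}

write_stage_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full paired-cohort analysis
#'
#' Executes every stage in order — filtering, per-rank alpha diversity with
#' paired tests, the ordination selection sweep plus the chosen ordination
#' and hierarchical clustering, three-method consensus differential
#' abundance with per-patient tallies and top-taxa ranking, scaling-factor
#' and topic-number selection followed by the LDA fit, topic-type
#' association, drivers and embedding, cross-validated classification, and
#' (when a pathway mapping is supplied) over-representation of the
#' consensus-significant taxa. Every artifact is written as TSV/JSON under
#' `cfg$out_dir`; `manifest.json` lists file MD5 hashes, the config echo and
#' the seed, so identical seeds yield hash-identical runs.
#'
#' @param cfg A validated [run_config()].
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop("invalid run_config: ", paste(problems, collapse = "; "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  stage_log <- function(stage, ...) {
    log_lines <<- c(log_lines, paste0("[", stage, "] ", paste0(...)))
  }
  files <- character()
  emit <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    } else {
      write_stage_tsv(x, path)
    }
    files <<- c(files, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- input + filtering ------------------------------------------------
  cohort_raw <- run_stage("read", read_tables(cfg$counts_path,
                                              cfg$metadata_path,
                                              cfg$taxonomy_path,
                                              require_pairing = FALSE))
  filt <- run_stage("filter",
                    filter_cohort(cohort_raw, cfg$contaminants, cfg$min_reads))
  cohort <- filt$cohort
  emit(filt$log, "filter_log.tsv")
  stage_log("filter", nrow(cohort$counts), " taxa x ", ncol(cohort$counts),
            " samples retained")

  # -- alpha diversity ---------------------------------------------------
  run_stage("alpha", {
    md <- cohort$metadata
    alpha <- data.frame(sample_id = colnames(cohort$counts),
                        shannon = shannon(cohort$counts),
                        observed = observed_richness(cohort$counts))
    ps_sh <- paired_split(matrix(alpha$shannon, nrow = 1,
                                 dimnames = list("shannon", alpha$sample_id)), md)
    ps_ob <- paired_split(matrix(alpha$observed, nrow = 1,
                                 dimnames = list("observed", alpha$sample_id)), md)
    tests <- data.frame(
      metric = c("shannon", "observed"),
      p = c(wilcoxon_signed_rank(ps_sh$plaque - ps_sh$abscess)$p_value,
            wilcoxon_signed_rank(ps_ob$plaque - ps_ob$abscess)$p_value))
    emit(alpha, "alpha_diversity.tsv")
    emit(tests, "alpha_tests.tsv")
  })

  # -- ordination --------------------------------------------------------
  ord_final <- run_stage("ordination", {
    sweep <- ordination_sweep(cohort, cfg$sweep_transforms, cfg$sweep_metrics)
    emit(sweep, "ordination_sweep.tsv")
    am <- tss(cohort$counts)
    d <- distance_matrix(am, "bray_curtis")
    ord <- pcoa(d, 2L)
    sil <- silhouette_by_group(d, stats::setNames(cohort$metadata$specimen_type,
                                                  cohort$metadata$sample_id))
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates)
    emit(coords, "ordination_coordinates.tsv")
    emit(data.frame(group = names(sil), median_silhouette = unname(sil),
                    rho_axis1_library = as.numeric(
                      spearman_axis_vs_library(ord, cohort$metadata))),
         "ordination_summary.tsv")
    hc <- hierarchical_cluster(cohort$counts)
    emit(data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                    height = hc$height), "hclust_merges.tsv")
    list(ord = ord, silhouette = sil)
  })

  # -- differential abundance -------------------------------------------
  da_rank <- intersect(cfg$ranks, c("genus", "species", "phylum"))[1]
  da <- run_stage("differential_abundance", {
    da <- run_da(cohort, da_rank, seed = derive_seed(cfg$seed, "da"),
                 n_mc = cfg$n_mc, q_threshold = cfg$q_threshold)
    for (m in names(da$methods)) {
      emit(da$methods[[m]], paste0("da_", m, ".tsv"))
    }
    emit(da$consensus, "da_consensus.tsv")
    emit(enrichment_tallies(cohort, da_rank), "da_tallies.tsv")
    emit(top_k_by_median_difference(da$methods$wilcoxon, 15L,
                                    cfg$q_threshold), "da_top15.tsv")
    da
  })

  # -- topic modeling ----------------------------------------------------
  lda <- run_stage("topics", {
    agg <- if (cfg$topic_rank == "asv") cohort else
      agglomerate(cohort, cfg$topic_rank)
    ssel <- select_scaling_factor(agg$counts, agg$metadata,
                                  K = max(2L, min(cfg$k_grid)),
                                  S_grid = cfg$s_grid,
                                  iterations = cfg$lda_iterations,
                                  burn_in = cfg$lda_burn_in,
                                  thin = cfg$lda_thin,
                                  seed = derive_seed(cfg$seed, "scale"))
    emit(ssel$diagnostics, "scaling_diagnostics.tsv")
    corpus <- build_scaled_corpus(agg$counts, ssel$S)
    ksel <- k_selection(corpus, cfg$k_grid,
                        iterations = cfg$lda_iterations,
                        burn_in = cfg$lda_burn_in, thin = cfg$lda_thin,
                        seed = derive_seed(cfg$seed, "kselect"))
    emit(ksel$table, "k_selection.tsv")
    fit <- fit_lda_gibbs(corpus, ksel$chosen_k,
                         iterations = cfg$lda_iterations,
                         burn_in = cfg$lda_burn_in, thin = cfg$lda_thin,
                         seed = derive_seed(cfg$seed, "lda"))
    emit(data.frame(sample_id = rownames(fit$gamma), fit$gamma),
         "lda_gamma.tsv")
    emit(data.frame(topic = rownames(fit$beta), fit$beta), "lda_beta.tsv")
    emit(list(K = fit$K, alpha = fit$alpha, eta = fit$eta, seed = fit$seed,
              S = ssel$S, iterations = fit$iterations,
              burn_in = fit$burn_in, thin = fit$thin,
              loglik_trace = fit$loglik_trace), "lda_params.json")
    assoc <- topic_type_association(fit, agg$metadata, cfg$q_threshold)
    emit(assoc, "topic_type_association.tsv")
    emit(topic_drivers(fit, 10L), "topic_drivers.tsv")
    emb <- embed_gamma(fit, agg$metadata,
                       seed = derive_seed(cfg$seed, "embed"))
    emit(data.frame(sample_id = rownames(emb$coordinates), emb$coordinates),
         "gamma_embedding.tsv")
    emit(data.frame(group = names(emb$silhouette),
                    median_silhouette = unname(emb$silhouette)),
         "gamma_embedding_silhouette.tsv")
    list(fit = fit, association = assoc, S = ssel$S, chosen_k = ksel$chosen_k)
  })

  # -- classification ----------------------------------------------------
  cv <- run_stage("classify", {
    cv <- kfold_classify(cohort, da_rank, n_folds = cfg$n_folds,
                         seed = derive_seed(cfg$seed, "classify"),
                         num_trees = cfg$num_trees)
    emit(cv$folds, "cv_auc.tsv")
    emit(data.frame(taxon = rownames(cv$importance_rank), cv$importance_rank),
         "cv_importance_rank.tsv")
    cv
  })

  # -- over-representation ----------------------------------------------
  if (!is.null(cfg$pathway_map_path)) {
    run_stage("enrich", {
      pathways <- read_pathway_map(cfg$pathway_map_path)
      cons <- da$consensus
      sig <- cons$taxon[cons$tier %in% c("high", "medium")]
      bg <- cons$taxon
      emit(over_representation(sig, bg, pathways), "over_representation.tsv")
    })
  }

  # -- manifest ----------------------------------------------------------
  cfg_echo <- unclass(cfg)
  cfg_echo$out_dir <- NULL  # path-independent echo so hashes are portable
  manifest <- list(
    seed = cfg$seed,
    config = cfg_echo,
    stages = log_lines,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(manifest)
}
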