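#' Configuration for the paired-cohort generator
#'
#' Defaults describe the emulated study: ~25 patients each contributing a
#' patient-matched supragingival-plaque and odontogenic-abscess specimen,
#' V3V4-scale libraries (~20,000 reads, log-normal), a six-topic latent
#' community structure (2 plaque-specific, 1 abscess-specific, 3 shared),
#' reagent-contaminant taxa at trace abundance, and PCR/reagent blanks.
#'
#' @param n_patients Number of patients (each yields one plaque + one abscess
#'   sample).
#' @param n_taxa Number of biological taxa (contaminants are extra).
#' @param k_true True number of latent topics.
#' @param n_plaque_topics,n_abscess_topics,n_shared_topics Per-class topic
#'   counts; must sum to `k_true`.
#' @param topic_concentration Symmetric Dirichlet parameter for topic-taxon
#'   rows; small values give sparse, well-separated topics.
#' @param membership_concentration Symmetric Dirichlet parameter for the
#'   patient-level base topic weights.
#' @param type_bias Type-separation strength in (0,1). A sample's own-type
#'   topics are up-weighted by `type_bias`, the other type's by
#'   `1 - type_bias`, shared topics by 1/2, then renormalized; 0.5 is an exact
#'   null (plaque and abscess share the patient's base weights) and values
#'   near 1 give disjoint type-specific support.
#' @param library_size_log_mean,library_size_log_sd Log-normal library-size
#'   parameters (natural log scale).
#' @param n_blanks Number of blank (contaminant-only) samples.
#' @param n_contaminants Number of contaminant taxa, spiked uniformly at
#'   relative abundance 1e-3 into every specimen and dominating the blanks.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 25L, n_taxa = 150L, k_true = 6L,
                             n_plaque_topics = 2L, n_abscess_topics = 1L,
                             n_shared_topics = 3L,
                             topic_concentration = 0.05,
                             membership_concentration = 1,
                             type_bias = 0.9,
                             library_size_log_mean = log(20000),
                             library_size_log_sd = 0.3,
                             n_blanks = 2L, n_contaminants = 5L, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_taxa = as.integer(n_taxa),
              k_true = as.integer(k_true),
              n_plaque_topics = as.integer(n_plaque_topics),
              n_abscess_topics = as.integer(n_abscess_topics),
              n_shared_topics = as.integer(n_shared_topics),
              topic_concentration = topic_concentration,
              membership_concentration = membership_concentration,
              type_bias = type_bias,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              n_blanks = as.integer(n_blanks),
              n_contaminants = as.integer(n_contaminants),
              seed = as.integer(seed))
  problems <- character()
  if (cfg$n_plaque_topics + cfg$n_abscess_topics + cfg$n_shared_topics !=
      cfg$k_true) {
    problems <- c(problems,
      "n_plaque_topics + n_abscess_topics + n_shared_topics must equal k_true")
  }
  if (cfg$topic_concentration <= 0) problems <- c(problems, "topic_concentration must be > 0")
  if (cfg$membership_concentration <= 0) problems <- c(problems, "membership_concentration must be > 0")
  if (cfg$type_bias <= 0 || cfg$type_bias >= 1) problems <- c(problems, "type_bias must lie in (0, 1)")
  if (cfg$n_patients < 1) problems <- c(problems, "n_patients must be >= 1")
  if (cfg$n_taxa < 2) problems <- c(problems, "n_taxa must be >= 2")
  if (cfg$k_true < 1) problems <- c(problems, "k_true must be >= 1")
  if (length(problems)) {
    stop("invalid generator_config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "generator_config")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  # guard: with very small concentrations all gammas can underflow to 0
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, sample.int(k, sum(zero), replace = TRUE)] <- 1
  x / rowSums(x)
}

#' Draw the latent ground truth of a synthetic cohort
#'
#' Topic-taxon rows are symmetric-Dirichlet draws; per-patient base topic
#' weights are shared between the pair and then reweighted by specimen type
#' (see [generator_config()]), which induces intra-patient correlation.
#' Truly enriched taxa are defined by a 4x rule: a taxon whose mean
#' probability across plaque-specific topics exceeds four times its mean
#' across abscess-specific topics is plaque-enriched, and symmetrically for
#' abscess.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `synthetic_truth` with `topic_taxon` (k x taxa,
#'   row-stochastic), `sample_topic` (samples x k, row-stochastic, plaque and
#'   abscess rows per patient), `topic_class`, `enriched_taxa` (named vector
#'   taxon -> "plaque"/"abscess"), and `contaminant_taxa`.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(derive_seed(cfg$seed, "truth"), {
    k <- cfg$k_true
    taxa <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
    topic_taxon <- rdirichlet(k, rep(cfg$topic_concentration, cfg$n_taxa))
    dimnames(topic_taxon) <- list(sprintf("topic_%d", seq_len(k)), taxa)
    topic_class <- rep(c("plaque", "abscess", "shared"),
                       c(cfg$n_plaque_topics, cfg$n_abscess_topics,
                         cfg$n_shared_topics))
    patients <- sprintf("P%02d", seq_len(cfg$n_patients))
    base <- rdirichlet(cfg$n_patients, rep(cfg$membership_concentration, k))
    mult <- function(type) {
      m <- ifelse(topic_class == "shared", 0.5,
                  ifelse(topic_class == type, cfg$type_bias,
                         1 - cfg$type_bias))
      m
    }
    reweight <- function(w, type) {
      v <- w * mult(type)
      v / sum(v)
    }
    sample_ids <- as.vector(rbind(paste0(patients, "_plaque"),
                                  paste0(patients, "_abscess")))
    sample_topic <- matrix(0, nrow = 2 * cfg$n_patients, ncol = k,
                           dimnames = list(sample_ids, rownames(topic_taxon)))
    for (i in seq_len(cfg$n_patients)) {
      sample_topic[2 * i - 1, ] <- reweight(base[i, ], "plaque")
      sample_topic[2 * i, ] <- reweight(base[i, ], "abscess")
    }
    enriched <- enriched_taxa_from_topics(topic_taxon, topic_class,
                                          min_abundance = 1 / cfg$n_taxa)
    contam <- if (cfg$n_contaminants > 0)
      sprintf("contam_%02d", seq_len(cfg$n_contaminants)) else character()
    structure(list(topic_taxon = topic_taxon, sample_topic = sample_topic,
                   topic_class = topic_class, enriched_taxa = enriched,
                   contaminant_taxa = contam),
              class = "synthetic_truth")
  })
}

#' Enriched-taxa ground truth from topic structure
#'
#' The 4x rule used to define truly enriched taxa from a topic-taxon matrix:
#' a taxon is plaque-enriched when its mean probability across plaque-specific
#' topics exceeds `fold` times its mean across abscess-specific topics
#' (symmetrically for abscess), provided the larger of the two means reaches
#' `min_abundance`. The floor keeps the ground truth within the generative
#' model's detection envelope: with sparse Dirichlet topics almost every taxon
#' satisfies the bare ratio at abundances (~1e-6) that no realistic library
#' could ever witness.
#'
#' @param topic_taxon Row-stochastic k x taxa matrix.
#' @param topic_class Per-topic class labels (plaque/abscess/shared).
#' @param fold Enrichment fold threshold.
#' @param min_abundance Detectability floor on the larger class-mean
#'   probability ([generate_truth()] uses `1 / n_taxa`, the uniform
#'   expectation).
#' @return Named character vector mapping taxon -> direction.
#' @export
enriched_taxa_from_topics <- function(topic_taxon, topic_class, fold = 4,
                                      min_abundance = 0) {
  pl <- topic_class == "plaque"
  ab <- topic_class == "abscess"
  if (!any(pl) || !any(ab)) return(stats::setNames(character(), character()))
  mp <- colMeans(topic_taxon[pl, , drop = FALSE])
  ma <- colMeans(topic_taxon[ab, , drop = FALSE])
  dir <- ifelse(mp > fold * ma, "plaque", ifelse(ma > fold * mp, "abscess", NA))
  dir[pmax(mp, ma) < min_abundance] <- NA
  out <- dir[!is.na(dir)]
  stats::setNames(as.character(out), names(out))
}

synthetic_taxonomy <- function(taxa, contam) {
  n <- length(taxa)
  genus_idx <- ceiling(seq_len(n) / 3)
  phyla <- sprintf("Phylum_%s", LETTERS[(genus_idx - 1L) %% 8L + 1L])
  tax <- data.frame(taxon_id = taxa,
                    phylum = phyla,
                    genus = sprintf("Genus_%03d", genus_idx),
                    species = taxa)
  if (length(contam)) {
    tax <- rbind(tax, data.frame(taxon_id = contam,
                                 phylum = "Phylum_contaminant",
                                 genus = "Genus_contaminant",
                                 species = contam))
  }
  tax
}

#' Draw a paired cohort's counts from its ground truth
#'
#' Per sample, taxon probabilities are the topic mixture
#' `w %*% topic_taxon` down-weighted to make room for a uniform contaminant
#' spike at relative abundance 1e-3 per contaminant; counts are a single
#' multinomial draw at a log-normal library size. Blanks contain contaminant
#' taxa only, at roughly one-twentieth the specimen depth.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param cfg The matching [generator_config()].
#' @return A `paired_cohort` (counts include contaminant taxa and blank
#'   samples; taxonomy synthetic).
#' @export
sample_cohort <- function(truth, cfg) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "generator_config"))
  if (nrow(truth$sample_topic) != 2L * cfg$n_patients ||
      ncol(truth$topic_taxon) != cfg$n_taxa) {
    stop("truth is inconsistent with cfg")
  }
  withr::with_seed(derive_seed(cfg$seed, "cohort"), {
    taxa <- colnames(truth$topic_taxon)
    contam <- truth$contaminant_taxa
    all_taxa <- c(taxa, contam)
    n_samp <- nrow(truth$sample_topic)
    contam_mass <- 1e-3 * length(contam)
    counts <- matrix(0L, nrow = length(all_taxa), ncol = n_samp + cfg$n_blanks,
                     dimnames = list(all_taxa,
                                     c(rownames(truth$sample_topic),
                                       if (cfg$n_blanks > 0)
                                         sprintf("blank_%02d", seq_len(cfg$n_blanks)))))
    lib <- pmax(1, round(stats::rlnorm(n_samp, cfg$library_size_log_mean,
                                       cfg$library_size_log_sd)))
    for (j in seq_len(n_samp)) {
      p_bio <- as.vector(truth$sample_topic[j, ] %*% truth$topic_taxon)
      p <- c(p_bio * (1 - contam_mass), rep(1e-3, length(contam)))
      counts[, j] <- stats::rmultinom(1, lib[j], p)[, 1]
    }
    if (cfg$n_blanks > 0) {
      if (length(contam) == 0)
        stop("blanks requested but n_contaminants is 0")
      blank_lib <- pmax(1, round(stats::rlnorm(cfg$n_blanks,
                                               cfg$library_size_log_mean - log(20),
                                               cfg$library_size_log_sd)))
      for (b in seq_len(cfg$n_blanks)) {
        counts[contam, n_samp + b] <-
          stats::rmultinom(1, blank_lib[b], rep(1, length(contam)))[, 1]
      }
    }
    patients <- sub("_(plaque|abscess)$", "", rownames(truth$sample_topic))
    md <- data.frame(
      sample_id = colnames(counts),
      patient_id = c(patients, rep(NA_character_, cfg$n_blanks)),
      specimen_type = c(sub("^.*_", "", rownames(truth$sample_topic)),
                        rep("blank", cfg$n_blanks)))
    paired_cohort(counts, md, synthetic_taxonomy(taxa, contam))
  })
}

#' Generate a complete synthetic paired cohort
#'
#' Convenience wrapper: [generate_truth()] then [sample_cohort()].
#'
#' @param cfg A [generator_config()].
#' @return List with `cohort` (a `paired_cohort`) and `truth`
#'   (a `synthetic_truth`).
#' @export
simulate_cohort <- function(cfg = generator_config()) {
  truth <- generate_truth(cfg)
  list(cohort = sample_cohort(truth, cfg), truth = truth)
}

#' Write a synthetic cohort and its truth to disk
#'
#' Writes `counts.tsv`, `metadata.tsv`, `taxonomy.tsv` (via [write_tables()])
#' plus `truth.json` holding the generator's ground truth and config.
#'
#' @param sim Output of [simulate_cohort()].
#' @param cfg The [generator_config()] used.
#' @param dir Output directory.
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(sim, cfg, dir) {
  paths <- write_tables(sim$cohort, dir)
  truth_path <- file.path(dir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(
    list(config = unclass(cfg),
         topic_taxon = tr$topic_taxon, sample_topic = tr$sample_topic,
         topic_class = tr$topic_class,
         enriched_taxa = as.list(tr$enriched_taxa),
         contaminant_taxa = tr$contaminant_taxa),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = truth_path))
}
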