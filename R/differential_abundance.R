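# Split a value matrix (taxa x samples) into aligned plaque/abscess matrices
# (taxa x patients), patient order = first appearance in metadata.
paired_split <- function(values, metadata) {
  md <- metadata[metadata$specimen_type %in% c("plaque", "abscess"), ,
                 drop = FALSE]
  patients <- unique(md$patient_id)
  pick <- function(type) {
    ids <- vapply(patients, function(p) {
      md$sample_id[md$patient_id == p & md$specimen_type == type]
    }, character(1))
    m <- values[, ids, drop = FALSE]
    colnames(m) <- patients
    m
  }
  list(plaque = pick("plaque"), abscess = pick("abscess"),
       patients = patients)
}

da_frame <- function(taxa, p, effect, q_threshold = 0.05) {
  q <- bh_fdr(p)
  data.frame(taxon = taxa, effect = effect,
             direction = ifelse(effect > 0, "plaque",
                                ifelse(effect < 0, "abscess", NA)),
             p = p, q = q, significant = !is.na(q) & q < q_threshold,
             row.names = NULL)
}

#' Per-taxon paired Wilcoxon differential abundance
#'
#' For every taxon at the chosen rank, a two-sided Wilcoxon signed-rank test
#' on per-patient differences of relative abundance (plaque minus abscess),
#' Benjamini-Hochberg corrected across taxa. The effect is the median paired
#' TSS difference; its sign gives the enrichment direction.
#'
#' @param cohort A filtered `paired_cohort`.
#' @param rank Taxonomic rank to agglomerate to, or `"asv"` for none.
#' @param q_threshold Significance threshold on the BH q-value.
#' @return Data frame with columns `taxon`, `effect`, `direction`, `p`, `q`,
#'   `significant`.
#' @export
paired_wilcoxon_per_taxon <- function(cohort, rank = "genus",
                                      q_threshold = 0.05) {
  if (rank != "asv") cohort <- agglomerate(cohort, rank)
  ps <- paired_split(tss(cohort$counts), cohort$metadata)
  if (length(ps$patients) < 5L) stop("need at least 5 pairs")
  diffs <- ps$plaque - ps$abscess
  p <- apply(diffs, 1, function(d) wilcoxon_signed_rank(d)$p_value)
  effect <- apply(diffs, 1, stats::median)
  da_frame(rownames(diffs), p, effect, q_threshold)
}

#' Top taxa by absolute median paired difference
#'
#' Among significant taxa (`q < q_threshold`), ranks by descending absolute
#' effect, ties broken by ascending q then taxon name.
#'
#' @param report Output of [paired_wilcoxon_per_taxon()] (or any data frame
#'   with `taxon`, `effect`, `q`, `significant`).
#' @param k Number of taxa to return.
#' @param q_threshold Significance threshold.
#' @return The top rows of `report`, at most `k` (with a warning if fewer are
#'   significant).
#' @export
top_k_by_median_difference <- function(report, k = 15L, q_threshold = 0.05) {
  sig <- report[!is.na(report$q) & report$q < q_threshold, , drop = FALSE]
  sig <- sig[order(-abs(sig$effect), sig$q, sig$taxon), , drop = FALSE]
  if (nrow(sig) < k) {
    warning("only ", nrow(sig), " significant taxa (k = ", k, ")")
  }
  utils::head(sig, k)
}

#' Per-patient enrichment tallies
#'
#' For every taxon, the number of patient pairs in which its relative
#' abundance is higher in plaque, higher in abscess, or tied.
#'
#' @param cohort A filtered `paired_cohort`.
#' @param rank Taxonomic rank, or `"asv"`.
#' @return Data frame with `taxon`, `n_plaque_higher`, `n_abscess_higher`,
#'   `n_tied` (rows sum to the pair count).
#' @export
enrichment_tallies <- function(cohort, rank = "genus") {
  if (rank != "asv") cohort <- agglomerate(cohort, rank)
  ps <- paired_split(tss(cohort$counts), cohort$metadata)
  diffs <- ps$plaque - ps$abscess
  data.frame(taxon = rownames(diffs),
             n_plaque_higher = rowSums(diffs > 0),
             n_abscess_higher = rowSums(diffs < 0),
             n_tied = rowSums(diffs == 0), row.names = NULL)
}

#' Resampling differential-abundance engine (Dirichlet / CSS-log10 / Wilcoxon)
#'
#' A simplified compositional resampling engine: per Monte-Carlo instance,
#' each sample's composition is drawn from Dirichlet(counts + 0.5); instance
#' values are CSS-scaled and log10-transformed; a paired signed-rank test is
#' run per taxon; the reported p is the mean over instances, BH-corrected
#' across taxa.
#'
#' @param cohort A filtered `paired_cohort`.
#' @param rank Taxonomic rank, or `"asv"`.
#' @param n_mc Number of Monte-Carlo instances.
#' @param seed Integer seed.
#' @param q_threshold Significance threshold.
#' @return Data frame as in [paired_wilcoxon_per_taxon()] (effect = median
#'   paired TSS difference, computed once on the observed counts).
#' @export
engine_clr_wilcoxon <- function(cohort, rank = "genus", n_mc = 128L,
                                seed = 1L, q_threshold = 0.05) {
  stopifnot(n_mc >= 1L)
  if (rank != "asv") cohort <- agglomerate(cohort, rank)
  counts <- cohort$counts
  md <- cohort$metadata
  p_mat <- withr::with_seed(seed, {
    vapply(seq_len(n_mc), function(m) {
      inst <- apply(counts + 0.5, 2, function(x) {
        g <- stats::rgamma(length(x), shape = x, rate = 1)
        g / sum(g)
      })
      rownames(inst) <- rownames(counts)
      vals <- css_log10(inst)
      ps <- paired_split(vals, md)
      d <- ps$plaque - ps$abscess
      apply(d, 1, function(dd) wilcoxon_signed_rank(dd)$p_value)
    }, numeric(nrow(counts)))
  })
  p <- rowMeans(matrix(p_mat, nrow = nrow(counts)))
  obs <- paired_split(tss(counts), md)
  effect <- apply(obs$plaque - obs$abscess, 1, stats::median)
  da_frame(rownames(counts), p, effect, q_threshold)
}

#' Linear-model differential-abundance engine (CSS-log / paired OLS)
#'
#' A simplified linear-model engine: per taxon, ordinary least squares of
#' CSS-log abundance on a specimen-type indicator plus per-patient intercepts
#' (honoring the pairing); p is the two-sided t-test of the type coefficient,
#' BH-corrected across taxa.
#'
#' @param cohort A filtered `paired_cohort`.
#' @param rank Taxonomic rank, or `"asv"`.
#' @param q_threshold Significance threshold.
#' @return Data frame as in [paired_wilcoxon_per_taxon()]; `effect` here is
#'   the type coefficient (plaque minus abscess on the CSS-log scale).
#' @export
engine_linear_model <- function(cohort, rank = "genus", q_threshold = 0.05) {
  if (rank != "asv") cohort <- agglomerate(cohort, rank)
  md <- cohort$metadata[cohort$metadata$specimen_type != "blank", , drop = FALSE]
  if (length(unique(md$patient_id)) < 2L) stop("rank-deficient design: need >= 2 pairs")
  vals <- css_log(cohort$counts[, md$sample_id, drop = FALSE])
  type <- as.integer(md$specimen_type == "plaque")
  patient <- factor(md$patient_id)
  X <- stats::model.matrix(~ type + patient)
  fit <- stats::lm.fit(X, t(vals))
  df_res <- nrow(X) - fit$rank
  coefs <- fit$coefficients["type", ]
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  jtype <- which(colnames(X) == "type")
  se <- sqrt(sigma2 * XtXinv[jtype, jtype])
  tol <- sqrt(.Machine$double.eps)
  # zero-noise taxa: p = 1 when the effect is also zero (degenerate), ~0 when
  # a nonzero effect is fitted exactly
  p <- ifelse(se > tol, 2 * stats::pt(-abs(coefs / se), df_res),
              ifelse(abs(coefs) < tol, 1, 0))
  da_frame(rownames(vals), p, unname(coefs), q_threshold)
}

#' Consensus confidence tiers across differential-abundance methods
#'
#' Aligns per-method significance calls by the union of taxa (absent = not
#' significant) and assigns a confidence tier per taxon: `high` when all
#' supplied methods (at least three) call it significant, `medium` when all
#' but one do (or 2 of 3), `low` when exactly one does, `none` otherwise.
#' Taxa whose significant calls disagree in direction are demoted to `none`
#' with `direction_conflict = TRUE`.
#'
#' @param reports Named list of per-method data frames with columns `taxon`,
#'   `significant`, `direction` (e.g. outputs of the engines, or imported
#'   external call-sets via [read_external_calls()]).
#' @return Data frame with `taxon`, `n_significant`, `tier`, `direction` (the
#'   agreed direction among significant calls, NA if none), and
#'   `direction_conflict`.
#' @export
consensus_tier <- function(reports) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  taxa <- sort(unique(unlist(lapply(reports, `[[`, "taxon"))))
  n_methods <- length(reports)
  sig <- sapply(reports, function(r) {
    v <- r$significant[match(taxa, r$taxon)]
    !is.na(v) & v
  })
  sig <- matrix(sig, nrow = length(taxa),
                dimnames = list(taxa, names(reports)))
  dir <- sapply(reports, function(r) r$direction[match(taxa, r$taxon)])
  dir <- matrix(dir, nrow = length(taxa))
  n_sig <- rowSums(sig)
  tier <- rep("none", length(taxa))
  tier[n_sig == 1L] <- "low"
  if (n_methods >= 3L) {
    tier[n_sig == n_methods - 1L] <- "medium"
    tier[n_sig == n_methods] <- "high"
  } else if (n_methods == 2L) {
    tier[n_sig == 2L] <- "medium"
  }
  agreed <- rep(NA_character_, length(taxa))
  conflict <- rep(FALSE, length(taxa))
  for (i in seq_along(taxa)) {
    ds <- unique(stats::na.omit(dir[i, sig[i, ]]))
    if (length(ds) == 1L) agreed[i] <- ds
    if (length(ds) > 1L) {
      conflict[i] <- TRUE
      tier[i] <- "none"
    }
  }
  data.frame(taxon = taxa, n_significant = n_sig, tier = tier,
             direction = agreed, direction_conflict = conflict,
             row.names = NULL)
}

#' Import an external differential-abundance call-set
#'
#' Reads a TSV of `taxon`, `significant` (logical/0-1), `direction`
#' (plaque/abscess) so that call-sets from external tools can participate in
#' [consensus_tier()].
#'
#' @param path TSV file path.
#' @return Data frame with `taxon`, `significant`, `direction`.
#' @export
read_external_calls <- function(path) {
  x <- read_tsv_strict(path, "external call-set")
  need <- c("taxon", "significant", "direction")
  if (!all(need %in% names(x))) {
    stop("external call-set must have columns: ", paste(need, collapse = ", "))
  }
  x$significant <- as.logical(x$significant)
  x[, need]
}

#' Run the built-in three-method consensus differential-abundance analysis
#'
#' Runs the plain paired Wilcoxon, the resampling engine, and the
#' linear-model engine at the chosen rank and combines them with
#' [consensus_tier()].
#'
#' @param cohort A filtered `paired_cohort`.
#' @param rank Taxonomic rank, or `"asv"`.
#' @param seed Seed for the resampling engine.
#' @param n_mc Monte-Carlo instances for the resampling engine.
#' @param q_threshold Significance threshold.
#' @return List with `methods` (named list of the three per-method reports)
#'   and `consensus` (the tier table).
#' @export
run_da <- function(cohort, rank = "genus", seed = 1L, n_mc = 128L,
                   q_threshold = 0.05) {
  methods <- list(
    wilcoxon = paired_wilcoxon_per_taxon(cohort, rank, q_threshold),
    resampling = engine_clr_wilcoxon(cohort, rank, n_mc = n_mc, seed = seed,
                                     q_threshold = q_threshold),
    linear = engine_linear_model(cohort, rank, q_threshold))
  list(methods = methods, consensus = consensus_tier(methods))
}
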