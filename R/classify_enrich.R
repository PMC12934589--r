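#' Rank-based AUC
#'
#' Area under the ROC curve in the Mann-Whitney form: the probability that a
#' random positive outscores a random negative, with half credit for ties.
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("roc_auc requires both classes")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Patient-stratified k-fold cross-validated classification
#'
#' Partitions patients (never splitting a plaque/abscess pair across folds)
#' into `n_folds` folds; per fold, trains an ensemble of randomized decision
#' trees (random forest via ranger, impurity importance) on the TSS values of
#' the training folds and scores the held-out samples. The positive class is
#' `abscess`.
#'
#' @param cohort A filtered `paired_cohort`.
#' @param rank Taxonomic rank to agglomerate to, or `"asv"`.
#' @param n_folds Number of folds.
#' @param seed Integer seed (fold assignment and forests).
#' @param num_trees Trees per forest.
#' @return List of class `cv_result`: `folds` (data frame with `fold`, `auc`,
#'   `n_test`), `held_out` (list of held-out sample ids per fold),
#'   `importance_rank` (taxa x folds integer matrix, 1 = most important,
#'   ties broken by name), `mean_auc`.
#' @export
kfold_classify <- function(cohort, rank = "genus", n_folds = 4L, seed = 1L,
                           num_trees = 500L) {
  if (rank != "asv") cohort <- agglomerate(cohort, rank)
  md <- cohort$metadata
  patients <- unique(md$patient_id[md$specimen_type != "blank"])
  if (length(patients) < n_folds) stop("need at least n_folds patients")
  x <- t(tss(cohort$counts))
  colnames(x) <- make.names(colnames(x))
  y <- factor(md$specimen_type[match(rownames(x), md$sample_id)],
              levels = c("plaque", "abscess"))
  fold_of <- withr::with_seed(derive_seed(seed, "folds"), {
    stats::setNames(rep(seq_len(n_folds), length.out = length(patients))[
      sample.int(length(patients))], patients)
  })
  sample_fold <- fold_of[md$patient_id[match(rownames(x), md$sample_id)]]
  aucs <- numeric(n_folds)
  held <- vector("list", n_folds)
  imp_rank <- matrix(NA_integer_, nrow = ncol(x), ncol = n_folds,
                     dimnames = list(colnames(x), paste0("fold", seq_len(n_folds))))
  for (f in seq_len(n_folds)) {
    test <- sample_fold == f
    if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L) {
      stop("fold ", f, " has a single class")
    }
    train_df <- data.frame(x[!test, , drop = FALSE], .type = y[!test],
                           check.names = FALSE)
    rf <- ranger::ranger(
      dependent.variable.name = ".type", data = train_df,
      num.trees = num_trees, probability = TRUE, importance = "impurity",
      seed = derive_seed(seed, paste0("fold", f)), num.threads = 1)
    prob <- stats::predict(rf, data.frame(x[test, , drop = FALSE],
                                          check.names = FALSE),
                           num.threads = 1)$predictions[, "abscess"]
    aucs[f] <- roc_auc(prob, y[test] == "abscess")
    held[[f]] <- rownames(x)[test]
    imp <- rf$variable.importance
    ord <- order(-imp, names(imp))
    imp_rank[names(imp)[ord], f] <- seq_along(ord)
  }
  structure(list(folds = data.frame(fold = seq_len(n_folds), auc = aucs,
                                    n_test = vapply(held, length, integer(1))),
                 held_out = held, importance_rank = imp_rank,
                 mean_auc = mean(aucs)),
            class = "cv_result")
}

#' Hypergeometric pathway over-representation
#'
#' Per pathway, the one-sided hypergeometric upper-tail probability of
#' observing at least `k` significant members given `n` significant items
#' drawn from a background of `N` items of which `K` belong to the pathway;
#' BH-corrected across pathways. Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param sig_items Character vector of significant item ids (subset of
#'   `background`).
#' @param background Character vector of all tested item ids.
#' @param pathways Named list mapping pathway id -> character vector of item
#'   ids (intersected with the background).
#' @return Data frame with `pathway`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `fold_enrichment`.
#' @export
over_representation <- function(sig_items, background, pathways) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  sig_items <- unique(sig_items)
  if (!all(sig_items %in% background)) {
    stop("sig_items must be a subset of background")
  }
  N <- length(background)
  n <- length(sig_items)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(unique(pathways[[pw]]), background)
    K <- length(members)
    k <- length(intersect(sig_items, members))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(pathway = pw, k = k, n = n, K = K, N = N, p = p,
               fold_enrichment = fe)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p)
  tab[, c("pathway", "k", "n", "K", "N", "p", "q", "fold_enrichment")]
}

#' Read an item-to-pathway mapping TSV
#'
#' Columns: `item_id`, `pathway_id`, optionally `pathway_name`.
#'
#' @param path TSV file path.
#' @return Named list mapping pathway id -> item ids, with a `pathway_name`
#'   attribute when names are present.
#' @export
read_pathway_map <- function(path) {
  x <- read_tsv_strict(path, "pathway mapping")
  if (!all(c("item_id", "pathway_id") %in% names(x))) {
    stop("pathway mapping needs columns item_id, pathway_id")
  }
  out <- split(as.character(x$item_id), x$pathway_id)
  if ("pathway_name" %in% names(x)) {
    nm <- x$pathway_name[!duplicated(x$pathway_id)]
    names(nm) <- x$pathway_id[!duplicated(x$pathway_id)]
    attr(out, "pathway_name") <- nm
  }
  out
}
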