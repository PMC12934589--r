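#' Build a scaled relative-abundance corpus
#'
#' Converts a count table into an LDA corpus: samples become documents and
#' taxa become tokens, with token counts `round(tss * S)` (rounding half away
#' from zero). Scaling makes relative abundances usable by a count-based
#' topic model while equalizing library sizes across documents.
#'
#' @param counts Numeric matrix, taxa x samples.
#' @param S Positive integer scaling factor (>= 10).
#' @return List of class `scaled_corpus`: `dtm` (documents x tokens integer
#'   matrix), `S`.
#' @export
build_scaled_corpus <- function(counts, S = 1000L) {
  stopifnot(S >= 10)
  p <- tss(counts)
  scaled <- t(p) * S
  dtm <- sign(scaled) * floor(abs(scaled) + 0.5)  # half away from zero
  storage.mode(dtm) <- "integer"
  zero <- rowSums(dtm) == 0
  if (any(zero)) {
    stop("zero-total document(s) after scaling: ",
         paste(rownames(dtm)[zero], collapse = ", "))
  }
  structure(list(dtm = dtm, S = as.integer(S)), class = "scaled_corpus")
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Collapsed Gibbs sampler over token-topic assignments with the standard
#' full conditional
#' `P(z = k | .) propto (n_dk + alpha) (n_kw + eta) / (n_k + V eta)`.
#' `beta` (topic-taxon) and `gamma` (sample-topic) are posterior-mean
#' estimates from the final state; the complete-data log-likelihood is
#' recorded at each thinned post-burn-in sweep. Fully reproducible given
#' `seed` (a private RNG stream; R's global RNG is untouched).
#'
#' @param corpus A [build_scaled_corpus()] result.
#' @param K Number of topics (>= 1).
#' @param alpha Document-topic Dirichlet prior (default `50 / K`).
#' @param eta Topic-taxon Dirichlet prior.
#' @param iterations,burn_in,thin Gibbs sweep schedule; `iterations` must
#'   exceed `burn_in` and `thin` must fit at least one recorded sweep.
#' @param seed Integer seed.
#' @return List of class `lda_model`: `K`, `alpha`, `eta`, `beta` (K x V,
#'   row-stochastic), `gamma` (D x K, row-stochastic), `loglik_trace`,
#'   `seed`, `iterations`, `burn_in`, `thin`.
#' @export
fit_lda_gibbs <- function(corpus, K, alpha = 50 / K, eta = 0.1,
                          iterations = 2000L, burn_in = 1000L, thin = 50L,
                          seed = 1L) {
  stopifnot(inherits(corpus, "scaled_corpus"), K >= 1L,
            iterations > burn_in, thin >= 1L,
            thin <= iterations - burn_in)
  fit <- .lda_gibbs_cpp(corpus$dtm, as.integer(K), alpha, eta,
                        as.integer(iterations), as.integer(burn_in),
                        as.integer(thin), as.integer(seed))
  dimnames(fit$beta) <- list(paste0("topic_", seq_len(K)),
                             colnames(corpus$dtm))
  dimnames(fit$gamma) <- list(rownames(corpus$dtm),
                              paste0("topic_", seq_len(K)))
  structure(list(K = as.integer(K), alpha = alpha, eta = eta,
                 beta = fit$beta, gamma = fit$gamma,
                 loglik_trace = fit$loglik_trace, seed = as.integer(seed),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin)),
            class = "lda_model")
}

#' @export
#' @method print lda_model
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: K = %d, %d samples x %d taxa, %d Gibbs sweeps\n",
              x$K, nrow(x$gamma), ncol(x$beta), x$iterations))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Harmonic-mean estimator of the log marginal likelihood over the post-burn-in
# log-likelihood trace.  Larger is better.
metric_griffiths2004 <- function(loglik_trace) {
  -(logsumexp(-loglik_trace) - log(length(loglik_trace)))
}

# Mean pairwise cosine similarity among topic-taxon rows; near-duplicate
# topics push it toward 1, so smaller is better.
metric_caojuan2009 <- function(beta) {
  K <- nrow(beta)
  stopifnot(K >= 2)
  nrm <- sqrt(rowSums(beta^2))
  cs <- (beta %*% t(beta)) / outer(nrm, nrm)
  mean(cs[upper.tri(cs)])
}

# Symmetric KL divergence between the normalized singular-value spectrum of
# beta and the normalized document-length-weighted topic totals of gamma.
# Smaller is better.
metric_arun2010 <- function(beta, gamma, doc_lengths) {
  cm1 <- svd(beta, nu = 0, nv = 0)$d
  cm1 <- sort(cm1 / sum(cm1), decreasing = TRUE)
  cm2 <- as.vector(doc_lengths %*% gamma)
  cm2 <- sort(cm2 / sum(cm2), decreasing = TRUE)
  eps <- 1e-12
  cm1 <- pmax(cm1, eps); cm2 <- pmax(cm2, eps)
  sum(cm1 * log(cm1 / cm2)) + sum(cm2 * log(cm2 / cm1))
}

# Mean over topic pairs of half the symmetric KL divergence between
# (eta-smoothed, hence strictly positive) topic-taxon rows.  Larger is better.
metric_deveaud2014 <- function(beta) {
  K <- nrow(beta)
  stopifnot(K >= 2)
  tot <- 0
  for (j in seq_len(K - 1)) {
    for (k in seq(j + 1, K)) {
      bj <- beta[j, ]; bk <- beta[k, ]
      tot <- tot + 0.5 * (sum(bj * log(bj / bk)) + sum(bk * log(bk / bj)))
    }
  }
  tot / (K * (K - 1) / 2)
}

#' Topic-number selection by four validation metrics
#'
#' Fits the corpus at every K in the grid (same seed policy per K) and
#' evaluates the four standard topic-number diagnostics: Griffiths2004
#' (harmonic-mean log marginal likelihood; maximize), CaoJuan2009 (mean
#' pairwise topic cosine; minimize), Arun2010 (symmetric KL between the
#' singular-value spectrum of beta and length-weighted topic totals of gamma;
#' minimize), Deveaud2014 (mean pairwise topic divergence; maximize).
#' `chosen_k` minimizes the sum of min-max-normalized
#' `caojuan + arun - deveaud - griffiths` over the grid.
#'
#' @param corpus A `scaled_corpus`.
#' @param k_grid Integer grid of candidate K (all >= 2).
#' @param iterations,burn_in,thin Gibbs schedule per fit.
#' @param seed Integer seed (used for every K).
#' @return List of class `k_selection_curve`: `table` (data frame with
#'   columns `K`, `griffiths2004`, `caojuan2009`, `arun2010`, `deveaud2014`,
#'   `score`), `chosen_k`, `degenerate` (TRUE for a size-1 grid).
#' @export
k_selection <- function(corpus, k_grid = 2:12, iterations = 800L,
                        burn_in = 400L, thin = 20L, seed = 1L) {
  k_grid <- sort(unique(as.integer(k_grid)))
  stopifnot(length(k_grid) >= 1L, all(k_grid >= 2L))
  doc_lengths <- rowSums(corpus$dtm)
  rows <- lapply(k_grid, function(K) {
    fit <- fit_lda_gibbs(corpus, K, iterations = iterations,
                         burn_in = burn_in, thin = thin, seed = seed)
    data.frame(K = K,
               griffiths2004 = metric_griffiths2004(fit$loglik_trace),
               caojuan2009 = metric_caojuan2009(fit$beta),
               arun2010 = metric_arun2010(fit$beta, fit$gamma, doc_lengths),
               deveaud2014 = metric_deveaud2014(fit$beta))
  })
  tab <- do.call(rbind, rows)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(0.5, length(x)))
    (x - r[1]) / diff(r)
  }
  tab$score <- norm01(tab$caojuan2009) + norm01(tab$arun2010) -
    norm01(tab$deveaud2014) - norm01(tab$griffiths2004)
  chosen <- tab$K[which.min(tab$score)]
  structure(list(table = tab, chosen_k = chosen,
                 degenerate = length(k_grid) == 1L),
            class = "k_selection_curve")
}

#' Scaling-factor selection by per-type silhouette
#'
#' For each candidate scaling factor, fits the model at fixed K and seed and
#' scores the per-specimen-type median silhouette widths on Euclidean
#' distances between gamma rows; the S maximizing the sum of the plaque and
#' abscess medians is chosen. Candidates that produce a zero-total document
#' are skipped with a logged reason.
#'
#' @param counts Numeric matrix, taxa x samples (non-blank samples).
#' @param metadata Metadata covering the samples.
#' @param K Fixed topic number used for every candidate.
#' @param S_grid Candidate scaling factors.
#' @param iterations,burn_in,thin,seed Gibbs schedule.
#' @return List with `S` (chosen factor) and `diagnostics` (data frame with
#'   `S`, `silhouette_plaque`, `silhouette_abscess`, `skip_reason`).
#' @export
select_scaling_factor <- function(counts, metadata, K,
                                  S_grid = c(10L, 100L, 1000L, 10000L),
                                  iterations = 800L, burn_in = 400L,
                                  thin = 20L, seed = 1L) {
  rows <- lapply(S_grid, function(S) {
    tryCatch({
      corpus <- build_scaled_corpus(counts, S)
      fit <- fit_lda_gibbs(corpus, K, iterations = iterations,
                           burn_in = burn_in, thin = thin, seed = seed)
      d <- as.matrix(stats::dist(fit$gamma))
      sil <- silhouette_by_group(d, stats::setNames(metadata$specimen_type,
                                                    metadata$sample_id))
      data.frame(S = S, silhouette_plaque = sil[["plaque"]],
                 silhouette_abscess = sil[["abscess"]],
                 skip_reason = NA_character_)
    }, error = function(e) {
      data.frame(S = S, silhouette_plaque = NA_real_,
                 silhouette_abscess = NA_real_,
                 skip_reason = conditionMessage(e))
    })
  })
  tab <- do.call(rbind, rows)
  ok <- is.na(tab$skip_reason)
  if (!any(ok)) stop("every scaling factor was skipped")
  tot <- tab$silhouette_plaque + tab$silhouette_abscess
  chosen <- tab$S[ok][which.max(tot[ok])]
  list(S = chosen, diagnostics = tab)
}

#' Topic-specimen-type association
#'
#' Per topic, a paired Wilcoxon signed-rank test on per-patient
#' (plaque minus abscess) gamma differences, BH-corrected across topics. A
#' topic is classified plaque- or abscess-specific when `q < q_threshold`
#' with the corresponding median gamma higher; otherwise shared.
#'
#' @param model An `lda_model`.
#' @param metadata Paired-cohort metadata covering the model's samples.
#' @param q_threshold Significance threshold.
#' @return Data frame with `topic`, `p`, `q`, `median_gamma_plaque`,
#'   `median_gamma_abscess`, `class`.
#' @export
topic_type_association <- function(model, metadata, q_threshold = 0.05) {
  ps <- paired_split(t(model$gamma), metadata)
  diffs <- ps$plaque - ps$abscess
  p <- apply(diffs, 1, function(d) wilcoxon_signed_rank(d)$p_value)
  q <- bh_fdr(p)
  med_p <- apply(ps$plaque, 1, stats::median)
  med_a <- apply(ps$abscess, 1, stats::median)
  class <- ifelse(q < q_threshold & med_p > med_a, "plaque",
                  ifelse(q < q_threshold & med_a > med_p, "abscess", "shared"))
  data.frame(topic = rownames(diffs), p = p, q = q,
             median_gamma_plaque = med_p, median_gamma_abscess = med_a,
             class = class, row.names = NULL)
}

#' Top driver taxa per topic
#'
#' Per topic, taxa ranked by beta (importance) score, descending; ties broken
#' by taxon name.
#'
#' @param model An `lda_model`.
#' @param top_n Number of taxa per topic.
#' @return Data frame with `topic`, `taxon`, `beta`, `rank`.
#' @export
topic_drivers <- function(model, top_n = 10L) {
  out <- lapply(seq_len(model$K), function(k) {
    b <- model$beta[k, ]
    ord <- order(-b, names(b))
    idx <- utils::head(ord, top_n)
    data.frame(topic = rownames(model$beta)[k], taxon = names(b)[idx],
               beta = unname(b[idx]), rank = seq_along(idx))
  })
  do.call(rbind, out)
}

#' 2-D embedding of sample-topic memberships
#'
#' Seeded UMAP of the gamma rows, with per-specimen-type median silhouette
#' widths computed on the embedding's Euclidean distances.
#'
#' @param model An `lda_model`.
#' @param metadata Metadata covering the model's samples.
#' @param seed Integer seed (embedding is deterministic given it).
#' @param n_neighbors UMAP neighborhood size (capped at n - 1).
#' @return List with `coordinates` (samples x 2) and `silhouette` (named
#'   vector of per-type medians).
#' @export
embed_gamma <- function(model, metadata, seed = 1L, n_neighbors = 15L) {
  g <- model$gamma
  if (nrow(g) < 4L) stop("embedding requires at least 4 samples")
  nn <- min(n_neighbors, nrow(g) - 1L)
  coords <- withr::with_seed(seed, {
    uwot::umap(g, n_neighbors = nn, n_components = 2, n_threads = 1,
               n_sgd_threads = 0, verbose = FALSE)
  })
  rownames(coords) <- rownames(g)
  colnames(coords) <- c("umap1", "umap2")
  d <- as.matrix(stats::dist(coords))
  sil <- silhouette_by_group(d, stats::setNames(metadata$specimen_type,
                                                metadata$sample_id))
  list(coordinates = coords, silhouette = sil)
}

#' Greedy best-match cosine between two topic-taxon matrices
#'
#' Matches rows of `beta` to rows of `reference` greedily by descending
#' cosine similarity (each row used once) and returns the per-match cosines.
#' Used to compare a fitted model against generator ground truth.
#'
#' @param beta,reference Row-stochastic matrices over the same taxa.
#' @return List with `matching` (data frame `beta_row`, `reference_row`,
#'   `cosine`) and `mean_cosine`.
#' @export
match_topics_cosine <- function(beta, reference) {
  stopifnot(ncol(beta) == ncol(reference))
  cs <- (beta %*% t(reference)) /
    outer(sqrt(rowSums(beta^2)), sqrt(rowSums(reference^2)))
  n <- min(nrow(beta), nrow(reference))
  used_b <- logical(nrow(beta)); used_r <- logical(nrow(reference))
  out <- data.frame(beta_row = integer(n), reference_row = integer(n),
                    cosine = numeric(n))
  for (i in seq_len(n)) {
    m <- cs
    m[used_b, ] <- -Inf
    m[, used_r] <- -Inf
    idx <- arrayInd(which.max(m), dim(m))
    out$beta_row[i] <- idx[1]
    out$reference_row[i] <- idx[2]
    out$cosine[i] <- cs[idx[1], idx[2]]
    used_b[idx[1]] <- TRUE
    used_r[idx[2]] <- TRUE
  }
  list(matching = out, mean_cosine = mean(out$cosine))
}
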