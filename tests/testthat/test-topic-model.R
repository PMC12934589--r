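# Two documents on disjoint 10-token vocabularies: the most separable corpus.
disjoint_corpus <- function(tokens_per_doc = 500L) {
  counts <- matrix(0L, nrow = 20, ncol = 2,
                   dimnames = list(sprintf("w%02d", 1:20), c("d1", "d2")))
  counts[1:10, 1] <- as.integer(tokens_per_doc / 10)
  counts[11:20, 2] <- as.integer(tokens_per_doc / 10)
  build_scaled_corpus(counts, tokens_per_doc)
}

test_that("scaled corpus applies tss, rounding, and token-total bounds", {
  m <- matrix(c(5, 3, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  corpus <- build_scaled_corpus(m, 1000L)
  expect_equal(unname(corpus$dtm["s1", ]), c(500L, 300L, 200L))
  tiny <- matrix(c(4, 9996), ncol = 1, dimnames = list(c("rare", "dom"), "s1"))
  expect_equal(unname(build_scaled_corpus(tiny, 1000L)$dtm["s1", "rare"]), 0L)
  withr::local_seed(51)
  for (i in 1:5) {
    v <- 40
    counts <- matrix(rpois(v * 3, 30) + 1, nrow = v,
                     dimnames = list(sprintf("t%02d", 1:v), c("a", "b", "c")))
    dtm <- build_scaled_corpus(counts, 1000L)$dtm
    expect_true(all(abs(rowSums(dtm) - 1000) <= v / 2))
  }
  expect_error(build_scaled_corpus(m, 5), "S >= 10")
})

test_that("K = 1 degenerates to corpus-wide token frequencies", {
  corpus <- disjoint_corpus()
  fit <- fit_lda_gibbs(corpus, 1L, iterations = 20L, burn_in = 10L,
                       thin = 5L, seed = 1L)
  expect_equal(unname(fit$gamma[, 1]), c(1, 1), tolerance = 0.05)
  tok <- colSums(corpus$dtm)
  expected <- (tok + fit$eta) / (sum(tok) + ncol(corpus$dtm) * fit$eta)
  expect_equal(unname(fit$beta[1, ]), unname(expected), tolerance = 1e-12)
})

test_that("a separable two-topic corpus is recovered almost exactly", {
  corpus <- disjoint_corpus()
  fit <- fit_lda_gibbs(corpus, 2L, iterations = 300L, burn_in = 150L,
                       thin = 10L, seed = 3L)
  expect_equal(unname(rowSums(fit$beta)), rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$gamma)), rep(1, 2), tolerance = 1e-9)
  expect_true(all(apply(fit$gamma, 1, max) >= 0.95))
  own_topic <- apply(fit$gamma, 1, which.max)
  expect_gte(sum(fit$beta[own_topic[1], 1:10]), 0.95)
  expect_gte(sum(fit$beta[own_topic[2], 11:20]), 0.95)
  expect_true(length(fit$loglik_trace) > 0)
})

test_that("fits are exactly reproducible given the seed and error when K exceeds tokens", {
  corpus <- disjoint_corpus(100L)
  a <- fit_lda_gibbs(corpus, 3L, iterations = 50L, burn_in = 20L, thin = 10L,
                     seed = 9L)
  b <- fit_lda_gibbs(corpus, 3L, iterations = 50L, burn_in = 20L, thin = 10L,
                     seed = 9L)
  expect_identical(a$beta, b$beta)
  expect_identical(a$gamma, b$gamma)
  expect_identical(a$loglik_trace, b$loglik_trace)
  c2 <- fit_lda_gibbs(corpus, 3L, iterations = 50L, burn_in = 20L, thin = 10L,
                      seed = 10L)
  expect_false(identical(a$beta, c2$beta))
  expect_error(fit_lda_gibbs(corpus, 1000L, iterations = 10L, burn_in = 5L,
                             thin = 5L, seed = 1L), "token")
})

test_that("log-likelihood is non-decreasing in running median on the separable corpus", {
  corpus <- disjoint_corpus()
  fit <- fit_lda_gibbs(corpus, 2L, iterations = 200L, burn_in = 0L,
                       thin = 1L, seed = 4L)
  trace <- fit$loglik_trace
  rm5 <- stats::runmed(trace, 5)
  expect_true(all(diff(rm5) >= -1e-6 * abs(rm5[-length(rm5)])))
  expect_gte(max(trace), trace[1])
})

test_that("K-selection metric primitives behave at their analytic limits", {
  beta_id <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  expect_equal(oraltopics:::metric_caojuan2009(beta_id), 1)
  expect_equal(oraltopics:::metric_deveaud2014(beta_id), 0)
  beta_diff <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.05, 0.9))
  expect_lt(oraltopics:::metric_caojuan2009(beta_diff), 0.2)
  expect_gt(oraltopics:::metric_deveaud2014(beta_diff), 0)
  # griffiths: harmonic mean of a constant trace is that constant
  expect_equal(oraltopics:::metric_griffiths2004(rep(-500, 10)), -500)
  # arun: orthogonal equal-norm topics + uniform gamma give zero divergence
  g <- matrix(0.5, nrow = 3, ncol = 2)
  b <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(oraltopics:::metric_arun2010(b, g, rep(1, 3)), 0,
               tolerance = 1e-9)
})

test_that("k_selection returns finite metrics, a size-1 grid degenerates", {
  corpus <- disjoint_corpus()
  sel <- k_selection(corpus, k_grid = c(2, 3), iterations = 100L,
                     burn_in = 50L, thin = 10L, seed = 5L)
  expect_true(all(is.finite(unlist(sel$table[, -1]))))
  expect_false(sel$degenerate)
  one <- k_selection(corpus, k_grid = 2, iterations = 50L, burn_in = 20L,
                     thin = 10L, seed = 5L)
  expect_true(one$degenerate)
  expect_equal(one$chosen_k, 2L)
  expect_error(k_selection(corpus, k_grid = 1), "k_grid")
})

test_that("scaling-factor selection prefers scales that separate the types", {
  cohort <- std_filtered()
  agg <- agglomerate(cohort, "genus")
  sel <- select_scaling_factor(agg$counts, agg$metadata, K = 6L,
                               S_grid = c(10L, 1000L), iterations = 150L,
                               burn_in = 50L, thin = 10L, seed = 6L)
  expect_true(sel$S %in% c(10L, 1000L))
  diag10 <- sel$diagnostics[sel$diagnostics$S == 10, ]
  diag1000 <- sel$diagnostics[sel$diagnostics$S == 1000, ]
  expect_lt(diag10$silhouette_plaque + diag10$silhouette_abscess,
            diag1000$silhouette_plaque + diag1000$silhouette_abscess)
  expect_equal(sel$S, 1000L)
  # reproducible at fixed seed
  sel2 <- select_scaling_factor(agg$counts, agg$metadata, K = 6L,
                                S_grid = c(10L, 1000L), iterations = 150L,
                                burn_in = 50L, thin = 10L, seed = 6L)
  expect_identical(sel$diagnostics, sel2$diagnostics)
})

test_that("topic-type association classifies extremes and is permutation-equivariant", {
  # hand-built model: topic 1 always higher in plaque, topic 2 constant
  n <- 12
  samples <- as.vector(rbind(sprintf("P%02d_plaque", 1:n),
                             sprintf("P%02d_abscess", 1:n)))
  gamma <- matrix(0, nrow = 2 * n, ncol = 3,
                  dimnames = list(samples, paste0("topic_", 1:3)))
  plq <- grepl("plaque", samples)
  jitter <- rep(seq_len(n) * 1e-3, each = 2)  # distinct |differences|
  gamma[plq, 1] <- 0.6 + jitter[plq]; gamma[!plq, 1] <- 0.2
  gamma[, 2] <- 0.2
  gamma[, 3] <- 1 - gamma[, 1] - gamma[, 2]
  md <- data.frame(sample_id = samples,
                   patient_id = rep(sprintf("P%02d", 1:n), each = 2),
                   specimen_type = rep(c("plaque", "abscess"), n))
  model <- structure(list(K = 3L, gamma = gamma,
                          beta = matrix(1 / 4, 3, 4,
                                        dimnames = list(paste0("topic_", 1:3),
                                                        letters[1:4]))),
                     class = "lda_model")
  assoc <- topic_type_association(model, md)
  expect_equal(assoc$class, c("plaque", "shared", "abscess"))
  expect_equal(assoc$p[1], 2 / 2^12)
  expect_equal(assoc$p[2], 1)
  # permuting topic indices permutes the classes identically
  perm <- c(3, 1, 2)
  model2 <- model
  model2$gamma <- model$gamma[, perm]
  colnames(model2$gamma) <- paste0("topic_", 1:3)
  assoc2 <- topic_type_association(model2, md)
  expect_equal(assoc2$class, assoc$class[perm])
})

test_that("topic drivers are beta-sorted with name tie-breaks and match a brute sort", {
  beta <- rbind(c(0.7, 0.2, 0.1), c(1 / 3, 1 / 3, 1 / 3))
  dimnames(beta) <- list(c("topic_1", "topic_2"), c("x", "a", "b"))
  model <- structure(list(K = 2L, beta = beta), class = "lda_model")
  drv <- topic_drivers(model, top_n = 3L)
  expect_equal(drv$taxon[drv$topic == "topic_1"], c("x", "a", "b"))
  expect_equal(drv$taxon[drv$topic == "topic_2"], c("a", "b", "x"))
  withr::local_seed(52)
  rb <- matrix(runif(40), nrow = 4)
  rb <- rb / rowSums(rb)
  dimnames(rb) <- list(paste0("topic_", 1:4), sprintf("t%02d", 1:10))
  m2 <- structure(list(K = 4L, beta = rb), class = "lda_model")
  drv2 <- topic_drivers(m2, top_n = 10L)
  for (k in 1:4) {
    got <- drv2$beta[drv2$topic == paste0("topic_", k)]
    expect_equal(got, sort(rb[k, ], decreasing = TRUE), ignore_attr = TRUE)
  }
})

test_that("gamma embedding separates separable groups and is seed-deterministic", {
  n <- 10
  samples <- as.vector(rbind(sprintf("P%02d_plaque", 1:n),
                             sprintf("P%02d_abscess", 1:n)))
  gamma <- matrix(0.01, nrow = 2 * n, ncol = 2,
                  dimnames = list(samples, c("topic_1", "topic_2")))
  plq <- grepl("plaque", samples)
  gamma[plq, 1] <- 0.99; gamma[plq, 2] <- 0.01
  gamma[!plq, 1] <- 0.01; gamma[!plq, 2] <- 0.99
  md <- data.frame(sample_id = samples,
                   patient_id = rep(sprintf("P%02d", 1:n), each = 2),
                   specimen_type = rep(c("plaque", "abscess"), n))
  model <- structure(list(K = 2L, gamma = gamma), class = "lda_model")
  emb <- embed_gamma(model, md, seed = 7L, n_neighbors = 5L)
  expect_gte(min(emb$silhouette), 0.9)
  emb2 <- embed_gamma(model, md, seed = 7L, n_neighbors = 5L)
  expect_identical(emb$coordinates, emb2$coordinates)
  tiny <- structure(list(K = 2L, gamma = gamma[1:3, ]), class = "lda_model")
  expect_error(embed_gamma(tiny, md), "4 samples")
})
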