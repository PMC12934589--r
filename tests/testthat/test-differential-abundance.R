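test_that("per-taxon paired wilcoxon flags a consistent 8-pair enrichment", {
  cohort <- toy_paired_cohort(n_taxa = 6, n_pairs = 8, effect_taxa = 1,
                              effect_size = 300)
  rep <- paired_wilcoxon_per_taxon(cohort, rank = "asv")
  row <- rep[rep$taxon == "t01", ]
  expect_equal(row$p, 2 / 256)  # all 8 pairs higher in plaque
  expect_equal(row$direction, "plaque")
  expect_gt(row$effect, 0)
})

test_that("degenerate taxa get p = 1 and undefined direction", {
  cohort <- toy_paired_cohort(n_taxa = 4, n_pairs = 6)
  counts <- cohort$counts
  counts["t01", ] <- 0L
  md <- cohort$metadata; md$library_size <- NULL
  cohort2 <- paired_cohort(counts, md, cohort$taxonomy)
  rep <- paired_wilcoxon_per_taxon(cohort2, rank = "asv")
  row <- rep[rep$taxon == "t01", ]
  expect_equal(row$p, 1)
  expect_equal(row$effect, 0)
  expect_true(is.na(row$direction))
})

test_that("top-k ranking orders significant taxa by |effect| with brute-force agreement", {
  rep <- data.frame(taxon = c("a", "b", "c", "d"),
                    effect = c(0.10, -0.20, 0.05, 0.5),
                    q = c(0.01, 0.01, 0.01, 0.4),
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(top <- top_k_by_median_difference(rep, k = 15), "3 significant")
  expect_equal(top$taxon, c("b", "a", "c"))
  withr::local_seed(21)
  for (i in 1:5) {
    n <- 30
    rnd <- data.frame(taxon = sprintf("t%02d", 1:n),
                      effect = round(rnorm(n), 2),
                      q = round(runif(n, 0, 0.1), 3))
    rnd$significant <- rnd$q < 0.05
    got <- suppressWarnings(top_k_by_median_difference(rnd, k = 10))
    sig <- rnd[rnd$q < 0.05, ]
    ref <- sig[order(-abs(sig$effect), sig$q, sig$taxon), ]
    expect_equal(got$taxon, head(ref$taxon, 10))
  }
})

test_that("enrichment tallies sum to the pair count and match a hand tally", {
  cohort <- toy_paired_cohort(n_taxa = 5, n_pairs = 7, effect_taxa = 2,
                              effect_size = 400)
  tal <- enrichment_tallies(cohort, rank = "asv")
  expect_true(all(tal$n_plaque_higher + tal$n_abscess_higher + tal$n_tied == 7))
  expect_equal(tal$n_plaque_higher[tal$taxon == "t02"], 7)
  # absent taxon ties in every pair
  counts <- cohort$counts; counts["t05", ] <- 0L
  md <- cohort$metadata; md$library_size <- NULL
  tal2 <- enrichment_tallies(paired_cohort(counts, md, cohort$taxonomy),
                             rank = "asv")
  expect_equal(tal2[tal2$taxon == "t05", c("n_plaque_higher", "n_abscess_higher",
                                           "n_tied")],
               data.frame(n_plaque_higher = 0, n_abscess_higher = 0, n_tied = 7),
               ignore_attr = TRUE)
  ps <- oraltopics:::paired_split(tss(cohort$counts), cohort$metadata)
  hand <- rowSums(ps$plaque > ps$abscess)
  expect_equal(tal$n_plaque_higher, unname(hand))
})

test_that("the resampling engine calls an overwhelming separation significant for any seed", {
  n_pairs <- 10
  counts <- matrix(100L, nrow = 8, ncol = 2 * n_pairs)
  plq <- rep(c(TRUE, FALSE), n_pairs)
  counts[1, plq] <- 1000L   # ~10% in plaque
  counts[1, !plq] <- 0L     # absent in abscess
  dimnames(counts) <- list(
    sprintf("t%02d", 1:8),
    as.vector(rbind(sprintf("P%02d_plaque", 1:n_pairs),
                    sprintf("P%02d_abscess", 1:n_pairs))))
  md <- data.frame(sample_id = colnames(counts),
                   patient_id = rep(sprintf("P%02d", 1:n_pairs), each = 2),
                   specimen_type = rep(c("plaque", "abscess"), n_pairs))
  cohort <- paired_cohort(counts, md)
  for (seed in 1:5) {
    rep <- engine_clr_wilcoxon(cohort, rank = "asv", n_mc = 16, seed = seed)
    row <- rep[rep$taxon == "t01", ]
    expect_true(row$significant)
    expect_equal(row$direction, "plaque")
  }
})

test_that("resampling p estimates are Monte-Carlo stable across seed sets", {
  cohort <- agglomerate(std_filtered(), "genus")
  a <- engine_clr_wilcoxon(cohort, rank = "asv", n_mc = 128, seed = 101)
  b <- engine_clr_wilcoxon(cohort, rank = "asv", n_mc = 128, seed = 202)
  expect_lt(mean(abs(a$p - b$p)), 0.05)
  # same seed: bitwise identical
  a2 <- engine_clr_wilcoxon(cohort, rank = "asv", n_mc = 128, seed = 101)
  expect_identical(a$p, a2$p)
})

test_that("linear-model engine recovers the paired-difference mean exactly", {
  # 2-pair toy with css_log values {(p1: 2, a1: 1), (p2: 4, a2: 3)} -> coef 1
  vals <- matrix(c(2, 1, 4, 3), nrow = 1,
                 dimnames = list("t1", c("P1_plaque", "P1_abscess",
                                         "P2_plaque", "P2_abscess")))
  md <- data.frame(sample_id = colnames(vals),
                   patient_id = rep(c("P1", "P2"), each = 2),
                   specimen_type = rep(c("plaque", "abscess"), 2))
  type <- as.integer(md$specimen_type == "plaque")
  fit <- lm(vals[1, ] ~ type + factor(md$patient_id))
  expect_equal(unname(coef(fit)["type"]), 1.0)

  # engine coefficient equals the mean per-patient css_log difference
  cohort <- toy_paired_cohort(n_taxa = 6, n_pairs = 8, effect_taxa = 3,
                              effect_size = 200)
  rep <- engine_linear_model(cohort, rank = "asv")
  vals2 <- css_log(cohort$counts)
  ps <- oraltopics:::paired_split(vals2, cohort$metadata)
  expect_equal(rep$effect, unname(rowMeans(ps$plaque - ps$abscess)),
               tolerance = 1e-10)
  expect_true(rep$significant[rep$taxon == "t03"])
})

test_that("consensus tiers follow the 3/2/1 vote and demote direction conflicts", {
  mk <- function(sig, dir = c("plaque", "plaque", "plaque")) {
    data.frame(taxon = "x", significant = sig, direction = dir[1])
  }
  three <- list(a = mk(TRUE), b = mk(TRUE), c = mk(TRUE))
  expect_equal(consensus_tier(three)$tier, "high")
  three$c$significant <- FALSE
  expect_equal(consensus_tier(three)$tier, "medium")
  three$b$significant <- FALSE
  expect_equal(consensus_tier(three)$tier, "low")
  three$a$significant <- FALSE
  expect_equal(consensus_tier(three)$tier, "none")
  conflict <- list(a = mk(TRUE), b = mk(TRUE), c = mk(TRUE))
  conflict$b$direction <- "abscess"
  out <- consensus_tier(conflict)
  expect_equal(out$tier, "none")
  expect_true(out$direction_conflict)
  # union alignment: taxa absent from a method count as not significant
  uneven <- list(
    a = data.frame(taxon = c("x", "y"), significant = c(TRUE, TRUE),
                   direction = "plaque"),
    b = data.frame(taxon = "x", significant = TRUE, direction = "plaque"),
    c = data.frame(taxon = "x", significant = TRUE, direction = "plaque"))
  out2 <- consensus_tier(uneven)
  expect_equal(out2$tier[out2$taxon == "x"], "high")
  expect_equal(out2$tier[out2$taxon == "y"], "low")
})

test_that("within-pair label permutation yields few significant taxa on a null cohort", {
  sim <- simulate_cohort(null_config(seed = 31L))
  cohort <- filter_cohort(sim$cohort,
                          contaminants = sim$truth$contaminant_taxa)$cohort
  fracs <- withr::with_seed(32, {
    vapply(1:20, function(i) {
      md <- cohort$metadata
      flip <- sample(c(TRUE, FALSE), length(unique(md$patient_id)),
                     replace = TRUE)
      names(flip) <- unique(md$patient_id)
      swap <- flip[md$patient_id]
      md$specimen_type[swap] <- ifelse(
        md$specimen_type[swap] == "plaque", "abscess", "plaque")
      perm <- paired_cohort(cohort$counts, md, cohort$taxonomy)
      rep <- paired_wilcoxon_per_taxon(perm, rank = "genus")
      mean(rep$q < 0.05, na.rm = TRUE)
    }, numeric(1))
  })
  expect_lte(mean(fracs), 0.10)
})

test_that("resampling engine and plain wilcoxon agree in direction on shared calls", {
  cohort <- std_filtered()
  w <- paired_wilcoxon_per_taxon(cohort, rank = "genus")
  e <- engine_clr_wilcoxon(cohort, rank = "genus", n_mc = 32, seed = 41)
  both <- merge(w, e, by = "taxon", suffixes = c("_w", "_e"))
  shared <- both$significant_w & both$significant_e
  expect_gt(sum(shared), 0)
  expect_true(all(both$direction_w[shared] == both$direction_e[shared]))
})

test_that("truth-enriched taxa are recovered by the paired wilcoxon at species level", {
  sim <- std_sim()
  cohort <- filter_cohort(sim$cohort,
                          contaminants = sim$truth$contaminant_taxa)$cohort
  rep <- paired_wilcoxon_per_taxon(cohort, rank = "species")
  truth <- sim$truth$enriched_taxa
  rep_sub <- rep[match(names(truth), rep$taxon), ]
  ok <- rep_sub$significant & rep_sub$direction == truth
  expect_gte(mean(ok, na.rm = FALSE), 0.8)
})
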