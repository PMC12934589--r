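# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The standard synthetic study cohort: 25 pairs, 150 taxa, 6 topics
# (2 plaque / 1 abscess / 3 shared), topic concentration 0.05.
std_config <- function(seed = 1L) generator_config(seed = seed)

std_sim <- function() cached("std_sim", simulate_cohort(std_config()))

# The same cohort filtered of contaminants and blanks.
std_filtered <- function() cached("std_filtered", {
  sim <- std_sim()
  filter_cohort(sim$cohort, contaminants = sim$truth$contaminant_taxa)$cohort
})

# Null cohort: type_bias = 0.5 makes plaque and abscess exchangeable.
null_config <- function(seed = 1L) generator_config(type_bias = 0.5, seed = seed)

# Small deterministic paired count fixture: n_taxa x (2 * n_pairs) counts with
# both specimen types per patient; optionally a type effect on chosen taxa.
toy_paired_cohort <- function(n_taxa = 6, n_pairs = 6, seed = 99,
                              effect_taxa = integer(), effect_size = 50) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_taxa * 2 * n_pairs, lambda = 40),
                     nrow = n_taxa,
                     dimnames = list(
                       sprintf("t%02d", seq_len(n_taxa)),
                       as.vector(rbind(sprintf("P%02d_plaque", seq_len(n_pairs)),
                                       sprintf("P%02d_abscess", seq_len(n_pairs))))))
    if (length(effect_taxa)) {
      plq <- grepl("plaque", colnames(counts))
      counts[effect_taxa, plq] <- counts[effect_taxa, plq] + effect_size
    }
    md <- data.frame(
      sample_id = colnames(counts),
      patient_id = rep(sprintf("P%02d", seq_len(n_pairs)), each = 2),
      specimen_type = rep(c("plaque", "abscess"), n_pairs))
    tax <- data.frame(taxon_id = rownames(counts),
                      phylum = rep(c("PhyA", "PhyB"), length.out = n_taxa),
                      genus = sprintf("g%02d", ceiling(seq_len(n_taxa) / 2)),
                      species = rownames(counts))
    paired_cohort(counts, md, tax)
  })
}

# Brute-force two-sided signed-rank p-value by enumerating all sign patterns.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}
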