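#' Total-sum scaling (relative abundance)
#'
#' Divides every sample column by its total so each column sums to 1.
#'
#' @param counts Numeric matrix, taxa x samples, non-negative.
#' @return Numeric matrix of the same shape with `attr(,"transform") == "tss"`.
#' @export
tss <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("tss: zero-total sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  out <- sweep(counts, 2, totals, "/")
  attr(out, "transform") <- "tss"
  out
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = ln(x_i + pseudocount) - mean_j ln(x_j + pseudocount)` per sample
#' column. The half-count pseudocount is the conventional default for count
#' data; every column of the result sums to zero.
#'
#' @param counts Numeric matrix, taxa x samples.
#' @param pseudocount Positive offset added to every count before the log.
#' @return Numeric matrix with `attr(,"transform") == "clr"`.
#' @export
clr <- function(counts, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  lx <- log(as.matrix(counts) + pseudocount)
  out <- sweep(lx, 2, colMeans(lx), "-")
  attr(out, "transform") <- "clr"
  out
}

# Cumulative-sum scaling factors: per sample, the sum of counts at or below the
# chosen quantile of that sample's nonzero counts.  Dialect of CSS with a fixed
# quantile rather than an adaptive one.
css_factors <- function(counts, quantile = 0.5) {
  stopifnot(quantile > 0, quantile < 1)
  counts <- as.matrix(counts)
  vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    nz <- x[x > 0]
    if (length(nz) == 0L) {
      stop("css: sample '", colnames(counts)[j], "' has all-zero counts")
    }
    q <- stats::quantile(nz, probs = quantile, names = FALSE)
    sum(x[x <= q])
  }, numeric(1))
}

#' Cumulative-sum-scaled log abundance
#'
#' Per sample, counts are divided by the cumulative sum of counts up to the
#' `quantile`-th quantile of the sample's nonzero counts, multiplied by
#' `scale_const`, then mapped through `log(x + 1)` (natural log; see
#' [css_log10()] for the base-10 variant used by the resampling DA engine).
#'
#' @param counts Numeric matrix, taxa x samples.
#' @param quantile Quantile in (0,1) defining the cumulative scaling factor.
#' @param scale_const Multiplier applied after normalization.
#' @return Numeric matrix with `attr(,"transform") == "css_log"`.
#' @export
css_log <- function(counts, quantile = 0.5, scale_const = 1000) {
  s <- css_factors(counts, quantile)
  out <- log(sweep(as.matrix(counts), 2, s, "/") * scale_const + 1)
  attr(out, "transform") <- "css_log"
  out
}

#' @rdname css_log
#' @export
css_log10 <- function(counts, quantile = 0.5, scale_const = 1000) {
  s <- css_factors(counts, quantile)
  out <- log10(sweep(as.matrix(counts), 2, s, "/") * scale_const + 1)
  attr(out, "transform") <- "css_log10"
  out
}

#' Shannon diversity per sample
#'
#' `H = -sum(p * ln p)` over nonzero proportions, natural log.
#'
#' @param counts Numeric matrix, taxa x samples, positive column totals.
#' @return Named numeric vector, one value per sample.
#' @export
shannon <- function(counts) {
  p <- tss(counts)
  apply(p, 2, function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  })
}

#' Observed richness per sample
#'
#' Number of taxa with a nonzero count.
#'
#' @param counts Numeric matrix, taxa x samples.
#' @return Named integer vector, one value per sample.
#' @export
observed_richness <- function(counts) {
  apply(as.matrix(counts) > 0, 2, sum)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on a vector of paired differences. Zero
#' differences are dropped; absolute differences are mid-ranked. The exact
#' signed-rank null is used when `n_effective <= exact_max` and there are no
#' ties among the absolute differences, otherwise a normal approximation with
#' continuity and tie correction.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max Largest tie-free `n_effective` for which the exact null
#'   distribution is used.
#' @return List with `statistic` (positive-rank sum W), `n_effective`,
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), and `degenerate`
#'   (TRUE when every difference was zero, in which case `p_value` is 1).
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25L) {
  d <- diffs[is.finite(diffs) & diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n_effective = 0L, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= exact_max) {
    p <- 2 * min(stats::psignrank(W, n), 1 - stats::psignrank(W - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      return(list(statistic = W, n_effective = n, p_value = 1,
                  method = "degenerate", degenerate = TRUE))
    }
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = W, n_effective = n, p_value = p, method = method,
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return Numeric vector of adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("bh_fdr: p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}
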