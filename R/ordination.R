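#' Pairwise sample distances
#'
#' Bray-Curtis (`sum|x-y| / sum(x+y)`), binary Jaccard
#' (`1 - |intersection|/|union|` on nonzero supports), or Euclidean distances
#' between sample columns of an abundance matrix.
#'
#' @param am Numeric matrix, taxa x samples (e.g. output of [tss()] or
#'   [clr()]).
#' @param metric One of `"bray_curtis"`, `"jaccard"`, `"euclidean"`.
#' @return Symmetric samples x samples matrix with zero diagonal and
#'   `attr(,"metric")` set.
#' @export
distance_matrix <- function(am, metric = c("bray_curtis", "jaccard",
                                           "euclidean")) {
  metric <- match.arg(metric)
  x <- t(as.matrix(am))  # vegan expects samples as rows
  if (metric %in% c("bray_curtis", "jaccard")) {
    if (any(x < 0)) {
      stop(metric, " requires non-negative values (got negatives; use tss, ",
           "not clr, for this metric)")
    }
    if (metric == "bray_curtis") {
      zero <- rowSums(x) == 0
      if (any(zero)) {
        stop("bray_curtis undefined for zero-total sample(s): ",
             paste(rownames(x)[zero], collapse = ", "))
      }
    }
  }
  d <- switch(metric,
              bray_curtis = vegan::vegdist(x, method = "bray"),
              jaccard = vegan::vegdist(x, method = "jaccard", binary = TRUE),
              euclidean = stats::dist(x))
  m <- as.matrix(d)
  attr(m, "metric") <- metric
  m
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of the squared distance
#' matrix followed by eigendecomposition. Coordinates are built from positive
#' eigenvalues only; negative eigenvalues are reported but excluded from the
#' coordinates and from `percent_variance`. Each axis is oriented so its
#' largest-magnitude coordinate is positive.
#'
#' @param d Symmetric distance matrix (samples x samples).
#' @param n_axes Number of axes requested; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return List of class `ordination_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `percent_variance` (over positive
#'   eigenvalues, length = ncol(coordinates)).
#' @export
pcoa <- function(d, n_axes = 2L) {
  stopifnot(n_axes >= 1L)
  d <- as.matrix(d)
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; that case is
  # handled explicitly below
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                         eig = TRUE))
  eig <- cs$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > n_pos) {
    warning("requested ", n_axes, " axes but only ", n_pos,
            " positive eigenvalues; truncating")
    n_axes <- n_pos
  }
  coords <- cs$points[, seq_len(n_axes), drop = FALSE]
  # orient each axis so its largest-magnitude loading is positive
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  pct <- 100 * eig[seq_len(n_pos)] / sum(eig[seq_len(n_pos)])
  structure(list(coordinates = coords, eigenvalues = eig,
                 percent_variance = pct[seq_len(n_axes)]),
            class = "ordination_result")
}

#' Median silhouette width per group
#'
#' Standard silhouette `s = (b - a) / max(a, b)` per sample, where `a` is the
#' mean within-group distance (excluding self) and `b` the smallest mean
#' distance to another group. Singleton groups and samples with
#' `a = b = 0` get `s = 0`. Returns the median width per group.
#'
#' @param d Symmetric distance matrix.
#' @param groups Character/factor vector of group labels, one per sample (in
#'   `d`'s order), or named by sample id.
#' @return Named numeric vector: median silhouette width per group label.
#' @export
silhouette_by_group <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(groups)) && !is.null(rownames(d))) {
    groups <- groups[rownames(d)]
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  labs <- unique(groups)
  if (length(labs) < 2L) stop("silhouette requires at least two groups")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(groups == groups[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(labs, groups[i]), function(g) {
      mean(d[i, groups == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  vapply(stats::setNames(labs, labs), function(g) {
    stats::median(s[groups == g])
  }, numeric(1))
}

#' Spearman correlation of ordination axis 1 with library size
#'
#' Rank correlation (mid-ranks for ties) between the first ordination axis and
#' per-sample library size; a diagnostic that the leading axis reflects
#' biology rather than sequencing depth.
#'
#' @param ord An `ordination_result` from [pcoa()].
#' @param metadata Cohort metadata with `sample_id` and `library_size`.
#' @return Spearman's rho, or `NA` with `attr(,"flag") == "constant"` when
#'   either variable is constant.
#' @export
spearman_axis_vs_library <- function(ord, metadata) {
  ax <- ord$coordinates[, 1]
  lib <- metadata$library_size[match(rownames(ord$coordinates),
                                     metadata$sample_id)]
  if (anyNA(lib)) stop("metadata does not cover all ordinated samples")
  if (stats::sd(ax) == 0 || stats::sd(lib) == 0) {
    out <- NA_real_
    attr(out, "flag") <- "constant"
    return(out)
  }
  stats::cor(ax, lib, method = "spearman")
}

#' Transform-by-distance ordination selection sweep
#'
#' Evaluates every (transform, metric) combination by PCoA: |Spearman rho| of
#' axis 1 with library size, per-specimen-type median silhouette width on the
#' full distance matrix, and percent variance of the first two axes.
#' Combinations are ranked lexicographically by ascending |rho| then
#' descending sum of per-type silhouettes; percent variance is reported but
#' not used for ranking. Invalid combinations (e.g. Bray-Curtis on CLR values,
#' which are negative) are skipped with a reason.
#'
#' @param cohort A filtered `paired_cohort` (no blanks).
#' @param transforms Subset of `c("tss", "clr")` (`"raw"` also accepted).
#' @param metrics Subset of `c("bray_curtis", "jaccard", "euclidean")`.
#' @return Data frame (one row per evaluated combination) with columns
#'   `transform`, `metric`, `rho`, `silhouette_plaque`, `silhouette_abscess`,
#'   `pct_axis1`, `pct_axis2`, `rank`; skipped combinations carry NA metrics
#'   and a `skip_reason`. The top combination is row `rank == 1`.
#' @export
ordination_sweep <- function(cohort,
                             transforms = c("tss", "clr"),
                             metrics = c("bray_curtis", "jaccard",
                                         "euclidean")) {
  stopifnot(length(transforms) > 0, length(metrics) > 0)
  md <- cohort$metadata
  grid <- expand.grid(transform = transforms, metric = metrics,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- grid$transform[i]; me <- grid$metric[i]
    am <- switch(tr,
                 raw = cohort$counts,
                 tss = tss(cohort$counts),
                 clr = clr(cohort$counts),
                 stop("unknown transform: ", tr))
    res <- tryCatch({
      d <- distance_matrix(am, me)
      ord <- pcoa(d, n_axes = 2L)
      sil <- silhouette_by_group(d, stats::setNames(md$specimen_type,
                                                    md$sample_id))
      rho <- spearman_axis_vs_library(ord, md)
      data.frame(transform = tr, metric = me, rho = as.numeric(rho),
                 silhouette_plaque = sil[["plaque"]],
                 silhouette_abscess = sil[["abscess"]],
                 pct_axis1 = ord$percent_variance[1],
                 pct_axis2 = ifelse(length(ord$percent_variance) > 1,
                                    ord$percent_variance[2], NA_real_),
                 skip_reason = NA_character_)
    }, error = function(e) {
      data.frame(transform = tr, metric = me, rho = NA_real_,
                 silhouette_plaque = NA_real_, silhouette_abscess = NA_real_,
                 pct_axis1 = NA_real_, pct_axis2 = NA_real_,
                 skip_reason = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  ok <- is.na(tab$skip_reason)
  sil_sum <- tab$silhouette_plaque + tab$silhouette_abscess
  tab$rank <- NA_integer_
  ord <- order(abs(tab$rho[ok]), -sil_sum[ok])
  tab$rank[ok][ord] <- seq_along(ord)
  tab[order(tab$rank), , drop = FALSE]
}

#' Hierarchical clustering of samples by abundance correlation
#'
#' Average-linkage clustering of samples on the distance
#' `1 - Pearson r` between log-transformed relative-abundance columns
#' (`ln(tss + pseudocount)`, pseudocount = half the smallest nonzero relative
#' abundance in the matrix).
#'
#' @param counts Numeric matrix, taxa x samples (raw counts; TSS is applied
#'   internally).
#' @return An [stats::hclust] object.
#' @export
hierarchical_cluster <- function(counts) {
  if (ncol(counts) < 2L) stop("clustering requires at least two samples")
  p <- tss(counts)
  pseudo <- min(p[p > 0]) / 2
  lp <- log(p + pseudo)
  sds <- apply(lp, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample column(s): ",
         paste(colnames(lp)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(lp)
  stats::hclust(stats::as.dist(d), method = "average")
}
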