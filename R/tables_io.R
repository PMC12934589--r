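#' Paired-cohort container
#'
#' Bundles a taxa x samples count matrix, per-sample metadata, and a taxonomy
#' lineage table into a single validated object.
#'
#' @param counts Non-negative integer matrix, taxa x samples, with row and
#'   column names.
#' @param metadata Data frame with columns `sample_id`, `patient_id`,
#'   `specimen_type` (one of plaque/abscess/blank) and optionally
#'   `library_size` (recomputed from `counts`; a mismatch is an error).
#' @param taxonomy Data frame with columns `taxon_id`, `phylum`, `genus`,
#'   `species`, covering every row of `counts`. May be `NULL`.
#' @param require_pairing Validate that every non-blank patient contributes
#'   exactly one plaque and one abscess sample.
#' @return An object of class `paired_cohort`: a list with elements `counts`,
#'   `metadata`, `taxonomy`.
#' @export
paired_cohort <- function(counts, metadata, taxonomy = NULL,
                          require_pairing = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  metadata <- as.data.frame(metadata)
  need <- c("sample_id", "patient_id", "specimen_type")
  if (!all(need %in% names(metadata))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids in metadata")
  if (!setequal(metadata$sample_id, colnames(counts))) {
    stop("metadata sample ids do not match count table columns")
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  bad_type <- setdiff(unique(metadata$specimen_type),
                      c("plaque", "abscess", "blank"))
  if (length(bad_type)) {
    stop("unknown specimen_type value(s): ", paste(bad_type, collapse = ", "))
  }
  lib <- unname(colSums(counts))
  if (!is.null(metadata$library_size)) {
    off <- which(metadata$library_size != lib)
    if (length(off)) {
      stop("declared library_size mismatches column sum for sample(s): ",
           paste(metadata$sample_id[off], collapse = ", "))
    }
  }
  metadata$library_size <- lib
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    needt <- c("taxon_id", "phylum", "genus", "species")
    if (!all(needt %in% names(taxonomy))) {
      stop("taxonomy must contain columns: ", paste(needt, collapse = ", "))
    }
    missing <- setdiff(rownames(counts), taxonomy$taxon_id)
    if (length(missing)) {
      stop("taxa missing from taxonomy: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  if (require_pairing) validate_pairing(metadata)
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "paired_cohort")
}

validate_pairing <- function(metadata) {
  md <- metadata[metadata$specimen_type != "blank", , drop = FALSE]
  tab <- table(md$patient_id, md$specimen_type)
  want <- c("abscess", "plaque")
  if (!all(want %in% colnames(tab))) {
    stop("cohort lacks one of the specimen types plaque/abscess")
  }
  bad <- rownames(tab)[tab[, "plaque"] != 1L | tab[, "abscess"] != 1L]
  if (length(bad)) {
    stop("patients without exactly one plaque and one abscess sample: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
#' @method print paired_cohort
print.paired_cohort <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "paired_cohort: %d taxa x %d samples (%d patients, %d blanks)\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(md$patient_id[md$specimen_type != "blank"])),
    sum(md$specimen_type == "blank")))
  invisible(x)
}

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read the pipeline's three input tables
#'
#' Reads the tab-delimited count, metadata and taxonomy tables (UTF-8, header
#' row, `#` comment lines ignored) and returns a validated [paired_cohort].
#' The count table's first column holds taxon ids; remaining columns are
#' samples.
#'
#' @param counts_path,metadata_path,taxonomy_path File paths.
#' @param require_pairing Passed to [paired_cohort()].
#' @return A `paired_cohort`.
#' @export
read_tables <- function(counts_path, metadata_path, taxonomy_path = NULL,
                        require_pairing = TRUE) {
  ctab <- read_tsv_strict(counts_path, "counts")
  if (ncol(ctab) < 2) stop("count table needs a taxon id column plus samples")
  taxa <- as.character(ctab[[1]])
  mat <- as.matrix(ctab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(ctab[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric count value near row ", bad[1], ", column ", bad[2] + 1,
         " of ", counts_path)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing count at taxon '%s', sample '%s'",
                 taxa[bad[1]], colnames(mat)[bad[2]]))
  }
  rownames(mat) <- taxa
  md <- read_tsv_strict(metadata_path, "metadata")
  tax <- if (!is.null(taxonomy_path)) read_tsv_strict(taxonomy_path, "taxonomy")
  paired_cohort(mat, md, tax, require_pairing = require_pairing)
}

#' Write a cohort's tables to TSV
#'
#' Inverse of [read_tables()]; round-trips bit-identically for integer counts.
#'
#' @param cohort A `paired_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_tables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"))
  ctab <- data.frame(taxon_id = rownames(cohort$counts),
                     cohort$counts, check.names = FALSE)
  utils::write.table(ctab, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$taxonomy)) {
    utils::write.table(cohort$taxonomy, paths["taxonomy"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[c("counts", "metadata")]
  }
  invisible(paths)
}

#' Cohort filtering
#'
#' Applies the cohort-retention rules in order: (1) drop taxa on the supplied
#' contaminant list; (2) drop taxa whose nonzero counts occur only in blank
#' samples; (3) drop the blank samples; (4) drop any patient pair where either
#' member's total reads are at or below `min_reads` (strict `> min_reads`
#' retention). Every removal is recorded with its rule.
#'
#' @param cohort A `paired_cohort` (blanks flagged via `specimen_type`).
#' @param contaminants Character vector of contaminant taxon ids.
#' @param min_reads Read-depth retention threshold (strictly greater-than).
#' @return List with the filtered `cohort` and `log`, a data.frame with
#'   columns `entity` (taxon/sample), `id`, `rule`.
#' @export
filter_cohort <- function(cohort, contaminants = character(), min_reads = 1000) {
  counts <- cohort$counts
  md <- cohort$metadata
  log <- list()
  note <- function(entity, ids, rule) {
    if (length(ids)) {
      log[[length(log) + 1L]] <<- data.frame(entity = entity, id = ids,
                                             rule = rule)
    }
  }

  drop_tax <- intersect(rownames(counts), contaminants)
  note("taxon", drop_tax, "contaminant_list")
  counts <- counts[setdiff(rownames(counts), drop_tax), , drop = FALSE]

  blank_ids <- md$sample_id[md$specimen_type == "blank"]
  nonblank <- setdiff(colnames(counts), blank_ids)
  in_nonblank <- rowSums(counts[, nonblank, drop = FALSE]) > 0
  anywhere <- rowSums(counts) > 0
  blank_only <- rownames(counts)[anywhere & !in_nonblank]
  note("taxon", blank_only, "blank_only")
  counts <- counts[setdiff(rownames(counts), blank_only), , drop = FALSE]

  note("sample", blank_ids, "blank_sample")
  counts <- counts[, nonblank, drop = FALSE]
  md <- md[md$specimen_type != "blank", , drop = FALSE]

  md$library_size <- colSums(counts)[md$sample_id]
  shallow <- md$sample_id[md$library_size <= min_reads]
  bad_patients <- unique(md$patient_id[md$sample_id %in% shallow])
  drop_samp <- md$sample_id[md$patient_id %in% bad_patients]
  note("sample", drop_samp, "min_reads_pair")
  counts <- counts[, setdiff(colnames(counts), drop_samp), drop = FALSE]
  md <- md[!md$sample_id %in% drop_samp, , drop = FALSE]

  if (ncol(counts) == 0L || nrow(counts) == 0L) {
    stop("empty cohort after filtering")
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(entity = character(), id = character(), rule = character())
  tax <- cohort$taxonomy
  if (!is.null(tax)) tax <- tax[tax$taxon_id %in% rownames(counts), , drop = FALSE]
  list(cohort = paired_cohort(counts, md, tax), log = log)
}

rank_parent <- c(species = "genus", genus = "phylum", phylum = "root")

#' Agglomerate counts at a taxonomic rank
#'
#' Sums counts over taxa sharing the rank label. Taxa unclassified at the rank
#' (empty, `NA`, or a label starting with "unclassified") are pooled under a
#' single placeholder per parent lineage, so per-sample totals are preserved
#' exactly.
#'
#' @param cohort A `paired_cohort` with taxonomy.
#' @param rank One of `"phylum"`, `"genus"`, `"species"`.
#' @return A `paired_cohort` whose taxa are rank labels (taxonomy truncated to
#'   the ranks at or above `rank`).
#' @export
agglomerate <- function(cohort, rank = c("genus", "phylum", "species")) {
  rank <- match.arg(rank)
  tax <- cohort$taxonomy
  if (is.null(tax)) stop("agglomerate requires a taxonomy table")
  lab <- as.character(tax[[rank]])
  uncl <- is.na(lab) | lab == "" | grepl("^unclassified", lab, ignore.case = TRUE)
  parent_rank <- rank_parent[[rank]]
  parent <- if (parent_rank == "root") rep("root", nrow(tax)) else
    as.character(tax[[parent_rank]])
  parent[is.na(parent) | parent == ""] <- "unknown"
  lab[uncl] <- paste0("unclassified_", parent[uncl])
  groups <- factor(lab, levels = unique(lab))
  agg <- rowsum(cohort$counts, groups, reorder = FALSE)
  new_tax <- data.frame(taxon_id = levels(groups),
                        phylum = NA_character_, genus = NA_character_,
                        species = NA_character_)
  keep_ranks <- switch(rank, phylum = "phylum",
                       genus = c("phylum", "genus"),
                       species = c("phylum", "genus", "species"))
  first <- tax[match(levels(groups), lab), , drop = FALSE]
  for (r in keep_ranks) new_tax[[r]] <- as.character(first[[r]])
  new_tax[[rank]] <- levels(groups)
  # pairing status is inherited from the input; no need to re-validate
  paired_cohort(agg, cohort$metadata, new_tax, require_pairing = FALSE)
}
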