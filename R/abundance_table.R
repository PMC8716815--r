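#' Abundance tables with sample metadata
#'
#' An `abundance_table` couples a non-negative integer count matrix
#' (taxa as rows, samples as columns) with a per-sample metadata table.
#' The metadata carries the study design factors used throughout the
#' pipeline: `site` (e.g. control vs radiation-stressed), `tissue`
#' (aerial vs root), `season` and `replicate`.
#'
#' @param counts numeric matrix of non-negative counts, taxa x samples,
#'   with unique row names (taxon ids) and column names (sample ids).
#' @param metadata data.frame with one row per sample. Must contain a
#'   `sample_id` column (or row names) matching the columns of `counts`;
#'   typical columns are `site`, `tissue`, `season`, `replicate`.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix) and `metadata` (data.frame, one row per
#'   column of `counts`, in the same order).
#' @examples
#' counts <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'                  dimnames = list(paste0("t", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), site = "control",
#'                    tissue = "root", season = "spring", replicate = 1:2)
#' abundance_table(counts, meta)
#' @export
abundance_table <- function(counts, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_endo("counts must have taxon row names and sample column names",
              class = "format_error")
  if (anyDuplicated(rownames(counts)))
    stop_endo("duplicate taxon ids in count table", class = "format_error")
  if (anyDuplicated(colnames(counts)))
    stop_endo("duplicate sample ids in count table", class = "format_error")
  if (!is.numeric(counts) || anyNA(counts))
    stop_endo("counts must be numeric and non-missing", class = "format_error")
  if (any(counts < 0))
    stop_endo("negative counts are not allowed", class = "format_error")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop_endo("counts must be integers", class = "format_error")
  storage.mode(counts) <- "integer"

  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = colnames(counts),
                           stringsAsFactors = FALSE)
  } else {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) {
      if (is.null(rownames(metadata)))
        stop_endo("metadata needs a sample_id column or row names",
                  class = "validation_error")
      metadata$sample_id <- rownames(metadata)
    }
    metadata$sample_id <- as.character(metadata$sample_id)
    missing <- setdiff(colnames(counts), metadata$sample_id)
    if (length(missing))
      stop_endo("metadata missing for sample(s): %s",
                paste(missing, collapse = ", "), class = "validation_error")
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                         drop = FALSE]
  }
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  vars <- setdiff(names(x$metadata), "sample_id")
  if (length(vars))
    cat("metadata:", paste(vars, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Subset an abundance table
#'
#' `x[taxa, samples]` subsets counts and keeps the metadata aligned to the
#' retained samples. Indices follow the usual matrix conventions.
#'
#' @param x an `abundance_table`.
#' @param i,j taxon and sample indices (logical, integer or character).
#' @param ... ignored.
#' @export
`[.abundance_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  meta <- x$metadata[match(colnames(counts), x$metadata$sample_id), ,
                     drop = FALSE]
  abundance_table(counts, meta)
}

#' Select samples of an abundance table by metadata values
#'
#' @param x an `abundance_table`.
#' @param ... named filters, e.g. `site = "control"`, `season = "spring"`.
#'   Each value may be a vector; samples matching all filters are kept.
#' @param drop_empty_taxa drop taxa with zero counts in the retained samples.
#' @return an `abundance_table`.
#' @export
subset_samples <- function(x, ..., drop_empty_taxa = FALSE) {
  stopifnot(inherits(x, "abundance_table"))
  filters <- list(...)
  keep <- rep(TRUE, ncol(x$counts))
  for (nm in names(filters)) {
    if (!nm %in% names(x$metadata))
      stop_endo("metadata column '%s' not found", nm,
                class = "validation_error")
    keep <- keep & (x$metadata[[nm]] %in% filters[[nm]])
  }
  out <- x[, keep]
  if (drop_empty_taxa) out <- out[rowSums(out$counts) > 0L, ]
  out
}

#' Read a taxa-by-sample count table
#'
#' Reads TSV/CSV tables (first column taxon ids, header row sample ids;
#' dialect auto-detected from the file extension) or BIOM (JSON flavour)
#' files, optionally joining a sample metadata table.
#'
#' @param path path to the count table.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"biom"`.
#' @param metadata optional metadata: a data.frame or the path of a TSV/CSV
#'   file with columns `sample_id`, `site`, `tissue`, `season`, `replicate`.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(path, format = c("auto", "tsv", "csv", "biom"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_endo("file not found: %s", path, class = "format_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", json = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_endo("reading BIOM files requires the 'biomformat' package",
                class = "format_error")
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    sep <- if (format == "csv") "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "\"", comment.char = "")
    if (ncol(raw) < 2)
      stop_endo("count table needs a taxon id column plus >=1 sample",
                class = "format_error")
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids))
      stop_endo("duplicate taxon ids in %s", path, class = "format_error")
    counts <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(counts))
      stop_endo("non-numeric counts in %s", path, class = "format_error")
    rownames(counts) <- ids
  }
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  abundance_table(counts, metadata)
}

#' Read a sample metadata table (TSV or CSV)
#'
#' @param path path to a delimited file with a `sample_id` column.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"")
}

#' Write an abundance table (and its metadata) to delimited files
#'
#' @param x an `abundance_table`.
#' @param path output path for the count table (TSV unless it ends in .csv).
#' @param metadata_path optional path for the metadata table.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$metadata, metadata_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Remove low-abundance taxa
#'
#' Drops taxa whose dataset-wide total count falls below `min_total_count`
#' (the default removes singletons and doubletons) and taxa whose
#' dataset-wide relative abundance (taxon total / grand total) is below
#' `min_rel_abund`. The sample set is unchanged. Thresholds are evaluated
#' on the table as given, so filtering is intended to precede rarefaction.
#'
#' @param x an `abundance_table`.
#' @param min_total_count keep taxa with total count >= this value.
#' @param min_rel_abund keep taxa with dataset-wide relative abundance
#'   >= this value; in `[0, 1)`.
#' @return a filtered `abundance_table`.
#' @export
filter_taxa <- function(x, min_total_count = 3, min_rel_abund = 0.001) {
  stopifnot(inherits(x, "abundance_table"),
            min_total_count >= 0, min_rel_abund >= 0, min_rel_abund < 1)
  totals <- rowSums(x$counts)
  grand <- sum(as.numeric(totals))
  keep <- totals >= min_total_count & (totals / grand) >= min_rel_abund
  if (!any(keep))
    stop_endo("all taxa removed by filtering", class = "filter_error")
  x[keep, ]
}

#' Rarefy samples to an even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total is below `depth` are dropped with a warning;
#' it is an error if no sample reaches the depth.
#'
#' @param x an `abundance_table`.
#' @param depth target reads per sample (>= 1). The default, `"min"`, uses
#'   the minimum sample sum (the convention used when all samples are kept).
#' @param seed integer seed for reproducible subsampling.
#' @return a rarefied `abundance_table`; every column sums to `depth`.
#' @export
rarefy_table <- function(x, depth = "min", seed = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  totals <- colSums(x$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  stopifnot(depth >= 1L)
  low <- totals < depth
  if (all(low))
    stop_endo("no sample reaches rarefaction depth %d", depth,
              class = "rarefaction_error")
  if (any(low))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(low), depth,
                    paste(colnames(x$counts)[low], collapse = ", ")))
  x <- x[, !low]
  counts <- with_seed(seed, {
    # rrarefy warns whenever the smallest count exceeds 1; that check is
    # about coverage estimation and irrelevant to plain subsampling
    withCallingHandlers(
      t(vegan::rrarefy(t(x$counts), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  storage.mode(counts) <- "integer"
  abundance_table(counts, x$metadata)
}

#' Per-taxon mean relative abundance and occupancy
#'
#' Computes the two per-taxon inputs of the neutral community model:
#' `p`, the mean across samples of the within-sample relative abundance,
#' and `freq`, the occupancy (fraction of samples where the taxon is
#' detected, count > 0).
#'
#' @param x an `abundance_table` with at least one sample; every sample
#'   must have a positive total (rarefy/validate first).
#' @return an object of class `taxon_stats`: list with `taxon_id`, `p`,
#'   `freq` and `n_samples`.
#' @export
taxon_stats <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (ncol(x$counts) < 1L)
    stop_endo("need at least one sample", class = "validation_error")
  totals <- colSums(x$counts)
  if (any(totals == 0))
    stop_endo("sample(s) with zero total: %s",
              paste(colnames(x$counts)[totals == 0], collapse = ", "),
              class = "validation_error")
  rel <- sweep(x$counts, 2, totals, "/")
  structure(list(taxon_id = rownames(x$counts),
                 p = rowMeans(rel),
                 freq = rowMeans(x$counts > 0L),
                 n_samples = ncol(x$counts)),
            class = "taxon_stats")
}

#' @export
print.taxon_stats <- function(x, ...) {
  cat(sprintf("taxon_stats: %d taxa over %d samples\n",
              length(x$p), x$n_samples))
  invisible(x)
}
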