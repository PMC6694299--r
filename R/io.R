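#' @keywords internal
"_PACKAGE"

#' Study group labels, in time order
#'
#' The four study groups: sham baseline and 2, 14 and 60 days post-injury.
#' @export
tg_groups <- function() c("sham", "d2", "d14", "d60")

#' Gene class labels
#'
#' Panel gene classes: endogenous targets plus the three nCounter control
#' classes (housekeeping genes, spiked positive controls, empty negative
#' controls).
#' @export
tg_gene_classes <- function() c("endogenous", "housekeeping", "positive", "negative")

#' Supported pairwise comparisons against sham
#' @export
tg_comparisons <- function() c("d2_vs_sham", "d14_vs_sham", "d60_vs_sham")

#' Construct and validate a count matrix
#'
#' Container for a raw targeted-panel count experiment: an integer matrix of
#' counts (genes as rows, samples as columns) together with a gene-class label
#' per row and a study-group label per column.
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param gene_class character vector, one of [tg_gene_classes()] per row.
#' @param group character vector, one of [tg_groups()] per column.
#' @return an object of class `tg_counts` with elements `counts`,
#'   `gene_class` (named character) and `group` (factor with the group levels
#'   in time order).
#' @export
count_matrix <- function(counts, gene_class, group) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have row names (gene ids) and column names (sample ids)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("count for gene '%s', sample '%s' is not a nonnegative integer (value: %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, 1], bad[1, 2]])))
  }
  if (length(gene_class) != nrow(counts))
    stop("`gene_class` must have one entry per gene")
  if (!all(gene_class %in% tg_gene_classes()))
    stop("unknown gene class: ", paste(setdiff(gene_class, tg_gene_classes()), collapse = ", "))
  if (length(group) != ncol(counts))
    stop("`group` must have one entry per sample")
  if (!all(group %in% tg_groups()))
    stop("unknown group label: ", paste(setdiff(group, tg_groups()), collapse = ", "))
  structure(list(
    counts = matrix(as.integer(round(counts)), nrow(counts), ncol(counts),
                    dimnames = dimnames(counts)),
    gene_class = stats::setNames(as.character(gene_class), rownames(counts)),
    group = factor(group, levels = tg_groups())
  ), class = "tg_counts")
}

#' @export
print.tg_counts <- function(x, ...) {
  cat(sprintf("tg_counts: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat("  gene classes:", paste(sprintf("%s=%d", names(table(x$gene_class)),
                                       table(x$gene_class)), collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read a count experiment from delimited text files
#'
#' Expects three tab-delimited files with header rows: the count table (first
#' column gene id, remaining columns one per sample), a gene annotation with
#' columns `gene_id` and `gene_class`, and a sample sheet with columns
#' `sample_id` and `group`. Row and column order of the count table is
#' preserved.
#'
#' @param count_path,annotation_path,sample_sheet_path file paths.
#' @param sep field delimiter (default tab).
#' @return a validated [count_matrix()].
#' @export
read_count_table <- function(count_path, annotation_path, sample_sheet_path, sep = "\t") {
  for (p in c(count_path, annotation_path, sample_sheet_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.table(count_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1]])
  cnt <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(cnt) <- "double"
  rownames(cnt) <- gene_ids
  ann <- utils::read.table(annotation_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "gene_class") %in% names(ann)))
    stop("annotation must have columns gene_id, gene_class")
  miss <- setdiff(gene_ids, ann$gene_id)
  if (length(miss) > 0)
    stop("gene(s) missing from annotation: ", paste(miss, collapse = ", "))
  cls <- ann$gene_class[match(gene_ids, ann$gene_id)]
  sheet <- utils::read.table(sample_sheet_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet must have columns sample_id, group")
  miss <- setdiff(colnames(cnt), sheet$sample_id)
  if (length(miss) > 0)
    stop("sample(s) missing from sample sheet: ", paste(miss, collapse = ", "))
  grp <- sheet$group[match(colnames(cnt), sheet$sample_id)]
  count_matrix(cnt, cls, grp)
}

#' Write a count experiment to delimited text files
#'
#' Inverse of [read_count_table()]: writes `counts.tsv`, `annotation.tsv`
#' and `samples.tsv` into a directory.
#'
#' @param m a `tg_counts` object.
#' @param dir output directory (created if absent).
#' @param sep field delimiter.
#' @return invisibly, the three file paths.
#' @export
write_count_table <- function(m, dir, sep = "\t") {
  stopifnot(inherits(m, "tg_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "annotation.tsv", "samples.tsv"))
  cnt <- data.frame(gene_id = rownames(m$counts), m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_table(cnt, paths[1], sep = sep)
  write_table(data.frame(gene_id = rownames(m$counts),
                         gene_class = unname(m$gene_class)), paths[2], sep = sep)
  write_table(data.frame(sample_id = colnames(m$counts),
                         group = as.character(m$group)), paths[3], sep = sep)
  invisible(paths)
}

#' Write a result table as delimited text
#'
#' Delimited text with a header row; numeric values keep full precision
#' (at least 6 significant digits survive a read/write round trip).
#'
#' @param obj a data.frame.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_table <- function(obj, path, sep = "\t") {
  obj <- as.data.frame(obj)
  ok <- tryCatch({
    utils::write.table(obj, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Load a gene set from a plain-text list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored; the
#' result is deduplicated.
#'
#' @param path file path.
#' @return character vector of unique identifiers.
#' @export
load_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- unique(lines[nzchar(lines)])
  if (length(ids) == 0) stop("gene set file is empty: ", path)
  ids
}

#' Run configuration
#'
#' Tunable parameters for the pipeline: the FDR threshold for significance,
#' the expression/variability filter quantile, the sub-pattern cutoff grids
#' scanned by [sensitivity_scan()], the p-measurement constant `c`, and
#' whether the clustering universe is restricted to genes differentially
#' expressed at the chronic time point.
#'
#' @param fdr_threshold adjusted p-value threshold, in (0,1).
#' @param filter_quantile quantile for the mean/SD filter, in (0,1).
#' @param cutoff_high_grid strictly increasing grid for the up/down cutoff.
#' @param cutoff_low_grid strictly increasing grid for the stable cutoff;
#'   every value must be below every `cutoff_high_grid` value.
#' @param c_constant positive scaling constant of the p-measurement score.
#' @param seed integer seed.
#' @param restrict_to_chronic_de if `TRUE` (default), cluster only genes
#'   significant at 60 dpi vs sham; if `FALSE`, all quantile-filtered genes.
#' @param background_method negative-control background estimator, `"mean"`
#'   or `"mean_plus_2sd"`.
#' @param dispersion_method `"common"` (dispersion pooled across the panel)
#'   or `"per_gene"`.
#' @return a list of class `tg_config`.
#' @export
run_config <- function(fdr_threshold = 0.05,
                       filter_quantile = 0.25,
                       cutoff_high_grid = seq(0.30, 0.75, by = 0.05),
                       cutoff_low_grid = seq(0.050, 0.275, by = 0.025),
                       c_constant = 1,
                       seed = 1L,
                       restrict_to_chronic_de = TRUE,
                       background_method = c("mean", "mean_plus_2sd"),
                       dispersion_method = c("common", "per_gene")) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            filter_quantile > 0, filter_quantile < 1,
            c_constant > 0)
  if (length(cutoff_high_grid) == 0 || length(cutoff_low_grid) == 0)
    stop("cutoff grids must be nonempty")
  if (any(diff(cutoff_high_grid) <= 0) || any(diff(cutoff_low_grid) <= 0))
    stop("cutoff grids must be strictly increasing")
  if (max(cutoff_low_grid) >= min(cutoff_high_grid))
    stop("all cutoff_low_grid values must be strictly below all cutoff_high_grid values")
  structure(list(
    fdr_threshold = fdr_threshold,
    filter_quantile = filter_quantile,
    cutoff_high_grid = cutoff_high_grid,
    cutoff_low_grid = cutoff_low_grid,
    c_constant = c_constant,
    seed = as.integer(seed),
    restrict_to_chronic_de = isTRUE(restrict_to_chronic_de),
    background_method = match.arg(background_method),
    dispersion_method = match.arg(dispersion_method)
  ), class = "tg_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take their
#' defaults.
#'
#' @param path YAML file path.
#' @return a `tg_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
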