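#' Construct a case-control count matrix
#'
#' Bundles a taxa-by-samples matrix of sequencing counts with a per-sample
#' group assignment (control vs treatment). This is the basic data container
#' for the whole package: the pilot data the community model is fitted to,
#' and the synthetic cohorts the simulator produces, are both stored this way.
#'
#' @param counts integer matrix, taxa in rows, samples in columns. Row names
#'   are taxon ids, column names sample ids; both must be unique.
#' @param group character or factor of length `ncol(counts)` with values
#'   `"control"` or `"treatment"`, aligned with the columns.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix), `group` (factor with levels control, treatment),
#'   `taxon_ids` and `sample_ids`.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m, c("control", "control", "treatment", "treatment"))
#' cm
#' @export
count_matrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("taxon%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  }
  group <- as.character(group)
  cm <- structure(
    list(counts = counts, group = factor(group, levels = c("control", "treatment")),
         taxon_ids = rownames(counts), sample_ids = colnames(counts)),
    class = "count_matrix")
  validate_count_matrix(cm)
  cm
}

validate_count_matrix <- function(cm) {
  counts <- cm$counts
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count (%g) at taxon '%s', sample '%s'",
                 counts[bad[1L], bad[2L]], rownames(counts)[bad[1L]],
                 colnames(counts)[bad[2L]]), call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop(sprintf("duplicated taxon id: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop(sprintf("duplicated sample id: '%s'", dup), call. = FALSE)
  }
  if (length(cm$group) != ncol(counts)) {
    stop("group length does not match number of samples", call. = FALSE)
  }
  if (anyNA(cm$group)) {
    stop("group labels must be 'control' or 'treatment'", call. = FALSE)
  }
  tab <- table(cm$group)
  if (any(tab < 2L)) {
    stop(sprintf("each group needs at least 2 samples (control: %d, treatment: %d)",
                 tab[["control"]], tab[["treatment"]]), call. = FALSE)
  }
  invisible(cm)
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("count_matrix: %d taxa x %d samples (%d control, %d treatment)\n",
              nrow(x$counts), ncol(x$counts), tab[["control"]], tab[["treatment"]]))
  cat(sprintf("  total reads: %s; zero fraction: %.2f\n",
              format(sum(x$counts), big.mark = ","), mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count table and sample metadata from delimited files
#'
#' The count table has taxon ids in the first column and a header row of
#' sample ids (the transposed orientation is auto-detected against the
#' metadata sample ids and fixed). Metadata must contain a `sample_id`
#' column and a group column; samples are matched by id, never by position.
#'
#' @param counts_path path to the count table (TSV or CSV; delimiter sniffed
#'   from the extension unless `delim` is given).
#' @param metadata_path path to the sample metadata table.
#' @param group_column name of the metadata column holding group labels.
#' @param control_label metadata value identifying control samples; every
#'   other label is treated as treatment.
#' @param delim optional delimiter override applied to both files.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path, group_column = "group",
                        control_label = "control", delim = NULL) {
  for (p in c(counts_path, metadata_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  cdl <- sniff_delim(counts_path, delim)
  mdl <- sniff_delim(metadata_path, delim)
  raw <- utils::read.table(counts_path, header = TRUE, sep = cdl, row.names = 1L,
                           check.names = FALSE, comment.char = "", quote = "\"")
  meta <- utils::read.table(metadata_path, header = TRUE, sep = mdl,
                            check.names = FALSE, comment.char = "", quote = "\"",
                            colClasses = "character")
  if (!"sample_id" %in% names(meta)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  if (!group_column %in% names(meta)) {
    stop(sprintf("metadata has no column '%s'", group_column), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  counts <- as.matrix(raw)
  # orientation: sample ids are expected on columns; if instead the row names
  # match the metadata ids better, transpose (both layouts circulate)
  hit_cols <- mean(colnames(counts) %in% meta$sample_id)
  hit_rows <- mean(rownames(counts) %in% meta$sample_id)
  if (hit_rows > hit_cols) {
    dap_log("read_counts: sample ids found on rows; transposing")
    counts <- t(counts)
  }
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0L) {
    stop(sprintf("samples in counts missing from metadata: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  grp <- ifelse(meta[[group_column]] == control_label, "control", "treatment")
  count_matrix(counts, grp)
}

#' Write a count matrix (and its metadata) to TSV files
#'
#' @param cm a [count_matrix()].
#' @param counts_path,metadata_path output paths.
#' @param group_column name of the metadata group column to write.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(cm, counts_path, metadata_path, group_column = "group") {
  df <- data.frame(taxon_id = cm$taxon_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = cm$sample_ids, group = as.character(cm$group))
  names(meta)[2L] <- group_column
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Remove low-abundance taxa
#'
#' Retains taxa observed with at least `min_count` reads in at least
#' `min_samples` samples, the routine pre-filter applied before any testing
#' or model fitting: rare taxa are too variable to test and produce
#' implausibly large fold-change estimates.
#'
#' @param cm a [count_matrix()].
#' @param min_count minimum reads per sample for a sample to count (default 5).
#' @param min_samples minimum number of qualifying samples (default 3).
#' @return The filtered `count_matrix`; the number of removed taxa is stored
#'   in `attr(, "n_removed")`.
#' @export
filter_low_abundance <- function(cm, min_count = 5L, min_samples = 3L) {
  validate_count_matrix(cm)
  keep <- rowSums(cm$counts >= min_count) >= min_samples
  if (!any(keep)) {
    stop(sprintf(paste0("no taxa pass the abundance filter (>= %d reads in >= %d ",
                        "samples); relax min_count/min_samples"),
                 min_count, min_samples), call. = FALSE)
  }
  out <- count_matrix(cm$counts[keep, , drop = FALSE], as.character(cm$group))
  attr(out, "n_removed") <- sum(!keep)
  dap_log("filter_low_abundance: removed %d of %d taxa", sum(!keep), length(keep))
  out
}
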