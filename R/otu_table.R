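#' OTU count table
#'
#' The universal input of the pipeline: a non-negative integer count matrix
#' with OTUs as rows and samples as columns, plus an optional taxonomy
#' lineage per OTU. Row and column ids must be unique.
#'
#' @param counts numeric matrix (OTUs x samples) of non-negative integers,
#'   with rownames (OTU ids) and colnames (sample ids).
#' @param taxonomy optional named character vector mapping OTU id to a
#'   lineage string; names must be a subset of the OTU ids.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry OTU rownames and sample colnames", call. = FALSE)
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate OTU id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% rownames(counts)))
      stop("taxonomy names must be OTU ids present in the table", call. = FALSE)
    taxonomy <- taxonomy[intersect(rownames(counts), names(taxonomy))]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples\n")
  cat("  total reads:", sum(x$counts),
      "| reads/sample:", paste(range(colSums(x$counts)), collapse = "-"), "\n")
  if (!is.null(x$taxonomy))
    cat("  taxonomy for", length(x$taxonomy), "OTUs\n")
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset an OTU table
#'
#' @param x an `otu_table`.
#' @param otus,samples character or logical/integer index of rows/columns to
#'   keep (default: all).
#' @export
subset_table <- function(x, otus = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[names(tax) %in% rownames(counts)]
  otu_table(counts, if (length(tax)) tax else NULL)
}

#' Sample metadata table
#'
#' Per-sample design information: site, treatment, sampling date and plot.
#' Dates are normalised to the `Date` class (ISO-8601 on disk); time
#' intervals downstream are measured in days.
#'
#' @param df data.frame with columns `sample_id`, `site`, `treatment`,
#'   `time_point`, `plot`.
#' @return validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "site", "treatment", "time_point", "plot")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  tp <- as.Date(df$time_point)
  if (anyNA(tp))
    stop("unparseable time_point value(s): ",
         paste(unique(df$time_point[is.na(tp)]), collapse = ", "),
         call. = FALSE)
  df$time_point <- tp
  df$sample_id <- as.character(df$sample_id)
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Align a metadata table with an OTU table
#'
#' @param meta a `sample_metadata`.
#' @param table an `otu_table`.
#' @return metadata reordered to the table's sample order.
#' @keywords internal
align_metadata <- function(meta, table) {
  ids <- sample_ids(table)
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss))
    stop("samples absent from metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta[match(ids, meta$sample_id), , drop = FALSE]
}
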