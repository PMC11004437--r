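## Tabular and tree I/O. All readers validate and refuse to silently coerce;
## all writer/reader pairs round-trip losslessly. TSVs are tab-delimited
## UTF-8; "#"-prefixed lines are comments, except the classic "#OTU ID"
## header line of an OTU table.

#' Read an OTU count table from TSV
#'
#' Expects OTUs as rows and samples as columns, with the first header field
#' `#OTU ID` (classic OTU-table convention). An optional trailing `taxonomy`
#' column is split off into the taxonomy slot. If `metadata` is supplied and
#' the column ids do not match its sample ids but the row ids do, the matrix
#' is transposed (the decision is reported via `message()`).
#'
#' @param path TSV file path.
#' @param metadata optional `sample_metadata` used for orientation detection.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, metadata = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") | startsWith(lines, "#OTU ID")
  lines <- lines[keep]
  if (!length(lines)) stop("no data in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (length(unique(nfield)) != 1L)
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nfield), collapse = "/"), " fields", call. = FALSE)
  header <- fields[[1L]]
  body <- fields[-1L]
  ids <- vapply(body, `[`, "", 1L)
  cols <- header[-1L]
  tax_col <- which(tolower(cols) == "taxonomy")
  taxonomy <- NULL
  vals <- lapply(body, `[`, -1L)
  if (length(tax_col)) {
    taxonomy <- vapply(vals, `[`, "", tax_col)
    names(taxonomy) <- ids
    vals <- lapply(vals, `[`, -tax_col)
    cols <- cols[-tax_col]
  }
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(length(cols))))
  num <- matrix(num, nrow = length(cols))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric count at OTU '", ids[bad[2L]], "', sample '",
         cols[bad[1L]], "' in ", path, call. = FALSE)
  }
  counts <- t(num)
  dimnames(counts) <- list(ids, cols)
  if (!is.null(metadata) &&
      !all(colnames(counts) %in% metadata$sample_id) &&
      all(rownames(counts) %in% metadata$sample_id)) {
    message("OTU table appears sample-by-OTU; transposing to match metadata")
    counts <- t(counts)
    taxonomy <- NULL
  }
  otu_table(counts, taxonomy)
}

#' Write an OTU table to TSV
#'
#' @param x an [otu_table].
#' @param path output file.
#' @export
write_otu_table <- function(x, path) {
  df <- as.data.frame(x$counts, check.names = FALSE)
  header <- c("#OTU ID", colnames(x$counts))
  if (!is.null(x$taxonomy)) {
    df$taxonomy <- unname(x$taxonomy[rownames(df)])
    header <- c(header, "taxonomy")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = TRUE, fileEncoding = "")
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Columns: `sample_id`, `site`, `treatment`, `time_point` (ISO-8601 date),
#' `plot`.
#'
#' @param path TSV file path.
#' @return a [sample_metadata].
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          check.names = FALSE)
  sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta a [sample_metadata].
#' @export
write_sample_metadata <- function(meta, path) {
  out <- as.data.frame(meta)
  out$time_point <- format(out$time_point, "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a samples-by-variables environmental table
#'
#' First column `sample_id`, remaining columns numeric variables.
#'
#' @param path TSV file path.
#' @return numeric matrix with sample ids as rownames.
#' @export
read_env_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("environmental table must have first column 'sample_id'",
         call. = FALSE)
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("non-numeric environmental values in ", path,
                           call. = FALSE)
  rownames(m) <- df$sample_id
  m
}

#' @rdname read_env_table
#' @param env numeric matrix (samples x variables, rownames = sample ids).
#' @export
write_env_table <- function(env, path) {
  df <- data.frame(sample_id = rownames(env), env, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Missing branch lengths default to 0; negative lengths and duplicate leaf
#' labels are rejected.
#'
#' @param path newick file containing a single tree.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("failed to parse newick in ", path, call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree", call. = FALSE)
  tree
}
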