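#' Expression dataset container
#'
#' A genes x samples matrix of continuous log2-scale expression values plus,
#' optionally, a per-sample class label. Gene and sample identifiers must be
#' unique, the matrix must be complete (no missing values), and every sample
#' must carry exactly one label. Classes keep the order in which they first
#' appear in the labels.
#'
#' @param exprs Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). No `NA`s allowed.
#' @param labels Optional named character vector or factor mapping every
#'   sample id to a class name.
#' @return An object of class `expression_dataset` with elements `exprs`,
#'   `labels` (factor or `NULL`) and `classes`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, setNames(rep(c("A", "B"), each = 2),
#'                                      colnames(m)))
expression_dataset <- function(exprs, labels = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(exprs)[duplicated(rownames(exprs))]),
               collapse = ", "))
  if (anyDuplicated(colnames(exprs)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(exprs)[duplicated(colnames(exprs))]),
               collapse = ", "))
  if (anyNA(exprs)) stop("expression matrix contains missing values")
  ds <- structure(list(exprs = exprs, labels = NULL, classes = NULL),
                  class = "expression_dataset")
  if (!is.null(labels)) ds <- attach_labels(ds, labels)
  ds
}

#' Attach class labels to an expression dataset
#'
#' Classes are ordered by first appearance in `labels`. Attaching never
#' reorders the matrix. A class with fewer than 3 samples triggers a warning
#' here and an error when an analysis is started.
#'
#' @param dataset An [expression_dataset()].
#' @param labels Named character vector or factor, names = sample ids.
#' @return The dataset with `labels` and `classes` filled in.
#' @export
attach_labels <- function(dataset, labels) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(names(labels)) && length(labels) == ncol(dataset$exprs)) {
    names(labels) <- colnames(dataset$exprs)
  }
  lab <- as.character(labels)
  names(lab) <- names(labels)
  if (anyDuplicated(names(lab)))
    stop("sample labelled more than once: ",
         paste(unique(names(lab)[duplicated(names(lab))]), collapse = ", "))
  samples <- colnames(dataset$exprs)
  missing_in_matrix <- setdiff(names(lab), samples)
  if (length(missing_in_matrix))
    stop("labelled samples absent from expression matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  missing_labels <- setdiff(samples, names(lab))
  if (length(missing_labels))
    stop("samples without a label: ", paste(missing_labels, collapse = ", "))
  lab <- lab[samples]                      # matrix order is never changed
  classes <- unique(as.character(labels))  # first-appearance order
  dataset$labels <- factor(lab, levels = classes)
  dataset$classes <- classes
  counts <- table(dataset$labels)
  if (length(classes) >= 2 && any(counts < 3))
    warning("classes with fewer than 3 samples: ",
            paste(names(counts)[counts < 3], collapse = ", "),
            " (analyses require >= 3 samples per class)")
  dataset
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$exprs), ncol(x$exprs)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  } else cat("no class labels attached\n")
  invisible(x)
}

# Checks a dataset is ready for a class-based analysis; called at the start
# of ranking / selection / validation.
assert_analysis_ready <- function(dataset, min_per_class = 3L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$labels)) stop("dataset has no class labels attached")
  if (length(dataset$classes) < 2) stop("at least 2 classes are required")
  counts <- table(dataset$labels)
  if (any(counts < min_per_class))
    stop("every class needs at least ", min_per_class, " samples; too few: ",
         paste(names(counts)[counts < min_per_class], collapse = ", "))
  invisible(dataset)
}

#' Read an expression matrix from TSV, CSV or GCT
#'
#' TSV/CSV: first column gene ids, header row sample ids. GCT 1.2: `#1.2`
#' version line, a dimensions line, then a table whose first two columns are
#' `Name` and `Description`. Values must be numeric and already on a log2
#' scale unless `log2_rpkm = TRUE`.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"csv"`, `"gct"`.
#' @param log2_rpkm If `TRUE` the file holds raw RPKM values and
#'   `log2(x + 1)` is applied after reading.
#' @return An [expression_dataset()] without labels.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct"),
                            log2_rpkm = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", gct = "gct", "tsv")
  }
  if (format == "gct") {
    mat <- read_gct(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) stop("cannot parse ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(df) < 2) stop("malformed expression file (", path,
                           "): need a gene-id column plus >= 1 sample")
    mat <- as_numeric_matrix(df[-1], df[[1]], path)
  }
  if (log2_rpkm) {
    if (any(mat < 0)) stop("negative values: RPKM input must be nonnegative")
    mat <- log2(mat + 1)
  }
  expression_dataset(mat)
}

read_gct <- function(path) {
  lines <- readLines(path, n = 2)
  if (length(lines) < 2 || !startsWith(lines[1], "#1.2"))
    stop("malformed GCT file (", path, "): line 1 must be '#1.2'")
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2]))
    stop("malformed GCT file (", path, "): line 2 must give dimensions")
  df <- read.delim(path, skip = 2, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 3)
    stop("malformed GCT file (", path, "): need Name, Description, samples")
  mat <- as_numeric_matrix(df[-(1:2)], df[[1]], path)
  if (nrow(mat) != dims[1] || ncol(mat) != dims[2])
    stop("GCT dimension line says ", dims[1], " x ", dims[2],
         " but table is ", nrow(mat), " x ", ncol(mat))
  mat
}

# Converts a character data.frame to a numeric matrix with row names,
# reporting the offending gene/sample on failure.
as_numeric_matrix <- function(df, gene_ids, path) {
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(gene_ids, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(df[[j]] %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value '", df[[j]][bad[1]], "' for gene '",
           gene_ids[bad[1]], "', sample '", colnames(df)[j], "' in ", path)
    if (anyNA(v))
      stop("missing value for gene '", gene_ids[which(is.na(v))[1]],
           "', sample '", colnames(df)[j], "' in ", path)
    mat[, j] <- v
  }
  mat
}

#' Read a sample-to-class label table
#'
#' Two-column TSV: sample id, class name. A header line is tolerated when
#' its first field is `sample` or `sample_id` (case-insensitive). Classes
#' are inferred in order of first appearance.
#'
#' @param path File path.
#' @return Named character vector mapping sample id to class.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0) stop("empty label file: ", path)
  if (ncol(df) < 2) stop("label file needs two columns (sample, class)")
  if (tolower(df[1, 1]) %in% c("sample", "sample_id", "sampleid"))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop("label file has a header but no samples: ", path)
  if (anyDuplicated(df[[1]]))
    stop("sample with two labels: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  setNames(df[[2]], df[[1]])
}

#' Write a tabular result to TSV
#'
#' Numeric columns are written with 12 significant digits so that
#' [read_result_table()] round-trips the table.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.12g", out[[j]])
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path File path.
#' @return A data frame with numeric columns restored.
#' @export
read_result_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      numeric_like <- !is.na(v) | df[[j]] %in% c("NA", "")
      if (length(df[[j]]) > 0 && all(numeric_like)) df[[j]] <- v
    }
  }
  df
}

#' Write an expression dataset to TSV (genes in rows)
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene = rownames(dataset$exprs),
                   dataset$exprs, check.names = FALSE)
  write_table(df, path)
}

#' Write sample labels to a two-column TSV
#' @param labels Named character vector (or a labelled dataset).
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "expression_dataset"))
    labels <- setNames(as.character(labels$labels), colnames(labels$exprs))
  df <- data.frame(sample = names(labels), class = as.character(labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
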