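#' Construct a feature matrix
#'
#' A feature matrix holds the items to be clustered as rows and their
#' features (expression levels, coordinates) as columns. This is the common
#' orientation for sample-clustering of expression data: one row per item,
#' one column per measured feature.
#'
#' @param values numeric matrix (or object coercible to one) with at least
#'   2 rows and 1 column; all entries must be finite.
#' @param item_ids optional character vector of unique row identifiers;
#'   defaults to existing rownames, or `item1..itemN`.
#' @param feature_names optional character vector of column names; defaults
#'   to existing colnames, or `f1..fM`.
#' @return a numeric matrix of class `feature_matrix` with row and column
#'   names set.
#' @details Constant (zero-variance) rows are legal geometry and are kept,
#'   but a message flags them because the Pearson and mutual-information
#'   distances reject them.
#' @export
#' @examples
#' fm <- feature_matrix(matrix(rnorm(12), nrow = 3))
feature_matrix <- function(values, item_ids = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature matrix values must be numeric")
  n <- nrow(values); m <- ncol(values)
  if (n < 2L) stop("a feature matrix needs at least 2 items (rows), got ", n)
  if (m < 1L) stop("a feature matrix needs at least 1 feature (column)")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]))
  }
  if (is.null(item_ids)) item_ids <- rownames(values)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(n))
  item_ids <- as.character(item_ids)
  if (length(item_ids) != n) stop("item_ids length does not match row count")
  if (anyDuplicated(item_ids))
    stop("duplicate item ids: ",
         paste(unique(item_ids[duplicated(item_ids)]), collapse = ", "))
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(m))
  if (length(feature_names) != m) stop("feature_names length does not match column count")
  dimnames(values) <- list(item_ids, as.character(feature_names))
  const <- apply(values, 1L, function(r) max(r) == min(r))
  if (any(const))
    message("constant rows (Pearson/MI distances will reject them): ",
            paste(item_ids[const], collapse = ", "))
  structure(values, class = c("feature_matrix", class(values)))
}

#' Read a feature matrix from delimited text
#'
#' Expects a rectangular table with a header row of feature names and a
#' leading column of unique item identifiers. The delimiter is
#' auto-detected from the header line (tab wins over comma) unless given.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one feature column")
  ids <- df[[1L]]
  vals <- df[-1L]
  num <- suppressWarnings(lapply(vals, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) | !is.finite(num[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   bad[1L], names(vals)[j]))
  }
  feature_matrix(do.call(cbind, num), item_ids = ids,
                 feature_names = names(vals))
}

#' Write a feature matrix as delimited text
#'
#' @param x a [feature_matrix()].
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(x, path, sep = "\t") {
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gold solution
#'
#' The gold solution is the externally known partition of the items into
#' classes, used as ground truth when scoring partitions and distance
#' functions.
#'
#' @param labels vector of class labels named by item id (or a 2-column
#'   data.frame of id, label).
#' @return named character vector of class `gold_solution`, with attribute
#'   `r` giving the number of distinct classes.
#' @export
gold_solution <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) stop("expected two columns: item id, class label")
    labels <- stats::setNames(as.character(labels[[2L]]), as.character(labels[[1L]]))
  }
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("gold labels must be named by item id")
  if (anyDuplicated(names(labels)))
    stop("duplicate item ids in gold solution")
  if (any(is.na(labels))) stop("missing class labels")
  structure(labels, class = "gold_solution", r = length(unique(labels)))
}

#' Read a gold solution and check it against a feature matrix
#'
#' @param path two-column delimited file (item_id, class label); a header
#'   line is tolerated and detected.
#' @param matrix the companion [feature_matrix()] whose items must be
#'   covered exactly.
#' @param sep delimiter; `NULL` auto-detects.
#' @return a [gold_solution()] ordered like the matrix rows.
#' @export
read_gold_solution <- function(path, matrix, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns: item id, class label")
  # drop a header line if its first field is not a known item id
  if (!(df[1L, 1L] %in% rownames(matrix)) && nrow(df) > 1L) df <- df[-1L, ]
  labels <- stats::setNames(df[[2L]], df[[1L]])
  ids <- rownames(matrix)
  missing <- setdiff(ids, names(labels))
  extra <- setdiff(names(labels), ids)
  if (length(missing))
    stop("gold solution misses items: ", paste(missing, collapse = ", "))
  if (length(extra))
    stop("gold solution has unknown items: ", paste(extra, collapse = ", "))
  gold_solution(labels[ids])
}

#' Write a table of records as delimited text
#'
#' Rows may be a data.frame or a list of homogeneous named lists/vectors;
#' column order is taken from the first record and kept, so output is
#' deterministic. An empty record set yields a header-only file when column
#' names are available.
#'
#' @param rows data.frame, or list of named records sharing one set of names.
#' @param path output path.
#' @param sep delimiter (default tab).
#' @return invisibly, `path`.
#' @export
write_report_table <- function(rows, path, sep = "\t") {
  if (!is.data.frame(rows)) {
    if (length(rows) == 0L) stop("empty record list with no column information; pass a 0-row data.frame")
    nms <- names(rows[[1L]])
    if (is.null(nms)) stop("records must be named")
    ok <- vapply(rows, function(r) identical(names(r), nms), logical(1L))
    if (!all(ok)) stop("records are not homogeneous (differing fields)")
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r))))
  }
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' @export
print.gold_solution <- function(x, ...) {
  cat("Gold solution:", length(x), "items,", attr(x, "r"), "classes\n")
  print(table(unclass(x)))
  invisible(x)
}
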