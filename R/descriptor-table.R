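#' Construct a descriptor table
#'
#' A descriptor table holds the data a QSAR applicability-domain analysis
#' works on: a numeric matrix of molecular descriptors (rows = molecules,
#' columns = precomputed descriptors), unique sample identifiers, and
#' optionally the measured response `y` and the model's predicted response
#' `y_hat` (both in the model's response units).
#'
#' @param X Numeric matrix, `n` samples by `p` descriptors. A data frame of
#'   numeric columns is accepted and coerced.
#' @param ids Character vector of `n` unique sample identifiers. Defaults to
#'   the row names of `X`, or `"s1" ... "sn"` when absent.
#' @param y Optional numeric vector of measured responses, length `n`.
#' @param y_hat Optional numeric vector of predicted responses, length `n`.
#' @param descriptor_names Optional character vector of `p` descriptor names;
#'   defaults to the column names of `X` or `"d1" ... "dp"`.
#' @return An object of class `descriptor_table`.
#' @examples
#' tab <- descriptor_table(matrix(rnorm(20), 10, 2), ids = paste0("mol", 1:10))
#' tab
#' @export
descriptor_table <- function(X, ids = NULL, y = NULL, y_hat = NULL,
                             descriptor_names = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix or all-numeric data frame.")
  n <- nrow(X); p <- ncol(X)
  if (n < 1L || p < 1L) stop("descriptor table needs at least 1 sample and 1 descriptor.")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing descriptor value at row %d, column %d.", bad[1L], bad[2L]))
  }
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` must have one entry per row of `X`.")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicated sample id(s): %s", paste(dup, collapse = ", ")))
  }
  if (is.null(descriptor_names)) descriptor_names <- colnames(X)
  if (is.null(descriptor_names)) descriptor_names <- paste0("d", seq_len(p))
  if (length(descriptor_names) != p)
    stop("`descriptor_names` must have one entry per column of `X`.")
  for (nm in c("y", "y_hat")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != n) stop(sprintf("`%s` must have length %d.", nm, n))
      if (!is.numeric(v)) stop(sprintf("`%s` must be numeric.", nm))
    }
  }
  dimnames(X) <- list(ids, descriptor_names)
  structure(list(ids = ids, X = X, y = y, y_hat = y_hat,
                 descriptor_names = descriptor_names),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table> %d samples x %d descriptors\n",
              nrow(x$X), ncol(x$X)))
  cat("  descriptors:", paste(utils::head(x$descriptor_names, 6L), collapse = ", "),
      if (length(x$descriptor_names) > 6L) "..." else "", "\n")
  cat("  response y:", if (is.null(x$y)) "absent" else "present",
      " predicted y_hat:", if (is.null(x$y_hat)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$X)

#' Subset the samples of a descriptor table
#'
#' @param x A `descriptor_table`.
#' @param i Row index (integer, logical or sample id).
#' @param ... Unused.
#' @return A `descriptor_table` with the selected samples.
#' @export
`[.descriptor_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  descriptor_table(x$X[i, , drop = FALSE], ids = x$ids[i],
                   y = if (!is.null(x$y)) x$y[i],
                   y_hat = if (!is.null(x$y_hat)) x$y_hat[i],
                   descriptor_names = x$descriptor_names)
}

#' Read a descriptor table from delimited text
#'
#' Reads a CSV-dialect file (comma, semicolon or tab delimited; header row;
#' UTF-8; decimal point). Every column other than the id, response and
#' prediction columns is taken as a descriptor, in file order. Missing or
#' non-numeric descriptor cells are a load error naming the offending cell.
#'
#' @param path Path to the file.
#' @param id_column Name of the identifier column (default: first column).
#' @param response_column Optional name of the measured-response column.
#' @param prediction_column Optional name of the predicted-response column.
#' @param delimiter Field delimiter; `"auto"` (default) tries comma,
#'   semicolon and tab on the header line.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, id_column = NULL,
                                  response_column = NULL,
                                  prediction_column = NULL,
                                  delimiter = "auto") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (identical(delimiter, "auto")) {
    header <- readLines(path, n = 1L)
    counts <- vapply(c(",", ";", "\t"), function(d)
      lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))), integer(1))
    delimiter <- c(",", ";", "\t")[which.max(counts)]
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("file must have an id column and at least one descriptor column.")
  if (is.null(id_column)) id_column <- names(df)[1L]
  for (col in c(id_column, response_column, prediction_column))
    if (!is.null(col) && !col %in% names(df))
      stop(sprintf("column '%s' not present in %s", col, path))
  ids <- df[[id_column]]
  desc_cols <- setdiff(names(df), c(id_column, response_column, prediction_column))
  if (length(desc_cols) < 1L) stop("no descriptor columns remain after routing id/response columns.")
  parse_num <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | !nzchar(trimws(raw)))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s', row %d (id '%s').",
                   col, bad[1L], ids[bad[1L]]))
    v
  }
  X <- vapply(desc_cols, parse_num, numeric(nrow(df)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(df), dimnames = list(NULL, desc_cols))
  y <- if (!is.null(response_column)) parse_num(response_column)
  y_hat <- if (!is.null(prediction_column)) parse_num(prediction_column)
  descriptor_table(X, ids = ids, y = y, y_hat = y_hat, descriptor_names = desc_cols)
}

#' Write a descriptor table to delimited text
#'
#' Values are written at full double precision (17 significant digits) so a
#' write/read round trip reproduces the table exactly.
#'
#' @param table A `descriptor_table`.
#' @param path Output file path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(id = table$ids, stringsAsFactors = FALSE)
  for (j in seq_along(table$descriptor_names))
    df[[table$descriptor_names[j]]] <- format(table$X[, j], digits = 17, trim = TRUE,
                                              scientific = FALSE)
  if (!is.null(table$y)) df[["y"]] <- format(table$y, digits = 17, trim = TRUE, scientific = FALSE)
  if (!is.null(table$y_hat)) df[["y_hat"]] <- format(table$y_hat, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit autoscaling parameters on training data
#'
#' Autoscaling (per-descriptor centering to zero mean and scaling to unit
#' standard deviation, `n - 1` denominator) is the standard chemometric
#' pretreatment. Statistics are computed on the training partition only;
#' query data must be transformed with the training parameters so no
#' information leaks from test to training.
#'
#' @param train A `descriptor_table` with at least 2 samples.
#' @param drop_constant If `TRUE`, zero-variance descriptors are dropped with
#'   a warning instead of raising an error.
#' @return An object of class `scaling_params` with fields `means`, `sds` and
#'   `keep` (indices of retained descriptors).
#' @export
autoscale_fit <- function(train, drop_constant = FALSE) {
  stopifnot(inherits(train, "descriptor_table"))
  X <- train$X
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 training samples.")
  means <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  zero <- which(sds == 0)
  keep <- seq_len(ncol(X))
  if (length(zero)) {
    if (drop_constant) {
      warning(sprintf("dropping constant descriptor(s): %s",
                      paste(train$descriptor_names[zero], collapse = ", ")))
      keep <- setdiff(keep, zero)
      if (!length(keep)) stop("all descriptors are constant; nothing to scale.")
      means <- means[keep]; sds <- sds[keep]
    } else {
      stop(sprintf("zero-variance descriptor(s): %s (set drop_constant = TRUE to drop).",
                   paste(train$descriptor_names[zero], collapse = ", ")))
    }
  }
  structure(list(means = means, sds = sds, keep = keep, p_full = ncol(X)),
            class = "scaling_params")
}

#' Apply (or invert) autoscaling
#'
#' @param X Numeric matrix whose column count matches the full descriptor
#'   count the parameters were fitted on.
#' @param params A `scaling_params` object from [autoscale_fit()].
#' @param invert If `TRUE`, undo the transform (`x * sd + mean`); input must
#'   then have the retained-descriptor column count.
#' @return The transformed matrix (retained descriptors only).
#' @export
autoscale_apply <- function(X, params, invert = FALSE) {
  stopifnot(inherits(params, "scaling_params"))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (invert) {
    if (ncol(X) != length(params$means)) stop("column count does not match scaling parameters.")
    return(sweep(sweep(X, 2L, params$sds, `*`), 2L, params$means, `+`))
  }
  if (ncol(X) != params$p_full)
    stop("column count does not match the descriptor count the scaling was fitted on.")
  X <- X[, params$keep, drop = FALSE]
  sweep(sweep(X, 2L, params$means, `-`), 2L, params$sds, `/`)
}
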