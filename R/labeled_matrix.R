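#' Labeled relationship/covariance matrix
#'
#' The basic carrier of every kernel in the package: a square, symmetric,
#' real matrix together with an ordered set of unique genotype (or trait)
#' labels.  Genomic relationship matrices, pedigree A-matrices, combined
#' estimates and phenotypic correlation matrices are all stored this way.
#'
#' @param values square numeric matrix (a data.frame is coerced).
#' @param labels character vector of unique labels, one per row/column.
#'   Defaults to the rownames of `values`.
#' @param source optional free-text provenance string.
#' @param n_features optional positive integer: the number of features
#'   (markers, transcripts, observations) used to build the matrix.  Used
#'   as the default Wishart degrees of freedom in [combine_em()].
#' @param symmetrize if `TRUE`, replace `values` by `(M + t(M))/2`
#'   unconditionally; if `FALSE` (default) the matrix must already be
#'   symmetric to within `tol` relative tolerance.
#' @param tol relative symmetry tolerance used when `symmetrize = FALSE`.
#'
#' @return an object of class `labeled_matrix`: a numeric matrix with
#'   `dimnames` set to the labels and attributes `source` and
#'   `n_features`.
#' @export
labeled_matrix <- function(values, labels = rownames(values), source = NULL,
                           n_features = NULL, symmetrize = FALSE,
                           tol = 1e-8) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (nrow(values) != ncol(values)) {
    stop(sprintf("'values' must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  if (is.null(labels)) stop("labels are required (or set rownames on 'values')")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("number of labels does not match matrix dimension")
  }
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L) {
    stop("duplicate labels: ", paste(unique(dup), collapse = ", "))
  }
  asym <- max(abs(values - t(values)), 0)
  scale <- max(abs(values), 1)
  if (symmetrize) {
    values <- (values + t(values)) / 2
  } else if (asym / scale > tol) {
    stop(sprintf(
      "matrix is not symmetric (max relative asymmetry %.3g); use symmetrize = TRUE",
      asym / scale))
  }
  if (!is.null(n_features)) {
    n_features <- as.integer(n_features)
    if (length(n_features) != 1L || is.na(n_features) || n_features < 1L) {
      stop("'n_features' must be a single positive integer")
    }
  }
  dimnames(values) <- list(labels, labels)
  structure(values,
            source = source,
            n_features = n_features,
            class = c("labeled_matrix", "matrix", "array"))
}

#' @export
labels.labeled_matrix <- function(object, ...) rownames(object)

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d x %d", nrow(x), ncol(x)))
  nf <- attr(x, "n_features")
  if (!is.null(nf)) cat(sprintf(" (n_features = %d)", nf))
  src <- attr(x, "source")
  if (!is.null(src)) cat(sprintf(" [%s]", src))
  cat("\n")
  m <- unclass(x)
  attr(m, "source") <- NULL
  attr(m, "n_features") <- NULL
  k <- min(nrow(m), 6L)
  print(m[seq_len(k), seq_len(k), drop = FALSE], ...)
  if (nrow(x) > k) cat(sprintf("... %d more rows/columns\n", nrow(x) - k))
  invisible(x)
}

# Plain numeric matrix of a labeled_matrix (drops class and extra attrs).
lm_values <- function(x) {
  m <- unclass(x)
  attr(m, "source") <- NULL
  attr(m, "n_features") <- NULL
  class(m) <- NULL
  m
}

#' Subset a labeled matrix to a set of labels
#'
#' @param x a [labeled_matrix()].
#' @param labs character vector of labels to keep (order respected).
#' @return a `labeled_matrix` over `labs`.
#' @export
subset_kernel <- function(x, labs) {
  idx <- match(labs, rownames(x))
  if (anyNA(idx)) {
    stop("labels not present in matrix: ",
         paste(labs[is.na(idx)], collapse = ", "))
  }
  labeled_matrix(lm_values(x)[idx, idx, drop = FALSE], labels = labs,
                 source = attr(x, "source"),
                 n_features = attr(x, "n_features"))
}

#' Read a labeled square matrix from a delimited text file
#'
#' The file must have a header row of labels and a first column of labels;
#' the numeric body is symmetrized as `(M + t(M))/2` on read.  A warning is
#' emitted when the maximum relative asymmetry exceeds 1e-6, since files
#' assembled from heterogeneous sources tend to drift.
#'
#' @param path file path.
#' @param delimiter field delimiter, default comma.
#' @return a [labeled_matrix()].
#' @export
read_labeled_matrix <- function(path, delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, row.names = NULL,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a label column plus a numeric body")
  row_labels <- as.character(df[[1L]])
  col_labels <- colnames(df)[-1L]
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   row_labels[if (length(bad)) bad else 1L], col_labels[j]))
    }
  }
  m <- as.matrix(body)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix body is not square: %d rows, %d columns",
                 nrow(m), ncol(m)))
  }
  if (!setequal(row_labels, col_labels)) {
    stop("row and column label sets differ")
  }
  # align column order to row order (exact, case-sensitive matching)
  m <- m[, match(row_labels, col_labels), drop = FALSE]
  asym <- max(abs(m - t(m)), 0) / max(abs(m), 1)
  if (asym > 1e-6) {
    warning(sprintf("asymmetry %.3g in '%s'; symmetrized as (M + t(M))/2",
                    asym, path))
  }
  labeled_matrix(m, labels = row_labels, source = path, symmetrize = TRUE)
}

#' Write a labeled matrix to a delimited text file
#'
#' @param x a [labeled_matrix()].
#' @param path output file path.
#' @param delimiter field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path, delimiter = ",") {
  m <- lm_values(x)
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Convert a covariance kernel to a correlation kernel
#'
#' Standardizes `k` to unit diagonal: `r_ij = k_ij / sqrt(k_ii * k_jj)`.
#'
#' @param k a [labeled_matrix()] with strictly positive diagonal.
#' @return a `labeled_matrix` with unit diagonal.
#' @export
cov2cor_kernel <- function(k) {
  d <- diag(lm_values(k))
  bad <- which(d <= 0)
  if (length(bad) > 0L) {
    stop("non-positive diagonal for label(s): ",
         paste(rownames(k)[bad], collapse = ", "))
  }
  labeled_matrix(stats::cov2cor(lm_values(k)), labels = rownames(k),
                 source = attr(k, "source"),
                 n_features = attr(k, "n_features"), symmetrize = TRUE)
}

#' Repair a symmetric matrix to positive semi-definiteness
#'
#' Eigenvalues are clipped at zero and an optional jitter is added to the
#' diagonal.  Among diagonal-clip repairs this is the Frobenius-nearest PSD
#' matrix to the input.
#'
#' @param k a symmetric [labeled_matrix()].
#' @param jitter non-negative ridge added to the diagonal after clipping.
#' @return a PSD `labeled_matrix`.
#' @export
ensure_psd <- function(k, jitter = 0) {
  stopifnot(jitter >= 0)
  m <- lm_values(k)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  out <- e$vectors %*% (ev * t(e$vectors))
  out <- (out + t(out)) / 2
  if (jitter > 0) out <- out + diag(jitter, nrow(out))
  labeled_matrix(out, labels = rownames(k), source = attr(k, "source"),
                 n_features = attr(k, "n_features"), symmetrize = TRUE)
}
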