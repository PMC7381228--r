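#' Marker dosage matrix
#'
#' Genotype-by-marker allele dosages, with values in `[0, ploidy]` or
#' missing (`NA`).  Dosages are usually integer counts of the alternate
#' allele but fractional values (e.g. imputed dosages) are accepted.
#'
#' @param dosages numeric matrix, genotypes in rows, markers in columns.
#' @param genotype_labels,marker_labels unique label vectors; default to
#'   the dimnames of `dosages`.
#' @param ploidy positive even integer, default 2.
#' @return an object of class `marker_matrix`: the dosage matrix with an
#'   attached `ploidy` attribute.
#' @export
marker_matrix <- function(dosages, genotype_labels = rownames(dosages),
                          marker_labels = colnames(dosages), ploidy = 2L) {
  dosages <- as.matrix(dosages)
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L || ploidy %% 2L != 0L) {
    stop("'ploidy' must be a positive even integer")
  }
  if (is.null(genotype_labels) || is.null(marker_labels)) {
    stop("genotype and marker labels are required")
  }
  genotype_labels <- as.character(genotype_labels)
  marker_labels <- as.character(marker_labels)
  if (length(genotype_labels) != nrow(dosages) ||
      length(marker_labels) != ncol(dosages)) {
    stop("label lengths do not match dosage dimensions")
  }
  if (anyDuplicated(genotype_labels)) stop("duplicate genotype labels")
  if (anyDuplicated(marker_labels)) stop("duplicate marker labels")
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > ploidy),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "dosage out of [0, %d] at genotype '%s', marker '%s' (value %g)",
      ploidy, genotype_labels[bad[1L, 1L]], marker_labels[bad[1L, 2L]],
      dosages[bad[1L, 1L], bad[1L, 2L]]))
  }
  dimnames(dosages) <- list(genotype_labels, marker_labels)
  structure(dosages, ploidy = ploidy,
            class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d genotypes x %d markers (ploidy %d, %.1f%% missing)\n",
              nrow(x), ncol(x), attr(x, "ploidy"),
              100 * mean(is.na(x))))
  invisible(x)
}

mm_values <- function(x) {
  m <- unclass(x)
  attr(m, "ploidy") <- NULL
  class(m) <- NULL
  m
}

#' Read a marker dosage matrix from a delimited text file
#'
#' Header row holds marker labels, first column holds genotype labels,
#' `NA` encodes missing dosages.  Dosage bounds are validated against
#' `ploidy`.
#'
#' @param path file path.
#' @param ploidy positive even integer, default 2.
#' @param delimiter field delimiter, default comma.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, ploidy = 2L, delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("marker file needs a label column plus dosages")
  g <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric dosage values in ", path)
  marker_matrix(m, genotype_labels = g, marker_labels = colnames(df)[-1L],
                ploidy = ploidy)
}

#' Write a marker dosage matrix to a delimited text file
#'
#' @param m a [marker_matrix()].
#' @param path output file path.
#' @param delimiter field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, delimiter = ",") {
  df <- data.frame(genotype = rownames(m), mm_values(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM from diploid dosages: `G = Z Z' / (2 * sum_j p_j (1 - p_j))`
#' with `Z = M - 2p`, allele frequencies `p_j` estimated per marker from
#' the non-missing dosages.  Missing dosages are mean-imputed per marker
#' before centering; monomorphic markers are dropped.
#'
#' @param m a diploid [marker_matrix()] with at least 2 genotypes.
#' @param allele_freq optional numeric vector of allele frequencies (one
#'   per marker) to use instead of the observed frequencies, e.g. base
#'   population frequencies in simulations.
#' @return a [labeled_matrix()] over the genotypes, with `n_features` set
#'   to the number of markers actually used.
#' @export
grm_vanraden <- function(m, allele_freq = NULL) {
  if (!inherits(m, "marker_matrix")) stop("'m' must be a marker_matrix")
  if (attr(m, "ploidy") != 2L) {
    stop("grm_vanraden implements the diploid (ploidy 2) GRM")
  }
  X <- mm_values(m)
  if (nrow(X) < 2L) stop("need at least 2 genotypes")
  if (is.null(allele_freq)) {
    p <- colMeans(X, na.rm = TRUE) / 2
  } else {
    if (length(allele_freq) != ncol(X)) {
      stop("'allele_freq' must have one entry per marker")
    }
    p <- as.numeric(allele_freq)
  }
  keep <- which(!is.na(p) & p > 0 & p < 1)
  if (length(keep) == 0L) stop("no informative markers (all monomorphic)")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  # per-marker mean imputation closes the centering formula
  if (anyNA(X)) {
    mu <- rep(2 * p, each = nrow(X))
    X[is.na(X)] <- mu[is.na(X)]
  }
  Z <- sweep(X, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  labeled_matrix(G, labels = rownames(m), source = "grm_vanraden",
                 n_features = length(keep), symmetrize = TRUE)
}
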