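#' Partial relationship sample
#'
#' One Wishart observation: a relationship matrix observed on a subset of
#' genotypes, with an optional reliability weight.  Under the model each
#' partial kernel `G_a` is a draw from `Wishart(nu, Psi_a)` where `Psi_a`
#' is the corresponding block of the scaled combined matrix.
#'
#' @param kernel a [labeled_matrix()] over the genotype subset.
#' @param weight reliability weight in `[0, 1]`; 1 (default) means the
#'   observed kernel is used as-is, smaller values shrink it toward the
#'   current model prediction inside [combine_em()].
#' @return an object of class `partial_sample`.
#' @export
partial_sample <- function(kernel, weight = 1) {
  if (!inherits(kernel, "labeled_matrix")) {
    stop("'kernel' must be a labeled_matrix")
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0 || weight > 1) {
    stop("'weight' must be a single number in [0, 1]")
  }
  structure(list(kernel = kernel, weight = weight),
            class = "partial_sample")
}

#' @export
print.partial_sample <- function(x, ...) {
  cat(sprintf("partial_sample: %d genotypes, weight %.3g\n",
              nrow(x$kernel), x$weight))
  invisible(x)
}

# Coerce a list of partial_sample / labeled_matrix into partial samples.
as_partial_samples <- function(samples) {
  if (inherits(samples, "partial_sample") ||
      inherits(samples, "labeled_matrix")) {
    samples <- list(samples)
  }
  if (!is.list(samples) || length(samples) == 0L) {
    stop("'samples' must be a non-empty list of partial samples")
  }
  lapply(samples, function(s) {
    if (inherits(s, "partial_sample")) s
    else if (inherits(s, "labeled_matrix")) partial_sample(s)
    else stop("each sample must be a partial_sample or labeled_matrix")
  })
}

#' Align partial samples on their label union
#'
#' Computes the sorted union `K` of the genotype subsets and, for each
#' sample, the integer positions of its labels inside `K`.  These index
#' maps play the role of the permutation matrices that place each partial
#' matrix in a common order; working with indices avoids quadratic-cost
#' multiplications.
#'
#' @param samples non-empty list of [partial_sample()] (bare
#'   [labeled_matrix()] objects are accepted and given weight 1).
#' @return list with elements `labels` (sorted union `K`) and
#'   `index_maps` (list of integer vectors, one per sample).
#' @export
union_align <- function(samples) {
  samples <- as_partial_samples(samples)
  label_sets <- lapply(samples, function(s) rownames(s$kernel))
  K <- sort(unique(unlist(label_sets)))
  maps <- lapply(label_sets, function(ls) match(ls, K))
  list(labels = K, index_maps = maps)
}
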