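#' EM configuration for combining partial relationship matrices
#'
#' @param nu Wishart degrees of freedom.  `NULL` (default) means: use the
#'   mean of the `n_features` attributes available across the samples, or
#'   1000 when none is recorded.  A large value on the order of the number
#'   of features behind each kernel is appropriate; the combined estimate
#'   itself does not depend on it.
#' @param tol relative Frobenius-norm convergence threshold on successive
#'   scale-matrix iterates.
#' @param max_iter maximum number of EM iterations.
#' @param jitter ridge (relative to the mean diagonal) added to blocks
#'   before inversion.  The default 0 keeps the iteration an exact EM;
#'   when a Cholesky factorization fails, an escalating ridge is applied
#'   automatically starting from 1e-10.
#' @param init either the string `"identity"` (identity matrix over the
#'   genotype union, an uninformative prior) or a symmetric
#'   positive-definite [labeled_matrix()] giving the initial combined
#'   relationship estimate on the relationship (Sigma) scale.  When a
#'   matrix is supplied its labels define the genotype set, and must cover
#'   every genotype appearing in the samples.
#' @return an object of class `em_config`.
#' @export
em_config <- function(nu = NULL, tol = 1e-6, max_iter = 200L, jitter = 0,
                      init = "identity") {
  if (!is.null(nu)) {
    stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0)
  }
  stopifnot(is.numeric(tol), length(tol) == 1L, tol >= 0)
  max_iter <- as.integer(max_iter)
  stopifnot(max_iter >= 1L)
  stopifnot(is.numeric(jitter), length(jitter) == 1L, jitter >= 0)
  if (!(identical(init, "identity") || inherits(init, "labeled_matrix"))) {
    stop("'init' must be \"identity\" or a labeled_matrix")
  }
  structure(list(nu = nu, tol = tol, max_iter = max_iter, jitter = jitter,
                 init = init),
            class = "em_config")
}

# Cholesky with escalating ridge; returns list(R, jitter_used).
chol_ridge <- function(m, jitter = 0, what = "block") {
  scale <- mean(diag(m))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  ridges <- unique(c(jitter, 1e-10, 1e-8, 1e-6, 1e-4))
  for (r in ridges) {
    mm <- if (r > 0) m + diag(r * scale, nrow(m)) else m
    R <- tryCatch(chol(mm), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter_used = r))
  }
  stop(sprintf("%s is singular even after regularization (labels: %s)",
               what, paste(utils::head(rownames(m), 5L), collapse = ", ")))
}

chol_solve <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

#' Conditional blocks of a partitioned scale matrix
#'
#' For a partition of the genotypes into the observed subset `a` and its
#' complement `b`, returns the matrix of regression coefficients of `b` on
#' `a`, `B = Psi_ba Psi_a^{-1}`, and the conditional covariance
#' `Psi_{b|a} = Psi_b - Psi_ba Psi_a^{-1} Psi_ab`.
#'
#' @param psi a [labeled_matrix()] over the full genotype set.
#' @param a character vector of labels in `psi` (the observed subset), in
#'   the order of the partial kernel.
#' @param jitter relative ridge used if the `a` block is numerically
#'   singular (see [em_config()]).
#' @return list with elements `B` (|b| x |a|), `psi_cond` (|b| x |b|,
#'   symmetric), `labels_a`, `labels_b`.
#' @export
conditional_blocks <- function(psi, a, jitter = 0) {
  labs <- rownames(psi)
  ia <- match(a, labs)
  if (anyNA(ia)) {
    stop("subset labels not in psi: ", paste(a[is.na(ia)], collapse = ", "))
  }
  ib <- setdiff(seq_along(labs), ia)
  m <- lm_values(psi)
  Pa <- m[ia, ia, drop = FALSE]
  if (length(ib) == 0L) {
    return(list(B = matrix(0, 0L, length(ia)),
                psi_cond = matrix(0, 0L, 0L),
                labels_a = labs[ia], labels_b = character(0)))
  }
  Pab <- m[ia, ib, drop = FALSE]
  cr <- chol_ridge(Pa, jitter, what = "observed block")
  AinvAab <- chol_solve(cr$R, Pab)          # Psi_a^{-1} Psi_ab, |a| x |b|
  B <- t(AinvAab)                           # Psi_ba Psi_a^{-1}, |b| x |a|
  psi_cond <- m[ib, ib, drop = FALSE] - crossprod(Pab, AinvAab)
  psi_cond <- (psi_cond + t(psi_cond)) / 2
  list(B = B, psi_cond = psi_cond,
       labels_a = labs[ia], labels_b = labs[ib])
}

# Shared completion kernel: given the current scale matrix psi over K, a
# genotype subset (labels) with an observed |a| x |a| kernel g, and nu,
# return the completed n x n matrix in psi's label order:
#   [ g, g B' ; B g, nu * Psi_{b|a} + B g B' ]
complete_one <- function(psi, labs_a, g, nu, jitter = 0) {
  labs <- rownames(psi)
  n <- length(labs)
  cb <- conditional_blocks(psi, labs_a, jitter)
  ia <- match(labs_a, labs)
  ib <- match(cb$labels_b, labs)
  out <- matrix(0, n, n)
  out[ia, ia] <- g
  if (length(ib) > 0L) {
    Bg <- cb$B %*% g
    out[ib, ia] <- Bg
    out[ia, ib] <- t(Bg)
    out[ib, ib] <- nu * cb$psi_cond + tcrossprod(Bg, cb$B)
  }
  (out + t(out)) / 2
}

#' Expected completion of one partial sample
#'
#' The E-step quantity for a single partial kernel: the conditional
#' expectation of the full Wishart draw given its observed block, aligned
#' to the label order of `psi`.  The observed block is reproduced exactly;
#' the unobserved blocks are filled by the conditional mean under the
#' Wishart model.
#'
#' @param psi current scale matrix ([labeled_matrix()] over the union).
#' @param sample a [partial_sample()] whose labels are contained in `psi`.
#' @param nu Wishart degrees of freedom.
#' @param jitter see [em_config()].
#' @return a symmetric numeric matrix with the dimension of `psi`.
#' @export
expected_completion <- function(psi, sample, nu, jitter = 0) {
  sample <- as_partial_samples(sample)[[1L]]
  complete_one(psi, rownames(sample$kernel), lm_values(sample$kernel),
               nu, jitter)
}

#' Reliability blend of an observed kernel with the model prediction
#'
#' Weighted version of the update: the observed kernel `G_a` is replaced
#' by the convex blend `w G_a + (1 - w) nu Psi_a` before completion.
#'
#' @param sample a [partial_sample()] with weight `w`.
#' @param psi current scale matrix over the union.
#' @param nu Wishart degrees of freedom.
#' @return numeric |a| x |a| matrix.
#' @export
blend_weighted <- function(sample, psi, nu) {
  sample <- as_partial_samples(sample)[[1L]]
  labs_a <- rownames(sample$kernel)
  ia <- match(labs_a, rownames(psi))
  if (anyNA(ia)) {
    stop("sample labels not in psi: ",
         paste(labs_a[is.na(ia)], collapse = ", "))
  }
  w <- sample$weight
  g <- lm_values(sample$kernel)
  if (w == 1) return(g)
  Pa <- lm_values(psi)[ia, ia, drop = FALSE]
  w * g + (1 - w) * nu * Pa
}

#' One EM update of the scale matrix
#'
#' Averages the (weight-blended) expected completions of all samples and
#' divides by `nu`:
#' `Psi^(t+1) = 1/(nu m) * sum_a P_a [completed_a] P_a'`.
#'
#' @param psi_t current scale matrix over the union `K`.
#' @param samples list of [partial_sample()] with labels inside `K`.
#' @param nu Wishart degrees of freedom.
#' @param jitter see [em_config()].
#' @return the updated scale matrix, a [labeled_matrix()] with the labels
#'   of `psi_t`.
#' @export
em_update <- function(psi_t, samples, nu, jitter = 0) {
  samples <- as_partial_samples(samples)
  m <- length(samples)
  n <- nrow(psi_t)
  acc <- matrix(0, n, n)
  for (s in samples) {
    g <- blend_weighted(s, psi_t, nu)
    acc <- acc + complete_one(psi_t, rownames(s$kernel), g, nu, jitter)
  }
  labeled_matrix(acc / (nu * m), labels = rownames(psi_t),
                 symmetrize = TRUE)
}

# log of the multivariate gamma function
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Wishart log-likelihood of the partial samples
#'
#' Sum over samples of the log density of `G_a ~ Wishart(nu, Psi_a)`,
#' where `Psi_a` is the block of `psi` for the sample's genotypes.
#' Samples with `nu <= |a| - 1` (density undefined) are skipped with a
#' warning.
#'
#' @param samples list of [partial_sample()].
#' @param psi scale matrix over the union ([labeled_matrix()]).
#' @param nu Wishart degrees of freedom.
#' @param jitter ridge used if a block factorization fails.
#' @return scalar log-likelihood.
#' @export
wishart_loglik <- function(samples, psi, nu, jitter = 0) {
  samples <- as_partial_samples(samples)
  labs <- rownames(psi)
  mpsi <- lm_values(psi)
  ll <- 0
  for (s in samples) {
    g <- lm_values(s$kernel)
    p <- nrow(g)
    if (nu <= p - 1) {
      warning(sprintf(
        "sample with %d genotypes skipped in log-likelihood: nu = %g <= %d",
        p, nu, p - 1L))
      next
    }
    ia <- match(rownames(s$kernel), labs)
    if (anyNA(ia)) stop("sample labels not in psi")
    Pa <- mpsi[ia, ia, drop = FALSE]
    crp <- chol_ridge(Pa, jitter, what = "scale block")
    crg <- chol_ridge(g, jitter, what = "observed kernel")
    logdet_psi <- 2 * sum(log(diag(crp$R)))
    logdet_g <- 2 * sum(log(diag(crg$R)))
    tr_term <- sum(diag(chol_solve(crp$R, g)))
    ll <- ll + (nu - p - 1) / 2 * logdet_g - tr_term / 2 -
      nu * p / 2 * log(2) - nu / 2 * logdet_psi - lmvgamma(nu / 2, p)
  }
  ll
}

#' Combine partial relationship matrices by the Wishart EM algorithm
#'
#' Each observed kernel `G_a` over a genotype subset `a` is modelled as a
#' draw from `Wishart(nu, Psi_a)`, so that `E[G_a] = nu Psi_a = Sigma_a`
#' is the corresponding block of the combined relationship matrix
#' `Sigma`.  Starting from `Sigma^(0)` (identity by default), the EM
#' iteration completes each sample by its conditional expectation given
#' the observed block and averages the completions; the estimate at the
#' last iteration converts to the combined relationship matrix
#' `Sigma = nu Psi`.  The estimate does not depend on `nu`.
#'
#' When `init` is a full relationship matrix (e.g. a pedigree A-matrix)
#' and a single nested genomic kernel is supplied, one iteration
#' reproduces the single-step H-matrix exactly (see [hmatrix_oracle()]).
#'
#' @param samples non-empty list of [partial_sample()] (bare
#'   [labeled_matrix()] objects accepted, weight 1).
#' @param config an [em_config()].
#' @return an object of class `combine_result` with elements
#'   `sigma` (combined relationship matrix, `labeled_matrix` over the
#'   genotype set `K`), `nu`, `n_iter`, `loglik_trace` (log-likelihood at
#'   the initial value and after each update), `converged`,
#'   `observed_mask` (logical matrix, `TRUE` where the entry was observed
#'   in at least one sample), and `config`.
#' @export
combine_em <- function(samples, config = em_config()) {
  samples <- as_partial_samples(samples)
  stopifnot(inherits(config, "em_config"))
  al <- union_align(samples)

  nu <- config$nu
  if (is.null(nu)) {
    nf <- unlist(lapply(samples, function(s) attr(s$kernel, "n_features")))
    nu <- if (length(nf) > 0L) mean(nf) else 1000
  }

  # genotype set: the sample union, or the init matrix's labels when a
  # full prior matrix is provided (its extra genotypes stay and are
  # updated through the conditional expectations)
  if (identical(config$init, "identity")) {
    K <- al$labels
    sigma0 <- diag(length(K))
    dimnames(sigma0) <- list(K, K)
  } else {
    K <- rownames(config$init)
    missing_labs <- setdiff(al$labels, K)
    if (length(missing_labs) > 0L) {
      stop("init matrix does not cover sample genotypes: ",
           paste(utils::head(missing_labs, 5L), collapse = ", "))
    }
    sigma0 <- lm_values(config$init)
    if (is.null(tryCatch(chol(sigma0), error = function(e) NULL))) {
      stop("init matrix must be symmetric positive definite")
    }
  }
  n <- length(K)
  psi <- labeled_matrix(sigma0 / nu, labels = K)

  loglik <- suppressWarnings(wishart_loglik(samples, psi, nu, config$jitter))
  trace <- loglik
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(config$max_iter)) {
    psi_new <- em_update(psi, samples, nu, config$jitter)
    delta <- frob(lm_values(psi_new) - lm_values(psi)) /
      max(frob(lm_values(psi)), .Machine$double.eps)
    trace <- c(trace,
               suppressWarnings(wishart_loglik(samples, psi_new, nu,
                                               config$jitter)))
    psi <- psi_new
    iter <- t
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d iterations (tol %g)",
                    config$max_iter, config$tol))
  }

  mask <- matrix(FALSE, n, n, dimnames = list(K, K))
  for (s in samples) {
    ia <- match(rownames(s$kernel), K)
    mask[ia, ia] <- TRUE
  }

  structure(list(
    sigma = labeled_matrix(nu * lm_values(psi), labels = K,
                           source = "combine_em"),
    nu = nu,
    n_iter = iter,
    loglik_trace = trace,
    converged = converged,
    observed_mask = mask,
    config = config
  ), class = "combine_result")
}

frob <- function(m) sqrt(sum(m^2))

#' @export
print.combine_result <- function(x, ...) {
  cat(sprintf(
    "combine_result: %d genotypes, nu = %g, %d iterations (%s)\n",
    nrow(x$sigma), x$nu, x$n_iter,
    if (x$converged) "converged" else "not converged"))
  cat(sprintf("  observed entries: %.1f%%; final loglik: %.4f\n",
              100 * mean(x$observed_mask),
              utils::tail(x$loglik_trace, 1L)))
  invisible(x)
}

#' Closed-form single-step H-matrix
#'
#' Blends a full relationship matrix `A` (e.g. pedigree-based) with a
#' genomic kernel `G` observed on a nested subset of genotypes (index 2 =
#' genotyped, 1 = the rest):
#' `H22 = G`, `H12 = A12 A22^{-1} G`,
#' `H11 = A11 + A12 A22^{-1} (G - A22) A22^{-1} A21`.
#' One EM iteration of [combine_em()] with `init = A` and the single
#' sample `G` reproduces this matrix exactly.
#'
#' @param a_full a [labeled_matrix()] over all genotypes.
#' @param g_nested a [labeled_matrix()] over a strict subset of
#'   `a_full`'s genotypes.
#' @return a [labeled_matrix()] with the labels (and order) of `a_full`.
#' @export
hmatrix_oracle <- function(a_full, g_nested) {
  labs <- rownames(a_full)
  labs_g <- rownames(g_nested)
  i2 <- match(labs_g, labs)
  if (anyNA(i2)) {
    stop("genotyped labels not in A: ",
         paste(labs_g[is.na(i2)], collapse = ", "))
  }
  i1 <- setdiff(seq_along(labs), i2)
  A <- lm_values(a_full)
  G <- lm_values(g_nested)
  A22 <- A[i2, i2, drop = FALSE]
  cr <- chol_ridge(A22, what = "A22 block")
  H <- A
  H[i2, i2] <- G
  if (length(i1) > 0L) {
    A12 <- A[i1, i2, drop = FALSE]
    W <- t(chol_solve(cr$R, t(A12)))          # A12 A22^{-1}
    H12 <- W %*% G
    H[i1, i2] <- H12
    H[i2, i1] <- t(H12)
    H[i1, i1] <- A[i1, i1, drop = FALSE] + W %*% (G - A22) %*% t(W)
  }
  labeled_matrix(H, labels = labs, source = "hmatrix_oracle",
                 symmetrize = TRUE)
}
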