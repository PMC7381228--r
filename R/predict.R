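#' Single-kernel REML by spectral decomposition
#'
#' Fits the G-BLUP model `y = 1 mu + g + e`, `g ~ N(0, sigma2_g K)`,
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood.  The kernel is
#' eigendecomposed once and the REML criterion is profiled down to a 1-D
#' optimization of the variance ratio `lambda = sigma2_g / sigma2_e`,
#' which is robust and dependency-light.
#'
#' @param y named numeric vector of phenotypes; names must be genotype
#'   labels contained in `k`.
#' @param k a PSD [labeled_matrix()] kernel.
#' @param lambda_bounds search interval for `log(lambda)`.
#' @return an object of class `mixed_model_fit` with elements
#'   `var_components` (named: one per kernel, then `residual`),
#'   `fixed_effects` (intercept), `genotype_effects` (named GEBVs for the
#'   training genotypes), `h2`, `train_labels`, `loglik` (profiled REML
#'   log-likelihood at the optimum, up to a constant), `method`.
#' @export
reml_spectral <- function(y, k, lambda_bounds = c(-12, 12)) {
  stopifnot(is.numeric(y), !is.null(names(y)))
  labs <- names(y)
  if (anyDuplicated(labs)) stop("duplicate genotype labels in 'y'")
  n <- length(y)
  if (n < 3L) stop("need at least 3 phenotyped genotypes")
  if (anyNA(match(labs, rownames(k)))) {
    stop("phenotyped genotypes missing from kernel: ",
         paste(setdiff(labs, rownames(k)), collapse = ", "))
  }
  K <- lm_values(subset_kernel(k, labs))

  if (stats::var(y) < 1e-14 * max(1, mean(y)^2)) {
    # no phenotypic variance: both components vanish
    return(new_mixed_model_fit(
      var_components = c(genetic = 0, residual = 0),
      fixed_effects = c(intercept = mean(y)),
      genotype_effects = stats::setNames(rep(0, n), labs),
      h2 = 0, train_labels = labs, loglik = NA_real_,
      method = "reml_spectral"))
  }

  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  if (diff(range(d)) < 1e-10 * max(d, 1)) {
    stop("kernel is proportional to the identity; genetic and residual ",
         "variances are not separately identifiable")
  }
  U <- e$vectors
  uy <- drop(crossprod(U, y))
  ux <- drop(crossprod(U, rep(1, n)))

  # profiled REML criterion in log(lambda)
  crit <- function(lt) {
    lam <- exp(lt)
    v <- lam * d + 1
    xvx <- sum(ux^2 / v)
    beta <- sum(ux * uy / v) / xvx
    r <- uy - beta * ux
    rvr <- sum(r^2 / v)
    0.5 * (sum(log(v)) + log(xvx) + (n - 1) * log(rvr))
  }
  opt <- stats::optimize(crit, lambda_bounds)
  lam <- exp(opt$minimum)
  v <- lam * d + 1
  xvx <- sum(ux^2 / v)
  beta <- sum(ux * uy / v) / xvx
  r <- uy - beta * ux
  sigma_e <- sum(r^2 / v) / (n - 1)
  sigma_g <- lam * sigma_e
  # BLUP: g_hat = sigma_g K V^{-1} (y - X beta) = U diag(lam d/(lam d+1)) U' r
  ghat <- drop(U %*% ((lam * d / v) * r))
  names(ghat) <- labs

  new_mixed_model_fit(
    var_components = c(genetic = sigma_g, residual = sigma_e),
    fixed_effects = c(intercept = beta),
    genotype_effects = ghat,
    h2 = sigma_g / (sigma_g + sigma_e),
    train_labels = labs,
    loglik = -opt$objective,
    method = "reml_spectral")
}

new_mixed_model_fit <- function(var_components, fixed_effects,
                                genotype_effects, h2, train_labels,
                                loglik, method) {
  structure(list(var_components = var_components,
                 fixed_effects = fixed_effects,
                 genotype_effects = genotype_effects,
                 h2 = h2, train_labels = train_labels,
                 loglik = loglik, method = method),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit (%s): %d training genotypes\n",
              x$method, length(x$train_labels)))
  vc <- paste(sprintf("%s = %.4g", names(x$var_components),
                      x$var_components), collapse = ", ")
  cat("  variance components:", vc, "\n")
  cat(sprintf("  h2 = %.3f\n", x$h2))
  invisible(x)
}

#' Predict GEBVs for unphenotyped genotypes
#'
#' Conditional-mean prediction: `g_test = K21 K11^{-1} g_train`, where
#' index 1 is the training set and 2 the test set.  Equivalent to solving
#' the full mixed-model equations with the test phenotypes missing.
#'
#' @param fit a `mixed_model_fit` from [reml_spectral()] or
#'   [multikernel_reml()] (for the latter, `k_full` should be the summed
#'   kernel or any kernel on the same scale used for prediction).
#' @param k_full a [labeled_matrix()] covering both training and test
#'   genotypes.
#' @param test_labels character vector of genotypes to predict.
#' @return named numeric vector of GEBVs for `test_labels`.
#' @export
gblup_predict <- function(fit, k_full, test_labels) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  labs <- rownames(k_full)
  missing_test <- setdiff(test_labels, labs)
  if (length(missing_test) > 0L) {
    stop("test genotypes absent from kernel: ",
         paste(missing_test, collapse = ", "))
  }
  missing_train <- setdiff(fit$train_labels, labs)
  if (length(missing_train) > 0L) {
    stop("training genotypes absent from kernel: ",
         paste(missing_train, collapse = ", "))
  }
  i1 <- match(fit$train_labels, labs)
  i2 <- match(test_labels, labs)
  Km <- lm_values(k_full)
  K11 <- Km[i1, i1, drop = FALSE]
  K21 <- Km[i2, i1, drop = FALSE]
  cr <- chol_ridge(K11, jitter = 1e-8, what = "training kernel block")
  g <- fit$genotype_effects[fit$train_labels]
  pred <- drop(K21 %*% chol_solve(cr$R, g))
  names(pred) <- test_labels
  pred
}

#' Multiple-kernel mixed model by AI-REML
#'
#' Fits `y = 1 mu + sum_k g_k + e` with `g_k ~ N(0, sigma2_k K_k)`; one
#' variance component per kernel plus a residual.  The components are
#' estimated by average-information REML with EM-REML fallback steps
#' whenever an AI step is unstable (warm-up, singular average
#' information, or a step outside the parameter space), which combines
#' the EM algorithm's monotone stability with quadratic convergence near
#' the optimum.  GEBVs are the sums of the per-kernel BLUPs.
#'
#' @param y named numeric vector of phenotypes.
#' @param kernels list of [labeled_matrix()] kernels covering the
#'   phenotyped genotypes.
#' @param max_iter,tol iteration controls (relative change in the
#'   variance components).
#' @return a `mixed_model_fit`; `var_components` holds one entry per
#'   kernel followed by `residual`.
#' @export
multikernel_reml <- function(y, kernels, max_iter = 200L, tol = 1e-10) {
  stopifnot(is.numeric(y), !is.null(names(y)))
  if (!is.list(kernels) || length(kernels) < 1L) {
    stop("'kernels' must be a non-empty list of labeled matrices")
  }
  labs <- names(y)
  n <- length(y)
  Ks <- lapply(kernels, function(k) lm_values(subset_kernel(k, labs)))
  nk <- length(Ks)
  if (nk >= 2L) {
    for (i in seq_len(nk - 1L)) {
      for (j in seq(i + 1L, nk)) {
        if (frob(Ks[[i]] - Ks[[j]]) <= 1e-10 * max(frob(Ks[[i]]), 1)) {
          warning(sprintf(
            "kernels %d and %d are numerically identical; only their summed genetic variance is identifiable",
            i, j))
        }
      }
    }
  }
  vy <- stats::var(y)
  if (vy < 1e-14 * max(1, mean(y)^2)) {
    return(new_mixed_model_fit(
      var_components = stats::setNames(rep(0, nk + 1L),
                                       c(paste0("kernel", seq_len(nk)),
                                         "residual")),
      fixed_effects = c(intercept = mean(y)),
      genotype_effects = stats::setNames(rep(0, n), labs),
      h2 = 0, train_labels = labs, loglik = NA_real_,
      method = "multikernel_emreml"))
  }

  sig <- rep(vy / (nk + 1L), nk + 1L)  # kernels 1..nk, residual last
  X <- matrix(1, n, 1L)
  floor_sig <- 1e-10 * vy
  for (it in seq_len(max_iter)) {
    V <- diag(sig[nk + 1L], n)
    for (kk in seq_len(nk)) V <- V + sig[kk] * Ks[[kk]]
    cr <- chol_ridge(V, what = "covariance matrix")
    Vinv <- chol2inv(cr$R)
    VinvX <- Vinv %*% X
    xvx <- drop(crossprod(X, VinvX))
    P <- Vinv - tcrossprod(VinvX) / xvx
    Py <- drop(P %*% y)
    KPy <- vector("list", nk + 1L)
    for (kk in seq_len(nk)) KPy[[kk]] <- drop(Ks[[kk]] %*% Py)
    KPy[[nk + 1L]] <- Py
    quad <- vapply(KPy, function(v) sum(Py * v), numeric(1L))
    trPK <- c(vapply(seq_len(nk), function(kk) sum(P * Ks[[kk]]),
                     numeric(1L)), sum(diag(P)))
    score <- 0.5 * (quad - trPK)

    sig_new <- NULL
    if (it > 3L) {
      # average-information step: AI_ij = 0.5 * y'P K_i P K_j P y
      PKPy <- lapply(KPy, function(v) drop(P %*% v))
      AI <- matrix(0, nk + 1L, nk + 1L)
      for (i in seq_len(nk + 1L)) {
        for (j in i:(nk + 1L)) {
          AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
        }
      }
      delta <- tryCatch(solve(AI, score), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- sig + delta
        if (all(is.finite(cand)) && all(cand > -floor_sig) &&
            max(cand) < 1e6 * vy) {
          sig_new <- pmax(cand, floor_sig)
        }
      }
    }
    if (is.null(sig_new)) {
      # EM-REML fallback: monotone and always inside the parameter space
      sig_new <- pmax(sig + sig^2 / n * (quad - trPK), floor_sig)
    }
    step <- max(abs(sig_new - sig) / (abs(sig) + 1e-12 * vy))
    sig <- sig_new
    if (step < tol) break
  }

  # final quantities at the converged components
  V <- diag(sig[nk + 1L], n)
  for (kk in seq_len(nk)) V <- V + sig[kk] * Ks[[kk]]
  cr <- chol_ridge(V, what = "covariance matrix")
  Vinv <- chol2inv(cr$R)
  VinvX <- Vinv %*% X
  xvx <- drop(crossprod(X, VinvX))
  beta <- drop(crossprod(VinvX, y)) / xvx
  P <- Vinv - tcrossprod(VinvX) / xvx
  Py <- drop(P %*% y)
  ghat <- rep(0, n)
  for (kk in seq_len(nk)) ghat <- ghat + sig[kk] * drop(Ks[[kk]] %*% Py)
  names(ghat) <- labs
  sg <- sum(sig[seq_len(nk)])

  new_mixed_model_fit(
    var_components = stats::setNames(sig, c(paste0("kernel", seq_len(nk)),
                                            "residual")),
    fixed_effects = c(intercept = beta),
    genotype_effects = ghat,
    h2 = if (sg + sig[nk + 1L] > 0) sg / (sg + sig[nk + 1L]) else 0,
    train_labels = labs,
    loglik = NA_real_,
    method = "multikernel_emreml")
}

#' Random k-fold cross-validation of G-BLUP accuracy
#'
#' Splits the phenotyped genotypes into random folds, fits the
#' single-kernel model on each training split and predicts the held-out
#' genotypes.  Accuracy is the Pearson correlation between GEBVs and
#' observed phenotypes, per fold and pooled over all out-of-fold
#' predictions.
#'
#' @param y named numeric vector of phenotypes.
#' @param k kernel ([labeled_matrix()]) covering the genotypes.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @return list with `folds` (data.frame: fold, n_test, accuracy),
#'   `pooled` (scalar pooled accuracy) and `predictions` (named vector of
#'   out-of-fold GEBVs).
#' @export
cv_random_folds <- function(y, k, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  labs <- names(y)
  n <- length(y)
  fold <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  sizes <- tabulate(fold, n_folds)
  if (any(sizes < 3L) || any(n - sizes < 3L)) {
    stop("a fold has fewer than 3 genotypes (or leaves fewer than 3 for ",
         "training); reduce n_folds")
  }
  preds <- stats::setNames(rep(NA_real_, n), labs)
  rows <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- labs[fold == f]
    train <- labs[fold != f]
    fit <- reml_spectral(y[train], k)
    p <- gblup_predict(fit, k, test)
    preds[test] <- p
    rows[[f]] <- data.frame(fold = f, n_test = length(test),
                            accuracy = safe_cor(p, y[test]))
  }
  list(folds = do.call(rbind, rows),
       pooled = safe_cor(preds, y),
       predictions = preds)
}

#' Leave-one-dataset-out cross-validation
#'
#' For every dataset, the phenotypes of its genotypes are held out, the
#' model is trained on all remaining genotypes and the held-out genotypes
#' are predicted; accuracy is the within-dataset Pearson correlation of
#' GEBVs and observed values.
#'
#' @param y named numeric vector of phenotypes.
#' @param k kernel covering the genotypes.
#' @param membership named character vector mapping genotype label to
#'   dataset id.
#' @return data.frame with columns `dataset`, `n_test`, `accuracy`.
#' @export
cv_leave_dataset_out <- function(y, k, membership) {
  labs <- names(y)
  if (is.null(names(membership))) stop("'membership' must be named")
  ds <- membership[labs]
  if (anyNA(ds)) {
    stop("genotypes without dataset membership: ",
         paste(utils::head(labs[is.na(ds)], 5L), collapse = ", "))
  }
  datasets <- unique(ds)
  if (length(datasets) < 2L) stop("need at least 2 datasets")
  rows <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    dd <- datasets[i]
    test <- labs[ds == dd]
    train <- labs[ds != dd]
    yt <- y[test]
    if (all(is.na(yt))) {
      warning("dataset '", dd, "' has no observed phenotypes; skipped")
      next
    }
    fit <- reml_spectral(y[train], k)
    p <- gblup_predict(fit, k, test)
    rows[[i]] <- data.frame(dataset = dd, n_test = length(test),
                            accuracy = safe_cor(p, yt))
  }
  do.call(rbind, rows)
}

safe_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])
}

# Run code under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
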