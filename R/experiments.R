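#' Low-rank matrix completion by iterative soft-thresholded SVD
#'
#' Completes a partially observed numeric matrix: missing entries are
#' initialized at column means, then the matrix is repeatedly replaced by
#' its soft-thresholded rank-`rank` SVD reconstruction on the missing
#' entries while observed entries are held fixed.  With `lam = 0` this is
#' hard-truncated iterative SVD.
#'
#' @param x numeric matrix with `NA` for missing entries; every row and
#'   column must have at least one observed entry.
#' @param rank maximum rank of the reconstruction.
#' @param lam non-negative soft-threshold applied to the singular values.
#' @param max_iter,tol iteration controls (relative Frobenius change of
#'   the reconstruction).
#' @return list with `completed` (observed entries exact, missing entries
#'   imputed), `fitted` (the low-rank reconstruction), `n_iter`,
#'   `converged`.
#' @export
soft_impute_matrix <- function(x, rank = min(50L, dim(x)), lam = 0,
                               max_iter = 100L, tol = 1e-5) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), lam >= 0)
  rank <- min(as.integer(rank)[1L], nrow(x), ncol(x))
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L)) stop("row with no observed entries")
  if (any(colSums(obs) == 0L)) stop("column with no observed entries")
  if (all(obs)) {
    return(list(completed = x, fitted = x, n_iter = 0L, converged = TRUE))
  }
  cm <- colMeans(x, na.rm = TRUE)
  Z <- x
  Z[!obs] <- rep(cm, each = nrow(x))[!obs]
  fitted_old <- NULL
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    sv <- trunc_svd(Z, rank)
    d <- pmax(sv$d - lam, 0)
    keep <- which(d > 0)
    if (length(keep) == 0L) {
      fitted <- matrix(0, nrow(x), ncol(x))
    } else {
      fitted <- sv$u[, keep, drop = FALSE] %*%
        (d[keep] * t(sv$v[, keep, drop = FALSE]))
    }
    iter <- it
    if (!is.null(fitted_old)) {
      delta <- frob(fitted - fitted_old) / max(frob(fitted_old), 1e-12)
      if (delta < tol) {
        converged <- TRUE
        fitted_old <- fitted
        Z[!obs] <- fitted[!obs]
        break
      }
    }
    fitted_old <- fitted
    Z[!obs] <- fitted[!obs]
  }
  completed <- x
  completed[!obs] <- Z[!obs]
  list(completed = completed, fitted = fitted_old, n_iter = iter,
       converged = converged)
}

# Truncated SVD via the Gram matrix of the smaller side; adequate here
# because small singular values are discarded anyway.
trunc_svd <- function(Z, rank) {
  nr <- nrow(Z)
  nc <- ncol(Z)
  r <- min(rank, nr, nc)
  if (nr <= nc) {
    e <- eigen(tcrossprod(Z), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(r)], 0))
    u <- e$vectors[, seq_len(r), drop = FALSE]
    v <- crossprod(Z, u)
    pos <- d > max(d[1L], 1e-300) * 1e-12
    v[, pos] <- sweep(v[, pos, drop = FALSE], 2L, d[pos], "/")
    v[, !pos] <- 0
  } else {
    e <- eigen(crossprod(Z), symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(r)], 0))
    v <- e$vectors[, seq_len(r), drop = FALSE]
    u <- Z %*% v
    pos <- d > max(d[1L], 1e-300) * 1e-12
    u[, pos] <- sweep(u[, pos, drop = FALSE], 2L, d[pos], "/")
    u[, !pos] <- 0
  }
  list(u = u, d = d, v = v)
}

#' Impute missing marker dosages by low-rank completion
#'
#' [soft_impute_matrix()] applied to a dosage matrix; imputed dosages are
#' clipped to `[0, ploidy]`, observed dosages are preserved exactly.
#'
#' @param m a [marker_matrix()] with missing entries.
#' @param rank,lam,max_iter,tol see [soft_impute_matrix()].
#' @return a completed [marker_matrix()].
#' @export
soft_impute <- function(m, rank = min(50L, dim(m)), lam = 0,
                        max_iter = 100L, tol = 1e-5) {
  if (!inherits(m, "marker_matrix")) stop("'m' must be a marker_matrix")
  ploidy <- attr(m, "ploidy")
  res <- soft_impute_matrix(mm_values(m), rank = rank, lam = lam,
                            max_iter = max_iter, tol = tol)
  comp <- pmin(pmax(res$completed, 0), ploidy)
  marker_matrix(comp, genotype_labels = rownames(m),
                marker_labels = colnames(m), ploidy = ploidy)
}

#' Compare an estimated relationship matrix with the truth
#'
#' Mean squared error and Pearson correlation over the upper triangle
#' (diagonal included) of the entries selected by `mask`.
#'
#' @param estimate,truth [labeled_matrix()] objects with identical
#'   labels.
#' @param mask logical matrix selecting entries (symmetric), or the
#'   string `"all"`.
#' @return list with `mse`, `correlation`, `n_entries`.
#' @export
evaluate_estimate <- function(estimate, truth, mask = "all") {
  if (!identical(rownames(estimate), rownames(truth))) {
    stop("'estimate' and 'truth' must carry identical labels")
  }
  n <- nrow(estimate)
  sel <- upper.tri(matrix(0, n, n), diag = TRUE)
  if (!identical(mask, "all")) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(sel))) stop("mask dimension mismatch")
    sel <- sel & mask
  }
  if (!any(sel)) stop("mask selects no entries")
  a <- lm_values(estimate)[sel]
  b <- lm_values(truth)[sel]
  list(mse = mean((a - b)^2),
       correlation = safe_cor(a, b),
       n_entries = length(a))
}

#' Anchoring experiment: connecting two pedigrees through a genomic kernel
#'
#' Per replicate, a pedigree population is simulated by gene drop and two
#' disjoint sets of individuals are treated as independent pedigrees whose
#' A-matrices carry no cross-information.  A genomic relationship matrix
#' built on a genotyped subsample (half from each pedigree) anchors them;
#' the three kernels are combined and the estimated cross-pedigree
#' relationships are compared with the full-pedigree A-matrix on the
#' entries observed in none of the three kernels.
#'
#' @param n_per_pedigree individuals per pedigree.
#' @param n_genotyped_per_pedigree scalar or vector: genotyped individuals
#'   sampled from each pedigree (each value is a condition).
#' @param n_markers markers used for the genomic kernel.
#' @param reps replicates per condition.
#' @param seed integer seed.
#' @param em_tol,em_max_iter convergence controls passed to [combine_em()].
#' @return data.frame (`accuracy_report`) with one row per replicate and
#'   condition: `replicate`, `n_per_pedigree`, `n_genotyped`, `mse`,
#'   `correlation`, `n_entries`.
#' @export
run_anchor_experiment <- function(n_per_pedigree = 100L,
                                  n_genotyped_per_pedigree = c(10L, 20L, 40L),
                                  n_markers = 2000L, reps = 20L, seed = 1L,
                                  em_tol = 1e-5, em_max_iter = 200L) {
  stopifnot(all(n_genotyped_per_pedigree <= n_per_pedigree))
  rows <- list()
  for (r in seq_len(reps)) {
    rep_seed <- seed + 1000L * r
    # enough non-founder individuals for the two pedigrees
    gens <- 2L
    while (pop_size(16L, gens, 4L) < 2L * n_per_pedigree) gens <- gens + 1L
    sim <- simulate_pedigree_genedrop(n_founders = 16L,
                                      n_generations = gens,
                                      offspring_per_cross = 4L,
                                      n_markers = n_markers,
                                      seed = rep_seed)
    A_full <- amatrix_tabular(sim$pedigree)
    nonf <- sim$pedigree$id[!is.na(sim$pedigree$sire)]
    picked <- with_seed(rep_seed + 1L,
                        sample(nonf, 2L * n_per_pedigree))
    set1 <- picked[seq_len(n_per_pedigree)]
    set2 <- picked[n_per_pedigree + seq_len(n_per_pedigree)]
    members <- c(set1, set2)
    truth <- subset_kernel(A_full, members)
    in1 <- members %in% set1
    cross <- outer(in1, in1, "!=")
    dimnames(cross) <- list(members, members)

    for (ng in n_genotyped_per_pedigree) {
      gsub <- c(with_seed(rep_seed + 2L + ng, sample(set1, ng)),
                with_seed(rep_seed + 3L + ng, sample(set2, ng)))
      G <- grm_vanraden(marker_subset(sim$markers, gsub))
      samples <- list(
        partial_sample(subset_kernel(A_full, set1)),
        partial_sample(subset_kernel(A_full, set2)),
        partial_sample(G))
      res <- combine_em(samples,
                        em_config(nu = n_markers, tol = em_tol,
                                  max_iter = em_max_iter))
      sig <- subset_kernel(res$sigma, c(set1, set2))
      mask_obs <- res$observed_mask[c(set1, set2), c(set1, set2)]
      ev <- evaluate_estimate(sig, truth, mask = cross & !mask_obs)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, n_per_pedigree = n_per_pedigree, n_genotyped = ng,
        mse = ev$mse, correlation = ev$correlation,
        n_entries = ev$n_entries)
    }
  }
  as_accuracy_report(do.call(rbind, rows))
}

pop_size <- function(n_founders, n_generations, opc) {
  cur <- n_founders
  tot <- 0L
  for (g in seq_len(n_generations)) {
    cur <- floor(cur / 2) * opc
    tot <- tot + cur
  }
  tot
}

marker_subset <- function(m, genotypes, markers = NULL) {
  X <- mm_values(m)
  gi <- match(genotypes, rownames(m))
  if (anyNA(gi)) stop("unknown genotype labels")
  X <- X[gi, , drop = FALSE]
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  marker_matrix(X, ploidy = attr(m, "ploidy"))
}

#' Combining sub-panel kernels versus imputing the markers
#'
#' Per replicate, a full marker panel is simulated and its VanRaden GRM
#' taken as the ground truth.  `n_kernels` sub-panels (random genotype and
#' marker subsets) are drawn; their GRMs are combined by the Wishart EM
#' algorithm, and, as the baseline, the union genotype-by-marker matrix
#' (markers unobserved in a genotype's panels set missing) is completed by
#' [soft_impute()] and turned into a GRM.  Both estimates are compared
#' with the ground-truth GRM over all entries and over the entries not
#' observed in any sub-panel.
#'
#' @param n_total genotypes in the ground-truth panel.
#' @param n_kernels scalar or vector: number of sub-panels (conditions).
#' @param genotypes_per_kernel,markers_per_kernel sub-panel dimensions.
#' @param n_markers_total markers in the ground-truth panel.
#' @param reps replicates per condition.
#' @param seed integer seed.
#' @param em_tol,em_max_iter [combine_em()] controls.
#' @param impute_rank,impute_lam,impute_max_iter,impute_tol
#'   [soft_impute()] controls.
#' @return data.frame (`accuracy_report`): columns `replicate`,
#'   `n_kernels`, `method` (`combined` / `imputed`), `scope` (`all` /
#'   `unobserved`), `mse`, `correlation`, `n_entries`.
#' @export
run_combine_vs_impute <- function(n_total = 300L, n_kernels = c(3L, 5L, 10L, 20L),
                                  genotypes_per_kernel = 100L,
                                  markers_per_kernel = 500L,
                                  n_markers_total = 5000L,
                                  reps = 20L, seed = 1L,
                                  em_tol = 1e-5, em_max_iter = 100L,
                                  impute_rank = 50L, impute_lam = 0,
                                  impute_max_iter = 30L, impute_tol = 1e-4) {
  stopifnot(genotypes_per_kernel <= n_total,
            markers_per_kernel <= n_markers_total)
  rows <- list()
  for (r in seq_len(reps)) {
    rep_seed <- seed + 10000L * r
    panel <- simulate_markers(n_total, n_markers_total, seed = rep_seed)
    G_true <- grm_vanraden(panel)
    for (m in n_kernels) {
      draws <- with_seed(rep_seed + m, {
        lapply(seq_len(m), function(i) {
          list(g = sample(rownames(panel), genotypes_per_kernel),
               mk = sample(colnames(panel), markers_per_kernel))
        })
      })
      kernels <- lapply(draws, function(d) {
        partial_sample(grm_vanraden(marker_subset(panel, d$g, d$mk)))
      })
      res <- combine_em(kernels,
                        em_config(nu = markers_per_kernel, tol = em_tol,
                                  max_iter = em_max_iter))
      K <- rownames(res$sigma)
      truth <- subset_kernel(G_true, K)

      # imputation route: union dosage matrix with unobserved cells missing
      union_mk <- sort(unique(unlist(lapply(draws, `[[`, "mk"))))
      X <- matrix(NA_real_, length(K), length(union_mk),
                  dimnames = list(K, union_mk))
      full <- mm_values(panel)
      for (d in draws) {
        X[d$g, d$mk] <- full[d$g, d$mk]
      }
      ok_col <- colSums(!is.na(X)) > 0L
      imp <- soft_impute(marker_matrix(X[, ok_col, drop = FALSE]),
                         rank = impute_rank, lam = impute_lam,
                         max_iter = impute_max_iter, tol = impute_tol)
      G_imp <- grm_vanraden(imp)

      for (scope in c("all", "unobserved")) {
        msk <- if (scope == "all") "all" else !res$observed_mask
        if (!identical(msk, "all") && !any(msk & upper.tri(msk, diag = TRUE))) next
        ev_c <- evaluate_estimate(res$sigma, truth, mask = msk)
        ev_i <- evaluate_estimate(G_imp, truth, mask = msk)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, n_kernels = m, method = "combined", scope = scope,
          mse = ev_c$mse, correlation = ev_c$correlation,
          n_entries = ev_c$n_entries)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, n_kernels = m, method = "imputed", scope = scope,
          mse = ev_i$mse, correlation = ev_i$correlation,
          n_entries = ev_i$n_entries)
      }
    }
  }
  out <- as_accuracy_report(do.call(rbind, rows))
  attr(out, "impute_settings") <- list(rank = impute_rank, lam = impute_lam)
  out
}

as_accuracy_report <- function(df) {
  rownames(df) <- NULL
  stopifnot(all(df$mse >= 0), all(df$n_entries > 0))
  class(df) <- c("accuracy_report", "data.frame")
  df
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy_report: %d rows\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
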