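test_that("spectral REML handles degenerate and textbook cases", {
  set.seed(51)
  K <- rand_pd(10)
  # constant phenotype: both variance components vanish, GEBVs zero
  y0 <- setNames(rep(3, 10), rownames(K))
  fit0 <- reml_spectral(y0, K)
  expect_equal(unname(fit0$var_components), c(0, 0))
  expect_equal(max(abs(fit0$genotype_effects)), 0)

  # kernel proportional to identity: not identifiable
  Kid <- labeled_matrix(2 * diag(10), labels = rownames(K))
  y <- simulate_phenotypes(K, h2 = 0.5, seed = 1)
  yv <- setNames(as.numeric(y), names(y))
  expect_error(reml_spectral(yv, Kid), "identifiable")
})

test_that("REML solutions satisfy the mixed-model equations", {
  set.seed(53)
  K <- rand_pd(20)
  y <- simulate_phenotypes(K, h2 = 0.6, seed = 2)
  yv <- setNames(as.numeric(y), names(y))
  fit <- reml_spectral(yv, K)
  sg <- fit$var_components[["genetic"]]
  se <- fit$var_components[["residual"]]
  # MME with Z = I: [X'X  X'Z; Z'X  Z'Z + (se/sg) K^{-1}] [b; g] = [X'y; Z'y]
  n <- 20
  X <- matrix(1, n, 1)
  Kin <- solve(lmv(K))
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + (se / sg) * Kin))
  rhs <- c(crossprod(X, yv), yv)
  sol <- unname(solve(lhs, rhs))
  expect_equal(unname(fit$fixed_effects), sol[1], tolerance = 1e-6)
  expect_equal(unname(fit$genotype_effects[names(yv)]),
               unname(sol[-1]), tolerance = 1e-6)
})

test_that("REML recovers a moderate heritability in simulation", {
  h2 <- numeric(8)
  for (i in seq_along(h2)) {
    m <- simulate_markers(150L, 800L, seed = 60L + i)
    K <- grm_vanraden(m)
    y <- simulate_phenotypes(K, h2 = 0.5, seed = 600L + i)
    h2[i] <- reml_spectral(setNames(as.numeric(y), names(y)), K)$h2
  }
  expect_lt(abs(mean(h2) - 0.5), 0.15)
})

test_that("GEBV prediction follows the conditional mean", {
  # 2 train / 1 test toy, hand-solved conditional mean K21 K11^{-1} g
  K <- labeled_matrix(matrix(c(1, 0.2, 0.5,
                               0.2, 1, 0.4,
                               0.5, 0.4, 1), 3),
                      labels = c("t1", "t2", "new"))
  fit <- structure(list(
    var_components = c(genetic = 1, residual = 1),
    fixed_effects = c(intercept = 0),
    genotype_effects = c(t1 = 0.3, t2 = -0.1),
    h2 = 0.5, train_labels = c("t1", "t2"), loglik = NA,
    method = "reml_spectral"), class = "mixed_model_fit")
  pred <- gblup_predict(fit, K, "new")
  K11 <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_equal(unname(pred),
               drop(c(0.5, 0.4) %*% solve(K11, c(0.3, -0.1))),
               tolerance = 1e-6)

  # a test genotype with a relationship row identical to a training one
  # inherits its GEBV; zero relationship gives the prior mean 0
  K4 <- labeled_matrix(rbind(c(1, 0.2, 1, 0),
                             c(0.2, 1, 0.2, 0),
                             c(1, 0.2, 1, 0),
                             c(0, 0, 0, 1)),
                       labels = c("t1", "t2", "copy", "lone"))
  pred2 <- gblup_predict(fit, K4, c("copy", "lone"))
  expect_equal(unname(pred2["copy"]), 0.3, tolerance = 1e-5)
  expect_equal(unname(pred2["lone"]), 0, tolerance = 1e-8)

  expect_error(gblup_predict(fit, K, "ghost"), "ghost")
})

test_that("multi-kernel EM-REML agrees with spectral REML on one kernel", {
  set.seed(71)
  m <- simulate_markers(120L, 600L, seed = 72L)
  K <- grm_vanraden(m)
  y <- simulate_phenotypes(K, h2 = 0.5, seed = 73L)
  yv <- setNames(as.numeric(y), names(y))
  f1 <- reml_spectral(yv, K)
  f2 <- multikernel_reml(yv, list(K))
  scale <- sum(f1$var_components)
  expect_lt(max(abs(f1$var_components - f2$var_components)) / scale, 1e-6)
  expect_lt(max(abs(f1$genotype_effects - f2$genotype_effects[names(yv)])),
            1e-5 * sqrt(scale))
})

test_that("duplicate kernels warn and keep the summed variance identifiable", {
  K <- related_sigma(100L, seed = 79L)
  y <- simulate_phenotypes(K, h2 = 0.5, seed = 85L)
  yv <- setNames(as.numeric(y), names(y))
  expect_warning(f2 <- multikernel_reml(yv, list(K, K)), "identical")
  f1 <- reml_spectral(yv, K)
  total2 <- sum(f2$var_components[1:2])
  total1 <- f1$var_components[["genetic"]]
  expect_equal(total2, total1, tolerance = 0.05 * max(total1, 0.01))
})

test_that("a null second kernel gets a near-zero variance component", {
  set.seed(83)
  m <- simulate_markers(150L, 600L, seed = 84L)
  K1 <- grm_vanraden(m)
  K2 <- rand_pd(150L, rownames(K1))   # unrelated kernel, no true effect
  y <- simulate_phenotypes(K1, h2 = 0.6, seed = 85L)
  yv <- setNames(as.numeric(y), names(y))
  fit <- multikernel_reml(yv, list(K1, K2))
  expect_lt(fit$var_components[[2]], 0.25 * fit$var_components[[1]])
})

test_that("random folds partition genotypes deterministically by seed", {
  set.seed(89)
  m <- simulate_markers(80L, 400L, seed = 90L)
  K <- grm_vanraden(m)
  y <- simulate_phenotypes(K, h2 = 0.9, seed = 91L)
  yv <- setNames(as.numeric(y), names(y))
  cv1 <- cv_random_folds(yv, K, n_folds = 5L, seed = 7L)
  cv2 <- cv_random_folds(yv, K, n_folds = 5L, seed = 7L)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(sum(cv1$folds$n_test), 80L)
  expect_false(anyNA(cv1$predictions))
  expect_error(cv_random_folds(yv[1:7], K, n_folds = 4L), "fold")
})

test_that("near-noiseless traits in a dense kernel are predicted accurately", {
  # genomic prediction draws its accuracy from train-test relatedness;
  # tight families (within-family relationship 0.85) put the
  # conditional-mean accuracy ceiling above 0.9
  n_fam <- 24L; fam_size <- 5L
  n <- n_fam * fam_size
  labs <- sprintf("f%02d_%d", rep(seq_len(n_fam), each = fam_size),
                  rep(seq_len(fam_size), n_fam))
  Kb <- matrix(0, n, n, dimnames = list(labs, labs))
  for (f in seq_len(n_fam)) {
    idx <- (f - 1L) * fam_size + seq_len(fam_size)
    Kb[idx, idx] <- 0.85
  }
  diag(Kb) <- 1
  K <- labeled_matrix(Kb)
  y <- simulate_phenotypes(K, h2 = 0.99, seed = 96L)
  yv <- setNames(as.numeric(y), names(y))
  cv <- cv_random_folds(yv, K, n_folds = 5L, seed = 8L)
  expect_gt(cv$pooled, 0.8)
})

test_that("leave-dataset-out respects membership structure", {
  set.seed(97)
  # two identical datasets by construction: duplicated kernel block
  n <- 30
  base <- rand_pd(n, sprintf("d1_%02d", 1:n))
  labs2 <- sprintf("d2_%02d", 1:n)
  big <- matrix(0.0, 2 * n, 2 * n,
                dimnames = list(c(rownames(base), labs2),
                                c(rownames(base), labs2)))
  big[1:n, 1:n] <- lmv(base)
  big[n + 1:n, n + 1:n] <- lmv(base)
  big[1:n, n + 1:n] <- lmv(base) * 0.999
  big[n + 1:n, 1:n] <- lmv(base) * 0.999
  K <- ensure_psd(labeled_matrix(big, symmetrize = TRUE), jitter = 1e-6)
  g <- simulate_phenotypes(subset_kernel(K, rownames(base)), h2 = 1,
                           seed = 98L)
  y <- c(setNames(as.numeric(g), rownames(base)),
         setNames(as.numeric(g), labs2))
  membership <- setNames(rep(c("A", "B"), each = n), names(y))
  res <- cv_leave_dataset_out(y, K, membership)
  expect_identical(nrow(res), 2L)
  expect_equal(res$accuracy[1], res$accuracy[2], tolerance = 1e-6)

  expect_error(cv_leave_dataset_out(y, K, membership[1:10]), "membership")
})
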