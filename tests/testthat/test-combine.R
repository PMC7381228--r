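test_that("conditional blocks implement the partitioned-matrix formulas", {
  psi <- labeled_matrix(matrix(c(1, 0.5, 0.5, 2), 2), labels = c("a", "b"))
  cb <- conditional_blocks(psi, "a")
  expect_equal(drop(cb$B), 0.5)                 # Psi_ba Psi_a^{-1}
  expect_equal(drop(cb$psi_cond), 1.75)          # 2 - 0.25/1

  # diagonal scale matrix: independence, B = 0, conditional = marginal
  dpsi <- labeled_matrix(diag(c(2, 3, 4)), labels = c("x", "y", "z"))
  cbd <- conditional_blocks(dpsi, c("x", "z"))
  expect_equal(max(abs(cbd$B)), 0)
  expect_equal(drop(cbd$psi_cond), 3)

  # degenerate partition: a = all labels
  cball <- conditional_blocks(psi, c("a", "b"))
  expect_identical(dim(cball$psi_cond), c(0L, 0L))
  expect_identical(cball$labels_b, character(0))

  # larger random check against direct solve
  set.seed(13)
  P <- rand_pd(7)
  a <- c("g03", "g06", "g01")
  cb7 <- conditional_blocks(P, a)
  ia <- match(a, rownames(P)); ib <- setdiff(1:7, ia)
  Bref <- lmv(P)[ib, ia] %*% solve(lmv(P)[ia, ia])
  expect_lt(max(abs(cb7$B - Bref)), 1e-10)
})

test_that("expected completion reproduces the conditional Wishart mean", {
  psi <- labeled_matrix(matrix(c(1, 0.5, 0.5, 2), 2), labels = c("a", "b"))
  s <- partial_sample(labeled_matrix(matrix(1.2), labels = "a"))
  comp <- expected_completion(psi, s, nu = 10)
  # cross: 0.5*1.2 = 0.6; bottom: 10*1.75 + 0.25*1.2 = 17.8
  expect_equal(unname(comp), matrix(c(1.2, 0.6, 0.6, 17.8), 2))

  # sample covering all labels: nothing to complete
  set.seed(17)
  G <- rand_pd(4)
  full <- expected_completion(labeled_matrix(diag(4), labels = rownames(G)),
                              partial_sample(G), nu = 100)
  expect_lt(max(abs(full - lmv(G))), 1e-12)

  # zero cross block in psi: bottom block is nu * Psi_b
  bd <- labeled_matrix(diag(c(1, 3)), labels = c("a", "b"))
  comp0 <- expected_completion(bd, s, nu = 10)
  expect_equal(comp0[2, 1], 0)
  expect_equal(comp0[2, 2], 30)
})

test_that("reliability weights blend the kernel with the model prediction", {
  psi <- labeled_matrix(matrix(2), labels = "a")   # nu*Psi_a = 4 at nu = 2
  g <- labeled_matrix(matrix(2), labels = "a")
  expect_equal(drop(blend_weighted(partial_sample(g, 1), psi, 2)), 2)
  expect_equal(drop(blend_weighted(partial_sample(g, 0), psi, 2)), 4)
  expect_equal(drop(blend_weighted(partial_sample(g, 0.5), psi, 2)), 3)
})

test_that("EM update has the documented fixed points", {
  set.seed(19)
  # fully observed single sample: next iterate is G/nu regardless of psi
  G <- rand_pd(5)
  psi0 <- labeled_matrix(diag(5), labels = rownames(G))
  up <- em_update(psi0, list(partial_sample(G)), nu = 50)
  expect_lt(max(abs(lmv(up) - lmv(G) / 50)), 1e-12)

  # disjoint samples at the block-diagonal point: fixed
  G1 <- rand_pd(3, paste0("a", 1:3))
  G2 <- rand_pd(3, paste0("b", 1:3))
  labs <- c(paste0("a", 1:3), paste0("b", 1:3))
  bd <- matrix(0, 6, 6, dimnames = list(labs, labs))
  bd[1:3, 1:3] <- lmv(G1); bd[4:6, 4:6] <- lmv(G2)
  psi_fix <- labeled_matrix(bd / 100, labels = labs)
  up2 <- em_update(psi_fix, list(partial_sample(G1), partial_sample(G2)),
                   nu = 100)
  expect_lt(max(abs(lmv(up2) - lmv(psi_fix))), 1e-12)

  # duplicated identical samples average to the single-sample update
  up3 <- em_update(psi0, list(partial_sample(G), partial_sample(G)), nu = 50)
  expect_lt(max(abs(lmv(up3) - lmv(up))), 1e-12)
})

test_that("scalar Wishart log-likelihood matches the chi-square density", {
  s <- partial_sample(labeled_matrix(matrix(2), labels = "a"))
  psi <- labeled_matrix(matrix(1), labels = "a")
  expect_equal(wishart_loglik(list(s), psi, nu = 2), -1 - log(2),
               tolerance = 1e-12)

  # independence: two samples add
  s2 <- partial_sample(labeled_matrix(matrix(3), labels = "b"))
  psi2 <- labeled_matrix(diag(2), labels = c("a", "b"))
  expect_equal(wishart_loglik(list(s, s2), psi2, nu = 2),
               wishart_loglik(list(s), psi, nu = 2) +
                 wishart_loglik(list(s2), subset_kernel(psi2, "b"), nu = 2),
               tolerance = 1e-12)

  # scalar calculus oracle: maximized over psi at G/nu
  G <- 2.7; nu <- 5
  f <- function(p) wishart_loglik(
    list(partial_sample(labeled_matrix(matrix(G), labels = "a"))),
    labeled_matrix(matrix(p), labels = "a"), nu = nu)
  opt <- optimize(f, c(0.01, 5), maximum = TRUE)
  expect_equal(opt$maximum, G / nu, tolerance = 1e-4)

  # density undefined when nu <= |a| - 1: warn and skip
  big <- partial_sample(rand_pd(4, paste0("c", 1:4)))
  psi4 <- labeled_matrix(diag(4), labels = paste0("c", 1:4))
  expect_warning(ll <- wishart_loglik(list(big), psi4, nu = 2), "skipped")
  expect_equal(ll, 0)
})

test_that("combine_em converges on fully observed data and keeps labels", {
  set.seed(23)
  G <- rand_pd(6)
  res <- combine_em(list(partial_sample(G), partial_sample(G)),
                    em_config(nu = 100))
  expect_true(res$converged)
  expect_lte(res$n_iter, 2L)
  expect_lt(max_abs(res$sigma, G), 1e-10)
  expect_true(all(res$observed_mask))
  expect_identical(rownames(res$sigma), sort(rownames(G)))
})

test_that("the combined estimate does not depend on the degrees of freedom", {
  set.seed(29)
  d <- make_overlap_design(12, 3, 6, 0.4, seed = 4)
  S <- rand_pd(12, d$labels)
  sm <- sample_wishart_partials(S, 50, d, seed = 5)
  r1 <- combine_em(sm, em_config(nu = 100, tol = 1e-9, max_iter = 300))
  r2 <- combine_em(sm, em_config(nu = 1000, tol = 1e-9, max_iter = 300))
  rel <- max_abs(r1$sigma, r2$sigma) / max(abs(lmv(r1$sigma)))
  expect_lt(rel, 1e-6)
})

test_that("relabeling genotypes permutes the estimate identically", {
  set.seed(31)
  d <- make_overlap_design(8, 2, 5, 0.4, seed = 6)
  S <- rand_pd(8, d$labels)
  sm <- sample_wishart_partials(S, 40, d, seed = 7)
  res <- combine_em(sm, em_config(nu = 40, tol = 1e-10, max_iter = 200))

  # rename g01 -> z99 etc: a pure relabeling
  rename <- function(x) chartr("g", "z", x)
  sm2 <- lapply(sm, function(s) partial_sample(
    labeled_matrix(lmv(s$kernel), labels = rename(rownames(s$kernel))),
    s$weight))
  res2 <- combine_em(sm2, em_config(nu = 40, tol = 1e-10, max_iter = 200))
  expect_identical(rownames(res2$sigma), rename(rownames(res$sigma)))
  expect_lt(max(abs(lmv(res2$sigma) - lmv(res$sigma))), 1e-10)
})

test_that("log-likelihood trace is non-decreasing along the iteration", {
  set.seed(37)
  for (i in 1:5) {
    d <- make_overlap_design(10, 3, 5, 0.3, seed = i)
    S <- rand_pd(10, d$labels)
    sm <- sample_wishart_partials(S, 60, d, seed = i + 100)
    res <- combine_em(sm, em_config(nu = 60, tol = 1e-8, max_iter = 200))
    expect_gte(min(diff(res$loglik_trace)), -1e-8)
  }
})

test_that("weighted samples shrink toward the prior as weight drops", {
  set.seed(41)
  G <- rand_pd(4)
  # weight 0: the sample carries no information, estimate stays at init
  res0 <- combine_em(list(partial_sample(G, 0)),
                     em_config(nu = 50, max_iter = 50))
  expect_lt(max(abs(lmv(res0$sigma) - diag(4))), 1e-8)
  # weight 1 reproduces the unweighted estimate
  res1 <- combine_em(list(partial_sample(G, 1)), em_config(nu = 50))
  expect_lt(max_abs(res1$sigma, G), 1e-10)
})

test_that("one EM iteration from a full prior equals the closed-form H-matrix", {
  # textbook 2x2: A = [[1,.5],[.5,1]], G = [1.5] on genotype 2
  A <- labeled_matrix(matrix(c(1, 0.5, 0.5, 1), 2), labels = c("p1", "p2"))
  G <- labeled_matrix(matrix(1.5), labels = "p2")
  H <- hmatrix_oracle(A, G)
  expect_equal(unname(lmv(H)),
               matrix(c(1.125, 0.75, 0.75, 1.5), 2))

  # no-linkage case: identity A leaves the unobserved block untouched
  H0 <- hmatrix_oracle(labeled_matrix(diag(2), labels = c("p1", "p2")),
                       labeled_matrix(matrix(2), labels = "p2"))
  expect_equal(unname(lmv(H0)), diag(c(1, 2)))

  # G = A22: no new information, H = A
  expect_lt(max_abs(hmatrix_oracle(A, subset_kernel(A, "p2")), A), 1e-12)

  # random instances: one combine_em iteration with init = A matches
  set.seed(43)
  for (i in 1:5) {
    n <- sample(5:15, 1)
    Af <- rand_pd(n)
    sub <- sort(sample(rownames(Af), sample(2:(n - 1), 1)))
    Gs <- rand_pd(length(sub), sub)
    Ho <- hmatrix_oracle(Af, Gs)
    res <- suppressWarnings(
      combine_em(list(partial_sample(Gs)),
                 em_config(nu = 777, init = Af, max_iter = 1, tol = 0)))
    expect_lt(max_abs(res$sigma, subset_kernel(Ho, rownames(res$sigma))),
              1e-10)
  }
})

test_that("init matrix must cover the samples; union drives K otherwise", {
  set.seed(47)
  G <- rand_pd(4)
  small_init <- rand_pd(2, rownames(G)[1:2])
  expect_error(combine_em(list(partial_sample(G)),
                          em_config(init = small_init)), "cover")
  expect_error(combine_em(list(), em_config()), "non-empty")
})
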