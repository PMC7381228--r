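# Shared fixtures: well-conditioned random PD kernels and small helpers.

# Random PD labeled matrix, Wishart-style with a ridge so condition
# numbers stay moderate.
rand_pd <- function(n, labs = sprintf("g%02d", seq_len(n)), ridge = 0.5) {
  X <- matrix(stats::rnorm(3L * n * n), 3L * n, n)
  labeled_matrix(crossprod(X) / (3 * n) + diag(ridge, n), labels = labs)
}

lmv <- function(x) {
  m <- unclass(x)
  attr(m, "source") <- NULL
  attr(m, "n_features") <- NULL
  m
}

max_abs <- function(a, b) max(abs(lmv(a) - lmv(b)))

frob <- function(m) sqrt(sum(m^2))
frob_gap <- function(a, b) frob(a - b)

# Dense relationship structure for recovery experiments: the realized
# GRM of a gene-drop pedigree population plus a small ridge (PD).
related_sigma <- function(n, seed, n_markers = 2000L) {
  sim <- simulate_pedigree_genedrop(n_founders = 16L, n_generations = 4L,
                                    offspring_per_cross = 4L,
                                    n_markers = n_markers, seed = seed)
  ids <- utils::tail(sim$pedigree$id, n)
  G <- grm_vanraden(marker_subset_test(sim$markers, ids),
                    allele_freq = sim$allele_freq)
  labeled_matrix(lmv(G) + diag(0.05, n), labels = rownames(G))
}

marker_subset_test <- function(m, genotypes) {
  X <- unclass(m)
  attr(X, "ploidy") <- NULL
  marker_matrix(X[match(genotypes, rownames(m)), , drop = FALSE],
                ploidy = 2L)
}
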