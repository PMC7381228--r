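#' Simulate a marker dosage panel
#'
#' Independent biallelic loci: per-marker allele frequencies are drawn
#' uniformly from `maf_range` and dosages are Binomial(2, p), i.e. an
#' unstructured panel in Hardy-Weinberg equilibrium.
#'
#' @param n_genotypes,n_markers panel dimensions.
#' @param maf_range length-2 vector `(lo, hi)` with `0 < lo <= hi <= 0.5`.
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return a [marker_matrix()] with the true allele frequencies attached
#'   as attribute `allele_freq`.
#' @export
simulate_markers <- function(n_genotypes, n_markers,
                             maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[1L] <= maf_range[2L], maf_range[2L] <= 0.5)
  with_seed(seed, {
    p <- stats::runif(n_markers, maf_range[1L], maf_range[2L])
    dos <- matrix(stats::rbinom(n_genotypes * n_markers, 2L,
                                rep(p, each = n_genotypes)),
                  nrow = n_genotypes)
    out <- marker_matrix(dos,
                         genotype_labels = sprintf("g%04d", seq_len(n_genotypes)),
                         marker_labels = sprintf("m%05d", seq_len(n_markers)))
    attr(out, "allele_freq") <- p
    out
  })
}

#' Simulate a pedigree with gene-drop genotypes
#'
#' Founders are drawn in Hardy-Weinberg equilibrium at independent loci;
#' each generation, the previous generation is paired at random and each
#' cross produces `offspring_per_cross` offspring whose alleles are
#' transmitted by Mendelian gene drop (one random allele per parent per
#' locus).
#'
#' @param n_founders even number of founders (>= 2).
#' @param n_generations number of generations of crosses.
#' @param offspring_per_cross offspring per mating pair.
#' @param n_markers number of independent loci.
#' @param seed integer seed.
#' @param maf_range founder allele-frequency range.
#' @return list with `pedigree` (a [pedigree()]), `markers` (a
#'   [marker_matrix()] over all individuals) and `allele_freq` (the true
#'   founder allele frequencies, for unbiased realized-relationship
#'   calculations).
#' @export
simulate_pedigree_genedrop <- function(n_founders = 16L, n_generations = 3L,
                                       offspring_per_cross = 4L,
                                       n_markers = 1000L, seed = 1L,
                                       maf_range = c(0.1, 0.5)) {
  n_founders <- as.integer(n_founders)
  stopifnot(n_founders >= 2L, n_founders %% 2L == 0L, n_generations >= 1L,
            offspring_per_cross >= 1L)
  # total population size is known up front; preallocate the gamete pools
  n_total <- n_founders
  cur <- n_founders
  for (g in seq_len(n_generations)) {
    cur <- floor(cur / 2) * offspring_per_cross
    n_total <- n_total + cur
  }
  with_seed(seed, {
    p <- stats::runif(n_markers, maf_range[1L], maf_range[2L])
    ids <- character(n_total)
    sires <- rep(NA_character_, n_total)
    dams <- rep(NA_character_, n_total)
    gam1 <- matrix(0L, n_total, n_markers)
    gam2 <- matrix(0L, n_total, n_markers)
    ids[seq_len(n_founders)] <- sprintf("F%03d", seq_len(n_founders))
    gam1[seq_len(n_founders), ] <-
      stats::rbinom(n_founders * n_markers, 1L, rep(p, each = n_founders))
    gam2[seq_len(n_founders), ] <-
      stats::rbinom(n_founders * n_markers, 1L, rep(p, each = n_founders))

    current <- seq_len(n_founders)
    filled <- n_founders
    for (g in seq_len(n_generations)) {
      parents <- sample(current)
      n_cross <- floor(length(parents) / 2)
      if (n_cross < 1L) break
      new_rows <- integer(0)
      for (cx in seq_len(n_cross)) {
        pa <- parents[2L * cx - 1L]
        ma <- parents[2L * cx]
        for (o in seq_len(offspring_per_cross)) {
          filled <- filled + 1L
          i <- filled
          ids[i] <- sprintf("I%05d", i - n_founders)
          sires[i] <- ids[pa]
          dams[i] <- ids[ma]
          # one random allele per locus from each parent
          pick_a <- stats::rbinom(n_markers, 1L, 0.5) == 1L
          pick_b <- stats::rbinom(n_markers, 1L, 0.5) == 1L
          gam1[i, ] <- ifelse(pick_a, gam1[pa, ], gam2[pa, ])
          gam2[i, ] <- ifelse(pick_b, gam1[ma, ], gam2[ma, ])
          new_rows <- c(new_rows, i)
        }
      }
      current <- new_rows
    }
    ids <- ids[seq_len(filled)]
    sires <- sires[seq_len(filled)]
    dams <- dams[seq_len(filled)]
    gam1 <- gam1[seq_len(filled), , drop = FALSE]
    gam2 <- gam2[seq_len(filled), , drop = FALSE]
    rownames(gam1) <- rownames(gam2) <- ids

    ped <- pedigree(ids, sires, dams)
    dos <- gam1 + gam2
    mm <- marker_matrix(dos[ped$id, , drop = FALSE],
                        genotype_labels = ped$id,
                        marker_labels = sprintf("m%05d", seq_len(n_markers)))
    attr(mm, "allele_freq") <- p
    list(pedigree = ped, markers = mm, allele_freq = p)
  })
}

#' Draw partial relationship matrices from a Wishart model
#'
#' For each subset `a` in the design, an independent full matrix
#' `W ~ Wishart(nu, Sigma / nu)` is drawn (Bartlett decomposition via
#' [stats::rWishart()]) and its `a x a` block is returned; since marginal
#' blocks of a Wishart are Wishart, this realizes
#' `G_a ~ Wishart(nu, Psi_a)` with `E[G_a] = Sigma_a`.
#'
#' @param sigma positive-definite ground-truth [labeled_matrix()].
#' @param nu degrees of freedom, must exceed `nrow(sigma) - 1`.
#' @param design an [make_overlap_design()] whose labels match `sigma`.
#' @param seed integer seed.
#' @return list of [partial_sample()], one per design subset, each with
#'   `n_features` set to `round(nu)`.
#' @export
sample_wishart_partials <- function(sigma, nu, design, seed = 1L) {
  labs <- rownames(sigma)
  n <- length(labs)
  if (nu <= n - 1) stop("'nu' must exceed nrow(sigma) - 1")
  S <- lm_values(sigma)
  if (is.null(tryCatch(chol(S), error = function(e) NULL))) {
    stop("'sigma' must be positive definite")
  }
  subsets <- design$subsets
  with_seed(seed, {
    lapply(subsets, function(a) {
      ia <- match(a, labs)
      if (anyNA(ia)) {
        stop("design labels not in sigma: ",
             paste(a[is.na(ia)], collapse = ", "))
      }
      W <- matrix(stats::rWishart(1L, nu, S / nu), n, n)
      partial_sample(labeled_matrix(W[ia, ia, drop = FALSE], labels = a,
                                    source = "sample_wishart_partials",
                                    n_features = round(nu),
                                    symmetrize = TRUE))
    })
  })
}

#' Construct a chained overlap design
#'
#' Produces `m` genotype subsets of size `subset_size` over `n` labels
#' such that consecutive subsets share `ceiling(overlap_fraction *
#' subset_size)` labels.  The label order is shuffled by `seed`; subsets
#' are consecutive windows advanced by `subset_size - overlap` positions,
#' wrapping cyclically when the chain passes `n`.  If the union does not
#' cover all labels, the uncovered labels are appended to the last
#' subset.
#'
#' @param n number of genotypes.
#' @param m number of subsets.
#' @param subset_size size of each subset (`<= n`).
#' @param overlap_fraction fraction in `[0, 1]` of each subset shared
#'   with its predecessor.
#' @param seed integer seed for the label shuffle.
#' @param labels optional character vector of `n` labels; defaults to
#'   `g0001...`.
#' @param feature_counts optional per-subset feature counts (recycled).
#' @return an object of class `overlap_design`: list with `n`, `labels`,
#'   `subsets` (list of character vectors) and `feature_counts`.
#' @export
make_overlap_design <- function(n, m, subset_size, overlap_fraction = 0,
                                seed = 1L, labels = NULL,
                                feature_counts = NULL) {
  stopifnot(m >= 1L, subset_size >= 1L)
  if (subset_size > n) stop("'subset_size' exceeds n")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("'overlap_fraction' must be in [0, 1]")
  }
  if (is.null(labels)) labels <- sprintf("g%04d", seq_len(n))
  stopifnot(length(labels) == n)
  o <- ceiling(overlap_fraction * subset_size)
  step <- subset_size - o
  if (step == 0L && m > 1L && subset_size < n) {
    stop("infeasible design: full overlap between consecutive subsets ",
         "can never cover all ", n, " labels; reduce overlap_fraction ",
         "or use subset_size = n")
  }
  shuffled <- with_seed(seed, sample(labels))
  subsets <- vector("list", m)
  for (i in seq_len(m)) {
    start <- (i - 1L) * step
    pos <- (start + seq_len(subset_size) - 1L) %% n + 1L
    subsets[[i]] <- shuffled[pos]
  }
  uncovered <- setdiff(shuffled, unlist(subsets))
  if (length(uncovered) > 0L) {
    subsets[[m]] <- c(subsets[[m]], uncovered)
  }
  if (!is.null(feature_counts)) {
    feature_counts <- rep_len(as.integer(feature_counts), m)
  }
  structure(list(n = n, labels = labels, subsets = subsets,
                 feature_counts = feature_counts),
            class = "overlap_design")
}

#' @export
print.overlap_design <- function(x, ...) {
  sizes <- vapply(x$subsets, length, integer(1L))
  cat(sprintf("overlap_design: %d subsets over %d labels (sizes %s)\n",
              length(x$subsets), x$n,
              paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' Simulate phenotypes from a kernel
#'
#' `y = g + e` with `g ~ N(0, h2 * K_std)` and
#' `e ~ N(0, (1 - h2) * I)`, where `K_std` is the kernel rescaled to mean
#' diagonal 1 so that `h2` is the heritability on the phenotype scale.
#'
#' @param k a PSD [labeled_matrix()].
#' @param h2 heritability in `[0, 1]`.
#' @param seed integer seed.
#' @return named numeric vector of phenotypes, with the true genetic
#'   values attached as attribute `genetic_values`.
#' @export
simulate_phenotypes <- function(k, h2, seed = 1L) {
  stopifnot(h2 >= 0, h2 <= 1)
  labs <- rownames(k)
  n <- length(labs)
  Ks <- lm_values(k) / mean(diag(lm_values(k)))
  e <- eigen((Ks + t(Ks)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  with_seed(seed, {
    g <- sqrt(h2) * drop(L %*% stats::rnorm(n))
    eps <- sqrt(1 - h2) * stats::rnorm(n)
    y <- stats::setNames(g + eps, labs)
    attr(y, "genetic_values") <- stats::setNames(g, labs)
    y
  })
}
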