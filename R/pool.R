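#' Simulate a coalescent haplotype pool
#'
#' Draws a sample of binary haplotypes under the standard (Kingman)
#' neutral coalescent with infinite-sites mutation and no intra-block
#' recombination -- the model matching the low-recombination-block
#' assumption under which windows of consecutive SNPs are tested together.
#' Site positions are uniform on (0, 1) and columns are ordered by
#' position. The number of ancestral chromosomes carrying any given variant
#' is itself a coalescent outcome, so disease mutations introduced on pool
#' haplotypes have a realistic frequency spectrum.
#'
#' @param n_hap Number of haplotypes to sample.
#' @param theta Scaled mutation rate (expected pairwise diversity driver);
#'   larger values yield more segregating sites.
#' @param min_common Minimum number of sites required inside `maf_range`;
#'   the sample is redrawn (up to `max_tries` times) until satisfied.
#' @param maf_range Minor-allele-frequency interval defining a "common"
#'   site.
#' @param max_tries Redraw limit before erroring.
#' @param recomb Expected number of template switches across the whole
#'   region (positions span (0, 1)). With `recomb = 0` the sample is the
#'   plain no-recombination coalescent; with `recomb > 0` an ancestral
#'   sample of `n_ancestral` haplotypes is drawn first and each pool
#'   haplotype is a recombinant mosaic that copies from a random ancestor
#'   and switches template between adjacent sites with probability
#'   `1 - exp(-recomb * distance)` -- the standard haplotype-copying
#'   approximation that restores recombination-driven haplotype diversity
#'   while preserving site frequencies and distance-decaying LD.
#' @param n_ancestral Size of the ancestral sample behind the mosaic
#'   layer.
#' @param seed Optional integer seed.
#' @return A [haplotype_pool()].
#' @export
coalescent_pool <- function(n_hap = 120L, theta = 30, min_common = 0L,
                            maf_range = c(0.1, 0.5), max_tries = 100L,
                            recomb = 0, n_ancestral = 60L, seed = NULL) {
  stopifnot(n_hap >= 2L, theta > 0, recomb >= 0)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      pool <- if (recomb > 0) {
        mosaic_sample(kingman_sample(n_ancestral, theta), n_hap, recomb)
      } else {
        kingman_sample(n_hap, theta)
      }
      if (min_common <= 0L) return(pool)
      maf <- pmin(colMeans(pool$haplotypes), 1 - colMeans(pool$haplotypes))
      if (sum(maf >= maf_range[1L] & maf <= maf_range[2L]) >= min_common) {
        return(pool)
      }
    }
    stop("could not draw a pool with enough common sites; raise theta")
  })
}

# recombinant mosaics over an ancestral sample: haplotype-copying with a
# distance-based template-switch probability
mosaic_sample <- function(anc, n_hap, recomb) {
  A <- anc$haplotypes
  s <- ncol(A)
  if (s == 0L) return(anc)
  tpl <- matrix(0L, n_hap, s)
  cur <- sample.int(nrow(A), n_hap, replace = TRUE)
  tpl[, 1L] <- cur
  if (s > 1L) {
    psw <- 1 - exp(-recomb * diff(anc$positions))
    for (j in 2:s) {
      sw <- stats::runif(n_hap) < psw[j - 1L]
      if (any(sw)) {
        cur[sw] <- sample.int(nrow(A), sum(sw), replace = TRUE)
      }
      tpl[, j] <- cur
    }
  }
  out <- matrix(A[cbind(as.vector(tpl),
                        rep(seq_len(s), each = n_hap))], n_hap, s)
  haplotype_pool(out, anc$positions, source = "coalescent+mosaic")
}

kingman_sample <- function(n, theta) {
  members <- as.list(seq_len(n))   # leaves below each active lineage
  k <- n
  carriers <- list()               # one entry per mutation (site)
  while (k > 1L) {
    t_k <- stats::rexp(1L, rate = k * (k - 1L) / 2)
    # Poisson(theta/2 * t_k) mutations on each of the k active branches
    n_mut <- stats::rpois(k, theta / 2 * t_k)
    for (i in which(n_mut > 0L)) {
      carriers <- c(carriers, rep(members[i], n_mut[i]))
    }
    pair <- sample.int(k, 2L)
    members[[pair[1L]]] <- c(members[[pair[1L]]], members[[pair[2L]]])
    members[[pair[2L]]] <- NULL
    k <- k - 1L
  }
  s <- length(carriers)
  if (s == 0L) {
    return(haplotype_pool(matrix(0L, n, 0L), numeric(),
                          source = "coalescent"))
  }
  mat <- matrix(0L, n, s)
  for (j in seq_len(s)) mat[carriers[[j]], j] <- 1L
  pos <- sort(stats::runif(s))
  haplotype_pool(mat, pos, source = "coalescent")
}
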