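# Trio simulators: stratified/admixed null populations, disease-linked
# trios drawn from a haplotype pool, null fixtures, and missing-data
# injection. All ascertainment is on an affected child via a genotype
# relative-risk penetrance model and rejection sampling.

#' Genetic disease models
#'
#' Penetrance models parameterised by the genotype relative risk
#' `RR = f(DD)/f(dd)` between the disease-homozygote and normal-homozygote
#' penetrances. One-locus kinds give heterozygote weights `RR` (dominant),
#' `1` (recessive) or `(1 + RR)/2` (additive). Two-locus kinds combine
#' per-locus dominant/recessive indicators: `dom-and-dom`, `rec-or-rec`,
#' `dom-or-dom`, `threshold` (total disease-allele count >= 2) and
#' `modified` (default: locus 1 dominant and locus 2 recessive; a
#' placeholder that an explicit `table` overrides). Any model may be
#' replaced cell by cell through `table`.
#'
#' @param kind Model name (see Details above).
#' @param rr Genotype relative risk, `>= 1`.
#' @param baseline Baseline penetrance of the normal homozygote, in (0, 1].
#' @param table Optional explicit relative-risk override: length-3 vector
#'   (one locus, genotypes 0/1/2 disease alleles) or 3 x 3 matrix (two
#'   loci).
#' @return An object of class `disease_model`.
#' @export
#' @examples
#' penetrance(disease_model("dominant", rr = 3), g1 = 0:2)
disease_model <- function(kind = c("additive", "dominant", "recessive",
                                   "dom-and-dom", "rec-or-rec",
                                   "dom-or-dom", "threshold", "modified"),
                          rr = 2, baseline = 0.05, table = NULL) {
  kind <- match.arg(kind)
  if (rr < 1) stop("rr must be >= 1")
  if (!(baseline > 0 && baseline <= 1)) stop("baseline must be in (0, 1]")
  two_locus <- !(kind %in% c("additive", "dominant", "recessive")) ||
    (is.matrix(table) && all(dim(table) == c(3L, 3L)))
  if (kind == "additive" && is.matrix(table)) two_locus <- TRUE
  structure(list(kind = kind, rr = rr, baseline = baseline, table = table,
                 two_locus = two_locus),
            class = "disease_model")
}

#' Relative penetrance weights for disease genotypes
#'
#' @param model A [disease_model()].
#' @param g1 Disease-allele counts (0/1/2) at the first locus.
#' @param g2 Counts at the second locus for two-locus kinds (`NULL`
#'   otherwise; a two-locus `additive` model averages the per-locus
#'   additive weights).
#' @return Numeric relative risks (weight 1 = normal homozygote); multiply
#'   by the model baseline for absolute penetrances.
#' @export
penetrance <- function(model, g1, g2 = NULL) {
  stopifnot(inherits(model, "disease_model"))
  rr <- model$rr
  if (!is.null(model$table)) {
    if (is.matrix(model$table)) {
      if (is.null(g2)) stop("two-locus table needs g2")
      return(model$table[cbind(g1 + 1L, g2 + 1L)])
    }
    return(model$table[g1 + 1L])
  }
  one <- function(kind, g) {
    w <- switch(kind,
                additive = c(1, (1 + rr) / 2, rr),
                dominant = c(1, rr, rr),
                recessive = c(1, 1, rr))
    w[g + 1L]
  }
  if (is.null(g2)) {
    if (!(model$kind %in% c("additive", "dominant", "recessive"))) {
      stop("two-locus model needs g2")
    }
    return(one(model$kind, g1))
  }
  dom <- function(g) g >= 1L
  rec <- function(g) g == 2L
  switch(model$kind,
         "additive" = 1 + (rr - 1) * (g1 + g2) / 4,
         "dominant" = one("dominant", g1),
         "recessive" = one("recessive", g1),
         "dom-and-dom" = ifelse(dom(g1) & dom(g2), rr, 1),
         "rec-or-rec" = ifelse(rec(g1) | rec(g2), rr, 1),
         "dom-or-dom" = ifelse(dom(g1) | dom(g2), rr, 1),
         "threshold" = ifelse(g1 + g2 >= 2L, rr, 1),
         "modified" = ifelse(dom(g1) & rec(g2), rr, 1))
}

# transmit one of two haplotypes with per-interval crossover probability rho;
# returns the gamete and the source haplotype (1/2) at the first marker
transmit_block <- function(h1, h2, pick, rho) {
  n <- nrow(h1); l <- ncol(h1)
  out <- h1
  cur <- pick
  for (k in seq_len(l)) {
    if (k > 1L && rho > 0) {
      sw <- stats::runif(n) < rho
      cur <- ifelse(sw, 3L - cur, cur)
    }
    out[, k] <- ifelse(cur == 1L, h1[, k], h2[, k])
  }
  out
}

interleave <- function(h1, h2) {
  l <- ncol(h1)
  g <- matrix("", nrow(h1), 2L * l)
  g[, seq.int(1L, 2L * l, 2L)] <- h1
  g[, seq.int(2L, 2L * l, 2L)] <- h2
  g
}

default_panel <- function(l) {
  marker_panel(paste0("M", seq_len(l)), seq_len(l) * 1000L, "1")
}

#' Simulate affected-child trios under population stratification
#'
#' Each family comes from subpopulation 1 with probability `pp`, otherwise
#' from subpopulation 2. Founder haplotypes have independent alleles at
#' every marker with the subpopulation's minor-allele frequency (`maf1`,
#' `q`), and carry a disease allele at an unlinked-or-linked locus adjacent
#' to the first marker with subpopulation frequency `p_d`. Children receive
#' one haplotype per parent (crossovers at rate `rho` within the block; the
#' disease allele decouples from the transmitted block with probability
#' `theta`) and families are ascertained on an affected child by rejection
#' sampling against the penetrance model. With `theta = 0.5` the markers
#' are unlinked to the disease locus and the dataset is a stratified null.
#'
#' @param n_families Number of trios to return.
#' @param n_markers Markers in the window (`l`).
#' @param q Minor-allele frequency in subpopulation 2.
#' @param pp Proportion of families from subpopulation 1.
#' @param maf1 Minor-allele frequency in subpopulation 1.
#' @param p_d Disease-allele frequencies `c(subpop1, subpop2)`.
#' @param theta Recombination fraction between the marker block and the
#'   disease locus (0.5 = no linkage).
#' @param rho Within-block per-interval recombination fraction.
#' @param model Ascertainment [disease_model()].
#' @param seed Optional integer seed.
#' @return A [trio_data()] with a `subpop` attribute giving each family's
#'   source subpopulation.
#' @export
simulate_stratified_null <- function(n_families = 500L, n_markers = 1L,
                                     q = 0.1, pp = 0.5, maf1 = 0.5,
                                     p_d = c(0.05, 0.25), theta = 0.5,
                                     rho = 1e-8,
                                     model = disease_model("dominant", 2),
                                     seed = NULL) {
  stopifnot(pp > 0, pp <= 1, q > 0, q < 1, maf1 > 0, maf1 < 1,
            theta >= 0, theta <= 0.5)
  l <- as.integer(n_markers)
  wmax <- max(penetrance(model, 0:2))
  with_seed(seed, {
    fa <- mo <- ch <- NULL
    sub <- integer()
    while (NROW(fa) < n_families) {
      m <- max(2L * (n_families - NROW(fa)), 64L)
      s <- 1L + (stats::runif(m) >= pp)
      maf <- ifelse(s == 1L, maf1, q)
      pd <- ifelse(s == 1L, p_d[1L], p_d[2L])
      hap <- function() matrix(stats::rbinom(m * l, 1L, maf), m, l)
      fh1 <- hap(); fh2 <- hap(); mh1 <- hap(); mh2 <- hap()
      df1 <- stats::rbinom(m, 1L, pd); df2 <- stats::rbinom(m, 1L, pd)
      dm1 <- stats::rbinom(m, 1L, pd); dm2 <- stats::rbinom(m, 1L, pd)
      pick_f <- stats::rbinom(m, 1L, 0.5) + 1L
      pick_m <- stats::rbinom(m, 1L, 0.5) + 1L
      tf <- transmit_block(fh1, fh2, pick_f, rho)
      tm <- transmit_block(mh1, mh2, pick_m, rho)
      src_f <- ifelse(stats::runif(m) < theta, 3L - pick_f, pick_f)
      src_m <- ifelse(stats::runif(m) < theta, 3L - pick_m, pick_m)
      g <- ifelse(src_f == 1L, df1, df2) + ifelse(src_m == 1L, dm1, dm2)
      acc <- stats::runif(m) < penetrance(model, g) / wmax
      tok <- function(x) matrix(as.character(x + 1L), nrow(x), ncol(x))
      fa <- rbind(fa, interleave(tok(fh1), tok(fh2))[acc, , drop = FALSE])
      mo <- rbind(mo, interleave(tok(mh1), tok(mh2))[acc, , drop = FALSE])
      ch <- rbind(ch, interleave(tok(tf), tok(tm))[acc, , drop = FALSE])
      sub <- c(sub, s[acc])
    }
    keep <- seq_len(n_families)
    ds <- trio_data(fa[keep, , drop = FALSE], mo[keep, , drop = FALSE],
                    ch[keep, , drop = FALSE], default_panel(l),
                    phased = TRUE)
    attr(ds, "subpop") <- sub[keep]
    ds
  })
}

#' Simulate disease-linked trios from a haplotype pool
#'
#' Founder haplotypes are drawn (with replacement) from a phased pool. The
#' disease susceptibility locus is the leftmost pool site whose minor
#' allele frequency falls in `maf_range` (one extreme of the
#' low-recombination block; the derived allele is the disease allele), and
#' the tested window consists of the `width` genotyped SNPs -- sites with
#' minor allele frequency at least `marker_maf`, emulating an array panel
#' of common variants -- immediately to its right. Transmission recombines
#' within the block at rate `rho` per
#' interval and decouples the disease allele from the block with
#' probability `theta`; trios are accepted by rejection sampling on the
#' child's penetrance. Two-locus models draw the second, unlinked locus
#' independently with allele frequency `second_locus_maf`.
#'
#' @param pool A [haplotype_pool()].
#' @param width Number of markers in the tested window.
#' @param n_families Number of trios.
#' @param model A [disease_model()].
#' @param theta Recombination fraction block-to-disease-locus (0 = perfect
#'   linkage, 0.5 = none).
#' @param rho Within-block per-interval recombination fraction.
#' @param maf_range Minor-allele-frequency interval for the disease site.
#' @param marker_maf Minimum minor allele frequency of a genotyped window
#'   SNP.
#' @param second_locus_maf Allele frequency of the unlinked second disease
#'   locus (two-locus models).
#' @param seed Optional integer seed.
#' @return A [trio_data()] over the window markers, with attributes
#'   `disease_site` (pool column index) and `marker_sites`.
#' @export
simulate_disease_trios <- function(pool, width, n_families = 250L,
                                   model = disease_model("dominant", 2.5),
                                   theta = 0, rho = 1e-8,
                                   maf_range = c(0.1, 0.5),
                                   marker_maf = 0.05,
                                   second_locus_maf = 0.25, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), width >= 1L)
  P <- pool$haplotypes
  if (nrow(P) < 2L) stop("pool is empty or too small")
  maf <- pmin(colMeans(P), 1 - colMeans(P))
  common <- which(maf >= marker_maf)
  eligible <- which(maf >= maf_range[1L] & maf <= maf_range[2L])
  eligible <- eligible[vapply(eligible, function(d) {
    sum(common > d) >= width
  }, NA)]
  if (!length(eligible)) {
    stop("no disease site with the requested MAF leaves room for the window")
  }
  dsite <- eligible[1L]
  msites <- utils::head(common[common > dsite], width)
  npool <- nrow(P)
  wmax <- if (model$two_locus) max(penetrance(model, rep(0:2, 3L),
                                              rep(0:2, each = 3L)))
          else max(penetrance(model, 0:2))
  with_seed(seed, {
    fa <- mo <- ch <- NULL
    while (NROW(fa) < n_families) {
      m <- max(2L * (n_families - NROW(fa)), 64L)
      idx <- matrix(sample.int(npool, 4L * m, replace = TRUE), m, 4L)
      fh1 <- P[idx[, 1L], msites, drop = FALSE]
      fh2 <- P[idx[, 2L], msites, drop = FALSE]
      mh1 <- P[idx[, 3L], msites, drop = FALSE]
      mh2 <- P[idx[, 4L], msites, drop = FALSE]
      df <- cbind(P[idx[, 1L], dsite], P[idx[, 2L], dsite])
      dm <- cbind(P[idx[, 3L], dsite], P[idx[, 4L], dsite])
      pick_f <- stats::rbinom(m, 1L, 0.5) + 1L
      pick_m <- stats::rbinom(m, 1L, 0.5) + 1L
      tf <- transmit_block(fh1, fh2, pick_f, rho)
      tm <- transmit_block(mh1, mh2, pick_m, rho)
      src_f <- ifelse(stats::runif(m) < theta, 3L - pick_f, pick_f)
      src_m <- ifelse(stats::runif(m) < theta, 3L - pick_m, pick_m)
      g1 <- df[cbind(seq_len(m), src_f)] + dm[cbind(seq_len(m), src_m)]
      g2 <- if (model$two_locus) stats::rbinom(m, 2L, second_locus_maf)
            else NULL
      w <- if (model$two_locus) penetrance(model, g1, g2)
           else penetrance(model, g1)
      acc <- stats::runif(m) < w / wmax
      tok <- function(x) matrix(as.character(x + 1L), nrow(x), ncol(x))
      fa <- rbind(fa, interleave(tok(fh1), tok(fh2))[acc, , drop = FALSE])
      mo <- rbind(mo, interleave(tok(mh1), tok(mh2))[acc, , drop = FALSE])
      ch <- rbind(ch, interleave(tok(tf), tok(tm))[acc, , drop = FALSE])
    }
    keep <- seq_len(n_families)
    pos <- as.integer(round(pool$positions[msites] * 1e6))
    for (j in seq_along(pos)[-1L]) {
      if (pos[j] <= pos[j - 1L]) pos[j] <- pos[j - 1L] + 1L
    }
    panel <- marker_panel(paste0("S", msites), pos, "1")
    ds <- trio_data(fa[keep, , drop = FALSE], mo[keep, , drop = FALSE],
                    ch[keep, , drop = FALSE], panel, phased = TRUE)
    attr(ds, "disease_site") <- dsite
    attr(ds, "marker_sites") <- msites
    ds
  })
}

#' Null trios with independent founder alleles
#'
#' Pure no-linkage fixture for property and calibration tests: founder
#' haplotypes have independent alleles at frequency `maf`, children receive
#' one untouched haplotype per parent, and no ascertainment is applied.
#'
#' @param n Number of trios.
#' @param l Number of markers.
#' @param maf Minor-allele frequency.
#' @param seed Optional integer seed.
#' @return A [trio_data()], Mendelian-consistent by construction.
#' @export
random_trios <- function(n, l, maf = 0.5, seed = NULL) {
  stopifnot(n >= 1L, l >= 1L)
  with_seed(seed, {
    hap <- function() matrix(stats::rbinom(n * l, 1L, maf), n, l)
    fh1 <- hap(); fh2 <- hap(); mh1 <- hap(); mh2 <- hap()
    pick_f <- stats::rbinom(n, 1L, 0.5) + 1L
    pick_m <- stats::rbinom(n, 1L, 0.5) + 1L
    tf <- transmit_block(fh1, fh2, pick_f, 0)
    tm <- transmit_block(mh1, mh2, pick_m, 0)
    tok <- function(x) matrix(as.character(x + 1L), nrow(x), ncol(x))
    trio_data(interleave(tok(fh1), tok(fh2)),
              interleave(tok(mh1), tok(mh2)),
              interleave(tok(tf), tok(tm)), default_panel(l),
              phased = TRUE)
  })
}

#' Delete parental genotypes at random
#'
#' Reproduces the missing-data design: exactly
#' `floor(proportion * n_parents * n_markers)` parent-marker genotype cells
#' are chosen uniformly without replacement and both allele tokens set to
#' the missing code. Children are never touched.
#'
#' @param trios A [trio_data()].
#' @param proportion Fraction of parent-marker cells to blank, in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A [trio_data()] with an `n_missing_cells` attribute.
#' @export
inject_missing <- function(trios, proportion, seed = NULL) {
  stopifnot(proportion >= 0, proportion < 1)
  n <- n_trios(trios); l <- n_markers(trios)
  total <- 2L * n * l
  k <- as.integer(floor(proportion * total))
  if (k == 0L) {
    attr(trios, "n_missing_cells") <- 0L
    return(trios)
  }
  sel <- with_seed(seed, sample.int(total, k)) - 1L
  parent <- sel %% 2L           # 0 = father, 1 = mother
  trio <- (sel %/% 2L) %% n + 1L
  markr <- sel %/% (2L * n) + 1L
  miss <- trios$missing_code
  for (p in 0:1) {
    rows <- trio[parent == p]; cols <- markr[parent == p]
    if (!length(rows)) next
    target <- if (p == 0L) "father" else "mother"
    trios[[target]][cbind(rows, 2L * cols - 1L)] <- miss
    trios[[target]][cbind(rows, 2L * cols)] <- miss
  }
  attr(trios, "n_missing_cells") <- k
  trios
}

#' Draw a pair of independent datasets from one population
#'
#' The sample-reproducibility protocol needs two independent same-size
#' draws from the same population: a model is fitted on the first and its
#' p-value recomputed on the second, mapping unseen haplotypes by length
#' similarity. The two draws use distinct seeds derived from the master
#' seed (identical streams are refused).
#'
#' @param sampler A function `function(seed)` returning a [trio_data()].
#' @param seed Master integer seed.
#' @return List with elements `first` and `second`.
#' @export
reproducibility_pair <- function(sampler, seed) {
  s1 <- derive_seed(seed, 1L)
  s2 <- derive_seed(seed, 2L)
  stopifnot(s1 != s2)
  list(first = sampler(s1), second = sampler(s2))
}
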