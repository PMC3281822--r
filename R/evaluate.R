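# Replicate-level harness: association rates with exact binomial CIs,
# type-I error tables under stratification, and power / locus-specificity
# curves. All stochastic acceptance checks elsewhere in the package are
# phrased as CI-band inclusions, never point equality.

#' Empirical association rate with an exact binomial CI
#'
#' The fraction of replicate p-values at or below the nominal level --
#' power when the tested window is linked to a disease locus, type-I error
#' when it is not.
#'
#' @param p_values Nonempty numeric vector of replicate p-values.
#' @param alpha Nominal level.
#' @return A list of class `rate_estimate`: `rate`, `n_replicates`,
#'   `alpha`, `ci95` (exact Clopper-Pearson interval).
#' @export
#' @examples
#' association_rate(c(0.04, 0.06), 0.05)$rate  # 0.5
association_rate <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("p_values must be nonempty")
  x <- sum(p_values <= alpha)
  n <- length(p_values)
  ci <- stats::binom.test(x, n)$conf.int
  structure(list(rate = x / n, n_replicates = n, alpha = alpha,
                 ci95 = as.numeric(ci)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("association rate %.4f (n = %d, alpha = %g, 95%% CI %.4f-%.4f)\n",
              x$rate, x$n_replicates, x$alpha, x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Type-I error table under population stratification
#'
#' Simulates `reps` null stratified datasets ([simulate_stratified_null()],
#' markers unlinked to the disease locus) for every combination of
#' subpopulation-2 MAF `q` and mixing proportion `pp`, applies the chosen
#' holdout test, and reports the empirical rejection rate at each nominal
#' level with its exact binomial 95% CI. Seeds are derived per replicate
#' from the master seed, so two runs with the same seed give identical
#' tables.
#'
#' @param q,pp Grids of subpopulation-2 MAFs and subpopulation-1 mixing
#'   proportions.
#' @param alpha Nominal levels to tabulate.
#' @param n_families Trios per replicate dataset.
#' @param n_markers Window width `l`.
#' @param reps Replicates per cell.
#' @param test Test name passed to [holdout_test()].
#' @param fraction Holdout training fraction.
#' @param model Ascertainment [disease_model()] for the null simulator.
#' @param seed Master integer seed.
#' @return Data frame keyed by `(alpha, q, pp, l)` with `rate`, `ci_lo`,
#'   `ci_hi`, `reps`.
#' @export
type1_table <- function(q = c(0.1, 0.3, 0.5), pp = c(0.5, 0.75, 0.833),
                        alpha = c(0.01, 0.05), n_families = 500L,
                        n_markers = 1L, reps = 1000L, test = "2g",
                        fraction = 0.5,
                        model = disease_model("dominant", 2), seed = 1L) {
  cells <- expand.grid(q = q, pp = pp, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    pv <- type1_pvalues(cells$q[ci], cells$pp[ci], n_families, n_markers,
                        reps, test, fraction, model,
                        derive_seed(seed, ci))
    for (a in alpha) {
      r <- association_rate(pv, a)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, q = cells$q[ci], pp = cells$pp[ci], l = n_markers,
        rate = r$rate, ci_lo = r$ci95[1L], ci_hi = r$ci95[2L], reps = reps)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$alpha, out$q, out$pp), , drop = FALSE]
}

# replicate p-values for one stratification cell
type1_pvalues <- function(q, pp, n_families, n_markers, reps, test,
                          fraction, model, seed) {
  vapply(seq_len(reps), function(i) {
    s <- derive_seed(seed, i)
    ds <- simulate_stratified_null(n_families, n_markers, q = q, pp = pp,
                                   theta = 0.5, model = model, seed = s)
    holdout_test(ds, test, fraction = fraction,
                 seed = derive_seed(s, 7L))$p.value
  }, numeric(1L))
}

#' Power and locus-specificity curve over recombination fractions
#'
#' Association rates of a holdout test on disease-linked trios drawn from a
#' haplotype pool, as the recombination fraction between the tested block
#' and the disease locus grows from perfect LD (`theta = 0`, power) to no
#' linkage (`theta = 0.5`, the specificity anchor).
#'
#' @param pool A [haplotype_pool()].
#' @param theta Grid of recombination fractions.
#' @param width Window width in markers.
#' @param model A [disease_model()].
#' @param n_families Trios per replicate.
#' @param reps Replicates per theta.
#' @param alpha Nominal level.
#' @param test Test name for [holdout_test()].
#' @param fraction Holdout training fraction.
#' @param seed Master integer seed.
#' @return Data frame with `theta`, `rate`, `ci_lo`, `ci_hi`, `reps`.
#' @export
#' Sample-reproducibility rates of a test across paired datasets
#'
#' Runs the reproducibility protocol: for each replicate, two independent
#' same-size datasets are drawn from the population sampler; the test's
#' model is learned from the first dataset (its training half under the
#' holdout protocol, the whole dataset for a plain test) and the statistic
#' is computed both on the first dataset's own scoring material and on an
#' equally sized subset of the second dataset, plugging unseen haplotypes
#' in by length similarity. Matching the two scoring sample sizes keeps the
#' paired rejection rates comparable.
#'
#' @param sampler Function `function(seed)` returning a [trio_data()].
#' @param test Test name (`"2g"`, `"mhet"`, `"max"`, `"tdt1"`).
#' @param reps Number of replicate pairs.
#' @param alpha Nominal level.
#' @param holdout Fit on a random half (holdout protocol) or on the whole
#'   first dataset (plain protocol).
#' @param fraction Holdout training fraction.
#' @param seed Master integer seed.
#' @return List with `rate_first`, `rate_second`, the per-replicate
#'   p-value matrix `p` (columns `first`, `second`) and `reps`.
#' @export
reproducibility_rates <- function(sampler, test = "2g", reps = 100L,
                                  alpha = 0.05, holdout = TRUE,
                                  fraction = 0.5, seed = 1L) {
  p <- matrix(NA_real_, reps, 2L,
              dimnames = list(NULL, c("first", "second")))
  for (i in seq_len(reps)) {
    pr <- reproducibility_pair(sampler, derive_seed(seed, i))
    if (holdout) {
      spA <- holdout_split(pr$first, fraction, derive_seed(seed, i, 3L))
      fit <- tdt_fit(spA$training, test)
      p[i, 1L] <- tdt_score(fit, spA$test)$p.value
      spB <- holdout_split(pr$second, fraction, derive_seed(seed, i, 4L))
      p[i, 2L] <- tdt_score(fit, spB$test)$p.value
    } else {
      fit <- tdt_fit(pr$first, test)
      p[i, 1L] <- tdt_score(fit, pr$first)$p.value
      p[i, 2L] <- tdt_score(fit, pr$second)$p.value
    }
  }
  list(rate_first = mean(p[, 1L] <= alpha),
       rate_second = mean(p[, 2L] <= alpha), p = p, reps = reps)
}

power_curve <- function(pool, theta = c(0, 0.001, 0.005, 0.01, 0.05, 0.1,
                                        0.5),
                        width = 8L, model = disease_model("dominant", 2.5),
                        n_families = 250L, reps = 100L, alpha = 0.05,
                        test = "2g", fraction = 0.5, seed = 1L) {
  rows <- lapply(seq_along(theta), function(ti) {
    pv <- vapply(seq_len(reps), function(i) {
      s <- derive_seed(seed, ti, i)
      ds <- simulate_disease_trios(pool, width, n_families, model,
                                   theta = theta[ti], seed = s)
      holdout_test(ds, test, fraction = fraction,
                   seed = derive_seed(s, 7L))$p.value
    }, numeric(1L))
    r <- association_rate(pv, alpha)
    data.frame(theta = theta[ti], rate = r$rate, ci_lo = r$ci95[1L],
               ci_hi = r$ci95[2L], reps = reps)
  })
  do.call(rbind, rows)
}
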