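# Comparison TDT statistics: the classic biallelic TDT, the multimarker
# heterozygosity TDT (H - 1 df) and the maximum one-vs-rest TDT, each
# available plain or under the same holdout wrapper as the 2G test.

#' Classic single-marker biallelic TDT
#'
#' McNemar chi-square on the discordant transmission counts of the two
#' alleles from heterozygous parents.
#'
#' @param b,c Counts of heterozygous parents transmitting allele 1 (and not
#'   allele 2) and vice versa.
#' @return A [tdt_result()] with statistic `(b - c)^2 / (b + c)` on 1 df;
#'   `b + c = 0` yields `p = 1` with a note.
#' @export
#' @examples
#' tdt_classic(20, 5)  # 9.0, p ~ 0.0027
tdt_classic <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be nonnegative")
  n <- b + c
  if (n == 0L) {
    return(tdt_result(NA_real_, 1L, 1, 0L, "classic TDT",
                      note = "no informative genotypes"))
  }
  stat <- (b - c)^2 / n
  tdt_result(stat, 1L, stats::pchisq(stat, 1L, lower.tail = FALSE), n,
             "classic TDT", b = b, c = c)
}

#' Multimarker heterozygosity TDT
#'
#' Sums the per-haplotype McNemar terms over all H distinct haplotypes,
#' scaled by (H - 1)/H, with a limiting chi-square on H - 1 df under no
#' linkage. Power degrades as H grows (sparse-data effect), which is the
#' behaviour the 2G grouping is designed to avoid.
#'
#' @param table A [transmission_table()].
#' @return A [tdt_result()]; fewer than two haplotypes give `p = 1` with a
#'   note.
#' @export
tdt_mhet <- function(table) {
  H <- nrow(table)
  n <- attr(table, "n_informative")
  if (H < 2L) {
    return(tdt_result(NA_real_, max(0L, H - 1L), 1, n %||% 0L,
                      "multimarker heterozygosity TDT",
                      note = "fewer than 2 haplotypes"))
  }
  use <- (table$T + table$U) > 0L
  stat <- (H - 1) / H *
    sum((table$T[use] - table$U[use])^2 / (table$T[use] + table$U[use]))
  tdt_result(stat, H - 1L,
             stats::pchisq(stat, H - 1L, lower.tail = FALSE), n,
             "multimarker heterozygosity TDT", H = H)
}

one_vs_rest <- function(table) {
  # per haplotype i the one-vs-rest discordant counts from heterozygous
  # genotypes are exactly (T_i, U_i): a genotype is discordant for i iff
  # exactly one of its two haplotypes is i
  cbind(b = table$T, c = table$U)
}

#' Maximum one-vs-rest TDT
#'
#' Collapses each haplotype against all others combined, computes the
#' biallelic TDT for each, and takes the maximum. The plain statistic does
#' not follow a chi-square under the null for more than one marker, so the
#' reported p-value is the Bonferroni bound `min(1, H * tail)` and is
#' flagged as such; the holdout variant ([holdout_test()] with
#' `test = "max"`) selects the haplotype on the training half and reports an
#' exact 1-df test on the held-out half.
#'
#' @param table A [transmission_table()].
#' @return A [tdt_result()] with the selected haplotype in `$selected`.
#' @export
tdt_max <- function(table) {
  H <- nrow(table)
  n <- attr(table, "n_informative")
  if (H < 2L) {
    return(tdt_result(NA_real_, 1L, 1, n %||% 0L, "max one-vs-rest TDT",
                      note = "fewer than 2 haplotypes"))
  }
  bc <- one_vs_rest(table)
  tot <- bc[, "b"] + bc[, "c"]
  stat_i <- ifelse(tot > 0, (bc[, "b"] - bc[, "c"])^2 / tot, 0)
  best <- which.max(stat_i)  # ties: first in table order (largest T + U)
  stat <- stat_i[best]
  p <- min(1, H * stats::pchisq(stat, 1L, lower.tail = FALSE))
  tdt_result(stat, 1L, p, n, "max one-vs-rest TDT",
             note = "bonferroni bound", selected = table$haplotype[best],
             H = H)
}

# --- generic fit/score used by the holdout wrapper --------------------------

map_haplotypes <- function(keys, members, weights, sep) {
  # map test haplotypes onto the fitted haplotype list: membership first,
  # otherwise max length similarity; ties broken toward the member with the
  # larger training count, then lexicographically
  u <- unique(keys)
  member_alleles <- lapply(members, split_key, sep = sep)
  mapped <- vapply(u, function(k) {
    hit <- match(k, members)
    if (!is.na(hit)) return(members[hit])
    a <- split_key(k, sep)
    sims <- vapply(member_alleles, function(g) max_run(a == g), 0L)
    cand <- which(sims == max(sims))
    if (length(cand) > 1L) {
      cand <- cand[order(-weights[cand], members[cand])]
    }
    members[cand[1L]]
  }, character(1L), USE.NAMES = FALSE)
  mapped[match(keys, u)]
}

#' Fit a TDT model on training trios
#'
#' The fit side of the generic holdout wrapper: what a test learns from the
#' training half. For `"2g"` it is the two-group model; for `"mhet"` the
#' training haplotype list (fixing H and the df); for `"max"` the selected
#' one-vs-rest haplotype. `"tdt1"` is the single-marker reduction and is
#' fitted as a two-group model on a width-1 window.
#'
#' @param trios Training [trio_data()].
#' @param test One of `"2g"`, `"mhet"`, `"max"`, `"tdt1"`.
#' @param window Marker indices.
#' @return A classed `tdt_model` list understood by [tdt_score()].
#' @export
tdt_fit <- function(trios, test = c("2g", "mhet", "max", "tdt1"),
                    window = NULL) {
  test <- match.arg(test)
  if (test == "tdt1") {
    window <- as.integer(window %||% 1L)
    if (length(window) != 1L) stop("tdt1 uses a single marker")
  }
  tbl <- transmission_table(trio_transmissions(trios, window))
  model <- switch(test,
    "2g" = , "tdt1" = build_groups(tbl),
    "mhet" = tbl,
    "max" = list(table = tbl, selected = tdt_max(tbl)$selected)
  )
  structure(list(test = test, model = model, window = window),
            class = "tdt_model")
}

#' Score a fitted TDT model on test trios
#'
#' Unseen test haplotypes are plugged into the fitted model through the
#' length-similarity rule before counting, mirroring how a model learned on
#' one dataset is validated on a second.
#'
#' @param fit A `tdt_model` from [tdt_fit()].
#' @param trios Test [trio_data()].
#' @param window Marker indices (defaults to the fitted window).
#' @return A [tdt_result()].
#' @export
tdt_score <- function(fit, trios, window = NULL) {
  stopifnot(inherits(fit, "tdt_model"))
  window <- window %||% fit$window
  tt <- trio_transmissions(trios, window)
  het <- tt[tt$het, , drop = FALSE]
  res <- switch(fit$test,
    "2g" = , "tdt1" = {
      r <- statistic_2g(two_group_counts(tt, fit$model))
      r$model <- fit$model
      if (fit$test == "tdt1") r$method <- "classic TDT (holdout)"
      r
    },
    "mhet" = {
      tbl <- fit$model
      if (nrow(tbl) < 2L || nrow(het) == 0L) {
        tdt_result(NA_real_, max(0L, nrow(tbl) - 1L), 1, 0L,
                   "multimarker heterozygosity TDT (holdout)",
                   note = "untestable model")
      } else {
        mt <- map_haplotypes(het$transmitted, tbl$haplotype,
                             tbl$T + tbl$U, attr(tbl, "sep"))
        mu <- map_haplotypes(het$nontransmitted, tbl$haplotype,
                             tbl$T + tbl$U, attr(tbl, "sep"))
        keep <- mt != mu
        H <- nrow(tbl)
        Tn <- table(factor(mt[keep], levels = tbl$haplotype))
        Un <- table(factor(mu[keep], levels = tbl$haplotype))
        tot <- as.integer(Tn) + as.integer(Un)
        use <- tot > 0L
        stat <- (H - 1) / H *
          sum((as.integer(Tn)[use] - as.integer(Un)[use])^2 / tot[use])
        tdt_result(stat, H - 1L,
                   stats::pchisq(stat, H - 1L, lower.tail = FALSE),
                   sum(keep), "multimarker heterozygosity TDT (holdout)",
                   H = H)
      }
    },
    "max" = {
      sel <- fit$model$selected
      tbl <- fit$model$table
      if (is.null(sel) || nrow(het) == 0L) {
        tdt_result(NA_real_, 1L, 1, 0L, "max one-vs-rest TDT (holdout)",
                   note = "untestable model")
      } else {
        mt <- map_haplotypes(het$transmitted, tbl$haplotype,
                             tbl$T + tbl$U, attr(tbl, "sep"))
        mu <- map_haplotypes(het$nontransmitted, tbl$haplotype,
                             tbl$T + tbl$U, attr(tbl, "sep"))
        b <- sum(mt == sel & mu != sel)
        c <- sum(mu == sel & mt != sel)
        r <- tdt_classic(b, c)
        r$method <- "max one-vs-rest TDT (holdout)"
        r$selected <- sel
        r
      }
    }
  )
  res$window <- as.integer(window %||% seq_len(n_markers(trios)))
  res
}

#' Apply a TDT under the holdout approach
#'
#' The generic split/fit/score wrapper: trios are randomly divided into a
#' training half (model learning: groups for 2G, the haplotype list for
#' mhet, the selected haplotype for max) and a test half on which the
#' statistic and p-value are computed, so every variant keeps its stated
#' null distribution without multiplicity correction. `test = "2g"` is
#' identical to [tdt2g()] for the same seed.
#'
#' @inheritParams tdt_fit
#' @param fraction Training fraction.
#' @param seed Optional split seed.
#' @return A [tdt_result()].
#' @export
holdout_test <- function(trios, test = c("2g", "mhet", "max", "tdt1"),
                         window = NULL, fraction = 0.5, seed = NULL) {
  test <- match.arg(test)
  halves <- holdout_split(trios, fraction, seed)
  fit <- tdt_fit(halves$training, test, window)
  res <- tdt_score(fit, halves$test, window)
  res$seed <- seed
  if (test == "2g") res$method <- "2-group multimarker TDT (holdout)"
  res
}

#' Apply a TDT without holdout (plain variant)
#'
#' Fits and scores on the same data. For `"mhet"` and `"max"` this is the
#' standard published statistic; for `"2g"` it is the overfit same-data
#' variant, exposed because the single-marker case reduces exactly to the
#' classic TDT.
#'
#' @inheritParams tdt_fit
#' @return A [tdt_result()].
#' @export
plain_test <- function(trios, test = c("2g", "mhet", "max", "tdt1"),
                       window = NULL) {
  test <- match.arg(test)
  if (test %in% c("mhet", "max")) {
    tbl <- transmission_table(trio_transmissions(trios, window))
    res <- if (test == "mhet") tdt_mhet(tbl) else tdt_max(tbl)
    res$window <- as.integer(window %||% seq_len(n_markers(trios)))
    return(res)
  }
  fit <- tdt_fit(trios, test, window)
  tdt_score(fit, trios, window)
}
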