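# The two-group multimarker TDT.
#
# The trios are split at random into a training and a test half (families
# intact). The training transmission table defines two disjoint haplotype
# groups: g1 (high risk), the haplotypes transmitted more often than
# nontransmitted, and g2 (low risk), those nontransmitted more often; ties
# stay unassigned at fit time. On the test half, a heterozygous parental
# genotype is informative only when its two haplotypes land in different
# groups -- membership first, otherwise the group holding the most
# length-similar member, with similarity ties left unassigned -- and the
# statistic is the McNemar chi-square (n_T - n_U)^2 / (n_T + n_U) on the
# cross-group transmission counts, which has 1 df under no linkage
# regardless of the number of markers.

#' Randomly split trios into training and test halves
#'
#' The splitting unit is the trio, so the two parental genotypes of a family
#' never straddle the split (training and test counts stay independent).
#' The training half receives `round(fraction * n)` trios with halves
#' rounded up, so 5 trios at `fraction = 0.5` give a 3 + 2 split.
#'
#' @param trios A [trio_data()].
#' @param fraction Training fraction, in (0, 1).
#' @param seed Optional integer seed making the split reproducible.
#' @return A list with elements `training` and `test` (both `trio_data`).
#' @export
holdout_split <- function(trios, fraction = 0.5, seed = NULL) {
  n <- n_trios(trios)
  if (n < 2L) stop("need at least 2 trios to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n_train <- as.integer(floor(fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(training = subset_trios(trios, sort(idx)),
       test = subset_trios(trios, setdiff(seq_len(n), idx)))
}

#' Build high- and low-risk haplotype groups from a training table
#'
#' @param table A [transmission_table()] computed on the training half.
#' @return A `group_model`: list with `g1` (haplotypes with T > U), `g2`
#'   (U > T), `unassigned` (T == U), the window width and the haplotype-key
#'   separator. Either group may be empty.
#' @export
build_groups <- function(table) {
  stopifnot(inherits(table, "transmission_table"))
  sep <- attr(table, "sep")
  g1 <- table$haplotype[table$T > table$U]
  g2 <- table$haplotype[table$U > table$T]
  un <- table$haplotype[table$T == table$U]
  structure(
    list(g1 = g1, g2 = g2, unassigned = un,
         g1_alleles = lapply(g1, split_key, sep = sep),
         g2_alleles = lapply(g2, split_key, sep = sep),
         width = attr(table, "width"), sep = sep, table = table),
    class = "group_model"
  )
}

#' @export
print.group_model <- function(x, ...) {
  cat("Two-group haplotype model\n")
  cat("  g1 (high risk): ", if (length(x$g1)) paste(x$g1, collapse = ", ")
      else "<empty>", "\n", sep = "")
  cat("  g2 (low risk):  ", if (length(x$g2)) paste(x$g2, collapse = ", ")
      else "<empty>", "\n", sep = "")
  if (length(x$unassigned)) {
    cat("  unassigned:     ", paste(x$unassigned, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Assign haplotypes to a fitted two-group model
#'
#' Members of `g1` or `g2` keep their group. Any other haplotype (unseen in
#' training, or tied at fit time) goes to the group containing the haplotype
#' most length-similar to it; an equal best similarity to both groups -- or
#' an empty model -- leaves it unassigned, which is conservative: the parental
#' genotype carrying it is skipped.
#'
#' @param h Character vector of haplotype keys (using the model's
#'   separator).
#' @param model A `group_model` from [build_groups()].
#' @return Character vector over `{"g1", "g2", "unassigned"}`.
#' @export
assign_group <- function(h, model) {
  stopifnot(inherits(model, "group_model"))
  u <- unique(h)
  grp <- vapply(u, function(k) {
    if (k %in% model$g1) return("g1")
    if (k %in% model$g2) return("g2")
    if (!length(model$g1) && !length(model$g2)) return("unassigned")
    a <- split_key(k, model$sep)
    s1 <- if (length(model$g1_alleles)) {
      max(vapply(model$g1_alleles, function(g) max_run(a == g), 0L))
    } else -1L
    s2 <- if (length(model$g2_alleles)) {
      max(vapply(model$g2_alleles, function(g) max_run(a == g), 0L))
    } else -1L
    if (s1 > s2) "g1" else if (s2 > s1) "g2" else "unassigned"
  }, character(1L), USE.NAMES = FALSE)
  grp[match(h, u)]
}

#' Collapse test-half transmissions onto the two groups
#'
#' A test parental genotype contributes only when it is heterozygous and its
#' two haplotypes are assigned to different groups; genotypes with both
#' haplotypes in one group are treated as homozygous and skipped, as is any
#' genotype with an unassigned side. `n_T` counts transmissions of the
#' g1-side haplotype, `n_U` of the g2 side.
#'
#' @param transmissions [trio_transmissions()] from the test half.
#' @param model A `group_model`.
#' @return A list of class `two_group_counts`: `n_T`, `n_U`, `n_used`
#'   (`= n_T + n_U`), `n_het`.
#' @export
two_group_counts <- function(transmissions, model) {
  het <- transmissions[transmissions$het, , drop = FALSE]
  if (nrow(het) == 0L) {
    return(structure(list(n_T = 0L, n_U = 0L, n_used = 0L, n_het = 0L),
                     class = "two_group_counts"))
  }
  gT <- assign_group(het$transmitted, model)
  gU <- assign_group(het$nontransmitted, model)
  n_T <- sum(gT == "g1" & gU == "g2")
  n_U <- sum(gT == "g2" & gU == "g1")
  structure(list(n_T = n_T, n_U = n_U, n_used = n_T + n_U,
                 n_het = nrow(het)),
            class = "two_group_counts")
}

#' The 2G McNemar statistic from collapsed counts
#'
#' @param counts A `two_group_counts` object, or `n_T` directly.
#' @param n_U Nontransmitted-group count when `counts` is numeric.
#' @return A [tdt_result()] with `(n_T - n_U)^2 / (n_T + n_U)`, 1 df, and
#'   the upper chi-square tail probability; zero used genotypes give
#'   `p = 1` with a note.
#' @export
#' @examples
#' statistic_2g(51, 34)  # the worked-example counts: 3.4, p ~ 0.065
statistic_2g <- function(counts, n_U = NULL) {
  if (inherits(counts, "two_group_counts")) {
    n_T <- counts$n_T; n_U <- counts$n_U
  } else {
    n_T <- counts
  }
  if (n_T < 0 || n_U < 0) stop("counts must be nonnegative")
  n <- n_T + n_U
  if (n == 0L) {
    return(tdt_result(NA_real_, 1L, 1, 0L, "2-group multimarker TDT",
                      note = "no informative genotypes",
                      n_T = 0L, n_U = 0L))
  }
  stat <- (n_T - n_U)^2 / n
  tdt_result(stat, 1L, stats::pchisq(stat, df = 1L, lower.tail = FALSE),
             n, "2-group multimarker TDT", n_T = n_T, n_U = n_U)
}

#' Fit the two-group model on (training) trios
#'
#' @param trios Training [trio_data()].
#' @param window Marker indices (default: all).
#' @return A `group_model` (the training [transmission_table()] is kept in
#'   `$table`).
#' @export
tdt2g_fit <- function(trios, window = NULL) {
  build_groups(transmission_table(trio_transmissions(trios, window)))
}

#' Score a fitted two-group model on (test) trios
#'
#' @param trios Test [trio_data()].
#' @param model A `group_model` from [tdt2g_fit()].
#' @param window Marker indices; must match the width the model was fitted
#'   on.
#' @return A [tdt_result()].
#' @export
tdt2g_score <- function(trios, model, window = NULL) {
  tt <- trio_transmissions(trios, window)
  if (nrow(tt) && attr(tt, "width") != model$width) {
    stop("window width differs from the fitted model's width")
  }
  counts <- two_group_counts(tt, model)
  res <- statistic_2g(counts)
  res$window <- as.integer(window %||% seq_len(n_markers(trios)))
  res$model <- model
  res$n_unresolved <- attr(tt, "n_unresolved")
  res
}

#' The two-group multimarker TDT (2G) with holdout
#'
#' Runs the full pipeline: split the trios into training and test halves,
#' learn the high-/low-risk haplotype groups on the training transmissions,
#' and score the 1-df McNemar statistic on the held-out half. The random
#' split is the only stochastic element; with one biallelic marker and the
#' groups learned on the scoring data itself the statistic reduces exactly
#' to the classic TDT.
#'
#' @param trios A [trio_data()] with at least 2 trios.
#' @param window Integer marker indices to test (default: all markers).
#' @param fraction Training fraction of the holdout split.
#' @param seed Optional integer seed for the split.
#' @return A [tdt_result()] carrying the fitted `group_model`, the split
#'   seed and the informative count.
#' @seealso [holdout_test()] for the comparison statistics under the same
#'   holdout wrapper, [tdt_scan()] for sliding windows.
#' @export
#' @examples
#' ds <- random_trios(80, 3, seed = 7)
#' tdt2g(ds, seed = 1)
tdt2g <- function(trios, window = NULL, fraction = 0.5, seed = NULL) {
  halves <- holdout_split(trios, fraction, seed)
  model <- tdt2g_fit(halves$training, window)
  res <- tdt2g_score(halves$test, model, window)
  res$seed <- seed
  res$method <- "2-group multimarker TDT (holdout)"
  res
}

#' Export a fitted group model as a data frame
#'
#' One row per training haplotype with its group label -- the starting point
#' the two groups offer to downstream haplotype fine-mapping methods.
#'
#' @param model A `group_model`.
#' @return Data frame with columns `haplotype`, `group`, `T`, `U`.
#' @export
group_model_frame <- function(model) {
  tbl <- model$table
  grp <- ifelse(tbl$haplotype %in% model$g1, "g1",
                ifelse(tbl$haplotype %in% model$g2, "g2", "unassigned"))
  data.frame(haplotype = tbl$haplotype, group = grp, T = tbl$T, U = tbl$U,
             stringsAsFactors = FALSE)
}
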