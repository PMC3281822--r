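#' Construct a TDT test result
#'
#' Light container for every statistic in the package, printed in the style
#' of `htest`. Degenerate inputs (no informative genotypes, fewer than two
#' haplotypes) yield `statistic = NA`, `p.value = 1` and an explanatory
#' `note` rather than an error, so window scans never abort.
#'
#' @param statistic Nonnegative chi-square statistic (or `NA`).
#' @param df Degrees of freedom.
#' @param p.value P-value in `[0, 1]`.
#' @param n_informative Number of parental genotypes used.
#' @param method Human-readable test label.
#' @param window Integer range of marker indices tested (1-based inclusive).
#' @param seed Holdout-split seed, if any.
#' @param note Optional flag, e.g. `"no informative genotypes"` or
#'   `"bonferroni bound"`.
#' @param ... Further fields stored on the object (e.g. counts, the fitted
#'   group model).
#' @return An object of class `tdt_result`.
#' @export
tdt_result <- function(statistic, df, p.value, n_informative, method,
                       window = NULL, seed = NULL, note = NULL, ...) {
  stopifnot(is.na(p.value) || (p.value >= 0 && p.value <= 1))
  structure(
    list(statistic = as.numeric(statistic), df = df,
         p.value = as.numeric(p.value),
         n_informative = as.integer(n_informative),
         method = method, window = window, seed = seed, note = note, ...),
    class = "tdt_result"
  )
}

#' @export
print.tdt_result <- function(x, digits = 4L, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  if (!is.null(x$window)) {
    cat(sprintf("markers: %d..%d   ", min(x$window), max(x$window)))
  }
  cat(sprintf("informative genotypes: %d\n", x$n_informative))
  cat(sprintf("chi-squared = %s, df = %s, p-value = %s\n",
              format(x$statistic, digits = digits),
              format(x$df), format.pval(x$p.value, digits = digits)))
  if (!is.null(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
summary.tdt_result <- function(object, ...) {
  out <- data.frame(statistic = object$statistic,
                    df = if (is.numeric(object$df)) object$df else NA_integer_,
                    p.value = object$p.value,
                    n_informative = object$n_informative,
                    test = object$method, stringsAsFactors = FALSE)
  if (!is.null(object$window)) {
    out$start_marker <- min(object$window)
    out$end_marker <- max(object$window)
  }
  out
}
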