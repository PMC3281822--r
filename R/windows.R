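# Sliding-window scan engine and per-marker aggregation.

#' Enumerate sliding windows over a marker panel
#'
#' Windows of `width` consecutive markers advance by `offset` markers while
#' they fit, giving `floor((n_markers - width) / offset) + 1` windows. Start
#' indices are 1-based and inclusive.
#'
#' @param n_markers Panel length.
#' @param width Window width in markers, `1 <= width <= n_markers`.
#' @param offset Step between window starts (default 1 SNP).
#' @return Data frame with columns `start`, `end` (inclusive marker
#'   indices).
#' @export
#' @examples
#' nrow(sliding_windows(103, 8))  # 96
sliding_windows <- function(n_markers, width, offset = 1L) {
  n_markers <- as.integer(n_markers); width <- as.integer(width)
  offset <- as.integer(offset)
  if (width < 1L || width > n_markers) stop("width must be in 1..n_markers")
  if (offset < 1L) stop("offset must be >= 1")
  starts <- seq.int(1L, n_markers - width + 1L, by = offset)
  data.frame(start = starts, end = starts + width - 1L)
}

#' Sliding-window association scan
#'
#' Applies the chosen TDT to every window of `width` consecutive markers.
#' Each window's holdout split uses a seed derived deterministically from
#' the master seed and the window start, so adding markers to the panel
#' never reshuffles the splits of existing windows, and two scans with the
#' same master seed are identical. Windows without informative genotypes
#' carry `p = 1` flags and never abort the scan.
#'
#' @param trios A [trio_data()].
#' @param width Window width in markers.
#' @param test One of `"2g"`, `"mhet"`, `"max"`, `"tdt1"` (`"tdt1"` forces
#'   `width = 1`).
#' @param offset Step between window starts.
#' @param holdout Apply the holdout wrapper (default) or the plain variant.
#' @param fraction Training fraction of each holdout split.
#' @param seed Master integer seed.
#' @return A data frame of class `tdt_scan`: one row per window with
#'   `chrom`, `start_marker`, `end_marker`, `start_pos`, `end_pos`,
#'   `n_informative`, `statistic`, `df`, `p_value`, `test_name`, `seed`,
#'   ordered by window start. The panel is kept as an attribute.
#' @export
tdt_scan <- function(trios, width, test = c("2g", "mhet", "max", "tdt1"),
                     offset = 1L, holdout = TRUE, fraction = 0.5,
                     seed = NULL) {
  test <- match.arg(test)
  if (test == "tdt1") width <- 1L
  wins <- sliding_windows(n_markers(trios), width, offset)
  panel <- trios$panel
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins$start[i]:wins$end[i]
    wseed <- if (is.null(seed)) NULL else derive_seed(seed, wins$start[i])
    res <- if (holdout) {
      holdout_test(trios, test, window = w, fraction = fraction,
                   seed = wseed)
    } else {
      plain_test(trios, test, window = w)
    }
    data.frame(
      chrom = panel$chrom[1L],
      start_marker = wins$start[i], end_marker = wins$end[i],
      start_pos = panel$pos[wins$start[i]], end_pos = panel$pos[wins$end[i]],
      n_informative = res$n_informative,
      statistic = res$statistic,
      df = if (is.numeric(res$df)) res$df else NA_integer_,
      p_value = res$p.value,
      test_name = res$method,
      seed = if (is.null(wseed)) NA_integer_ else wseed,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start_marker), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, panel = panel, width = width,
            class = c("tdt_scan", "data.frame"))
}

#' Per-marker aggregation of window p-values
#'
#' Maps window-level results back to markers: the value at marker m is the
#' mean of the p-values of all windows covering m (the quantity plotted in
#' sliding-window association maps). Edge markers are covered by fewer
#' windows than interior ones; the coverage count is reported alongside.
#'
#' @param scan A [tdt_scan()] result.
#' @param type Arithmetic (default) or geometric mean of the covering
#'   p-values.
#' @return Data frame with one row per marker: `marker`, `pos`,
#'   `n_windows`, `mean_p`.
#' @export
per_marker_aggregate <- function(scan, type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  panel <- attr(scan, "panel")
  m <- nrow(panel)
  vals <- vapply(seq_len(m), function(j) {
    cover <- scan$p_value[scan$start_marker <= j & scan$end_marker >= j]
    if (!length(cover)) return(c(0, NA_real_))
    mp <- if (type == "arithmetic") mean(cover)
          else exp(mean(log(pmax(cover, .Machine$double.xmin))))
    c(length(cover), mp)
  }, numeric(2L))
  data.frame(marker = panel$marker, pos = panel$pos,
             n_windows = as.integer(vals[1L, ]), mean_p = vals[2L, ],
             stringsAsFactors = FALSE)
}

#' @export
print.tdt_scan <- function(x, ...) {
  cat(sprintf("TDT sliding-window scan: %d windows of width %d (%s)\n",
              nrow(x), attr(x, "width"), x$test_name[1L]))
  top <- x[order(x$p_value), , drop = FALSE]
  cat("smallest p-values:\n")
  print.data.frame(utils::head(top[, c("start_marker", "end_marker",
                                       "n_informative", "statistic",
                                       "p_value")], 5L), row.names = FALSE)
  invisible(x)
}

#' @export
plot.tdt_scan <- function(x, type = "arithmetic", ...) {
  agg <- per_marker_aggregate(x, type)
  plot(agg$pos, -log10(agg$mean_p), type = "b", pch = 19, cex = 0.6,
       xlab = "position (bp)", ylab = "-log10 mean window p",
       main = x$test_name[1L], ...)
  invisible(agg)
}

#' Write scan results as tab-separated text
#'
#' Header columns: chrom, window_start_marker (1-based), window_end_marker
#' (inclusive), n_informative, statistic (two decimals), df, p_value,
#' test_name, seed; rows ordered by window start. An empty scan writes the
#' header only.
#'
#' @param results A [tdt_scan()] data frame (or any data frame with the
#'   scan columns).
#' @param file Path or connection.
#' @return Invisibly, the formatted data frame written.
#' @export
write_results <- function(results, file) {
  df <- as.data.frame(results)
  out <- data.frame(
    chrom = df$chrom,
    window_start_marker = df$start_marker,
    window_end_marker = df$end_marker,
    n_informative = df$n_informative,
    statistic = ifelse(is.na(df$statistic), "NA",
                       formatC(df$statistic, format = "f", digits = 2L)),
    df = df$df,
    p_value = signif(df$p_value, 6L),
    test_name = df$test_name,
    seed = df$seed,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$window_start_marker), , drop = FALSE]
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
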