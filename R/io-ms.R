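# ms / msHOT output dialect: replicate blocks introduced by "//", a
# "segsites:" line, a "positions:" line, then 0/1 haplotype rows.

#' Haplotype pools
#'
#' A pool of phased binary haplotypes from which simulated founders are
#' drawn -- typically a coalescent sample, read from ms/msHOT output or
#' generated by [coalescent_pool()].
#'
#' @param haplotypes Integer 0/1 matrix, one row per haplotype, one column
#'   per segregating site.
#' @param positions Numeric site positions (fractional ms coordinates or
#'   integers), one per column.
#' @param source Free-text provenance.
#' @return An object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotypes, positions = NULL, source = "") {
  haplotypes <- as.matrix(haplotypes)
  if (length(haplotypes) && !all(haplotypes %in% c(0L, 1L))) {
    stop("pool alleles must be 0/1")
  }
  storage.mode(haplotypes) <- "integer"
  positions <- positions %||%
    (if (ncol(haplotypes)) seq_len(ncol(haplotypes)) / (ncol(haplotypes) + 1)
     else numeric())
  if (length(positions) != ncol(haplotypes)) {
    stop("one position per site required")
  }
  structure(list(haplotypes = haplotypes, positions = as.numeric(positions),
                 source = source, empty = ncol(haplotypes) == 0L),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("Haplotype pool: %d haplotypes x %d segregating sites%s\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              if (nzchar(x$source)) paste0(" (", x$source, ")") else ""))
  invisible(x)
}

#' Read a haplotype pool from ms/msHOT output
#'
#' @param file Path or connection to ms-format text.
#' @param replicate Which `//` block to read (default: first).
#' @return A [haplotype_pool()]; `segsites: 0` yields an empty pool with
#'   `$empty = TRUE`.
#' @export
read_ms <- function(file, replicate = 1L) {
  lines <- readLines(file)
  starts <- grep("^//", lines)
  if (!length(starts)) stop("no '//' replicate block found")
  if (replicate > length(starts)) stop("replicate block not present")
  i <- starts[replicate] + 1L
  seg_line <- lines[i]
  if (!grepl("^segsites:", seg_line)) stop("expected 'segsites:' line")
  segsites <- as.integer(sub("^segsites:\\s*", "", seg_line))
  if (is.na(segsites)) stop("unparseable segsites count")
  if (segsites == 0L) {
    return(haplotype_pool(matrix(integer(), 0L, 0L), numeric(),
                          source = "ms"))
  }
  pos_line <- lines[i + 1L]
  if (!grepl("^positions:", pos_line)) stop("expected 'positions:' line")
  positions <- as.numeric(strsplit(trimws(sub("^positions:", "", pos_line)),
                                   "\\s+")[[1L]])
  if (length(positions) != segsites) stop("positions/segsites mismatch")
  j <- i + 2L
  haps <- character()
  while (j <= length(lines) && grepl("^[01]+$", lines[j])) {
    haps <- c(haps, lines[j])
    j <- j + 1L
  }
  if (!length(haps)) stop("no haplotype rows in block")
  if (any(nchar(haps) != segsites)) {
    stop("haplotype row length does not match segsites")
  }
  mat <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  haplotype_pool(mat, positions, source = "ms")
}

#' Write a haplotype pool in ms output dialect
#'
#' Writes a single-replicate ms block; [read_ms()] of the output
#' reconstructs the pool token for token.
#'
#' @param pool A [haplotype_pool()].
#' @param file Output path or connection.
#' @return Invisibly, `pool`.
#' @export
write_ms <- function(pool, file) {
  stopifnot(inherits(pool, "haplotype_pool"))
  n <- nrow(pool$haplotypes)
  s <- ncol(pool$haplotypes)
  lines <- c(sprintf("ms %d 1", n), "", "//", sprintf("segsites: %d", s))
  if (s > 0L) {
    lines <- c(lines,
               paste("positions:",
                     paste(formatC(pool$positions, format = "f",
                                   digits = 6L), collapse = " ")),
               apply(pool$haplotypes, 1L, paste, collapse = ""))
  }
  writeLines(lines, file)
  invisible(pool)
}
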