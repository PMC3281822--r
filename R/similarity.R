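#' Length similarity between two haplotypes
#'
#' The length similarity of two equal-length haplotypes is the largest
#' number of consecutive markers at which their alleles match -- the longest
#' shared run, not the total number of matches. It is symmetric and bounded
#' by the window width, and is the rule by which haplotypes unseen in (or
#' unassigned by) the training data are placed into the fitted group model.
#'
#' @param h1,h2 Haplotypes, given either as character vectors of allele
#'   tokens or as single key strings (split on `sep`).
#' @param sep Token separator used when `h1`/`h2` are single strings; `""`
#'   splits into single characters.
#' @return Integer: the maximum matching run length (0 when no position
#'   matches).
#' @export
#' @examples
#' length_similarity("ab", "Ab")  # 1
#' length_similarity("AB", "ab")  # 0
#' length_similarity(c("A", "B", "b"), c("A", "B", "B"))  # 2
length_similarity <- function(h1, h2, sep = "") {
  if (is.character(h1) && length(h1) == 1L && length(h2) == 1L) {
    h1 <- split_key(h1, sep)
    h2 <- split_key(h2, sep)
  }
  if (length(h1) != length(h2)) {
    stop("haplotypes must have equal length")
  }
  max_run(h1 == h2)
}

max_run <- function(m) {
  if (!any(m)) return(0L)
  r <- rle(m)
  max(r$lengths[r$values])
}
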