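#' Ordered marker panels
#'
#' A marker panel is the ordered set of SNPs over which trio genotypes are
#' stored: one identifier and one physical position (base pairs, strictly
#' increasing) per marker, on a single chromosome label. All window
#' coordinates reported by the package are 1-based inclusive indices into
#' this order.
#'
#' @param ids Character vector of unique marker identifiers.
#' @param pos Integer vector of physical positions, strictly increasing.
#' @param chrom Chromosome label (recycled to one value).
#' @return A `marker_panel`, a data frame with columns `marker`, `chrom`,
#'   `pos`.
#' @export
#' @examples
#' marker_panel(c("rs1", "rs2"), c(1000L, 2000L))
marker_panel <- function(ids, pos, chrom = "1") {
  ids <- as.character(ids)
  pos <- as.integer(pos)
  if (length(ids) < 1L) stop("a marker panel needs at least one marker")
  if (length(pos) != length(ids)) stop("ids and pos lengths differ")
  if (anyDuplicated(ids)) stop("marker ids must be unique")
  if (length(pos) > 1L && any(diff(pos) <= 0L)) {
    stop("marker positions must be strictly increasing")
  }
  structure(
    data.frame(marker = ids, chrom = as.character(chrom)[1L], pos = pos,
               stringsAsFactors = FALSE),
    class = c("marker_panel", "data.frame")
  )
}

#' Trio genotype datasets
#'
#' A `trio_data` object holds genotypes for a collection of nuclear-family
#' trios (father, mother, one affected child) over a [marker_panel()].
#' Genotypes are stored as two allele tokens per marker in PED column
#' order: columns `2j - 1` and `2j` hold the allele pair at marker `j`.
#' The missing-allele code (default `"0"`, the LINKAGE convention) is
#' preserved as-is.
#'
#' Unphased data (`phased = FALSE`, the PED situation) carry no meaning in
#' the within-marker column order and go through family-based phase
#' inference in [trio_transmissions()]. Phased data (`phased = TRUE`, what
#' the simulators produce, mirroring haplotype-level study designs) use the
#' convention that parent columns `2j - 1` / `2j` hold the alleles of the
#' parent's first/second haplotype and child columns hold the
#' paternal/maternal gamete allele, so transmissions are read off directly
#' with no inference and no ambiguity.
#'
#' @param father,mother,child Character matrices with one row per trio and
#'   `2 * nrow(panel)` columns of allele tokens.
#' @param panel A [marker_panel()].
#' @param family Optional character vector of family identifiers.
#' @param missing_code Allele token denoting a missing call.
#' @param phased Whether the column order encodes phase (see Details).
#' @return An object of class `trio_data`.
#' @seealso [read_ped_map()], [trio_transmissions()], [tdt2g()]
#' @export
trio_data <- function(father, mother, child, panel, family = NULL,
                      missing_code = "0", phased = FALSE) {
  father <- as.matrix(father); mother <- as.matrix(mother)
  child <- as.matrix(child)
  storage.mode(father) <- "character"
  storage.mode(mother) <- "character"
  storage.mode(child) <- "character"
  if (!inherits(panel, "marker_panel")) stop("panel must be a marker_panel")
  l <- nrow(panel)
  if (ncol(father) != 2L * l || ncol(mother) != 2L * l ||
      ncol(child) != 2L * l) {
    stop("genotype matrices must have 2 columns per panel marker")
  }
  n <- nrow(father)
  if (nrow(mother) != n || nrow(child) != n) {
    stop("father, mother and child must have the same number of rows")
  }
  family <- as.character(family %||% if (n) paste0("F", seq_len(n)) else character())
  if (length(family) != n) stop("family must have one id per trio")
  dimnames(father) <- dimnames(mother) <- dimnames(child) <- NULL
  structure(
    list(family = family, father = father, mother = mother, child = child,
         panel = panel, missing_code = as.character(missing_code),
         phased = isTRUE(phased)),
    class = "trio_data"
  )
}

#' Discard phase information from a trio dataset
#'
#' Marks the dataset unphased, so [trio_transmissions()] re-infers phase
#' from family information -- useful for checking the inference path
#' against data whose truth is known.
#'
#' @param x A `trio_data`.
#' @return The same dataset with `phased = FALSE`.
#' @export
unphase_trios <- function(x) {
  x$phased <- FALSE
  x
}

#' Number of trios in a dataset
#' @param x A `trio_data`.
#' @return Integer count.
#' @export
n_trios <- function(x) nrow(x$father)

#' Number of markers in a dataset or panel
#' @param x A `trio_data` or `marker_panel`.
#' @return Integer count.
#' @export
n_markers <- function(x) {
  if (inherits(x, "trio_data")) nrow(x$panel) else nrow(x)
}

#' Subset a trio dataset by trio index
#'
#' Families stay intact: subsetting selects whole trios, never individual
#' parents, so a holdout split can never place the two parental genotypes of
#' one family on different sides.
#'
#' @param x A `trio_data`.
#' @param i Integer or logical index of trios to keep.
#' @return A `trio_data` over the same panel.
#' @export
subset_trios <- function(x, i) {
  trio_data(x$father[i, , drop = FALSE], x$mother[i, , drop = FALSE],
            x$child[i, , drop = FALSE], x$panel, x$family[i],
            x$missing_code, phased = x$phased)
}

#' @export
print.trio_data <- function(x, ...) {
  cat(sprintf("Trio dataset: %d trios x %d markers (chrom %s)\n",
              n_trios(x), n_markers(x), x$panel$chrom[1L]))
  nm <- sum(x$father == x$missing_code) + sum(x$mother == x$missing_code) +
    sum(x$child == x$missing_code)
  if (nm > 0L) cat(sprintf("  %d missing allele calls\n", nm))
  invisible(x)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d markers on chrom %s (%s..%s bp)\n",
              nrow(x), x$chrom[1L], format(min(x$pos)), format(max(x$pos))))
  NextMethod()
}
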