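# LINKAGE-style PED/MAP input and output (pre-makeped dialect:
# whitespace-separated, alleles as arbitrary single tokens, "0" missing).

#' Read trio genotypes from PED + MAP files
#'
#' PED rows carry family id, individual id, father id, mother id, sex and
#' phenotype followed by two allele columns per marker; MAP rows carry
#' chromosome, marker id, genetic distance and physical position. One trio
#' record is formed per individual whose father and mother ids both resolve
#' to rows of the same family; all other individuals are counted as
#' excluded. Genotypes are aligned to MAP order. A child allele pair that is
#' Mendelian-impossible given its parents at a marker causes that marker to
#' be set missing for the whole family (a local fix that preserves the rest
#' of the window) and is tallied, never fatal.
#'
#' @param ped,map Paths (or connections) to the PED and MAP files.
#' @param missing_code Allele token denoting missing (default `"0"`).
#' @return A [trio_data()] with attributes `n_excluded` (individuals not
#'   forming a complete trio) and `n_mendel_flagged` (family-marker cells
#'   blanked for Mendelian inconsistency).
#' @export
read_ped_map <- function(ped, map, missing_code = "0") {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("MAP file needs 4 columns: chr id dist pos")
  panel <- marker_panel(mp[[2L]], mp[[4L]], chrom = mp[[1L]][1L])
  l <- nrow(panel)

  pd <- tryCatch(
    utils::read.table(ped, header = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed PED file: ", conditionMessage(e))
  )
  if (ncol(pd) != 6L + 2L * l) {
    bad <- which(utils::count.fields(ped) != 6L + 2L * l)
    stop(sprintf("PED row %s has %d fields, expected %d",
                 if (length(bad)) bad[1L] else "?", ncol(pd), 6L + 2L * l))
  }
  fid <- pd[[1L]]; iid <- pd[[2L]]; pat <- pd[[3L]]; mat <- pd[[4L]]
  key <- paste(fid, iid, sep = "\r")
  is_child <- pat != "0" & mat != "0"
  f_row <- match(paste(fid, pat, sep = "\r"), key)
  m_row <- match(paste(fid, mat, sep = "\r"), key)
  complete <- is_child & !is.na(f_row) & !is.na(m_row)
  used_rows <- unique(c(which(complete), f_row[complete], m_row[complete]))
  n_excluded <- nrow(pd) - length(used_rows)

  gcols <- as.matrix(pd[, -(1:6), drop = FALSE])
  ds <- trio_data(gcols[f_row[complete], , drop = FALSE],
                  gcols[m_row[complete], , drop = FALSE],
                  gcols[complete, , drop = FALSE],
                  panel,
                  family = fid[complete],
                  missing_code = missing_code)
  ds <- mendel_clean(ds)
  attr(ds, "n_excluded") <- n_excluded
  ds
}

# blank family-marker genotypes that are Mendelian-impossible
mendel_clean <- function(ds) {
  miss <- ds$missing_code
  flagged <- 0L
  for (j in seq_len(n_markers(ds))) {
    cols <- c(2L * j - 1L, 2L * j)
    f1 <- ds$father[, cols[1L]]; f2 <- ds$father[, cols[2L]]
    m1 <- ds$mother[, cols[1L]]; m2 <- ds$mother[, cols[2L]]
    c1 <- ds$child[, cols[1L]];  c2 <- ds$child[, cols[2L]]
    fmiss <- f1 == miss | f2 == miss
    mmiss <- m1 == miss | m2 == miss
    cmiss <- c1 == miss | c2 == miss
    feasA <- (fmiss | c1 == f1 | c1 == f2) & (mmiss | c2 == m1 | c2 == m2)
    feasB <- (fmiss | c2 == f1 | c2 == f2) & (mmiss | c1 == m1 | c1 == m2)
    bad <- !cmiss & !feasA & !feasB
    if (any(bad)) {
      flagged <- flagged + sum(bad)
      ds$father[bad, cols] <- miss
      ds$mother[bad, cols] <- miss
      ds$child[bad, cols] <- miss
    }
  }
  attr(ds, "n_mendel_flagged") <- flagged
  ds
}

#' Write a trio dataset as PED + MAP files
#'
#' Inverse of [read_ped_map()]: each trio becomes three PED rows (father,
#' mother, child with parent pointers; the child is coded affected). The
#' genotype multiset per family round-trips exactly.
#'
#' @param trios A [trio_data()].
#' @param ped,map Output paths.
#' @return Invisibly, `trios`.
#' @export
write_ped_map <- function(trios, ped, map) {
  panel <- trios$panel
  utils::write.table(
    data.frame(panel$chrom, panel$marker, 0, panel$pos),
    map, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- n_trios(trios)
  fam <- trios$family
  rows <- vector("list", 3L * n)
  for (i in seq_len(n)) {
    fa <- paste0(fam[i], "_f"); mo <- paste0(fam[i], "_m")
    ch <- paste0(fam[i], "_c")
    rows[[3L * i - 2L]] <- c(fam[i], fa, "0", "0", "1", "1",
                             trios$father[i, ])
    rows[[3L * i - 1L]] <- c(fam[i], mo, "0", "0", "2", "1",
                             trios$mother[i, ])
    rows[[3L * i]] <- c(fam[i], ch, fa, mo, "1", "2", trios$child[i, ])
  }
  writeLines(vapply(rows, paste, character(1L), collapse = " "), ped)
  invisible(trios)
}
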