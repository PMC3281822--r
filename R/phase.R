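# Trio phase resolution.
#
# Phase is inferred from family information alone. At each window marker the
# two orderings of the child's allele pair are checked for Mendelian
# compatibility with the parental genotypes; a marker is determined when the
# orderings agree on the parental origin (child homozygous, or exactly one
# ordering feasible) and ambiguous when both orderings are feasible and the
# child is heterozygous (which requires both parents to be heterozygous
# there). For trios with ambiguous markers and no missing data, all
# 2^a origin configurations are enumerated: when every configuration yields
# the same *multiset* of the two (transmitted, nontransmitted) parental
# pairs, the transmissions are determined even though their attribution to
# father versus mother may not be -- the single-marker case with all three
# members heterozygous is the canonical example, and is what makes the
# one-marker tests reduce exactly to the classic TDT. Only when distinct
# configurations yield distinct transmission multisets is the trio
# genuinely unresolved and dropped (never guessed). No population-level
# (E-M or sampling-based) phase completion is attempted. Under the
# no-recombination meiosis model the nontransmitted haplotype is the
# marker-wise complement of the transmitted one within the parent's
# genotype.
#
# A parent with a missing allele anywhere in the window is unresolved for
# that window (the similarity rule needs full-length haplotypes); the other
# parent is still used when its origins are determined at every marker.

hap_sep <- function(tokens) {
  if (all(nchar(tokens) == 1L)) "" else ":"
}

hap_key <- function(mat, sep) {
  if (ncol(mat) == 1L) return(as.character(mat[, 1L]))
  do.call(paste, c(lapply(seq_len(ncol(mat)), function(j) mat[, j]),
                   list(sep = sep)))
}

split_key <- function(key, sep) {
  if (identical(sep, "")) strsplit(key, "", fixed = TRUE)[[1L]]
  else strsplit(key, sep, fixed = TRUE)[[1L]]
}

#' Resolve trio phase and enumerate parental transmissions
#'
#' For phased datasets (what the simulators produce) transmissions are
#' read off directly: the child's stored gametes identify each parent's
#' transmitted haplotype and the nontransmitted one is its complement
#' within the parent's genotype. For unphased (PED-style) data,
#' family-based inference determines the transmitted and nontransmitted
#' haplotype of each parent over the marker window whenever family
#' information determines them -- exactly, or up to the attribution of the two
#' (transmitted, nontransmitted) pairs to father and mother, which no
#' transmission statistic depends on. Parents with a missing window allele,
#' trios whose phase configurations yield genuinely different transmission
#' multisets, and Mendelian-impossible trios are excluded (never guessed)
#' and tallied in the attributes.
#'
#' @param trios A [trio_data()].
#' @param window Integer vector of marker indices (1-based); default all
#'   markers.
#' @param max_ambiguous Enumeration cap: trios with more than this many
#'   ambiguous markers are counted unresolved.
#' @return A data frame of class `trio_transmissions` with columns
#'   `family`, `parent` (`"father"`/`"mother"`; arbitrary for
#'   attribution-symmetric trios), `transmitted`, `nontransmitted`
#'   (haplotype keys) and `het` (transmitted != nontransmitted).
#'   Attributes: `sep` (token separator in keys), `width`, `n_unresolved`
#'   (parents dropped), `n_mendel` (trios with a Mendelian-impossible
#'   window marker).
#' @export
#' @examples
#' ds <- random_trios(5, 2, seed = 1)
#' trio_transmissions(ds)
trio_transmissions <- function(trios, window = NULL, max_ambiguous = 10L) {
  stopifnot(inherits(trios, "trio_data"))
  window <- as.integer(window %||% seq_len(n_markers(trios)))
  if (any(window < 1L) || any(window > n_markers(trios))) {
    stop("window indices out of range")
  }
  if (isTRUE(trios$phased)) {
    return(phased_transmissions(trios, window))
  }
  n <- n_trios(trios)
  l <- length(window)
  miss <- trios$missing_code
  ft <- fu <- mt <- mu <- matrix(NA_character_, n, l)
  amb <- matrix(FALSE, n, l)
  anymiss <- rep(FALSE, n)
  mendel <- rep(FALSE, n)
  for (k in seq_len(l)) {
    j <- window[k]
    f1 <- trios$father[, 2L * j - 1L]; f2 <- trios$father[, 2L * j]
    m1 <- trios$mother[, 2L * j - 1L]; m2 <- trios$mother[, 2L * j]
    c1 <- trios$child[, 2L * j - 1L];  c2 <- trios$child[, 2L * j]
    fmiss <- f1 == miss | f2 == miss
    mmiss <- m1 == miss | m2 == miss
    cmiss <- c1 == miss | c2 == miss
    anymiss <- anymiss | fmiss | mmiss | cmiss
    # orderings of the child pair: A = (c1 from father, c2 from mother)
    feasA <- !cmiss & (fmiss | c1 == f1 | c1 == f2) &
      (mmiss | c2 == m1 | c2 == m2)
    feasB <- !cmiss & (fmiss | c2 == f1 | c2 == f2) &
      (mmiss | c1 == m1 | c1 == m2)
    mendel <- mendel | (!cmiss & !feasA & !feasB)
    amb[, k] <- feasA & feasB & c1 != c2
    det <- (feasA | feasB) & !amb[, k]
    tf <- ifelse(det & feasA, c1, ifelse(det, c2, NA_character_))
    tm <- ifelse(det & feasA, c2, ifelse(det, c1, NA_character_))
    f_res <- !fmiss & !is.na(tf)
    m_res <- !mmiss & !is.na(tm)
    ft[, k] <- ifelse(f_res, tf, NA_character_)
    fu[, k] <- ifelse(f_res, ifelse(tf == f1, f2, f1), NA_character_)
    mt[, k] <- ifelse(m_res, tm, NA_character_)
    mu[, k] <- ifelse(m_res, ifelse(tm == m1, m2, m1), NA_character_)
  }
  f_ok <- rowSums(is.na(ft)) == 0L
  m_ok <- rowSums(is.na(mt)) == 0L

  # trios whose only undetermined markers are attribution-ambiguous:
  # enumerate origin configurations and keep those with a unique
  # transmission multiset
  n_amb <- rowSums(amb)
  try_enum <- which(!(f_ok & m_ok) & !anymiss & !mendel & n_amb >= 1L &
                      n_amb <= max_ambiguous &
                      rowSums(is.na(ft) & !amb) == 0L &
                      rowSums(is.na(mt) & !amb) == 0L)
  for (i in try_enum) {
    res <- enumerate_trio(trios, window, i, ft[i, ], fu[i, ], mt[i, ],
                          mu[i, ], which(amb[i, ]))
    if (!is.null(res)) {
      ft[i, ] <- res$ft; fu[i, ] <- res$fu
      mt[i, ] <- res$mt; mu[i, ] <- res$mu
      f_ok[i] <- m_ok[i] <- TRUE
    }
  }

  toks <- c(ft[f_ok, , drop = FALSE], fu[f_ok, , drop = FALSE],
            mt[m_ok, , drop = FALSE], mu[m_ok, , drop = FALSE])
  sep <- hap_sep(if (length(toks)) toks else "0")
  res <- data.frame(
    family = c(trios$family[f_ok], trios$family[m_ok]),
    parent = rep(c("father", "mother"), c(sum(f_ok), sum(m_ok))),
    transmitted = c(hap_key(ft[f_ok, , drop = FALSE], sep),
                    hap_key(mt[m_ok, , drop = FALSE], sep)),
    nontransmitted = c(hap_key(fu[f_ok, , drop = FALSE], sep),
                       hap_key(mu[m_ok, , drop = FALSE], sep)),
    stringsAsFactors = FALSE
  )
  res$het <- res$transmitted != res$nontransmitted
  structure(res,
            sep = sep, width = l,
            n_unresolved = sum(!f_ok) + sum(!m_ok),
            n_mendel = sum(mendel),
            class = c("trio_transmissions", "data.frame"))
}

# Direct transmission extraction for phased data: the child's paternal
# (maternal) gamete is column 2j-1 (2j); the nontransmitted allele is the
# complement of the gamete within the parent's genotype. A parent with a
# missing window allele is dropped, as is any parent whose gamete is
# Mendelian-impossible; no inference, no ambiguity.
phased_transmissions <- function(trios, window) {
  n <- n_trios(trios)
  l <- length(window)
  miss <- trios$missing_code
  ft <- fu <- mt <- mu <- matrix(NA_character_, n, l)
  f_ok <- m_ok <- rep(TRUE, n)
  mendel <- rep(FALSE, n)
  for (k in seq_len(l)) {
    j <- window[k]
    f1 <- trios$father[, 2L * j - 1L]; f2 <- trios$father[, 2L * j]
    m1 <- trios$mother[, 2L * j - 1L]; m2 <- trios$mother[, 2L * j]
    cf <- trios$child[, 2L * j - 1L];  cm <- trios$child[, 2L * j]
    fmiss <- f1 == miss | f2 == miss | cf == miss
    mmiss <- m1 == miss | m2 == miss | cm == miss
    fbad <- !fmiss & cf != f1 & cf != f2
    mbad <- !mmiss & cm != m1 & cm != m2
    mendel <- mendel | fbad | mbad
    f_res <- !fmiss & !fbad
    m_res <- !mmiss & !mbad
    ft[, k] <- ifelse(f_res, cf, NA_character_)
    fu[, k] <- ifelse(f_res, ifelse(cf == f1, f2, f1), NA_character_)
    mt[, k] <- ifelse(m_res, cm, NA_character_)
    mu[, k] <- ifelse(m_res, ifelse(cm == m1, m2, m1), NA_character_)
    f_ok <- f_ok & f_res
    m_ok <- m_ok & m_res
  }
  toks <- c(ft[f_ok, , drop = FALSE], fu[f_ok, , drop = FALSE],
            mt[m_ok, , drop = FALSE], mu[m_ok, , drop = FALSE])
  sep <- hap_sep(if (length(toks)) toks else "0")
  res <- data.frame(
    family = c(trios$family[f_ok], trios$family[m_ok]),
    parent = rep(c("father", "mother"), c(sum(f_ok), sum(m_ok))),
    transmitted = c(hap_key(ft[f_ok, , drop = FALSE], sep),
                    hap_key(mt[m_ok, , drop = FALSE], sep)),
    nontransmitted = c(hap_key(fu[f_ok, , drop = FALSE], sep),
                       hap_key(mu[m_ok, , drop = FALSE], sep)),
    stringsAsFactors = FALSE
  )
  res$het <- res$transmitted != res$nontransmitted
  structure(res,
            sep = sep, width = l,
            n_unresolved = sum(!f_ok) + sum(!m_ok),
            n_mendel = sum(mendel),
            class = c("trio_transmissions", "data.frame"))
}

# Enumerate the 2^a origin configurations of one trio's ambiguous markers.
# Returns completed transmission vectors when all configurations agree on
# the multiset of the two (transmitted, nontransmitted) pairs, else NULL.
# At an ambiguous marker both parents are heterozygous for the child's two
# alleles, so the complement allele is always well defined.
enumerate_trio <- function(trios, window, i, ft, fu, mt, mu, amb_at) {
  a <- length(amb_at)
  c1 <- trios$child[i, 2L * window - 1L]
  c2 <- trios$child[i, 2L * window]
  f1 <- trios$father[i, 2L * window - 1L]; f2 <- trios$father[i, 2L * window]
  m1 <- trios$mother[i, 2L * window - 1L]; m2 <- trios$mother[i, 2L * window]
  best <- NULL
  seen <- NULL
  for (cfg in 0:(2L^a - 1L)) {
    bits <- bitwAnd(bitwShiftR(cfg, seq_len(a) - 1L), 1L) == 1L
    tf <- ft; tm <- mt; uf <- fu; um <- mu
    pat <- ifelse(bits, c2[amb_at], c1[amb_at])  # paternal child allele
    mat <- ifelse(bits, c1[amb_at], c2[amb_at])
    tf[amb_at] <- pat
    uf[amb_at] <- ifelse(pat == f1[amb_at], f2[amb_at], f1[amb_at])
    tm[amb_at] <- mat
    um[amb_at] <- ifelse(mat == m1[amb_at], m2[amb_at], m1[amb_at])
    key <- paste(sort(c(paste(c(tf, uf), collapse = "\r"),
                        paste(c(tm, um), collapse = "\r"))),
                 collapse = "\n")
    if (is.null(seen)) {
      seen <- key
      best <- list(ft = tf, fu = uf, mt = tm, mu = um)
    } else if (key != seen) {
      return(NULL)
    }
  }
  best
}

#' Tabulate transmitted and nontransmitted counts per haplotype
#'
#' Accumulates, over heterozygous (informative) parental genotypes only, how
#' often each distinct haplotype is transmitted (T) and nontransmitted (U)
#' to the affected child. Homozygous parents (transmitted equal to
#' nontransmitted) carry no linkage information and are excluded, so the
#' column sums obey `sum(T) == sum(U) == n_informative`.
#'
#' @param transmissions A [trio_transmissions()] data frame (or a data frame
#'   with `transmitted`, `nontransmitted`, `het` columns).
#' @return A data frame of class `transmission_table` with columns
#'   `haplotype`, `T`, `U`, ordered by total count; attributes
#'   `n_informative`, `sep`, `width`.
#' @export
transmission_table <- function(transmissions) {
  het <- transmissions[transmissions$het, , drop = FALSE]
  haps <- sort(unique(c(het$transmitted, het$nontransmitted)))
  Tn <- table(factor(het$transmitted, levels = haps))
  Un <- table(factor(het$nontransmitted, levels = haps))
  out <- data.frame(haplotype = haps, T = as.integer(Tn), U = as.integer(Un),
                    stringsAsFactors = FALSE)
  out <- out[order(-(out$T + out$U), out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            n_informative = nrow(het),
            sep = attr(transmissions, "sep") %||% hap_sep(haps),
            width = attr(transmissions, "width") %||%
              if (nrow(out)) length(split_key(out$haplotype[1L],
                                              hap_sep(haps))) else 0L,
            class = c("transmission_table", "data.frame"))
}

#' @export
print.transmission_table <- function(x, ...) {
  cat(sprintf("Transmission table: %d distinct haplotypes, %d informative genotypes\n",
              nrow(x), attr(x, "n_informative")))
  print.data.frame(x, ...)
  invisible(x)
}
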