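# Shared fixtures and independent brute-force oracles.

# Build a trio_data from per-member genotype strings, one string of
# 2 * n_markers space-separated allele tokens per trio.
make_trios <- function(father, mother, child, l = NULL) {
  tok <- function(x) do.call(rbind, strsplit(x, "\\s+"))
  fa <- tok(father); mo <- tok(mother); ch <- tok(child)
  l <- l %||% (ncol(fa) / 2L)
  trio_data(fa, mo, ch, marker_panel(paste0("M", seq_len(l)),
                                     seq_len(l) * 100L))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent phase oracle: enumerate every parental phase and every
# transmission choice, keep combinations whose per-marker allele pairs
# reproduce the child genotype, and return the set of distinct
# (transmitted, nontransmitted) pair multisets. Resolution = exactly one
# multiset survives. Tractable for l <= 3.
oracle_phase <- function(fa, mo, ch, miss = "0") {
  l <- length(fa) / 2L
  f1 <- fa[seq(1, 2 * l, 2)]; f2 <- fa[seq(2, 2 * l, 2)]
  m1 <- mo[seq(1, 2 * l, 2)]; m2 <- mo[seq(2, 2 * l, 2)]
  c1 <- ch[seq(1, 2 * l, 2)]; c2 <- ch[seq(2, 2 * l, 2)]
  if (any(c(fa, mo, ch) == miss)) return(list(multisets = character()))
  bits <- function(k) {
    vapply(seq_len(l), function(j) bitwAnd(bitwShiftR(k, j - 1L), 1L) == 1L,
           NA)
  }
  multisets <- character()
  for (pf in 0:(2^l - 1)) {
    bf <- bits(pf)
    tf <- ifelse(bf, f2, f1); uf <- ifelse(bf, f1, f2)
    for (pm in 0:(2^l - 1)) {
      bm <- bits(pm)
      tm <- ifelse(bm, m2, m1); um <- ifelse(bm, m1, m2)
      ok <- all((tf == c1 & tm == c2) | (tf == c2 & tm == c1))
      if (!ok) next
      ms <- paste(sort(c(paste(c(tf, uf), collapse = ","),
                         paste(c(tm, um), collapse = ","))),
                  collapse = ";")
      multisets <- union(multisets, ms)
    }
  }
  list(multisets = multisets)
}

# Independent maximum-run similarity (scan every start/length pair).
oracle_similarity <- function(a, b) {
  best <- 0L
  for (s in seq_along(a)) {
    for (e in s:length(a)) {
      if (all(a[s:e] == b[s:e])) best <- max(best, e - s + 1L)
    }
  }
  best
}

# Random unphased trio genotypes (not necessarily Mendelian-consistent).
random_raw_trio <- function(l, alleles = c("1", "2")) {
  draw <- function() sample(alleles, 2 * l, replace = TRUE)
  list(fa = draw(), mo = draw(), ch = draw())
}
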