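---
title: "The two-group multimarker TDT: model, assumptions and design choices"
author: "tdt2g"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-group multimarker TDT: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdt2g)
```

## The problem

Family-trio designs test genetic association through transmission: a
heterozygous parent of an affected child transmits one of its two
haplotypes, and under no linkage between the tested markers and a disease
locus each is transmitted with probability 1/2, regardless of population
structure. The classic biallelic TDT applies this to one SNP. Multimarker
extensions gain power by testing a window of `l` SNPs jointly -- a window
haplotype can tag an unsequenced risk variant, or an interaction, that no
single SNP tags -- but the obvious extensions pay for it in degrees of
freedom. The heterozygosity TDT (`tdt_mhet()`) tests all `H` distinct
window haplotypes at once on `H - 1` df, and `H` grows quickly with `l`;
with realistic sample sizes its findings become noisy and fail to
replicate in a second sample from the same population. That failure mode,
sample reproducibility, is what this package is organised around.

## The two-group statistic

The 2G test (`tdt2g()`) collapses all haplotypes into two groups and
always tests 1 df, whatever `l`:

1. **Holdout split.** The trios are randomly divided into a training and a
   test half (`holdout_split()`; families stay intact, default fraction
   1/2, odd counts round the training half up).
2. **Group learning.** On the training half, every distinct transmitted or
   nontransmitted haplotype `h` gets counts `T(h)` (transmitted by
   heterozygous parents) and `U(h)` (nontransmitted). The high-risk group
   `g1` collects haplotypes with `T(h) > U(h)`, the low-risk group `g2`
   those with `U(h) > T(h)`; ties stay unassigned.
3. **Scoring.** On the test half, a heterozygous parental genotype is used
   iff its two haplotypes fall in different groups. Test haplotypes not in
   the fitted groups (unseen, or tied in training) are placed by the
   *length similarity* rule: the group containing the member with the
   longest run of consecutive matching alleles wins; an exact tie leaves
   the haplotype unassigned and the genotype skipped. With `n_T` counting
   transmissions of the g1-side haplotype and `n_U` of the g2 side, the
   statistic is the McNemar chi-square
   `(n_T - n_U)^2 / (n_T + n_U)` on 1 df.

Because the groups are learned on data independent of the scoring counts,
each used test genotype transmits its g1-side haplotype with probability
1/2 under no linkage, conditional on the fitted model -- so the statistic
is asymptotically chi-square(1) without any multiplicity correction, which
is what the holdout buys compared with fitting and testing on the same
data (there are `2^H - 2` ways to split `H` haplotypes into two nonempty
groups; picking the best one on the same data would require a correction
that costs most of the power). Cross-validation-style multisampling is
deliberately not offered: folds are dependent, and the pooled statistic is
no longer chi-square under the null.

With a single biallelic marker and the groups learned on the scoring data
itself, the construction reduces exactly to the classic TDT -- the package
asserts this property in its test suite.

The same split/fit/score wrapper (`holdout_test()`) applies to the
comparison statistics: `mhet` (the haplotype list and hence `H` is fixed
on the training half) and `max` (the best one-vs-rest haplotype is
selected on the training half and tested exactly on 1 df on the test
half; the plain `tdt_max()` reports only a Bonferroni-bounded p-value,
flagged as such, since its maximum does not follow a chi-square).

## Phase: haplotype data versus genotype data

Transmission counting needs each parent's transmitted and nontransmitted
haplotype. Two situations arise:

* **Phased data** (`trio_data(..., phased = TRUE)`): what all the
  simulators produce, mirroring haplotype-level study designs. The child's
  stored gametes identify the transmissions directly; nothing is dropped
  and the null distribution of the statistic is exact.
* **Unphased (PED) data:** phase is inferred from family information only
  (`trio_transmissions()`). Per marker, the two possible parental origins
  of the child's allele pair are checked for Mendelian feasibility; when
  both are feasible and the child is heterozygous the marker is ambiguous,
  and all ambiguous-marker configurations are enumerated. A trio is kept
  whenever every configuration yields the same multiset of the two
  (transmitted, nontransmitted) pairs -- attribution to father or mother
  may stay open, which no statistic here depends on. This keeps, for
  example, the fully heterozygous single-marker family that the classic
  TDT also counts. Genuinely ambiguous trios, parents with a missing
  window allele, and Mendelian-impossible trios are dropped and tallied
  (`n_unresolved`, `n_mendel` attributes); no population-level (E-M or
  sampling) phase completion is attempted.

One caveat is worth stating plainly: dropping ambiguous families selects
trios whose two parental transmissions are correlated, and at multimarker
widths this overdisperses the null statistic slightly (we measured about
+18% variance at width 3 with common alleles and no missing data). For
simulated, phased data the issue does not exist; for genotype-only real
data with wide windows the reported p-values are mildly anticonservative
and the `n_unresolved` count should be monitored. Completing phase by E-M
under family constraints would remove the selection but is outside this
package's scope.

## Simulators: what they emulate, and what they do not

All generators ascertain one affected child per family by rejection
sampling against a penetrance model (`disease_model()`): genotype relative
risk `RR = f(DD)/f(dd)` with heterozygote weight `RR` (dominant), `1`
(recessive) or `(1+RR)/2` (additive); two-locus kinds combine per-locus
dominant/recessive indicators (`dom-and-dom`, `rec-or-rec`, `dom-or-dom`,
a `threshold` on total disease-allele count >= 2, and a configurable
`modified` kind), and any model can be overridden cell by cell with an
explicit table.

**Stratified null** (`simulate_stratified_null()`): two subpopulations
mixed in proportion `pp`, founder alleles independent per marker with
subpopulation MAFs (`maf1 = 0.5`, `q` free), subpopulation-specific
disease-allele frequencies `p_d = (0.05, 0.25)`, and a disease locus at
recombination fraction `theta` from the marker block (`theta = 0.5` for
the null). This is the design under which a valid TDT must keep its
nominal type-I error even though the two subpopulations differ in both
marker and disease-allele frequencies. The defaults for the masked
quantities (`maf1`, `p_d`, the ascertainment model dominant `RR = 2`) are
fixed once; under no linkage the calibration targets are insensitive to
them.

**Disease-linked trios from a pool** (`simulate_disease_trios()`): founder
haplotypes are drawn from a phased pool -- read from ms/msHOT output
(`read_ms()`) or generated by `coalescent_pool()`. The disease locus is
the leftmost pool site with minor allele frequency in `[0.1, 0.5]` (one
extreme of the low-recombination block; the derived allele is the disease
allele), and the tested window consists of the `width` nearest sites to
its right with MAF >= 0.05, emulating an array panel of common SNPs.
Meioses recombine within the block at `rho = 1e-8` per interval and the
disease allele decouples from the block with probability `theta`; the
locus-specificity grid is `{0.001, 0.005, 0.01, 0.05, 0.1, 0.5}` on top of
perfect LD at `theta = 0`.

`coalescent_pool()` draws the pool under the neutral Kingman coalescent
with infinite-sites mutation. Because a no-recombination sample yields too
few distinct window haplotypes to exhibit the sparse-data phenomena under
study, an optional haplotype-copying layer (`recomb > 0`) turns each pool
haplotype into a recombinant mosaic over an ancestral sample, with
template switches at probability `1 - exp(-recomb * distance)` between
adjacent sites -- preserving site frequencies and distance-decaying LD.
The reproducibility and missing-data studies use a pool of 1000
haplotypes with `theta = 60`, `recomb = 3` over 60 ancestors, giving
roughly 20 distinct width-8 haplotypes per 250-trio dataset. What the
generator does *not* emulate: recombination hotspots, demography,
genotyping error, and linkage between the second locus of two-locus
models and the markers (it is drawn unlinked by design). Passing tests
therefore show calibration and comparative behaviour under a clean,
ascertainment-correct trio model -- not robustness to artefacts real
genotype data may carry.

**Missing data** (`inject_missing()`): exactly
`floor(proportion * n_parents * n_markers)` parent-marker genotypes are
blanked uniformly without replacement, reproducing the deletion design;
a parent missing anywhere in a window is dropped from that window.

**Reproducibility pairs** (`reproducibility_pair()`,
`reproducibility_rates()`): two independent same-size datasets; the model
is fitted from the first (its training half for holdout tests, all of it
for plain tests) and the statistic recomputed both on the first dataset's
own scoring material and on an equally sized subset of the second,
mapping unseen haplotypes by length similarity. Matching the two scoring
sample sizes is a deliberate choice -- rates on the two sides are then
directly comparable -- and the second-half subset is drawn with its own
derived seed.

## Numerical and design choices

* **Indexing** is 1-based inclusive everywhere (marker indices, window
  coordinates in results files), the R convention.
* **Seeds**: every stochastic step takes one integer seed; nested
  components derive their streams with `derive_seed()` (a mixed
  congruential step kept inside 32-bit range), so a window scan's splits
  do not reshuffle when markers are appended, and replicate loops are
  reproducible end to end. Seeded helpers restore the caller's RNG state.
* **Degenerate inputs** never abort a scan: zero informative genotypes,
  empty groups, or fewer than two haplotypes yield `p = 1` with an
  explanatory note on the result object.
* **Similarity ties**: for 2G group assignment a tie means *unassigned*
  (the genotype is skipped -- conservative, and exactly what reproduces
  the worked example's tied-haplotype behaviour). For mapping test
  haplotypes into a fitted mhet/max haplotype list a tie is instead broken
  toward the training haplotype with the larger training count (then
  lexicographically): the mapped table must stay dense for the fixed-`H`
  statistic to be computable, and the frequency-weighted choice is
  deterministic.
* **The mhet scaling** follows the limiting-distribution form
  `((H-1)/H) * sum((T_i - U_i)^2 / (T_i + U_i))` on `H - 1` df.
* **p-values are reported raw per window**; the holdout construction is
  the package's answer to multiplicity across haplotype groupings, and no
  genome-wide correction is applied across windows. Per-marker summaries
  average the p-values of covering windows (arithmetic by default,
  geometric behind a flag).
* **Problem sizes in the test suite** follow the study designs at desk
  scale: 1000 replicates of 500 trios per stratification cell (three
  representative cells), 2000 null replicates of 500 trios for the
  null-distribution check, 100 replicate pairs of 250 trios at width 8
  for reproducibility, and 100-replicate power runs at width 4 with
  common random numbers across missing-data proportions (pairing the
  rates so the comparison is sharper at the same cost).

## Known limitations

* No E-M or sampler-based phase completion; wide windows on genotype-only
  data lose ambiguous families (logged) and inherit the mild null
  overdispersion discussed above.
* The ms reader handles the plain ms/msHOT text dialect (single
  population, 0/1 alleles), not gzipped or multi-population variants.
* Two-locus "threshold" and "modified" kinds are documented defaults, not
  canonical definitions; studies needing exact published penetrances
  should pass an explicit `table`.
* The CLI is a convenience wrapper; the R functions are the interface of
  record.
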