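test_that("penetrance weights: relative-risk definitions and truth tables", {
  # RR = 1 flattens every model
  for (k in c("additive", "dominant", "recessive")) {
    expect_equal(penetrance(disease_model(k, rr = 1), 0:2), rep(1, 3))
  }
  for (k in c("dom-and-dom", "rec-or-rec", "dom-or-dom", "threshold",
              "modified")) {
    g <- expand.grid(g1 = 0:2, g2 = 0:2)
    expect_equal(penetrance(disease_model(k, rr = 1), g$g1, g$g2),
                 rep(1, 9))
  }
  expect_equal(penetrance(disease_model("dominant", rr = 3), 0:2),
               c(1, 3, 3))
  expect_equal(penetrance(disease_model("recessive", rr = 3), 0:2),
               c(1, 1, 3))
  expect_equal(penetrance(disease_model("additive", rr = 3), 0:2),
               c(1, 2, 3))
  # rec-or-rec over all 9 two-locus genotypes, against the truth table
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  w <- penetrance(disease_model("rec-or-rec", rr = 5), g$g1, g$g2)
  expect_equal(w, ifelse(g$g1 == 2 | g$g2 == 2, 5, 1))
  expect_equal(w[g$g1 == 1 & g$g2 == 1], 1)  # double het stays baseline
  # explicit table override wins
  m <- disease_model("dominant", rr = 2, table = c(1, 7, 9))
  expect_equal(penetrance(m, 0:2), c(1, 7, 9))
})

test_that("missing-data injection blanks exactly the requested cells", {
  ds <- random_trios(50, 10, seed = 12)
  expect_identical(inject_missing(ds, 0)$father, ds$father)
  out <- inject_missing(ds, 0.1, seed = 3)
  expect_equal(attr(out, "n_missing_cells"), 100L)  # floor(.1 * 100 * 10)
  n_missing_tokens <- sum(out$father == "0") + sum(out$mother == "0")
  expect_equal(n_missing_tokens, 200L)              # two tokens per cell
  expect_identical(out$child, ds$child)             # children untouched
  # reproducible and without replacement
  out2 <- inject_missing(ds, 0.1, seed = 3)
  expect_identical(out$father, out2$father)
})

test_that("null trio fixtures are deterministic and Mendelian-consistent", {
  a <- random_trios(30, 4, seed = 5)
  b <- random_trios(30, 4, seed = 5)
  expect_identical(a$child, b$child)
  tt <- trio_transmissions(a)
  expect_equal(attr(tt, "n_mendel"), 0L)
})

test_that("stratified simulator: provenance, frequencies and consistency", {
  ds1 <- simulate_stratified_null(80, 2, pp = 1, seed = 31)
  expect_true(all(attr(ds1, "subpop") == 1L))
  expect_equal(attr(trio_transmissions(ds1), "n_mendel"), 0L)

  # founder MAF recovery in subpopulation 2 within 3 SE at n = 500
  q <- 0.3
  ds <- simulate_stratified_null(500, 1, q = q, pp = 0.5, seed = 77)
  sub2 <- attr(ds, "subpop") == 2L
  alle <- c(ds$father[sub2, ], ds$mother[sub2, ])
  est <- mean(alle == "2")
  se <- sqrt(q * (1 - q) / length(alle))
  expect_lt(abs(est - q), 3 * se)
})

test_that("coalescent pools are valid 0/1 samples with ordered positions", {
  pool <- coalescent_pool(60, theta = 20, min_common = 6, seed = 19)
  expect_true(all(pool$haplotypes %in% 0:1))
  expect_equal(nrow(pool$haplotypes), 60L)
  expect_false(is.unsorted(pool$positions))
  maf <- pmin(colMeans(pool$haplotypes), 1 - colMeans(pool$haplotypes))
  expect_gte(sum(maf >= 0.1 & maf <= 0.5), 6L)
  pool2 <- coalescent_pool(60, theta = 20, min_common = 6, seed = 19)
  expect_identical(pool$haplotypes, pool2$haplotypes)
})

test_that("pool-based disease trios: placement, consistency, transmission bias", {
  pool <- coalescent_pool(100, theta = 25, min_common = 8, seed = 23)
  ds <- simulate_disease_trios(pool, width = 4, n_families = 400,
                               model = disease_model("dominant", 3.5),
                               theta = 0, seed = 41)
  expect_equal(n_trios(ds), 400L)
  expect_equal(n_markers(ds), 4L)
  expect_equal(attr(trio_transmissions(ds), "n_mendel"), 0L)
  maf <- pmin(colMeans(pool$haplotypes), 1 - colMeans(pool$haplotypes))
  d <- attr(ds, "disease_site")
  expect_true(maf[d] >= 0.1 && maf[d] <= 0.5)
  ms <- attr(ds, "marker_sites")
  expect_length(ms, 4L)
  expect_true(all(ms > d))
  expect_true(all(maf[ms] >= 0.05))  # genotyped SNPs are common

  # under linkage and RR > 1 some haplotype must be clearly over-transmitted
  tbl <- transmission_table(trio_transmissions(ds))
  expect_gt(max((tbl$T - tbl$U) / pmax(1, tbl$T + tbl$U)), 0.1)

  # RR = 1 reduces to the null: the same check stays near zero on average
  ds0 <- simulate_disease_trios(pool, width = 4, n_families = 400,
                                model = disease_model("dominant", 1),
                                theta = 0, seed = 42)
  tbl0 <- transmission_table(trio_transmissions(ds0))
  expect_lt(abs(sum(tbl0$T - tbl0$U)), 1e-9)  # conservation, both ways
  r0 <- plain_test(ds0, "mhet")
  expect_gt(r0$p.value, 0.001)
})

test_that("reproducibility pairs use distinct derived streams", {
  sampler <- function(seed) random_trios(20, 2, seed = seed)
  pr <- reproducibility_pair(sampler, seed = 7)
  expect_false(identical(pr$first$child, pr$second$child))
  pr2 <- reproducibility_pair(sampler, seed = 7)
  expect_identical(pr$first$child, pr2$first$child)
})

test_that("errors: impossible configurations are refused", {
  pool <- haplotype_pool(matrix(c(0L, 1L), 2, 1), 0.5)
  expect_error(simulate_disease_trios(pool, width = 3, n_families = 10),
               "no disease site")
  expect_error(disease_model("dominant", rr = 0.5), "rr")
  expect_error(inject_missing(random_trios(5, 2, seed = 1), 1), "proportion")
})
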