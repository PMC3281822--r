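tiny_table <- function(haps, T, U, width = nchar(haps[1])) {
  structure(data.frame(haplotype = haps, T = as.integer(T),
                       U = as.integer(U), stringsAsFactors = FALSE),
            n_informative = sum(T), sep = "", width = width,
            class = c("transmission_table", "data.frame"))
}

test_that("classic TDT closed forms", {
  expect_equal(tdt_classic(10, 10)$statistic, 0)
  expect_equal(tdt_classic(10, 10)$p.value, 1)
  r <- tdt_classic(20, 5)
  expect_equal(r$statistic, 9)
  expect_equal(r$p.value, 0.0027, tolerance = 1e-4)
  expect_match(tdt_classic(0, 0)$note, "no informative")
  expect_error(tdt_classic(-1, 3), "nonnegative")
})

test_that("heterozygosity TDT: scaling, df, and degenerate inputs", {
  # 2 haplotypes with mirrored counts: each term is the classic TDT value,
  # the (H-1)/H factor halves the sum of the two equal terms
  tbl <- tiny_table(c("1", "2"), c(20, 5), c(5, 20))
  r <- tdt_mhet(tbl)
  expect_equal(r$statistic, tdt_classic(20, 5)$statistic)
  expect_equal(r$df, 1L)

  balanced <- tiny_table(c("1", "2", "3"), c(4, 6, 2), c(4, 6, 2))
  expect_equal(tdt_mhet(balanced)$statistic, 0)

  one <- tiny_table("1", 0, 0)
  expect_equal(tdt_mhet(one)$p.value, 1)
  expect_match(tdt_mhet(one)$note, "fewer than 2")
})

test_that("max one-vs-rest TDT: H = 2 reduction, argmax, bounded p", {
  tbl <- tiny_table(c("1", "2"), c(20, 5), c(5, 20))
  r <- tdt_max(tbl)
  expect_equal(r$statistic, 9)
  expect_equal(r$p.value, min(1, 2 * tdt_classic(20, 5)$p.value))
  expect_match(r$note, "bound")

  # worked-example training grid: enumerate every one-vs-rest comparison
  ex <- worked_example_dataset()
  tbl3 <- transmission_table(trio_transmissions(ex$training))
  stats <- (tbl3$T - tbl3$U)^2 / (tbl3$T + tbl3$U)
  expect_equal(tdt_max(tbl3)$selected, tbl3$haplotype[which.max(stats)])
  expect_equal(tdt_max(tbl3)$statistic, max(stats))
})

test_that("mhet and max are invariant to haplotype listing order", {
  ex <- worked_example_dataset()
  tbl <- transmission_table(trio_transmissions(ex$training))
  i <- c(3, 1, 4, 2)
  perm <- tiny_table(tbl$haplotype[i], tbl$T[i], tbl$U[i], width = 2)
  expect_equal(tdt_mhet(perm)$statistic, tdt_mhet(tbl)$statistic)
  expect_equal(tdt_max(perm)$statistic, tdt_max(tbl)$statistic)
})

test_that("holdout wrapper: 2G self-consistency and df bookkeeping", {
  ds <- random_trios(120, 3, maf = 0.4, seed = 31)
  a <- holdout_test(ds, "2g", seed = 77)
  b <- tdt2g(ds, seed = 77)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$n_informative, b$n_informative)

  h <- holdout_test(ds, "mhet", seed = 77)
  sp <- holdout_split(ds, 0.5, seed = 77)
  Hfit <- nrow(transmission_table(trio_transmissions(sp$training)))
  expect_equal(h$df, Hfit - 1L)
})

test_that("holdout max equals a hand-computed one-vs-rest on the test half", {
  ds <- random_trios(60, 2, maf = 0.5, seed = 13)
  s <- 99
  r <- holdout_test(ds, "max", seed = s)
  sp <- holdout_split(ds, 0.5, seed = s)
  tbl <- transmission_table(trio_transmissions(sp$training))
  sel <- tbl$haplotype[which.max((tbl$T - tbl$U)^2 / pmax(1, tbl$T + tbl$U))]
  tt <- trio_transmissions(sp$test)
  het <- tt[tt$het, ]
  # at maf 0.5 and width 2 every test haplotype is in the training list
  expect_true(all(c(het$transmitted, het$nontransmitted) %in%
                    tbl$haplotype))
  b <- sum(het$transmitted == sel)
  c <- sum(het$nontransmitted == sel)
  expect_equal(r$selected, sel)
  expect_equal(r$statistic, (b - c)^2 / (b + c))
  expect_equal(r$df, 1L)
  expect_false(isTRUE(grepl("bound", r$note)))  # exact 1-df, not bounded
})

test_that("tdt1 is the single-marker holdout reduction", {
  ds <- random_trios(100, 1, maf = 0.3, seed = 8)
  a <- holdout_test(ds, "tdt1", seed = 5)
  b <- holdout_test(ds, "2g", window = 1L, seed = 5)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$df, 1L)
})
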