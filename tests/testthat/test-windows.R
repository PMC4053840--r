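twoArmMap <- function(nLeft, nRight, fragLen = 1000L) {
  # centromere between the two blocks
  cenW <- 2L * fragLen
  starts <- c((seq_len(nLeft) - 1L) * fragLen,
    nLeft * fragLen + cenW + (seq_len(nRight) - 1L) * fragLen)
  frags <- data.frame(chrom = "chrA",
    start = c(starts, nLeft * fragLen),
    end = c(starts + fragLen, nLeft * fragLen + cenW))
  frags <- frags[order(frags$start), ]
  makeFragmentMap(frags, centromeres = data.frame(chrom = "chrA",
    start = nLeft * fragLen, end = nLeft * fragLen + cenW))
}

test_that("window counts follow the size/step geometry per arm", {
  map <- twoArmMap(100, 130)
  expect_equal(sum(windowTable(buildWindows(map, 100, 1))$arm == "chrAS"),
    1L)
  tr <- buildWindows(map, 100, 1)
  expect_equal(sum(windowTable(tr)$arm == "chrAL"), 31L)   # 130 - 100 + 1
  trn <- buildWindows(map, 25, 25)
  expect_equal(sum(windowTable(trn)$arm == "chrAL"), 5L)   # floor(130/25)
  expect_equal(sum(windowTable(trn)$arm == "chrAS"), 4L)
  # windows never cross the centromere: spans stay within one side
  w <- windowTable(trn)
  cenS <- 100 * 1000
  expect_true(all(w$end[w$arm == "chrAS"] <= cenS))
  expect_true(all(w$start[w$arm == "chrAL"] > cenS))
  # an arm smaller than the window yields no windows, not an error
  expect_message(smallTr <- buildWindows(twoArmMap(3, 130), 100, 1),
    "no windows")
  expect_equal(sum(windowTable(smallTr)$arm == "chrAS"), 0L)
})

test_that("interaction values sum log2 counts with zero floor", {
  map <- armMap(4, 1000L)
  tr <- buildWindows(map, 4, 1)
  tr <- windowValues(tr, countsOn(map, c(4, 2, 1, 0)))
  expect_equal(windowValuesOf(tr), 3)            # 2 + 1 + 0 + 0
  expect_equal(windowTable(tr)$readSum, 7)
  tr0 <- windowValues(tr, countsOn(map, rep(0, 4)))
  expect_equal(windowValuesOf(tr0), 0)
  expect_equal(windowTable(tr0)$readSum, 0)
  # doubling every positive count adds one per nonzero fragment
  tr2 <- windowValues(tr, countsOn(map, 2 * c(4, 2, 1, 0)))
  expect_equal(windowValuesOf(tr2), 3 + 3)
  expect_error(windowValues(tr, new("FragmentCounts", viewpoint = "v",
    sample = "A", counts = rep(1, 4), librarySize = 4,
    tallies = list())), NA)
})

test_that("all-equal counts give the degenerate P of one", {
  map <- armMap(50, 1000L)
  tr <- buildWindows(map, 5, 1)
  fc <- countsOn(map, rep(4, 50))
  tr <- shufflePvalues(tr, fc, nShuffles = 10, seed = 1)
  expect_true(all(pvalues(tr) == 1))
})

test_that("hot-fragment P matches exhaustive enumeration of placements", {
  n <- 200L; size <- 2L
  map <- armMap(n, 1000L)
  counts <- numeric(n); counts[100] <- 2^10
  tr <- buildWindows(map, size, 1)
  fc <- countsOn(map, counts)
  tr <- shufflePvalues(tr, fc, nShuffles = 2000, seed = 9)
  P <- pvalues(tr)
  # windows holding the hot fragment carry the arm-minimal P
  hot <- which(windowTable(tr)$firstIdx %in% c(99L, 100L))
  expect_true(all(P[hot] == min(P)))
  # exhaustive oracle over all n distinct placements of the hot fragment
  nw <- n - size + 1L
  oracle10 <- numeric(n); oracle0 <- numeric(n)
  for (p in seq_len(n)) {
    k <- if (p == 1L || p == n) 1L else 2L   # windows containing the hot
    vals <- c(rep(10, k), rep(0, nw - k))
    mu <- mean(vals); sdv <- sd(vals)
    oracle10[p] <- pnorm(10, mu, sdv, lower.tail = FALSE)
    oracle0[p] <- pnorm(0, mu, sdv, lower.tail = FALSE)
  }
  mcSd10 <- sd(oracle10) / sqrt(2000)
  expect_equal(unique(P[hot]), mean(oracle10),
    tolerance = max(1e-6, 5 * mcSd10 / mean(oracle10)))
  expect_equal(mean(P[-hot]), mean(oracle0), tolerance = 0.01)
  # monotone: P never increases with the window value
  o <- order(windowValuesOf(tr), decreasing = TRUE)
  expect_true(all(diff(P[o]) >= -1e-12))
})

test_that("shuffle P-values are seed-reproducible and seed-stable", {
  map <- armMap(300, 1000L)
  set.seed(3)
  fc <- countsOn(map, rpois(300, 5))
  tr <- buildWindows(map, 20, 1)
  a <- pvalues(shufflePvalues(tr, fc, nShuffles = 300, seed = 11))
  b <- pvalues(shufflePvalues(tr, fc, nShuffles = 300, seed = 11))
  c <- pvalues(shufflePvalues(tr, fc, nShuffles = 300, seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_lt(max(abs(a - c)), 0.05)
})

test_that("prey calling honours thresholds, replicates and masks", {
  map <- armMap(30, 1000L)
  tr <- buildWindows(map, 10, 10)        # 3 windows
  mk <- function(p) {
    t2 <- tr; t2@windows$P <- p; t2
  }
  both <- callPreys(list(mk(c(0.005, 0.005, 0.5)),
    mk(c(0.004, 0.02, 0.5))), threshold = 0.01)
  expect_equal(preyCalls(both), c(TRUE, FALSE, FALSE))
  # single track defaults to <=
  single <- callPreys(mk(c(0.01, 0.011, NA)), threshold = 0.01)
  expect_equal(preyCalls(single), c(TRUE, FALSE, FALSE))
  # larger threshold yields a superset
  loose <- callPreys(mk(c(0.01, 0.011, NA)), threshold = 0.05)
  expect_true(all(preyCalls(single) <= preyCalls(loose)))
  # masked windows are never preys
  masked <- callPreys(mk(c(0.001, 0.001, 0.001)),
    mask = GRanges("chrA", IRanges(1, 10000)))
  expect_equal(preyCalls(masked), c(FALSE, TRUE, TRUE))
  # mismatched window definitions across replicates are an error
  trOther <- buildWindows(armMap(40, 1000L), 10, 10)
  trOther@windows$P <- rep(0.001, nrow(windowTable(trOther)))
  expect_error(callPreys(list(mk(c(1, 1, 1)), trOther)), "mismatched")
})

test_that("P-values are exchangeable under fragment relabeling within an arm", {
  map <- armMap(120, 1000L)
  set.seed(8)
  cc <- rpois(120, 3)
  tr <- buildWindows(map, 10, 10)
  p1 <- pvalues(shufflePvalues(tr, countsOn(map, cc), nShuffles = 200,
    seed = 4))
  # relabel: reverse the fragments; windows pick up permuted values
  p2 <- pvalues(shufflePvalues(tr, countsOn(map, rev(cc)),
    nShuffles = 200, seed = 4))
  expect_equal(sort(round(p1, 3)), sort(round(p2, 3)), tolerance = 0.02)
})
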