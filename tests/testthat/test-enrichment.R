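test_that("EMD densities equal interval arithmetic and the per-base mask oracle", {
  map <- makeFragmentMap(data.frame(chrom = "chr1",
    start = c(0, 100), end = c(100, 200)))
  # covered [10,35) over fragment [0,100)
  d1 <- emdTrack(data.frame(chrom = "chr1", start = 10, end = 35), map)
  expect_equal(d1$fragmentDensity[1], 0.25)
  # overlapping intervals union to 40 nt
  d2 <- emdTrack(data.frame(chrom = "chr1", start = c(10, 20),
    end = c(35, 50)), map)
  expect_equal(d2$fragmentDensity[1], 0.40)
  # bounds
  d3 <- emdTrack(data.frame(chrom = "chr1", start = 0, end = 200), map)
  expect_equal(d3$fragmentDensity, c(1, 1))
  expect_equal(emdTrack(data.frame(chrom = "chr1", start = 1,
    end = 2)[0, ], map)$fragmentDensity, c(0, 0))
  expect_error(emdTrack(data.frame(chrom = "chr1", start = 150,
    end = 250), map), "outside")

  # random intervals against the per-base boolean-mask oracle
  set.seed(12)
  bigMap <- armMap(5, 10000L)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    s <- sample(0:49900, n); e <- s + sample(10:2000, n, replace = TRUE)
    iv <- data.frame(chrom = "chrA", start = s, end = pmin(e, 50000))
    got <- emdTrack(iv, bigMap)$fragmentDensity
    fr <- fragments(bigMap)
    oracle <- vapply(seq_along(fr), function(i)
      naiveEmd(iv, start(fr)[i] - 1L, end(fr)[i]), numeric(1))
    expect_equal(got, oracle)
  }
})

test_that("control selection is seeded, disjoint from preys and pool-aware", {
  map <- armMap(200, 1000L)
  tr <- buildWindows(map, 10, 10)       # 20 windows
  tr@windows$P <- rep(0.5, 20)
  tr@windows$prey <- rep(c(TRUE, FALSE), 10)
  c1 <- selectControls(tr, n = 5, seed = 3)
  c2 <- selectControls(tr, n = 5, seed = 3)
  c3 <- selectControls(tr, n = 5, seed = 4)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
  expect_true(all(!windowTable(tr)$prey[c1]))
  expect_warning(cBig <- selectControls(tr, n = 50, seed = 1),
    "with replacement")
  expect_equal(length(cBig), 50L)
  tr@windows$prey <- rep(TRUE, 20)
  expect_error(selectControls(tr, n = 5, seed = 1), "no eligible")
})

test_that("PCA matches the eigen oracle and separates anticorrelated groups", {
  # 2-feature toy with one dominant axis
  set.seed(9)
  z <- rnorm(20)
  m <- cbind(f1 = z + rnorm(20, 0, 0.05), f2 = -z + rnorm(20, 0, 0.05))
  res <- pcaPreyControl(m)
  expect_equal(sum(res$varianceFraction), 1)
  ev <- eigen(cov(scale(m, scale = FALSE)))$vectors[, 1]
  dotp <- abs(sum(res$loadings[, 1] * ev))
  expect_equal(dotp, 1, tolerance = 1e-8)
  # rows split into two feature-anticorrelated groups separate on PC1
  g1 <- cbind(f1 = rnorm(6, 2, 0.1), f2 = rnorm(6, -2, 0.1))
  g2 <- cbind(f1 = rnorm(6, -2, 0.1), f2 = rnorm(6, 2, 0.1))
  res2 <- pcaPreyControl(rbind(g1, g2))
  s <- res2$scores[, 1]
  expect_true(all(sign(s[1:6]) == sign(s[1])))
  expect_true(all(sign(s[7:12]) == -sign(s[1])))
  # constant matrix: defined zero result
  res0 <- pcaPreyControl(matrix(1, 4, 3))
  expect_equal(res0$varianceFraction, rep(0, 3))
  expect_true(all(res0$scores == 0))
})

test_that("permutation test matches the 3+3 exhaustive enumeration", {
  emd <- list(feat = c(0.9, 0.7, 0.8, 0.1, 0.2, 0.3))
  rs <- list(vp1 = list(prey = 1:3, control = 4:6))
  # exact: all 20 ways to split the pooled six into two threes
  pool <- emd$feat
  splits <- combn(6, 3)
  realM <- abs(mean(pool[1:3]) - mean(pool[4:6]))
  randD <- apply(splits, 2, function(ix)
    abs(mean(pool[ix]) - mean(pool[-ix])))
  pExact <- mean(randD > realM)
  got <- permutationTest(emd, rs, i = 4000, nPerGroup = 3, seed = 2)
  tol <- 3 * sqrt(pExact * (1 - pExact) / 4000) + 1e-9
  expect_equal(got$p, pExact, tolerance = max(tol / max(pExact, 1e-9),
    0.02))
  # extreme separation: no random split can beat the real difference
  emdX <- list(f = c(1, 1, 1, 0, 0, 0))
  gotX <- permutationTest(emdX, rs, i = 500, nPerGroup = 3, seed = 2)
  expect_equal(gotX$p, 0)
  # degenerate all-equal input: strict > gives 0, >= gives 1
  emdE <- list(f = rep(0.4, 6))
  expect_equal(permutationTest(emdE, rs, i = 200, nPerGroup = 3,
    seed = 2)$p, 0)
  expect_equal(permutationTest(emdE, rs, i = 200, nPerGroup = 3,
    seed = 2, gte = TRUE)$p, 1)
  # viewpoints without preys are dropped
  rs2 <- c(rs, list(vp2 = list(prey = integer(0), control = 4:6)))
  expect_message(permutationTest(emd, rs2, i = 50, nPerGroup = 3,
    seed = 1), "excluded")
})

test_that("the enrichment score follows the stated weights and is order-symmetric", {
  # n = 4, m = 1, test region ranked 2nd: cumulative (-1, 2, 1, 0)
  map <- armMap(4, 1000L)
  tr <- buildWindows(map, 1, 1)
  emd <- list(f = c(0.9, 0.8, 0.7, 0.6))
  res <- gseaLikeTest(emd, tr, testSets = list(vp = 2L),
    viewpointArms = c(vp = NA), nRand = 50, seed = 1)
  expect_equal(res$perViewpoint$ES, 2)
  expect_equal(res$perViewpoint$n, 4L)
  expect_equal(res$perViewpoint$m, 1L)
  # weights sum to zero: cumulative sum ends at 0 for random fixtures
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:30, 1); m <- sample(1:(n - 1), 1)
    isTest <- logical(n); isTest[sample(n, m)] <- TRUE
    w <- ifelse(isTest, (n - m) / m, -1)
    expect_equal(sum(w), 0)
    # reversing the ranking leaves the maximal |cumsum| unchanged
    expect_equal(max(abs(cumsum(w))), max(abs(cumsum(rev(w)))))
  }
  # m = n gives a zero score
  resAll <- gseaLikeTest(emd, tr, testSets = list(vp = 1:4),
    viewpointArms = c(vp = NA), nRand = 20, seed = 1)
  expect_equal(resAll$perViewpoint$ES, 0)
})

test_that("GSEA-like empirical p matches subset enumeration for small n, m", {
  set.seed(21)
  for (spec in list(c(6L, 2L), c(8L, 3L), c(4L, 1L))) {
    n <- spec[1]; m <- spec[2]
    map <- armMap(n, 1000L)
    tr <- buildWindows(map, 1, 1)
    emd <- list(f = runif(n))
    testIdx <- sample(n, m)
    res <- gseaLikeTest(emd, tr, testSets = list(vp = testIdx),
      viewpointArms = c(vp = NA), nRand = 4000, seed = 5)
    # exact ES null over all m-subsets of the n ranks
    subsets <- combn(n, m)
    esAll <- apply(subsets, 2, function(ix) {
      isTest <- logical(n); isTest[ix] <- TRUE
      w <- ifelse(isTest, (n - m) / m, -1)
      max(abs(cumsum(w)))
    })
    ord <- order(-emd$f, seq_len(n))
    isTest <- (seq_len(n) %in% testIdx)[ord]
    esObs <- max(abs(cumsum(ifelse(isTest, (n - m) / m, -1))))
    expect_equal(res$perViewpoint$ES, esObs)
    pExact <- mean(esAll >= esObs)
    se <- sqrt(pExact * (1 - pExact) / 4000)
    expect_lt(abs(res$table$p - pExact), 3 * se + 1e-9)
  }
})

test_that("BH adjustment is the step-up procedure with monotonicity", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.3, 0.02, 0.9, 0.04)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_equal(q, p.adjust(p, "BH"))
  expect_error(bhAdjust(c(0.1, 1.2)), "0,1")
  expect_error(bhAdjust(c(0.1, -0.1)), "0,1")
})

test_that("permutation p is calibrated on exchangeable data and powered on shifts", {
  set.seed(31)
  nullHits <- 0; shiftHits <- 0; runs <- 20
  for (r in seq_len(runs)) {
    emdNull <- list(f = rnorm(120, 0.5, 0.05))
    rs <- list(vp = list(prey = 1:60, control = 61:120))
    pN <- permutationTest(emdNull, rs, i = 400, nPerGroup = 50,
      seed = r)$p
    nullHits <- nullHits + (pN > 0.05)
    emdShift <- list(f = c(rnorm(60, 0.6, 0.05), rnorm(60, 0.5, 0.05)))
    pS <- permutationTest(emdShift, rs, i = 400, nPerGroup = 50,
      seed = r)$p
    shiftHits <- shiftHits + (pS < 0.01)
  }
  expect_gte(nullHits / runs, 0.9)   # exchangeable: mostly insignificant
  expect_gte(shiftHits / runs, 0.95) # 2-sd mean shift: detected
})
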