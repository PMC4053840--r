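test_that("Spearman correlation and clustering recover replicate structure", {
  map <- armMap(60, 1000L)
  tr <- buildWindows(map, 10, 10)
  mk <- function(counts) windowValues(tr, countsOn(map, counts))
  set.seed(2)
  base <- rpois(60, 20)
  t1 <- mk(base)
  expect_equal(unname(replicateCorrelation(list(a = t1, b = t1))$rho[1, 2]),
    1)
  # rank-reversed read sums
  rev1 <- mk(max(base) - base + 1)
  expect_equal(unname(replicateCorrelation(list(a = t1,
    b = rev1))$rho[1, 2]), -1, tolerance = 1e-6)
  # two planted replicate pairs: pairs merge before any cross-pair merge
  sigA <- rpois(60, 50); sigB <- rpois(60, 50)
  tracks <- list(
    a1 = mk(sigA + rpois(60, 3)), a2 = mk(sigA + rpois(60, 3)),
    b1 = mk(sigB + rpois(60, 3)), b2 = mk(sigB + rpois(60, 3)))
  hc <- replicateCorrelation(tracks)$linkage
  firstMerges <- hc$merge[1:2, ]
  merged <- lapply(seq_len(2), function(i)
    sort(hc$labels[-firstMerges[i, ]]))
  expect_true(all(vapply(merged, function(m)
    identical(m, c("a1", "a2")) || identical(m, c("b1", "b2")),
    logical(1))))
  expect_error(replicateCorrelation(list(t1)), "at least 2")
})

decayFixture <- function(gamma, nReads = 2e5, fragLen = 2000L,
    L = 10.3e6, seed = 3) {
  frags <- data.frame(chrom = "chrA",
    start = seq(0, L - fragLen, by = fragLen),
    end = seq(fragLen, L, by = fragLen))
  map <- makeFragmentMap(frags,
    centromeres = data.frame(chrom = "chrA", start = 0, end = fragLen))
  fr <- fragments(map)
  vp <- Viewpoint("vp", "chrA", position = fragLen + 1000,
    primerSeq = "ACGT", fragment = 2L)
  g1 <- gamma + 1
  set.seed(seed)
  u <- runif(nReads)
  d <- if (g1 == 0) 1e3 * (1e7 / 1e3)^u else
    (1e3^g1 + u * (1e7^g1 - 1e3^g1))^(1 / g1)
  pos <- vp@position + d
  idx <- findInterval(pos, start(fr) - 1L)
  counts <- numeric(length(fr))
  tc <- table(idx)
  counts[as.integer(names(tc))] <- as.numeric(tc)
  list(map = map, vp = vp, counts = countsOn(map, counts))
}

test_that("decay binning covers 1 kb-10 Mb in 41 bins and normalizes", {
  fx <- decayFixture(-0.8, nReads = 5e4)
  prof <- decayProfile(fx$counts, fx$vp, fx$map)
  b <- prof@bins
  expect_equal(nrow(b), 41L)
  expect_equal(b$center, seq(3, 7, by = 0.1))
  expect_equal(sum(b$rawProb), 1)
  # all reads at one distance: that bin takes probability 1
  map <- fx$map
  cc <- numeric(nFragments(map))
  fr <- fragments(map)
  mids <- (start(fr) - 1 + end(fr)) / 2
  target <- which.min(abs(mids - (fx$vp@position + 1e4)))
  cc[target] <- 100
  prof1 <- decayProfile(countsOn(map, cc), fx$vp, map)
  expect_equal(prof1@bins$rawProb[prof1@bins$center == 4], 1)
  expect_error(decayProfile(countsOn(map, numeric(nFragments(map))),
    fx$vp, map), "no reads")
})

test_that("the decay exponent is recovered on analytic and sampled power laws", {
  # exact power law placed directly in the bins
  centers <- seq(3, 7, by = 0.1)
  raw <- 10^(-0.8 * centers)
  raw <- raw / sum(raw)
  prof <- new("DecayProfile",
    bins = S4Vectors::DataFrame(center = centers, rawProb = raw,
      smoothProb = NA_real_, nReads = raw, nFragments = rep(1, 41)),
    slope = NA_real_, fitP = NA_real_, dMin = 1e3, dMax = 1e7,
    binWidth = 0.1)
  expect_equal(decaySlope(fitDecayExponent(prof)), -0.8,
    tolerance = 1e-3)
  expect_equal(decaySlope(fitDecayExponent(prof, useLoess = FALSE)),
    -0.8, tolerance = 1e-3)
  # flat profile
  flat <- prof
  flat@bins$rawProb <- rep(1 / 41, 41)
  expect_equal(decaySlope(fitDecayExponent(flat)), 0, tolerance = 1e-9)
  # sampled reads with three generating exponents
  for (g in c(-0.5, -0.73, -1.0)) {
    fx <- decayFixture(g, nReads = 1e5, seed = round(1000 * abs(g)))
    est <- fitDecayExponent(decayProfile(fx$counts, fx$vp, fx$map))
    expect_equal(decaySlope(est), g, tolerance = 0.05)
  }
  # library-size invariance: scaling all counts leaves the slope as is
  fx <- decayFixture(-0.73, nReads = 5e4)
  p1 <- fitDecayExponent(decayProfile(fx$counts, fx$vp, fx$map))
  scaled <- countsOn(fx$map, fx$counts@counts * 7)
  p2 <- fitDecayExponent(decayProfile(scaled, fx$vp, fx$map))
  expect_equal(decaySlope(p1), decaySlope(p2), tolerance = 1e-9)
})

rpmFixture <- function() {
  # three chromosomes of two arms each, equal fragment grids
  frags <- do.call(rbind, lapply(1:3, function(k)
    data.frame(chrom = paste0("chr", k),
      start = (0:99) * 1e4, end = (1:100) * 1e4)))
  cen <- data.frame(chrom = paste0("chr", 1:3), start = 49e4,
    end = 51e4)
  makeFragmentMap(frags, centromeres = cen)
}

test_that("arm-class RPM, masking and paired t-tests are exact", {
  map <- rpmFixture()
  fr <- fragments(map)
  m <- mcols(fr)
  vps <- lapply(1:3, function(k) Viewpoint(paste0("vp", k),
    paste0("chr", k), 75e4, "ACGT",
    fragment = m$genome_index[which(as.character(seqnames(fr)) ==
      paste0("chr", k) & start(fr) <= 75e4 & end(fr) >= 75e4)]))
  # all reads on the viewpoint arm
  ccAll <- lapply(1:3, function(k) {
    cc <- numeric(length(fr))
    sel <- which(m$arm == paste0("chr", k, "L"))
    cc[sel] <- 5
    countsOn(map, cc, viewpoint = paste0("vp", k))
  })
  res <- armClassRpm(ccAll, map, vps)
  cs <- res$classSummary
  expect_equal(cs$rpm[cs$cls == "viewpoint"], rep(1e6, 3))
  expect_equal(cs$rpm[cs$cls == "cis"], rep(0, 3))
  expect_equal(cs$rpm[cs$cls == "trans"], rep(0, 3))
  # masking removes exactly the reads within +/- 2 Mb (here: all of them)
  expect_equal(cs$rpm[cs$cls == "viewpoint_masked"], rep(0, 3))
  # constant differences leave the paired t undefined, not an error
  expect_true(is.na(res$tTests$t[res$tTests$comparison ==
    "viewpoint vs cis"]))
  # a structured fixture with distinct arm loads per viewpoint
  set.seed(4)
  ccMix <- lapply(1:3, function(k) {
    cc <- rpois(length(fr), 2) + 1
    armSel <- which(m$arm == paste0("chr", k, "L"))
    cc[armSel] <- 50 + rpois(length(armSel), 10)
    countsOn(map, cc, viewpoint = paste0("vp", k))
  })
  res2 <- armClassRpm(ccMix, map, vps)
  # per-viewpoint RPM over all arms sums to 1e6 minus centromeric share
  arms2 <- res2$arms[res2$arms$cls != "viewpoint_masked", ]
  for (k in 1:3) {
    vpn <- paste0("vp", k)
    frac <- sum(ccMix[[k]]@counts[!is.na(m$arm)]) /
      ccMix[[k]]@librarySize
    expect_equal(sum(arms2$rpm[arms2$viewpoint == vpn]), 1e6 * frac)
  }
  d2 <- with(res2, {
    cs2 <- classSummary
    cs2$rpm[cs2$cls == "viewpoint"] - cs2$rpm[cs2$cls == "cis"]
  })
  tHand2 <- mean(d2) / (sd(d2) / sqrt(3))
  expect_equal(res2$tTests$t[res2$tTests$comparison ==
    "viewpoint vs cis"], tHand2)
})

test_that("dist50 follows the first-crossing convention", {
  map <- rpmFixture()
  fr <- fragments(map)
  m <- mcols(fr)
  vp <- Viewpoint("vp1", "chr1", 75e4, "ACGT",
    fragment = m$genome_index[which(as.character(seqnames(fr)) ==
      "chr1" & start(fr) <= 75e4 & end(fr) >= 75e4)])
  # all reads on one fragment of chr2S at 30% of the arm from the cen
  armLen <- 49e4
  cc <- numeric(length(fr))
  sel <- which(m$arm == "chr2S")
  target <- sel[which.min(abs(m$cen_dist[sel] - 0.3 * armLen))]
  cc[target] <- 99
  d50 <- dist50PerArm(countsOn(map, cc), map, vp)
  got <- d50[d50$arm == "chr2S", ]
  expect_equal(got$dist50Rel, m$cen_dist[target] / armLen)
  expect_equal(got$dist50Rel, 0.3, tolerance = 0.05)
  # uniform reads over an equal-fragment arm put dist50 near the middle
  cc2 <- numeric(length(fr)); cc2[m$arm %in% "chr3L"] <- 1
  d50u <- dist50PerArm(countsOn(map, cc2), map, vp)
  expect_equal(d50u$dist50Rel[d50u$arm == "chr3L"], 0.5,
    tolerance = 0.06)
  # bounds and zero-read sentinel
  expect_true(all(is.na(d50$dist50Rel) | (d50$dist50Rel >= 0 &
    d50$dist50Rel <= 1)))
  expect_true(is.na(d50$dist50Rel[d50$arm == "chr3S"]))
  # the viewpoint arm is excluded
  expect_false(any(d50$arm == "chr1L"))
})

test_that("centromere-distance regressions recover a monotone construction", {
  map <- rpmFixture()
  fr <- fragments(map)
  m <- mcols(fr)
  # viewpoints at increasing relative distance from the centromere
  pos <- c(60e4, 75e4, 95e4)
  vps <- lapply(1:3, function(k) Viewpoint(paste0("vp", k),
    paste0("chr", k), pos[k], "ACGT",
    fragment = m$genome_index[which(as.character(seqnames(fr)) ==
      paste0("chr", k) & start(fr) <= pos[k] & end(fr) >= pos[k])]))
  vpRel <- vapply(1:3, function(k)
    m$cen_dist[match(vps[[k]]@fragment, m$genome_index)] / 49e4,
    numeric(1))
  # counts whose dist50 equals the viewpoint's own relative distance
  ccList <- lapply(1:3, function(k) {
    cc <- numeric(length(fr))
    for (a in unique(na.omit(m$arm))) {
      if (a == paste0("chr", k, "L")) next
      sel <- which(m$arm == a)
      tgt <- sel[which.min(abs(m$cen_dist[sel] - vpRel[k] * 49e4))]
      cc[tgt] <- 100
    }
    countsOn(map, cc, viewpoint = paste0("vp", k))
  })
  reg <- centromereRegressions(ccList, map, vps)
  expect_equal(unname(reg$dist50$rho), 1)
  expect_true(reg$dist50$slope > 0)
  # arcsine-sqrt closed form on the response scale
  expect_equal(asin(sqrt(c(0, 0.5, 1))), c(0, pi / 4, pi / 2))
  # shuffled pairing: rho centred on zero under the permutation null
  set.seed(6)
  d <- reg$dist50$data
  rhos <- replicate(200, suppressWarnings(
    cor(sample(d$vpRel), d$asinSqrtD50, method = "spearman")))
  expect_lt(abs(mean(rhos)), 0.12)
  expect_error(centromereRegressions(ccList[1:2], map, vps[1:2]),
    "at least 3")
})
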