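#' Replicate/viewpoint correlation and clustering
#'
#' Pairwise Spearman correlation of per-window read sums across tracks,
#' followed by average-linkage hierarchical clustering on the distance
#' `1 - rho`. Reproducible replicate pairs merge before any cross-pair
#' merge.
#'
#' @param tracks A named list of two or more [WindowTrack-class] objects
#'   on identical windows, each with values attached.
#' @return A list with `rho` (symmetric Spearman matrix) and `linkage`
#'   (an [stats::hclust] tree).
#' @export
replicateCorrelation <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least 2 tracks")
  ref <- tracks[[1L]]@windows
  mat <- vapply(tracks, function(t) {
    w <- t@windows
    if (nrow(w) != nrow(ref) || !all(w$arm == ref$arm) ||
        !all(w$start == ref$start))
      stop("tracks have mismatched window definitions")
    w$readSum
  }, numeric(nrow(ref)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("track", seq_along(tracks))
  rho <- cor(mat, method = "spearman")
  linkage <- hclust(as.dist(1 - rho), method = "average")
  list(rho = rho, linkage = linkage)
}

#' Binned cis contact probability versus distance
#'
#' Pools reads of one or more viewpoint libraries into log10-spaced
#' distance bins (default 41 bins of width 0.1 log10 centred on
#' `log10(d) = 3.0 ... 7.0`, covering 1 kb - 10 Mb). Only fragments on
#' each viewpoint's own arm count (the centromere acts as an interaction
#' boundary); distance is measured from the fragment midpoint to the
#' viewpoint position. The per-bin contact probability is the mean read
#' count per fragment in the bin (so that near-uniform fragment spacing
#' does not tilt the profile), normalized across bins to sum to 1;
#' `perFragment = FALSE` instead uses the plain bin read share. Empty
#' bins carry probability 0.
#'
#' @param counts A [FragmentCounts-class] or list of them.
#' @param viewpoints A [Viewpoint-class] or list matching `counts`.
#' @param map A filtered [FragmentMap-class].
#' @param dMin,dMax Distance range in bp (defaults 1 kb, 10 Mb).
#' @param binWidth Bin width in log10 units (default 0.1).
#' @param perFragment Normalize bin read sums by the number of fragments
#'   in the bin (default `TRUE`).
#' @return A [DecayProfile-class] with raw probabilities; fit it with
#'   [fitDecayExponent()].
#' @export
decayProfile <- function(counts, viewpoints, map, dMin = 1000,
    dMax = 1e7, binWidth = 0.1, perFragment = TRUE) {
  if (is(counts, "FragmentCounts")) counts <- list(counts)
  if (is(viewpoints, "Viewpoint")) viewpoints <- list(viewpoints)
  stopifnot(length(counts) == length(viewpoints), is(map, "FragmentMap"))
  fr <- map@fragments
  m <- mcols(fr)
  mid <- .midpoints(fr)
  nBins <- as.integer(round((log10(dMax) - log10(dMin)) / binWidth)) + 1L
  centers <- log10(dMin) + (seq_len(nBins) - 1L) * binWidth
  binReads <- numeric(nBins)
  binFrags <- numeric(nBins)
  for (k in seq_along(counts)) {
    vp <- viewpoints[[k]]
    vi <- match(vp@fragment, m$genome_index)
    if (is.na(vi)) stop("viewpoint fragment not in map")
    vpArm <- m$arm[vi]
    if (is.na(vpArm)) stop("viewpoint fragment has no arm assignment")
    sel <- which(m$arm == vpArm & m$valid)
    d <- abs(mid[sel] - vp@position)
    keep <- d >= dMin & d <= dMax
    bin <- pmin(pmax(as.integer(round((log10(d[keep]) - log10(dMin)) /
      binWidth)) + 1L, 1L), nBins)
    cc <- counts[[k]]@counts[m$genome_index[sel][keep]]
    binReads <- binReads + as.numeric(tapply(cc, factor(bin,
      levels = seq_len(nBins)), sum, default = 0))
    binFrags <- binFrags + tabulate(bin, nbins = nBins)
  }
  if (sum(binReads) == 0) stop("no reads in the distance range")
  rawProb <- if (perFragment) {
    pr <- ifelse(binFrags > 0, binReads / binFrags, 0)
    pr / sum(pr)
  } else binReads / sum(binReads)
  bins <- DataFrame(center = centers, rawProb = rawProb,
    smoothProb = NA_real_, nReads = binReads, nFragments = binFrags)
  new("DecayProfile", bins = bins, slope = NA_real_, fitP = NA_real_,
    dMin = dMin, dMax = dMax, binWidth = binWidth)
}

#' Fit the interaction decay exponent
#'
#' Fits a LOESS smoother (degree 2, tricube weights, default span 0.75)
#' to `log10(rawProb)` over `log10(distance)` on the non-empty bins,
#' predicts one probability per bin, and passes the predictions through
#' an ordinary least-squares line whose slope is the interaction decay
#' exponent. With `useLoess = FALSE` the line is fitted directly to the
#' non-empty raw bins (the two routes agree closely on smooth profiles).
#' If too few bins support the LOESS, the direct fit is used with a
#' warning.
#'
#' @param profile A [DecayProfile-class] from [decayProfile()].
#' @param useLoess Smooth before the linear fit (default `TRUE`).
#' @param span LOESS span (default 0.75).
#' @return The profile with `slope`, `fitP` and `smoothProb` filled in.
#' @export
fitDecayExponent <- function(profile, useLoess = TRUE, span = 0.75) {
  stopifnot(is(profile, "DecayProfile"))
  b <- profile@bins
  ok <- b$rawProb > 0
  if (sum(ok) < 5L) stop("need at least 5 non-empty bins")
  x <- b$center[ok]
  y <- log10(b$rawProb[ok])
  fit <- NULL
  if (useLoess) {
    fit <- tryCatch(
      loess(y ~ x, span = span, degree = 2,
        control = loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit))
      warning("LOESS failed; falling back to direct linear fit")
  }
  if (!is.null(fit)) {
    inRange <- b$center >= min(x) & b$center <= max(x)
    pred <- predict(fit, data.frame(x = b$center[inRange]))
    lmfit <- lm(pred ~ b$center[inRange])
    sm <- rep(NA_real_, nrow(b))
    sm[inRange] <- 10^pred
    profile@bins$smoothProb <- sm
  } else {
    lmfit <- lm(y ~ x)
    cf <- coef(lmfit)
    profile@bins$smoothProb <- 10^(cf[1L] + cf[2L] * b$center)
  }
  co <- suppressWarnings(summary(lmfit))$coefficients
  profile@slope <- unname(co[2L, 1L])
  profile@fitP <- unname(co[2L, 4L])
  profile
}

#' Reads-per-million by chromosome-arm class
#'
#' For every viewpoint, each chromosome arm receives
#' `rpm = 1e6 * arm reads / library size` and a class: the viewpoint's
#' own arm (`viewpoint`), the other arm of its chromosome (`cis`), or
#' any arm of another chromosome (`trans`). A fourth value,
#' `viewpoint_masked`, is the viewpoint arm's RPM recomputed after
#' removing reads within `maskMb` of the viewpoint position (the
#' towering signal around the viewpoint otherwise dominates its arm).
#' Class summaries are unweighted means over member arms, and two-sided
#' paired t-tests across viewpoints compare viewpoint vs cis, cis vs
#' trans, and viewpoint_masked vs cis.
#'
#' @param countsList List of [FragmentCounts-class], one per viewpoint.
#' @param map An arm-annotated [FragmentMap-class].
#' @param viewpoints Matching list of [Viewpoint-class].
#' @param maskMb Exclusion half-width around the viewpoint in bp
#'   (default 2 Mb).
#' @return A list with `arms` (long table: viewpoint, arm, cls, rpm),
#'   `classSummary` (mean rpm per viewpoint and class) and `tTests`
#'   (comparison, t, df, p).
#' @export
armClassRpm <- function(countsList, map, viewpoints, maskMb = 2e6) {
  stopifnot(length(countsList) == length(viewpoints))
  fr <- map@fragments
  m <- mcols(fr)
  mid <- .midpoints(fr)
  armNames <- unique(m$arm[!is.na(m$arm)])
  chromOf <- sub("[SL]$", "", armNames)
  for (chr in unique(chromOf))
    if (sum(chromOf == chr) < 2L)
      stop(sprintf("chromosome %s has a single arm; unsupported", chr))
  armRows <- list()
  for (k in seq_along(viewpoints)) {
    vp <- viewpoints[[k]]
    cc <- countsList[[k]]@counts
    lib <- countsList[[k]]@librarySize
    vi <- match(vp@fragment, m$genome_index)
    vpArm <- m$arm[vi]
    rpm <- vapply(armNames, function(a)
      1e6 * sum(cc[which(m$arm == a)]) / lib, numeric(1))
    cls <- ifelse(armNames == vpArm, "viewpoint",
      ifelse(chromOf == vp@chrom, "cis", "trans"))
    maskedSel <- which(m$arm == vpArm &
      abs(mid - vp@position) > maskMb)
    rpmMasked <- 1e6 * sum(cc[maskedSel]) / lib
    armRows[[k]] <- data.frame(viewpoint = vp@name, arm = armNames,
      cls = cls, rpm = rpm, row.names = NULL)
    armRows[[k]] <- rbind(armRows[[k]], data.frame(viewpoint = vp@name,
      arm = vpArm, cls = "viewpoint_masked", rpm = rpmMasked))
  }
  arms <- do.call(rbind, armRows)
  classSummary <- aggregate(rpm ~ viewpoint + cls, data = arms, FUN = mean)
  tt <- NULL
  if (length(viewpoints) >= 2L) {
    wide <- reshape(classSummary, idvar = "viewpoint", timevar = "cls",
      direction = "wide")
    pick <- function(cls) wide[[paste0("rpm.", cls)]]
    pairTest <- function(a, b) {
      tr <- tryCatch(t.test(pick(a), pick(b), paired = TRUE),
        error = function(e) NULL)   # constant differences: no test
      if (is.null(tr))
        return(data.frame(comparison = paste(a, "vs", b), t = NA_real_,
          df = NA_real_, p = NA_real_))
      data.frame(comparison = paste(a, "vs", b),
        t = unname(tr$statistic), df = unname(tr$parameter),
        p = tr$p.value)
    }
    tt <- rbind(pairTest("viewpoint", "cis"), pairTest("cis", "trans"),
      pairTest("viewpoint_masked", "cis"))
  }
  list(arms = arms, classSummary = classSummary, tTests = tt)
}

#' Median read distance to the centromere per arm
#'
#' For every chromosome arm except the viewpoint's own, fragments are
#' ordered by centromere distance and `dist50Abs` is the centromere
#' distance of the first fragment at which the cumulative read fraction
#' reaches one half (first-crossing convention, no interpolation).
#' `dist50Rel` divides by the arm length. Arms without reads carry `NA`
#' and are excluded from downstream regressions.
#'
#' @param counts A [FragmentCounts-class].
#' @param map An arm-annotated [FragmentMap-class].
#' @param viewpoint The library's [Viewpoint-class].
#' @return data.frame: arm, chrom, nReads, armLength, dist50Abs,
#'   dist50Rel.
#' @export
dist50PerArm <- function(counts, map, viewpoint) {
  fr <- map@fragments
  m <- mcols(fr)
  cen <- map@centromeres
  cchr <- as.character(seqnames(cen))
  vi <- match(viewpoint@fragment, m$genome_index)
  vpArm <- m$arm[vi]
  armNames <- setdiff(unique(m$arm[!is.na(m$arm)]), vpArm)
  lens <- seqlengths(fr)
  rows <- lapply(armNames, function(a) {
    chr <- sub("[SL]$", "", a)
    ci <- match(chr, cchr)
    armLength <- if (endsWith(a, "S")) start(cen)[ci] - 1L else
      lens[[chr]] - end(cen)[ci]
    sel <- which(m$arm == a)
    sel <- sel[order(m$cen_dist[sel])]
    cc <- counts@counts[m$genome_index[sel]]
    tot <- sum(cc)
    if (tot == 0)
      return(data.frame(arm = a, chrom = chr, nReads = 0,
        armLength = armLength, dist50Abs = NA_real_,
        dist50Rel = NA_real_))
    cum <- cumsum(cc) / tot
    i <- which(cum >= 0.5)[1L]
    d50 <- m$cen_dist[sel][i]
    data.frame(arm = a, chrom = chr, nReads = tot, armLength = armLength,
      dist50Abs = d50, dist50Rel = d50 / armLength)
  })
  do.call(rbind, rows)
}

#' Centromere-distance regressions across viewpoints
#'
#' Two complementary regressions of interactome shape on centromere
#' distance:
#' \describe{
#'   \item{dist50 model}{Response: `asin(sqrt(dist50Rel))` (the arcsine
#'     square-root transform of a proportion) for every non-viewpoint
#'     arm of every viewpoint; predictor: the viewpoint's relative
#'     distance to its centromere (viewpoint centromere distance / its
#'     arm length).}
#'   \item{trans-RPKM model}{Per viewpoint, the reads per kilobase per
#'     million over all arms except the viewpoint's own (the cis arm
#'     included), with the kb denominator counting valid fragment
#'     territory only; predictor: the viewpoint's absolute distance to
#'     its centromere.}
#' }
#' Each model reports the OLS slope and p plus Spearman's rho and its p.
#'
#' @param countsList List of [FragmentCounts-class], one per viewpoint.
#' @param map A filtered, arm-annotated [FragmentMap-class].
#' @param viewpoints Matching list of [Viewpoint-class].
#' @return A list with `dist50` and `transRpkm`, each carrying `data`,
#'   `slope`, `slopeP`, `rho`, `rhoP`.
#' @export
centromereRegressions <- function(countsList, map, viewpoints) {
  if (length(viewpoints) < 3L) stop("need at least 3 viewpoints")
  fr <- map@fragments
  m <- mcols(fr)
  cen <- map@centromeres
  cchr <- as.character(seqnames(cen))
  lens <- seqlengths(fr)
  vpRel <- vapply(viewpoints, function(vp) {
    vi <- match(vp@fragment, m$genome_index)
    a <- m$arm[vi]
    ci <- match(vp@chrom, cchr)
    armLength <- if (endsWith(a, "S")) start(cen)[ci] - 1L else
      lens[[vp@chrom]] - end(cen)[ci]
    m$cen_dist[vi] / armLength
  }, numeric(1))
  vpAbs <- vapply(viewpoints, function(vp)
    m$cen_dist[match(vp@fragment, m$genome_index)], numeric(1))
  if (length(unique(round(vpRel, 12))) < 2L)
    stop("degenerate predictor: all viewpoints equidistant")
  d50rows <- list()
  rpkmRows <- list()
  for (k in seq_along(viewpoints)) {
    vp <- viewpoints[[k]]
    d50 <- dist50PerArm(countsList[[k]], map, vp)
    d50 <- d50[!is.na(d50$dist50Rel), , drop = FALSE]
    if (nrow(d50))
      d50rows[[k]] <- data.frame(viewpoint = vp@name, vpRel = vpRel[k],
        asinSqrtD50 = asin(sqrt(pmin(pmax(d50$dist50Rel, 0), 1))),
        arm = d50$arm)
    vpArm <- m$arm[match(vp@fragment, m$genome_index)]
    sel <- which(!is.na(m$arm) & m$arm != vpArm & m$valid)
    kb <- sum(width(fr)[sel]) / 1000
    reads <- sum(countsList[[k]]@counts[m$genome_index[sel]])
    rpkm <- reads / kb / (countsList[[k]]@librarySize / 1e6)
    rpkmRows[[k]] <- data.frame(viewpoint = vp@name, vpAbs = vpAbs[k],
      rpkm = rpkm)
  }
  d50df <- do.call(rbind, d50rows)
  rpkmDf <- do.call(rbind, rpkmRows)
  report <- function(x, y, data) {
    f <- lm(y ~ x)
    co <- suppressWarnings(summary(f))$coefficients
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    list(data = data, slope = unname(co[2L, 1L]),
      slopeP = unname(co[2L, 4L]), rho = unname(ct$estimate),
      rhoP = ct$p.value)
  }
  list(dist50 = report(d50df$vpRel, d50df$asinSqrtD50, d50df),
    transRpkm = report(rpkmDf$vpAbs, rpkmDf$rpkm, rpkmDf))
}
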