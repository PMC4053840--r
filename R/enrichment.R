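#' Epigenetic modification density (EMD) per fragment and window
#'
#' The EMD of a fragment is the fraction of its bases covered by at least
#' one feature interval (the union of the supplied coverage intervals
#' intersected with the fragment, divided by fragment length); a window's
#' EMD is the arithmetic mean over its member fragments.
#'
#' @param featureIntervals Coverage intervals as a
#'   [GenomicRanges::GRanges], a data.frame (`chrom`, `start`, `end`;
#'   0-based half-open), or a path to a BED/bedGraph file (bedGraph rows
#'   with value > 0 count as presence).
#' @param map A [FragmentMap-class].
#' @param track Optional [WindowTrack-class]; when given, per-window mean
#'   densities are returned as well.
#' @param feature Feature name recorded with the result.
#' @return A list with `feature`, `fragmentDensity` (numeric in \[0,1\]
#'   over `genome_index`) and, with a track, `windowDensity`.
#' @export
emdTrack <- function(featureIntervals, map, track = NULL,
    feature = "feature") {
  stopifnot(is(map, "FragmentMap"))
  gr <- featureIntervals
  if (is.character(gr) && length(gr) == 1L) {
    fmt <- if (grepl("\\.bedgraph$|\\.bdg$", gr, ignore.case = TRUE))
      "bedGraph" else "BED"
    gr <- rtracklayer::import(gr, format = fmt)
    if (!is.null(mcols(gr)$score)) gr <- gr[mcols(gr)$score > 0]
  } else if (is.data.frame(gr)) {
    gr <- GRanges(gr$chrom, IRanges(gr$start + 1L, gr$end))
  }
  fr <- map@fragments
  lens <- seqlengths(fr)
  grChr <- as.character(seqnames(gr))
  known <- grChr %in% names(lens)
  if (any(known & (end(gr) > lens[grChr] | start(gr) < 1L)))
    stop("feature interval outside chromosome bounds")
  red <- reduce(GRanges(grChr, IRanges(start(gr), end(gr))))
  ov <- findOverlaps(fr, red)
  covered <- numeric(length(fr))
  if (length(ov)) {
    pw <- width(pintersect(fr[S4Vectors::queryHits(ov)],
      red[S4Vectors::subjectHits(ov)]))
    agg <- tapply(pw, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  dens <- covered / width(fr)
  out <- list(feature = feature, fragmentDensity = dens)
  if (!is.null(track))
    out$windowDensity <- windowMeanDensity(track, dens)
  out
}

#' Select control windows for a prey set
#'
#' Draws `n` control windows uniformly from the eligible pool: windows
#' that are not preys, have a defined P-value, and do not overlap the
#' exclusion ranges (by default the caller passes the viewpoint's
#' +/- 2 Mb neighbourhood). When the pool is smaller than `n` the draw
#' is with replacement and a warning is emitted. Seeded and
#' reproducible; controls are disjoint from preys by construction.
#'
#' @param track A [WindowTrack-class] with P-values and prey calls.
#' @param n Number of controls (default 50).
#' @param seed RNG seed.
#' @param exclude Optional [GenomicRanges::GRanges] of regions whose
#'   overlapping windows are ineligible.
#' @return Integer indices of control windows into `windowTable(track)`.
#' @export
selectControls <- function(track, n = 50L, seed = 1L, exclude = NULL) {
  w <- track@windows
  eligible <- which(!(w$prey %in% TRUE) & !is.na(w$P))
  if (!is.null(exclude) && length(exclude)) {
    wgr <- GRanges(w$chrom, IRanges(w$start, w$end))
    bad <- unique(S4Vectors::queryHits(findOverlaps(wgr, exclude)))
    eligible <- setdiff(eligible, bad)
  }
  if (!length(eligible)) stop("no eligible control windows")
  replace <- length(eligible) < n
  if (replace)
    warning(sprintf("eligible pool (%d) smaller than n = %d; %s",
      length(eligible), n, "sampling with replacement"))
  .withSeed(.subSeed(seed, "controls"),
    sample(eligible, n, replace = replace))
}

#' Per-window mean of a per-fragment density
#'
#' Averages a per-fragment density vector (e.g. the `fragmentDensity` of
#' [emdTrack()] or a simulated feature track) over the member fragments
#' of every window of a track.
#'
#' @param track A [WindowTrack-class].
#' @param fragmentDensity Numeric vector over `genome_index`.
#' @return Numeric vector over the track's windows.
#' @export
windowMeanDensity <- function(track, fragmentDensity) {
  w <- track@windows
  wd <- rep(NA_real_, nrow(w))
  for (a in names(track@armFragments)) {
    sel <- which(w$arm == a)
    if (!length(sel)) next
    dd <- fragmentDensity[track@armFragments[[a]]]
    wd[sel] <- .windowSums(dd, w$firstIdx[sel], track@size) / track@size
  }
  wd
}

#' Mean EMD matrix of prey and control regions per viewpoint
#'
#' Builds the viewpoint-by-group mean density matrix that
#' [pcaPreyControl()] consumes: one row per viewpoint and group
#' (`<viewpoint>.prey`, `<viewpoint>.control`), one column per feature,
#' each entry the mean window density over the group's regions.
#'
#' @param windowEmds Named list: feature -> numeric density vector over
#'   windows.
#' @param regionSets Named list per viewpoint: `list(prey = indices,
#'   control = indices)`.
#' @return Numeric matrix.
#' @export
meanEmdMatrix <- function(windowEmds, regionSets) {
  rows <- list()
  for (v in names(regionSets)) {
    for (g in c("prey", "control")) {
      idx <- regionSets[[v]][[g]]
      rows[[paste(v, g, sep = ".")]] <- vapply(windowEmds,
        function(e) mean(e[idx]), numeric(1))
    }
  }
  do.call(rbind, rows)
}

#' Principal component analysis of prey/control mean EMD profiles
#'
#' Covariance-based PCA (centered, unscaled by default, mirroring the
#' classical routine) of a matrix whose rows are viewpoint-by-group
#' (prey/control) mean EMDs and whose columns are epigenetic features.
#' On real 4C data the first component typically captures the
#' heterochromatin-euchromatin axis.
#'
#' @param m Numeric matrix, rows = viewpoint x group, columns = features.
#' @param scale Scale columns to unit variance first (default `FALSE`).
#' @return A list with `loadings`, `varianceFraction`, `scores`.
#' @export
pcaPreyControl <- function(m, scale = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and features")
  totVar <- sum(apply(m, 2L, stats::var))
  if (totVar == 0) {
    k <- min(dim(m))
    return(list(loadings = matrix(0, ncol(m), k,
        dimnames = list(colnames(m), paste0("PC", seq_len(k)))),
      varianceFraction = rep(0, k),
      scores = matrix(0, nrow(m), k,
        dimnames = list(rownames(m), paste0("PC", seq_len(k))))))
  }
  pc <- prcomp(m, center = TRUE, scale. = scale)
  list(loadings = pc$rotation,
    varianceFraction = pc$sdev^2 / sum(pc$sdev^2), scores = pc$x)
}

#' Permutation test of prey-versus-control EMD differences
#'
#' For each feature, each of `i` repetitions and each viewpoint `j`:
#' `nPerGroup` prey and control EMD values are sampled from the
#' viewpoint's prey and control windows, and the absolute difference of
#' the group means is recorded (`RealDiff_ij`); the pooled `2*nPerGroup`
#' values are then re-split at random into two groups of `nPerGroup`
#' and the absolute mean difference recorded again (`RandDiff_ij`). The
#' empirical P is `sum(RandDiff_ij > RealDiff_m) / (i*j)` with
#' `RealDiff_m` the grand mean of the real differences (strict `>`, as
#' conventional; `gte = TRUE` switches to `>=`, which turns the
#' degenerate all-values-equal case from p = 0 into p = 1). Viewpoints
#' without preys are excluded from `j`. P-values are BH-adjusted across
#' features.
#'
#' @param windowEmds Named list: feature -> numeric EMD vector over the
#'   track's windows.
#' @param regionSets Named list per viewpoint: `list(prey = indices,
#'   control = indices)` into the window vector.
#' @param i Repetitions per viewpoint (default 1000).
#' @param nPerGroup Group size per draw (default 50; sampled with
#'   replacement when a pool is smaller).
#' @param seed RNG seed.
#' @param gte Use `>=` instead of `>` in the tail count.
#' @return data.frame: feature, realDiffMean, p, q.
#' @export
permutationTest <- function(windowEmds, regionSets, i = 1000L,
    nPerGroup = 50L, seed = 1L, gte = FALSE) {
  usable <- Filter(function(rs) length(rs$prey) > 0L, regionSets)
  dropped <- setdiff(names(regionSets), names(usable))
  if (length(dropped))
    message("viewpoints without preys excluded: ",
      paste(dropped, collapse = ", "))
  if (!length(usable)) stop("no viewpoint with prey regions")
  j <- length(usable)
  res <- lapply(names(windowEmds), function(feat) {
    emd <- windowEmds[[feat]]
    realDiff <- matrix(NA_real_, i, j)
    randDiff <- matrix(NA_real_, i, j)
    .withSeed(.subSeed(seed, paste0("perm:", feat)), {
      for (vj in seq_len(j)) {
        preyPool <- emd[usable[[vj]]$prey]
        ctrlPool <- emd[usable[[vj]]$control]
        for (rep_ in seq_len(i)) {
          ps <- sample(preyPool, nPerGroup,
            replace = length(preyPool) < nPerGroup)
          cs <- sample(ctrlPool, nPerGroup,
            replace = length(ctrlPool) < nPerGroup)
          realDiff[rep_, vj] <- abs(mean(ps) - mean(cs))
          pool <- c(ps, cs)
          pick <- sample.int(2L * nPerGroup, nPerGroup)
          randDiff[rep_, vj] <- abs(mean(pool[pick]) -
            mean(pool[-pick]))
        }
      }
    })
    realM <- mean(realDiff)
    p <- if (gte) mean(randDiff >= realM) else mean(randDiff > realM)
    data.frame(feature = feat, realDiffMean = realM, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out
}

# Enrichment score: regions sorted by density (descending, stable ties),
# test members weighted (n-m)/m, others -1; ES = max |cumulative sum|.
.enrichmentScore <- function(ord, isTest) {
  n <- length(ord)
  m <- sum(isTest)
  if (m == 0L || m == n) return(0)
  wgt <- ifelse(isTest[ord], (n - m) / m, -1)
  max(abs(cumsum(wgt)))
}

#' GSEA-like enrichment of preys along a feature-density ranking
#'
#' For each viewpoint, all non-overlapping regions outside the
#' viewpoint's arm are sorted by feature density (descending, ties
#' broken by window index); regions in the test set (the replicated
#' preys) receive weight `(n-m)/m` and the rest `-1`, so the weights sum
#' to zero, and the enrichment score (ES) is the maximum absolute
#' deviation of the cumulative sum from zero. The null distribution
#' draws `nRand` random `m`-subsets per viewpoint; the observed mean ES
#' across viewpoints is compared with the per-draw mean of the matched
#' random ES (`p = mean(null >= observed)`). Because the null depends
#' only on `(n, m)`, it is computed once per viewpoint and shared across
#' features. P-values are BH-adjusted across features.
#'
#' @param windowEmds Named list: feature -> numeric EMD vector over the
#'   track's windows.
#' @param track The [WindowTrack-class] the EMDs and preys live on
#'   (non-overlapping windows, e.g. size 25 step 25).
#' @param testSets Named list per viewpoint: integer indices (into
#'   `windowTable(track)`) of the viewpoint's prey windows.
#' @param viewpointArms Named character: per viewpoint, its own arm
#'   (regions on it are excluded — only long-range interactions are
#'   scored). Entries may be `NA` to skip exclusion.
#' @param nRand Random subsets per viewpoint (default 10000).
#' @param seed RNG seed.
#' @return A list with `table` (data.frame: feature, meanES, p, q) and
#'   `perViewpoint` (data.frame: feature, viewpoint, n, m, ES).
#' @export
gseaLikeTest <- function(windowEmds, track, testSets, viewpointArms,
    nRand = 10000L, seed = 1L) {
  w <- track@windows
  vps <- names(testSets)
  regionIdx <- lapply(vps, function(v) {
    a <- viewpointArms[[v]]
    if (is.na(a)) seq_len(nrow(w)) else which(w$arm != a)
  })
  names(regionIdx) <- vps
  mOf <- vapply(vps, function(v)
    length(intersect(testSets[[v]], regionIdx[[v]])), integer(1))
  keep <- vps[mOf > 0L]
  if (!length(keep)) stop("no viewpoint with test regions")
  # null ES per viewpoint depends only on (n, m); one draw set, reused
  nullES <- lapply(keep, function(v) {
    n <- length(regionIdx[[v]])
    m <- mOf[[v]]
    .withSeed(.subSeed(seed, paste0("gsea:", v)), {
      vapply(seq_len(nRand), function(r) {
        isTest <- logical(n)
        isTest[sample.int(n, m)] <- TRUE
        .enrichmentScore(seq_len(n), isTest)
      }, numeric(1))
    })
  })
  names(nullES) <- keep
  nullMean <- Reduce(`+`, nullES) / length(keep)
  rows <- list(); pervp <- list()
  for (feat in names(windowEmds)) {
    emd <- windowEmds[[feat]]
    esObs <- vapply(keep, function(v) {
      idx <- regionIdx[[v]]
      isTest <- idx %in% testSets[[v]]
      ord <- order(-emd[idx], seq_along(idx))
      .enrichmentScore(ord, isTest)
    }, numeric(1))
    meanES <- mean(esObs)
    p <- mean(nullMean >= meanES)
    rows[[feat]] <- data.frame(feature = feat, meanES = meanES, p = p)
    pervp[[feat]] <- data.frame(feature = feat, viewpoint = keep,
      n = vapply(keep, function(v) length(regionIdx[[v]]), integer(1)),
      m = mOf[keep], ES = esObs, row.names = NULL)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$q <- bhAdjust(tab$p)
  list(table = tab, perViewpoint = do.call(rbind,
    c(pervp, list(make.row.names = FALSE))))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with monotonicity enforcement,
#' order-preserving (a validated front-end to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in \[0,1\].
#' @return Adjusted q-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0,1]")
  p.adjust(pvalues, method = "BH")
}
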