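#' Build fragment windows per chromosome arm
#'
#' Windows of `size` valid fragments are laid per arm over the
#' arm-index-ordered valid fragments of a filtered map, advancing by
#' `step` fragments. Windows never cross an arm boundary (the centromere
#' acts as an interaction boundary and the per-arm null requires it).
#' With `step = 1` an arm of `n` valid fragments yields `n - size + 1`
#' overlapping windows; with `step = size`, `floor(n / size)`
#' non-overlapping windows (trailing fragments stay unwindowed). Arms
#' with fewer than `size` valid fragments yield no windows (logged, not
#' an error).
#'
#' @param map A filtered, arm-annotated [FragmentMap-class].
#' @param size,step Window geometry in fragments. The reference settings
#'   are 100/1 (overlapping) and 25/25 (non-overlapping).
#' @return A [WindowTrack-class] with empty value columns.
#' @export
buildWindows <- function(map, size = 100L, step = 1L) {
  stopifnot(is(map, "FragmentMap"))
  size <- as.integer(size); step <- as.integer(step)
  if (size < 1L || step < 1L) stop("size and step must be >= 1")
  fr <- map@fragments
  m <- mcols(fr)
  sel <- which(m$valid & !is.na(m$arm))
  armOf <- m$arm[sel]
  armNames <- unique(armOf)
  armFragments <- list()
  rows <- list()
  for (a in armNames) {
    asel <- sel[armOf == a]
    asel <- asel[order(m$arm_index[asel])]
    armFragments[[a]] <- m$genome_index[asel]
    n <- length(asel)
    if (n < size) {
      message(sprintf("arm %s: %d valid fragments < window size %d; no windows",
        a, n, size))
      next
    }
    starts <- seq.int(1L, n - size + 1L, by = step)
    spanStart <- spanEnd <- integer(length(starts))
    fs <- start(fr)[asel]; fe <- end(fr)[asel]
    for (j in seq_along(starts)) {
      mem <- starts[j]:(starts[j] + size - 1L)
      spanStart[j] <- min(fs[mem])
      spanEnd[j] <- max(fe[mem])
    }
    rows[[a]] <- DataFrame(arm = a,
      chrom = as.character(seqnames(fr))[asel[1L]], start = spanStart,
      end = spanEnd, firstIdx = starts)
  }
  w <- if (length(rows)) do.call(rbind, rows) else
    DataFrame(arm = character(), chrom = character(), start = integer(),
      end = integer(), firstIdx = integer())
  w$readSum <- rep(NA_real_, nrow(w))
  w$value <- rep(NA_real_, nrow(w))
  w$valueScaled <- rep(NA_real_, nrow(w))
  w$P <- rep(NA_real_, nrow(w))
  w$prey <- rep(NA, nrow(w))
  rownames(w) <- NULL
  new("WindowTrack", windows = w, armFragments = armFragments,
    size = size, step = step, viewpoint = NA_character_,
    sample = NA_character_, librarySize = NA_real_,
    nShuffles = NA_integer_, seed = NA_integer_)
}

# Rolling window sums of x at the track's window starts for one arm.
.windowSums <- function(x, starts, size) {
  cs <- c(0, cumsum(x))
  cs[starts + size] - cs[starts]
}

#' Compute window interaction values
#'
#' The interaction value of a window is the sum of log2-transformed
#' fragment counts over its member fragments; fragments with fewer than
#' one read contribute 0 (the log transform damps outlier fragments
#' before summation). `readSum` is the plain count sum and `valueScaled`
#' the interaction value per million library reads.
#'
#' @param track A [WindowTrack-class] from [buildWindows()].
#' @param counts A [FragmentCounts-class] on the same fragment map.
#' @return The track with `readSum`, `value`, `valueScaled` filled in.
#' @export
windowValues <- function(track, counts) {
  stopifnot(is(track, "WindowTrack"), is(counts, "FragmentCounts"))
  if (any(counts@counts < 0)) stop("negative counts")
  w <- track@windows
  for (a in names(track@armFragments)) {
    sel <- which(w$arm == a)
    if (!length(sel)) next
    cc <- counts@counts[track@armFragments[[a]]]
    contrib <- ifelse(cc >= 1, log2(cc), 0)
    w$value[sel] <- .windowSums(contrib, w$firstIdx[sel], track@size)
    w$readSum[sel] <- .windowSums(cc, w$firstIdx[sel], track@size)
  }
  ls <- counts@librarySize
  w$valueScaled <- if (ls > 0) w$value * 1e6 / ls else NA_real_
  track@windows <- w
  track@viewpoint <- counts@viewpoint
  track@sample <- counts@sample
  track@librarySize <- ls
  track
}

#' Assign shuffle-null P-values to windows
#'
#' For each chromosome arm independently and each of `nShuffles`
#' shuffles: fragment counts are permuted among the arm's valid
#' fragments, all window interaction values are recomputed, a normal
#' distribution is fitted to that shuffle's window values (sample mean
#' and sd), and each observed window receives a preliminary upper-tail P
#' under that normal. The final P is the mean of the preliminary P-values
#' across shuffles. Because neighbouring fragments of a true interaction
#' are enriched jointly, this within-arm shuffle erases local structure
#' while conditioning on the arm's count distribution.
#'
#' Degenerate cases: an arm with fewer than 2 windows keeps `P = NA`
#' (logged); a shuffle with zero sd gives preliminary P 1 when the
#' observed value is at most the mean, else 0.
#'
#' @param track A [WindowTrack-class] with values (run [windowValues()]
#'   first, or pass `counts` and they are computed here).
#' @param counts The [FragmentCounts-class] the values came from.
#' @param nShuffles Number of shuffles (default 1000).
#' @param seed Master seed; per-arm streams are derived deterministically,
#'   so results are independent of arm evaluation order.
#' @param pooled Alternative null: pool window values across all shuffles
#'   and fit a single normal (default `FALSE`, fit per shuffle then
#'   average P).
#' @return The track with `P` filled in.
#' @export
shufflePvalues <- function(track, counts, nShuffles = 1000L, seed = 1L,
    pooled = FALSE) {
  stopifnot(is(track, "WindowTrack"), is(counts, "FragmentCounts"))
  nShuffles <- as.integer(nShuffles)
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  if (all(is.na(track@windows$value)) || nrow(track@windows) == 0L)
    track <- windowValues(track, counts)
  w <- track@windows
  size <- track@size
  for (a in names(track@armFragments)) {
    sel <- which(w$arm == a)
    if (length(sel) < 2L) {
      if (length(sel)) message(sprintf(
        "arm %s has fewer than 2 windows; P undefined", a))
      next
    }
    obs <- w$value[sel]
    starts <- w$firstIdx[sel]
    cc <- counts@counts[track@armFragments[[a]]]
    contrib0 <- ifelse(cc >= 1, log2(cc), 0)
    n <- length(contrib0)
    acc <- numeric(length(sel))
    pooledVals <- if (pooled) numeric(0) else NULL
    .withSeed(.subSeed(seed, a), {
      for (s in seq_len(nShuffles)) {
        vals <- .windowSums(contrib0[sample.int(n)], starts, size)
        if (pooled) {
          pooledVals <- c(pooledVals, vals)
        } else {
          mu <- mean(vals); sdv <- sd(vals)
          if (sdv == 0) {
            acc <- acc + ifelse(obs <= mu, 1, 0)
          } else {
            acc <- acc + pnorm(obs, mu, sdv, lower.tail = FALSE)
          }
        }
      }
    })
    if (pooled) {
      mu <- mean(pooledVals); sdv <- sd(pooledVals)
      w$P[sel] <- if (sdv == 0) ifelse(obs <= mu, 1, 0) else
        pnorm(obs, mu, sdv, lower.tail = FALSE)
    } else {
      w$P[sel] <- acc / nShuffles
    }
  }
  track@windows <- w
  track@nShuffles <- nShuffles
  track@seed <- as.integer(seed)
  track
}

#' Call prey windows from one or two replicate tracks
#'
#' With a single track, preys are windows with `P <= threshold` (the
#' single-replicate rule); with two replicate tracks, windows with
#' `P < threshold` in both replicates (the replicated rule). Strictness
#' is configurable via `strict`. Windows overlapping `mask` (e.g. the
#' viewpoint's +/- 2 Mb neighbourhood) are never called prey.
#'
#' @param tracks A [WindowTrack-class] or a list of two replicate tracks
#'   with identical window definitions.
#' @param threshold P-value threshold (default 0.01).
#' @param bothReplicates Require the threshold in both replicates
#'   (default `TRUE` when two tracks are given).
#' @param strict Use `<` instead of `<=`; defaults to `FALSE` for a
#'   single track and `TRUE` for the both-replicate rule.
#' @param mask Optional [GenomicRanges::GRanges]; overlapping windows are
#'   excluded from prey calls.
#' @return The (first) track with the `prey` flag set.
#' @export
callPreys <- function(tracks, threshold = 0.01, bothReplicates = NULL,
    strict = NULL, mask = NULL) {
  if (is(tracks, "WindowTrack")) tracks <- list(tracks)
  if (is.null(bothReplicates)) bothReplicates <- length(tracks) > 1L
  if (is.null(strict)) strict <- bothReplicates
  if (bothReplicates && length(tracks) < 2L)
    stop("both-replicate rule requires two tracks")
  w1 <- tracks[[1L]]@windows
  if (length(tracks) > 1L) {
    for (t in tracks[-1L]) {
      w2 <- t@windows
      if (nrow(w1) != nrow(w2) || !all(w1$arm == w2$arm) ||
          !all(w1$start == w2$start) || !all(w1$end == w2$end))
        stop("replicate tracks have mismatched window definitions")
    }
  }
  cmp <- function(p) if (strict) p < threshold else p <= threshold
  prey <- cmp(w1$P)
  if (bothReplicates)
    for (t in tracks[-1L]) prey <- prey & cmp(t@windows$P)
  prey[is.na(prey)] <- FALSE
  if (!is.null(mask) && length(mask)) {
    wgr <- GRanges(w1$chrom, IRanges(w1$start, w1$end))
    prey[S4Vectors::queryHits(findOverlaps(wgr, mask))] <- FALSE
  }
  out <- tracks[[1L]]
  out@windows$prey <- prey
  out
}

#' Mean bp span of windows
#'
#' Average genomic extent of the track's windows, e.g. the mean span of
#' 100-fragment windows over a digest.
#'
#' @param track A [WindowTrack-class].
#' @return Mean window span in bp.
#' @export
meanWindowSpan <- function(track) {
  w <- track@windows
  if (!nrow(w)) return(NA_real_)
  mean(w$end - w$start + 1)
}
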