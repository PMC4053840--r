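#' In-silico restriction digest of a genome
#'
#' Scans the forward strand of every chromosome for exact occurrences of
#' the (palindromic) recognition motif and cuts at `motif start +
#' cutOffset`, producing a fragment map that tiles each chromosome without
#' gaps or overlaps. `N` bases never match. Non-palindromic or degenerate
#' (IUPAC) motifs are not supported.
#'
#' 4C reads start at the enzymatic cut, so the cut offset reflects cut
#' chemistry: HindIII (`A^AGCTT`) cuts at offset 1, DpnII (`^GATC`) at
#' offset 0.
#'
#' @param genome A [GenomeModel-class].
#' @param motif Recognition motif (A/C/G/T only, length >= 4).
#' @param cutOffset 0-based cut position within the motif, in
#'   `[0, nchar(motif)]`.
#' @return A [FragmentMap-class] with unannotated arm/secondary columns.
#' @examples
#' gm <- GenomeModel(c(chr1 = "GGGAAGCTTGGG"))
#' map <- digestGenome(gm, "AAGCTT", 1)
#' fragments(map)
#' @export
digestGenome <- function(genome, motif, cutOffset = 0L) {
  stopifnot(is(genome, "GenomeModel"))
  if (length(genome@sequences) == 0L) stop("empty genome")
  .checkMotif(motif, minLen = 4L)
  cutOffset <- as.integer(cutOffset)
  if (cutOffset < 0L || cutOffset > nchar(motif))
    stop("cutOffset must lie within the motif")
  pat <- DNAString(motif)
  dfl <- lapply(names(genome@sequences), function(chr) {
    s <- genome@sequences[[chr]]
    len <- length(s)
    sites <- start(matchPattern(pat, s, fixed = TRUE))      # 1-based
    cuts <- sites - 1L + cutOffset                           # 0-based
    b <- sort(unique(c(0L, cuts[cuts > 0L & cuts < len], len)))
    data.frame(chrom = chr, start = head(b, -1L) + 1L, end = b[-1L])
  })
  df <- do.call(rbind, dfl)
  lens <- chromLengths(genome)
  fr <- GRanges(df$chrom, IRanges(df$start, df$end),
    seqinfo = GenomeInfoDb::Seqinfo(names(lens), unname(lens)))
  fr <- sort(fr, ignore.strand = TRUE)
  mcols(fr) <- .emptyFragmentMcols(length(fr))
  new("FragmentMap", fragments = fr, primaryMotif = toupper(motif),
    cutOffset = cutOffset, secondaryMotif = NA_character_,
    centromeres = genome@centromeres)
}

#' Build a FragmentMap from explicit fragment coordinates
#'
#' Arithmetic constructor for fragment maps that do not come from a
#' sequence digest (imported digests, synthetic maps for calibration
#' studies). Fragments must tile each chromosome.
#'
#' @param frags A data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) or a [GenomicRanges::GRanges] (1-based closed).
#' @param centromeres Optional centromere intervals (data.frame in BED
#'   convention or GRanges); when given, arms are annotated immediately.
#' @param primaryMotif,cutOffset Bookkeeping for the digest this map
#'   stands for (optional).
#' @return A [FragmentMap-class].
#' @export
makeFragmentMap <- function(frags, centromeres = NULL,
    primaryMotif = NA_character_, cutOffset = 0L) {
  if (is.data.frame(frags)) {
    fr <- GRanges(frags$chrom, IRanges(frags$start + 1L, frags$end))
  } else fr <- GenomicRanges::granges(frags)
  fr <- sort(fr, ignore.strand = TRUE)
  lens <- tapply(end(fr), as.character(seqnames(fr)), max)
  sl <- setNames(as.integer(lens[seqlevels(fr)]), seqlevels(fr))
  GenomeInfoDb::seqlengths(fr) <- sl
  mcols(fr) <- .emptyFragmentMcols(length(fr))
  cen <- GRanges()
  if (!is.null(centromeres)) {
    if (is.data.frame(centromeres))
      cen <- GRanges(centromeres$chrom,
        IRanges(centromeres$start + 1L, centromeres$end))
    else cen <- centromeres
  }
  map <- new("FragmentMap", fragments = fr,
    primaryMotif = as.character(primaryMotif),
    cutOffset = as.integer(cutOffset), secondaryMotif = NA_character_,
    centromeres = cen)
  if (length(cen)) map <- annotateArms(map) else map
}

#' Assign fragments to chromosome arms
#'
#' Each fragment is assigned to the arm on its midpoint's side of the
#' centromere: `<chrom>S` left of the centromere, `<chrom>L` right of it.
#' Fragments whose midpoint falls inside the centromere are flagged
#' centromeric and carry no arm. `cen_dist` is the distance from the
#' fragment midpoint to the nearest centromere boundary; `arm_index` ranks
#' fragments within each arm by increasing `cen_dist`.
#'
#' @param map A [FragmentMap-class].
#' @param centromeres Optional replacement centromere intervals
#'   (data.frame in BED convention or GRanges); defaults to the ones
#'   carried by the map. Exactly one interval per chromosome is required.
#' @return The map with arm annotations filled in.
#' @export
annotateArms <- function(map, centromeres = NULL) {
  stopifnot(is(map, "FragmentMap"))
  cen <- map@centromeres
  if (!is.null(centromeres)) {
    if (is.data.frame(centromeres))
      cen <- GRanges(centromeres$chrom,
        IRanges(centromeres$start + 1L, centromeres$end))
    else cen <- centromeres
  }
  fr <- map@fragments
  chroms <- unique(as.character(seqnames(fr)))
  cchr <- as.character(seqnames(cen))
  if (anyDuplicated(cchr))
    stop("exactly one centromere interval per chromosome required")
  missing <- setdiff(chroms, cchr)
  if (length(missing))
    stop("no centromere interval for chromosome(s): ",
      paste(missing, collapse = ", "))
  mid <- .midpoints(fr)
  cs0 <- setNames(start(cen) - 1L, cchr)[as.character(seqnames(fr))]
  ce0 <- setNames(end(cen), cchr)[as.character(seqnames(fr))]
  leftArm <- mid < cs0
  rightArm <- mid >= ce0
  inCen <- !leftArm & !rightArm
  arm <- rep(NA_character_, length(fr))
  arm[leftArm] <- paste0(as.character(seqnames(fr))[leftArm], "S")
  arm[rightArm] <- paste0(as.character(seqnames(fr))[rightArm], "L")
  cenDist <- rep(NA_real_, length(fr))
  cenDist[leftArm] <- cs0[leftArm] - mid[leftArm]
  cenDist[rightArm] <- mid[rightArm] - ce0[rightArm]
  armIndex <- rep(NA_integer_, length(fr))
  for (a in unique(arm[!is.na(arm)])) {
    sel <- which(arm == a)
    armIndex[sel] <- rank(cenDist[sel], ties.method = "first")
  }
  mcols(fr)$arm <- arm
  mcols(fr)$arm_index <- armIndex
  mcols(fr)$cen_dist <- cenDist
  mcols(fr)$centromeric <- inCen
  map@fragments <- fr
  map@centromeres <- cen
  map
}

#' Annotate distances to the first secondary restriction site
#'
#' For every fragment, records the distance from each fragment end to the
#' start of the first secondary-enzyme site encountered scanning inward
#' from that end (`sec5` from the 5' end, `sec3` from the 3' end). Only
#' sites fully contained in the fragment count. Absence of a site is a
#' value (`NA`), not an error.
#'
#' @param map A [FragmentMap-class].
#' @param genome The [GenomeModel-class] the map was digested from.
#' @param secondaryMotif Secondary enzyme motif (e.g. DpnII `GATC`).
#' @return The map with `sec5`/`sec3` filled in.
#' @export
annotateSecondary <- function(map, genome, secondaryMotif) {
  stopifnot(is(map, "FragmentMap"), is(genome, "GenomeModel"))
  .checkMotif(secondaryMotif)
  pat <- DNAString(secondaryMotif)
  mlen <- nchar(secondaryMotif)
  fr <- map@fragments
  sec5 <- rep(NA_real_, length(fr))
  sec3 <- rep(NA_real_, length(fr))
  for (chr in names(genome@sequences)) {
    idx <- which(as.character(seqnames(fr)) == chr)
    if (!length(idx)) next
    sites <- start(matchPattern(pat, genome@sequences[[chr]], fixed = TRUE))
    if (!length(sites)) next
    fs <- start(fr)[idx]; fe <- end(fr)[idx]
    # fragments are sorted by start; sites sorted ascending
    firstIn <- sites[findInterval(fs - 1L, sites) + 1L]
    # site fully inside: start >= fs and start + mlen - 1 <= fe
    ok5 <- !is.na(firstIn) & firstIn + mlen - 1L <= fe
    sec5[idx[ok5]] <- firstIn[ok5] - fs[ok5]
    lastStartAllowed <- fe - mlen + 1L
    li <- findInterval(lastStartAllowed, sites)
    lastIn <- ifelse(li >= 1L, sites[pmax(li, 1L)], NA_integer_)
    ok3 <- !is.na(lastIn) & lastIn >= fs
    sec3[idx[ok3]] <- fe[ok3] - lastIn[ok3] + 1L   # 3' end to site start
  }
  mcols(fr)$sec5 <- sec5
  mcols(fr)$sec3 <- sec3
  map@fragments <- fr
  map@secondaryMotif <- toupper(secondaryMotif)
  map
}

#' Flag fragments usable for a viewpoint's interaction analysis
#'
#' Marks `valid = FALSE` for fragments that are (a) closer than
#' `minVpDist` to the viewpoint fragment (edge-to-edge gap; the viewpoint
#' fragment itself is at distance 0 and is discarded — its reads are
#' dominated by self-circles and incomplete digestion), (b) centromeric or
#' closer than `minCenDist` to a centromere boundary, or (c) without a
#' secondary restriction site within `maxSecDist` of either fragment end
#' (a missing site counts as infinitely far). All other fragments are
#' marked valid. Idempotent.
#'
#' @param map An arm- and secondary-annotated [FragmentMap-class].
#' @param vp A [Viewpoint-class] whose `fragment` is in the map.
#' @param minVpDist,minCenDist,maxSecDist Thresholds in bp (defaults 1 kb,
#'   100 kb, 1 kb).
#' @return The map with the `valid` flag set for this viewpoint.
#' @export
filterFragments <- function(map, vp, minVpDist = 1000, minCenDist = 1e5,
    maxSecDist = 1000) {
  stopifnot(is(map, "FragmentMap"), is(vp, "Viewpoint"))
  fr <- map@fragments
  if (all(is.na(mcols(fr)$arm)) && !any(mcols(fr)$centromeric %in% TRUE))
    stop("map must be arm-annotated (run annotateArms first)")
  vi <- match(vp@fragment, mcols(fr)$genome_index)
  if (is.na(vi)) stop("viewpoint fragment not found in map")
  vpFrag <- fr[vi]
  sameChrom <- as.character(seqnames(fr)) == as.character(seqnames(vpFrag))
  gap <- rep(Inf, length(fr))
  gap[sameChrom] <- pmax(0, pmax(start(fr)[sameChrom] - end(vpFrag) - 1L,
    start(vpFrag) - end(fr)[sameChrom] - 1L))
  gap[vi] <- 0
  nearVp <- gap < minVpDist
  m <- mcols(fr)
  nearCen <- (m$centromeric %in% TRUE) |
    (!is.na(m$cen_dist) & m$cen_dist < minCenDist)
  s5 <- ifelse(is.na(m$sec5), Inf, m$sec5)
  s3 <- ifelse(is.na(m$sec3), Inf, m$sec3)
  noSec <- s5 >= maxSecDist & s3 >= maxSecDist
  mcols(fr)$valid <- !(nearVp | nearCen | noSec)
  map@fragments <- fr
  map
}

#' Write a fragment map as BED and/or annotated TSV
#'
#' BED output is 6-column, 0-based half-open: name = `genome_index`,
#' score = `arm_index` (0 when unassigned), strand = `.`. The TSV carries
#' every annotation column.
#'
#' @param map A [FragmentMap-class].
#' @param bed,tsv Output paths (`NULL` to skip either).
#' @return Invisibly, the annotated data.frame written to the TSV.
#' @export
writeFragmentMap <- function(map, bed = NULL, tsv = NULL) {
  fr <- map@fragments
  m <- as.data.frame(mcols(fr))
  df <- data.frame(chrom = as.character(seqnames(fr)),
    start = start(fr) - 1L, end = end(fr), m, check.names = FALSE)
  if (!is.null(bed)) {
    bedDf <- data.frame(df$chrom, df$start, df$end, df$genome_index,
      ifelse(is.na(df$arm_index), 0L, df$arm_index), ".")
    write.table(bedDf, bed, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
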