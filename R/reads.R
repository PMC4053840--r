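#' Demultiplex raw 4C reads by viewpoint primer
#'
#' Assigns a read to a viewpoint iff it begins with exactly that
#' viewpoint's primer (exact match, no mismatches) and — when
#' `requireSite` — the primary restriction motif directly follows the
#' primer (the library design places the primary site at the
#' primer/fragment junction). Primer and motif are removed and the
#' remainder is trimmed to exactly `trimTo` nt; shorter remainders are
#' discarded and tallied. Reads matching no primer, more than one primer,
#' or lacking the expected site are discarded and tallied.
#'
#' @param reads A [Biostrings::DNAStringSet] of raw reads, or a path to a
#'   FASTQ file (gzip-aware).
#' @param viewpoints A list of [Viewpoint-class] objects with distinct
#'   primer sequences.
#' @param primaryMotif Primary restriction motif expected after the
#'   primer.
#' @param sample Replicate identifier recorded with the output.
#' @param trimTo Final read length in nt (default 30).
#' @param requireSite Check for the primary motif directly after the
#'   primer (default `TRUE`).
#' @return A list with `reads` (named list of 30-nt
#'   [Biostrings::DNAStringSet] per viewpoint), `sample`, and `tallies`
#'   (named integer vector: per-viewpoint assigned counts plus
#'   `no_primer`, `ambiguous`, `no_site`, `too_short`). The tallies
#'   partition the input: they sum to the number of input reads.
#' @export
demultiplex <- function(reads, viewpoints, primaryMotif, sample = "A",
    trimTo = 30L, requireSite = TRUE) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- readDNAStringSet(reads, format = "fastq")
  .checkMotif(primaryMotif)
  primers <- vapply(viewpoints, function(v) v@primerSeq, character(1))
  vpNames <- vapply(viewpoints, function(v) v@name, character(1))
  if (anyDuplicated(primers))
    stop("two viewpoints share an identical primer")
  names(primers) <- vpNames
  n <- length(reads)
  w <- width(reads)
  hit <- matrix(FALSE, n, length(primers))
  for (k in seq_along(primers)) {
    pl <- nchar(primers[k])
    ok <- w >= pl
    hit[ok, k] <- as.character(subseq(reads[ok], 1L, pl)) == primers[k]
  }
  nHit <- rowSums(hit)
  assignedVp <- rep(NA_integer_, n)
  assignedVp[nHit == 1L] <- max.col(hit[nHit == 1L, , drop = FALSE])
  mlen <- nchar(primaryMotif)
  out <- vector("list", length(primers))
  names(out) <- vpNames
  tal <- setNames(integer(length(vpNames) + 4L),
    c(vpNames, "no_primer", "ambiguous", "no_site", "too_short"))
  tal["no_primer"] <- sum(nHit == 0L)
  tal["ambiguous"] <- sum(nHit > 1L)
  for (k in seq_along(primers)) {
    idx <- which(assignedVp == k)
    pl <- nchar(primers[k])
    if (requireSite) {
      hasSite <- width(reads[idx]) >= pl + mlen &
        as.character(subseq(reads[idx], pl + 1L,
          pmin(pl + mlen, width(reads[idx])))) == primaryMotif
      tal["no_site"] <- tal["no_site"] + sum(!hasSite)
      idx <- idx[hasSite]
    }
    rem <- subseq(reads[idx], pl + mlen + 1L)
    long <- width(rem) >= trimTo
    tal["too_short"] <- tal["too_short"] + sum(!long)
    trimmed <- subseq(rem[long], 1L, trimTo)
    tal[k] <- length(trimmed)
    out[[k]] <- trimmed
  }
  list(reads = out, sample = sample, tallies = tal)
}

#' Exact-match mapping of trimmed 4C reads
#'
#' Looks up every read (all of identical length) against both strands of
#' the genome with zero mismatches and returns all hits per distinct read
#' sequence. Reads with no hit are unmapped; reads with more than
#' `maxHits` hits are discarded (the repeat cap); 2..`maxHits` hits make a
#' multiread. Reads containing non-ACGT letters cannot match exactly and
#' are tallied unmapped.
#'
#' @param reads A [Biostrings::DNAStringSet] of equal-width reads
#'   (default design: 30 nt).
#' @param genome A [GenomeModel-class].
#' @param maxHits Discard reads with more than this many genomic hits
#'   (default 25).
#' @return A list of class `fourcAlignments`: `hits` data.frame
#'   (`seqId`, `chrom`, `start` 1-based, `strand`, `nHits`), `seqReads`
#'   integer vector (number of input reads per distinct sequence),
#'   `readLength`, and `tallies` (`unmapped`, `discarded_repeat` in
#'   reads).
#' @export
mapReadsExact <- function(reads, genome, maxHits = 25L) {
  stopifnot(is(genome, "GenomeModel"))
  if (length(reads) == 0L)
    return(structure(list(hits = data.frame(seqId = integer(),
      chrom = character(), start = integer(), strand = character(),
      nHits = integer()), seqReads = integer(), readLength = NA_integer_,
      tallies = c(unmapped = 0L, discarded_repeat = 0L)),
      class = "fourcAlignments"))
  if (length(unique(width(reads))) != 1L)
    stop("all reads must have identical length")
  rl <- width(reads)[1L]
  seqs <- as.character(reads)
  clean <- !grepl("[^ACGT]", seqs)
  useq <- unique(seqs[clean])
  seqReads <- as.integer(table(factor(seqs[clean], levels = useq)))
  hitList <- list()
  if (length(useq)) {
    dict <- DNAStringSet(useq)
    pd <- PDict(dict)
    pdRc <- PDict(reverseComplement(dict))
    for (chr in names(genome@sequences)) {
      s <- genome@sequences[[chr]]
      fwd <- matchPDict(pd, s)
      rev <- matchPDict(pdRc, s)
      nf <- elementNROWS(fwd); nr <- elementNROWS(rev)
      if (sum(nf) + sum(nr) == 0) next
      hitList[[length(hitList) + 1L]] <- data.frame(
        seqId = c(rep(seq_along(useq), nf), rep(seq_along(useq), nr)),
        chrom = chr,
        start = c(unlist(start(fwd)), unlist(start(rev))),
        strand = c(rep("+", sum(nf)), rep("-", sum(nr))))
    }
  }
  hits <- if (length(hitList)) do.call(rbind, hitList) else
    data.frame(seqId = integer(), chrom = character(), start = integer(),
      strand = character())
  nHitsPerSeq <- tabulate(hits$seqId, nbins = length(useq))
  hits$nHits <- nHitsPerSeq[hits$seqId]
  keepSeq <- nHitsPerSeq >= 1L & nHitsPerSeq <= maxHits
  tallies <- c(
    unmapped = sum(!clean) + sum(seqReads[nHitsPerSeq == 0L]),
    discarded_repeat = sum(seqReads[nHitsPerSeq > maxHits]))
  hits <- hits[keepSeq[hits$seqId], , drop = FALSE]
  structure(list(hits = hits, seqReads = seqReads, readLength = rl,
    tallies = tallies), class = "fourcAlignments")
}

#' Import externally aligned reads
#'
#' Accepts alignments from an external aligner as BED6 (0-based
#' half-open; the `name` column groups hits of the same read) or a
#' SAM-like TSV with columns `read`, `chrom`, `start` (1-based), `end`,
#' `strand`. The result enters the pipeline at [countFragmentReads()],
#' bypassing [mapReadsExact()].
#'
#' @param path File path, or a data.frame already in the TSV layout.
#' @param format `"bed"` or `"tsv"`.
#' @param maxHits Repeat cap, as in [mapReadsExact()].
#' @return A `fourcAlignments` list (see [mapReadsExact()]).
#' @export
importAlignments <- function(path, format = c("bed", "tsv"),
    maxHits = 25L) {
  format <- match.arg(format)
  if (is.data.frame(path)) {
    df <- path
  } else if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(read = mcols(gr)$name,
      chrom = as.character(seqnames(gr)), start = start(gr),
      end = end(gr), strand = as.character(strand(gr)))
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
      colClasses = c("character", "character", "integer", "integer",
        "character"))
    names(df) <- c("read", "chrom", "start", "end", "strand")
  }
  rl <- unique(df$end - df$start + 1L)
  if (length(rl) != 1L) stop("all alignments must share one read length")
  reads <- unique(df$read)
  seqId <- match(df$read, reads)
  nHits <- tabulate(seqId, nbins = length(reads))
  keep <- nHits[seqId] <= maxHits
  hits <- data.frame(seqId = seqId[keep], chrom = df$chrom[keep],
    start = df$start[keep], strand = df$strand[keep],
    nHits = nHits[seqId][keep])
  structure(list(hits = hits, seqReads = rep(1L, length(reads)),
    readLength = rl,
    tallies = c(unmapped = 0L, discarded_repeat = sum(nHits > maxHits))),
    class = "fourcAlignments")
}

#' Count end-anchored reads per restriction fragment
#'
#' A hit counts for a fragment iff it is end-anchored: a forward-strand
#' hit starting exactly at the fragment's 5' boundary, or a
#' reverse-strand hit ending exactly at the fragment's 3' boundary (4C
#' reads begin at the primary cut site by construction; `endTolerance`
#' relaxes the match). Interior hits are dropped and tallied `off_end`.
#' Uniquely mapping reads increment fragment counts by 1; multireads are
#' returned as candidate fragment lists for [allocateMultireads()].
#'
#' @param alignments A `fourcAlignments` list from [mapReadsExact()] or
#'   [importAlignments()].
#' @param map A [FragmentMap-class] digested with the same primary motif.
#' @param viewpoint,sample Library identity for the returned counts.
#' @param endTolerance Allowed bp offset from the fragment boundary
#'   (default 0, exact).
#' @return A list with `counts` (a [FragmentCounts-class] holding unique
#'   reads) and `multireads` (data.frame of `nReads` and a list-column
#'   `candidates` of end-anchored fragment `genome_index` vectors).
#' @export
countFragmentReads <- function(alignments, map, viewpoint = "vp",
    sample = "A", endTolerance = 0L) {
  stopifnot(inherits(alignments, "fourcAlignments"), is(map, "FragmentMap"))
  fr <- map@fragments
  hits <- alignments$hits
  rl <- alignments$readLength
  if (nrow(hits)) {
    lens <- seqlengths(fr)[hits$chrom]
    if (any(is.na(lens)) || any(hits$start < 1L) ||
        any(hits$start + rl - 1L > lens))
      stop("alignment beyond chromosome bounds")
  }
  counts <- numeric(length(fr))
  tallies <- c(alignments$tallies, off_end = 0L, counted = 0L)
  multiN <- integer(0)
  multiCands <- list()
  if (nrow(hits)) {
    chroms <- unique(as.character(seqnames(fr)))
    fragIdx <- rep(NA_integer_, nrow(hits))
    for (chr in chroms) {
      sel <- which(hits$chrom == chr)
      if (!length(sel)) next
      fidx <- which(as.character(seqnames(fr)) == chr)
      fs <- start(fr)[fidx]; fe <- end(fr)[fidx]
      fwd <- sel[hits$strand[sel] == "+"]
      rev <- sel[hits$strand[sel] == "-"]
      if (endTolerance == 0L) {
        fragIdx[fwd] <- fidx[match(hits$start[fwd], fs)]
        fragIdx[rev] <- fidx[match(hits$start[rev] + rl - 1L, fe)]
      } else {
        # nearest boundary within tolerance
        fi <- findInterval(hits$start[fwd], fs)
        cand <- fidx[pmax(fi, 1L)]
        ok <- abs(hits$start[fwd] - fs[pmax(fi, 1L)]) <= endTolerance
        fi2 <- pmin(fi + 1L, length(fs))
        ok2 <- abs(hits$start[fwd] - fs[fi2]) <= endTolerance
        fragIdx[fwd] <- ifelse(ok, cand, ifelse(ok2, fidx[fi2], NA))
        he <- hits$start[rev] + rl - 1L
        ri <- findInterval(he, fe) + 1L
        ri <- pmin(pmax(ri, 1L), length(fe))
        okr <- abs(he - fe[ri]) <= endTolerance
        ri0 <- pmax(ri - 1L, 1L)
        okr0 <- abs(he - fe[ri0]) <= endTolerance
        fragIdx[rev] <- ifelse(okr, fidx[ri], ifelse(okr0, fidx[ri0], NA))
      }
    }
    anchored <- !is.na(fragIdx)
    bySeq <- split(fragIdx[anchored], hits$seqId[anchored])
    nH <- alignments$seqReads
    uniqueSeqs <- hits$seqId[!duplicated(hits$seqId)]
    nHitsOf <- hits$nHits[!duplicated(hits$seqId)]
    names(nHitsOf) <- uniqueSeqs
    for (sidStr in names(bySeq)) {
      sid <- as.integer(sidStr)
      cands <- unique(bySeq[[sidStr]])
      nr <- alignments$seqReads[sid]
      if (nHitsOf[[sidStr]] == 1L) {
        counts[cands] <- counts[cands] + nr
        tallies["counted"] <- tallies["counted"] + nr
      } else {
        multiN <- c(multiN, nr)
        multiCands[[length(multiCands) + 1L]] <- cands
      }
    }
    # unique-read hits that were not end-anchored
    uni <- hits$nHits == 1L & is.na(fragIdx)
    offEnd <- sum(alignments$seqReads[hits$seqId[uni]])
    # multireads with no end-anchored candidate at all
    multiIds <- unique(hits$seqId[hits$nHits > 1L])
    noCand <- setdiff(as.character(multiIds), names(bySeq))
    offEnd <- offEnd + sum(alignments$seqReads[as.integer(noCand)])
    tallies["off_end"] <- offEnd
  }
  multi <- data.frame(nReads = multiN)
  multi$candidates <- multiCands
  fc <- new("FragmentCounts", viewpoint = viewpoint, sample = sample,
    counts = counts, librarySize = sum(counts), tallies = as.list(tallies))
  list(counts = fc, multireads = multi)
}

#' Fractionally allocate multireads by local unique-read support
#'
#' Each multiread is split across its candidate fragments proportionally
#' to the unique-read mass within `allocationDistance` of each candidate
#' (counts summed over fragments whose midpoints lie within the distance
#' of the candidate's midpoint). Multireads with no unique support near
#' any candidate are discarded and tallied. The total allocated mass
#' equals the number of allocated multireads.
#'
#' @param multireads The `multireads` component of
#'   [countFragmentReads()]'s result.
#' @param uniqueCounts The matching [FragmentCounts-class] of unique
#'   reads.
#' @param map The [FragmentMap-class].
#' @param allocationDistance Half-width of the support window in bp
#'   (default 50 kb, one half of the ~100 kb interaction unit).
#' @return A new [FragmentCounts-class] including the fractional
#'   multiread mass, with updated tallies (`multi_allocated`,
#'   `multi_discarded`).
#' @export
allocateMultireads <- function(multireads, uniqueCounts, map,
    allocationDistance = 5e4) {
  stopifnot(is(uniqueCounts, "FragmentCounts"), is(map, "FragmentMap"))
  fr <- map@fragments
  counts <- uniqueCounts@counts
  mid <- .midpoints(fr)
  chrom <- as.character(seqnames(fr))
  # per-fragment local unique mass via per-chromosome cumulative sums
  localMass <- numeric(length(fr))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    m <- mid[idx]
    cs <- c(0, cumsum(counts[idx]))
    lo <- findInterval(m - allocationDistance, m, left.open = TRUE)
    hi <- findInterval(m + allocationDistance, m)
    localMass[idx] <- cs[hi + 1L] - cs[lo + 1L]
  }
  newCounts <- counts
  allocated <- 0; discarded <- 0
  if (nrow(multireads)) {
    for (i in seq_len(nrow(multireads))) {
      cands <- multireads$candidates[[i]]
      wgt <- localMass[cands]
      nr <- multireads$nReads[i]
      if (sum(wgt) == 0) {
        discarded <- discarded + nr
      } else {
        newCounts[cands] <- newCounts[cands] + nr * wgt / sum(wgt)
        allocated <- allocated + nr
      }
    }
  }
  tal <- uniqueCounts@tallies
  tal$multi_allocated <- allocated
  tal$multi_discarded <- discarded
  new("FragmentCounts", viewpoint = uniqueCounts@viewpoint,
    sample = uniqueCounts@sample, counts = newCounts,
    librarySize = sum(newCounts), tallies = tal)
}
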