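#' Simulation configuration
#'
#' Assembles the parameter list the synthetic-data generators consume.
#' The defaults describe the study conditions the analysis is validated
#' under: five 2 Mb chromosomes with central centromeres, a HindIII-like
#' 6-cutter planted at ~4 kb mean spacing (the natural 6-cutter rate)
#' with a DpnII-like 4-cutter at ~256 bp, two viewpoints (one
#' euchromatic, one heterochromatic), power-law cis contact decay with
#' exponent -0.73, ten planted prey windows of 25 fragments per
#' viewpoint at 8-fold enrichment, 200,000 reads per library, and
#' Beta-distributed chromatin-state-dependent feature densities
#' (heterochromatic marks mean 0.6 in heterochromatin vs 0.1 in
#' euchromatin; euchromatic marks mirrored).
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Length of each chromosome in bp.
#' @param cenFraction Centromere width as a fraction of the chromosome,
#'   centred.
#' @param primaryMotif,primaryCutOffset,primarySpacing Primary enzyme
#'   motif, cut offset, mean site spacing (bp).
#' @param secondaryMotif,secondarySpacing Secondary enzyme motif and
#'   mean spacing (bp).
#' @param viewpoints data.frame with `name`, `chrom`, `relPos` (fraction
#'   of the chromosome), `state` (`"eu"`/`"het"`), `primer`.
#' @param gamma Cis contact decay exponent (< 0).
#' @param cisFraction Fraction of non-self reads on the viewpoint arm.
#' @param selfLigation Fraction of reads from the viewpoint fragment
#'   itself.
#' @param libSize Reads per library.
#' @param nPreyWindows Planted prey windows per viewpoint.
#' @param preyFragments Fragments per planted prey window.
#' @param enrichment Multiplicative sampling-mass factor on prey
#'   fragments (>= 1).
#' @param hetHalfWidth Heterochromatin half-width around each centromere
#'   as a fraction of the chromosome length.
#' @param features data.frame with `name` and `type`
#'   (`"het"`/`"eu"`/`"neutral"`).
#' @param densityMeans Named list `high`/`low`/`neutral`: Beta means for
#'   a mark in its matching state, the opposite state, and for neutral
#'   features.
#' @param betaConcentration Beta concentration (shape1 + shape2).
#' @return A list of class `fourcSimConfig`.
#' @export
simulationConfig <- function(nChrom = 5L, chromLength = 2e6,
    cenFraction = 0.1, primaryMotif = "AAGCTT", primaryCutOffset = 1L,
    primarySpacing = 4000, secondaryMotif = "GATC",
    secondarySpacing = 256,
    viewpoints = data.frame(
      name = c("vpEu", "vpHet"),
      chrom = paste0("chr", c(1L, min(4L, nChrom))),
      relPos = c(0.75, 0.35), state = c("eu", "het"),
      primer = c("ACGTACGTACGTACGTACCA", "TGCATGCATGCATGCATGGT"),
      stringsAsFactors = FALSE),
    gamma = -0.73, cisFraction = 0.5, selfLigation = 0.02,
    libSize = 2e5, nPreyWindows = 10L, preyFragments = 25L,
    enrichment = 8, hetHalfWidth = 0.18,
    features = data.frame(
      name = c("H3K9me2", "H3K27me1", "H3K4me3", "H3K36me3",
        "genomicControl"),
      type = c("het", "het", "eu", "eu", "neutral"),
      stringsAsFactors = FALSE),
    densityMeans = list(high = 0.6, low = 0.1, neutral = 0.5),
    betaConcentration = 20) {
  stopifnot(gamma < 0, cisFraction >= 0, cisFraction <= 1,
    enrichment >= 1, selfLigation >= 0, selfLigation < 1)
  structure(list(nChrom = as.integer(nChrom), chromLength = chromLength,
    cenFraction = cenFraction, primaryMotif = primaryMotif,
    primaryCutOffset = as.integer(primaryCutOffset),
    primarySpacing = primarySpacing, secondaryMotif = secondaryMotif,
    secondarySpacing = secondarySpacing, viewpoints = viewpoints,
    gamma = gamma, cisFraction = cisFraction,
    selfLigation = selfLigation, libSize = libSize,
    nPreyWindows = as.integer(nPreyWindows),
    preyFragments = as.integer(preyFragments), enrichment = enrichment,
    hetHalfWidth = hetHalfWidth, features = features,
    densityMeans = densityMeans,
    betaConcentration = betaConcentration), class = "fourcSimConfig")
}

# Plant a motif into a character base vector at 0-based positions.
.stampMotif <- function(bases, pos0, motif) {
  mm <- strsplit(motif, "")[[1L]]
  for (p in pos0) bases[(p + 1L):(p + length(mm))] <- mm
  bases
}

# Remove accidental motif occurrences, protecting planted site intervals.
.scrubMotifs <- function(seqStr, motifs, protectedMask) {
  s <- DNAString(seqStr)
  for (iter in 1:50) {
    bad <- integer(0)
    badLen <- integer(0)
    for (mo in motifs) {
      st <- start(matchPattern(DNAString(mo), s, fixed = TRUE))
      planted <- protectedMask[st]
      bad <- c(bad, st[!planted])
      badLen <- c(badLen, rep(nchar(mo), sum(!planted)))
    }
    if (!length(bad)) break
    for (k in seq_along(bad)) {
      span <- bad[k]:(bad[k] + badLen[k] - 1L)
      free <- span[!protectedMask[span]]
      if (!length(free)) next
      at <- free[ceiling(length(free) / 2)]
      old <- as.character(subseq(s, at, at))
      repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      s <- replaceLetterAt(s, at, repl)
    }
  }
  s
}

#' Simulate a genome with planted restriction sites
#'
#' Generates random A/C/G/T chromosomes with the primary motif planted
#' at exponential spacings around `primarySpacing` and the secondary
#' motif around `secondarySpacing`, then removes accidental extra motif
#' occurrences (so the digest is exactly the planted map). Centromeres
#' are central intervals of width `cenFraction` of the chromosome.
#' Deterministic under the seed.
#'
#' @param config A [simulationConfig()] list.
#' @param seed Master seed; a genome-specific stream is derived.
#' @return A [GenomeModel-class]; the planted primary/secondary site
#'   positions (0-based starts) are attached as
#'   `metadata(centromeres(x))$plantedSites`.
#' @export
simulateGenome <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fourcSimConfig"))
  lens <- rep(config$chromLength, config$nChrom)
  names(lens) <- paste0("chr", seq_len(config$nChrom))
  pm <- config$primaryMotif; sm <- config$secondaryMotif
  pl <- nchar(pm); sl <- nchar(sm)
  minGapP <- 200
  if (config$primarySpacing <= minGapP)
    stop("primary spacing incompatible with minimum gap")
  seqChars <- character(0)
  planted <- list()
  for (chr in names(lens)) {
    len <- lens[[chr]]
    .withSeed(.subSeed(seed, paste0("genome:", chr)), {
      if (config$primarySpacing >= len) {
        pPos <- numeric(0)
      } else {
        gaps <- minGapP + rexp(ceiling(2 * len / config$primarySpacing),
          1 / (config$primarySpacing - minGapP))
        pPos <- cumsum(gaps)
        pPos <- round(pPos[pPos < len - pl - 10])
      }
      sGaps <- 20 + rexp(ceiling(2 * len / config$secondarySpacing),
        1 / (config$secondarySpacing - 20))
      sPos <- round(cumsum(sGaps))
      sPos <- sPos[sPos < len - sl - 10]
      nearPrimary <- vapply(sPos, function(p)
        any(abs(p - pPos) < pl + sl), logical(1))
      sPos <- sPos[!nearPrimary]
      bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      bases <- .stampMotif(bases, sPos, sm)
      bases <- .stampMotif(bases, pPos, pm)
      mask <- logical(len)
      for (p in pPos) mask[(p + 1L):(p + pl)] <- TRUE
      for (p in sPos) mask[(p + 1L):(p + sl)] <- TRUE
      s <- .scrubMotifs(paste(bases, collapse = ""), c(pm, sm), mask)
      seqChars[chr] <- as.character(s)
      planted[[chr]] <- list(primary = pPos, secondary = sPos)
    })
  }
  seqs <- DNAStringSet(seqChars)
  cs <- round(lens * (0.5 - config$cenFraction / 2))
  ce <- round(lens * (0.5 + config$cenFraction / 2))
  cen <- GRanges(names(lens), IRanges(cs + 1L, ce))
  metadata(cen)$plantedSites <- planted
  GenomeModel(seqs, cen)
}

#' Chromatin-state domains of a simulated genome
#'
#' Heterochromatin is modelled as the pericentromeric band: the region
#' within `hetHalfWidth * chromLength` of either centromere boundary
#' (centromere included); everything else is euchromatin. The domains
#' tile the genome.
#'
#' @param config A [simulationConfig()] list.
#' @param genome The simulated [GenomeModel-class].
#' @return A list with `het` and `eu` [GenomicRanges::GRanges].
#' @export
chromatinDomains <- function(config, genome) {
  cen <- centromeres(genome)
  lens <- chromLengths(genome)
  hw <- round(config$hetHalfWidth * lens[as.character(seqnames(cen))])
  het <- GRanges(seqnames(cen),
    IRanges(pmax(1, start(cen) - hw), pmin(lens[as.character(
      seqnames(cen))], end(cen) + hw)))
  eu <- GenomicRanges::setdiff(GRanges(names(lens), IRanges(1L, lens)),
    het)
  list(het = het, eu = eu)
}

# Chromatin state per fragment, by midpoint.
.fragmentStates <- function(map, domains) {
  fr <- map@fragments
  midGr <- GRanges(seqnames(fr), IRanges(floor(.midpoints(fr)) + 1L,
    width = 1L))
  st <- rep("eu", length(fr))
  st[S4Vectors::queryHits(findOverlaps(midGr, domains$het))] <- "het"
  st
}

#' Plan planted prey windows
#'
#' Chooses, for every viewpoint, `nPreyWindows` disjoint runs of
#' `preyFragments` consecutive fragments (in arm-index order) on
#' chromosomes other than the viewpoint's, restricted to fragments that
#' survive the standard centromere/secondary-site filters and whose
#' midpoints lie in domains matching the viewpoint's chromatin state.
#' Seeded and reproducible; prey windows of different viewpoints never
#' overlap.
#'
#' @param config A [simulationConfig()] list.
#' @param map An arm- and secondary-annotated [FragmentMap-class].
#' @param domains Output of [chromatinDomains()].
#' @param seed Master seed.
#' @return Named list per viewpoint: a list of integer `genome_index`
#'   vectors, one per planted window.
#' @export
planPreys <- function(config, map, domains, seed = 1L) {
  fr <- map@fragments
  m <- mcols(fr)
  states <- .fragmentStates(map, domains)
  s5 <- ifelse(is.na(m$sec5), Inf, m$sec5)
  s3 <- ifelse(is.na(m$sec3), Inf, m$sec3)
  okBase <- !is.na(m$arm) & !is.na(m$cen_dist) & m$cen_dist >= 1e5 &
    (s5 < 1000 | s3 < 1000) & width(fr) >= 30
  pf <- config$preyFragments
  taken <- logical(length(fr))
  plan <- list()
  for (k in seq_len(nrow(config$viewpoints))) {
    vrow <- config$viewpoints[k, ]
    ok <- okBase & as.character(seqnames(fr)) != vrow$chrom &
      states == vrow$state & !taken
    blocks <- list()
    for (a in unique(m$arm[ok])) {
      sel <- which(ok & m$arm == a)
      sel <- sel[order(m$arm_index[sel])]
      runs <- split(sel, cumsum(c(1L, diff(m$arm_index[sel]) != 1L)))
      for (r in runs) {
        nb <- length(r) %/% pf
        if (nb >= 1L)
          for (b in seq_len(nb))
            blocks[[length(blocks) + 1L]] <-
              r[((b - 1L) * pf + 1L):(b * pf)]
      }
    }
    if (length(blocks) < config$nPreyWindows)
      stop(sprintf("not enough candidate prey blocks for %s (%d < %d)",
        vrow$name, length(blocks), config$nPreyWindows))
    pick <- .withSeed(.subSeed(seed, paste0("preys:", vrow$name)),
      sample(length(blocks), config$nPreyWindows))
    chosen <- blocks[pick]
    taken[unlist(chosen)] <- TRUE
    plan[[vrow$name]] <- lapply(chosen, function(ix)
      m$genome_index[ix])
  }
  plan
}

#' Simulate a 4C read library for one viewpoint
#'
#' Draws `libSize` reads. A `selfLigation` fraction comes from the
#' viewpoint fragment; of the rest, a `cisFraction` share is drawn from
#' the viewpoint's arm with per-fragment probability proportional to
#' `d^gamma` (`d` = fragment-midpoint-to-viewpoint distance, truncated
#' to at least 1 kb), the remainder uniformly over the fragments of all
#' other arms (the cis arm included). Fragments inside the viewpoint's
#' planted prey windows carry `enrichment`-fold sampling mass
#' (renormalized). Each read is `primer + primary motif + the first 30
#' nt of a randomly chosen fragment end` (5' end forward, 3' end
#' reverse-complemented), i.e. it maps end-anchored to its source
#' fragment.
#'
#' @param config A [simulationConfig()] list.
#' @param genome The simulated [GenomeModel-class].
#' @param map The annotated [FragmentMap-class] of that genome.
#' @param viewpoint A [Viewpoint-class] (see [simulateExperiment()]).
#' @param preyWindows List of `genome_index` vectors of this viewpoint's
#'   planted prey windows (possibly empty).
#' @param sample Replicate identifier.
#' @param seed Master seed; the stream is derived from viewpoint and
#'   sample so replicates differ.
#' @param nReads Override `config$libSize`.
#' @return A list with `reads` (full-length [Biostrings::DNAStringSet])
#'   and `truth` (data.frame `fragment`, `class` in
#'   self/cis/trans/prey).
#' @export
simulateReads <- function(config, genome, map, viewpoint,
    preyWindows = list(), sample = "A", seed = 1L, nReads = NULL) {
  fr <- map@fragments
  m <- mcols(fr)
  mid <- .midpoints(fr)
  if (is.null(nReads)) nReads <- config$libSize
  vi <- match(viewpoint@fragment, m$genome_index)
  vpArm <- m$arm[vi]
  if (is.na(vpArm)) stop("viewpoint fragment has no arm")
  wide <- width(fr) >= 30
  cisSel <- which(m$arm %in% vpArm & wide)
  dCis <- pmax(abs(mid[cisSel] - viewpoint@position), 1000)
  keep <- cisSel != vi
  cisSel <- cisSel[keep]; dCis <- dCis[keep]
  wCis <- dCis^config$gamma
  transSel <- which(!is.na(m$arm) & m$arm != vpArm & wide)
  wTrans <- rep(1, length(transSel))
  preyIdx <- match(unlist(preyWindows), m$genome_index)
  wCis[cisSel %in% preyIdx] <- wCis[cisSel %in% preyIdx] *
    config$enrichment
  wTrans[transSel %in% preyIdx] <- wTrans[transSel %in% preyIdx] *
    config$enrichment
  if (!length(cisSel) && !length(transSel))
    stop("no eligible fragments to sample reads from")
  .withSeed(.subSeed(seed, paste0("reads:", viewpoint@name, ":", sample)), {
    cls <- sample(c("self", "cis", "trans"), nReads, replace = TRUE,
      prob = c(config$selfLigation,
        (1 - config$selfLigation) * config$cisFraction,
        (1 - config$selfLigation) * (1 - config$cisFraction)))
    nSelf <- sum(cls == "self"); nCis <- sum(cls == "cis")
    nTrans <- sum(cls == "trans")
    srcFrag <- c(rep(vi, nSelf),
      if (nCis) sample(cisSel, nCis, replace = TRUE, prob = wCis)
      else integer(0),
      if (nTrans) sample(transSel, nTrans, replace = TRUE,
        prob = wTrans) else integer(0))
    fromEnd3 <- sample(c(FALSE, TRUE), length(srcFrag), replace = TRUE)
  })
  cls <- c(rep("self", nSelf), rep("cis", nCis), rep("trans", nTrans))
  cls[srcFrag %in% preyIdx] <- "prey"
  seq30 <- character(length(srcFrag))
  chrom <- as.character(seqnames(fr))
  for (chr in unique(chrom[srcFrag])) {
    s <- genome@sequences[[chr]]
    i5 <- which(chrom[srcFrag] == chr & !fromEnd3)
    i3 <- which(chrom[srcFrag] == chr & fromEnd3)
    if (length(i5)) {
      at <- IRanges(start(fr)[srcFrag[i5]], width = 30L)
      seq30[i5] <- as.character(Biostrings::extractAt(s, at))
    }
    if (length(i3)) {
      at <- IRanges(end = end(fr)[srcFrag[i3]], width = 30L)
      seq30[i3] <- as.character(reverseComplement(
        Biostrings::extractAt(s, at)))
    }
  }
  reads <- DNAStringSet(paste0(viewpoint@primerSeq, config$primaryMotif,
    seq30))
  names(reads) <- sprintf("read%07d", seq_along(reads))
  truth <- data.frame(read = names(reads),
    fragment = m$genome_index[srcFrag], class = cls)
  list(reads = reads, truth = truth)
}

#' Simulate chromatin-state-dependent feature density tracks
#'
#' Per fragment and feature, a density in \[0,1\] is drawn from a Beta
#' distribution whose mean depends on the fragment's chromatin state:
#' heterochromatic marks have mean `densityMeans$high` in
#' heterochromatin and `densityMeans$low` in euchromatin, euchromatic
#' marks the mirror image, neutral features `densityMeans$neutral`
#' everywhere. Deterministic under the seed.
#'
#' @param config A [simulationConfig()] list.
#' @param map The annotated [FragmentMap-class].
#' @param domains Output of [chromatinDomains()].
#' @param seed Master seed.
#' @return A list with `features` (named list of per-fragment density
#'   vectors), `states` (per-fragment `"eu"`/`"het"`) and `domains`.
#' @export
simulateEmd <- function(config, map, domains, seed = 1L) {
  states <- .fragmentStates(map, domains)
  conc <- config$betaConcentration
  if (conc <= 0) stop("betaConcentration must be positive")
  n <- nFragments(map)
  feats <- list()
  for (k in seq_len(nrow(config$features))) {
    frow <- config$features[k, ]
    mu <- switch(frow$type,
      het = ifelse(states == "het", config$densityMeans$high,
        config$densityMeans$low),
      eu = ifelse(states == "eu", config$densityMeans$high,
        config$densityMeans$low),
      neutral = rep(config$densityMeans$neutral, n),
      stop("unknown feature type: ", frow$type))
    if (any(mu <= 0 | mu >= 1)) stop("Beta means must lie in (0,1)")
    feats[[frow$name]] <- .withSeed(
      .subSeed(seed, paste0("emd:", frow$name)),
      rbeta(n, mu * conc, (1 - mu) * conc))
  }
  list(features = feats, states = states, domains = domains)
}

#' Run the full synthetic-data generator
#'
#' Generates the genome, digests and annotates the fragment map, plans
#' planted preys, simulates one read library per viewpoint and
#' replicate and the feature density tracks, and returns everything
#' with its truth tables. All stages derive named sub-streams from the
#' master seed, so each is independently reproducible.
#'
#' @param config A [simulationConfig()] list.
#' @param seed Master seed.
#' @param nReplicates Libraries per viewpoint (default 1).
#' @return A list: `config`, `genome`, `map` (annotated, unfiltered),
#'   `domains`, `viewpoints` (list of [Viewpoint-class]), `preyPlan`,
#'   `libraries` (per viewpoint x replicate: `reads`, `truth`,
#'   `viewpoint`, `sample`), `emd`.
#' @export
simulateExperiment <- function(config = simulationConfig(), seed = 1L,
    nReplicates = 1L) {
  genome <- simulateGenome(config, seed)
  map <- digestGenome(genome, config$primaryMotif,
    config$primaryCutOffset)
  map <- annotateArms(map)
  map <- annotateSecondary(map, genome, config$secondaryMotif)
  domains <- chromatinDomains(config, genome)
  vps <- lapply(seq_len(nrow(config$viewpoints)), function(k) {
    vrow <- config$viewpoints[k, ]
    pos <- round(vrow$relPos * chromLengths(genome)[[vrow$chrom]])
    Viewpoint(vrow$name, vrow$chrom, pos, vrow$primer, map = map,
      secondaryMotif = config$secondaryMotif)
  })
  names(vps) <- config$viewpoints$name
  preyPlan <- planPreys(config, map, domains, seed)
  libraries <- list()
  for (vp in vps) {
    for (r in seq_len(nReplicates)) {
      sampleId <- LETTERS[r]
      lib <- simulateReads(config, genome, map, vp,
        preyWindows = preyPlan[[vp@name]], sample = sampleId,
        seed = seed)
      libraries[[paste0(vp@name, ".", sampleId)]] <- c(lib,
        list(viewpoint = vp@name, sample = sampleId))
    }
  }
  emd <- simulateEmd(config, map, domains, seed)
  list(config = config, genome = genome, map = map, domains = domains,
    viewpoints = vps, preyPlan = preyPlan, libraries = libraries,
    emd = emd)
}
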