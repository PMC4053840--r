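# Shared fixtures and independent oracles, built in code at test time.

suppressMessages({
  library(GenomicRanges)
  library(Biostrings)
})

.fx <- new.env()

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
  replace = TRUE), collapse = "")

# Brute-force digest oracle: scan every position for the motif, cut at
# site start + cutOffset; returns 0-based half-open fragments.
naiveDigest <- function(seq, motif, cutOffset) {
  len <- nchar(seq); ml <- nchar(motif)
  sites <- integer(0)
  if (len >= ml)
    for (i in seq_len(len - ml + 1L))
      if (substr(seq, i, i + ml - 1L) == motif) sites <- c(sites, i)
  cuts <- sites - 1L + cutOffset
  b <- sort(unique(c(0L, cuts[cuts > 0L & cuts < len], len)))
  data.frame(start = head(b, -1L), end = b[-1L])
}

# Remove all occurrences of a motif from a string (for constructing
# sequences with sites only where planted).
naiveScrub <- function(s, motif) {
  repl <- if (substr(motif, 2, 2) == "A") "C" else "A"
  repeat {
    i <- regexpr(motif, s, fixed = TRUE)
    if (i < 0) break
    substr(s, i + 1L, i + 1L) <- repl
  }
  s
}

# Per-base boolean-mask coverage oracle for EMD densities.
naiveEmd <- function(intervals0, fragStart0, fragEnd0) {
  mask <- logical(fragEnd0 - fragStart0)
  for (k in seq_len(nrow(intervals0))) {
    s <- max(intervals0$start[k], fragStart0)
    e <- min(intervals0$end[k], fragEnd0)
    if (e > s) mask[(s - fragStart0 + 1L):(e - fragStart0)] <- TRUE
  }
  mean(mask)
}

# One-arm arithmetic fragment map with nFrag fragments of fragLen bp,
# arm to the right of a token centromere at the chromosome start.
armMap <- function(nFrag, fragLen = 100L, chrom = "chrA") {
  frags <- data.frame(chrom = chrom,
    start = (seq_len(nFrag) - 1L) * fragLen,
    end = seq_len(nFrag) * fragLen)
  makeFragmentMap(frags,
    centromeres = data.frame(chrom = chrom, start = 0L,
      end = min(fragLen %/% 2L, 50L)))
}

countsOn <- function(map, counts, viewpoint = "vp", sample = "A") {
  new("FragmentCounts", viewpoint = viewpoint, sample = sample,
    counts = as.numeric(counts), librarySize = sum(counts),
    tallies = list())
}

# Shared small simulation: two 0.8 Mb chromosomes, two euchromatic
# viewpoints, two replicates, planted preys of 10 fragments.
toySimConfig <- function() {
  simulationConfig(nChrom = 2L, chromLength = 8e5, libSize = 20000,
    nPreyWindows = 2L, preyFragments = 10L,
    viewpoints = data.frame(name = c("vpEu", "vpTwo"),
      chrom = c("chr1", "chr2"), relPos = c(0.75, 0.75),
      state = c("eu", "eu"),
      primer = c("ACGTACGTACGTACGTACCA", "TGCATGCATGCATGCATGGT"),
      stringsAsFactors = FALSE))
}

toySim <- function() {
  if (is.null(.fx$sim))
    .fx$sim <- simulateExperiment(toySimConfig(), seed = 101L,
      nReplicates = 2L)
  .fx$sim
}

# Demultiplexed/mapped/counted library from the shared simulation.
toyCounts <- function(key = "vpEu.A") {
  slot <- paste0("counts_", key)
  if (is.null(.fx[[slot]])) {
    sim <- toySim()
    lib <- sim$libraries[[key]]
    dm <- demultiplex(lib$reads, sim$viewpoints,
      sim$config$primaryMotif, sample = lib$sample)
    aln <- mapReadsExact(dm$reads[[lib$viewpoint]], sim$genome)
    cr <- countFragmentReads(aln, sim$map, viewpoint = lib$viewpoint,
      sample = lib$sample)
    .fx[[slot]] <- allocateMultireads(cr$multireads, cr$counts,
      sim$map)
  }
  .fx[[slot]]
}
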