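#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#'   elementNROWS
#' @importFrom GenomicRanges strand granges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect reduce
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom Biostrings DNAString DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet matchPattern vmatchPattern reverseComplement subseq
#'   alphabetFrequency width PDict matchPDict replaceLetterAt
#' @importFrom stats cor cor.test hclust as.dist lm loess loess.control
#'   coef predict pnorm p.adjust prcomp rbeta rbinom rexp runif sd t.test
#'   setNames quantile aggregate reshape
#' @importFrom utils head read.table write.table
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' GenomeModel: genome sequences plus centromere intervals
#'
#' Container for the reference a 4C analysis runs against: one DNA sequence
#' per chromosome and exactly one (pre-merged) centromere interval per
#' chromosome. Coordinates follow the Bioconductor convention (1-based,
#' closed) internally; BED input/output is converted automatically.
#'
#' @slot sequences A named [Biostrings::DNAStringSet], one entry per
#'   chromosome. Alphabet must be within A, C, G, T, N.
#' @slot centromeres A [GenomicRanges::GRanges] with at most one interval per
#'   chromosome, each contained in its chromosome.
#'
#' @seealso [GenomeModel()], [readGenome()], [digestGenome()]
#' @export
setClass("GenomeModel",
  representation(sequences = "DNAStringSet", centromeres = "GRanges"))

setValidity("GenomeModel", function(object) {
  msg <- character()
  nm <- names(object@sequences)
  if (length(object@sequences) == 0L)
    msg <- c(msg, "genome must contain at least one chromosome")
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "chromosome names must be present and unique")
  af <- alphabetFrequency(object@sequences, collapse = TRUE)
  bad <- sum(af) - sum(af[c("A", "C", "G", "T", "N")])
  if (!is.na(bad) && bad > 0)
    msg <- c(msg, "sequence alphabet must be within {A,C,G,T,N}")
  cen <- object@centromeres
  if (length(cen)) {
    cchr <- as.character(seqnames(cen))
    if (anyDuplicated(cchr))
      msg <- c(msg, "at most one centromere interval per chromosome")
    if (!all(cchr %in% nm))
      msg <- c(msg, "centromere chromosome absent from genome")
    lens <- setNames(width(object@sequences), nm)
    if (any(start(cen) < 1L) || any(end(cen) > lens[cchr]))
      msg <- c(msg, "centromere interval outside chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentMap: annotated in-silico restriction fragments
#'
#' The ordered restriction-fragment tiling of a genome produced by
#' [digestGenome()], progressively annotated with chromosome-arm
#' assignments ([annotateArms()]), distances to the first secondary
#' restriction site from either fragment end ([annotateSecondary()]) and a
#' per-viewpoint validity flag ([filterFragments()]).
#'
#' Fragment metadata columns: `genome_index` (1-based rank over the whole
#' genome), `arm` (e.g. `"chr1S"`/`"chr1L"`, `NA` for centromeric
#' fragments), `arm_index` (rank of increasing centromere distance within
#' the arm), `cen_dist` (bp, fragment midpoint to nearest centromere
#' boundary), `centromeric` (logical), `sec5`/`sec3` (bp from fragment
#' 5'/3' end to the first secondary site inside the fragment; `NA` = no
#' site), `valid` (logical, viewpoint-specific).
#'
#' @slot fragments A [GenomicRanges::GRanges] tiling each chromosome
#'   without gaps or overlaps, carrying the metadata columns above.
#' @slot primaryMotif,cutOffset Primary enzyme recognition motif and the
#'   0-based cut offset within it (HindIII `AAGCTT`/1, DpnII `GATC`/0).
#' @slot secondaryMotif Secondary enzyme motif once annotated, else `NA`.
#' @slot centromeres Centromere intervals used by [annotateArms()].
#'
#' @seealso [digestGenome()], [makeFragmentMap()], [filterFragments()]
#' @export
setClass("FragmentMap",
  representation(fragments = "GRanges", primaryMotif = "character",
    cutOffset = "integer", secondaryMotif = "character",
    centromeres = "GRanges"))

setValidity("FragmentMap", function(object) {
  msg <- character()
  fr <- object@fragments
  need <- c("genome_index", "arm", "arm_index", "cen_dist", "centromeric",
    "sec5", "sec3", "valid")
  if (!all(need %in% colnames(mcols(fr))))
    msg <- c(msg, "fragment metadata columns incomplete")
  if (length(fr)) {
    if (any(width(fr) < 1L)) msg <- c(msg, "zero-width fragment")
    sp <- split(fr, seqnames(fr))
    for (chr in names(sp)) {
      g <- sp[[chr]]
      if (length(g) == 0L) next
      o <- order(start(g))
      if (any(start(g)[o][-1L] != end(g)[o][-length(g)] + 1L))
        msg <- c(msg, sprintf("fragments do not tile chromosome %s", chr))
    }
    gi <- mcols(fr)$genome_index
    if (!identical(as.integer(gi), seq_along(fr)))
      msg <- c(msg, "genome_index must be 1..n in order")
  }
  if (length(msg)) msg else TRUE
})

#' Viewpoint: the anchor fragment of a 4C library
#'
#' @slot name Viewpoint identifier.
#' @slot chrom,position Genomic location (1-based bp) of the viewpoint;
#'   must fall inside the referenced fragment.
#' @slot fragment `genome_index` of the viewpoint's restriction fragment.
#' @slot primerSeq Reading primer used for demultiplexing (exact match).
#' @slot secondaryMotif Secondary restriction enzyme motif for this
#'   viewpoint's library design.
#'
#' @seealso [Viewpoint()], [demultiplex()], [filterFragments()]
#' @export
setClass("Viewpoint",
  representation(name = "character", chrom = "character",
    position = "numeric", fragment = "integer", primerSeq = "character",
    secondaryMotif = "character"))

setValidity("Viewpoint", function(object) {
  msg <- character()
  if (!nzchar(object@primerSeq)) msg <- c(msg, "primerSeq must be non-empty")
  if (length(msg)) msg else TRUE
})

#' FragmentCounts: per-fragment 4C read counts for one library
#'
#' Read counts over the fragments of a [FragmentMap] for a single
#' viewpoint/replicate library. Counts may be fractional after
#' [allocateMultireads()]. Counts on invalid fragments are retained; the
#' validity flag is applied downstream by the window machinery.
#'
#' @slot viewpoint,sample Library identity.
#' @slot counts Non-negative numeric vector over `genome_index`.
#' @slot librarySize Total of `counts`.
#' @slot tallies Named list of processing tallies (off-end, discarded
#'   multireads, ...).
#'
#' @seealso [countFragmentReads()], [windowValues()]
#' @export
setClass("FragmentCounts",
  representation(viewpoint = "character", sample = "character",
    counts = "numeric", librarySize = "numeric", tallies = "list"))

setValidity("FragmentCounts", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@counts) &&
      abs(object@librarySize - sum(object@counts)) > 1e-6)
    msg <- c(msg, "librarySize must equal sum of counts")
  if (length(msg)) msg else TRUE
})

#' WindowTrack: fragment windows with interaction values and P-values
#'
#' Sliding or blocked windows of `size` valid fragments (stepping by
#' `step` fragments) built per chromosome arm over a filtered
#' [FragmentMap]. Window columns: `arm`, `chrom`, `start`, `end` (bp span,
#' 1-based closed), `firstIdx` (offset of the first member fragment within
#' the arm's valid-fragment list), `readSum`, `value` (interaction value,
#' sum of log2 counts), `valueScaled` (per million library reads), `P`
#' (final shuffle-null P), `prey` (logical call).
#'
#' @slot windows A [S4Vectors::DataFrame] of windows, ordered by arm then
#'   `arm_index` of the first member fragment.
#' @slot armFragments Named list: per arm, the `genome_index` vector of its
#'   valid fragments in `arm_index` order (window membership is
#'   `armFragments[[arm]][firstIdx..firstIdx+size-1]`).
#' @slot size,step Window geometry in fragments.
#' @slot viewpoint,sample,librarySize Library identity once values are
#'   attached.
#' @slot nShuffles,seed Null-model bookkeeping once P-values are attached.
#'
#' @seealso [buildWindows()], [windowValues()], [shufflePvalues()],
#'   [callPreys()]
#' @export
setClass("WindowTrack",
  representation(windows = "DataFrame", armFragments = "list",
    size = "integer", step = "integer", viewpoint = "character",
    sample = "character", librarySize = "numeric", nShuffles = "integer",
    seed = "integer"))

setValidity("WindowTrack", function(object) {
  msg <- character()
  w <- object@windows
  if (nrow(w)) {
    if (any(!is.na(w$P) & (w$P < 0 | w$P > 1)))
      msg <- c(msg, "P must lie in [0,1]")
    if (any(!is.na(w$value) & w$value < 0))
      msg <- c(msg, "interaction values must be non-negative")
  }
  if (object@size < 1L || object@step < 1L)
    msg <- c(msg, "size and step must be >= 1")
  if (length(msg)) msg else TRUE
})

#' DecayProfile: binned contact probability versus genomic distance
#'
#' Log10-binned cis contact probabilities around one or more viewpoints
#' (41 bins of width 0.1 log10 over 1 kb - 10 Mb by default), optionally
#' LOESS-smoothed, with the fitted power-law decay exponent.
#'
#' @slot bins A [S4Vectors::DataFrame] with `center` (log10 bp),
#'   `rawProb`, `smoothProb`, `nReads`, `nFragments` per bin; `rawProb`
#'   sums to 1.
#' @slot slope,fitP Fitted decay exponent (slope of log10 probability on
#'   log10 distance) and the p-value of the linear fit; `NA` until
#'   [fitDecayExponent()] is run.
#' @slot dMin,dMax,binWidth Binning parameters (bp, bp, log10 units).
#'
#' @seealso [decayProfile()], [fitDecayExponent()]
#' @export
setClass("DecayProfile",
  representation(bins = "DataFrame", slope = "numeric", fitP = "numeric",
    dMin = "numeric", dMax = "numeric", binWidth = "numeric"))

setValidity("DecayProfile", function(object) {
  msg <- character()
  b <- object@bins
  if (nrow(b)) {
    if (is.unsorted(b$center)) msg <- c(msg, "bins must be ordered ascending")
    if (abs(sum(b$rawProb) - 1) > 1e-8)
      msg <- c(msg, "rawProb must sum to 1")
  }
  if (length(msg)) msg else TRUE
})
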