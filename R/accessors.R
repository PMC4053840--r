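#' @describeIn GenomeModel-class Chromosome sequences as a DNAStringSet.
#' @export
setMethod("fragments", "GenomeModel", function(x) x@sequences)

#' @describeIn GenomeModel-class Centromere intervals.
#' @export
setMethod("centromeres", "GenomeModel", function(x) x@centromeres)

#' @describeIn GenomeModel-class Named chromosome lengths (bp).
#' @export
setMethod("chromLengths", "GenomeModel",
  function(x) setNames(width(x@sequences), names(x@sequences)))

#' @describeIn FragmentMap-class Fragment GRanges with all annotations.
#' @export
setMethod("fragments", "FragmentMap", function(x) x@fragments)

#' @describeIn FragmentMap-class Number of fragments in the map.
#' @export
setMethod("nFragments", "FragmentMap", function(x) length(x@fragments))

#' @describeIn FragmentMap-class Centromere intervals used for arm
#'   annotation (empty before [annotateArms()]).
#' @export
setMethod("centromeres", "FragmentMap", function(x) x@centromeres)

#' @describeIn FragmentCounts-class Numeric count vector over
#'   `genome_index`.
#' @export
setMethod("fragmentCounts", "FragmentCounts", function(x) x@counts)

#' @describeIn FragmentCounts-class Total read count of the library.
#' @export
setMethod("librarySize", "FragmentCounts", function(x) x@librarySize)

#' @describeIn WindowTrack-class Window table as a DataFrame.
#' @export
setMethod("windowTable", "WindowTrack", function(x) x@windows)

#' @describeIn WindowTrack-class Interaction values per window.
#' @export
setMethod("windowValuesOf", "WindowTrack", function(x) x@windows$value)

#' @describeIn WindowTrack-class Final shuffle-null P-values per window.
#' @export
setMethod("pvalues", "WindowTrack", function(x) x@windows$P)

#' @describeIn WindowTrack-class Logical prey flag per window.
#' @export
setMethod("preyCalls", "WindowTrack", function(x) x@windows$prey)

#' @describeIn DecayProfile-class Fitted interaction decay exponent.
#' @export
setMethod("decaySlope", "DecayProfile", function(x) x@slope)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", length(object@sequences), "chromosome(s),",
    sum(width(object@sequences)), "bp total,",
    length(object@centromeres), "centromere interval(s)\n")
})

setMethod("show", "FragmentMap", function(object) {
  fr <- object@fragments
  cat("FragmentMap:", length(fr), "fragments on",
    length(unique(as.character(seqnames(fr)))), "chromosome(s)\n")
  cat("  primary motif:", object@primaryMotif,
    "(cut offset", paste0(object@cutOffset, ")"),
    "| secondary motif:", object@secondaryMotif, "\n")
  if (length(fr)) {
    cat("  arm-annotated:", !all(is.na(mcols(fr)$arm)),
      "| valid fragments:", sum(mcols(fr)$valid, na.rm = TRUE), "\n")
  }
})

setMethod("show", "Viewpoint", function(object) {
  cat("Viewpoint", object@name, "at", object@chrom, object@position,
    "(fragment", paste0(object@fragment, ")"), "\n")
})

setMethod("show", "FragmentCounts", function(object) {
  cat("FragmentCounts:", object@viewpoint, "/", object@sample, "-",
    length(object@counts), "fragments, library size",
    round(object@librarySize, 2), "\n")
})

setMethod("show", "WindowTrack", function(object) {
  w <- object@windows
  cat("WindowTrack:", nrow(w), "windows (size", object@size, "step",
    paste0(object@step, ")"), "over", length(object@armFragments),
    "arm(s)\n")
  if (nrow(w) && any(!is.na(w$P)))
    cat("  P-values from", object@nShuffles, "shuffles; preys called:",
      sum(w$prey, na.rm = TRUE), "\n")
})

setMethod("show", "DecayProfile", function(object) {
  cat("DecayProfile:", nrow(object@bins), "bins over",
    object@dMin, "-", object@dMax, "bp; slope:",
    if (is.na(object@slope)) "unfitted" else round(object@slope, 3), "\n")
})
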