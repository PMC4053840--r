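#' @rdname FragmentMap-class
#' @param x A fourCarch object.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentMap-class
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))

#' @rdname FragmentCounts-class
#' @param x A fourCarch object.
#' @export
setGeneric("fragmentCounts", function(x) standardGeneric("fragmentCounts"))

#' @rdname FragmentCounts-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname WindowTrack-class
#' @param x A fourCarch object.
#' @export
setGeneric("windowTable", function(x) standardGeneric("windowTable"))

#' @rdname WindowTrack-class
#' @export
setGeneric("windowValuesOf", function(x) standardGeneric("windowValuesOf"))

#' @rdname WindowTrack-class
#' @export
setGeneric("pvalues", function(x) standardGeneric("pvalues"))

#' @rdname WindowTrack-class
#' @export
setGeneric("preyCalls", function(x) standardGeneric("preyCalls"))

#' @rdname DecayProfile-class
#' @param x A fourCarch object.
#' @export
setGeneric("decaySlope", function(x) standardGeneric("decaySlope"))

#' @rdname GenomeModel-class
#' @param x A fourCarch object.
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))

#' @rdname GenomeModel-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
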