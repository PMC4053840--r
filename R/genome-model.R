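#' Construct a GenomeModel
#'
#' @param sequences A named [Biostrings::DNAStringSet] or a named character
#'   vector of chromosome sequences.
#' @param centromeres Centromere intervals: a [GenomicRanges::GRanges] or a
#'   data.frame with columns `chrom`, `start`, `end` in 0-based half-open
#'   (BED) convention. One interval per chromosome; pre-merge multi-interval
#'   assemblies.
#' @return A [GenomeModel-class] object.
#' @examples
#' gm <- GenomeModel(c(chr1 = "GGGAAGCTTGGG"),
#'   data.frame(chrom = "chr1", start = 5, end = 7))
#' chromLengths(gm)
#' @export
GenomeModel <- function(sequences, centromeres = GRanges()) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (is.data.frame(centromeres)) {
    centromeres <- GRanges(centromeres$chrom,
      IRanges(centromeres$start + 1L, centromeres$end))
  }
  new("GenomeModel", sequences = sequences, centromeres = centromeres)
}

#' Read a genome from FASTA plus a centromere BED file
#'
#' @param fasta Path to a (multi-record, line-wrapped) FASTA file.
#' @param centromereBed Path to a 3-column BED file of centromere
#'   intervals (0-based half-open), or `NULL` for none.
#' @return A [GenomeModel-class] object.
#' @export
readGenome <- function(fasta, centromereBed = NULL) {
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cen <- GRanges()
  if (!is.null(centromereBed)) {
    tab <- read.table(centromereBed, sep = "\t", header = FALSE,
      col.names = c("chrom", "start", "end")[1:3],
      colClasses = c("character", "integer", "integer"))
    cen <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
  }
  GenomeModel(seqs, cen)
}

#' Construct a Viewpoint
#'
#' @param name Viewpoint identifier.
#' @param chrom,position Genomic location (1-based bp).
#' @param primerSeq Exact reading-primer sequence.
#' @param map Optional [FragmentMap-class]; when given, the viewpoint's
#'   fragment `genome_index` is located automatically and the position is
#'   checked to lie inside it.
#' @param fragment `genome_index` of the viewpoint fragment (required when
#'   `map` is not given and fragment-level operations will be used).
#' @param secondaryMotif Secondary restriction enzyme motif (e.g. `GATC`).
#' @return A [Viewpoint-class] object.
#' @export
Viewpoint <- function(name, chrom, position, primerSeq, map = NULL,
    fragment = NA_integer_, secondaryMotif = NA_character_) {
  if (!is.null(map)) {
    fr <- fragments(map)
    hit <- which(as.character(seqnames(fr)) == chrom &
      start(fr) <= position & end(fr) >= position)
    if (length(hit) != 1L)
      stop("viewpoint position does not fall inside exactly one fragment")
    fragment <- mcols(fr)$genome_index[hit]
  }
  new("Viewpoint", name = as.character(name), chrom = as.character(chrom),
    position = as.numeric(position), fragment = as.integer(fragment),
    primerSeq = toupper(as.character(primerSeq)),
    secondaryMotif = as.character(secondaryMotif))
}
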