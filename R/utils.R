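# Internal helpers shared across modules.

.checkMotif <- function(motif, minLen = 1L) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop("motif must be a single character string")
  if (nchar(motif) < minLen)
    stop(sprintf("motif must be at least %d bp", minLen))
  if (grepl("[^ACGT]", motif))
    stop("motif may only contain A, C, G, T")
  invisible(motif)
}

# Deterministic sub-seed derived from a master seed and a text tag, so each
# randomized stage (genome, reads per library, shuffles per arm, ...) has
# its own reproducible stream. Kept below 2^31 - 1.
.subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_len(nchar(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Fragment midpoints as continuous bp coordinates ((start0 + end0)/2 in
# half-open terms; may end in .5, kept numeric on purpose).
.midpoints <- function(gr) (start(gr) - 1 + end(gr)) / 2

.emptyFragmentMcols <- function(n) {
  DataFrame(genome_index = seq_len(n), arm = rep(NA_character_, n),
    arm_index = rep(NA_integer_, n), cen_dist = rep(NA_real_, n),
    centromeric = rep(NA, n), sec5 = rep(NA_real_, n),
    sec3 = rep(NA_real_, n), valid = rep(TRUE, n))
}
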