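mkVp <- function(name, primer) {
  Viewpoint(name, "chr1", 1, primer, fragment = 1L)
}

test_that("demultiplexing assigns exact primer+site reads and partitions the input", {
  vps <- list(mkVp("a", "ACGTACGTAC"), mkVp("b", "TGCATGCATG"))
  tail40 <- randomSeq(40)
  reads <- DNAStringSet(c(
    paste0("ACGTACGTAC", "AAGCTT", tail40),       # a, fine
    paste0("ACGTACGTAG", "AAGCTT", tail40),       # 1 mismatch in primer
    paste0("TGCATGCATG", "AAGCTT", randomSeq(29)),# b but remainder < 30
    paste0("TGCATGCATG", "GGGGGG", tail40),       # b but no site
    randomSeq(46)))                               # no primer
  dm <- demultiplex(reads, vps, "AAGCTT")
  expect_equal(unname(dm$tallies["a"]), 1L)
  expect_equal(unname(dm$tallies["b"]), 0L)
  expect_equal(unname(dm$tallies["no_primer"]), 2L)
  expect_equal(unname(dm$tallies["too_short"]), 1L)
  expect_equal(unname(dm$tallies["no_site"]), 1L)
  expect_equal(sum(dm$tallies), length(reads))
  expect_equal(as.character(dm$reads$a[[1]]), substr(tail40, 1, 30))
  expect_equal(unique(width(dm$reads$a)), 30L)
  expect_error(demultiplex(reads, list(mkVp("a", "ACGT"),
    mkVp("b", "ACGT")), "AAGCTT"), "identical primer")
})

test_that("ambiguous reads matching two primers are discarded", {
  vps <- list(mkVp("a", "ACGTAC"), mkVp("b", "ACGTACGTAC"))
  reads <- DNAStringSet(paste0("ACGTACGTAC", "AAGCTT", randomSeq(30)))
  dm <- demultiplex(reads, vps, "AAGCTT")
  expect_equal(unname(dm$tallies["ambiguous"]), 1L)
  expect_equal(sum(dm$tallies), 1L)
})

test_that("exact mapping reports position, strand and multiplicity", {
  set.seed(7)
  core <- randomSeq(2000)
  probe <- substr(core, 101, 130)
  # plant the probe a second time and its reverse complement once
  rc <- as.character(reverseComplement(DNAString(probe)))
  gseq <- paste0(core, probe, randomSeq(50), rc, randomSeq(20))
  gm <- GenomeModel(c(chr1 = gseq))
  reads <- DNAStringSet(c(unique1 = substr(core, 501, 530),
    multi = probe, absent = naiveScrub(paste0(randomSeq(30)), "ACGT")))
  # the "absent" read may occur by chance; make it impossible
  reads[[3]] <- DNAStringSet(paste0(strrep("AC", 15)))[[1]]
  aln <- mapReadsExact(reads, gm)
  h1 <- aln$hits[aln$hits$seqId == match(as.character(reads[[1]]),
    unique(as.character(reads))), ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$start, 501L)
  expect_equal(h1$strand, "+")
  hm <- aln$hits[aln$hits$nHits == 3L, ]
  expect_equal(sort(hm$strand), sort(c("-", "+", "+")))
  expect_equal(sort(hm$start[hm$strand == "+"]), c(101L, 2001L))
  expect_equal(unname(aln$tallies["unmapped"]), 1L)
  expect_error(mapReadsExact(DNAStringSet(c("ACGT", "ACGTACGT")), gm),
    "identical length")
})

test_that("reads beyond the repeat cap are discarded", {
  unit <- randomSeq(30)
  gm <- GenomeModel(c(chr1 = paste0(strrep(paste0(unit, randomSeq(10)),
    5), randomSeq(100))))
  aln <- mapReadsExact(DNAStringSet(unit), gm, maxHits = 3L)
  expect_equal(unname(aln$tallies["discarded_repeat"]), 1L)
  expect_equal(nrow(aln$hits), 0L)
})

test_that("fragment counting is strictly end-anchored and conserves hits", {
  sim <- toySim()
  fr <- fragments(sim$map)
  chr1len <- chromLengths(sim$genome)[["chr1"]]
  f10 <- fr[10]
  aln <- structure(list(hits = data.frame(
    seqId = 1:4,
    chrom = "chr1",
    start = c(start(f10),                 # fwd at 5' boundary
      start(f10) + 5L,                    # interior
      end(f10) - 29L,                     # rev ending at 3' boundary
      start(f10) + 1L),                   # rev not at boundary
    strand = c("+", "+", "-", "-"),
    nHits = 1L), seqReads = rep(1L, 4), readLength = 30L,
    tallies = c(unmapped = 0L, discarded_repeat = 0L)),
    class = "fourcAlignments")
  cr <- countFragmentReads(aln, sim$map)
  expect_equal(cr$counts@counts[10], 2)   # 5'-fwd and 3'-rev anchored
  expect_equal(cr$counts@tallies$counted, 2)
  expect_equal(cr$counts@tallies$off_end, 2)
  expect_equal(cr$counts@tallies$counted + cr$counts@tallies$off_end,
    4)
  badAln <- aln
  badAln$hits$start[1] <- chr1len - 10L
  expect_error(countFragmentReads(badAln, sim$map), "beyond")
})

test_that("synthetic end-anchored reads recover their source fragments exactly", {
  sim <- toySim()
  fc <- toyCounts("vpEu.A")
  truth <- sim$libraries$vpEu.A$truth
  tc <- as.numeric(table(factor(truth$fragment,
    levels = seq_len(nFragments(sim$map)))))
  # error-free unique reads: every read countable and placed correctly
  expect_equal(fc@librarySize, nrow(truth))
  expect_equal(fc@counts, tc, tolerance = 1e-12)
})

test_that("multiread allocation is proportional to local unique mass", {
  map <- armMap(100, fragLen = 1000L)
  unique <- numeric(100)
  unique[13:17] <- 6                      # 30 reads near candidate A (15)
  unique[59:63] <- 2                      # 10 reads near candidate B (61)
  fc <- countsOn(map, unique)
  multi <- data.frame(nReads = 2L)
  multi$candidates <- list(c(15L, 61L))
  out <- allocateMultireads(multi, fc, map, allocationDistance = 5e3)
  added <- out@counts - fc@counts
  expect_equal(sum(added), 2)
  expect_equal(added[15], 2 * 0.75)
  expect_equal(added[61], 2 * 0.25)

  # no unique support anywhere near: discarded
  multi2 <- data.frame(nReads = 5L)
  multi2$candidates <- list(c(15L, 61L))
  empty <- countsOn(map, numeric(100))
  out2 <- allocateMultireads(multi2, empty, map)
  expect_equal(sum(out2@counts), 0)
  expect_equal(out2@tallies$multi_discarded, 5)

  # conservation on a random fixture
  set.seed(5)
  uc <- countsOn(map, rpois(100, 2))
  nm <- 20L
  multi3 <- data.frame(nReads = rep(1L, nm))
  multi3$candidates <- lapply(seq_len(nm), function(i)
    sample(100L, sample(2:4, 1)))
  out3 <- allocateMultireads(multi3, uc, map)
  expect_equal(sum(out3@counts) - sum(uc@counts),
    out3@tallies$multi_allocated)
  expect_equal(out3@tallies$multi_allocated +
    out3@tallies$multi_discarded, nm)
})
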