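# fourCarch

Circular chromosome conformation capture (4C-seq) measures the
genome-wide contact frequencies of one chosen locus — the *viewpoint* —
in a one-to-all design. `fourCarch` is an R/Bioconductor-style package
that turns raw 4C reads (or pre-aligned read positions) and a reference
genome into:

* an annotated **in-silico restriction fragment map** (primary digest,
  chromosome-arm assignment, centromere distances, secondary-site
  distances, per-viewpoint validity filters);
* **per-fragment read counts** via exact primer demultiplexing,
  zero-mismatch end-anchored mapping and fractional multiread
  allocation (±50 kb local-support rule);
* **window interaction values** with shuffle-null **P-values** and
  **prey** (specific-interactor) calls;
* **chromosome-architecture statistics**: replicate
  correlation/clustering, the contact distance-decay exponent,
  arm-class read shares (RPM) with paired t-tests, dist₀.₅ per arm and
  two centromere-distance regressions;
* **epigenome–interactome integration**: per-fragment epigenetic
  modification densities (EMD), prey/control permutation tests, a
  GSEA-like enrichment score with an empirical null, and
  Benjamini–Hochberg FDR.

A first-class synthetic-data module generates genomes with planted
restriction sites, viewpoint-anchored reads with power-law cis decay
and planted enriched prey windows, and chromatin-state-dependent
feature tracks — with full truth tables — so that every stage of the
pipeline is testable at desk scale without downloads.

## The model in brief

For a window *w* of consecutive valid restriction fragments on one
chromosome arm, the interaction value is

&nbsp;&nbsp;&nbsp;&nbsp;v(w) = Σ_{i ∈ w, n_i ≥ 1} log₂(n_i)

where n_i is the (possibly fractional) read count of fragment *i*. The
null distribution of v is obtained by permuting fragment counts among
the valid fragments of the same arm; for each of 1,000 shuffles a
normal distribution is fitted to the shuffled window values, each
observed window receives an upper-tail preliminary P, and the final P
is the mean over shuffles. Windows with P ≤ 0.01 (or P < 0.01 in both
replicates) are preys.

Cis contact probability is modelled as a power law p(d) ∝ d^γ of the
fragment–viewpoint distance d; the decay exponent γ is estimated from
41 log₁₀-distance bins (1 kb–10 Mb, width 0.1) by LOESS smoothing
followed by an ordinary least-squares line through the smoothed values.

The GSEA-like enrichment score of a prey set (m of n regions) along a
feature-density ranking assigns weight (n−m)/m to test regions and −1
otherwise; ES = max |cumulative sum|, compared against random m-subsets.

## Worked example

A complete synthetic experiment — two 0.8 Mb chromosomes, two
viewpoints, 20,000 reads, two planted 10-fragment prey windows per
viewpoint at 8-fold enrichment — analysed end to end:

```r
library(fourCarch)

cfg <- simulationConfig(nChrom = 2, chromLength = 8e5, libSize = 20000,
  nPreyWindows = 2, preyFragments = 10,
  viewpoints = data.frame(name = c("vpEu", "vpTwo"),
    chrom = c("chr1", "chr2"), relPos = c(0.75, 0.75),
    state = c("eu", "eu"),
    primer = c("ACGTACGTACGTACGTACCA", "TGCATGCATGCATGCATGGT")))
sim <- simulateExperiment(cfg, seed = 101)
sim$map
#> FragmentMap: 375 fragments on 2 chromosome(s)
#>   primary motif: AAGCTT (cut offset 1) | secondary motif: GATC

lib <- sim$libraries$vpEu.A
dm  <- demultiplex(lib$reads, sim$viewpoints, cfg$primaryMotif)
dm$tallies
#>      vpEu     vpTwo no_primer ambiguous   no_site too_short
#>     20000         0         0         0         0         0

aln <- mapReadsExact(dm$reads$vpEu, sim$genome)
cnt <- countFragmentReads(aln, sim$map, viewpoint = "vpEu", sample = "A")
fc  <- allocateMultireads(cnt$multireads, cnt$counts, sim$map)
fc
#> FragmentCounts: vpEu / A - 375 fragments, library size 20000

fmap <- filterFragments(sim$map, sim$viewpoints$vpEu)
tr <- buildWindows(fmap, size = 25, step = 1)
tr <- windowValues(tr, fc)
tr <- shufflePvalues(tr, fc, nShuffles = 1000, seed = 7)
tr <- callPreys(tr, threshold = 0.01)
tr
#> WindowTrack: 122 windows (size 25 step 1) over 4 arm(s)
#>   P-values from 1000 shuffles; preys called: 38

w <- as.data.frame(windowTable(tr))
head(w[w$prey & w$chrom == "chr2", c("arm","start","end","readSum","value","P")], 3)
#>      arm start    end readSum value        P
#> 84 chr2S 80184 183831    2202 142.7 0.004512
#> 85 chr2S 77464 183391    2386 145.7 0.001399
#> 86 chr2S 71728 182256    2389 145.8 0.001318
```

Every simulated read was demultiplexed, mapped uniquely and counted
end-anchored (library size 20,000 of 20,000). The prey calls on chr2
overlap the planted enriched windows; the remaining calls sit on the
viewpoint's own arm, where the genuine distance-decay gradient makes
near-viewpoint windows truly enriched under the per-arm null (mask them
with `callPreys(..., mask = )` when long-range interactions are the
focus). `runPipeline(config, outDir, seed)` runs the same stages — plus
decay, arm-class, dist₀.₅, correlation and enrichment statistics — from
a single configuration and writes TSV/bedGraph/BED outputs with a
structured log.

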