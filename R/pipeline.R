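# Orchestration: one configuration in, a documented output tree out.

.logLine <- function(logPath, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  cat(line, "\n", file = logPath, append = TRUE, sep = "")
  invisible(line)
}

.headerLines <- function(params) {
  vapply(names(params), function(k)
    sprintf("# %s=%s", k, paste(params[[k]], collapse = ",")),
    character(1))
}

.writeWithHeader <- function(df, path, params, colNames = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = colNames)
}

#' Write window, prey and summary tracks to standard formats
#'
#' Windows are written as TSV (all columns) and as two bedGraph tracks
#' (library-scaled interaction value; -log10 P), preys as BED, and any
#' extra tables as TSV. bedGraph lines are sorted by chromosome and
#' start; every file carries `#` header comments recording the
#' originating parameters and seed. BED/bedGraph coordinates are 0-based
#' half-open.
#'
#' @param track A [WindowTrack-class] with values (and optionally P and
#'   prey calls).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default the track's
#'   viewpoint/sample).
#' @param extraTables Named list of data.frames written as
#'   `<prefix>.<name>.tsv`.
#' @return Invisibly, the paths written.
#' @export
writeTracks <- function(track, dir, prefix = NULL, extraTables = list()) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  if (is.null(prefix))
    prefix <- paste(track@viewpoint, track@sample, sep = ".")
  params <- list(viewpoint = track@viewpoint, sample = track@sample,
    size = track@size, step = track@step, nShuffles = track@nShuffles,
    seed = track@seed)
  w <- as.data.frame(track@windows)
  paths <- character(0)
  p <- file.path(dir, paste0(prefix, ".windows.tsv"))
  .writeWithHeader(w, p, params); paths <- c(paths, p)
  ord <- order(w$chrom, w$start)
  bg <- data.frame(chrom = w$chrom, start = w$start - 1L, end = w$end,
    value = round(w$valueScaled, 6))[ord, ]
  p <- file.path(dir, paste0(prefix, ".value.bedGraph"))
  .writeWithHeader(bg, p, params, colNames = FALSE); paths <- c(paths, p)
  if (any(!is.na(w$P))) {
    bgp <- data.frame(chrom = w$chrom, start = w$start - 1L,
      end = w$end, value = round(-log10(pmax(w$P, 1e-300)), 6))[ord, ]
    bgp <- bgp[!is.na(bgp$value), ]
    p <- file.path(dir, paste0(prefix, ".minusLog10P.bedGraph"))
    .writeWithHeader(bgp, p, params, colNames = FALSE)
    paths <- c(paths, p)
  }
  if (any(w$prey %in% TRUE)) {
    pw <- w[w$prey %in% TRUE, ]
    bed <- data.frame(chrom = pw$chrom, start = pw$start - 1L,
      end = pw$end, name = paste0("prey_", seq_len(nrow(pw))),
      score = round(-log10(pmax(pw$P, 1e-300)), 3), strand = ".")
    bed <- bed[order(bed$chrom, bed$start), ]
    p <- file.path(dir, paste0(prefix, ".preys.bed"))
    .writeWithHeader(bed, p, params, colNames = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(extraTables)) {
    p <- file.path(dir, paste0(prefix, ".", nm, ".tsv"))
    .writeWithHeader(extraTables[[nm]], p, params)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run the full 4C analysis pipeline
#'
#' Executes digest, demultiplex/count, window statistics, prey calls,
#' architecture statistics and (when feature tracks are present)
#' epigenome enrichment in order, writing standard outputs plus a
#' structured log and the resolved configuration to `outDir`. With
#' `config$simulate = TRUE` the synthetic-data generator supplies
#' genome, reads and feature tracks; otherwise `config$genomeFasta`,
#' `config$centromereBed` and `config$libraries` (a data.frame with
#' `viewpoint`, `sample`, `fastq`) are read from disk. Reruns with an
#' identical configuration and seed produce byte-identical tables.
#'
#' @param config A named list or a path to a JSON file. Recognised
#'   fields (defaults follow the reference analysis): `simulate`,
#'   `simConfig` (arguments to [simulationConfig()]), `genomeFasta`,
#'   `centromereBed`, `libraries`, `viewpointTable` (data.frame `name`,
#'   `chrom`, `position`, `primer`), `primaryMotif`, `primaryCutOffset`,
#'   `secondaryMotif`, `windowSize` (100), `windowStep` (1),
#'   `nShuffles` (1000), `preyThreshold` (0.01), `allocationDistance`
#'   (50000), `minVpDist` (1000), `minCenDist` (1e5), `maxSecDist`
#'   (1000), `controlExclusionMb` (2e6, half-width of the
#'   around-viewpoint exclusion for control regions), `permutationReps`
#'   (1000), `gseaRandom` (10000), `nReplicates` (1, simulate mode).
#' @param outDir Output directory.
#' @param seed Master seed for every random stage.
#' @return Invisibly, a list with the computed objects (`map`, `counts`,
#'   `tracks`, `stats`, `enrichment`) and `outputs` (paths).
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  defaults <- list(simulate = FALSE, windowSize = 100L, windowStep = 1L,
    nShuffles = 1000L, preyThreshold = 0.01, allocationDistance = 5e4,
    minVpDist = 1000, minCenDist = 1e5, maxSecDist = 1000,
    primaryMotif = "AAGCTT", primaryCutOffset = 1L,
    secondaryMotif = "GATC")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  logPath <- file.path(outDir, "pipeline.log")
  cat("", file = logPath)
  .logLine(logPath, "fourCarch pipeline start; seed=", seed)
  emdFeatures <- NULL
  if (isTRUE(config$simulate)) {
    simCfg <- do.call(simulationConfig,
      if (is.null(config$simConfig)) list() else config$simConfig)
    sim <- simulateExperiment(simCfg, seed = seed,
      nReplicates = if (is.null(config$nReplicates)) 1L else
        config$nReplicates)
    genome <- sim$genome
    map0 <- sim$map
    vps <- sim$viewpoints
    libReads <- lapply(sim$libraries, function(l) {
      vp <- vps[[l$viewpoint]]
      dm <- demultiplex(l$reads, vps, simCfg$primaryMotif,
        sample = l$sample)
      list(viewpoint = l$viewpoint, sample = l$sample,
        reads30 = dm$reads[[l$viewpoint]], tallies = dm$tallies)
    })
    config$primaryMotif <- simCfg$primaryMotif
    config$primaryCutOffset <- simCfg$primaryCutOffset
    config$secondaryMotif <- simCfg$secondaryMotif
    emdFeatures <- sim$emd$features
    .logLine(logPath, "simulated ", length(libReads), " libraries on a ",
      sum(chromLengths(genome)), " bp genome")
  } else {
    for (p in c(config$genomeFasta, config$centromereBed))
      if (!file.exists(p)) stop("input path missing: ", p)
    genome <- readGenome(config$genomeFasta, config$centromereBed)
    vpt <- as.data.frame(config$viewpointTable)
    map0 <- digestGenome(genome, config$primaryMotif,
      config$primaryCutOffset)
    map0 <- annotateArms(map0)
    map0 <- annotateSecondary(map0, genome, config$secondaryMotif)
    vps <- lapply(seq_len(nrow(vpt)), function(k)
      Viewpoint(vpt$name[k], vpt$chrom[k], vpt$position[k],
        vpt$primer[k], map = map0))
    names(vps) <- vpt$name
    libs <- as.data.frame(config$libraries)
    libReads <- lapply(seq_len(nrow(libs)), function(k) {
      if (!file.exists(libs$fastq[k]))
        stop("input path missing: ", libs$fastq[k])
      dm <- demultiplex(libs$fastq[k], vps, config$primaryMotif,
        sample = libs$sample[k])
      list(viewpoint = libs$viewpoint[k], sample = libs$sample[k],
        reads30 = dm$reads[[libs$viewpoint[k]]], tallies = dm$tallies)
    })
  }
  countsList <- list()
  for (l in libReads) {
    aln <- mapReadsExact(l$reads30, genome)
    cr <- countFragmentReads(aln, map0, viewpoint = l$viewpoint,
      sample = l$sample)
    fc <- allocateMultireads(cr$multireads, cr$counts, map0,
      allocationDistance = config$allocationDistance)
    countsList[[paste0(l$viewpoint, ".", l$sample)]] <- fc
    .logLine(logPath, l$viewpoint, ".", l$sample, ": library size ",
      round(fc@librarySize, 1))
  }
  tracks <- list()
  statsTables <- list()
  for (key in names(countsList)) {
    fc <- countsList[[key]]
    vp <- vps[[fc@viewpoint]]
    fmap <- filterFragments(map0, vp, minVpDist = config$minVpDist,
      minCenDist = config$minCenDist, maxSecDist = config$maxSecDist)
    tr <- buildWindows(fmap, config$windowSize, config$windowStep)
    tr <- windowValues(tr, fc)
    tr <- shufflePvalues(tr, fc, nShuffles = config$nShuffles,
      seed = .subSeed(seed, key))
    tr <- callPreys(tr, threshold = config$preyThreshold)
    tracks[[key]] <- tr
    writeTracks(tr, outDir, prefix = key)
    .logLine(logPath, key, ": ", nrow(tr@windows), " windows, ",
      sum(tr@windows$prey, na.rm = TRUE), " preys")
  }
  stats <- list()
  vpOf <- vapply(countsList, function(fc) fc@viewpoint, character(1))
  firstPerVp <- countsList[!duplicated(vpOf)]
  vpList <- lapply(firstPerVp, function(fc) vps[[fc@viewpoint]])
  fmapAny <- filterFragments(map0, vpList[[1L]],
    minVpDist = config$minVpDist, minCenDist = config$minCenDist,
    maxSecDist = config$maxSecDist)
  prof <- tryCatch({
    pr <- decayProfile(unname(firstPerVp), unname(vpList), fmapAny)
    fitDecayExponent(pr)
  }, error = function(e) {
    .logLine(logPath, "decay profile skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(prof)) {
    stats$decay <- prof
    .writeWithHeader(as.data.frame(prof@bins),
      file.path(outDir, "decay.tsv"),
      list(slope = prof@slope, fitP = prof@fitP, seed = seed))
  }
  if (length(firstPerVp) >= 2L) {
    stats$armClasses <- armClassRpm(unname(firstPerVp), map0,
      unname(vpList))
    .writeWithHeader(stats$armClasses$arms,
      file.path(outDir, "arm_rpm.tsv"), list(seed = seed))
    if (!is.null(stats$armClasses$tTests))
      .writeWithHeader(stats$armClasses$tTests,
        file.path(outDir, "arm_ttests.tsv"), list(seed = seed))
  }
  d50all <- list()
  for (k in seq_along(firstPerVp))
    d50all[[k]] <- cbind(viewpoint = vpList[[k]]@name,
      dist50PerArm(firstPerVp[[k]], map0, vpList[[k]]))
  stats$dist50 <- do.call(rbind, d50all)
  .writeWithHeader(stats$dist50, file.path(outDir, "dist50.tsv"),
    list(seed = seed))
  if (length(firstPerVp) >= 3L) {
    stats$centromere <- centromereRegressions(unname(firstPerVp), fmapAny,
      unname(vpList))
  }
  if (length(tracks) >= 2L) {
    sameGeom <- vapply(tracks, function(t)
      nrow(t@windows) == nrow(tracks[[1L]]@windows), logical(1))
    if (all(sameGeom))
      stats$correlation <- tryCatch(replicateCorrelation(tracks),
        error = function(e) NULL)
  }
  enrichment <- NULL
  if (!is.null(emdFeatures) || !is.null(config$featureTracks)) {
    enrichment <- tryCatch({
      .enrichmentStage(config, map0, vps, countsList, emdFeatures,
        outDir, seed, logPath)
    }, error = function(e) {
      .logLine(logPath, "enrichment stage failed: ",
        conditionMessage(e))
      NULL
    })
  }
  resolved <- config
  resolved$seed <- seed
  resolved$libraries <- NULL
  jsonlite::write_json(resolved[!vapply(resolved, is.data.frame,
    logical(1))], file.path(outDir, "resolved_config.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  .logLine(logPath, "pipeline complete")
  invisible(list(map = map0, counts = countsList, tracks = tracks,
    stats = stats, enrichment = enrichment,
    outputs = list.files(outDir, full.names = TRUE)))
}

# Non-overlapping-window EMD + permutation + GSEA-like stage.
.enrichmentStage <- function(config, map0, vps, countsList, emdFeatures,
    outDir, seed, logPath) {
  vpNames <- vapply(countsList, function(fc) fc@viewpoint, character(1))
  firstPerVp <- countsList[!duplicated(vpNames)]
  regionSets <- list()
  testSets <- list()
  vpArms <- character(0)
  emdWindows <- NULL
  trackNo <- NULL
  rf <- if (is.null(config$regionFragments)) 25L else
    as.integer(config$regionFragments)
  for (fc in firstPerVp) {
    vp <- vps[[fc@viewpoint]]
    fmap <- filterFragments(map0, vp, minVpDist = config$minVpDist,
      minCenDist = config$minCenDist, maxSecDist = config$maxSecDist)
    trackNo <- buildWindows(fmap, rf, rf)
    trackNo <- windowValues(trackNo, fc)
    trackNo <- shufflePvalues(trackNo, fc,
      nShuffles = config$nShuffles,
      seed = .subSeed(seed, paste0("no25:", fc@viewpoint)))
    trackNo <- callPreys(trackNo, threshold = config$preyThreshold)
    if (is.null(emdWindows)) {
      if (!is.null(emdFeatures)) {
        emdWindows <- lapply(emdFeatures, function(tmp)
          windowMeanDensity(trackNo, tmp))
      } else {
        emdWindows <- lapply(config$featureTracks, function(path)
          emdTrack(path, map0, trackNo)$windowDensity)
      }
    }
    preyIdx <- which(trackNo@windows$prey %in% TRUE)
    exMb <- if (is.null(config$controlExclusionMb)) 2e6 else
      config$controlExclusionMb
    vgr <- GRanges(vp@chrom, IRanges(max(1, vp@position - exMb),
      vp@position + exMb))
    ctrl <- selectControls(trackNo, n = 50L,
      seed = .subSeed(seed, paste0("ctl:", vp@name)), exclude = vgr)
    regionSets[[vp@name]] <- list(prey = preyIdx, control = ctrl)
    vi <- match(vp@fragment, mcols(map0@fragments)$genome_index)
    vpArms[vp@name] <- mcols(map0@fragments)$arm[vi]
    testSets[[vp@name]] <- preyIdx
  }
  perm <- permutationTest(emdWindows, regionSets,
    i = if (is.null(config$permutationReps)) 1000L else
      config$permutationReps,
    seed = .subSeed(seed, "perm"))
  gsea <- gseaLikeTest(emdWindows, trackNo, testSets, vpArms,
    nRand = if (is.null(config$gseaRandom)) 10000L else
      config$gseaRandom,
    seed = .subSeed(seed, "gsea"))
  .writeWithHeader(perm, file.path(outDir, "enrichment_permutation.tsv"),
    list(seed = seed))
  .writeWithHeader(gsea$table, file.path(outDir, "enrichment_gsea.tsv"),
    list(seed = seed))
  .logLine(logPath, "enrichment: ", nrow(perm), " features tested")
  pca <- tryCatch(
    pcaPreyControl(meanEmdMatrix(emdWindows, regionSets)),
    error = function(e) NULL)
  list(permutation = perm, gsea = gsea, regionSets = regionSets,
    windowEmds = emdWindows, track = trackNo, pca = pca)
}
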