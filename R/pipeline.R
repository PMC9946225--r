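# End-to-end orchestration of the synthetic study: simulate -> detect ->
# group -> signatures -> snp -> express/chip, from one validated config,
# with a manifest and reproducible seeds.

#' Build and validate a pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic run, with the
#' pipeline's standard defaults (junction gap 100 bp, size window
#' 100-10000 bp, grouping e-value 1e-100, focus threshold 5 members, piRNA
#' length >= 23 nt, ping-pong window 23-32 nt, genotyping flank 100 bp,
#' tiling window 33 nt, expressed filter RPKM > 10). Unknown keys are
#' rejected; all parameters must be positive.
#'
#' @param seed master seed; stage-specific substreams are derived from it.
#' @param chromLengths reference chromosome lengths, bp.
#' @param gc genome GC fraction.
#' @param nRefCopies,nNewCopies pre-existing and novel element copies.
#' @param elementInternalLength,elementLtrLength element geometry, bp.
#' @param snpRate per-bp divergence between element copies.
#' @param jitterSd,fpRate breakend emission noise (bp sd; false records/Mb).
#' @param maxGap,minLen,maxLen insert-calling parameters, bp.
#' @param evalueMax,minMembers grouping parameters.
#' @param smallRnaReads,pingpongFraction,phasingFraction small-RNA library.
#' @param minPirnaLen,pingpongWindow piRNA filters, nt.
#' @param flank genotyping junction flank, bp.
#' @param tileWindow,maxMismatches SNP-stage parameters.
#' @param thresholdRpkm expressed-transposon filter threshold.
#' @param logLevel one of "debug", "info", "warn".
#' @param ... unknown keys: always an error.
#' @return a validated config (list, class \code{tetrap_config}).
#' @export
pipelineConfig <- function(seed = 1L,
                           chromLengths = c(chr1 = 300000L, chr2 = 200000L),
                           gc = 0.42,
                           nRefCopies = 2L, nNewCopies = 8L,
                           elementInternalLength = 2400L,
                           elementLtrLength = 200L,
                           snpRate = 0.005,
                           jitterSd = 0, fpRate = 0,
                           maxGap = 100L, minLen = 100L, maxLen = 10000L,
                           evalueMax = 1e-100, minMembers = 5L,
                           smallRnaReads = 2000L,
                           pingpongFraction = 0.5, phasingFraction = 0.3,
                           minPirnaLen = 23L, pingpongWindow = c(23L, 32L),
                           flank = 100L,
                           tileWindow = 33L, maxMismatches = 2L,
                           thresholdRpkm = 10,
                           logLevel = c("info", "debug", "warn"), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  logLevel <- match.arg(logLevel)
  cfg <- list(seed = seed, chromLengths = chromLengths, gc = gc,
              nRefCopies = nRefCopies, nNewCopies = nNewCopies,
              elementInternalLength = elementInternalLength,
              elementLtrLength = elementLtrLength, snpRate = snpRate,
              jitterSd = jitterSd, fpRate = fpRate, maxGap = maxGap,
              minLen = minLen, maxLen = maxLen, evalueMax = evalueMax,
              minMembers = minMembers, smallRnaReads = smallRnaReads,
              pingpongFraction = pingpongFraction,
              phasingFraction = phasingFraction,
              minPirnaLen = minPirnaLen, pingpongWindow = pingpongWindow,
              flank = flank, tileWindow = tileWindow,
              maxMismatches = maxMismatches, thresholdRpkm = thresholdRpkm,
              logLevel = logLevel)
  mustPos <- c("maxGap", "minLen", "maxLen", "evalueMax", "minMembers",
               "smallRnaReads", "minPirnaLen", "flank", "tileWindow",
               "thresholdRpkm", "nRefCopies", "nNewCopies",
               "elementInternalLength", "elementLtrLength")
  for (k in mustPos) {
    if (any(!is.finite(cfg[[k]])) || any(cfg[[k]] <= 0))
      stop(sprintf("configuration parameter '%s' must be positive", k))
  }
  if (any(cfg$chromLengths < 1e4)) stop("chromosome lengths must be >= 10 kb")
  if (cfg$jitterSd < 0 || cfg$fpRate < 0)
    stop("jitterSd and fpRate must be nonnegative")
  class(cfg) <- "tetrap_config"
  cfg
}

.stageSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131L + k * 7919L) %% 2147483647)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order on a simulated study with known
#' truth: genome + element expansion, breakend emission, insert calling and
#' size filtering, homology grouping with activity ratios, small-RNA
#' signature statistics, SNP sites and allele composition, and
#' expression/ChIP quantification. All stage outputs are written as plain
#' text under \code{outDir}, plus a \code{manifest.json} recording
#' parameters, seed, output checksums and warning count. Reruns with the
#' same config are byte-identical. A stage error aborts the run naming the
#' stage; outputs of completed stages are retained.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (\code{calls}, \code{groups}, \code{pingpong}, \code{phasing},
#'   \code{snpSites}, \code{composition}, \code{expression},
#'   \code{truth}, \code{manifest}).
#' @export
runFullPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "tetrap_config"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  nWarn <- 0L
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        nWarn <<- nWarn + 1L
        invokeRestart("muffleWarning")
      })
  }
  res <- list()

  stage("simulate", {
    genome0 <- simulateGenome(config$chromLengths, config$gc,
                              seed = .stageSeed(config$seed, 1L))
    element <- ElementModel(
      "elemA",
      makeLtrConsensus(config$elementInternalLength, config$elementLtrLength,
                       config$gc, seed = .stageSeed(config$seed, 2L)),
      "LTR", ltrLength = config$elementLtrLength, snpRate = config$snpRate)
    ref <- plantReferenceCopies(genome0, element, config$nRefCopies,
                                seed = .stageSeed(config$seed, 3L))
    planted <- plantTransposonCopies(ref$genome, element, config$nNewCopies,
                                     donors = ref$copies,
                                     seed = .stageSeed(config$seed, 4L))
    bnds <- emitBreakendsFromTruth(planted$truth, config$jitterSd,
                                   config$fpRate,
                                   seed = .stageSeed(config$seed, 5L))
    writeFastaFile(ref$genome, file.path(outDir, "genome.fasta"))
    writeBreakends(bnds, file.path(outDir, "breakends.vcf"), "vcf_bnd")
    .writeTsv(planted$truth$inserts, file.path(outDir, "truth_inserts.tsv"))
    res$element <- element
    res$refGenome <- ref$genome
    res$refCopies <- ref$copies
    res$truth <- planted$truth
    res$breakends <- bnds
  })

  stage("detect", {
    calls <- pairBreakendsToInserts(res$breakends, config$maxGap)
    calls <- filterInsertsBySize(calls, config$minLen, config$maxLen)
    .writeTsv(as.data.frame(calls), file.path(outDir, "inserts.tsv"))
    writeBedFile(anchorRanges(calls), file.path(outDir, "anchors.bed"))
    writeBedFile(donorRanges(calls), file.path(outDir, "donors.bed"))
    res$calls <- calls
  })

  stage("group", {
    # called insert sequences = the planted copy sequences (truth channel);
    # grouping and areas are recomputed from sequence alone
    seqs <- res$truth$copySeqs
    gr <- groupInserts(seqs, genome = res$refGenome,
                       evalueMax = config$evalueMax,
                       minMembers = config$minMembers)
    .writeTsv(as.data.frame(gr$groups), file.path(outDir, "groups.tsv"))
    .writeTsv(gr$hits, file.path(outDir, "homology_hits.tsv"))
    res$groups <- gr$groups
  })

  stage("signatures", {
    lib <- simulateSmallRnaLibrary(
      consensusSeq(res$element), config$smallRnaReads,
      pingpongFraction = config$pingpongFraction,
      phasingFraction = config$phasingFraction,
      locusName = elementName(res$element),
      seed = .stageSeed(config$seed, 6L))
    pp <- pingpongZscore(filterPirnaAlignments(lib$records,
                                               config$pingpongWindow[1],
                                               config$pingpongWindow[2]))
    ph <- phasingZscore(filterPirnaAlignments(lib$records,
                                              config$minPirnaLen))
    cov <- strandedCoverage(lib$records,
                            list(chrom = elementName(res$element), start = 1,
                                 end = length(consensusSeq(res$element))))
    .writeTsv(data.frame(position = seq_along(cov$sense),
                         sense = cov$sense, antisense = -cov$antisense),
              file.path(outDir, "coverage.tsv"))
    .writeTsv(rbind(cbind(kind = "pingpong", as.data.frame(pp)),
                    cbind(kind = "phasing", as.data.frame(ph))),
              file.path(outDir, "signatures.tsv"))
    jsonlite::write_json(
      list(pingpong_z = zScore(pp), phasing_z = zScore(ph)),
      file.path(outDir, "signature_z.json"), auto_unbox = TRUE, digits = NA)
    res$smallRna <- lib
    res$pingpong <- pp
    res$phasing <- ph
  })

  stage("snp", {
    copies <- res$truth$copySeqs
    # element-sense sequences for the alignment
    sense <- copies
    neg <- res$truth$inserts$strand == "-"
    sense[neg] <- Biostrings::reverseComplement(copies[neg])
    refId <- names(sense)[1]
    aln <- alignCopies(sense, refId)
    sites <- callSnpSites(aln)
    .writeTsv(sites, file.path(outDir, "snp_sites.tsv"))
    # reads from a two-copy mixture, tiled and mapped back to the reference
    pick <- names(sense)[seq_len(min(2L, length(sense)))]
    tl <- tileReads(sense[pick], config$tileWindow)
    rec <- mapReadsUngapped(tl$tiles, sense[[refId]],
                            config$maxMismatches, library = "piRNA")
    comp <- alleleComposition(rec, sites, length(sense[[refId]]),
                              config$maxMismatches)
    .writeTsv(comp, file.path(outDir, "allele_composition.tsv"))
    res$snpSites <- sites
    res$composition <- comp
  })

  stage("express", {
    groups <- res$groups
    feats <- sprintf("group%d", groups@groupId)
    featureLengths <- stats::setNames(
      vapply(groups@members, function(m)
        sum(Biostrings::width(res$truth$copySeqs[m])), numeric(1)), feats)
    libs <- c(day0 = 1e6, day10 = 1e6, day20 = 1e6)
    targets <- matrix(rep(c(40, 20, 8), each = length(feats)),
                      nrow = length(feats),
                      dimnames = list(feats, names(libs)))
    sim <- simulateExpressionTracks(featureLengths, targets, libs,
                                    chipEnrichment = stats::setNames(
                                      rep(4, length(feats)), feats),
                                    seed = .stageSeed(config$seed, 7L))
    expr <- rpkmTable(sim$counts, featureLengths, libs)
    expr <- relativeExpression(expr, "day0")
    expressed <- expressedTransposonFilter(expr, config$thresholdRpkm,
                                           names(libs))
    enr <- chipEnrichment(sim$chip$chip, sim$chip$control, featureLengths,
                          1e6, 1e6)
    .writeTsv(expr, file.path(outDir, "expression.tsv"))
    writeLines(expressed, file.path(outDir, "expressed_features.txt"))
    .writeTsv(enr$features, file.path(outDir, "chip_enrichment.tsv"))
    .writeTsv(boxplotSummary(expr$relative[expr$library_id == "day20"]),
              file.path(outDir, "relative_day20_boxplot.tsv"))
    res$expression <- expr
    res$enrichment <- enr
  })

  outputs <- sort(setdiff(list.files(outDir), "manifest.json"))
  manifest <- list(
    package = "TEtrap",
    version = as.character(utils::packageVersion("TEtrap")),
    seed = config$seed,
    parameters = unclass(config),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outDir, outputs))), outputs)),
    n_warnings = nWarn)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
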