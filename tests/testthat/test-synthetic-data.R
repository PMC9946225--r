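# Simulators: determinism, distributional bounds, and truth sufficiency.

test_that("genome simulation is deterministic and hits the GC target", {
  g1 <- simulateGenome(c(chr1 = 1e4, chr2 = 12000, chr3 = 15000), 0.42,
                       seed = 5)
  g2 <- simulateGenome(c(chr1 = 1e4, chr2 = 12000, chr3 = 15000), 0.42,
                       seed = 5)
  expect_identical(as.character(g1), as.character(g2))
  expect_identical(length(g1), 3L)
  big <- simulateGenome(c(chr1 = 1e6), 0.5, seed = 1)
  gc <- Biostrings::letterFrequency(big, "GC", as.prob = TRUE)[1]
  expect_lt(abs(gc - 0.5), 0.01)  # binomial bound at n = 1e6
  expect_error(simulateGenome(c(chr1 = 500)), ">= 10 kb")
  expect_error(simulateGenome(c(chr1 = 1e4), gc = 1.2), "gc")
})

test_that("element models enforce the LTR terminal-repeat structure", {
  cons <- makeLtrConsensus(400, 50, seed = 1)
  em <- ElementModel("e", cons, "LTR", ltrLength = 50)
  expect_identical(em@elementClass, "LTR")
  # breaking one terminal base violates validity
  bad <- as.character(cons)
  substr(bad, 1, 1) <- if (substr(bad, 1, 1) == "A") "C" else "A"
  expect_error(ElementModel("e", bad, "LTR", ltrLength = 50),
               "identical terminal repeats")
  expect_error(ElementModel("e", cons, "LTR", ltrLength = 50,
                            snpRate = 0.2), "snpRate")
})

test_that("planted copies carry the expected SNP load and zygosity", {
  g <- simulateGenome(c(chr1 = 1e5, chr2 = 1e5), seed = 2)
  em <- ElementModel("e", makeLtrConsensus(7600, 200, seed = 3), "LTR",
                     200, snpRate = 0.005)
  pl <- plantTransposonCopies(g, em, 8, seed = 4)
  ins <- pl$truth$inserts
  expect_identical(nrow(ins), 8L)
  # LTR class: every planted copy full length
  expect_true(all(ins$length == length(consensusSeq(em))))
  # expected ~40 SNPs per copy (8 kb x 0.005); 3-sigma Poisson bound on total
  totalSnps <- sum(vapply(pl$truth$copySnps, nrow, integer(1)))
  mu <- 8 * length(consensusSeq(em)) * 0.005
  expect_lt(abs(totalSnps - mu), 3 * sqrt(mu))
  # heterozygous copies are in exactly one haplotype
  expect_true(all(ins$haplotypes %in% c("A", "B")))
  widthA <- sum(Biostrings::width(pl$haplotypes$A))
  widthB <- sum(Biostrings::width(pl$haplotypes$B))
  expect_identical(widthA + widthB,
                   2L * 200000L + sum(ins$length))
  # donor sequence reconstructible from consensus + copy SNPs
  cons <- strsplit(as.character(consensusSeq(em)), "")[[1]]
  for (id in ins$copy_id[1:2]) {
    snp <- pl$truth$copySnps[[id]]
    rebuilt <- cons
    rebuilt[snp$offset] <- snp$alt
    rebuilt <- paste(rebuilt, collapse = "")
    if (ins$strand[ins$copy_id == id] == "-")
      rebuilt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rebuilt)))
    expect_identical(as.character(pl$truth$copySeqs[[id]]), rebuilt)
  }
})

test_that("zero-divergence copies equal the consensus and placement can fail", {
  g <- simulateGenome(c(chr1 = 5e4), seed = 6)
  em <- ElementModel("e", makeLtrConsensus(800, 100, seed = 7), "LTR", 100,
                     snpRate = 0)
  pl <- plantTransposonCopies(g, em, 3, seed = 8)
  sense <- pl$truth$copySeqs
  neg <- pl$truth$inserts$strand == "-"
  sense[neg] <- Biostrings::reverseComplement(sense[neg])
  expect_true(all(as.character(sense) == as.character(consensusSeq(em))))
  expect_error(plantTransposonCopies(g, em, 500, seed = 9), "too short")
})

test_that("non-LTR copies are 5'-truncated, never 3'-truncated", {
  g <- simulateGenome(c(chr1 = 1e5), seed = 10)
  em <- ElementModel("line1", makeLtrConsensus(4000, 10, seed = 11),
                     "non_LTR", snpRate = 0)
  pl <- plantTransposonCopies(g, em, 6, seed = 12)
  consChar <- as.character(consensusSeq(em))
  for (i in seq_len(6)) {
    s <- as.character(pl$truth$copySeqs[[i]])
    if (pl$truth$inserts$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # retained part is a suffix of the consensus
    expect_identical(s, substr(consChar, nchar(consChar) - nchar(s) + 1,
                               nchar(consChar)))
  }
  expect_true(any(pl$truth$inserts$length < length(consensusSeq(em))))
})

test_that("breakend emission is exact without jitter and Poisson with fp", {
  g <- simulateGenome(c(chr1 = 5e5, chr2 = 5e5), seed = 13)
  em <- ElementModel("e", makeLtrConsensus(2000, 150, seed = 14), "LTR", 150)
  pl <- plantTransposonCopies(g, em, 10, seed = 15)
  b0 <- emitBreakendsFromTruth(pl$truth, 0, 0, seed = 16)
  expect_identical(nrow(b0), 20L)  # two junctions per insert
  ins <- pl$truth$inserts
  for (i in seq_len(nrow(ins))) {
    expect_identical(b0$pos_a[2 * i - 1], ins$pos[i])
    expect_identical(b0$pos_a[2 * i], ins$pos[i] + 1L)
    expect_setequal(b0$side_a[c(2 * i - 1, 2 * i)], c("right", "left"))
    # both junctions carry mutually consistent donor flags
    expect_setequal(b0$side_b[c(2 * i - 1, 2 * i)], c("left", "right"))
  }
  # fp_rate 10/Mb on a 1 Mb genome: ~10 false records, 3-sigma Poisson
  nFp <- replicate(10, nrow(emitBreakendsFromTruth(
    pl$truth, 0, 10, seed = sample.int(1e6, 1))) - 20L)
  expect_lt(abs(mean(nFp) - 10), 3 * sqrt(10 / 10))
  # determinism
  expect_identical(emitBreakendsFromTruth(pl$truth, 5, 10, seed = 99),
                   emitBreakendsFromTruth(pl$truth, 5, 10, seed = 99))
})

test_that("long reads are exact substrings at zero error, balanced by haplotype", {
  g <- simulateGenome(c(chr1 = 6e4), seed = 17)
  haps <- list(A = g, B = g)
  lr <- simulateLongReads(haps, meanLen = 2000, lenSd = 300, errorRate = 0,
                          depth = 5, seed = 18)
  expect_identical(nrow(lr$truth), length(lr$reads))
  for (i in sample(length(lr$reads), 10)) {
    tr <- lr$truth[i, ]
    sub <- substr(as.character(haps[[tr$haplotype]][[tr$chrom]]),
                  tr$start, tr$end)
    got <- as.character(lr$reads[[i]])
    if (tr$strand == "-")
      got <- as.character(Biostrings::reverseComplement(lr$reads[[i]]))
    expect_identical(got, sub)
  }
  # haplotype balance, 3-sigma binomial
  nA <- sum(lr$truth$haplotype == "A")
  n <- nrow(lr$truth)
  expect_lt(abs(nA - n / 2), 3 * sqrt(n * 0.25))
  expect_error(simulateLongReads(haps, meanLen = 500), ">= 1 kb")
})

test_that("small-RNA simulation produces the requested signature structure", {
  locus <- randomDnaStr(3000, seed = 19)
  # pingpong_fraction 1: every read participates in an exact 10-nt pair
  lib <- simulateSmallRnaLibrary(locus, 200, pingpongFraction = 1, seed = 20)
  expect_true(all(lib$truth$class == "pingpong"))
  rec <- lib$records
  for (g in unique(lib$truth$group_id)) {
    pairIds <- lib$truth$read_id[lib$truth$group_id == g]
    pr <- rec[rec$read_id %in% pairIds, ]
    expect_setequal(pr$strand, c("+", "-"))
    p5 <- pr$start[pr$strand == "+"]
    m5 <- pr$end[pr$strand == "-"]
    expect_identical(m5 - p5 + 1L, 10L)
  }
  # phasing_fraction 1: head-to-tail distance 1 dominates
  lib2 <- simulateSmallRnaLibrary(locus, 200, phasingFraction = 1, seed = 21)
  ph <- phasingZscore(lib2$records)
  fr <- signatureFrequencies(ph)
  expect_identical(unname(which.max(fr)), which(names(fr) == "1"))
  # first-U bias within 3-sigma binomial
  lib3 <- simulateSmallRnaLibrary(locus, 1000, firstUBias = 0.9, seed = 22)
  fU <- mean(substr(lib3$records$seq, 1, 1) == "T")
  expect_lt(abs(fU - 0.9), 3 * sqrt(0.9 * 0.1 / 1000) + 0.02)
  expect_error(simulateSmallRnaLibrary(substr(locus, 1, 30), 10),
               "shorter")
  # determinism
  expect_identical(simulateSmallRnaLibrary(locus, 100, 0.4, 0.2, seed = 23),
                   simulateSmallRnaLibrary(locus, 100, 0.4, 0.2, seed = 23))
})

test_that("expression simulation recovers its RPKM targets", {
  lens <- stats::setNames(rep(1000, 100), sprintf("f%03d", 1:100))
  targets <- matrix(10, 100, 1, dimnames = list(names(lens), "lib1"))
  sim <- simulateExpressionTracks(lens, targets, c(lib1 = 1e6), seed = 24)
  # mean count 10 per feature; Poisson 3-sigma bound on the mean of 100
  expect_lt(abs(mean(sim$counts) - 10), 3 * sqrt(10 / 100))
  est <- rpkmTable(sim$counts, lens, c(lib1 = 1e6))
  expect_lt(abs(mean(est$rpkm) - 10), 3 * sqrt(10 / 100))
  # enrichment 1 for all features: chip/control ratio ~ 1
  sim2 <- simulateExpressionTracks(lens, targets, c(lib1 = 1e6),
                                   chipEnrichment = stats::setNames(
                                     rep(1, 100), names(lens)),
                                   chipBaseRpkm = 20, seed = 25)
  ratio <- sum(sim2$chip$chip) / sum(sim2$chip$control)
  expect_lt(abs(ratio - 1), 0.05)
})
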