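# Junction pairing, size filtering, genotyping and nested-insertion rules.

test_that("two consistent junctions under 100 bp apart yield one insert call", {
  b <- breakendRecords(c("chrA", "chrA"), c(1000L, 1040L), c("right", "left"),
                       c("chrB", "chrB"), c(5000L, 8000L), c("left", "right"))
  calls <- pairBreakendsToInserts(b)
  expect_identical(length(calls), 1L)
  df <- as.data.frame(calls)
  expect_identical(df$acceptor_start, 1000L)
  expect_identical(df$acceptor_end, 1040L)
  expect_identical(df$donor_start, 5000L)
  expect_identical(df$donor_end, 8000L)
  expect_identical(df$insert_length, 3000L)
  expect_identical(df$orientation, "same")
  # the gap threshold is strict: 150 bp apart pairs nothing
  b2 <- breakendRecords(c("chrA", "chrA"), c(1000L, 1150L), c("right", "left"),
                        c("chrB", "chrB"), c(5000L, 8000L), c("left", "right"))
  expect_identical(length(pairBreakendsToInserts(b2)), 0L)
  expect_identical(nrow(residualBreakends(pairBreakendsToInserts(b2))), 2L)
  # exactly 100 bp apart is also excluded (strictly less than)
  b3 <- breakendRecords(c("chrA", "chrA"), c(1000L, 1100L), c("right", "left"),
                        c("chrB", "chrB"), c(5000L, 8000L), c("left", "right"))
  expect_identical(length(pairBreakendsToInserts(b3)), 0L)
})

test_that("inverted donors are recognized by their outward side flags", {
  b <- breakendRecords(c("chrA", "chrA"), c(1000L, 1010L), c("right", "left"),
                       c("chrB", "chrB"), c(8000L, 5000L), c("right", "left"))
  df <- as.data.frame(pairBreakendsToInserts(b))
  expect_identical(df$orientation, "inverted")
  expect_identical(df$donor_start, 5000L)
  expect_identical(df$donor_end, 8000L)
  # opposing-but-wrong geometry (both donors 'left') never pairs
  b2 <- breakendRecords(c("chrA", "chrA"), c(1000L, 1010L), c("right", "left"),
                        c("chrB", "chrB"), c(5000L, 8000L), c("left", "left"))
  expect_identical(length(pairBreakendsToInserts(b2)), 0L)
})

test_that("pairing equals the exhaustive all-pairs oracle on random sets", {
  for (seed in 1:20) {
    b <- randomBreakendSet(80, seed)
    calls <- pairBreakendsToInserts(b, 100)
    got <- as.data.frame(calls)[, c("acceptor_chrom", "acceptor_start",
                                    "acceptor_end", "donor_chrom",
                                    "donor_start", "donor_end",
                                    "orientation", "insert_length")]
    exp_ <- oraclePairInserts(b, 100)
    expect_equal(got, exp_$calls, ignore_attr = TRUE)
    expect_identical(nrow(residualBreakends(calls)), exp_$nResidual)
  }
})

test_that("pairing is order-invariant and idempotent", {
  b <- randomBreakendSet(60, 99)
  ref <- as.data.frame(pairBreakendsToInserts(b))
  for (s in 1:5) {
    set.seed(s)
    perm <- b[sample(nrow(b)), , drop = FALSE]
    rownames(perm) <- NULL
    expect_equal(as.data.frame(pairBreakendsToInserts(perm)), ref)
  }
})

test_that("planted inserts are recovered exactly on jitter-free breakends", {
  g <- simulateGenome(c(chr1 = 2e5, chr2 = 2e5), seed = 31)
  em <- ElementModel("e", makeLtrConsensus(2500, 150, seed = 32), "LTR", 150)
  pl <- plantTransposonCopies(g, em, 12, seed = 33)
  b <- emitBreakendsFromTruth(pl$truth, 0, 0, seed = 34)
  calls <- pairBreakendsToInserts(b)
  expect_identical(length(calls), 12L)
  expect_identical(nrow(residualBreakends(calls)), 0L)
  df <- as.data.frame(calls)
  ins <- pl$truth$inserts[order(pl$truth$inserts$chrom,
                                pl$truth$inserts$pos), ]
  expect_identical(df$acceptor_start, ins$pos)
  expect_identical(df$donor_start, ins$donor_start)
  expect_identical(df$donor_end, ins$donor_end)
  expect_identical(df$orientation,
                   ifelse(ins$strand == "+", "same", "inverted"))
})

test_that("size filter uses inclusive bounds and matches a brute-force filter", {
  mk <- function(lens) {
    n <- length(lens)
    b <- breakendRecords(rep("chrA", 2 * n),
                         as.integer(rbind(seq(1000, by = 5000, length.out = n),
                                          seq(1001, by = 5000, length.out = n))),
                         rep(c("right", "left"), n),
                         rep("chrB", 2 * n),
                         as.integer(rbind(seq(1e6, by = 1e5, length.out = n),
                                          seq(1e6, by = 1e5, length.out = n) + lens)),
                         rep(c("left", "right"), n))
    pairBreakendsToInserts(b)
  }
  calls <- mk(c(50L, 100L, 9999L, 10000L, 10001L))
  kept <- filterInsertsBySize(calls, 100, 10000)
  expect_setequal(insertLengths(kept), c(100L, 9999L, 10000L))
  expect_identical(attr(kept, "discarded_below"), 1L)
  expect_identical(attr(kept, "discarded_above"), 1L)
  expect_error(filterInsertsBySize(calls, 200, 100), "minLen")
  # empty input
  empty <- filterInsertsBySize(calls[integer(0)], 100, 10000)
  expect_identical(length(empty), 0L)
  # random lengths against direct subsetting
  set.seed(41)
  lens <- sample.int(20000, 30)
  calls2 <- mk(lens)
  kept2 <- filterInsertsBySize(calls2, 100, 10000)
  expect_setequal(insertLengths(kept2), lens[lens >= 100 & lens <= 10000])
})

test_that("genotyping counts reads by allele with the two-sided flank rule", {
  set.seed(51)
  flankL <- 400
  left <- randomDnaStr(flankL)
  right <- randomDnaStr(flankL)
  insseq <- randomDnaStr(300)
  aW <- paste0(left, insseq, right)
  aO <- paste0(left, right)
  span <- function(allele, n, len = 450) {
    vapply(seq_len(n), function(i) {
      s <- sample(seq(flankL - 300, flankL - 150), 1)
      substr(allele, s, s + len - 1)
    }, character(1))
  }
  # pure insertion-allele reads, zero error: ratio 1.0
  rw <- span(aW, 10)
  names(rw) <- paste0("w", 1:10)
  gt <- genotypeInsertionSite(rw, aW, aO, flankL, flank = 100)
  expect_identical(gt$n_with, 10L)
  expect_identical(gt$ratio, 1)
  # a read covering only 99 bp on one side is never counted
  short <- substr(aW, flankL - 99, flankL + 99)  # 99 bp left of junction
  gt2 <- genotypeInsertionSite(stats::setNames(short, "s1"), aW, aO,
                               flankL, flank = 100)
  expect_identical(gt2$n_with + gt2$n_without, 0L)
  expect_true(is.na(gt2$ratio))
  # allele sequences must leave room for the flanks
  expect_error(genotypeInsertionSite(rw, substr(aW, 1, 150), aO, 100,
                                     flank = 100), "flank")
})

test_that("genotype ratios track a 30/70 with/without mixture", {
  set.seed(52)
  flankL <- 400
  left <- randomDnaStr(flankL); right <- randomDnaStr(flankL)
  aW <- paste0(left, randomDnaStr(300), right)
  aO <- paste0(left, right)
  n <- 60L; nW <- 18L  # 30 % insertion allele
  span <- function(allele) {
    s <- sample(seq(flankL - 280, flankL - 160), 1)
    substr(allele, s, s + 430)
  }
  reads <- c(vapply(seq_len(nW), function(i) span(aW), character(1)),
             vapply(seq_len(n - nW), function(i) span(aO), character(1)))
  names(reads) <- paste0("r", seq_len(n))
  reads <- reads[sample(n)]
  gt <- genotypeInsertionSite(reads, aW, aO, flankL, flank = 100)
  expect_identical(gt$n_with, nW)
  expect_identical(gt$n_without, n - nW)
  expect_equal(gt$ratio, 0.3)
})

test_that("nested insertions follow the one-end terminus rule", {
  focal <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 18000))
  names(focal) <- "trap_element_copy1"
  tls <- c(nestedTE = 4000L)
  b <- breakendRecords(
    chromA = c("nestedTE", "nestedTE", "nestedTE", "nestedTE"),
    posA = c(10L, 3950L, 150L, 2000L),
    sideA = rep("left", 4),
    chromB = c("chr1", "chr1", "chr1", "chr1"),
    posB = c(12000L, 15000L, 13000L, 14000L),
    sideB = rep("right", 4))
  hits <- detectNestedInsertions(b, focal, tls, tolerance = 100)
  # 5' end (pos 10) and 3' end (3950, within 100 of 4000) are reported;
  # positions 150 and 2000 are beyond the terminus tolerance
  expect_identical(hits$breakend, c(1L, 2L))
  expect_identical(hits$terminus, c("5prime", "3prime"))
  expect_true(all(hits$focal_element == "trap_element_copy1"))
  # a junction outside the focal element is not reported
  b2 <- breakendRecords("nestedTE", 10L, "left", "chr1", 500L, "right")
  expect_identical(nrow(detectNestedInsertions(b2, focal, tls)), 0L)
})

test_that("planted nested insertions are recovered exactly", {
  set.seed(61)
  focal <- GenomicRanges::GRanges(c("chr2", "chr3"),
                                  IRanges::IRanges(c(5000, 20000),
                                                   c(13000, 28000)))
  names(focal) <- c("copyA", "copyB")
  tls <- c(tpA = 3000L, tpB = 1500L)
  n <- 15
  tp <- sample(names(tls), n, replace = TRUE)
  term <- sample(c("5prime", "3prime"), n, replace = TRUE)
  tpos <- ifelse(term == "5prime", sample(100, n, replace = TRUE),
                 tls[tp] - sample(100, n, replace = TRUE) + 1L)
  ei <- sample(1:2, n, replace = TRUE)
  gpos <- GenomicRanges::start(focal)[ei] +
    sample.int(7000, n, replace = TRUE)
  gpos <- pmin(gpos, GenomicRanges::end(focal)[ei])
  b <- breakendRecords(tp, as.integer(tpos), sample(c("left", "right"), n, TRUE),
                       "genome", as.integer(gpos),
                       sample(c("left", "right"), n, TRUE))
  b$chrom_b <- as.character(GenomicRanges::seqnames(focal))[ei]
  hits <- detectNestedInsertions(b, focal, tls, tolerance = 100)
  expect_identical(hits$breakend, seq_len(n))
  expect_identical(hits$terminus, unname(term))
  expect_identical(hits$focal_element, names(focal)[ei])
})
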