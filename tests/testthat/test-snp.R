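# Copy alignment, SNP-site calling, read tiling and allele composition.

mkCopies <- function(nCopies = 4, len = 1200, snpRate = 0.01, seed = 141) {
  cons <- randomDnaStr(len, seed = seed)
  set.seed(seed + 1)
  copies <- list(); snps <- list()
  for (i in seq_len(nCopies)) {
    bases <- strsplit(cons, "")[[1]]
    k <- rbinom(1, len, snpRate)
    off <- sort(sample.int(len, k))
    alt <- vapply(bases[off], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    bases[off] <- alt
    copies[[i]] <- paste(bases, collapse = "")
    snps[[i]] <- off
  }
  cs <- Biostrings::DNAStringSet(unlist(copies))
  names(cs) <- paste0("cp", seq_len(nCopies))
  list(copies = cs, snpOffsets = snps, consensus = cons)
}

test_that("identical copies align gap-free and yield zero SNP sites", {
  s <- randomDnaStr(800, seed = 151)
  cs <- Biostrings::DNAStringSet(c(cp1 = s, cp2 = s, cp3 = s))
  aln <- alignCopies(cs, "cp1")
  expect_identical(dim(aln), c(3L, 800L))
  expect_false(any(aln == "-"))
  expect_identical(nrow(callSnpSites(aln)), 0L)
})

test_that("a single substitution produces exactly one variant column", {
  s <- randomDnaStr(800, seed = 152)
  s2 <- s
  old <- substr(s2, 500, 500)
  substr(s2, 500, 500) <- setdiff(c("A", "C", "G", "T"), old)[1]
  aln <- alignCopies(Biostrings::DNAStringSet(c(cp1 = s, cp2 = s2)), "cp1")
  sites <- callSnpSites(aln)
  expect_identical(sites$ref_position, 500L)
  expect_identical(sites$cp1, old)
})

test_that("planted substitutions across copies are all recovered, no extras", {
  mk <- mkCopies(8, 1500, 0.01, seed = 161)
  aln <- alignCopies(mk$copies, "cp1")
  sites <- callSnpSites(aln)
  # expected variant columns: positions where copies disagree
  mat <- t(vapply(as.character(mk$copies),
                  function(s) strsplit(s, "")[[1]],
                  character(1500)))
  expected <- which(apply(mat, 2, function(col) length(unique(col)) >= 2))
  expect_identical(sites$ref_position, as.integer(expected))
  # allele letters match the actual copy sequences
  for (cp in rownames(aln))
    expect_identical(sites[[cp]], mat[cp, expected])
})

test_that("columns with a gap are never SNP sites", {
  s <- randomDnaStr(900, seed = 171)
  sDel <- paste0(substr(s, 1, 449), substr(s, 460, 900))  # 10 bp deletion
  sSub <- s
  substr(sSub, 700, 700) <- setdiff(c("A", "C", "G", "T"),
                                    substr(s, 700, 700))[1]
  aln <- alignCopies(Biostrings::DNAStringSet(
    c(cp1 = s, cp2 = sDel, cp3 = sSub)), "cp1")
  expect_true(any(aln["cp2", ] == "-"))
  sites <- callSnpSites(aln)
  expect_identical(sites$ref_position, 700L)
})

test_that("diverged sequences outside the near-identical regime error", {
  a <- randomDnaStr(600, seed = 181)
  b <- randomDnaStr(600, seed = 182)
  expect_error(alignCopies(Biostrings::DNAStringSet(c(cp1 = a, cp2 = b)),
                           "cp1"), "near-identical")
})

test_that("tiling splits reads into 33-mers and drops remainders", {
  s <- randomDnaStr(100, seed = 191)
  tl <- tileReads(c(readA = s), 33)
  expect_identical(length(tl$tiles), 3L)
  expect_identical(tl$provenance$offset, c(1L, 34L, 67L))
  expect_identical(as.character(tl$tiles[[1]]), substr(s, 1, 33))
  expect_identical(as.character(tl$tiles[[3]]), substr(s, 67, 99))
  # 32-nt read: no output
  expect_identical(length(tileReads(c(r = substr(s, 1, 32)), 33)$tiles), 0L)
  expect_error(tileReads(c(r = s), 19), "window")
  # total output length arithmetic over random reads
  set.seed(192)
  lens <- sample(20:300, 15)
  reads <- stats::setNames(vapply(lens, randomDnaStr, character(1)),
                           sprintf("r%02d", seq_along(lens)))
  tl2 <- tileReads(reads, 33)
  expect_identical(sum(Biostrings::width(tl2$tiles)),
                   sum(33L * (lens %/% 33L)))
})

test_that("ungapped mapping respects the mismatch bound on both strands", {
  ref <- randomDnaStr(2000, seed = 201)
  r0 <- substr(ref, 101, 133)
  r2 <- r0
  substr(r2, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(r2, 5, 5))[1]
  substr(r2, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(r2, 20, 20))[1]
  r3 <- r2
  substr(r3, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(r3, 30, 30))[1]
  rminus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref, 501, 533))))
  rec <- mapReadsUngapped(c(a = r0, b = r2, c = r3, d = rminus), ref, 2)
  expect_setequal(rec$read_id, c("a", "b", "d"))  # 3-mismatch read dropped
  expect_identical(rec$start[rec$read_id == "a"], 101L)
  expect_identical(rec$mismatches[rec$read_id == "b"], 2L)
  expect_identical(rec$strand[rec$read_id == "d"], "-")
  expect_identical(rec$start[rec$read_id == "d"], 501L)
})

test_that("reads from one copy give a pure composition at every site", {
  mk <- mkCopies(2, 1000, 0.02, seed = 211)
  aln <- alignCopies(mk$copies, "cp1")
  sites <- callSnpSites(aln)
  tl <- tileReads(mk$copies["cp2"], 33)
  rec <- mapReadsUngapped(tl$tiles, mk$copies[["cp1"]], 2, library = "piRNA")
  comp <- alleleComposition(rec, sites, 1000)
  nt <- c("A", "C", "G", "T")
  for (si in unique(comp$site_index)) {
    rows <- comp[comp$site_index == si & comp$coverage > 0, , drop = FALSE]
    if (!nrow(rows)) next
    counts <- colSums(rows[, nt])
    seen <- nt[counts > 0]
    expect_identical(seen, sites$cp2[si])
  }
})

test_that("a 50/50 two-copy mixture shows both alleles at shared sites", {
  mk <- mkCopies(2, 1000, 0.005, seed = 221)
  aln <- alignCopies(mk$copies, "cp1")
  sites <- callSnpSites(aln)
  skip_if(nrow(sites) < 3)
  target <- sites$ref_position[ceiling(nrow(sites) / 2)]
  # 200 reads overlapping the target site, drawn half from each copy
  set.seed(222)
  mkReads <- function(copy, n) {
    starts <- sample(seq(max(1, target - 32), min(target, 1000 - 32)), n,
                     replace = TRUE)
    stats::setNames(substring(as.character(mk$copies[[copy]]), starts,
                              starts + 32), sprintf("%s_%03d", copy, 1:n))
  }
  reads <- c(mkReads("cp1", 100), mkReads("cp2", 100))
  rec <- mapReadsUngapped(reads, mk$copies[["cp1"]], 2, library = "piRNA")
  comp <- alleleComposition(rec, sites, 1000)
  rows <- comp[comp$ref_position == target, ]
  nt <- c("A", "C", "G", "T")
  counts <- colSums(rows[, nt])
  cov <- sum(rows$coverage)
  a1 <- sites$cp1[sites$ref_position == target]
  a2 <- sites$cp2[sites$ref_position == target]
  frac <- counts[[a2]] / cov
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / cov))
  expect_gt(counts[[a1]], 0)
})

test_that("composition is strand-correct under global complementation", {
  mk <- mkCopies(2, 600, 0.02, seed = 231)
  aln <- alignCopies(mk$copies, "cp1")
  sites <- callSnpSites(aln)
  skip_if(nrow(sites) < 1)
  tl <- tileReads(mk$copies, 33)
  rec <- mapReadsUngapped(tl$tiles, mk$copies[["cp1"]], 2, library = "x")
  # flip every read: reverse-complement sequences and swap strands
  flipped <- rec
  flipped$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rec$seq)))
  flipped$strand <- ifelse(rec$strand == "+", "-", "+")
  c1 <- alleleComposition(rec, sites, 600)
  c2 <- alleleComposition(flipped, sites, 600)
  nt <- c("A", "C", "G", "T")
  for (si in unique(c1$site_index)) {
    t1 <- colSums(c1[c1$site_index == si, nt])
    t2 <- colSums(c2[c2$site_index == si, nt])
    expect_identical(t1, t2)  # sense-space counts unchanged
  }
  # sites outside the reference are rejected
  expect_error(alleleComposition(rec, data.frame(ref_position = 601), 600),
               "outside")
})

test_that("reads exceeding the mismatch allowance are excluded entirely", {
  ref <- randomDnaStr(500, seed = 241)
  r <- substr(ref, 101, 133)
  for (p in c(3, 12, 25)) {
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
  }
  rec3 <- alignmentRecords("bad", "reference", 101L, 133L, "+",
                           mismatches = 3L, seq = r)
  comp <- alleleComposition(rec3, data.frame(ref_position = 110L), 500)
  expect_identical(sum(comp$coverage), 0L)
})
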