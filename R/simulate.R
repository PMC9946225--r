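# Synthetic-data generators with known truth.
#
# Every simulator is deterministic for a fixed seed and leaves the caller's
# RNG stream untouched. Truth objects are sufficient: the expected answer of
# every downstream stage is computable from the returned truth alone.

#' Simulate a random genome
#'
#' Generates i.i.d. chromosome sequences at a given GC fraction.
#'
#' @param chromLengths integer vector of chromosome lengths (each >= 10 kb);
#'   names become chromosome names (default \code{chr1..chrN}).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed RNG seed.
#' @return A named \code{DNAStringSet}.
#' @export
simulateGenome <- function(chromLengths, gc = 0.42, seed = NULL) {
  if (any(chromLengths < 1e4))
    stop("chromosome lengths must be >= 10 kb")
  .assertScalarNum(gc, "gc", min = 1e-9, max = 1 - 1e-9)
  nm <- names(chromLengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chromLengths))
  withSeed(seed, {
    seqs <- vapply(chromLengths, randomDna, character(1), gc = gc)
    stats::setNames(Biostrings::DNAStringSet(seqs), nm)
  })
}

# Draw one diverged copy of an element: consensus + i.i.d. substitutions at
# snpRate; non_LTR copies lose a 5' fraction (retained 3' fraction ~ Beta).
# Returns the copy sequence (element-sense), its SNP list in consensus
# coordinates and the first retained consensus offset.
.mutateCopy <- function(element) {
  cons <- as.character(element@consensus)
  L <- nchar(cons)
  bases <- strsplit(cons, "")[[1]]
  k <- stats::rbinom(1L, L, element@snpRate)
  snps <- data.frame(offset = integer(0), ref = character(0),
                     alt = character(0), stringsAsFactors = FALSE)
  if (k > 0) {
    off <- sort(sample.int(L, k))
    alt <- vapply(bases[off], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    snps <- data.frame(offset = off, ref = bases[off], alt = unname(alt),
                       stringsAsFactors = FALSE)
    bases[off] <- alt
  }
  truncStart <- 1L
  if (element@elementClass == "non_LTR") {
    f <- stats::rbeta(1L, element@truncationShape[1], element@truncationShape[2])
    keep <- max(200L, ceiling(f * L))
    truncStart <- L - min(keep, L) + 1L
  }
  list(seq = paste(bases[truncStart:L], collapse = ""),
       snps = snps, truncStart = truncStart)
}

# Sample non-overlapping placement positions across a genome, keeping
# minGap bp away from each other and from `avoid` intervals.
.samplePlacements <- function(chromLengths, n, minGap, avoid = NULL) {
  taken <- if (is.null(avoid)) {
    data.frame(chrom = character(0), pos = integer(0))
  } else {
    data.frame(chrom = as.character(GenomicRanges::seqnames(avoid)),
               pos = as.integer((GenomicRanges::start(avoid) +
                                   GenomicRanges::end(avoid)) / 2))
  }
  out <- data.frame(chrom = character(0), pos = integer(0))
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("genome too short to place the requested copies without overlap")
    chrom <- sample(names(chromLengths), 1L, prob = chromLengths)
    len <- chromLengths[[chrom]]
    if (len < 2L * minGap + 2L) next
    pos <- sample.int(len - 2L * minGap, 1L) + minGap
    near <- taken$chrom == chrom & abs(taken$pos - pos) < minGap
    nearOut <- out$chrom == chrom & abs(out$pos - pos) < minGap
    if (any(near) || any(nearOut)) next
    out <- rbind(out, data.frame(chrom = chrom, pos = pos))
  }
  out
}

#' Plant pre-existing ("old") element copies into a reference genome
#'
#' Inserts diverged copies of an element into the genome itself; these model
#' the copies already present in the reference assembly and serve as donor
#' loci and as the "old area" for activity-ratio analyses.
#'
#' @param genome \code{DNAStringSet}.
#' @param element \linkS4class{ElementModel}.
#' @param nCopies number of copies to plant.
#' @param minGap minimum distance between planted copies, bp.
#' @param seed RNG seed.
#' @return list with \code{genome} (modified \code{DNAStringSet}),
#'   \code{copies} (\code{GRanges} of planted copy locations, names =
#'   copy ids) and \code{copySnps} (per-copy SNP tables in consensus
#'   coordinates).
#' @export
plantReferenceCopies <- function(genome, element, nCopies, minGap = 2000L,
                                 seed = NULL) {
  stopifnot(nCopies >= 1)
  withSeed(seed, {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    plc <- .samplePlacements(lens, nCopies, minGap)
    copyIds <- sprintf("%s_ref%02d", element@name, seq_len(nCopies))
    copies <- vector("list", nCopies)
    snpL <- vector("list", nCopies)
    strands <- sample(c("+", "-"), nCopies, replace = TRUE)
    for (i in seq_len(nCopies)) {
      mc <- .mutateCopy(element)
      s <- mc$seq
      if (strands[i] == "-") s <- revcompChar(s)
      copies[[i]] <- s
      snpL[[i]] <- mc$snps
    }
    # apply insertions chromosome by chromosome, right to left
    seqs <- as.character(genome)
    finalStart <- integer(nCopies)
    for (chrom in unique(plc$chrom)) {
      idx <- which(plc$chrom == chrom)
      idx <- idx[order(plc$pos[idx], decreasing = TRUE)]
      for (i in idx) {
        p <- plc$pos[i]
        seqs[[chrom]] <- paste0(substr(seqs[[chrom]], 1L, p), copies[[i]],
                                substr(seqs[[chrom]], p + 1L,
                                       nchar(seqs[[chrom]])))
      }
      # final coordinates account for upstream insertions on the same chrom
      idxUp <- order(plc$pos[which(plc$chrom == chrom)])
      ord <- which(plc$chrom == chrom)[idxUp]
      shift <- 0L
      for (i in ord) {
        finalStart[i] <- plc$pos[i] + shift + 1L
        shift <- shift + nchar(copies[[i]])
      }
    }
    gr <- GenomicRanges::GRanges(
      plc$chrom,
      IRanges::IRanges(finalStart,
                       finalStart + nchar(unlist(copies)) - 1L),
      strand = strands)
    names(gr) <- copyIds
    names(snpL) <- copyIds
    list(genome = Biostrings::DNAStringSet(seqs), copies = gr,
         copySnps = snpL)
  })
}

#' Plant novel transposon insertions into a diploid genome
#'
#' Creates a haplotype pair derived from the reference genome, carrying novel
#' element copies at uniformly sampled acceptor sites. Each copy carries
#' independent substitutions at the element's \code{snpRate}; non-LTR copies
#' are 5'-truncated; LTR and ITR copies are always full length. Heterozygous
#' copies are present in exactly one haplotype, homozygous copies in both.
#' The returned truth records every placement, per-copy SNPs, donor
#' intervals and copy sequences, and is sufficient to predict the output of
#' every downstream stage.
#'
#' Acceptor junction coordinates in the truth follow the convention used by
#' the insert caller: the insertion sits between reference bases \code{pos}
#' and \code{pos + 1}, and the donor junction coordinates are the first and
#' last base of the donor interval (so the called insert length equals
#' \code{donor_end - donor_start}).
#'
#' @param genome reference \code{DNAStringSet}.
#' @param element \linkS4class{ElementModel}.
#' @param nCopies number of novel copies.
#' @param zygosityMix named probabilities \code{c(het = , hom = )}.
#' @param donors optional \code{GRanges} of existing genomic copies to use
#'   as donor intervals (e.g. \code{plantReferenceCopies()$copies}); when
#'   NULL the donor is a virtual contig named after the element.
#' @param minGap minimum distance between acceptor sites, bp.
#' @param seed RNG seed.
#' @return list with \code{haplotypes} (list \code{A}, \code{B} of
#'   \code{DNAStringSet}) and \code{truth} (list: \code{inserts} data.frame,
#'   \code{copySnps}, \code{copySeqs}, \code{chromLengths}, \code{element}).
#' @export
plantTransposonCopies <- function(genome, element, nCopies,
                                  zygosityMix = c(het = 1, hom = 0),
                                  donors = NULL, minGap = 2000L, seed = NULL) {
  stopifnot(nCopies >= 1)
  if (abs(sum(zygosityMix) - 1) > 1e-9)
    stop("zygosityMix probabilities must sum to 1")
  withSeed(seed, {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    avoid <- donors
    plc <- .samplePlacements(lens, nCopies, minGap, avoid = avoid)
    copyIds <- sprintf("%s_new%02d", element@name, seq_len(nCopies))
    strands <- sample(c("+", "-"), nCopies, replace = TRUE)
    zyg <- sample(names(zygosityMix), nCopies, replace = TRUE,
                  prob = zygosityMix)
    hap <- ifelse(zyg == "hom", "AB", sample(c("A", "B"), nCopies,
                                             replace = TRUE))
    seqs <- vector("list", nCopies)
    snpL <- vector("list", nCopies)
    donorTbl <- data.frame(donor_chrom = character(nCopies),
                           donor_start = integer(nCopies),
                           donor_end = integer(nCopies),
                           stringsAsFactors = FALSE)
    for (i in seq_len(nCopies)) {
      mc <- .mutateCopy(element)
      s <- mc$seq
      if (strands[i] == "-") s <- revcompChar(s)
      seqs[[i]] <- s
      snpL[[i]] <- mc$snps
      if (is.null(donors)) {
        donorTbl$donor_chrom[i] <- paste0(element@name, "_consensus")
        donorTbl$donor_start[i] <- 1L
        donorTbl$donor_end[i] <- nchar(s)
      } else {
        j <- sample.int(length(donors), 1L)
        donorTbl$donor_chrom[i] <- as.character(
          GenomicRanges::seqnames(donors)[j])
        donorTbl$donor_start[i] <- GenomicRanges::start(donors)[j]
        donorTbl$donor_end[i] <- GenomicRanges::end(donors)[j]
      }
    }
    inserts <- data.frame(
      copy_id = copyIds, chrom = plc$chrom, pos = plc$pos,
      strand = strands, length = nchar(unlist(seqs)),
      zygosity = zyg, haplotypes = hap, donorTbl,
      stringsAsFactors = FALSE)
    applyHap <- function(which) {
      s <- as.character(genome)
      sel <- which(grepl(which, inserts$haplotypes, fixed = TRUE))
      for (chrom in unique(inserts$chrom[sel])) {
        idx <- sel[inserts$chrom[sel] == chrom]
        idx <- idx[order(inserts$pos[idx], decreasing = TRUE)]
        for (i in idx) {
          p <- inserts$pos[i]
          s[[chrom]] <- paste0(substr(s[[chrom]], 1L, p), seqs[[i]],
                               substr(s[[chrom]], p + 1L, nchar(s[[chrom]])))
        }
      }
      Biostrings::DNAStringSet(s)
    }
    names(snpL) <- copyIds
    cs <- Biostrings::DNAStringSet(unlist(seqs))
    names(cs) <- copyIds
    list(haplotypes = list(A = applyHap("A"), B = applyHap("B")),
         truth = list(inserts = inserts, copySnps = snpL, copySeqs = cs,
                      chromLengths = lens, element = element@name))
  })
}

#' Emit breakend records from a planted-insertion truth
#'
#' Bypasses an external structural-variant caller: each planted insert
#' yields two breakends (one per junction) whose coordinates are perturbed
#' by rounded Gaussian jitter; false breakends joining random positions are
#' added at \code{fpRate} per Mb of reference genome.
#'
#' @param truth truth list from \code{\link{plantTransposonCopies}}.
#' @param jitterSd standard deviation of the coordinate jitter, bp.
#' @param fpRate false-breakend rate per Mb.
#' @param nSupport supporting read ids fabricated per insert.
#' @param seed RNG seed.
#' @return breakend data.frame (see \code{\link{breakendRecords}}).
#' @export
emitBreakendsFromTruth <- function(truth, jitterSd = 0, fpRate = 0,
                                   nSupport = 3L, seed = NULL) {
  stopifnot(jitterSd >= 0, fpRate >= 0)
  withSeed(seed, {
    ins <- truth$inserts
    n <- nrow(ins)
    jit <- function(x) pmax(1L, x + as.integer(round(stats::rnorm(length(x),
                                                                  0, jitterSd))))
    recs <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      reads <- sprintf("%s_sup%d", ins$copy_id[i], seq_len(nSupport))
      if (ins$strand[i] == "+") {
        d1 <- c(ins$donor_start[i], "left"); d2 <- c(ins$donor_end[i], "right")
      } else {
        d1 <- c(ins$donor_end[i], "right"); d2 <- c(ins$donor_start[i], "left")
      }
      recs[[2L * i - 1L]] <- list(ins$chrom[i], jit(ins$pos[i]), "right",
                                  ins$donor_chrom[i], jit(as.integer(d1[1])),
                                  d1[2], reads)
      recs[[2L * i]] <- list(ins$chrom[i], jit(ins$pos[i] + 1L), "left",
                             ins$donor_chrom[i], jit(as.integer(d2[1])),
                             d2[2], reads)
    }
    totalMb <- sum(truth$chromLengths) / 1e6
    nFp <- stats::rpois(1L, fpRate * totalMb)
    chroms <- names(truth$chromLengths)
    for (k in seq_len(nFp)) {
      ca <- sample(chroms, 1L, prob = truth$chromLengths)
      cb <- sample(chroms, 1L, prob = truth$chromLengths)
      recs[[length(recs) + 1L]] <- list(
        ca, sample.int(truth$chromLengths[[ca]], 1L),
        sample(c("left", "right"), 1L),
        cb, sample.int(truth$chromLengths[[cb]], 1L),
        sample(c("left", "right"), 1L),
        sprintf("fp%03d_sup1", k))
    }
    breakendRecords(
      vapply(recs, `[[`, character(1), 1),
      vapply(recs, function(r) as.integer(r[[2]]), integer(1)),
      vapply(recs, `[[`, character(1), 3),
      vapply(recs, `[[`, character(1), 4),
      vapply(recs, function(r) as.integer(r[[5]]), integer(1)),
      vapply(recs, `[[`, character(1), 6),
      lapply(recs, `[[`, 7))
  })
}

#' Simulate long reads from a haplotype pair
#'
#' Reads are sampled uniformly from both haplotypes with a substitution-only
#' error model (no indels); the per-read truth records the originating
#' haplotype, interval and strand.
#'
#' @param haplotypes list of two \code{DNAStringSet} (or a single one).
#' @param meanLen,lenSd read length distribution (Gaussian, floored at 200 bp
#'   and clipped at the chromosome end); \code{meanLen} >= 1 kb.
#' @param errorRate per-base substitution probability.
#' @param depth mean coverage over the haplotype set.
#' @param seed RNG seed.
#' @return list with \code{reads} (\code{DNAStringSet}) and \code{truth}
#'   (data.frame: read_id, haplotype, chrom, start, end, strand).
#' @export
simulateLongReads <- function(haplotypes, meanLen = 5000, lenSd = 1000,
                              errorRate = 0, depth = 10, seed = NULL) {
  if (!is.list(haplotypes)) haplotypes <- list(A = haplotypes)
  if (meanLen < 1000) stop("meanLen must be >= 1 kb")
  withSeed(seed, {
    gsize <- mean(vapply(haplotypes, function(h) sum(Biostrings::width(h)),
                         numeric(1)))
    nReads <- max(1L, round(depth * gsize / meanLen))
    hapIds <- names(haplotypes)
    if (is.null(hapIds)) hapIds <- paste0("hap", seq_along(haplotypes))
    out <- vector("list", nReads)
    truth <- vector("list", nReads)
    for (i in seq_len(nReads)) {
      h <- sample.int(length(haplotypes), 1L)
      hap <- haplotypes[[h]]
      lens <- Biostrings::width(hap)
      ci <- sample.int(length(hap), 1L, prob = lens)
      len <- max(200L, round(stats::rnorm(1L, meanLen, lenSd)))
      start <- sample.int(max(1L, lens[ci] - 200L), 1L)
      end <- min(lens[ci], start + len - 1L)
      s <- substr(as.character(hap[[ci]]), start, end)
      nerr <- stats::rbinom(1L, nchar(s), errorRate)
      if (nerr > 0) {
        pos <- sample.int(nchar(s), nerr)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        s <- paste(ch, collapse = "")
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") s <- revcompChar(s)
      out[[i]] <- s
      truth[[i]] <- data.frame(read_id = sprintf("lr%05d", i),
                               haplotype = hapIds[h],
                               chrom = names(hap)[ci], start = start,
                               end = end, strand = strand,
                               stringsAsFactors = FALSE)
    }
    reads <- Biostrings::DNAStringSet(unlist(out))
    truth <- do.call(rbind, truth)
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth)
  })
}

# default small-RNA length weights: 23-35 nt with the mode in 26-32
.defaultLengthProbs <- function() {
  w <- c(2, 3, 4, 5, 7, 8, 8, 7, 5, 4, 3, 2, 1)
  stats::setNames(w / sum(w), 23:35)
}

#' Simulate a small-RNA library over a locus
#'
#' Generates aligned small-RNA records with configurable ping-pong and
#' phasing structure: ping-pong pairs are opposite-strand reads whose 5'
#' ends overlap by exactly 10 nt; phased reads are same-strand head-to-tail
#' runs (each 5' end one nt after the previous 3' end); the remainder is
#' uniform. Read lengths follow \code{lengthProbs} (default: 23-35 nt with
#' the mode in 26-32 nt). 5' U and position-10 A biases can be imposed on
#' the read sequences. The truth labels each read's generative class.
#'
#' @param locus locus sequence (character or \code{DNAString}).
#' @param nReads number of reads.
#' @param pingpongFraction,phasingFraction fractions of reads generated as
#'   ping-pong pairs / phased runs; their sum must be <= 1.
#' @param lengthProbs named probability vector over read lengths.
#' @param firstUBias,tenthABias probability of forcing the 5'-most base to U
#'   (T) and the 10th base to A, respectively.
#' @param locusName reference name stored on the records.
#' @param library library label.
#' @param seed RNG seed.
#' @return list with \code{records} (alignment record data.frame with
#'   \code{seq}) and \code{truth} (read_id, class, group_id).
#' @export
simulateSmallRnaLibrary <- function(locus, nReads, pingpongFraction = 0,
                                    phasingFraction = 0, lengthProbs = NULL,
                                    firstUBias = 0, tenthABias = 0,
                                    locusName = "locus",
                                    library = NA_character_, seed = NULL) {
  if (!is.character(locus)) locus <- as.character(locus)
  if (is.null(lengthProbs)) lengthProbs <- .defaultLengthProbs()
  lensAvail <- as.integer(names(lengthProbs))
  L <- nchar(locus)
  if (L < max(lensAvail) + 20L)
    stop("locus shorter than the read length range")
  stopifnot(pingpongFraction >= 0, phasingFraction >= 0,
            pingpongFraction + phasingFraction <= 1 + 1e-12)
  withSeed(seed, {
    rl <- function(n) sample(lensAvail, n, replace = TRUE, prob = lengthProbs)
    nPP <- 2L * floor(nReads * pingpongFraction / 2)
    nPH <- floor(nReads * phasingFraction)
    nBG <- nReads - nPP - nPH
    rows <- list(); labels <- list(); gid <- 0L
    addRead <- function(start, end, strand, class, group) {
      rows[[length(rows) + 1L]] <<- c(start, end, strand)
      labels[[length(labels) + 1L]] <<- c(class, group)
    }
    for (p in seq_len(nPP / 2L)) {
      gid <- gid + 1L
      l1 <- rl(1L); l2 <- rl(1L)
      lo <- max(1L, l2 - 9L)
      hi <- min(L - l1 + 1L, L - 9L)
      p5 <- resampleFrom(seq(lo, hi))
      init <- sample(c("+", "-"), 1L)  # which strand initiated the pair
      addRead(p5, p5 + l1 - 1L, "+", "pingpong", paste0("pp", gid, "_", init))
      addRead(p5 + 9L - l2 + 1L, p5 + 9L, "-", "pingpong",
              paste0("pp", gid, "_", init))
    }
    left <- nPH
    while (left > 0L) {
      gid <- gid + 1L
      runLen <- min(5L, left)
      strand <- sample(c("+", "-"), 1L)
      span <- runLen * max(lensAvail)
      if (L <= span + 1L) stop("locus too short for phased runs")
      if (strand == "+") {
        cur <- sample.int(L - span, 1L)
        for (r in seq_len(runLen)) {
          l <- rl(1L)
          addRead(cur, cur + l - 1L, "+", "phased", paste0("ph", gid))
          cur <- cur + l
        }
      } else {
        cur <- resampleFrom(seq(span, L))  # 5' end (highest coordinate)
        for (r in seq_len(runLen)) {
          l <- rl(1L)
          addRead(cur - l + 1L, cur, "-", "phased", paste0("ph", gid))
          cur <- cur - l
        }
      }
      left <- left - runLen
    }
    for (b in seq_len(nBG)) {
      gid <- gid + 1L
      l <- rl(1L)
      s <- sample.int(L - l + 1L, 1L)
      addRead(s, s + l - 1L, sample(c("+", "-"), 1L), "background",
              paste0("bg", gid))
    }
    m <- do.call(rbind, rows)
    starts <- as.integer(m[, 1]); ends <- as.integer(m[, 2])
    strands <- m[, 3]
    n <- length(starts)
    seqs <- substring(locus, starts, ends)
    neg <- strands == "-"
    if (any(neg)) seqs[neg] <- revcompChar(seqs[neg])
    mism <- integer(n)
    forceBase <- function(seqs, mism, posIdx, base, prob) {
      hit <- stats::runif(n) < prob
      for (i in which(hit)) {
        if (substr(seqs[i], posIdx, posIdx) != base) {
          substr(seqs[i], posIdx, posIdx) <- base
          mism[i] <- mism[i] + 1L
        }
      }
      list(seqs = seqs, mism = mism)
    }
    if (firstUBias > 0) {
      fb <- forceBase(seqs, mism, 1L, "T", firstUBias)
      seqs <- fb$seqs; mism <- fb$mism
    }
    if (tenthABias > 0) {
      fb <- forceBase(seqs, mism, 10L, "A", tenthABias)
      seqs <- fb$seqs; mism <- fb$mism
    }
    ids <- sprintf("sr%05d", seq_len(n))
    lab <- do.call(rbind, labels)
    records <- alignmentRecords(ids, locusName, starts, ends, strands,
                                mism, 1L, seqs, library)
    truth <- data.frame(read_id = ids, class = lab[, 1], group_id = lab[, 2],
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Simulate expression count tables and a ChIP/control pair
#'
#' Counts are drawn Poisson with mean
#' \code{rpkm_target x feature_kb x library_size / 1e6}; ChIP counts are
#' scaled by a per-feature enrichment relative to the control library.
#'
#' @param featureLengths named feature lengths, bp.
#' @param rpkmTargets matrix (features x libraries) of target RPKM values,
#'   all > 0, or a named vector for a single library.
#' @param librarySizes named library sizes (mapped reads).
#' @param chipEnrichment optional named per-feature fold enrichment; when
#'   given, \code{chip} and \code{control} count vectors are simulated at
#'   \code{chipBaseRpkm} (control) and \code{chipBaseRpkm x enrichment}
#'   (ChIP), both with library size \code{chipLibrarySize}.
#' @param chipBaseRpkm,chipLibrarySize ChIP simulation parameters.
#' @param seed RNG seed.
#' @return list with \code{counts} (matrix features x libraries) and, when
#'   requested, \code{chip} (list of \code{chip}, \code{control} counts).
#' @export
simulateExpressionTracks <- function(featureLengths, rpkmTargets,
                                     librarySizes, chipEnrichment = NULL,
                                     chipBaseRpkm = 5, chipLibrarySize = 1e6,
                                     seed = NULL) {
  if (is.null(dim(rpkmTargets)))
    rpkmTargets <- matrix(rpkmTargets, ncol = 1,
                          dimnames = list(names(rpkmTargets),
                                          names(librarySizes)[1]))
  stopifnot(all(rpkmTargets > 0), all(featureLengths > 0),
            all(librarySizes > 0))
  feats <- rownames(rpkmTargets)
  stopifnot(all(feats %in% names(featureLengths)))
  withSeed(seed, {
    kb <- featureLengths[feats] / 1000
    counts <- rpkmTargets
    for (j in seq_len(ncol(rpkmTargets))) {
      mu <- rpkmTargets[, j] * kb * librarySizes[[colnames(rpkmTargets)[j]]] / 1e6
      counts[, j] <- stats::rpois(length(mu), mu)
    }
    out <- list(counts = counts)
    if (!is.null(chipEnrichment)) {
      stopifnot(all(names(chipEnrichment) %in% names(featureLengths)))
      kbC <- featureLengths[names(chipEnrichment)] / 1000
      muCtrl <- chipBaseRpkm * kbC * chipLibrarySize / 1e6
      out$chip <- list(
        chip = stats::setNames(stats::rpois(length(muCtrl),
                                            muCtrl * chipEnrichment),
                               names(chipEnrichment)),
        control = stats::setNames(stats::rpois(length(muCtrl), muCtrl),
                                  names(chipEnrichment)))
    }
    out
  })
}
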