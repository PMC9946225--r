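# Novel-insertion calling from structural-variant breakends, size filtering,
# long-read genotyping of insertion sites, and nested-insertion detection.

# Orientation-consistency predicate for one candidate pairing.
#
# Geometry: an inserted donor segment produces two junctions at the acceptor
# locus. The two acceptor-side flags must oppose (one 'right': the junction
# after the left flank; one 'left': the junction before the right flank).
# Let B_R be the donor position linked to the acceptor-'right' junction and
# B_L the one linked to the acceptor-'left' junction:
#   same orientation:     side(B_R) == left,  side(B_L) == right, B_R < B_L
#   inverted orientation: side(B_R) == right, side(B_L) == left,  B_R > B_L
# The donor junction span (insert length) must be positive either way.
.checkPairGeometry <- function(accSide1, accSide2,
                               donChrom1, donPos1, donSide1,
                               donChrom2, donPos2, donSide2) {
  if (accSide1 == accSide2) return(NULL)
  if (donChrom1 != donChrom2) return(NULL)
  if (accSide1 == "right") {
    bR <- donPos1; sR <- donSide1; bL <- donPos2; sL <- donSide2
  } else {
    bR <- donPos2; sR <- donSide2; bL <- donPos1; sL <- donSide1
  }
  if (sR == "left" && sL == "right" && bR < bL) {
    list(orientation = "same", donorLow = bR, donorHigh = bL)
  } else if (sR == "right" && sL == "left" && bR > bL) {
    list(orientation = "inverted", donorLow = bL, donorHigh = bR)
  } else {
    NULL
  }
}

# Enumerate all valid pairings between breakends i and j under the rule.
# Each breakend has two ends; either end may play the acceptor role.
.candidatePairings <- function(bnds, i, j, maxGap) {
  ends <- function(k, which) {
    if (which == "a") list(chrom = bnds$chrom_a[k], pos = bnds$pos_a[k],
                           side = bnds$side_a[k], oChrom = bnds$chrom_b[k],
                           oPos = bnds$pos_b[k], oSide = bnds$side_b[k])
    else list(chrom = bnds$chrom_b[k], pos = bnds$pos_b[k],
              side = bnds$side_b[k], oChrom = bnds$chrom_a[k],
              oPos = bnds$pos_a[k], oSide = bnds$side_a[k])
  }
  out <- list()
  for (wi in c("a", "b")) {
    for (wj in c("a", "b")) {
      ei <- ends(i, wi); ej <- ends(j, wj)
      if (ei$chrom != ej$chrom) next
      gap <- abs(ei$pos - ej$pos)
      if (gap >= maxGap) next
      geo <- .checkPairGeometry(ei$side, ej$side,
                                ei$oChrom, ei$oPos, ei$oSide,
                                ej$oChrom, ej$oPos, ej$oSide)
      if (is.null(geo)) next
      out[[length(out) + 1L]] <- list(
        i = i, j = j, gap = gap,
        accChrom = ei$chrom,
        accLow = min(ei$pos, ej$pos), accHigh = max(ei$pos, ej$pos),
        donChrom = ei$oChrom, donLow = geo$donorLow, donHigh = geo$donorHigh,
        span = geo$donorHigh - geo$donorLow,
        orientation = geo$orientation)
    }
  }
  out
}

#' Pair breakends into insertion calls
#'
#' Implements the paired-junction insert rule: two breakends form one insert
#' call when their acceptor-side coordinates lie on the same chromosome less
#' than \code{maxGap} bp apart (strictly), their side flags oppose at the
#' acceptor, and their donor-side positions lie on one chromosome bracketing
#' the donor interval with flags consistent with a single inserted segment
#' in one orientation. When several pairings compete, pairing is resolved
#' greedily by smallest acceptor gap, then smallest donor span; each
#' breakend participates in at most one call. Unpairable breakends are
#' reported in the residual slot, never as an error.
#'
#' @param bnds breakend data.frame (see \code{\link{breakendRecords}}).
#' @param maxGap maximum acceptor-side junction separation, bp (exclusive).
#' @return An \linkS4class{InsertCalls}, sorted by acceptor position.
#' @export
pairBreakendsToInserts <- function(bnds, maxGap = 100L) {
  validateBreakends(bnds)
  stopifnot(maxGap > 0)
  n <- nrow(bnds)
  cands <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        cs <- .candidatePairings(bnds, i, j, maxGap)
        if (length(cs)) {
          # if both end-assignments of the same pair validate, keep the one
          # with the smaller acceptor gap (then smaller donor span)
          o <- order(vapply(cs, `[[`, numeric(1), "gap"),
                     vapply(cs, `[[`, numeric(1), "span"))
          cands[[length(cands) + 1L]] <- cs[[o[1]]]
        }
      }
    }
  }
  if (length(cands)) {
    key <- order(vapply(cands, `[[`, numeric(1), "gap"),
                 vapply(cands, `[[`, numeric(1), "span"),
                 vapply(cands, `[[`, character(1), "accChrom"),
                 vapply(cands, `[[`, numeric(1), "accLow"),
                 vapply(cands, `[[`, character(1), "donChrom"),
                 vapply(cands, `[[`, numeric(1), "donLow"))
    cands <- cands[key]
  }
  used <- rep(FALSE, n)
  picked <- list()
  for (cnd in cands) {
    if (used[cnd$i] || used[cnd$j]) next
    used[cnd$i] <- used[cnd$j] <- TRUE
    picked[[length(picked) + 1L]] <- cnd
  }
  readsOf <- function(k) {
    if ("read_ids" %in% names(bnds)) bnds$read_ids[[k]] else character(0)
  }
  if (length(picked)) {
    ord <- order(vapply(picked, `[[`, character(1), "accChrom"),
                 vapply(picked, `[[`, numeric(1), "accLow"),
                 vapply(picked, `[[`, numeric(1), "accHigh"))
    picked <- picked[ord]
    anchors <- GenomicRanges::GRanges(
      vapply(picked, `[[`, character(1), "accChrom"),
      IRanges::IRanges(vapply(picked, `[[`, numeric(1), "accLow"),
                       vapply(picked, `[[`, numeric(1), "accHigh")))
    orient <- vapply(picked, `[[`, character(1), "orientation")
    donors <- GenomicRanges::GRanges(
      vapply(picked, `[[`, character(1), "donChrom"),
      IRanges::IRanges(vapply(picked, `[[`, numeric(1), "donLow"),
                       vapply(picked, `[[`, numeric(1), "donHigh")),
      strand = ifelse(orient == "same", "+", "-"))
    support <- lapply(picked, function(p) list(readsOf(p$i), readsOf(p$j)))
    lens <- as.integer(vapply(picked, `[[`, numeric(1), "span"))
  } else {
    anchors <- GenomicRanges::GRanges()
    donors <- GenomicRanges::GRanges()
    orient <- character(0)
    support <- list()
    lens <- integer(0)
  }
  residual <- bnds[!used, , drop = FALSE]
  rownames(residual) <- NULL
  new("InsertCalls", anchors = anchors, donors = donors,
      orientation = orient, insertLength = lens, support = support,
      residual = residual)
}

#' Filter insert calls by donor span
#'
#' Retains calls with \code{minLen <= insert length <= maxLen} (inclusive
#' bounds). The counts of calls discarded below and above the window are
#' attached as attributes \code{"discarded_below"} / \code{"discarded_above"}.
#'
#' @param calls \linkS4class{InsertCalls}.
#' @param minLen,maxLen inclusive size window, bp.
#' @return Filtered \linkS4class{InsertCalls}.
#' @export
filterInsertsBySize <- function(calls, minLen = 100L, maxLen = 10000L) {
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  len <- insertLengths(calls)
  keep <- len >= minLen & len <= maxLen
  out <- calls[which(keep)]
  attr(out, "discarded_below") <- sum(len < minLen)
  attr(out, "discarded_above") <- sum(len > maxLen)
  out
}

# best local alignment of a read against an allele sequence, trying both
# orientations; returns score and subject range
.bestLocalAlignment <- function(read, allele, mat) {
  aln1 <- Biostrings::pairwiseAlignment(read, allele, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(read))
  aln2 <- Biostrings::pairwiseAlignment(rc, allele, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
  aln <- if (Biostrings::score(aln1) >= Biostrings::score(aln2)) aln1 else aln2
  rng <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       sStart = Biostrings::start(rng), sEnd = Biostrings::end(rng))
}

#' Genotype an insertion site from long reads
#'
#' For each read, a best local alignment is computed against the
#' insertion-carrying allele and the empty allele (both orientations). A
#' read counts for an allele iff its alignment to that allele covers at
#' least \code{flank} bp on both sides of the junction and scores strictly
#' better than its alignment to the other allele; score ties count for
#' neither. The genotype is summarized as
#' \code{ratio = n_with / (n_with + n_without)}; when both counts are zero
#' the ratio is \code{NA} (flagged undefined).
#'
#' @param reads \code{DNAStringSet} (or character vector) of long reads.
#' @param alleleWith allele sequence carrying the insertion.
#' @param alleleWithout empty allele sequence.
#' @param junctionOffset position of the last base before the junction;
#'   either a single offset shared by both alleles or
#'   \code{c(with = , without = )}.
#' @param flank minimum covered bp required on each side of the junction.
#' @return one-row data.frame: \code{n_with}, \code{n_without},
#'   \code{ratio}, \code{n_uninformative}.
#' @export
genotypeInsertionSite <- function(reads, alleleWith, alleleWithout,
                                  junctionOffset, flank = 100L) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  alleleWith <- as.character(alleleWith)
  alleleWithout <- as.character(alleleWithout)
  if (length(junctionOffset) == 1L)
    junctionOffset <- c(with = junctionOffset, without = junctionOffset)
  offW <- junctionOffset[["with"]]; offO <- junctionOffset[["without"]]
  if (nchar(alleleWith) < 2L * flank || nchar(alleleWithout) < 2L * flank)
    stop("allele sequences must be at least 2 x flank long")
  if (offW < flank || nchar(alleleWith) - offW < flank ||
      offO < flank || nchar(alleleWithout) - offO < flank)
    stop("junction offset leaves less than 'flank' bp on one side")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  nWith <- 0L; nWithout <- 0L; nUninf <- 0L
  for (i in seq_along(reads)) {
    r <- as.character(reads[[i]])
    aW <- .bestLocalAlignment(r, alleleWith, mat)
    aO <- .bestLocalAlignment(r, alleleWithout, mat)
    covW <- aW$sStart <= offW - flank + 1L && aW$sEnd >= offW + flank
    covO <- aO$sStart <= offO - flank + 1L && aO$sEnd >= offO + flank
    if (covW && aW$score > aO$score) nWith <- nWith + 1L
    else if (covO && aO$score > aW$score) nWithout <- nWithout + 1L
    else nUninf <- nUninf + 1L
  }
  ratio <- if (nWith + nWithout == 0L) NA_real_ else
    nWith / (nWith + nWithout)
  data.frame(n_with = nWith, n_without = nWithout, ratio = ratio,
             n_uninformative = nUninf)
}

#' Detect nested insertions inside focal elements
#'
#' Reports every breakend with one side inside a focal element interval and
#' the other side within \code{tolerance} bp of a terminus of a transposon
#' sequence. Single-end evidence suffices (unlike
#' \code{\link{pairBreakendsToInserts}}, which requires both junctions).
#'
#' @param bnds breakend data.frame.
#' @param focalElements \code{GRanges} of focal element intervals (e.g. the
#'   genomic copies of the trapping element); names are reported.
#' @param transposonLengths named integer vector: length of each transposon
#'   reference sequence; a breakend side on one of these sequences is a
#'   "transposon end" when its coordinate is within \code{tolerance} of
#'   position 1 or of the sequence length.
#' @param tolerance bp tolerance around the transposon termini.
#' @return data.frame: breakend index, transposon, terminus
#'   (\code{"5prime"}/\code{"3prime"}), transposon coordinate, focal element,
#'   offset of the junction inside the focal element.
#' @export
detectNestedInsertions <- function(bnds, focalElements, transposonLengths,
                                   tolerance = 100L) {
  validateBreakends(bnds)
  stopifnot(!is.null(names(transposonLengths)))
  rows <- list()
  elNames <- names(focalElements)
  if (is.null(elNames)) elNames <- paste0("focal", seq_along(focalElements))
  for (k in seq_len(nrow(bnds))) {
    for (w in c("a", "b")) {
      tChrom <- if (w == "a") bnds$chrom_a[k] else bnds$chrom_b[k]
      tPos <- if (w == "a") bnds$pos_a[k] else bnds$pos_b[k]
      gChrom <- if (w == "a") bnds$chrom_b[k] else bnds$chrom_a[k]
      gPos <- if (w == "a") bnds$pos_b[k] else bnds$pos_a[k]
      if (!tChrom %in% names(transposonLengths)) next
      L <- transposonLengths[[tChrom]]
      d5 <- tPos - 1L
      d3 <- L - tPos
      if (min(d5, d3) > tolerance) next
      hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(gChrom, IRanges::IRanges(gPos, gPos)),
        focalElements)
      if (!length(hit)) next
      ei <- S4Vectors::subjectHits(hit)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        breakend = k, transposon = tChrom,
        terminus = if (d5 <= d3) "5prime" else "3prime",
        transposon_pos = tPos, focal_element = elNames[ei],
        offset_in_element = gPos - GenomicRanges::start(focalElements)[ei] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(breakend = integer(0), transposon = character(0),
                      terminus = character(0), transposon_pos = integer(0),
                      focal_element = character(0),
                      offset_in_element = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
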