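# piRNA-defining filters, stranded coverage, and the ping-pong / phasing
# signature statistics.
#
# Conventions (1-based closed coordinates):
#   '+' read: 5' end = start, 3' end = end.
#   '-' read: 5' end = end,   3' end = start.
# Ping-pong: for every opposite-strand placement pair, the 5'-5' overlap is
#   k = (minus 5') - (plus 5') + 1, accumulated for k in 1..20; z at k = 10,
#   background {1..9, 11..20}.
# Phasing: for every same-strand ordered placement pair, the distance from
#   the upstream 3' end to the downstream 5' end is accumulated for
#   d in 0..19 with immediately head-to-tail reads at d = 1 and a 1-nt
#   overlap at d = 0; z at d = 1, background {0, 2..19}.
# Each placement pair contributes weight 1, so multi-mapped placements all
# contribute and frequencies are invariant under uniform duplication of the
# library.

#' Filter alignment records to piRNA length bounds
#'
#' @param records alignment record data.frame.
#' @param minLen minimum read length (nt), inclusive.
#' @param maxLen maximum read length, inclusive; \code{NULL} for no bound.
#' @return the retained records.
#' @export
filterPirnaAlignments <- function(records, minLen = 23L, maxLen = NULL) {
  validateAlignmentRecords(records)
  if (!is.null(maxLen) && minLen > maxLen) stop("minLen must be <= maxLen")
  keep <- records$read_length >= minLen
  if (!is.null(maxLen)) keep <- keep & records$read_length <= maxLen
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stranded per-nucleotide coverage over a region
#'
#' Counts each mapped placement once; reads partially overlapping the region
#' contribute only their in-region positions. For display conventions the
#' antisense track is conventionally plotted with negative values; the
#' returned vectors are both nonnegative.
#'
#' @param records alignment record data.frame.
#' @param region a \code{GRanges} of length 1, or a list/vector with
#'   \code{chrom}, \code{start}, \code{end}.
#' @return list with integer vectors \code{sense} and \code{antisense} of
#'   length \code{width(region)}.
#' @export
strandedCoverage <- function(records, region) {
  validateAlignmentRecords(records)
  if (methods::is(region, "GRanges")) {
    stopifnot(length(region) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(region))
    rs <- GenomicRanges::start(region); re <- GenomicRanges::end(region)
  } else {
    chrom <- as.character(region[["chrom"]])
    rs <- as.integer(region[["start"]]); re <- as.integer(region[["end"]])
  }
  w <- re - rs + 1L
  cov1 <- function(df) {
    if (!nrow(df)) return(integer(w))
    s <- pmax(df$start, rs) - rs + 1L
    e <- pmin(df$end, re) - rs + 1L
    ok <- s <= e
    if (!any(ok)) return(integer(w))
    as.integer(IRanges::coverage(IRanges::IRanges(s[ok], e[ok]), width = w))
  }
  sel <- records$chrom == chrom
  list(sense = cov1(records[sel & records$strand == "+", , drop = FALSE]),
       antisense = cov1(records[sel & records$strand == "-", , drop = FALSE]))
}

# weighted position tallies: named count vectors of 5'/3' end coordinates
.endWeights <- function(pos) {
  t <- table(pos)
  stats::setNames(as.numeric(t), names(t))
}

# sum over positions of wA[p] * wB[p + delta]
.pairCountAtOffset <- function(wA, wB, delta) {
  pa <- as.integer(names(wA))
  tgt <- as.character(pa + delta)
  hit <- wB[tgt]
  hit[is.na(hit)] <- 0
  sum(wA * hit)
}

#' Ping-pong signature z-score
#'
#' Accumulates the 5'-5' overlap of every opposite-strand placement pair
#' over overlaps 1..20 nt, normalizes to frequencies, and reports the
#' z-score at the 10-nt overlap against the background overlaps
#' \{1..9, 11..20\}. Callers should supply records already restricted to
#' the ping-pong length window (conventionally 23-32 nt, see
#' \code{\link{filterPirnaAlignments}}).
#'
#' @param records alignment record data.frame; must contain reads on both
#'   strands.
#' @param uniqueOnly drop multi-mapped placements (\code{n_placements > 1}).
#' @return A \linkS4class{SignatureResult}.
#' @export
pingpongZscore <- function(records, uniqueOnly = FALSE) {
  validateAlignmentRecords(records)
  if (uniqueOnly) records <- records[records$n_placements == 1L, , drop = FALSE]
  plus <- records[records$strand == "+", , drop = FALSE]
  minus <- records[records$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0L || nrow(minus) == 0L)
    stop("ping-pong signature requires reads on both strands")
  counts <- numeric(20)
  byChrom <- intersect(unique(plus$chrom), unique(minus$chrom))
  for (ch in byChrom) {
    w5p <- .endWeights(plus$start[plus$chrom == ch])
    w5m <- .endWeights(minus$end[minus$chrom == ch])
    for (k in 1:20)
      counts[k] <- counts[k] + .pairCountAtOffset(w5p, w5m, k - 1L)
  }
  n <- sum(counts)
  .SignatureResult("pingpong", 1:20,
                   if (n > 0) counts / n else counts,
                   focal = 10L, background = c(1:9, 11:20), n = n)
}

#' Phasing (head-to-tail) signature z-score
#'
#' Accumulates, for every same-strand ordered placement pair, the distance
#' between the upstream read's 3' end and the downstream read's 5' end over
#' distances 0..19 nt (immediately adjacent head-to-tail reads give
#' distance 1), normalizes to frequencies, and reports the z-score at
#' distance 1 against the background distances \{0, 2..19\}.
#'
#' @param records alignment record data.frame; must contain at least two
#'   same-strand reads.
#' @param uniqueOnly drop multi-mapped placements.
#' @return A \linkS4class{SignatureResult}.
#' @export
phasingZscore <- function(records, uniqueOnly = FALSE) {
  validateAlignmentRecords(records)
  if (uniqueOnly) records <- records[records$n_placements == 1L, , drop = FALSE]
  nPlus <- sum(records$strand == "+")
  nMinus <- sum(records$strand == "-")
  if (max(nPlus, nMinus) < 2L)
    stop("phasing signature requires at least two same-strand reads")
  counts <- numeric(20)  # distances 0..19
  for (ch in unique(records$chrom)) {
    plus <- records[records$chrom == ch & records$strand == "+", ,
                    drop = FALSE]
    minus <- records[records$chrom == ch & records$strand == "-", ,
                     drop = FALSE]
    if (nrow(plus) >= 2L) {
      w3 <- .endWeights(plus$end)    # upstream 3' ends
      w5 <- .endWeights(plus$start)  # downstream 5' ends
      for (d in 0:19)
        counts[d + 1L] <- counts[d + 1L] + .pairCountAtOffset(w3, w5, d)
    }
    if (nrow(minus) >= 2L) {
      w3 <- .endWeights(minus$start)  # 3' end of a '-' read is its start
      w5 <- .endWeights(minus$end)    # 5' end is its end
      for (d in 0:19)
        counts[d + 1L] <- counts[d + 1L] + .pairCountAtOffset(w3, w5, -d)
    }
  }
  # self-pairing cannot occur (a read's own 5' is upstream of its 3'),
  # but identically-placed distinct placements contribute at d = read
  # length apart only; both are handled by the coordinate arithmetic.
  n <- sum(counts)
  .SignatureResult("phasing", 0:19,
                   if (n > 0) counts / n else counts,
                   focal = 1L, background = c(0L, 2:19), n = n)
}

#' Read length distribution
#'
#' @param records alignment record data.frame (nonempty).
#' @param window length-2 integer window \code{c(a, b)}; the fraction of
#'   reads with a <= length <= b is reported.
#' @return list with \code{histogram} (named integer counts) and
#'   \code{windowFraction}.
#' @export
lengthDistribution <- function(records, window = c(26L, 32L)) {
  validateAlignmentRecords(records)
  if (!nrow(records)) stop("no records: length distribution undefined")
  h <- table(records$read_length)
  frac <- sum(records$read_length >= window[1] &
                records$read_length <= window[2]) / nrow(records)
  list(histogram = h, windowFraction = frac)
}
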