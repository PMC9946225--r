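# SNP sites distinguishing near-identical element copies, and the allele
# composition of reads at those sites.

#' Align element copies onto a reference copy
#'
#' Each copy is globally aligned to the reference copy and projected onto
#' the reference coordinate system: the result is a character matrix with
#' one row per copy and one column per reference position. A deletion in a
#' copy appears as \code{"-"}; insertions relative to the reference carry
#' no reference coordinate and are dropped (they can never be substitution
#' SNP sites). This assumes the near-identical regime of recently expanded
#' copies: a copy with < \code{minIdentity} percent identity to the
#' reference is an error.
#'
#' @param copies named \code{DNAStringSet} of copy sequences
#'   (element-sense).
#' @param referenceId name of the reference copy.
#' @param minIdentity minimum percent identity to the reference.
#' @return character matrix (copies x reference positions), reference row
#'   included; attribute \code{"referenceId"} names the reference.
#' @export
alignCopies <- function(copies, referenceId, minIdentity = 90) {
  stopifnot(!is.null(names(copies)), referenceId %in% names(copies))
  refChar <- as.character(copies[[referenceId]])
  L <- nchar(refChar)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  out <- matrix("-", nrow = length(copies), ncol = L,
                dimnames = list(names(copies), NULL))
  out[referenceId, ] <- strsplit(refChar, "")[[1]]
  for (id in setdiff(names(copies), referenceId)) {
    aln <- Biostrings::pairwiseAlignment(copies[[id]], refChar,
                                         type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    if (Biostrings::pid(aln) < minIdentity)
      stop(sprintf("copy '%s' is only %.1f%% identical to '%s'; ",
                   id, Biostrings::pid(aln), referenceId),
           "outside the near-identical regime this method assumes")
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    refPos <- cumsum(sub != "-")
    keep <- sub != "-"
    out[id, refPos[keep]] <- pat[keep]
  }
  attr(out, "referenceId") <- referenceId
  out
}

#' Call SNP sites from a copy alignment
#'
#' A reference column is a SNP site iff it contains at least two distinct
#' non-gap nucleotides and no copy has a gap there (gap columns are
#' excluded: the sites are substitution polymorphisms). Sites are ordered
#' by reference offset.
#'
#' @param alignment character matrix from \code{\link{alignCopies}}.
#' @return data.frame with \code{ref_position} (1-based offset in the
#'   reference copy) and one allele column per copy.
#' @export
callSnpSites <- function(alignment) {
  nt <- c("A", "C", "G", "T")
  isSite <- apply(alignment, 2, function(col) {
    all(col %in% nt) && length(unique(col)) >= 2L
  })
  pos <- which(isSite)
  df <- data.frame(ref_position = pos)
  for (cp in rownames(alignment)) df[[cp]] <- alignment[cp, pos]
  df
}

#' Tile long reads into fixed-width windows
#'
#' Splits each input sequence into consecutive non-overlapping windows of
#' \code{window} nt; a terminal remainder shorter than the window is
#' discarded. Provenance (parent read and offset) is retained in the names
#' and in the returned table.
#'
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @param window tile width, nt (>= 20).
#' @return list with \code{tiles} (\code{DNAStringSet}, names
#'   \code{parent|offset}) and \code{provenance} (data.frame: tile_id,
#'   parent_id, offset).
#' @export
tileReads <- function(seqs, window = 33L) {
  window <- as.integer(window)
  if (window < 20L) stop("window must be >= 20")
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)))
  tiles <- list(); prov <- list()
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    nTiles <- nchar(s) %/% window
    if (nTiles == 0L) next
    offs <- (seq_len(nTiles) - 1L) * window + 1L
    tl <- substring(s, offs, offs + window - 1L)
    ids <- sprintf("%s|%d", names(seqs)[i], offs)
    tiles[[length(tiles) + 1L]] <- stats::setNames(tl, ids)
    prov[[length(prov) + 1L]] <- data.frame(
      tile_id = ids, parent_id = names(seqs)[i], offset = offs,
      stringsAsFactors = FALSE)
  }
  if (!length(tiles)) {
    return(list(tiles = Biostrings::DNAStringSet(),
                provenance = data.frame(tile_id = character(0),
                                        parent_id = character(0),
                                        offset = integer(0))))
  }
  list(tiles = Biostrings::DNAStringSet(unlist(tiles)),
       provenance = do.call(rbind, prov))
}

#' Map reads ungapped to a single reference copy
#'
#' Places each read on the reference by exact/near-exact ungapped matching
#' on both strands, allowing up to \code{maxMismatches} substitutions.
#' Multi-mapping reads are reported at every placement when
#' \code{multimap = TRUE}, otherwise only at their best placement (fewest
#' mismatches; ties broken by position, plus strand first). Reads with no
#' placement within the mismatch bound are dropped.
#'
#' @param reads named \code{DNAStringSet} or named character vector.
#' @param reference reference sequence (character or \code{DNAString}).
#' @param maxMismatches mismatch allowance.
#' @param multimap report all placements (TRUE) or the best one (FALSE).
#' @param library library label stored on the records.
#' @return alignment record data.frame (with \code{seq} in read
#'   orientation).
#' @export
mapReadsUngapped <- function(reads, reference, maxMismatches = 2L,
                             multimap = TRUE, library = NA_character_) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  stopifnot(!is.null(names(reads)))
  ref <- if (is.character(reference)) Biostrings::DNAString(reference) else
    reference
  rows <- list()
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    hits <- list()
    for (std in c("+", "-")) {
      pat <- if (std == "+") r else Biostrings::reverseComplement(r)
      m <- Biostrings::matchPattern(pat, ref, max.mismatch = maxMismatches)
      if (!length(m)) next
      nm <- Biostrings::neditStartingAt(pat, ref, starting.at = IRanges::start(m))
      hits[[std]] <- data.frame(start = IRanges::start(m),
                                end = IRanges::end(m), strand = std,
                                mismatches = nm, stringsAsFactors = FALSE)
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    h <- h[order(h$mismatches, h$start, h$strand), , drop = FALSE]
    if (!multimap) h <- h[1, , drop = FALSE]
    np <- nrow(h)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = names(reads)[i], start = h$start, end = h$end,
      strand = h$strand, mismatches = h$mismatches, n_placements = np,
      seq = as.character(r), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(alignmentRecords(character(0), character(0), integer(0),
                            integer(0), character(0)))
  }
  df <- do.call(rbind, rows)
  alignmentRecords(df$read_id, "reference", df$start, df$end, df$strand,
                   df$mismatches, df$n_placements, df$seq, library)
}

#' Allele composition of reads at SNP sites
#'
#' For each SNP site, reads overlapping the site contribute the nucleotide
#' their sequence places at that reference position, stratified by mapping
#' strand and library. Antisense reads are complement-corrected so the
#' table is in reference-copy sense space. Reads exceeding the mismatch
#' allowance are excluded entirely; a read with an ambiguous base (N) at a
#' site is excluded from that site only. Multi-mapped reads contribute once
#' per read at their best placement when \code{perPlacement = FALSE}
#' (default), or once per placement otherwise.
#'
#' @param records alignment record data.frame with \code{seq} (read
#'   orientation) and optionally \code{library}.
#' @param snpSites data.frame with \code{ref_position} (e.g. from
#'   \code{\link{callSnpSites}}).
#' @param referenceLength length of the reference copy (sites outside it
#'   are an error).
#' @param maxMismatches records with more mismatches are excluded.
#' @param perPlacement count every placement of a multi-mapped read.
#' @return data.frame: site_index, ref_position, strand (sense/antisense),
#'   library, nucleotide counts \code{A,C,G,T}, and \code{coverage} (reads
#'   overlapping the site in that stratum, N-reads included).
#' @export
alleleComposition <- function(records, snpSites, referenceLength,
                              maxMismatches = 2L, perPlacement = FALSE) {
  validateAlignmentRecords(records)
  if (any(snpSites$ref_position < 1L | snpSites$ref_position > referenceLength))
    stop("SNP site outside the reference copy")
  records <- records[records$mismatches <= maxMismatches, , drop = FALSE]
  if (!nrow(records)) {
    out <- expand.grid(site_index = seq_len(nrow(snpSites)),
                       strand = c("sense", "antisense"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- out[order(out$site_index), ]
    res <- data.frame(site_index = out$site_index,
                      ref_position = snpSites$ref_position[out$site_index],
                      strand = out$strand, library = "library",
                      A = 0, C = 0, G = 0, T = 0, coverage = 0L)
    rownames(res) <- NULL
    return(res)
  }
  if (!perPlacement) {
    # best placement per read: fewest mismatches, then position, + first
    o <- order(records$read_id, records$mismatches, records$start,
               records$strand)
    records <- records[o, , drop = FALSE]
    records <- records[!duplicated(records$read_id), , drop = FALSE]
  }
  if (!("library" %in% names(records)) || all(is.na(records$library)))
    records$library <- "library"
  nt <- c("A", "C", "G", "T")
  out <- list()
  for (si in seq_len(nrow(snpSites))) {
    p <- snpSites$ref_position[si]
    ov <- records[records$start <= p & records$end >= p, , drop = FALSE]
    for (lib in unique(ov$library)) {
      for (std in c("+", "-")) {
        sub <- ov[ov$library == lib & ov$strand == std, , drop = FALSE]
        counts <- stats::setNames(numeric(4), nt)
        if (nrow(sub)) {
          # nucleotide the read places at reference position p, sense space
          idx <- ifelse(sub$strand == "+", p - sub$start + 1L,
                        sub$end - p + 1L)
          base <- substr(sub$seq, idx, idx)
          base[sub$strand == "-"] <- complementBase(base[sub$strand == "-"])
          tb <- table(factor(base, levels = nt))
          counts[names(tb)] <- as.numeric(tb)
        }
        out[[length(out) + 1L]] <- data.frame(
          site_index = si, ref_position = p,
          strand = if (std == "+") "sense" else "antisense",
          library = lib, A = counts["A"], C = counts["C"], G = counts["G"],
          T = counts["T"], coverage = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(site_index = integer(0), ref_position = integer(0),
                      strand = character(0), library = character(0),
                      A = numeric(0), C = numeric(0), G = numeric(0),
                      T = numeric(0), coverage = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
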