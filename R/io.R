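# Readers/writers for the standard formats the pipeline touches.
#
# Coordinate convention: 1-based, closed intervals everywhere inside the
# package (the native GRanges/Biostrings convention). Conversions happen only
# at format boundaries: BED (0-based half-open) is shifted on read/write,
# VCF and SAM are already 1-based.

#' Read a FASTA file into a named DNAStringSet
#'
#' Sequences are uppercased; IUPAC letters are preserved; record order is
#' retained. Duplicated identifiers and empty sequences are format errors
#' (the offending header line is named).
#'
#' @param path path to a FASTA file.
#' @return A named \code{DNAStringSet}.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  nm <- sub("\\s.*$", "", names(x))
  names(x) <- nm
  bad <- which(Biostrings::width(x) == 0L)
  if (length(bad)) {
    lines <- readLines(path)
    ln <- which(lines == paste0(">", names(x)[bad[1]]) |
                  startsWith(lines, paste0(">", names(x)[bad[1]], " ")))[1]
    stop(sprintf("empty sequence for record '%s' (line %s) in %s",
                 names(x)[bad[1]], ifelse(is.na(ln), "?", ln), path))
  }
  if (anyDuplicated(nm)) {
    dup <- nm[duplicated(nm)][1]
    lines <- readLines(path)
    ln <- which(lines == paste0(">", dup) | startsWith(lines, paste0(">", dup, " ")))
    stop(sprintf("duplicated FASTA identifier '%s' (lines %s) in %s",
                 dup, paste(ln, collapse = ", "), path))
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param x named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaFile <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Breakends
# ---------------------------------------------------------------------------

#' Construct a breakend record table
#'
#' A breakend is one junction between two genomic positions; each side
#' carries a flag naming the side of the coordinate on which the junction
#' lies (\code{"left"} or \code{"right"}). The record is symmetric: swapping
#' the A and B sides denotes the same junction.
#'
#' @param chromA,posA,sideA first position (chrom, 1-based coordinate, side).
#' @param chromB,posB,sideB second position.
#' @param readIds list of character vectors of supporting read ids (one
#'   vector per record), or NULL.
#' @return data.frame with columns \code{chrom_a, pos_a, side_a, chrom_b,
#'   pos_b, side_b, read_ids} (list column).
#' @export
breakendRecords <- function(chromA, posA, sideA, chromB, posB, sideB,
                            readIds = NULL) {
  n <- length(chromA)
  if (is.null(readIds)) readIds <- rep(list(character(0)), n)
  df <- data.frame(chrom_a = as.character(chromA), pos_a = as.integer(posA),
                   side_a = as.character(sideA), chrom_b = as.character(chromB),
                   pos_b = as.integer(posB), side_b = as.character(sideB),
                   stringsAsFactors = FALSE)
  df$read_ids <- readIds
  validateBreakends(df)
  df
}

validateBreakends <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom_a", "pos_a", "side_a", "chrom_b", "pos_b", "side_b")
                %in% names(df)))
  if (nrow(df)) {
    if (any(df$pos_a < 1L) || any(df$pos_b < 1L))
      stop("breakend coordinates must be >= 1")
    if (!all(df$side_a %in% c("left", "right")) ||
        !all(df$side_b %in% c("left", "right")))
      stop("breakend sides must be 'left' or 'right'")
  }
  invisible(df)
}

# VCF 4.2 BND bracket notation <-> side flags.
#   t[p[  : junction right of POS, attaches left of mate  -> (right, left)
#   t]p]  : junction right of POS, attaches right of mate -> (right, right)
#   ]p]t  : junction left of POS, attaches right of mate  -> (left, right)
#   [p[t  : junction left of POS, attaches left of mate   -> (left, left)
.decodeBndAlt <- function(alt) {
  m <- regmatches(alt, regexec("^([ACGTN]*)(\\[|\\])([^\\[\\]:]+):([0-9]+)(\\[|\\])([ACGTN]*)$",
                               alt, perl = TRUE))[[1]]
  if (length(m) != 7L || m[3] != m[6]) return(NULL)
  pre <- m[2]; post <- m[7]; br <- m[3]
  if (nzchar(pre) == nzchar(post)) return(NULL)  # exactly one side carries bases
  if (nzchar(pre)) {
    sideA <- "right"
    sideB <- if (br == "[") "left" else "right"
  } else {
    sideA <- "left"
    sideB <- if (br == "]") "right" else "left"
  }
  list(chromB = m[4], posB = as.integer(m[5]), sideA = sideA, sideB = sideB)
}

.encodeBndAlt <- function(chromB, posB, sideA, sideB) {
  p <- paste0(chromB, ":", posB)
  if (sideA == "right") {
    if (sideB == "left") paste0("N[", p, "[") else paste0("N]", p, "]")
  } else {
    if (sideB == "right") paste0("]", p, "]N") else paste0("[", p, "[N")
  }
}

#' Read breakend records
#'
#' Two dialects are supported: \code{"vcf_bnd"} (VCF 4.2 BND records, bracket
#' notation decoded into side flags; non-BND records ignored) and
#' \code{"candidates_bed"}, a 6-column tab-separated breakend-pair layout
#' with 0-based coordinates: chromA, posA0, chromB, posB0, sideA-sideB,
#' comma-joined read ids (\code{.} when none). Records whose bracket or side
#' string cannot be decoded are skipped with a warning giving the skip count.
#'
#' @param path input file.
#' @param dialect \code{"vcf_bnd"} or \code{"candidates_bed"}.
#' @return breakend data.frame (see \code{\link{breakendRecords}}); the
#'   number of skipped records is attached as attribute \code{"skipped"}.
#' @export
readBreakends <- function(path, dialect = c("vcf_bnd", "candidates_bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  skipped <- 0L
  if (dialect == "vcf_bnd") {
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 8L) { skipped <- skipped + 1L; next }
      dec <- .decodeBndAlt(f[5])
      if (is.null(dec)) { skipped <- skipped + 1L; next }
      reads <- character(0)
      rm_ <- regmatches(f[8], regexec("(?:^|;)READS=([^;]*)", f[8]))[[1]]
      if (length(rm_) == 2L && nzchar(rm_[2]))
        reads <- strsplit(rm_[2], ",", fixed = TRUE)[[1]]
      recs[[i]] <- list(f[1], as.integer(f[2]), dec$sideA,
                        dec$chromB, dec$posB, dec$sideB, reads)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      ok <- length(f) >= 6L
      sides <- if (ok) strsplit(f[5], "-", fixed = TRUE)[[1]] else character(0)
      if (!ok || length(sides) != 2L || !all(sides %in% c("left", "right"))) {
        skipped <- skipped + 1L; next
      }
      reads <- if (f[6] == ".") character(0) else
        strsplit(f[6], ",", fixed = TRUE)[[1]]
      recs[[i]] <- list(f[1], as.integer(f[2]) + 1L, sides[1],
                        f[3], as.integer(f[4]) + 1L, sides[2], reads)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d unparseable breakend record(s) in %s",
                    skipped, path))
  out <- if (length(recs)) {
    breakendRecords(
      vapply(recs, `[[`, character(1), 1), vapply(recs, `[[`, integer(1), 2),
      vapply(recs, `[[`, character(1), 3), vapply(recs, `[[`, character(1), 4),
      vapply(recs, function(r) as.integer(r[[5]]), integer(1)),
      vapply(recs, `[[`, character(1), 6), lapply(recs, `[[`, 7))
  } else {
    breakendRecords(character(0), integer(0), character(0), character(0),
                    integer(0), character(0))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write breakend records
#'
#' @param df breakend data.frame.
#' @param path output path.
#' @param dialect see \code{\link{readBreakends}}.
#' @return \code{path}, invisibly.
#' @export
writeBreakends <- function(df, path, dialect = c("vcf_bnd", "candidates_bed")) {
  dialect <- match.arg(dialect)
  validateBreakends(df)
  reads <- if ("read_ids" %in% names(df)) df$read_ids else
    rep(list(character(0)), nrow(df))
  rstr <- vapply(reads, function(r)
    if (length(r)) paste(r, collapse = ",") else "", character(1))
  if (dialect == "vcf_bnd") {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=READS,Number=.,Type=String,Description=\"Supporting reads\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      alt <- .encodeBndAlt(df$chrom_b[i], df$pos_b[i], df$side_a[i], df$side_b[i])
      info <- paste0("SVTYPE=BND",
                     if (nzchar(rstr[i])) paste0(";READS=", rstr[i]) else "")
      body[i] <- paste(df$chrom_a[i], df$pos_a[i], paste0("bnd_", i), "N",
                       alt, ".", "PASS", info, sep = "\t")
    }
    writeLines(c(hdr, body), path)
  } else {
    body <- paste(df$chrom_a, df$pos_a - 1L, df$chrom_b, df$pos_b - 1L,
                  paste0(df$side_a, "-", df$side_b),
                  ifelse(nzchar(rstr), rstr, "."), sep = "\t")
    writeLines(body, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED
# ---------------------------------------------------------------------------

#' Read a BED file as GRanges
#'
#' 0-based half-open BED coordinates are converted to the internal 1-based
#' closed convention (via rtracklayer).
#'
#' @param path BED file.
#' @return \code{GRanges}.
#' @export
readBedFile <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write intervals as BED6
#'
#' Writes 0-based half-open BED6 lines (name and score as \code{.} unless a
#' \code{name} metadata column is present). Round-trips with
#' \code{\link{readBedFile}} on chrom/start/end/strand.
#'
#' @param gr \code{GRanges} (negative or zero coordinates are an error).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedFile <- function(gr, path) {
  if (length(gr) && any(GenomicRanges::start(gr) < 1L))
    stop("negative or zero start coordinate cannot be written as BED")
  if (!length(gr)) { writeLines(character(0), path); return(invisible(path)) }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(".", length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                 nm, ".", strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Alignment records (SAM subset / tabular)
# ---------------------------------------------------------------------------

#' Construct an alignment record table
#'
#' The tabular form of ungapped small-RNA/mRNA alignments used throughout:
#' one row per mapped placement; multi-mapped reads appear as multiple rows
#' sharing \code{read_id}, with the multiplicity in \code{n_placements}.
#' Coordinates are 1-based closed; for ungapped records
#' \code{end - start + 1 == read_length}.
#'
#' @param readId read identifiers.
#' @param chrom reference names.
#' @param start,end 1-based closed coordinates.
#' @param strand \code{"+"} or \code{"-"} (mapping strand).
#' @param mismatches mismatch counts (>= 0).
#' @param nPlacements multi-mapping multiplicities (>= 1).
#' @param seq read sequences in original (read) orientation, or NA.
#' @param library library labels, or NA.
#' @return data.frame of alignment records.
#' @export
alignmentRecords <- function(readId, chrom, start, end, strand,
                             mismatches = 0L, nPlacements = 1L,
                             seq = NA_character_, library = NA_character_) {
  n <- length(readId)
  chrom <- rep_len(as.character(chrom), n)
  mismatches <- rep_len(as.integer(mismatches), n)
  nPlacements <- rep_len(as.integer(nPlacements), n)
  seq <- rep_len(as.character(seq), n)
  library <- rep_len(as.character(library), n)
  df <- data.frame(read_id = as.character(readId), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   read_length = as.integer(end) - as.integer(start) + 1L,
                   mismatches = as.integer(mismatches),
                   n_placements = as.integer(nPlacements),
                   seq = as.character(seq), library = as.character(library),
                   stringsAsFactors = FALSE)
  validateAlignmentRecords(df)
  df
}

validateAlignmentRecords <- function(df) {
  need <- c("read_id", "chrom", "start", "end", "strand", "read_length",
            "mismatches", "n_placements")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (nrow(df)) {
    if (any(df$start < 1L) || any(df$end < df$start))
      stop("alignment records need 1 <= start <= end")
    if (any(df$end - df$start + 1L != df$read_length))
      stop("ungapped records require end - start + 1 == read_length")
    if (any(df$mismatches < 0L)) stop("mismatches must be >= 0")
    if (any(df$n_placements < 1L)) stop("n_placements must be >= 1")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  invisible(df)
}

#' Read a SAM-text subset into alignment records
#'
#' Parses only the fields the pipeline needs (QNAME, FLAG strand bit, RNAME,
#' POS, sequence length, NM and NH tags); full CIGAR semantics are not
#' interpreted (records are treated as ungapped, spanning the sequence
#' length). Unmapped records are dropped. An absent NM tag is treated as 0
#' mismatches with one warning; an absent NH tag falls back to the
#' within-file multiplicity of the read name.
#'
#' @param path SAM text file.
#' @param library optional library label stored on every record.
#' @return alignment record data.frame (with \code{seq}).
#' @export
readSamSubset <- function(path, library = NA_character_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(alignmentRecords(character(0), character(0), integer(0), integer(0),
                            character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmMissing <- FALSE
  rows <- lapply(fields, function(f) {
    if (length(f) < 11L) stop("malformed SAM line: ", paste(f, collapse = " "))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    if (f[10] == "*") stop("SAM record without sequence: ", f[1])
    tags <- if (length(f) > 11L) f[12:length(f)] else character(0)
    nm <- sub("^NM:i:", "", grep("^NM:i:", tags, value = TRUE))
    nh <- sub("^NH:i:", "", grep("^NH:i:", tags, value = TRUE))
    list(read_id = f[1], chrom = f[3], start = as.integer(f[4]),
         len = nchar(f[10]),
         strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
         mismatches = if (length(nm)) as.integer(nm[1]) else NA_integer_,
         n_placements = if (length(nh)) as.integer(nh[1]) else NA_integer_,
         seq = f[10])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  mm <- vapply(rows, `[[`, integer(1), "mismatches")
  if (anyNA(mm)) {
    warning("NM tag absent for some records; mismatches treated as 0")
    mm[is.na(mm)] <- 0L
  }
  ids <- vapply(rows, `[[`, character(1), "read_id")
  np <- vapply(rows, `[[`, integer(1), "n_placements")
  mult <- table(ids)
  np[is.na(np)] <- as.integer(mult[ids[is.na(np)]])
  st <- vapply(rows, `[[`, integer(1), "start")
  ln <- vapply(rows, `[[`, integer(1), "len")
  alignmentRecords(ids, vapply(rows, `[[`, character(1), "chrom"),
                   st, st + ln - 1L,
                   vapply(rows, `[[`, character(1), "strand"),
                   mm, np, vapply(rows, `[[`, character(1), "seq"), library)
}

#' Write / read alignment records as TSV
#'
#' Plain tab-separated serialization of the alignment record table, for
#' stage-to-stage plumbing.
#'
#' @param df alignment record data.frame.
#' @param path file path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
writeAlignmentRecords <- function(df, path) {
  validateAlignmentRecords(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignmentRecords
#' @export
readAlignmentRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(read_id = "character",
                                         chrom = "character",
                                         seq = "character",
                                         library = "character"))
  validateAlignmentRecords(df)
  df
}
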