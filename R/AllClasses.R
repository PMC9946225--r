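#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString
NULL

# ---------------------------------------------------------------------------
# ElementModel
# ---------------------------------------------------------------------------

#' Transposable-element model for the simulators
#'
#' Describes one element family: its consensus sequence, structural class, and
#' the divergence model applied when copies are planted in a genome. LTR
#' elements carry identical terminal repeats of \code{ltrLength} bp at both
#' ends and transpose as full-length copies; non-LTR elements produce
#' 5'-truncated copies whose retained 3' fraction is drawn from a Beta
#' distribution; ITR elements transpose full length.
#'
#' @slot name single identifier for the family.
#' @slot consensus \code{DNAString} consensus sequence.
#' @slot elementClass one of \code{"LTR"}, \code{"non_LTR"}, \code{"ITR"}.
#' @slot ltrLength terminal-repeat length in bp (LTR class only, else 0).
#' @slot snpRate per-bp substitution probability between copies, in [0, 0.05].
#' @slot truncationShape length-2 Beta shape parameters for the retained
#'   3' fraction of non_LTR copies.
#' @exportClass ElementModel
setClass("ElementModel",
  representation(
    name = "character",
    consensus = "DNAString",
    elementClass = "character",
    ltrLength = "integer",
    snpRate = "numeric",
    truncationShape = "numeric"
  )
)

setValidity("ElementModel", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!object@elementClass %in% c("LTR", "non_LTR", "ITR"))
    msg <- c(msg, "'elementClass' must be LTR, non_LTR or ITR")
  if (object@snpRate < 0 || object@snpRate > 0.05)
    msg <- c(msg, "'snpRate' must lie in [0, 0.05]")
  if (object@elementClass == "LTR") {
    L <- length(object@consensus)
    k <- object@ltrLength
    if (k < 1L || 2L * k > L) {
      msg <- c(msg, "LTR class requires 0 < ltrLength <= consensus length / 2")
    } else {
      lt <- as.character(Biostrings::subseq(object@consensus, 1L, k))
      rt <- as.character(Biostrings::subseq(object@consensus, L - k + 1L, L))
      if (!identical(lt, rt))
        msg <- c(msg, "LTR consensus must begin and end with identical terminal repeats")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ElementModel
#'
#' @param name family identifier.
#' @param consensus consensus sequence (character or \code{DNAString}).
#' @param elementClass \code{"LTR"}, \code{"non_LTR"} or \code{"ITR"}.
#' @param ltrLength terminal-repeat length in bp (LTR only).
#' @param snpRate per-bp substitution probability between copies.
#' @param truncationShape Beta shape parameters for the retained 3' fraction
#'   of non_LTR copies; the default (1, 1) draws the fraction uniformly.
#' @return An \linkS4class{ElementModel}.
#' @examples
#' em <- ElementModel("toy", makeLtrConsensus(400, 50, seed = 1),
#'                    "LTR", ltrLength = 50, snpRate = 0.005)
#' @export
ElementModel <- function(name, consensus, elementClass = c("LTR", "non_LTR", "ITR"),
                         ltrLength = 0L, snpRate = 0.005,
                         truncationShape = c(1, 1)) {
  elementClass <- match.arg(elementClass)
  if (is.character(consensus)) consensus <- Biostrings::DNAString(consensus)
  new("ElementModel", name = name, consensus = consensus,
      elementClass = elementClass, ltrLength = as.integer(ltrLength),
      snpRate = snpRate, truncationShape = truncationShape)
}

#' Random LTR-element consensus
#'
#' Builds a random consensus of the form LTR + internal + LTR, with the two
#' terminal repeats identical, suitable for \code{\link{ElementModel}}.
#'
#' @param internalLength internal (non-repeat) length in bp.
#' @param ltrLength terminal-repeat length in bp.
#' @param gc GC fraction of the random sequence.
#' @param seed RNG seed.
#' @return A \code{DNAString}.
#' @export
makeLtrConsensus <- function(internalLength, ltrLength, gc = 0.42, seed = NULL) {
  withSeed(seed, {
    ltr <- randomDna(ltrLength, gc)
    Biostrings::DNAString(paste0(ltr, randomDna(internalLength, gc), ltr))
  })
}

setMethod("show", "ElementModel", function(object) {
  cat(sprintf("ElementModel '%s' (%s), consensus %d bp", object@name,
              object@elementClass, length(object@consensus)))
  if (object@elementClass == "LTR")
    cat(sprintf(", LTR %d bp", object@ltrLength))
  cat(sprintf(", snpRate %.4g\n", object@snpRate))
})

#' @describeIn ElementModel consensus sequence accessor
#' @param object an \code{ElementModel}.
#' @export
setGeneric("consensusSeq", function(object) standardGeneric("consensusSeq"))

#' @rdname ElementModel
#' @export
setMethod("consensusSeq", "ElementModel", function(object) object@consensus)

#' @describeIn ElementModel element name accessor
#' @export
setGeneric("elementName", function(object) standardGeneric("elementName"))

#' @rdname ElementModel
#' @export
setMethod("elementName", "ElementModel", function(object) object@name)

# ---------------------------------------------------------------------------
# SignatureResult
# ---------------------------------------------------------------------------

#' Ping-pong / phasing signature result
#'
#' Holds the distance- or overlap-frequency histogram of a small-RNA
#' signature together with its focal-position z-score. For the ping-pong
#' signature the positions are 5'-5' overlaps 1..20 with focal position 10
#' and background \{1..9, 11..20\}; for the phasing signature the positions
#' are 3'-to-downstream-5' distances 0..19 with focal position 1 and
#' background \{0, 2..19\}. The z-score is
#' (f(focal) - mean(background)) / sd(background).
#'
#' When no pair events fall inside the position window the histogram is
#' undefined and \code{zScore} is \code{NA} (flagged, not propagated NaN);
#' likewise when the background standard deviation is zero.
#'
#' @slot kind \code{"pingpong"} or \code{"phasing"}.
#' @slot positions integer positions of the histogram.
#' @slot frequencies frequencies summing to 1 over positions (all \code{NA}
#'   when no events were observed).
#' @slot focalPosition focal position (10 or 1).
#' @slot backgroundPositions background positions.
#' @slot zScore the signature z-score (\code{NA} when undefined).
#' @slot nEvents total weighted pair events inside the window.
#' @exportClass SignatureResult
setClass("SignatureResult",
  representation(
    kind = "character",
    positions = "integer",
    frequencies = "numeric",
    focalPosition = "integer",
    backgroundPositions = "integer",
    zScore = "numeric",
    nEvents = "numeric"
  )
)

setValidity("SignatureResult", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("pingpong", "phasing"))
    msg <- c(msg, "'kind' must be 'pingpong' or 'phasing'")
  if (length(object@frequencies) != length(object@positions))
    msg <- c(msg, "'frequencies' and 'positions' lengths differ")
  if (!object@focalPosition %in% object@positions)
    msg <- c(msg, "focal position must be one of the histogram positions")
  if (!all(object@backgroundPositions %in% object@positions))
    msg <- c(msg, "background positions must be histogram positions")
  if (object@nEvents > 0) {
    s <- sum(object@frequencies)
    if (is.na(s) || abs(s - 1) > 1e-9)
      msg <- c(msg, "frequencies must sum to 1 when events exist")
  }
  if (length(msg)) msg else TRUE
})

.SignatureResult <- function(kind, positions, freqs, focal, background, n) {
  if (n > 0 && sum(freqs) > 0) {
    bg <- freqs[match(background, positions)]
    sdbg <- stats::sd(bg)
    z <- if (is.na(sdbg) || sdbg == 0) NA_real_ else
      (freqs[match(focal, positions)] - mean(bg)) / sdbg
  } else {
    freqs <- rep(NA_real_, length(positions))
    z <- NA_real_
  }
  new("SignatureResult", kind = kind, positions = as.integer(positions),
      frequencies = as.numeric(freqs), focalPosition = as.integer(focal),
      backgroundPositions = as.integer(background), zScore = z,
      nEvents = as.numeric(n))
}

#' @describeIn SignatureResult-class z-score accessor
#' @param object a \code{SignatureResult}.
#' @export
setGeneric("zScore", function(object) standardGeneric("zScore"))

#' @rdname SignatureResult-class
#' @export
setMethod("zScore", "SignatureResult", function(object) object@zScore)

#' @describeIn SignatureResult-class named frequency vector accessor
#' @export
setGeneric("signatureFrequencies", function(object) standardGeneric("signatureFrequencies"))

#' @rdname SignatureResult-class
#' @export
setMethod("signatureFrequencies", "SignatureResult", function(object) {
  stats::setNames(object@frequencies, object@positions)
})

setMethod("show", "SignatureResult", function(object) {
  cat(sprintf("SignatureResult (%s): %d positions, focal %d, z = %s, events = %g\n",
              object@kind, length(object@positions), object@focalPosition,
              ifelse(is.na(object@zScore), "undefined",
                     sprintf("%.3f", object@zScore)),
              object@nEvents))
})

#' @rdname SignatureResult-class
#' @param x a \code{SignatureResult}.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.SignatureResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(position = x@positions, frequency = x@frequencies,
             focal = x@positions == x@focalPosition)
}

# ---------------------------------------------------------------------------
# InsertCalls
# ---------------------------------------------------------------------------

#' Paired-junction insertion calls
#'
#' Container for insertion events called by pairing structural-variant
#' breakends: each call has an anchor interval at the acceptor locus (the two
#' junction coordinates, which must be less than the maximum gap apart), a
#' donor interval bracketing the inserted segment, an orientation, and the
#' supporting read identifiers of each junction. The \code{insertLength} of a
#' call is the span between its two donor junction coordinates.
#'
#' Breakends that could not be paired are retained in the \code{residual}
#' slot (they are reported, never an error).
#'
#' @slot anchors \code{GRanges}, one range per call, spanning the two
#'   acceptor-side junction coordinates.
#' @slot donors \code{GRanges} of donor intervals (strand \code{+} for same
#'   orientation, \code{-} for inverted).
#' @slot orientation \code{"same"} or \code{"inverted"} per call.
#' @slot insertLength donor junction span in bp per call.
#' @slot support list (one element per call) of length-2 lists of supporting
#'   read ids, one per junction.
#' @slot residual data.frame of unpaired breakend records.
#' @exportClass InsertCalls
setClass("InsertCalls",
  representation(
    anchors = "GRanges",
    donors = "GRanges",
    orientation = "character",
    insertLength = "integer",
    support = "list",
    residual = "data.frame"
  )
)

setValidity("InsertCalls", function(object) {
  n <- length(object@anchors)
  msg <- character(0)
  if (length(object@donors) != n || length(object@orientation) != n ||
      length(object@insertLength) != n || length(object@support) != n)
    msg <- c(msg, "all per-call slots must have equal length")
  if (n && any(object@insertLength <= 0L))
    msg <- c(msg, "insert lengths must be positive")
  if (n && !all(object@orientation %in% c("same", "inverted")))
    msg <- c(msg, "orientation must be 'same' or 'inverted'")
  if (length(msg)) msg else TRUE
})

#' @describeIn InsertCalls-class number of calls
#' @param x an \code{InsertCalls}.
#' @export
setMethod("length", "InsertCalls", function(x) length(x@anchors))

#' @describeIn InsertCalls-class subset calls
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "InsertCalls", function(x, i, j, ..., drop = FALSE) {
  new("InsertCalls", anchors = x@anchors[i], donors = x@donors[i],
      orientation = x@orientation[i], insertLength = x@insertLength[i],
      support = x@support[i], residual = x@residual)
})

#' @describeIn InsertCalls-class acceptor anchor ranges
#' @param object an \code{InsertCalls}.
#' @export
setGeneric("anchorRanges", function(object) standardGeneric("anchorRanges"))

#' @rdname InsertCalls-class
#' @export
setMethod("anchorRanges", "InsertCalls", function(object) object@anchors)

#' @describeIn InsertCalls-class donor ranges
#' @export
setGeneric("donorRanges", function(object) standardGeneric("donorRanges"))

#' @rdname InsertCalls-class
#' @export
setMethod("donorRanges", "InsertCalls", function(object) object@donors)

#' @describeIn InsertCalls-class insert lengths (donor junction spans)
#' @export
setGeneric("insertLengths", function(object) standardGeneric("insertLengths"))

#' @rdname InsertCalls-class
#' @export
setMethod("insertLengths", "InsertCalls", function(object) object@insertLength)

#' @describeIn InsertCalls-class unpaired breakend records
#' @export
setGeneric("residualBreakends", function(object) standardGeneric("residualBreakends"))

#' @rdname InsertCalls-class
#' @export
setMethod("residualBreakends", "InsertCalls", function(object) object@residual)

setMethod("show", "InsertCalls", function(object) {
  cat(sprintf("InsertCalls with %d call(s), %d residual breakend(s)\n",
              length(object), nrow(object@residual)))
  if (length(object)) {
    df <- as.data.frame(object)
    print(utils::head(df, 5))
    if (nrow(df) > 5) cat("...\n")
  }
})

#' @rdname InsertCalls-class
#' @param row.names,optional passed on conventionally; unused.
#' @export
as.data.frame.InsertCalls <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x)
  if (!n) {
    return(data.frame(acceptor_chrom = character(0), acceptor_start = integer(0),
                      acceptor_end = integer(0), donor_chrom = character(0),
                      donor_start = integer(0), donor_end = integer(0),
                      orientation = character(0), insert_length = integer(0),
                      support = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    acceptor_chrom = as.character(GenomicRanges::seqnames(x@anchors)),
    acceptor_start = GenomicRanges::start(x@anchors),
    acceptor_end = GenomicRanges::end(x@anchors),
    donor_chrom = as.character(GenomicRanges::seqnames(x@donors)),
    donor_start = GenomicRanges::start(x@donors),
    donor_end = GenomicRanges::end(x@donors),
    orientation = x@orientation,
    insert_length = x@insertLength,
    support = vapply(x@support, function(s)
      paste(unlist(s), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# InsertGroups
# ---------------------------------------------------------------------------

#' Homology groups of insert sequences
#'
#' One row per connected component of the insert homology graph: members,
#' representative (the longest member, ties broken by smallest id), the
#' "old" genomic area (union of homologous reference regions, bp), the "new"
#' area (summed member insert lengths, bp), and their ratio, which ranks
#' mobilization activity. Groups are ordered by descending member count and
#' numbered from 1 (mirroring the convention that group 1 is the largest);
#' groups reaching \code{minMembers} are flagged as focus groups.
#'
#' An \code{activityRatio} of \code{Inf} flags groups with no detectable
#' pre-existing homologous region (\code{oldAreaBp == 0}).
#'
#' @slot groupId integer group numbers (1 = most members).
#' @slot members list of member id character vectors.
#' @slot representative representative member id per group.
#' @slot focus logical, member count >= the focus threshold.
#' @slot oldAreaBp union length of homologous reference regions (NA until
#'   filled by \code{\link{computeActivityRatio}}).
#' @slot newAreaBp summed member insert lengths (NA until filled).
#' @slot activityRatio newArea / oldArea (NA until filled; Inf flagged).
#' @exportClass InsertGroups
setClass("InsertGroups",
  representation(
    groupId = "integer",
    members = "list",
    representative = "character",
    focus = "logical",
    oldAreaBp = "numeric",
    newAreaBp = "numeric",
    activityRatio = "numeric"
  )
)

setValidity("InsertGroups", function(object) {
  n <- length(object@groupId)
  msg <- character(0)
  if (length(object@members) != n || length(object@representative) != n ||
      length(object@focus) != n || length(object@oldAreaBp) != n ||
      length(object@newAreaBp) != n || length(object@activityRatio) != n)
    msg <- c(msg, "all slots must have one entry per group")
  ok <- !is.na(object@representative)
  if (any(ok & !mapply(function(r, m) r %in% m,
                       object@representative[ok], object@members[ok])))
    msg <- c(msg, "representative must be a group member")
  if (any(object@activityRatio < 0, na.rm = TRUE))
    msg <- c(msg, "activity ratio must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @describeIn InsertGroups-class number of groups
#' @param x an \code{InsertGroups}.
#' @export
setMethod("length", "InsertGroups", function(x) length(x@groupId))

#' @describeIn InsertGroups-class member id lists
#' @param object an \code{InsertGroups}.
#' @export
setGeneric("groupMembers", function(object) standardGeneric("groupMembers"))

#' @rdname InsertGroups-class
#' @export
setMethod("groupMembers", "InsertGroups", function(object)
  stats::setNames(object@members, object@groupId))

#' @describeIn InsertGroups-class representative ids
#' @export
setGeneric("representatives", function(object) standardGeneric("representatives"))

#' @rdname InsertGroups-class
#' @export
setMethod("representatives", "InsertGroups", function(object)
  stats::setNames(object@representative, object@groupId))

#' @describeIn InsertGroups-class activity ratios (new/old area)
#' @export
setGeneric("activityRatios", function(object) standardGeneric("activityRatios"))

#' @rdname InsertGroups-class
#' @export
setMethod("activityRatios", "InsertGroups", function(object)
  stats::setNames(object@activityRatio, object@groupId))

setMethod("show", "InsertGroups", function(object) {
  cat(sprintf("InsertGroups with %d group(s) (%d focus)\n",
              length(object), sum(object@focus)))
  if (length(object)) print(utils::head(as.data.frame(object), 5))
})

#' @rdname InsertGroups-class
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.InsertGroups <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    group_id = x@groupId,
    n_members = lengths(x@members),
    members = vapply(x@members, paste, character(1), collapse = ","),
    representative = x@representative,
    focus = x@focus,
    old_area_bp = x@oldAreaBp,
    new_area_bp = x@newAreaBp,
    activity_ratio = x@activityRatio,
    stringsAsFactors = FALSE
  )
}
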