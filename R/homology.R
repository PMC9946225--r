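# Pairwise homology search among insert sequences and against a reference
# genome, transitive grouping, representative selection, and the old/new
# area activity ratio.
#
# The built-in search is a seed-and-extend local aligner: exact word seeds
# (matchPDict) grouped by diagonal, a maximal-scoring ungapped segment per
# diagonal (vectorized Kadane scan), and an optional gapped refinement of
# candidate hits with pairwiseAlignment. Significance uses the
# Karlin-Altschul expectation E = K * m * n * exp(-lambda * S) with fixed
# constants for the default scoring; e-values far below double precision
# are kept in log10 space.

.kadaneSegment <- function(v) {
  # maximal-sum contiguous segment; returns (start, end, sum)
  pre <- cumsum(v)
  preLag <- c(0, pre[-length(pre)])
  runMin <- cummin(preLag)
  gains <- pre - runMin
  end <- which.max(gains)
  start <- which.min(preLag[seq_len(end)])
  c(start = start, end = end, score = gains[end])
}

.diagonalHits <- function(qChar, sChar, wordSize, match, mismatch, minScore) {
  m <- nchar(qChar); n <- nchar(sChar)
  if (m < wordSize || n < wordSize) return(NULL)
  qStarts <- seq_len(m - wordSize + 1L)
  qWords <- substring(qChar, qStarts, qStarts + wordSize - 1L)
  uw <- unique(qWords)
  uw <- uw[!grepl("[^ACGT]", uw)]
  if (!length(uw)) return(NULL)
  pd <- Biostrings::PDict(uw)
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(sChar))
  qByWord <- split(qStarts, qWords)
  diags <- integer(0)
  for (w in seq_along(uw)) {
    ss <- IRanges::start(mi[[w]])
    if (!length(ss)) next
    qs <- qByWord[[uw[w]]]
    diags <- c(diags, as.vector(outer(ss, qs, `-`)))
  }
  diags <- unique(diags)
  if (!length(diags)) return(NULL)
  qRaw <- charToRaw(qChar)
  sRaw <- charToRaw(sChar)
  rows <- vector("list", length(diags))
  for (ii in seq_along(diags)) {
    d <- diags[ii]
    qlo <- max(1L, 1L - d); qhi <- min(m, n - d)
    if (qhi - qlo + 1L < wordSize) next
    eq <- qRaw[qlo:qhi] == sRaw[(qlo + d):(qhi + d)]
    v <- ifelse(eq, match, mismatch)
    seg <- .kadaneSegment(v)
    if (seg[["score"]] < minScore) next
    rows[[ii]] <- c(q_start = qlo + seg[["start"]] - 1L,
                    q_end = qlo + seg[["end"]] - 1L,
                    s_start = qlo + d + seg[["start"]] - 1L,
                    s_end = qlo + d + seg[["end"]] - 1L,
                    score = seg[["score"]])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# drop hits nested inside a higher-scoring hit (same diagonal family noise)
.pruneNestedHits <- function(h) {
  if (nrow(h) <= 1L) return(h)
  o <- order(-h[, "score"])
  h <- h[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (h[i, "q_start"] >= h[j, "q_start"] && h[i, "q_end"] <= h[j, "q_end"] &&
          h[i, "s_start"] >= h[j, "s_start"] && h[i, "s_end"] <= h[j, "s_end"]) {
        keep[i] <- FALSE; break
      }
    }
  }
  h[keep, , drop = FALSE]
}

#' Seed-and-extend local homology search
#'
#' Finds local alignments of a query against one or more subject sequences
#' on both strands. Exact \code{wordSize}-mers seed diagonals, each diagonal
#' is scanned for its maximal-scoring ungapped segment, and candidate hits
#' are optionally refined with a gapped local alignment. The expectation
#' value of a hit of score S is \code{K * m * n * exp(-lambda * S)}
#' (ungapped-statistics approximation applied to gapped scores); e-values
#' below double precision underflow to 0, so \code{log10_evalue} is the
#' authoritative significance measure.
#'
#' @param query a \code{DNAString}/character (one sequence).
#' @param subjects named \code{DNAStringSet} or named character vector.
#' @param queryId identifier reported for the query.
#' @param wordSize seed word size (>= 8).
#' @param match,mismatch,gapOpening,gapExtension alignment scoring; the
#'   mismatch penalty must be negative.
#' @param evalueMax report hits with e-value <= this bound.
#' @param K,lambda Karlin-Altschul constants for the chosen scoring.
#' @param bothStrands also search the reverse complement of the query.
#' @param gappedRefine refine candidate hits with a gapped local alignment.
#' @return data.frame of hits: query_id, subject_id, strand, q_start, q_end,
#'   s_start, s_end, score, evalue, log10_evalue; highest score first.
#'   Query intervals of minus-strand hits are in original query coordinates.
#' @export
localHomologySearch <- function(query, subjects, queryId = "query",
                                wordSize = 11L, match = 1, mismatch = -2,
                                gapOpening = 5, gapExtension = 2,
                                evalueMax = Inf, K = 0.28, lambda = 1.07,
                                bothStrands = TRUE, gappedRefine = TRUE) {
  if (wordSize < 8L) stop("wordSize must be >= 8")
  if (mismatch >= 0) stop("degenerate scoring: mismatch penalty must be negative")
  qChar <- toupper(as.character(query))
  if (!nchar(qChar)) stop("empty query sequence")
  if (is.character(subjects) && is.null(names(subjects)) &&
      length(subjects) == 1L) names(subjects) <- "subject"
  sChars <- toupper(as.character(subjects))
  if (is.null(names(sChars))) names(sChars) <- paste0("subject", seq_along(sChars))
  m <- nchar(qChar)
  minScore <- 2 * wordSize * match  # candidate floor before e-value filter
  logE <- function(S, n) (log(K) + log(m) + log(n) - lambda * S) / log(10)
  out <- list()
  strands <- if (bothStrands) c("+", "-") else "+"
  for (sid in names(sChars)) {
    sc <- sChars[[sid]]
    n <- nchar(sc)
    for (std in strands) {
      qc <- if (std == "+") qChar else revcompChar(qChar)
      h <- .diagonalHits(qc, sc, wordSize, match, mismatch, minScore)
      if (is.null(h)) next
      h <- .pruneNestedHits(h)
      if (gappedRefine && nrow(h) <= 50L) {
        mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                        mismatch = mismatch)
        for (i in seq_len(nrow(h))) {
          qlo <- max(1L, h[i, "q_start"] - 50L)
          qhi <- min(nchar(qc), h[i, "q_end"] + 50L)
          slo <- max(1L, h[i, "s_start"] - 50L)
          shi <- min(n, h[i, "s_end"] + 50L)
          if ((qhi - qlo) > 2e4 || (shi - slo) > 2e4) next
          aln <- Biostrings::pairwiseAlignment(
            substr(qc, qlo, qhi), substr(sc, slo, shi), type = "local",
            substitutionMatrix = mat, gapOpening = gapOpening,
            gapExtension = gapExtension)
          if (Biostrings::score(aln) > h[i, "score"]) {
            pr <- Biostrings::pattern(aln); sr <- Biostrings::subject(aln)
            h[i, "q_start"] <- qlo + Biostrings::start(pr) - 1L
            h[i, "q_end"] <- qlo + Biostrings::end(pr) - 1L
            h[i, "s_start"] <- slo + Biostrings::start(sr) - 1L
            h[i, "s_end"] <- slo + Biostrings::end(sr) - 1L
            h[i, "score"] <- Biostrings::score(aln)
          }
        }
        h <- .pruneNestedHits(h)
      }
      qs <- h[, "q_start"]; qe <- h[, "q_end"]
      if (std == "-") {  # map back to original query coordinates
        tmp <- m - qe + 1L
        qe <- m - qs + 1L
        qs <- tmp
      }
      l10 <- logE(h[, "score"], n)
      df <- data.frame(query_id = queryId, subject_id = sid, strand = std,
                       q_start = as.integer(qs), q_end = as.integer(qe),
                       s_start = as.integer(h[, "s_start"]),
                       s_end = as.integer(h[, "s_end"]),
                       score = as.numeric(h[, "score"]),
                       evalue = 10 ^ pmax(l10, -320), log10_evalue = l10,
                       stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      strand = character(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), score = numeric(0),
                      evalue = numeric(0), log10_evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[res$log10_evalue <= log10(evalueMax), , drop = FALSE]
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' All-vs-all homology among insert sequences
#'
#' Runs \code{\link{localHomologySearch}} for every ordered pair (i, j) with
#' i < j; the grouping graph symmetrizes hits, so one direction suffices.
#'
#' @param seqs named \code{DNAStringSet} of insert sequences.
#' @param ... passed to \code{\link{localHomologySearch}}.
#' @return combined hit data.frame.
#' @export
allVsAllHomology <- function(seqs, ...) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  out <- list()
  for (i in seq_along(seqs)) {
    if (i == length(seqs)) break
    hits <- localHomologySearch(seqs[[i]], seqs[(i + 1):length(seqs)],
                                queryId = ids[i], ...)
    if (nrow(hits)) out[[length(out) + 1L]] <- hits
  }
  if (!length(out)) {
    return(localHomologySearch(Biostrings::DNAString("ACGTACGTACGTACGT"),
                               c(x = "TTTT"), evalueMax = 0)[0, ])
  }
  do.call(rbind, out)
}

#' Build the insert homology graph
#'
#' Undirected simple graph on insert ids with an edge wherever any hit in
#' either direction has e-value strictly below the threshold.
#'
#' @param insertIds node identifiers (all inserts, including hit-less ones).
#' @param hits hit data.frame from \code{\link{allVsAllHomology}}.
#' @param evalueMax significance threshold (strict).
#' @return an \code{igraph} graph.
#' @export
buildHomologyGraph <- function(insertIds, hits, evalueMax = 1e-100) {
  sig <- hits[hits$log10_evalue < log10(evalueMax) &
                hits$query_id != hits$subject_id, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(insertIds), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(insertIds))
  if (nrow(sig)) {
    edges <- unique(t(apply(cbind(sig$query_id, sig$subject_id), 1, sort)))
    g <- igraph::add_edges(g, t(matrix(match(edges, insertIds),
                                       ncol = 2)))
    g <- igraph::simplify(g)
  }
  g
}

#' Connected-component insert groups
#'
#' Groups are the connected components of the homology graph (transitive
#' closure of pairwise significance: locally homologous inserts bridged by
#' a shared neighbour fall in one group). Groups are ordered by descending
#' member count, ties by smallest member id, and numbered from 1; groups
#' with at least \code{minMembers} members are flagged as focus groups.
#'
#' @param graph igraph graph from \code{\link{buildHomologyGraph}}.
#' @param minMembers focus-group member threshold.
#' @param insertLengths optional named lengths used to pick representatives.
#' @return An \linkS4class{InsertGroups} (areas unfilled).
#' @export
connectedComponentGroups <- function(graph, minMembers = 5L,
                                     insertLengths = NULL) {
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  members <- split(ids, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1))
  members <- unname(members[ord])
  reps <- if (is.null(insertLengths)) rep(NA_character_, length(members)) else
    vapply(members, selectRepresentative, character(1),
           insertLengths = insertLengths)
  new("InsertGroups", groupId = seq_along(members), members = members,
      representative = reps, focus = lengths(members) >= minMembers,
      oldAreaBp = rep(NA_real_, length(members)),
      newAreaBp = rep(NA_real_, length(members)),
      activityRatio = rep(NA_real_, length(members)))
}

#' Select a group's representative insert
#'
#' The longest member; ties are broken by the lexicographically smallest id.
#'
#' @param members character vector of member ids.
#' @param insertLengths named lengths (bp) covering all members.
#' @return the representative id.
#' @export
selectRepresentative <- function(members, insertLengths) {
  stopifnot(length(members) >= 1, all(members %in% names(insertLengths)))
  lens <- insertLengths[members]
  cand <- sort(members[lens == max(lens)])
  cand[1]
}

#' Fill old/new areas and the activity ratio of insert groups
#'
#' The old area of a group is the total genomic length covered by the
#' merged (union of overlapping) homologous regions of its representative
#' in the reference genome; the new area is the plain sum of its member
#' insert lengths; the activity ratio is new/old. A group whose old area is
#' zero gets ratio \code{Inf} (flagged infinite, not an error).
#'
#' @param groups \linkS4class{InsertGroups}.
#' @param genomeHits hit data.frame of representative-vs-genome searches
#'   (query_id must be representative ids; subject intervals are genomic).
#' @param insertLengths named insert lengths, bp.
#' @param evalueMax significance threshold for genomic homology (strict).
#' @return the \linkS4class{InsertGroups} with areas and ratios filled.
#' @export
computeActivityRatio <- function(groups, genomeHits, insertLengths,
                                 evalueMax = 1e-100) {
  sig <- genomeHits[genomeHits$log10_evalue < log10(evalueMax), ,
                    drop = FALSE]
  old <- numeric(length(groups))
  new_ <- numeric(length(groups))
  for (i in seq_along(groups@groupId)) {
    rep_ <- groups@representative[i]
    h <- sig[sig$query_id == rep_, , drop = FALSE]
    old[i] <- if (nrow(h)) {
      gr <- GenomicRanges::GRanges(h$subject_id,
                                   IRanges::IRanges(h$s_start, h$s_end))
      sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
    } else 0
    new_[i] <- sum(insertLengths[groups@members[[i]]])
  }
  groups@oldAreaBp <- old
  groups@newAreaBp <- new_
  groups@activityRatio <- ifelse(old > 0, new_ / old, Inf)
  methods::validObject(groups)
  groups
}

#' Group insert sequences end to end
#'
#' Convenience wrapper: all-vs-all homology, graph, connected components,
#' representative selection, and (when a genome is given) representative
#' vs genome search and activity ratios.
#'
#' @param insertSeqs named \code{DNAStringSet} of insert sequences.
#' @param genome optional reference \code{DNAStringSet}.
#' @param evalueMax grouping/genomic significance threshold (strict).
#' @param minMembers focus-group threshold.
#' @param ... passed to \code{\link{localHomologySearch}}.
#' @return list with \code{hits}, \code{graph}, \code{groups}
#'   (\linkS4class{InsertGroups}) and \code{genomeHits} (NULL without a
#'   genome).
#' @export
groupInserts <- function(insertSeqs, genome = NULL, evalueMax = 1e-100,
                         minMembers = 5L, ...) {
  lens <- stats::setNames(Biostrings::width(insertSeqs), names(insertSeqs))
  hits <- allVsAllHomology(insertSeqs, evalueMax = Inf, ...)
  graph <- buildHomologyGraph(names(insertSeqs), hits, evalueMax)
  groups <- connectedComponentGroups(graph, minMembers, lens)
  genomeHits <- NULL
  if (!is.null(genome)) {
    reps <- stats::setNames(groups@representative, groups@representative)
    gh <- list()
    for (r in unique(reps)) {
      gh[[r]] <- localHomologySearch(insertSeqs[[r]], genome, queryId = r,
                                     evalueMax = Inf, ...)
    }
    genomeHits <- do.call(rbind, gh)
    rownames(genomeHits) <- NULL
    groups <- computeActivityRatio(groups, genomeHits, lens, evalueMax)
  }
  list(hits = hits, graph = graph, groups = groups, genomeHits = genomeHits)
}
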