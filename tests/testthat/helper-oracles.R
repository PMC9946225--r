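# Independent brute-force oracles and random-instance generators.
# These deliberately re-derive each rule from first principles, separately
# from the package implementation, so agreement is informative.

# --- breakend pairing oracle -----------------------------------------------

# plain re-statement of the paired-junction rule for two breakend records;
# returns NULL or a call description
oracleTryPair <- function(b, i, j, maxGap) {
  # each record contributes two (chrom,pos,side) ends; try both roles
  endsOf <- function(k) list(
    list(ch = b$chrom_a[k], p = b$pos_a[k], s = b$side_a[k],
         och = b$chrom_b[k], op = b$pos_b[k], os = b$side_b[k]),
    list(ch = b$chrom_b[k], p = b$pos_b[k], s = b$side_b[k],
         och = b$chrom_a[k], op = b$pos_a[k], os = b$side_a[k]))
  best <- NULL
  for (ei in endsOf(i)) for (ej in endsOf(j)) {
    if (ei$ch != ej$ch) next
    if (abs(ei$p - ej$p) >= maxGap) next
    if (ei$s == ej$s) next                      # acceptor sides must oppose
    if (ei$och != ej$och) next                  # one donor chromosome
    # donor ends keyed by the acceptor side they hang off
    if (ei$s == "right") { bR <- ei$op; sR <- ei$os; bL <- ej$op; sL <- ej$os }
    else { bR <- ej$op; sR <- ej$os; bL <- ei$op; sL <- ei$os }
    cand <- NULL
    if (sR == "left" && sL == "right" && bR < bL)
      cand <- list(orientation = "same", lo = bR, hi = bL)
    if (sR == "right" && sL == "left" && bR > bL)
      cand <- list(orientation = "inverted", lo = bL, hi = bR)
    if (is.null(cand)) next
    cand$gap <- abs(ei$p - ej$p)
    cand$span <- cand$hi - cand$lo
    cand$accChrom <- ei$ch
    cand$accLow <- min(ei$p, ej$p); cand$accHigh <- max(ei$p, ej$p)
    cand$donChrom <- ei$och
    if (is.null(best) || cand$gap < best$gap ||
        (cand$gap == best$gap && cand$span < best$span)) best <- cand
  }
  best
}

# exhaustive all-pairs pairing with greedy resolution (smallest gap, then
# smallest donor span), each breakend used once
oraclePairInserts <- function(b, maxGap = 100) {
  n <- nrow(b)
  cands <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- oracleTryPair(b, i, j, maxGap)
    if (!is.null(p)) { p$i <- i; p$j <- j; cands[[length(cands) + 1]] <- p }
  }
  if (length(cands)) {
    o <- order(sapply(cands, `[[`, "gap"), sapply(cands, `[[`, "span"),
               sapply(cands, `[[`, "accChrom"),
               sapply(cands, `[[`, "accLow"),
               sapply(cands, `[[`, "donChrom"),
               sapply(cands, `[[`, "lo"))
    cands <- cands[o]
  }
  used <- rep(FALSE, n)
  out <- list()
  for (p in cands) {
    if (used[p$i] || used[p$j]) next
    used[p$i] <- used[p$j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      acceptor_chrom = p$accChrom, acceptor_start = p$accLow,
      acceptor_end = p$accHigh, donor_chrom = p$donChrom,
      donor_start = p$lo, donor_end = p$hi, orientation = p$orientation,
      insert_length = p$span, stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(acceptor_chrom = character(0), acceptor_start = integer(0),
               acceptor_end = integer(0), donor_chrom = character(0),
               donor_start = integer(0), donor_end = integer(0),
               orientation = character(0), insert_length = integer(0))
  calls <- calls[order(calls$acceptor_chrom, calls$acceptor_start,
                       calls$acceptor_end), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, nResidual = sum(!used))
}

# random breakend sets: a mixture of genuine insert-like pairs and noise
randomBreakendSet <- function(n, seed) {
  set.seed(seed)
  chroms <- c("chr1", "chr2", "chr3")
  nPairs <- floor(n / 4)
  recs <- list()
  for (k in seq_len(nPairs)) {
    accCh <- sample(chroms, 1); donCh <- sample(chroms, 1)
    a <- sample.int(1e6, 1)
    gap <- sample.int(150, 1)  # some exceed the 100 bp rule
    d1 <- sample.int(1e6, 1); span <- sample.int(20000, 1)
    inv <- runif(1) < 0.3
    if (!inv) {
      recs[[length(recs) + 1]] <- list(accCh, a, "right", donCh, d1, "left")
      recs[[length(recs) + 1]] <- list(accCh, a + gap, "left", donCh,
                                       d1 + span, "right")
    } else {
      recs[[length(recs) + 1]] <- list(accCh, a, "right", donCh, d1 + span,
                                       "right")
      recs[[length(recs) + 1]] <- list(accCh, a + gap, "left", donCh, d1,
                                       "left")
    }
  }
  while (length(recs) < n) {
    recs[[length(recs) + 1]] <- list(sample(chroms, 1), sample.int(1e6, 1),
                                     sample(c("left", "right"), 1),
                                     sample(chroms, 1), sample.int(1e6, 1),
                                     sample(c("left", "right"), 1))
  }
  recs <- recs[sample(length(recs))]  # shuffle
  breakendRecords(sapply(recs, `[[`, 1), sapply(recs, function(r) r[[2]]),
                  sapply(recs, `[[`, 3), sapply(recs, `[[`, 4),
                  sapply(recs, function(r) r[[5]]), sapply(recs, `[[`, 6))
}

# --- signature oracles ------------------------------------------------------

# all-pairs 5'-5' overlap histogram (ping-pong), overlaps 1..20
oraclePingpongCounts <- function(records) {
  plus <- records[records$strand == "+", , drop = FALSE]
  minus <- records[records$strand == "-", , drop = FALSE]
  counts <- numeric(20)
  for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
    if (plus$chrom[i] != minus$chrom[j]) next
    k <- minus$end[j] - plus$start[i] + 1
    if (k >= 1 && k <= 20) counts[k] <- counts[k] + 1
  }
  counts
}

# all ordered same-strand pairs, upstream-3' to downstream-5' distances 0..19
oraclePhasingCounts <- function(records) {
  counts <- numeric(20)
  n <- nrow(records)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (records$strand[i] != records$strand[j]) next
    if (records$chrom[i] != records$chrom[j]) next
    d <- if (records$strand[i] == "+")
      records$start[j] - records$end[i]
    else
      records$start[i] - records$end[j]
    if (d >= 0 && d <= 19) counts[d + 1] <- counts[d + 1] + 1
  }
  counts
}

oracleZ <- function(freqs, positions, focal, background) {
  bg <- freqs[match(background, positions)]
  (freqs[match(focal, positions)] - mean(bg)) / sd(bg)
}

# per-base coverage by explicit position counting
oracleCoverage <- function(records, chrom, start, end, strand) {
  v <- integer(end - start + 1)
  sub <- records[records$chrom == chrom & records$strand == strand, ,
                 drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    for (p in seq(sub$start[i], sub$end[i])) {
      if (p >= start && p <= end) v[p - start + 1] <- v[p - start + 1] + 1L
    }
  }
  v
}

# random small-RNA alignment records on one locus
randomLibrary <- function(n, locusLen = 2000, seed = 1,
                          lengths = 23:32) {
  set.seed(seed)
  len <- lengths[sample.int(length(lengths), n, replace = TRUE)]
  start <- sapply(len, function(l) sample.int(locusLen - l + 1, 1))
  alignmentRecords(sprintf("r%04d", seq_len(n)), "locus", start,
                   start + len - 1, sample(c("+", "-"), n, replace = TRUE))
}

# --- graph oracle -----------------------------------------------------------

# transitive closure of an undirected edge relation (Floyd-Warshall style)
oracleComponents <- function(nodes, edges) {
  n <- length(nodes)
  reach <- diag(TRUE, n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- match(edges[r, 1], nodes); j <- match(edges[r, 2], nodes)
    reach[i, j] <- reach[j, i] <- TRUE
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  # canonical form: sorted list of sorted member sets
  sets <- lapply(split(nodes, comp), sort)
  unname(sets[order(sapply(sets, `[`, 1))])
}

# synthetic significant-hit table for graph construction
hitsFromEdges <- function(edges) {
  if (!nrow(edges)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      log10_evalue = numeric(0)))
  }
  data.frame(query_id = edges[, 1], subject_id = edges[, 2],
             log10_evalue = -200, stringsAsFactors = FALSE)
}

randomDnaStr <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
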