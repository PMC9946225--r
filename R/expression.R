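# RPKM quantification, relative expression across timepoints,
# expressed-transposon filtering, and ChIP enrichment versus a control.

#' RPKM expression table
#'
#' \code{rpkm = count / (feature_kb x library_millions)}. Zero counts give
#' RPKM 0. Optionally merges split gene models before quantification
#' (summed counts, summed lengths).
#'
#' @param counts matrix (features x libraries) of mapped-read counts.
#' @param featureLengths named feature lengths, bp (> 0; a feature without
#'   a length is an error).
#' @param librarySizes named total mapped reads per library (> 0).
#' @param mergeTable optional data.frame with columns \code{feature_id},
#'   \code{merged_id}: listed features are combined into the merged model.
#' @return long data.frame: feature_id, library_id, count, rpkm.
#' @export
rpkmTable <- function(counts, featureLengths, librarySizes,
                      mergeTable = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (!all(rownames(counts) %in% names(featureLengths)))
    stop("missing feature length for: ",
         paste(setdiff(rownames(counts), names(featureLengths)),
               collapse = ", "))
  stopifnot(all(featureLengths[rownames(counts)] > 0),
            all(colnames(counts) %in% names(librarySizes)),
            all(librarySizes > 0))
  lens <- featureLengths[rownames(counts)]
  if (!is.null(mergeTable)) {
    for (mid in unique(mergeTable$merged_id)) {
      parts <- mergeTable$feature_id[mergeTable$merged_id == mid]
      parts <- intersect(parts, rownames(counts))
      if (length(parts) < 2L) next
      merged <- colSums(counts[parts, , drop = FALSE])
      counts <- counts[setdiff(rownames(counts), parts), , drop = FALSE]
      counts <- rbind(counts, matrix(merged, nrow = 1,
                                     dimnames = list(mid, names(merged))))
      lens <- c(lens[setdiff(names(lens), parts)],
                stats::setNames(sum(featureLengths[parts]), mid))
    }
  }
  out <- expand.grid(feature_id = rownames(counts),
                     library_id = colnames(counts),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- as.vector(counts)
  out$rpkm <- out$count /
    ((lens[out$feature_id] / 1000) *
       (librarySizes[out$library_id] / 1e6))
  rownames(out) <- NULL
  out
}

#' Relative expression against a baseline library
#'
#' Adds \code{relative = rpkm / rpkm(baseline)} per feature. Features with
#' baseline RPKM 0 are flagged undefined (\code{NA}), not infinite.
#'
#' @param records RPKM table from \code{\link{rpkmTable}}.
#' @param baselineLibrary baseline library id (e.g. the untreated
#'   timepoint); must be present for each feature.
#' @return the table with a \code{relative} column.
#' @export
relativeExpression <- function(records, baselineLibrary) {
  if (!baselineLibrary %in% records$library_id)
    stop("unknown baseline library: ", baselineLibrary)
  base <- records[records$library_id == baselineLibrary, ]
  if (!all(records$feature_id %in% base$feature_id))
    stop("baseline library missing for some features")
  b <- stats::setNames(base$rpkm, base$feature_id)
  records$relative <- ifelse(b[records$feature_id] > 0,
                             records$rpkm / b[records$feature_id], NA_real_)
  records
}

#' Expressed-transposon filter
#'
#' Keeps features whose RPKM is strictly greater than the threshold in at
#' least one of the named libraries.
#'
#' @param records RPKM table.
#' @param thresholdRpkm strict lower bound (default 10).
#' @param libraries library ids to inspect (default: all present).
#' @return character vector of retained feature ids.
#' @export
expressedTransposonFilter <- function(records, thresholdRpkm = 10,
                                      libraries = NULL) {
  if (is.null(libraries)) libraries <- unique(records$library_id)
  if (!all(libraries %in% records$library_id))
    stop("records do not cover the named libraries")
  sel <- records[records$library_id %in% libraries &
                   records$rpkm > thresholdRpkm, ]
  sort(unique(sel$feature_id))
}

#' ChIP enrichment versus a control library
#'
#' Per-feature \code{log2(chip_rpkm / control_rpkm)}; features with control
#' RPKM 0 are flagged (\code{NA}). When \code{groups} is given, a per-group
#' summary is added using the ratio of pooled length-corrected counts
#' (robust to zero-count members), not the mean of per-feature ratios.
#'
#' @param chipCounts,controlCounts named per-feature counts.
#' @param featureLengths named feature lengths, bp.
#' @param chipLibrarySize,controlLibrarySize total mapped reads.
#' @param groups optional named list of feature-id vectors.
#' @return list with \code{features} (data.frame: feature_id, chip_rpkm,
#'   control_rpkm, log2_enrichment) and \code{groups} (data.frame or NULL).
#' @export
chipEnrichment <- function(chipCounts, controlCounts, featureLengths,
                           chipLibrarySize, controlLibrarySize,
                           groups = NULL) {
  feats <- names(chipCounts)
  stopifnot(!is.null(feats), identical(sort(feats), sort(names(controlCounts))),
            all(feats %in% names(featureLengths)))
  kb <- featureLengths[feats] / 1000
  chipR <- chipCounts[feats] / (kb * chipLibrarySize / 1e6)
  ctrlR <- controlCounts[feats] / (kb * controlLibrarySize / 1e6)
  lfc <- ifelse(ctrlR > 0 & chipR > 0, log2(chipR / ctrlR), NA_real_)
  featDf <- data.frame(feature_id = feats, chip_rpkm = unname(chipR),
                       control_rpkm = unname(ctrlR),
                       log2_enrichment = unname(lfc),
                       stringsAsFactors = FALSE)
  grpDf <- NULL
  if (!is.null(groups)) {
    grpDf <- do.call(rbind, lapply(names(groups), function(g) {
      mem <- intersect(groups[[g]], feats)
      lc <- function(x) sum(x[mem] / (featureLengths[mem] / 1000))
      chipP <- lc(chipCounts) / (chipLibrarySize / 1e6)
      ctrlP <- lc(controlCounts) / (controlLibrarySize / 1e6)
      data.frame(group = g, n_features = length(mem),
                 log2_enrichment = if (ctrlP > 0 && chipP > 0)
                   log2(chipP / ctrlP) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(features = featDf, groups = grpDf)
}

#' Box-plot summary statistics
#'
#' Median, quartiles, whiskers at 1.5 x IQR (clipped to the data) and the
#' outlier count, for summarizing relative-expression distributions.
#'
#' @param values numeric vector (NAs dropped).
#' @return one-row data.frame: n, median, q1, q3, whisker_low,
#'   whisker_high, n_outliers.
#' @export
boxplotSummary <- function(values) {
  v <- values[!is.na(values)]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
             whisker_low = lo, whisker_high = hi,
             n_outliers = sum(v < lo | v > hi))
}
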