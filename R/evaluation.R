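# Evaluation statistics for compressed track representations.  Positional
# signals are plain numeric vectors; intervals are data.frames with 0-based
# half-open start/end in the same coordinate space as the vector (position i
# of the vector covers [i-1, i)).

interval_mask <- function(intervals, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(intervals$start[i] + 1L, 1L)
    hi <- min(intervals$end[i], n)
    if (hi >= lo) mask[lo:hi] <- TRUE
  }
  mask
}

#' Compression ratio of a segmented representation
#'
#' Input positions per output segment, on average: a 1 Mb region held as 100
#' segments has compression ratio 10,000.
#'
#' @param n_points number of positions in the original signal.
#' @param n_segments number of segments representing it (>= 1).
#' @return `n_points / n_segments`.
#' @export
compression_ratio <- function(n_points, n_segments) {
  stopifnot(n_segments >= 1, n_points >= 1)
  n_points / n_segments
}

#' Median fold change under peak regions
#'
#' Per peak, the mean reconstructed value inside the peak divided by the mean
#' reconstructed value over the background (every position outside all
#' peaks); the median over peaks is returned.  A representation that merges
#' peaks into their surroundings drags this statistic towards 1.
#'
#' @param signal numeric positional signal (typically a reconstruction).
#' @param peaks interval data.frame with `start`, `end`.
#' @return Median fold change, with the per-peak values as attribute
#'   `"per_peak"`.
#' @export
peak_fold_change <- function(signal, peaks) {
  n <- length(signal)
  stopifnot(nrow(peaks) >= 1)
  mask <- interval_mask(peaks, n)
  if (all(mask)) stop("peaks cover every position: background is empty")
  bg <- mean(signal[!mask])
  if (bg == 0) stop("background mean is zero")
  fc <- vapply(seq_len(nrow(peaks)), function(i) {
    lo <- max(peaks$start[i] + 1L, 1L); hi <- min(peaks$end[i], n)
    mean(signal[lo:hi]) / bg
  }, numeric(1))
  structure(median(fc), per_peak = fc)
}

#' Maximal runs of constant signal as intervals
#'
#' @param signal numeric positional signal.
#' @param offset coordinate of the first position's interval start (default
#'   0).
#' @param scale basepairs per position (default 1).
#' @return Interval data.frame with `start`, `end`, `value`.
#' @export
signal_segments <- function(signal, offset = 0, scale = 1) {
  n <- length(signal)
  change <- which(signal[-n] != signal[-1])
  seg_start <- c(1L, change + 1L)
  seg_end <- c(change, n)
  data.frame(start = offset + (seg_start - 1) * scale,
             end = offset + seg_end * scale,
             value = signal[seg_start])
}

#' Maximum Jaccard index of each peak with the segmentation
#'
#' Segments are the maximal runs of constant reconstructed value; for each
#' peak the Jaccard index |intersection| / |union| is maximized over all
#' overlapping segments (0 when no segment overlaps).
#'
#' @param segments interval data.frame (e.g. [signal_segments()] output).
#' @param peaks interval data.frame with `start`, `end`.
#' @return List with `per_peak`, `median` and `q90` (90% quantile).
#' @export
max_jaccard <- function(segments, peaks) {
  si <- IRanges::IRanges(segments$start + 1L, segments$end)
  pi <- IRanges::IRanges(peaks$start + 1L, peaks$end)
  hits <- IRanges::findOverlaps(pi, si)
  best <- numeric(nrow(peaks))
  if (length(hits)) {
    p <- pi[S4Vectors::queryHits(hits)]
    s <- si[S4Vectors::subjectHits(hits)]
    inter <- IRanges::width(IRanges::pintersect(p, s))
    uni <- IRanges::width(p) + IRanges::width(s) - inter
    jac <- inter / uni
    agg <- tapply(jac, S4Vectors::queryHits(hits), max)
    best[as.integer(names(agg))] <- agg
  }
  list(per_peak = best, median = median(best),
       q90 = unname(quantile(best, 0.9)))
}

#' Signal enrichment of labelled region classes
#'
#' Per label (e.g. a ChromHMM state), the mean signal within its intervals
#' divided by the mean signal over the shared background (positions outside
#' every labelled interval).  For methylation tracks the signal is the
#' reconstructed fraction.
#'
#' @param signal numeric positional signal.
#' @param classes interval data.frame with `start`, `end`, `label`.
#' @return Named numeric vector of per-label enrichment ratios.
#' @export
region_enrichment <- function(signal, classes) {
  stopifnot(all(c("start", "end", "label") %in% names(classes)))
  n <- length(signal)
  all_mask <- interval_mask(classes, n)
  if (all(all_mask)) stop("classes cover every position: background is empty")
  bg <- mean(signal[!all_mask])
  if (bg == 0) stop("background mean is zero")
  labs <- unique(classes$label)
  out <- vapply(labs, function(l) {
    mask <- interval_mask(classes[classes$label == l, , drop = FALSE], n)
    mean(signal[mask]) / bg
  }, numeric(1))
  names(out) <- labs
  out
}

#' Median distance from transcription end sites to the nearest breakpoint
#'
#' @param breakpoints numeric basepair positions of segmentation boundaries.
#' @param tes numeric basepair positions of transcription end sites.
#' @return Median over TES of the distance to the closest breakpoint.
#' @export
tes_breakpoint_distance <- function(breakpoints, tes) {
  stopifnot(length(breakpoints) >= 1, length(tes) >= 1)
  bp <- sort(breakpoints)
  i <- findInterval(tes, bp)
  left <- ifelse(i >= 1, tes - bp[pmax(i, 1)], Inf)
  right <- ifelse(i < length(bp), bp[pmin(i + 1, length(bp))] - tes, Inf)
  median(pmin(abs(left), abs(right)))
}

#' Treat peak calls as a segmentation
#'
#' For a fair comparison of peak-based representations with segmentations,
#' the gaps between peaks become additional segments, so peaks and gaps
#' together tile the region.
#'
#' @param peaks interval data.frame with `start`, `end` (non-overlapping).
#' @param region_start,region_end 0-based half-open bounds of the region.
#' @return Interval data.frame with `start`, `end`, `is_peak`.
#' @export
peaks_to_segments <- function(peaks, region_start, region_end) {
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  starts <- pmax(peaks$start, region_start)
  ends <- pmin(peaks$end, region_end)
  out_start <- c()
  out_end <- c()
  is_peak <- c()
  cur <- region_start
  for (i in seq_along(starts)) {
    if (starts[i] > cur) {
      out_start <- c(out_start, cur); out_end <- c(out_end, starts[i])
      is_peak <- c(is_peak, FALSE)
    }
    out_start <- c(out_start, starts[i]); out_end <- c(out_end, ends[i])
    is_peak <- c(is_peak, TRUE)
    cur <- ends[i]
  }
  if (cur < region_end) {
    out_start <- c(out_start, cur); out_end <- c(out_end, region_end)
    is_peak <- c(is_peak, FALSE)
  }
  data.frame(start = out_start, end = out_end, is_peak = is_peak)
}

#' Rand index between two segmentations of the same positions
#'
#' Agreement on whether pairs of positions fall in the same segment; 1 means
#' identical partitions.
#'
#' @param labels1,labels2 integer segment labels per position.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(labels1, labels2) {
  stopifnot(length(labels1) == length(labels2))
  n <- length(labels1)
  tab <- table(labels1, labels2)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Evaluation report for a segmented track
#'
#' Bundles the statistics computed against the provided annotation sets and
#' optionally writes them as a two-column TSV.
#'
#' @param signal reconstructed positional signal.
#' @param n_points,n_segments sizes for [compression_ratio()].
#' @param peaks,classes,tes optional annotation inputs for
#'   [peak_fold_change()], [region_enrichment()] and
#'   [tes_breakpoint_distance()]; `breakpoints` (positions) is required with
#'   `tes`.
#' @param breakpoints segmentation boundary positions used for the TES
#'   distance.
#' @param output optional TSV path.
#' @return Named list of the computed statistics.
#' @export
eval_report <- function(signal, n_points = length(signal),
                        n_segments = nrow(signal_segments(signal)),
                        peaks = NULL, classes = NULL, tes = NULL,
                        breakpoints = NULL, output = NULL) {
  rep <- list(compression_ratio = compression_ratio(n_points, n_segments))
  if (!is.null(peaks)) {
    rep$peak_fold_change <- as.numeric(peak_fold_change(signal, peaks))
    mj <- max_jaccard(signal_segments(signal), peaks)
    rep$jaccard_median <- mj$median
    rep$jaccard_q90 <- mj$q90
  }
  if (!is.null(classes)) {
    enr <- region_enrichment(signal, classes)
    for (l in names(enr)) rep[[paste0("enrichment_", l)]] <- unname(enr[l])
  }
  if (!is.null(tes)) {
    if (is.null(breakpoints)) stop("TES evaluation needs 'breakpoints'")
    rep$tes_median_distance <- tes_breakpoint_distance(breakpoints, tes)
  }
  if (!is.null(output)) {
    write.table(data.frame(metric = names(rep), value = unlist(rep)),
                output, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}
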