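# End-to-end workflows: track in, segmented BedGraph out.

fit_segment <- function(series, family, penalty, lambda) {
  if (penalty == "L0") l0_segment(series, family, lambda)
  else l1_segment(series, family, lambda)
}

#' Find the penalty that yields a target segment count
#'
#' The number of segments is non-increasing in the penalty, so a bisection on
#' lambda converges to the penalty whose fit has segment count closest to
#' `k`; when two penalties tie in closeness the one giving fewer segments
#' (larger lambda) is returned.  Used to compare methods at matched
#' representation size.
#'
#' @inheritParams l0_segment
#' @param penalty `"L0"` or `"L1"`.
#' @param k target segment count, `1 <= k <= length(series)`.
#' @param max_iter bisection iterations.
#' @return List with `lambda` and the achieved `n_segments`.
#' @export
lambda_for_target_segments <- function(series,
                                       family = c("gaussian", "poisson", "binomial"),
                                       penalty = c("L0", "L1"), k,
                                       max_iter = 60) {
  family <- check_family_series(series, family)
  penalty <- match.arg(penalty)
  n <- length(series)
  stopifnot(k >= 1, k <= n)
  count <- function(lam) n_segments(fit_segment(series, family, penalty, lam))
  hi <- 1
  c_hi <- count(hi)
  it <- 0
  while (c_hi > k && it < 80) {
    hi <- hi * 2
    c_hi <- count(hi)
    it <- it + 1
  }
  lo <- 0
  c_lo <- count(lo)
  best_lambda <- hi
  best_count <- c_hi
  consider <- function(lam, cnt) {
    d <- abs(cnt - k)
    db <- abs(best_count - k)
    if (d < db || (d == db && cnt < best_count) ||
        (d == db && cnt == best_count && lam > best_lambda)) {
      best_lambda <<- lam
      best_count <<- cnt
    }
  }
  consider(lo, c_lo)
  consider(hi, c_hi)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cm <- count(mid)
    consider(mid, cm)
    if (cm == k) {
      # exact hit; push towards larger lambda among exact hits
      lo <- mid
      if (c_lo == k || (hi - lo) / max(hi, 1) < 1e-10) break
    } else if (cm > k) lo <- mid else hi <- mid
    if ((hi - lo) / max(hi, 1) < 1e-12) break
  }
  list(lambda = best_lambda, n_segments = best_count)
}

resolve_lambda <- function(series, family, penalty, lambda, target_segments,
                           cv) {
  if (!is.null(target_segments)) {
    if (is.numeric(lambda))
      stop("specify only one of a numeric 'lambda' and 'target_segments'")
    return(lambda_for_target_segments(series, family, penalty,
                                      target_segments)$lambda)
  }
  if (is.numeric(lambda)) {
    if (length(lambda) != 1 || is.na(lambda) || lambda < 0)
      stop("'lambda' must be a single non-negative number")
    return(lambda)
  }
  if (identical(lambda, "cv"))
    return(select_lambda(series, family, penalty, cv)$lambda)
  stop("'lambda' must be numeric or \"cv\"")
}

#' Compress a signal track into a segmented BedGraph
#'
#' Reads a BigWig or BedGraph, collates per-base values into fixed-width
#' bins (20 bp by default), segments each chromosome independently, and
#' writes the merged piecewise-constant representation as a BedGraph.
#'
#' @param input BigWig or BedGraph path.
#' @param output BedGraph path to write.
#' @param chrom chromosome(s) to process; default all in the file.
#' @param start,end optional 0-based half-open region (single chromosome
#'   only).
#' @param family loss family; Poisson is the natural choice for read counts.
#' @param penalty `"L0"` or `"L1"`.
#' @param lambda numeric penalty, or `"cv"` to select it by binned
#'   cross-validation.
#' @param target_segments alternatively, a target segment count per
#'   chromosome (overrides `lambda`).
#' @param bin_bp bin width in basepairs.
#' @param cv a [cv_config()] used when `lambda = "cv"`.
#' @param quiet suppress the per-chromosome log messages.
#' @return Invisibly, a data.frame with one row per chromosome: `n` bins,
#'   `n_segments`, `lambda`, `compression_ratio`.
#' @export
compress_bigwig <- function(input, output, chrom = NULL, start = NULL,
                            end = NULL, family = "poisson", penalty = "L0",
                            lambda = "cv", target_segments = NULL,
                            bin_bp = 20, cv = cv_config(bin_bp = bin_bp),
                            quiet = FALSE) {
  family <- match.arg(family, FAMILIES)
  penalty <- match.arg(penalty, c("L0", "L1"))
  if (is.null(chrom)) chrom <- track_chroms(input)
  if (length(chrom) > 1 && (!is.null(start) || !is.null(end)))
    stop("a start/end region needs a single chromosome")
  tracks <- list()
  info <- list()
  for (ch in chrom) {
    tr <- read_track_binned(input, ch, start, end, bin_bp = bin_bp)
    if (length(tr$series) == 0) {
      warning("empty region on ", ch, "; nothing written for it")
      next
    }
    lam <- resolve_lambda(tr$series, family, penalty, lambda,
                          target_segments, cv)
    fit <- fit_segment(tr$series, family, penalty, lam)
    tracks[[ch]] <- segmentation_to_track(fit, tr)
    cr <- compression_ratio(fit$n, n_segments(fit))
    info[[ch]] <- data.frame(chrom = ch, n = fit$n,
                             n_segments = n_segments(fit), lambda = lam,
                             compression_ratio = cr)
    if (!quiet)
      message(sprintf("%s: n = %d bins, %d segments (%.1fx), lambda = %g",
                      ch, fit$n, n_segments(fit), cr, lam))
  }
  all_tracks <- do.call(rbind, tracks)
  if (is.null(all_tracks))
    all_tracks <- data.frame(chrom = character(), start = numeric(),
                             end = numeric(), value = numeric())
  write_bedgraph(all_tracks, output)
  invisible(do.call(rbind, info))
}

#' Compress a methylation track into a BedGraph of segment fractions
#'
#' Reads a bismark coverage file into a dual-count series, fits the binomial
#' dual-track segmentation (the loss weighs each CpG by its read coverage,
#' so unreliable low-coverage stretches merge with their neighbours), and
#' writes one BedGraph line per segment holding the pooled methylated
#' fraction.  Segments span CpG ranks; output intervals span the genomic
#' extent of their CpGs.
#'
#' @param input bismark coverage path or a `meth_track` from
#'   [read_bismark()].
#' @param output BedGraph path to write.
#' @param chrom passed to [read_bismark()].
#' @param penalty,lambda,target_segments,cv as in [compress_bigwig()];
#'   cross-validation defaults to the pointwise mode appropriate for
#'   methylation.
#' @param quiet suppress the log message.
#' @return Invisibly, a one-row data.frame as in [compress_bigwig()].
#' @export
compress_methylation <- function(input, output, chrom = NULL,
                                 penalty = "L0", lambda = "cv",
                                 target_segments = NULL,
                                 cv = cv_config(mode = "pointwise", bin_bp = 1),
                                 quiet = FALSE) {
  penalty <- match.arg(penalty, c("L0", "L1"))
  meth <- if (inherits(input, "meth_track")) input else read_bismark(input, chrom)
  if (is.null(meth$series)) stop("no CpGs to segment")
  lam <- resolve_lambda(meth$series, "binomial", penalty, lambda,
                        target_segments, cv)
  fit <- fit_segment(meth$series, "binomial", penalty, lam)
  write_bedgraph(meth_segmentation_to_track(fit, meth), output)
  cr <- compression_ratio(fit$n, n_segments(fit))
  if (!quiet)
    message(sprintf("%s: %d CpGs, %d segments (%.1fx), lambda = %g",
                    meth$chrom, fit$n, n_segments(fit), cr, lam))
  invisible(data.frame(chrom = meth$chrom, n = fit$n,
                       n_segments = n_segments(fit), lambda = lam,
                       compression_ratio = cr))
}
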