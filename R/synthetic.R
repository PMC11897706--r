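# Seeded generators reproducing the statistical structure of the scenarios
# the segmentation families are designed for, so the whole pipeline is
# testable without downloads.  All generators are pure functions of their
# arguments plus the seed and leave the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a piecewise-constant series from a loss family
#'
#' Each position is drawn from the family's distribution at its segment's
#' true parameter: Gaussian mean with noise `sd`, Poisson rate, or (binomial)
#' a total count from the coverage model followed by a methylated count
#' `Binomial(total, fraction)`.
#'
#' @param seg_lengths integer segment lengths (>= 1).
#' @param params true per-segment parameter: mean, rate, or fraction.
#' @param family loss family.
#' @param sd Gaussian noise standard deviation.
#' @param coverage mean read coverage (binomial); scalar or per-position.
#' @param coverage_model `"poisson"` (totals drawn Poisson around
#'   `coverage`) or `"constant"`.
#' @param seed integer seed; same seed, same draw.
#' @return List with `series`, `truth` (list of `lengths`, `params`,
#'   `changepoints`, `labels`, `mean` per position) and `family`.
#' @export
sim_piecewise <- function(seg_lengths, params,
                          family = c("gaussian", "poisson", "binomial"),
                          sd = 1, coverage = 30,
                          coverage_model = c("poisson", "constant"),
                          seed = NULL) {
  family <- match.arg(family)
  coverage_model <- match.arg(coverage_model)
  stopifnot(length(seg_lengths) == length(params), all(seg_lengths >= 1))
  if (family == "binomial") stopifnot(all(params >= 0 & params <= 1))
  if (family == "poisson") stopifnot(all(params >= 0))
  n <- sum(seg_lengths)
  mu <- rep(params, seg_lengths)
  truth <- list(lengths = seg_lengths, params = params,
                changepoints = cumsum(seg_lengths)[-length(seg_lengths)],
                labels = rep(seq_along(seg_lengths), seg_lengths),
                mean = mu)
  series <- with_seed(seed, {
    if (family == "gaussian") {
      weighted_series(rnorm(n, mu, sd))
    } else if (family == "poisson") {
      weighted_series(rpois(n, mu))
    } else {
      cov <- rep(coverage, length.out = n)
      total <- if (coverage_model == "poisson") rpois(n, cov) else round(cov)
      dual_count_series(rbinom(n, total, mu), total)
    }
  })
  list(series = series, truth = truth, family = family)
}

#' Simulate a ChIP-like autocorrelated count track
#'
#' Point-source peak intensities are spread by a box kernel of
#' `fragment_length` positions (immunoprecipitated fragments are much larger
#' than the occupancy site, so capture probability decays around it), added
#' to a uniform background rate, and Poisson-sampled.  The induced local
#' dependence is what binned cross-validation is designed to ignore.
#'
#' @param n series length in positions.
#' @param peak_pos integer positions of point sources; default equally
#'   spaced interior positions.
#' @param peak_intensity expected reads contributed by each source.
#' @param background uniform background rate per position.
#' @param fragment_length box kernel width in positions (>= 1).
#' @param n_peaks number of sources when `peak_pos` is NULL.
#' @param seed integer seed.
#' @return List with `series`, `rate` (true per-position rate) and
#'   `peak_pos`.
#' @export
sim_chip_like <- function(n = 2000, peak_pos = NULL, peak_intensity = 200,
                          background = 1, fragment_length = 15, n_peaks = 5,
                          seed = NULL) {
  stopifnot(fragment_length >= 1)
  if (is.null(peak_pos))
    peak_pos <- round(seq(n / (n_peaks + 1), n * n_peaks / (n_peaks + 1),
                          length.out = n_peaks))
  peak_intensity <- rep(peak_intensity, length.out = length(peak_pos))
  rate <- rep(background, n)
  half <- (fragment_length - 1) %/% 2
  for (i in seq_along(peak_pos)) {
    lo <- peak_pos[i] - half
    hi <- lo + fragment_length - 1
    win <- max(lo, 1):min(hi, n)
    rate[win] <- rate[win] + peak_intensity[i] / fragment_length
  }
  series <- with_seed(seed, weighted_series(rpois(n, rate)))
  list(series = series, rate = rate, peak_pos = peak_pos,
       fragment_length = fragment_length)
}

#' Simulate a Pol II-like track: TSS spike, gene-body plateau, background
#'
#' The hallmark polymerase pattern: a sharp peak at the transcription start
#' site (paused polymerase) and a broad plateau over the transcribed gene
#' body that drops back to background at the transcription end site.
#'
#' @param n series length.
#' @param tss,tes positions of the start and end site (`tss < tes <= n`).
#' @param tss_height added rate at the TSS spike.
#' @param tss_width spike width in positions.
#' @param gene_rate plateau rate over `[tss, tes]`.
#' @param background rate elsewhere.
#' @param seed integer seed.
#' @return List with `series`, `rate`, `tss`, `tes`.
#' @export
sim_pol2_like <- function(n = 500, tss = 50, tes = 350, tss_height = 50,
                          tss_width = 5, gene_rate = 8, background = 1,
                          seed = NULL) {
  stopifnot(tss < tes, tes <= n)
  rate <- rep(background, n)
  rate[tss:tes] <- gene_rate
  rate[tss:min(tss + tss_width - 1, n)] <- gene_rate + tss_height
  series <- with_seed(seed, weighted_series(rpois(n, rate)))
  list(series = series, rate = rate, tss = tss, tes = tes)
}

#' Simulate methylation blocks with a low-coverage discordant insert
#'
#' Three high-coverage blocks with two true methylation-fraction changes,
#' plus a short insert inside the first block whose beta value differs
#' dramatically but whose coverage is so low that the evidence is weak.  A
#' coverage-aware (binomial) segmentation should merge the insert with its
#' neighbourhood; a segmentation of the raw beta values sees only the
#' dramatic fraction and is tempted to break it out.
#'
#' @param block_len CpGs per block.
#' @param betas true fractions of the three blocks.
#' @param coverage mean read coverage of the blocks.
#' @param insert_len,insert_beta,insert_coverage,insert_start geometry of the
#'   low-coverage insert (1-based CpG rank of its first position, inside
#'   block 1).
#' @param seed integer seed.
#' @return List with `series` (dual counts), `beta_series` (observed beta as
#'   a [weighted_series()], zero-coverage CpGs carry weight 0), `truth`
#'   (block changepoints and fractions) and `insert` (CpG ranks).
#' @export
sim_meth_low_coverage_insert <- function(block_len = 100,
                                         betas = c(0.8, 0.2, 0.8),
                                         coverage = 30, insert_len = 5,
                                         insert_beta = 0.2,
                                         insert_coverage = 1,
                                         insert_start = 48, seed = NULL) {
  stopifnot(length(betas) == 3, insert_start + insert_len - 1 <= block_len)
  n <- 3 * block_len
  beta <- rep(betas, each = block_len)
  cov_mean <- rep(coverage, n)
  insert <- insert_start:(insert_start + insert_len - 1)
  beta[insert] <- insert_beta
  cov_mean[insert] <- insert_coverage
  out <- with_seed(seed, {
    total <- rpois(n, cov_mean)
    meth <- rbinom(n, total, beta)
    list(total = total, meth = meth)
  })
  beta_obs <- ifelse(out$total > 0, out$meth / out$total, 0)
  list(series = dual_count_series(out$meth, out$total),
       beta_series = weighted_series(beta_obs, as.numeric(out$total > 0)),
       truth = list(changepoints = c(block_len, 2 * block_len),
                    betas = betas, beta = beta),
       insert = insert)
}

#' Simulate a constant methylation region with two single-CpG outliers
#'
#' A long run of constant beta at ample coverage holding exactly two isolated
#' CpGs whose methylation differs sharply.  An L0 segmentation can afford to
#' break them out as single-CpG segments; the convex L1 penalty, which pays
#' for the size of each jump, resists.
#'
#' @param n number of CpGs.
#' @param beta background fraction.
#' @param coverage mean read coverage.
#' @param outliers CpG ranks of the two outliers.
#' @param outlier_beta their true fraction.
#' @param seed integer seed.
#' @return List with `series`, `truth` (per-CpG fraction) and `outliers`.
#' @export
sim_meth_cpg_outliers <- function(n = 200, beta = 0.9, coverage = 30,
                                  outliers = c(60, 140), outlier_beta = 0.1,
                                  seed = NULL) {
  stopifnot(all(outliers >= 1 & outliers <= n))
  bvec <- rep(beta, n)
  bvec[outliers] <- outlier_beta
  out <- with_seed(seed, {
    total <- rpois(n, coverage)
    total[total == 0] <- 1  # ample coverage everywhere by construction
    meth <- rbinom(n, total, bvec)
    list(total = total, meth = meth)
  })
  list(series = dual_count_series(out$meth, out$total),
       truth = list(beta = bvec), outliers = outliers)
}

#' Write a simulated methylation series as a bismark coverage file
#'
#' CpGs are placed every `spacing` bp from `start`; the 6-column 1-based
#' `.cov` dialect is emitted so the I/O path is exercised end to end.
#'
#' @param series a [dual_count_series()].
#' @param path output file.
#' @param chrom chromosome name.
#' @param start 0-based position of the first CpG.
#' @param spacing distance between consecutive CpGs in bp.
#' @return The path, invisibly.
#' @export
write_bismark_cov <- function(series, path, chrom = "chrSim", start = 1000,
                              spacing = 10) {
  pos0 <- start + (seq_along(series$meth) - 1L) * spacing
  meth <- series$meth
  unmeth <- series$total - series$meth
  pct <- ifelse(series$total > 0, 100 * meth / series$total, 0)
  out <- data.frame(chrom, pos0 + 1L, pos0 + 1L, sprintf("%.6g", pct),
                    meth, unmeth)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
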