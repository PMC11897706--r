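# Genome-track I/O.  All coordinates are 0-based half-open end to end;
# conversion to the 1-based closed convention of GRanges happens only at the
# rtracklayer boundary.

# sum/mean per-base coverage of a region into fixed-width bins
binned_from_coverage <- function(cov, chrom, start, end, bin_bp, method) {
  bin_start <- seq.int(start, end - 1L, by = bin_bp)
  bin_end <- pmin(bin_start + bin_bp, end)
  v <- IRanges::Views(cov, start = bin_start + 1L, end = bin_end)
  vals <- IRanges::viewSums(v)
  if (method == "mean") vals <- vals / (bin_end - bin_start)
  # partial last bin keeps a fractional weight equal to its covered width
  weights <- (bin_end - bin_start) / bin_bp
  list(chrom = chrom, start = start, end = end, bin_bp = bin_bp,
       bin_start = bin_start, bin_end = bin_end,
       series = weighted_series(as.numeric(vals), weights))
}

track_coverage <- function(gr, chrom, start, end) {
  if (!chrom %in% as.character(GenomicRanges::seqnames(gr)) &&
      !chrom %in% GenomeInfoDb::seqlevels(gr))
    stop("chromosome '", chrom, "' not present in the track")
  cov <- GenomicRanges::coverage(gr, weight = "score")[[chrom]]
  # absent intervals read as 0 with full weight: no reads is an observation
  if (length(cov) < end) cov <- c(cov, S4Vectors::Rle(0, end - length(cov)))
  cov
}

#' Read a BigWig region into fixed-width bins
#'
#' Per-base values are summed (default) or averaged into consecutive bins of
#' `bin_bp` basepairs; the last bin may be partial, in which case its weight
#' is the fraction of the bin it covers.  Bases with no interval in the file
#' are read as 0 with full weight (absence of reads is an observation of
#' zero under count losses).
#'
#' @param path BigWig file.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region; default the whole chromosome.
#' @param bin_bp bin width in basepairs (default 20).
#' @param method `"sum"` (count semantics, default) or `"mean"`.
#' @return A list of class `binned_track`: region coordinates, `bin_start`,
#'   `bin_end` and a [weighted_series()] of bin values.
#' @export
read_bigwig_binned <- function(path, chrom, start = NULL, end = NULL,
                               bin_bp = 20, method = c("sum", "mean")) {
  method <- match.arg(method)
  si <- rtracklayer::seqinfo(rtracklayer::BigWigFile(path))
  if (!chrom %in% GenomeInfoDb::seqnames(si))
    stop("chromosome '", chrom, "' not present in ", path)
  clen <- GenomeInfoDb::seqlengths(si)[[chrom]]
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- clen
  if (start < 0 || end > clen || end <= start)
    stop("region [", start, ", ", end, ") outside chromosome bounds")
  sel <- rtracklayer::BigWigSelection(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end)))
  gr <- rtracklayer::import.bw(path, selection = sel)
  out <- binned_from_coverage(track_coverage(gr, chrom, start, end),
                              chrom, start, end, bin_bp, method)
  structure(out, class = "binned_track")
}

#' Read a BedGraph region into fixed-width bins
#'
#' Same contract as [read_bigwig_binned()] for the text BedGraph format.
#'
#' @inheritParams read_bigwig_binned
#' @export
read_bedgraph_binned <- function(path, chrom, start = NULL, end = NULL,
                                 bin_bp = 20, method = c("sum", "mean")) {
  method <- match.arg(method)
  gr <- rtracklayer::import(path, format = "bedGraph")
  keep <- as.character(GenomicRanges::seqnames(gr)) == chrom
  if (!any(keep)) stop("chromosome '", chrom, "' not present in ", path)
  gr <- gr[keep]
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- max(GenomicRanges::end(gr))
  if (end <= start) stop("empty region")
  out <- binned_from_coverage(track_coverage(gr, chrom, start, end),
                              chrom, start, end, bin_bp, method)
  structure(out, class = "binned_track")
}

#' Read a signal track (BigWig or BedGraph) into bins
#'
#' Dispatches on the file extension: `.bw`/`.bigwig` to
#' [read_bigwig_binned()], anything else to [read_bedgraph_binned()].
#'
#' @inheritParams read_bigwig_binned
#' @export
read_track_binned <- function(path, chrom, start = NULL, end = NULL,
                              bin_bp = 20, method = c("sum", "mean")) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    read_bigwig_binned(path, chrom, start, end, bin_bp, method)
  } else {
    read_bedgraph_binned(path, chrom, start, end, bin_bp, method)
  }
}

#' Chromosomes available in a track file
#' @param path BigWig or BedGraph file.
#' @return Character vector of chromosome names.
#' @export
track_chroms <- function(path) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    GenomeInfoDb::seqnames(rtracklayer::seqinfo(rtracklayer::BigWigFile(path)))
  } else {
    unique(as.character(GenomicRanges::seqnames(
      rtracklayer::import(path, format = "bedGraph"))))
  }
}

#' Read a bismark coverage file
#'
#' Accepts the 6-column `.cov` dialect (`chrom start end pct meth unmeth`,
#' 1-based start in standard exports) and the 7-column cytosine report
#' (`chrom pos strand meth unmeth context tri`, 1-based), auto-detected by
#' column count.  Both counts are preserved; the methylation fraction is
#' never rounded into being.
#'
#' @param path bismark file (plain text or gzip).
#' @param chrom restrict to one chromosome (default: require the file to be
#'   single-chromosome or take all, in file order).
#' @param start,end optional 0-based half-open region filter.
#' @param coords `"auto"` (0-based if any start is 0, else 1-based),
#'   `"zero"` or `"one"`.
#' @return List of class `meth_track`: `chrom`, `pos` (0-based cytosine
#'   positions) and a [dual_count_series()].
#' @export
read_bismark <- function(path, chrom = NULL, start = NULL, end = NULL,
                         coords = c("auto", "zero", "one")) {
  coords <- match.arg(coords)
  tab <- tryCatch(read.table(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  nc <- ncol(tab)
  if (nc == 6) {
    pos <- suppressWarnings(as.numeric(tab[[2]]))
    meth <- suppressWarnings(as.numeric(tab[[5]]))
    unmeth <- suppressWarnings(as.numeric(tab[[6]]))
    total <- meth + unmeth
  } else if (nc == 7) {
    pos <- suppressWarnings(as.numeric(tab[[2]]))
    meth <- suppressWarnings(as.numeric(tab[[4]]))
    unmeth <- suppressWarnings(as.numeric(tab[[5]]))
    total <- meth + unmeth
  } else {
    stop("unrecognized bismark dialect: ", nc, " columns")
  }
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad)) stop("malformed bismark record at line ", bad[1])
  if (coords == "auto") coords <- if (any(pos == 0)) "zero" else "one"
  if (coords == "one") pos <- pos - 1
  chroms <- as.character(tab[[1]])
  if (!is.null(chrom)) {
    keep <- chroms == chrom
    if (!any(keep) && nrow(tab)) stop("chromosome '", chrom, "' not in ", path)
    pos <- pos[keep]; meth <- meth[keep]; total <- total[keep]
    chroms <- chroms[keep]
  } else if (length(unique(chroms)) > 1) {
    stop("file spans several chromosomes; pass 'chrom'")
  }
  if (!is.null(start) || !is.null(end)) {
    keep <- rep(TRUE, length(pos))
    if (!is.null(start)) keep <- keep & pos >= start
    if (!is.null(end)) keep <- keep & pos < end
    pos <- pos[keep]; meth <- meth[keep]; total <- total[keep]
    chroms <- chroms[keep]
  }
  if (length(pos) && is.unsorted(pos, strictly = TRUE))
    stop("positions are not strictly increasing within the chromosome")
  structure(list(chrom = if (length(chroms)) chroms[1] else chrom,
                 pos = pos,
                 series = if (length(pos)) dual_count_series(meth, total)
                          else NULL),
            class = "meth_track")
}

#' Counts from paired fraction and coverage tracks
#'
#' Roadmap-style WGBS releases store a methylation-fraction BigWig and a read
#' coverage BigWig; methylated counts are recovered as
#' `round(fraction * coverage)`.
#'
#' @param fraction,coverage numeric vectors over the same positions.
#' @return A [dual_count_series()].
#' @export
fraction_coverage_to_counts <- function(fraction, coverage) {
  stopifnot(length(fraction) == length(coverage))
  dual_count_series(round(fraction * coverage), coverage)
}

#' Convert a segmentation of a binned track to basepair intervals
#'
#' A segment spanning bins `b1..b2` becomes the interval
#' `[region_start + (b1-1)*bin_bp, region_start + b2*bin_bp)`, clipped to the
#' region end so a partial last bin ends at the region end rather than the
#' bin end.
#'
#' @param seg a `segmentation` fit on the track's series.
#' @param track a `binned_track`.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
segmentation_to_track <- function(seg, track) {
  stopifnot(inherits(seg, "segmentation"), inherits(track, "binned_track"))
  if (seg$n != length(track$series)) stop("segmentation does not match track")
  data.frame(
    chrom = track$chrom,
    start = track$bin_start[seg$seg_start],
    end = track$bin_end[seg$seg_end],
    value = seg$segment_values,
    stringsAsFactors = FALSE
  )
}

#' Convert a CpG-indexed methylation segmentation to basepair intervals
#'
#' Segments span CpG ranks; the output interval of a segment covering CpGs
#' `s..e` spans the genomic extent `[pos[s], pos[e] + 1)`.
#'
#' @param seg a `segmentation` fit on the methylation series.
#' @param meth a `meth_track` from [read_bismark()].
#' @return data.frame with `chrom`, `start`, `end`, `value` (fractions).
#' @export
meth_segmentation_to_track <- function(seg, meth) {
  stopifnot(inherits(seg, "segmentation"), inherits(meth, "meth_track"))
  if (seg$n != length(meth$pos)) stop("segmentation does not match track")
  data.frame(
    chrom = meth$chrom,
    start = meth$pos[seg$seg_start],
    end = meth$pos[seg$seg_end] + 1,
    value = seg$segment_values,
    stringsAsFactors = FALSE
  )
}

#' Write a segment track as BedGraph
#'
#' One line per segment, `chrom start end value`, 0-based half-open; adjacent
#' intervals on the same chromosome with identical value are merged first.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (nrow(track)) {
    keep <- logical(nrow(track))
    keep[1] <- TRUE
    j <- 1
    for (i in seq_len(nrow(track))[-1]) {
      if (track$chrom[i] == track$chrom[j] && track$start[i] == track$end[j] &&
          track$value[i] == track$value[j]) {
        track$end[j] <- track$end[i]
      } else {
        j <- i
        keep[i] <- TRUE
      }
    }
    track <- track[keep, , drop = FALSE]
  }
  out <- data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                    format(track$end, scientific = FALSE, trim = TRUE),
                    format(track$value, scientific = FALSE, trim = TRUE, digits = 10))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BedGraph as a segment track
#' @param path BedGraph file.
#' @return data.frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score,
             stringsAsFactors = FALSE)
}

#' Read BED intervals
#'
#' BED3/6/12 via rtracklayer; coordinates returned 0-based half-open.
#'
#' @param path BED file (narrowPeak-style extra columns are ignored).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   # narrowPeak and friends: keep the six standard columns
                   tab <- read.table(path, header = FALSE, sep = "",
                                     stringsAsFactors = FALSE)
                   GenomicRanges::GRanges(
                     tab[[1]], IRanges::IRanges(tab[[2]] + 1L, tab[[3]]),
                     strand = if (ncol(tab) >= 6) tab[[6]] else "*",
                     name = if (ncol(tab) >= 4) tab[[4]] else NA,
                     score = if (ncol(tab) >= 5) suppressWarnings(as.numeric(tab[[5]])) else NA)
                 })
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df$strand <- as.character(GenomicRanges::strand(gr))
  df
}

#' Strand-aware transcript end and start sites
#'
#' For a `+` (or unstranded) transcript the TES is its end coordinate and the
#' TSS its start; for `-` the roles swap.  Accepts the interval data.frame of
#' [read_bed()] or a GTF path (transcript records are used; gene records if
#' no transcripts are present).
#'
#' @param x interval data.frame with a `strand` column, or a GTF file path.
#' @return data.frame with `chrom`, `tss`, `tes`, `strand` (and `name` when
#'   available).
#' @export
transcript_ends <- function(x) {
  if (is.character(x) && length(x) == 1) {
    gr <- rtracklayer::import(x)
    type <- as.character(gr$type)
    keep <- if (any(type == "transcript")) type == "transcript" else type == "gene"
    gr <- gr[keep]
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  minus <- x$strand == "-"
  out <- data.frame(chrom = x$chrom,
                    tss = ifelse(minus, x$end, x$start),
                    tes = ifelse(minus, x$start, x$end),
                    strand = x$strand,
                    stringsAsFactors = FALSE)
  if (!is.null(x$name)) out$name <- x$name
  out
}
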