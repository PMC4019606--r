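# Per-nucleotide probability tracks. Rather than calling hard DMR intervals
# with ad hoc minimum-length/gap rules, each covered position carries the
# probability P(p1 > p2) and downstream analysis works on the track itself:
# kernel smoothing at a chosen bandwidth, fixed-size window averaging, or
# mean probability over annotated regions. No operation here produces a
# boundary.

#' Construct a per-position probability track
#'
#' An ordered set of covered positions on one chromosome, each carrying a
#' probability (typically `P(p1 > p2)` from [diff_methylation()]).
#'
#' @param chrom Single chromosome identifier.
#' @param pos Strictly increasing 1-based integer positions.
#' @param value Probabilities in `[0, 1]`, one per position.
#' @return Data frame of class `position_track` with columns `chrom`, `pos`,
#'   `value`.
#' @examples
#' position_track("chr1", c(100, 150, 400), c(0.9, 0.95, 0.5))
#' @export
position_track <- function(chrom, pos, value) {
  if (length(chrom) != 1) stop("a track lives on one chromosome", call. = FALSE)
  if (length(pos) != length(value)) {
    stop("pos and value must have equal length", call. = FALSE)
  }
  if (length(pos) > 1 && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(pos < 1) || any(pos != round(pos))) {
    stop("positions must be 1-based integers", call. = FALSE)
  }
  if (any(value < 0) || any(value > 1) || any(!is.finite(value))) {
    stop("values must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(data.frame(chrom = chrom, pos = as.integer(pos), value = value),
            class = c("position_track", "data.frame"))
}

#' Kernel-smooth a probability track
#'
#' Nadaraya-Watson weighted average with a Gaussian kernel over genomic
#' distance, evaluated at the covered positions themselves; weights are
#' truncated beyond four bandwidths. Methylation levels are spatially
#' correlated, so borrowing strength from neighbours suppresses
#' single-position noise; the bandwidth sets the length scale and is a
#' modelling choice, not something estimated here. Only covered positions
#' contribute -- uncovered bases are not imputed.
#'
#' Each output value is a convex combination of input values inside the
#' truncation window, so the output stays within the range of its
#' contributing inputs. A bandwidth smaller than half the minimum
#' inter-position gap leaves only the self-weight and returns the track
#' unchanged.
#'
#' @param track A [position_track()].
#' @param bandwidth Gaussian kernel standard deviation, in bases (> 0).
#' @return A `position_track` at the same positions with smoothed values.
#' @examples
#' tr <- position_track("chr1", c(100, 200), c(0, 1))
#' smooth_track(tr, bandwidth = 1e4)  # both values near 0.5
#' @export
smooth_track <- function(track, bandwidth) {
  stopifnot(inherits(track, "position_track"))
  if (nrow(track) == 0) stop("track is empty", call. = FALSE)
  if (length(bandwidth) != 1 || bandwidth <= 0) {
    stop("bandwidth must be a single positive number", call. = FALSE)
  }
  pos <- as.numeric(track$pos)
  val <- track$value
  cutoff <- 4 * bandwidth
  # window of contributing neighbours per position; positions are sorted
  lo <- findInterval(pos - cutoff, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + cutoff, pos)
  out <- vapply(seq_along(pos), function(i) {
    j <- lo[i]:hi[i]
    w <- exp(-0.5 * ((pos[j] - pos[i]) / bandwidth)^2)
    sum(w * val[j]) / sum(w)
  }, numeric(1))
  position_track(track$chrom[1], track$pos, out)
}

#' Average a track over fixed-size blocks of covered positions
#'
#' Clumps consecutive runs of `window` covered positions into a single
#' entry placed at the block's first position and carrying the block mean;
#' a trailing partial block is averaged over its own size. Block means
#' weighted by block sizes conserve the track's value total exactly.
#'
#' @param track A [position_track()].
#' @param window Number of consecutive covered positions per block (>= 1).
#' @return A `position_track` with one entry per block.
#' @examples
#' tr <- position_track("chr1", c(10, 20, 30, 40), c(0.2, 0.4, 0.9, 0.1))
#' window_average(tr, 3)  # values 0.5 and 0.1
#' @export
window_average <- function(track, window) {
  stopifnot(inherits(track, "position_track"))
  if (length(window) != 1 || window < 1 || window != round(window)) {
    stop("window must be a positive integer", call. = FALSE)
  }
  if (window == 1 || nrow(track) == 0) return(track)
  block <- (seq_len(nrow(track)) - 1L) %/% as.integer(window)
  means <- tapply(track$value, block, mean)
  firsts <- tapply(track$pos, block, function(p) p[1])
  position_track(track$chrom[1], as.integer(firsts), as.numeric(means))
}

#' Mean track probability over genomic regions
#'
#' For each region, the arithmetic mean of track values at covered
#' positions inside it; regions containing no covered position report `NA`
#' (an explicit no-data marker). This supports questions of the form "is the
#' average differential-methylation probability over these annotated
#' intervals higher than over comparison regions?" without ever calling
#' discrete DMR boundaries.
#'
#' @param track A [position_track()].
#' @param regions A [GenomicRanges::GRanges] (1-based, closed intervals, the
#'   Bioconductor convention; BED input read via [read_bed3()] is converted
#'   automatically). Regions on other chromosomes report `NA`.
#' @return Data frame with columns `chrom`, `start`, `end`, `n_positions`,
#'   `mean_value`.
#' @examples
#' tr <- position_track("chr1", c(10, 20, 30), c(0.1, 0.5, 0.9))
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 25))
#' region_mean(tr, rg)
#' @export
region_mean <- function(track, regions) {
  stopifnot(inherits(track, "position_track"))
  if (!methods::is(regions, "GRanges")) {
    stop("regions must be a GRanges", call. = FALSE)
  }
  chrom <- as.character(GenomicRanges::seqnames(regions))
  start <- GenomicRanges::start(regions)
  end <- GenomicRanges::end(regions)
  pos <- track$pos
  res <- lapply(seq_along(regions), function(i) {
    if (chrom[i] != track$chrom[1]) return(c(0L, NA_real_))
    j <- which(pos >= start[i] & pos <= end[i])
    if (length(j) == 0) return(c(0L, NA_real_))
    c(length(j), mean(track$value[j]))
  })
  res <- do.call(rbind, res)
  data.frame(chrom = chrom, start = start, end = end,
             n_positions = as.integer(res[, 1]), mean_value = res[, 2])
}

#' Write a probability track as bedGraph
#'
#' Each covered position becomes a width-1 interval with the probability as
#' score; coordinates are converted from the track's 1-based positions to
#' bedGraph's 0-based half-open convention by the exporter.
#'
#' @param track A [position_track()].
#' @param path Output file path (should end in `.bedGraph` / `.bedgraph`
#'   for format detection; otherwise the format is forced).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "position_track"))
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom[1],
    ranges = IRanges::IRanges(start = track$pos, width = 1L),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED3 region file as GRanges
#'
#' Thin wrapper over [rtracklayer::import()]: BED's 0-based half-open
#' records come back as 1-based closed GRanges ready for [region_mean()].
#'
#' @param path Path to a BED file (first three columns used).
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed3 <- function(path) {
  rtracklayer::import(path, format = "BED")
}
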