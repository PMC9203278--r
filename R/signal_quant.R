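#' Tile a genome into fixed-width bins
#'
#' @param genome Named integer vector of contig lengths.
#' @param bin_size Bin width in bp; the last bin of a contig may be short
#'   (kept, so counts are conserved).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
genome_bins <- function(genome, bin_size = 1000L) {
  stopifnot(bin_size >= 1, all(genome > 0), !is.null(names(genome)))
  out <- lapply(names(genome), function(ch) {
    starts <- seq.int(0L, genome[[ch]] - 1L, by = bin_size)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size, genome[[ch]])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count fragments in genome bins
#'
#' Each fragment is assigned to the single bin containing its midpoint
#' (integer midpoint, half-open bins), so the total assigned equals the
#' fragment count exactly.
#'
#' @param frags A [fragment_set()] (target-genome records expected).
#' @param genome Named integer vector of contig lengths; every fragment's
#'   contig must be present.
#' @param bin_size Bin width in bp.
#' @return Data frame with columns `chrom`, `start`, `end`, `count`.
#' @export
bin_counts <- function(frags, genome, bin_size = 1000L) {
  bins <- genome_bins(genome, bin_size)
  unknown <- setdiff(unique(frags$chrom), names(genome))
  if (length(unknown))
    stop("fragment on contig unknown to the bin frame: ", unknown[1])
  bins$count <- 0L
  if (nrow(frags)) {
    mid <- .fragment_midpoint(frags)
    key <- paste(frags$chrom, mid %/% bin_size)
    tab <- table(key)
    bkey <- paste(bins$chrom, bins$start %/% bin_size)
    hit <- match(bkey, names(tab))
    bins$count <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  bins
}

#' Kernel density estimate of log2 bin counts
#'
#' Gaussian KDE (Silverman's rule-of-thumb bandwidth, 512-point grid
#' spanning the data range +/- 3 bandwidths) of the log2-transformed per-bin
#' counts. By default zero-count bins are excluded (log2 of 0 is undefined);
#' supplying `pseudocount` instead transforms all bins as
#' `log2(count + pseudocount)`.
#'
#' @param bins Output of [bin_counts()].
#' @param pseudocount `NULL` (drop zero bins) or a positive value added to
#'   every count before log2.
#' @return List of class `"density_curve"` with `grid`, `density`, and the
#'   zero-bin `policy` used.
#' @export
log_density <- function(bins, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    x <- log2(bins$count[bins$count > 0])
    policy <- "drop_zero_bins"
  } else {
    stopifnot(pseudocount > 0)
    x <- log2(bins$count + pseudocount)
    policy <- sprintf("pseudocount_%g", pseudocount)
  }
  if (sum(bins$count > 0) < 2)
    stop("need at least 2 nonzero bins for a density estimate")
  d <- density(x, bw = "nrd0", kernel = "gaussian", n = 512, cut = 3)
  structure(list(grid = d$x, density = d$y, policy = policy),
            class = "density_curve")
}

#' Fraction of reads in peaks (FRiP)
#'
#' Percentage of fragments whose midpoint falls inside any peak. Peaks must
#' be non-overlapping (pre-merged) so no fragment is double counted.
#'
#' @param frags A [fragment_set()].
#' @param peaks Data frame with `chrom`, `start`, `end` (merged peaks).
#' @return Percentage in \[0, 100\].
#' @export
frip <- function(frags, peaks) {
  if (nrow(frags) == 0) stop("FRiP undefined for an empty fragment set")
  if (nrow(peaks) == 0) return(0)
  mid <- .fragment_midpoint(frags)
  100 * sum(.point_in_intervals(frags$chrom, mid, peaks)) / nrow(frags)
}

#' Fragment percentage per repeat class
#'
#' For each annotation class independently (classes may overlap each other),
#' the percentage of fragments whose midpoint falls inside the class's
#' intervals.
#'
#' @param frags A [fragment_set()].
#' @param repeat_annotation Named list of interval data frames
#'   (`chrom`, `start`, `end`), one per repeat class.
#' @return Named numeric vector of percentages.
#' @export
repeat_class_fractions <- function(frags, repeat_annotation) {
  if (nrow(frags) == 0) stop("empty fragment set")
  mid <- .fragment_midpoint(frags)
  vapply(repeat_annotation, function(ivs) {
    100 * sum(.point_in_intervals(frags$chrom, mid, ivs)) / nrow(frags)
  }, 0)
}

#' Replicate correlation over genome bins
#'
#' Pearson correlation of log(1 + count) across identical bin frames — the
#' standard binned reproducibility measure for calibrated tracks.
#'
#' @param a,b Outputs of [bin_counts()] on the same genome and bin size.
#' @return Pearson r in \[-1, 1\].
#' @export
bin_correlation <- function(a, b) {
  if (!identical(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")]))
    stop("bin frames differ")
  x <- log1p(a$count)
  y <- log1p(b$count)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in binned counts")
  cor(x, y)
}

#' Base-resolution coverage track
#'
#' Piles up fragments into maximal constant-value coverage runs
#' (value = `scale` x overlap count); zero-coverage stretches are omitted,
#' so `sum(value * width)` equals `scale` times the summed fragment lengths
#' exactly (at `scale = 1`, an integer identity).
#'
#' @param frags A [fragment_set()].
#' @param scale Positive multiplier (e.g. a calibration factor when scaling
#'   tracks rather than downsampling).
#' @return bedGraph-style data frame (`chrom`, `start`, `end`, `value`),
#'   sorted, non-overlapping.
#' @export
coverage_track <- function(frags, scale = 1) {
  stopifnot(scale > 0)
  if (nrow(frags) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  out <- lapply(split(seq_len(nrow(frags)), frags$chrom), function(idx) {
    cov <- IRanges::coverage(.ir(frags$start[idx], frags$end[idx]))
    rd <- data.frame(
      chrom = frags$chrom[idx[1]],
      start = cumsum(c(0L, S4Vectors::runLength(cov)))[seq_along(S4Vectors::runLength(cov))],
      width = S4Vectors::runLength(cov),
      value = S4Vectors::runValue(cov), stringsAsFactors = FALSE)
    rd$end <- rd$start + rd$width
    rd[rd$value > 0, c("chrom", "start", "end", "value")]
  })
  out <- do.call(rbind, out)
  out$value <- out$value * scale
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
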