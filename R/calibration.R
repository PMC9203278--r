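#' Quality-filter a fragment set
#'
#' Retains records with mapping quality strictly greater than `mapq_min`
#' (records with unknown MAPQ pass), optionally deduplicated to at most one
#' record per (chrom, start, end, genome) — the "unique mapped tags" used
#' for spike-in counting.
#'
#' @param frags A [fragment_set()].
#' @param mapq_min Strict MAPQ threshold; a record with `mapq == mapq_min`
#'   is removed.
#' @param dedupe Collapse exact coordinate duplicates within each genome.
#' @return Filtered [fragment_set()], input order preserved (first occurrence
#'   kept when deduplicating).
#' @export
filter_quality <- function(frags, mapq_min = 20L, dedupe = TRUE) {
  keep <- is.na(frags$mapq) | frags$mapq > mapq_min
  out <- frags[keep, , drop = FALSE]
  if (dedupe && nrow(out) > 1) {
    key <- paste(out$chrom, out$start, out$end, out$genome)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Spike-in calibration factors
#'
#' The factor for each sample is the ratio of the lowest spike-in fragment
#' count across samples to that sample's spike-in count. The sample with the
#' fewest spike-in fragments is the anchor (factor exactly 1); every other
#' sample is scaled down towards it.
#'
#' @param spikein_counts Named integer vector of unique, quality-passing
#'   spike-in fragment counts per sample.
#' @return Data frame with columns `sample`, `spikein_count`, `factor`.
#' @export
compute_calibration_factors <- function(spikein_counts) {
  stopifnot(length(spikein_counts) >= 1, !is.null(names(spikein_counts)))
  if (any(spikein_counts == 0)) {
    bad <- names(spikein_counts)[spikein_counts == 0][1]
    stop("sample '", bad, "' has no spike-in; cannot calibrate")
  }
  m <- min(spikein_counts)
  data.frame(sample = names(spikein_counts),
             spikein_count = as.integer(spikein_counts),
             factor = m / as.numeric(spikein_counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Seeded random downsampling of target fragments
#'
#' Retains exactly `round(factor * N)` of the `N` target-genome records
#' (round half to even), sampled uniformly without replacement; spike-in
#' records are dropped from the output — once the factor is known their job
#' is done. Deterministic under `seed`; input order of retained records is
#' preserved.
#'
#' @param frags A [fragment_set()].
#' @param factor Retention fraction in (0, 1].
#' @param seed Integer seed.
#' @return Downsampled [fragment_set()] of target records only.
#' @export
downsample_fragments <- function(frags, factor, seed = 1L) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("downsampling factor must lie in (0, 1]")
  tgt <- frags[frags$genome == "target", , drop = FALSE]
  n <- nrow(tgt)
  k <- round(factor * n)
  if (k < n) {
    idx <- withr::with_seed(seed, sort(sample.int(n, k)))
    tgt <- tgt[idx, , drop = FALSE]
  }
  rownames(tgt) <- NULL
  class(tgt) <- c("fragment_set", "data.frame")
  tgt
}

#' Calibrate a multi-sample experiment
#'
#' Composition of the calibration pipeline: quality-filter every sample,
#' count unique spike-in fragments, derive per-sample calibration factors
#' (optionally within antibody batches, each batch anchored separately), and
#' randomly downsample each sample's target fragments by its factor. The
#' anchor sample of each batch passes through unscaled.
#'
#' @param samples Named list of [fragment_set()]s (>= 2 samples).
#' @param mapq_min,dedupe Passed to [filter_quality()].
#' @param batches Optional named character vector assigning samples to
#'   calibration batches (e.g. antibody groups); factors are computed within
#'   each batch. Default: one batch.
#' @param seed Integer seed; each sample's downsampling stream is derived
#'   from it.
#' @return List with `samples` (named list of calibrated target-only
#'   fragment sets) and `calibration` (the factor table, plus a `batch`
#'   column).
#' @export
calibrate_experiment <- function(samples, mapq_min = 20L, dedupe = TRUE,
                                 batches = NULL, seed = 1L) {
  stopifnot(is.list(samples), length(samples) >= 2, !is.null(names(samples)))
  if (is.null(batches)) batches <- setNames(rep("all", length(samples)), names(samples))
  filtered <- lapply(samples, filter_quality, mapq_min = mapq_min, dedupe = dedupe)
  spike <- vapply(filtered, function(f) sum(f$genome == "spikein"), 0L)
  calib <- NULL
  for (b in unique(batches[names(samples)])) {
    in_b <- names(samples)[batches[names(samples)] == b]
    cb <- compute_calibration_factors(spike[in_b])
    cb$batch <- b
    calib <- rbind(calib, cb)
  }
  out <- list()
  for (i in seq_along(calib$sample)) {
    s <- calib$sample[i]
    out[[s]] <- downsample_fragments(filtered[[s]], calib$factor[i],
                                     seed = seed + i)
  }
  list(samples = out[names(samples)], calibration = calib)
}
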