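# Independent brute-force oracles used against the interval algebra and
# counting code. They share no code with the implementation: interval
# relations are resolved by base painting on an integer position vector or
# by explicit pairwise comparison, never via IRanges.

# Random interval set on a single small chromosome (coords < limit so base
# painting stays cheap).
random_intervals <- function(n, limit = 5000L, max_width = 200L, chrom = "chr1") {
  start <- sample.int(limit - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             score = stats::runif(n), stringsAsFactors = FALSE)
}

# Transitive gap-merge by painting gap-padded intervals: two intervals are
# chained iff their gap is < max_gap; connected runs of painted bases give
# the merged clusters. Padding stops at end + max_gap - 1 so a gap of
# exactly max_gap leaves an unpainted position (strict "closer than").
# Requires max_gap >= 1.
oracle_merge <- function(ivs, max_gap) {
  stopifnot(max_gap >= 1)
  out <- lapply(split(ivs, ivs$chrom), function(d) {
    limit <- max(d$end) + max_gap + 2L
    painted <- logical(limit)
    for (i in seq_len(nrow(d)))
      painted[(d$start[i] + 1L):(d$end[i] + max_gap - 1L)] <- TRUE
    r <- rle(painted)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    comp_of_pos <- integer(limit)
    cid <- 0L
    for (k in seq_along(r$values)) {
      if (r$values[k]) {
        cid <- cid + 1L
        comp_of_pos[run_start[k]:run_end[k]] <- cid
      }
    }
    comp <- comp_of_pos[d$start + 1L]
    data.frame(chrom = d$chrom[1],
               start = as.integer(tapply(d$start, comp, min)),
               end = as.integer(tapply(d$end, comp, max)),
               score = as.numeric(tapply(d$score, comp, sum)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pairwise >= 1 bp overlap via outer comparison.
oracle_overlap_any <- function(a, b) {
  hit <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    if (!length(bi)) next
    m <- outer(a$start[ai], b$end[bi], `<`) & outer(a$end[ai], b$start[bi], `>`)
    hit[ai] <- rowSums(m) > 0
  }
  hit
}

# Union/coalesce by painting raw intervals.
oracle_union <- function(ivs) {
  out <- lapply(split(ivs, ivs$chrom), function(d) {
    limit <- max(d$end) + 1L
    painted <- logical(limit)
    for (i in seq_len(nrow(d)))
      painted[(d$start[i] + 1L):d$end[i]] <- TRUE
    r <- rle(painted)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(chrom = d$chrom[1], start = starts[r$values],
               end = ends[r$values], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-fragment midpoint membership by explicit loop.
oracle_midpoint_in <- function(frags, ivs) {
  vapply(seq_len(nrow(frags)), function(i) {
    mid <- (frags$start[i] + frags$end[i]) %/% 2L
    any(ivs$chrom == frags$chrom[i] & ivs$start <= mid & mid < ivs$end)
  }, logical(1))
}

# Best Jaccard of each truth region against a peak set; recall at a cutoff.
region_recall <- function(truth, peaks, jaccard_min = 0.5) {
  j <- vapply(seq_len(nrow(truth)), function(i) {
    p <- peaks[peaks$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(p) == 0) return(0)
    ov <- pmax(0L, pmin(p$end, truth$end[i]) - pmax(p$start, truth$start[i]))
    un <- (p$end - p$start) + (truth$end[i] - truth$start[i]) - ov
    max(ov / un)
  }, 0)
  mean(j >= jaccard_min)
}

# Small helpers used across tests -------------------------------------------

toy_genome <- function() c(chrT = 1e6)
toy_spikein <- function() c(chrS = 2e5)

# A compact two-condition CUT&RUN design used by several module tests.
toy_sim_params <- function(regions = NULL, global = c(cond1 = 1, cond2 = 1),
                           depth = c(c1r1 = 1, c1r2 = 1, c2r1 = 1, c2r2 = 1),
                           fragment_length = 100L, n_cells = 10000) {
  cutrun_sim_params(
    toy_genome(), toy_spikein(), n_cells = n_cells,
    global_level = global, planted_regions = regions, spikein_rate = 0.4,
    depth_scale = depth,
    conditions = setNames(
      ifelse(grepl("^c1", names(depth)), "cond1", "cond2"), names(depth)),
    fragment_length = fragment_length)
}

# hPTM truth table: 3 residues, mixed state counts, valid closure.
toy_marks <- function() {
  data.frame(
    histone = c("H3", "H3", "H3", "H3", "H3", "H3", "H4", "H4"),
    residue = c("K27", "K27", "K27", "K79", "K79", "K79", "K16", "K16"),
    state = c("un", "me2", "me3", "un", "me1", "me2", "un", "ac"),
    prop_cond1 = c(0.2, 0.3, 0.5, 0.5, 0.1, 0.4, 0.7, 0.3),
    prop_cond2 = c(0.5, 0.3, 0.2, 0.6, 0.2, 0.2, 0.4, 0.6),
    stringsAsFactors = FALSE)
}
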