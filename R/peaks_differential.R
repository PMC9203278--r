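#' Sparse-enrichment peak calling on a coverage track
#'
#' Candidate blocks are maximal contiguous runs of positive coverage in the
#' track (adjacent track intervals with no zero gap belong to one block);
#' with `max_gap > 0`, blocks separated by less than `max_gap` bp are fused
#' during block formation. Each block is scored by its area under the
#' coverage curve (sum of value x width). Blocks with score at or above the
#' `1 - retain_fraction` quantile of all block scores are retained; ties at
#' the threshold are all kept.
#'
#' With genuinely sparse background the default `max_gap = 0` (strict runs)
#' and a post-hoc [merge_peaks()] give the same peaks as gap-tolerant block
#' formation; at appreciable background density only the latter reconstructs
#' broad domains, so pipelines over dense simulated tracks should pass the
#' merge distance here.
#'
#' @param track bedGraph-style data frame (`chrom`, `start`, `end`, `value`),
#'   sorted, non-overlapping; zero-value intervals allowed (they split
#'   blocks).
#' @param retain_fraction Fraction of top-scoring blocks retained (the
#'   "top 1%" rule is `0.01`).
#' @param max_gap Gap (bp) below which adjacent blocks are fused before
#'   scoring; 0 means strict positive runs.
#' @return Peak data frame (`chrom`, `start`, `end`, `score`), sorted.
#' @export
call_peaks_sparse <- function(track, retain_fraction = 0.01, max_gap = 0L) {
  pos <- track[track$value > 0, , drop = FALSE]
  if (nrow(pos) == 0) stop("all-zero coverage track: no blocks to call")
  blocks <- lapply(split(seq_len(nrow(pos)), pos$chrom), function(idx) {
    s <- pos$start[idx]; e <- pos$end[idx]; v <- pos$value[idx]
    o <- order(s)
    s <- s[o]; e <- e[o]; v <- v[o]
    gap_break <- if (length(s) > 1) s[-1] - cummax(e[-length(e)]) >= max(1L, max_gap) else logical(0)
    block_id <- cumsum(c(TRUE, gap_break))
    data.frame(chrom = pos$chrom[idx[1]],
               start = tapply(s, block_id, min),
               end = tapply(e, block_id, max),
               score = tapply(v * (e - s), block_id, sum),
               stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, blocks)
  thr <- quantile(blocks$score, 1 - retain_fraction, names = FALSE)
  out <- blocks[blocks$score >= thr, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby peaks
#'
#' Peaks on the same chromosome closer than `max_gap` bp are merged
#' transitively (strictly closer: a gap of exactly `max_gap` is not merged);
#' a merged peak's score is the sum of its members' scores.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, optional `score`).
#' @param max_gap Merge distance in bp.
#' @return Sorted peak data frame with pairwise gaps >= `max_gap`.
#' @export
merge_peaks <- function(peaks, max_gap = 300L) {
  if (nrow(peaks) == 0) return(peaks)
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  out <- lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(idx) {
    red <- IRanges::reduce(.ir(peaks$start[idx], peaks$end[idx]),
                           min.gapwidth = max(1L, max_gap))
    hits <- IRanges::findOverlaps(.ir(peaks$start[idx], peaks$end[idx]), red)
    data.frame(chrom = peaks$chrom[idx[1]],
               start = .ir_start0(red), end = .ir_end0(red),
               score = as.numeric(tapply(score[idx][S4Vectors::queryHits(hits)],
                                         S4Vectors::subjectHits(hits), sum)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-reproducible peaks
#'
#' Retains the peaks of `a` that overlap any peak of `b` by at least 1 bp,
#' keeping the first set's coordinates — the replicate-intersection step
#' that builds a condition's final peak set.
#'
#' @param a,b Merged, sorted peak data frames.
#' @return Subset of `a`.
#' @export
intersect_replicates <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, , drop = FALSE])
  keep <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!length(bi)) next
    keep[ai] <- IRanges::overlapsAny(.ir(a$start[ai], a$end[ai]),
                                     .ir(b$start[bi], b$end[bi]))
  }
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combined, de-duplicated peak list
#'
#' Concatenates peak sets from several conditions and coalesces overlapping
#' intervals into their union, producing the disjoint combined region list
#' over which differential testing runs. Scores of coalesced members are
#' summed.
#'
#' @param sets List of peak data frames.
#' @return Sorted, non-overlapping peak data frame.
#' @export
combine_peak_lists <- function(sets) {
  all <- do.call(rbind, lapply(sets, function(s)
    s[, c("chrom", "start", "end",
          if ("score" %in% names(s)) "score" else NULL), drop = FALSE]))
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  if (is.null(all$score)) all$score <- 0
  merge_peaks(all, max_gap = 0L)
}

#' Remove peaks overlapping an exclusion list
#'
#' Peaks overlapping any interval of the exclusion list (ENCODE
#' blacklist-style coverage outliers) are removed entirely.
#'
#' @param peaks Peak data frame.
#' @param exclusion Interval data frame (`chrom`, `start`, `end`).
#' @return Filtered peak data frame.
#' @export
filter_exclusion <- function(peaks, exclusion) {
  if (nrow(peaks) == 0 || nrow(exclusion) == 0) return(peaks)
  drop <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ei <- which(exclusion$chrom == ch)
    if (!length(ei)) next
    drop[pi] <- IRanges::overlapsAny(.ir(peaks$start[pi], peaks$end[pi]),
                                     .ir(exclusion$start[ei], exclusion$end[ei]))
  }
  out <- peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Midpoint count of each sample's fragments in each region.
.region_counts <- function(regions, samples) {
  counts <- sapply(samples, function(f) {
    mid <- .fragment_midpoint(f)
    n <- integer(nrow(regions))
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      fi <- which(f$chrom == ch)
      if (!length(fi)) next
      hits <- IRanges::findOverlaps(IRanges::IRanges(mid[fi] + 1L, width = 1L),
                                    .ir(regions$start[ri], regions$end[ri]))
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(ri))
      n[ri] <- tab
    }
    n
  })
  matrix(counts, nrow = nrow(regions),
         dimnames = list(NULL, names(samples)))
}

#' Differential region classification
#'
#' Tests each region of the combined peak list for a condition effect on
#' calibrated fragment counts (fragments assigned by midpoint; counts taken
#' post-calibration with size factors fixed at 1). The count model is
#' negative binomial with a single common dispersion estimated by method of
#' moments pooled across all regions and conditions (floored at 1e-8); the
#' test is a Wald test on the log2 fold change of condition means
#' (pseudocount 1), with Benjamini-Hochberg correction across regions.
#' Regions with `q < alpha` are classified toward the condition with the
#' higher mean; the rest are `common` — enriched in neither.
#'
#' With two replicates per condition, per-region dispersion is not
#' estimable; pooling across regions is what makes the test possible at the
#' design's replication level.
#'
#' @param regions Disjoint region data frame (`chrom`, `start`, `end`).
#' @param samples Named list of calibrated [fragment_set()]s.
#' @param design Named character vector mapping sample name to condition
#'   (exactly 2 conditions; >= 2 samples each).
#' @param alpha FDR threshold for calling a region differential.
#' @param pseudocount Added to condition means before the log2 ratio.
#' @return Data frame: region coordinates, per-sample counts, `log2fc`
#'   (condition 1 over condition 2, in sorted-unique condition order of
#'   `design` values unless `design` is a factor), `p`, `q`, `class`.
#' @export
differential_regions <- function(regions, samples, design, alpha = 0.05,
                                 pseudocount = 1) {
  if (nrow(regions) == 0) stop("empty region list")
  stopifnot(all(names(samples) %in% names(design)))
  design <- design[names(samples)]
  conds <- unique(design)
  if (length(conds) != 2) stop("exactly two conditions required")
  if (any(table(design) < 2)) stop("each condition needs >= 2 samples")
  cnt <- .region_counts(regions, samples)
  g1 <- names(design)[design == conds[1]]
  g2 <- names(design)[design == conds[2]]
  m1 <- rowMeans(cnt[, g1, drop = FALSE])
  m2 <- rowMeans(cnt[, g2, drop = FALSE])
  v1 <- apply(cnt[, g1, drop = FALSE], 1, var)
  v2 <- apply(cnt[, g2, drop = FALSE], 1, var)
  # pooled method-of-moments dispersion: Var = mu + a * mu^2
  num <- sum(v1 - m1) + sum(v2 - m2)
  den <- sum(m1^2) + sum(m2^2)
  disp <- max(num / den, 1e-8)
  lfc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  var_mean1 <- (m1 + disp * m1^2) / length(g1)
  var_mean2 <- (m2 + disp * m2^2) / length(g2)
  se <- sqrt(var_mean1 / ((m1 + pseudocount) * log(2))^2 +
               var_mean2 / ((m2 + pseudocount) * log(2))^2)
  z <- ifelse(se == 0, 0, lfc / se)
  p <- 2 * pnorm(-abs(z))
  q <- p.adjust(p, method = "BH")
  cls <- ifelse(q < alpha,
                ifelse(lfc > 0, paste0(conds[1], "_enriched"),
                       paste0(conds[2], "_enriched")),
                "common")
  out <- data.frame(regions[, c("chrom", "start", "end")], cnt,
                    log2fc = lfc, p = p, q = q, class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate regions with promoters and nearest genes
#'
#' A region is a promoter region if it overlaps the window
#' `[tss - promoter_halfwidth, tss + promoter_halfwidth)` of any gene. Each
#' region's nearest gene is found by distance to the TSS (0 if the TSS lies
#' inside the region); a gene is reported as the region's marked gene only
#' when that distance is at most `marked_gene_dist` bp.
#'
#' @param regions Region data frame (`chrom`, `start`, `end`).
#' @param genes Gene models from [read_gene_annotation()] (columns
#'   `gene_id`, `chrom`, `tss`).
#' @param promoter_halfwidth Promoter window half-width in bp.
#' @param marked_gene_dist Maximum TSS distance (bp) for a marked gene.
#' @return Data frame: region coordinates, `promoter` flag, `nearest_gene`,
#'   `tss_distance`, `marked_gene` (`NA` beyond the cutoff).
#' @export
annotate_regions <- function(regions, genes, promoter_halfwidth = 3000L,
                             marked_gene_dist = 10000L) {
  if (nrow(genes) == 0) stop("empty gene list")
  n <- nrow(regions)
  promoter <- logical(n)
  nearest <- character(n)
  dist <- integer(n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      nearest[i] <- NA_character_; dist[i] <- NA_integer_; next
    }
    d <- pmax(0L, regions$start[i] - g$tss, g$tss - regions$end[i] + 1L)
    j <- which.min(d)
    nearest[i] <- g$gene_id[j]
    dist[i] <- d[j]
    promoter[i] <- any(regions$start[i] < g$tss + promoter_halfwidth &
                         regions$end[i] > g$tss - promoter_halfwidth)
  }
  data.frame(regions[, c("chrom", "start", "end")],
             promoter = promoter, nearest_gene = nearest,
             tss_distance = dist,
             marked_gene = ifelse(!is.na(dist) & dist <= marked_gene_dist,
                                  nearest, NA_character_),
             stringsAsFactors = FALSE)
}
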