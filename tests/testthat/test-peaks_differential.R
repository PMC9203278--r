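test_that("sparse caller retains the top-score quantile with ties", {
  # single block: trivially retained
  tr <- data.frame(chrom = "chr1", start = 0L, end = 100L, value = 2)
  pk <- call_peaks_sparse(tr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$score, 200)
  # 100 equal-width separated blocks, scores 1..100: top 1% is score 100
  tr <- data.frame(chrom = "chr1", start = seq(0L, by = 200L, length.out = 100),
                   end = seq(100L, by = 200L, length.out = 100),
                   value = 1:100)
  pk <- call_peaks_sparse(tr, retain_fraction = 0.01)
  expect_equal(pk$score, 10000)
  # retained count equals the quantile-oracle count
  scores <- (1:100) * 100
  expect_equal(nrow(pk), sum(scores >= quantile(scores, 0.99)))
  # ties at the threshold all retained
  tr$value <- rep(c(1, 5), 50)
  pk <- call_peaks_sparse(tr, retain_fraction = 0.4)
  expect_equal(nrow(pk), 50)
  expect_error(call_peaks_sparse(data.frame(chrom = "c", start = 0L,
                                            end = 10L, value = 0)), "all-zero")
})

test_that("caller fuses blocks across sub-threshold gaps when asked", {
  tr <- data.frame(chrom = "chr1", start = c(0L, 150L, 1000L),
                   end = c(100L, 250L, 1100L), value = 1)
  strict <- call_peaks_sparse(tr, retain_fraction = 1, max_gap = 0)
  expect_equal(nrow(strict), 3)
  fused <- call_peaks_sparse(tr, retain_fraction = 1, max_gap = 300)
  expect_equal(nrow(fused), 2)
  expect_equal(fused$score[1], 200)  # area only, gap contributes nothing
})

test_that("merge uses strict 'closer than' semantics and conserves score", {
  pk <- data.frame(chrom = "chr1", start = c(0L, 250L), end = c(100L, 350L),
                   score = c(1, 2))
  m <- merge_peaks(pk, 300)           # gap 150 < 300 -> merged
  expect_equal(m[, c("start", "end", "score")],
               data.frame(start = 0L, end = 350L, score = 3))
  pk <- data.frame(chrom = "chr1", start = c(0L, 400L), end = c(100L, 500L),
                   score = c(1, 2))
  m <- merge_peaks(pk, 300)           # gap exactly 300 -> not merged
  expect_equal(nrow(m), 2)
  # idempotence
  expect_equal(merge_peaks(m, 300), m)
})

test_that("interval algebra matches brute-force oracles on random instances", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(c(5:50, 200, 500), 1)
    ivs <- random_intervals(n)
    gap <- sample(c(1L, 50L, 300L), 1)
    got <- merge_peaks(ivs, gap)
    want <- oracle_merge(ivs, gap)
    expect_equal(got[c("chrom", "start", "end")],
                 want[c("chrom", "start", "end")])
    expect_equal(got$score, want$score)          # score conservation
    expect_equal(sum(got$score), sum(ivs$score))

    a <- merge_peaks(random_intervals(max(2, n %/% 2)), 1L)
    b <- merge_peaks(random_intervals(max(2, n %/% 3)), 1L)
    expect_equal(intersect_replicates(a, b),
                 a[oracle_overlap_any(a, b), , drop = FALSE],
                 ignore_attr = TRUE)
    u <- combine_peak_lists(list(a, b))
    expect_equal(u[c("chrom", "start", "end")],
                 oracle_union(rbind(a[1:3], b[1:3])), ignore_attr = TRUE)
    excl <- random_intervals(3)
    expect_equal(filter_exclusion(a, excl),
                 a[!oracle_overlap_any(a, excl), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("replicate intersection and combination honour their edge cases", {
  a <- data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(100L, 1100L),
                  score = c(1, 2))
  expect_equal(intersect_replicates(a, a), a, ignore_attr = TRUE)
  b <- data.frame(chrom = "chr1", start = 5000L, end = 5100L, score = 1)
  expect_equal(nrow(intersect_replicates(a, b)), 0)
  # identical lists in, the list once out
  expect_equal(combine_peak_lists(list(a, a))[c("chrom", "start", "end")],
               a[c("chrom", "start", "end")], ignore_attr = TRUE)
  # disjoint lists concatenate sorted
  u <- combine_peak_lists(list(a, b))
  expect_equal(u$start, c(0L, 1000L, 5000L))
  # commutative up to interval equality
  expect_equal(combine_peak_lists(list(b, a))[c("start", "end")],
               u[c("start", "end")])
  # exclusion edge cases
  expect_equal(nrow(filter_exclusion(a, data.frame(chrom = "chr1", start = 0L,
                                                   end = 1e7L))), 0)
  expect_equal(filter_exclusion(a, a[0, ]), a)
})

test_that("planted peaks are recovered from a calibrated coverage track", {
  tg <- c(chrT = 10e6)
  reg <- data.frame(chrom = "chrT",
                    start = round(seq(2e5, 9.2e6, length.out = 20)), end = NA,
                    class = "common", fold = 5)
  reg$end <- reg$start + 1e5
  p <- cutrun_sim_params(tg, c(chrS = 1e6), n_cells = 50000,
                         global_level = c(cond1 = 2.23, cond2 = 2.23),
                         planted_regions = reg, spikein_rate = 0.1,
                         depth_scale = c(s = 1), conditions = c(s = "cond1"),
                         fragment_length = 50L)
  sim <- simulate_cutrun(p, seed = 31)
  f <- sim$samples$s[sim$samples$s$genome == "target", ]
  tr <- coverage_track(f)
  blocks <- call_peaks_sparse(tr, retain_fraction = 1, max_gap = 300)
  pk <- call_peaks_sparse(tr, retain_fraction = nrow(reg) / nrow(blocks),
                          max_gap = 300)
  pk <- merge_peaks(pk, 300)
  expect_gte(region_recall(reg, pk, 0.5), 0.9)
})

test_that("differential regions recover planted classes", {
  reg <- data.frame(chrom = "chrT",
                    start = round(seq(1e4, 9.4e5, length.out = 30)), end = NA,
                    class = rep(c("cond1_enriched", "cond2_enriched", "common"),
                                each = 10), fold = 4)
  reg$end <- reg$start + 1e4
  p <- toy_sim_params(reg, global = c(cond1 = 3, cond2 = 3), n_cells = 20000)
  sim <- simulate_cutrun(p, seed = 32)
  cal <- calibrate_experiment(sim$samples, seed = 32)
  design <- c(c1r1 = "cond1", c1r2 = "cond1", c2r1 = "cond2", c2r2 = "cond2")
  dr <- differential_regions(reg, cal$samples, design)
  expect_gte(mean(dr$class == reg$class), 0.9)
  expect_true(all(dr$q >= dr$p))
  expect_true(all(dr$class %in%
                    c("cond1_enriched", "cond2_enriched", "common")))
  # identical counts across samples -> log2fc 0, common
  flat <- lapply(design, function(cond)
    fragment_set("chrT", reg$start + 100L, reg$start + 200L))
  names(flat) <- names(design)
  dr0 <- differential_regions(reg, flat, design)
  expect_true(all(dr0$log2fc == 0))
  expect_true(all(dr0$class == "common"))
  # error paths
  expect_error(differential_regions(reg[0, ], cal$samples, design), "empty")
  expect_error(differential_regions(reg, cal$samples[c(1, 3)],
                                    design[c(1, 3)]), ">= 2 samples")
})

test_that("differential testing controls type I error on permuted null data", {
  reg <- data.frame(chrom = "chrT",
                    start = seq(0L, 999000L, 5000L), end = NA)
  reg <- reg[1:200, ]
  reg$end <- reg$start + 5000L
  sim <- simulate_cutrun(toy_sim_params(global = c(cond1 = 5, cond2 = 5),
                                        n_cells = 20000), seed = 33)
  cal <- calibrate_experiment(sim$samples, seed = 33)
  worst <- 0
  for (perm in list(c("cond1", "cond1", "cond2", "cond2"),
                    c("cond1", "cond2", "cond1", "cond2"),
                    c("cond1", "cond2", "cond2", "cond1"))) {
    design <- setNames(perm, names(cal$samples))
    dr <- differential_regions(reg, cal$samples, design)
    worst <- max(worst, mean(dr$q < 0.05))
  }
  expect_lte(worst, 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(reg)))
})

test_that("regions are annotated with promoters and nearest marked genes", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(10000L, 50000L), end = c(12000L, 52000L),
                      strand = c("+", "-"), tss = c(10000L, 51999L))
  # region centred on a TSS
  r <- data.frame(chrom = "chr1", start = 9500L, end = 10500L)
  ann <- annotate_regions(r, genes)
  expect_true(ann$promoter)
  expect_equal(ann$tss_distance, 0L)
  expect_equal(ann$marked_gene, "g1")
  # boundary: 10,001 bp away is not a marked gene; 10,000 bp is
  r <- data.frame(chrom = "chr1", start = 20001L, end = 21000L)
  expect_true(is.na(annotate_regions(r, genes)$marked_gene))
  r <- data.frame(chrom = "chr1", start = 20000L, end = 21000L)
  expect_equal(annotate_regions(r, genes)$marked_gene, "g1")
  expect_error(annotate_regions(r, genes[0, ]), "empty")
  # random layouts match a brute-force nearest-TSS scan
  set.seed(22)
  genes <- data.frame(gene_id = paste0("g", 1:30), chrom = "chr1",
                      start = s <- sort(sample.int(2e5, 30)), end = s + 1000L,
                      strand = sample(c("+", "-"), 30, TRUE))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  r <- random_intervals(50, limit = 200000L, max_width = 5000L)
  ann <- annotate_regions(r, genes)
  for (i in seq_len(nrow(r))) {
    d <- pmax(0L, r$start[i] - genes$tss, genes$tss - r$end[i] + 1L)
    expect_equal(ann$tss_distance[i], min(d))
  }
})
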