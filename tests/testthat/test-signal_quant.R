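test_that("bin counting assigns by midpoint with half-open boundaries", {
  g <- c(chr1 = 10000)
  fs <- fragment_set("chr1", 0L, 150L, "target", 60L)
  b <- bin_counts(fs, g)
  expect_equal(b$count, c(1L, rep(0L, 9)))
  # midpoint exactly on a bin boundary goes to the right bin
  fs <- fragment_set("chr1", 950L, 1050L, "target", 60L)   # midpoint 1000
  b <- bin_counts(fs, g)
  expect_equal(b$count[b$start == 1000], 1L)
  expect_equal(sum(b$count), 1L)
  expect_error(bin_counts(fragment_set("chrX", 0L, 10L), g), "unknown")
})

test_that("bin counts match a brute-force midpoint tally and conserve totals", {
  set.seed(11)
  g <- c(chr1 = 50000, chr2 = 30000)
  n <- 10000
  chrom <- sample(names(g), n, replace = TRUE)
  start <- floor(runif(n) * (g[chrom] - 200))
  fs <- fragment_set(chrom, start, start + sample.int(200, n, TRUE))
  b <- bin_counts(fs, g)
  expect_equal(sum(b$count), n)
  mid <- (fs$start + fs$end) %/% 2L
  brute <- mapply(function(ch, s, e) {
    sum(fs$chrom == ch & mid >= s & mid < e)
  }, b$chrom, b$start, b$end)
  expect_equal(b$count, unname(brute))
  # last partial bin is kept
  expect_equal(max(b$end[b$chrom == "chr2"]), 30000)
})

test_that("log2 KDE has unit mass, tracks the mode, and shifts under doubling", {
  g <- c(chr1 = 20000)
  b <- data.frame(chrom = "chr1", start = seq(0, 19000, 1000),
                  end = seq(1000, 20000, 1000), count = 4L)
  d <- log_density(b)
  step <- diff(d$grid[1:2])
  expect_lt(abs(d$grid[which.max(d$density)] - 2), step + 1e-9)
  integral <- sum(diff(d$grid) * (head(d$density, -1) + d$density[-1]) / 2)
  expect_true(integral >= 0.99 && integral <= 1.01)

  set.seed(1)
  b$count <- rpois(20, 16) + 1L
  d1 <- log_density(b)
  b2 <- b; b2$count <- b$count * 2L
  d2 <- log_density(b2)
  expect_equal(d2$grid[which.max(d2$density)] -
                 d1$grid[which.max(d1$density)], 1, tolerance = 0.02)
})

test_that("KDE mean matches the moment of log2 counts on Poisson bins", {
  set.seed(2)
  b <- data.frame(chrom = "chr1", start = seq(0, 999000, 1000),
                  end = seq(1000, 1000000, 1000),
                  count = rpois(1000, 16))
  d <- log_density(b)
  kde_mean <- sum(d$grid * d$density) / sum(d$density)
  expect_lt(abs(kde_mean - mean(log2(b$count[b$count > 0]))), 0.1)
  expect_error(log_density(data.frame(chrom = "c", start = 0, end = 1000,
                                      count = 5L)), "2 nonzero")
})

test_that("FRiP is the midpoint-in-peak percentage", {
  fs <- fragment_set("chr1", c(10, 20, 500), c(60, 80, 700))
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(frip(fs, peaks), 100 * 2 / 3)
  expect_equal(frip(fs, data.frame(chrom = "chr1", start = 0L, end = 1000L)), 100)
  expect_equal(frip(fs, peaks[0, ]), 0)
  expect_error(frip(fs[0, ], peaks), "empty")
  # random layout equals the explicit per-fragment oracle
  set.seed(3)
  n <- 500
  fs <- fragment_set("chr1", s <- sample.int(5000, n, TRUE), s + 50L)
  pk <- oracle_union(random_intervals(20))
  expect_equal(frip(fs, pk), 100 * mean(oracle_midpoint_in(fs, pk)))
})

test_that("FRiP is monotone as peaks grow by superset", {
  set.seed(4)
  fs <- fragment_set("chr1", s <- sample.int(5000, 300, TRUE), s + 40L)
  small <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  big <- data.frame(chrom = "chr1", start = c(1000L, 3000L),
                    end = c(2500L, 4000L))
  expect_lte(frip(fs, small), frip(fs, big))
})

test_that("repeat-class fractions are per-class independent percentages", {
  fs <- fragment_set("chr1", c(0, 100, 4000), c(50, 160, 4100))
  ann <- list(
    ALL = data.frame(chrom = "chr1", start = 0L, end = 5000L),
    NONE = data.frame(chrom = "chr2", start = 0L, end = 5000L),
    HALF = data.frame(chrom = "chr1", start = 0L, end = 200L))
  fr <- repeat_class_fractions(fs, ann)
  expect_equal(unname(fr), c(100, 0, 100 * 2 / 3))
  expect_error(repeat_class_fractions(fs[0, ], ann), "empty")
  # random setup equals brute force per class
  set.seed(5)
  fs <- fragment_set("chr1", s <- sample.int(5000, 400, TRUE), s + 30L)
  ann <- list(a = random_intervals(15), b = random_intervals(3))
  fr <- repeat_class_fractions(fs, ann)
  expect_equal(unname(fr["a"]), 100 * mean(oracle_midpoint_in(fs, ann$a)))
  expect_equal(unname(fr["b"]), 100 * mean(oracle_midpoint_in(fs, ann$b)))
})

test_that("bin correlation is 1 on self, ~0 on permutation, high on replicates", {
  g <- c(chr1 = 1e6)
  set.seed(6)
  b <- data.frame(genome_bins(g), count = rpois(1000, 8))
  expect_equal(bin_correlation(b, b), 1)
  b2 <- b; b2$count <- sample(b$count)
  expect_lt(abs(bin_correlation(b, b2)), 3 / sqrt(1000))
  flat <- b; flat$count <- 5L
  expect_error(bin_correlation(b, flat), "variance")
  # simulated same-condition replicates correlate strongly
  reg <- data.frame(chrom = "chrT", start = seq(1e5, 8e5, 1e5), end = NA,
                    class = "common", fold = 6)
  reg$end <- reg$start + 2e4
  sim <- simulate_cutrun(toy_sim_params(reg, n_cells = 25000), seed = 12)
  ba <- bin_counts(sim$samples$c1r1[sim$samples$c1r1$genome == "target", ],
                   toy_genome())
  bb <- bin_counts(sim$samples$c1r2[sim$samples$c1r2$genome == "target", ],
                   toy_genome())
  expect_gt(bin_correlation(ba, bb), 0.8)
})

test_that("coverage runs conserve total signal exactly", {
  fs <- fragment_set("chr1", 0L, 100L)
  tr <- coverage_track(fs, 1)
  expect_equal(tr, data.frame(chrom = "chr1", start = 0L, end = 100L, value = 1))
  fs <- fragment_set("chr1", c(0L, 0L), c(100L, 100L))
  expect_equal(coverage_track(fs, 1)$value, 2)
  set.seed(7)
  n <- 1000
  fs <- fragment_set(sample(c("chr1", "chr2"), n, TRUE),
                     s <- sample.int(5000, n, TRUE),
                     s + sample.int(300, n, TRUE))
  tr <- coverage_track(fs, 1)
  expect_equal(sum(tr$value * (tr$end - tr$start)), sum(fs$end - fs$start))
  # scaled track scales the conservation identity
  tr2 <- coverage_track(fs, 0.25)
  expect_equal(sum(tr2$value * (tr2$end - tr2$start)),
               0.25 * sum(fs$end - fs$start))
  # writable as bedGraph (sorted, disjoint)
  path <- withr::local_tempfile()
  expect_silent(write_bedgraph(tr, path))
})

test_that("high-coat weak-peak condition has more signal but lower FRiP", {
  reg <- data.frame(chrom = "chrT", start = seq(1e5, 8e5, 1e5), end = NA,
                    class = "common", fold = NA)
  reg$end <- reg$start + 2e4
  # cond1: high coating, weak peaks; cond2: low coating, strong peaks
  reg$fold <- 2
  sim_hi <- simulate_cutrun(cutrun_sim_params(
    toy_genome(), toy_spikein(), n_cells = 50000,
    global_level = c(cond1 = 3, cond2 = 1), planted_regions = reg,
    spikein_rate = 0.2, depth_scale = c(s = 1), conditions = c(s = "cond1"),
    fragment_length = 100L), seed = 13)
  reg$fold <- 8
  sim_lo <- simulate_cutrun(cutrun_sim_params(
    toy_genome(), toy_spikein(), n_cells = 50000,
    global_level = c(cond1 = 3, cond2 = 1), planted_regions = reg,
    spikein_rate = 0.2, depth_scale = c(s = 1), conditions = c(s = "cond2"),
    fragment_length = 100L), seed = 14)
  hi <- sim_hi$samples$s[sim_hi$samples$s$genome == "target", ]
  lo <- sim_lo$samples$s[sim_lo$samples$s$genome == "target", ]
  peaks <- reg[, c("chrom", "start", "end")]
  expect_gt(nrow(hi), nrow(lo))            # more total calibrated signal
  expect_lt(frip(hi, peaks), frip(lo, peaks))  # but less focal
})
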