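#' Simulation parameters for a calibrated CUT&RUN experiment
#'
#' Describes a two-genome, two-condition experiment: each sequenced sample
#' mixes fragments from the target genome (whose per-cell signal differs
#' between conditions — the "coating" level) with fragments from a constant
#' per-cell exogenous spike-in genome. This constancy is the biological
#' premise of spike-in calibration, so `spikein_rate` is a single number
#' shared by all samples.
#'
#' @param target_genome Named integer vector: contig lengths (bp) of the
#'   genome under study.
#' @param spikein_genome Named integer vector: contig lengths of the spike-in
#'   genome.
#' @param n_cells Cell-equivalents per sample (the per-sample material input;
#'   e.g. 50,000 target cells spiked with a fixed batch of exogenous cells).
#' @param global_level Named numeric vector, one expected target fragment per
#'   cell-equivalent for each condition (the genome-wide coating level).
#' @param planted_regions Data frame with columns `chrom`, `start`, `end`,
#'   `class` (`"cond1_enriched"`, `"cond2_enriched"` or `"common"`) and
#'   `fold` (enrichment over background, >= 1). May have zero rows.
#' @param spikein_rate Expected spike-in fragments per cell-equivalent,
#'   identical across samples.
#' @param depth_scale Named numeric vector, one sequencing-depth multiplier
#'   per sample; names define the sample names. Sample names must encode
#'   their condition via the `conditions` argument.
#' @param conditions Named character vector mapping each sample name to a
#'   condition named in `global_level`.
#' @param fragment_length Fragment length in bp (uniform start positions,
#'   truncated at contig ends).
#' @param igg If `TRUE`, planted enrichment is ignored: background-only
#'   fragments, emulating a nonspecific-antibody control.
#' @return A list of class `"cutrun_sim_params"`.
#' @export
cutrun_sim_params <- function(target_genome,
                              spikein_genome,
                              n_cells = 50000,
                              global_level = c(cond1 = 2, cond2 = 1),
                              planted_regions = NULL,
                              spikein_rate = 0.4,
                              depth_scale = c(c1r1 = 1, c1r2 = 1, c2r1 = 1, c2r2 = 1),
                              conditions = c(c1r1 = "cond1", c1r2 = "cond1",
                                             c2r1 = "cond2", c2r2 = "cond2"),
                              fragment_length = 150L,
                              igg = FALSE) {
  if (is.null(planted_regions)) {
    planted_regions <- data.frame(chrom = character(), start = integer(),
                                  end = integer(), class = character(),
                                  fold = numeric())
  }
  stopifnot(length(target_genome) >= 1, length(spikein_genome) >= 1,
            !is.null(names(target_genome)), !is.null(names(spikein_genome)),
            spikein_rate > 0, all(depth_scale >= 0),
            !is.null(names(depth_scale)),
            all(names(depth_scale) %in% names(conditions)),
            all(conditions %in% names(global_level)),
            fragment_length >= 1)
  if (any(target_genome <= 0) || any(spikein_genome <= 0))
    stop("zero-length contig in genome definition")
  if (nrow(planted_regions) > 0) {
    if (any(planted_regions$fold < 1)) stop("enrichment fold must be >= 1")
    if (!all(planted_regions$class %in%
             c("cond1_enriched", "cond2_enriched", "common")))
      stop("unknown planted region class")
    if (!all(planted_regions$chrom %in% names(target_genome)))
      stop("planted region outside target genome")
    clen <- target_genome[planted_regions$chrom]
    if (any(planted_regions$start < 0 | planted_regions$end > clen))
      stop("planted region outside target genome")
  }
  structure(list(
    target_genome = target_genome, spikein_genome = spikein_genome,
    n_cells = n_cells, global_level = global_level,
    planted_regions = planted_regions, spikein_rate = spikein_rate,
    depth_scale = depth_scale, conditions = conditions[names(depth_scale)],
    fragment_length = as.integer(fragment_length), igg = igg
  ), class = "cutrun_sim_params")
}

# Draw n fragment start positions on a genome where per-bp weight is 1
# outside `regions` and `fold` inside. Returns a fragment_set.
.place_fragments <- function(n, genome, regions, fragment_length) {
  glen <- sum(as.numeric(genome))
  if (n == 0) {
    return(fragment_set(character(), integer(), integer(), "target", 60L))
  }
  # weighted segments: whole contigs minus active regions at weight 1,
  # active regions at their fold
  segs <- data.frame(chrom = names(genome), start = 0,
                     end = as.numeric(genome), w = 1)
  if (!is.null(regions) && nrow(regions) > 0) {
    pieces <- list()
    for (ch in names(genome)) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      if (nrow(r) == 0) {
        pieces[[ch]] <- data.frame(chrom = ch, start = 0,
                                   end = as.numeric(genome[[ch]]), w = 1)
        next
      }
      r <- r[order(r$start), , drop = FALSE]
      bg <- IRanges::setdiff(.ir(0L, as.integer(genome[[ch]])),
                             IRanges::reduce(.ir(r$start, r$end)))
      pieces[[ch]] <- rbind(
        data.frame(chrom = ch, start = .ir_start0(bg), end = .ir_end0(bg), w = 1),
        data.frame(chrom = ch, start = r$start, end = r$end, w = r$fold))
    }
    segs <- do.call(rbind, pieces)
  }
  segs$len <- segs$end - segs$start
  segs <- segs[segs$len > 0, , drop = FALSE]
  wt <- segs$len * segs$w
  seg_idx <- sample.int(nrow(segs), n, replace = TRUE, prob = wt)
  pos <- floor(segs$start[seg_idx] + runif(n) * segs$len[seg_idx])
  chrom <- segs$chrom[seg_idx]
  clen <- as.numeric(genome[chrom])
  start <- pmin(pos, clen - 1)
  end <- pmin(start + fragment_length, clen)
  ord <- order(chrom, start, end)
  fragment_set(chrom[ord], start[ord], end[ord], "target", 60L)
}

#' Simulate a calibrated CUT&RUN experiment
#'
#' Per sample, the total target fragment count is Poisson with mean
#' `depth_scale * n_cells * global_level * (1 + planted mass)`, where the
#' planted mass is the extra expected density contributed by regions active
#' in that sample's condition (`common` regions are active in both). Fragment
#' start positions are uniform, with `fold`-times the background density
#' inside active regions. Spike-in counts are Poisson with mean
#' `depth_scale * n_cells * spikein_rate` — proportional to material and
#' depth, independent of target biology. Identical `seed` gives identical
#' output.
#'
#' @param params A [cutrun_sim_params()] object.
#' @param seed Integer seed.
#' @return List with `samples` (named list of [fragment_set()]s) and `truth`
#'   (params echo, per-sample expected/realised totals, true global ratio
#'   between the two conditions, planted region classes).
#' @export
simulate_cutrun <- function(params, seed = 1L) {
  stopifnot(inherits(params, "cutrun_sim_params"))
  p <- params
  glen <- sum(as.numeric(p$target_genome))
  withr::with_seed(seed, {
    samples <- list()
    totals <- numeric(0)
    for (s in names(p$depth_scale)) {
      cond <- p$conditions[[s]]
      active <- p$planted_regions[
        !p$igg & (p$planted_regions$class == "common" |
                    p$planted_regions$class == paste0(cond, "_enriched")), ,
        drop = FALSE]
      mass <- if (nrow(active)) sum((active$fold - 1) * (active$end - active$start)) / glen else 0
      mu_t <- p$depth_scale[[s]] * p$n_cells * p$global_level[[cond]] * (1 + mass)
      n_t <- rpois(1, mu_t)
      tgt <- .place_fragments(n_t, p$target_genome, active, p$fragment_length)
      mu_s <- p$depth_scale[[s]] * p$n_cells * p$spikein_rate
      n_s <- rpois(1, mu_s)
      spk <- .place_fragments(n_s, p$spikein_genome, NULL, p$fragment_length)
      if (nrow(spk)) spk$genome <- "spikein"
      smp <- rbind(tgt, spk)
      class(smp) <- c("fragment_set", "data.frame")
      samples[[s]] <- smp
      totals[[s]] <- n_t
    }
    conds <- names(p$global_level)
    truth <- list(
      params = p,
      target_totals = totals,
      global_ratio = unname(p$global_level[[conds[1]]] / p$global_level[[conds[2]]]),
      region_classes = p$planted_regions
    )
    list(samples = samples, truth = truth)
  })
}

#' Simulate a peptidoform intensity table
#'
#' Generates one peptidoform row per (histone, residue, state) with
#' intensities lognormal around `total * proportion`; the lognormal is
#' parameterised so the mean equals the target exactly and the coefficient
#' of variation is `cv` (cv = 0 gives noise-free intensities).
#'
#' @param marks Data frame with columns `histone`, `residue`, `state`, and
#'   one `prop_<condition>` column per condition giving that state's true
#'   proportion of the residue total. Proportions must sum to 1 within each
#'   (histone, residue) for every condition (tolerance 1e-9).
#' @param n_samples Named integer vector: samples per condition; condition
#'   names must match the `prop_` columns.
#' @param cv Coefficient of variation of the lognormal intensity noise.
#' @param total Expected summed intensity per residue (arbitrary MS units).
#' @param seed Integer seed.
#' @return List with `table` (a peptidoform table: `peptide_id`,
#'   `annotations` as `histone:residue:state`, one intensity column per
#'   sample), `design` (named condition per sample) and `truth` (the `marks`
#'   input).
#' @export
simulate_peptidoforms <- function(marks, n_samples = c(cond1 = 7, cond2 = 5),
                                  cv = 0.1, total = 1e6, seed = 1L) {
  conds <- names(n_samples)
  prop_cols <- paste0("prop_", conds)
  stopifnot(all(prop_cols %in% names(marks)))
  key <- paste(marks$histone, marks$residue)
  for (pc in prop_cols) {
    sums <- tapply(marks[[pc]], key, sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("proportions do not sum to 1 within each residue (", pc, ")")
  }
  sdlog <- sqrt(log1p(cv^2))
  withr::with_seed(seed, {
    tab <- data.frame(
      peptide_id = sprintf("pep%03d", seq_len(nrow(marks))),
      annotations = paste(marks$histone, marks$residue, marks$state, sep = ":"),
      stringsAsFactors = FALSE)
    design <- character(0)
    for (cond in conds) {
      mu <- total * marks[[paste0("prop_", cond)]]
      for (i in seq_len(n_samples[[cond]])) {
        nm <- paste0(cond, "_s", i)
        design[[nm]] <- cond
        if (cv == 0) {
          tab[[nm]] <- mu
        } else {
          tab[[nm]] <- rlnorm(nrow(marks), log(pmax(mu, .Machine$double.xmin)) -
                                sdlog^2 / 2, sdlog)
          tab[[nm]][mu == 0] <- 0
        }
      }
    }
    list(table = tab, design = design, truth = marks)
  })
}

#' Simulate a label-free chromatin proteome matrix
#'
#' Per protein, a baseline log2 intensity is drawn; replicate values are
#' normal around it with standard deviation `sd_log2`. A planted fraction of
#' proteins is shifted by `true_log2fc` in the first group. Values falling
#' below the `detection_limit_quantile` of the global intensity distribution
#' are set missing (missing-not-at-random, emulating intensities under or
#' close to the detection limit), and a small number of extra decoy rows are
#' flagged as reverse/contaminant.
#'
#' @param n_proteins Number of real proteins.
#' @param n_per_group Named integer vector of group sizes (two groups).
#' @param frac_differential Fraction of proteins shifted in group 1.
#' @param true_log2fc Planted shift (log2 units).
#' @param sd_log2 Replicate standard deviation on the log2 scale.
#' @param detection_limit_quantile Global quantile below which values go
#'   missing (0 disables missingness).
#' @param baseline_mean,baseline_sd Mean/SD of protein baseline log2
#'   intensities.
#' @param n_flagged Number of extra flagged decoy rows appended.
#' @param seed Integer seed.
#' @return List with `matrix` (a [proteome_matrix()]) and `truth` (character
#'   vector of planted differential protein ids, and the planted log2 fold
#'   change).
#' @export
simulate_proteome <- function(n_proteins = 1000,
                              n_per_group = c(cond1 = 3, cond2 = 3),
                              frac_differential = 0.1,
                              true_log2fc = 2,
                              sd_log2 = 0.3,
                              detection_limit_quantile = 0.05,
                              baseline_mean = 26, baseline_sd = 2,
                              n_flagged = 10, seed = 1L) {
  stopifnot(frac_differential >= 0, frac_differential <= 1,
            length(n_per_group) == 2)
  if (any(n_per_group < 2)) stop("n_per_group < 2: group variance undefined downstream")
  n_diff <- round(n_proteins * frac_differential)
  withr::with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    diff_ids <- ids[seq_len(n_diff)]
    base <- rnorm(n_proteins, baseline_mean, baseline_sd)
    groups <- rep(names(n_per_group), n_per_group)
    samples <- paste0(groups, "_r", unlist(lapply(n_per_group, seq_len)))
    m <- matrix(rnorm(n_proteins * length(samples), base, sd_log2),
                nrow = n_proteins,
                dimnames = list(ids, samples))
    if (n_diff > 0)
      m[seq_len(n_diff), groups == names(n_per_group)[1]] <-
        m[seq_len(n_diff), groups == names(n_per_group)[1]] + true_log2fc
    if (detection_limit_quantile > 0) {
      lim <- quantile(m, detection_limit_quantile)
      m[m < lim] <- NA
    }
    flags <- data.frame(protein_id = ids, reverse = FALSE,
                        contaminant = FALSE, only_identified_by_site = FALSE,
                        stringsAsFactors = FALSE)
    if (n_flagged > 0) {
      fid <- sprintf("REV%03d", seq_len(n_flagged))
      fm <- matrix(rnorm(n_flagged * length(samples), baseline_mean, sd_log2),
                   nrow = n_flagged, dimnames = list(fid, samples))
      m <- rbind(m, fm)
      which_flag <- sample(c("reverse", "contaminant", "only_identified_by_site"),
                           n_flagged, replace = TRUE)
      ff <- data.frame(protein_id = fid, reverse = which_flag == "reverse",
                       contaminant = which_flag == "contaminant",
                       only_identified_by_site = which_flag == "only_identified_by_site",
                       stringsAsFactors = FALSE)
      flags <- rbind(flags, ff)
    }
    pm <- proteome_matrix(m, setNames(groups, samples), flags)
    list(matrix = pm,
         truth = list(differential = diff_ids, log2fc = true_log2fc))
  })
}
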