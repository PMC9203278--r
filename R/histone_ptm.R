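# Peptidoform tables: data.frame with `peptide_id`, `annotations`
# (semicolon-separated histone:residue:state triplets, e.g.
# "H3:K27:me3;H3:K36:me2"), then one numeric intensity column per sample.

.pf_sample_cols <- function(table) {
  setdiff(names(table), c("peptide_id", "annotations"))
}

.parse_annotations <- function(ann) {
  lapply(strsplit(ann, ";", fixed = TRUE), function(a) {
    parts <- strsplit(a, ":", fixed = TRUE)
    if (any(lengths(parts) != 3))
      stop("annotation must be histone:residue:state")
    do.call(rbind, lapply(parts, function(p)
      data.frame(histone = p[1], residue = p[2], state = p[3],
                 stringsAsFactors = FALSE)))
  })
}

#' Read a peptidoform intensity table
#'
#' @param path TSV with header: `peptide_id`, `annotations`
#'   (semicolon-separated `histone:residue:state` triplets), then one
#'   intensity column per sample.
#' @return Peptidoform data frame.
#' @export
read_peptidoform_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide_id", "annotations") %in% names(tab)))
  tab
}

#' Normalize a peptidoform table against all histone peptides
#'
#' Rescales every sample so its total intensity over all histone peptides
#' equals the grand mean total — the loading correction applied before any
#' rollup. Relative abundances are invariant to this per-sample scaling; the
#' normalization only matters for absolute-intensity displays.
#'
#' @param table Peptidoform data frame.
#' @return Normalized table of the same shape.
#' @export
normalize_total <- function(table) {
  sc <- .pf_sample_cols(table)
  totals <- vapply(table[sc], sum, 0)
  if (any(totals <= 0)) stop("sample with zero total intensity: ",
                             sc[which(totals <= 0)[1]])
  target <- mean(totals)
  for (s in sc) table[[s]] <- table[[s]] * (target / totals[[s]])
  table
}

#' Roll peptidoform intensities up to per-residue relative abundances
#'
#' For each (histone, residue, state), the relative abundance in a sample is
#' 100 x the summed intensity of peptidoforms annotating that residue in
#' that state, divided by the summed intensity of all peptidoforms
#' annotating that residue in any state — so the states of one residue
#' always add up to 100%. A peptidoform carrying modifications at two
#' residues contributes its full intensity to both residues' tallies (the
#' per-residue marginal).
#'
#' @param table Peptidoform data frame (normalized or not; the rollup is
#'   scale invariant per sample).
#' @return Data frame: `histone`, `residue`, `state`, `mark`
#'   (`histone:residue:state`), one abundance column per sample
#'   (percentages). Residues with zero total intensity in a sample get `NA`
#'   with a warning.
#' @export
rollup_relative_abundance <- function(table) {
  sc <- .pf_sample_cols(table)
  ann <- .parse_annotations(table$annotations)
  long <- do.call(rbind, lapply(seq_along(ann), function(i) {
    a <- ann[[i]]
    a$row <- i
    a
  }))
  key_state <- paste(long$histone, long$residue, long$state, sep = ":")
  key_res <- paste(long$histone, long$residue, sep = ":")
  states <- !duplicated(key_state)
  out <- data.frame(histone = long$histone[states],
                    residue = long$residue[states],
                    state = long$state[states],
                    mark = key_state[states], stringsAsFactors = FALSE)
  for (s in sc) {
    ints <- table[[s]][long$row]
    num <- tapply(ints, key_state, sum)[out$mark]
    den <- tapply(ints, key_res, sum)[paste(out$histone, out$residue, sep = ":")]
    ab <- ifelse(den > 0, 100 * num / den, NA_real_)
    if (anyNA(ab))
      warning("residue with zero total intensity in sample ", s,
              "; abundance flagged missing")
    out[[s]] <- as.numeric(ab)
  }
  ord <- order(out$histone, out$residue, out$state)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Two-sided two-sample t test returning p; equal-variance Student by
# default. Zero variance in both groups with equal means -> p = 1.
.t_test_p <- function(x, y, var_equal = TRUE) {
  if (var(x) == 0 && var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Differential histone marks between conditions
#'
#' Per mark (histone:residue:state), the log2 fold change of condition-mean
#' relative abundances (pseudocount 0.01 percentage points) and a two-sided
#' two-sample Student t-test (equal variance) on the per-sample abundances,
#' Benjamini-Hochberg corrected across all marks tested.
#'
#' @param abund Output of [rollup_relative_abundance()].
#' @param design Named character vector mapping sample column to condition
#'   (exactly two conditions).
#' @param alpha FDR threshold for the `significant` flag.
#' @param pseudocount Percentage points added to both condition means before
#'   the log2 ratio.
#' @param var_equal Student (`TRUE`, default) or Welch (`FALSE`) t-test.
#' @return `abund` with `log2fc` (condition 1 over condition 2), `p`, `q`,
#'   `significant` appended. Marks with missing abundances in any used
#'   sample are dropped with a warning.
#' @export
hptm_differential <- function(abund, design, alpha = 0.05,
                              pseudocount = 0.01, var_equal = TRUE) {
  conds <- unique(design)
  stopifnot(length(conds) == 2, all(names(design) %in% names(abund)))
  if (any(table(design) < 2)) stop("each condition needs >= 2 samples")
  g1 <- names(design)[design == conds[1]]
  g2 <- names(design)[design == conds[2]]
  m1 <- as.matrix(abund[, g1, drop = FALSE])
  m2 <- as.matrix(abund[, g2, drop = FALSE])
  ok <- complete.cases(m1) & complete.cases(m2)
  if (!all(ok)) {
    warning(sum(!ok), " mark(s) dropped for missing abundances")
    abund <- abund[ok, , drop = FALSE]
    m1 <- m1[ok, , drop = FALSE]; m2 <- m2[ok, , drop = FALSE]
  }
  abund$log2fc <- log2((rowMeans(m1) + pseudocount) /
                         (rowMeans(m2) + pseudocount))
  abund$p <- vapply(seq_len(nrow(abund)), function(i)
    .t_test_p(m1[i, ], m2[i, ], var_equal), 0)
  abund$q <- p.adjust(abund$p, method = "BH")
  abund$significant <- abund$q < alpha
  abund
}

#' Compare per-mark fold changes across datasets
#'
#' Ordinary least squares of `y` on `x` over the marks shared by both
#' datasets, with Pearson correlation and the pointwise 95% confidence band
#' of the mean response — the cross-dataset concordance display for two
#' independently measured fold-change panels.
#'
#' @param x,y Named numeric vectors of per-mark log2 fold changes; names are
#'   mark identifiers, intersected before fitting (>= 3 shared marks
#'   required).
#' @return List: `marks` (shared identifiers), `r`, `slope`, `intercept`,
#'   and `band` (data frame `x`, `fit`, `lwr`, `upr`).
#' @export
cross_dataset_compare <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3) stop("fewer than 3 shared marks")
  xv <- x[shared]; yv <- y[shared]
  fit <- lm(yv ~ xv)
  grid <- data.frame(xv = seq(min(xv), max(xv), length.out = 100))
  ci <- predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  list(marks = shared,
       r = cor(xv, yv),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       band = data.frame(x = grid$xv, fit = ci[, "fit"],
                         lwr = ci[, "lwr"], upr = ci[, "upr"]))
}
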