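#' Construct a chromatin proteome matrix
#'
#' Container for label-free quantification of chromatin-bound proteins:
#' a log2 intensity matrix (proteins x samples, `NA` for missing values),
#' a group label per sample, and per-protein database flags.
#'
#' @param intensities Numeric matrix of log2 intensities with protein row
#'   names and sample column names; `NA` marks missing values.
#' @param groups Named character vector mapping sample to group.
#' @param flags Optional data frame with `protein_id` plus logical columns
#'   `reverse`, `contaminant`, `only_identified_by_site`; defaults to all
#'   `FALSE`.
#' @return List of class `"proteome_matrix"`.
#' @export
proteome_matrix <- function(intensities, groups, flags = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)),
            all(colnames(intensities) %in% names(groups)))
  if (is.null(flags)) {
    flags <- data.frame(protein_id = rownames(intensities),
                        reverse = FALSE, contaminant = FALSE,
                        only_identified_by_site = FALSE,
                        stringsAsFactors = FALSE)
  }
  stopifnot(identical(flags$protein_id, rownames(intensities)))
  structure(list(intensities = intensities,
                 groups = groups[colnames(intensities)],
                 flags = flags),
            class = "proteome_matrix")
}

#' Filter a proteome matrix
#'
#' Removes proteins flagged `reverse`, `contaminant` or
#' `only_identified_by_site`, then keeps a protein only if it has at least
#' `min_valid` non-missing values in at least one group — the valid-values
#' rule that guards the downstream t-test.
#'
#' @param m A [proteome_matrix()].
#' @param min_valid Minimum non-missing values required in some group.
#' @return Filtered [proteome_matrix()].
#' @export
filter_proteins <- function(m, min_valid = 3L) {
  stopifnot(inherits(m, "proteome_matrix"))
  flagged <- m$flags$reverse | m$flags$contaminant |
    m$flags$only_identified_by_site
  x <- m$intensities[!flagged, , drop = FALSE]
  keep <- rep(FALSE, nrow(x))
  for (g in unique(m$groups)) {
    cols <- names(m$groups)[m$groups == g]
    keep <- keep | rowSums(!is.na(x[, cols, drop = FALSE])) >= min_valid
  }
  proteome_matrix(x[keep, , drop = FALSE], m$groups,
                  m$flags[!flagged, , drop = FALSE][keep, , drop = FALSE])
}

#' Impute missing values from a downshifted normal
#'
#' Perseus-style detection-limit imputation: per sample (column-wise), each
#' missing value is drawn from a normal distribution with mean
#' `mu - downshift * sigma` and standard deviation `width * sigma`, where
#' `mu` and `sigma` are that sample's observed mean and SD — placing imputed
#' values just below the observed distribution, the assumed position of
#' intensities under the detection limit. Observed values are never altered;
#' deterministic under `seed`.
#'
#' @param m A filtered [proteome_matrix()].
#' @param width Imputation SD as a fraction of the sample SD (default 0.3).
#' @param downshift Mean shift in sample SD units (default 1.8).
#' @param seed Integer seed.
#' @return Complete [proteome_matrix()].
#' @export
impute_missing <- function(m, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(m, "proteome_matrix"))
  x <- m$intensities
  withr::with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      obs <- x[, j][!is.na(x[, j])]
      miss <- which(is.na(x[, j]))
      if (!length(miss)) next
      if (length(obs) < 2)
        stop("sample ", colnames(x)[j],
             " has fewer than 2 observed values; SD undefined")
      x[miss, j] <- rnorm(length(miss),
                          mean(obs) - downshift * sd(obs),
                          width * sd(obs))
    }
  })
  proteome_matrix(x, m$groups, m$flags)
}

#' Differential protein abundance
#'
#' Per protein, a two-sided equal-variance Student t-test on log2
#' intensities between the two groups; the log2 fold change is the group
#' mean difference. A protein is significant when `p < alpha` AND the linear
#' fold change exceeds `fc_min` (i.e. `|log2fc| > log2(fc_min)`). Raw p
#' values gate significance by default — the fold-change requirement stands
#' in for multiple-testing correction; set `adjust = TRUE` for an additional
#' BH-adjusted column and gate.
#'
#' @param m A complete (imputed) [proteome_matrix()] with two groups.
#' @param alpha P-value threshold.
#' @param fc_min Minimum linear fold change.
#' @param adjust Gate significance on BH-adjusted p instead of raw p.
#' @return Data frame: `protein_id`, group means, `log2fc` (group 1 over
#'   group 2), `p`, `neg_log10_p`, `q`, `significant` — volcano-ready.
#' @export
differential_proteins <- function(m, alpha = 0.05, fc_min = 2,
                                  adjust = FALSE) {
  stopifnot(inherits(m, "proteome_matrix"))
  grp <- unique(m$groups)
  if (length(grp) != 2) stop("exactly two groups required")
  if (any(table(m$groups) < 2)) stop("each group needs >= 2 samples")
  x <- m$intensities
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  c1 <- names(m$groups)[m$groups == grp[1]]
  c2 <- names(m$groups)[m$groups == grp[2]]
  mean1 <- rowMeans(x[, c1, drop = FALSE])
  mean2 <- rowMeans(x[, c2, drop = FALSE])
  p <- vapply(seq_len(nrow(x)), function(i)
    .t_test_p(x[i, c1], x[i, c2], var_equal = TRUE), 0)
  q <- p.adjust(p, method = "BH")
  lfc <- mean1 - mean2
  gate_p <- if (adjust) q else p
  out <- data.frame(protein_id = rownames(x), mean1 = mean1, mean2 = mean2,
                    log2fc = lfc, p = p, neg_log10_p = -log10(p), q = q,
                    significant = gate_p < alpha & abs(lfc) > log2(fc_min),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", grp)
  rownames(out) <- NULL
  out
}
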