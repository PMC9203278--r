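#' Read a writer/eraser edge table
#'
#' @param path TSV with header columns `modifier`, `mark`
#'   (`histone:residue:state`), `relation` (`writes` or `erases`). A curated
#'   starter table ships with the package:
#'   `system.file("extdata", "writer_eraser_edges.tsv", package = "chromaquant")`.
#' @return Edge data frame.
#' @export
read_modifier_edges <- function(path) {
  e <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("modifier", "mark", "relation") %in% names(e)))
  if (!all(e$relation %in% c("writes", "erases")))
    stop("relation must be 'writes' or 'erases'")
  e
}

#' Join modifier and mark fold changes over an edge network
#'
#' For every writer/eraser edge, attaches the chromatin-proteome log2 fold
#' change of the modifier protein and the histone-PTM log2 fold change of
#' its target mark. Edges whose modifier or mark lacks a measured fold
#' change are kept with status `missing` (the grey, not-detected nodes of a
#' network display); all other edges carry both fold changes and await
#' scoring.
#'
#' @param edges Edge data frame from [read_modifier_edges()] (duplicate
#'   (modifier, mark, relation) rows are an error).
#' @param protein_fc Named numeric vector: log2 fold change per protein.
#' @param mark_fc Named numeric vector: log2 fold change per mark.
#' @return Concordance data frame: edge columns plus `modifier_fc`,
#'   `mark_fc`, `expected_sign` (+1 writes, -1 erases), `status`.
#' @export
build_network <- function(edges, protein_fc, mark_fc) {
  key <- paste(edges$modifier, edges$mark, edges$relation)
  if (anyDuplicated(key)) stop("duplicate edge: ", key[duplicated(key)][1])
  out <- edges
  out$modifier_fc <- unname(protein_fc[out$modifier])
  out$mark_fc <- unname(mark_fc[out$mark])
  out$expected_sign <- ifelse(out$relation == "writes", 1, -1)
  out$status <- ifelse(is.na(out$modifier_fc) | is.na(out$mark_fc),
                       "missing", NA_character_)
  out
}

#' Score edge concordance between modifier and mark changes
#'
#' An edge is `neutral` when either fold change sits inside the neutrality
#' band (`|fc| < fc_threshold`); otherwise it is `concordant` when the
#' mark's direction matches the direction the modifier change predicts
#' (same sign for a writer, opposite for an eraser) and `discordant` when
#' it contradicts it — the formal version of reading a
#' writer-up/mark-up pair as consistent and an eraser-up/mark-up pair as
#' decoupled.
#'
#' @param table Output of [build_network()].
#' @param fc_threshold Neutrality band half-width in log2 units (default
#'   0.5, the conventional high-change cutoff).
#' @return The table with `status` filled in; a `summary` attribute holds
#'   counts per status.
#' @export
score_concordance <- function(table, fc_threshold = 0.5) {
  scored <- is.na(table$status)
  neutral <- scored & (abs(table$modifier_fc) < fc_threshold |
                         abs(table$mark_fc) < fc_threshold)
  table$status[neutral] <- "neutral"
  rest <- scored & !neutral
  agree <- sign(table$mark_fc) == table$expected_sign * sign(table$modifier_fc)
  table$status[rest] <- ifelse(agree[rest], "concordant", "discordant")
  attr(table, "summary") <- table(factor(
    table$status, levels = c("concordant", "discordant", "neutral", "missing")))
  table
}
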