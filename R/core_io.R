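#' @importFrom stats complete.cases density ks.test lm p.adjust pnorm predict
#'   pt quantile rnorm rpois runif sd setNames var cor coef rlnorm
#' @importFrom utils read.delim write.table head
NULL

# All genomic coordinates in this package are 0-based half-open (BED
# convention): an interval [start, end) covers bases start .. end-1.
# 1-based closed coordinates appear only transiently inside IRanges calls.

#' Construct a fragment set
#'
#' A fragment set is the package's representation of aligned sequenced
#' fragments: a data frame with one row per fragment, columns `chrom`,
#' `start`, `end` (0-based half-open), `genome` (`"target"` for the genome
#' under study, `"spikein"` for the exogenous calibration genome) and `mapq`
#' (mapping quality; `NA` means unknown and is treated as passing quality
#' filters).
#'
#' @param chrom Character vector of contig names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param genome Character vector, each element `"target"` or `"spikein"`.
#' @param mapq Integer vector of mapping qualities, or `NA`.
#' @return A `data.frame` with class `"fragment_set"` prepended.
#' @export
fragment_set <- function(chrom, start, end, genome = "target", mapq = NA_integer_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    genome = rep_len(as.character(genome), n),
    mapq = rep_len(as.integer(mapq), n),
    stringsAsFactors = FALSE
  )
  validate_fragment_set(df)
  class(df) <- c("fragment_set", "data.frame")
  df
}

validate_fragment_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "genome", "mapq") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$chrom == "" | is.na(df$chrom)))
    stop("fragment set has empty contig names")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  if (!all(df$genome %in% c("target", "spikein")))
    stop("genome tag must be 'target' or 'spikein'")
  invisible(df)
}

#' Read aligned fragments from a BED-like file
#'
#' Reads a tab-separated BED3+ file and tags every record as coming from the
#' target genome or the spike-in genome, based on contig membership. An
#' optional 5th column is taken as mapping quality (MAPQ); when absent, MAPQ
#' is `NA` and the record passes downstream quality filters.
#'
#' @param path Path to a tab-separated file with at least 3 columns
#'   (chrom, start, end); lines starting with `#` or `track` are skipped.
#' @param genome_map Named list with elements `target` and/or `spikein`, each
#'   a character vector of contig names belonging to that genome.
#' @return A [fragment_set()] with records in file order.
#' @export
read_fragments <- function(path, genome_map) {
  stopifnot(is.list(genome_map), all(names(genome_map) %in% c("target", "spikein")))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(fragment_set(character(), integer(), integer(), character(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop("line ", line_no[which(ncol < 3)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", line_no[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("line ", line_no[bad[1]], ": invalid interval (start >= end)")
  mapq <- rep(NA_integer_, length(lines))
  has5 <- ncol >= 5
  if (any(has5)) {
    mapq[has5] <- suppressWarnings(
      as.integer(vapply(fields[has5], `[[`, "", 5L)))
  }
  tag <- rep(NA_character_, length(chrom))
  for (g in names(genome_map)) tag[chrom %in% genome_map[[g]]] <- g
  bad <- which(is.na(tag))
  if (length(bad))
    stop("line ", line_no[bad[1]], ": contig '", chrom[bad[1]],
         "' not present in genome_map")
  fragment_set(chrom, start, end, tag, mapq)
}

#' Write a fragment set as BED
#'
#' Emits chrom/start/end/name/mapq columns (name is `.`); the genome tag is
#' not written, so the same `genome_map` used to read the file back must be
#' supplied to [read_fragments()].
#'
#' @param frags A [fragment_set()].
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  mapq <- ifelse(is.na(frags$mapq), ".", as.character(frags$mapq))
  out <- data.frame(frags$chrom, frags$start, frags$end, ".", mapq)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return Data frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) stop("bedGraph line with fewer than 4 columns")
  data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Write a 4-column bedGraph track
#'
#' Intervals must be sorted by (chrom, start) and non-overlapping within a
#' chromosome: bedGraph forbids overlap. Round-trips bit-identically through
#' [read_bedgraph()].
#'
#' @param track Data frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (nrow(track) > 1) {
    ord <- order(track$chrom, track$start)
    if (!identical(ord, seq_len(nrow(track))))
      stop("track must be sorted by (chrom, start)")
    same <- track$chrom[-1] == track$chrom[-nrow(track)]
    if (any(same & track$start[-1] < track$end[-nrow(track)]))
      stop("overlapping intervals: bedGraph forbids overlap")
  }
  out <- data.frame(track$chrom, track$start, track$end,
                    format(track$value, trim = TRUE, scientific = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or minimal GTF
#'
#' Computes each gene's transcription start site (TSS) from strand: `start`
#' for `+` genes, `end - 1` for `-` genes (0-based). For GTF input only rows
#' with feature `gene` are honoured; the gene id is taken from a
#' `gene_id "..."` attribute when present.
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score, strand)
#'   or a GTF file (detected by a 9-column layout with feature in column 3).
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  is_gtf <- all(nfield >= 8) &&
    all(grepl("^[a-zA-Z_]+$", vapply(fields, `[[`, "", 3L))) &&
    !all(vapply(fields, `[[`, "", 3L) %in% c("+", "-", "."))
  if (is_gtf) {
    feat <- vapply(fields, `[[`, "", 3L)
    fields <- fields[feat == "gene"]
    if (length(fields) == 0) stop("no feature=gene rows in GTF")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 4L)) - 1L  # GTF is 1-based closed
    end <- as.integer(vapply(fields, `[[`, "", 5L))
    strand <- vapply(fields, `[[`, "", 7L)
    attrs <- vapply(fields, function(f) if (length(f) >= 9) f[[9]] else "", "")
    gene_id <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", attrs)
    gene_id[!grepl("gene_id", attrs)] <-
      paste0("gene", seq_len(sum(!grepl("gene_id", attrs))))
  } else {
    if (any(nfield < 6)) stop("BED gene annotation requires 6 columns (strand missing)")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 2L))
    end <- as.integer(vapply(fields, `[[`, "", 3L))
    gene_id <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
  }
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tss <- ifelse(strand == "+", start, end - 1L)
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, tss = as.integer(tss), stringsAsFactors = FALSE)
}

# IRanges helpers: convert 0-based half-open to 1-based closed and back.
.ir <- function(start0, end0) IRanges::IRanges(start0 + 1L, end0)
.ir_start0 <- function(ir) IRanges::start(ir) - 1L
.ir_end0 <- function(ir) IRanges::end(ir)

# Split intervals by chromosome, apply f(IRanges) per chromosome, return
# data.frame(chrom, start, end) rebuilt 0-based.
.per_chrom_reduce <- function(df, f) {
  out <- lapply(split(seq_len(nrow(df)), df$chrom), function(idx) {
    ir <- f(.ir(df$start[idx], df$end[idx]))
    data.frame(chrom = df$chrom[idx[1]], start = .ir_start0(ir),
               end = .ir_end0(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Midpoint of 0-based half-open fragments (integer floor).
.fragment_midpoint <- function(frags) (frags$start + frags$end) %/% 2L

# For each query point (chrom, pos), TRUE if it lies inside any interval of
# `ivs` (data.frame chrom/start/end, 0-based half-open).
.point_in_intervals <- function(chrom, pos, ivs) {
  hit <- logical(length(chrom))
  if (nrow(ivs) == 0 || length(chrom) == 0) return(hit)
  for (ch in unique(ivs$chrom)) {
    qi <- which(chrom == ch)
    if (!length(qi)) next
    si <- ivs$chrom == ch
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(pos[qi] + 1L, width = 1L),
      .ir(ivs$start[si], ivs$end[si]))
    hit[qi] <- ov
  }
  hit
}
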