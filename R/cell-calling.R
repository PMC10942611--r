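#' Quality-filter cells on expression depth
#'
#' Retains cells with at least `min_counts` total gene reads and at least
#' `min_genes` detected genes (inclusive thresholds).
#'
#' @param cells cell table with columns `total_count` and `n_genes`.
#' @param min_counts,min_genes inclusive thresholds (published values: 20
#'   counts/cell and 5 genes/cell).
#' @return the filtered cell table.
#' @export
qc_filter_cells <- function(cells, min_counts = 20L, min_genes = 5L) {
  stopifnot(min_counts >= 0L, min_genes >= 0L)
  cells <- as.data.table(cells)
  if (nrow(cells) == 0L) return(cells)
  cells[total_count >= min_counts & n_genes >= min_genes]
}

#' Linguistic sequence complexity of a barcode
#'
#' The complexity `C` of a sequence of length `M` is the product over
#' `n = 1..M` of the vocabulary-usage measures
#' `U_n = (# distinct n-grams observed) / min(4^n, M - n + 1)`,
#' using overlapping n-grams. Maximally diverse sequences score 1;
#' homopolymers score astronomically low (a 15-nt homopolymer scores
#' `1 / (4 * 14!)`). Degenerate barcode calls - image background,
#' incomplete cells - are rejected by thresholding `C`.
#'
#' @param seq a single barcode string over `A/C/G/T`.
#' @return list of class `complexity_profile` with `length`,
#'   `vocabulary_usage` (vector `U_n`), and `complexity`.
#' @examples
#' linguistic_complexity("ACGT")$complexity  # 1
#' linguistic_complexity("AAAA")$complexity  # 1/24
#' @export
linguistic_complexity <- function(seq) {
  if (length(seq) != 1L || !nzchar(seq)) stop("need one non-empty sequence", call. = FALSE)
  if (!is_acgt(seq)) stop("sequence must contain only A/C/G/T", call. = FALSE)
  M <- nchar(seq)
  U <- vapply(seq_len(M), function(n) {
    grams <- substring(seq, 1:(M - n + 1L), n:M)
    length(unique(grams)) / min(4^n, M - n + 1L)
  }, numeric(1))
  structure(list(length = M, vocabulary_usage = U, complexity = prod(U)),
            class = "complexity_profile")
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat(sprintf("<complexity_profile> length %d, C = %.4g (log10 = %.2f)\n",
              x$length, x$complexity, log10(x$complexity)))
  invisible(x)
}

## Vectorized complexity over unique barcodes (memoized for call tables).
#' @noRd
complexity_of <- function(barcodes) {
  ub <- unique(barcodes)
  cx <- vapply(ub, function(b) linguistic_complexity(b)$complexity, numeric(1))
  cx[match(barcodes, ub)]
}

#' Within-cell barcode error correction
#'
#' Basecalling errors scatter reads of a true barcode onto near-identical
#' sequences. Within each cell, barcodes are processed in descending
#' count order (ties broken lexicographically) and any barcode within
#' `max_mismatch` of an already-retained, more abundant barcode is merged
#' into it (counts added). Passes repeat until a fixed point, so the
#' operation is idempotent. Cells are processed independently.
#'
#' @param reads `data.table` with `cell_id`, `barcode`, `count`.
#' @param max_mismatch merge radius in Hamming distance (published
#'   value: 2).
#' @return corrected read table, aggregated per (cell, barcode).
#' @export
correct_within_cell <- function(reads, max_mismatch = 2L) {
  reads <- as.data.table(reads)
  stopifnot(all(c("cell_id", "barcode", "count") %in% names(reads)))
  if (nrow(reads) == 0L) return(copy(reads))
  if (any(reads$count <= 0L)) stop("counts must be positive", call. = FALSE)
  out <- reads[, correct_one_cell(.SD, max_mismatch), by = cell_id]
  setorder(out, cell_id, -count, barcode)
  out[]
}

#' @noRd
correct_one_cell <- function(sd, max_mismatch) {
  if (length(unique(nchar(sd$barcode))) != 1L)
    stop("mixed barcode lengths within a cell", call. = FALSE)
  cur <- sd[, .(count = sum(count)), by = barcode]
  repeat {
    setorder(cur, -count, barcode)
    if (nrow(cur) == 1L) return(cur)
    dist <- hamming_cross(cur$barcode, cur$barcode)
    target <- rep(NA_integer_, nrow(cur))
    retained <- integer(0)
    for (i in seq_len(nrow(cur))) {
      if (length(retained)) {
        d <- dist[i, retained]
        hit <- which(d <= max_mismatch)
        if (length(hit)) { target[i] <- retained[hit[1L]]; next }
      }
      retained <- c(retained, i)
    }
    if (all(is.na(target))) return(cur)
    grp <- ifelse(is.na(target), seq_len(nrow(cur)), target)
    cur <- data.table(barcode = cur$barcode[grp], count = cur$count)[
      , .(count = sum(count)), by = barcode]
  }
}

#' Call per-cell barcodes
#'
#' Applies the published QC rule: a (cell, barcode) call is retained iff
#' its (corrected) read count reaches `min_count` and the barcode's
#' linguistic complexity exceeds `min_complexity`. The most abundant
#' retained barcode per cell is flagged primary, and `primary_fraction`
#' reports the primary count against the cell's total barcode reads
#' before thresholding.
#'
#' `min_count` is a profile parameter with no default: the published
#' thresholds are 8 counts for the in situ transsynaptic profile and 6
#' for the in situ retrograde profile (see [calling_profile()]).
#'
#' @param reads corrected read table (`cell_id`, `barcode`, `count`).
#' @param min_count minimum reads of the same barcode in a cell.
#' @param min_complexity linguistic-complexity threshold; calls must
#'   exceed it strictly (published: `10^-0.9`).
#' @return `data.table` of calls: `cell_id`, `barcode`, `count`,
#'   `complexity`, `is_primary`, `primary_fraction`.
#' @export
call_cell_barcodes <- function(reads, min_count, min_complexity = 10^-0.9) {
  stopifnot(!missing(min_count), min_count >= 1L)
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L)
    return(data.table(cell_id = character(0), barcode = character(0),
                      count = integer(0), complexity = numeric(0),
                      is_primary = logical(0), primary_fraction = numeric(0)))
  pre_total <- reads[, .(total = sum(count)), by = cell_id]
  calls <- copy(reads)[, complexity := complexity_of(barcode)]
  calls <- calls[count >= min_count & complexity > min_complexity]
  if (nrow(calls) == 0L) return(calls[, `:=`(is_primary = logical(0),
                                             primary_fraction = numeric(0))][])
  setorder(calls, cell_id, -count, barcode)
  calls[, is_primary := seq_len(.N) == 1L, by = cell_id]
  calls[pre_total, total := i.total, on = "cell_id"]
  calls[, primary_fraction := count[is_primary] / total, by = cell_id]
  calls[, total := NULL]
  calls[]
}

#' Built-in calling profiles
#'
#' Named bundles of the published thresholds: the `transsynaptic` in situ
#' profile (8 counts), the `retrograde` in situ profile (6 counts), and
#' `conventional_g12`, which raises the source-cell glycoprotein
#' threshold to 12 transcripts (the level matching fluorescence-defined
#' source cells) for sensitivity analysis.
#'
#' @param name one of `"transsynaptic"`, `"retrograde"`,
#'   `"conventional_g12"`.
#' @return list with `min_count`, `min_complexity`, `g_source_min`,
#'   `g_exclude_exact`.
#' @export
calling_profile <- function(name = c("transsynaptic", "retrograde",
                                     "conventional_g12")) {
  name <- match.arg(name)
  switch(name,
    transsynaptic   = list(min_count = 8L, min_complexity = 10^-0.9,
                           g_source_min = 2L, g_exclude_exact = 1L),
    retrograde      = list(min_count = 6L, min_complexity = 10^-0.9,
                           g_source_min = 2L, g_exclude_exact = 1L),
    conventional_g12 = list(min_count = 8L, min_complexity = 10^-0.9,
                            g_source_min = 12L, g_exclude_exact = 1L))
}

#' Assign source / presynaptic roles from glycoprotein counts
#'
#' Barcoded cells with at least `g_source_min` glycoprotein transcripts
#' are potential source cells; barcoded cells with exactly
#' `g_exclude_exact` transcripts are excluded as unclassifiable (the
#' published conservative rule removes single-read cells); remaining
#' barcoded cells are potential presynaptic cells. Cells without a
#' barcode call are `"unassigned"`.
#'
#' @param calls call table from [call_cell_barcodes()].
#' @param cells cell table with `cell_id` and `g_count`; every call's
#'   cell must be present.
#' @param g_source_min source threshold (published conservative value 2;
#'   12 for the conventional profile).
#' @param g_exclude_exact glycoprotein count that excludes a cell
#'   (published value 1).
#' @return the calls table with a `role` column (`source`, `presynaptic`,
#'   `excluded`).
#' @export
classify_cell_roles <- function(calls, cells, g_source_min = 2L,
                                g_exclude_exact = 1L) {
  calls <- as.data.table(calls)
  cells <- as.data.table(cells)
  missing_cells <- setdiff(calls$cell_id, cells$cell_id)
  if (length(missing_cells))
    stop(sprintf("missing cell record(s): %s",
                 paste(head(missing_cells, 3L), collapse = ", ")), call. = FALSE)
  out <- copy(calls)
  out[cells, g_count := i.g_count, on = "cell_id"]
  out[, role := fifelse(g_count >= g_source_min, "source",
                 fifelse(g_count == g_exclude_exact, "excluded",
                         "presynaptic"))]
  out[, g_count := NULL]
  out[]
}
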