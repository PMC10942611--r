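#' Extract (barcode, UMI) pairs from library sequencing reads
#'
#' Locates the two fixed flanking sequences in each read, allowing up to
#' `max_flank_mismatch` substitutions per flank, and cuts out the barcode
#' and UMI windows. The expected read layout is
#' `flank5 | barcode | flank3 | UMI`, matching an RT primer that appends
#' the UMI beyond the 3' flank. A pair is emitted only when both flanks
#' are found, the read is long enough, and neither window contains `N`;
#' everything else is tallied by rejection reason.
#'
#' @param reads either a character vector of read sequences, a
#'   `data.frame` with columns `read_id` and `sequence`, or the path to a
#'   FASTQ file (optionally gzipped; requires the Biostrings package).
#' @param flank5,flank3 non-empty fixed flanking sequences.
#' @param barcode_len,umi_len window lengths (20 and 20 for the published
#'   libraries).
#' @param max_flank_mismatch maximum substitutions tolerated per flank.
#' @return list with `pairs` (`data.table`: `read_id`, `barcode`, `umi`)
#'   and `rejected` (named integer tally:
#'   `too_short`, `flank5_not_found`, `flank3_not_found`, `has_N`).
#' @export
extract_barcode_umi <- function(reads, flank5, flank3,
                                barcode_len = 20L, umi_len = 20L,
                                max_flank_mismatch = 1L) {
  if (!nzchar(flank5) || !nzchar(flank3))
    stop("flanks must be non-empty", call. = FALSE)
  stopifnot(barcode_len >= 1L, umi_len >= 1L, max_flank_mismatch >= 0L)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq_sequences(reads)
  if (is.character(reads))
    reads <- data.table(read_id = sprintf("read_%07d", seq_along(reads)),
                        sequence = reads)
  reads <- as.data.table(reads)
  if (!all(c("read_id", "sequence") %in% names(reads)))
    stop("reads need columns `read_id` and `sequence`", call. = FALSE)
  if (any(!nzchar(reads$sequence) | is.na(reads$sequence)))
    stop(sprintf("malformed read record: %s",
                 reads$read_id[which(!nzchar(reads$sequence) | is.na(reads$sequence))[1]]),
         call. = FALSE)

  tally <- c(too_short = 0L, flank5_not_found = 0L,
             flank3_not_found = 0L, has_N = 0L)
  n5 <- nchar(flank5); n3 <- nchar(flank3)
  min_len <- n5 + barcode_len + n3 + umi_len
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    if (nchar(s) < min_len) { tally["too_short"] <- tally["too_short"] + 1L; next }
    p5 <- locate_flank(s, flank5, max_flank_mismatch)
    if (is.na(p5)) { tally["flank5_not_found"] <- tally["flank5_not_found"] + 1L; next }
    bc_start <- p5 + n5
    p3_expect <- bc_start + barcode_len
    ## flank3 must sit immediately after the barcode window
    if (nchar(s) < p3_expect + n3 + umi_len - 1L ||
        hamming_dist(substr(s, p3_expect, p3_expect + n3 - 1L), flank3) > max_flank_mismatch) {
      tally["flank3_not_found"] <- tally["flank3_not_found"] + 1L; next
    }
    bc <- substr(s, bc_start, bc_start + barcode_len - 1L)
    umi <- substr(s, p3_expect + n3, p3_expect + n3 + umi_len - 1L)
    if (grepl("N", bc, fixed = TRUE) || grepl("N", umi, fixed = TRUE)) {
      tally["has_N"] <- tally["has_N"] + 1L; next
    }
    out[[i]] <- list(read_id = reads$read_id[i], barcode = bc, umi = umi)
  }
  pairs <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(pairs) == 0L)
    pairs <- data.table(read_id = character(0), barcode = character(0),
                        umi = character(0))
  list(pairs = pairs, rejected = tally)
}

## First position (1-based) where `flank` matches `s` within `k`
## mismatches; exact match is tried first as a fast path.
#' @noRd
locate_flank <- function(s, flank, k) {
  exact <- regexpr(flank, s, fixed = TRUE)
  if (exact > 0L) return(as.integer(exact))
  if (k == 0L) return(NA_integer_)
  L <- nchar(flank)
  sv <- utf8ToInt(s)
  fv <- utf8ToInt(flank)
  n_win <- length(sv) - L + 1L
  if (n_win < 1L) return(NA_integer_)
  for (p in seq_len(n_win)) {
    if (sum(sv[p:(p + L - 1L)] != fv) <= k) return(p)
  }
  NA_integer_
}

#' @noRd
read_fastq_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTQ requires the Biostrings package", call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = names(x), sequence = as.character(x))
}

#' Build a library frequency table from (barcode, UMI) pairs
#'
#' UMI-based counting: each barcode's abundance is the number of distinct
#' UMIs observed with it (PCR duplicates with identical barcode and UMI
#' collapse to one molecule). Optionally, UMIs within Hamming distance 1
#' of a more abundant UMI of the same barcode are merged first
#' (directional merge for deeply sequenced libraries). Frequencies are
#' the normalized UMI counts.
#'
#' @param pairs `data.table`/`data.frame` with columns `barcode`, `umi`.
#' @param umi_merge_mismatch 0 (exact UMI dedup, default) or 1
#'   (additionally merge 1-mismatch UMIs into more-abundant ones).
#' @param library_id,has_ccs metadata for the returned library.
#' @return a [barcode_library] with `umi_count` and `frequency` columns.
#' @export
build_library_table <- function(pairs, umi_merge_mismatch = 0L,
                                library_id = "library", has_ccs = FALSE) {
  pairs <- as.data.table(pairs)
  if (nrow(pairs) == 0L) stop("empty (barcode, umi) stream", call. = FALSE)
  stopifnot(all(c("barcode", "umi") %in% names(pairs)),
            umi_merge_mismatch %in% c(0L, 1L))
  ## reads per (barcode, umi), then optional 1-mismatch directional merge
  bu <- pairs[, .(reads = .N), by = .(barcode, umi)]
  if (umi_merge_mismatch == 1L) {
    bu <- bu[, merge_umis_directional(.SD), by = barcode]
  }
  counts <- bu[, .(umi_count = .N), by = barcode]
  barcode_library(counts$barcode, umi_count = counts$umi_count,
                  library_id = library_id, has_ccs = has_ccs)
}

## Directional single-mismatch UMI merging within one barcode: walk UMIs
## by descending read count and absorb any unclaimed UMI within Hamming
## distance 1 of an already-retained one.
#' @noRd
merge_umis_directional <- function(sd) {
  if (nrow(sd) <= 1L) return(sd[, .(umi, reads)])
  setorder(sd, -reads, umi)
  keep <- logical(nrow(sd))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(sd))) {
    if (length(kept_idx)) {
      d <- hamming_cross(sd$umi[i], sd$umi[kept_idx])
      if (min(d) <= 1L) next
    }
    keep[i] <- TRUE
    kept_idx <- c(kept_idx, i)
  }
  sd[keep, .(umi, reads)]
}

#' Minimum Hamming distance of queries to a library
#'
#' For each query barcode, the minimum Hamming distance over all library
#' barcodes, both truncated to the first `prefix_len` bases (in situ
#' experiments sequence only 15 of the 20 barcode bases). The profile of
#' these minima separates true library barcodes (0-1 mismatches) from
#' unrelated sequences (mode near `0.75 * prefix_len` for random
#' barcodes).
#'
#' @param queries character vector of observed barcodes (length >=
#'   `prefix_len`).
#' @param library a [barcode_library].
#' @param prefix_len number of leading bases compared.
#' @return integer vector of per-query minimum distances.
#' @export
min_hamming_profile <- function(queries, library, prefix_len = 15L) {
  stopifnot(is_barcode_library(library))
  if (nrow(library$records) == 0L) stop("empty library", call. = FALSE)
  if (length(queries) == 0L) return(integer(0))
  if (min(nchar(queries)) < prefix_len ||
      nchar(library$records$barcode[1]) < prefix_len)
    stop("prefix_len exceeds query or library barcode length", call. = FALSE)
  min_hamming_impl(queries, library$records$barcode, prefix_len)$dist
}

#' Match observed barcodes to injected libraries
#'
#' Assigns each query to the unique library containing a barcode within
#' `max_mismatch` of the query's `prefix_len`-base prefix (the published
#' rule: one mismatch over 15 sequenced bases). Queries within reach of
#' more than one library are reported `"ambiguous"` and excluded from
#' downstream analysis rather than silently assigned; queries matching no
#' library are `"unmatched"`.
#'
#' @param queries character vector of observed barcodes.
#' @param libraries list of [barcode_library] objects.
#' @param max_mismatch maximum Hamming distance for a match.
#' @param prefix_len number of leading bases compared.
#' @return `data.table` with `barcode`, `assignment` (a `library_id`,
#'   `"unmatched"` or `"ambiguous"`) and one `dist_<library_id>` column
#'   of per-library minimum distances.
#' @export
match_to_libraries <- function(queries, libraries, max_mismatch = 1L,
                               prefix_len = 15L) {
  stopifnot(length(libraries) >= 1L)
  lapply(libraries, function(l) stopifnot(is_barcode_library(l)))
  if (length(queries) && min(nchar(queries)) < prefix_len)
    stop("queries must be at least prefix_len long", call. = FALSE)
  dmat <- vapply(libraries, function(lib)
    min_hamming_profile(queries, lib, prefix_len), integer(length(queries)))
  dmat <- matrix(dmat, nrow = length(queries))
  ids <- vapply(libraries, `[[`, character(1), "library_id")
  hits <- dmat <= max_mismatch
  n_hit <- rowSums(hits)
  assignment <- rep("unmatched", length(queries))
  assignment[n_hit > 1L] <- "ambiguous"
  one <- which(n_hit == 1L)
  if (length(one))
    assignment[one] <- ids[apply(hits[one, , drop = FALSE], 1L, which)]
  out <- data.table(barcode = queries, assignment = assignment)
  for (j in seq_along(ids)) out[[paste0("dist_", ids[j])]] <- dmat[, j]
  out[]
}
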