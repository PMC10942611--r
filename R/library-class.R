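#' Barcode library objects
#'
#' A `barcode_library` holds the barcodes of one injected virus library
#' together with their UMI counts and normalized frequencies. The
#' frequency column is the quantity `f` used throughout the collision
#' statistics: the probability that one infection event carries that
#' barcode.
#'
#' @param barcodes character vector of unique barcode sequences over
#'   `A/C/G/T`, all the same length (20 nt for full-length libraries).
#' @param umi_count integer vector of non-negative UMI counts, or `NA` for
#'   synthetic libraries whose frequencies are known directly.
#' @param frequency optional numeric vector of frequencies. When omitted,
#'   computed as `umi_count / sum(umi_count)`.
#' @param library_id character scalar naming the library.
#' @param has_ccs logical; whether the library carries the capture-sequence
#'   tag that distinguishes the two retrograde libraries.
#'
#' @return An object of class `barcode_library`: a list with elements
#'   `library_id`, `has_ccs` and `records` (a `data.table` with columns
#'   `barcode`, `umi_count`, `frequency`).
#' @export
barcode_library <- function(barcodes, umi_count = NA_integer_,
                            frequency = NULL, library_id = "library",
                            has_ccs = FALSE) {
  if (length(barcodes) == 0L) stop("library must contain >= 1 barcode", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("barcodes must be unique within a library", call. = FALSE)
  if (!all(is_acgt(barcodes))) stop("barcodes must contain only A/C/G/T", call. = FALSE)
  if (length(unique(nchar(barcodes))) != 1L)
    stop("barcodes must all have the same length", call. = FALSE)
  umi_count <- rep_len(as.integer(umi_count), length(barcodes))
  if (is.null(frequency)) {
    if (anyNA(umi_count)) stop("supply `frequency` when umi_count is NA", call. = FALSE)
    if (any(umi_count < 0L)) stop("umi_count must be non-negative", call. = FALSE)
    tot <- sum(as.double(umi_count))
    if (tot <= 0) stop("total UMI count must be positive", call. = FALSE)
    frequency <- umi_count / tot
  } else {
    if (any(frequency < 0)) stop("frequencies must be non-negative", call. = FALSE)
    s <- sum(frequency)
    if (abs(s - 1) > 1e-9) stop("frequencies must sum to 1", call. = FALSE)
  }
  records <- data.table(barcode = as.character(barcodes),
                        umi_count = umi_count,
                        frequency = as.numeric(frequency))
  structure(list(library_id = as.character(library_id)[1],
                 has_ccs = isTRUE(has_ccs),
                 records = records),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("<barcode_library '%s'>  %d barcodes, %d nt, CCS tag: %s\n",
              x$library_id, nrow(x$records), nchar(x$records$barcode[1]),
              if (x$has_ccs) "yes" else "no"))
  top <- x$records[order(-frequency)][seq_len(min(3L, nrow(x$records)))]
  cat(sprintf("  top frequency %.3g; %d barcodes carry 50%% of mass\n",
              top$frequency[1],
              sum(cumsum(sort(x$records$frequency, decreasing = TRUE)) < 0.5) + 1L))
  invisible(x)
}

#' @export
format.barcode_library <- function(x, ...) {
  sprintf("<barcode_library '%s': %d barcodes>", x$library_id, nrow(x$records))
}

#' @rdname barcode_library
#' @param x object to test.
#' @export
is_barcode_library <- function(x) inherits(x, "barcode_library")

#' Read and write library tables
#'
#' Plain-TSV serialization of [barcode_library] objects with columns
#' `barcode`, `umi_count`, `frequency`.
#'
#' @param library a [barcode_library].
#' @param path file path of the TSV.
#' @param library_id,has_ccs metadata applied on read (the TSV stores only
#'   the records).
#' @return `write_library_tsv` returns `path` invisibly;
#'   `read_library_tsv` returns a [barcode_library].
#' @export
write_library_tsv <- function(library, path) {
  stopifnot(is_barcode_library(library))
  fwrite(library$records, path, sep = "\t")
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path, library_id = "library", has_ccs = FALSE) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "barcode"))
  if (!all(c("barcode", "frequency") %in% names(dt)))
    stop("library TSV needs columns `barcode` and `frequency`", call. = FALSE)
  if (!"umi_count" %in% names(dt)) dt[, umi_count := NA_integer_]
  fr <- dt$frequency / sum(dt$frequency)  # re-normalize against rounding
  barcode_library(dt$barcode, umi_count = dt$umi_count, frequency = fr,
                  library_id = library_id, has_ccs = has_ccs)
}

## Frequency lookup for arbitrary barcodes; absent barcodes get `absent`.
#' @noRd
library_frequency <- function(library, barcodes, absent = 0) {
  idx <- match(barcodes, library$records$barcode)
  out <- library$records$frequency[idx]
  out[is.na(idx)] <- absent
  out
}
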