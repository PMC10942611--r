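## Internal helpers: sequence encoding, Hamming distances, seeded RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

#' @noRd
assert_fraction <- function(x, name) assert_scalar_number(x, name, 0, 1)

## Evaluate `code` under a fixed seed without disturbing the caller's RNG
## state. All exported stochastic operations take an explicit seed and go
## through this, so there is no hidden global RNG coupling between calls.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

## Deterministically derive a child seed for an internal sub-stream.
#' @noRd
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 1103 * k) %% 2147483563
}

## Encode equal-length DNA strings as an L x n integer matrix of code
## points (one column per sequence). utf8ToInt on the concatenation is far
## faster than strsplit for thousands of barcodes.
#' @noRd
encode_seq_matrix <- function(x) {
  L <- unique(nchar(x))
  if (length(L) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = L)
}

## Minimum Hamming distance (and argmin) of each query against a set of
## references, all truncated to `prefix_len`. Returns list(dist, index).
#' @noRd
min_hamming_impl <- function(queries, refs, prefix_len) {
  qm <- encode_seq_matrix(substr(queries, 1L, prefix_len))
  rm_ <- encode_seq_matrix(substr(refs, 1L, prefix_len))
  nq <- length(queries)
  d <- integer(nq)
  idx <- integer(nq)
  for (i in seq_len(nq)) {
    mism <- .colSums(rm_ != qm[, i], m = prefix_len, n = ncol(rm_))
    j <- which.min(mism)
    d[i] <- as.integer(mism[j])
    idx[i] <- j
  }
  list(dist = as.integer(d), index = idx)
}

## Pairwise Hamming distance matrix between two small sets of equal-length
## strings (used inside cells; counts are tiny).
#' @noRd
hamming_cross <- function(a, b) {
  am <- encode_seq_matrix(a)
  bm <- encode_seq_matrix(b)
  L <- nrow(am)
  out <- matrix(0L, length(a), length(b))
  for (j in seq_along(b))
    out[, j] <- .colSums(am != bm[, j], m = L, n = ncol(am))
  out
}

#' @noRd
hamming_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## n unique random DNA strings of length `len`. Caller provides RNG state.
#' @noRd
random_barcodes <- function(n, len) {
  draw <- function(k) {
    m <- matrix(sample(DNA_BASES, k * len, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  bc <- unique(draw(n))
  while (length(bc) < n)
    bc <- unique(c(bc, draw(n - length(bc))))
  bc[seq_len(n)]
}

#' @noRd
is_acgt <- function(x) !grepl("[^ACGT]", x)
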