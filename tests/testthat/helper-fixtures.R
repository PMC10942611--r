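## Shared fixture builders. Everything is generated in code at test time;
## no binary fixtures.

library(data.table)

## Deterministic toy library from explicit barcodes/counts.
toy_library <- function(barcodes, umi_count = NULL, frequency = NULL,
                        library_id = "toy") {
  if (is.null(umi_count) && is.null(frequency))
    umi_count <- rep(1L, length(barcodes))
  barcode_library(barcodes, umi_count = if (is.null(umi_count)) NA_integer_ else umi_count,
                  frequency = frequency, library_id = library_id)
}

## Random fixed-length barcodes (test-local RNG; callers set seeds).
rand_bc <- function(n, len = 20L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Deterministic distinct DNA barcodes: index written in base 4.
index_barcodes <- function(idx, len = 20L) {
  vapply(idx, function(i) {
    digits <- integer(len)
    for (p in seq_len(len)) { digits[p] <- i %% 4L; i <- i %/% 4L }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

## Substitute exactly k positions of one sequence.
mutate_k <- function(seq, k, positions = NULL) {
  s <- strsplit(seq, "")[[1]]
  pos <- if (is.null(positions)) sample(seq_along(s), k) else positions
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

## Minimal cells table for role classification / convergence tests.
toy_cells <- function(cell_id, g_count = 0L, subclass = "L2/3 IT",
                      area = "SSp", type = NULL) {
  n <- length(cell_id)
  data.table(cell_id = cell_id,
             slice_id = "slice_01",
             x_um = seq_len(n) * 10, y_um = 0,
             area = rep_len(area, n),
             subclass = rep_len(subclass, n),
             type = if (is.null(type)) paste0(rep_len(subclass, n), "_1")
                    else rep_len(type, n),
             g_count = rep_len(as.integer(g_count), n),
             total_count = 100L, n_genes = 20L)
}

## Sourceless membership networks with given sizes and subclass labels:
## used by the convergence permutation machinery (networks table + cells
## table), bypassing the calling pipeline.
membership_networks <- function(sizes, labels) {
  stopifnot(sum(sizes) == length(labels))
  cell_id <- sprintf("cell_%05d", seq_along(labels))
  net_id <- rep.int(seq_along(sizes), sizes)
  nets <- data.table(
    barcode = index_barcodes(seq_along(sizes)),
    member_cell_ids = split(cell_id, net_id),
    source_cell_ids = replicate(length(sizes), character(0), simplify = FALSE),
    n_cells = as.integer(sizes),
    n_sources = 0L,
    network_class = "lost_source")
  cells <- toy_cells(cell_id, subclass = labels)
  list(networks = nets, cells = cells)
}

## Null convergence world: `n_nets` filtered-size networks with subclass
## labels drawn independently of membership.
null_convergence_world <- function(n_nets = 150L,
                                   props = c(A = 0.3, B = 0.25, C = 0.2,
                                             D = 0.1, E = 0.1, F = 0.05)) {
  sizes <- 5L + rnbinom(n_nets, size = 0.78, mu = 7)
  labels <- sample(names(props), sum(sizes), replace = TRUE, prob = props)
  membership_networks(sizes, labels)
}

## Brute-force Hamming helpers used as independent oracles.
oracle_hamming <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  sum(sa != sb)
}
oracle_min_hamming <- function(queries, refs, prefix_len) {
  vapply(queries, function(q) {
    qq <- substr(q, 1, prefix_len)
    min(vapply(refs, function(r)
      oracle_hamming(qq, substr(r, 1, prefix_len)), numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}
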