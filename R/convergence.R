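#' Filter networks for convergence analysis
#'
#' Convergence analysis uses networks whose members genuinely synapse
#' onto one postsynaptic cell, so the two confounded network types are
#' removed: small networks (fewer than `min_cells` members, dominated by
#' direct-infection no-source networks) and networks of barcodes that
#' are abundant in the library (above `max_barcode_freq`, at risk of
#' double labeling). Barcodes absent from the library table are retained
#' - the library tail is undersequenced, and an unsequenced barcode is a
#' rare one.
#'
#' @param networks a [build_networks()] table.
#' @param library a [barcode_library].
#' @param min_cells minimum network size (published value 5).
#' @param max_barcode_freq maximum library frequency (the published
#'   analysis derived 1.3e-3 from [single_infection_threshold()]).
#' @return the filtered networks table.
#' @export
filter_for_convergence <- function(networks, library, min_cells = 5L,
                                   max_barcode_freq = 1.3e-3) {
  stopifnot(is_barcode_library(library), min_cells >= 1L,
            max_barcode_freq >= 0)
  nets <- as.data.table(networks)
  freq <- library_frequency(library, nets$barcode, absent = 0)
  out <- nets[n_cells >= min_cells & freq <= max_barcode_freq]
  setattr(out, "class", c("barcode_networks", class(out)))
  out[]
}

#' Observed converging-pair counts by subclass
#'
#' Every unordered pair of presynaptic cells sharing a barcode synapses
#' onto the same postsynaptic cell ("converging outputs"). Pairs are
#' accumulated over networks into a symmetric subclass-by-subclass count
#' matrix: a network with members of subclasses `{A, A, B}` contributes
#' `O_AA = 1` and `O_AB = 2`. Source cells are excluded by default
#' (convergence is a statement about the presynaptic members).
#'
#' @param networks filtered [build_networks()] table.
#' @param cells cell table with `cell_id` and `subclass` covering every
#'   member.
#' @param include_sources count source-cell members as well.
#' @param subclasses optional label ordering for the matrix.
#' @return symmetric integer matrix of pair counts.
#' @export
converging_pairs <- function(networks, cells, include_sources = FALSE,
                             subclasses = NULL) {
  counts <- membership_counts(networks, cells, include_sources, subclasses)
  pair_counts_from_membership(counts)
}

## Network-by-subclass membership count matrix shared by the observed
## statistic and the permutation null.
#' @noRd
membership_counts <- function(networks, cells, include_sources = FALSE,
                              subclasses = NULL) {
  nets <- as.data.table(networks)
  cells <- as.data.table(cells)
  if (nrow(nets) == 0L) stop("no networks to analyse", call. = FALSE)
  members <- nets[, .(cell_id = member_cell_ids[[1L]],
                      src = member_cell_ids[[1L]] %in% source_cell_ids[[1L]]),
                  by = barcode]
  if (!include_sources) members <- members[!(src)]
  members[cells, subclass := i.subclass, on = "cell_id"]
  if (anyNA(members$subclass))
    stop("network member without a subclass label", call. = FALSE)
  if (is.null(subclasses)) subclasses <- sort(unique(members$subclass))
  members[, subclass := factor(subclass, levels = subclasses)]
  net_f <- factor(members$barcode)
  m <- matrix(0L, nlevels(net_f), length(subclasses),
              dimnames = list(levels(net_f), subclasses))
  idx <- cbind(as.integer(net_f), as.integer(members$subclass))
  tab <- tabulate((idx[, 2L] - 1L) * nlevels(net_f) + idx[, 1L],
                  nbins = length(m))
  m[] <- tab
  m
}

## O from a network x subclass membership matrix: off-diagonal
## O_AB = sum_net n_A n_B; diagonal O_AA = sum_net choose(n_A, 2).
#' @noRd
pair_counts_from_membership <- function(m) {
  o <- crossprod(m)
  diag(o) <- (diag(o) - colSums(m)) / 2
  storage.mode(o) <- "double"
  o
}

#' Expected converging pairs under random connectivity and bias ratios
#'
#' Under label-independent membership the expected pair counts follow
#' the subclass abundances: `E_AB` is proportional to `2 n_A n_B` for
#' `A != B` and to `n_A^2` on the diagonal (the published "square of
#' cell counts" convention; `diagonal = "choose"` uses
#' `n_A (n_A - 1) / 2` instead). The matrix is scaled so total expected
#' pairs equal total observed pairs, and the convergence bias is
#' `R = O / E` elementwise.
#'
#' @param observed symmetric observed-pair matrix from
#'   [converging_pairs()].
#' @param subclass_counts named vector: number of participating cells per
#'   subclass (every subclass in `observed` must be present and
#'   positive).
#' @param diagonal `"square"` (published) or `"choose"`.
#' @return list with `expected` and `bias` matrices.
#' @export
expected_and_bias <- function(observed, subclass_counts,
                              diagonal = c("square", "choose")) {
  diagonal <- match.arg(diagonal)
  labs <- colnames(observed)
  if (is.null(labs)) stop("observed matrix must have subclass dimnames", call. = FALSE)
  if (!all(labs %in% names(subclass_counts)))
    stop("subclass_counts missing labels present in observed", call. = FALSE)
  n <- as.numeric(subclass_counts[labs])
  active <- rowSums(observed) + colSums(observed) > 0
  if (any(n <= 0 & active))
    stop("zero cell count for a subclass with observed pairs", call. = FALSE)
  ## "square": diag n^2, off-diag 2 n_A n_B (published convention, in
  ## which label-independent data give flat bias). "choose": the exact
  ## unordered-pair weights C(n_A, 2) and n_A n_B.
  w <- if (diagonal == "square") 2 * outer(n, n) else outer(n, n)
  diag(w) <- if (diagonal == "square") n^2 else n * (n - 1) / 2
  tot_o <- sum(observed[upper.tri(observed, diag = TRUE)])
  if (tot_o <= 0) stop("zero total observed pairs", call. = FALSE)
  tot_w <- sum(w[upper.tri(w, diag = TRUE)])
  expected <- w * tot_o / tot_w
  dimnames(expected) <- dimnames(observed)
  bias <- observed / expected
  bias[expected == 0] <- NaN
  list(expected = expected, bias = bias)
}

#' Permutation significance of convergence biases
#'
#' Shuffles subclass labels over the pooled participating cells
#' (preserving network memberships, sizes, and the marginal subclass
#' composition) and recomputes the pair-count matrix each iteration. The
#' p-value for a subclass pair doubles the fraction of iterations at
#' least as extreme as the observation in the observed direction
#' (direction taken against the permutation mean), clipped at 1.
#'
#' @param networks filtered [build_networks()] table.
#' @param cells cell table with `subclass` labels.
#' @param n_iter permutation iterations (published: 10,000).
#' @param seed integer seed.
#' @param fpr_alpha significance level for the mask.
#' @param include_sources passed to the pair counting.
#' @param pseudo_count if `TRUE`, apply a +1 pseudo-count
#'   (`p >= 1/(n_iter+1)`); off by default to match the published
#'   estimator.
#' @return list with `p_values`, `mask` (p < `fpr_alpha`), `observed`,
#'   `perm_mean`.
#' @export
permutation_significance <- function(networks, cells, n_iter = 10000L,
                                     seed = 1L, fpr_alpha = 0.05,
                                     include_sources = FALSE,
                                     pseudo_count = FALSE) {
  stopifnot(n_iter >= 1L)
  m <- membership_counts(networks, cells, include_sources)
  observed <- pair_counts_from_membership(m)
  net_sizes <- rowSums(m)
  K <- ncol(m)
  labels <- rep.int(seq_len(K), colSums(m))
  net_of_cell <- rep.int(seq_len(nrow(m)), net_sizes)
  n_cells <- length(net_of_cell)
  ge <- le <- matrix(0L, K, K)
  acc <- matrix(0, K, K)
  with_seed(seed, for (it in seq_len(n_iter)) {
    lab <- labels[sample.int(n_cells)]
    mm <- matrix(tabulate((lab - 1L) * nrow(m) + net_of_cell,
                          nbins = nrow(m) * K), nrow(m), K)
    o <- pair_counts_from_membership(mm)
    ge <- ge + (o >= observed)
    le <- le + (o <= observed)
    acc <- acc + o
  })
  perm_mean <- acc / n_iter
  up <- observed >= perm_mean
  extreme <- ifelse(up, ge, le)
  p <- 2 * extreme / n_iter
  if (pseudo_count) p <- (2 * extreme + 1) / (n_iter + 1)
  p <- pmin(p, 1)
  dimnames(p) <- dimnames(observed)
  dimnames(perm_mean) <- dimnames(observed)
  list(p_values = p, mask = p < fpr_alpha, observed = observed,
       perm_mean = perm_mean)
}

#' Full convergence analysis
#'
#' Convenience wrapper chaining [filter_for_convergence()],
#' [converging_pairs()], [expected_and_bias()] and
#' [permutation_significance()] into one `convergence_matrix` result.
#'
#' @param networks a [build_networks()] table.
#' @param cells cell table with `subclass`.
#' @param library a [barcode_library].
#' @param min_cells,max_barcode_freq filtering thresholds.
#' @param n_iter,seed,fpr_alpha permutation settings.
#' @param diagonal expected-count convention, see [expected_and_bias()].
#' @return list of class `convergence_matrix`: `subclasses`, `observed`,
#'   `expected`, `bias`, `p_values`, `mask`, `n_permutations`,
#'   `fpr_alpha`, `meta`.
#' @export
convergence_matrix <- function(networks, cells, library, min_cells = 5L,
                               max_barcode_freq = 1.3e-3, n_iter = 10000L,
                               seed = 1L, fpr_alpha = 0.05,
                               diagonal = "square") {
  filtered <- filter_for_convergence(networks, library, min_cells,
                                     max_barcode_freq)
  if (nrow(filtered) == 0L) stop("no networks pass the filters", call. = FALSE)
  m <- membership_counts(filtered, cells)
  observed <- pair_counts_from_membership(m)
  eb <- expected_and_bias(observed, colSums(m), diagonal = diagonal)
  sig <- permutation_significance(filtered, cells, n_iter = n_iter,
                                  seed = seed, fpr_alpha = fpr_alpha)
  structure(list(subclasses = colnames(observed), observed = observed,
                 expected = eb$expected, bias = eb$bias,
                 p_values = sig$p_values, mask = sig$mask,
                 n_permutations = as.integer(n_iter),
                 fpr_alpha = fpr_alpha,
                 meta = list(min_cells = min_cells,
                             max_barcode_freq = max_barcode_freq,
                             diagonal = diagonal, seed = seed)),
            class = "convergence_matrix")
}

#' @export
print.convergence_matrix <- function(x, ...) {
  cat(sprintf("<convergence_matrix> %d subclasses, %d pairs observed, %d permutations\n",
              length(x$subclasses),
              sum(x$observed[upper.tri(x$observed, diag = TRUE)]),
              x$n_permutations))
  sig <- which(x$mask & upper.tri(x$mask, diag = TRUE), arr.ind = TRUE)
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s ~ %s: bias %.2f (p = %.3g)\n",
                  x$subclasses[sig[i, 1]], x$subclasses[sig[i, 2]],
                  x$bias[sig[i, 1], sig[i, 2]],
                  x$p_values[sig[i, 1], sig[i, 2]]))
  } else cat("  no significant pairs at the configured FPR\n")
  invisible(x)
}
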