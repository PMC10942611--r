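#' Group barcoded cells into barcode-sharing networks
#'
#' One network per barcode: its member cells, its source cells (role
#' `"source"`), and an observational class. A network is
#' `single_source` with exactly one source, `multi_source` with two or
#' more, `lost_source` with no source but at least
#' `min_cells_lost_source` members (a dead or missed source cell is the
#' likeliest explanation for a sizeable sourceless network), and
#' `no_source` otherwise (small sourceless networks arise from direct
#' infection of glycoprotein-negative cells).
#'
#' @param calls call table with roles from [classify_cell_roles()];
#'   excluded cells are dropped before grouping.
#' @param min_cells_lost_source size boundary separating lost-source from
#'   no-source networks (published value 5).
#' @return `data.table` of class `barcode_networks`: `barcode`,
#'   `n_cells`, `n_sources`, `network_class`, `member_cell_ids`,
#'   `source_cell_ids` (list columns).
#' @export
build_networks <- function(calls, min_cells_lost_source = 5L) {
  calls <- as.data.table(calls)
  stopifnot(all(c("cell_id", "barcode", "role") %in% names(calls)))
  calls <- calls[role != "excluded"]
  nets <- calls[, .(member_cell_ids = list(cell_id),
                    source_cell_ids = list(cell_id[role == "source"]),
                    n_cells = .N,
                    n_sources = sum(role == "source")),
                by = barcode]
  nets[, network_class := fifelse(
    n_sources == 1L, "single_source",
    fifelse(n_sources >= 2L, "multi_source",
            fifelse(n_cells >= min_cells_lost_source,
                    "lost_source", "no_source")))]
  setorder(nets, -n_cells, barcode)
  setattr(nets, "class", c("barcode_networks", class(nets)))
  nets[]
}

#' @export
print.barcode_networks <- function(x, ...) {
  cat(sprintf("<barcode_networks> %d networks, %d cells\n",
              nrow(x), length(unique(unlist(x$member_cell_ids)))))
  print(table(class = x$network_class))
  invisible(x)
}

#' Binomial barcode-multiplicity probability
#'
#' Probability that a barcode with library frequency `f` is involved in
#' at least `m_min` of `n_total` independent infection events:
#' `P(X >= m_min)` for `X ~ Binomial(n_total, f)`, evaluated on the
#' numerically stable upper tail. This is the model behind the size
#' distribution of no-source networks: in an experiment with 1000
#' events, a barcode at `f = 0.001` reaches 2 events with probability
#' 0.26 but 7 events with probability only 8e-5.
#'
#' @param f barcode frequency in the library.
#' @param n_total total number of independent infection events.
#' @param m_min event multiplicity of interest.
#' @return `P(X >= m_min)` (vectorized over `f`).
#' @examples
#' multiplicity_prob(0.001, 1000, 2)  # ~0.26
#' multiplicity_prob(0.001, 1000, 7)  # ~8e-5
#' @export
multiplicity_prob <- function(f, n_total, m_min) {
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]", call. = FALSE)
  assert_scalar_number(n_total, "n_total", 1)
  assert_scalar_number(m_min, "m_min", 0, n_total)
  if (m_min == 0) return(rep(1, length(f)))
  pbinom(m_min - 1, size = n_total, prob = f, lower.tail = FALSE)
}

#' Posterior over the number of independent infection events
#'
#' Observing `M` unique barcodes among the source cells of an experiment
#' is compatible with any number `N >= M` of independent infection
#' events, because abundant library barcodes collide. With a uniform
#' prior on `N` over `[M, C]` - `C` being the observed number of unique
#' source-cell/barcode combinations, the largest number of infections
#' the data admit - Bayes' rule gives
#' `P(N | M) \propto P(M | N)`, where `P(M | N)` is the probability that
#' `N` draws by library frequency yield exactly `M` distinct barcodes.
#' `P(M | N)` is estimated by Monte Carlo (`mc_reps` draws per support
#' point); for libraries of at most `exact_max` barcodes it is computed
#' exactly by inclusion-exclusion instead (the testing oracle).
#'
#' @param m_unique observed number of unique barcodes in source cells
#'   (`M`).
#' @param c_combinations observed number of unique source-cell/barcode
#'   combinations (`C`), the upper end of the prior support.
#' @param library a [barcode_library] giving barcode frequencies.
#' @param mc_reps Monte-Carlo replicates per support point.
#' @param seed integer seed.
#' @param exact_max libraries with at most this many barcodes use exact
#'   inclusion-exclusion enumeration.
#' @return list of class `infection_posterior`: `support`, `mass`,
#'   `mode`, `ci95` (central 95% interval), `m_unique`,
#'   `c_combinations`, `mc_reps`, `seed`.
#' @export
infection_posterior <- function(m_unique, c_combinations, library,
                                mc_reps = 2000L, seed = 1L,
                                exact_max = 12L) {
  assert_scalar_number(m_unique, "m_unique", 1)
  assert_scalar_number(c_combinations, "c_combinations", m_unique)
  stopifnot(is_barcode_library(library))
  support <- seq.int(m_unique, c_combinations)
  f <- library$records$frequency
  use_exact <- length(f) <= exact_max
  lik <- if (use_exact) {
    vapply(support, function(N) p_distinct_exact(f, N, m_unique), numeric(1))
  } else {
    with_seed(seed, vapply(support, function(N) {
      draws <- sample.int(length(f), N * mc_reps, replace = TRUE, prob = f)
      m <- matrix(draws, nrow = mc_reps)
      distinct <- vapply(seq_len(mc_reps),
                         function(i) length(unique(m[i, ])), integer(1))
      mean(distinct == m_unique)
    }, numeric(1)))
  }
  if (sum(lik) <= 0)
    stop("all-zero likelihood across the support; increase mc_reps",
         call. = FALSE)
  mass <- lik / sum(lik)
  mode <- support[which.max(mass)]
  cum <- cumsum(mass)
  ci95 <- c(support[which(cum >= 0.025)[1L]],
            support[which(cum >= 0.975)[1L]])
  structure(list(support = support, mass = mass, mode = mode,
                 ci95 = ci95, m_unique = as.integer(m_unique),
                 c_combinations = as.integer(c_combinations),
                 mc_reps = if (use_exact) 0L else as.integer(mc_reps),
                 exact = use_exact, seed = as.integer(seed)),
            class = "infection_posterior")
}

#' @export
print.infection_posterior <- function(x, ...) {
  cat(sprintf("<infection_posterior> M = %d, C = %d: mode %d, 95%% CI [%d, %d] (%s)\n",
              x$m_unique, x$c_combinations, x$mode, x$ci95[1], x$ci95[2],
              if (x$exact) "exact" else sprintf("MC x %d", x$mc_reps)))
  invisible(x)
}

## Exact P(exactly M distinct | N draws) for a small library by
## inclusion-exclusion over covered subsets: P(exactly S covered) =
## sum_{T subset S} (-1)^{|S|-|T|} p(T)^N. O(3^K); used for K <= ~12.
#' @noRd
p_distinct_exact <- function(p, N, M) {
  K <- length(p)
  if (M > K || M > N) return(0)
  n_mask <- bitwShiftL(1L, K)
  psum <- numeric(n_mask)
  bits <- integer(n_mask)
  for (mask in 0:(n_mask - 1L)) {
    s <- 0; b <- 0L; mm <- mask; i <- 1L
    while (mm > 0L) {
      if (mm %% 2L == 1L) { s <- s + p[i]; b <- b + 1L }
      mm <- mm %/% 2L; i <- i + 1L
    }
    psum[mask + 1L] <- s; bits[mask + 1L] <- b
  }
  total <- 0
  for (mask in which(bits == M) - 1L) {
    ## iterate submasks of `mask`
    sub <- mask
    acc <- 0
    repeat {
      sgn <- if ((M - bits[sub + 1L]) %% 2L == 0L) 1 else -1
      acc <- acc + sgn * psum[sub + 1L]^N
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, mask)
    }
    total <- total + acc
  }
  max(0, total)
}

#' Decompose the source-cell/barcode ledger
#'
#' Splits the observed unique source-cell/barcode combinations `C` into
#' three bookkeeping classes using the posterior mode `N^` of the number
#' of independent infections: barcodes seen in exactly one source cell
#' (`singles`), double-labeled pairs (`N^ - singles`: independent
#' infections that re-used a barcode), and connected-source pairs
#' (`C - N^`: combinations created by transsynaptic spread between
#' glycoprotein-expressing cells).
#'
#' @param networks a [build_networks()] table (its `n_sources` column
#'   supplies `singles`), or directly the integer count of single-source
#'   barcodes.
#' @param posterior an [infection_posterior] computed on the same source
#'   set, or a list with elements `mode` and `c_combinations` (e.g.
#'   published values).
#' @return list of class `ledger_decomposition` with `singles`,
#'   `est_independent_infections`, `est_double_labeled_pairs`,
#'   `est_connected_pairs`, `c_combinations`.
#' @export
decompose_ledger <- function(networks, posterior) {
  stopifnot(is.list(posterior), !is.null(posterior$mode),
            !is.null(posterior$c_combinations))
  singles <- if (inherits(networks, "data.frame"))
    sum(as.data.table(networks)$n_sources == 1L)
  else as.integer(networks)
  mode <- posterior$mode
  C <- posterior$c_combinations
  if (mode < singles)
    stop("posterior mode below the single-source count: model inconsistency",
         call. = FALSE)
  if (C < mode) stop("c_combinations below posterior mode", call. = FALSE)
  structure(list(singles = as.integer(singles),
                 est_independent_infections = as.integer(mode),
                 est_double_labeled_pairs = as.integer(mode - singles),
                 est_connected_pairs = as.integer(C - mode),
                 c_combinations = C),
            class = "ledger_decomposition")
}

#' @export
print.ledger_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<ledger_decomposition> C = %d combinations: ",
                     "%d single-source, est. %d double-labeled, ",
                     "est. %d connected-source\n"),
              x$c_combinations, x$singles, x$est_double_labeled_pairs,
              x$est_connected_pairs))
  invisible(x)
}

#' Fraction of large networks whose source cell was detected
#'
#' Restricts to barcodes that are confidently real (at least
#' `min_reads_per_cell` reads in some cell) and in networks large enough
#' to exclude most sourceless networks (at least `min_cells_per_barcode`
#' cells), then asks what fraction were found in a source cell with at
#' least `X` reads. Thresholding at `X = 10` underestimates and `X = 3`
#' overestimates source detection, so the pair brackets the truth.
#'
#' @param reads raw per-cell barcode reads (`cell_id`, `barcode`,
#'   `count`).
#' @param cells cell table with `g_count`.
#' @param min_cells_per_barcode,min_reads_per_cell qualification
#'   thresholds (published values 12 and 10).
#' @param source_read_thresholds the bracketing read thresholds `X`.
#' @param g_source_min glycoprotein threshold defining source cells.
#' @return named numeric vector `c(lower = ..., upper = ...)`: detected
#'   fractions at the stricter and looser threshold.
#' @export
source_detection_fraction <- function(reads, cells,
                                      min_cells_per_barcode = 12L,
                                      min_reads_per_cell = 10L,
                                      source_read_thresholds = c(10L, 3L),
                                      g_source_min = 2L) {
  stopifnot(all(source_read_thresholds > 0L))
  reads <- as.data.table(reads)
  cells <- as.data.table(cells)
  if (nrow(reads) == 0L) stop("no qualifying barcodes", call. = FALSE)
  reads[cells, g_count := i.g_count, on = "cell_id"]
  qual <- reads[, .(max_reads = max(count), n_cells_bc = .N), by = barcode][
    max_reads >= min_reads_per_cell & n_cells_bc >= min_cells_per_barcode]
  if (nrow(qual) == 0L) stop("no qualifying barcodes", call. = FALSE)
  sub <- reads[barcode %in% qual$barcode]
  sub[, is_source := !is.na(g_count) & g_count >= g_source_min]
  fr <- vapply(source_read_thresholds, function(X)
    mean(sub[, any(is_source & count >= X), by = barcode]$V1), numeric(1))
  c(lower = fr[1L], upper = fr[2L])
}

#' Single-infection barcode-frequency threshold
#'
#' Estimates, by simulation, (i) how many infection events were needed to
#' produce the observed number of distinct barcodes, and (ii) the largest
#' library frequency for which a barcode is still overwhelmingly likely
#' to stem from a single infection. Each replicate draws barcodes by
#' library frequency until `n_observed_barcodes` distinct ones have been
#' obtained, records the number of draws `N_r`, and solves for the
#' largest `f` with `P(X >= 2 | X >= 1) <= 1 - confidence` for
#' `X ~ Binomial(N_r, f)` (an unconditional variant
#' `P(X >= 2) <= 1 - confidence` is available). Medians over replicates
#' are returned.
#'
#' @param library a [barcode_library].
#' @param n_observed_barcodes number of distinct barcodes seen in the
#'   experiment.
#' @param confidence required single-infection probability (published:
#'   0.95).
#' @param reps simulation replicates (published: 10,000).
#' @param seed integer seed.
#' @param conditional if `TRUE` (default) use the conditional criterion
#'   `P(X >= 2 | X >= 1)`; if `FALSE`, the unconditional `P(X >= 2)`.
#' @return list with `freq_threshold`, `n_infections` (medians),
#'   and the per-replicate vectors `thresholds`, `draws`.
#' @export
single_infection_threshold <- function(library, n_observed_barcodes,
                                       confidence = 0.95, reps = 10000L,
                                       seed = 1L, conditional = TRUE) {
  stopifnot(is_barcode_library(library))
  assert_scalar_number(n_observed_barcodes, "n_observed_barcodes", 1)
  assert_fraction(confidence, "confidence")
  f <- library$records$frequency
  if (n_observed_barcodes > length(f))
    stop("library smaller than the number of observed barcodes", call. = FALSE)
  target <- as.integer(n_observed_barcodes)
  draws <- with_seed(seed, vapply(seq_len(reps), function(r) {
    got <- integer(0)
    n <- 0L
    block <- max(64L, 2L * target)
    repeat {
      d <- sample.int(length(f), block, replace = TRUE, prob = f)
      is_new <- !duplicated(c(got, d))[length(got) + seq_len(block)]
      hit <- which(length(got) + cumsum(is_new) >= target)
      if (length(hit)) return(n + hit[1L])
      got <- unique(c(got, d))
      n <- n + block
    }
  }, numeric(1)))
  alpha <- 1 - confidence
  thr_for_n <- function(N) {
    crit <- function(fv) {
      p1 <- pbinom(0, N, fv, lower.tail = FALSE)   # P(X >= 1)
      p2 <- pbinom(1, N, fv, lower.tail = FALSE)   # P(X >= 2)
      if (conditional) { if (p1 == 0) 0 else p2 / p1 } else p2
    }
    if (crit(1 - 1e-12) <= alpha) return(1)
    uniroot(function(fv) crit(fv) - alpha, c(1e-14, 1 - 1e-12),
            tol = 1e-12)$root
  }
  uniq_n <- sort(unique(draws))
  thr_map <- vapply(uniq_n, thr_for_n, numeric(1))
  thresholds <- thr_map[match(draws, uniq_n)]
  list(freq_threshold = median(thresholds),
       n_infections = median(draws),
       thresholds = thresholds, draws = draws)
}
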