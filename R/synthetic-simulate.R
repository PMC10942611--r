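#' Simulate a barcoded transsynaptic tracing experiment
#'
#' Generates a complete synthetic experiment under the generative model
#' the downstream inference assumes. `n_infections` primary infection
#' events draw barcodes i.i.d. by library frequency. With probability
#' `p_direct_infection` an event lands in a glycoprotein-negative cell
#' and goes no further (a no-source network). Otherwise it lands in a
#' TVA+/glycoprotein+ cell, which spreads its barcode to a
#' negative-binomial number of presynaptic bystander cells and, with
#' probability `p_intersource_connection` per other glycoprotein+ cell,
#' transsynaptically to connected candidate source cells; those secondary
#' sources spread further with a smaller expected network
#' (`secondary_scale * presyn_mean`). Infected glycoprotein+ cells die
#' with probability `p_source_death`; dead cells spread normally first
#' and are then removed from the emitted cell table, but their spread is
#' retained. Glycoprotein transcript counts are Poisson with a high mean
#' in glycoprotein-expressing cells and a leaky low mean elsewhere.
#' Finally, per-(cell, barcode) read counts are Poisson and reads pass
#' through [corrupt_reads()].
#'
#' @param config a [sim_config()].
#' @param library a [barcode_library]; typically from [sample_library()].
#' @param barcode_read_len emitted barcode read length; the default emits
#'   the full barcode, while 15 mimics sequencing only 15 of 20 bases.
#' @return A list of class `barnet_sim` with elements
#'   \describe{
#'     \item{cells}{`data.table` of surviving cells: `cell_id`,
#'       `slice_id`, `x_um`, `y_um`, `area`, `subclass`, `type`,
#'       `g_count`, `total_count`, `n_genes`.}
#'     \item{reads}{`data.table` of per-cell barcode reads: `cell_id`,
#'       `barcode`, `count` (after sequencing error).}
#'     \item{truth}{ground truth: `barcodes` (per-barcode network class
#'       under the five-class taxonomy and the expected observable
#'       four-class label, member/source cell ids), `cells` (true role
#'       per cell, death flag), and the raw `infections` ledger.}
#'   }
#' @seealso [simulate_retrograde()], [build_networks()]
#' @export
simulate_transsynaptic <- function(config, library,
                                   barcode_read_len = NULL) {
  stopifnot(inherits(config, "sim_config"), is_barcode_library(library))
  with_seed(config$seed, {
    cells <- simulate_cell_population(config)
    tva_ids <- cells$cell_id[cells$is_tva]
    by_ids <- cells$cell_id[!cells$is_tva]

    rec <- library$records
    n_inf <- config$n_infections
    ev <- data.table(
      event_id = seq_len(n_inf),
      barcode = rec$barcode[sample.int(nrow(rec), n_inf, replace = TRUE,
                                       prob = rec$frequency)],
      direct = runif(n_inf) < config$p_direct_infection)
    ev[, target := fifelse(direct,
                           sample(by_ids, n_inf, replace = TRUE),
                           sample(tva_ids, n_inf, replace = TRUE))]

    inf <- vector("list", 4L * n_inf)
    k <- 0L
    add <- function(cell, barcode, origin, event) {
      k <<- k + 1L
      inf[[k]] <<- data.table(cell_id = cell, barcode = barcode,
                              origin = origin, event_id = event)
    }
    spread_to_bystanders <- function(mu, exclude) {
      n <- rnbinom(1L, size = config$presyn_dispersion, mu = mu)
      n <- min(n, length(by_ids))
      if (n == 0L) return(character(0))
      sample(by_ids, n)
    }
    for (i in seq_len(n_inf)) {
      bc <- ev$barcode[i]
      tgt <- ev$target[i]
      if (ev$direct[i]) {
        add(tgt, bc, "direct", i)
        next
      }
      add(tgt, bc, "primary", i)
      pre <- spread_to_bystanders(config$presyn_mean, tgt)
      if (length(pre)) add(pre, bc, "presynaptic", i)
      n_partner <- rbinom(1L, max(0L, length(tva_ids) - 1L),
                          config$p_intersource_connection)
      if (n_partner > 0L) {
        partners <- sample(setdiff(tva_ids, tgt), n_partner)
        add(partners, bc, "intersource", i)
        for (p in partners) {
          ter <- spread_to_bystanders(
            config$secondary_scale * config$presyn_mean, p)
          if (length(ter)) add(ter, bc, "tertiary", i)
        }
      }
    }
    inf <- rbindlist(inf[seq_len(k)])
    ## one truth record per (cell, barcode); keep the strongest origin
    origin_rank <- c(primary = 1L, intersource = 2L, direct = 3L,
                     presynaptic = 4L, tertiary = 5L)
    inf[, rank := origin_rank[origin]]
    setorder(inf, cell_id, barcode, rank)
    infections <- inf[, .(origin = origin[1L],
                          event_id = event_id[1L]), by = .(cell_id, barcode)]

    ## source-cell death (per infected glycoprotein+ cell)
    src_cells <- unique(infections[origin %in% c("primary", "intersource"), cell_id])
    died <- src_cells[runif(length(src_cells)) < config$p_source_death]
    if (config$necrosis_spread && length(died)) {
      extra <- infections[cell_id %in% died & origin %in% c("primary", "intersource")]
      nec <- extra[, {
        n <- rpois(1L, 2)
        if (n > 0L) .(cell_id = sample(by_ids, min(n, length(by_ids)))) else
          .(cell_id = character(0))
      }, by = .(barcode)]
      if (nrow(nec)) {
        nec[, `:=`(origin = "necrosis", event_id = NA_integer_)]
        infections <- unique(rbindlist(list(infections, nec[, .(cell_id, barcode, origin, event_id)])),
                             by = c("cell_id", "barcode"))
      }
    }

    truth <- build_transsyn_truth(infections, died, tva_ids)
    cells[, g_count := fifelse(is_tva,
                               rpois(.N, config$g_count_source_mean),
                               rpois(.N, config$g_count_leak_mean))]
    cells_out <- cells[!cell_id %in% died]
    reads <- emit_reads(infections[!cell_id %in% died], config, library,
                        barcode_read_len)
    structure(list(cells = cells_out[, .(cell_id, slice_id, x_um, y_um, area,
                                         subclass, type, g_count, total_count,
                                         n_genes)],
                   reads = reads, truth = truth, config = config),
              class = "barnet_sim")
  })
}

## Shared cell-population scaffold: positions, labels, expression totals.
#' @noRd
simulate_cell_population <- function(config, areas = "SSp") {
  n <- config$n_tva_cells + config$n_bystander_cells
  props <- config$subclass_proportions
  subclass <- sample(names(props), n, replace = TRUE, prob = props)
  width <- 1100 * length(areas)
  x <- runif(n, 0, width)
  cells <- data.table(
    cell_id = sprintf("cell_%06d", seq_len(n)),
    slice_id = sprintf("slice_%02d", sample.int(config$n_slices, n, replace = TRUE)),
    x_um = x,
    y_um = runif(n, 0, 1100),
    area = areas[pmin(length(areas), 1L + floor(x / 1100))],
    subclass = subclass,
    type = paste0(subclass, "_", sample.int(2L, n, replace = TRUE)))
  cells[, total_count := rnbinom(.N, size = 5, mu = 200)]
  cells[, n_genes := pmin(total_count, rpois(.N, 30))]
  cells[, is_tva := seq_len(.N) %in% sample.int(.N, config$n_tva_cells)]
  cells
}

## Poisson read counts per retained (cell, barcode), then sequencing error.
#' @noRd
emit_reads <- function(infections, config, library, barcode_read_len) {
  reads <- infections[, .(cell_id, barcode)]
  reads[, count := rpois(.N, config$reads_per_barcode_mean)]
  reads <- reads[count > 0L]
  if (!is.null(barcode_read_len))
    reads[, barcode := substr(barcode, 1L, barcode_read_len)]
  corrupt_reads(reads, config$per_base_error,
                seed = child_seed(config$seed, 7L))
}

## Per-barcode network truth under the five-class taxonomy plus the
## expected observable four-class label.
#' @noRd
build_transsyn_truth <- function(infections, died, tva_ids) {
  bt <- infections[, {
    src <- cell_id[origin %in% c("primary", "intersource")]
    n_primary <- sum(origin == "primary")
    srv <- setdiff(src, died)
    gen <- if (length(src) == 0L) "no_source"
           else if (any(origin == "intersource")) "connected_source"
           else if (n_primary >= 2L) "double_labeled"
           else if (length(srv) == 0L) "lost_source"
           else "single_source"
    obs <- if (length(src) == 0L) "no_source"
           else if (length(srv) == 0L) "lost_source"
           else if (length(srv) == 1L) "single_source"
           else "multi_source"
    .(member_cell_ids = list(cell_id),
      source_cell_ids = list(src),
      surviving_source_ids = list(srv),
      n_primary_events = n_primary,
      n_events = length(unique(event_id[!is.na(event_id)])),
      class_generative = gen,
      class_observable = obs)
  }, by = barcode]
  roles <- infections[, {
    r <- if (any(origin %in% c("primary", "intersource"))) "source"
         else if (any(origin %in% c("presynaptic", "tertiary", "necrosis"))) "presynaptic"
         else "direct"
    .(true_role = r, true_barcodes = list(barcode))
  }, by = cell_id]
  roles[, died := cell_id %in% died]
  list(barcodes = bt, cells = roles, infections = infections)
}

#' Simulate a multiplexed retrograde labeling experiment
#'
#' Two barcoded libraries (with disjoint barcode sets) are injected into
#' two targets; each simulated cell is labeled by each library
#' independently with a probability depending on its (area, type), and a
#' labeled cell receives one barcode drawn by that library's frequency
#' distribution. Ground truth records the injecting library per barcode
#' and per cell.
#'
#' @param config a [sim_config()]; `n_bystander_cells` sets the
#'   population size.
#' @param libraries list of two [barcode_library] objects with disjoint
#'   barcode sets.
#' @param projection_probabilities `data.frame` with columns `area`,
#'   `type`, `prob` and optionally `library_id` (when absent, the same
#'   probabilities apply to both libraries). Missing (area, type)
#'   combinations have probability 0.
#' @param areas area labels tiling the simulated cortex mediolaterally.
#' @param barcode_read_len emitted barcode read length (see
#'   [simulate_transsynaptic()]).
#' @return list of class `barnet_sim` with `cells`, `reads`, `truth`
#'   (per-barcode injecting library; per-cell true label sets).
#' @export
simulate_retrograde <- function(config, libraries, projection_probabilities,
                                areas = c("VISp", "VISl", "TEa", "ECT"),
                                barcode_read_len = NULL) {
  stopifnot(inherits(config, "sim_config"), length(libraries) == 2L)
  lapply(libraries, function(l) stopifnot(is_barcode_library(l)))
  if (length(intersect(libraries[[1]]$records$barcode,
                       libraries[[2]]$records$barcode)) > 0L)
    stop("libraries must have disjoint barcode sets", call. = FALSE)
  pp <- as.data.table(projection_probabilities)
  if (!all(c("area", "type", "prob") %in% names(pp)))
    stop("projection_probabilities needs columns area, type, prob", call. = FALSE)
  with_seed(config$seed, {
    cfg <- config
    cfg$n_tva_cells <- 1L  # no TVA compartment in retrograde labeling
    cells <- simulate_cell_population(cfg, areas = areas)
    cells[, is_tva := NULL]
    cells <- cells[seq_len(min(.N, config$n_bystander_cells))]
    cells[, g_count := rpois(.N, config$g_count_leak_mean)]

    label_rows <- list()
    truth_bc <- list()
    for (li in seq_along(libraries)) {
      lib <- libraries[[li]]
      ppl <- if ("library_id" %in% names(pp)) pp[library_id == lib$library_id] else pp
      p <- ppl[cells, on = c("area", "type")]$prob
      p[is.na(p)] <- 0
      lab <- which(runif(nrow(cells)) < p)
      if (length(lab)) {
        rec <- lib$records
        bidx <- sample.int(nrow(rec), length(lab), replace = TRUE,
                           prob = rec$frequency)
        label_rows[[li]] <- data.table(cell_id = cells$cell_id[lab],
                                       barcode = rec$barcode[bidx],
                                       library_id = lib$library_id)
      }
      truth_bc[[li]] <- data.table(barcode = lib$records$barcode,
                                   library_id = lib$library_id)
    }
    labels <- rbindlist(label_rows)
    if (nrow(labels)) {
      reads <- labels[, .(cell_id, barcode)]
      reads[, count := 1L + rpois(.N, config$reads_per_barcode_mean - 1)]
      if (!is.null(barcode_read_len))
        reads[, barcode := substr(barcode, 1L, barcode_read_len)]
      reads <- corrupt_reads(reads, config$per_base_error,
                             seed = child_seed(config$seed, 11L))
    } else {
      reads <- data.table(cell_id = character(0), barcode = character(0),
                          count = integer(0))
    }
    truth <- list(
      barcode_library_map = rbindlist(truth_bc),
      cells = if (nrow(labels))
        labels[, .(true_targets = list(unique(library_id)),
                   true_barcodes = list(barcode)), by = cell_id]
      else data.table(cell_id = character(0)),
      labels = labels)
    structure(list(cells = cells[, .(cell_id, slice_id, x_um, y_um, area,
                                     subclass, type, g_count, total_count,
                                     n_genes)],
                   reads = reads, truth = truth, config = config),
              class = "barnet_sim")
  })
}

#' Apply per-base substitution errors to barcode reads
#'
#' Models sequencing and viral-mutation noise: every base of every read is
#' substituted independently with probability `per_base_error`, to one of
#' the three other bases. Read counts are preserved (a corrupted read
#' moves count from its true barcode to the mutated sequence).
#'
#' @param reads `data.table` with columns `cell_id`, `barcode`, `count`.
#'   All barcodes must share one length.
#' @param per_base_error per-base substitution probability in \[0, 1\].
#' @param seed integer seed; the same seed gives identical output.
#' @return `data.table` with the same columns, aggregated by
#'   (cell, observed barcode).
#' @export
corrupt_reads <- function(reads, per_base_error, seed) {
  assert_fraction(per_base_error, "per_base_error")
  reads <- as.data.table(reads)
  stopifnot(all(c("cell_id", "barcode", "count") %in% names(reads)))
  if (nrow(reads) == 0L || per_base_error == 0) return(copy(reads))
  L <- unique(nchar(reads$barcode))
  if (length(L) != 1L) stop("barcodes must share one length", call. = FALSE)
  with_seed(seed, {
    p_any <- 1 - (1 - per_base_error)^L
    n_mut <- rbinom(nrow(reads), reads$count, p_any)
    keep <- copy(reads)[, count := count - n_mut][count > 0L]
    rows <- rep.int(seq_len(nrow(reads)), n_mut)
    if (length(rows)) {
      ## per corrupted read: number of substitutions ~ Binomial(L, e) | >= 1
      pm <- dbinom(seq_len(L), L, per_base_error)
      m <- sample.int(L, length(rows), replace = TRUE, prob = pm)
      seqs <- strsplit(reads$barcode[rows], "", fixed = TRUE)
      mut <- vapply(seq_along(rows), function(j) {
        s <- seqs[[j]]
        pos <- sample.int(L, m[j])
        cur <- match(s[pos], DNA_BASES)
        s[pos] <- DNA_BASES[((cur - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L]
        paste(s, collapse = "")
      }, character(1))
      mutated <- data.table(cell_id = reads$cell_id[rows], barcode = mut,
                            count = 1L)
      keep <- rbindlist(list(keep, mutated))
    }
    out <- keep[, .(count = sum(count)), by = .(cell_id, barcode)]
    setorder(out, cell_id, barcode)
    out[]
  })
}

#' Bin cells into synthetic cubelets
#'
#' Helper for simulated retrograde data only: real cubelets are drawn by
#' hand on tissue sections, so cubelet membership is normally an input.
#' This bins cells into ~`width_um`-wide mediolateral bins within each
#' slice, mimicking that parcellation.
#'
#' @param cells cell table with `slice_id` and `x_um`.
#' @param width_um cubelet width along the mediolateral axis.
#' @return `data.table` with `cell_id`, `cubelet_id`, `area`.
#' @export
assign_cubelets <- function(cells, width_um = 110) {
  cells <- as.data.table(cells)
  out <- cells[, .(cell_id, area,
                   cubelet_id = sprintf("%s_cub%03d", slice_id,
                                        as.integer(floor(x_um / width_um))))]
  out[]
}

#' Write a simulated experiment to plain-text files
#'
#' Emits `cells.tsv`, `barcode_reads.tsv` and `truth.json` into a
#' directory, the on-disk interface consumed by the command-line entry
#' point.
#'
#' @param sim result of [simulate_transsynaptic()] or
#'   [simulate_retrograde()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "barnet_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(sim$cells, file.path(dir, "cells.tsv"), sep = "\t")
  fwrite(sim$reads, file.path(dir, "barcode_reads.tsv"), sep = "\t")
  truth <- rapply(sim$truth, f = function(x) x, how = "replace")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
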