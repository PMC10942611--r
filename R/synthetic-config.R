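#' Configuration for synthetic tracing experiments
#'
#' Collects every tunable of the generative model with defaults anchored
#' to the published transsynaptic experiment: a highly skewed library
#' (13,211 barcodes, log-normal sigma = 2 so that the top ~14% of barcodes
#' carry ~82% of the mass), ~600 infection events of which ~3/4 are
#' glycoprotein-independent direct infections, ~50% source-cell death,
#' presynaptic network sizes that are negative-binomial with mean 12 and
#' standard deviation 14, and a leaky low-expression mode for the
#' glycoprotein transcript in non-source cells.
#'
#' @param seed integer master seed; all randomness in the simulators
#'   derives from it.
#' @param n_library_barcodes number of barcodes in the virus library.
#' @param library_skew_sigma log-normal dispersion of barcode abundances
#'   (0 = perfectly uniform library).
#' @param n_tva_cells number of TVA+/glycoprotein-expressing cells
#'   (candidate source cells).
#' @param n_bystander_cells number of glycoprotein-negative cells that can
#'   be infected transsynaptically or directly.
#' @param n_infections true number of independent primary infection
#'   events (`N_true`).
#' @param p_source_death probability that an infected glycoprotein+ cell
#'   dies before sequencing.
#' @param p_direct_infection per-event probability that an infection lands
#'   in a glycoprotein-negative cell, seeding a no-source network.
#' @param presyn_mean,presyn_dispersion mean and negative-binomial size
#'   parameter of the presynaptic network size. The defaults reproduce
#'   the observed 12 +/- 14 cells-per-barcode regime
#'   (`size = 12^2 / (14^2 - 12)`).
#' @param secondary_scale factor (< 1) applied to `presyn_mean` for
#'   tertiary spread from a transsynaptically labeled source cell.
#' @param p_intersource_connection probability that a given source cell is
#'   connected to (and infects) a given other glycoprotein+ cell.
#' @param subclass_proportions named numeric vector summing to 1: cortical
#'   subclass composition of the simulated cells.
#' @param g_count_source_mean Poisson mean of glycoprotein transcript
#'   counts in glycoprotein-expressing cells.
#' @param g_count_leak_mean Poisson mean of the leaky low-expression mode
#'   in glycoprotein-negative cells.
#' @param per_base_error per-base substitution probability applied to
#'   emitted barcode reads.
#' @param reads_per_barcode_mean Poisson mean of read counts per (cell,
#'   barcode); draws of zero are dropouts.
#' @param necrosis_spread logical; if `TRUE`, dying source cells
#'   additionally spread their barcode to a small number of neighbors
#'   (off by default).
#' @param n_slices number of simulated coronal sections.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_transsynaptic()], [simulate_retrograde()],
#'   [sample_library()]
#' @export
sim_config <- function(seed = 1L,
                       n_library_barcodes = 13211L,
                       library_skew_sigma = 2,
                       n_tva_cells = 300L,
                       n_bystander_cells = 6000L,
                       n_infections = 600L,
                       p_source_death = 0.5,
                       p_direct_infection = 0.75,
                       presyn_mean = 12,
                       presyn_dispersion = 12^2 / (14^2 - 12),
                       secondary_scale = 0.5,
                       p_intersource_connection = 0.0022,
                       subclass_proportions = default_subclass_proportions(),
                       g_count_source_mean = 8,
                       g_count_leak_mean = 0.07,
                       per_base_error = 0.01,
                       reads_per_barcode_mean = 40,
                       necrosis_spread = FALSE,
                       n_slices = 8L) {
  assert_scalar_number(n_library_barcodes, "n_library_barcodes", 1)
  assert_scalar_number(library_skew_sigma, "library_skew_sigma", 0)
  assert_scalar_number(n_tva_cells, "n_tva_cells", 1)
  assert_scalar_number(n_bystander_cells, "n_bystander_cells", 1)
  assert_scalar_number(n_infections, "n_infections", 1)
  assert_fraction(p_source_death, "p_source_death")
  assert_fraction(p_direct_infection, "p_direct_infection")
  assert_fraction(p_intersource_connection, "p_intersource_connection")
  assert_scalar_number(presyn_mean, "presyn_mean", 1e-12)
  assert_scalar_number(presyn_dispersion, "presyn_dispersion", 1e-12)
  assert_scalar_number(secondary_scale, "secondary_scale", 0, 1)
  assert_scalar_number(g_count_source_mean, "g_count_source_mean", 0)
  assert_scalar_number(g_count_leak_mean, "g_count_leak_mean", 0)
  assert_fraction(per_base_error, "per_base_error")
  assert_scalar_number(reads_per_barcode_mean, "reads_per_barcode_mean", 1e-12)
  if (is.null(names(subclass_proportions)) ||
      abs(sum(subclass_proportions) - 1) > 1e-6 ||
      any(subclass_proportions < 0))
    stop("`subclass_proportions` must be a named non-negative vector summing to 1",
         call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_library_barcodes = as.integer(n_library_barcodes),
              library_skew_sigma = library_skew_sigma,
              n_tva_cells = as.integer(n_tva_cells),
              n_bystander_cells = as.integer(n_bystander_cells),
              n_infections = as.integer(n_infections),
              p_source_death = p_source_death,
              p_direct_infection = p_direct_infection,
              presyn_mean = presyn_mean,
              presyn_dispersion = presyn_dispersion,
              secondary_scale = secondary_scale,
              p_intersource_connection = p_intersource_connection,
              subclass_proportions = subclass_proportions,
              g_count_source_mean = g_count_source_mean,
              g_count_leak_mean = g_count_leak_mean,
              per_base_error = per_base_error,
              reads_per_barcode_mean = reads_per_barcode_mean,
              necrosis_spread = isTRUE(necrosis_spread),
              n_slices = as.integer(n_slices))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in setdiff(names(x), "subclass_proportions"))
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  cat(sprintf("  %-26s %s\n", "subclass_proportions",
              paste(names(x$subclass_proportions), collapse = ", ")))
  invisible(x)
}

#' Default cortical subclass composition
#'
#' Rough proportions of excitatory and inhibitory subclasses in sensory
#' cortex, used by the generators when no composition is supplied.
#'
#' @return named numeric vector summing to 1.
#' @export
default_subclass_proportions <- function() {
  c("L2/3 IT" = 0.20, "L4/5 IT" = 0.15, "L5 IT" = 0.15, "L6 IT" = 0.10,
    "L5 ET" = 0.05, "L6 CT" = 0.10, "NP" = 0.04,
    "Lamp5" = 0.05, "Pvalb" = 0.06, "Sst" = 0.06, "Vip" = 0.04)
}
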