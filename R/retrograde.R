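#' Assign projection targets from library-matched barcodes
#'
#' Each cell projects to the injection site(s) whose library its
#' barcode(s) match (via [match_to_libraries()]). A cell carrying
#' barcodes from both libraries is dual-projecting; unmatched or
#' ambiguous barcodes carry no target but keep their reason.
#'
#' @param calls call table (`cell_id`, `barcode`; from
#'   [call_cell_barcodes()] or any per-cell barcode table).
#' @param libraries list of [barcode_library] objects with disjoint
#'   barcodes.
#' @param site_map named character vector mapping `library_id` to an
#'   injection-site label; must cover every library.
#' @param max_mismatch,prefix_len matching parameters, see
#'   [match_to_libraries()].
#' @return list of class `projection_assignment` with
#'   `assignments` (`data.table`: `cell_id`, `barcode`, `assignment`,
#'   `target`, per-library distance columns) and `targets_by_cell`
#'   (`data.table`: `cell_id`, `targets` list column).
#' @export
assign_projections <- function(calls, libraries, site_map,
                               max_mismatch = 1L, prefix_len = 15L) {
  calls <- as.data.table(calls)
  ids <- vapply(libraries, `[[`, character(1), "library_id")
  if (!all(ids %in% names(site_map)))
    stop("site_map must name every library_id", call. = FALSE)
  if (length(intersect(libraries[[1]]$records$barcode,
                       if (length(libraries) > 1) libraries[[2]]$records$barcode else character(0))))
    stop("libraries must be disjoint", call. = FALSE)
  ub <- unique(calls$barcode)
  matched <- match_to_libraries(ub, libraries, max_mismatch, prefix_len)
  out <- merge(calls[, .(cell_id, barcode)], matched, by = "barcode",
               sort = FALSE)
  out[, target := fifelse(assignment %in% ids,
                          unname(site_map[assignment]), NA_character_)]
  setcolorder(out, c("cell_id", "barcode", "assignment", "target"))
  targets <- out[!is.na(target),
                 .(targets = list(sort(unique(target)))), by = cell_id]
  structure(list(assignments = out[], targets_by_cell = targets),
            class = "projection_assignment")
}

#' @export
print.projection_assignment <- function(x, ...) {
  tab <- table(x$assignments$assignment)
  cat("<projection_assignment>\n")
  for (nm in names(tab)) cat(sprintf("  %-12s %d barcode calls\n", nm, tab[[nm]]))
  n_multi <- sum(vapply(x$targets_by_cell$targets, length, integer(1)) >= 2L)
  cat(sprintf("  %d cells with targets, %d dual-projecting\n",
              nrow(x$targets_by_cell), n_multi))
  invisible(x)
}

#' Area-by-subclass projection count matrices
#'
#' Cross-tabulates projecting cells by (area, subclass) for each
#' injection site. Dual-projecting cells count once per target.
#'
#' @param assignments a [assign_projections()] result.
#' @param cells cell table with `cell_id`, `area`, `subclass`.
#' @return named list (one element per target) of count matrices with
#'   areas as rows and subclasses as columns; each has `marginals`
#'   attribute `list(area =, subclass =, total =)`.
#' @export
projection_matrix <- function(assignments, cells) {
  stopifnot(inherits(assignments, "projection_assignment"))
  cells <- as.data.table(cells)
  tb <- assignments$targets_by_cell
  if (nrow(tb) == 0L) {
    return(structure(list(), names = character(0)))
  }
  long <- tb[, .(target = targets[[1L]]), by = cell_id]
  long[cells, `:=`(area = i.area, subclass = i.subclass), on = "cell_id"]
  areas <- sort(unique(cells$area))
  subs <- sort(unique(cells$subclass))
  lapply(split(long, by = "target", sorted = TRUE), function(sd) {
    m <- table(factor(sd$area, areas), factor(sd$subclass, subs))
    m <- unclass(m)
    attr(m, "marginals") <- list(area = rowSums(m), subclass = colSums(m),
                                 total = sum(m))
    m
  })
}

#' Cubelet-level projection probabilities
#'
#' For a given injection site, the projection probability of cell type
#' `t` in cubelet `c` is the fraction of type-`t` cells in that cubelet
#' assigned to the target. Entries with no type-`t` cells are undefined
#' (`NaN`) and excluded from all downstream sums, not imputed as zero.
#'
#' @param cells QC-passed cell table (`cell_id`, `type`).
#' @param assignments a [assign_projections()] result.
#' @param cubelet_labels `data.table`/`data.frame` mapping `cell_id` to
#'   `cubelet_id` (and optionally `area`); see [assign_cubelets()].
#' @param target the injection-site label analysed.
#' @return list of class `cubelet_matrix`: `P` (cubelets x types
#'   probability matrix with `NaN` where undefined), `counts`
#'   (denominators), `n_projecting`, `cubelets` (`data.table` with
#'   `cubelet_id`, `area` when supplied).
#' @export
cubelet_probabilities <- function(cells, assignments, cubelet_labels,
                                  target) {
  stopifnot(inherits(assignments, "projection_assignment"))
  cells <- as.data.table(cells)
  cub <- as.data.table(cubelet_labels)
  stopifnot(all(c("cell_id", "cubelet_id") %in% names(cub)))
  dt <- merge(cells[, .(cell_id, type)], cub, by = "cell_id")
  proj_cells <- assignments$targets_by_cell[
    vapply(targets, function(t) target %in% t, logical(1)), cell_id]
  dt[, proj := cell_id %in% proj_cells]
  cubs <- sort(unique(dt$cubelet_id))
  types <- sort(unique(dt$type))
  fc <- factor(dt$cubelet_id, cubs)
  ft <- factor(dt$type, types)
  n <- unclass(table(fc, ft))
  np <- unclass(table(fc[dt$proj], ft[dt$proj]))
  dimnames(n) <- dimnames(np) <- list(cubs, types)
  P <- np / n   # 0/0 -> NaN marks undefined entries
  meta <- if ("area" %in% names(cub))
    unique(cub[, .(cubelet_id, area)])[order(cubelet_id)]
  else data.table(cubelet_id = cubs)
  structure(list(P = P, counts = n, n_projecting = np,
                 cubelets = meta, target = target),
            class = "cubelet_matrix")
}

#' Variance decomposition of cubelet projection probabilities
#'
#' Decomposes the variability of `P_ct` (projection probability of type
#' `t` in cubelet `c`) into the parts explained by area, subclass, type,
#' and type-within-area. With `M` the grand mean over all defined
#' entries and `TV = sum (P_ct - M)^2` the total variance, each
#' component is an unweighted sum of squared deviations of group means:
#' for example `VE_area = sum_a (mean_{c in a, t} P_ct - M)^2 / TV` and
#' `VE_{type,area} = sum_{t,a} (mean_{c in a} P_ct - M)^2 / TV`.
#' A consequence of the unweighted convention is that a probability
#' depending on type alone gives `VE_type = 1 / n_cubelets`, not 1; a
#' size-weighted one-way-ANOVA variant (`mode = "weighted"`) is provided
#' for sensitivity analysis. Significance of the type-by-area component
#' comes from recomputing it with area labels shuffled across cubelets.
#' By default the p-value is the empirical two-sided permutation
#' p (twice the fraction of shuffles at least as extreme as the
#' observation, clipped at 1), which is calibrated under the null;
#' `test = "t"` instead applies a two-tailed one-sample t-test of the
#' shuffled sample against the observed value, which is the historical
#' formulation but becomes anti-conservative as the number of shuffles
#' grows.
#'
#' @param P a `cubelet_matrix` or a plain cubelets-by-types numeric
#'   matrix (`NaN`/`NA` entries are undefined and excluded).
#' @param area_of_cubelet named character vector mapping cubelet ids to
#'   area labels (taken from the `cubelet_matrix` metadata when absent).
#' @param subclass_of_type named character vector mapping type labels to
#'   subclass labels; defaults to stripping a `_<n>` suffix.
#' @param n_shuffles shuffled-area iterations (published: 100).
#' @param seed integer seed.
#' @param mode `"printed"` (unweighted group sums, default) or
#'   `"weighted"` (group sums weighted by group size).
#' @param test `"empirical"` (calibrated permutation p-value, default) or
#'   `"t"` (one-sample t-test of the shuffled sample against the
#'   observation).
#' @return list of class `variance_decomposition`: `grand_mean`,
#'   `total_variance`, `ve_area`, `ve_subclass`, `ve_type`,
#'   `ve_type_area`, `shuffled_ve`, `p_value`, `mode`, `test`.
#' @export
variance_explained <- function(P, area_of_cubelet = NULL,
                               subclass_of_type = NULL, n_shuffles = 100L,
                               seed = 1L, mode = c("printed", "weighted"),
                               test = c("empirical", "t")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (inherits(P, "cubelet_matrix")) {
    if (is.null(area_of_cubelet) && "area" %in% names(P$cubelets))
      area_of_cubelet <- setNames(P$cubelets$area, P$cubelets$cubelet_id)
    P <- P$P
  }
  stopifnot(is.matrix(P), nrow(P) >= 2L, ncol(P) >= 2L)
  if (is.null(area_of_cubelet))
    stop("area_of_cubelet is required", call. = FALSE)
  areas <- unname(area_of_cubelet[rownames(P)])
  if (anyNA(areas)) stop("area label missing for some cubelets", call. = FALSE)
  if (is.null(subclass_of_type))
    subclass_of_type <- setNames(sub("_[0-9]+$", "", colnames(P)), colnames(P))
  subs <- unname(subclass_of_type[colnames(P)])
  def <- is.finite(P)
  M <- mean(P[def])
  TV <- sum((P[def] - M)^2)
  if (TV <= 0) stop("no variance to decompose", call. = FALSE)
  group_sum <- function(groups_row, groups_col) {
    ## groups_row / groups_col: factor per row / col or NULL (= pooled)
    gr <- if (is.null(groups_row)) rep("all", nrow(P)) else groups_row
    gc_ <- if (is.null(groups_col)) rep("all", ncol(P)) else groups_col
    key <- outer(gr, gc_, paste, sep = "\r")
    ve <- 0
    for (kk in unique(key[def])) {
      sel <- def & key == kk
      mu <- mean(P[sel])
      w <- if (mode == "weighted") sum(sel) else 1
      ve <- ve + w * (mu - M)^2
    }
    ve / TV
  }
  ve_area <- group_sum(areas, NULL)
  ve_subclass <- group_sum(NULL, subs)
  ve_type <- group_sum(NULL, colnames(P))
  ve_type_area <- group_sum(areas, colnames(P))
  shuffled <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    group_sum(sample(areas), colnames(P))
  }, numeric(1)))
  p <- if (test == "t") {
    if (sd(shuffled) == 0) {
      if (isTRUE(all.equal(mean(shuffled), ve_type_area))) 1 else 0
    } else t.test(shuffled, mu = ve_type_area)$p.value
  } else {
    min(1, 2 * min(mean(shuffled >= ve_type_area),
                   mean(shuffled <= ve_type_area)))
  }
  structure(list(grand_mean = M, total_variance = TV,
                 ve_area = ve_area, ve_subclass = ve_subclass,
                 ve_type = ve_type, ve_type_area = ve_type_area,
                 shuffled_ve = shuffled, p_value = p, mode = mode,
                 test = test, n_shuffles = as.integer(n_shuffles),
                 seed = as.integer(seed)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<variance_decomposition> (%s) M = %.4f, TV = %.4f\n",
                     "  VE area %.3f | subclass %.3f | type %.3f | ",
                     "type,area %.3f (shuffled %.3f +/- %.3f; p = %.3g)\n"),
              x$mode, x$grand_mean, x$total_variance, x$ve_area,
              x$ve_subclass, x$ve_type, x$ve_type_area,
              mean(x$shuffled_ve), sd(x$shuffled_ve), x$p_value))
  invisible(x)
}

#' Shuffled-area significance of the type-by-area component
#'
#' Permutes area labels across cubelets, recomputes the type-by-area
#' variance-explained each iteration, and returns a two-sided p-value of
#' the observed statistic against the shuffled sample (see
#' [variance_explained()] for the `test` conventions).
#'
#' @inheritParams variance_explained
#' @param n_iter shuffles.
#' @return the p-value.
#' @export
shuffled_area_test <- function(P, area_of_cubelet = NULL,
                               subclass_of_type = NULL, n_iter = 100L,
                               seed = 1L, test = "empirical") {
  if (inherits(P, "cubelet_matrix") && is.null(area_of_cubelet) &&
      "area" %in% names(P$cubelets))
    area_of_cubelet <- setNames(P$cubelets$area, P$cubelets$cubelet_id)
  if (length(unique(unname(area_of_cubelet))) < 2L)
    stop("need >= 2 distinct areas", call. = FALSE)
  vd <- variance_explained(P, area_of_cubelet, subclass_of_type,
                           n_shuffles = n_iter, seed = seed, test = test)
  vd$p_value
}

#' False-positive-rate point estimate and upper bound
#'
#' `FPR = FP / (FP + TN)`. When no false positive is observed the true
#' count plausibly lies between 0 and 1, so `(1 + FP) / (FP + TN)` is
#' reported as an upper bound (with `FP = 0`, `TN = 32`: 1/32 = 3.1%).
#'
#' @param fp number of false-positive detections.
#' @param tn number of true-negative detections.
#' @return list of class `fpr_estimate`: `fp`, `tn`, `fpr`,
#'   `upper_bound`.
#' @export
fpr_upper_bound <- function(fp, tn) {
  assert_scalar_number(fp, "fp", 0)
  assert_scalar_number(tn, "tn", 0)
  if (fp + tn < 1) stop("fp + tn must be >= 1", call. = FALSE)
  structure(list(fp = as.integer(fp), tn = as.integer(tn),
                 fpr = fp / (fp + tn),
                 upper_bound = (1 + fp) / (fp + tn)),
            class = "fpr_estimate")
}

#' @export
print.fpr_estimate <- function(x, ...) {
  cat(sprintf("<fpr_estimate> FP = %d, TN = %d: FPR = %.3g (upper bound %.3g)\n",
              x$fp, x$tn, x$fpr, x$upper_bound))
  invisible(x)
}
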