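test_that("assign_projections maps barcodes to sites, including dual targets", {
  set.seed(1)
  bcA <- rand_bc(4); bcB <- rand_bc(4)
  libA <- toy_library(bcA, library_id = "A")
  libB <- toy_library(bcB, library_id = "B")
  sites <- c(A = "VISal", B = "SC/RSP")
  calls <- data.table(cell_id = c("c1", "c2", "c2", "c3"),
                      barcode = c(bcA[1], bcA[2], bcB[1], rand_bc(1)))
  pa <- assign_projections(calls, list(libA, libB), sites)
  expect_equal(pa$assignments[cell_id == "c1", target], "VISal")
  ## c2 carries barcodes from both libraries -> dual-projecting
  t2 <- pa$targets_by_cell[cell_id == "c2", targets][[1]]
  expect_equal(t2, sort(c("VISal", "SC/RSP")))
  ## unmatched barcode: no target, reason retained
  expect_equal(pa$assignments[cell_id == "c3", assignment], "unmatched")
  expect_false("c3" %in% pa$targets_by_cell$cell_id)
})

test_that("zero-error synthetic retrograde assignments equal ground truth", {
  libA <- sample_library(300, 1, seed = 2, library_id = "A")
  libB <- sample_library(300, 1, seed = 3, library_id = "B")
  cfg <- sim_config(seed = 4, n_bystander_cells = 2000L, per_base_error = 0)
  types <- unique(paste0(rep(names(cfg$subclass_proportions), each = 2), "_", 1:2))
  pp <- expand.grid(area = c("VISp", "VISl", "TEa", "ECT"), type = types,
                    stringsAsFactors = FALSE)
  pp$prob <- 0.2
  sim <- simulate_retrograde(cfg, list(libA, libB), pp)
  pa <- assign_projections(sim$reads, list(libA, libB),
                           c(A = "siteA", B = "siteB"))
  truth <- sim$truth$labels[, .(want = list(sort(unique(
    ifelse(library_id == "A", "siteA", "siteB"))))), by = cell_id]
  got <- pa$targets_by_cell
  m <- merge(truth, got, by = "cell_id")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(mapply(identical, m$want, m$targets)))
  ## dual-projecting cells are exactly the truth dual-labeled cells
  dual_truth <- truth[lengths(want) == 2L, cell_id]
  dual_got <- got[lengths(targets) == 2L, cell_id]
  expect_equal(sort(dual_got), sort(dual_truth))
})

test_that("projection_matrix cross-tabulates with conserved marginals", {
  set.seed(5)
  bcA <- rand_bc(3)
  libA <- toy_library(bcA, library_id = "A")
  cells <- toy_cells(c("c1", "c2", "c3"),
                     subclass = c("L5 IT", "L5 IT", "L6 CT"),
                     area = c("VISp", "VISl", "VISp"))
  calls <- data.table(cell_id = c("c1", "c2", "c3"), barcode = bcA)
  pa <- assign_projections(calls, list(libA), c(A = "target1"))
  pm <- projection_matrix(pa, cells)
  m <- pm[["target1"]]
  expect_equal(sum(m), 3)
  expect_equal(m["VISp", "L5 IT"], 1)
  marg <- attr(m, "marginals")
  expect_equal(sum(marg$area), marg$total)
  expect_equal(sum(marg$subclass), marg$total)

  ## no assignments -> empty result list
  none <- assign_projections(data.table(cell_id = "c1", barcode = rand_bc(1)),
                             list(libA), c(A = "target1"))
  expect_length(projection_matrix(none, cells), 0L)
})

test_that("cubelet probabilities are fractions with undefined cells excluded", {
  set.seed(6)
  bc <- rand_bc(5)
  lib <- toy_library(bc, library_id = "A")
  ids <- sprintf("c%02d", 1:9)
  cells <- toy_cells(ids, type = c(rep("t1", 8), "t2"))
  cub <- data.table(cell_id = ids,
                    cubelet_id = c(rep("cub1", 4), rep("cub2", 4), "cub2"),
                    area = c(rep("VISp", 4), rep("VISl", 5)))
  ## cub1: 4 t1 cells, 1 projecting; cub2: 4 t1 cells, all projecting
  calls <- data.table(cell_id = c("c01", "c05", "c06", "c07", "c08"),
                      barcode = bc[1:5])
  pa <- assign_projections(calls, list(lib), c(A = "tgt"))
  cm <- cubelet_probabilities(cells, pa, cub, target = "tgt")
  expect_equal(cm$P["cub1", "t1"], 0.25)
  expect_equal(cm$P["cub2", "t1"], 1)
  expect_true(is.nan(cm$P["cub1", "t2"]))   # no t2 cells in cub1
  expect_equal(cm$counts["cub1", "t2"], 0L)
})

test_that("variance_explained matches a literal re-evaluation of the formulas", {
  set.seed(7)
  n_cub <- 20L; n_type <- 5L
  P <- matrix(runif(n_cub * n_type), n_cub, n_type,
              dimnames = list(sprintf("cub%02d", 1:n_cub),
                              c("a_1", "a_2", "b_1", "b_2", "c_1")))
  areas <- setNames(rep(c("A1", "A2", "A3", "A4"), each = 5), rownames(P))
  vd <- variance_explained(P, areas, n_shuffles = 10, seed = 8)

  ## independent literal evaluation (naive loops over the group sums)
  M <- mean(P)
  TV <- sum((P - M)^2)
  subs <- sub("_[0-9]+$", "", colnames(P))
  ve_area <- 0
  for (a in unique(areas))
    ve_area <- ve_area + (mean(P[areas == a, ]) - M)^2
  ve_sub <- 0
  for (h in unique(subs))
    ve_sub <- ve_sub + (mean(P[, subs == h]) - M)^2
  ve_type <- 0
  for (t in colnames(P))
    ve_type <- ve_type + (mean(P[, t]) - M)^2
  ve_ta <- 0
  for (t in colnames(P)) for (a in unique(areas))
    ve_ta <- ve_ta + (mean(P[areas == a, t]) - M)^2
  expect_equal(vd$grand_mean, M, tolerance = 1e-12)
  expect_equal(vd$total_variance, TV, tolerance = 1e-12)
  expect_equal(vd$ve_area, ve_area / TV, tolerance = 1e-12)
  expect_equal(vd$ve_subclass, ve_sub / TV, tolerance = 1e-12)
  expect_equal(vd$ve_type, ve_type / TV, tolerance = 1e-12)
  expect_equal(vd$ve_type_area, ve_ta / TV, tolerance = 1e-12)
})

test_that("type-only probabilities give ve_type = 1 / n_cubelets exactly", {
  g <- c(a_1 = 0.1, a_2 = 0.4, b_1 = 0.7, b_2 = 0.2)
  P <- matrix(rep(g, each = 12), 12, 4,
              dimnames = list(sprintf("cub%02d", 1:12), names(g)))
  areas <- setNames(rep(c("A1", "A2", "A3"), each = 4), rownames(P))
  vd <- variance_explained(P, areas, n_shuffles = 5, seed = 9)
  expect_equal(vd$ve_type, 1 / 12, tolerance = 1e-12)
  ## the weighted variant restores ve_type = 1 in this case
  vdw <- variance_explained(P, areas, n_shuffles = 5, seed = 9,
                            mode = "weighted")
  expect_equal(vdw$ve_type, 1, tolerance = 1e-12)

  ## constant P: no variance to decompose
  expect_error(variance_explained(matrix(0.5, 4, 3,
                 dimnames = list(paste0("c", 1:4), paste0("t", 1:3))),
               setNames(rep(c("A", "B"), 2), paste0("c", 1:4))),
               "no variance")
})

test_that("undefined entries are excluded, not imputed", {
  P <- matrix(c(0.2, NaN, 0.4, 0.6, 0.8, NaN), 3, 2,
              dimnames = list(c("c1", "c2", "c3"), c("t1", "t2")))
  areas <- c(c1 = "A", c2 = "A", c3 = "B")
  vd <- variance_explained(P, areas, n_shuffles = 5, seed = 10)
  def <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(vd$grand_mean, mean(def))
  expect_equal(vd$total_variance, sum((def - mean(def))^2))
})

test_that("shuffled-area test: deterministic, calibrated, and powered", {
  set.seed(11)
  ## null: P independent of area
  n_null_pass <- 0L
  for (i in 1:20) {
    P <- matrix(runif(60), 12, 5,
                dimnames = list(sprintf("c%02d", 1:12), paste0("t", 1:5)))
    areas <- setNames(sample(rep(c("A1", "A2", "A3"), each = 4)), rownames(P))
    p <- shuffled_area_test(P, areas, n_iter = 60, seed = i)
    n_null_pass <- n_null_pass + (p > 0.05)
  }
  expect_gte(n_null_pass, 15L)

  ## planted area effect (enough cubelets that no shuffle can recreate
  ## the planted partition by chance)
  P <- matrix(0.1, 20, 5, dimnames = list(sprintf("c%02d", 1:20),
                                          paste0("t", 1:5)))
  areas <- setNames(rep(c("A1", "A2", "A3", "A4"), each = 5), rownames(P))
  P[areas == "A1", ] <- P[areas == "A1", ] + 0.6
  P <- P + matrix(runif(100, 0, 0.05), 20, 5)
  p <- shuffled_area_test(P, areas, n_iter = 100, seed = 12)
  expect_lt(p, 0.01)

  p1 <- shuffled_area_test(P, areas, n_iter = 50, seed = 13)
  p2 <- shuffled_area_test(P, areas, n_iter = 50, seed = 13)
  expect_identical(p1, p2)
  expect_error(shuffled_area_test(P, setNames(rep("A", 20), rownames(P))),
               "2 distinct areas")
})

test_that("fpr_upper_bound reproduces the worked example", {
  est <- fpr_upper_bound(0, 32)
  expect_equal(est$fpr, 0)
  expect_equal(est$upper_bound, 1 / 32)
  expect_equal(round(100 * est$upper_bound, 1), 3.1)

  est2 <- fpr_upper_bound(1, 31)
  expect_equal(est2$fpr, 1 / 32)
  expect_equal(est2$upper_bound, 2 / 32)
  expect_error(fpr_upper_bound(0, 0), "fp \\+ tn")
})

test_that("assign_cubelets bins the synthetic cortex by mediolateral position", {
  cells <- toy_cells(c("c1", "c2", "c3"))
  cells$x_um <- c(5, 115, 115)
  cells$slice_id <- c("slice_01", "slice_01", "slice_02")
  cub <- assign_cubelets(cells, width_um = 110)
  expect_equal(length(unique(cub$cubelet_id)), 3L)
})
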