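test_that("tissue_config validates inputs", {
  expect_error(tissue_config(type_proportions = c(leukemia = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(tissue_config(type_proportions = c(foo = 1)), "leukemia")
  expect_error(tissue_config(n_cells_per_fov = 0), ">= 1")
  expect_error(tissue_config(fov_width_um = -1), "> 0")
})

test_that("simulate_tissue is deterministic given the seed", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 1,
                       n_cells_per_fov = 200, seed = 3)
  t1 <- simulate_tissue(cfg)
  t2 <- simulate_tissue(cfg)
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$polygons, t2$polygons)
})

test_that("generated tissue has plausible scale and valid geometry", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 1,
                       n_cells_per_fov = 500, seed = 8)
  tis <- simulate_tissue(cfg)
  expect_identical(nrow(tis$cells), 500L)
  # counts depth in the sparse in situ regime (~100 median counts per cell)
  med <- stats::median(rowSums(tis$counts))
  expect_gt(med, 60)
  expect_lt(med, 160)
  expect_identical(rownames(tis$counts), tis$cells$cell_id)
  # polygons stay inside the FOV and have positive area
  eps <- 1e-9   # half-plane clipping is exact up to floating-point noise
  for (p in tis$polygons) {
    expect_gte(min(p[, 1]), -eps)
    expect_lte(max(p[, 1]), cfg$fov_width_um + eps)
    expect_gte(min(p[, 2]), -eps)
    expect_lte(max(p[, 2]), cfg$fov_height_um + eps)
    expect_gt(polygon_area(p), 0)
  }
  # packed tissue: cells typically touch several neighbors
  dd <- pairwise_min_distances(tis$polygons, cutoff = 1)
  touching <- vapply(tis$cells$cell_id, count_touching_neighbors,
                     integer(1), dists = dd, touch_tol = 1e-9)
  expect_gte(stats::median(touching), 3)
})

test_that("planted proximity enrichment realizes the requested multiplier", {
  cfg <- tissue_config(
    n_patients = 1, timepoints = "B", fovs_per_sample = 5,
    n_cells_per_fov = 400, type_proportions = sparse_props(), seed = 7,
    enrichment_spec = list(list(cell_type = "T_CD8", timepoint = "B",
                                response = NULL, max_dist_um = 15,
                                multiplier = 3)))
  tis <- simulate_tissue(cfg)
  rate_near <- c(); rate_far <- c()
  for (fov in unique(tis$cells$fov_id)) {
    fc <- tis$cells[tis$cells$fov_id == fov, ]
    leuk <- fc$cell_id[fc$cell_type == "leukemia"]
    oth <- fc$cell_id[fc$cell_type != "leukemia"]
    d <- vapply(oth, function(id) min(vapply(leuk, function(l)
      min_edge_distance(tis$polygons[[id]], tis$polygons[[l]]),
      numeric(1))), numeric(1))
    ty <- fc$cell_type[match(oth, fc$cell_id)]
    rate_near <- c(rate_near, mean(ty[d <= 15] == "T_CD8"))
    rate_far <- c(rate_far, mean(ty[d > 15] == "T_CD8"))
  }
  ratio <- mean(rate_near) / mean(rate_far)
  expect_gt(ratio, 2)     # planted 3x enrichment clearly realized
  expect_lt(ratio, 4.5)
})

test_that("simulate_neighborhood_counts has consistent structure", {
  set.seed(1)
  tab <- simulate_neighborhood_counts(n_fovs_per_group = 2,
                                      n_index_per_fov = 10, rr = 1)
  expect_true(all(tab$count <= tab$ring_total))
  expect_setequal(unique(tab$ring), 0:4)
  expect_setequal(unique(tab$timepoint), c("A", "B"))
  expect_setequal(unique(tab$response), c("nonresponder", "responder"))
  # FOVs are nested in (response, timepoint) groups
  grp <- unique(tab[, c("fov_id", "response", "timepoint")])
  expect_identical(anyDuplicated(grp$fov_id), 0L)
})

test_that("write_tissue / read_cell_table round trip preserves cells and polygons", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 1,
                       n_cells_per_fov = 100, seed = 5)
  tis <- simulate_tissue(cfg)
  dir <- tempfile()
  write_tissue(tis, dir)
  back <- read_cell_table(file.path(dir, "cells.csv"))
  expect_identical(back$cells$cell_id, tis$cells$cell_id)
  expect_identical(back$cells$cell_type, tis$cells$cell_type)
  for (id in names(tis$polygons))
    expect_equal(unname(back$polygons[[id]]), unname(tis$polygons[[id]]),
                 tolerance = 1e-3)
  unlink(dir, recursive = TRUE)
})

test_that("negative probes are sparse background", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 1,
                       n_cells_per_fov = 300, seed = 9)
  tis <- simulate_tissue(cfg)
  expect_identical(dim(tis$neg_counts), c(300L, 10L))
  expect_lt(mean(tis$neg_counts), 0.2)
})
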