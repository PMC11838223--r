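test_that("estimate_pdf evaluates on the shared grid", {
  d <- c(1, 2, 3, 8, 13)
  pdf <- estimate_pdf(d)
  expect_length(pdf$x, 512)
  expect_equal(pdf$x[1], 0)
  expect_equal(pdf$x[512], 45)
  ref <- stats::density(d, bw = "nrd0", from = 0, to = 45, n = 512)
  expect_equal(pdf$y, ref$y)
  expect_error(estimate_pdf(1), ">= 2")
})

test_that("observed_shift subtracts densities and checks the grid", {
  a <- estimate_pdf(c(1, 2, 3, 4))
  b <- estimate_pdf(c(10, 12, 14, 20))
  expect_equal(observed_shift(a, b), a$y - b$y)
  bad <- estimate_pdf(c(10, 12), grid_max = 30)
  expect_error(observed_shift(a, bad), "grid mismatch")
})

test_that("flag_shift applies the 1-SD rule exactly", {
  bg <- list(mean = c(0, 0, 1), sd = c(1, 2, 0.5))
  expect_identical(flag_shift(c(1.5, 1.5, 1.4), bg), c(TRUE, FALSE, FALSE))
  expect_identical(flag_shift(c(-1.5, -2.5, 0.4), bg), c(TRUE, TRUE, TRUE))
})

test_that("permutation_background validates inputs", {
  da <- list(f1 = list(d = c(1, 2, 3), N = 2))
  db <- list(f1 = list(d = c(4, 5, 6), N = 2))
  expect_error(permutation_background(da, db, J = 1), ">= 2")
  bad <- list(f1 = list(d = c(1, 2), N = 5))
  expect_error(permutation_background(bad, db, J = 5), "cannot permute")
})

test_that("min_distance_sample pools FOVs and records N and K", {
  polys <- list(L1 = square_at(0, 0), q1 = square_at(3, 0),
                q2 = square_at(10, 0), o1 = square_at(20, 0),
                L2 = square_at(100, 100), o2 = square_at(104, 100))
  cells <- data.frame(
    cell_id = names(polys),
    fov_id = c("f1", "f1", "f1", "f1", "f2", "f2"),
    cell_type = c("leukemia", "T_CD8", "T_CD8", "B", "leukemia", "B"),
    stringsAsFactors = FALSE)
  s <- min_distance_sample(cells, polys, "T_CD8")
  expect_true(s$usable)
  expect_equal(sort(s$d), c(2, 9))       # f2 has no query cell
  expect_identical(s$per_fov$fov_id, "f1")
  expect_identical(s$per_fov$N, 2L)
  expect_identical(s$per_fov$K, 3L)
})

test_that("density_shift_test is deterministic under a seed", {
  cfg <- tissue_config(n_patients = 1, timepoints = c("A", "B"),
                       fovs_per_sample = 2, n_cells_per_fov = 300,
                       type_proportions = sparse_props(), seed = 21)
  tis <- simulate_tissue(cfg)
  d1 <- density_shift_test(tis$cells, tis$polygons, "T_CD8", J = 20, seed = 5)
  d2 <- density_shift_test(tis$cells, tis$polygons, "T_CD8", J = 20, seed = 5)
  expect_identical(d1$S, d2$S)
  expect_identical(d1$perm_S, d2$perm_S)
  expect_identical(d1$flag, d2$flag)
  d3 <- density_shift_test(tis$cells, tis$polygons, "T_CD8", J = 20, seed = 6)
  expect_false(identical(d3$perm_S, d1$perm_S))
  # the observed curve does not depend on the permutation seed
  expect_identical(d3$S, d1$S)
})

test_that("plant_density_shift relabels a neighbor of each leukemia cell", {
  cfg <- tissue_config(n_patients = 1, timepoints = "B", fovs_per_sample = 1,
                       n_cells_per_fov = 200,
                       type_proportions = sparse_props(), seed = 12)
  tis <- simulate_tissue(cfg)
  before <- sum(tis$cells$cell_type == "planted_q")
  expect_identical(before, 0L)
  out <- plant_density_shift(tis, "planted_q", "closest")
  n_leuk <- sum(tis$cells$cell_type == "leukemia")
  n_planted <- sum(out$cells$cell_type == "planted_q")
  expect_gt(n_planted, 0)
  expect_lte(n_planted, n_leuk)          # collisions can reuse a neighbor
  # planted cells sit at the very first ring of some leukemia cell
  pl <- out$cells$cell_id[out$cells$cell_type == "planted_q"]
  leuk <- out$cells$cell_id[out$cells$cell_type == "leukemia"]
  for (id in pl[seq_len(min(5, length(pl)))]) {
    d <- min(vapply(leuk, function(l)
      min_edge_distance(out$polygons[[id]], out$polygons[[l]]), numeric(1)))
    expect_lt(d, 5)
  }
})
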