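test_that("min_edge_distance is exact on constructed cases", {
  a <- square_at(0, 0)
  expect_equal(min_edge_distance(a, square_at(3, 0)), 2)
  expect_equal(min_edge_distance(a, square_at(1, 0)), 0)       # touching edge
  expect_equal(min_edge_distance(a, square_at(2, 2)), sqrt(2)) # corner gap
  expect_equal(min_edge_distance(a, square_at(0.5, 0.5)), 0)   # overlapping
  inner <- square_at(0.25, 0.25, side = 0.5)
  expect_equal(min_edge_distance(a, inner), 0)                 # nested
  expect_equal(min_edge_distance(a, square_at(3, 0)),
               min_edge_distance(square_at(3, 0), a))          # symmetry
})

test_that("check_polygon validates input and drops the closing vertex", {
  expect_error(min_edge_distance(cbind(0:1, 0:1), square_at(0, 0)),
               "3")
  closed <- rbind(square_at(0, 0), c(0, 0))
  expect_equal(min_edge_distance(closed, square_at(3, 0)), 2)
})

test_that("polygon area and centroid are exact for simple shapes", {
  sq <- square_at(2, 3, side = 2)
  expect_equal(polygon_area(sq), 4)
  expect_equal(polygon_centroid(sq), c(3, 4))
  tri <- cbind(c(0, 3, 0), c(0, 0, 3))
  expect_equal(polygon_area(tri), 4.5)
  expect_equal(polygon_centroid(tri), c(1, 1))
})

test_that("ring assignment uses half-open intervals", {
  sp <- ring_spec()
  expect_identical(sp$n_rings, 5L)
  expect_identical(assign_ring(0, sp), 0L)
  expect_identical(assign_ring(5, sp), 1L)      # boundary goes to upper ring
  expect_identical(assign_ring(4.999, sp), 0L)
  expect_identical(assign_ring(44.999, sp), 4L)
  expect_identical(assign_ring(45, sp), NA_integer_)
  expect_identical(assign_ring(100, sp), NA_integer_)
  expect_error(assign_ring(-1, sp), "negative")
  expect_error(ring_spec(c(1, 5)), "start at 0")
  expect_error(ring_spec(c(0, 5, 5)), "increasing")
})

test_that("pairwise_min_distances matches min_edge_distance and honors cutoff", {
  set.seed(42)
  polys <- lapply(1:8, function(i)
    random_polygon(7, center = stats::runif(2, 0, 30), r = 3))
  names(polys) <- paste0("c", 1:8)
  dd <- pairwise_min_distances(polys, cutoff = 12)
  expect_true(all(dd$dist_um <= 12))
  for (k in seq_len(nrow(dd)))
    expect_equal(dd$dist_um[k],
                 min_edge_distance(polys[[dd$id_a[k]]], polys[[dd$id_b[k]]]),
                 tolerance = 1e-12)
  # every pair below the cutoff must be reported
  full <- pairwise_min_distances(polys, cutoff = 1e6)
  expect_equal(nrow(full), choose(8, 2))
  expect_setequal(paste(dd$id_a, dd$id_b),
                  paste(full$id_a, full$id_b)[full$dist_um <= 12])
})

test_that("neighborhood_counts is exact on a constructed FOV", {
  # four cells on a line: leukemia at 0, neighbors at gaps 2, 10 and 48 um
  polys <- list(L1 = square_at(0, 0), a = square_at(3, 0),
                b = square_at(11, 0), c = square_at(49, 0))
  cells <- data.frame(
    cell_id = names(polys), fov_id = "f1", patient_id = "P1",
    timepoint = "A", response = "responder",
    cell_type = c("leukemia", "T_CD8", "T_CD8", "B"),
    stringsAsFactors = FALSE)
  nc <- neighborhood_counts(cells, polys)
  expect_s3_class(nc, "neighborhood_counts")
  l1 <- nc[nc$index_cell_id == "L1", ]
  expect_identical(sort(l1$ring), c(0L, 1L))          # 2 and 10 um; 48 beyond 45
  expect_identical(l1$cell_type, c("T_CD8", "T_CD8"))
  expect_identical(l1$count, c(1L, 1L))
  expect_identical(l1$ring_total, c(1L, 1L))
})

test_that("ring totals equal the per-ring sum of counts", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 1,
                       n_cells_per_fov = 300, seed = 4)
  tis <- simulate_tissue(cfg)
  nc <- neighborhood_counts(tis$cells, tis$polygons)
  chk <- stats::aggregate(count ~ index_cell_id + ring, data = nc, FUN = sum)
  m <- merge(unique(nc[, c("index_cell_id", "ring", "ring_total")]), chk)
  expect_equal(m$ring_total, m$count)
})

test_that("count_touching_neighbors counts dist-0 pairs", {
  polys <- list(a = square_at(0, 0), b = square_at(1, 0), c = square_at(5, 0))
  dd <- pairwise_min_distances(polys, cutoff = 10)
  expect_identical(count_touching_neighbors("a", dd), 1L)
  expect_identical(count_touching_neighbors("c", dd), 0L)
})

test_that("WKT round trip preserves vertices", {
  p <- random_polygon(9, center = c(100, 50), r = 8)
  q <- wkt_to_polygon(polygon_to_wkt(p, digits = 6))
  expect_equal(unname(q), unname(p), tolerance = 1e-5)
})

test_that("qc_filter removes in two stages with a removal log", {
  cells <- data.frame(
    cell_id = paste0("c", 1:10),
    fov_id = rep(c("f1", "f2"), each = 5),
    total_counts = c(50, 5, 50, 50, 50, 50, 50, 50, 50, 50),
    stringsAsFactors = FALSE)
  out <- qc_filter(cells, min_transcripts = 20, min_cells_per_fov = 5)
  log <- attr(out, "removal_log")
  expect_identical(log$low_count_cells, "c2")
  expect_identical(log$removed_fovs, "f1")   # f1 drops to 4 < 5 cells
  expect_identical(unique(out$fov_id), "f2")
  # manifest completeness: every input cell is kept or accounted for
  expect_identical(nrow(cells),
                   nrow(out) + length(log$low_count_cells) + 4L)
})
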