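test_that("select_reference_cells keeps cells hitting exactly one type's markers", {
  counts <- rbind(
    c1 = c(CD3E = 5, CD19 = 0, HBB = 0),
    c2 = c(CD3E = 0, CD19 = 4, HBB = 0),
    c3 = c(CD3E = 2, CD19 = 1, HBB = 0),   # ambiguous
    c4 = c(CD3E = 0, CD19 = 0, HBB = 0))   # no markers
  markers <- list(`T cell` = "CD3E", `B cell` = "CD19",
                  erythroid = "HBB")
  ref <- suppressWarnings(select_reference_cells(counts, markers))
  expect_identical(ref, c(c1 = "T cell", c2 = "B cell"))
})

test_that("build_reference_profiles averages counts and estimates background", {
  counts <- rbind(c1 = c(g1 = 2, g2 = 0), c2 = c(g1 = 4, g2 = 2),
                  c3 = c(g1 = 0, g2 = 6))
  ref <- c(c1 = "T", c2 = "T", c3 = "B")
  neg <- matrix(c(0, 1, 0, 0, 1, 0), nrow = 3)
  prof <- build_reference_profiles(counts, ref, neg)
  expect_equal(prof$profiles[, "T"], c(g1 = 3, g2 = 1))
  expect_equal(prof$profiles[, "B"], c(g1 = 0, g2 = 6))
  expect_equal(prof$background, mean(neg))
})

test_that("posterior is normalized and matches the analytic oracle", {
  # two genes, profiles scaled to the cell's total count (s = 1 here):
  # log-lik difference is 6*log 5, so the posterior ratio is 5^6
  prof <- cbind(T1 = c(gA = 5, gB = 1), T2 = c(gA = 1, gB = 5))
  x <- rbind(cell = c(gA = 6, gB = 0))
  res <- assign_types(x, prof)
  expect_equal(rowSums(res$posterior), c(cell = 1))
  expect_identical(unname(res$assigned), "T1")
  ratio <- res$posterior["cell", "T1"] / res$posterior["cell", "T2"]
  expect_equal(ratio, 5^6, tolerance = 1e-9)
  expect_equal(res$posterior["cell", "T1"], 5^6 / (5^6 + 1))
})

test_that("zero-count cells get a uniform posterior and are flagged", {
  prof <- cbind(T1 = c(gA = 5, gB = 1), T2 = c(gA = 1, gB = 5))
  x <- rbind(ok = c(gA = 3, gB = 0), empty = c(gA = 0, gB = 0))
  res <- assign_types(x, prof)
  expect_identical(res$flagged_zero, "empty")
  expect_equal(unname(res$posterior["empty", ]), c(0.5, 0.5))
})

test_that("priors shift the posterior exactly", {
  prof <- cbind(T1 = c(gA = 2, gB = 2), T2 = c(gA = 2, gB = 2))
  x <- rbind(cell = c(gA = 1, gB = 1))
  res <- assign_types(x, prof, prior = c(T1 = 0.9, T2 = 0.1))
  expect_equal(unname(res$posterior["cell", "T1"]), 0.9)
})

test_that("two-round typing recovers planted types on synthetic tissue", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 2,
                       n_cells_per_fov = 600, seed = 7)
  tis <- simulate_tissue(cfg)
  oth <- tis$cells$cell_id[tis$cells$cell_type != "leukemia"]
  truth <- stats::setNames(tis$cells$cell_type, tis$cells$cell_id)[oth]
  tr <- suppressWarnings(
    type_cells(tis$counts[oth, , drop = FALSE],
               tis$neg_counts[oth, , drop = FALSE]))
  broad_truth <- nicheshift:::broad_type_of(truth)
  expect_gt(mean(tr$round1[names(truth)] == broad_truth), 0.9)
  expect_gt(mean(tr$assigned[names(truth)] == truth), 0.85)
  # non-lymphocytes are never relabeled in round 2
  nl <- names(truth)[!broad_truth %in% c("T cell", "B cell")]
  expect_identical(tr$assigned[nl], tr$round1[nl])
})

test_that("validate_by_size flags large cells not typed as megakaryocytes", {
  assigned <- c(c1 = "T cell", c2 = "megakaryocyte", c3 = "B cell")
  areas <- c(c1 = 700, c2 = 900, c3 = 100)
  v <- validate_by_size(assigned, areas)
  expect_identical(v$n_large, 2L)
  expect_equal(v$fraction, 0.5)
  # no large cells at all -> NA consistency
  v2 <- validate_by_size(assigned, c(c1 = 10, c2 = 10, c3 = 10))
  expect_true(is.na(v2$fraction))
  expect_identical(v2$n_large, 0L)
})
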