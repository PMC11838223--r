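test_that("read_lr_pairs returns an uppercased, deduplicated pair table", {
  pairs <- read_lr_pairs()
  expect_named(pairs, c("ligand", "receptor"))
  expect_identical(anyDuplicated(pairs), 0L)
  expect_true(all(pairs$ligand == toupper(pairs$ligand)))
  expect_true(any(pairs$ligand == "TNFSF12" & pairs$receptor == "TNFRSF12A"))
})

test_that("Mann-Whitney close/far test matches exact enumeration", {
  res <- mann_whitney_close_far(c(5, 6, 7), c(1, 2, 3))
  expect_equal(res$U, 9)
  expect_equal(res$p, 0.1)   # 2/20 orderings as extreme, two-sided
  expect_error(mann_whitney_close_far(numeric(0), 1:3), "empty")
})

test_that("leukemia_high_genes applies the k-SD rule on per-type medians", {
  med <- rbind(
    leukemia = c(g1 = 10, g2 = 2, g3 = 5),
    t1 = c(2, 2, 5), t2 = c(3, 2, 5), t3 = c(4, 2, 5))
  hi <- leukemia_high_genes(med)
  # g1: mean 3, sd 1 -> 10 > 5; g2 equal; g3 sd 0 and equal
  expect_identical(as.character(hi), "g1")
  med2 <- med; med2["leukemia", "g3"] <- 6
  hi2 <- leukemia_high_genes(med2)
  expect_setequal(as.character(hi2), c("g1", "g3"))
  expect_identical(attr(hi2, "zero_sd"), "g3")
  expect_error(leukemia_high_genes(med[1:3, ]), ">= 3")
})

test_that("pseudobulk computes exact per-group means", {
  counts <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), nrow = 4,
                   dimnames = list(paste0("c", 1:4), c("gA", "gB")))
  pb <- pseudobulk(counts, paste0("c", 1:4),
                   fov = c("f1", "f1", "f1", "f2"),
                   cell_type = c("T", "T", "B", "T"))
  row <- pb[pb$fov_id == "f1" & pb$cell_type == "T", ]
  expect_equal(row$gA, 2)
  expect_equal(row$gB, 3)
  expect_identical(row$n_cells, 2L)
  expect_equal(pb[pb$fov_id == "f2" & pb$cell_type == "T", "gA"], 7)
})

test_that("assign_proximity_groups uses inclusive thresholds", {
  polys <- list(L = square_at(0, 0),
                a = square_at(6, 0),    # gap 5: close (inclusive)
                b = square_at(31, 0),   # gap 30: far (inclusive)
                c = square_at(16, 0),   # gap 15: neither
                d = square_at(200, 0))  # FOV without leukemia
  cells <- data.frame(
    cell_id = names(polys),
    fov_id = c("f1", "f1", "f1", "f1", "f2"),
    cell_type = c("leukemia", "T", "T", "T", "T"),
    stringsAsFactors = FALSE)
  pg <- assign_proximity_groups(cells, polys)
  expect_identical(pg$group[pg$cell_id == "a"], "close")
  expect_identical(pg$group[pg$cell_id == "b"], "far")
  expect_identical(pg$group[pg$cell_id == "c"], "neither")
  expect_false("d" %in% pg$cell_id)
  expect_identical(attr(pg, "no_leukemia_fovs"), "f2")
})

test_that("run_lr_analysis returns a typed empty result when nothing qualifies", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 2,
                       n_cells_per_fov = 200, seed = 2)
  tis <- simulate_tissue(cfg)
  none <- data.frame(ligand = "NOSUCHGENE", receptor = "ALSOABSENT")
  res <- run_lr_analysis(tis$cells, tis$polygons, tis$counts, none)
  expect_identical(nrow(res), 0L)
  expect_true(all(c("cell_type", "anchor_gene", "partner_gene", "p_raw",
                    "p_adj") %in% names(res)))
})

test_that("run_lr_analysis finds the leukemia ligand anchor on synthetic tissue", {
  cfg <- tissue_config(n_patients = 1, timepoints = "A", fovs_per_sample = 4,
                       n_cells_per_fov = 400, seed = 13)
  tis <- simulate_tissue(cfg)
  res <- run_lr_analysis(tis$cells, tis$polygons, tis$counts, read_lr_pairs(),
                         direction = "ligand-on-leukemia")
  # TNFSF12 is a leukemia marker in the generator, so it anchors the tests
  expect_true(nrow(res) > 0)
  expect_identical(unique(res$anchor_gene), "TNFSF12")
  expect_identical(unique(res$partner_gene), "TNFRSF12A")
  expect_false("leukemia" %in% res$cell_type)
  expect_equal(res$p_adj, stats::p.adjust(res$p_raw, "BH"))
})
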