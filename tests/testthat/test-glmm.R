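make_table <- function(seed = 1, rr = 1, nf = 3, ni = 30) {
  set.seed(seed)
  simulate_neighborhood_counts(n_fovs_per_group = nf, n_index_per_fov = ni,
                               rr = rr)
}

test_that("build_design drops zero ring totals and builds factors", {
  tab <- make_table()
  tab$ring_total <- pmax(tab$ring_total, 1L)   # start with no empty rings
  tab$ring_total[1:3] <- 0L
  fr <- build_design(tab)
  expect_identical(attr(fr, "n_dropped"), 3L)
  expect_identical(nrow(fr), nrow(tab) - 3L)
  expect_s3_class(fr$ring, "factor")
  expect_identical(levels(fr$response), c("nonresponder", "responder"))
  expect_identical(levels(fr$timepoint)[1], "A")
  expect_identical(levels(fr$ring)[1], "r0")
  expect_true(all(is.finite(fr$log_ring_total)))
  expect_error(build_design(tab[0, ]), "empty")
})

test_that("contrast vectors equal manual coefficient sums", {
  fit <- fit_poisson_glmm(build_design(make_table(seed = 2, rr = 2)))
  b <- coef(fit)
  for (r in c(0, 2, 4)) {
    manual <- b[["timepointB"]] + b[["responseresponder:timepointB"]]
    if (r > 0) {
      manual <- manual + b[[paste0("timepointB:ringr", r)]] +
        b[[paste0("responseresponder:timepointB:ringr", r)]]
    }
    auto <- contrast_rr(fit, niche_contrast(fit, "B_vs_A_responders",
                                            ring = r))$estimate
    expect_equal(auto, manual, tolerance = 1e-12)
  }
  base <- contrast_rr(fit, niche_contrast(fit,
                                          "responder_vs_nonresponder_at_A",
                                          ring = 3))$estimate
  expect_equal(base, b[["responseresponder"]] +
                 b[["responseresponder:ringr3"]], tolerance = 1e-12)
})

test_that("contrast_rr reports exponentiated estimate, Wald CI and p", {
  fit <- fit_poisson_glmm(build_design(make_table(seed = 3, rr = 2.5)))
  cv <- niche_contrast(fit, "B_vs_A_responders", ring = 1)
  res <- contrast_rr(fit, cv)
  expect_equal(res$rate_ratio, exp(res$estimate))
  se <- res$se
  expect_equal(res$ci_low, exp(res$estimate - stats::qnorm(0.975) * se))
  expect_equal(res$ci_high, exp(res$estimate + stats::qnorm(0.975) * se))
  expect_equal(res$p_raw,
               2 * stats::pnorm(-abs(res$estimate / se)))
  expect_error(contrast_rr(fit, numeric(0)), "zero contrast")
  expect_error(contrast_rr(fit, c(not_a_coef = 1)), "unknown")
})

test_that("rate-ratio contrasts are invariant to scaling the offset", {
  tab <- make_table(seed = 4, rr = 1.5)
  fit1 <- fit_poisson_glmm(build_design(tab))
  tab2 <- tab
  tab2$ring_total <- tab2$ring_total * 2L
  fit2 <- fit_poisson_glmm(build_design(tab2))
  b1 <- coef(fit1); b2 <- coef(fit2)
  # only the intercept absorbs the offset scale
  expect_equal(b2[["(Intercept)"]], b1[["(Intercept)"]] - log(2),
               tolerance = 1e-5)
  nz <- setdiff(names(b1), "(Intercept)")
  expect_equal(b1[nz], b2[nz], tolerance = 1e-5)
})

test_that("adjust_bonferroni multiplies and caps at 1", {
  res <- data.frame(p_raw = c(0.001, 0.2, 0.9))
  out <- adjust_bonferroni(res, m = 10)
  expect_equal(out$p_adj, c(0.01, 1, 1))
  expect_error(adjust_bonferroni(res, m = 0), ">= 1")
})

test_that("niche_enrichment reports every type x contrast x ring with Bonferroni", {
  tab <- make_table(seed = 5)
  # relabel the single simulated type into two to exercise the per-type loop
  tab$cell_type <- ifelse(seq_len(nrow(tab)) %% 2 == 0, "typeA", "typeB")
  res <- niche_enrichment(tab)
  expect_setequal(unique(res$cell_type), c("typeA", "typeB"))
  expect_setequal(unique(res$ring), 0:4)
  expect_equal(res$p_adj, pmin(1, 4 * res$p_raw))  # 2 types x 2 contrasts
})

test_that("fit_poisson_glmm requires at least two FOVs", {
  tab <- make_table()
  tab <- tab[tab$fov_id == tab$fov_id[1], ]
  expect_error(suppressWarnings(fit_poisson_glmm(build_design(tab))), ">= 2 FOVs")
})

test_that("complete_type_table zero-fills absent type-in-ring rows", {
  tab <- make_table(seed = 6)
  other <- tab
  tab$cell_type <- "query"; other$cell_type <- "other"
  # drop one occupied (index cell, ring) row of the query type only; the
  # other type keeps the ring occupied, so the query row must come back as 0
  drop_row <- which(tab$count > 0)[1]
  key <- tab[drop_row, c("index_cell_id", "ring")]
  both <- rbind(tab[-drop_row, ], other)
  full <- nicheshift:::complete_type_table(both, "query")
  got <- full[full$index_cell_id == key$index_cell_id &
                full$ring == key$ring, ]
  expect_identical(nrow(got), 1L)
  expect_identical(got$count, 0L)
})
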