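test_that("the calibrated cutoff equals an independent brute-force maximum", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(50:200, 1)
    cells <- data.frame(cell_id = sprintf("c%03d", 1:n),
                        TIGIT = stats::rlnorm(n, 1.6, 0.4),
                        stringsAsFactors = FALSE)
    got <- calibrate_threshold(cells, "TIGIT", cells$cell_id)
    # independent oracle: explicit linear scan
    best <- -Inf
    for (v in cells$TIGIT) if (v > best) best <- v
    expect_identical(got, best)
  }
})

test_that("worked calibration examples hold", {
  cells <- data.frame(cell_id = as.character(1:60), TIGIT = as.numeric(1:60))
  expect_equal(calibrate_threshold(cells, "TIGIT", cells$cell_id), 60)
  zero <- data.frame(cell_id = as.character(1:50), TIGIT = rep(0, 50))
  expect_equal(calibrate_threshold(zero, "TIGIT", zero$cell_id), 0)
  # determinism: identical inputs, identical cutoff
  expect_identical(calibrate_threshold(cells, "TIGIT", cells$cell_id),
                   calibrate_threshold(cells, "TIGIT", cells$cell_id))
})

test_that("the negative-control count window is enforced", {
  cells <- data.frame(cell_id = as.character(1:300), TIGIT = as.numeric(1:300))
  expect_error(calibrate_threshold(cells, "TIGIT", cells$cell_id[1:40]),
               "outside the calibration window")
  expect_error(calibrate_threshold(cells, "TIGIT", cells$cell_id[1:250]),
               "outside the calibration window")
  expect_error(calibrate_threshold(cells, "TIGIT", c(cells$cell_id[1:49], "nope")),
               "not found")
  expect_error(calibrate_threshold(cells, "CD99", cells$cell_id[1:60]),
               "CD99")
})

test_that("negative-control selection is rule-driven, bounded and reproducible", {
  co <- generate_cells(tiny_config(n_cells = 2000, seed = 8))
  cells <- co$cells
  # explicit eligibility: all 200 flagged cells are selected
  mask <- seq_len(nrow(cells)) <= 200
  ids <- select_negative_controls(cells, "TIGIT", rule = mask, max_n = 200, seed = 3)
  expect_length(ids, 200)
  expect_true(all(ids %in% cells$cell_id[mask]))
  # fewer than the minimum eligible cells is an error
  expect_error(select_negative_controls(cells, "TIGIT",
                                        rule = seq_len(nrow(cells)) <= 40),
               "larger input region")
  # seeded determinism
  expect_identical(
    select_negative_controls(cells, "TIGIT", max_n = 150, seed = 11),
    select_negative_controls(cells, "TIGIT", max_n = 150, seed = 11))
  # anchor enrichment picks marker-negative (B) cells for TIGIT
  ids <- select_negative_controls(cells, "TIGIT", rule = "CD20", max_n = 200, seed = 2)
  types <- co$truth$true_cell_type[match(ids, co$truth$cell_id)]
  expect_true(mean(types == "CD20_B") > 0.95)
})

test_that("full-panel calibration records provenance for every marker", {
  co <- generate_cells(tiny_config(n_cells = 1500, seed = 6))
  ts <- calibrate_thresholds(co$cells, seed = 4)
  expect_setequal(names(ts$cutoffs), marker_panel()$markers)
  expect_true(all(ts$cutoffs >= 0))
  expect_true(all(ts$n_negative_cells >= 50 & ts$n_negative_cells <= 200))
  expect_match(ts$negative_selector[["TIGIT"]], "CD20")
  expect_match(ts$negative_selector[["CD20"]], "CD3")
})
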