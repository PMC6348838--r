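test_that("cell counts and compartment labels are conserved", {
  co <- generate_cells(tiny_config(n_cells = 1000, seed = 7))
  expect_equal(nrow(co$cells), 1000L)
  expect_true(all(co$cells$compartment == "spotA"))
  expect_equal(nrow(co$truth), 1000L)
  expect_setequal(co$cells$cell_id, co$truth$cell_id)
})

test_that("a degenerate zero positive fraction yields no positive draws", {
  co <- generate_cells(tiny_config(n_cells = 800, seed = 3, p_tigit_cd4 = 0))
  expect_false(any(co$truth$TIGIT_truth_pos))
  expect_false(any(co$truth$`PD-1_truth_pos`))
})

test_that("a fixed config and seed reproduce the serialized table bitwise", {
  cfg <- tiny_config(n_cells = 500, seed = 11)
  a <- generate_cells(cfg); b <- generate_cells(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cells(a$cells, f1); write_cells(b$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated positions lie within the configured spot disc", {
  for (d in c(0.6, 4)) {
    co <- generate_cells(tiny_config(n_cells = 600, seed = 5, spot_diameter_mm = d))
    r <- sqrt(co$cells$x_um^2 + co$cells$y_um^2)
    expect_true(all(r <= d * 500))
  }
})

test_that("realized marker positivity recovers the encoded marginal over many seeds", {
  p <- 0.5
  for (s in 1:10) {
    co <- generate_cells(tiny_config(n_cells = 2000, seed = s, p_tigit_cd4 = p))
    cd4 <- co$truth$true_cell_type == "CD4_T"
    n <- sum(cd4)
    frac <- mean(co$truth$TIGIT_truth_pos[cd4])
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("realized checkpoint co-positivity recovers the configured conditionals", {
  c1 <- 0.78; c2 <- 0.96
  nt <- 0; np <- 0; nj <- 0
  for (s in 1:10) {
    co <- generate_cells(tiny_config(n_cells = 2000, seed = 20 + s,
                                     p_tigit_cd4 = 0.5, c1 = c1, c2 = c2))
    tp <- co$truth$TIGIT_truth_pos; pp <- co$truth$`PD-1_truth_pos`
    nt <- nt + sum(tp); np <- np + sum(pp); nj <- nj + sum(tp & pp)
  }
  expect_lt(abs(nj / nt - c1), 3 * sqrt(c1 * (1 - c1) / nt))
  expect_lt(abs(nj / np - c2), 3 * sqrt(c2 * (1 - c2) / np))
})

test_that("invalid configurations are rejected with informative errors", {
  # proportions not summing to one
  expect_error(compartment_spec("A", 100, c(CD4_T = 0.5, other = 0.4)),
               "sum to 1")
  # inconsistent joint/marginal co-positivity names the offending cell type
  expect_error(
    generator_config(
      panel = marker_panel(),
      compartments = list(compartment_spec("A", 100,
                                           c(CD20_B = 0.5, CD4_T = 0.3, other = 0.2))),
      mixtures = tiny_mixtures(p_tigit_cd4 = 0.5),
      copositivity = {
        cp <- tiny_copositivity()
        cp$CD4_T <- c(p_pd1_given_tigit = 0.9, p_tigit_given_pd1 = 0.2)
        cp
      },
      n_cells_range = c(1, 6000)),
    "CD4_T")
  # n_cells outside the configured window
  expect_error(
    generator_config(
      panel = marker_panel(),
      compartments = list(compartment_spec("A", 100,
                                           c(CD20_B = 0.5, CD4_T = 0.3, other = 0.2))),
      mixtures = tiny_mixtures(), copositivity = tiny_copositivity(),
      n_cells_range = c(800, 6000)),
    "outside the configured range")
  # positive component must be brighter than background
  expect_error(intensity_mixture(0.5, pos_log_mean = 1.0, neg_log_mean = 1.6),
               "brighter")
})
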