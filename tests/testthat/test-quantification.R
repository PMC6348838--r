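test_that("relative expression follows the reference-normalization arithmetic", {
  expect_identical(relative_expression(c(5, 10, 15), c(5, 10, 15)), 100)
  expect_equal(relative_expression(c(40, 60), c(100, 300)), 25)
  ref <- stats::rlnorm(50, 4, 0.5)
  expect_identical(relative_expression(ref, ref), 100)  # reference vs itself
  expect_error(relative_expression(numeric(0), ref), "non-empty")
  expect_error(relative_expression(ref, numeric(0)), "non-empty")
  expect_error(relative_expression(c(1, 2), c(0, 0)), "reference mean")
  df <- data.frame(TIGIT = c(50, 50)); rf <- data.frame(TIGIT = c(200, 200))
  expect_equal(relative_expression(df, rf, "TIGIT"), 25)
})

test_that("RE and ratios are invariant under global intensity rescaling", {
  set.seed(7)
  test_v <- stats::rlnorm(200, 3, 0.5); ref_v <- stats::rlnorm(150, 4, 0.5)
  base <- relative_expression(test_v, ref_v)
  for (c_ in c(1e-3, 0.5, 7, 1e4))
    expect_equal(relative_expression(c_ * test_v, c_ * ref_v), base,
                 tolerance = 1e-12)
})

test_that("the TIGIT:PD-1 ratio is the quotient of the two REs", {
  expect_equal(tigit_pd1_ratio(100, 100), 1)
  expect_equal(tigit_pd1_ratio(80, 40), 2)
  expect_equal(tigit_pd1_ratio(30, 40), 0.75)
  expect_error(tigit_pd1_ratio(50, 0), "undefined")
})

test_that("coexpression fractions match a counting oracle and report undefined cleanly", {
  ph <- blank_pheno(20)
  ph$TIGIT <- rep(c(TRUE, FALSE), c(10, 10))
  ph$`PD-1` <- c(rep(TRUE, 7), rep(FALSE, 3), TRUE, rep(FALSE, 9))
  res <- coexpression_fractions(ph)
  expect_equal(res$frac_tigit_pos_that_are_pd1_pos, 0.7)
  expect_equal(res$frac_pd1_pos_that_are_tigit_pos, 0.875)
  expect_equal(res$n_double_pos, 7)
  expect_lte(res$n_double_pos, min(res$n_tigit_pos, res$n_pd1_pos))

  ph$`PD-1` <- FALSE
  res <- coexpression_fractions(ph)
  expect_true(is.na(res$frac_pd1_pos_that_are_tigit_pos))
  expect_equal(res$frac_tigit_pos_that_are_pd1_pos, 0)

  all_pos <- blank_pheno(5); all_pos$TIGIT <- TRUE; all_pos$`PD-1` <- TRUE
  res <- coexpression_fractions(all_pos)
  expect_equal(res$frac_tigit_pos_that_are_pd1_pos, 1)
  expect_equal(res$frac_pd1_pos_that_are_tigit_pos, 1)
})

test_that("positivity fractions count gated cells of a type", {
  ph <- blank_pheno(100)
  ph$CD3 <- TRUE; ph$CD4 <- TRUE
  ph <- assign_cell_type(ph)
  ph$TIGIT <- rep(c(TRUE, FALSE), c(47, 53))
  expect_equal(positivity_fraction(ph, "CD4_T", "TIGIT"), 0.47)
  expect_equal(positivity_fraction(ph, "CD4_T", "TIGIT", require = "CD3"), 0.47)
  expect_true(is.na(positivity_fraction(ph, "CD56_NK", "TIGIT")))
  ph$TIGIT <- TRUE
  expect_equal(positivity_fraction(ph, "CD4_T", "TIGIT"), 1)
})

test_that("density conversion matches the closed-form disc area", {
  g06 <- spot_geometry(0.6)
  expect_equal(g06$area_mm2, pi * 0.3^2, tolerance = 1e-12)
  expect_equal(cell_density(80, g06), 80 / (pi * 0.09), tolerance = 1e-9)
  g4 <- spot_geometry(4)
  expect_equal(cell_density(100, g4), 100 / (pi * 4), tolerance = 1e-9)
  expect_equal(cell_density(0, g06), 0)
  # linearity in the count
  expect_equal(cell_density(7 * 13, g4), 7 * cell_density(13, g4),
               tolerance = 1e-12)
  expect_error(spot_geometry(0), "positive")
  expect_error(spot_geometry(-1), "positive")
  expect_error(cell_density(-5, g06), "non-negative")
})

test_that("densities per 0.1 mm^2 rescale linearly", {
  expect_equal(density_per_0p1mm2(59, 0.1), 59)
  expect_equal(density_per_0p1mm2(118, 0.2), 59)
  expect_equal(density_per_0p1mm2(0, 0.35), 0)
  expect_error(density_per_0p1mm2(10, 0), "positive")
})

test_that("compartment summaries reproduce hand arithmetic on a small table", {
  # reference (Gcp) CD4 cells: TIGIT mean 150, PD-1 mean 100
  # test compartment X CD4 cells: TIGIT mean 37.5, PD-1 mean 25
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:6),
    tissue_id = c("ref", "ref", "ref", "t1", "t1", "t1"),
    tissue_role = c("reference", "reference", "reference", "test", "test", "test"),
    compartment = c("Gcp", "Gcp", "Gcp", "X", "X", "X"),
    x_um = 0, y_um = 0,
    TIGIT = c(100, 200, 150, 30, 45, 37.5),
    "PD-1" = c(50, 150, 100, 20, 30, 25),
    stringsAsFactors = FALSE, check.names = FALSE)
  pheno <- data.frame(cell_id = cells$cell_id, cell_type = "CD4_T",
                      stringsAsFactors = FALSE)
  s <- summarize_compartments(cells, pheno, cell_types = "CD4_T", min_n = 2)
  t1 <- s[s$tissue_id == "t1", ]
  expect_equal(t1$mean_TIGIT, 37.5)
  expect_equal(t1$RE_TIGIT, 100 * 37.5 / 150)
  expect_equal(t1$`RE_PD-1`, 100 * 25 / 100)
  expect_equal(t1$ratio_tigit_pd1, (100 * 37.5 / 150) / (100 * 25 / 100))
  ref <- s[s$tissue_id == "ref", ]
  expect_identical(ref$RE_TIGIT, 100)   # reference compartment is exactly 100
  expect_identical(ref$`RE_PD-1`, 100)
  expect_equal(ref$ratio_tigit_pd1, 1)
  expect_false(any(s$low_n))
  expect_true(all(summarize_compartments(cells, pheno, cell_types = "CD4_T",
                                         min_n = 20)$low_n))
})

test_that("a single-compartment table identical to the reference gives RE 100", {
  co <- generate_cells(tiny_config(n_cells = 900, seed = 17))
  cells <- co$cells
  ref <- cells; ref$tissue_id <- "ref"; ref$tissue_role <- "reference"
  ref$compartment <- "Gcp"; ref$cell_id <- paste0("r_", ref$cell_id)
  cells$compartment <- "Gcp"
  both <- rbind(cells, ref)
  pheno <- data.frame(cell_id = both$cell_id,
                      cell_type = rep(co$truth$true_cell_type, 2),
                      stringsAsFactors = FALSE)
  s <- summarize_compartments(both, pheno, cell_types = c("CD4_T", "CD20_B"))
  expect_true(all(s$RE_TIGIT == 100))
  expect_true(all(s$`RE_PD-1` == 100))
  expect_true(all(s$ratio_tigit_pd1 == 1))
})

test_that("a missing reference population is a hard error", {
  co <- generate_cells(tiny_config(n_cells = 900, seed = 17))
  pheno <- data.frame(cell_id = co$cells$cell_id,
                      cell_type = co$truth$true_cell_type,
                      stringsAsFactors = FALSE)
  expect_error(summarize_compartments(co$cells, pheno),
               "reference population")
})
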