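test_that("substrate masking recovers the generator footprint", {
  agree <- vapply(1:6, function(s) {
    m <- generate_cell_map(curve_spec(), seed = s)
    px <- process_map(m)
    cl <- classify_pixels(px)
    mean(cl$is_cell == m$is_cell_truth)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("an all-substrate map is unusable and masked pixels sit above threshold", {
  flat <- generate_cell_map(curve_spec(), apex_height = 0, seed = 2)
  expect_error(classify_pixels(process_map(flat)),
               class = "rbcmech_unusable_map")

  m <- generate_cell_map(curve_spec(), seed = 2)
  cl <- classify_pixels(process_map(m))
  cfg <- aggregation_config()
  expect_true(all(cl$height_above_plane[cl$is_cell] > cfg$substrate_threshold))
})

test_that("cell height equals the generated apex height", {
  m <- generate_cell_map(curve_spec(), apex_height = 2.64e-6, seed = 5)
  cl <- classify_pixels(process_map(m))
  expect_equal(compute_cell_height(cl), 2.64e-6, tolerance = 0.02)
})

test_that("mask is monotone in the substrate threshold", {
  m <- generate_cell_map(curve_spec(), seed = 8)
  px <- process_map(m)
  lo <- classify_pixels(px, aggregation_config(substrate_threshold = 300e-9))
  hi <- classify_pixels(px, aggregation_config(substrate_threshold = 900e-9))
  # raising the threshold can only remove pixels from the cell mask
  expect_true(all(which(hi$is_cell) %in% which(lo$is_cell)))
})

test_that("patient aggregation weights cells equally, not pixels", {
  # two cells with different pixel counts and different means
  fake <- tibble::tibble(
    patient_id = "P1",
    cell_id = rep(c("C1", "C2"), c(6, 3)),
    n_pixels = 1, cell_height = 2e-6,
    youngs_modulus = rep(c(1000, 2000), c(6, 3)),
    stiffness = 0.002, dissipated_energy = 1e-16, hysteresis = 0.5,
    work_of_adhesion = 0
  )
  cells <- fake |>
    dplyr::group_by(patient_id, cell_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
  pat <- aggregate_patients(cells, aggregation_config(min_cells = 2))
  expect_equal(pat$youngs_modulus, 1500)
  expect_equal(pat$youngs_modulus,
               brute_force_two_level_mean(fake$youngs_modulus, fake$cell_id))
  expect_equal(pat$n_cells, 2L)
})

test_that("aggregation is invariant to pixel and cell ordering", {
  m <- generate_cell_map(curve_spec(cell_id = "C1", patient_id = "P1"),
                         seed = 9)
  px <- process_map(m)
  cells_a <- summarize_cells(px)
  cells_b <- summarize_cells(px[sample(nrow(px)), ])
  expect_equal(cells_a$youngs_modulus, cells_b$youngs_modulus)
  expect_equal(cells_a$cell_height, cells_b$cell_height)
})

test_that("patients with too few usable cells are rejected", {
  cells <- tibble::tibble(
    patient_id = "P1", cell_id = c("C1", "C2"), n_pixels = 10,
    cell_height = 2e-6, youngs_modulus = 1000, stiffness = 0.002,
    dissipated_energy = 1e-16, hysteresis = 0.5, work_of_adhesion = 0
  )
  expect_error(aggregate_patients(cells, aggregation_config(min_cells = 10)),
               class = "rbcmech_insufficient_cells")
})
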