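test_that("degenerate single-region phantom without pores is constant", {
  p <- phantom_params(grid_shape = c(8, 10, 12), voxel_size_nm = 100,
                      region_gv_means = 140, lacuna_gv = 60, noise_sd = 0)
  ph <- generate_phantom(p)
  expect_true(all(ph$volume$data == 140))
  expect_true(all(ph$truth$region_labels == 1L))
})

test_that("crossing counts and distances derive from construction", {
  seg <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  lac <- list(lacuna_spec(c(2, 2, 2), c(0.8, 0.8, 0.8)))
  can <- list(
    canaliculus_spec(seg(2, 2, 2, 2, 5.5, 2.0), 0.2, "crossing", 1L),
    canaliculus_spec(seg(2, 2, 2, 2, 5.5, 3.0), 0.2, "crossing", 1L),
    canaliculus_spec(seg(2, 2, 2, 2.4, 5.5, 4.0), 0.2, "crossing", 1L))
  p <- phantom_params(grid_shape = c(40, 60, 60), voxel_size_nm = 100,
                      region_gv_means = c(150, 165), cement_gv = 195,
                      lacuna_gv = 60, region_boundaries_um = 4,
                      cement_thickness_um = 0.8,
                      cement_wave_amplitude_um = 0.3,
                      cement_wave_period_um = 4,
                      lacunae = lac, canaliculi = can, noise_sd = 0)
  ph <- generate_phantom(p)
  cc <- ph$truth$true_crossing_counts
  expect_identical(cc$n_within[1], 3L)
  expect_identical(cc$n_beyond[1], 0L)
  expect_true(all(ph$truth$crossing_distances$distance_um < 25))
  # every crossing tube has rasterized voxels on both sides of the surface
  for (i in seq_along(can)) {
    m <- olcn:::rasterize_tube(array(FALSE, c(40, 60, 60)),
                               can[[i]]$path_um, 0.2, 0.1)
    reg <- ph$truth$region_labels[m]
    expect_true(all(c(1L, 2L) %in% reg))
  }
})

test_that("analytic porosity equals an exhaustive voxel scan", {
  can <- list(canaliculus_spec(rbind(c(1.5, 0.4, 0.3), c(1.5, 2.4, 2.6)),
                               0.25, "intra_region"))
  p <- phantom_params(grid_shape = c(30, 30, 30), voxel_size_nm = 100,
                      region_gv_means = 160, lacuna_gv = 60,
                      canaliculi = can, noise_sd = 0)
  ph <- generate_phantom(p)
  # brute force: classify every voxel center against the segment directly
  a <- c(1.5, 0.4, 0.3); b <- c(1.5, 2.4, 2.6); u <- b - a
  inside <- 0L
  for (i in 1:30) for (j in 1:30) for (k in 1:30) {
    w <- c(i - 1, j - 1, k - 1) * 0.1 - a
    tt <- min(max(sum(w * u) / sum(u^2), 0), 1)
    if (sum((w - tt * u)^2) <= 0.25^2 + 1e-12) inside <- inside + 1L
  }
  expect_identical(sum(ph$truth$canal_mask), inside)
  expect_equal(ph$truth$analytic_region_porosity,
               inside / (30^3 - inside))
})

test_that("seed drives only the noise field", {
  a <- default_validation_phantom(1)
  b <- default_validation_phantom(1)
  expect_identical(a$volume$data, b$volume$data)
  c2 <- default_validation_phantom(2)
  expect_false(identical(a$volume$data, c2$volume$data))
  expect_identical(a$truth$region_labels, c2$truth$region_labels)
  expect_identical(a$truth$lacuna_labels, c2$truth$lacuna_labels)
  expect_identical(a$truth$true_crossing_counts,
                   c2$truth$true_crossing_counts)
})

test_that("noise-free gray values hit exactly the constructed levels", {
  ph <- get_fixture(1, noise_sd = 0)
  lv <- sort(unique(c(ph$volume$data)))
  expect_identical(lv, c(60, 150, 165, 195))
})

test_that("fixture ground truth matches its documented construction", {
  ph <- get_fixture(1, noise_sd = 0)
  cc <- ph$truth$true_crossing_counts
  expect_identical(cc$n_within[1:4], c(3L, 2L, 1L, 0L))
  info <- ph$truth$lacuna_info
  expect_identical(sum(info$above_size_filter), 7L)   # 7 lacunae, 8 blobs
  expect_identical(sum(!info$above_size_filter), 8L)
  # denser young network in ground truth
  por <- ph$truth$analytic_region_porosity
  expect_gt(por[1], por[2])
})

test_that("invalid geometry is rejected with the offending spec named", {
  expect_error(
    phantom_params(grid_shape = c(20, 20, 20), voxel_size_nm = 100,
                   region_gv_means = 150, lacuna_gv = 60,
                   lacunae = list(lacuna_spec(c(1.8, 1.0, 1.0),
                                              c(0.5, 0.5, 0.5)))),
    "lacuna spec 1")
  expect_error(
    phantom_params(grid_shape = c(20, 20, 20), voxel_size_nm = 100,
                   region_gv_means = 150, lacuna_gv = 60,
                   canaliculi = list(canaliculus_spec(
                     rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 5)), 0.2))),
    "canaliculus spec 1")
  expect_error(
    phantom_params(grid_shape = c(20, 20, 20), voxel_size_nm = 100,
                   region_gv_means = c(150, 140), cement_gv = 195,
                   lacuna_gv = 60, region_boundaries_um = 1),
    "strictly increasing")
  # a declared loop that would touch the cement line is refused
  p <- phantom_params(grid_shape = c(20, 40, 40), voxel_size_nm = 100,
                      region_gv_means = c(150, 165), cement_gv = 195,
                      lacuna_gv = 60, region_boundaries_um = 2,
                      cement_thickness_um = 0.8,
                      cement_wave_amplitude_um = 0.2,
                      cement_wave_period_um = 4,
                      canaliculi = list(canaliculus_spec(
                        rbind(c(1, 1, 1), c(1, 1.75, 2), c(1, 1, 3)),
                        0.2, "loop")))
  expect_error(generate_phantom(p), "touches the cement line")
})
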