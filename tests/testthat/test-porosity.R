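test_that("projections of a constant volume are constant", {
  vol <- volume(array(120, c(12, 8, 8)), 100)
  ps <- min_intensity_projections(vol, window_slices = 4, n_projections = 3)
  for (p in ps$projections) expect_true(all(p == 120))
})

test_that("a single dark voxel appears in exactly one projection", {
  dat <- array(200, c(12, 8, 8)); dat[6, 3, 4] <- 10
  ps <- min_intensity_projections(volume(dat, 100), 4, 3)
  hits <- vapply(ps$projections, function(p) sum(p == 10), integer(1))
  expect_identical(hits, c(0L, 1L, 0L))
  expect_identical(ps$projections[[2]][3, 4], 10)
})

test_that("standard windows partition a 2160-slice stack as documented", {
  set.seed(1)
  vol <- volume(array(sample(100:200, 2160 * 9, TRUE), c(2160, 3, 3)), 50)
  ps <- min_intensity_projections(vol)  # defaults: 15 windows of 130
  expect_identical(nrow(ps$windows), 15L)
  expect_identical(ps$windows$start, seq(1L, 1821L, by = 130L))
  expect_identical(ps$windows$end, seq(130L, 1950L, by = 130L))
  # trailing slices 1951..2160 unused
  expect_lt(max(ps$windows$end), 2160L)
  expect_error(min_intensity_projections(volume(array(1:2, c(100, 1, 1)),
                                                50)),
               "at least 1950")
})

test_that("label companions follow the gray argmin and lacuna presence", {
  dat <- array(200, c(4, 2, 2))
  reg <- array(1L, c(4, 2, 2)); reg[3, , ] <- 2L
  lacs <- array(0L, c(4, 2, 2)); lacs[2, 1, 1] <- 5L
  dat[3, 1, 2] <- 10  # argmin slice 3 carries region 2
  ps <- min_intensity_projections(volume(dat, 100), 4, 1,
                                  region_labels = reg, lacuna_labels = lacs)
  expect_identical(ps$region_proj[[1]][1, 2], 2L)
  expect_identical(ps$region_proj[[1]][2, 2], 1L)  # tie -> first slice
  expect_identical(ps$lacuna_proj[[1]][1, 1], 5L)
})

test_that("canalicular segmentation recovers a tube footprint", {
  proj <- matrix(150, 80, 80)
  proj[40:42, 11:70] <- 60             # 3 x 60 = 180 px footprint
  m <- segment_canaliculi_2d(proj)
  expect_gt(sum(m), 180 * 0.8)
  expect_lt(sum(m), 180 * 1.2)
  expect_gte(mean(m[40:42, 11:70]), 0.8)
})

test_that("blobs below the 100-pixel filter are discarded as noise", {
  proj <- matrix(150, 100, 100)
  set.seed(4)
  for (i in 1:10) {                     # 10 dark blobs of ~50 px each
    cy <- sample(10:90, 1); cx <- sample(10:90, 1)
    for (dy in -3:3) for (dx in -3:3)
      if (dy^2 + dx^2 <= 8) proj[cy + dy, cx + dx] <- 60
  }
  expect_identical(sum(segment_canaliculi_2d(proj)), 0L)
  # constant projection -> empty mask, not an error
  expect_identical(sum(segment_canaliculi_2d(matrix(7, 20, 20))), 0L)
})

test_that("top-hat segmentation is invariant to additive offsets", {
  proj <- matrix(150, 60, 60)
  proj[30:32, 6:55] <- 60
  expect_identical(segment_canaliculi_2d(proj),
                   segment_canaliculi_2d(proj + 321))
})

test_that("pCan.P follows the printed pooled-ratio formula", {
  np <- 15L
  projections <- replicate(np, matrix(100, 25, 40), simplify = FALSE)
  region <- replicate(np, matrix(1L, 25, 40), simplify = FALSE)
  lacuna <- replicate(np, matrix(0L, 25, 40), simplify = FALSE)
  canal <- lapply(seq_len(np), function(i) {
    m <- matrix(FALSE, 25, 40); m[1:5, 1:10] <- TRUE; m  # 50 px
  })
  ps <- structure(list(projections = projections,
                       windows = data.frame(start = seq_len(np),
                                            end = seq_len(np)),
                       region_proj = region, lacuna_proj = lacuna,
                       voxel_size_nm = 100),
                  class = "projection_set")
  rp <- regional_porosity(ps, canal)
  expect_equal(rp$pcan_p, 750 / 14250)  # 15 * 50 / (15 * 950)
  # no canalicular pixels anywhere -> exactly zero
  rp0 <- regional_porosity(ps, replicate(np, matrix(FALSE, 25, 40),
                                         simplify = FALSE))
  expect_identical(rp0$pcan_p, 0)
  # duplicating every projection leaves the pooled ratio unchanged
  ps2 <- ps
  ps2$projections <- c(projections, projections)
  ps2$region_proj <- c(region, region)
  ps2$lacuna_proj <- c(lacuna, lacuna)
  ps2$windows <- rbind(ps$windows, ps$windows)
  expect_equal(regional_porosity(ps2, c(canal, canal))$pcan_p, rp$pcan_p)
  # adding a canalicular component strictly increases the porosity
  canal2 <- canal
  canal2[[1]][20:24, 30:39] <- TRUE
  expect_gt(regional_porosity(ps, canal2)$pcan_p, rp$pcan_p)
})

test_that("a region without mineral pixels is flagged", {
  np <- 2L
  projections <- replicate(np, matrix(100, 10, 10), simplify = FALSE)
  region <- replicate(np, {
    m <- matrix(1L, 10, 10); m[6:10, ] <- 2L; m
  }, simplify = FALSE)
  lacuna <- replicate(np, {
    m <- matrix(0L, 10, 10); m[6:10, ] <- 1L; m  # region 2 fully lacunar
  }, simplify = FALSE)
  canal <- replicate(np, matrix(FALSE, 10, 10), simplify = FALSE)
  ps <- structure(list(projections = projections,
                       windows = data.frame(start = 1:2, end = 1:2),
                       region_proj = region, lacuna_proj = lacuna,
                       voxel_size_nm = 100),
                  class = "projection_set")
  rp <- regional_porosity(ps, canal)
  expect_false(rp$flagged[1])
  expect_true(rp$flagged[2])
  expect_true(is.na(rp$pcan_p[2]))
})

test_that("phantom porosity tracks the projected tube-density oracle", {
  ph <- porosity_validation_phantom(41)
  cfg <- olcn:::porosity_phantom_config(41)
  seg <- segment_lacunae(ph$volume)
  ps <- min_intensity_projections(ph$volume, cfg$window_slices,
                                  cfg$n_projections,
                                  ph$truth$region_labels, seg$labels)
  cms <- lapply(ps$projections, function(p)
    segment_canaliculi_2d(p, min_component_px = cfg$min_component_px))
  rp <- regional_porosity(ps, cms)
  oracle <- oracle_projected_pcanp(ph, ps$windows)
  expect_equal(rp$pcan_p, oracle, tolerance = 0.25)
  # generated density ordering (young denser) is recovered
  expect_gt(rp$pcan_p[1], rp$pcan_p[2])
})
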