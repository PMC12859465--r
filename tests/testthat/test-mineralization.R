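# small pore-vs-mineral phantom used across mineralization tests: one region
# at GV 180, one lacuna at GV 60, desk-scale morphology radii
single_region_phantom <- function(noise_sd = 0, seed = 1L) {
  generate_phantom(phantom_params(
    grid_shape = c(40L, 40L, 40L), voxel_size_nm = 100,
    region_gv_means = 180, lacuna_gv = 60,
    lacunae = list(lacuna_spec(c(2, 2, 2), c(0.9, 0.9, 0.9))),
    noise_sd = noise_sd, seed = seed))
}

test_that("low-intensity mask captures the rasterized pores", {
  ph <- single_region_phantom()
  mb <- low_intensity_mask(ph$volume)
  pores <- ph$truth$lacuna_labels > 0L
  expect_gte(mean(mb[pores]), 0.99)
  expect_lte(mean(mb[!pores]), 0.01)
  expect_error(low_intensity_mask(volume(array(100, c(4, 4, 4)), 100)),
               "constant")
})

test_that("lacunar segmentation separates ellipsoids and drops fragments", {
  set.seed(9)
  lacs <- list(lacuna_spec(c(2.0, 2.2, 2.0), c(1.6, 1.2, 1.0)),
               lacuna_spec(c(4.2, 5.0, 5.5), c(1.4, 1.1, 0.9)),
               lacuna_spec(c(2.0, 6.0, 2.2), c(1.3, 1.1, 0.9)))
  frags <- lapply(1:20, function(i) {
    z <- runif(1, 0.5, 5.3); y <- runif(1, 0.5, 7.3); x <- runif(1, 4, 7.3)
    canaliculus_spec(rbind(c(z, y, x), c(z, y + 0.2, min(x + 2, 7.6))),
                     0.2, "intra_region")
  })
  ph <- generate_phantom(phantom_params(
    grid_shape = c(60L, 80L, 80L), voxel_size_nm = 100,
    region_gv_means = 180, lacuna_gv = 60,
    lacunae = lacs, canaliculi = frags, noise_sd = 0))
  seg <- segment_lacunae(ph$volume)
  expect_identical(seg$n, 3L)
  expect_true(all(seg$sizes >= 1500L))
  # matching recovers the three constructed ellipsoids
  expect_setequal(match_lacunae(seg$labels, ph$truth$lacuna_labels), 1:3)
})

test_that("exact 1500-voxel boundary semantics at the size filter", {
  base <- array(180, c(24, 24, 24))
  base[2:11, 2:11, 2:16] <- 60          # exactly 1500 dark voxels
  seg <- segment_lacunae(volume(base, 100), opening_radius_vox = 0)
  expect_identical(seg$n, 1L)
  expect_identical(seg$sizes, 1500L)
  base[2, 2, 2] <- 180                  # 1499 voxels
  seg2 <- segment_lacunae(volume(base, 100), opening_radius_vox = 0)
  expect_identical(seg2$n, 0L)
})

test_that("a thin neck is severed by the radius-7 opening", {
  m <- phantom_params(
    grid_shape = c(50L, 50L, 90L), voxel_size_nm = 100,
    region_gv_means = 180, lacuna_gv = 60,
    lacunae = list(lacuna_spec(c(2.5, 2.5, 2.0), c(1.1, 1.1, 1.1)),
                   lacuna_spec(c(2.5, 2.5, 6.8), c(1.1, 1.1, 1.1))),
    canaliculi = list(canaliculus_spec(
      rbind(c(2.5, 2.5, 2.0), c(2.5, 2.5, 6.8)), 0.3, "intra_region")),
    noise_sd = 0)
  ph <- generate_phantom(m)
  # one dark component before opening, two lacunae after
  pores <- ph$volume$data <= 100
  expect_identical(max(label_components(pores, 26)), 1L)
  seg <- segment_lacunae(ph$volume)
  expect_identical(seg$n, 2L)
})

test_that("segmentation is invariant to a constant gray-value offset", {
  ph <- single_region_phantom(noise_sd = 5)
  seg <- segment_lacunae(ph$volume)
  shifted <- volume(ph$volume$data + 500, ph$volume$voxel_size_nm)
  seg2 <- segment_lacunae(shifted)
  expect_identical(seg$labels, seg2$labels)
})

test_that("normalized mean gray value is exact on constant regions", {
  ph <- single_region_phantom()
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  mb <- low_intensity_mask(ph$volume)
  seg <- segment_lacunae(ph$volume, opening_radius_vox = 3)
  st <- regional_mean_gv(ph$volume, masks, mb, seg$labels,
                         region_erosion_px = 4, b_dilation_px = 2,
                         c_erosion_px = 2)
  expect_identical(st$excluded, FALSE)
  expect_identical(st$mean_gv_mineral, 180)
  expect_identical(st$mean_gv_lacunar, 60)
  expect_identical(st$norm_mean_gv, 3)
  # with noise the ratio stays within the expected band
  phn <- single_region_phantom(noise_sd = 5)
  stn <- regional_mean_gv(phn$volume, masks, low_intensity_mask(phn$volume),
                          segment_lacunae(phn$volume,
                                          opening_radius_vox = 3)$labels,
                          region_erosion_px = 4, b_dilation_px = 2,
                          c_erosion_px = 2)
  expect_equal(stn$norm_mean_gv, 3, tolerance = 0.05 / 3)
})

test_that("regions annihilated by the erosion are excluded with a flag", {
  ph <- get_fixture(1)
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  mb <- low_intensity_mask(ph$volume)
  seg <- segment_lacunae(ph$volume)
  # erosion radius larger than any region half-thickness kills both regions
  st <- regional_mean_gv(ph$volume, masks, mb, seg$labels,
                         region_erosion_px = 120)
  expect_true(all(st$excluded))
  expect_error(rank_regions(st), "no region")
})

test_that("ranking follows normalized gray value with stable ties", {
  st <- data.frame(region_id = 1:3, norm_mean_gv = c(2.1, 3.0, 2.6),
                   excluded = FALSE)
  expect_identical(rank_regions(st)$rank, c(1L, 3L, 2L))
  one <- data.frame(region_id = 1L, norm_mean_gv = 2.5, excluded = FALSE)
  expect_identical(rank_regions(one)$rank, 1L)
  tie <- data.frame(region_id = c(2L, 1L), norm_mean_gv = c(2.5, 2.5),
                    excluded = FALSE)
  r <- rank_regions(tie)
  expect_identical(r$rank[r$region_id == 1L], 1L)
  # permuting region ids permutes but preserves the order relation
  st2 <- st[c(3, 1, 2), ]
  r2 <- rank_regions(st2)
  expect_identical(r2$rank[match(1:3, st2$region_id)],
                   c(1L, 3L, 2L))
})

test_that("fixture ranks reproduce the generation order young to old", {
  ph <- get_fixture(1)
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  st <- rank_regions(regional_mean_gv(
    ph$volume, masks, low_intensity_mask(ph$volume),
    segment_lacunae(ph$volume)$labels))
  expect_identical(st$rank, c(1L, 2L))
  expect_gt(st$norm_mean_gv[2], st$norm_mean_gv[1])
})
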