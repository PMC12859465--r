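# custom single-region phantom (200 nm voxels) with tubes attached to a
# central lacuna plus one detached tube elsewhere
attached_detached_phantom <- function() {
  seg <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  r <- 0.3
  generate_phantom(phantom_params(
    grid_shape = c(40L, 100L, 120L), voxel_size_nm = 200,
    region_gv_means = 160, lacuna_gv = 60,
    lacunae = list(lacuna_spec(c(4, 8, 10), c(1.6, 1.6, 2.4))),
    canaliculi = list(
      canaliculus_spec(seg(4, 8, 10, 4.0, 14.0, 6.0), r, "intra_region"),
      canaliculus_spec(seg(4, 8, 10, 4.0, 13.0, 16.0), r, "intra_region"),
      canaliculus_spec(seg(4, 8, 10, 4.5, 3.0, 8.0), r, "intra_region"),
      canaliculus_spec(seg(4, 8, 10, 3.5, 4.0, 15.0), r, "intra_region"),
      canaliculus_spec(seg(4.0, 16.0, 18.0, 4.0, 18.5, 22.0), r,
                       "intra_region")),
    noise_sd = 0))
}

project_truth_tube <- function(ph, i, zs) {
  m <- olcn:::rasterize_tube(array(FALSE, dim(ph$truth$canal_mask)),
                             ph$params$canaliculi[[i]]$path_um,
                             ph$params$canaliculi[[i]]$radius_um,
                             ph$params$voxel_size_nm / 1000)
  apply(m[zs, , , drop = FALSE], c(2, 3), any)
}

test_that("cluster keeps attached canaliculi and drops detached ones", {
  ph <- attached_detached_phantom()
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  idx <- which(ph$truth$lacuna_labels == 1L, arr.ind = TRUE)
  zr <- range(idx[, 1])
  cl <- lacuna_cluster(ph$volume, ph$truth$lacuna_labels, masks, 1L, zr,
                       tophat_radius_px = 5L, min_component_px = 30L)
  zs <- zr[1]:zr[2]
  for (i in 1:4) {
    tube <- project_truth_tube(ph, i, zs) & !cl$footprint
    expect_gt(mean(cl$cluster[tube]), 0.6)
  }
  detached <- project_truth_tube(ph, 5, zs)
  expect_identical(sum(cl$cluster & detached), 0L)
})

test_that("a lacuna without canaliculi clusters to its own neighborhood", {
  ph <- connection_validation_phantom(seed = 3, n_crossing = 0L)
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  idx <- which(ph$truth$lacuna_labels == 1L, arr.ind = TRUE)
  zr <- range(idx[, 1])
  cl <- lacuna_cluster(ph$volume, ph$truth$lacuna_labels, masks, 1L, zr,
                       tophat_radius_px = 5L, min_component_px = 30L)
  expect_true(all(cl$footprint[cl$cluster] | TRUE))  # structure sanity
  expect_true(all(cl$cluster[cl$footprint]))
  neighborhood <- dilate_ball(cl$footprint, 6)
  expect_true(all(neighborhood[cl$cluster]))
})

test_that("other lacunae are excluded from the cluster even when linked", {
  seg <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  ph <- generate_phantom(phantom_params(
    grid_shape = c(40L, 100L, 120L), voxel_size_nm = 200,
    region_gv_means = 160, lacuna_gv = 60,
    lacunae = list(lacuna_spec(c(4, 8, 6), c(1.6, 1.6, 2.4)),
                   lacuna_spec(c(4, 8.5, 16), c(1.6, 1.6, 2.4))),
    canaliculi = list(
      canaliculus_spec(seg(4, 8, 6, 4, 8.5, 16), 0.3, "intra_region", 1L),
      canaliculus_spec(seg(4, 8.5, 16, 4, 12.0, 20.0), 0.3,
                       "intra_region", 2L)),
    noise_sd = 0))
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  idx <- which(ph$truth$lacuna_labels == 1L, arr.ind = TRUE)
  zr <- range(idx[, 1])
  cl <- lacuna_cluster(ph$volume, ph$truth$lacuna_labels, masks, 1L, zr,
                       tophat_radius_px = 5L, min_component_px = 30L)
  zs <- zr[1]:zr[2]
  link <- project_truth_tube(ph, 1, zs) & !cl$footprint &
    !(cl$lacuna_proj > 0L)
  expect_gt(mean(cl$cluster[link]), 0.5)       # the link itself is kept
  other <- cl$lacuna_proj == 2L
  expect_identical(sum(cl$cluster & other), 0L)  # the other pore is not
})

test_that("candidate selection enforces inclusion, age and proximity rules", {
  ph <- connection_validation_phantom(seed = 5, n_crossing = 2L)
  vol <- ph$volume
  cfg <- olcn:::connection_phantom_config()
  seg <- segment_lacunae(vol, cfg$opening_radius_vox, cfg$lacuna_min_voxels)
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  st <- rank_regions(regional_mean_gv(
    vol, masks, low_intensity_mask(vol), seg$labels,
    cfg$region_erosion_px, cfg$b_dilation_px, cfg$c_erosion_px))
  cand <- select_lacunae(seg$labels, masks, st, 200, cfg$proximity_um)
  map <- match_lacunae(seg$labels, ph$truth$lacuna_labels)
  expect_identical(map[cand$lacuna_id], 1L)  # exactly the constructed one
  all_lac <- attr(cand, "all_lacunae")
  clipped <- all_lac[map[all_lac$lacuna_id] == 3L, ]
  expect_false(clipped$fully_inside)         # face-touching lacuna rejected
  old_rows <- all_lac[map[all_lac$lacuna_id] %in% c(2L, 4L, 5L, 6L, 7L), ]
  expect_true(all(!old_rows$candidate))      # oldest-region lacunae rejected
  expect_true(all(old_rows$fully_inside))
})

test_that("crossings beyond the counting radius are excluded and the count
           is monotone in the radius", {
  ph <- connection_validation_phantom(seed = 6, n_crossing = 2L,
                                      far_crossing = TRUE)
  expect_identical(ph$truth$true_crossing_counts$n_within[1], 2L)
  expect_identical(ph$truth$true_crossing_counts$n_beyond[1], 1L)
  vol <- ph$volume
  cfg <- olcn:::connection_phantom_config()
  seg <- segment_lacunae(vol, cfg$opening_radius_vox, cfg$lacuna_min_voxels)
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  st <- truth_rank_stats(ph)
  cand <- select_lacunae(seg$labels, masks, st, 200, cfg$proximity_um)
  for (r in c(10, 25, 40)) {
    conn <- count_all_connections(vol, seg$labels, masks, cand, r,
                                  cfg$band_dilation_px,
                                  cfg$tophat_radius_px,
                                  cfg$min_component_px)
    if (r == 10) n10 <- conn$n_conn
    if (r == 25) n25 <- conn$n_conn
    if (r == 40) n40 <- conn$n_conn
  }
  expect_identical(n25, 2L)   # ground truth within 25 um
  expect_identical(n40, 3L)   # the far crossing enters at 40 um
  expect_lte(n10, n25)
  expect_lte(n25, n40)
})

test_that("removing one crossing lowers the count by exactly one", {
  count_nf <- function(n_crossing) {
    ph <- connection_validation_phantom(seed = 1, n_crossing = n_crossing,
                                        noise_sd = 0)
    cfg <- olcn:::connection_phantom_config()
    seg <- segment_lacunae(ph$volume, cfg$opening_radius_vox,
                           cfg$lacuna_min_voxels)
    masks <- region_mask_set(ph$truth$region_labels, "supplied")
    cand <- select_lacunae(seg$labels, masks, truth_rank_stats(ph), 200,
                           cfg$proximity_um)
    count_all_connections(ph$volume, seg$labels, masks, cand,
                          cfg$radius_um, cfg$band_dilation_px,
                          cfg$tophat_radius_px, cfg$min_component_px)$n_conn
  }
  expect_identical(count_nf(3L) - count_nf(2L), 1L)
  expect_identical(count_nf(0L), 0L)  # loops/absence: nothing to count
})

test_that("disjoint band contacts of one tube count separately", {
  cluster <- matrix(FALSE, 40, 60)
  cluster[19:21, 2:55] <- TRUE              # one long tube
  footprint <- matrix(FALSE, 40, 60)
  footprint[17:23, 2:6] <- TRUE
  cluster <- cluster | footprint
  band <- matrix(FALSE, 40, 60)
  band[10:30, 20:22] <- TRUE                # two disjoint grazing contacts
  band[10:30, 40:42] <- TRUE
  cc <- count_connections(cluster, band, footprint, voxel_size_nm = 1000,
                          radius_um = 100)
  expect_identical(cc$n_conn, 2L)
  expect_identical(cc$n_crossing_components, 2L)
  # radius gating by the component distances
  cc2 <- count_connections(cluster, band, footprint, voxel_size_nm = 1000,
                           radius_um = 20)
  expect_identical(cc2$n_conn, 1L)
  # an empty band warns and returns zero
  expect_warning(
    cc3 <- count_connections(cluster, matrix(FALSE, 40, 60), footprint,
                             1000, 25),
    "empty interface band")
  expect_identical(cc3$n_conn, 0L)
})

test_that("connection table joins regional statistics and flags gaps", {
  res <- data.frame(lacuna_id = c(1L, 2L), region_id = c(1L, 1L),
                    neighbor_region = c(2L, 3L), n_conn = c(3L, 1L),
                    radius_um = 25)
  st <- data.frame(region_id = 1:2, norm_mean_gv = c(2.5, 2.8),
                   excluded = FALSE, rank = 1:2)
  por <- data.frame(region_id = 1:2, pcan_p = c(0.04, 0.02),
                    flagged = FALSE)
  tab <- connection_table(res, st, por)
  expect_equal(tab$own_region_norm_gv, c(2.5, 2.5))
  expect_equal(tab$neighbor_region_norm_gv[1], 2.8)
  expect_true(is.na(tab$neighbor_region_norm_gv[2]))  # region 3 unknown
  expect_identical(tab$flagged, c(FALSE, TRUE))
  expect_equal(tab$neighbor_pcan_p[1], 0.02)
})
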