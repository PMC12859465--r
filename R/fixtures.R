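#' The default validation phantom
#'
#' A documented desk-scale fixture exercising every pipeline stage: two
#' remodeling regions (young GV 150 below, old GV 165 above a wavy cement
#' line at GV 195, pores at GV 60; regional contrast is kept small relative
#' to the pore-mineral contrast, as in phase-retrieved nano-CT of bone),
#' 100 nm voxels on a 112 x 228 x 160 grid
#' (11.1 x 22.7 x 15.9 um). It contains four candidate lacunae in the young
#' region near the cement line with 3 / 2 / 1 / 0 crossing canaliculi (the
#' last carries two canalicular loops instead), one lacuna clipped by a
#' volume face, two lacunae in the old region, eight sub-resolution noise
#' blobs below the lacunar size filter, and intra-region canaliculi with a
#' denser network in the young region. Geometry is fixed; the seed drives
#' only the Gaussian noise field, so ground truth is identical across seeds.
#'
#' @param seed noise seed.
#' @param noise_sd noise standard deviation in gray-value units (default 6,
#'   about 7\% of the pore-mineral contrast of 90).
#' @return an \code{olcn_phantom} (see \code{\link{generate_phantom}}).
#' @export
default_validation_phantom <- function(seed = 1L, noise_sd = 6) {
  lac <- list(
    lacuna_spec(c(3.0, 9.7, 2.0),  c(1.1, 1.1, 1.8)),   # L1: 3 crossings
    lacuna_spec(c(5.5, 7.7, 6.0),  c(1.1, 1.1, 1.8)),   # L2: 2 crossings
    lacuna_spec(c(8.0, 9.7, 10.0), c(1.1, 1.1, 1.8)),   # L3: 1 crossing
    lacuna_spec(c(3.0, 7.7, 13.8), c(1.1, 1.1, 1.8)),   # L4: loops only
    lacuna_spec(c(0.5, 6.0, 8.0),  c(1.1, 1.1, 1.8),
                touches_boundary = TRUE),                # L5: clipped
    lacuna_spec(c(5.5, 15.5, 3.0), c(1.1, 1.1, 1.8)),   # L6: old region
    lacuna_spec(c(8.5, 18.0, 11.0), c(1.1, 1.1, 1.8)))  # L7: old region
  blob_centers <- list(c(2.0, 3.0, 5.0), c(9.0, 4.0, 12.0),
                       c(4.0, 16.0, 3.0), c(7.0, 19.0, 14.0),
                       c(10.0, 2.5, 8.0), c(2.0, 20.0, 7.0),
                       c(6.0, 5.0, 14.5), c(9.0, 17.5, 2.5))
  for (b in blob_centers)
    lac[[length(lac) + 1L]] <- lacuna_spec(b, c(0.15, 0.15, 0.15))

  seg <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  r <- 0.2
  can <- list(
    # crossings from L1 (fanning out so band components stay separated)
    canaliculus_spec(seg(3.0, 9.7, 2.0,  3.0, 14.0, 0.3),  r, "crossing", 1L),
    canaliculus_spec(seg(3.0, 9.7, 2.0,  3.0, 14.0, 2.0),  r, "crossing", 1L),
    canaliculus_spec(seg(3.0, 9.7, 2.0,  3.4, 14.0, 3.9),  r, "crossing", 1L),
    # crossings from L2
    canaliculus_spec(seg(5.5, 7.7, 6.0,  5.5, 13.0, 4.6),  r, "crossing", 2L),
    canaliculus_spec(seg(5.5, 7.7, 6.0,  5.5, 13.0, 7.4),  r, "crossing", 2L),
    # crossing from L3
    canaliculus_spec(seg(8.0, 9.7, 10.0, 8.0, 14.2, 10.0), r, "crossing", 3L),
    # loops from L4 (U-shaped, apex short of the cement line)
    canaliculus_spec(seg(3.0, 8.5, 12.6, 3.0, 9.3, 13.2,
                         3.0, 9.3, 14.4, 3.0, 8.5, 15.0), r, "loop", 4L),
    canaliculus_spec(seg(2.6, 8.3, 12.8, 2.6, 9.2, 13.5,
                         2.6, 9.2, 14.2, 2.6, 8.3, 14.8), r, "loop", 4L),
    # intra-region canaliculi, young region (denser network)
    canaliculus_spec(seg(1.0, 8.0, 1.0,   1.5, 8.6, 6.0),  r, "intra_region"),
    canaliculus_spec(seg(2.0, 8.8, 4.0,   2.5, 9.0, 9.0),  r, "intra_region"),
    canaliculus_spec(seg(4.0, 7.5, 9.5,   4.0, 8.8, 14.0), r, "intra_region"),
    canaliculus_spec(seg(6.5, 8.2, 1.5,   7.0, 9.0, 5.5),  r, "intra_region"),
    canaliculus_spec(seg(7.5, 7.0, 7.5,   8.0, 8.5, 12.5), r, "intra_region"),
    canaliculus_spec(seg(9.5, 8.5, 2.0,   10.0, 9.0, 7.0), r, "intra_region"),
    canaliculus_spec(seg(10.5, 7.2, 9.0,  10.5, 8.8, 13.5), r, "intra_region"),
    canaliculus_spec(seg(1.5, 6.9, 8.0,   2.0, 7.6, 12.5), r, "intra_region"),
    canaliculus_spec(seg(5.0, 8.9, 10.5,  5.5, 9.0, 15.0), r, "intra_region"),
    canaliculus_spec(seg(8.5, 6.8, 0.5,   9.0, 8.0, 4.0),  r, "intra_region"),
    # intra-region canaliculi, old region (sparser network)
    canaliculus_spec(seg(2.0, 14.5, 2.0,  2.5, 15.0, 6.5), r, "intra_region"),
    canaliculus_spec(seg(7.5, 14.2, 8.0,  8.0, 15.2, 12.0), r, "intra_region"),
    canaliculus_spec(seg(3.5, 15.5, 9.0,  3.5, 16.0, 13.0), r, "intra_region"),
    canaliculus_spec(seg(9.0, 14.0, 1.0,  9.5, 14.6, 5.0), r, "intra_region"))

  params <- phantom_params(
    grid_shape = c(112L, 228L, 160L), voxel_size_nm = 100,
    region_gv_means = c(150, 165), cement_gv = 195, lacuna_gv = 60,
    region_boundaries_um = 11.4, cement_thickness_um = 1.2,
    cement_wave_amplitude_um = 1, cement_wave_period_um = 8,
    lacunae = lac, canaliculi = can, noise_sd = noise_sd, seed = seed)
  generate_phantom(params)
}

#' Tube-density phantom for porosity validation
#'
#' Two regions on a 100 x 120 x 140 grid (100 nm voxels) populated with
#' randomly placed intra-region canaliculi, the young region holding
#' \code{density_ratio} times as many tubes as the old one, plus two
#' lacunae per region. The default tube count gives a low-intensity voxel
#' fraction of about 3\%, in the range of real lacunar-canalicular
#' networks; much sparser networks would leave the gray-value histogram
#' dominated by the (subtle) regional contrast and break the pore/mineral
#' Otsu separation that the whole analysis presumes. Unlike
#' \code{\link{default_validation_phantom}}, the tube geometry is drawn
#' from the seed, giving an independent phantom per seed.
#'
#' @param seed seed for both tube placement and noise.
#' @param density_ratio young/old tube-count ratio (default 2, a clearly
#'   denser young network as seen across remodeling regions).
#' @param n_young number of young-region tubes.
#' @param noise_sd image noise sd.
#' @return an \code{olcn_phantom}.
#' @export
porosity_validation_phantom <- function(seed = 1L, density_ratio = 2,
                                        n_young = 24L, noise_sd = 6) {
  set.seed(seed)
  ext <- c(9.9, 11.9, 13.9)  # grid (100, 120, 140) at 100 nm
  rand_tube <- function(ylo, yhi) {
    len <- stats::runif(1, 3.5, 5.5)
    ang <- stats::runif(1, 0, 2 * pi)
    z0 <- stats::runif(1, 0.8, ext[1] - 0.8)
    y0 <- stats::runif(1, ylo, yhi)
    x0 <- stats::runif(1, 0.5, ext[3] - 0.5)
    dz <- stats::runif(1, -0.6, 0.6)
    p2 <- c(z0 + dz, min(max(y0 + len * 0.15 * sin(ang), ylo), yhi),
            x0 + len * cos(ang))
    p2[1] <- min(max(p2[1], 0.3), ext[1] - 0.3)
    p2[3] <- min(max(p2[3], 0.3), ext[3] - 0.3)
    canaliculus_spec(rbind(c(z0, y0, x0), p2), 0.2, "intra_region")
  }
  n_old <- max(1L, round(n_young / density_ratio))
  can <- c(lapply(seq_len(n_young), function(i) rand_tube(1.0, 4.3)),
           lapply(seq_len(n_old), function(i) rand_tube(7.7, 10.9)))
  lac <- list(lacuna_spec(c(5.0, 2.6, 3.0), c(1.1, 1.1, 1.6)),
              lacuna_spec(c(2.5, 2.8, 9.5), c(1.1, 1.1, 1.6)),
              lacuna_spec(c(5.0, 9.2, 9.0), c(1.1, 1.1, 1.6)),
              lacuna_spec(c(2.5, 9.0, 3.5), c(1.1, 1.1, 1.6)))
  params <- phantom_params(
    grid_shape = c(100L, 120L, 140L), voxel_size_nm = 100,
    region_gv_means = c(150, 165), cement_gv = 195, lacuna_gv = 60,
    region_boundaries_um = 6.0, cement_thickness_um = 1.0,
    cement_wave_amplitude_um = 0.8, cement_wave_period_um = 6,
    lacunae = lac, canaliculi = can, noise_sd = noise_sd, seed = seed)
  generate_phantom(params)
}

#' Coarse-voxel phantom for connection counting
#'
#' A 200 nm voxel phantom (64 x 150 x 220 grid, 12.6 x 29.8 x 43.8 um) with
#' one candidate lacuna in the young region carrying a configurable number
#' of cement-line crossings, optionally one additional long crossing whose
#' interface contact lies beyond 25 um of the lacuna, a face-clipped lacuna,
#' an old-region lacuna, and a few intra-region canaliculi. The wide x
#' extent is what allows beyond-radius crossings to exist. The old-region
#' gray value is a parameter so families of these phantoms can encode a
#' relation between crossing number and neighbor mineralization.
#'
#' @param seed noise seed (geometry is fixed given the other arguments).
#' @param n_crossing number of within-radius crossings from the candidate
#'   lacuna (0 to 4).
#' @param old_gv old-region mean gray value (young region is 150; keep the
#'   regional contrast small against the pore-mineral contrast, e.g.
#'   154-164, as in real phase-retrieved data).
#' @param far_crossing add one crossing at ~27 um in-plane distance.
#' @param noise_sd image noise sd.
#' @return an \code{olcn_phantom}.
#' @export
connection_validation_phantom <- function(seed = 1L, n_crossing = 3L,
                                          old_gv = 160, far_crossing = FALSE,
                                          noise_sd = 6) {
  stopifnot(n_crossing >= 0L, n_crossing <= 4L, old_gv > 150)
  seg <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  r <- 0.25
  lac <- list(
    lacuna_spec(c(6.0, 11.8, 10.0), c(1.6, 1.6, 2.4)),             # candidate
    lacuna_spec(c(6.0, 22.0, 30.0), c(1.6, 1.6, 2.4)),             # old region
    lacuna_spec(c(1.0, 8.0, 35.0), c(1.6, 1.6, 2.4),
                touches_boundary = TRUE),                          # clipped
    lacuna_spec(c(3.5, 24.0, 12.0), c(1.6, 1.6, 2.4)),             # old region
    lacuna_spec(c(9.0, 20.5, 38.0), c(1.6, 1.6, 2.4)),             # old region
    lacuna_spec(c(2.5, 18.5, 22.0), c(1.6, 1.6, 2.4)),             # old region
    lacuna_spec(c(10.0, 26.5, 6.0), c(1.6, 1.6, 2.4)))             # old region
  offs <- c(-4, -1.5, 1.5, 4)
  can <- lapply(seq_len(n_crossing), function(i)
    canaliculus_spec(seg(6.0, 11.8, 10.0, 6.0, 18.0, 10.0 + offs[i]),
                     r, "crossing", 1L))
  if (far_crossing)
    can[[length(can) + 1L]] <- canaliculus_spec(
      seg(6.0, 11.8, 10.0, 6.0, 13.0, 38.0, 6.0, 18.0, 42.0),
      r, "crossing", 1L)
  rl <- 0.3
  can <- c(can, list(
    canaliculus_spec(seg(2.0, 8.0, 3.0, 2.5, 10.0, 15.0), rl, "intra_region"),
    canaliculus_spec(seg(9.0, 5.0, 18.0, 9.5, 9.0, 30.0), rl, "intra_region"),
    canaliculus_spec(seg(3.0, 9.5, 26.0, 3.0, 12.0, 38.0), rl, "intra_region"),
    canaliculus_spec(seg(10.5, 3.0, 2.0, 11.0, 6.0, 14.0), rl, "intra_region"),
    canaliculus_spec(seg(1.5, 11.0, 20.0, 2.0, 7.0, 32.0), rl, "intra_region"),
    canaliculus_spec(seg(3.0, 20.0, 4.0, 3.5, 22.0, 16.0), rl, "intra_region"),
    canaliculus_spec(seg(8.0, 24.0, 18.0, 8.0, 26.0, 30.0), rl, "intra_region"),
    canaliculus_spec(seg(5.0, 27.0, 28.0, 5.5, 24.5, 40.0), rl, "intra_region"),
    canaliculus_spec(seg(1.5, 19.5, 32.0, 2.0, 21.5, 42.0), rl, "intra_region"),
    canaliculus_spec(seg(10.5, 21.0, 2.0, 11.0, 19.0, 12.0), rl, "intra_region")))
  params <- phantom_params(
    grid_shape = c(64L, 150L, 220L), voxel_size_nm = 200,
    region_gv_means = c(150, old_gv), cement_gv = old_gv + 35,
    lacuna_gv = 60, region_boundaries_um = 15.0,
    cement_thickness_um = 1.0, cement_wave_amplitude_um = 0.6,
    cement_wave_period_um = 8,
    lacunae = lac, canaliculi = can, noise_sd = noise_sd, seed = seed)
  generate_phantom(params)
}
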