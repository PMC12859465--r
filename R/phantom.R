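#' Lacuna specification for the bone phantom
#'
#' An axis-aligned ellipsoidal pore. Centers and semi-axes are physical
#' (micrometers), in (z, y, x) order matching the volume axes.
#'
#' @param center_um 3D center (z, y, x) in um.
#' @param semi_axes_um 3 semi-axis lengths (z, y, x) in um.
#' @param touches_boundary if TRUE the ellipsoid may be clipped by the grid
#'   (used to build lacunae that are not fully included in the scan).
#' @return an object of class \code{lacuna_spec}.
#' @export
lacuna_spec <- function(center_um, semi_axes_um, touches_boundary = FALSE) {
  stopifnot(length(center_um) == 3L, length(semi_axes_um) == 3L,
            all(semi_axes_um > 0))
  structure(list(center_um = as.numeric(center_um),
                 semi_axes_um = as.numeric(semi_axes_um),
                 touches_boundary = isTRUE(touches_boundary)),
            class = "lacuna_spec")
}

#' Canaliculus specification for the bone phantom
#'
#' A tube of constant radius along a 3D polyline. \code{kind} records the
#' intended topology relative to the cement line: \code{crossing} paths must
#' intersect the cement surface exactly once, \code{loop} and
#' \code{intra_region} paths must stay clear of it (checked at generation).
#'
#' @param path_um n x 3 matrix of (z, y, x) points in um.
#' @param radius_um tube radius in um (canaliculi are ~0.1-0.5 um thick).
#' @param kind one of "intra_region", "crossing", "loop", "dead_end".
#' @param source_lacuna index into the phantom's lacuna list, or NA.
#' @return an object of class \code{canaliculus_spec}.
#' @export
canaliculus_spec <- function(path_um, radius_um,
                             kind = c("intra_region", "crossing", "loop",
                                      "dead_end"),
                             source_lacuna = NA_integer_) {
  kind <- match.arg(kind)
  path_um <- as.matrix(path_um)
  stopifnot(ncol(path_um) == 3L, nrow(path_um) >= 2L, radius_um > 0)
  structure(list(path_um = path_um, radius_um = as.numeric(radius_um),
                 kind = kind, source_lacuna = as.integer(source_lacuna)),
            class = "canaliculus_spec")
}

#' Parameters of the synthetic bone phantom
#'
#' Defines a stack of 1-3 remodeling regions along y, separated by sinusoidal
#' hyper-mineralized cement lines (wave along x, constant in z, emulating the
#' groove pattern left by aligned resorption pits), populated with ellipsoidal
#' lacunae and tubular canaliculi. Gray values follow the tissue-age contract
#' of phase-contrast nano-CT: pores darkest, then younger (less mineralized)
#' matrix, older matrix, and the cement line brightest.
#'
#' @param grid_shape voxels per axis (nz, ny, nx).
#' @param voxel_size_nm isotropic voxel size (default 100 nm, so realistic
#'   lacunae fit a desk-scale grid; physical thresholds are converted through
#'   this value, never hard-coded in voxels).
#' @param region_gv_means mean gray value per region, ordered young to old,
#'   strictly increasing; region 1 occupies the lowest y band.
#' @param cement_gv cement-line gray value, strictly above all region means.
#' @param lacuna_gv pore gray value, strictly below all region means.
#' @param region_boundaries_um base y positions (um) of the region
#'   boundaries, strictly increasing, length \code{length(region_gv_means)-1}.
#' @param cement_thickness_um,cement_wave_amplitude_um,cement_wave_period_um
#'   cement sheet geometry (um).
#' @param lacunae list of \code{\link{lacuna_spec}}.
#' @param canaliculi list of \code{\link{canaliculus_spec}}.
#' @param noise_sd standard deviation of the additive Gaussian image noise
#'   (gray-value units).
#' @param seed integer seed for the noise field.
#' @param within_radius_um counting radius used to split ground-truth
#'   crossing counts into within/beyond (default 25 um).
#' @return an object of class \code{phantom_params}.
#' @export
phantom_params <- function(grid_shape, voxel_size_nm = 100,
                           region_gv_means, cement_gv = NA_real_,
                           lacuna_gv, region_boundaries_um = numeric(0),
                           cement_thickness_um = 1.2,
                           cement_wave_amplitude_um = 1,
                           cement_wave_period_um = 8,
                           lacunae = list(), canaliculi = list(),
                           noise_sd = 0, seed = 1L,
                           within_radius_um = 25) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            voxel_size_nm > 0, noise_sd >= 0)
  n_regions <- length(region_gv_means)
  if (n_regions < 1L || n_regions > 3L)
    stop("phantom_params: 1 to 3 regions supported")
  if (n_regions > 1L && any(diff(region_gv_means) <= 0))
    stop("phantom_params: region_gv_means must be strictly increasing (young to old)")
  if (lacuna_gv >= min(region_gv_means))
    stop("phantom_params: lacuna_gv must be below all region means")
  if (n_regions > 1L) {
    if (length(region_boundaries_um) != n_regions - 1L)
      stop("phantom_params: need ", n_regions - 1L, " region boundaries")
    if (is.na(cement_gv) || cement_gv <= max(region_gv_means))
      stop("phantom_params: cement_gv must exceed all region means")
    if (any(diff(c(0, region_boundaries_um)) <= 0))
      stop("phantom_params: region boundaries must be increasing and positive")
  }
  px <- voxel_size_nm / 1000
  ext <- (grid_shape - 1L) * px  # physical extent (z, y, x) in um
  for (i in seq_along(lacunae)) {
    sp <- lacunae[[i]]
    stopifnot(inherits(sp, "lacuna_spec"))
    if (!sp$touches_boundary &&
        (any(sp$center_um - sp$semi_axes_um < 0) ||
         any(sp$center_um + sp$semi_axes_um > ext)))
      stop("phantom_params: lacuna spec ", i, " exits the grid")
  }
  for (i in seq_along(canaliculi)) {
    sp <- canaliculi[[i]]
    stopifnot(inherits(sp, "canaliculus_spec"))
    if (any(sp$path_um < 0) || any(sweep(sp$path_um, 2, ext) > 0))
      stop("phantom_params: canaliculus spec ", i, " exits the grid")
    if (!is.na(sp$source_lacuna) &&
        (sp$source_lacuna < 1L || sp$source_lacuna > length(lacunae)))
      stop("phantom_params: canaliculus spec ", i,
           " references unknown lacuna")
  }
  structure(list(grid_shape = grid_shape, voxel_size_nm = voxel_size_nm,
                 region_gv_means = as.numeric(region_gv_means),
                 cement_gv = as.numeric(cement_gv),
                 lacuna_gv = as.numeric(lacuna_gv),
                 region_boundaries_um = as.numeric(region_boundaries_um),
                 cement_thickness_um = cement_thickness_um,
                 cement_wave_amplitude_um = cement_wave_amplitude_um,
                 cement_wave_period_um = cement_wave_period_um,
                 lacunae = lacunae, canaliculi = canaliculi,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 within_radius_um = within_radius_um),
            class = "phantom_params")
}

# y position of cement boundary k at in-plane position x (vectors, um)
boundary_y <- function(params, k, x_um) {
  params$region_boundaries_um[k] +
    params$cement_wave_amplitude_um *
      sin(2 * pi * x_um / params$cement_wave_period_um)
}

# mark voxels whose center lies within radius of the polyline
rasterize_tube <- function(mask, path_um, radius_um, px) {
  d <- dim(mask)
  r2 <- radius_um^2 + 1e-12
  for (s in seq_len(nrow(path_um) - 1L)) {
    p <- path_um[s, ]; q <- path_um[s + 1L, ]
    u <- q - p
    L2 <- sum(u^2)
    lo <- pmax(floor((pmin(p, q) - radius_um) / px) + 1, 1)
    hi <- pmin(ceiling((pmax(p, q) + radius_um) / px) + 1, d)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    zz <- (iz - 1) * px; yy <- (iy - 1) * px; xx <- (ix - 1) * px
    lz <- length(iz); ly <- length(iy); lx <- length(ix)
    Z <- array(zz, c(lz, ly, lx))
    Y <- aperm(array(yy, c(ly, lz, lx)), c(2, 1, 3))
    X <- aperm(array(xx, c(lx, lz, ly)), c(2, 3, 1))
    if (L2 < 1e-12) {
      d2 <- (Z - p[1])^2 + (Y - p[2])^2 + (X - p[3])^2
    } else {
      tt <- ((Z - p[1]) * u[1] + (Y - p[2]) * u[2] + (X - p[3]) * u[3]) / L2
      tt[tt < 0] <- 0; tt[tt > 1] <- 1
      d2 <- (Z - p[1] - tt * u[1])^2 + (Y - p[2] - tt * u[2])^2 +
            (X - p[3] - tt * u[3])^2
    }
    sub <- mask[iz, iy, ix, drop = FALSE]
    sub[d2 <= r2] <- TRUE
    mask[iz, iy, ix] <- sub
  }
  mask
}

rasterize_ellipsoid <- function(d, center_um, semi_um, px) {
  lo <- pmax(floor((center_um - semi_um) / px) + 1, 1)
  hi <- pmin(ceiling((center_um + semi_um) / px) + 1, d)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  zz <- ((iz - 1) * px - center_um[1]) / semi_um[1]
  yy <- ((iy - 1) * px - center_um[2]) / semi_um[2]
  xx <- ((ix - 1) * px - center_um[3]) / semi_um[3]
  lz <- length(iz); ly <- length(iy); lx <- length(ix)
  Z <- array(zz^2, c(lz, ly, lx))
  Y <- aperm(array(yy^2, c(ly, lz, lx)), c(2, 1, 3))
  X <- aperm(array(xx^2, c(lx, lz, ly)), c(2, 3, 1))
  list(iz = iz, iy = iy, ix = ix, inside = (Z + Y + X) <= 1)
}

# crossing points of a polyline with the cement center surfaces; returns a
# list of (z, y, x, boundary) rows
path_crossings <- function(params, path_um, step_um) {
  pts <- NULL
  for (s in seq_len(nrow(path_um) - 1L)) {
    p <- path_um[s, ]; q <- path_um[s + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((q - p)^2)) / step_um) + 1L)
    tt <- seq(0, 1, length.out = n)
    seg <- cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]),
                 p[3] + tt * (q[3] - p[3]))
    pts <- rbind(pts, if (s == 1L) seg else seg[-1L, , drop = FALSE])
  }
  out <- NULL
  for (k in seq_along(params$region_boundaries_um)) {
    f <- pts[, 2] - boundary_y(params, k, pts[, 3])
    sgn <- sign(f)
    sgn[sgn == 0] <- 1e-9  # a sample exactly on the surface counts as above
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in idx) {
      w <- abs(f[i]) / (abs(f[i]) + abs(f[i + 1L]))
      out <- rbind(out, c(pts[i, ] + w * (pts[i + 1L, ] - pts[i, ]), k))
    }
  }
  out
}

# minimum clearance of a polyline from all cement center surfaces (um)
path_clearance <- function(params, path_um, step_um) {
  if (length(params$region_boundaries_um) == 0L) return(Inf)
  best <- Inf
  for (s in seq_len(nrow(path_um) - 1L)) {
    p <- path_um[s, ]; q <- path_um[s + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((q - p)^2)) / step_um) + 1L)
    tt <- seq(0, 1, length.out = n)
    y <- p[2] + tt * (q[2] - p[2]); x <- p[3] + tt * (q[3] - p[3])
    for (k in seq_along(params$region_boundaries_um))
      best <- min(best, min(abs(y - boundary_y(params, k, x))))
  }
  best
}

dist_to_lacuna_surface <- function(point_um, spec) {
  th <- seq(0, pi, length.out = 60)
  ph <- seq(0, 2 * pi, length.out = 121)[-121]
  g <- expand.grid(th = th, ph = ph)
  sz <- spec$center_um[1] + spec$semi_axes_um[1] * cos(g$th)
  sy <- spec$center_um[2] + spec$semi_axes_um[2] * sin(g$th) * cos(g$ph)
  sx <- spec$center_um[3] + spec$semi_axes_um[3] * sin(g$th) * sin(g$ph)
  sqrt(min((sz - point_um[1])^2 + (sy - point_um[2])^2 +
           (sx - point_um[3])^2))
}

#' Generate a synthetic bone volume with ground truth
#'
#' Rasterizes the phantom described by \code{params}: mineral regions first,
#' then the cement line, then canaliculi and lacunae (pores overwrite), adds
#' Gaussian image noise last and quantizes gray values to the 16-bit integer
#' grid. Ground truth (region labels, lacuna labels, canalicular mask,
#' per-lacuna crossing counts within/beyond the counting radius, analytic
#' regional porosity) is computed on the noise-free rasterization. The result
#' is deterministic for a fixed seed; the seed affects only the noise field.
#'
#' @param params a \code{\link{phantom_params}} object.
#' @return list of class \code{olcn_phantom} with elements \code{volume}
#'   (an \code{\link{volume}}), \code{truth} and \code{params}.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$grid_shape
  px <- params$voxel_size_nm / 1000
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  y_um <- (seq_len(ny) - 1) * px
  x_um <- (seq_len(nx) - 1) * px

  n_regions <- length(params$region_gv_means)
  region_yx <- matrix(1L, ny, nx)
  cement_yx <- matrix(FALSE, ny, nx)
  for (k in seq_along(params$region_boundaries_um)) {
    b <- boundary_y(params, k, x_um)
    region_yx <- region_yx + outer(y_um, b, ">")
    cement_yx <- cement_yx |
      outer(y_um, b, function(y, b) abs(y - b) <=
              params$cement_thickness_um / 2)
  }
  mode(region_yx) <- "integer"
  to3d <- function(m) aperm(array(m, c(ny, nx, nz)), c(3, 1, 2))
  region_labels <- to3d(region_yx)
  cement <- to3d(cement_yx)

  gv <- array(params$region_gv_means[region_labels], dim = d)
  if (any(cement)) gv[cement] <- params$cement_gv

  canal <- array(FALSE, dim = d)
  step <- px / 2
  crossings <- list()
  for (i in seq_along(params$canaliculi)) {
    sp <- params$canaliculi[[i]]
    canal <- rasterize_tube(canal, sp$path_um, sp$radius_um, px)
    cr <- path_crossings(params, sp$path_um, step)
    ncr <- if (is.null(cr)) 0L else nrow(cr)
    if (sp$kind == "crossing") {
      if (ncr != 1L)
        stop("generate_phantom: canaliculus spec ", i, " (crossing) ",
             "intersects the cement surface ", ncr, " times, expected 1")
      crossings[[length(crossings) + 1L]] <-
        list(canaliculus = i, source_lacuna = sp$source_lacuna,
             point_um = cr[1, 1:3], boundary = cr[1, 4])
    } else if (sp$kind %in% c("loop", "intra_region")) {
      if (ncr != 0L)
        stop("generate_phantom: canaliculus spec ", i, " (", sp$kind,
             ") crosses the cement surface")
      clr <- path_clearance(params, sp$path_um, step)
      if (clr <= params$cement_thickness_um / 2 + sp$radius_um)
        stop("generate_phantom: canaliculus spec ", i, " (", sp$kind,
             ") touches the cement line (clearance ", round(clr, 3), " um)")
    }
  }
  gv[canal] <- params$lacuna_gv

  lacuna_labels <- array(0L, dim = d)
  for (i in seq_along(params$lacunae)) {
    sp <- params$lacunae[[i]]
    e <- rasterize_ellipsoid(d, sp$center_um, sp$semi_axes_um, px)
    sub <- lacuna_labels[e$iz, e$iy, e$ix, drop = FALSE]
    sub[e$inside] <- i
    lacuna_labels[e$iz, e$iy, e$ix] <- sub
  }
  gv[lacuna_labels > 0L] <- params$lacuna_gv

  # ground truth on the noise-free rasterization
  pores <- canal | lacuna_labels > 0L
  canal_only <- canal & lacuna_labels == 0L
  porosity <- vapply(seq_len(n_regions), function(r) {
    reg <- region_labels == r
    sum(canal_only & reg) / sum(reg & !pores)
  }, numeric(1))

  cross_df <- data.frame(canaliculus = integer(0), source_lacuna = integer(0),
                         distance_um = numeric(0))
  for (cr in crossings) {
    dist <- if (is.na(cr$source_lacuna)) NA_real_ else
      dist_to_lacuna_surface(cr$point_um, params$lacunae[[cr$source_lacuna]])
    cross_df <- rbind(cross_df,
                      data.frame(canaliculus = cr$canaliculus,
                                 source_lacuna = cr$source_lacuna,
                                 distance_um = dist))
  }
  counts <- data.frame(lacuna_id = seq_along(params$lacunae))
  counts$n_within <- vapply(counts$lacuna_id, function(id)
    sum(cross_df$source_lacuna == id &
          cross_df$distance_um <= params$within_radius_um, na.rm = TRUE),
    integer(1))
  counts$n_beyond <- vapply(counts$lacuna_id, function(id)
    sum(cross_df$source_lacuna == id &
          cross_df$distance_um > params$within_radius_um, na.rm = TRUE),
    integer(1))

  lac_vox <- tabulate(lacuna_labels[lacuna_labels > 0L],
                      nbins = length(params$lacunae))
  lacuna_info <- data.frame(lacuna_id = seq_along(params$lacunae),
                            n_voxels = lac_vox,
                            above_size_filter = lac_vox >= 1500L)

  if (params$noise_sd > 0) {
    set.seed(params$seed)
    gv <- gv + rnorm(length(gv), 0, params$noise_sd)
  }
  gv <- round(gv)
  gv[gv < 0] <- 0
  gv[gv > 65535] <- 65535

  truth <- list(region_labels = region_labels,
                lacuna_labels = lacuna_labels,
                canal_mask = canal,
                cement_mask = cement,
                cement_surface = list(
                  base_y_um = params$region_boundaries_um,
                  amplitude_um = params$cement_wave_amplitude_um,
                  period_um = params$cement_wave_period_um,
                  thickness_um = params$cement_thickness_um),
                crossing_distances = cross_df,
                true_crossing_counts = counts,
                analytic_region_porosity = porosity,
                lacuna_info = lacuna_info,
                within_radius_um = params$within_radius_um)
  structure(list(volume = volume(gv, params$voxel_size_nm),
                 truth = truth, params = params),
            class = "olcn_phantom")
}

#' Match segmented lacuna labels to ground-truth labels
#'
#' Maps every label of a segmented lacunar grid to the ground-truth lacuna
#' with which it overlaps most (0 when there is no overlap).
#'
#' @param seg_labels labeled grid from \code{\link{segment_lacunae}}.
#' @param truth_labels ground-truth lacuna label grid.
#' @return integer vector: element i is the truth id for segmented label i.
#' @export
match_lacunae <- function(seg_labels, truth_labels) {
  n <- max(seg_labels, 0L)
  vapply(seq_len(n), function(i) {
    ov <- truth_labels[seg_labels == i]
    ov <- ov[ov > 0L]
    if (length(ov) == 0L) 0L else as.integer(names(which.max(table(ov))))
  }, integer(1))
}
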