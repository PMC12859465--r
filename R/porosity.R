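#' Minimum-intensity projections with aligned companion projections
#'
#' Splits the stack into \code{n_projections} consecutive, non-overlapping
#' windows of \code{window_slices} slices starting at slice
#' \code{offset + 1}; trailing slices are unused. Each projection pixel is
#' the minimum gray value across its window. When a regional label volume
#' is supplied, its companion projection takes, per pixel, the label at the
#' argmin slice of the gray volume (ties to the first slice), so a dark
#' canaliculus pixel inherits the region in which that minimum lives. A
#' lacunar label companion takes, per pixel, the maximal lacuna label
#' present anywhere in the window (a pore is dark if any slice holds it).
#'
#' The defaults (15 projections over 130 slices, i.e. 6.5 um at 50 nm
#' voxels) are the quantification settings used on full-size 2160-slice
#' stacks; desk-scale volumes use proportionally smaller windows.
#'
#' @param vol an \code{\link{volume}}.
#' @param window_slices slices per window (default 130).
#' @param n_projections number of windows (default 15).
#' @param region_labels optional 3D region label array (mask A).
#' @param lacuna_labels optional 3D lacuna label array (mask C).
#' @param offset slices to skip before the first window (default 0).
#' @return list of class \code{projection_set}: \code{projections} (list of
#'   matrices), \code{windows} (data frame with 1-based inclusive
#'   \code{start}, \code{end}), \code{region_proj}, \code{lacuna_proj},
#'   \code{voxel_size_nm}.
#' @export
min_intensity_projections <- function(vol, window_slices = 130L,
                                      n_projections = 15L,
                                      region_labels = NULL,
                                      lacuna_labels = NULL,
                                      offset = 0L) {
  stopifnot(inherits(vol, "olcn_volume"))
  nz <- dim(vol$data)[1]
  need <- offset + n_projections * window_slices
  if (need > nz)
    stop("min_intensity_projections: ", n_projections, " windows of ",
         window_slices, " slices (offset ", offset, ") require at least ",
         need, " slices, volume has ", nz)
  projections <- vector("list", n_projections)
  region_proj <- if (!is.null(region_labels)) vector("list", n_projections)
  lacuna_proj <- if (!is.null(lacuna_labels)) vector("list", n_projections)
  windows <- data.frame(start = integer(n_projections),
                        end = integer(n_projections))
  for (i in seq_len(n_projections)) {
    z0 <- offset + (i - 1L) * window_slices + 1L
    z1 <- z0 + window_slices - 1L
    windows$start[i] <- z0; windows$end[i] <- z1
    p <- project_window(vol$data, z0:z1, region_labels, lacuna_labels)
    projections[[i]] <- p$gray
    if (!is.null(region_labels)) region_proj[[i]] <- p$region
    if (!is.null(lacuna_labels)) lacuna_proj[[i]] <- p$lacuna
  }
  structure(list(projections = projections, windows = windows,
                 region_proj = region_proj, lacuna_proj = lacuna_proj,
                 voxel_size_nm = vol$voxel_size_nm),
            class = "projection_set")
}

# min/argmin projection over an explicit slice window
project_window <- function(data, zs, region_labels = NULL,
                           lacuna_labels = NULL) {
  cur <- data[zs[1], , ]
  reg <- if (!is.null(region_labels)) region_labels[zs[1], , ]
  lac <- if (!is.null(lacuna_labels)) lacuna_labels[zs[1], , ]
  for (z in zs[-1]) {
    sl <- data[z, , ]
    upd <- sl < cur  # strict: ties keep the first slice
    cur[upd] <- sl[upd]
    if (!is.null(reg)) {
      rl <- region_labels[z, , ]
      reg[upd] <- rl[upd]
    }
    if (!is.null(lac))
      lac <- pmax(lac, lacuna_labels[z, , ])
  }
  list(gray = cur, region = reg, lacuna = lac)
}

#' Segment canaliculi in a minimum-intensity projection
#'
#' Black top-hat (closing minus image) with a disk structuring element of
#' radius \code{tophat_radius_px} enhances dark tubular structures while
#' removing additive offsets and slow background variation; an Otsu
#' threshold on the top-hat response (foreground = response >= threshold)
#' binarizes it; 8-connected components below \code{min_component_px}
#' pixels are discarded as noise (a component of exactly that size is
#' kept). A constant projection yields an empty mask.
#'
#' @param projection 2D gray-value matrix.
#' @param tophat_radius_px disk radius in pixels (default 10, about 0.5 um
#'   at 50 nm voxels, comfortably wider than a canaliculus).
#' @param min_component_px minimum component size in pixels (default 100).
#' @param n_bins histogram bins for the Otsu threshold.
#' @return logical matrix (canalicular mask).
#' @export
segment_canaliculi_2d <- function(projection, tophat_radius_px = 10L,
                                  min_component_px = 100L, n_bins = 256L) {
  rng <- range(projection)
  if (rng[1] >= rng[2])
    return(matrix(FALSE, nrow(projection), ncol(projection)))
  scaled <- (projection - rng[1]) / (rng[2] - rng[1])
  brush <- EBImage::makeBrush(2L * tophat_radius_px + 1L, "disc")
  response <- EBImage::blackTopHat(scaled, brush)
  if (max(response) <= min(response))
    return(matrix(FALSE, nrow(projection), ncol(projection)))
  thr <- otsu_threshold(response, n_bins)
  fg <- matrix(response >= thr, nrow(projection), ncol(projection))
  lab <- label_components(fg, 8L)
  filter_components(lab, min_component_px)$binary
}

#' Projected regional canalicular porosity (pCan.P)
#'
#' Assigns canalicular pixels to remodeling regions by multiplying the
#' canalicular mask with the projected regional mask; pixels also covered
#' by the lacunar projection count as lacunar, not canalicular. Mineral
#' pixels are the regional pixels minus lacunar and canalicular ones. Per
#' region the projected canalicular volume pCan.V(i) and mineral volume
#' pMin.V(i) are tallied for every projection i, and the projected
#' canalicular porosity is pooled as
#' \deqn{pCan.P = \sum_i pCan.V(i) / \sum_i pMin.V(i).}
#' This is a projected (overlay) quantity: a relative network-density
#' measure comparable between regions, deliberately not corrected to a 3D
#' porosity. Regions with no mineral pixels in any projection are flagged.
#'
#' @param pset a \code{\link{min_intensity_projections}} result that was
#'   built with both \code{region_labels} and \code{lacuna_labels}.
#' @param canal_masks list of logical matrices, one per projection, e.g.
#'   from \code{\link{segment_canaliculi_2d}}.
#' @return data frame with one row per region (\code{region_id},
#'   \code{pcan_p}, \code{flagged}) and attributes \code{pcan_v},
#'   \code{pmin_v} (region x projection count matrices).
#' @export
regional_porosity <- function(pset, canal_masks) {
  stopifnot(inherits(pset, "projection_set"))
  if (is.null(pset$region_proj) || is.null(pset$lacuna_proj))
    stop("regional_porosity: projection set lacks regional/lacunar companions")
  np <- length(pset$projections)
  if (length(canal_masks) != np)
    stop("regional_porosity: need one canalicular mask per projection")
  R <- max(vapply(pset$region_proj, max, numeric(1)))
  pcan_v <- matrix(0L, R, np)
  pmin_v <- matrix(0L, R, np)
  for (i in seq_len(np)) {
    if (!all(dim(canal_masks[[i]]) == dim(pset$projections[[i]])))
      stop("regional_porosity: mask shape mismatch in projection ", i)
    lacunar <- pset$lacuna_proj[[i]] > 0L
    canal <- canal_masks[[i]] & !lacunar
    reg <- pset$region_proj[[i]]
    for (r in seq_len(R)) {
      in_r <- reg == r
      pcan_v[r, i] <- sum(canal & in_r)
      pmin_v[r, i] <- sum(in_r & !lacunar & !canal)
    }
  }
  res <- data.frame(region_id = seq_len(R),
                    pcan_p = NA_real_,
                    flagged = rowSums(pmin_v) == 0)
  ok <- !res$flagged
  res$pcan_p[ok] <- rowSums(pcan_v)[ok] / rowSums(pmin_v)[ok]
  attr(res, "pcan_v") <- pcan_v
  attr(res, "pmin_v") <- pmin_v
  res
}
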