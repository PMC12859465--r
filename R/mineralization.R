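#' Low-intensity mask (mask B)
#'
#' All low-intensity elements of the volume (lacunae, canaliculi, vessel
#' structures and image noise): voxels at or below the Otsu threshold of the
#' full gray-value distribution. The standard contrast convention (pores
#' darker than mineral) is the caller's responsibility; on inverted-contrast
#' input the mask captures the mineral instead.
#'
#' @param vol an \code{\link{volume}} (or bare numeric array).
#' @param n_bins histogram bins for the Otsu search.
#' @return logical array with attribute \code{threshold}.
#' @export
low_intensity_mask <- function(vol, n_bins = 256L) {
  dat <- if (inherits(vol, "olcn_volume")) vol$data else vol
  thr <- otsu_threshold(dat, n_bins)
  structure(dat <= thr, threshold = thr)
}

#' Segment lacunae (mask C)
#'
#' The lacunar segmentation pipeline: initial Otsu mask, morphological
#' opening with a ball of radius \code{opening_radius_vox} voxels to
#' separate individual elements and remove thin canaliculi, connected
#' component analysis (26-connectivity), size filtering that excludes
#' components below \code{min_voxels} voxels (a component of exactly
#' \code{min_voxels} is retained), and a final compact relabeling. The
#' result is invariant to adding a constant offset to all gray values.
#'
#' @param vol an \code{\link{volume}} (or bare numeric array).
#' @param opening_radius_vox opening ball radius in voxels (default 7).
#' @param min_voxels minimum component size (default 1500).
#' @param connectivity 26 (default) or 6.
#' @param n_bins histogram bins for the Otsu threshold.
#' @return list with \code{labels} (labeled lacunar grid), \code{binary},
#'   \code{sizes}, \code{n} and \code{threshold}.
#' @export
segment_lacunae <- function(vol, opening_radius_vox = 7, min_voxels = 1500L,
                            connectivity = 26L, n_bins = 256L) {
  dat <- if (inherits(vol, "olcn_volume")) vol$data else vol
  thr <- otsu_threshold(dat, n_bins)
  mask <- open_ball(dat <= thr, opening_radius_vox)
  lab <- label_components(mask, connectivity)
  out <- filter_components(lab, min_voxels)
  out$threshold <- thr
  out
}

# majority-vote region assignment of labeled lacunae (ties -> lower region id)
assign_lacunae_to_regions <- function(lacuna_labels, mask_a, n_regions) {
  n <- max(lacuna_labels, 0L)
  if (n == 0L) return(integer(0))
  vapply(seq_len(n), function(i) {
    regs <- mask_a[lacuna_labels == i]
    counts <- tabulate(regs, nbins = n_regions)
    which.max(counts)  # first maximum -> lower region id on ties
  }, integer(1))
}

#' Regional mean gray values, normalized to the lacunar gray value
#'
#' Implements the regional degree-of-mineralization measurement. Per region:
#' the regional mask is eroded with a ball of radius
#' \code{region_erosion_px} to exclude edge effects and the cement lines;
#' the low-intensity mask B is dilated by \code{b_dilation_px} and
#' subtracted to isolate the mineral matrix; lacunae (mask C, assigned to
#' regions by majority voxel vote over mask A) are eroded by
#' \code{c_erosion_px} and their interior mean gray value is the lacunar
#' reference. The normalized mean gray value, mineral mean divided by
#' lacunar mean, controls for low-frequency imaging artifacts and tracks
#' the local degree of mineralization. Regions whose mineral or lacunar
#' voxel sets are annihilated by the morphology (regions of minimal size)
#' are flagged \code{excluded}.
#'
#' @param vol an \code{\link{volume}}.
#' @param masks a \code{\link{region_mask_set}}.
#' @param mask_b logical low-intensity mask from
#'   \code{\link{low_intensity_mask}}.
#' @param lacuna_labels labeled lacunar grid from
#'   \code{\link{segment_lacunae}}.
#' @param region_erosion_px,b_dilation_px,c_erosion_px structuring element
#'   radii in pixels (defaults 50, 10, 10).
#' @return data frame with one row per region: \code{region_id},
#'   \code{mean_gv_mineral}, \code{mean_gv_lacunar}, \code{norm_mean_gv},
#'   \code{n_lacunae}, \code{excluded}.
#' @export
regional_mean_gv <- function(vol, masks, mask_b, lacuna_labels,
                             region_erosion_px = 50, b_dilation_px = 10,
                             c_erosion_px = 10) {
  stopifnot(inherits(vol, "olcn_volume"), inherits(masks, "region_mask_set"))
  if (!all(dim(vol$data) == dim(masks$mask_a)) ||
      !all(dim(vol$data) == dim(mask_b)) ||
      !all(dim(vol$data) == dim(lacuna_labels)))
    stop("regional_mean_gv: shapes disagree")
  R <- masks$n_regions
  b_dil <- dilate_ball(mask_b, b_dilation_px)
  c_er <- erode_ball(lacuna_labels > 0L, c_erosion_px)
  assignment <- assign_lacunae_to_regions(lacuna_labels, masks$mask_a, R)

  res <- data.frame(region_id = seq_len(R), mean_gv_mineral = NA_real_,
                    mean_gv_lacunar = NA_real_, norm_mean_gv = NA_real_,
                    n_lacunae = 0L, excluded = FALSE)
  for (r in seq_len(R)) {
    a_er <- erode_ball(masks$mask_a == r, region_erosion_px)
    mineral <- a_er & !b_dil
    own <- which(assignment == r)
    res$n_lacunae[r] <- length(own)
    lac_vox <- if (length(own)) c_er & (lacuna_labels %in% own) else FALSE
    if (!any(mineral) || !any(lac_vox)) {
      res$excluded[r] <- TRUE
      next
    }
    res$mean_gv_mineral[r] <- mean(vol$data[mineral])
    res$mean_gv_lacunar[r] <- mean(vol$data[lac_vox])
    res$norm_mean_gv[r] <- res$mean_gv_mineral[r] / res$mean_gv_lacunar[r]
  }
  attr(res, "lacuna_assignment") <- assignment
  res
}

#' Rank regions by relative tissue age
#'
#' Regions are ranked from 1 (youngest) upward by ascending normalized mean
#' gray value: younger, less mineralized matrix has lower gray levels. Ties
#' go to the lower region id; excluded regions get rank NA.
#'
#' @param stats data frame from \code{\link{regional_mean_gv}}.
#' @return the same data frame with a \code{rank} column.
#' @export
rank_regions <- function(stats) {
  ok <- !stats$excluded & !is.na(stats$norm_mean_gv)
  if (!any(ok)) stop("rank_regions: no region with a valid norm_mean_gv")
  stats$rank <- NA_integer_
  ord <- order(stats$norm_mean_gv[ok], stats$region_id[ok])
  stats$rank[which(ok)[ord]] <- seq_len(sum(ok))
  stats
}
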