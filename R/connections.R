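#' Select candidate lacunae for connection counting
#'
#' Candidates are lacunae that are fully included in the scan (their
#' component touches no volume face), lie within the locally younger
#' remodeling region (their majority region has an adjacent region of
#' higher age rank), and whose surface lies within \code{proximity_um} of
#' the interface to an older region. Distances are Euclidean, measured in
#' 3D from the lacuna surface voxels to the nearest voxel of each older
#' region.
#'
#' @param lacuna_labels labeled lacunar grid (mask C from
#'   \code{\link{segment_lacunae}}).
#' @param masks a \code{\link{region_mask_set}}.
#' @param stats ranked region statistics from \code{\link{rank_regions}}.
#' @param voxel_size_nm voxel size of the grid.
#' @param proximity_um maximal surface-to-interface distance (default 25).
#' @return data frame of candidates: \code{lacuna_id}, \code{region_id},
#'   \code{rank}, \code{neighbor_region}, \code{distance_um},
#'   \code{z_start}, \code{z_end} (1-based inclusive slice range),
#'   \code{centroid_z/y/x_um}. The full per-lacuna table (with exclusion
#'   reasons) is attached as attribute \code{all_lacunae}.
#' @export
select_lacunae <- function(lacuna_labels, masks, stats, voxel_size_nm,
                           proximity_um = 25) {
  stopifnot(inherits(masks, "region_mask_set"))
  if (is.null(stats$rank)) stop("select_lacunae: stats must carry ranks")
  d <- dim(lacuna_labels)
  px <- voxel_size_nm / 1000
  n <- max(lacuna_labels, 0L)
  if (n == 0L) return(empty_candidates())
  assignment <- assign_lacunae_to_regions(lacuna_labels, masks$mask_a,
                                          masks$n_regions)
  # distance fields to each region that is older than something (computed once)
  ranks <- stats$rank[match(seq_len(masks$n_regions), stats$region_id)]
  dist_to_region <- list()
  for (r in seq_len(masks$n_regions))
    if (!is.na(ranks[r]))
      dist_to_region[[r]] <- sqrt(edt_squared(masks$mask_a == r))

  rows <- lapply(seq_len(n), function(id) {
    idx <- which(lacuna_labels == id, arr.ind = TRUE)
    touches <- any(idx == 1L) ||
      any(idx[, 1] == d[1]) || any(idx[, 2] == d[2]) || any(idx[, 3] == d[3])
    own <- assignment[id]
    own_rank <- ranks[own]
    neighbor <- NA_integer_; dist_um <- NA_real_
    if (!is.na(own_rank)) {
      older <- which(!is.na(ranks) & ranks > own_rank)
      if (length(older)) {
        dmins <- vapply(older, function(r) {
          lin <- (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] +
            idx[, 1]
          min(dist_to_region[[r]][lin])
        }, numeric(1))
        neighbor <- older[which.min(dmins)]
        dist_um <- min(dmins) * px
      }
    }
    data.frame(lacuna_id = id, region_id = own, rank = own_rank,
               neighbor_region = neighbor, distance_um = dist_um,
               z_start = min(idx[, 1]), z_end = max(idx[, 1]),
               centroid_z_um = mean(idx[, 1] - 1L) * px,
               centroid_y_um = mean(idx[, 2] - 1L) * px,
               centroid_x_um = mean(idx[, 3] - 1L) * px,
               fully_inside = !touches)
  })
  all_lac <- do.call(rbind, rows)
  all_lac$candidate <- all_lac$fully_inside & !is.na(all_lac$neighbor_region) &
    !is.na(all_lac$distance_um) & all_lac$distance_um <= proximity_um
  out <- all_lac[all_lac$candidate, setdiff(names(all_lac), "candidate"),
                 drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_lacunae") <- all_lac
  out
}

empty_candidates <- function() {
  data.frame(lacuna_id = integer(0), region_id = integer(0),
             rank = integer(0), neighbor_region = integer(0),
             distance_um = numeric(0), z_start = integer(0),
             z_end = integer(0), centroid_z_um = numeric(0),
             centroid_y_um = numeric(0), centroid_x_um = numeric(0),
             fully_inside = logical(0))
}

#' Canalicular cluster connected to one lacuna
#'
#' Builds, for one candidate lacuna, the minimum-intensity projection over
#' exactly the slices containing the lacuna (identical window for the gray
#' volume, the lacunar mask and the regional mask), segments canaliculi in
#' it with the same operator as the porosity analysis, removes all other
#' lacunae from the lacunar projection, adds the target lacuna's footprint
#' to the canalicular mask, and keeps the 8-connected component containing
#' the lacuna: the lacuna plus all canaliculi directly connected to it.
#'
#' The black top-hat cannot respond within about one structuring-element
#' radius of the boundary of a wide dark blob (the element still fits
#' inside the dark union there), so canaliculi would systematically
#' disconnect from their lacuna in a thin ring around the footprint. The
#' footprint is therefore extended by its dark halo: low-intensity pixels
#' (projection-level Otsu) within \code{tophat_radius_px} of the footprint.
#' Dark pixels at the interface band are canalicular by construction, so
#' the halo cannot fabricate crossings.
#'
#' @param vol an \code{\link{volume}}.
#' @param lacuna_labels labeled lacunar grid.
#' @param masks a \code{\link{region_mask_set}}.
#' @param lacuna_id target lacuna label.
#' @param z_range length-2 vector of 1-based inclusive slice range (taken
#'   from \code{\link{select_lacunae}}).
#' @param tophat_radius_px,min_component_px passed to
#'   \code{\link{segment_canaliculi_2d}}.
#' @return list with \code{cluster}, \code{footprint}, \code{canal},
#'   \code{region_proj}, \code{lacuna_proj}, \code{window}.
#' @export
lacuna_cluster <- function(vol, lacuna_labels, masks, lacuna_id, z_range,
                           tophat_radius_px = 10L, min_component_px = 100L) {
  stopifnot(inherits(vol, "olcn_volume"))
  nz <- dim(vol$data)[1]
  if (z_range[1] < 1L || z_range[2] > nz || z_range[1] > z_range[2])
    stop("lacuna_cluster: slice range outside volume")
  zs <- z_range[1]:z_range[2]
  p <- project_window(vol$data, zs, masks$mask_a, lacuna_labels)
  footprint <- p$lacuna == lacuna_id
  if (!any(footprint))
    stop("lacuna_cluster: lacuna ", lacuna_id,
         " absent from its projection (inconsistent inputs)")
  canal <- segment_canaliculi_2d(p$gray, tophat_radius_px, min_component_px)
  canal <- canal & !(p$lacuna > 0L)  # lacunar pixels are not canalicular
  dark <- tryCatch(p$gray <= otsu_threshold(p$gray),
                   error = function(e) footprint & FALSE)
  halo <- dilate_ball(footprint, tophat_radius_px) & dark & !(p$lacuna > 0L)
  newmask <- canal | footprint | halo
  comp <- label_components(newmask, 8L)
  target <- comp[footprint][1]
  cluster <- comp == target
  list(cluster = cluster, footprint = footprint, canal = canal,
       region_proj = p$region, lacuna_proj = p$lacuna, window = z_range)
}

#' Count canalicular connections crossing the interface (N.Conn)
#'
#' Intersects a lacuna's canalicular cluster with the segmented interface
#' band towards the older region; each 8-connected component of the
#' intersection is one candidate crossing, and it counts when its minimum
#' Euclidean pixel distance to the lacuna footprint is at most
#' \code{radius_um}. Two canaliculi merging before the band count once;
#' one canaliculus grazing a wavy band in two disjoint places counts
#' twice (counting unit = disjoint band component).
#'
#' @param cluster logical matrix from \code{\link{lacuna_cluster}}.
#' @param band an \code{\link{interface_band}} built on the projected
#'   regional mask (2D).
#' @param footprint logical matrix, the target lacuna's projected footprint.
#' @param voxel_size_nm voxel size.
#' @param radius_um counting radius from the lacuna surface (default 25).
#' @return list with \code{n_conn}, \code{component_distances_um} and
#'   \code{n_crossing_components} (components irrespective of radius).
#' @export
count_connections <- function(cluster, band, footprint, voxel_size_nm,
                              radius_um = 25) {
  mask <- if (inherits(band, "interface_band")) band$mask else band
  if (!all(dim(mask) == dim(cluster)))
    stop("count_connections: shapes disagree")
  if (!any(mask)) {
    warning("count_connections: empty interface band (no older neighbor ",
            "in this window)")
    return(list(n_conn = 0L, component_distances_um = numeric(0),
                n_crossing_components = 0L))
  }
  px <- voxel_size_nm / 1000
  inter <- cluster & mask
  if (!any(inter))
    return(list(n_conn = 0L, component_distances_um = numeric(0),
                n_crossing_components = 0L))
  comp <- label_components(inter, 8L)
  dfield <- sqrt(edt_squared(footprint)) * px
  ncomp <- max(comp)
  dists <- vapply(seq_len(ncomp), function(k) min(dfield[comp == k]),
                  numeric(1))
  list(n_conn = sum(dists <= radius_um),
       component_distances_um = dists,
       n_crossing_components = ncomp)
}

#' Count interface crossings for every candidate lacuna
#'
#' Convenience driver running \code{\link{lacuna_cluster}},
#' \code{\link{interface_band}} (on the candidate's projected regional
#' mask, towards its older neighbor region) and
#' \code{\link{count_connections}} for each row of a candidate table.
#'
#' @param vol an \code{\link{volume}}.
#' @param lacuna_labels labeled lacunar grid.
#' @param masks a \code{\link{region_mask_set}}.
#' @param candidates data frame from \code{\link{select_lacunae}}.
#' @param radius_um counting radius (default 25).
#' @param band_dilation_px interface dilation in pixels (default 3).
#' @param tophat_radius_px,min_component_px canalicular segmentation
#'   parameters.
#' @return data frame: \code{lacuna_id}, \code{region_id},
#'   \code{neighbor_region}, \code{n_conn}, \code{radius_um}.
#' @export
count_all_connections <- function(vol, lacuna_labels, masks, candidates,
                                  radius_um = 25, band_dilation_px = 3,
                                  tophat_radius_px = 10L,
                                  min_component_px = 100L) {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    cl <- lacuna_cluster(vol, lacuna_labels, masks, cand$lacuna_id,
                         c(cand$z_start, cand$z_end),
                         tophat_radius_px, min_component_px)
    bd <- interface_band(cl$region_proj, cand$neighbor_region,
                         band_dilation_px)
    cc <- count_connections(cl$cluster, bd, cl$footprint,
                            vol$voxel_size_nm, radius_um)
    data.frame(lacuna_id = cand$lacuna_id, region_id = cand$region_id,
               neighbor_region = cand$neighbor_region, n_conn = cc$n_conn,
               radius_um = radius_um)
  })
  if (!length(rows)) {
    return(data.frame(lacuna_id = integer(0), region_id = integer(0),
                      neighbor_region = integer(0), n_conn = integer(0),
                      radius_um = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Join connection counts with regional statistics
#'
#' Produces the per-lacuna analysis table: the number of interface
#' crossings next to the normalized mean gray value of the lacuna's own
#' region and of the neighboring (older) region, plus the neighbor's
#' projected canalicular porosity when available. Rows whose neighbor
#' statistics are missing are flagged.
#'
#' @param results data frame from \code{\link{count_all_connections}}.
#' @param stats ranked region statistics from \code{\link{rank_regions}}.
#' @param porosity optional data frame from \code{\link{regional_porosity}}.
#' @return per-lacuna data frame with \code{own_region_norm_gv},
#'   \code{neighbor_region_norm_gv}, \code{neighbor_pcan_p},
#'   \code{flagged}.
#' @export
connection_table <- function(results, stats, porosity = NULL) {
  own <- match(results$region_id, stats$region_id)
  nb <- match(results$neighbor_region, stats$region_id)
  out <- results
  out$own_region_norm_gv <- stats$norm_mean_gv[own]
  out$neighbor_region_norm_gv <- stats$norm_mean_gv[nb]
  out$neighbor_pcan_p <- if (!is.null(porosity))
    porosity$pcan_p[match(results$neighbor_region, porosity$region_id)]
  else NA_real_
  out$flagged <- is.na(out$neighbor_region_norm_gv)
  out
}
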