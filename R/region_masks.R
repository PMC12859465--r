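#' Sparse manual region labels
#'
#' Manual remodeling-region annotations on selected slices, the input to
#' \code{\link{interpolate_region_mask}}. Every annotated slice must be
#' fully labeled (regions partition the slice; the cement line is not a
#' separate label, it is excluded later by erosion of the regional mask).
#'
#' @param entries list of \code{list(slice = <1-based slice index>,
#'   labels = <ny x nx integer matrix>)}.
#' @param n_regions number of regions; inferred from the labels if NULL.
#' @return an object of class \code{sparse_region_labels}.
#' @export
sparse_region_labels <- function(entries, n_regions = NULL) {
  if (length(entries) < 1L) stop("sparse_region_labels: no entries")
  shapes <- vapply(entries, function(e) paste(dim(e$labels), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("sparse_region_labels: label images differ in shape")
  labs <- unlist(lapply(entries, function(e) unique(as.integer(e$labels))))
  if (any(labs < 1L))
    stop("sparse_region_labels: annotated slices must be fully labeled ",
         "(no background 0)")
  if (is.null(n_regions)) n_regions <- max(labs)
  slices <- vapply(entries, function(e) as.integer(e$slice), integer(1))
  if (anyDuplicated(slices)) stop("sparse_region_labels: duplicate slice")
  entries <- entries[order(slices)]
  structure(list(entries = entries, n_regions = as.integer(n_regions)),
            class = "sparse_region_labels")
}

#' Dense remodeling-region mask set (mask A)
#'
#' @param mask_a integer 3D array; every voxel carries a label in
#'   \code{1..n_regions} (regions partition the volume).
#' @param provenance "interpolated" or "supplied".
#' @param n_regions region count.
#' @return an object of class \code{region_mask_set}.
#' @export
region_mask_set <- function(mask_a, provenance = c("supplied", "interpolated"),
                            n_regions = max(mask_a)) {
  provenance <- match.arg(provenance)
  if (length(dim(mask_a)) != 3L)
    stop("region_mask_set: mask_a must be a 3D array")
  if (any(mask_a < 1L) || any(mask_a > n_regions))
    stop("region_mask_set: labels must partition the volume into 1..",
         n_regions)
  structure(list(mask_a = mask_a, provenance = provenance,
                 n_regions = as.integer(n_regions)),
            class = "region_mask_set")
}

# per-region signed distance on one slice: positive inside, negative outside,
# capped so absent regions blend linearly rather than with infinities
signed_distance_2d <- function(labels, r, cap = 1e6) {
  inside <- labels == r
  d_in <- sqrt(edt_squared(inside))
  d_out <- sqrt(edt_squared(!inside))
  sd <- d_out - d_in
  pmin(pmax(sd, -cap), cap)
}

#' Interpolate a dense region mask from sparse slice labels
#'
#' Shape-based interpolation: on each annotated slice a signed distance map
#' is computed per region (positive inside); between two bracketing
#' annotated slices the maps are blended linearly and each voxel takes the
#' region with the maximal blended value (ties go to the lower region id).
#' Annotated slices are reproduced exactly; slices outside the annotated
#' range copy the nearest annotated slice.
#'
#' @param labels a \code{\link{sparse_region_labels}} object with >= 2
#'   annotated slices, every region present on at least one of them.
#' @param target_shape volume shape (nz, ny, nx).
#' @return a \code{\link{region_mask_set}} with provenance "interpolated".
#' @export
interpolate_region_mask <- function(labels, target_shape) {
  stopifnot(inherits(labels, "sparse_region_labels"))
  nz <- target_shape[1]
  if (length(labels$entries) < 2L)
    stop("interpolate_region_mask: need at least 2 labeled slices")
  R <- labels$n_regions
  present <- vapply(seq_len(R), function(r)
    any(vapply(labels$entries, function(e) any(e$labels == r), logical(1))),
    logical(1))
  if (!all(present))
    stop("interpolate_region_mask: region ", which(!present)[1],
         " absent from all labeled slices")
  zs <- vapply(labels$entries, function(e) e$slice, integer(1))
  if (any(zs < 1L | zs > nz))
    stop("interpolate_region_mask: labeled slice outside target volume")
  d2 <- dim(labels$entries[[1]]$labels)
  if (any(d2 != target_shape[2:3]))
    stop("interpolate_region_mask: label shape does not match target")

  sdmaps <- lapply(labels$entries, function(e)
    lapply(seq_len(R), function(r) signed_distance_2d(e$labels, r)))

  mask_a <- array(0L, dim = c(nz, d2))
  for (z in seq_len(nz)) {
    if (z %in% zs) {
      mask_a[z, , ] <- labels$entries[[match(z, zs)]]$labels
    } else if (z < zs[1]) {
      mask_a[z, , ] <- labels$entries[[1]]$labels
    } else if (z > zs[length(zs)]) {
      mask_a[z, , ] <- labels$entries[[length(zs)]]$labels
    } else {
      i1 <- max(which(zs < z)); i2 <- i1 + 1L
      w <- (zs[i2] - z) / (zs[i2] - zs[i1])
      blended <- vapply(seq_len(R), function(r)
        c(w * sdmaps[[i1]][[r]] + (1 - w) * sdmaps[[i2]][[r]]),
        numeric(prod(d2)))
      lab <- max.col(blended, ties.method = "first")
      mask_a[z, , ] <- matrix(as.integer(lab), d2[1], d2[2])
    }
  }
  region_mask_set(mask_a, "interpolated", R)
}

#' Check a region mask against the gray values
#'
#' Advisory validation of a (typically interpolated) regional mask: regions
#' of different tissue age should have clearly separated mean gray values.
#' The check passes when all pairwise differences of region means exceed
#' \code{margin_factor} times the pooled within-region standard deviation of
#' slice-wise means. The result never blocks the pipeline.
#'
#' @param vol an \code{\link{volume}}.
#' @param masks a \code{\link{region_mask_set}}.
#' @param margin_factor separation margin (default 2).
#' @return list with \code{pass}, \code{region_means}, \code{pooled_sd} and
#'   the per-region slice-mean table.
#' @export
validate_regions_against_gv <- function(vol, masks, margin_factor = 2) {
  stopifnot(inherits(vol, "olcn_volume"), inherits(masks, "region_mask_set"))
  if (!all(dim(vol$data) == dim(masks$mask_a)))
    stop("validate_regions_against_gv: shapes disagree")
  R <- masks$n_regions
  nz <- dim(vol$data)[1]
  slice_means <- matrix(NA_real_, nz, R)
  for (z in seq_len(nz)) {
    sl <- vol$data[z, , ]
    lb <- masks$mask_a[z, , ]
    for (r in seq_len(R))
      if (any(lb == r)) slice_means[z, r] <- mean(sl[lb == r])
  }
  region_means <- colMeans(slice_means, na.rm = TRUE)
  vars <- apply(slice_means, 2, var, na.rm = TRUE)
  pooled_sd <- sqrt(mean(vars, na.rm = TRUE))
  if (!is.finite(pooled_sd)) pooled_sd <- 0
  pass <- TRUE
  if (R > 1L) {
    dmin <- min(dist(region_means))
    pass <- dmin > margin_factor * pooled_sd
  }
  list(pass = pass, region_means = region_means, pooled_sd = pooled_sd,
       slice_means = slice_means, margin_factor = margin_factor)
}

#' Cement-line interface band by dilation and subtraction
#'
#' Segments the interface towards an older region by dilating that region's
#' label by \code{dilation_px} (Euclidean disk in 2D, ball in 3D) and
#' subtracting the original label, yielding a band of at most
#' \code{dilation_px} width on the younger side. The band is clipped at the
#' grid border.
#'
#' @param x a \code{\link{region_mask_set}}, a 3D label array, or a 2D label
#'   matrix (e.g. a projected regional mask).
#' @param older_label region id of the locally older region.
#' @param dilation_px dilation radius in pixels (default 3).
#' @return list of class \code{interface_band} with \code{mask},
#'   \code{older_label}, \code{dilation_px}.
#' @export
interface_band <- function(x, older_label, dilation_px = 3) {
  labels <- if (inherits(x, "region_mask_set")) x$mask_a else x
  older <- labels == older_label
  if (!any(older))
    stop("interface_band: no voxels with label ", older_label)
  band <- dilate_ball(older, dilation_px) & !older
  structure(list(mask = band, older_label = as.integer(older_label),
                 dilation_px = dilation_px),
            class = "interface_band")
}
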