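#' Otsu threshold on a 256-bin histogram of the observed range
#'
#' Computes the threshold maximizing the between-class variance over a
#' histogram of \code{n_bins} uniform bins spanning \code{[min(values),
#' max(values)]}. Works identically for 8-bit, 16-bit and floating-point
#' gray values. Ties are broken towards the lower threshold. The
#' classification contract used throughout the package is: low-intensity
#' foreground = \code{value <= threshold} (pores are dark); callers that
#' threshold a top-hat response use the opposite side.
#'
#' @param values numeric vector or array of gray values (NAs dropped).
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, a single gray value (the upper edge of the last
#'   low-class bin).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("otsu_threshold: need at least 2 values")
  rng <- range(v)
  if (rng[1] >= rng[2])
    stop("otsu_threshold: constant input, degenerate histogram")
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((v - rng[1]) / width) + 1L, n_bins)
  h <- tabulate(idx, nbins = n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  n <- length(v)
  cw <- cumsum(h)
  cm <- cumsum(h * centers)
  k <- seq_len(n_bins - 1L)
  w0 <- cw[k]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- cm[k][valid] / w0[valid]
  mu1 <- (cm[n_bins] - cm[k][valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  kstar <- which.max(bcv)  # first maximum -> lower threshold on ties
  rng[1] + kstar * width
}

#' Squared Euclidean distance transform
#'
#' For every voxel, the squared Euclidean distance (in voxel units, isotropic
#' grid) to the nearest \code{TRUE} voxel. \code{Inf} if the mask is empty.
#' Accepts a 2D matrix or 3D array.
#'
#' @param mask logical matrix or 3D array.
#' @return numeric array of the same shape.
#' @export
edt_squared <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("edt_squared: mask must be a matrix or 3D array")
  out <- cpp_edt_sq(as.logical(mask), as.integer(d))
  dim(out) <- d
  out
}

#' Binary morphology with exact Euclidean ball/disk structuring elements
#'
#' The structuring element of radius \code{r} is the set of voxels whose
#' center lies within Euclidean distance \code{r} of the origin (a disk for
#' 2D input, a ball for 3D). Implemented via the distance transform, so
#' \code{dilate_ball(m, r)} is exactly \code{\{v : dist(v, m) <= r\}} and
#' erosion is its dual. Voxels outside the grid count as background.
#'
#' @param mask logical matrix or 3D array.
#' @param radius structuring element radius in voxels (0 = identity).
#' @return logical array of the same shape.
#' @export
dilate_ball <- function(mask, radius) {
  mask <- mask != 0
  if (radius <= 0) return(mask)
  edt_squared(mask) <= radius^2 + 1e-9
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius) {
  mask <- mask != 0
  if (radius <= 0) return(mask)
  mask & (edt_squared(!mask) > radius^2 + 1e-9)
}

#' @rdname dilate_ball
#' @export
open_ball <- function(mask, radius) {
  dilate_ball(erode_ball(mask, radius), radius)
}

#' Connected component labeling
#'
#' Labels connected foreground components with consecutive positive
#' integers (background 0). Default connectivity is 26 in 3D and, for a 2D
#' matrix, the equivalent 8-connectivity, so thin tubular structures survive
#' diagonal steps.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 26 (8 in 2D) or 6 (4 in 2D).
#' @return integer array of the same shape.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("label_components: mask must be a matrix or 3D array")
  connectivity <- as.integer(connectivity)
  if (connectivity %in% c(8L, 4L))  # 2D aliases
    connectivity <- if (connectivity == 8L) 26L else 6L
  if (!connectivity %in% c(26L, 6L))
    stop("label_components: connectivity must be 26/8 or 6/4")
  out <- cpp_label_components(as.logical(mask), as.integer(d), connectivity)
  dim(out) <- d
  out
}

#' Discard labeled components below a voxel-count threshold
#'
#' Components with fewer than \code{min_voxels} voxels are removed
#' (a component with exactly \code{min_voxels} voxels is retained);
#' survivors are relabeled compactly in order of their original label.
#'
#' @param labels integer array from \code{\link{label_components}}.
#' @param min_voxels minimum voxel (pixel) count to retain.
#' @return list with \code{labels} (relabeled array), \code{binary},
#'   \code{sizes} (voxel counts of retained components) and \code{n}.
#' @export
filter_components <- function(labels, min_voxels) {
  nlab <- max(labels, 0L)
  if (nlab == 0L) {
    return(list(labels = labels, binary = labels > 0L,
                sizes = integer(0), n = 0L))
  }
  sizes <- tabulate(labels[labels > 0L], nbins = nlab)
  keep <- which(sizes >= min_voxels)
  map <- integer(nlab)
  map[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  list(labels = out, binary = out > 0L, sizes = sizes[keep],
       n = length(keep))
}
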