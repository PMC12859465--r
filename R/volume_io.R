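#' Gray-value volume container
#'
#' A 3D gray-value grid with isotropic voxel size. The array axis order is
#' (slice z, row y, column x); \code{data[z, , ]} is one cross-section.
#' Indices are 1-based as usual in R; the physical coordinate of voxel
#' \code{i} along an axis is \code{(i - 1) * voxel_size}, so physical
#' distances are \code{voxel_size} times Euclidean index distances.
#'
#' @param data numeric 3D array (nz, ny, nx).
#' @param voxel_size_nm isotropic voxel size in nanometers.
#' @return an object of class \code{olcn_volume}.
#' @export
volume <- function(data, voxel_size_nm) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("volume: data must be a non-empty 3D array (z, y, x)")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("volume: voxel_size_nm must be a single positive number")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "olcn_volume")
}

#' @export
print.olcn_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<olcn_volume> %d x %d x %d voxels (z,y,x), %.0f nm/voxel, GV range [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.olcn_volume <- function(x) dim(x$data)

# natural (numeric-aware) filename sort: s2 < s10
natural_sort <- function(x) {
  key <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    num <- grepl("^[0-9]+$", parts)
    parts[num] <- sprintf("%020d", as.numeric(parts[num]))
    paste(parts, collapse = "")
  }, character(1))
  x[order(key)]
}

GV_SCALE <- 65535  # canonical 16-bit storage

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "volume_meta.json")
  else paste0(path, ".meta.json")
}

#' Read a volume from TIFF
#'
#' Reads either a multipage TIFF (pages become slices in page order) or a
#' directory of equally shaped single-page TIFFs (slices ordered by natural
#' sort of the file names, so \code{s2.tif} precedes \code{s10.tif}). Gray
#' values are returned on the 16-bit integer scale. The voxel size is taken
#' from the JSON metadata sidecar written by \code{\link{write_volume}}, or
#' must be given explicitly.
#'
#' @param path multipage TIFF file or directory of single-page TIFFs.
#' @param voxel_size_nm voxel size in nm; required when no sidecar exists.
#' @return an \code{\link{volume}} object.
#' @export
read_volume <- function(path, voxel_size_nm = NULL) {
  meta_file <- sidecar_path(path)
  if (is.null(voxel_size_nm)) {
    if (!file.exists(meta_file))
      stop("read_volume: no metadata sidecar at '", meta_file,
           "'; pass voxel_size_nm explicitly")
    voxel_size_nm <- jsonlite::read_json(meta_file)$voxel_size_nm
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE)
    if (length(files) == 0L) stop("read_volume: no TIFF files in ", path)
    files <- natural_sort(files)
    slices <- lapply(files, function(f)
      tiff::readTIFF(file.path(path, f)))
    shapes <- vapply(slices, function(s) paste(dim(s), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) != 1L)
      stop("read_volume: inconsistent slice shape in file '",
           files[which(shapes != shapes[1])[1]], "'")
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]]); nz <- length(slices)
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- round(slices[[z]] * GV_SCALE)
  volume(arr, voxel_size_nm)
}

#' Write a volume to TIFF
#'
#' Writes a multipage 16-bit TIFF (when \code{path} ends in .tif/.tiff) or a
#' directory of numbered single-page TIFFs, plus a JSON metadata sidecar
#' carrying the voxel size. Gray values must be integers in [0, 65535];
#' the round trip through \code{\link{read_volume}} is then lossless.
#'
#' @param vol an \code{\link{volume}} object.
#' @param path destination file (.tif) or directory.
#' @param extra_meta optional named list merged into the sidecar.
#' @export
write_volume <- function(vol, path, extra_meta = NULL) {
  stopifnot(inherits(vol, "olcn_volume"))
  dat <- vol$data
  if (any(dat < 0) || any(dat > GV_SCALE) ||
      max(abs(dat - round(dat))) > 1e-6)
    stop("write_volume: gray values must be integers in [0, 65535]")
  nz <- dim(dat)[1]
  slices <- lapply(seq_len(nz), function(z) dat[z, , ] / GV_SCALE)
  meta <- c(list(voxel_size_nm = vol$voxel_size_nm,
                 dims_zyx = dim(dat), gv_scale = GV_SCALE),
            extra_meta)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    ok <- tryCatch(tiff::writeTIFF(slices, path, bits.per.sample = 16L),
                   error = function(e)
                     stop("write_volume: cannot write '", path, "': ",
                          conditionMessage(e)))
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop("write_volume: cannot create ", path)
    for (z in seq_len(nz))
      tiff::writeTIFF(slices[[z]],
                      file.path(path, sprintf("s%05d.tif", z)),
                      bits.per.sample = 16L)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write result tables as CSV
#'
#' Writes the pipeline's tabular outputs with fixed, documented headers:
#' \itemize{
#'   \item \code{per_region.csv}: sample, region_id, rank, norm_mean_gv, pcanp
#'   \item \code{per_lacuna.csv}: sample, lacuna_id, n_conn,
#'     own_region_norm_gv, neighbor_region_norm_gv
#'   \item \code{per_test.csv}: name, statistic, p_value
#' }
#' Empty tables produce header-only files. Extra columns beyond the
#' documented ones are preserved after the documented ones.
#'
#' @param tables named list with any of \code{per_region},
#'   \code{per_lacuna}, \code{per_test} data frames.
#' @param path output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  schema <- list(
    per_region = c("sample", "region_id", "rank", "norm_mean_gv", "pcanp"),
    per_lacuna = c("sample", "lacuna_id", "n_conn",
                   "own_region_norm_gv", "neighbor_region_norm_gv"),
    per_test = c("name", "statistic", "p_value"))
  written <- character(0)
  for (nm in names(schema)) {
    if (is.null(tables[[nm]])) next
    df <- as.data.frame(tables[[nm]])
    cols <- schema[[nm]]
    if (nrow(df) == 0L && ncol(df) == 0L)
      df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop("write_results: table '", nm, "' lacks columns: ",
           paste(missing, collapse = ", "))
    df <- df[, c(cols, setdiff(names(df), cols)), drop = FALSE]
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(df, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
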