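#' Test result container
#'
#' @param name test name.
#' @param statistic test statistic value.
#' @param p_value two-sided p-value.
#' @param n sample sizes per group.
#' @param alpha significance level (default 0.05).
#' @param ... additional named fields (medians, correlations, flags).
#' @return list of class \code{olcn_test}.
#' @export
test_result <- function(name, statistic, p_value, n, alpha = 0.05, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("test_result: p_value outside [0, 1]")
  structure(list(name = name, statistic = statistic, p_value = p_value,
                 n = n, alpha = alpha, ...),
            class = "olcn_test")
}

#' @export
print.olcn_test <- function(x, ...) {
  cat(sprintf("<olcn_test> %s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$name, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (!is.na(x$p_value) && x$p_value < x$alpha)
                " *significant*" else ""))
  invisible(x)
}

#' Compare canalicular porosity of youngest vs older regions
#'
#' Groups per-region projected porosities into the youngest regions (rank
#' 1, one per sample) versus all relatively older regions, and compares
#' them with a two-sample Student's t-test (equal variance by default;
#' Welch via \code{var_equal = FALSE}). Group medians are reported
#' alongside, as is the Pearson correlation of porosity with age rank.
#' When both groups have zero variance the t statistic degenerates: equal
#' means give statistic 0 and p = 1, distinct means are reported as exact
#' separation (infinite statistic, p = 0) with a \code{degenerate} flag.
#'
#' @param records data frame with columns \code{rank} and \code{pcan_p}
#'   (one row per region per sample; NAs dropped).
#' @param alpha significance level.
#' @param var_equal use the pooled-variance Student's t-test (default).
#' @return an \code{\link{test_result}} with extras \code{median_young},
#'   \code{median_older}, \code{pearson_r}, \code{pearson_p},
#'   \code{degenerate}.
#' @export
porosity_group_test <- function(records, alpha = 0.05, var_equal = TRUE) {
  rec <- records[!is.na(records$pcan_p) & !is.na(records$rank), ]
  a <- rec$pcan_p[rec$rank == 1L]
  b <- rec$pcan_p[rec$rank > 1L]
  if (length(a) == 0L || length(b) == 0L)
    stop("porosity_group_test: a group is empty")
  degenerate <- FALSE
  if ((length(a) < 2L || var(a) == 0) && (length(b) < 2L || var(b) == 0)) {
    degenerate <- TRUE
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      statistic <- 0; p <- 1
    } else {
      statistic <- Inf * sign(mean(a) - mean(b)); p <- 0
    }
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
    statistic <- unname(tt$statistic); p <- tt$p.value
  }
  pr <- pp <- NA_real_
  if (nrow(rec) >= 3L && var(rec$pcan_p) > 0 && var(rec$rank) > 0) {
    ct <- cor.test(rec$pcan_p, rec$rank)
    pr <- unname(ct$estimate); pp <- ct$p.value
  }
  test_result("porosity_young_vs_older_t", statistic, p,
              n = c(length(a), length(b)), alpha = alpha,
              median_young = median(a), median_older = median(b),
              pearson_r = pr, pearson_p = pp, degenerate = degenerate)
}

#' Correlate per-lacuna connection counts with neighbor mineralization
#'
#' Pearson correlation between the number of interface crossings per
#' lacuna (N.Conn) and the normalized mean gray value of the neighboring
#' older region, with the two-sided p-value from the t-transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom.
#'
#' @param records per-lacuna data frame from \code{\link{connection_table}}
#'   (needs \code{n_conn} and \code{neighbor_region_norm_gv}).
#' @param alpha significance level.
#' @return an \code{\link{test_result}}; \code{statistic} is the Pearson r,
#'   extras carry the t value.
#' @export
connection_correlation <- function(records, alpha = 0.05) {
  rec <- records[!is.na(records$n_conn) &
                   !is.na(records$neighbor_region_norm_gv), ]
  n <- nrow(rec)
  if (n < 3L) stop("connection_correlation: need at least 3 lacunae")
  if (var(rec$n_conn) == 0 || var(rec$neighbor_region_norm_gv) == 0)
    stop("connection_correlation: zero variance in a variable")
  ct <- cor.test(rec$n_conn, rec$neighbor_region_norm_gv)
  test_result("n_conn_vs_neighbor_gv_pearson", unname(ct$estimate),
              ct$p.value, n = n, alpha = alpha,
              t_value = unname(ct$statistic), df = unname(ct$parameter))
}

#' Pipeline configuration
#'
#' All tunable parameters of the analysis with their standard values:
#' morphology radii in pixels (region erosion 50, mask-B dilation 10,
#' mask-C erosion 10, lacunar opening 7), the 1500-voxel lacunar and
#' 100-pixel canalicular size filters, 15 minimum-intensity projections
#' over 130 slices, top-hat radius 10 px, interface dilation 3 px, and the
#' 25 um counting/proximity radii (converted through the voxel size, never
#' hard-coded in voxels). Override any subset via \code{...}.
#'
#' @param ... named overrides of the defaults.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_id = "sample",
    seed = 1L,
    # input: either a phantom generator or volume + labels on disk
    phantom = NULL,           # "default" | "porosity" | "connection" | fn
    phantom_args = list(),
    input_volume = NULL,      # path for read_volume
    input_labels = NULL,      # path to a dense label TIFF volume
    voxel_size_nm = NULL,     # required with input_volume lacking sidecar
    label_slices = 5L,        # sparse slices drawn from truth for phantoms
    # mineralization
    otsu_bins = 256L,
    opening_radius_vox = 7,
    lacuna_min_voxels = 1500L,
    region_erosion_px = 50,
    b_dilation_px = 10,
    c_erosion_px = 10,
    connectivity = 26L,
    # porosity
    window_slices = 130L,
    n_projections = 15L,
    tophat_radius_px = 10L,
    min_component_px = 100L,
    projection_offset = 0L,
    # connections
    radius_um = 25,
    band_dilation_px = 3,
    proximity_um = 25,
    # statistics
    alpha = 0.05,
    var_equal = TRUE,
    out_dir = NULL)
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown keys: ", paste(unknown, collapse = ", "))
  structure(modifyList(cfg, user), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of \code{\link{pipeline_config}}
#'   keys.
#' @return a \code{pipeline_config}.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Configuration matched to the default validation phantom
#'
#' The default fixture has 112 slices at 100 nm voxels, so the projection
#' windows shrink to 4 windows of 28 slices (1.4 um each); all other keys
#' keep their standard values.
#'
#' @param seed phantom noise seed.
#' @param ... further overrides.
#' @return a \code{pipeline_config}.
#' @export
default_phantom_config <- function(seed = 1L, ...) {
  base <- list(phantom = "default", seed = seed,
               window_slices = 28L, n_projections = 4L)
  do.call(pipeline_config, modifyList(base, list(...)))
}

# desk-scale config for the 200 nm connection phantoms: same physical
# dimensions as the standard pixel values at their native voxel size
connection_phantom_config <- function(seed = 1L, ...) {
  base <- list(phantom = "connection", seed = seed,
               opening_radius_vox = 3, region_erosion_px = 20,
               b_dilation_px = 5, c_erosion_px = 5,
               tophat_radius_px = 5L, min_component_px = 30L,
               window_slices = 16L, n_projections = 4L)
  do.call(pipeline_config, modifyList(base, list(...)))
}

# config for the porosity phantoms (100 slices; smaller region erosion so
# the 12 um regions keep a mineral core; the 2D noise filter keeps its
# physical area of 0.25 um^2, i.e. 25 px at 100 nm voxels)
porosity_phantom_config <- function(seed = 1L, ...) {
  base <- list(phantom = "porosity", seed = seed,
               window_slices = 50L, n_projections = 2L,
               region_erosion_px = 15, b_dilation_px = 5,
               c_erosion_px = 5, min_component_px = 25L)
  do.call(pipeline_config, modifyList(base, list(...)))
}

#' Analyze a family of tube-density phantoms
#'
#' Runs the full pipeline on \code{\link{porosity_validation_phantom}}s for
#' several seeds and stacks their per-region tables, giving the multi-sample
#' porosity-by-age records on which
#' \code{\link{porosity_group_test}} operates (the youngest region of each
#' sample versus the older ones).
#'
#' @param seeds integer seeds, one phantom per seed.
#' @param density_ratio young/old tube-count ratio of the generator.
#' @return data frame with columns \code{sample}, \code{region_id},
#'   \code{rank}, \code{norm_mean_gv}, \code{pcanp}.
#' @export
porosity_family_analysis <- function(seeds = 1:6, density_ratio = 2) {
  do.call(rbind, lapply(seeds, function(s) {
    cfg <- porosity_phantom_config(
      s, sample_id = paste0("phantom", s),
      phantom_args = list(density_ratio = density_ratio))
    run_pipeline(cfg)$tables$per_region
  }))
}

#' Analyze a family of connection phantoms
#'
#' Runs the full pipeline on \code{\link{connection_validation_phantom}}s
#' whose old-region gray value varies across the family while the number of
#' generated crossings follows \code{n_crossings}, and stacks the per-lacuna
#' tables: the input for \code{\link{connection_correlation}} (N.Conn versus
#' neighbor-region normalized mean gray value).
#'
#' @param old_gvs old-region gray values, one phantom each.
#' @param n_crossings generated crossing counts (same length); the default
#'   decreases with \code{old_gvs}, encoding fewer connections towards more
#'   mineralized neighbors.
#' @param seeds noise seeds (same length).
#' @return data frame with columns \code{sample}, \code{lacuna_id},
#'   \code{n_conn}, \code{own_region_norm_gv},
#'   \code{neighbor_region_norm_gv}.
#' @export
connection_family_analysis <- function(old_gvs = seq(154, 164,
                                                     length.out = 8),
                                       n_crossings = pmin(4, pmax(0, floor(
                                         (166 - old_gvs) / 3))),
                                       seeds = seq_along(old_gvs) + 100L) {
  stopifnot(length(old_gvs) == length(n_crossings),
            length(old_gvs) == length(seeds))
  do.call(rbind, lapply(seq_along(old_gvs), function(i) {
    cfg <- connection_phantom_config(
      seeds[i], sample_id = paste0("phantom", seeds[i]),
      phantom_args = list(n_crossing = n_crossings[i],
                          old_gv = old_gvs[i]))
    run_pipeline(cfg)$tables$per_lacuna
  }))
}

# sparse slice labels extracted from a phantom's ground-truth region mask
truth_sparse_labels <- function(truth, n_slices) {
  nz <- dim(truth$region_labels)[1]
  zs <- unique(round(seq(1, nz, length.out = max(2L, n_slices))))
  sparse_region_labels(lapply(zs, function(z)
    list(slice = as.integer(z), labels = truth$region_labels[z, , ])),
    n_regions = max(truth$region_labels))
}

phantom_generators <- function() {
  list(default = default_validation_phantom,
       porosity = porosity_validation_phantom,
       connection = connection_validation_phantom)
}

#' Run the full analysis pipeline
#'
#' Executes regional-mask construction, mineralization assessment,
#' projected canalicular porosity, interface-crossing counting and the
#' statistical summaries on one volume (a phantom or data read from disk),
#' and optionally writes the CSV tables plus a machine-readable run
#' manifest. All randomness flows from \code{config$seed}; reruns with an
#' identical configuration are bit-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list (invisible) with elements \code{volume}, \code{truth}
#'   (phantom runs), \code{masks}, \code{gv_check}, \code{region_stats},
#'   \code{projections}, \code{canal_masks}, \code{porosity},
#'   \code{candidates}, \code{connections}, \code{tests}, \code{tables}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " stage: ", conditionMessage(e), call. = FALSE))
  }

  truth <- NULL
  vol <- stage("input", {
    if (!is.null(config$phantom)) {
      gen <- if (is.function(config$phantom)) config$phantom
             else phantom_generators()[[config$phantom]]
      if (is.null(gen)) stop("unknown phantom '", config$phantom, "'")
      ph <- do.call(gen, c(list(seed = config$seed), config$phantom_args))
      truth <- ph$truth
      ph$volume
    } else if (!is.null(config$input_volume)) {
      read_volume(config$input_volume, config$voxel_size_nm)
    } else stop("config must name a phantom or an input volume")
  })

  masks <- stage("region_masks", {
    if (!is.null(truth)) {
      sp <- truth_sparse_labels(truth, config$label_slices)
      interpolate_region_mask(sp, dim(vol$data))
    } else if (!is.null(config$input_labels)) {
      lv <- read_volume(config$input_labels, vol$voxel_size_nm)
      region_mask_set(array(as.integer(lv$data), dim(lv$data)), "supplied")
    } else stop("no region labels available")
  })
  gv_check <- stage("region_masks", validate_regions_against_gv(vol, masks))

  mask_b <- stage("mineralization", low_intensity_mask(vol, config$otsu_bins))
  seg <- stage("mineralization",
               segment_lacunae(vol, config$opening_radius_vox,
                               config$lacuna_min_voxels, config$connectivity,
                               config$otsu_bins))
  region_stats <- stage("mineralization", rank_regions(
    regional_mean_gv(vol, masks, mask_b, seg$labels,
                     config$region_erosion_px, config$b_dilation_px,
                     config$c_erosion_px)))

  pset <- stage("porosity", min_intensity_projections(
    vol, config$window_slices, config$n_projections,
    region_labels = masks$mask_a, lacuna_labels = seg$labels,
    offset = config$projection_offset))
  canal_masks <- stage("porosity", lapply(pset$projections, function(p)
    segment_canaliculi_2d(p, config$tophat_radius_px,
                          config$min_component_px, config$otsu_bins)))
  porosity <- stage("porosity", regional_porosity(pset, canal_masks))

  candidates <- stage("connections", select_lacunae(
    seg$labels, masks, region_stats, vol$voxel_size_nm, config$proximity_um))
  conn <- stage("connections", count_all_connections(
    vol, seg$labels, masks, candidates, config$radius_um,
    config$band_dilation_px, config$tophat_radius_px,
    config$min_component_px))
  conn_tab <- stage("connections",
                    connection_table(conn, region_stats, porosity))

  per_region <- data.frame(sample = config$sample_id,
                           region_id = region_stats$region_id,
                           rank = region_stats$rank,
                           norm_mean_gv = region_stats$norm_mean_gv,
                           pcanp = porosity$pcan_p[
                             match(region_stats$region_id,
                                   porosity$region_id)])
  per_lacuna <- data.frame(sample = rep(config$sample_id, nrow(conn_tab)),
                           lacuna_id = conn_tab$lacuna_id,
                           n_conn = conn_tab$n_conn,
                           own_region_norm_gv = conn_tab$own_region_norm_gv,
                           neighbor_region_norm_gv =
                             conn_tab$neighbor_region_norm_gv)

  tests <- list()
  gt <- tryCatch(porosity_group_test(
    data.frame(rank = per_region$rank, pcan_p = per_region$pcanp),
    config$alpha, config$var_equal), error = function(e) NULL)
  if (!is.null(gt)) tests$porosity_group <- gt
  cc <- tryCatch(connection_correlation(conn_tab, config$alpha),
                 error = function(e) NULL)
  if (!is.null(cc)) tests$connection_correlation <- cc
  per_test <- data.frame(
    name = vapply(tests, `[[`, character(1), "name"),
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"))
  if (nrow(per_test) == 0L)
    per_test <- data.frame(name = character(0), statistic = numeric(0),
                           p_value = numeric(0))

  tables <- list(per_region = per_region, per_lacuna = per_lacuna,
                 per_test = per_test)
  if (!is.null(config$out_dir)) {
    files <- write_results(tables, config$out_dir)
    manifest <- list(
      package_version = as.character(utils::packageVersion("olcn")),
      config = unclass(config)[!vapply(unclass(config), is.function,
                                       logical(1))],
      n_regions = masks$n_regions,
      n_lacunae = seg$n,
      n_candidates = nrow(candidates),
      outputs = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(volume = vol, truth = truth, masks = masks,
                 gv_check = gv_check, mask_b = mask_b, lacunae = seg,
                 region_stats = region_stats, projections = pset,
                 canal_masks = canal_masks, porosity = porosity,
                 candidates = candidates, connections = conn_tab,
                 tests = tests, tables = tables, config = config))
}
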