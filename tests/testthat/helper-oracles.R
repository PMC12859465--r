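# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (naive loops / definitional scans).

# exhaustive Otsu: naive loop over all bin boundaries
brute_otsu <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((v - rng[1]) / width) + 1L, n_bins)
  h <- tabulate(idx, n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  n <- length(v)
  best <- -Inf
  bestk <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(h[1:k])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * centers[1:k]) / w0
    mu1 <- sum(h[(k + 1):n_bins] * centers[(k + 1):n_bins]) / w1
    bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      bestk <- k
    }
  }
  rng[1] + bestk * width
}

# exhaustive squared EDT: per voxel, min over all foreground voxels
brute_edt_sq <- function(mask) {
  d <- dim(mask)
  co <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(co) == 0L) return(out)
  if (length(d) == 2L) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j] <- min((co[, 1] - i)^2 + (co[, 2] - j)^2)
  } else {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      out[i, j, k] <- min((co[, 1] - i)^2 + (co[, 2] - j)^2 +
                            (co[, 3] - k)^2)
  }
  out
}

# definitional interface band: voxels outside `older` whose minimal distance
# to any `older` voxel is <= d, computed by shifting the older mask over all
# integer offsets within the ball (no distance transform involved)
brute_band <- function(labels, older_label, d) {
  older <- labels == older_label
  dims <- dim(older)
  nd <- length(dims)
  acc <- array(FALSE, dims)
  rng <- -floor(d):floor(d)
  offs <- if (nd == 2L) expand.grid(rng, rng, 0) else
    expand.grid(rng, rng, rng)
  offs <- offs[rowSums(offs^2) <= d^2, , drop = FALSE]
  shift_mask <- function(m, o) {
    out <- array(FALSE, dims)
    src <- dst <- vector("list", nd)
    for (ax in seq_len(nd)) {
      n <- dims[ax]
      s <- o[[ax]]
      if (abs(s) >= n) return(out)
      src[[ax]] <- if (s >= 0) seq_len(n - s) else (1 - s):n
      dst[[ax]] <- if (s >= 0) (1 + s):n else seq_len(n + s)
    }
    if (nd == 2L) out[dst[[1]], dst[[2]]] <- m[src[[1]], src[[2]]]
    else out[dst[[1]], dst[[2]], dst[[3]]] <-
        m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (i in seq_len(nrow(offs)))
    acc <- acc | shift_mask(older, as.list(offs[i, ]))
  acc & !older
}

# noise-free projected tube-density oracle: OR-project the rasterized
# canaliculi (minus lacunae) over the same windows, assign pixels by the
# noise-free argmin region projection, and pool the ratio per region
oracle_projected_pcanp <- function(ph, windows) {
  tr <- ph$truth
  R <- max(tr$region_labels)
  num <- den <- rep(0, R)
  for (i in seq_len(nrow(windows))) {
    zs <- windows$start[i]:windows$end[i]
    canal <- apply(tr$canal_mask[zs, , ] & tr$lacuna_labels[zs, , ] == 0L,
                   c(2, 3), any)
    lac <- apply(tr$lacuna_labels[zs, , ] > 0L, c(2, 3), any)
    pore <- tr$canal_mask[zs, , ] | tr$lacuna_labels[zs, , ] > 0L
    gv0 <- array(ifelse(pore, 60, 160), dim = c(length(zs), dim(canal)))
    p <- olcn:::project_window(gv0, seq_along(zs), tr$region_labels[zs, , ])
    for (r in seq_len(R)) {
      in_r <- p$region == r
      num[r] <- num[r] + sum(canal & !lac & in_r)
      den[r] <- den[r] + sum(in_r & !lac & !canal)
    }
  }
  num / den
}

# cached phantoms (one generation per noise level across the whole suite)
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(seed = 1L, noise_sd = 6) {
  key <- paste0("fix_", seed, "_", noise_sd)
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- default_validation_phantom(seed, noise_sd)
  fixture_cache[[key]]
}

# minimal age-rank table taken from phantom construction order (region ids
# are ordered young -> old by the generator's contract)
truth_rank_stats <- function(ph) {
  gv <- ph$params$region_gv_means
  data.frame(region_id = seq_along(gv), norm_mean_gv = gv / ph$params$lacuna_gv,
             excluded = FALSE, rank = seq_along(gv))
}

# lean crossing-count measurement on the default fixture: ground-truth
# region mask and ranks, pipeline lacunar segmentation + cluster + band +
# counting; returns per-candidate pipeline counts next to ground truth
fixture_crossing_counts <- function(seed, noise_sd) {
  ph <- default_validation_phantom(seed, noise_sd)
  vol <- ph$volume
  seg <- segment_lacunae(vol)
  masks <- region_mask_set(ph$truth$region_labels, "supplied")
  stats <- truth_rank_stats(ph)
  cand <- select_lacunae(seg$labels, masks, stats, vol$voxel_size_nm, 25)
  conn <- count_all_connections(vol, seg$labels, masks, cand)
  map <- match_lacunae(seg$labels, ph$truth$lacuna_labels)
  data.frame(truth_id = map[conn$lacuna_id],
             truth_within =
               ph$truth$true_crossing_counts$n_within[map[conn$lacuna_id]],
             n_conn = conn$n_conn)
}
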