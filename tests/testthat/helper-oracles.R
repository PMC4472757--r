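# Independent oracles and fixture builders. Everything here is brute force
# or closed form on purpose: none of it shares code with the package paths
# it checks.

# straight axial tube mask (axis along x at row jc/kc), radius in voxels
make_tube_mask <- function(nx, ny, nz, radius_vox, spacing = 1) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  arr <- array(FALSE, c(nx, ny, nz))
  jc <- (ny + 1) / 2; kc <- (nz + 1) / 2
  for (j in 1:ny) for (k in 1:nz)
    if ((j - jc)^2 + (k - kc)^2 <= radius_vox^2) arr[, j, k] <- TRUE
  structure(list(mask = arr, spacing = spacing, origin = c(0, 0, 0),
                 provenance = list(threshold = NA, seed_point = NA)),
            class = "segmentation_mask")
}

# brute-force anisotropic distance to nearest background voxel center,
# counting out-of-grid voxels as background
bf_distance_map <- function(mask, spacing) {
  d <- dim(mask)
  out <- array(0, d)
  bg <- which(!mask, arr.ind = TRUE)
  for (v in which(mask)) {
    ai <- arrayInd(v, d)
    best <- Inf
    if (nrow(bg) > 0)
      best <- min(sqrt(((bg[, 1] - ai[1]) * spacing[1])^2 +
                       ((bg[, 2] - ai[2]) * spacing[2])^2 +
                       ((bg[, 3] - ai[3]) * spacing[3])^2))
    for (ax in 1:3)
      best <- min(best, ai[ax] * spacing[ax], (d[ax] + 1 - ai[ax]) * spacing[ax])
    out[v] <- best
  }
  out
}

# exhaustive optimal radius-weighted path cost by Bellman-Ford relaxation
# over the 26-neighbor graph; edge cost = step * (1/r_u + 1/r_v) / 2
bf_trace_cost <- function(mask, spacing, radius, start_ijk, end_ijk) {
  d <- dim(mask)
  vox <- which(mask)
  id <- array(NA_integer_, d)
  id[vox] <- seq_along(vox)
  coords <- arrayInd(vox, d)
  eu <- ev <- integer(0); ew <- numeric(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (n in seq_along(vox)) {
    nb <- sweep(offs, 2, coords[n, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    tid <- id[nb]
    keep <- !is.na(tid)
    if (!any(keep)) next
    nb <- nb[keep, , drop = FALSE]; tid <- tid[keep]
    step <- sqrt(colSums((t(nb) - coords[n, ])^2 * spacing^2))
    w <- step * 0.5 * (1 / radius[vox[n]] + 1 / radius[vox][tid])
    eu <- c(eu, rep(n, length(tid))); ev <- c(ev, tid); ew <- c(ew, w)
  }
  s <- id[start_ijk[1], start_ijk[2], start_ijk[3]]
  e <- id[end_ijk[1], end_ijk[2], end_ijk[3]]
  dist <- rep(Inf, length(vox)); dist[s] <- 0
  repeat {
    nd <- dist
    relax <- dist[eu] + ew
    agg <- tapply(relax, ev, min)
    idx <- as.integer(names(agg))
    nd[idx] <- pmin(nd[idx], agg)
    if (all(nd >= dist - 1e-15)) break
    dist <- nd
  }
  dist[e]
}

# random connected 26-neighborhood mask containing at least 2 voxels
random_connected_mask <- function(nx, ny, nz, p_fill = 0.55) {
  repeat {
    arr <- array(stats::runif(nx * ny * nz) < p_fill, c(nx, ny, nz))
    if (!any(arr)) next
    # keep the component of a random foreground voxel (26-connected BFS)
    seed <- sample(which(arr), 1)
    comp <- array(FALSE, dim(arr))
    comp[seed] <- TRUE
    frontier <- seed
    d <- dim(arr)
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        ai <- arrayInd(v, d)
        for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
          if (a == 0 && b == 0 && cc == 0) next
          q <- ai + c(a, b, cc)
          if (any(q < 1) || any(q > d)) next
          lin <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
          if (arr[lin] && !comp[lin]) { comp[lin] <- TRUE; nxt <- c(nxt, lin) }
        }
      }
      frontier <- nxt
    }
    if (sum(comp) >= 2) return(comp)
  }
}

# small curved stenosed vessel + default-intensity scene, cheap to render
small_test_scene <- function(diameter = 0.2, length_mm = 1.5, seed = 1,
                             severity = 0.4, noise_sd = 2, psf = 0.018) {
  cp <- rbind(c(0, 0, 0), c(length_mm / 2, 0.08, 0.02), c(length_mm, 0, 0))
  v <- vessel_spec(cp, base_diameter = diameter,
                   stenoses = data.frame(position = 0.5, severity = severity,
                                         extent = 0.2),
                   length = length_mm)
  scene_spec(v, noise_sd = noise_sd, psf_sigma = psf, rng_seed = seed)
}

seed_xyz <- function(ph, which_end, vessel = 1) {
  s <- ph$seed_points[ph$seed_points$vessel_id ==
                        unique(ph$seed_points$vessel_id)[vessel], ]
  unlist(s[s$end == which_end, c("x_mm", "y_mm", "z_mm")])
}
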