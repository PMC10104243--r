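# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's accelerated code paths.

library(tibble)
library(dplyr)

# straight filament along a direction
straight_filament <- function(id, from, to, kind = "actin", n_nodes = 2) {
  t <- seq(0, 1, length.out = n_nodes)
  tibble(
    filament_id = id, kind = kind, node_index = seq_len(n_nodes),
    x = from[1] + t * (to[1] - from[1]),
    y = from[2] + t * (to[2] - from[2]),
    z = from[3] + t * (to[3] - from[3])
  )
}

# dense-walk arc-length resampling oracle (0.01 nm steps)
oracle_resample <- function(nodes_mat, interval, step = 0.01) {
  seg <- diff(nodes_mat)
  lens <- sqrt(rowSums(seg^2))
  L <- sum(lens)
  dense_t <- seq(0, L, by = step)
  walk <- matrix(NA_real_, length(dense_t), 3)
  cum <- c(0, cumsum(lens))
  for (i in seq_along(dense_t)) {
    s <- dense_t[i]
    j <- max(which(cum <= s + 1e-12))
    j <- min(j, nrow(seg))
    f <- (s - cum[j]) / lens[j]
    walk[i, ] <- nodes_mat[j, ] + f * seg[j, ]
  }
  targets <- seq(0, L, by = interval)
  if (L - targets[length(targets)] >= interval / 2 - 1e-9 &&
      L - targets[length(targets)] > 1e-9) {
    targets <- c(targets, L)
  }
  idx <- vapply(targets, function(s) which.min(abs(dense_t - s)), integer(1))
  walk[idx, , drop = FALSE]
}

# exhaustive nearest-foreign-point search with the package's tie-break
# (lowest filament id, then lowest point index)
oracle_nearest_foreign <- function(points, ref_points = points) {
  ref <- ref_points %>% arrange(filament_id, point_index)
  out_d <- numeric(nrow(points))
  out_id <- character(nrow(points))
  out_pi <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    cand <- ref[ref$filament_id != points$filament_id[i], ]
    d <- sqrt((cand$x - points$x[i])^2 + (cand$y - points$y[i])^2 +
                (cand$z - points$z[i])^2)
    j <- which(d == min(d))[1]  # cand is sorted: first hit = tie-break winner
    out_d[i] <- d[j]
    out_id[i] <- cand$filament_id[j]
    out_pi[i] <- cand$point_index[j]
  }
  tibble(nn_distance = out_d, nn_filament_id = out_id, nn_point_index = out_pi)
}

# exhaustive point-to-boundary-voxel-center distances
oracle_mask_distance <- function(points_mat, mask) {
  grid <- mask$grid != 0L
  d <- dim(grid)
  bnd <- c()
  idx <- which(grid, arr.ind = TRUE)
  is_bnd <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    if (i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3]) {
      is_bnd[r] <- TRUE
    } else {
      is_bnd[r] <- !(grid[i - 1, j, k] && grid[i + 1, j, k] &&
                       grid[i, j - 1, k] && grid[i, j + 1, k] &&
                       grid[i, j, k - 1] && grid[i, j, k + 1])
    }
  }
  centers <- sweep((idx[is_bnd, , drop = FALSE] - 0.5) * mask$voxel_size,
                   2, mask$origin, "+")
  vapply(seq_len(nrow(points_mat)), function(i) {
    p <- points_mat[i, ]
    vi <- floor((p - mask$origin) / mask$voxel_size) + 1
    if (all(vi >= 1) && all(vi <= d) && grid[vi[1], vi[2], vi[3]]) return(0)
    min(sqrt(colSums((t(centers) - p)^2)))
  }, numeric(1))
}

# recursive-free flood fill (26-connectivity) for component counting
oracle_component_count <- function(grid) {
  fg <- grid != 0L
  d <- dim(fg)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(fg & lab == 0L)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (cur - 1) %/% (d[1] * d[2])
      j <- ((cur - 1) %/% d[1]) %% d[2]
      i <- (cur - 1) %% d[1]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] || kk < 0 || kk >= d[3]) next
        t <- ii + d[1] * (jj + d[2] * kk) + 1
        if (fg[t] && lab[t] == 0L) {
          lab[t] <- nxt
          queue <- c(queue, t)
        }
      }
    }
  }
  nxt
}

# slab PM mask: two horizontal slabs centered at the given z values
slab_pm_mask <- function(extent = c(200, 200, 300), voxel_size = 5,
                         z_centers = c(20, 220), thickness = 10) {
  dims <- round(extent / voxel_size)
  g <- array(0L, dims)
  zc <- (seq_len(dims[3]) - 0.5) * voxel_size
  for (z0 in z_centers) {
    g[, , abs(zc - z0) <= thickness / 2] <- 1L
  }
  volume_mask(g, voxel_size, role = "pm")
}

# spherical mask (single label)
sphere_mask <- function(center, radius, extent, voxel_size, role = "isg") {
  dims <- round(extent / voxel_size)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size - center[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  volume_mask(array(as.integer(d2 <= radius^2), dims), voxel_size, role = role)
}

# random multi-filament scene for oracle comparisons (no masks)
random_filament_set <- function(n_fil, seed, kind = "actin", box = c(300, 300, 300)) {
  set.seed(seed)
  bind_rows(lapply(seq_len(n_fil), function(i) {
    from <- runif(3, 20, box - 20)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    len <- runif(1, 60, 150)
    to <- pmin(pmax(from + dir * len, 5), box - 5)
    straight_filament(sprintf("%s_%02d", kind, i), from, to, kind = kind,
                      n_nodes = sample(2:4, 1))
  }))
}

# rigid motion helpers
rotation_matrix <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

apply_rigid <- function(tbl, R, t) {
  m <- as.matrix(tbl[, c("x", "y", "z")]) %*% t(R)
  tbl$x <- m[, 1] + t[1]
  tbl$y <- m[, 2] + t[2]
  tbl$z <- m[, 3] + t[3]
  tbl
}
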