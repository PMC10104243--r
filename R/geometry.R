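#' Resample filaments at a fixed arc-length interval
#'
#' Every filament polyline is re-parameterized by arc length and sampled at
#' 0, `interval`, 2×`interval`, ... nm. The original terminal node is
#' appended when its arc distance from the last regular sample is at least
#' half the interval, so total length is covered without biasing point
#' counts. The 4 nm default matches the convention used for distance
#' analyses of traced cytoskeletal filaments.
#'
#' @param tbl filament node tibble.
#' @param interval sampling interval in nm (> 0).
#' @return tibble with `filament_id`, `kind`, `point_index` (1-based),
#'   `x`, `y`, `z`.
#' @export
resample_filaments <- function(tbl, interval = 4) {
  if (!is.numeric(interval) || interval <= 0) abort("interval must be > 0")
  validate_filaments(tbl)
  groups <- split(tbl, tbl$filament_id)
  res <- lapply(groups, function(g) {
    p <- cbind(g$x, g$y, g$z)
    pts <- resample_polyline(p, interval)
    tibble(
      filament_id = g$filament_id[1], kind = g$kind[1],
      point_index = seq_len(nrow(pts)),
      x = pts[, 1], y = pts[, 2], z = pts[, 3]
    )
  })
  bind_rows(res) %>% arrange(.data$filament_id, .data$point_index)
}

# arc-length parameterization of one polyline (matrix of xyz rows)
resample_polyline <- function(p, interval) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (interval >= L) {
    warn("interval >= filament arc length; returning the two end nodes")
    return(p[c(1, nrow(p)), , drop = FALSE])
  }
  targets <- seq(0, L, by = interval)
  # append the terminal node when the residual is at least interval/2
  if (L - targets[length(targets)] > interval / 2 - 1e-9 &&
      L - targets[length(targets)] > 1e-9) {
    targets <- c(targets, L)
  }
  out <- matrix(0, nrow = length(targets), ncol = 3)
  j <- 1
  for (i in seq_along(targets)) {
    t <- min(targets[i], L)
    while (j < length(s) - 1 && s[j + 1] < t) j <- j + 1
    span <- s[j + 1] - s[j]
    f <- if (span > 0) (t - s[j]) / span else 0
    out[i, ] <- p[j, ] + f * (p[j + 1, ] - p[j, ])
  }
  out
}

#' End-to-end chord of each filament
#'
#' The filament direction used for all angle computations is the unit
#' vector between the two end nodes of the original (unresampled) polyline.
#' A per-segment mean direction is available via `direction = "mean"`, but
#' the chord is the analysis default.
#'
#' @param tbl filament node tibble.
#' @param direction `"chord"` (end-to-end, default) or `"mean"`
#'   (length-weighted mean of segment directions).
#' @return tibble with one row per filament: unit direction (`ux`, `uy`,
#'   `uz`), arc length, and both end nodes.
#' @export
filament_chords <- function(tbl, direction = c("chord", "mean")) {
  direction <- match.arg(direction)
  validate_filaments(tbl)
  tbl %>%
    group_by(.data$filament_id, .data$kind) %>%
    summarise(
      x0 = first(.data$x), y0 = first(.data$y), z0 = first(.data$z),
      x1 = last(.data$x), y1 = last(.data$y), z1 = last(.data$z),
      arc_length = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2)),
      mx = sum(diff(.data$x)), my = sum(diff(.data$y)), mz = sum(diff(.data$z)),
      .groups = "drop"
    ) %>%
    mutate(
      dx = if (direction == "chord") .data$x1 - .data$x0 else .data$mx,
      dy = if (direction == "chord") .data$y1 - .data$y0 else .data$my,
      dz = if (direction == "chord") .data$z1 - .data$z0 else .data$mz,
      norm = sqrt(.data$dx^2 + .data$dy^2 + .data$dz^2),
      ux = .data$dx / .data$norm, uy = .data$dy / .data$norm, uz = .data$dz / .data$norm
    ) %>%
    select("filament_id", "kind", "ux", "uy", "uz", "arc_length",
           "x0", "y0", "z0", "x1", "y1", "z1")
}

unit_check <- function(v, name) {
  n <- sqrt(rowSums(v^2))
  if (any(n < 1e-12)) abort(paste0(name, " contains a zero vector"))
  if (any(abs(n - 1) > 1e-6)) v <- v / n
  v
}

as_vec_matrix <- function(v) {
  if (is.null(dim(v))) matrix(v, ncol = 3, byrow = FALSE) else as.matrix(v)
}

#' Angle between two direction vectors
#'
#' Undirected mode folds antiparallel directions together
#' (`acos(|a.b|)`, 0-90 degrees); directed mode keeps the full 0-180 degree
#' range (`acos(a.b)`), as used for anchored filament vectors that point
#' away from the membrane.
#'
#' @param a,b unit 3-vectors, or n x 3 matrices of unit rows.
#' @param mode `"undirected"` or `"directed"`.
#' @return angle(s) in degrees.
#' @export
angle_between_chords <- function(a, b, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  a <- unit_check(as_vec_matrix(a), "a")
  b <- unit_check(as_vec_matrix(b), "b")
  d <- rowSums(a * b)
  d <- pmin(pmax(d, -1), 1)
  if (mode == "undirected") deg(acos(abs(d))) else deg(acos(d))
}

#' Elevation of a chord out of a reference plane
#'
#' With the default z-axis normal this is the filament's elevation out of
#' the tomogram XY plane, the proxy used for orientation relative to the
#' plasma membrane: 0 degrees is PM-parallel, 90 degrees PM-orthogonal.
#'
#' @param chord unit 3-vector(s), n x 3 accepted.
#' @param normal unit plane normal (default z axis).
#' @return angle(s) in degrees, in \[0, 90\].
#' @export
angle_to_reference_plane <- function(chord, normal = c(0, 0, 1)) {
  chord <- unit_check(as_vec_matrix(chord), "chord")
  normal <- unit_check(matrix(normal, ncol = 3), "normal")
  d <- abs(chord %*% t(normal))[, 1]
  deg(asin(pmin(d, 1)))
}

#' Nearest foreign-filament point for every resampled point
#'
#' For each point of `points`, finds the nearest resampled point belonging
#' to a *different* filament among `ref_points` and returns the Euclidean
#' distance plus the identity of that neighbor. The grid-accelerated search
#' is exact and breaks distance ties deterministically: lowest neighbor
#' filament id (string sort order), then lowest point index.
#'
#' @param points resampled point tibble (query side).
#' @param ref_points resampled point tibble to search (defaults to
#'   `points`, i.e. all-against-all with self-filament exclusion).
#' @return `points` with `nn_distance` (nm), `nn_filament_id`,
#'   `nn_point_index` columns.
#' @export
nearest_foreign_points <- function(points, ref_points = points) {
  if (nrow(ref_points) == 0) {
    warn("no foreign filaments to search")
    return(points %>% mutate(nn_distance = NA_real_,
                             nn_filament_id = NA_character_,
                             nn_point_index = NA_integer_))
  }
  ref <- ref_points %>% arrange(.data$filament_id, .data$point_index)
  ids <- sort(unique(c(points$filament_id, ref$filament_id)))
  qg <- match(points$filament_id, ids)
  rg <- match(ref$filament_id, ids)
  nn <- cpp_nn_points(as.matrix(points[, c("x", "y", "z")]), as.integer(qg),
                      as.matrix(ref[, c("x", "y", "z")]), as.integer(rg))
  if (all(is.na(nn$index))) warn("no foreign filaments to search")
  points %>% mutate(
    nn_distance = nn$distance,
    nn_filament_id = ref$filament_id[nn$index],
    nn_point_index = ref$point_index[nn$index]
  )
}

#' Euclidean distance from points to a mask surface
#'
#' Distances are measured to the nearest boundary-voxel center of the
#' mask's nonzero region; points inside the region are at distance 0.
#' `method = "edt"` (default) samples an exact Euclidean distance transform
#' of the grid at each point's enclosing voxel, which matches a direct
#' nearest-boundary-voxel search to within one voxel diagonal; `method =
#' "exact"` performs that direct search on the point coordinates
#' themselves. Points outside the grid are clamped to it and flagged.
#'
#' @param points tibble with `x`, `y`, `z` (nm), or an n x 3 matrix.
#' @param mask a [volume_mask()].
#' @param method `"edt"` or `"exact"`.
#' @return tibble with `distance` (nm), `inside` and `clamped` logicals.
#' @export
distance_to_mask_surface <- function(points, mask, method = c("edt", "exact")) {
  method <- match.arg(method)
  if (!any(mask$grid != 0L)) abort("mask is empty")
  pm <- if (is.matrix(points)) points else as.matrix(points[, c("x", "y", "z")])
  pv <- point_voxel_index(pm, mask)
  d <- dim(mask$grid)
  lin <- pv$index[, 1] + d[1] * (pv$index[, 2] + d[2] * pv$index[, 3]) + 1
  inside <- as.vector(mask$grid)[lin] != 0L & !pv$clamped
  if (method == "edt") {
    edt <- mask_edt(mask)
    dist <- edt[lin] * mask$voxel_size
  } else {
    bnd <- mask_boundary_points(mask)
    nn <- cpp_nn_points(pm, rep(-1L, nrow(pm)),
                        as.matrix(bnd[, c("x", "y", "z")]),
                        rep(0L, nrow(bnd)))
    dist <- nn$distance
  }
  dist[inside] <- 0
  if (any(pv$clamped)) {
    warn(sprintf("%d point(s) outside the mask grid; distances computed via clamped coordinates",
                 sum(pv$clamped)))
  }
  tibble(distance = dist, inside = inside, clamped = pv$clamped)
}

# memoised-per-call exact EDT of a mask's nonzero region (voxel units)
mask_edt <- function(mask) {
  v <- cpp_edt3d(as.vector(mask$grid != 0L), dim(mask$grid))
  v
}

#' Boundary voxel centers of a mask's nonzero region
#'
#' Boundary voxels are foreground voxels with a background 6-neighbor (or
#' on the grid edge). Used for exact surface-distance queries and for
#' assigning PM component ids to filament end points.
#'
#' @param mask a [volume_mask()].
#' @return tibble with voxel-center `x`, `y`, `z` (nm), the voxel `label`,
#'   and 0-based `i`, `j`, `k` indices.
#' @export
mask_boundary_points <- function(mask) {
  b <- cpp_boundary_voxels(as.vector(mask$grid != 0L), dim(mask$grid))
  if (nrow(b) == 0) abort("mask is empty")
  centers <- voxel_centers(b, mask)
  d <- dim(mask$grid)
  lin <- b[, 1] + d[1] * (b[, 2] + d[2] * b[, 3]) + 1
  tibble(
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    label = as.vector(mask$grid)[lin],
    i = b[, 1], j = b[, 2], k = b[, 3]
  )
}
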