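#' Label connected components of a PM mask
#'
#' 26-connected component labeling of the nonzero region. Two membrane
#' patches count as "the same PM" for the neighbor analysis when they fall
#' in the same component.
#'
#' @param mask a [volume_mask()] with role `"pm"`.
#' @return list with `mask` (a relabeled [volume_mask()]) and
#'   `n_components`.
#' @export
label_pm_components <- function(mask) {
  if (mask$role != "pm") abort("mask role must be 'pm'")
  if (!any(mask$grid != 0L)) abort("pm mask is empty")
  lab <- cpp_label3d(as.vector(mask$grid != 0L), dim(mask$grid))
  k <- attr(lab, "n_components")
  grid <- array(as.integer(lab), dim = dim(mask$grid))
  list(mask = volume_mask(grid, mask$voxel_size, mask$origin, role = "pm"),
       n_components = k)
}

#' Detect PM-anchored filaments
#'
#' A filament is anchored when the smaller of its two end-point distances
#' to the PM surface is at most `threshold` (60 nm by default, the actin
#' tracing unit length; the boundary case of exactly 60 nm counts as
#' anchored). End-point distances are measured exactly against boundary
#' voxel centers -- end nodes of the original polyline, not resampled
#' points. Each anchored filament carries the component id of its nearest
#' PM patch and a directed unit vector from the PM-near end to the far
#' end.
#'
#' @param scene a [scene_bundle()] with a PM mask.
#' @param threshold anchoring distance threshold, nm.
#' @param kind filament class to analyze.
#' @return record tibble, one row per filament: `anchored`,
#'   `end_pm_distance`, `pm_component_id`, near/far end coordinates,
#'   directed vector (`vx`, `vy`, `vz`), `angle_to_pm`,
#'   `orientation_class`. Attributes are a summary with anchored count and
#'   percentage.
#' @export
find_anchored <- function(scene, threshold = 60, kind = "actin") {
  if (is.null(scene$masks$pm)) abort("scene has no PM mask")
  fil <- dplyr::filter(scene$filaments, .data$kind == !!kind)
  if (nrow(fil) == 0) abort(paste0("scene has no ", kind, " filaments"))
  lab <- label_pm_components(scene$masks$pm)
  bnd <- mask_boundary_points(lab$mask)
  chords <- filament_chords(fil)
  ends <- bind_rows(
    chords %>% select("filament_id", x = "x0", y = "y0", z = "z0") %>% mutate(end = 1L),
    chords %>% select("filament_id", x = "x1", y = "y1", z = "z1") %>% mutate(end = 2L)
  )
  nn <- cpp_nn_points(as.matrix(ends[, c("x", "y", "z")]),
                      rep(-1L, nrow(ends)),
                      as.matrix(bnd[, c("x", "y", "z")]),
                      rep(0L, nrow(bnd)))
  ends$pm_distance <- nn$distance
  ends$pm_component <- bnd$label[nn$index]
  near <- ends %>%
    group_by(.data$filament_id) %>%
    arrange(.data$pm_distance, .data$end, .by_group = TRUE) %>%
    summarise(
      end_pm_distance = first(.data$pm_distance),
      pm_component_id = first(.data$pm_component),
      near_x = first(.data$x), near_y = first(.data$y), near_z = first(.data$z),
      far_x = last(.data$x), far_y = last(.data$y), far_z = last(.data$z),
      .groups = "drop"
    )
  orient <- orientation_records(fil, scene_id = scene$scene_id,
                                condition = scene$condition)
  rec <- near %>%
    mutate(
      anchored = .data$end_pm_distance <= threshold,
      pm_component_id = ifelse(.data$anchored, .data$pm_component_id, NA_integer_),
      dx = .data$far_x - .data$near_x,
      dy = .data$far_y - .data$near_y,
      dz = .data$far_z - .data$near_z,
      norm = sqrt(.data$dx^2 + .data$dy^2 + .data$dz^2),
      vx = .data$dx / .data$norm, vy = .data$dy / .data$norm, vz = .data$dz / .data$norm
    ) %>%
    left_join(orient %>% select("filament_id", "angle_to_pm", "orientation_class"),
              by = "filament_id") %>%
    mutate(scene_id = scene$scene_id) %>%
    select("scene_id", "filament_id", "anchored", "end_pm_distance",
           "pm_component_id", "near_x", "near_y", "near_z",
           "far_x", "far_y", "far_z", "vx", "vy", "vz",
           "angle_to_pm", "orientation_class")
  out <- record_table(rec, "anchor_records",
                      list(scene_id = scene$scene_id, threshold = threshold,
                           n_pm_components = lab$n_components))
  attr(out, "summary") <- tibble(
    scene_id = scene$scene_id, condition = scene$condition,
    n_filaments = nrow(rec),
    anchored_count = sum(rec$anchored),
    anchored_percentage = 100 * mean(rec$anchored)
  )
  out
}

#' Directed angles between neighboring anchored filaments
#'
#' Neighbors are anchored filaments on the same PM component whose
#' PM-near end points are strictly closer than `neighbor_threshold`
#' (120 nm by default: twice the 60 nm tracing unit). Each unordered pair
#' is recorded in both directions so that per-host-class histograms are
#' well defined; the angle is the directed angle (0-180 degrees) between
#' the two near-to-far filament vectors.
#'
#' @param anchors output of [find_anchored()].
#' @param neighbor_threshold near-end separation threshold, nm.
#' @return record tibble: `filament_id_a`, `filament_id_b`,
#'   `near_end_separation`, `directed_angle`, host orientation columns.
#' @export
neighbor_angles <- function(anchors, neighbor_threshold = 120) {
  anc <- dplyr::filter(anchors, .data$anchored)
  if (nrow(anc) < 2) {
    warn("fewer than two anchored filaments")
    return(record_table(tibble(), "neighbor_angle_records",
                        list(neighbor_threshold = neighbor_threshold)))
  }
  out <- vector("list", 0)
  for (comp in unique(anc$pm_component_id)) {
    g <- anc[anc$pm_component_id == comp, ]
    if (nrow(g) < 2) next
    p <- as.matrix(g[, c("near_x", "near_y", "near_z")])
    dmat <- as.matrix(stats::dist(p))
    ij <- which(dmat < neighbor_threshold & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(ij) == 0) next
    va <- as.matrix(g[ij[, 1], c("vx", "vy", "vz")])
    vb <- as.matrix(g[ij[, 2], c("vx", "vy", "vz")])
    ang <- angle_between_chords(va, vb, mode = "directed")
    sep <- dmat[ij]
    half <- function(i, j) tibble(
      filament_id_a = g$filament_id[i], filament_id_b = g$filament_id[j],
      pm_component_id = comp,
      near_end_separation = sep, directed_angle = ang,
      host_angle_to_pm = g$angle_to_pm[i],
      host_orientation_class = g$orientation_class[i]
    )
    out[[length(out) + 1]] <- half(ij[, 1], ij[, 2])
    out[[length(out) + 1]] <- half(ij[, 2], ij[, 1])
  }
  if (length(out) == 0) {
    warn("no neighboring anchored filaments under the separation threshold")
    return(record_table(tibble(), "neighbor_angle_records",
                        list(neighbor_threshold = neighbor_threshold)))
  }
  rec <- bind_rows(out) %>%
    mutate(scene_id = anchors$scene_id[1]) %>%
    arrange(.data$filament_id_a, .data$filament_id_b)
  record_table(rec, "neighbor_angle_records",
               list(neighbor_threshold = neighbor_threshold))
}

#' Normalized anchored-angle histograms by host orientation class
#'
#' Bins the directed neighbor angles over \[0, 180\] degrees (15 degree
#' bins by default), separately for hosts oriented parallel versus
#' quasi-orthogonal to the PM. The raw (directed angle, host PM angle)
#' point set for density mapping is attached as attribute `"points"`.
#'
#' @param records output of [neighbor_angles()].
#' @param bin_width bin width in degrees.
#' @return record tibble: `host_orientation_class`, `bin_lo`, `bin_hi`,
#'   `n`, `probability`.
#' @export
anchored_angle_histograms <- function(records, bin_width = 15) {
  if (nrow(records) == 0) abort("no neighbor-angle records")
  classes <- c("parallel", "quasi_orthogonal")
  present <- intersect(classes, unique(records$host_orientation_class))
  if (length(present) < length(classes)) {
    inform(paste0("histogram omitted for empty class: ",
                  paste(setdiff(classes, present), collapse = ", ")))
  }
  edges <- seq(0, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  out <- lapply(present, function(cl) {
    a <- records$directed_angle[records$host_orientation_class == cl]
    bin <- pmin(findInterval(a, edges, rightmost.closed = TRUE), length(edges) - 1)
    tibble(
      host_orientation_class = cl,
      bin_lo = edges[-length(edges)], bin_hi = edges[-1],
      n = as.integer(tabulate(bin, nbins = length(edges) - 1))
    ) %>% mutate(probability = .data$n / sum(.data$n))
  })
  res <- record_table(bind_rows(out), "anchored_angle_histogram",
                      list(bin_width = bin_width))
  attr(res, "points") <- records %>%
    select(dplyr::any_of(c("directed_angle", "host_angle_to_pm",
                           "host_orientation_class")))
  res
}

#' Classify the anchored architecture of a scene
#'
#' Compares the neighbor-angle mass at 60-90 degrees (mutually crossing,
#' "netlike") against the mass below 30 degrees (radial near-parallel
#' projections, "blooming") and returns the label with the larger mass.
#'
#' @param records output of [neighbor_angles()].
#' @return list with `label`, `mass_60_90`, `mass_0_30`.
#' @export
classify_architecture <- function(records) {
  if (nrow(records) == 0) abort("no neighbor-angle records")
  a <- records$directed_angle
  m_net <- mean(a >= 60 & a < 90)
  m_bloom <- mean(a < 30)
  list(
    label = if (m_net > m_bloom) "netlike" else "blooming",
    mass_60_90 = m_net, mass_0_30 = m_bloom
  )
}

#' Height of the cell periphery
#'
#' With a PM mask holding two (or more) components -- the upper and lower
#' membrane of a milled lamella -- the height is the difference between the
#' mean z of the boundary voxel centers of the uppermost and the lowermost
#' component. For a slab-like membrane this equals the center-to-center
#' separation; the definition is one defensible operationalization and is
#' recorded as such in provenance.
#'
#' @param scene a [scene_bundle()] with a PM mask of at least two
#'   components.
#' @return height in nm, with attribute `"provenance"`.
#' @export
periphery_height <- function(scene) {
  if (is.null(scene$masks$pm)) abort("scene has no PM mask")
  lab <- label_pm_components(scene$masks$pm)
  if (lab$n_components < 2) {
    abort(paste0("PM mask has a single component; the z-based height needs ",
                 "both membranes (or configure a cytoplasm extent upstream)"))
  }
  bnd <- mask_boundary_points(lab$mask)
  mz <- bnd %>%
    group_by(.data$label) %>%
    summarise(mean_z = mean(.data$z), .groups = "drop")
  h <- max(mz$mean_z) - min(mz$mean_z)
  attr(h, "provenance") <- list(mode = "mean_boundary_z",
                                n_components = lab$n_components)
  h
}
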