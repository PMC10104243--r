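#' Per-filament orientation relative to the plasma membrane
#'
#' Computes each filament's chord elevation out of the reference plane
#' (tomogram XY by default, the PM proxy) and assigns the orientation
#' class: parallel below 45 degrees, quasi-orthogonal at or above 45
#' degrees. The boundary angle of exactly 45 degrees is quasi-orthogonal.
#'
#' @param tbl filament node tibble (typically the actin subset of a scene).
#' @param normal unit reference-plane normal, default the z axis.
#' @param scene_id,condition provenance labels carried into the records.
#' @return tibble with `filament_id`, `kind`, `angle_to_pm` (degrees),
#'   `orientation_class`.
#' @export
orientation_records <- function(tbl, normal = c(0, 0, 1),
                                scene_id = NA_character_,
                                condition = NA_character_) {
  chords <- filament_chords(tbl)
  chords %>%
    mutate(
      angle_to_pm = angle_to_reference_plane(cbind(.data$ux, .data$uy, .data$uz), normal),
      # exactly-45-degree chords classify as quasi-orthogonal (closed-right
      # rule); the 1e-9 guard absorbs arcsin round-off at the boundary
      orientation_class = ifelse(.data$angle_to_pm < 45 - 1e-9,
                                 "parallel", "quasi_orthogonal"),
      scene_id = scene_id, condition = condition
    ) %>%
    select("filament_id", "kind", "angle_to_pm", "orientation_class",
           "scene_id", "condition")
}

#' Orientation distribution of actin filaments in a scene
#'
#' Bins the per-filament PM angles over \[0, 90\] degrees and reports
#' per-bin fractions plus the aggregate parallel (\[0, 45)),
#' quasi-orthogonal (\[45, 90\]) and steep (\[60, 90\]) fractions used in
#' condition summaries.
#'
#' @param scene a [scene_bundle()].
#' @param bin_width bin width in degrees.
#' @param kind filament class to analyze.
#' @return list with `histogram` (per-bin fractions summing to 1),
#'   `fractions` (one-row aggregate tibble), and `records` (per-filament
#'   [orientation_records()]).
#' @export
orientation_distribution <- function(scene, bin_width = 5, kind = "actin") {
  fil <- dplyr::filter(scene$filaments, .data$kind == !!kind)
  if (nrow(fil) == 0) {
    warn(paste0("scene has no ", kind, " filaments"))
    empty <- record_table(tibble(bin_lo = double(), bin_hi = double(),
                                 n = integer(), fraction = double()),
                          "orientation_histogram",
                          list(scene_id = scene$scene_id))
    return(list(histogram = empty, fractions = tibble(), records = tibble()))
  }
  rec <- orientation_records(fil, scene_id = scene$scene_id,
                             condition = scene$condition)
  edges <- seq(0, 90, by = bin_width)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  bin <- pmin(findInterval(rec$angle_to_pm, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  hist <- tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    n = as.integer(tabulate(bin, nbins = length(edges) - 1))
  ) %>% mutate(fraction = .data$n / sum(.data$n))
  fr <- tibble(
    scene_id = scene$scene_id, condition = scene$condition,
    n_filaments = nrow(rec),
    parallel_fraction = mean(rec$orientation_class == "parallel"),
    quasi_orthogonal_fraction = mean(rec$orientation_class == "quasi_orthogonal"),
    steep_fraction = mean(rec$angle_to_pm >= 60)
  )
  list(
    histogram = record_table(hist, "orientation_histogram",
                             list(scene_id = scene$scene_id, bin_width = bin_width)),
    fractions = fr,
    records = record_table(rec, "orientation_records",
                           list(scene_id = scene$scene_id))
  )
}

#' Filament volume ratio of a scene
#'
#' Models each filament as a cylinder around its centerline and reports the
#' summed cylinder volume over the tomogram volume. Default radii follow
#' the tracing templates: 4 nm for actin (8 nm diameter), 7.5 nm for
#' microtubules (15 nm diameter).
#'
#' @param scene a [scene_bundle()].
#' @param kind `"actin"` or `"mt"`.
#' @param radius cylinder radius in nm; default by kind.
#' @return dimensionless ratio.
#' @export
volume_ratio <- function(scene, kind = c("actin", "mt"), radius = NULL) {
  kind <- match.arg(kind)
  if (any(!is.finite(scene$extent)) || any(scene$extent <= 0)) {
    abort("degenerate tomogram extent")
  }
  radius <- radius %||% c(actin = 4, mt = 7.5)[[kind]]
  fil <- dplyr::filter(scene$filaments, .data$kind == !!kind)
  if (nrow(fil) == 0) return(0)
  len <- filament_lengths(fil)
  sum(len$arc_length) * pi * radius^2 / prod(scene$extent)
}

#' Pairwise distance and angle structure of the filament network
#'
#' For every resampled point of every filament of the requested kind, the
#' distance to the nearest point on any *other* filament of that kind, the
#' undirected angle between the two filaments' chords, and the host
#' filament's orientation class. This is the record set behind the
#' distance-versus-angle density maps and the bundle criterion.
#'
#' @param scene a [scene_bundle()].
#' @param kind filament class (`"actin"` default; `"mt"` reuses the same
#'   machinery for the cell interior).
#' @param interval resampling interval, nm.
#' @return record tibble with one row per resampled point: `nn_distance`,
#'   `pair_angle` (degrees, \[0, 90\]), `host_orientation_class`.
#' @export
pair_distance_angle <- function(scene, kind = "actin", interval = 4) {
  fil <- dplyr::filter(scene$filaments, .data$kind == !!kind)
  n_fil <- dplyr::n_distinct(fil$filament_id)
  if (n_fil < 2) {
    warn("fewer than two filaments; no pairs to measure")
    return(record_table(tibble(), "pair_point_records",
                        list(scene_id = scene$scene_id)))
  }
  pts <- resample_filaments(fil, interval = interval)
  nn <- nearest_foreign_points(pts)
  orient <- orientation_records(fil, scene_id = scene$scene_id,
                                condition = scene$condition)
  chords <- filament_chords(fil)
  u <- as.matrix(chords[, c("ux", "uy", "uz")])
  rownames(u) <- chords$filament_id
  host_u <- u[nn$filament_id, , drop = FALSE]
  nbr_u <- u[nn$nn_filament_id, , drop = FALSE]
  out <- nn %>%
    mutate(
      pair_angle = angle_between_chords(host_u, nbr_u, mode = "undirected"),
      scene_id = scene$scene_id
    ) %>%
    left_join(orient %>% select("filament_id", host_angle_to_pm = "angle_to_pm",
                                host_orientation_class = "orientation_class"),
              by = "filament_id") %>%
    select("scene_id", host_filament_id = "filament_id", "point_index",
           "nn_distance", "nn_filament_id", "pair_angle",
           "host_angle_to_pm", "host_orientation_class")
  record_table(out, "pair_point_records",
               list(scene_id = scene$scene_id, kind = kind, interval = interval))
}

#' Normalized pair-distance histograms split by host orientation class
#'
#' Mirrors the figure convention of separate distance histograms for hosts
#' oriented parallel (< 45 degrees to the PM) and quasi-orthogonal: fixed
#' 10 nm bins from 0, probabilities summing to 1 within each class.
#'
#' @param records output of [pair_distance_angle()].
#' @param bin_width histogram bin width in nm.
#' @param max_distance upper edge (records beyond it are pooled into the
#'   last bin's edge sequence automatically).
#' @return record tibble: `host_orientation_class`, `bin_lo`, `bin_hi`,
#'   `n`, `probability`.
#' @export
distance_histograms_by_class <- function(records, bin_width = 10,
                                         max_distance = NULL) {
  if (nrow(records) == 0) abort("no pair records")
  classes <- c("parallel", "quasi_orthogonal")
  present <- intersect(classes, unique(records$host_orientation_class))
  if (length(present) < length(classes)) {
    inform(paste0("histogram omitted for empty class: ",
                  paste(setdiff(classes, present), collapse = ", ")))
  }
  top <- max_distance %||% (ceiling(max(records$nn_distance) / bin_width) * bin_width)
  edges <- seq(0, max(top, bin_width), by = bin_width)
  out <- lapply(present, function(cl) {
    d <- records$nn_distance[records$host_orientation_class == cl]
    bin <- pmin(findInterval(d, edges, rightmost.closed = FALSE) , length(edges) - 1)
    tibble(
      host_orientation_class = cl,
      bin_lo = edges[-length(edges)], bin_hi = edges[-1],
      n = as.integer(tabulate(bin, nbins = length(edges) - 1))
    ) %>% mutate(probability = .data$n / sum(.data$n))
  })
  record_table(bind_rows(out), "pair_distance_histogram",
               list(bin_width = bin_width))
}

#' Flag bundle-like point pairs
#'
#' Operationalizes the bundle signature -- nearly parallel filaments at
#' lateral spacings around 12-13 nm -- as a configurable box in
#' (angle, distance) space: a point is bundle-like when its pair angle is
#' at most `angle_max` and its nearest-neighbor distance falls in
#' `dist_range`. The thresholds are reported in provenance; the defaults
#' describe the observed density peak, not a derived physical bound.
#'
#' @param records output of [pair_distance_angle()].
#' @param angle_max maximal pair angle in degrees.
#' @param dist_range length-2 distance window in nm.
#' @return list with `records` (input plus `bundle_flag`) and `fraction`
#'   (flagged share of points).
#' @export
bundle_flags <- function(records, angle_max = 15, dist_range = c(8, 17)) {
  if (nrow(records) == 0) abort("no pair records")
  if (length(dist_range) != 2 || dist_range[1] < 0 || dist_range[2] <= dist_range[1]) {
    abort("dist_range must be an increasing nonnegative pair (nm)")
  }
  rec <- records %>%
    mutate(bundle_flag = .data$pair_angle <= angle_max &
             .data$nn_distance >= dist_range[1] &
             .data$nn_distance <= dist_range[2])
  list(
    records = record_table(rec, "bundle_flags",
                           list(angle_max = angle_max, dist_range = dist_range)),
    fraction = mean(rec$bundle_flag)
  )
}
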