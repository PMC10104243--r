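#' Distances from filament points to the nearest granule surface
#'
#' Resamples the filaments of the requested kind and measures every
#' point's Euclidean distance to the nearest insulin-secretory-granule
#' surface (mask boundary; points inside a granule are at distance 0). The
#' full record set is always returned; the reporting cutoff (200 nm by
#' default, the myosin-V reach argument) is applied only when building the
#' histogram so that sensitivity analyses can vary it. Each record carries
#' its host filament's PM angle for density mapping.
#'
#' @param scene a [scene_bundle()] with an ISG mask.
#' @param kind `"actin"` or `"mt"`.
#' @param interval resampling interval, nm (4 for both kinds).
#' @param method surface-distance method, see [distance_to_mask_surface()].
#' @return record tibble, one row per resampled point: `distance`,
#'   `inside`, `clamped`, `host_angle_to_pm`, `host_orientation_class`.
#' @export
filament_isg_distances <- function(scene, kind = c("actin", "mt"),
                                   interval = 4, method = "edt") {
  kind <- match.arg(kind)
  if (is.null(scene$masks$isg)) {
    warn("scene has no ISG mask")
    return(record_table(tibble(), "proximity_records",
                        list(scene_id = scene$scene_id, kind = kind)))
  }
  fil <- dplyr::filter(scene$filaments, .data$kind == !!kind)
  if (nrow(fil) == 0) {
    warn(paste0("scene has no ", kind, " filaments"))
    return(record_table(tibble(), "proximity_records",
                        list(scene_id = scene$scene_id, kind = kind)))
  }
  pts <- resample_filaments(fil, interval = interval)
  d <- distance_to_mask_surface(pts, scene$masks$isg, method = method)
  orient <- orientation_records(fil)
  rec <- pts %>%
    mutate(distance = d$distance, inside = d$inside, clamped = d$clamped,
           target = "isg_surface", scene_id = scene$scene_id,
           source_kind = kind) %>%
    left_join(orient %>% select("filament_id", host_angle_to_pm = "angle_to_pm",
                                host_orientation_class = "orientation_class"),
              by = "filament_id") %>%
    select("scene_id", "source_kind", "filament_id", "point_index", "target",
           "distance", "inside", "clamped",
           "host_angle_to_pm", "host_orientation_class")
  record_table(rec, "proximity_records",
               list(scene_id = scene$scene_id, kind = kind,
                    interval = interval, method = method))
}

#' Normalized distance histogram with a reporting cutoff
#'
#' Only records at or below `cutoff` enter the histogram; probabilities sum
#' to 1 over the included records. Default bins follow the figure
#' conventions: 75 nm for actin-granule distances, 100 nm for
#' microtubule-granule distances (pass `bin_width` accordingly).
#'
#' @param records a record tibble with a `distance` column.
#' @param cutoff inclusion cutoff in nm (`NULL` for none).
#' @param bin_width bin width in nm.
#' @return record tibble: `bin_lo`, `bin_hi`, `n`, `probability`.
#' @export
distance_histogram <- function(records, cutoff = 200, bin_width = 75) {
  if (nrow(records) == 0) abort("no records")
  d <- records$distance
  if (!is.null(cutoff)) d <- d[d <= cutoff]
  if (length(d) == 0) {
    warn("no records at or below the cutoff")
    return(record_table(tibble(bin_lo = double(), bin_hi = double(),
                               n = integer(), probability = double()),
                        "distance_histogram",
                        list(cutoff = cutoff, bin_width = bin_width)))
  }
  top <- max(ceiling(max(d) / bin_width) * bin_width, bin_width)
  edges <- seq(0, top, by = bin_width)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), length(edges) - 1)
  out <- tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    n = as.integer(tabulate(bin, nbins = length(edges) - 1))
  ) %>% mutate(probability = .data$n / sum(.data$n))
  record_table(out, "distance_histogram",
               list(cutoff = cutoff, bin_width = bin_width,
                    n_included = length(d), n_total = nrow(records)))
}

#' Actin-to-microtubule centerline distances
#'
#' Distance from every resampled actin point to the nearest resampled
#' microtubule point (centerline to centerline; no tube-radius
#' subtraction by default). Also reports, per actin filament, the minimum
#' over its points -- the "shortest MT distance" -- together with the
#' host's PM angle for density mapping.
#'
#' @param scene a [scene_bundle()] with at least one actin filament and
#'   one microtubule.
#' @param interval resampling interval, nm.
#' @param mt_radius optional radius (nm) subtracted from every distance
#'   (floored at 0) to approximate surface rather than centerline
#'   distances; off (`0`) by default.
#' @return list with `points` (per-point records) and `filaments`
#'   (per-filament minima).
#' @export
actin_mt_distances <- function(scene, interval = 4, mt_radius = 0) {
  actin <- scene_actin(scene)
  mts <- scene_mt(scene)
  if (nrow(mts) == 0 || nrow(actin) == 0) {
    warn("need at least one actin filament and one MT")
    empty <- record_table(tibble(), "actin_mt_records",
                          list(scene_id = scene$scene_id))
    return(list(points = empty, filaments = empty))
  }
  apts <- resample_filaments(actin, interval = interval)
  mpts <- resample_filaments(mts, interval = interval)
  nn <- nearest_foreign_points(apts, mpts)
  orient <- orientation_records(actin)
  pts <- nn %>%
    mutate(
      distance = pmax(.data$nn_distance - mt_radius, 0),
      scene_id = scene$scene_id
    ) %>%
    left_join(orient %>% select("filament_id", host_angle_to_pm = "angle_to_pm",
                                host_orientation_class = "orientation_class"),
              by = "filament_id") %>%
    select("scene_id", "filament_id", "point_index", "distance",
           mt_id = "nn_filament_id", "host_angle_to_pm", "host_orientation_class")
  per_fil <- pts %>%
    group_by(.data$scene_id, .data$filament_id, .data$host_angle_to_pm,
             .data$host_orientation_class) %>%
    summarise(shortest_mt_distance = min(.data$distance), .groups = "drop")
  list(
    points = record_table(pts, "actin_mt_records",
                          list(scene_id = scene$scene_id, interval = interval,
                               mt_radius = mt_radius)),
    filaments = record_table(per_fil, "actin_mt_minima",
                             list(scene_id = scene$scene_id, interval = interval))
  )
}
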