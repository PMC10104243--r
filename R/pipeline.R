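#' Default analysis configuration
#'
#' All thresholds default to the conventions used throughout the package:
#' 4 nm resampling, 60 nm anchoring, 120 nm neighbor separation, 200 nm
#' granule-proximity cutoff, histogram bins of 10 nm (pairwise), 15
#' degrees (anchored angles), 75 nm (actin-granule) and 100 nm
#' (microtubule-granule), and the 45 degree orientation class boundary.
#' Overrides are echoed into every output's provenance.
#'
#' @return nested list of parameter blocks.
#' @export
default_config <- function() {
  list(
    geometry = list(interval = 4, reference_normal = c(0, 0, 1)),
    architecture = list(orientation_bin_width = 5, pair_bin_width = 10,
                        bundle_angle_max = 15, bundle_dist_range = c(8, 17),
                        actin_radius = 4, mt_radius = 7.5),
    anchoring = list(threshold = 60, neighbor_threshold = 120,
                     angle_bin_width = 15),
    proximity = list(cutoff = 200, actin_bin_width = 75, mt_bin_width = 100),
    meshwork = list(pixel_size = 31.3, min_branch_px = 1),
    density = list(bandwidth = NULL),
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default. The file may also carry a `scenes` list
#' (`path` + `condition` entries) and an `output_dir`.
#'
#' @param path YAML file.
#' @return config list with attribute `"hash"` (stable digest of the
#'   merged configuration).
#' @export
read_run_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user, keep.null = TRUE)
  attr(cfg, "hash") <- rlang::hash(cfg)
  cfg
}

#' Run every applicable analysis on one scene
#'
#' Executes, in order: orientation distribution, volume ratios, pairwise
#' distance/angle records and histograms, bundle flags, anchoring and
#' neighbor-angle analysis, periphery height, granule proximity for actin
#' and microtubules, and actin-microtubule distances. Analyses whose
#' required mask is missing are skipped with a warning; the rest proceed.
#' Every record table carries the configuration hash in its provenance.
#'
#' @param scene a [scene_bundle()].
#' @param config a configuration list (see [default_config()]).
#' @return named list of record tables plus a one-row `summary` tibble of
#'   scalar per-scene metrics.
#' @export
run_scene <- function(scene, config = default_config()) {
  cfg_hash <- attr(config, "hash") %||% rlang::hash(config)
  out <- list()
  stamp <- function(tbl) {
    prov <- attr(tbl, "provenance") %||% list()
    prov$config_hash <- cfg_hash
    attr(tbl, "provenance") <- prov
    tbl
  }
  orient <- orientation_distribution(scene,
    bin_width = config$architecture$orientation_bin_width)
  out$orientation_histogram <- stamp(orient$histogram)
  out$orientation_records <- stamp(orient$records)

  ratios <- tibble(
    kind = c("actin", "mt"),
    volume_ratio = c(volume_ratio(scene, "actin", config$architecture$actin_radius),
                     volume_ratio(scene, "mt", config$architecture$mt_radius))
  )
  out$volume_ratios <- stamp(record_table(ratios, "volume_ratios",
                                          list(scene_id = scene$scene_id)))

  pairs <- pair_distance_angle(scene, interval = config$geometry$interval)
  out$pair_records <- stamp(pairs)
  bundle_fraction <- NA_real_
  if (nrow(pairs) > 0) {
    out$pair_histograms <- stamp(distance_histograms_by_class(
      pairs, bin_width = config$architecture$pair_bin_width))
    bf <- bundle_flags(pairs, angle_max = config$architecture$bundle_angle_max,
                       dist_range = config$architecture$bundle_dist_range)
    out$bundle_records <- stamp(bf$records)
    bundle_fraction <- bf$fraction
  }

  anchored_count <- NA_integer_
  anchored_percentage <- NA_real_
  height <- NA_real_
  if (!is.null(scene$masks$pm)) {
    anchors <- find_anchored(scene, threshold = config$anchoring$threshold)
    out$anchor_records <- stamp(anchors)
    s <- attr(anchors, "summary")
    anchored_count <- s$anchored_count
    anchored_percentage <- s$anchored_percentage
    nb <- neighbor_angles(anchors,
      neighbor_threshold = config$anchoring$neighbor_threshold)
    out$neighbor_records <- stamp(nb)
    if (nrow(nb) > 0) {
      out$anchored_histograms <- stamp(anchored_angle_histograms(
        nb, bin_width = config$anchoring$angle_bin_width))
    }
    height <- tryCatch(as.numeric(periphery_height(scene)),
                       error = function(e) {
                         warn(conditionMessage(e))
                         NA_real_
                       })
  } else {
    warn("no PM mask: anchoring analysis skipped")
  }

  if (!is.null(scene$masks$isg)) {
    for (kd in c("actin", "mt")) {
      rec <- filament_isg_distances(scene, kind = kd,
                                    interval = config$geometry$interval)
      if (nrow(rec) > 0) {
        bw <- if (kd == "actin") config$proximity$actin_bin_width else config$proximity$mt_bin_width
        out[[paste0(kd, "_isg_records")]] <- stamp(rec)
        out[[paste0(kd, "_isg_histogram")]] <- stamp(distance_histogram(
          rec, cutoff = config$proximity$cutoff, bin_width = bw))
      }
    }
  } else {
    warn("no ISG mask: proximity analysis skipped")
  }

  amt <- suppressWarnings(actin_mt_distances(scene,
                                             interval = config$geometry$interval))
  if (nrow(amt$points) > 0) {
    out$actin_mt_records <- stamp(amt$points)
    out$actin_mt_minima <- stamp(amt$filaments)
  }

  fr <- orient$fractions
  out$summary <- tibble(
    scene_id = scene$scene_id, condition = scene$condition,
    n_actin = dplyr::n_distinct(scene_actin(scene)$filament_id),
    n_mt = dplyr::n_distinct(scene_mt(scene)$filament_id),
    parallel_fraction = if (nrow(fr) > 0) fr$parallel_fraction else NA_real_,
    quasi_orthogonal_fraction = if (nrow(fr) > 0) fr$quasi_orthogonal_fraction else NA_real_,
    actin_volume_ratio = ratios$volume_ratio[1],
    mt_volume_ratio = ratios$volume_ratio[2],
    bundle_fraction = bundle_fraction,
    anchored_count = anchored_count,
    anchored_percentage = anchored_percentage,
    periphery_height = height
  )
  out
}

#' Write a scene's analysis outputs to a directory
#'
#' @param results output of [run_scene()].
#' @param dir output directory.
#' @export
write_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    write_records(results[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' Compare scalar metrics across conditions
#'
#' Takes per-scene summary rows (as produced by [run_scene()]) and, for
#' each scalar metric, reports per-condition means with standard errors
#' and a significance test: one-way ANOVA with Tukey comparisons for
#' three or more conditions, F-test plus t-test for two. Conditions with a
#' single scene are summarized descriptively but excluded from testing.
#'
#' @param summaries tibble of per-scene summaries with a `condition`
#'   column.
#' @param metrics metric column names to compare (default: all numeric
#'   summary metrics present).
#' @return list with `groups` (per-condition descriptives) and `tests`
#'   (tidy test table per metric).
#' @export
compare_conditions <- function(summaries, metrics = NULL) {
  if (is.null(summaries$condition)) abort("summaries need a condition column")
  counts <- summaries %>% count(.data$condition)
  if (any(counts$n == 0) || nrow(counts) < 2) {
    abort("need at least 2 non-empty conditions")
  }
  metrics <- metrics %||% intersect(
    c("parallel_fraction", "quasi_orthogonal_fraction", "actin_volume_ratio",
      "mt_volume_ratio", "bundle_fraction", "anchored_count",
      "anchored_percentage", "periphery_height", "total_length", "n_junctions"),
    names(summaries))
  testable <- counts$condition[counts$n >= 2]
  if (length(testable) < nrow(counts)) {
    warn(paste0("condition(s) with a single scene excluded from tests: ",
                paste(setdiff(counts$condition, testable), collapse = ", ")))
  }
  groups <- list()
  tests <- list()
  for (m in metrics) {
    v <- summaries[[m]]
    ok <- is.finite(v)
    if (sum(ok) == 0) next
    d <- summaries[ok, c("condition", m)]
    groups[[m]] <- d %>%
      group_by(.data$condition) %>%
      summarise(n = n(), mean = mean(.data[[m]]),
                sem = sd(.data[[m]]) / sqrt(n()), .groups = "drop") %>%
      mutate(metric = m, .before = 1)
    dt <- d[d$condition %in% testable, ]
    k <- dplyr::n_distinct(dt$condition)
    within_sd <- tapply(dt[[m]], dt$condition, sd)
    if (k >= 2 && all(table(dt$condition) >= 2) && sd(dt[[m]]) > 0 &&
        all(within_sd > 0)) {
      design <- if (k >= 3) "anova_tukey" else "ttest"
      cmp <- group_compare(dt, m, "condition", design = design)
      tst <- tidy(cmp) %>% mutate(metric = m, .before = 1)
      if (k == 2) {
        ftst <- tidy(group_compare(dt, m, "condition", design = "ftest")) %>%
          mutate(metric = m, .before = 1)
        tst <- bind_rows(tst, ftst)
      }
      tests[[m]] <- tst
    }
  }
  list(
    groups = record_table(bind_rows(groups), "condition_descriptives", list()),
    tests = record_table(bind_rows(tests), "condition_tests", list())
  )
}
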