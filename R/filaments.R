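#' Build a validated filament node table
#'
#' Filament traces are held as a tidy tibble with one row per centerline
#' node: `filament_id`, `kind` (`"actin"` or `"mt"`), `node_index`, and the
#' node position `x`, `y`, `z` in nanometres. All geometry in the package is
#' in nanometres; unit conversion happens exactly once, at ingest.
#'
#' @param nodes a data frame with columns `filament_id`, `kind`,
#'   `node_index`, `x`, `y`, `z`. Coordinates must already be in nm.
#' @param source_unit_length optional named vector giving the tracing
#'   template length per kind (nm); defaults to 60 for actin and 100 for
#'   microtubules. Stored as an attribute, used nowhere in computation.
#' @return a tibble of nodes, ordered by filament and node index, that
#'   passes [validate_filaments()].
#' @export
filaments <- function(nodes, source_unit_length = c(actin = 60, mt = 100)) {
  tbl <- as_tibble(nodes)
  required <- c("filament_id", "kind", "node_index", "x", "y", "z")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("filament table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tbl <- tbl %>%
    mutate(
      filament_id = as.character(.data$filament_id),
      kind = as.character(.data$kind),
      node_index = as.integer(.data$node_index),
      x = as.double(.data$x), y = as.double(.data$y), z = as.double(.data$z)
    ) %>%
    arrange(.data$filament_id, .data$node_index)
  validate_filaments(tbl)
  attr(tbl, "source_unit_length") <- source_unit_length
  tbl
}

#' Validate filament invariants
#'
#' Checks that every filament has at least two nodes, strictly distinct
#' consecutive nodes, positive arc length, finite coordinates, and a kind
#' of `"actin"` or `"mt"`. Violations are collected per filament and
#' reported together.
#'
#' @param tbl a filament node table.
#' @return `tbl`, invisibly, if valid; otherwise an error itemizing every
#'   offending `filament_id`.
#' @export
validate_filaments <- function(tbl) {
  bad_kind <- unique(tbl$filament_id[!tbl$kind %in% c("actin", "mt")])
  not_finite <- unique(tbl$filament_id[!is.finite(tbl$x) | !is.finite(tbl$y) | !is.finite(tbl$z)])
  per <- tbl %>%
    group_by(.data$filament_id) %>%
    summarise(
      n_nodes = n(),
      min_step = if (n() < 2) NA_real_ else {
        min(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2))
      },
      .groups = "drop"
    )
  too_short <- per$filament_id[per$n_nodes < 2]
  dup_nodes <- per$filament_id[!is.na(per$min_step) & per$min_step <= 0]
  problems <- c(
    if (length(too_short) > 0) paste0("fewer than 2 nodes: ", paste(too_short, collapse = ", ")),
    if (length(dup_nodes) > 0) paste0("duplicated consecutive nodes: ", paste(dup_nodes, collapse = ", ")),
    if (length(bad_kind) > 0) paste0("kind not in {actin, mt}: ", paste(bad_kind, collapse = ", ")),
    if (length(not_finite) > 0) paste0("non-finite coordinates: ", paste(not_finite, collapse = ", "))
  )
  if (length(problems) > 0) {
    abort(paste0("invalid filament(s) -- ", paste(problems, collapse = "; ")))
  }
  invisible(tbl)
}

#' Read filament traces from a plain-text table
#'
#' Reads a tab-separated node table (columns `filament_id`, `kind`,
#' `node_index`, `x`, `y`, `z`) as written by tracing exports or by
#' [write_scene()]. Coordinates may be given in nanometres or in voxel
#' units; voxel coordinates are converted to nm at read time and never
#' touched again.
#'
#' @param path path to the table.
#' @param units `"nm"` (default) or `"voxel"`.
#' @param voxel_size voxel edge length in nm; required when `units =
#'   "voxel"`.
#' @return a validated filament tibble (see [filaments()]).
#' @export
read_filaments <- function(path, units = c("nm", "voxel"), voxel_size = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (units == "voxel" && (is.null(voxel_size) || voxel_size <= 0)) {
    abort("units = 'voxel' requires a positive voxel_size (nm)")
  }
  tbl <- tryCatch(
    as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE)),
    error = function(e) abort(paste0("parse error in ", path, ": ", conditionMessage(e)))
  )
  num_cols <- intersect(c("x", "y", "z"), names(tbl))
  bad <- unlist(lapply(num_cols, function(cc) which(is.na(suppressWarnings(as.numeric(tbl[[cc]]))))))
  if (length(bad) > 0) {
    abort(paste0("parse error in ", path, ": non-numeric coordinate at data line ",
                 paste(sort(unique(bad)), collapse = ", ")))
  }
  if (units == "voxel") {
    tbl$x <- tbl$x * voxel_size
    tbl$y <- tbl$y * voxel_size
    tbl$z <- tbl$z * voxel_size
  }
  filaments(tbl)
}

#' Read filament traces from an Amira-style ASCII spatial graph
#'
#' A second input dialect: HyperSurface/HxSpatialGraph ASCII exports with
#' `VERTEX`, `EDGE`, `POINT` sections. Each edge (with its ordered point
#' chain) becomes one filament. Coordinates are interpreted with `units`
#' as in [read_filaments()].
#'
#' @inheritParams read_filaments
#' @param kind filament class to assign to every trace in the file
#'   (spatial graphs do not carry one).
#' @export
read_amira_ascii <- function(path, kind = "actin", units = c("nm", "voxel"),
                             voxel_size = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (units == "voxel" && (is.null(voxel_size) || voxel_size <= 0)) {
    abort("units = 'voxel' requires a positive voxel_size (nm)")
  }
  lines <- readLines(path, warn = FALSE)
  grab <- function(marker) {
    i <- grep(marker, lines, fixed = TRUE)
    if (length(i) == 0) abort(paste0("missing section '", marker, "' in ", path))
    i[1]
  }
  parse_block <- function(start, n_values) {
    out <- numeric(0)
    i <- start + 1
    while (i <= length(lines) && length(out) < n_values) {
      ln <- trimws(lines[i])
      if (nzchar(ln) && !startsWith(ln, "@")) {
        vals <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
        if (anyNA(vals)) abort(paste0("parse error at line ", i, " of ", path))
        out <- c(out, vals)
      }
      i <- i + 1
    }
    out
  }
  # section markers announce their data blocks as @<n>
  n_edges <- as.integer(sub(".*EDGE ([0-9]+).*", "\\1",
                            lines[grep("define EDGE", lines)][1]))
  n_points <- as.integer(sub(".*POINT ([0-9]+).*", "\\1",
                             lines[grep("define POINT", lines)][1]))
  npe_at <- grab("NumEdgePoints")
  npe_tag <- sub(".*(@[0-9]+).*", "\\1", lines[npe_at])
  coord_at <- grep("EdgePointCoordinates", lines)[1]
  coord_tag <- sub(".*(@[0-9]+).*", "\\1", lines[coord_at])
  data_at <- function(tag) {
    i <- which(trimws(lines) == tag)
    if (length(i) == 0) abort(paste0("missing data block ", tag, " in ", path))
    i[1]
  }
  npe <- as.integer(parse_block(data_at(npe_tag), n_edges))
  coords <- parse_block(data_at(coord_tag), 3 * n_points)
  xyz <- matrix(coords, ncol = 3, byrow = TRUE)
  if (units == "voxel") xyz <- xyz * voxel_size
  edge_of <- rep(seq_len(n_edges), times = npe)
  tbl <- tibble(
    filament_id = sprintf("%s_%04d", kind, edge_of),
    kind = kind,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ) %>%
    group_by(.data$filament_id) %>%
    mutate(node_index = row_number()) %>%
    ungroup() %>%
    select("filament_id", "kind", "node_index", "x", "y", "z")
  filaments(tbl)
}

#' Per-filament arc length
#'
#' @param tbl filament node table.
#' @return tibble with `filament_id`, `kind`, `arc_length` (nm).
#' @export
filament_lengths <- function(tbl) {
  tbl %>%
    group_by(.data$filament_id, .data$kind) %>%
    summarise(
      arc_length = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2)),
      .groups = "drop"
    )
}
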