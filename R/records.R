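#' Tag a tibble as an analysis record table
#'
#' Record tables are ordinary tibbles carrying a declared schema name and a
#' provenance list (scene id, parameters, seed) so that every written
#' artifact can state how it was produced.
#'
#' @param tbl a tibble of records.
#' @param schema_name identifier for the row schema.
#' @param provenance named list of parameters used to produce the rows.
#' @return the tibble with `schema_name` and `provenance` attributes.
#' @export
record_table <- function(tbl, schema_name, provenance = list()) {
  tbl <- as_tibble(tbl)
  attr(tbl, "schema_name") <- schema_name
  attr(tbl, "provenance") <- provenance
  tbl
}

#' Write a record table (with JSON provenance sidecar)
#'
#' Writes tab-separated text with a header row. Numeric columns are
#' serialized with 17 significant digits so that reading the file back
#' reproduces every double bit-for-bit. A `<path>.json` sidecar records the
#' schema, provenance, and package version. Output is deterministic:
#' writing the same table twice yields byte-identical files.
#'
#' @param tbl a record table (see [record_table()]; plain tibbles accepted).
#' @param path output path for the TSV.
#' @return `path`, invisibly.
#' @export
write_records <- function(tbl, path) {
  schema <- attr(tbl, "schema_name") %||% "records"
  prov <- attr(tbl, "provenance") %||% list()
  out <- as.data.frame(tbl)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  ok <- tryCatch({
    con <- file(path, "wb")
    writeLines(paste(names(out), collapse = "\t"), con)
    if (nrow(out) > 0) {
      writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
    }
    close(con)
    TRUE
  }, error = function(e) {
    abort(paste0("cannot write ", path, ": ", conditionMessage(e)))
  })
  meta <- list(
    schema_name = schema,
    provenance = prov,
    n_rows = nrow(tbl),
    software = paste0("filarch ", as.character(packageVersion("filarch")))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a record table written by [write_records()]
#'
#' @param path path to the TSV.
#' @return a tibble; schema and provenance are restored from the sidecar
#'   when present.
#' @export
read_records <- function(path) {
  tbl <- as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(tbl, "schema_name") <- meta$schema_name
    attr(tbl, "provenance") <- meta$provenance
  }
  tbl
}

#' Bundle one tomogram-equivalent scene
#'
#' A scene is the unit of per-tomogram statistics: a filament table, the
#' role-tagged masks that exist for it, a condition label, and the physical
#' extent of the tomogram in nm.
#'
#' @param filaments filament node tibble (see [filaments()]).
#' @param masks named list of [volume_mask()] objects (at most one per
#'   role), e.g. `list(pm = ..., isg = ...)`.
#' @param condition `"basal"`, `"phase1"`, `"phase2"`, or `"synthetic"`.
#' @param scene_id identifier.
#' @param extent length-3 box size in nm (the tomogram bounds, anchored at
#'   the coordinate origin).
#' @return an object of class `scene_bundle`.
#' @export
scene_bundle <- function(filaments, masks = list(),
                         condition = c("synthetic", "basal", "phase1", "phase2"),
                         scene_id = "scene", extent) {
  condition <- match.arg(condition)
  if (length(extent) != 3 || any(extent <= 0)) {
    abort("extent must be a positive length-3 box (nm)")
  }
  roles <- vapply(masks, function(m) m$role, character(1))
  if (anyDuplicated(roles)) abort("at most one mask per role")
  if (length(masks) > 0) names(masks) <- roles
  validate_filaments(filaments)
  tol <- if (length(masks) > 0) max(vapply(masks, function(m) m$voxel_size, 1)) else 0
  out_x <- filaments$x < -tol | filaments$x > extent[1] + tol
  out_y <- filaments$y < -tol | filaments$y > extent[2] + tol
  out_z <- filaments$z < -tol | filaments$z > extent[3] + tol
  if (any(out_x | out_y | out_z)) {
    bad <- unique(filaments$filament_id[out_x | out_y | out_z])
    abort(paste0("filament nodes outside tomogram extent: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  structure(
    list(filaments = filaments, masks = masks, condition = condition,
         scene_id = scene_id, extent = as.double(extent)),
    class = "scene_bundle"
  )
}

#' @export
print.scene_bundle <- function(x, ...) {
  nf <- dplyr::n_distinct(x$filaments$filament_id)
  cat(sprintf("<scene_bundle '%s' (%s): %d filaments, masks: %s, extent %s nm>\n",
              x$scene_id, x$condition, nf,
              if (length(x$masks) > 0) paste(names(x$masks), collapse = "+") else "none",
              paste(round(x$extent), collapse = "x")))
  invisible(x)
}

scene_actin <- function(scene) dplyr::filter(scene$filaments, .data$kind == "actin")
scene_mt <- function(scene) dplyr::filter(scene$filaments, .data$kind == "mt")
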