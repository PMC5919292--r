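# File formats: multi-channel TIFF fields with JSON sidecars, 16-bit label
# maps, CSV cell tables, JSON profiles / plate maps / screen summaries.
# All intensities are integer arbitrary units (AU) <= 65535, so 16-bit
# TIFF round trips are lossless.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a multi-channel field as TIFF (+ JSON sidecar)
#'
#' One 16-bit page per channel; channel names, pixel size and provenance go
#' to a `<path>.json` sidecar. Pixel values must be integers in
#' `[0, 65535]` (the generator's digitized AU), which round-trip exactly.
#'
#' @param field A `field_image`.
#' @param path Output TIFF path.
#' @param truth Optional `ground_truth_cells` data frame; written as a
#'   companion CSV `<path>.truth.csv`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, truth = NULL) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(ch) {
    if (any(ch < 0 | ch > 65535) || any(ch != round(ch)))
      stop("channel values must be integers in [0, 65535]; ",
           "render with a digitizing noise model")
    ch / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  write_sidecar(path, list(type = "field_image",
                           channels = names(field$channels),
                           pixel_size = field$pixel_size,
                           provenance = field$provenance))
  if (!is.null(truth))
    write.csv(as.data.frame(truth), paste0(path, ".truth.csv"),
              row.names = FALSE)
  invisible(path)
}

#' Read a multi-channel field from TIFF
#'
#' @param path TIFF written by [write_field()] (or any multi-page TIFF).
#' @param channel_map Channels to load: a character vector of names present
#'   in the file, or a named integer vector mapping channel names to page
#'   numbers for foreign files. `NULL` loads everything.
#' @param pixel_size Overrides the sidecar pixel size; a conflict logs a
#'   warning and the supplied value wins.
#' @return A `field_image` with integer-AU channels.
#' @export
read_field <- function(path, channel_map = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) round(p * 65535))
  meta <- read_sidecar(path)
  names(pages) <- if (!is.null(meta$channels)) meta$channels
                  else paste0("channel", seq_along(pages))
  if (!is.null(channel_map)) {
    if (!is.null(names(channel_map))) {
      idx <- as.integer(channel_map)
      if (any(idx < 1 | idx > length(pages)))
        stop("channel_map page index out of range (file has ",
             length(pages), " pages)")
      pages <- setNames(pages[idx], names(channel_map))
    } else {
      missing <- setdiff(channel_map, names(pages))
      if (length(missing) > 0)
        stop("channel(s) not in file: ", paste(missing, collapse = ", "),
             "; available: ", paste(names(pages), collapse = ", "))
      pages <- pages[channel_map]
    }
  }
  ps_meta <- meta$pixel_size
  ps <- pixel_size %||% ps_meta %||% 0.65
  if (!is.null(pixel_size) && !is.null(ps_meta) &&
      abs(pixel_size - ps_meta) > 1e-9)
    warning(sprintf(
      "pixel_size %.4g from config overrides %.4g from file metadata",
      pixel_size, ps_meta))
  new_field_image(pages, ps, provenance = meta$provenance %||%
                    list(path = path))
}

#' Write / read a label map as single-page 16-bit TIFF
#'
#' @param map A `label_map` (labels must be < 65536).
#' @param path TIFF path; kind and pixel size go to a JSON sidecar.
#' @return `path` (write) or a `label_map` (read).
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  if (max(map$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  write_sidecar(path, list(type = "label_map", kind = map$kind,
                           pixel_size = map$pixel_size))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- round(tiff::readTIFF(path) * 65535)
  meta <- read_sidecar(path)
  if (is.null(meta) || !identical(meta$type, "label_map"))
    stop("missing or invalid label-map sidecar for ", path)
  new_label_map(m, meta$kind, meta$pixel_size)
}

#' Write / read a cell table as CSV
#'
#' Columns are written in the fixed documented order (identity, nuclear
#' features, cell features, MFIs, gates, class, labels), followed by any
#' extra columns; provenance entries become leading `plate`/`well`/...
#' columns and the pixel size is stored in a `pixel_size` column.
#'
#' @param table A `cell_table`.
#' @param path CSV path.
#' @return `path` (write) or a `cell_table` (read).
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  df <- as.data.frame(table)
  prov <- attr(table, "provenance")
  keep <- as.character(names(prov)[vapply(prov, function(v)
    is.atomic(v) && length(v) == 1, logical(1))])
  if (nrow(df) > 0) {
    for (nm in keep) df[[paste0("prov_", nm)]] <- prov[[nm]]
    df$pixel_size <- attr(table, "pixel_size")
    first <- c(paste0("prov_", keep, recycle0 = TRUE), "pixel_size")
    df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ps <- if ("pixel_size" %in% names(df)) df$pixel_size[1] else 0.65
  prov_cols <- grep("^prov_", names(df), value = TRUE)
  prov <- lapply(prov_cols, function(cn) df[[cn]][1])
  names(prov) <- sub("^prov_", "", prov_cols)
  df <- df[, setdiff(names(df), c(prov_cols, "pixel_size")), drop = FALSE]
  if ("assigned_class" %in% names(df))
    df$assigned_class <- as.character(df$assigned_class)
  new_cell_table(df, ps, prov)
}

#' Write / read a reference profile as JSON
#'
#' Versioned schema; the full ROC curve is included so calibration can be
#' audited downstream.
#'
#' @param profile A `reference_profile`.
#' @param path JSON path.
#' @return `path` (write) or a `reference_profile` (read).
#' @export
write_reference_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reference_profile"))
  obj <- list(schema = "hlindex.reference_profile", schema_version = 1L,
              morphology_gates = lapply(profile$morphology_gates, unname),
              albumin_cutoff = profile$albumin_cutoff,
              calibration_meta = profile$calibration_meta,
              roc = list(thresholds = profile$roc$thresholds,
                         tpr = profile$roc$tpr, fpr = profile$roc$fpr,
                         auc = profile$roc$auc,
                         optimal_cutoff = profile$roc$optimal_cutoff,
                         youden = profile$roc$youden))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "hlindex.reference_profile"))
    stop("not a reference-profile JSON: ", path)
  gates <- lapply(obj$morphology_gates, function(g)
    c(low = g[1], high = g[2]))
  roc <- obj$roc
  class(roc) <- "roc_curve"
  structure(list(morphology_gates = gates,
                 albumin_cutoff = obj$albumin_cutoff, roc = roc,
                 calibration_meta = obj$calibration_meta),
            class = "reference_profile")
}

#' Read a plate map from JSON or CSV
#'
#' CSV needs `well,condition` columns; JSON needs `wells` (array of
#' `{well, condition}`) plus optional `control_condition` and `plate_id`.
#'
#' @param path File path (`.json` or `.csv`).
#' @param control_condition,plate_id Used for CSV input (JSON carries its
#'   own).
#' @return A `plate_map`.
#' @export
read_plate_map <- function(path, control_condition = "collagen-1",
                           plate_id = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    plate_map(as.data.frame(obj$wells),
              control_condition = obj$control_condition %||% control_condition,
              plate_id = obj$plate_id %||% plate_id %||%
                tools::file_path_sans_ext(basename(path)))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    plate_map(df, control_condition = control_condition,
              plate_id = plate_id %||%
                tools::file_path_sans_ext(basename(path)))
  }
}

#' Write a plate map as JSON
#' @param pm A `plate_map`.
#' @param path JSON path.
#' @export
write_plate_map <- function(pm, path) {
  stopifnot(inherits(pm, "plate_map"))
  jsonlite::write_json(list(plate_id = pm$plate_id,
                            control_condition = pm$control_condition,
                            wells = pm$wells),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a screen result (CSV table + JSON summary)
#'
#' `<path>.csv` holds the per-condition table (condition, mean, SD, number
#' of wells, hit flag); `<path>.json` the full result including per-well
#' HLIs and the control summary. Report floats are rounded to 6 significant
#' digits.
#'
#' @param result A `screen_result`.
#' @param path Output path prefix (without extension).
#' @export
write_screen_result <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  pc <- result$per_condition
  pc$hit <- pc$condition %in% result$hits
  pc$mean_hli <- signif(pc$mean_hli, 6)
  pc$sd_hli <- signif(pc$sd_hli, 6)
  write.csv(pc, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(schema = "hlindex.screen_result", schema_version = 1L,
         plate_id = result$plate_id, round = result$round,
         control_condition = result$control_condition,
         control = result$control, hli_threshold = result$hli_threshold,
         hit_rule = result$hit_rule, hits = result$hits,
         per_condition = pc, per_well = result$per_well),
    paste0(path, ".json"), auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(path)
}
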