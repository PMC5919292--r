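# Per-cell morphometry and intensity quantification (the feature layer the
# gates operate on).

.feature_cols <- c("cell_id", "nuclear_area", "nuclear_width", "cell_area",
                   "cell_width", "symmetry", "mfi_nuclear_stain",
                   "mfi_albumin", "mfi_gfp", "is_polyploid", "gate_nuclear",
                   "gate_cell", "gate_albumin", "assigned_class", "true_class")

new_cell_table <- function(df, pixel_size, provenance = list()) {
  for (col in setdiff(.feature_cols, names(df))) {
    proto <- switch(col,
      is_polyploid = , gate_nuclear = , gate_cell = , gate_albumin = NA,
      assigned_class = , true_class = NA_character_,
      NA_real_)
    df[[col]] <- rep(proto, length.out = nrow(df))
  }
  df <- df[, c(.feature_cols, setdiff(names(df), .feature_cols)), drop = FALSE]
  if (anyDuplicated(df$cell_id)) stop("cell_ids must be unique")
  structure(df, pixel_size = pixel_size, provenance = provenance,
            class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<cell_table>", nrow(x), "cells @", attr(x, "pixel_size"), "um/px")
  if (length(prov)) cat(" |", paste(names(prov), unlist(prov),
                                    sep = "=", collapse = " "))
  cat("\n")
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

# Per-label area/centroid/second-moment-ellipse statistics.
moment_stats <- function(lab, pixel_size) {
  idx <- which(lab > 0L)
  v <- lab[idx]
  nr <- nrow(lab)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  s <- rowsum(cbind(1, cc, rr, cc^2, rr^2, cc * rr), v)
  ids <- as.integer(rownames(s))
  n <- s[, 1]
  mx <- s[, 2] / n; my <- s[, 3] / n
  cxx <- s[, 4] / n - mx^2
  cyy <- s[, 5] / n - my^2
  cxy <- s[, 6] / n - mx * my
  tr <- cxx + cyy
  d <- sqrt(pmax((cxx - cyy)^2 + 4 * cxy^2, 0))
  l1 <- pmax((tr + d) / 2, 0)
  l2 <- pmax((tr - d) / 2, 0)
  # Solid ellipse: variance along an axis is (semi-axis)^2 / 4.
  data.frame(label = ids, n_px = n,
             area = n * pixel_size^2,
             major = 4 * sqrt(l1) * pixel_size,
             width = 4 * sqrt(l2) * pixel_size,
             symmetry = ifelse(l1 > 0, sqrt(l2 / l1), 1))
}

mean_by_label <- function(channel, lab) {
  idx <- which(lab > 0L)
  v <- lab[idx]
  s <- rowsum(cbind(1, channel[idx]), v)
  setNames(s[, 2] / s[, 1], rownames(s))
}

#' Extract per-cell features from a segmented field
#'
#' Computes, for every cell label: nuclear and cell area (pixel counts
#' scaled by `pixel_size^2`), nuclear and cell width (minor-axis length of
#' the second-central-moment ellipse of the mask), symmetry (minor/major
#' axis ratio of the cell ellipse), and per-channel background-subtracted
#' mean fluorescence intensity over the cell mask (clamped at 0).
#'
#' @param field A `field_image`.
#' @param nuclei,cells Label maps sharing labels one-to-one (as returned by
#'   [segment_field()] or [render_field()]). `cells = NULL` computes
#'   nuclear features only (e.g. for polyploidy scoring), with cell-level
#'   columns left `NA`.
#' @param background Named per-channel background intensities; estimated
#'   with [estimate_background()] when `NULL`.
#' @param provenance Named list (e.g. plate/well/field ids) attached to the
#'   table.
#' @return A `cell_table` with one row per cell.
#' @export
extract_features <- function(field, nuclei, cells, background = NULL,
                             provenance = list()) {
  stopifnot(inherits(field, "field_image"), inherits(nuclei, "label_map"))
  p <- field$pixel_size
  dm <- dim(field$channels[[1]])
  if (!identical(dim(nuclei$labels), dm))
    stop("nuclei map shape does not match the field")
  nuc_only <- is.null(cells)
  if (!nuc_only) {
    stopifnot(inherits(cells, "label_map"))
    if (!identical(dim(cells$labels), dm))
      stop("cells map shape does not match the field")
  }
  ref_map <- if (nuc_only) nuclei else cells
  if (is.null(background)) {
    background <- vapply(field$channels, estimate_background,
                         numeric(1), cells = ref_map)
  }
  stopifnot(all(background >= 0))
  if (n_labels(ref_map) == 0L)
    return(new_cell_table(data.frame(cell_id = integer(0)), p, provenance))
  if (n_labels(nuclei) == 0L)
    stop("cell(s) without a nucleus: the nuclei map is empty but the ",
         "cells map is not")
  ns <- moment_stats(nuclei$labels, p)
  if (nuc_only) {
    df <- data.frame(cell_id = ns$label, nuclear_area = ns$area,
                     nuclear_width = ns$width)
  } else {
    cs <- moment_stats(cells$labels, p)
    if (!all(cs$label %in% ns$label)) {
      missing <- setdiff(cs$label, ns$label)
      stop("cell(s) without a nucleus: label ",
           paste(head(missing, 5), collapse = ", "),
           " (nuclei and cells maps must be nested; see match_nuclei_to_cells)")
    }
    ns <- ns[match(cs$label, ns$label), ]
    df <- data.frame(cell_id = cs$label,
                     nuclear_area = ns$area, nuclear_width = ns$width,
                     cell_area = cs$area, cell_width = cs$width,
                     symmetry = cs$symmetry)
  }
  for (ch in names(field$channels)) {
    m <- mean_by_label(field$channels[[ch]], ref_map$labels)
    df[[paste0("mfi_", ch)]] <-
      pmax(m[as.character(df$cell_id)] - background[[ch]], 0)
  }
  rownames(df) <- NULL
  new_cell_table(df, p, provenance)
}

#' Flag polyploid nuclei by nuclear area
#'
#' A nucleus is called polyploid when its area exceeds `factor` times the
#' mononucleate modal area. By default the modal area is estimated from the
#' table's own nuclear-area histogram (Freedman--Diaconis bins), which is
#' robust to the polyploid shoulder because the mononucleate mode dominates.
#'
#' @param table A `cell_table`.
#' @param reference_mode_area Mononucleate modal nuclear area in square
#'   micrometres; estimated from the table when `NULL`.
#' @param factor Multiplier above the mode that defines polyploidy
#'   (default 1.5, the midpoint discriminator between the 1x and 2x modes).
#' @return The table with `is_polyploid` filled in; the mode used is
#'   recorded in attribute `reference_mode_area`.
#' @export
call_polyploidy <- function(table, reference_mode_area = NULL, factor = 1.5) {
  stopifnot(inherits(table, "cell_table"), factor > 1)
  if (nrow(table) == 0L) return(table)
  if (is.null(reference_mode_area)) {
    x <- table$nuclear_area
    if (any(is.na(x))) stop("missing feature 'nuclear_area'")
    if (diff(range(x)) == 0) {
      reference_mode_area <- x[1]
    } else {
      h <- graphics::hist(x, breaks = "FD", plot = FALSE)
      reference_mode_area <- h$mids[which.max(h$counts)]
    }
  }
  stopifnot(reference_mode_area > 0)
  table$is_polyploid <- table$nuclear_area > factor * reference_mode_area
  attr(table, "reference_mode_area") <- reference_mode_area
  table
}

#' Build a feature table directly from ground truth
#'
#' Computes the same features as [extract_features()] analytically from the
#' generated ellipses and intensities, bypassing rendering and
#' segmentation. This is the fast path used for plate-scale simulations;
#' image-derived and truth-derived tables agree up to rasterization and
#' noise (see the methods vignette).
#'
#' @param cells A `ground_truth_cells` data frame (placement not required).
#' @param pixel_size Recorded pixel size (features are analytic and do not
#'   depend on it).
#' @param provenance Named list attached to the table.
#' @return A `cell_table` with `true_class` and `true_polyploid` columns.
#' @export
cell_table_from_truth <- function(cells, pixel_size = 0.65,
                                  provenance = list()) {
  stopifnot(inherits(cells, "ground_truth_cells") || is.data.frame(cells))
  nuc_area <- pi * cells$nuc_a * cells$nuc_b
  cell_area <- pi * cells$cell_a * cells$cell_b
  df <- data.frame(
    cell_id = cells$cell_id,
    nuclear_area = nuc_area, nuclear_width = 2 * cells$nuc_b,
    cell_area = cell_area, cell_width = 2 * cells$cell_b,
    symmetry = cells$cell_b / cells$cell_a,
    mfi_nuclear_stain = cells$nuclear_stain_mfi * nuc_area / cell_area,
    mfi_albumin = cells$true_albumin_mfi,
    mfi_gfp = ifelse(cells$is_gfp, cells$gfp_mfi * nuc_area / cell_area, 0),
    true_class = cells$true_class,
    stringsAsFactors = FALSE)
  out <- new_cell_table(df, pixel_size, provenance)
  out$true_polyploid <- cells$is_polyploid
  out
}

#' Construct a cell table from a data frame
#'
#' Fills any missing standard columns with `NA` and enforces unique cell
#' ids; used for fixtures and foreign data ([extract_features()] is the
#' normal producer).
#'
#' @param df Data frame with at least a `cell_id` column.
#' @param pixel_size Micrometres per pixel.
#' @param provenance Named list recorded with the table.
#' @return A `cell_table`.
#' @export
cell_table <- function(df, pixel_size = 0.65, provenance = list()) {
  stopifnot(is.data.frame(df), "cell_id" %in% names(df))
  new_cell_table(df, pixel_size, provenance)
}
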