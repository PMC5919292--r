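# Two-step segmentation: nuclei from the nuclear stain, then cells grown
# from nuclear seeds over the cytoplasm/albumin foreground.

as_channel <- function(channel) {
  if (inherits(channel, "field_image"))
    stop("pass a single channel matrix, e.g. field$channels$nuclear_stain")
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  channel
}

# Otsu foreground mask on offset-log intensity after light Gaussian
# smoothing. The log transform keeps dimly stained cells above threshold
# when per-cell intensities span orders of magnitude (e.g. highly variable
# albumin); the median offset stops noise-clamped zero pixels from forming
# a spurious histogram mode, and the robust floor (median + 3 MADN of the
# smoothed image) guards Otsu against splitting the background cluster
# when foreground occupies a tiny area fraction. Returns a logical matrix,
# all-FALSE for (near-)constant images.
foreground_mask <- function(channel, sigma = 1) {
  if (diff(range(channel)) <= 0)
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  lg <- log(channel + max(1, median(channel)))
  lo <- min(lg); hi <- max(lg)
  img <- EBImage::Image((lg - lo) / (hi - lo))
  sm <- if (sigma > 0) EBImage::gblur(img, sigma = sigma) else img
  sm[sm < 0] <- 0; sm[sm > 1] <- 1
  th <- EBImage::otsu(sm, range = c(0, 1))
  v <- EBImage::imageData(sm)
  sub <- v[seq(1L, length(v), length.out = min(length(v), 200000L))]
  th <- max(th, median(sub) + 3 * mad(sub))
  m <- v > th
  # Degenerate threshold (everything or nothing foreground) => no objects.
  if (all(m) || !any(m)) m[] <- FALSE
  m
}

# Relabel a label matrix 1..K in centroid scan order (row, then column).
relabel_scan_order <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  idx <- which(lab > 0L)
  v <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  cy <- rowsum(rr, v)[, 1] / as.vector(table(v))
  cx <- rowsum(cc, v)[, 1] / as.vector(table(v))
  new_id <- integer(max(ids))
  new_id[ids[order(cy, cx)]] <- seq_along(ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[idx] <- new_id[v]
  out
}

border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Foreground is detected by Otsu thresholding after Gaussian smoothing,
#' touching nuclei are split by distance-transform watershed, and objects
#' outside the area bounds or touching the image border are removed.
#' Surviving labels are renumbered in centroid scan order.
#'
#' @param nuclear_channel 2D intensity matrix.
#' @param pixel_size Micrometres per pixel.
#' @param min_nuclear_area_um2,max_nuclear_area_um2 Area bounds in square
#'   micrometres; objects outside are dropped.
#' @param sigma Gaussian smoothing SD in pixels (default 1).
#' @param tolerance Watershed tolerance (minimum distance-transform depth,
#'   in pixels, separating two objects).
#' @return A `label_map` of kind `"nuclei"`. A blank or constant image
#'   yields an empty map (0 labels), not an error.
#' @export
segment_nuclei <- function(nuclear_channel, pixel_size = 0.65,
                           min_nuclear_area_um2 = 20,
                           max_nuclear_area_um2 = 600,
                           sigma = 1, tolerance = 1) {
  ch <- as_channel(nuclear_channel)
  stopifnot(pixel_size > 0, min_nuclear_area_um2 > 0,
            min_nuclear_area_um2 < max_nuclear_area_um2)
  mask <- foreground_mask(ch, sigma)
  if (!any(mask))
    return(new_label_map(matrix(0L, nrow(ch), ncol(ch)), "nuclei", pixel_size))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
  storage.mode(ws) <- "integer"
  counts <- tabulate(ws[ws > 0L])
  px_area <- pixel_size^2
  bad <- which(counts * px_area < min_nuclear_area_um2 |
                 counts * px_area > max_nuclear_area_um2)
  drop <- union(bad, border_labels(ws))
  ws[ws %in% drop] <- 0L
  new_label_map(relabel_scan_order(ws), "nuclei", pixel_size)
}

#' Segment cells by nucleus-seeded growth over the cytoplasm foreground
#'
#' Grows cell regions from the nuclear seeds across the Otsu foreground of
#' the cytoplasm (albumin) channel using seeded propagation (a watershed on
#' intensity-weighted distance), so every cell contains exactly one seed
#' nucleus and nucleus-free foreground stays background. Cells touching the
#' image border are removed; survivors are renumbered in centroid scan
#' order, and the matching nuclei can be recovered with
#' [match_nuclei_to_cells()].
#'
#' @param cyto_channel 2D intensity matrix used for cell segmentation (the
#'   albumin stain doubles as the cytoplasm stain in primary hepatocytes).
#' @param nuclei Nuclei `label_map` from [segment_nuclei()].
#' @param sigma Gaussian smoothing SD in pixels.
#' @param lambda Regularization of the propagation metric (EBImage
#'   `propagate`).
#' @return A `label_map` of kind `"cells"`; empty if `nuclei` is empty or
#'   the channel has no foreground.
#' @export
segment_cells <- function(cyto_channel, nuclei, sigma = 1, lambda = 1e-4) {
  ch <- as_channel(cyto_channel)
  stopifnot(inherits(nuclei, "label_map"))
  if (!identical(dim(ch), dim(nuclei$labels)))
    stop("cyto channel and nuclei map have mismatched shapes")
  p <- nuclei$pixel_size
  empty <- new_label_map(matrix(0L, nrow(ch), ncol(ch)), "cells", p)
  if (n_labels(nuclei) == 0L) return(empty)
  mask <- foreground_mask(ch, sigma)
  if (!any(mask)) return(empty)
  mask <- mask | nuclei$labels > 0L  # seeds are foreground by definition
  cells <- EBImage::propagate(EBImage::Image(ch / max(ch)),
                              seeds = EBImage::Image(nuclei$labels),
                              mask = mask, lambda = lambda)
  cells <- EBImage::imageData(cells)
  storage.mode(cells) <- "integer"
  cells[cells %in% border_labels(cells)] <- 0L
  new_label_map(relabel_scan_order(cells), "cells", p)
}

#' Subset and renumber a nuclei map to match a cells map
#'
#' After border-cell removal and renumbering in [segment_cells()], nucleus
#' labels no longer correspond to cell labels. This maps each nucleus to
#' the cell covering the majority of its pixels, drops nuclei without a
#' surviving cell, and renumbers the survivors with their cell's label.
#'
#' @param nuclei,cells `label_map`s over the same pixel grid.
#' @return A nuclei `label_map` whose labels equal the containing cell's
#'   label (one nucleus per cell).
#' @export
match_nuclei_to_cells <- function(nuclei, cells) {
  stopifnot(inherits(nuclei, "label_map"), inherits(cells, "label_map"))
  if (!identical(dim(nuclei$labels), dim(cells$labels)))
    stop("nuclei and cells maps have mismatched shapes")
  out <- matrix(0L, nrow(nuclei$labels), ncol(nuclei$labels))
  idx <- which(nuclei$labels > 0L)
  if (length(idx) > 0) {
    nv <- nuclei$labels[idx]; cv <- cells$labels[idx]
    keep <- cv > 0L
    if (any(keep)) {
      tab <- table(nv[keep], cv[keep])
      owner <- integer(max(nv))
      owner[as.integer(rownames(tab))] <-
        as.integer(colnames(tab))[max.col(tab, ties.method = "first")]
      ow <- owner[nv]
      good <- keep & ow > 0L & cv == ow
      out[idx[good]] <- ow[good]
    }
  }
  new_label_map(out, "nuclei", nuclei$pixel_size)
}

#' Estimate the background intensity of a channel
#'
#' @param channel 2D intensity matrix.
#' @param cells A cells `label_map`; pixels outside all labels are treated
#'   as background.
#' @return The median intensity of background pixels. Errors if fewer than
#'   1% of pixels are background.
#' @export
estimate_background <- function(channel, cells) {
  ch <- as_channel(channel)
  stopifnot(inherits(cells, "label_map"))
  if (!identical(dim(ch), dim(cells$labels)))
    stop("channel and cells map have mismatched shapes")
  bg <- ch[cells$labels == 0L]
  if (length(bg) < 0.01 * length(ch))
    stop("no usable background: fewer than 1% of pixels lie outside cells")
  median(bg)
}

#' Segment a whole field (nuclei + cells, consistently labelled)
#'
#' Convenience wrapper running [segment_nuclei()], [segment_cells()] and
#' [match_nuclei_to_cells()] so the returned maps share labels one-to-one.
#'
#' @param field A `field_image`.
#' @param cyto_channel Name of the channel used for cell segmentation.
#' @param ... Passed to [segment_nuclei()].
#' @return List with `nuclei` and `cells` label maps.
#' @export
segment_field <- function(field, cyto_channel = "albumin", ...) {
  stopifnot(inherits(field, "field_image"))
  if (!cyto_channel %in% names(field$channels))
    stop("channel '", cyto_channel, "' not present; available: ",
         paste(names(field$channels), collapse = ", "))
  nuc <- segment_nuclei(field$channels$nuclear_stain,
                        pixel_size = field$pixel_size, ...)
  cells <- segment_cells(field$channels[[cyto_channel]], nuc)
  list(nuclei = match_nuclei_to_cells(nuc, cells), cells = cells)
}
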