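# Rendering of ground-truth cells into multi-channel fluorescence fields
# plus exact rasterized label maps.

#' Imaging noise model for rendered fields
#'
#' @param gaussian_sd_frac Additive Gaussian read-noise SD as a fraction of
#'   the mean foreground intensity of each channel (default 5%).
#' @param poisson If `TRUE`, replace each pixel value by a Poisson draw with
#'   that mean (shot noise) before adding Gaussian noise.
#' @param background Uniform background level in AU added to every channel.
#' @param digitize If `TRUE` (default), round final pixel values to integer
#'   AU, emulating camera digitization; required for lossless 16-bit TIFF
#'   round trips.
#' @return A `noise_model` list.
#' @export
noise_model <- function(gaussian_sd_frac = 0.05, poisson = FALSE,
                        background = 50, digitize = TRUE) {
  stopifnot(gaussian_sd_frac >= 0, background >= 0)
  structure(list(gaussian_sd_frac = gaussian_sd_frac, poisson = poisson,
                 background = background, digitize = digitize),
            class = "noise_model")
}

new_field_image <- function(channels, pixel_size, provenance = list()) {
  stopifnot(length(channels) > 0, !is.null(names(channels)), pixel_size > 0)
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  structure(list(channels = channels, pixel_size = pixel_size,
                 width = d[2], height = d[1], provenance = provenance),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat("<field_image>", x$height, "x", x$width, "px @", x$pixel_size,
      "um/px; channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

new_label_map <- function(labels, kind = c("nuclei", "cells"),
                          pixel_size = 0.65) {
  kind <- match.arg(kind)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind, pixel_size = pixel_size),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map>", x$kind, paste(dim(x$labels), collapse = " x "),
      "px;", max(x$labels), "objects @", x$pixel_size, "um/px\n")
  invisible(x)
}

n_labels <- function(map) max(0L, max(map$labels))

# Linear indices (into an nr x nc matrix) of pixels inside an ellipse given
# in micrometre coordinates. Pixel (i, j) is centred at ((j-0.5)p, (i-0.5)p):
# columns carry x, rows carry y.
ellipse_pixels <- function(e, nr, nc, p) {
  jr <- floor((e$x - e$a) / p):ceiling((e$x + e$a) / p + 1)
  ir <- floor((e$y - e$a) / p):ceiling((e$y + e$a) / p + 1)
  jr <- jr[jr >= 1 & jr <= nc]; ir <- ir[ir >= 1 & ir <= nr]
  if (length(jr) == 0 || length(ir) == 0) return(integer(0))
  jj <- rep(jr, each = length(ir)); ii <- rep(ir, times = length(jr))
  inside <- points_in_ellipse(e, (jj - 0.5) * p, (ii - 0.5) * p)
  (jj[inside] - 1L) * nr + ii[inside]
}

#' Render ground-truth cells as a multi-channel fluorescence field
#'
#' Paints every cell ellipse into the albumin channel at its true albumin
#' MFI, every nucleus into the nuclear-stain channel, and (for
#' GFP-positive cells) every nucleus into the GFP channel, on top of a
#' uniform background; then applies the noise model. The returned label
#' maps are the exact rasterized ground truth, with each nucleus clipped to
#' its parent cell.
#'
#' @param cells A placed `ground_truth_cells` data frame ([sample_cells()]).
#' @param pixel_size Micrometres per pixel (default 0.65).
#' @param shape Image `c(rows, cols)` in pixels.
#' @param noise A [noise_model()].
#' @param channels Channels to render, a subset of
#'   `c("nuclear_stain", "albumin", "gfp")`. The GFP channel is rendered
#'   only when requested and some cell is GFP-positive, or when forced.
#' @param seed Seed for the noise draws; defaults to a seed derived from
#'   the generating spec so that identical `(spec, seed)` give bit-identical
#'   images.
#' @return A list with elements `field` (a `field_image`), `nuclei` and
#'   `cells` (ground-truth `label_map`s).
#' @export
render_field <- function(cells, pixel_size = 0.65, shape = c(1024L, 1024L),
                         noise = noise_model(),
                         channels = c("nuclear_stain", "albumin", "gfp"),
                         seed = NULL) {
  stopifnot(inherits(noise, "noise_model"), length(shape) == 2L,
            all(shape >= 8L), pixel_size > 0)
  channels <- match.arg(channels, several.ok = TRUE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  ext <- c(nc, nr) * pixel_size
  if (nrow(cells) > 0) {
    if (any(cells$x - cells$cell_a < 0 | cells$x + cells$cell_a > ext[1] |
            cells$y - cells$cell_a < 0 | cells$y + cells$cell_a > ext[2]))
      stop("shape too small: some cell ellipses extend beyond the image")
  }
  want_gfp <- "gfp" %in% channels &&
    (any(cells$is_gfp) || isTRUE(attr(cells, "force_gfp")))
  cell_lab <- matrix(0L, nr, nc)
  nuc_lab <- matrix(0L, nr, nc)
  alb <- if ("albumin" %in% channels) matrix(0, nr, nc)
  nst <- if ("nuclear_stain" %in% channels) matrix(0, nr, nc)
  gfp <- if (want_gfp) matrix(0, nr, nc)
  for (i in seq_len(nrow(cells))) {
    ce <- list(x = cells$x[i], y = cells$y[i], a = cells$cell_a[i],
               b = cells$cell_b[i], theta = cells$cell_theta[i])
    ne <- list(x = cells$nuc_x[i], y = cells$nuc_y[i], a = cells$nuc_a[i],
               b = cells$nuc_b[i], theta = cells$nuc_theta[i])
    cpx <- ellipse_pixels(ce, nr, nc, pixel_size)
    cpx <- cpx[cell_lab[cpx] == 0L]  # first-painted wins (overlap guard)
    npx <- intersect(ellipse_pixels(ne, nr, nc, pixel_size), cpx)
    cell_lab[cpx] <- cells$cell_id[i]
    nuc_lab[npx] <- cells$cell_id[i]
    if (!is.null(alb)) alb[cpx] <- cells$true_albumin_mfi[i]
    if (!is.null(nst)) nst[npx] <- cells$nuclear_stain_mfi[i]
    if (want_gfp && cells$is_gfp[i]) gfp[npx] <- cells$gfp_mfi[i]
  }
  out <- list()
  if (!is.null(nst)) out$nuclear_stain <- nst
  if (!is.null(alb)) out$albumin <- alb
  if (want_gfp) out$gfp <- gfp
  spec <- attr(cells, "spec")
  if (is.null(seed) && !is.null(spec)) seed <- derive_seed(spec$seed, 2L)
  out <- with_seed(seed, lapply(out, apply_noise, noise = noise))
  prov <- list(generator = "hlindex::render_field",
               preset = if (!is.null(spec)) spec$preset_name else NA,
               seed = if (!is.null(spec)) spec$seed else NA,
               n_cells = nrow(cells))
  list(field = new_field_image(out, pixel_size, prov),
       nuclei = new_label_map(nuc_lab, "nuclei", pixel_size),
       cells = new_label_map(cell_lab, "cells", pixel_size))
}

apply_noise <- function(ch, noise) {
  fg <- ch > 0
  ch <- ch + noise$background
  if (noise$poisson) ch[] <- rpois(length(ch), pmax(ch, 0))
  if (noise$gaussian_sd_frac > 0 && any(fg)) {
    sd <- noise$gaussian_sd_frac * mean(ch[fg])
    ch <- ch + rnorm(length(ch), 0, sd)
  }
  ch[ch < 0] <- 0
  if (noise$digitize) ch <- round(ch)
  ch
}

#' Construct a field image / label map from raw matrices
#'
#' Low-level constructors used when assembling fixtures or ingesting data
#' from foreign sources; [render_field()] and [segment_nuclei()] produce
#' these objects in normal use.
#'
#' @param channels Named list of equally sized 2D intensity matrices.
#' @param pixel_size Micrometres per pixel.
#' @param provenance Named list recorded with the object.
#' @return A `field_image`.
#' @export
field_image <- function(channels, pixel_size = 0.65, provenance = list()) {
  new_field_image(channels, pixel_size, provenance)
}

#' @rdname field_image
#' @param labels 2D non-negative integer matrix (0 = background).
#' @param kind `"nuclei"` or `"cells"`.
#' @return `label_map()`: a `label_map`.
#' @export
label_map <- function(labels, kind = c("nuclei", "cells"),
                      pixel_size = 0.65) {
  stopifnot(is.matrix(labels), all(labels >= 0), all(labels == round(labels)))
  new_label_map(labels, kind, pixel_size)
}
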