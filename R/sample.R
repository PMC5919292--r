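# Ground-truth sampling: per-cell geometry and intensities, then
# non-overlapping placement of cell ellipses in a field.

.truth_cols <- c("cell_id", "true_class", "x", "y",
                 "cell_a", "cell_b", "cell_theta",
                 "nuc_x", "nuc_y", "nuc_a", "nuc_b", "nuc_theta",
                 "is_polyploid", "true_albumin_mfi", "nuclear_stain_mfi",
                 "gfp_mfi", "is_gfp")

empty_truth <- function() {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(.truth_cols)),
                               .truth_cols))
  df$true_class <- character(0)
  df$is_polyploid <- logical(0)
  df$is_gfp <- logical(0)
  df$cell_id <- integer(0)
  df
}

# Semi-axes (micrometres) from area A = pi*a*b and aspect q = b/a.
axes_from_area <- function(area, aspect) {
  a <- sqrt(area / (pi * aspect))
  cbind(a = a, b = a * aspect)
}

sample_aspect <- function(n, ms) {
  x <- rnorm(n, ms[1], ms[2])
  for (i in 1:50) {
    bad <- x <= 0.05 | x > 1
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), ms[1], ms[2])
  }
  pmin(pmax(x, 0.05), 1)
}

# Draw per-cell ground truth for a single (non-mixture) spec; no placement.
sample_features_single <- function(spec, n) {
  if (n == 0L) return(empty_truth())
  cell_area <- rnorm_floor(n, spec$cell_area[1], spec$cell_area[2], floor = 150)
  cell_aspect <- sample_aspect(n, spec$cell_aspect)
  is_poly <- runif(n) < spec$polyploid_fraction
  # Polyploid nuclei are drawn at twice the mononucleate mean area with the
  # mononucleate SD (binucleate/tetraploid model).
  nuc_area <- rnorm_floor(n, spec$nuclear_area[1], spec$nuclear_area[2],
                          floor = 5)
  if (any(is_poly))
    nuc_area[is_poly] <- rnorm_floor(sum(is_poly), 2 * spec$nuclear_area[1],
                                     spec$nuclear_area[2], floor = 5)
  cell_area <- pmax(cell_area, nuc_area / 0.65)  # nucleus must fit the cell
  nuc_aspect <- sample_aspect(n, spec$nuclear_aspect)
  alb <- rnorm_floor(n, spec$albumin_mfi[1], spec$albumin_mfi[2], floor = 30)
  nst <- rnorm_floor(n, spec$nuclear_stain_mfi[1], spec$nuclear_stain_mfi[2],
                     floor = 100)
  gfp <- if (spec$gfp_positive)
    rnorm_floor(n, spec$gfp_mfi[1], spec$gfp_mfi[2], floor = 100)
  else rep(0, n)
  ca <- axes_from_area(cell_area, cell_aspect)
  na <- axes_from_area(nuc_area, nuc_aspect)
  data.frame(
    cell_id = seq_len(n), true_class = rep(spec$preset_name, n),
    x = NA_real_, y = NA_real_,
    cell_a = ca[, "a"], cell_b = ca[, "b"],
    cell_theta = runif(n, 0, pi),
    nuc_x = NA_real_, nuc_y = NA_real_,
    nuc_a = na[, "a"], nuc_b = na[, "b"],
    nuc_theta = runif(n, 0, pi),
    is_polyploid = is_poly, true_albumin_mfi = alb,
    nuclear_stain_mfi = nst, gfp_mfi = gfp,
    is_gfp = rep(spec$gfp_positive, n),
    stringsAsFactors = FALSE)
}

#' Draw per-cell ground-truth features (no spatial placement)
#'
#' Samples cell/nuclear ellipse geometry and channel intensities for
#' `spec$n_cells` cells. For mixtures the class of each cell is drawn from
#' the component weights. Positions are left `NA`; use [sample_cells()] to
#' also place the cells in a field, or [cell_table_from_truth()] to turn
#' the draw directly into a feature table.
#'
#' @param spec A [make_population_spec()] object.
#' @param seed Seed; defaults to `spec$seed`.
#' @return A data frame with one row per cell (`ground_truth_cells`).
#' @export
sample_cell_features <- function(spec, seed = spec$seed) {
  validate_population_spec(spec)
  n <- spec$n_cells
  with_seed(seed, {
    if (is.null(spec$mixture_components)) {
      out <- sample_features_single(spec, n)
    } else {
      w <- vapply(spec$mixture_components, function(m) m$weight, numeric(1))
      comp <- sample.int(length(w), n, replace = TRUE, prob = w)
      parts <- vector("list", length(w))
      for (k in seq_along(w)) {
        sub <- spec$mixture_components[[k]]$spec
        parts[[k]] <- sample_features_single(sub, sum(comp == k))
      }
      out <- empty_truth()
      if (n > 0) {
        out <- do.call(rbind, parts)
        out <- out[order(order(comp)), , drop = FALSE]  # drawn order
        out$cell_id <- seq_len(n)
        rownames(out) <- NULL
      }
    }
    class(out) <- c("ground_truth_cells", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}

# Place the nucleus ellipse inside its parent cell ellipse (bounded retries,
# falling back to a centred, axis-aligned, if needed shrunken nucleus).
place_nucleus <- function(row) {
  cell <- list(x = row$x, y = row$y, a = row$cell_a, b = row$cell_b,
               theta = row$cell_theta)
  ct <- cos(row$cell_theta); st <- sin(row$cell_theta)
  for (i in 1:25) {
    r <- runif(1, 0, 0.35); ang <- runif(1, 0, 2 * pi)
    u <- r * row$cell_a * cos(ang); v <- r * row$cell_b * sin(ang)
    nuc <- list(x = row$x + u * ct - v * st, y = row$y + u * st + v * ct,
                a = row$nuc_a, b = row$nuc_b, theta = row$nuc_theta)
    if (ellipse_contained(nuc, cell)) return(nuc)
  }
  nuc <- list(x = row$x, y = row$y, a = row$nuc_a, b = row$nuc_b,
              theta = row$cell_theta)
  if (!ellipse_contained(nuc, cell)) {
    s <- 0.95 * min(row$cell_a / row$nuc_a, row$cell_b / row$nuc_b, 1)
    nuc$a <- nuc$a * s; nuc$b <- nuc$b * s
  }
  nuc
}

#' Sample ground-truth cells and place them in a field
#'
#' Draws per-cell features with [sample_cell_features()] and places the
#' cell ellipses in a `field_um[1]` x `field_um[2]` micrometre field by
#' dart throwing: candidate centres are drawn uniformly (with a border
#' margin of one semi-major axis so cells lie fully inside) and rejected on
#' overlap with any already placed ellipse. Each nucleus ellipse is then
#' placed inside its parent cell.
#'
#' @param spec A [make_population_spec()] object.
#' @param field_um Field width and height in micrometres. The default
#'   matches a 1024 x 1024 pixel field at 0.65 um/pixel.
#' @param seed Seed; defaults to `spec$seed`.
#' @param max_retries Placement attempts per cell before giving up.
#' @return A `ground_truth_cells` data frame with placed centres; attribute
#'   `field_um` records the field size.
#' @export
sample_cells <- function(spec, field_um = c(665.6, 665.6), seed = spec$seed,
                         max_retries = 1000L) {
  validate_population_spec(spec)
  stopifnot(length(field_um) == 2L, all(field_um > 0))
  cells <- sample_cell_features(spec, seed = seed)
  if (nrow(cells) > 0) {
    mean_area <- mean(pi * cells$cell_a * cells$cell_b)
    if (nrow(cells) * mean_area > 0.45 * prod(field_um))
      stop("field too small to place ", nrow(cells), " cells without ",
           "overlap; use a larger field or fewer cells")
  }
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, 1L), {
    placed <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      a <- cells$cell_a[i]; b <- cells$cell_b[i]
      m <- a + 0.5
      if (2 * m >= min(field_um))
        stop("field too small to place cell of semi-major axis ", round(a, 1),
             " um; use a larger field")
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- list(x = runif(1, m, field_um[1] - m),
                     y = runif(1, m, field_um[2] - m),
                     a = a, b = b, theta = cells$cell_theta[i])
        hit <- FALSE
        for (p in placed[seq_len(i - 1L)]) {
          if (ellipses_overlap(cand, p)) { hit <- TRUE; break }
        }
        if (!hit) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place cell ", i, " after ", max_retries,
             " attempts; use a larger field or fewer cells")
      placed[[i]] <- cand
      cells$x[i] <- cand$x; cells$y[i] <- cand$y
      nuc <- place_nucleus(cells[i, ])
      cells$nuc_x[i] <- nuc$x; cells$nuc_y[i] <- nuc$y
      cells$nuc_a[i] <- nuc$a; cells$nuc_b[i] <- nuc$b
      cells$nuc_theta[i] <- nuc$theta
    }
    attr(cells, "field_um") <- field_um
    cells
  })
}
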