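# Population presets for the synthetic-field generator.
#
# The five presets emulate the cell populations used to build and validate
# the index: freshly isolated adult hepatocytes (the gold standard), fetal
# hepatocytes, iPSC-derived hepatocytes (i-Heps), dermal fibroblasts (the
# negative control) and nuclear-GFP-labelled HUVECs (for co-culture
# exclusion). Magnitudes are generator conventions chosen to preserve the
# reported qualitative contrasts: adult cells are large, symmetric, high in
# albumin and ~30% polyploid; fetal cells are smaller, less symmetric and
# <5% polyploid; i-Heps match adult symmetry but have larger, more variable
# nuclei, variable cell size, and intermediate, highly variable albumin;
# fibroblasts are elongated and albumin-negative.

.presets <- list(
  adult_hep = list(
    cell_area = c(1600, 300), cell_aspect = c(0.85, 0.08),
    nuclear_area = c(110, 20), nuclear_aspect = c(0.90, 0.04),
    polyploid_fraction = 0.30, albumin_mfi = c(2000, 300),
    nuclear_stain_mfi = c(800, 100), gfp_mfi = c(0, 0), gfp_positive = FALSE),
  fetal_hep = list(
    cell_area = c(900, 250), cell_aspect = c(0.65, 0.12),
    nuclear_area = c(80, 15), nuclear_aspect = c(0.90, 0.04),
    polyploid_fraction = 0.03, albumin_mfi = c(1200, 350),
    nuclear_stain_mfi = c(800, 100), gfp_mfi = c(0, 0), gfp_positive = FALSE),
  ihep = list(
    cell_area = c(1300, 500), cell_aspect = c(0.85, 0.08),
    nuclear_area = c(150, 45), nuclear_aspect = c(0.90, 0.04),
    polyploid_fraction = 0.05, albumin_mfi = c(600, 400),
    nuclear_stain_mfi = c(800, 100), gfp_mfi = c(0, 0), gfp_positive = FALSE),
  fibroblast = list(
    cell_area = c(1500, 400), cell_aspect = c(0.25, 0.08),
    nuclear_area = c(105, 20), nuclear_aspect = c(0.90, 0.04),
    polyploid_fraction = 0, albumin_mfi = c(120, 60),
    nuclear_stain_mfi = c(800, 100), gfp_mfi = c(0, 0), gfp_positive = FALSE),
  huvec_gfp = list(
    cell_area = c(1000, 300), cell_aspect = c(0.55, 0.12),
    nuclear_area = c(95, 20), nuclear_aspect = c(0.90, 0.04),
    polyploid_fraction = 0, albumin_mfi = c(130, 60),
    nuclear_stain_mfi = c(800, 100), gfp_mfi = c(1200, 150),
    gfp_positive = TRUE)
)

.ms_fields <- c("cell_area", "cell_aspect", "nuclear_area", "nuclear_aspect",
                "albumin_mfi", "nuclear_stain_mfi", "gfp_mfi")

#' Names of the built-in population presets
#'
#' @return Character vector of preset names accepted by
#'   [make_population_spec()] (the additional name `"mixture"` builds a
#'   weighted mixture of other specs).
#' @export
population_presets <- function() c(names(.presets), "mixture")

#' Build a population specification for the synthetic generator
#'
#' A population spec fixes the sampling distributions of per-cell ground
#' truth: cell and nuclear ellipse geometry (areas in square micrometres,
#' aspect = minor/major axis ratio), the polyploid fraction (cells whose
#' nucleus is drawn at twice the mononucleate modal area), and per-channel
#' fluorescence intensities in arbitrary units (AU).
#'
#' @param preset_name One of [population_presets()]. `"mixture"` requires a
#'   `mixture_components` override: a list of `list(spec =, weight =)`
#'   entries whose weights sum to 1.
#' @param overrides Named list overriding preset fields. Mean/SD fields
#'   (`cell_area`, `cell_aspect`, `nuclear_area`, `nuclear_aspect`,
#'   `albumin_mfi`, `nuclear_stain_mfi`, `gfp_mfi`) take a numeric
#'   `c(mean, sd)`; `polyploid_fraction` a proportion; `gfp_positive` a
#'   logical.
#' @param n_cells Number of cells the spec asks the generator for.
#' @param seed Integer seed threaded through all sampling from this spec.
#' @return An object of class `population_spec`.
#' @examples
#' spec <- make_population_spec("adult_hep", n_cells = 50, seed = 1)
#' spec$polyploid_fraction
#' @export
make_population_spec <- function(preset_name, overrides = list(),
                                 n_cells = 100L, seed = 1L) {
  if (!is.character(preset_name) || length(preset_name) != 1L ||
      !preset_name %in% population_presets()) {
    stop("unknown preset '", paste(preset_name, collapse = ","),
         "'; valid presets: ", paste(population_presets(), collapse = ", "))
  }
  if (identical(preset_name, "mixture")) {
    base <- .presets[["adult_hep"]]
    if (is.null(overrides$mixture_components))
      stop("preset 'mixture' requires a 'mixture_components' override")
  } else {
    base <- .presets[[preset_name]]
  }
  unknown <- setdiff(names(overrides),
                     c(names(base), "mixture_components", "polyploid_fraction"))
  if (length(unknown) > 0)
    stop("unknown spec field(s) in overrides: ", paste(unknown, collapse = ", "))
  spec <- modifyList(base, overrides[names(overrides) != "mixture_components"])
  spec$preset_name <- preset_name
  spec$n_cells <- as.integer(n_cells)
  spec$seed <- as.integer(seed)
  spec$mixture_components <- overrides$mixture_components
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.na(spec$n_cells) || spec$n_cells < 0L)
    stop("invalid field 'n_cells': must be a non-negative count")
  for (f in .ms_fields) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)))
      stop("invalid field '", f, "': expected numeric c(mean, sd)")
    if (v[2] < 0) stop("invalid field '", f, "': SD must be >= 0")
    if (!f %in% c("gfp_mfi") && v[1] <= 0)
      stop("invalid field '", f, "': mean must be > 0")
  }
  p <- spec$polyploid_fraction
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("invalid field 'polyploid_fraction': must lie in [0, 1]")
  if (spec$cell_aspect[1] > 1 || spec$nuclear_aspect[1] > 1)
    stop("invalid field 'cell_aspect'/'nuclear_aspect': mean must lie in (0, 1]")
  if (!is.logical(spec$gfp_positive) || length(spec$gfp_positive) != 1L)
    stop("invalid field 'gfp_positive': must be TRUE or FALSE")
  if (!is.null(spec$mixture_components)) {
    w <- vapply(spec$mixture_components, function(m) m$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-8)
      stop("invalid field 'mixture_components': weights must sum to 1")
    for (m in spec$mixture_components)
      stopifnot(inherits(m$spec, "population_spec"))
  }
  invisible(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>", x$preset_name, "- n_cells:", x$n_cells,
      "seed:", x$seed, "\n")
  cat(sprintf("  cell area %.0f±%.0f um2, aspect %.2f±%.2f | nuclear area %.0f±%.0f um2\n",
              x$cell_area[1], x$cell_area[2], x$cell_aspect[1],
              x$cell_aspect[2], x$nuclear_area[1], x$nuclear_area[2]))
  cat(sprintf("  polyploid fraction %.2f | albumin %.0f±%.0f AU | GFP: %s\n",
              x$polyploid_fraction, x$albumin_mfi[1], x$albumin_mfi[2],
              if (x$gfp_positive) "positive" else "negative"))
  if (!is.null(x$mixture_components))
    cat("  mixture of", length(x$mixture_components), "components\n")
  invisible(x)
}
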