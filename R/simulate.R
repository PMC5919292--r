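# High-level simulation helpers: whole populations measured through the
# imaging pipeline, and plate-scale screens at the feature level.

#' Simulate a population and measure it through the pipeline
#'
#' Generates `n` cells from `spec`, splits them across as many fields as
#' needed (at roughly `coverage` foreground fraction per field), renders
#' each field, segments it, extracts features, and concatenates the
#' per-field tables. With `via = "truth"` the rendering/segmentation steps
#' are skipped and features are computed analytically from the ground
#' truth ([cell_table_from_truth()]); with `via = "image_nuclei"` only the
#' nuclear channel is rendered and segmented (cell-level columns are `NA`),
#' which is sufficient for polyploidy scoring and much faster.
#'
#' @param spec A [make_population_spec()] (its `n_cells` is overridden).
#' @param n Total number of cells to generate.
#' @param via `"image"`, `"image_nuclei"`, or `"truth"`.
#' @param seed Base seed; per-field seeds are derived from it.
#' @param pixel_size Micrometres per pixel.
#' @param shape Field size in pixels.
#' @param coverage Target foreground area fraction per field.
#' @param noise A [noise_model()].
#' @return A `cell_table`; an added `field` column records the source field
#'   for image routes.
#' @export
simulate_population_table <- function(spec, n = spec$n_cells,
                                      via = c("image", "image_nuclei", "truth"),
                                      seed = spec$seed, pixel_size = 0.65,
                                      shape = c(1024L, 1024L),
                                      coverage = 0.15,
                                      noise = noise_model()) {
  via <- match.arg(via)
  validate_population_spec(spec)
  prov <- list(preset = spec$preset_name, seed = seed, route = via)
  if (via == "truth") {
    spec$n_cells <- as.integer(n)
    cells <- sample_cell_features(spec, seed = seed)
    return(cell_table_from_truth(cells, pixel_size, provenance = prov))
  }
  mean_area <- spec$cell_area[1]
  field_area <- prod(shape) * pixel_size^2
  per_field <- max(1L, floor(coverage * field_area / mean_area))
  n_fields <- ceiling(n / per_field)
  channels <- if (via == "image_nuclei") "nuclear_stain"
              else c("nuclear_stain", "albumin", "gfp")
  parts <- vector("list", n_fields)
  done <- 0L
  for (i in seq_len(n_fields)) {
    chunk <- min(per_field, n - done)
    fs <- spec
    fs$n_cells <- as.integer(chunk)
    fs$seed <- derive_seed(seed, i)
    cells <- sample_cells(fs, field_um = rev(shape) * pixel_size,
                          seed = fs$seed)
    rf <- render_field(cells, pixel_size = pixel_size, shape = shape,
                       noise = noise, channels = channels)
    if (via == "image_nuclei") {
      nuc <- segment_nuclei(rf$field$channels$nuclear_stain,
                            pixel_size = pixel_size)
      tab <- extract_features(rf$field, nuc, cells = NULL)
    } else {
      seg <- segment_field(rf$field)
      tab <- extract_features(rf$field, seg$nuclei, seg$cells)
    }
    tab$field <- i
    parts[[i]] <- as.data.frame(tab)
    done <- done + chunk
  }
  df <- do.call(rbind, parts)
  df$cell_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  new_cell_table(df, pixel_size, prov)
}

#' Simulate a niche-factor screen plate at the feature level
#'
#' Builds a plate map with `n_conditions` coating conditions plus the
#' control, `replicates` wells each, and generates an ungated `cell_table`
#' per well. Baseline wells draw cells from `baseline_preset` (i-Heps on a
#' control substrate by default); wells of implanted efficacious conditions
#' draw from a mixture of adult-hepatocyte-like responders and baseline
#' cells with responder weight `hit_weight`.
#'
#' @param seed Base seed (condition selection and all well draws).
#' @param n_conditions Number of non-control conditions.
#' @param n_hits Number of implanted efficacious conditions.
#' @param replicates Wells per condition.
#' @param cells_per_well Cells generated per well.
#' @param hit_weight Mixture weight of adult-like responder cells in hit
#'   wells.
#' @param baseline_preset Preset for non-efficacious wells and the control.
#' @param plate_id Identifier for the plate.
#' @param hit_conditions Conditions to implant as efficacious; drawn at
#'   random when `NULL`.
#' @param non_reproducing Conditions simulated as baseline despite being
#'   listed in `hit_conditions` (used for second-round plates where an
#'   effect fails to reproduce).
#' @return List with `plate_map`, `tables` (named list of ungated
#'   `cell_table`s) and `implanted_hits`.
#' @export
simulate_screen <- function(seed = 1L, n_conditions = 58L, n_hits = 8L,
                            replicates = 3L, cells_per_well = 120L,
                            hit_weight = 0.5, baseline_preset = "ihep",
                            plate_id = "round1",
                            hit_conditions = NULL,
                            non_reproducing = character(0)) {
  stopifnot(n_hits <= n_conditions, replicates >= 1, cells_per_well >= 1)
  conditions <- sprintf("factor-%02d", seq_len(n_conditions))
  if (is.null(hit_conditions)) {
    hit_conditions <- with_seed(derive_seed(seed, 0L),
                                sort(sample(conditions, n_hits)))
  }
  stopifnot(all(hit_conditions %in% conditions))
  all_cond <- c(conditions, "collagen-1")
  wells <- data.frame(
    well = sprintf("w%03d", seq_len(length(all_cond) * replicates)),
    condition = rep(all_cond, each = replicates),
    stringsAsFactors = FALSE)
  pm <- plate_map(wells, control_condition = "collagen-1",
                  plate_id = plate_id)
  base_spec <- make_population_spec(baseline_preset, n_cells = cells_per_well)
  adult <- make_population_spec("adult_hep", n_cells = cells_per_well)
  hit_spec <- make_population_spec(
    "mixture",
    overrides = list(mixture_components = list(
      list(spec = adult, weight = hit_weight),
      list(spec = base_spec, weight = 1 - hit_weight))),
    n_cells = cells_per_well)
  effective_hits <- setdiff(hit_conditions, non_reproducing)
  tables <- lapply(seq_len(nrow(wells)), function(i) {
    sp <- if (wells$condition[i] %in% effective_hits) hit_spec else base_spec
    cells <- sample_cell_features(sp, seed = derive_seed(seed, 10L + i))
    cell_table_from_truth(cells, provenance = list(
      plate = plate_id, well = wells$well[i], condition = wells$condition[i]))
  })
  names(tables) <- wells$well
  list(plate_map = pm, tables = tables, implanted_hits = hit_conditions)
}

#' Gate, score and call hits on a simulated screen
#'
#' @param sim A [simulate_screen()] result.
#' @param profile A [fit_reference_profile()] object.
#' @param hli_threshold,rule Passed to [call_hits()].
#' @param min_cells Passed to [score_plate()].
#' @return A `screen_result` with hits called.
#' @export
score_screen <- function(sim, profile, hli_threshold = 0.2,
                         rule = "conjunction", min_cells = 20L) {
  gated <- lapply(sim$tables, apply_gates, profile = profile)
  call_hits(score_plate(gated, sim$plate_map, min_cells = min_cells),
            hli_threshold = hli_threshold, rule = rule)
}
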