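# Shared fixtures, generated in code and cached for the duration of a run.

fx <- new.env()

spec_of <- function(preset, n, seed, overrides = list()) {
  make_population_spec(preset, overrides = overrides, n_cells = n, seed = seed)
}

truth_table <- function(preset, n, seed, overrides = list()) {
  simulate_population_table(spec_of(preset, n, seed, overrides), via = "truth")
}

# One small rendered adult-hepatocyte field plus its segmentation.
adult_field <- function() {
  if (is.null(fx$adult)) {
    spec <- spec_of("adult_hep", 30, 42)
    cells <- sample_cells(spec, field_um = c(520, 520))
    rf <- render_field(cells, shape = c(800L, 800L))
    seg <- segment_field(rf$field)
    fx$adult <- list(spec = spec, cells = cells, rf = rf, seg = seg)
  }
  fx$adult
}

# Reference profile calibrated on adult vs fibroblast feature-level draws.
shared_profile <- function() {
  if (is.null(fx$profile)) {
    fx$ref <- truth_table("adult_hep", 500, 11)
    fx$neg <- truth_table("fibroblast", 500, 12)
    fx$profile <- fit_reference_profile(fx$ref, fx$neg)
  }
  fx$profile
}

paint_ellipse_mat <- function(base, cy, cx, a, b, theta = 0, value = 1) {
  nr <- nrow(base); nc <- ncol(base)
  rr <- matrix(rep(seq_len(nr), nc), nr)
  cc <- matrix(rep(seq_len(nc), each = nr), nr)
  dx <- cc - cx; dy <- rr - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  base[(u / a)^2 + (v / b)^2 <= 1] <- value
  base
}

# Best-achievable IoU of each ground-truth object against a segmentation.
best_iou <- function(truth, seg) {
  ids <- sort(unique(truth[truth > 0]))
  vapply(ids, function(id) {
    tm <- truth == id
    ov <- seg[tm]; ov <- ov[ov > 0]
    if (length(ov) == 0) return(0)
    lab <- as.integer(names(which.max(table(ov))))
    sm <- seg == lab
    sum(tm & sm) / sum(tm | sm)
  }, numeric(1))
}

# Artificial gated table with a known number of positives.
gated_table <- function(n, n_pos) {
  tab <- cell_table(data.frame(cell_id = seq_len(n)))
  tab$gate_nuclear <- TRUE
  tab$gate_cell <- TRUE
  tab$gate_albumin <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
  tab$assigned_class <- ifelse(tab$gate_albumin %in% TRUE,
                               "hepatocyte_positive", "hepatocyte_negative")
  tab
}

# Exact AUC by brute force over all (positive, negative) pairs.
u_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

as_truth <- function(df) {
  class(df) <- c("ground_truth_cells", "data.frame")
  df
}

one_cell_truth <- function(x = 40, y = 40, cell_a = 15, cell_b = 15,
                           cell_theta = 0, nuc_a = 6, nuc_b = 5.4,
                           albumin = 1234.5, gfp = FALSE) {
  as_truth(data.frame(
    cell_id = 1L, true_class = "adult_hep", x = x, y = y,
    cell_a = cell_a, cell_b = cell_b, cell_theta = cell_theta,
    nuc_x = x, nuc_y = y, nuc_a = nuc_a, nuc_b = nuc_b, nuc_theta = 0,
    is_polyploid = FALSE, true_albumin_mfi = albumin,
    nuclear_stain_mfi = 800, gfp_mfi = if (gfp) 1200 else 0, is_gfp = gfp,
    stringsAsFactors = FALSE))
}
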