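# Reference-profile fitting, ROC calibration of the albumin cutoff,
# sequential gating, and the Hepatocyte Likeness Index.

.morph_features <- c("nuclear_area", "nuclear_width", "cell_area",
                     "cell_width", "symmetry")
.nuclear_features <- c("nuclear_area", "nuclear_width")

#' Calibrate the albumin intensity cutoff by ROC analysis
#'
#' Builds the empirical receiver-operating-characteristic curve of the rule
#' "albumin MFI >= threshold" over all distinct observed intensities,
#' computes the area under the curve by the trapezoid rule, and selects the
#' cutoff maximizing Youden's J = TPR - FPR (ties broken toward the higher
#' threshold).
#'
#' @param positive_mfi Albumin MFIs of the reference (hepatocyte) cells.
#' @param negative_mfi Albumin MFIs of the negative-control cells.
#' @return A `roc_curve`: `thresholds` (increasing), aligned `tpr` and
#'   `fpr`, `auc`, and `optimal_cutoff`.
#' @export
calibrate_albumin_cutoff <- function(positive_mfi, negative_mfi) {
  pos <- positive_mfi[!is.na(positive_mfi)]
  neg <- negative_mfi[!is.na(negative_mfi)]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both positive and negative MFI lists must be non-empty")
  th <- sort(unique(c(pos, neg)))
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  # Trapezoid AUC over the curve traced from the highest threshold down;
  # (fpr, tpr) runs from (0, 0) (above max) to (1, 1) (at the minimum).
  k <- length(th)
  fp <- c(0, fpr[k:1]); tp <- c(0, tpr[k:1])
  auc <- sum(diff(fp) * (head(tp, -1) + tp[-1]) / 2)
  j <- tpr - fpr
  best <- max(which(j >= max(j) - 1e-12))  # ties -> higher threshold
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc,
                 optimal_cutoff = th[best], youden = j[best]),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f; optimal cutoff = %.4g (Youden J = %.3f); %d thresholds\n",
              x$auc, x$optimal_cutoff, x$youden, length(x$thresholds)))
  invisible(x)
}

madn_interval <- function(x, k = 3) {
  med <- median(x)
  s <- mad(x)  # 1.4826 * MAD, consistent for the normal
  c(low = med - k * s, high = med + k * s)
}

#' Fit the gold-standard reference profile
#'
#' Morphology gates are robust acceptance intervals, median +/- 3 MADN
#' (MADN = 1.4826 x MAD), fit on the reference population; the albumin
#' cutoff comes from [calibrate_albumin_cutoff()] against the negatives.
#' Because roughly a third of adult hepatocyte nuclei are polyploid, the
#' nuclear-feature distributions of a healthy reference are bimodal, and a
#' single robust interval would reject most polyploid nuclei. With
#' `ploidy_aware = TRUE` (default) polyploidy is first called on the
#' reference ([call_polyploidy()]) and each nuclear gate is the hull of the
#' per-ploidy-class intervals, so both ploidy classes of a healthy
#' reference pass.
#'
#' @param reference `cell_table` of the gold-standard population (>= 50
#'   cells, albumin MFI present).
#' @param negatives `cell_table` of the negative control (>= 50 cells).
#' @param ploidy_aware Use ploidy-split nuclear gates (see above).
#' @param k Half-width of the robust interval in MADN units (default 3).
#' @param min_cells Minimum cells required in each table.
#' @return A `reference_profile` with `morphology_gates`, `albumin_cutoff`,
#'   `roc` and `calibration_meta`.
#' @export
fit_reference_profile <- function(reference, negatives, ploidy_aware = TRUE,
                                  k = 3, min_cells = 50L) {
  stopifnot(inherits(reference, "cell_table"), inherits(negatives, "cell_table"))
  if (nrow(reference) < min_cells || nrow(negatives) < min_cells)
    stop("reference and negatives must each have at least ", min_cells,
         " cells")
  for (f in c(.morph_features, "mfi_albumin")) {
    if (any(is.na(reference[[f]])))
      stop("missing feature '", f, "' in the reference table")
  }
  if (any(is.na(negatives$mfi_albumin)))
    stop("missing feature 'mfi_albumin' in the negatives table")
  gates <- list()
  degenerate <- character(0)
  ref <- call_polyploidy(reference)
  for (f in .morph_features) {
    x <- ref[[f]]
    if (ploidy_aware && f %in% .nuclear_features &&
        sum(ref$is_polyploid) >= 10 && sum(!ref$is_polyploid) >= 10) {
      g1 <- madn_interval(x[!ref$is_polyploid], k)
      g2 <- madn_interval(x[ref$is_polyploid], k)
      g <- c(low = min(g1["low"], g2["low"]),
             high = max(g1["high"], g2["high"]))
    } else {
      g <- madn_interval(x, k)
    }
    if (g["low"] >= g["high"]) {
      g <- c(low = median(x), high = median(x))
      degenerate <- c(degenerate, f)
    }
    gates[[f]] <- g
  }
  roc <- calibrate_albumin_cutoff(reference$mfi_albumin, negatives$mfi_albumin)
  meta <- list(n_reference = nrow(reference), n_negative = nrow(negatives),
               method = sprintf("median +/- %g MADN%s", k,
                                if (ploidy_aware) ", ploidy-aware nuclear gates"
                                else ""),
               auc = roc$auc, degenerate = degenerate,
               reference_mode_area = attr(ref, "reference_mode_area"),
               low_auc_warning = FALSE)
  if (roc$auc < 0.6) {
    meta$low_auc_warning <- TRUE
    warning(sprintf(
      "albumin separates the reference from the negatives poorly (AUC = %.3f)",
      roc$auc))
  }
  structure(list(morphology_gates = gates, albumin_cutoff = roc$optimal_cutoff,
                 roc = roc, calibration_meta = meta),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile>", x$calibration_meta$method, "\n")
  for (f in names(x$morphology_gates)) {
    g <- x$morphology_gates[[f]]
    cat(sprintf("  %-13s [%.3g, %.3g]\n", f, g[1], g[2]))
  }
  cat(sprintf("  albumin cutoff %.4g AU (ROC AUC %.4f; n_ref = %d, n_neg = %d)\n",
              x$albumin_cutoff, x$calibration_meta$auc,
              x$calibration_meta$n_reference, x$calibration_meta$n_negative))
  invisible(x)
}

#' Apply the sequential hepatocyte gates
#'
#' Cells are gated strictly in order: nuclear morphology (nuclear area and
#' width), then cell morphology (cell area, width and symmetry), then
#' albumin (MFI >= cutoff). Gate intervals are closed, so boundary values
#' pass. With `short_circuit = TRUE` (default) a cell failing a stage is
#' not evaluated at later stages (their gate columns stay `NA`), so
#' attrition is attributed to the first failing stage; with `FALSE` every
#' stage is evaluated for every cell.
#'
#' @param table A `cell_table` with complete morphology and albumin
#'   features.
#' @param profile A [fit_reference_profile()] object.
#' @param short_circuit Stop evaluating a cell at its first failing stage.
#' @return The table with `gate_nuclear`, `gate_cell`, `gate_albumin` and
#'   `assigned_class` filled in.
#' @export
apply_gates <- function(table, profile, short_circuit = TRUE) {
  stopifnot(inherits(table, "cell_table"), inherits(profile, "reference_profile"))
  gates <- profile$morphology_gates
  for (f in c(names(gates), "mfi_albumin")) {
    if (is.null(table[[f]]) || any(is.na(table[[f]])))
      stop("missing feature '", f, "' in table")
  }
  pass_stage <- function(features) {
    ok <- rep(TRUE, nrow(table))
    for (f in features) {
      g <- gates[[f]]
      ok <- ok & table[[f]] >= g["low"] & table[[f]] <= g["high"]
    }
    ok
  }
  nuc <- pass_stage(intersect(names(gates), .nuclear_features))
  cell <- pass_stage(setdiff(names(gates), .nuclear_features))
  alb <- table$mfi_albumin >= profile$albumin_cutoff
  if (short_circuit) {
    cell[!nuc] <- NA
    alb[!(nuc & !is.na(cell) & cell)] <- NA
  }
  table$gate_nuclear <- nuc
  table$gate_cell <- cell
  table$gate_albumin <- alb
  pos <- nuc & !is.na(cell) & cell & !is.na(alb) & alb
  table$assigned_class <- ifelse(pos, "hepatocyte_positive",
                                 "hepatocyte_negative")
  table
}

#' Compute the Hepatocyte Likeness Index of a gated population
#'
#' HLI = number of hepatocyte-positive cells / total cells analysed.
#'
#' @param gated A `cell_table` processed by [apply_gates()].
#' @return An `hli_result`: `n_total`, `n_positive`, `hli`, and
#'   `per_gate_attrition` (cells failing first at each stage).
#' @export
compute_hli <- function(gated) {
  stopifnot(inherits(gated, "cell_table"))
  if (nrow(gated) == 0L) stop("HLI undefined for an empty table")
  if (all(is.na(gated$gate_nuclear)))
    stop("gate results not populated; run apply_gates() first")
  pos <- gated$assigned_class %in% "hepatocyte_positive"
  att <- c(
    nuclear = sum(gated$gate_nuclear %in% FALSE),
    cell = sum(gated$gate_nuclear %in% TRUE & gated$gate_cell %in% FALSE),
    albumin = sum(gated$gate_nuclear %in% TRUE & gated$gate_cell %in% TRUE &
                    gated$gate_albumin %in% FALSE))
  structure(list(n_total = nrow(gated), n_positive = sum(pos),
                 hli = sum(pos) / nrow(gated), per_gate_attrition = att),
            class = "hli_result")
}

#' @export
print.hli_result <- function(x, ...) {
  cat(sprintf("<hli_result> HLI = %.3f (%d / %d positive); attrition nuclear/cell/albumin = %d/%d/%d\n",
              x$hli, x$n_positive, x$n_total, x$per_gate_attrition["nuclear"],
              x$per_gate_attrition["cell"], x$per_gate_attrition["albumin"]))
  invisible(x)
}

#' Exclude GFP-positive cells from a table
#'
#' Used to remove nuclear-GFP-labelled cells (e.g. HUVECs in co-culture)
#' before scoring hepatocytes.
#'
#' @param table A `cell_table` with an `mfi_gfp` column.
#' @param gfp_channel_cutoff Cells with GFP MFI above this are removed.
#' @return The filtered table; the number removed is recorded in the
#'   table's provenance as `n_gfp_excluded`.
#' @export
exclude_gfp <- function(table, gfp_channel_cutoff = 50) {
  stopifnot(inherits(table, "cell_table"), gfp_channel_cutoff > 0)
  if (is.null(table$mfi_gfp) || all(is.na(table$mfi_gfp)))
    stop("missing gfp channel: table has no usable 'mfi_gfp' column")
  keep <- table$mfi_gfp <= gfp_channel_cutoff
  out <- table[keep, , drop = FALSE]
  prov <- attr(table, "provenance")
  prov$n_gfp_excluded <- sum(!keep)
  attr(out, "provenance") <- prov
  attr(out, "pixel_size") <- attr(table, "pixel_size")
  class(out) <- class(table)
  out
}

#' Rank feature importance for hepatocyte identification
#'
#' Trains a random-forest classifier (hepatocyte vs rest) on a labelled
#' table and scores each feature by permutation importance: the mean
#' increase in held-out Brier score (squared error of the predicted class
#' probability) when that feature's column is shuffled, averaged over
#' `n_permutations` shuffles. The probability-based loss credits every
#' feature the forest uses, including mutually redundant informative
#' features that a hard-accuracy loss would mask.
#'
#' @param labeled A `cell_table` with a `true_class` column, >= 2 classes
#'   and >= 50 cells per class.
#' @param features Feature columns to rank.
#' @param positive_classes Classes counted as "hepatocyte"; defaults to any
#'   of the hepatocyte presets present in the table.
#' @param n_permutations Permutations per feature (>= 10 recommended).
#' @param seed RNG seed (forest and permutations).
#' @param num_trees Trees in the forest.
#' @return A data frame of `(feature, importance)` sorted by decreasing
#'   importance; importances are non-negative up to permutation noise.
#' @export
rank_feature_importance <- function(labeled,
                                    features = c(.morph_features, "mfi_albumin"),
                                    positive_classes = NULL,
                                    n_permutations = 10L, seed = 1L,
                                    num_trees = 300L) {
  stopifnot(inherits(labeled, "cell_table"))
  cls <- labeled$true_class
  if (is.null(cls) || all(is.na(cls))) stop("table has no 'true_class' labels")
  tab <- table(cls)
  if (length(tab) < 2L) stop("need at least 2 classes to rank features")
  if (any(tab < 50L)) stop("need at least 50 cells per class")
  if (is.null(positive_classes)) {
    positive_classes <- intersect(c("adult_hep", "fetal_hep", "ihep"),
                                  names(tab))
    if (length(positive_classes) == 0) positive_classes <- names(tab)[1]
  }
  for (f in features) {
    if (is.null(labeled[[f]]) || any(is.na(labeled[[f]])))
      stop("missing feature '", f, "' in table")
  }
  df <- as.data.frame(labeled)[, features, drop = FALSE]
  names(df) <- make.names(names(df), unique = TRUE)
  feat_names <- names(df)
  df$.y <- factor(ifelse(cls %in% positive_classes, "hep", "rest"))
  with_seed(seed, {
    idx <- sample.int(nrow(df))
    half <- floor(nrow(df) / 2)
    train <- df[idx[seq_len(half)], ]
    hold <- df[idx[-seq_len(half)], ]
    fit <- ranger::ranger(.y ~ ., data = train, num.trees = num_trees,
                          probability = TRUE, num.threads = 1L,
                          seed = derive_seed(seed, 1L))
    y01 <- as.numeric(hold$.y == "hep")
    brier <- function(d)
      mean((predict(fit, d, num.threads = 1L)$predictions[, "hep"] - y01)^2)
    b0 <- brier(hold)
    imp <- vapply(feat_names, function(f) {
      rises <- vapply(seq_len(n_permutations), function(i) {
        perm <- hold
        perm[[f]] <- sample(perm[[f]])
        brier(perm) - b0
      }, numeric(1))
      mean(rises)
    }, numeric(1))
    out <- data.frame(feature = features, importance = unname(imp),
                      stringsAsFactors = FALSE)
    out[order(-out$importance), , drop = FALSE]
  })
}
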