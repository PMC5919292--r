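# Plate-level niche-factor screen analysis: per-well HLI, control-referenced
# hit calling, and two-round confirmation.

#' Build a plate map
#'
#' @param wells Data frame with columns `well` and `condition` (one row per
#'   well), or a named character vector `well -> condition`.
#' @param control_condition Name of the control coating condition.
#' @param plate_id Identifier recorded in results.
#' @return A `plate_map`.
#' @export
plate_map <- function(wells, control_condition = "collagen-1",
                      plate_id = "plate1") {
  if (is.character(wells) && !is.null(names(wells)))
    wells <- data.frame(well = names(wells), condition = unname(wells),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(wells), all(c("well", "condition") %in% names(wells)))
  if (anyDuplicated(wells$well)) stop("duplicated well ids in plate map")
  if (any(is.na(wells$condition) | wells$condition == ""))
    stop("every well must have a condition")
  if (!control_condition %in% wells$condition)
    stop("control condition '", control_condition,
         "' is not present in any well")
  structure(list(plate_id = plate_id, wells = wells,
                 control_condition = control_condition),
            class = "plate_map")
}

#' @export
print.plate_map <- function(x, ...) {
  cat("<plate_map>", x$plate_id, "-", nrow(x$wells), "wells,",
      length(unique(x$wells$condition)), "conditions; control:",
      x$control_condition, "\n")
  invisible(x)
}

#' Score a plate of gated cell tables
#'
#' Computes the per-well HLI with [compute_hli()] and aggregates replicate
#' wells per condition (mean +/- SD). Wells with fewer than `min_cells`
#' cells are flagged `low_count` and excluded from the per-condition means.
#'
#' @param tables Named list of gated `cell_table`s, one per well id.
#' @param plate_map A [plate_map()]; every table's well must appear in it.
#' @param min_cells Minimum cells for a well to enter the condition mean.
#' @return A `screen_result` with `per_well` and `per_condition` data
#'   frames, a `control` summary, and an empty `hits` slot (see
#'   [call_hits()]).
#' @export
score_plate <- function(tables, plate_map, min_cells = 20L) {
  stopifnot(inherits(plate_map, "plate_map"))
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)))
    stop("'tables' must be a non-empty named list of cell tables")
  unknown <- setdiff(names(tables), plate_map$wells$well)
  if (length(unknown) > 0)
    stop("well(s) absent from the plate map: ",
         paste(unknown, collapse = ", "))
  per_well <- do.call(rbind, lapply(names(tables), function(w) {
    res <- compute_hli(tables[[w]])
    data.frame(well = w,
               condition = plate_map$wells$condition[
                 match(w, plate_map$wells$well)],
               n_cells = res$n_total, hli = res$hli,
               low_count = res$n_total < min_cells,
               stringsAsFactors = FALSE)
  }))
  rownames(per_well) <- NULL
  ok <- per_well[!per_well$low_count, , drop = FALSE]
  conds <- sort(unique(per_well$condition))
  per_condition <- do.call(rbind, lapply(conds, function(cn) {
    h <- ok$hli[ok$condition == cn]
    data.frame(condition = cn, mean_hli = if (length(h)) mean(h) else NA_real_,
               sd_hli = if (length(h) > 1) stats::sd(h) else NA_real_,
               n_wells = length(h), stringsAsFactors = FALSE)
  }))
  rownames(per_condition) <- NULL
  ctrl <- per_condition[per_condition$condition == plate_map$control_condition, ]
  structure(list(plate_id = plate_map$plate_id, per_well = per_well,
                 per_condition = per_condition,
                 control_condition = plate_map$control_condition,
                 control = list(mean_hli = ctrl$mean_hli, sd_hli = ctrl$sd_hli,
                                n_wells = ctrl$n_wells),
                 hits = character(0), hli_threshold = NA_real_,
                 hit_rule = NA_character_, round = 1L),
            class = "screen_result")
}

#' Call screen hits
#'
#' A condition is a hit when its mean HLI strictly exceeds the threshold
#' (default 0.2) and, under the default conjunction rule, also strictly
#' exceeds the control-condition mean; the control itself is never a hit.
#' `rule = "absolute"` uses the threshold alone.
#'
#' @param result A [score_plate()] result.
#' @param hli_threshold Hit threshold on the per-condition mean HLI.
#' @param rule `"conjunction"` (above threshold AND above control) or
#'   `"absolute"` (above threshold only).
#' @return The `screen_result` with `hits` filled in.
#' @export
call_hits <- function(result, hli_threshold = 0.2,
                      rule = c("conjunction", "absolute")) {
  stopifnot(inherits(result, "screen_result"),
            hli_threshold > 0, hli_threshold < 1)
  rule <- match.arg(rule)
  if (is.null(result$control$n_wells) || length(result$control$n_wells) == 0 ||
      result$control$n_wells == 0 || is.na(result$control$mean_hli))
    stop("missing control wells: cannot call hits without the control mean")
  pc <- result$per_condition
  is_hit <- !is.na(pc$mean_hli) & pc$mean_hli > hli_threshold &
    pc$condition != result$control_condition
  if (rule == "conjunction")
    is_hit <- is_hit & pc$mean_hli > result$control$mean_hli
  result$hits <- pc$condition[is_hit]
  result$hli_threshold <- hli_threshold
  result$hit_rule <- rule
  result
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", x$plate_id, "- round", x$round, "-",
      nrow(x$per_well), "wells,", nrow(x$per_condition), "conditions\n")
  cat(sprintf("  control (%s): mean HLI %.3f +/- %.3f over %d wells\n",
              x$control_condition, x$control$mean_hli,
              x$control$sd_hli %||% NA, x$control$n_wells))
  if (length(x$hits))
    cat("  hits (>", x$hli_threshold, "):", paste(x$hits, collapse = ", "),
        "\n")
  invisible(x)
}

#' Confirm first-round hits against second-round screens
#'
#' A first-round hit is confirmed when it satisfies the hit rule in every
#' second-round result (e.g. screens repeated in additional iPSC lines).
#'
#' @param round1 A `screen_result` with hits called.
#' @param round2_results Non-empty list of second-round `screen_result`s
#'   (scored; hits are (re-)called here with the same threshold and rule).
#' @param hli_threshold,rule Passed to [call_hits()] for each round-2
#'   result; default to the round-1 settings.
#' @return Character vector of confirmed conditions.
#' @export
confirm_hits <- function(round1, round2_results, hli_threshold = NULL,
                         rule = NULL) {
  stopifnot(inherits(round1, "screen_result"))
  if (length(round1$hits) == 0) stop("round 1 has no hits to confirm")
  if (!is.list(round2_results) || length(round2_results) == 0)
    stop("at least one second-round result is required")
  hli_threshold <- hli_threshold %||% round1$hli_threshold
  rule <- rule %||% round1$hit_rule
  if (is.na(hli_threshold)) stop("call_hits() must be run on round 1 first")
  confirmed <- round1$hits
  for (r2 in round2_results) {
    stopifnot(inherits(r2, "screen_result"))
    missing <- setdiff(round1$hits, r2$per_condition$condition)
    if (length(missing) > 0)
      stop("round-1 hit(s) missing from a round-2 plate: ",
           paste(missing, collapse = ", "))
    r2 <- call_hits(r2, hli_threshold, rule)
    confirmed <- intersect(confirmed, r2$hits)
  }
  confirmed
}
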