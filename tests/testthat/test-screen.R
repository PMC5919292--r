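# Plate scoring, hit calling against the collagen-1 control, confirmation.

toy_plate <- function(well_hli, conditions, n = 100,
                      control = "collagen-1") {
  tables <- lapply(well_hli, function(h) gated_table(n, round(h * n)))
  names(tables) <- sprintf("w%02d", seq_along(well_hli))
  pm <- plate_map(data.frame(well = names(tables), condition = conditions),
                  control_condition = control)
  score_plate(tables, pm)
}

test_that("a plate of only control wells yields no hits", {
  res <- toy_plate(c(0.1, 0.12, 0.08), rep("collagen-1", 3))
  res <- call_hits(res)
  expect_length(res$hits, 0)
})

test_that("the hit rule is strict at 0.2 and requires beating the control", {
  res <- toy_plate(c(0.35, 0.20, 0.05),
                   c("factor-a", "factor-b", "collagen-1"))
  res <- call_hits(res, 0.2)
  expect_identical(res$hits, "factor-a")  # exactly 0.2 is not a hit
  # above 0.2 but below the control: conjunction rejects, absolute accepts
  res2 <- toy_plate(c(0.25, 0.30), c("factor-a", "collagen-1"))
  expect_length(call_hits(res2, 0.2, rule = "conjunction")$hits, 0)
  expect_identical(call_hits(res2, 0.2, rule = "absolute")$hits, "factor-a")
})

test_that("low-count wells are flagged and excluded from condition means", {
  tables <- list(w1 = gated_table(10, 10),   # tiny well, HLI 1
                 w2 = gated_table(100, 10),
                 w3 = gated_table(100, 12),
                 w4 = gated_table(100, 5))
  pm <- plate_map(data.frame(well = c("w1", "w2", "w3", "w4"),
                             condition = c("factor-a", "factor-a", "factor-a",
                                           "collagen-1")))
  res <- score_plate(tables, pm, min_cells = 20)
  expect_true(res$per_well$low_count[res$per_well$well == "w1"])
  pc <- res$per_condition
  expect_equal(pc$n_wells[pc$condition == "factor-a"], 2)
  expect_equal(pc$mean_hli[pc$condition == "factor-a"], 0.11)
})

test_that("scoring validates its inputs", {
  pm <- plate_map(data.frame(well = "w1", condition = "collagen-1"))
  expect_error(score_plate(list(), pm), "non-empty")
  expect_error(score_plate(list(w9 = gated_table(30, 3)), pm),
               "absent from the plate map")
  res <- toy_plate(c(0.3, 0.1), c("factor-a", "factor-b"),
                   control = "factor-b")
  res$control$n_wells <- 0
  expect_error(call_hits(res), "control")
})

test_that("an implanted screen separates cleanly and is order-invariant", {
  prof <- shared_profile()
  sim <- simulate_screen(seed = 71, n_conditions = 12, n_hits = 3,
                         replicates = 2, cells_per_well = 80)
  res <- score_screen(sim, prof)
  expect_setequal(res$hits, sim$implanted_hits)
  pc <- res$per_condition
  base <- pc$mean_hli[!pc$condition %in% c(sim$implanted_hits, "collagen-1")]
  hit <- pc$mean_hli[pc$condition %in% sim$implanted_hits]
  expect_lt(max(base), 0.2)
  expect_gt(min(hit), 0.2)
  # shuffling well order changes nothing
  shuffled <- sim
  shuffled$tables <- rev(sim$tables)
  res2 <- score_screen(shuffled, prof)
  expect_setequal(res2$hits, res$hits)
  # raising the threshold never adds hits
  prev <- NULL
  for (thr in c(0.1, 0.2, 0.3, 0.5, 0.9)) {
    h <- call_hits(res, thr)$hits
    if (!is.null(prev)) expect_true(all(h %in% prev))
    prev <- h
  }
})

test_that("two-round confirmation keeps only reproducing hits", {
  prof <- shared_profile()
  sim <- simulate_screen(seed = 81, n_conditions = 16, n_hits = 4,
                         replicates = 2, cells_per_well = 80)
  r1 <- score_screen(sim, prof)
  expect_length(r1$hits, 4)
  failing <- sort(r1$hits)[2]
  line_a <- score_screen(simulate_screen(seed = 82, n_conditions = 16,
                                         replicates = 2, cells_per_well = 80,
                                         hit_conditions = r1$hits,
                                         non_reproducing = failing,
                                         plate_id = "round2-lineA"), prof)
  line_b <- score_screen(simulate_screen(seed = 83, n_conditions = 16,
                                         replicates = 2, cells_per_well = 80,
                                         hit_conditions = r1$hits,
                                         plate_id = "round2-lineB"), prof)
  confirmed <- confirm_hits(r1, list(line_a, line_b))
  expect_setequal(confirmed, setdiff(r1$hits, failing))
  # every round-1 hit reproducing confirms the full set
  expect_setequal(confirm_hits(r1, list(line_b)), r1$hits)
  # no round-2 results, or a hit missing from a round-2 plate, is an error
  expect_error(confirm_hits(r1, list()), "second-round")
  tiny <- score_screen(simulate_screen(seed = 84, n_conditions = 2,
                                       n_hits = 0, replicates = 2,
                                       cells_per_well = 80), prof)
  expect_error(confirm_hits(r1, list(tiny)), "missing from a round-2")
})

test_that("a null screen produces (almost) no hits across many seeds", {
  prof <- shared_profile()
  hits <- vapply(1:100, function(s) {
    sim <- simulate_screen(seed = 1000 + s, n_conditions = 12, n_hits = 0,
                           replicates = 2, cells_per_well = 60)
    length(score_screen(sim, prof)$hits)
  }, numeric(1))
  expect_lte(mean(hits), 0.05)
})
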