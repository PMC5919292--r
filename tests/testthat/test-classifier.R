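# Profile fitting, ROC calibration, sequential gating, HLI, GFP exclusion
# and feature-importance ranking.

test_that("ROC handles perfect separation and identity", {
  roc <- calibrate_albumin_cutoff(rep(2000, 40), rep(100, 40))
  expect_equal(roc$auc, 1.0)
  expect_gt(roc$optimal_cutoff, 100)
  expect_lte(roc$optimal_cutoff, 2000)
  same <- c(1, 2, 3, 4, 5)
  expect_equal(calibrate_albumin_cutoff(same, same)$auc, 0.5)
  expect_error(calibrate_albumin_cutoff(numeric(0), 1:3), "non-empty")
})

test_that("empirical AUC equals the scaled Mann-Whitney U statistic", {
  set.seed(11)
  for (i in 1:20) {
    pos <- sample(0:10, 15, replace = TRUE)
    neg <- sample(0:10, 12, replace = TRUE)
    roc <- calibrate_albumin_cutoff(pos, neg)
    expect_equal(roc$auc, u_auc(pos, neg))
    w <- suppressWarnings(wilcox.test(pos, neg))
    expect_equal(roc$auc, unname(w$statistic) / (15 * 12))
  }
  # independent cross-check against pROC on one continuous sample
  pos <- rnorm(60, 1); neg <- rnorm(50)
  roc <- calibrate_albumin_cutoff(pos, neg)
  pr <- pROC::roc(c(rep(1, 60), rep(0, 50)), c(pos, neg), quiet = TRUE,
                  direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(pr)))
})

test_that("AUC at preset separation matches the binormal closed form", {
  set.seed(3)
  pos <- rnorm(500, 2000, 300)
  neg <- rnorm(500, 120, 60)
  roc <- calibrate_albumin_cutoff(pos, neg)
  closed <- pnorm((2000 - 120) / sqrt(300^2 + 60^2))
  expect_lt(abs(roc$auc - closed), 0.005)
})

test_that("a healthy reference population falls inside its own gates", {
  prof <- shared_profile()
  indep <- truth_table("adult_hep", 2000, 21)
  gated <- apply_gates(indep, prof, short_circuit = FALSE)
  joint_morph <- mean(gated$gate_nuclear & gated$gate_cell)
  expect_gte(joint_morph, 0.985)
  # the nuclear gates accept both ploidy classes of the reference
  poly <- gated$true_polyploid
  expect_gt(mean(gated$gate_nuclear[poly]), 0.97)
})

test_that("degenerate features and uninformative negatives are flagged", {
  ref0 <- truth_table("adult_hep", 120, 31,
                      overrides = list(cell_aspect = c(0.85, 0)))
  neg <- truth_table("fibroblast", 120, 32)
  prof <- fit_reference_profile(ref0, neg)
  expect_true("symmetry" %in% prof$calibration_meta$degenerate)
  g <- prof$morphology_gates$symmetry
  expect_equal(unname(g["low"]), unname(g["high"]))
  ref <- truth_table("adult_hep", 120, 33)
  expect_warning(prof2 <- fit_reference_profile(ref, ref), "poorly")
  expect_equal(prof2$calibration_meta$auc, 0.5)
  expect_true(prof2$calibration_meta$low_auc_warning)
  expect_error(fit_reference_profile(truth_table("adult_hep", 20, 1), neg),
               "at least 50")
})

test_that("gate boundaries pass and stages short-circuit in order", {
  prof <- shared_profile()
  g <- prof$morphology_gates
  boundary <- cell_table(data.frame(
    cell_id = 1:2,
    nuclear_area = c(g$nuclear_area["low"], g$nuclear_area["high"]),
    nuclear_width = c(g$nuclear_width["low"], g$nuclear_width["high"]),
    cell_area = c(g$cell_area["low"], g$cell_area["high"]),
    cell_width = c(g$cell_width["low"], g$cell_width["high"]),
    symmetry = pmin(c(g$symmetry["low"], g$symmetry["high"]), 1),
    mfi_nuclear_stain = 60, mfi_albumin = prof$albumin_cutoff, mfi_gfp = 0))
  gated <- apply_gates(boundary, prof)
  expect_true(all(gated$assigned_class == "hepatocyte_positive"))
  # fibroblast-shaped cells fail at the cell-morphology stage even with
  # adult-level albumin; albumin is never evaluated for them
  fib <- truth_table("fibroblast", 200, 30)
  fib$mfi_albumin <- 2000
  gf <- apply_gates(fib, prof)
  second <- gf$gate_nuclear %in% TRUE & gf$gate_cell %in% FALSE
  expect_gt(sum(second), 0)
  expect_true(all(is.na(gf$gate_albumin[second])))
  att <- compute_hli(gf)$per_gate_attrition
  expect_equal(unname(att["cell"]), sum(second))
  expect_equal(compute_hli(gf)$hli, 0)
  # missing features are named
  broken <- fib
  broken$symmetry <- NA_real_
  expect_error(apply_gates(broken, prof), "symmetry")
})

test_that("HLI arithmetic, bounds and order invariance", {
  expect_equal(compute_hli(gated_table(100, 100))$hli, 1.0)
  expect_equal(compute_hli(gated_table(100, 0))$hli, 0.0)
  res <- compute_hli(gated_table(400, 92))
  expect_equal(res$hli, 0.23)
  expect_equal(sum(res$per_gate_attrition), res$n_total - res$n_positive)
  expect_error(compute_hli(cell_table(data.frame(cell_id = integer(0)))),
               "empty")
  expect_error(compute_hli(cell_table(data.frame(cell_id = 1:3))),
               "apply_gates")
  prof <- shared_profile()
  tab <- truth_table("adult_hep", 300, 41)
  h1 <- compute_hli(apply_gates(tab, prof))$hli
  perm <- tab[sample(nrow(tab)), , drop = FALSE]
  attr(perm, "pixel_size") <- attr(tab, "pixel_size")
  class(perm) <- class(tab)
  h2 <- compute_hli(apply_gates(perm, prof))$hli
  expect_equal(h1, h2)
  expect_gte(h1, 0); expect_lte(h1, 1)
})

test_that("profile applied to its own population gives HLI near 1, and
           suppressing albumin drives HLI to 0", {
  prof <- shared_profile()
  tab <- truth_table("adult_hep", 500, 44)
  expect_gte(compute_hli(apply_gates(tab, prof))$hli, 0.9)
  dark <- tab
  dark$mfi_albumin <- prof$albumin_cutoff * 0.5
  expect_equal(compute_hli(apply_gates(dark, prof))$hli, 0)
})

test_that("GFP-positive cells are excluded at the generator mixing fraction", {
  mix <- make_population_spec("mixture", overrides = list(
    mixture_components = list(
      list(spec = make_population_spec("adult_hep"), weight = 0.5),
      list(spec = make_population_spec("huvec_gfp"), weight = 0.5))),
    n_cells = 400, seed = 9)
  tab <- cell_table_from_truth(sample_cell_features(mix))
  out <- exclude_gfp(tab, 50)
  removed <- nrow(tab) - nrow(out)
  expect_lt(abs(removed - 200), 2.576 * sqrt(400 * 0.25))
  expect_true(all(out$mfi_gfp <= 50))
  expect_equal(attr(out, "provenance")$n_gfp_excluded, removed)
  # cutoff above the maximum observed GFP leaves the table unchanged
  expect_equal(nrow(exclude_gfp(tab, max(tab$mfi_gfp) + 1)), nrow(tab))
  # all-GFP population: empty result, downstream HLI undefined
  huv <- cell_table_from_truth(sample_cell_features(
    spec_of("huvec_gfp", 50, 2)))
  none <- exclude_gfp(huv, 1)
  expect_equal(nrow(none), 0)
  expect_error(compute_hli(none), "empty")
  noch <- cell_table(data.frame(cell_id = 1:3))
  expect_error(exclude_gfp(noch, 50), "gfp")
})

test_that("feature importance finds the informative features", {
  # construct populations separated ONLY in symmetry and albumin
  ref <- sample_cell_features(spec_of("adult_hep", 250, 61))
  alt <- sample_cell_features(spec_of("fibroblast", 250, 62, overrides = list(
    cell_area = c(1600, 300), nuclear_area = c(110, 20),
    polyploid_fraction = 0.30)))
  tab <- cell_table(rbind(as.data.frame(cell_table_from_truth(ref)),
                          within(as.data.frame(cell_table_from_truth(alt)),
                                 cell_id <- cell_id + 1000)))
  imp <- rank_feature_importance(tab, seed = 5)
  ranks <- setNames(seq_len(nrow(imp)), imp$feature)
  expect_lt(ranks[["symmetry"]], ranks[["nuclear_area"]])
  expect_lt(ranks[["mfi_albumin"]], ranks[["nuclear_area"]])
  expect_gt(imp$importance[imp$feature == "symmetry"], 0.05)
  # shuffled labels carry no signal
  shuf <- tab
  set.seed(8)
  shuf$true_class <- sample(shuf$true_class)
  imp0 <- rank_feature_importance(shuf, seed = 5)
  expect_true(all(abs(imp0$importance) < 0.05))
  # single class errors
  solo <- cell_table_from_truth(ref)
  expect_error(rank_feature_importance(solo), "2 classes")
})

test_that("a duplicated feature splits importance without reshuffling others", {
  ref <- sample_cell_features(spec_of("adult_hep", 250, 63))
  alt <- sample_cell_features(spec_of("fibroblast", 250, 64, overrides = list(
    cell_area = c(1600, 300), nuclear_area = c(110, 20),
    polyploid_fraction = 0.30)))
  tab <- cell_table(rbind(as.data.frame(cell_table_from_truth(ref)),
                          within(as.data.frame(cell_table_from_truth(alt)),
                                 cell_id <- cell_id + 1000)))
  tab$symmetry_copy <- tab$symmetry
  single <- rank_feature_importance(
    tab, features = c("nuclear_area", "symmetry"), seed = 5)
  dup <- rank_feature_importance(
    tab, features = c("nuclear_area", "symmetry", "symmetry_copy"),
    seed = 5)
  imp_of <- function(res, f) res$importance[res$feature == f]
  # combined importance of the duplicated pair still dominates, while each
  # copy alone may carry less than the original single column
  expect_gt(imp_of(dup, "symmetry") + imp_of(dup, "symmetry_copy"),
            imp_of(dup, "nuclear_area") + 0.02)
  expect_lte(imp_of(dup, "symmetry"), imp_of(single, "symmetry") + 0.02)
  # the uninformative feature stays unimportant in both rankings
  expect_lt(abs(imp_of(dup, "nuclear_area") - imp_of(single, "nuclear_area")),
            0.05)
})
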