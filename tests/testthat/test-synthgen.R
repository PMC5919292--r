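# Synthetic population generator: presets, sampling, placement, rendering.

test_that("presets encode the reported population contrasts", {
  a <- make_population_spec("adult_hep")
  f <- make_population_spec("fetal_hep")
  i <- make_population_spec("ihep")
  fb <- make_population_spec("fibroblast")
  expect_equal(a$polyploid_fraction, 0.30)
  expect_lt(f$polyploid_fraction, 0.05)
  expect_gt(a$cell_area[1], f$cell_area[1])
  expect_gt(a$cell_aspect[1], f$cell_aspect[1])
  expect_gt(i$nuclear_area[1], a$nuclear_area[1])
  expect_gt(i$nuclear_area[2], a$nuclear_area[2])
  expect_lt(fb$albumin_mfi[1], a$albumin_mfi[1])
  # fibroblast albumin sits below the ROC-separable range of the reference
  expect_lt(fb$albumin_mfi[1] + 3 * fb$albumin_mfi[2],
            a$albumin_mfi[1] - 3 * a$albumin_mfi[2])
})

test_that("spec validation rejects unknown presets and bad overrides", {
  expect_error(make_population_spec("hepatocyte"), "valid presets")
  expect_error(make_population_spec("adult_hep",
                                    overrides = list(polyploid_fraction = 1.5)),
               "polyploid_fraction")
  expect_error(make_population_spec("adult_hep",
                                    overrides = list(cell_area = c(1600, -5))),
               "cell_area")
  expect_error(make_population_spec("adult_hep",
                                    overrides = list(nonsense = 1)),
               "unknown")
  expect_error(make_population_spec("mixture"), "mixture_components")
})

test_that("sampling and rendering are deterministic; n_cells = 0 is empty", {
  s <- spec_of("adult_hep", 20, 3)
  c1 <- sample_cells(s, field_um = c(455, 455))
  c2 <- sample_cells(s, field_um = c(455, 455))
  expect_identical(c1, c2)
  r1 <- render_field(c1, shape = c(700L, 700L))
  r2 <- render_field(c2, shape = c(700L, 700L))
  expect_identical(r1$field$channels, r2$field$channels)
  expect_identical(r1$cells$labels, r2$cells$labels)
  expect_equal(nrow(sample_cell_features(spec_of("adult_hep", 0, 1))), 0)
})

test_that("sample moments recover the spec parameters", {
  n <- 1500
  for (preset in c("adult_hep", "fetal_hep", "ihep")) {
    s <- spec_of(preset, n, 17)
    d <- sample_cell_features(s)
    area <- pi * d$cell_a * d$cell_b
    expect_lt(abs(mean(area) - s$cell_area[1]), 3 * sd(area) / sqrt(n))
    alb <- d$true_albumin_mfi
    # intensities are normals truncated below at 30 AU; oracle = the
    # truncated-normal mean mu + sd * phi(a) / (1 - Phi(a))
    a <- (30 - s$albumin_mfi[1]) / s$albumin_mfi[2]
    mu_trunc <- s$albumin_mfi[1] +
      s$albumin_mfi[2] * dnorm(a) / (1 - pnorm(a))
    expect_lt(abs(mean(alb) - mu_trunc), 3 * sd(alb) / sqrt(n))
    nuc <- pi * d$nuc_a * d$nuc_b
    exp_nuc <- (1 - s$polyploid_fraction) * s$nuclear_area[1] +
      s$polyploid_fraction * 2 * s$nuclear_area[1]
    expect_lt(abs(mean(nuc) - exp_nuc), 3 * sd(nuc) / sqrt(n))
  }
})

test_that("polyploid draws hit the preset fraction within the binomial CI", {
  d <- sample_cell_features(spec_of("adult_hep", 1000, 23))
  ci99 <- 2.576 * sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(mean(d$is_polyploid) - 0.30), ci99)
  # polyploid nuclei are drawn around twice the mononucleate mean area
  poly_area <- pi * d$nuc_a[d$is_polyploid] * d$nuc_b[d$is_polyploid]
  expect_lt(abs(mean(poly_area) - 220), 3 * sd(poly_area) / sqrt(sum(d$is_polyploid)))
})

test_that("mixtures draw classes at the specified weights", {
  mix <- make_population_spec("mixture", overrides = list(
    mixture_components = list(
      list(spec = make_population_spec("adult_hep"), weight = 0.5),
      list(spec = make_population_spec("fibroblast"), weight = 0.5))),
    n_cells = 400, seed = 5)
  d <- sample_cell_features(mix)
  counts <- table(d$true_class)
  ci99 <- 2.576 * sqrt(400 * 0.25)
  expect_lt(abs(counts[["adult_hep"]] - 200), ci99)
  expect_setequal(names(counts), c("adult_hep", "fibroblast"))
})

test_that("placed cells do not overlap and nuclei are nested in their cells", {
  af <- adult_field()
  cl <- af$rf$cells$labels
  nl <- af$rf$nuclei$labels
  expect_equal(sort(unique(cl[cl > 0])), 1:30)
  # every nuclear pixel carries its parent cell's label
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
  # labelled area matches the sum of analytic ellipse areas (no overlap loss)
  p <- af$rf$cells$pixel_size
  analytic <- sum(pi * af$cells$cell_a * af$cells$cell_b) / p^2
  expect_lt(abs(sum(cl > 0) - analytic) / analytic, 0.02)
})

test_that("noise-free rendering is exact", {
  tr <- one_cell_truth()
  rf <- render_field(tr, pixel_size = 1, shape = c(80L, 80L),
                     noise = noise_model(0, FALSE, background = 50,
                                         digitize = FALSE))
  m <- rf$cells$labels == 1L
  expect_equal(mean(rf$field$channels$albumin[m]) - 50, 1234.5)
  expect_equal(unique(rf$field$channels$albumin[!m]), 50)
  # rasterized mask area within 2% of pi*a*b for semi-axes >= 10 px
  tr2 <- one_cell_truth(cell_a = 20, cell_b = 12, cell_theta = 0.7)
  rf2 <- render_field(tr2, pixel_size = 1, shape = c(80L, 80L),
                      noise = noise_model(0, FALSE, digitize = FALSE))
  expect_lt(abs(sum(rf2$cells$labels == 1L) - pi * 20 * 12), 0.02 * pi * 20 * 12)
})

test_that("impossible placements fail with advice rather than hanging", {
  expect_error(sample_cells(spec_of("adult_hep", 80, 5),
                            field_um = c(200, 200)),
               "larger field|too small")
  tr <- one_cell_truth(x = 5, y = 40)  # ellipse extends beyond the image
  expect_error(render_field(tr, pixel_size = 1, shape = c(80L, 80L)),
               "shape too small")
})
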