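# Synthetic column generator and the oblique-crushing model.

test_that("undistorted generator honours trend, noise and determinism", {
  flat <- true_column_model(n = 5, vh_start = 0.8, vh_end = 0.8, noise_sd = 0)
  col <- generate_true_column(flat)
  expect_equal(series_ratios(col)$vh, rep(0.8, 5))
  sv <- serial_variation(col)
  expect_equal(sv$metric_diff_x100, 0)
  expect_equal(sv$metric_ratio_x100, 0)

  lin <- true_column_model(n = 5, vh_start = 0.7, vh_end = 0.9, noise_sd = 0)
  expect_equal(consecutive_diffs(series_ratios(generate_true_column(lin))),
               rep(0.05, 4))

  noisy <- true_column_model(n = 8, noise_sd = 0.05, seed = 99L)
  expect_identical(generate_true_column(noisy), generate_true_column(noisy))

  geo <- true_column_model(n = 4, vh_start = 0.5, vh_end = 4, noise_sd = 0,
                           trend = "geometric")
  expect_equal(series_ratios(generate_true_column(geo))$vh, c(0.5, 1, 2, 4))

  expect_error(true_column_model(n = 1), "n must be")
  expect_error(true_column_model(noise_sd = -0.1), "noise_sd")
})

test_that("simulate() draws reproducible independent realizations", {
  m <- true_column_model(n = 6, noise_sd = 0.05, seed = 5L)
  cols <- simulate(m, nsim = 3)
  expect_length(cols, 3)
  expect_false(identical(cols[[1]]$horizontal, cols[[2]]$horizontal))
  expect_identical(simulate(m, nsim = 3), cols)
})

test_that("crush_section matches its worked examples", {
  # identity at k = 1 regardless of orientation and volume response
  expect_equal(crush_section(7, 3, crush_params(theta = 123, k = 1, gamma = 0.4)),
               c(height = 7, width = 3))
  # axis-aligned volume-loss compression scales only the height
  expect_equal(crush_section(10, 6, crush_params(theta = 0, k = 0.5, gamma = 0)),
               c(height = 5, width = 6))
  # area-preserving oblique crushing of a circle inflates BOTH extents
  got <- crush_section(2, 2, crush_params(theta = 45, k = 0.5, gamma = 1))
  want <- sampled_crush_extents(2, 2, 45, 0.5, 1)
  expect_equal(got, want, tolerance = 1e-6)
  expect_equal(unname(got), c(2.915476, 2.915476), tolerance = 1e-6)
  expect_true(all(got > 2))

  expect_error(crush_params(k = 0), "k must")
  expect_error(crush_params(k = 1.2), "k must")
  expect_error(crush_params(gamma = -0.1), "gamma")
  expect_error(crush_section(-1, 2, crush_params()), "positive")
})

test_that("support-function extents agree with the boundary-sampling oracle", {
  set.seed(31)
  for (rep in 1:25) {
    h <- runif(1, 1, 50); w <- runif(1, 1, 50)
    th <- runif(1, 0, 180); k <- runif(1, 0.3, 1); g <- runif(1)
    got <- crush_section(h, w, crush_params(th, k, g))
    want <- sampled_crush_extents(h, w, th, k, g)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("crush_section is invariant under theta -> theta + 180", {
  set.seed(13)
  for (rep in 1:20) {
    h <- runif(1, 1, 40); w <- runif(1, 1, 40)
    th <- runif(1, 0, 180); k <- runif(1, 0.3, 1); g <- runif(1)
    expect_equal(crush_section(h, w, crush_params(th, k, g)),
                 crush_section(h, w, crush_params(th + 180, k, g)))
  }
})

test_that("gamma = 0 crushing is a contraction; gamma = 1 conserves area", {
  # the map has singular values {1, k} <= 1, so no apparent extent can exceed
  # the facet's largest original extent; the stronger per-axis bound holds
  # for axis-aligned crushing and for circular facets
  set.seed(17)
  for (rep in 1:200) {
    h <- runif(1, 1, 100); w <- runif(1, 1, 100)
    th <- runif(1, 0, 180); k <- runif(1, 0.05, 1)
    e0 <- crush_section(h, w, crush_params(th, k, gamma = 0))
    expect_lte(max(e0), max(h, w) + 1e-12)

    e_axis <- crush_section(h, w, crush_params(0, k, gamma = 0))
    expect_equal(e_axis, c(height = k * h, width = w))

    d <- runif(1, 1, 50)
    e_circ <- crush_section(d, d, crush_params(th, k, gamma = 0))
    expect_lte(max(e_circ), d + 1e-12)
  }
  # area of the mapped ellipse is pi*(h/2)(w/2)*k^(1-gamma): check against a
  # shoelace polygon area of the mapped boundary, and exactly via |det M|
  for (g in c(0, 0.5, 1)) {
    h <- 9; w <- 4; th <- 37; k <- 0.6
    analytic <- pi * (h / 2) * (w / 2) * k^(1 - g)
    expect_equal(sampled_crush_area(h, w, th, k, g), analytic,
                 tolerance = 1e-6)
  }
})

test_that("crush_column is seeded, records draws, and respects regimes", {
  col <- generate_true_column(true_column_model(n = 10, noise_sd = 0))

  # k_min = k_max = 1: V/H untouched
  no_crush <- crush_column(col, crush_intensity(1, 1, gamma = 1, seed = 4L))
  expect_equal(series_ratios(no_crush)$vh, series_ratios(col)$vh)

  intense <- crush_intensity(0.5, 0.9, gamma = 0, seed = 21L)
  crushed <- crush_column(col, intense)
  expect_identical(crush_column(col, intense), crushed)
  draws <- attr(crushed, "crush_draws")
  expect_equal(nrow(draws), 10)
  expect_true(all(draws$theta >= 0 & draws$theta < 180))
  expect_true(all(draws$k >= 0.5 & draws$k <= 0.9))

  # gamma = 0: no apparent extent exceeds the facet's largest original
  # extent, for any seed
  for (seed in 1:5) {
    cr <- crush_column(col, crush_intensity(0.4, 1, gamma = 0, seed = seed))
    orig_max <- pmax(col$vertical, col$horizontal)
    expect_true(all(cr$vertical <= orig_max + 1e-12))
    expect_true(all(cr$horizontal <= orig_max + 1e-12))
  }
  expect_error(crush_intensity(0, 0.5), "k_min")
  expect_error(crush_intensity(0.8, 0.5), "k_min")
})

test_that("discrimination experiment separates crushed from uncrushed columns", {
  m <- true_column_model(seed = 2026L)
  one <- discrimination_experiment(m, crush_intensity(seed = 1L), replicates = 1)
  expect_equal(nrow(one), 1)

  none <- discrimination_experiment(m, crush_intensity(1, 1, seed = 1L),
                                    replicates = 10)
  expect_equal(attr(none, "exceed_fraction_diff"), 0)

  ex <- discrimination_experiment(m, crush_intensity(0.7, 1, gamma = 1),
                                  replicates = 40)
  expect_gte(attr(ex, "exceed_fraction_diff"), 0.95)
})

test_that("harsher crushing (smaller k_min) inflates the diff metric", {
  m <- true_column_model(seed = 77L)
  mean_metric <- function(k_min) {
    ex <- discrimination_experiment(m, crush_intensity(k_min, 1, gamma = 1),
                                    replicates = 30)
    mean(ex$crushed_diff_x100)
  }
  expect_gt(mean_metric(0.4), mean_metric(0.9))
})
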