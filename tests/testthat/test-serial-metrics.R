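# Aspect ratios and the two serial-variation metrics.

test_that("aspect_ratio matches printed per-vertebra values", {
  expect_equal(round(aspect_ratio(437, 638), 3), 0.685)   # giraffe C2
  expect_equal(round(aspect_ratio(134, 199), 3), 0.673)   # Diplodocus C14
  expect_equal(aspect_ratio(100, 100), 1.0)
  expect_error(aspect_ratio(0, 5), "positive")
  expect_error(aspect_ratio(5, -1), "positive")
})

test_that("series_ratios reproduces the printed V/H columns", {
  g <- series_ratios(load_fixture("giraffatitan_mbr2180"))
  expect_equal(round(g$vh, 3), c(1.205, 1.025, 1.043, 0.666, 0.697, 0.904))
  m <- series_ratios(load_fixture("monitor"))
  expect_equal(round(m$vh[1], 3), 0.608)
  same <- make_series(c(3, 7, 11), c(3, 7, 11))
  expect_equal(series_ratios(same)$vh, rep(1, 3))
})

test_that("consecutive differences and normalized ratios match printed pairs", {
  dip <- series_ratios(load_fixture("diplodocus_cm84"))
  d <- consecutive_diffs(dip)
  expect_equal(round(d[12], 3), 0.243)                    # C13 -> C14
  r <- consecutive_abs_ratios(dip)
  expect_equal(round(r[1], 3), 1.105)                     # C2 -> C3

  gir <- series_ratios(load_fixture("giraffe"))
  expect_equal(round(consecutive_diffs(gir)[1], 3), 0.086)

  gt <- series_ratios(load_fixture("giraffatitan_mbr2180"))
  expect_equal(round(consecutive_abs_ratios(gt)[3], 3), 1.568)  # C4 -> C5

  expect_equal(consecutive_diffs(c(0.8, 0.8, 0.8)), c(0, 0))
  expect_equal(consecutive_abs_ratios(c(0.37, 0.37)), 1.0)
  expect_true(all(consecutive_abs_ratios(runif(10, 0.2, 5)) >= 1))
  expect_error(consecutive_diffs(0.8), "insufficient")
  expect_error(consecutive_abs_ratios(1.2), "insufficient")
})

test_that("summaries reproduce every printed cell on all six fixtures", {
  printed <- read.csv(system.file("extdata", "table1_printed_summary.csv",
                                  package = "vertcol"),
                      stringsAsFactors = FALSE)
  series <- read_measurements(table1_path())
  for (i in seq_len(nrow(printed))) {
    sv <- serial_variation(series[[printed$specimen_id[i]]])
    for (cell in c("max_diff", "avg_diff", "metric_diff_x100",
                   "max_ratio", "avg_ratio", "metric_ratio_x100")) {
      if (identical(printed$erratum[i], cell)) next  # known source erratum
      expect_lte(abs(sv[[cell]] - printed[[cell]][i]), 0.005)
    }
  }
  # the flagged cell is internally inconsistent in the source: the computed
  # maximum equals the largest printed first ratio, not the printed max cell
  dip <- serial_variation(series[["CM 84"]])
  expect_equal(round(dip$max_ratio, 3), 1.361)
})

test_that("degenerate and invalid series are handled as specified", {
  two <- make_series(c(10, 20), c(12, 24))   # identical V/H
  sv <- serial_variation(two)
  expect_equal(sv$metric_diff_x100, 0)
  expect_equal(sv$metric_ratio_x100, 0)
  one <- make_series(5, 7)
  expect_error(serial_variation(one), "insufficient")
})

test_that("gap policy: span bridges missing vertebrae, strict names them", {
  gappy <- make_series(c(10, 11, 13), c(12, 12, 12),
                       serial_index = c(2L, 3L, 6L))
  expect_error(serial_variation(gappy, gap_policy = "strict"), "4, 5")
  sv <- serial_variation(gappy, gap_policy = "span")
  expect_length(sv$first_diffs, 2)
})

test_that("summaries are scale- and reversal-invariant", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    s <- random_series(n)
    sv <- serial_variation(s)

    scaled <- make_series(s$vertical * 3.7, s$horizontal * 3.7)
    sv_s <- serial_variation(scaled)
    for (f in c("max_diff", "avg_diff", "max_ratio", "avg_ratio"))
      expect_equal(sv_s[[f]], sv[[f]])

    rev_s <- make_series(rev(s$vertical), rev(s$horizontal))
    sv_r <- serial_variation(rev_s)
    for (f in c("max_diff", "avg_diff", "max_ratio", "avg_ratio"))
      expect_equal(sv_r[[f]], sv[[f]])
  }
})

test_that("both metrics are zero exactly when the V/H series is constant", {
  const <- make_series(c(5, 10, 20), c(4, 8, 16))
  svc <- serial_variation(const)
  expect_identical(svc$metric_diff_x100, 0)
  expect_identical(svc$metric_ratio_x100, 0)

  set.seed(7)
  for (rep in 1:20) {
    sv <- serial_variation(random_series(sample(2:30, 1)))
    constant <- length(unique(round(sv$vh, 12))) == 1L
    expect_equal(sv$metric_diff_x100 == 0, constant)
    expect_equal(sv$metric_ratio_x100 == 0, constant)
  }
})

test_that("production metrics agree with the naive-loop oracle to 1e-12", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    s <- random_series(n)
    got <- serial_variation(s)
    want <- naive_serial_summary(s$vertical, s$horizontal)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, info = f)
  }
})
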