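# Independent oracles and generators shared across the suite.

# Naive index-loop serial-variation summary, written directly from the metric
# definitions; deliberately kept independent of the package's vectorized path.
naive_serial_summary <- function(vertical, horizontal) {
  n <- length(vertical)
  vh <- numeric(n)
  for (i in seq_len(n)) vh[i] <- vertical[i] / horizontal[i]
  d <- numeric(n - 1)
  r <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    d[i] <- abs(vh[i] - vh[i + 1])
    rr <- vh[i] / vh[i + 1]
    if (rr < 1) rr <- 1 / rr
    r[i] <- rr
  }
  sd_ <- 0; sr_ <- 0; md <- -Inf; mr <- -Inf
  for (i in seq_len(n - 1)) {
    sd_ <- sd_ + d[i]; sr_ <- sr_ + r[i]
    if (d[i] > md) md <- d[i]
    if (r[i] > mr) mr <- r[i]
  }
  list(first_diffs = d, first_ratios = r, max_diff = md, max_ratio = mr,
       avg_diff = sd_ / (n - 1), avg_ratio = sr_ / (n - 1),
       metric_diff_x100 = sd_ / (n - 1) * 100,
       metric_ratio_x100 = (sr_ / (n - 1) - 1) * 100)
}

# Random valid column series with V/H ratios in [0.2, 5].
random_series <- function(n, id = "rnd") {
  vh <- runif(n, 0.2, 5)
  vertical <- runif(n, 10, 500)
  make_series(vertical, vertical / vh, id = id)
}

make_series <- function(vertical, horizontal, id = "test",
                        serial_index = seq_along(vertical) + 1L) {
  column_series(data.frame(element_label = paste0("C", serial_index),
                           serial_index = serial_index, region = "cervical",
                           facet = "posterior", convention = "midline",
                           vertical = vertical, horizontal = horizontal),
                specimen_id = id)
}

# Brute-force extents of the crushed ellipse by sampling boundary points and
# taking axis-aligned ranges; independent of the support-function formula.
sampled_crush_extents <- function(height, width, theta, k, gamma,
                                  n_points = 100000) {
  t <- seq(0, 2 * pi, length.out = n_points)
  pts <- rbind(width / 2 * cos(t), height / 2 * sin(t))
  th <- theta * pi / 180
  R <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  M <- R(th) %*% diag(c(k^(-gamma), k)) %*% R(-th)
  mapped <- M %*% pts
  c(height = diff(range(mapped[2, ])), width = diff(range(mapped[1, ])))
}

# Shoelace area of the mapped ellipse boundary.
sampled_crush_area <- function(height, width, theta, k, gamma,
                               n_points = 20000) {
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  pts <- rbind(width / 2 * cos(t), height / 2 * sin(t))
  th <- theta * pi / 180
  R <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  M <- R(th) %*% diag(c(k^(-gamma), k)) %*% R(-th)
  p <- M %*% pts
  x <- p[1, ]; y <- p[2, ]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

table1_path <- function() system.file("extdata", "table1.csv", package = "vertcol")
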