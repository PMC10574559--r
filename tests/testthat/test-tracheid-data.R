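test_that("measurement files round-trip and invalid records are rejected", {
  cells <- toy_cells()
  path <- tempfile(fileext = ".csv")
  write_measurements(cells, path)
  back <- read_measurements(path)
  expect_equal(back$D_um, cells$D_um)
  expect_equal(back$CWT_um, cells$CWT_um)
  expect_equal(back$rank, cells$rank)

  # schema error names the missing column
  bad <- cells; bad$CWT_um <- NULL
  path2 <- tempfile(fileext = ".csv")
  utils::write.table(bad, path2, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_measurements(path2), "CWT_um")

  # zero lumen: D = 10, CWT = 5 sits exactly on the forbidden boundary
  bad2 <- cells; bad2$D_um[3] <- 10; bad2$CWT_um[3] <- 5
  expect_error(validate_measurements(bad2), "CWT/D < 0.5")

  # ranks must be consecutive from 1 within each radial row
  bad3 <- cells; bad3$rank[2] <- 7L
  expect_error(validate_measurements(bad3), "consecutive")

  expect_error(read_measurements(tempfile()), "not found")
})

test_that("tracheidogram normalization conserves values and matches the overlap oracle", {
  expect_equal(normalize_row(c(10, 20, 30), 3), c(10, 20, 30))
  expect_equal(normalize_row(rep(25, 7), 4), rep(25, 4))

  # brute-force oracle: integrate the piecewise-constant trait profile over
  # each output cell interval
  oracle <- function(v, m) {
    n <- length(v)
    prof <- function(t) v[pmin(n, floor(t * n) + 1)]
    vapply(seq_len(m), function(k) {
      stats::integrate(function(t) prof(t), (k - 1) / m, k / m,
                       subdivisions = 1000, rel.tol = 1e-10)$value * m
    }, numeric(1))
  }
  for (case in list(list(v = c(10, 20, 30, 40), m = 2),
                    list(v = c(5, 9, 14), m = 5),
                    list(v = c(1, 10, 2, 8, 3), m = 7))) {
    expect_equal(normalize_row(case$v, case$m), oracle(case$v, case$m),
                 tolerance = 1e-6)
  }
  # values never leave the input range
  set.seed(4)
  v <- stats::runif(9, 10, 50)
  out <- normalize_row(v, 13)
  expect_true(all(out >= min(v) - 1e-12 & out <= max(v) + 1e-12))
  expect_error(normalize_row(numeric(0), 3), "empty")
})

test_that("row averaging is the positionwise mean", {
  t1 <- tracheidogram(c(10, 20), c(2, 3))
  t2 <- tracheidogram(c(30, 40), c(4, 5))
  expect_equal(average_rows(list(t1))$D, c(10, 20))
  avg <- average_rows(list(t1, t2))
  expect_equal(avg$D, c(20, 30))
  expect_equal(avg$CWT, c(3, 4))
  set.seed(5)
  rows <- lapply(1:5, function(i)
    tracheidogram(stats::runif(6, 20, 40), stats::runif(6, 2, 4)))
  avg5 <- average_rows(rows)
  j <- 3
  expect_equal(avg5$D[j], mean(vapply(rows, function(t) t$D[j], numeric(1))),
               tolerance = 1e-12)
  expect_error(average_rows(list(t1, tracheidogram(1:3 * 10, 1:3))),
               "same length")
})

test_that("ring normalization resamples each row to the mean cell count", {
  cells <- toy_cells()
  # two rows of 5 cells -> target 5, averaging the two rows
  avg <- normalize_dataset(cells)
  expect_equal(nrow(avg), 5L)
  expect_equal(avg$D_um, (cells$D_um[1:5] + cells$D_um[6:10]) / 2)
  # unequal rows: 4 and 5 cells -> target round(4.5) = 5 (half up)
  cells2 <- cells[-5, ]
  cells2$rank <- c(1:4, 1:5)
  avg2 <- normalize_dataset(cells2)
  expect_equal(nrow(avg2), 5L)
  expect_true(all(avg2$D_um >= min(cells2$D_um) &
                    avg2$D_um <= max(cells2$D_um)))
})

test_that("standardization yields unit means, 45-degree center and scale equivariance", {
  cells <- toy_cells()
  st <- standardize_cells(cells)
  expect_equal(mean(st$cells$D_i), 1, tolerance = 1e-9)
  expect_equal(mean(st$cells$CWT_i), 1, tolerance = 1e-9)
  # a cell sitting at both trait means has phi_i = arctan(1) = 45 degrees
  st2 <- standardize_cells(data.frame(D_um = c(10, 20, 30),
                                      CWT_um = c(1, 2, 3)))
  expect_equal(st2$cells$phi_i[2], 45, tolerance = 1e-12)
  # scale equivariance: multiplying all D by a constant leaves D_i unchanged
  scaled <- cells; scaled$D_um <- scaled$D_um * 3.7
  expect_equal(standardize_cells(scaled)$cells$D_i, st$cells$D_i,
               tolerance = 1e-12)
  # per-tree scope standardizes within trees
  cells$tree_id <- rep(1:2, each = 5)
  stt <- standardize_cells(cells, scope = "tree")
  expect_equal(as.numeric(tapply(stt$cells$D_i, stt$cells$tree_id, mean)),
               c(1, 1), tolerance = 1e-9)
  expect_error(standardize_cells(cells[0, ]), "empty")
})

test_that("slope angle is the arctangent in degrees and strictly monotone", {
  expect_equal(compute_slope_angle(1), 45)
  # independent oracle: integral of 1/(1+t^2)
  oracle_deg <- function(r)
    stats::integrate(function(t) 1 / (1 + t^2), 0, r,
                     rel.tol = 1e-12)$value * 180 / pi
  expect_equal(compute_slope_angle(0.167), oracle_deg(0.167),
               tolerance = 1e-9)
  expect_equal(round(compute_slope_angle(0.167), 2), 9.48)
  set.seed(6)
  r1 <- stats::runif(1000, 0.01, 3)
  r2 <- r1 + stats::runif(1000, 0.001, 1)
  expect_true(all(compute_slope_angle(r2) > compute_slope_angle(r1)))
  expect_error(compute_slope_angle(-0.1), "positive")
})

test_that("histograms use left-closed fixed-width bins and conserve counts", {
  h <- bin_histogram(c(0.05, 0.059), width = 0.01)
  expect_equal(length(h$counts), 1L)
  expect_equal(h$lower_edges, 0.05, tolerance = 1e-12)
  # an exact edge value belongs to the bin it labels
  h2 <- bin_histogram(c(0.05, 0.06), width = 0.01)
  expect_equal(h2$counts, c(1L, 1L))
  expect_equal(h2$lower_edges[2], 0.06, tolerance = 1e-12)
  set.seed(7)
  v <- stats::rnorm(500, 45, 10)
  h3 <- bin_histogram(v, width = 1.5)
  expect_equal(sum(h3$counts), 500L)
  expect_equal(sum(h3$densities), 1, tolerance = 1e-9)
  expect_equal(diff(h3$lower_edges),
               rep(1.5, length(h3$lower_edges) - 1), tolerance = 1e-9)
  expect_error(bin_histogram(numeric(0), 1), "non-empty")
})

test_that("dataset summary reports per-trait ranges and counts", {
  st <- standardize_cells(toy_cells())
  s <- st$summary
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  expect_equal(s$mean[s$trait == "D_i"], 1, tolerance = 1e-9)
  expect_equal(attr(s, "n_cells"), 10L)
  expect_equal(attr(s, "n_trees"), 1L)
})
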