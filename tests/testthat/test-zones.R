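test_that("Mork thresholds are the exact classical rationals", {
  expect_identical(mork_threshold("eq1"), 1 / 6)
  expect_identical(mork_threshold("eq2"), 1 / 4)
  # cells between the two forms flip class between the criteria
  k <- 0.2
  expect_true(k > mork_threshold("eq1") && k < mork_threshold("eq2"))
})

test_that("back-transformation inverts the angular standardization", {
  expect_equal(back_transform(45, 28.6, 2.6), 2.6 / 28.6, tolerance = 1e-12)
  # identity on ratios: angle of r, back-transformed with unit means, is r
  r <- c(0.3, 0.9, 1.7, 4)
  expect_equal(back_transform(compute_slope_angle(r), 1, 1), r,
               tolerance = 1e-12)
  expect_error(back_transform(95, 30, 3), "between 0 and 90")
  expect_error(back_transform(45, -1, 3), "positive")
})

test_that("transition-center thresholds reproduce the published species values", {
  ref <- list(picea_obovata = 0.105, pinus_sibirica = 0.136,
              pinus_sylvestris = 0.110)
  for (sp in names(ref)) {
    thr <- two_zone_threshold(species_profile(sp)$model)
    # published values are printed to 3 decimals: absolute comparison
    expect_lt(abs(thr$k_two_zone - ref[[sp]]), 0.002)
    expect_equal(thr$method, "tw-center")
  }
  # symmetric toy: tw center 45 degrees and equal means give k = cwt/d
  toy <- tracheid_mixture(0.4, 0.4,
                          ew = list(alpha = 3, beta = 3, a = 10, b = 40),
                          tw = list(mu = 45, alpha = 5, beta = 2),
                          lw = list(alpha = 3, beta = 3, a = 50, b = 80))
  expect_equal(two_zone_threshold(toy, 30, 3)$k_two_zone, 0.1,
               tolerance = 1e-12)
})

test_that("a vanishing transition amplitude falls back to the density intersection", {
  toy <- tracheid_mixture(0.5, 0.5 - 1e-8,
                          ew = list(alpha = 4, beta = 4, a = 10, b = 40),
                          tw = list(mu = 45, alpha = 5, beta = 2),
                          lw = list(alpha = 4, beta = 4, a = 50, b = 80))
  thr <- two_zone_threshold(toy, 30, 3)
  expect_equal(thr$method, "intersection")
  # symmetric geometry puts the intersection midway
  expect_equal(thr$phi_two_zone, 45, tolerance = 1e-6)
})

test_that("two-zone proportions split the transition mass in half", {
  m <- tracheid_mixture(0.492, 0.287,
                        ew = list(alpha = 3, beta = 3, a = 15, b = 45),
                        tw = list(mu = 49, alpha = 10, beta = 4),
                        lw = list(alpha = 3, beta = 3, a = 55, b = 80))
  p <- two_zone_proportions(m)
  expect_equal(as.numeric(p["EW"]), 100 * (0.492 + (1 - 0.492 - 0.287) / 2),
               tolerance = 1e-12)
  expect_equal(sum(p), 100)
})

test_that("three-zone boundaries satisfy their defining equations", {
  m <- species_profile("picea_obovata")$model
  b <- three_zone_boundaries(m, method = "intersection")
  expect_lt(b$phi_ew_tw, b$phi_tw_lw)
  # weighted densities are equal at the boundaries
  wew <- m$A_ew * dbeta4(b$phi_ew_tw, m$ew$alpha, m$ew$beta, m$ew$a, m$ew$b)
  wtw <- m$A_tw * dgnorm(b$phi_ew_tw, m$tw$mu, m$tw$alpha, m$tw$beta)
  expect_equal(wew, wtw, tolerance = 1e-9)
  # grid-scan oracle agrees with the bisection root
  grid <- seq(beta4_stats(m$ew$alpha, m$ew$beta, m$ew$a, m$ew$b)$mode,
              m$tw$mu, by = 0.001)
  d1 <- m$A_ew * dbeta4(grid, m$ew$alpha, m$ew$beta, m$ew$a, m$ew$b)
  d2 <- m$A_tw * dgnorm(grid, m$tw$mu, m$tw$alpha, m$tw$beta)
  expect_lt(abs(grid[which.min(abs(d1 - d2))] - b$phi_ew_tw), 0.002)

  pb <- three_zone_boundaries(m, method = "percentile")
  expect_equal(mixture_cdf(pb$phi_ew_tw, m), m$A_ew, tolerance = 1e-8)
  expect_equal(mixture_cdf(pb$phi_tw_lw, m), m$A_ew + m$A_tw,
               tolerance = 1e-8)

  # mirror-symmetric toy model has boundaries symmetric about the center
  toy <- tracheid_mixture(0.4, 0.4,
                          ew = list(alpha = 4, beta = 4, a = 15, b = 45),
                          tw = list(mu = 45, alpha = 6, beta = 4),
                          lw = list(alpha = 4, beta = 4, a = 45, b = 75))
  tb <- three_zone_boundaries(toy, method = "intersection")
  expect_equal(tb$phi_ew_tw + tb$phi_tw_lw, 90, tolerance = 1e-6)
})

test_that("ring classification honours boundaries and irreversibility", {
  thr <- structure(list(k_two_zone = NA_real_, phi_two_zone = NA_real_,
                        phi_ew_tw = 40, phi_tw_lw = 60,
                        method = "intersection"),
                   class = "zone_thresholds")
  phi <- c(20, 35, 45, 55, 65, 80)
  lab <- classify_ring(phi, thr)
  expect_equal(as.character(lab), c("EW", "EW", "TW", "TW", "LW", "LW"))
  # boundary values take the later zone
  expect_equal(as.character(classify_ring(c(40, 60), thr)), c("TW", "LW"))
  # a first cell beyond the latewood boundary is forced back to earlywood
  phi2 <- c(70, 30, 50, 70)
  expect_equal(as.character(classify_ring(phi2, thr))[1], "LW")
  lab2 <- classify_ring(phi2, thr, enforce_order = TRUE)
  expect_equal(as.character(lab2), c("EW", "EW", "TW", "LW"))
  # irreversibility: no earlywood after transition, none of either after LW
  set.seed(31)
  for (i in 1:20) {
    p <- stats::runif(30, 15, 85)
    lab3 <- as.integer(classify_ring(p, thr, enforce_order = TRUE))
    expect_true(all(diff(lab3) >= 0))
    expect_equal(lab3[1], 1L)
  }
  # two-zone thresholds classify EW/LW only
  thr2 <- two_zone_threshold(species_profile("picea_obovata")$model)
  lab4 <- classify_ring(c(30, 49, 60), thr2)
  expect_equal(as.character(lab4), c("EW", "LW", "LW"))
  # tracheidograms are indexed with the standardization means first
  tg <- tracheidogram(c(40, 30, 14), c(2, 3, 3.2))
  lab5 <- classify_ring(tg, thr, d_mean = 28.6, cwt_mean = 2.6)
  expect_equal(length(lab5), 3L)
  expect_error(classify_ring(numeric(0), thr), "empty")
})

test_that("zone fractions under percentile boundaries converge to the amplitudes", {
  m <- separated_model()
  b <- three_zone_boundaries(m, method = "percentile")
  ang <- sample_angles(m, 40000, seed = 32)
  lab <- classify_ring(ang$phi, b)
  frac <- as.numeric(table(lab) / length(lab))
  expect_equal(frac, c(m$A_ew, m$A_tw, m$A_lw), tolerance = 0.01)
})

test_that("zone reports back-transform each angle statistic like the published tables", {
  prof <- species_profile("pinus_sibirica")
  rep <- zone_report(prof$model)
  expect_equal(rep$zone, c("EW", "TW", "LW"))
  expect_equal(sum(rep$amplitude_pct), 100, tolerance = 0.05)
  tw <- rep[rep$zone == "TW", ]
  expect_equal(tw$mean_deg, tw$median_deg)
  expect_equal(tw$mean_deg, tw$mode_deg)
  expect_lt(abs(rep$ratio_mean[rep$zone == "LW"] - 0.270), 0.002)
  expect_lt(abs(rep$ratio_mean[rep$zone == "TW"] - 0.136), 0.002)
  p <- attr(rep, "two_zone")
  expect_equal(as.numeric(p["EW"]), 84.5, tolerance = 1e-9)
  expect_output(print(rep), "Two-zone")
})
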