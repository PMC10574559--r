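test_that("four-parameter beta density matches closed forms and log-gamma oracle", {
  # B(2,2) = 1/6 so the density at the midpoint of (0,1) is 6 * 0.25
  expect_equal(dbeta4(0.5, 2, 2, 0, 1), 1.5, tolerance = 1e-12)
  expect_identical(dbeta4(c(-1, 0, 1, 2), 2, 2, 0, 1)[c(1, 2, 4)],
                   c(0, 0, 0))
  # independent evaluation through the log-gamma representation
  alpha <- 2.5; beta <- 1.8; a <- 20; b <- 60; x <- 35
  logf <- (alpha - 1) * log(x - a) + (beta - 1) * log(b - x) -
    (lgamma(alpha) + lgamma(beta) - lgamma(alpha + beta)) -
    (alpha + beta - 1) * log(b - a)
  expect_equal(dbeta4(x, alpha, beta, a, b), exp(logf), tolerance = 1e-12)
  # normalization by quadrature for assorted shapes
  for (p in list(c(2, 2, 0, 1), c(2.5, 1.8, 20, 60), c(8, 3, 10, 85))) {
    q <- stats::integrate(function(x) dbeta4(x, p[1], p[2], p[3], p[4]),
                          p[3], p[4], rel.tol = 1e-10)$value
    expect_equal(q, 1, tolerance = 1e-8)
  }
  expect_error(dbeta4(0.5, 0.9, 2, 0, 1), "> 1")
  expect_error(dbeta4(0.5, 2, 2, 1, 0), "a < b")
})

test_that("beta statistics agree with symmetry, worked values and quadrature", {
  s <- beta4_stats(2, 2, 0, 1)
  expect_equal(s$mean, 0.5)
  expect_equal(s$mode, 0.5)
  expect_equal(s$median, 0.5)
  expect_equal(s$sigma, sqrt(4 / (16 * 5)), tolerance = 1e-12)
  s <- beta4_stats(3, 2, 10, 20)
  expect_equal(s$mean, 16)
  expect_equal(s$mode, 10 + 10 * 2 / 3, tolerance = 1e-12)
  # quadrature oracle across a parameter grid
  for (alpha in c(1.5, 3, 7)) for (beta in c(2, 5)) {
    a <- 10; b <- 70
    st <- beta4_stats(alpha, beta, a, b)
    qm <- quad_moments(function(x) dbeta4(x, alpha, beta, a, b), a, b)
    expect_equal(st$mean, qm$mean, tolerance = 1e-6)
    expect_equal(st$sigma, qm$sigma, tolerance = 1e-6)
    # exact median is the cdf midpoint; printed approximation is close
    expect_equal(pbeta4(st$median_exact, alpha, beta, a, b), 0.5,
                 tolerance = 1e-9)
    expect_lt(abs(st$median - st$median_exact), 0.05 * (b - a))
    if (alpha != beta) {
      # mean and mode bracket the median for skewed shapes
      expect_true((st$mean - st$median) * (st$median - st$mode) > 0)
    }
  }
})

test_that("generalized normal reduces to the normal at shape 2 and matches quadrature", {
  set.seed(11)
  x <- stats::runif(100, -8, 8)
  expect_equal(dgnorm(x, 1, 2, 2), stats::dnorm(x, 1, 2 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(dgnorm(0, 0, 1, 2), 1 / sqrt(pi), tolerance = 1e-14)
  expect_equal(gnorm_stats(0, 1, 2)$sigma, 1 / sqrt(2), tolerance = 1e-12)
  # flat-topped member: normalization and near-uniform concentration
  q <- stats::integrate(function(x) dgnorm(x, 50, 10, 8), 0, 100,
                        rel.tol = 1e-10)$value
  expect_equal(q, 1, tolerance = 1e-8)
  expect_lt(dgnorm(50 + 15, 50, 10, 8), 1e-5)
  # sigma formula vs quadrature second moment across shapes; the quadrature
  # window adapts to the shape so the near-uniform members are not missed
  for (beta in c(2, 3, 8, 50)) {
    st <- gnorm_stats(5, 3, beta)
    half <- max(2 * 3, 10 * st$sigma)
    qm <- quad_moments(function(x) dgnorm(x, 5, 3, beta), 5 - half, 5 + half)
    expect_equal(st$sigma, qm$sigma, tolerance = 1e-6)
  }
  # uniform limit on (mu - alpha, mu + alpha)
  expect_lt(abs(gnorm_stats(0, 1, 200)$sigma - 1 / sqrt(3)), 1e-2)
  expect_error(dgnorm(0, 0, 1, 1.5), ">= 2")
})

test_that("gnorm cdf, quantile and sampler are mutually consistent", {
  mu <- 49; al <- 12; be <- 4
  expect_equal(pgnorm(mu, mu, al, be), 0.5)
  x <- seq(20, 80, by = 2.5)
  # cdf by quadrature
  for (xx in c(35, 49, 60)) {
    q <- stats::integrate(function(t) dgnorm(t, mu, al, be), -200, xx,
                          rel.tol = 1e-10)$value
    expect_equal(pgnorm(xx, mu, al, be), q, tolerance = 1e-8)
  }
  p <- c(0.05, 0.3, 0.5, 0.9)
  expect_equal(pgnorm(qgnorm(p, mu, al, be), mu, al, be), p,
               tolerance = 1e-10)
  set.seed(2)
  s <- rgnorm(40000, mu, al, be)
  expect_equal(mean(s), mu, tolerance = 0.2)
  expect_equal(sd(s), gnorm_stats(mu, al, be)$sigma, tolerance = 0.1)
})

test_that("mixture density and cdf behave as a convex combination", {
  m <- separated_model()
  q <- stats::integrate(function(x) mixture_pdf(x, m), 0, 90,
                        rel.tol = 1e-9)$value
  expect_equal(q, 1, tolerance = 1e-6)
  expect_equal(mixture_cdf(-10, m), 0, tolerance = 1e-12)
  expect_equal(mixture_cdf(120, m), 1, tolerance = 1e-12)
  grid <- seq(5, 85, by = 0.5)
  expect_true(all(diff(mixture_cdf(grid, m)) >= 0))
  # cdf consistent with pdf by differentiation
  h <- 1e-5
  mid <- c(20, 45, 70)
  expect_equal((mixture_cdf(mid + h, m) - mixture_cdf(mid - h, m)) / (2 * h),
               mixture_pdf(mid, m), tolerance = 1e-5)
  # quantile inverts the cdf
  p <- c(0.1, 0.5, 0.9)
  expect_equal(mixture_cdf(mixture_quantile(p, m), m), p, tolerance = 1e-6)
  # a dominant earlywood weight degenerates to the EW beta
  md <- tracheid_mixture(A_ew = 1 - 2e-6, A_lw = 1e-6,
                         ew = m$ew, tw = m$tw, lw = m$lw)
  x <- seq(10, 34, by = 1)
  expect_equal(mixture_pdf(x, md),
               dbeta4(x, m$ew$alpha, m$ew$beta, m$ew$a, m$ew$b),
               tolerance = 1e-4)
})

test_that("published spruce mixture is bimodal with an interior minimum", {
  m <- species_profile("picea_obovata")$model
  grid <- seq(20, 80, by = 0.1)
  f <- mixture_pdf(grid, m)
  maxima <- which(diff(sign(diff(f))) == -2) + 1
  expect_gte(length(maxima), 2)
  between <- grid > 30.57 & grid < 49
  expect_lt(min(f[between]), f[which.min(abs(grid - 30.57))])
})

test_that("component parameters can be recovered from their printed statistics", {
  p0 <- list(alpha = 3.2, beta = 7.5, a = 18, b = 70)
  s <- beta4_stats(p0$alpha, p0$beta, p0$a, p0$b)
  p1 <- beta4_from_stats(s$mean, s$median, s$mode, s$sigma)
  s1 <- beta4_stats(p1$alpha, p1$beta, p1$a, p1$b)
  expect_equal(s1$mean, s$mean, tolerance = 1e-3)
  expect_equal(s1$mode, s$mode, tolerance = 1e-3)
  expect_equal(s1$sigma, s$sigma, tolerance = 1e-3)
  # support constraint selects a range-consistent member
  p2 <- beta4_from_stats(30.57, 29.98, 28.70, 4.80,
                         support_min = 20, support_max = 77)
  expect_gte(p2$a, 20 - 1e-6)
  expect_lte(p2$b, 77 + 1e-6)
  s2 <- beta4_stats(p2$alpha, p2$beta, p2$a, p2$b)
  expect_equal(s2$mean, 30.57, tolerance = 0.02)
  expect_equal(s2$sigma, 4.80, tolerance = 0.02)
})

test_that("model serialization round-trips through JSON", {
  m <- species_profile("pinus_sylvestris")$model
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(m2$label, m$label)
  expect_equal(m2$d_mean, m$d_mean)
})
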