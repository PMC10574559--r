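# shared fixtures: models built in code, no stored data

# a well-separated three-component mixture; strongly identified, used to
# exercise the fitting machinery where the statistics allow tight recovery
separated_model <- function() {
  tracheid_mixture(
    A_ew = 0.50, A_lw = 0.30,
    ew = list(alpha = 5, beta = 5, a = 8, b = 36),
    tw = list(mu = 45, alpha = 5.5, beta = 4),
    lw = list(alpha = 5, beta = 5, a = 54, b = 82))
}

# small synthetic measurement table with consecutive ranks
toy_cells <- function() {
  data.frame(
    tree_id = rep(1L, 10),
    year = rep(2000L, 10),
    row_id = rep(1:2, each = 5),
    rank = rep(1:5, 2),
    D_um = c(40, 38, 30, 20, 12, 41, 37, 29, 21, 13),
    CWT_um = c(2.0, 2.1, 2.5, 3.0, 3.4, 2.1, 2.0, 2.6, 2.9, 3.5))
}

# quadrature moments of a density on (lo, hi): independent oracle for the
# closed-form component statistics
quad_moments <- function(f, lo, hi) {
  m0 <- stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(x) x * f(x), lo, hi,
                         rel.tol = 1e-10)$value / m0
  v <- stats::integrate(function(x) (x - m1)^2 * f(x), lo, hi,
                        rel.tol = 1e-10)$value / m0
  list(total = m0, mean = m1, sigma = sqrt(v))
}
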