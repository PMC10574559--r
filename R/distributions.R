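#' Four-parameter beta distribution
#'
#' Density, distribution function, quantile function, random generation and
#' closed-form summary statistics for the beta distribution with shape
#' parameters \code{alpha}, \code{beta} and support \code{(a, b)}:
#' \deqn{f(x) = \frac{(x-a)^{\alpha-1} (b-x)^{\beta-1}}
#'   {B(\alpha,\beta)\,(b-a)^{\alpha+\beta-1}}, \quad a < x < b.}
#' Both shapes must exceed 1 so the density is unimodal; earlywood and
#' latewood slope-angle components are modelled with this family because the
#' angle is bounded and may be skewed.
#'
#' @param x,q vector of quantiles (degrees in the zonation context).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param alpha,beta shape parameters, both > 1.
#' @param a,b support bounds, \code{a < b}.
#' @return \code{dbeta4} the density per unit of \code{x}; \code{pbeta4} the
#'   cdf; \code{qbeta4} quantiles; \code{rbeta4} random draws.
#' @seealso [beta4_stats()] for the closed-form mean, mode, median and
#'   standard deviation; [dgnorm()] for the transition-wood component.
#' @examples
#' dbeta4(0.5, 2, 2, 0, 1)              # 1.5
#' beta4_stats(3, 2, 10, 20)$mean       # 16
#' @export
dbeta4 <- function(x, alpha, beta, a, b) {
  check_beta4(alpha, beta, a, b)
  out <- numeric(length(x))
  inside <- x > a & x < b
  out[inside] <- stats::dbeta((x[inside] - a) / (b - a), alpha, beta) / (b - a)
  out
}

#' @rdname dbeta4
#' @export
pbeta4 <- function(q, alpha, beta, a, b) {
  check_beta4(alpha, beta, a, b)
  stats::pbeta(pmin(pmax((q - a) / (b - a), 0), 1), alpha, beta)
}

#' @rdname dbeta4
#' @export
qbeta4 <- function(p, alpha, beta, a, b) {
  check_beta4(alpha, beta, a, b)
  a + (b - a) * stats::qbeta(p, alpha, beta)
}

#' @rdname dbeta4
#' @export
rbeta4 <- function(n, alpha, beta, a, b) {
  check_beta4(alpha, beta, a, b)
  a + (b - a) * stats::rbeta(n, alpha, beta)
}

check_beta4 <- function(alpha, beta, a, b) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 1 || beta <= 1)
    stop("beta shape parameters must be finite and > 1 (unimodal component)",
         call. = FALSE)
  if (!is.finite(a) || !is.finite(b) || a >= b)
    stop("beta support must satisfy a < b", call. = FALSE)
  invisible(TRUE)
}

#' Summary statistics of the four-parameter beta distribution
#'
#' Closed-form mean, mode, approximate median and standard deviation:
#' mean \eqn{= a + (b-a)\alpha/(\alpha+\beta)}, mode
#' \eqn{= a + (b-a)(\alpha-1)/(\alpha+\beta-2)}, median
#' \eqn{\approx a + (b-a)(\alpha-1/3)/(\alpha+\beta-2/3)} and
#' \eqn{\sigma = (b-a)\sqrt{\alpha\beta/((\alpha+\beta)^2(\alpha+\beta+1))}}.
#' The median approximation is the one conventionally printed in zone
#' reports; \code{median_exact} (root of cdf = 1/2) is returned alongside.
#'
#' @inheritParams dbeta4
#' @return list with \code{mean}, \code{mode}, \code{median} (approximation),
#'   \code{median_exact} and \code{sigma}.
#' @export
beta4_stats <- function(alpha, beta, a, b) {
  check_beta4(alpha, beta, a, b)
  w <- b - a
  list(
    mean         = a + w * alpha / (alpha + beta),
    mode         = a + w * (alpha - 1) / (alpha + beta - 2),
    median       = a + w * (alpha - 1 / 3) / (alpha + beta - 2 / 3),
    median_exact = a + w * stats::qbeta(0.5, alpha, beta),
    sigma        = w * sqrt(alpha * beta /
                              ((alpha + beta)^2 * (alpha + beta + 1)))
  )
}

#' Recover four-parameter beta parameters from printed zone statistics
#'
#' Numerically inverts the four closed-form statistics of [beta4_stats()]
#' (mean, approximate median, mode, sigma) to the parameters
#' \code{(alpha, beta, a, b)}. Used to rebuild full component parameters from
#' published per-zone summary tables, which report statistics rather than the
#' parameters themselves.
#'
#' @param mean,median,mode,sigma target statistics (same units, e.g. degrees).
#' @param support_min,support_max optional bounds the support \code{(a, b)}
#'   must respect, e.g. the observed range of the variable. The inversion of
#'   four statistics is severely ill-conditioned in \code{(beta, b)} for
#'   skewed components — a long, thin tail changes the statistics by less
#'   than their printed rounding — so constraining the support to the
#'   observed data range selects the compact member of that near-equivalent
#'   family.
#' @param tol maximum acceptable root-mean-square mismatch between the target
#'   statistics and those of the recovered parameters.
#' @return list with \code{alpha}, \code{beta}, \code{a}, \code{b}.
#' @export
beta4_from_stats <- function(mean, median, mode, sigma,
                             support_min = -Inf, support_max = Inf,
                             tol = 0.05) {
  stopifnot(is.finite(mean), is.finite(median), is.finite(mode),
            is.finite(sigma), sigma > 0)
  target <- c(mean, median, mode, sigma)
  obj <- function(z) {
    alpha <- 1 + exp(z[1]); beta <- 1 + exp(z[2])
    a <- z[3]; b <- a + exp(z[4])
    if (!is.finite(b)) return(1e10)
    s <- try(beta4_stats(alpha, beta, a, b), silent = TRUE)
    if (inherits(s, "try-error")) return(1e10)
    sum((c(s$mean, s$median, s$mode, s$sigma) - target)^2) +
      1000 * (max(0, support_min - a)^2 + max(0, b - support_max)^2)
  }
  best <- NULL
  for (k in c(1, 2, 4, 8)) {
    # start from a symmetric bell (alpha = beta = k) reproducing sigma
    w0 <- sigma / sqrt(k^2 / ((2 * k)^2 * (2 * k + 1)))
    z0 <- c(log(k), log(k), mean - w0 / 2, log(w0))
    fit <- stats::optim(z0, obj, method = "Nelder-Mead",
                        control = list(maxit = 10000, reltol = 1e-13))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 10000, reltol = 1e-13))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (sqrt(best$value / 4) > tol)
    stop("could not recover beta parameters matching the requested statistics",
         call. = FALSE)
  z <- best$par
  list(alpha = 1 + exp(z[1]), beta = 1 + exp(z[2]),
       a = z[3], b = z[3] + exp(z[4]))
}

#' Generalized normal (exponential-power) distribution
#'
#' Density, distribution function, quantile function, random generation and
#' summary statistics for the symmetric generalized normal distribution
#' \deqn{f(x) = \frac{\beta}{2\alpha\Gamma(1/\beta)}
#'   e^{-(|x-\mu|/\alpha)^\beta}.}
#' With shape \eqn{\beta = 2} this is the normal distribution with standard
#' deviation \eqn{\alpha/\sqrt{2}}; as \eqn{\beta \to \infty} it tends to the
#' uniform distribution on \eqn{(\mu-\alpha, \mu+\alpha)}. Transition-wood
#' slope angles are modelled with shape \eqn{\ge 2}: a gradual, near-uniform
#' drift of cell proportions blurred by normally distributed noise.
#'
#' The cdf and quantile function use the regularized incomplete gamma
#' function; random draws use the gamma transform
#' \eqn{X = \mu + s\,\alpha G^{1/\beta}}, \eqn{G \sim} Gamma\eqn{(1/\beta)},
#' \eqn{s = \pm 1} equiprobably.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu center (mean = median = mode).
#' @param alpha scale parameter, > 0.
#' @param beta shape parameter, >= 2 in the zonation context.
#' @return \code{dgnorm} density; \code{pgnorm} cdf; \code{qgnorm} quantiles;
#'   \code{rgnorm} draws; \code{gnorm_stats} a list with \code{mean},
#'   \code{median}, \code{mode} and \code{sigma}
#'   \eqn{= \alpha\sqrt{\Gamma(3/\beta)/\Gamma(1/\beta)}}.
#' @examples
#' dgnorm(0, 0, 1, 2)           # 1/sqrt(pi)
#' gnorm_stats(0, 1, 2)$sigma   # 1/sqrt(2)
#' @export
dgnorm <- function(x, mu, alpha, beta) {
  check_gnorm(mu, alpha, beta)
  beta / (2 * alpha * gamma(1 / beta)) * exp(-(abs(x - mu) / alpha)^beta)
}

#' @rdname dgnorm
#' @export
pgnorm <- function(q, mu, alpha, beta) {
  check_gnorm(mu, alpha, beta)
  r <- abs(q - mu) / alpha
  z <- r^beta
  p <- stats::pgamma(z, shape = 1 / beta)
  # large shapes make z underflow for r < 1; use the small-z expansion
  # P(s, z) ~ z^s / Gamma(1 + s) = exp(log(r) - lgamma(1 + 1/beta)),
  # which recovers the uniform limit on (mu - alpha, mu + alpha)
  bad <- z == 0 & r > 0
  if (any(bad))
    p[bad] <- exp(log(r[bad]) - lgamma(1 + 1 / beta))
  0.5 + sign(q - mu) * 0.5 * p
}

#' @rdname dgnorm
#' @export
qgnorm <- function(p, mu, alpha, beta) {
  check_gnorm(mu, alpha, beta)
  s <- sign(p - 0.5)
  u <- abs(2 * p - 1)
  g <- stats::qgamma(u, shape = 1 / beta)
  r <- g^(1 / beta)
  # large shapes make the gamma quantile underflow; invert the small-z
  # expansion of the cdf instead: r = u * Gamma(1 + 1/beta)
  bad <- g == 0 & u > 0
  if (any(bad))
    r[bad] <- u[bad] * gamma(1 + 1 / beta)
  mu + s * alpha * r
}

#' @rdname dgnorm
#' @export
rgnorm <- function(n, mu, alpha, beta) {
  check_gnorm(mu, alpha, beta)
  s <- sample(c(-1, 1), n, replace = TRUE)
  r <- stats::rgamma(n, shape = 1 / beta)^(1 / beta)
  # large shapes underflow the gamma draw; in that limit r is uniform(0, 1)
  bad <- r == 0
  if (any(bad))
    r[bad] <- stats::runif(sum(bad))
  mu + s * alpha * r
}

#' @rdname dgnorm
#' @export
gnorm_stats <- function(mu, alpha, beta) {
  check_gnorm(mu, alpha, beta)
  list(mean = mu, median = mu, mode = mu,
       sigma = alpha * sqrt(gamma(3 / beta) / gamma(1 / beta)))
}

check_gnorm <- function(mu, alpha, beta) {
  if (!is.finite(mu)) stop("gnorm center mu must be finite", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0)
    stop("gnorm scale alpha must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta < 2)
    stop("gnorm shape beta must be >= 2 (normal limit or flatter)",
         call. = FALSE)
  invisible(TRUE)
}
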