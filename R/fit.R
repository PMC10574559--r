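# Parameter transforms: the 13 free parameters are optimized on an
# unconstrained scale. Amplitudes use the additive log-ratio relative to the
# TW residual; beta shapes use log(shape - 1) (unimodality), supports are
# (a, log(b - a)) (ordering), the TW shape is 2 + exp(z) (normal limit).
model_to_vec <- function(m) {
  c(log(m$A_ew / m$A_tw), log(m$A_lw / m$A_tw),
    log(m$ew$alpha - 1), log(m$ew$beta - 1), m$ew$a, log(m$ew$b - m$ew$a),
    m$tw$mu, log(m$tw$alpha), log(max(m$tw$beta - 2, 1e-8)),
    log(m$lw$alpha - 1), log(m$lw$beta - 1), m$lw$a, log(m$lw$b - m$lw$a))
}

vec_to_model <- function(z, template = NULL) {
  e1 <- exp(z[1]); e2 <- exp(z[2])
  den <- 1 + e1 + e2
  tracheid_mixture(
    A_ew = e1 / den, A_lw = e2 / den,
    ew = list(alpha = 1 + exp(z[3]), beta = 1 + exp(z[4]),
              a = z[5], b = z[5] + exp(z[6])),
    tw = list(mu = z[7], alpha = exp(z[8]), beta = 2 + exp(z[9])),
    lw = list(alpha = 1 + exp(z[10]), beta = 1 + exp(z[11]),
              a = z[12], b = z[12] + exp(z[13])),
    label = template$label, d_mean = template$d_mean,
    cwt_mean = template$cwt_mean)
}

# soft penalty keeping beta supports near the physical (0, 90) degree range
support_penalty <- function(m) {
  100 * (max(0, -m$ew$a)^2 + max(0, m$ew$b - 90)^2 +
           max(0, -m$lw$a)^2 + max(0, m$lw$b - 90)^2)
}

# solve a unimodal beta on (lo, hi) with prescribed mode and standard
# deviation; parameterized by total concentration t = alpha + beta
beta_from_mode_sd <- function(mode, sd, lo, hi) {
  u <- (mode - lo) / (hi - lo)
  u <- min(max(u, 0.02), 0.98)
  shapes <- function(t) c(1 + u * (t - 2), 1 + (1 - u) * (t - 2))
  sd_of <- function(t) {
    s <- shapes(t)
    (hi - lo) * sqrt(s[1] * s[2] / ((s[1] + s[2])^2 * (s[1] + s[2] + 1)))
  }
  target <- min(max(sd, sd_of(1e5) * 1.001), sd_of(2.2) * 0.999)
  t <- stats::uniroot(function(t) sd_of(t) - target,
                      lower = 2.2, upper = 1e5, tol = 1e-10)$root
  s <- shapes(t)
  list(alpha = s[1], beta = s[2], a = lo, b = hi)
}

#' Heuristic starting values from a slope-angle histogram
#'
#' Deterministic initialization of the 13-parameter mixture from a binned
#' histogram of indexed slope angles: the two highest well-separated local
#' maxima of the (lightly smoothed) bin densities seed the earlywood and
#' latewood modes; each beta component gets support
#' \code{[max(0, mode - 6 s), min(90, mode + 6 s)]} with shapes solved so the
#' component mode and spread match the histogram on that side of the
#' between-peak density minimum. The transition-wood component starts midway
#' between the peaks with shape 4. Amplitudes split the histogram mass at
#' the minimum, reserving a fifth of the mass for transition wood.
#'
#' A unimodal histogram (no second separated peak) falls back to a
#' quantile-based split (peaks at the 25th and 75th percentile bins) with a
#' warning.
#'
#' @param hist a [bin_histogram()] of indexed slope angles with >= 3 bins.
#' @param min_separation minimum peak separation in degrees (default 9).
#' @return a [tracheid_mixture()] starting model.
#' @export
initialize_parameters <- function(hist, min_separation = 9) {
  pr <- peak_regions(hist, min_separation)
  assemble_init(pr, c(5, 5), c(5, 5))
}

# locate the EW and LW peaks of a slope-angle histogram, the density minimum
# between them, and provisional zone regions (halfway between each peak and
# the minimum); region masses approximate amplitudes, region moments seed
# the component shapes
peak_regions <- function(hist, min_separation = 9) {
  stopifnot(inherits(hist, "binned_histogram"))
  d <- hist$densities
  nb <- length(d)
  if (nb < 3) stop("need at least 3 bins to initialize", call. = FALSE)
  centers <- hist$lower_edges + hist$width / 2
  s <- d
  s[2:(nb - 1)] <- (d[1:(nb - 2)] + d[2:(nb - 1)] + d[3:nb]) / 3
  is_peak <- c(FALSE, s[2:(nb - 1)] > s[1:(nb - 2)] &
                 s[2:(nb - 1)] >= s[3:nb], FALSE)
  peaks <- which(is_peak)[order(s[is_peak], decreasing = TRUE)]
  p1 <- p2 <- NA_integer_
  if (length(peaks)) {
    p1 <- peaks[1]
    far <- peaks[abs(centers[peaks] - centers[p1]) >= min_separation]
    if (length(far)) p2 <- far[1]
  }
  if (is.na(p1) || is.na(p2)) {
    warning("histogram not clearly bimodal; using quantile-based split")
    cum <- cumsum(d)
    p1 <- which(cum >= 0.25)[1]
    p2 <- which(cum >= 0.75)[1]
    if (p2 <= p1) p2 <- min(nb, p1 + 1L)
  }
  ew_i <- min(p1, p2); lw_i <- max(p1, p2)
  ew_peak <- centers[ew_i]; lw_peak <- centers[lw_i]
  split <- ew_i + which.min(s[ew_i:lw_i]) - 1L
  b1 <- (ew_peak + centers[split]) / 2
  b2 <- (centers[split] + lw_peak) / 2
  region_moments <- function(keep) {
    w <- d[keep] / sum(d[keep])
    m <- sum(w * centers[keep])
    list(mean = m,
         sd = max(sqrt(sum(w * (centers[keep] - m)^2)), hist$width / 2))
  }
  list(ew_peak = ew_peak, lw_peak = lw_peak,
       ewm = region_moments(centers < b1),
       lwm = region_moments(centers > b2),
       A_ew = min(max(sum(d[centers < b1]), 0.05), 0.9),
       A_lw_raw = sum(d[centers > b2]),
       width = hist$width)
}

# build a starting model from peak regions; k_ew and k_lw give the support
# extent (in region sds) below and above each region mean, so skewed
# variants (long EW right tail, long LW left tail) can be generated
assemble_init <- function(pr, k_ew, k_lw) {
  moment_beta <- function(m, s, kl, kr) {
    lo <- max(1e-3, m - kl * s); hi <- min(90 - 1e-3, m + kr * s)
    u <- (m - lo) / (hi - lo)
    t <- max(u * (1 - u) * (hi - lo)^2 / s^2 - 1, 2.2)
    list(alpha = max(u * t, 1.05), beta = max((1 - u) * t, 1.05),
         a = lo, b = hi)
  }
  tw_sigma <- max((pr$lw_peak - pr$ew_peak) / 6, pr$width)
  A_ew <- pr$A_ew
  A_lw <- min(max(pr$A_lw_raw, 0.05), 0.95 - A_ew)
  tracheid_mixture(
    A_ew = A_ew, A_lw = A_lw,
    ew = moment_beta(pr$ewm$mean, pr$ewm$sd, k_ew[1], k_ew[2]),
    tw = list(mu = (pr$ew_peak + pr$lw_peak) / 2,
              alpha = tw_sigma / sqrt(gamma(3 / 4) / gamma(1 / 4)),
              beta = 4),
    lw = moment_beta(pr$lwm$mean, pr$lwm$sd, k_lw[1], k_lw[2]))
}

# deterministic portfolio of starting models spanning component skewness:
# the intra-seasonal drift makes the earlywood component tail toward the
# transition (right) and the latewood component tail away from it, but the
# degree is unknown a priori, so both neutral and strongly skewed starts
# are screened
init_candidates <- function(hist, min_separation = 9) {
  pr <- peak_regions(hist, min_separation)
  grids_ew <- list(c(5, 5), c(3, 8), c(2.5, 12))
  grids_lw <- list(c(5, 5), c(3, 2), c(8, 3))
  out <- list()
  for (ke in grids_ew) for (kl in grids_lw)
    out[[length(out) + 1L]] <- assemble_init(pr, ke, kl)
  out
}

fit_control <- function(control = list()) {
  ctl <- list(maxit = 10000, reltol = 1e-8)
  ctl[names(control)] <- control
  ctl
}

new_tzm_fit <- function(model, method, converged, trace, logLik = NA_real_,
                        objective = NA_real_, chi2 = NULL, n = NA_integer_,
                        phi = NULL, hist = NULL, init = NULL) {
  structure(list(model = model, method = method, converged = converged,
                 trace = trace, logLik = logLik, objective = objective,
                 chi2 = chi2$chi2, dof = chi2$dof, p_value = chi2$p_value,
                 n_bins_final = chi2$n_bins_final, chi2_detail = chi2,
                 n = n, phi = phi, hist = hist, init = init),
            class = "tzm_fit")
}

#' Binned least-squares stage of the mixture fit
#'
#' Minimizes the sum of squared differences between observed bin densities
#' (probability per bin) and model bin probabilities (cdf differences) over
#' the 13 transformed parameters, by Nelder-Mead simplex search. The
#' conventional bin width for indexed slope angles is 1.5 degrees.
#'
#' @param hist a [bin_histogram()] of indexed slope angles.
#' @param init starting [tracheid_mixture()] (e.g. from
#'   [initialize_parameters()]).
#' @param control list overriding \code{maxit} (default 10000) and
#'   \code{reltol} (default 1e-8) of [stats::optim()].
#' @return a \code{"tzm_fit"} object (no chi-squared slot; see
#'   [chi_squared_test()]).
#' @export
fit_least_squares <- function(hist, init, control = list()) {
  stopifnot(inherits(hist, "binned_histogram"),
            inherits(init, "tracheid_mixture"))
  ctl <- fit_control(control)
  edges <- c(hist$lower_edges, hist$lower_edges[length(hist$lower_edges)] +
               hist$width)
  obj <- function(z) {
    m <- try(vec_to_model(z, init), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    p <- diff(mixture_cdf(edges, m))
    sum((hist$densities - p)^2) + support_penalty(m)
  }
  z0 <- model_to_vec(init)
  opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  new_tzm_fit(vec_to_model(opt$par, init), method = "ls",
              converged = opt$convergence == 0,
              trace = data.frame(stage = "ls", evaluations = opt$counts[1],
                                 start = obj(z0), objective = opt$value),
              objective = opt$value, n = hist$n, hist = hist, init = init)
}

#' Maximum-likelihood stage of the mixture fit
#'
#' Maximizes the log-likelihood of raw indexed slope angles under the
#' mixture, by Nelder-Mead on the transformed parameters, typically warm
#' started from the binned least-squares solution. Before optimization the
#' beta supports are widened to cover the data range if any observation
#' carries (numerically) zero total density — observations outside both beta
#' supports otherwise contribute through the transition-wood component,
#' which has full support.
#'
#' @param phi numeric vector of indexed slope angles (degrees).
#' @param init starting [tracheid_mixture()].
#' @inheritParams fit_least_squares
#' @return a \code{"tzm_fit"} object with \code{logLik}.
#' @export
fit_mle <- function(phi, init, control = list()) {
  stopifnot(is.numeric(phi), length(phi) >= 1,
            inherits(init, "tracheid_mixture"))
  if (length(phi) < 100)
    warning("fewer than 100 observations; mixture MLE may be unstable")
  ctl <- fit_control(control)
  if (any(mixture_pdf(phi, init) <= 0)) {
    init$ew$a <- min(init$ew$a, min(phi) - 0.5)
    init$lw$b <- max(init$lw$b, max(phi) + 0.5)
    bad <- which(mixture_pdf(phi, init) <= 0)
    if (length(bad))
      stop("observation with zero mixture density after support expansion: ",
           phi[bad[1]], call. = FALSE)
  }
  obj <- function(z) {
    m <- try(vec_to_model(z, init), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    f <- mixture_pdf(phi, m)
    if (any(f <= 0) || any(!is.finite(f))) return(1e10)
    -sum(log(f)) + length(phi) * support_penalty(m)
  }
  z0 <- model_to_vec(init)
  opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  new_tzm_fit(vec_to_model(opt$par, init), method = "mle",
              converged = opt$convergence == 0,
              trace = data.frame(stage = "mle", evaluations = opt$counts[1],
                                 start = obj(z0), objective = opt$value),
              logLik = -opt$value, n = length(phi), phi = phi, init = init)
}

#' Pearson chi-squared goodness of fit on merged bins
#'
#' Divides the observed angle range into \code{n_bins} equal-width bins,
#' merges bins with fewer than \code{min_count} observations inward from the
#' two outskirts of the distribution, and compares observed counts with
#' expected counts from the mixture cdf (outermost bins extended over the
#' full support). Degrees of freedom are \code{m - n_params - 1} with
#' \code{m} the final number of bins and \code{n_params = 13} estimated
#' parameters; the model is adequate when the significance level exceeds
#' 0.05.
#'
#' @param phi numeric vector of indexed slope angles (degrees).
#' @param model a fitted [tracheid_mixture()].
#' @param n_bins initial number of equal-width bins (default 50).
#' @param min_count minimum observed count per outskirt bin (default 5).
#' @param n_params number of estimated parameters (default 13).
#' @return list with \code{chi2}, \code{dof}, \code{p_value},
#'   \code{n_bins_final}, \code{observed}, \code{expected}, \code{edges}.
#' @export
chi_squared_test <- function(phi, model, n_bins = 50, min_count = 5,
                             n_params = 13) {
  stopifnot(is.numeric(phi), length(phi) >= 1,
            inherits(model, "tracheid_mixture"))
  mb <- merge_outskirt_bins(phi, n_bins, min_count)
  observed <- mb$observed
  edges <- mb$edges
  m <- length(observed)
  dof <- m - n_params - 1
  if (dof < 1)
    stop("degrees of freedom < 1 after merging (", m,
         " bins); use fewer, wider bins", call. = FALSE)
  expected <- length(phi) * bin_probs(edges, model)
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, dof = dof,
       p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
       n_bins_final = m, observed = observed, expected = expected,
       edges = edges)
}

# equal-width binning over the observed range with outskirt bins holding
# fewer than min_count observations merged inward
merge_outskirt_bins <- function(phi, n_bins = 50, min_count = 5) {
  edges <- seq(min(phi), max(phi), length.out = n_bins + 1)
  idx <- findInterval(phi, edges, rightmost.closed = TRUE)
  observed <- tabulate(idx, nbins = n_bins)
  while (length(observed) > 1 && observed[1] < min_count) {
    observed[2] <- observed[2] + observed[1]
    observed <- observed[-1]
    edges <- edges[-2]
  }
  while (length(observed) > 1 && observed[length(observed)] < min_count) {
    k <- length(observed)
    observed[k - 1] <- observed[k - 1] + observed[k]
    observed <- observed[-k]
    edges <- edges[-k]
  }
  list(observed = observed, edges = edges)
}

# expected bin probabilities under a model, outermost bins extended over
# the full support
bin_probs <- function(edges, model) {
  cdf <- mixture_cdf(edges, model)
  diff(c(0, cdf[-c(1, length(cdf))], 1))
}

#' Re-estimate a mixture by minimum chi-squared on merged bins
#'
#' Warm-started grouped (Pearson-Fisher) estimation: minimizes the Pearson
#' chi-squared statistic over the 13 transformed parameters, on the same
#' merged equal-width binning that [chi_squared_test()] uses. Estimating
#' parameters by minimizing the grouped statistic is the classical condition
#' under which the test statistic follows the chi-squared distribution with
#' \code{m - 13 - 1} degrees of freedom; it is also fast, since the
#' objective needs only the cdf at the bin edges. Restarts continue until
#' the statistic stalls or clearly passes.
#'
#' @param phi numeric vector of indexed slope angles (degrees).
#' @param init warm-start [tracheid_mixture()] (e.g. the generating or
#'   previously fitted model).
#' @param n_bins,min_count binning settings as in [chi_squared_test()].
#' @param max_rounds maximum simplex restarts (default 8).
#' @param maxit iterations per restart (default 4000).
#' @return a list with \code{model} (the refitted mixture) and \code{chi2}
#'   (the minimized statistic on the fixed binning).
#' @export
fit_min_chi2 <- function(phi, init, n_bins = 50, min_count = 5,
                         max_rounds = 8, maxit = 4000) {
  stopifnot(inherits(init, "tracheid_mixture"))
  mb <- merge_outskirt_bins(phi, n_bins, min_count)
  nn <- length(phi)
  dof <- length(mb$observed) - 13 - 1
  clear_pass <- if (dof >= 1) stats::qchisq(0.8, dof) else 0
  obj <- function(z) {
    m <- try(vec_to_model(z, init), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    pr <- bin_probs(mb$edges, m)
    if (any(pr <= 0)) return(1e10)
    sum((mb$observed - nn * pr)^2 / (nn * pr))
  }
  z <- model_to_vec(init)
  val <- obj(z)
  for (r in seq_len(max_rounds)) {
    opt <- stats::optim(z, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    improved <- val - opt$value
    z <- opt$par
    val <- opt$value
    if (val < clear_pass || improved < 0.01) break
  }
  list(model = vec_to_model(z, init), chi2 = val)
}

#' Calibration study of the chi-squared adequacy test
#'
#' Draws \code{n_rep} replicate samples from a mixture, re-estimates the 13
#' parameters on each replicate by warm-started minimum chi-squared
#' ([fit_min_chi2()]) and applies [chi_squared_test()]. For data truly
#' generated from the fitted family the test should reject at about the
#' nominal 5 percent rate.
#'
#' @param model the generating [tracheid_mixture()].
#' @param n cells per replicate (default 4800).
#' @param n_rep number of replicates (default 100).
#' @param seed integer seed for the replicate stream.
#' @param n_bins,min_count binning settings.
#' @return list with \code{pass_rate} (fraction of replicates with
#'   p > 0.05), \code{p_values} and \code{chi2} vectors.
#' @export
chi2_calibration <- function(model, n = 4800, n_rep = 100, seed = 1,
                             n_bins = 50, min_count = 5) {
  stopifnot(inherits(model, "tracheid_mixture"))
  p_values <- chi2 <- numeric(n_rep)
  with_seed(seed, {
    for (i in seq_len(n_rep)) {
      ang <- sample_angles(model, n)
      ref <- fit_min_chi2(ang$phi, model, n_bins = n_bins,
                          min_count = min_count)
      ch <- chi_squared_test(ang$phi, ref$model, n_bins = n_bins,
                             min_count = min_count)
      p_values[i] <- ch$p_value
      chi2[i] <- ch$chi2
    }
  })
  list(pass_rate = mean(p_values > 0.05), p_values = p_values, chi2 = chi2)
}

#' Fit the tracheid slope-angle mixture model
#'
#' The main estimator. Indexed slope angles are binned (1.5-degree bins by
#' default), starting values are derived from the histogram
#' ([initialize_parameters()]), the 13 parameters are estimated by binned
#' least squares ([fit_least_squares()]) and refined by maximum likelihood
#' on the raw angles ([fit_mle()]), and model adequacy is assessed with the
#' Pearson chi-squared test on merged bins ([chi_squared_test()]). Either
#' stage can be run alone via \code{method}.
#'
#' @param phi numeric vector of indexed slope angles in degrees, or a data
#'   frame with a \code{phi_i} column (e.g. from [standardize_cells()]).
#' @param bin_width histogram bin width in degrees for initialization and
#'   the least-squares stage (default 1.5).
#' @param method \code{"ls+mle"} (default), \code{"ls"} or \code{"mle"}.
#' @param init optional starting [tracheid_mixture()]; by default derived
#'   from the histogram.
#' @param d_mean,cwt_mean optional standardization means (\eqn{\mu m}) to
#'   attach to the fitted model for back-transformation to the CWT/D scale.
#' @param label optional label attached to the fitted model.
#' @param n_bins,min_count chi-squared harness settings (defaults 50 and 5).
#' @param multistart screen a deterministic portfolio of skew-variant
#'   starting values with short likelihood runs and refine the best
#'   (default \code{TRUE} when no \code{init} is given). The mixture
#'   likelihood has near-equivalent re-decompositions (a very flat, wide
#'   transition component can absorb the flanks of the beta components), so
#'   a single local search from one start can settle on an uninterpretable
#'   optimum; the portfolio spans the plausible component skewness patterns
#'   and the best final likelihood wins.
#' @param control optimizer control list, see [fit_least_squares()].
#' @return an object of class \code{"tzm_fit"}: the fitted model plus
#'   chi-squared adequacy, log-likelihood, convergence diagnostics and the
#'   data used. Methods: \code{print}, \code{summary} (zone report),
#'   \code{coef}, \code{logLik}, \code{predict}, \code{plot},
#'   \code{simulate}, \code{residuals}.
#' @examples
#' set.seed(1)
#' prof <- species_profile("picea_obovata")
#' ang <- sample_angles(prof$model, 2000)
#' fit <- fit_tracheid_mixture(ang$phi, control = list(maxit = 2000))
#' coef(fit)
#' @export
fit_tracheid_mixture <- function(phi, bin_width = 1.5,
                                 method = c("ls+mle", "ls", "mle"),
                                 init = NULL, d_mean = NULL, cwt_mean = NULL,
                                 label = NULL, n_bins = 50, min_count = 5,
                                 multistart = is.null(init),
                                 control = list()) {
  method <- match.arg(method)
  force(multistart)
  if (is.data.frame(phi)) {
    stopifnot("phi_i" %in% names(phi))
    phi <- phi$phi_i
  }
  stopifnot(is.numeric(phi), length(phi) >= 3)
  hist <- bin_histogram(phi, bin_width)
  if (is.null(init)) init <- initialize_parameters(hist)
  init$label <- label; init$d_mean <- d_mean; init$cwt_mean <- cwt_mean
  trace <- NULL
  objective <- NA_real_
  if (method %in% c("ls+mle", "ls")) {
    ls <- fit_least_squares(hist, init, control)
    trace <- ls$trace
    objective <- ls$objective
    current <- ls$model
  } else current <- init
  if (method %in% c("ls+mle", "mle")) {
    if (multistart) {
      starts <- c(list(current),
                  lapply(init_candidates(hist), function(s) {
                    s$label <- init$label; s$d_mean <- init$d_mean
                    s$cwt_mean <- init$cwt_mean
                    s
                  }))
      # coarse screen, then medium runs on the leaders; simplex restarts
      # are essential here — a single run stalls on the likelihood ridges
      screened <- lapply(starts, function(s)
        fit_mle(phi, s, control = list(maxit = 1000)))
      lls <- vapply(screened, function(f) f$logLik, numeric(1))
      top <- order(lls, decreasing = TRUE)[seq_len(min(3, length(lls)))]
      medium <- lapply(screened[top], function(f)
        fit_mle(phi, f$model, control = list(maxit = 3000)))
      best <- which.max(vapply(medium, function(f) f$logLik, numeric(1)))
      current <- medium[[best]]$model
      ll_now <- medium[[best]]$logLik
      evals <- sum(vapply(c(screened, medium), function(f)
        f$trace$evaluations, numeric(1)))
      trace <- rbind(trace,
                     data.frame(stage = "multistart", evaluations = evals,
                                start = -max(lls), objective = -ll_now))
    }
    mle <- fit_mle(phi, current, control)
    for (round in 1:4) {      # restart until the improvement stalls
      again <- fit_mle(phi, mle$model, control)
      if (again$logLik < mle$logLik + 0.05) { mle <- again; break }
      mle <- again
    }
    trace <- rbind(trace, mle$trace)
    current <- mle$model
    logLik <- mle$logLik
    converged <- mle$converged
  } else {
    logLik <- sum(log(pmax(mixture_pdf(phi, current), 1e-300)))
    converged <- ls$converged
  }
  chi2 <- chi_squared_test(phi, current, n_bins = n_bins,
                           min_count = min_count)
  out <- new_tzm_fit(current, method = method, converged = converged,
                     trace = trace, logLik = logLik, objective = objective,
                     chi2 = chi2, n = length(phi), phi = phi, hist = hist,
                     init = init)
  out
}
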