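#' Three-component mixture model of tracheid slope angles
#'
#' Constructs the parametric model of the indexed slope angle
#' \eqn{\varphi_i = \arctan(\mathrm{CWT}_i/D_i)} (degrees) across a ring
#' population: a four-parameter beta component for earlywood (EW), a
#' generalized normal component for transition wood (TW) and a second beta
#' component for latewood (LW), combined with convex weights
#' \eqn{A_{EW} + A_{TW} + A_{LW} = 1}. The TW weight is the residual
#' \eqn{A_{TW} = 1 - A_{EW} - A_{LW}}, so the model has 13 free parameters:
#' 2 amplitudes + 4 + 4 beta parameters + 3 generalized-normal parameters.
#'
#' @param A_ew,A_lw earlywood and latewood weights, each in (0, 1) with
#'   \code{A_ew + A_lw < 1}.
#' @param ew,lw beta component parameters: lists with \code{alpha},
#'   \code{beta} (shapes > 1) and \code{a}, \code{b} (support, degrees).
#' @param tw transition-wood parameters: list with \code{mu} (degrees),
#'   \code{alpha} (scale, degrees) and \code{beta} (shape >= 2).
#' @param label optional species or dataset label carried in reports.
#' @param d_mean,cwt_mean optional standardization means (\eqn{\mu m}) of the
#'   dataset the model refers to; used by back-transformations to the CWT/D
#'   scale when available.
#' @return an object of class \code{"tracheid_mixture"}.
#' @examples
#' m <- tracheid_mixture(
#'   A_ew = 0.492, A_lw = 0.287,
#'   ew = list(alpha = 4, beta = 6, a = 15, b = 48),
#'   tw = list(mu = 49, alpha = 9, beta = 4),
#'   lw = list(alpha = 5, beta = 3, a = 55, b = 80))
#' mixture_pdf(45, m)
#' @export
tracheid_mixture <- function(A_ew, A_lw, ew, tw, lw, label = NULL,
                             d_mean = NULL, cwt_mean = NULL) {
  if (!is.numeric(A_ew) || !is.numeric(A_lw) ||
      A_ew <= 0 || A_lw <= 0 || A_ew + A_lw >= 1)
    stop("amplitudes must satisfy A_ew > 0, A_lw > 0, A_ew + A_lw < 1",
         call. = FALSE)
  ew <- as.list(ew); lw <- as.list(lw); tw <- as.list(tw)
  check_beta4(ew$alpha, ew$beta, ew$a, ew$b)
  check_beta4(lw$alpha, lw$beta, lw$a, lw$b)
  check_gnorm(tw$mu, tw$alpha, tw$beta)
  structure(
    list(A_ew = A_ew, A_tw = 1 - A_ew - A_lw, A_lw = A_lw,
         ew = ew[c("alpha", "beta", "a", "b")],
         tw = tw[c("mu", "alpha", "beta")],
         lw = lw[c("alpha", "beta", "a", "b")],
         label = label, d_mean = d_mean, cwt_mean = cwt_mean),
    class = "tracheid_mixture")
}

#' Mixture density, distribution and quantile functions
#'
#' Evaluate the mixture density (per degree), its cdf, and the inverse cdf of
#' a [tracheid_mixture()] model. The cdf combines the closed-form component
#' cdfs (regularized incomplete beta and gamma functions); the quantile
#' function inverts it by monotone root finding.
#'
#' @param x,q angles in degrees.
#' @param p probabilities in (0, 1).
#' @param model a \code{tracheid_mixture} object.
#' @return numeric vector.
#' @export
mixture_pdf <- function(x, model) {
  stopifnot(inherits(model, "tracheid_mixture"))
  model$A_ew * dbeta4(x, model$ew$alpha, model$ew$beta, model$ew$a, model$ew$b) +
    model$A_tw * dgnorm(x, model$tw$mu, model$tw$alpha, model$tw$beta) +
    model$A_lw * dbeta4(x, model$lw$alpha, model$lw$beta, model$lw$a, model$lw$b)
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(q, model) {
  stopifnot(inherits(model, "tracheid_mixture"))
  model$A_ew * pbeta4(q, model$ew$alpha, model$ew$beta, model$ew$a, model$ew$b) +
    model$A_tw * pgnorm(q, model$tw$mu, model$tw$alpha, model$tw$beta) +
    model$A_lw * pbeta4(q, model$lw$alpha, model$lw$beta, model$lw$a, model$lw$b)
}

#' @rdname mixture_pdf
#' @export
mixture_quantile <- function(p, model) {
  stopifnot(inherits(model, "tracheid_mixture"),
            all(p > 0), all(p < 1))
  lo <- min(model$ew$a, model$lw$a,
            qgnorm(1e-12, model$tw$mu, model$tw$alpha, model$tw$beta))
  hi <- max(model$ew$b, model$lw$b,
            qgnorm(1 - 1e-12, model$tw$mu, model$tw$alpha, model$tw$beta))
  vapply(p, function(pp) {
    stats::uniroot(function(x) mixture_cdf(x, model) - pp,
                   lower = lo, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' @export
print.tracheid_mixture <- function(x, ...) {
  cat("Tracheid slope-angle mixture model",
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  amplitudes: EW %.1f%%  TW %.1f%%  LW %.1f%%\n",
              100 * x$A_ew, 100 * x$A_tw, 100 * x$A_lw))
  cat(sprintf("  EW beta : alpha %.3f beta %.3f on (%.2f, %.2f) deg\n",
              x$ew$alpha, x$ew$beta, x$ew$a, x$ew$b))
  shape_str <- if (x$tw$beta > 1e3)
    sprintf("%.3g (near-uniform)", x$tw$beta) else sprintf("%.3f", x$tw$beta)
  cat(sprintf("  TW gnorm: mu %.2f deg  scale %.3f  shape %s\n",
              x$tw$mu, x$tw$alpha, shape_str))
  cat(sprintf("  LW beta : alpha %.3f beta %.3f on (%.2f, %.2f) deg\n",
              x$lw$alpha, x$lw$beta, x$lw$a, x$lw$b))
  if (!is.null(x$d_mean))
    cat(sprintf("  standardization means: D %.2f um, CWT %.2f um\n",
                x$d_mean, x$cwt_mean))
  invisible(x)
}

#' @export
coef.tracheid_mixture <- function(object, ...) {
  c(A_ew = object$A_ew, A_lw = object$A_lw,
    ew_alpha = object$ew$alpha, ew_beta = object$ew$beta,
    ew_a = object$ew$a, ew_b = object$ew$b,
    tw_mu = object$tw$mu, tw_alpha = object$tw$alpha, tw_beta = object$tw$beta,
    lw_alpha = object$lw$alpha, lw_beta = object$lw$beta,
    lw_a = object$lw$a, lw_b = object$lw$b)
}

#' Read and write mixture models as flat JSON
#'
#' Serializes the 13 parameters (degrees) plus metadata (label,
#' standardization means) to a flat key-value JSON file, and reads it back.
#'
#' @param model a \code{tracheid_mixture} object.
#' @param path file path.
#' @return \code{read_model} returns a \code{tracheid_mixture};
#'   \code{write_model} returns \code{path} invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tracheid_mixture"))
  x <- as.list(coef(model))
  x$label <- model$label
  x$d_mean <- model$d_mean
  x$cwt_mean <- model$cwt_mean
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tracheid_mixture(
    A_ew = x$A_ew, A_lw = x$A_lw,
    ew = list(alpha = x$ew_alpha, beta = x$ew_beta, a = x$ew_a, b = x$ew_b),
    tw = list(mu = x$tw_mu, alpha = x$tw_alpha, beta = x$tw_beta),
    lw = list(alpha = x$lw_alpha, beta = x$lw_beta, a = x$lw_a, b = x$lw_b),
    label = x$label, d_mean = x$d_mean, cwt_mean = x$cwt_mean)
}
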