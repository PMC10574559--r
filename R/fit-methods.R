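#' @export
print.tzm_fit <- function(x, ...) {
  cat("Tracheid slope-angle mixture fit (method:", x$method, ")\n")
  cat(sprintf("  n = %d angles; logLik = %.2f%s\n", x$n, x$logLik,
              if (x$converged) "" else "  [NOT converged]"))
  print(x$model)
  if (!is.null(x$chi2))
    cat(sprintf(paste0("  chi-squared: %.2f on %d df (m = %d bins), ",
                       "p = %.3g -> %s\n"),
                x$chi2, x$dof, x$n_bins_final, x$p_value,
                if (x$p_value > 0.05) "adequate" else "inadequate"))
  invisible(x)
}

#' @export
coef.tzm_fit <- function(object, ...) coef(object$model)

#' @export
logLik.tzm_fit <- function(object, ...) {
  structure(object$logLik, df = 13, nobs = object$n, class = "logLik")
}

#' Summarize a mixture fit as a per-zone report
#'
#' @param object a \code{"tzm_fit"}.
#' @param d_mean,cwt_mean standardization means; default those stored in the
#'   fitted model.
#' @param ... unused.
#' @return a [zone_report()] (per-zone amplitudes, angle statistics,
#'   back-transformed CWT/D statistics) with the chi-squared adequacy
#'   attached.
#' @export
summary.tzm_fit <- function(object, d_mean = NULL, cwt_mean = NULL, ...) {
  rep <- zone_report(object$model,
                     d_mean = d_mean %||% object$model$d_mean,
                     cwt_mean = cwt_mean %||% object$model$cwt_mean)
  attr(rep, "chi2") <- object$chi2
  attr(rep, "dof") <- object$dof
  attr(rep, "p_value") <- object$p_value
  rep
}

#' Predict from a fitted slope-angle mixture
#'
#' @param object a \code{"tzm_fit"}.
#' @param newdata angles in degrees (default: the fitted angles).
#' @param type \code{"density"}, \code{"cdf"} or \code{"zone"} (maximum
#'   posterior component membership).
#' @param ... unused.
#' @return numeric vector, or a factor of zone labels for
#'   \code{type = "zone"}.
#' @export
predict.tzm_fit <- function(object, newdata = NULL,
                            type = c("density", "cdf", "zone"), ...) {
  type <- match.arg(type)
  x <- newdata %||% object$phi
  m <- object$model
  switch(type,
         density = mixture_pdf(x, m),
         cdf = mixture_cdf(x, m),
         zone = {
           comp <- cbind(
             EW = m$A_ew * dbeta4(x, m$ew$alpha, m$ew$beta, m$ew$a, m$ew$b),
             TW = m$A_tw * dgnorm(x, m$tw$mu, m$tw$alpha, m$tw$beta),
             LW = m$A_lw * dbeta4(x, m$lw$alpha, m$lw$beta, m$lw$a, m$lw$b))
           factor(c("EW", "TW", "LW")[max.col(comp)],
                  levels = c("EW", "TW", "LW"))
         })
}

#' @export
residuals.tzm_fit <- function(object, ...) {
  if (is.null(object$chi2_detail)) return(NULL)
  d <- object$chi2_detail
  (d$observed - d$expected) / sqrt(d$expected)
}

#' Simulate angles from a fitted mixture
#'
#' @param object a \code{"tzm_fit"}.
#' @param nsim number of angles to draw.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return data frame with \code{phi} (degrees) and the true \code{zone}.
#' @export
simulate.tzm_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  sample_angles(object$model, nsim, seed = seed)
}

#' Plot a fitted slope-angle mixture over its histogram
#'
#' Draws the fitted histogram (probability density per degree) with the
#' mixture density and its three weighted components.
#'
#' @param x a \code{"tzm_fit"}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tzm_fit <- function(x, ...) {
  h <- x$hist
  m <- x$model
  dens <- h$densities / h$width
  grid <- seq(h$lower_edges[1],
              h$lower_edges[length(h$lower_edges)] + h$width, by = 0.1)
  ylim <- c(0, max(dens, mixture_pdf(grid, m)) * 1.05)
  graphics::plot(NA, xlim = range(grid), ylim = ylim,
                 xlab = expression(phi[i] * " (degrees)"),
                 ylab = "probability density", ...)
  graphics::rect(h$lower_edges, 0, h$lower_edges + h$width, dens,
                 col = "grey85", border = "grey60")
  graphics::lines(grid, m$A_ew * dbeta4(grid, m$ew$alpha, m$ew$beta,
                                        m$ew$a, m$ew$b), lty = 2)
  graphics::lines(grid, m$A_tw * dgnorm(grid, m$tw$mu, m$tw$alpha,
                                        m$tw$beta), lty = 3)
  graphics::lines(grid, m$A_lw * dbeta4(grid, m$lw$alpha, m$lw$beta,
                                        m$lw$a, m$lw$b), lty = 4)
  graphics::lines(grid, mixture_pdf(grid, m), lwd = 2)
  graphics::legend("topright", bty = "n", lwd = c(2, 1, 1, 1),
                   lty = c(1, 2, 3, 4),
                   legend = c("mixture", "EW", "TW", "LW"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
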