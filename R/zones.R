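#' Classical Mork thresholds on the CWT/D scale
#'
#' The two historical readings of the Mork latewood criterion, expressed as
#' thresholds on the wall-thickness-to-diameter ratio via the lumen identity
#' \eqn{L = D - 2\,\mathrm{CWT}}: form (1), \eqn{4\,\mathrm{CWT} > L},
#' gives \eqn{\mathrm{CWT}/D > 1/6 \approx 0.167}; form (2),
#' \eqn{2\,\mathrm{CWT} > L}, gives \eqn{\mathrm{CWT}/D > 1/4 = 0.25}.
#'
#' @param form \code{"eq1"} or \code{"eq2"}.
#' @return the exact threshold ratio (1/6 or 1/4).
#' @export
mork_threshold <- function(form = c("eq1", "eq2")) {
  switch(match.arg(form), eq1 = 1 / 6, eq2 = 1 / 4)
}

#' Back-transform an indexed slope angle to the CWT/D scale
#'
#' Inverts the standardization:
#' \eqn{\mathrm{CWT}/D = (\overline{\mathrm{CWT}}/\overline{D})
#'   \tan\varphi_i}, with the means over the standardization scope.
#'
#' @param phi indexed slope angle(s) in degrees, in (0, 90).
#' @param d_mean,cwt_mean standardization means in \eqn{\mu m}.
#' @return CWT/D ratio(s).
#' @examples
#' back_transform(49, 28.6, 2.6)   # ~0.105
#' @export
back_transform <- function(phi, d_mean, cwt_mean) {
  if (any(!is.finite(phi) | phi <= 0 | phi >= 90))
    stop("phi must lie strictly between 0 and 90 degrees", call. = FALSE)
  if (!is.finite(d_mean) || !is.finite(cwt_mean) || d_mean <= 0 ||
      cwt_mean <= 0)
    stop("standardization means must be positive", call. = FALSE)
  (cwt_mean / d_mean) * tan(phi * pi / 180)
}

new_zone_thresholds <- function(k_two_zone = NA_real_,
                                phi_two_zone = NA_real_,
                                phi_ew_tw = NA_real_, phi_tw_lw = NA_real_,
                                method) {
  structure(list(k_two_zone = k_two_zone, phi_two_zone = phi_two_zone,
                 phi_ew_tw = phi_ew_tw, phi_tw_lw = phi_tw_lw,
                 method = method),
            class = "zone_thresholds")
}

#' @export
print.zone_thresholds <- function(x, ...) {
  cat("Zone thresholds (method:", x$method, ")\n")
  if (!is.na(x$k_two_zone))
    cat(sprintf("  two-zone: phi = %.2f deg, k = CWT/D = %.3f\n",
                x$phi_two_zone, x$k_two_zone))
  if (!is.na(x$phi_ew_tw))
    cat(sprintf("  three-zone: EW|TW at %.2f deg, TW|LW at %.2f deg\n",
                x$phi_ew_tw, x$phi_tw_lw))
  invisible(x)
}

#' Species-specific two-zone threshold from the transition-wood center
#'
#' Uses the center \eqn{\mu} of the symmetric transition-wood distribution
#' as the earlywood/latewood boundary, so the more earlywood-like half of
#' the TW cells joins the EW cluster and the other half joins LW. The angle
#' is back-transformed to the CWT/D scale with the standardization means.
#' If the TW amplitude is numerically zero the boundary falls back to the
#' intersection of the weighted EW and LW densities.
#'
#' @param model a fitted [tracheid_mixture()].
#' @param d_mean,cwt_mean standardization means (\eqn{\mu m}); default those
#'   stored in the model.
#' @return a \code{"zone_thresholds"} object with \code{k_two_zone},
#'   \code{phi_two_zone} and \code{method} (\code{"tw-center"} or
#'   \code{"intersection"}).
#' @export
two_zone_threshold <- function(model, d_mean = NULL, cwt_mean = NULL) {
  stopifnot(inherits(model, "tracheid_mixture"))
  d_mean <- d_mean %||% model$d_mean
  cwt_mean <- cwt_mean %||% model$cwt_mean
  if (is.null(d_mean) || is.null(cwt_mean))
    stop("standardization means required (d_mean, cwt_mean)", call. = FALSE)
  if (model$A_tw >= 1e-6) {
    phi <- model$tw$mu
    method <- "tw-center"
  } else {
    f <- function(x)
      model$A_ew * dbeta4(x, model$ew$alpha, model$ew$beta,
                          model$ew$a, model$ew$b) -
      model$A_lw * dbeta4(x, model$lw$alpha, model$lw$beta,
                          model$lw$a, model$lw$b)
    ew_mode <- beta4_stats(model$ew$alpha, model$ew$beta,
                           model$ew$a, model$ew$b)$mode
    lw_mode <- beta4_stats(model$lw$alpha, model$lw$beta,
                           model$lw$a, model$lw$b)$mode
    phi <- stats::uniroot(f, lower = ew_mode, upper = lw_mode,
                          tol = 1e-10)$root
    method <- "intersection"
  }
  new_zone_thresholds(k_two_zone = back_transform(phi, d_mean, cwt_mean),
                      phi_two_zone = phi, method = method)
}

#' Two-zone earlywood and latewood proportions
#'
#' With the transition-wood center as the boundary, half the TW mass joins
#' each neighbour: \eqn{EW\% = 100 (A_{EW} + A_{TW}/2)} and
#' \eqn{LW\% = 100 - EW\%} (exactly).
#'
#' @param model a [tracheid_mixture()].
#' @return named vector \code{c(EW = , LW = )} in percent.
#' @examples
#' m <- species_profile("picea_obovata")$model
#' two_zone_proportions(m)   # EW ~60.3, LW ~39.7
#' @export
two_zone_proportions <- function(model) {
  stopifnot(inherits(model, "tracheid_mixture"))
  ew <- 100 * (model$A_ew + model$A_tw / 2)
  c(EW = ew, LW = 100 - ew)
}

#' Three-zone boundaries between neighbouring components
#'
#' \code{method = "intersection"}: the angles where the weighted densities
#' of neighbouring zones are equal (EW-TW between the EW mode and the TW
#' center; TW-LW between the TW center and the LW mode), found by monotone
#' root bracketing. \code{method = "percentile"}: the angles at which the
#' mixture cdf equals \eqn{A_{EW}} and \eqn{A_{EW} + A_{TW}}, so classified
#' zone fractions reproduce the amplitudes.
#'
#' @param model a fitted [tracheid_mixture()].
#' @param method \code{"intersection"} or \code{"percentile"}.
#' @return a \code{"zone_thresholds"} object with \code{phi_ew_tw} and
#'   \code{phi_tw_lw} (degrees).
#' @export
three_zone_boundaries <- function(model,
                                  method = c("intersection", "percentile")) {
  stopifnot(inherits(model, "tracheid_mixture"))
  method <- match.arg(method)
  if (method == "percentile") {
    b <- mixture_quantile(c(model$A_ew, model$A_ew + model$A_tw), model)
    return(new_zone_thresholds(phi_ew_tw = b[1], phi_tw_lw = b[2],
                               method = "percentile"))
  }
  ew_mode <- beta4_stats(model$ew$alpha, model$ew$beta,
                         model$ew$a, model$ew$b)$mode
  lw_mode <- beta4_stats(model$lw$alpha, model$lw$beta,
                         model$lw$a, model$lw$b)$mode
  wdens <- function(x, zone)
    switch(zone,
           ew = model$A_ew * dbeta4(x, model$ew$alpha, model$ew$beta,
                                    model$ew$a, model$ew$b),
           tw = model$A_tw * dgnorm(x, model$tw$mu, model$tw$alpha,
                                    model$tw$beta),
           lw = model$A_lw * dbeta4(x, model$lw$alpha, model$lw$beta,
                                    model$lw$a, model$lw$b))
  root_between <- function(z1, z2, lo, hi) {
    f <- function(x) wdens(x, z1) - wdens(x, z2)
    if (f(lo) * f(hi) > 0)
      stop("no sign change for the ", toupper(z1), "-", toupper(z2),
           " boundary in (", round(lo, 2), ", ", round(hi, 2), ") degrees",
           call. = FALSE)
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
  }
  new_zone_thresholds(
    phi_ew_tw = root_between("ew", "tw", ew_mode, model$tw$mu),
    phi_tw_lw = root_between("tw", "lw", model$tw$mu, lw_mode),
    method = "intersection")
}

#' Classify cells of a ring into zones
#'
#' Labels each cell of a tracheidogram EW/TW/LW (or EW/LW for two-zone
#' thresholds) by comparing its indexed slope angle with the boundaries.
#' Cells exactly on a boundary take the later (more latewood-like) zone.
#' With \code{enforce_order} the irreversibility of the intra-seasonal
#' transition is imposed: the first cell of the ring is always earlywood,
#' and labels are made non-decreasing along the ring in the order
#' EW, TW, LW (once TW starts no cell reverts to EW; once LW starts, none
#' reverts to EW or TW). Rings with intra-annual density fluctuations are
#' the known exception and should be classified with
#' \code{enforce_order = FALSE}.
#'
#' @param tg a [tracheidogram()], or a numeric vector of indexed slope
#'   angles (degrees) already standardized.
#' @param thresholds a \code{"zone_thresholds"} object (two- or three-zone).
#' @param d_mean,cwt_mean standardization means used to index the
#'   tracheidogram traits (required when \code{tg} is a tracheidogram).
#' @param enforce_order impose the EW-to-LW irreversibility constraint
#'   (default \code{FALSE}).
#' @return factor of zone labels, levels \code{EW}, \code{TW}, \code{LW}.
#' @export
classify_ring <- function(tg, thresholds, d_mean = NULL, cwt_mean = NULL,
                          enforce_order = FALSE) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  if (inherits(tg, "tracheidogram")) {
    if (is.null(d_mean) || is.null(cwt_mean))
      stop("standardization means required to index a tracheidogram",
           call. = FALSE)
    phi <- compute_slope_angle((tg$CWT / cwt_mean) / (tg$D / d_mean))
  } else {
    phi <- as.numeric(tg)
  }
  if (!length(phi)) stop("empty ring", call. = FALSE)
  three <- !is.na(thresholds$phi_ew_tw)
  code <- if (three) {
    1L + (phi >= thresholds$phi_ew_tw) + (phi >= thresholds$phi_tw_lw)
  } else {
    if (is.na(thresholds$phi_two_zone))
      stop("thresholds carry neither two- nor three-zone boundaries",
           call. = FALSE)
    1L + 2L * (phi >= thresholds$phi_two_zone)
  }
  if (enforce_order) {
    code[1] <- 1L
    code <- cummax(code)
  }
  factor(c("EW", "TW", "LW")[code], levels = c("EW", "TW", "LW"))
}

#' Per-zone report of a fitted mixture
#'
#' For each zone: amplitude (percent), the angle-scale mean, median, mode
#' and standard deviation from the closed-form component statistics, and
#' the mean, median and mode back-transformed to the CWT/D scale (each angle
#' statistic transformed individually). The transition-wood rows have
#' mean = median = mode by symmetry. Two-zone proportions are attached as
#' attributes.
#'
#' @param model a fitted [tracheid_mixture()].
#' @param d_mean,cwt_mean standardization means (\eqn{\mu m}); default those
#'   stored in the model. Without means the CWT/D columns are \code{NA}.
#' @return a \code{"zone_report"} data frame with one row per zone.
#' @export
zone_report <- function(model, d_mean = NULL, cwt_mean = NULL) {
  stopifnot(inherits(model, "tracheid_mixture"))
  d_mean <- d_mean %||% model$d_mean
  cwt_mean <- cwt_mean %||% model$cwt_mean
  ew <- beta4_stats(model$ew$alpha, model$ew$beta, model$ew$a, model$ew$b)
  tw <- gnorm_stats(model$tw$mu, model$tw$alpha, model$tw$beta)
  lw <- beta4_stats(model$lw$alpha, model$lw$beta, model$lw$a, model$lw$b)
  bt <- function(phi)
    if (is.null(d_mean) || is.null(cwt_mean)) NA_real_
    else back_transform(phi, d_mean, cwt_mean)
  row <- function(zone, A, s)
    data.frame(zone = zone, amplitude_pct = 100 * A, mean_deg = s$mean,
               median_deg = s$median, mode_deg = s$mode,
               sigma_deg = s$sigma, ratio_mean = bt(s$mean),
               ratio_median = bt(s$median), ratio_mode = bt(s$mode),
               stringsAsFactors = FALSE)
  out <- rbind(row("EW", model$A_ew, ew), row("TW", model$A_tw, tw),
               row("LW", model$A_lw, lw))
  rownames(out) <- NULL
  prop <- two_zone_proportions(model)
  structure(out, class = c("zone_report", "data.frame"),
            two_zone = prop, label = model$label,
            d_mean = d_mean, cwt_mean = cwt_mean)
}

#' @export
print.zone_report <- function(x, digits = 3, ...) {
  lab <- attr(x, "label")
  cat("Per-zone distribution characteristics",
      if (!is.null(lab)) paste0("(", lab, ")"), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  p <- attr(x, "two_zone")
  cat(sprintf("Two-zone split at TW center: EW %.1f%%, LW %.1f%%\n",
              p["EW"], p["LW"]))
  if (!is.null(attr(x, "chi2")))
    cat(sprintf("Adequacy: chi-squared %.2f on %d df, p = %.3g\n",
                attr(x, "chi2"), attr(x, "dof"), attr(x, "p_value")))
  invisible(x)
}
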