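#' Fall-configuration probability model
#'
#' The exposure model converting a critical-velocity curve into a fracture
#' probability. Fall angles follow a piecewise-uniform distribution over three
#' segments — anterior falls (-90 to -30 degrees) with mass 12%, sideways
#' falls (-30 to 30) with 39.36%, posterior falls (30 to 90) with 48.64% —
#' uniform within each segment (maximum entropy given only the segment
#' masses). Impact speed is normal with mean 2.14 m/s and SD 0.63 m/s,
#' truncated at 0 and renormalised (the untruncated mass below zero, about
#' 3.4e-4, is negligible but a speed must be non-negative). Because only about
#' 40% of real-life falls involve impact to the hip, the integrated fracture
#' probability is scaled by the hip-impact factor 0.4.
#'
#' @param segment_bounds Increasing vector of segment boundaries in degrees.
#' @param segment_masses Probability mass of each segment (must sum to 1).
#' @param speed_mean,speed_sd Impact-speed distribution parameters (m/s).
#' @param speed_truncation Lower truncation of the speed distribution (m/s).
#' @param hip_impact_factor Probability that a fall impacts the hip, in (0, 1].
#' @return Object of class `fall_config`.
#' @export
#' @examples
#' fall_config()
fall_config <- function(segment_bounds = c(-90, -30, 30, 90),
                        segment_masses = c(0.12, 0.3936, 0.4864),
                        speed_mean = 2.14, speed_sd = 0.63,
                        speed_truncation = 0,
                        hip_impact_factor = 0.4) {
  if (length(segment_masses) != length(segment_bounds) - 1) {
    stop("need one segment mass per pair of adjacent bounds")
  }
  if (is.unsorted(segment_bounds, strictly = TRUE)) {
    stop("segment_bounds must be strictly increasing")
  }
  if (abs(sum(segment_masses) - 1) > 1e-12) {
    stop("segment masses must sum to 1")
  }
  if (any(segment_masses < 0)) stop("segment masses must be non-negative")
  if (speed_sd <= 0) stop("speed_sd must be > 0")
  if (hip_impact_factor <= 0 || hip_impact_factor > 1) {
    stop("hip_impact_factor must lie in (0, 1]")
  }
  structure(
    list(segment_bounds = segment_bounds, segment_masses = segment_masses,
         speed_mean = speed_mean, speed_sd = speed_sd,
         speed_truncation = speed_truncation,
         hip_impact_factor = hip_impact_factor),
    class = "fall_config"
  )
}

#' @export
print.fall_config <- function(x, ...) {
  cat("Fall-configuration model\n")
  seg <- paste(sprintf("[%g, %g]: %.2f%%", head(x$segment_bounds, -1),
                       x$segment_bounds[-1], 100 * x$segment_masses),
               collapse = "  ")
  cat("  fall-angle segments (deg):", seg, "\n")
  cat(sprintf("  impact speed: N(%.2f, %.2f^2) m/s truncated at %g\n",
              x$speed_mean, x$speed_sd, x$speed_truncation))
  cat(sprintf("  hip-impact factor: %.2f\n", x$hip_impact_factor))
  invisible(x)
}

#' Fall-angle probability density
#'
#' Piecewise-uniform density of the fall angle: within each segment the
#' density is the segment mass divided by the segment width (per degree).
#' At an interior segment boundary the right segment's density is returned.
#'
#' @param model A [fall_config()].
#' @param fall_angle Degrees, within the segment range (vectorised).
#' @return Density per degree.
#' @export
#' @examples
#' angle_density(fall_config(), 0)   # 0.3936 / 60
angle_density <- function(model, fall_angle) {
  b <- model$segment_bounds
  if (any(fall_angle < b[1] | fall_angle > b[length(b)])) {
    stop("fall_angle outside the modelled range [", b[1], ", ", b[length(b)], "]")
  }
  seg <- findInterval(fall_angle, b, rightmost.closed = TRUE)
  model$segment_masses[seg] / diff(b)[seg]
}

#' Fracture probability at one angle given its critical velocity
#'
#' Probability that the (truncated-normal) impact speed exceeds the critical
#' velocity: `[1 - Phi((v - mu)/sigma)] / [1 - Phi((t - mu)/sigma)]` with
#' truncation point `t`. The `+Inf` no-fracture sentinel maps to probability
#' 0; a critical velocity at or below the truncation point gives probability 1.
#'
#' @param model A [fall_config()].
#' @param v_crit Critical velocity in m/s, or `+Inf` (vectorised).
#' @return Probability in [0, 1].
#' @export
fracture_prob_given_angle <- function(model, v_crit) {
  if (any(v_crit < model$speed_truncation)) {
    stop("v_crit must be >= the speed truncation point (", model$speed_truncation, ")")
  }
  norm <- stats::pnorm(model$speed_truncation, model$speed_mean, model$speed_sd,
                       lower.tail = FALSE)
  p <- ifelse(is.infinite(v_crit), 0,
              stats::pnorm(v_crit, model$speed_mean, model$speed_sd,
                           lower.tail = FALSE) / norm)
  pmin(p, 1)
}

#' Probability of hip fracture given a fall (P_Fx)
#'
#' Integrates the fracture probability over the fall-configuration
#' distribution and applies the hip-impact scaling:
#' `P_Fx = 100 * hip_impact_factor * integral over angle of
#' angle_density(theta) * P(speed > v_crit(theta)) dtheta`.
#' The integral is evaluated per angle segment by the trapezoid rule on the
#' curve's grid (segment boundaries must be grid nodes, so the density
#' discontinuities at -30 and 30 degrees never straddle a trapezoid), and the
#' result is clamped to [0, 100 * hip_impact_factor].
#'
#' @param curve A `cv_curve` (columns `fall_angle`, `v_crit`) covering the
#'   full modelled angle range with the segment boundaries among its nodes.
#' @param model A [fall_config()].
#' @return P_Fx in percent.
#' @export
#' @examples
#' curve <- data.frame(fall_angle = seq(-90, 90, 1), v_crit = 2.14)
#' compute_pfx(curve, fall_config())   # ~20%: 0.4 x 0.5
compute_pfx <- function(curve, model = fall_config()) {
  b <- model$segment_bounds
  ang <- curve$fall_angle
  if (min(ang) > b[1] || max(ang) < b[length(b)]) {
    stop("curve grid must cover the full angle range [", b[1], ", ",
         b[length(b)], "]")
  }
  if (!all(b %in% ang)) {
    stop("curve grid must include the segment boundaries (",
         paste(b, collapse = ", "), ")")
  }
  p_frac <- fracture_prob_given_angle(model, curve$v_crit)
  total <- 0
  for (s in seq_along(model$segment_masses)) {
    in_seg <- ang >= b[s] & ang <= b[s + 1]
    a_s <- ang[in_seg]; p_s <- p_frac[in_seg]
    dens <- model$segment_masses[s] / (b[s + 1] - b[s])
    # trapezoid rule within the segment (density constant there)
    total <- total + dens * sum(diff(a_s) * (head(p_s, -1) + p_s[-1]) / 2)
  }
  p <- 100 * model$hip_impact_factor * total
  min(max(p, 0), 100 * model$hip_impact_factor)
}

#' Monte-Carlo estimate of P_Fx
#'
#' Cross-check of [compute_pfx()]: samples fall configurations (angle from the
#' piecewise-uniform segments, speed from the truncated normal), evaluates the
#' fracture indicator against the critical-velocity curve (linear
#' interpolation; the `+Inf` sentinel never fractures) and scales by the
#' hip-impact factor.
#'
#' @inheritParams compute_pfx
#' @param n_samples Number of sampled falls.
#' @param seed Integer seed.
#' @return List with `p_fx` (percent), `se` (Monte-Carlo standard error of the
#'   percent estimate) and `n_samples`.
#' @export
compute_pfx_mc <- function(curve, model = fall_config(), n_samples = 1e6,
                           seed = 0) {
  set.seed(as.integer(seed))
  b <- model$segment_bounds
  seg <- sample.int(length(model$segment_masses), n_samples, replace = TRUE,
                    prob = model$segment_masses)
  ang <- stats::runif(n_samples, b[seg], b[seg + 1])
  u <- stats::runif(n_samples)
  plo <- stats::pnorm(model$speed_truncation, model$speed_mean, model$speed_sd)
  spd <- stats::qnorm(plo + u * (1 - plo), model$speed_mean, model$speed_sd)
  vcrit_interp <- stats::approx(curve$fall_angle,
                                pmin(curve$v_crit, 1e9),  # Inf-safe
                                xout = ang, rule = 2)$y
  hit <- spd > vcrit_interp
  p_hat <- mean(hit)
  list(
    p_fx = 100 * model$hip_impact_factor * p_hat,
    se = 100 * model$hip_impact_factor * sqrt(p_hat * (1 - p_hat) / n_samples),
    n_samples = n_samples
  )
}

#' Per-subject relative risk of the hip protector
#'
#' `RR = P_Fx_HP / P_Fx`. The RR is undefined when the baseline fracture
#' probability is zero; such subjects are returned as `NA` and must be
#' excluded from cohort RR summaries.
#'
#' @param p_fx,p_fx_hp Percent probabilities in [0, 100] (vectorised).
#' @return RR (unitless), `NA` where `p_fx` is 0.
#' @export
relative_risk <- function(p_fx, p_fx_hp) {
  if (any(p_fx < 0 | p_fx_hp < 0)) stop("fracture probabilities must be >= 0")
  if (any(p_fx > 100 | p_fx_hp > 100)) stop("fracture probabilities are percentages <= 100")
  ifelse(p_fx > 0, p_fx_hp / p_fx, NA_real_)
}

#' Risk estimate for one subject from the two critical-velocity curves
#'
#' @param curve,curve_hp Critical-velocity curves without and with the hip
#'   protector.
#' @param model A [fall_config()].
#' @return One-row data.frame `p_fx`, `p_fx_hp`, `rr` (NA when P_Fx = 0).
#' @export
risk_estimate <- function(curve, curve_hp, model = fall_config()) {
  p <- compute_pfx(curve, model)
  p_hp <- compute_pfx(curve_hp, model)
  data.frame(p_fx = p, p_fx_hp = p_hp, rr = relative_risk(p, p_hp))
}
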