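#' Default covariate strata for the synthetic cohort
#'
#' Per sex-by-ethnicity stratum means and standard deviations of the subject
#' covariates used by [generate_cohort()]. The defaults describe an elderly
#' Southeast-Asian community-dwelling population (Chinese, Indian and Malay
#' ethnicities, both sexes): age in years, weight in kg, height in cm,
#' trochanteric soft-tissue thickness (TSTT) in cm, FRAX 10-year hip-fracture
#' probability (FRAX-HFP) in percent, femoral-neck areal BMD in g/cm^2 and its
#' T-score.
#'
#' @return A data.frame with one row per stratum and paired `<covariate>_mean` /
#'   `<covariate>_sd` columns.
#' @export
#' @examples
#' cohort_strata_defaults()
cohort_strata_defaults <- function() {
  cov_names <- c("age", "weight", "height", "tstt", "frax_hfp", "abmd", "t_score")
  tab <- rbind(
    # sex,     ethnicity, age,          weight,        height,        tstt,        frax,        abmd,        t_score
    c("male",   "Chinese", 72.62, 7.12, 65.43,  9.41, 164.83, 5.01, 2.43, 0.55, 4.54, 3.31, 0.72, 0.13, -1.96, 1.01),
    c("male",   "Indian",  71.19, 8.17, 71.71, 13.91, 167.15, 6.73, 3.16, 0.75, 2.11, 2.15, 0.84, 0.16, -1.04, 1.26),
    c("male",   "Malay",   72.22, 7.34, 69.71, 13.18, 164.07, 5.68, 2.94, 0.65, 2.82, 2.33, 0.76, 0.13, -1.64, 1.01),
    c("female", "Chinese", 71.54, 7.01, 55.58,  9.48, 154.13, 6.13, 3.06, 0.96, 4.36, 4.22, 0.62, 0.10, -1.82, 0.94),
    c("female", "Indian",  71.81, 8.39, 62.93, 10.73, 153.79, 5.92, 4.23, 0.99, 1.81, 1.81, 0.69, 0.13, -1.15, 1.21),
    c("female", "Malay",   69.71, 7.30, 62.61, 12.70, 150.09, 5.38, 4.21, 1.17, 2.61, 3.64, 0.64, 0.11, -1.61, 1.07)
  )
  out <- data.frame(
    sex = tab[, 1], ethnicity = tab[, 2],
    stringsAsFactors = FALSE
  )
  num <- matrix(as.numeric(tab[, -(1:2)]), nrow = nrow(tab))
  for (i in seq_along(cov_names)) {
    out[[paste0(cov_names[i], "_mean")]] <- num[, 2 * i - 1]
    out[[paste0(cov_names[i], "_sd")]] <- num[, 2 * i]
  }
  out
}

# physiological truncation bounds for covariate sampling
.covariate_bounds <- list(
  age      = c(55, 100),
  weight   = c(30, 150),
  height   = c(130, 200),
  tstt     = c(0.5, 8),
  frax_hfp = c(0, 30),
  abmd     = c(0.2, 1.5),
  t_score  = c(-5, 2)
)

# inverse-CDF truncated-normal draw from uniforms in (0,1)
.qtruncnorm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) {
    return(rep(min(max(mean, lo), hi), length(u)))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort of virtual subjects
#'
#' Draws subject covariates per sex-by-ethnicity stratum from independent
#' normal distributions truncated at physiological bounds (age 55-100 yr,
#' weight 30-150 kg, height 130-200 cm, TSTT 0.5-8 cm, FRAX-HFP 0-30 %, aBMD
#' 0.2-1.5 g/cm^2, T-score -5 to 2). BMI is recomputed from the sampled weight
#' and height rather than sampled, so the `bmi = weight/(height/100)^2`
#' identity holds exactly. An optional correlation matrix induces a Gaussian
#' copula across the seven covariates within each stratum; the default is
#' independence, since only marginal stratum statistics are specified.
#'
#' @param strata Stratum specification as returned by
#'   [cohort_strata_defaults()]: one row per stratum with `sex`, `ethnicity`
#'   and `<covariate>_mean` / `<covariate>_sd` columns.
#' @param n_per_stratum Number of subjects per stratum (>= 1).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param corr Optional 7x7 covariate correlation matrix (order: age, weight,
#'   height, tstt, frax_hfp, abmd, t_score). `NULL` means independent.
#' @return A data.frame with one row per subject: `subject_id`, `sex`,
#'   `ethnicity`, `age`, `weight`, `height`, `bmi`, `tstt`, `t_score`, `abmd`,
#'   `frax_hfp`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_strata_defaults(), n_per_stratum = 5, seed = 1)
#' head(coh)
generate_cohort <- function(strata, n_per_stratum, seed, corr = NULL) {
  stopifnot(is.data.frame(strata), n_per_stratum >= 1)
  cov_names <- names(.covariate_bounds)
  needed <- c("sex", "ethnicity", paste0(cov_names, "_mean"), paste0(cov_names, "_sd"))
  missing_cols <- setdiff(needed, names(strata))
  if (length(missing_cols) > 0) {
    stop("stratum spec is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(strata$sex %in% c("male", "female"))) {
    stop("unknown sex label in stratum spec (expected 'male'/'female')")
  }
  if (!all(strata$ethnicity %in% c("Chinese", "Indian", "Malay"))) {
    stop("unknown ethnicity label in stratum spec (expected Chinese/Indian/Malay)")
  }
  sds <- as.matrix(strata[, paste0(cov_names, "_sd")])
  if (any(sds < 0) || any(!is.finite(sds))) {
    stop("invalid stratum spec: SDs must be finite and >= 0")
  }
  p <- length(cov_names)
  if (is.null(corr)) corr <- diag(p)
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(dim(corr), c(p, p))) || !isSymmetric(unname(corr))) {
    stop("corr must be a symmetric ", p, "x", p, " matrix")
  }
  cl <- chol(corr)

  set.seed(as.integer(seed))
  rows <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    z <- matrix(stats::rnorm(n_per_stratum * p), n_per_stratum, p) %*% cl
    u <- stats::pnorm(z)
    vals <- matrix(NA_real_, n_per_stratum, p, dimnames = list(NULL, cov_names))
    for (j in seq_len(p)) {
      nm <- cov_names[j]
      b <- .covariate_bounds[[nm]]
      vals[, j] <- .qtruncnorm(
        u[, j],
        mean = strata[[paste0(nm, "_mean")]][s],
        sd = strata[[paste0(nm, "_sd")]][s],
        lo = b[1], hi = b[2]
      )
    }
    rows[[s]] <- data.frame(
      subject_id = sprintf(
        "%s_%s_%03d", substr(strata$sex[s], 1, 1), strata$ethnicity[s],
        seq_len(n_per_stratum)
      ),
      sex = strata$sex[s],
      ethnicity = strata$ethnicity[s],
      age = vals[, "age"],
      weight = vals[, "weight"],
      height = vals[, "height"],
      bmi = vals[, "weight"] / (vals[, "height"] / 100)^2,
      tstt = vals[, "tstt"],
      t_score = vals[, "t_score"],
      abmd = vals[, "abmd"],
      frax_hfp = vals[, "frax_hfp"],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default covariate-to-fracture-response link coefficients
#'
#' Coefficients mapping subject covariates to the latent fracture-response
#' parameters of the synthetic fall-simulation oracle. The baseline critical
#' velocity at a lateral fall is
#' `v_c0 = b0 + b_t * t_score + b_s * tstt - b_a * (age - 70)` (m/s), clamped
#' below at `v_c0_min`, so stronger bone (higher T-score), thicker trochanteric
#' soft tissue and younger age all raise the impact speed a subject can
#' tolerate. Heterogeneity not explained by covariates enters as a zero-mean
#' Gaussian jitter on `v_c0` (`v_c0_jitter_sd`) and a truncated-normal draw of
#' the per-subject hip-protector shift.
#'
#' @param b0 Intercept of the lateral critical velocity (m/s).
#' @param b_t T-score coefficient (m/s per T-score unit).
#' @param b_s TSTT coefficient (m/s per cm).
#' @param b_a Age coefficient (m/s per year above 70; subtracted).
#' @param v_c0_min Lower clamp on `v_c0` (m/s).
#' @param v_c0_jitter_sd SD of the subject-level residual on `v_c0` (m/s).
#' @param angle_curvature Quadratic growth of critical velocity toward +-90
#'   degrees (unitless, >= 0).
#' @param slope Fracture-length growth rate above the limit state (mm per m/s).
#' @param protector_shift_mean,protector_shift_sd Mean and SD (m/s) of the
#'   truncated-at-0.05 normal from which the per-subject protector shift is
#'   drawn.
#' @param noise_sd Oracle observation noise SD in mm (0 = deterministic
#'   simulations, the default).
#' @return A list of class `response_link`.
#' @export
default_response_link <- function(b0 = 2.2, b_t = 0.25, b_s = 0.15, b_a = 0.02,
                                  v_c0_min = 0.3, v_c0_jitter_sd = 0.15,
                                  angle_curvature = 0.6, slope = 20,
                                  protector_shift_mean = 0.35,
                                  protector_shift_sd = 0.15,
                                  noise_sd = 0) {
  link <- list(
    b0 = b0, b_t = b_t, b_s = b_s, b_a = b_a,
    v_c0_min = v_c0_min, v_c0_jitter_sd = v_c0_jitter_sd,
    angle_curvature = angle_curvature, slope = slope,
    protector_shift_mean = protector_shift_mean,
    protector_shift_sd = protector_shift_sd,
    noise_sd = noise_sd
  )
  if (!all(vapply(link, is.finite, logical(1)))) {
    stop("link coefficients must be finite")
  }
  structure(link, class = "response_link")
}

#' Construct fracture-response parameters directly
#'
#' Latent parameters of the parametric fracture-length oracle for one subject:
#' the noiseless fracture length is
#' `FxL(v, theta) = slope * max(0, v - v_c(theta))` with
#' `v_c(theta) = v_c0 * (1 + angle_curvature * (theta/90)^2)` and, when a hip
#' protector is worn, `v_c(theta) + protector_shift * cos^2(pi*theta/180)`
#' (attenuation maximal at the lateral angle 0 degrees, vanishing at +-90).
#'
#' @param v_c0 Baseline critical velocity at a lateral fall (m/s, > 0).
#' @param angle_curvature Unitless >= 0.
#' @param slope mm per (m/s), > 0.
#' @param protector_shift Additive critical-velocity increase with a protector
#'   (m/s, >= 0); 0 makes the protected and unprotected oracles identical.
#' @param noise_sd Observation noise SD (mm, >= 0).
#' @return Object of class `fracture_response_params`.
#' @export
fracture_response_params <- function(v_c0, angle_curvature = 0.6, slope = 10,
                                     protector_shift = 0.35, noise_sd = 0) {
  stopifnot(v_c0 > 0, angle_curvature >= 0, slope > 0, protector_shift >= 0,
            noise_sd >= 0)
  structure(
    list(v_c0 = v_c0, angle_curvature = angle_curvature, slope = slope,
         protector_shift = protector_shift, noise_sd = noise_sd),
    class = "fracture_response_params"
  )
}

#' @export
print.fracture_response_params <- function(x, ...) {
  cat("Fracture-response parameters (synthetic FE oracle)\n")
  cat(sprintf("  v_c0 (lateral critical velocity): %.3f m/s\n", x$v_c0))
  cat(sprintf("  angle curvature: %.3f   slope: %.2f mm/(m/s)\n",
              x$angle_curvature, x$slope))
  cat(sprintf("  protector shift: %.3f m/s   noise sd: %.3f mm\n",
              x$protector_shift, x$noise_sd))
  invisible(x)
}

#' Assign latent fracture-response parameters to a subject
#'
#' Maps one subject's covariates through the response link (see
#' [default_response_link()]) to the parameters of their personal
#' fracture-length oracle. The link makes the lateral critical velocity
#' strictly increasing in T-score and TSTT and strictly decreasing in age;
#' clamping at `v_c0_min` handles extreme covariates without errors.
#'
#' @param subject A one-row data.frame (or list) with at least `t_score`,
#'   `tstt`, `age`.
#' @param link A `response_link`; defaults to [default_response_link()].
#' @param seed Integer seed for the subject-level jitter and protector-shift
#'   draw.
#' @return A `fracture_response_params` object.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_strata_defaults(), 2, seed = 1)
#' assign_response_params(coh[1, ], seed = 42)
assign_response_params <- function(subject, link = default_response_link(),
                                   seed = 0) {
  stopifnot(inherits(link, "response_link"))
  v0 <- link$b0 + link$b_t * subject$t_score + link$b_s * subject$tstt -
    link$b_a * (subject$age - 70)
  set.seed(as.integer(seed))
  if (link$v_c0_jitter_sd > 0) {
    v0 <- v0 + stats::rnorm(1, 0, link$v_c0_jitter_sd)
  }
  v0 <- max(v0, link$v_c0_min)
  shift <- .qtruncnorm(stats::runif(1), link$protector_shift_mean,
                       link$protector_shift_sd, lo = 0.05, hi = Inf)
  fracture_response_params(
    v_c0 = v0,
    angle_curvature = link$angle_curvature,
    slope = link$slope,
    protector_shift = shift,
    noise_sd = link$noise_sd
  )
}

#' Fracture-length threshold defining a fracture outcome
#'
#' A simulated fall counts as a fracture when the fracture length on the
#' femoral surface reaches 10 mm.
#' @export
FXL_THRESHOLD_MM <- 10

#' True (noiseless) critical-velocity of the synthetic oracle
#'
#' Closed form of the minimum impact speed at which the noiseless oracle's
#' fracture length reaches the 10 mm threshold:
#' `v_c(theta) + threshold/slope`, with the protector shift included when
#' `protector = TRUE`. Used as the analytic reference when validating the
#' surrogate.
#'
#' @param params A `fracture_response_params`.
#' @param fall_angle Angle(s) in degrees, -90 (anterior) .. 0 (lateral) .. +90
#'   (posterior).
#' @param protector Logical.
#' @param threshold Fracture-length threshold in mm.
#' @return Critical velocity in m/s (vectorised over `fall_angle`).
#' @export
true_critical_velocity <- function(params, fall_angle, protector = FALSE,
                                   threshold = FXL_THRESHOLD_MM) {
  .oracle_vc(params, fall_angle, protector) + threshold / params$slope
}

# limit-state speed v_c(theta) below which fracture length is zero
.oracle_vc <- function(params, fall_angle, protector) {
  vc <- params$v_c0 * (1 + params$angle_curvature * (fall_angle / 90)^2)
  if (protector) {
    vc <- vc + params$protector_shift * cos(pi * fall_angle / 180)^2
  }
  vc
}

#' Evaluate the synthetic fall-simulation oracle
#'
#' Stand-in for a subject-specific finite-element fall simulation: returns the
#' fracture length produced by a fall at the given angle and impact velocity,
#' with or without a hip protector. The deterministic core is a ramp,
#' `slope * max(0, v - v_c(theta))`; optional Gaussian observation noise
#' (`params$noise_sd`) is added and the result floored at 0. The `fractured`
#' flag tests the fracture length against the 10 mm threshold.
#'
#' @param params A `fracture_response_params`.
#' @param fall_angle Degrees in [-90, 90] (vectorised).
#' @param impact_velocity m/s, > 0 (vectorised).
#' @param protector Logical scalar.
#' @param seed Optional integer seed for the observation noise.
#' @return A data.frame of fall-simulation records: `fall_angle`,
#'   `impact_velocity`, `fracture_length` (mm), `protector`, `fractured`.
#' @export
#' @examples
#' p <- fracture_response_params(v_c0 = 1.8)
#' oracle_fracture_length(p, fall_angle = 0, impact_velocity = 3)
oracle_fracture_length <- function(params, fall_angle, impact_velocity,
                                   protector = FALSE, seed = NULL) {
  stopifnot(inherits(params, "fracture_response_params"))
  if (any(fall_angle < -90 | fall_angle > 90)) {
    stop("fall_angle must lie in [-90, 90] degrees")
  }
  if (any(impact_velocity <= 0)) {
    stop("impact_velocity must be > 0")
  }
  n <- max(length(fall_angle), length(impact_velocity))
  fall_angle <- rep_len(fall_angle, n)
  impact_velocity <- rep_len(impact_velocity, n)
  vc <- .oracle_vc(params, fall_angle, protector)
  fxl <- params$slope * pmax(0, impact_velocity - vc)
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    fxl <- pmax(0, fxl + stats::rnorm(n, 0, params$noise_sd))
  }
  data.frame(
    fall_angle = fall_angle,
    impact_velocity = impact_velocity,
    fracture_length = fxl,
    protector = protector,
    fractured = fxl >= FXL_THRESHOLD_MM
  )
}
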