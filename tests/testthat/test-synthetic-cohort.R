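test_that("cohort generation matches stratum targets and is reproducible", {
  strata <- cohort_strata_defaults()
  coh <- generate_cohort(strata, n_per_stratum = 35, seed = 11)
  expect_equal(nrow(coh), 35 * nrow(strata))

  # male-Chinese sample mean age within 3*SD/sqrt(n) of the stratum target
  mc <- coh[coh$sex == "male" & coh$ethnicity == "Chinese", ]
  expect_lt(abs(mean(mc$age) - 72.62), 3 * 7.12 / sqrt(35))
  expect_lt(abs(mean(mc$tstt) - 2.43), 3 * 0.55 / sqrt(35))

  # BMI is recomputed from sampled weight/height
  expect_equal(coh$bmi, coh$weight / (coh$height / 100)^2, tolerance = 1e-12)

  # same seed -> byte-identical tables
  coh2 <- generate_cohort(strata, n_per_stratum = 35, seed = 11)
  expect_identical(coh, coh2)
  coh3 <- generate_cohort(strata, n_per_stratum = 35, seed = 12)
  expect_false(identical(coh$age, coh3$age))
})

test_that("degenerate SDs collapse every subject onto the stratum mean", {
  strata <- cohort_strata_defaults()[1, ]
  for (nm in c("age", "weight", "height", "tstt", "frax_hfp", "abmd", "t_score")) {
    strata[[paste0(nm, "_sd")]] <- 0
  }
  coh <- generate_cohort(strata, n_per_stratum = 5, seed = 1)
  expect_true(all(coh$age == strata$age_mean))
  expect_true(all(coh$t_score == strata$t_score_mean))
  expect_true(all(coh$weight == strata$weight_mean))
})

test_that("per-stratum means converge to targets at large n", {
  strata <- cohort_strata_defaults()[c(1, 4), ]
  n <- 1e4
  coh <- generate_cohort(strata, n_per_stratum = n, seed = 5)
  for (s in seq_len(nrow(strata))) {
    d <- coh[coh$sex == strata$sex[s] & coh$ethnicity == strata$ethnicity[s], ]
    for (nm in c("age", "tstt", "t_score", "weight")) {
      tol <- 4 * strata[[paste0(nm, "_sd")]][s] / sqrt(n)
      expect_lt(abs(mean(d[[nm]]) - strata[[paste0(nm, "_mean")]][s]), tol)
    }
  }
  # truncation bounds respected
  expect_true(all(coh$age >= 55 & coh$age <= 100))
  expect_true(all(coh$frax_hfp >= 0))
  expect_true(all(coh$tstt >= 0.5))
})

test_that("invalid stratum specs are rejected", {
  strata <- cohort_strata_defaults()
  bad <- strata; bad$age_sd[1] <- -1
  expect_error(generate_cohort(bad, 5, seed = 1), "SD")
  bad2 <- strata; bad2$ethnicity[1] <- "Martian"
  expect_error(generate_cohort(bad2, 5, seed = 1), "ethnicity")
  expect_error(generate_cohort(strata[, -3], 5, seed = 1), "missing")
})

test_that("response link is monotone in bone and soft-tissue covariates", {
  base <- list(t_score = 0, tstt = 3, age = 70)
  link <- default_response_link(v_c0_jitter_sd = 0)  # deterministic link
  v_osteo <- assign_response_params(within(as.data.frame(base), t_score <- -3),
                                    link, seed = 1)$v_c0
  v_norm <- assign_response_params(as.data.frame(base), link, seed = 1)$v_c0
  expect_lt(v_osteo, v_norm)

  older <- assign_response_params(within(as.data.frame(base), age <- 85),
                                  link, seed = 1)$v_c0
  expect_lt(older, v_norm)
  thick <- assign_response_params(within(as.data.frame(base), tstt <- 5),
                                  link, seed = 1)$v_c0
  expect_gt(thick, v_norm)

  # all coefficients but the intercept zero -> v_c0 = b0 for everyone
  flat <- default_response_link(b0 = 1.7, b_t = 0, b_s = 0, b_a = 0,
                                v_c0_jitter_sd = 0)
  for (ts in c(-3, 0, 2)) {
    subj <- data.frame(t_score = ts, tstt = 2, age = 80)
    expect_equal(assign_response_params(subj, flat, seed = 9)$v_c0, 1.7)
  }
  expect_gt(assign_response_params(as.data.frame(base), link, seed = 3)$protector_shift, 0)
})

test_that("stratum-mean subjects order Chinese above Indian males in risk", {
  strata <- cohort_strata_defaults()
  mean_subject <- function(row) {
    data.frame(t_score = row$t_score_mean, tstt = row$tstt_mean,
               age = row$age_mean)
  }
  link <- default_response_link(v_c0_jitter_sd = 0)
  v_chinese <- assign_response_params(mean_subject(strata[1, ]), link, 1)$v_c0
  v_indian <- assign_response_params(mean_subject(strata[2, ]), link, 1)$v_c0
  expect_lt(v_chinese, v_indian)  # higher T-score & TSTT protect Indians
  # lower critical velocity -> higher fracture probability downstream
  fc <- fall_config()
  p_ch <- compute_pfx(brute_force_critical_velocity(fracture_response_params(v_chinese)), fc)
  p_in <- compute_pfx(brute_force_critical_velocity(fracture_response_params(v_indian)), fc)
  expect_gt(p_ch, p_in)
})

test_that("oracle ramp is analytic at and above the limit state", {
  p <- fracture_response_params(v_c0 = 1.5, angle_curvature = 0.6, slope = 10,
                                protector_shift = 0.4, noise_sd = 0)
  for (theta in c(-90, -45, 0, 30, 90)) {
    vc <- true_critical_velocity(p, theta) - FXL_THRESHOLD_MM / p$slope
    at <- oracle_fracture_length(p, theta, vc)
    expect_equal(at$fracture_length, 0, tolerance = 1e-12)
    expect_false(at$fractured)
    above <- oracle_fracture_length(p, theta, vc + 1)
    expect_equal(above$fracture_length, 10, tolerance = 1e-9)
    expect_true(oracle_fracture_length(p, theta, vc + 1.01)$fractured)
  }
  expect_error(oracle_fracture_length(p, 95, 2), "fall_angle")
  expect_error(oracle_fracture_length(p, 0, -1), "impact_velocity")
})

test_that("protector never increases fracture length and is strict laterally", {
  p <- fracture_response_params(v_c0 = 1.5, protector_shift = 0.5)
  ang <- seq(-90, 90, by = 5)
  for (v in c(1.8, 2.6, 3.4)) {
    unprot <- oracle_fracture_length(p, ang, v, protector = FALSE)$fracture_length
    prot <- oracle_fracture_length(p, ang, v, protector = TRUE)$fracture_length
    expect_true(all(prot <= unprot + 1e-12))
  }
  v0 <- true_critical_velocity(p, 0) + 0.2
  expect_lt(oracle_fracture_length(p, 0, v0, protector = TRUE)$fracture_length,
            oracle_fracture_length(p, 0, v0, protector = FALSE)$fracture_length)
})

test_that("noiseless fracture length is monotone in velocity on a dense grid", {
  p <- fracture_response_params(v_c0 = 1.2, angle_curvature = 0.9, slope = 15)
  ang <- seq(-90, 90, length.out = 100)
  vel <- seq(0.1, 5, length.out = 100)
  for (a in ang) {
    fxl <- oracle_fracture_length(p, a, vel)$fracture_length
    expect_true(all(diff(fxl) >= -1e-12))
  }
})

test_that("brute-force bisection on the oracle matches the closed-form curve", {
  p <- fracture_response_params(v_c0 = 1.4, angle_curvature = 0.7, slope = 12,
                                protector_shift = 0.45)
  for (prot in c(FALSE, TRUE)) {
    for (theta in c(-90, -40, 0, 25, 60, 90)) {
      expect_equal(bisect_oracle_vcrit(p, theta, protector = prot),
                   true_critical_velocity(p, theta, protector = prot),
                   tolerance = 1e-6)
    }
    # protector never lowers the critical velocity
    ang <- seq(-90, 90, by = 3)
    expect_true(all(true_critical_velocity(p, ang, protector = TRUE) >=
                      true_critical_velocity(p, ang, protector = FALSE) - 1e-12))
  }
})

test_that("oracle noise is seed-reproducible and floored at zero", {
  p <- fracture_response_params(v_c0 = 2, slope = 10, noise_sd = 3)
  r1 <- oracle_fracture_length(p, 0, 2.1, seed = 4)
  r2 <- oracle_fracture_length(p, 0, 2.1, seed = 4)
  expect_identical(r1, r2)
  many <- oracle_fracture_length(p, rep(0, 500), rep(0.5, 500), seed = 8)
  expect_true(all(many$fracture_length >= 0))
})
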