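test_that("initial design is deterministic, in-bounds and prefix-stable", {
  cfg <- surrogate_config()
  des <- initial_design(cfg)
  expect_equal(nrow(des), 6)
  expect_true(all(des$fall_angle >= -90 & des$fall_angle <= 90))
  expect_true(all(des$impact_velocity >= 0.5 & des$impact_velocity <= 4.5))
  expect_equal(des, initial_design(cfg))

  des3 <- initial_design(surrogate_config(n_initial = 3))
  expect_equal(des3, des[1:3, ])
  # lateral extremes, off-lateral midpoints, then low-velocity corner anchors
  expect_equal(des$fall_angle, c(0, 0, -60, 60, -90, 90))
  expect_equal(des$impact_velocity, c(0.5, 4.5, 2.5, 2.5, 0.5, 0.5))
  expect_error(initial_design(surrogate_config(angle_bounds = c(10, 10))),
               "degenerate")
})

test_that("surrogate_config enforces its invariants", {
  expect_error(surrogate_config(n_initial = 2), ">= 3")
  expect_error(surrogate_config(n_initial = 10, budget = 8), "budget")
  expect_error(surrogate_config(velocity_bounds = c(0, 4.5)), "> 0")
  expect_error(surrogate_config(hyper_bounds = list(
    constant = c(1e-4, 1e4), length_scale = c(1, 0.1),
    sigma0 = c(1e-2, 1e2), noise = c(1e-8, 1))), "length_scale")
})

test_that("acquisition objective follows its closed form", {
  cfg <- surrogate_config()
  at_thres <- mock_surrogate(function(a, v) rep(10, length(a)),
                             function(a, v) rep(2, length(a)), cfg)
  expect_equal(acquisition_objective(at_thres, 0, 2, cfg), -2)

  no_sd <- mock_surrogate(function(a, v) rep(10, length(a)),
                          function(a, v) rep(0, length(a)), cfg)
  expect_equal(acquisition_objective(no_sd, 0, 2, cfg), 0)

  # 1 mm off the threshold the exponential term annihilates the objective
  off <- mock_surrogate(function(a, v) rep(11, length(a)),
                        function(a, v) rep(5, length(a)), cfg)
  expect_lte(abs(acquisition_objective(off, 0, 2, cfg)), 5 * exp(-900))
})

test_that("proposals seek uncertainty away from the training angles", {
  cfg <- surrogate_config(seed = 3)
  recs <- data.frame(fall_angle = 0,
                     impact_velocity = c(0.8, 1.5, 2.2, 3.0, 3.8),
                     fracture_length = 10 * pmax(0, c(0.8, 1.5, 2.2, 3.0, 3.8) - 1.8))
  model <- fit_gpr(recs, cfg)
  prop <- propose_next(model, cfg)
  expect_gt(abs(prop$fall_angle), 0)
  sd_prop <- surrogate_predict(model, prop$fall_angle, prop$impact_velocity)$sd
  sd_lateral <- surrogate_predict(model, 0, prop$impact_velocity)$sd
  expect_gte(sd_prop, sd_lateral)
  # strictly inside the domain
  expect_true(prop$fall_angle > -90 && prop$fall_angle < 90)
  expect_true(prop$impact_velocity > 0.5 && prop$impact_velocity < 4.5)
})

test_that("a degenerate zero-uncertainty surrogate falls back to the first grid point", {
  cfg <- surrogate_config()
  dead <- mock_surrogate(function(a, v) rep(0, length(a)),
                         function(a, v) rep(0, length(a)), cfg)
  prop <- propose_next(dead, cfg)
  first_angle <- seq(-90, 90, length.out = cfg$acq_screen[1] + 2)[2]
  first_vel <- seq(0.5, 4.5, length.out = cfg$acq_screen[2] + 2)[2]
  expect_equal(prop$fall_angle, first_angle)
  expect_equal(prop$impact_velocity, first_vel)
})

test_that("active learning spends exactly the budget and is seed-reproducible", {
  p <- fracture_response_params(v_c0 = 1.8, angle_curvature = 0.6, slope = 10)
  cfg <- surrogate_config(budget = 8, n_initial = 4, seed = 21)
  fit <- active_learning_loop(p, cfg)
  expect_equal(fit$n_oracle_calls, 8)
  expect_equal(nrow(fit$records), 8)
  expect_equal(sum(fit$records$iteration == 0), 4)
  expect_equal(max(fit$records$iteration), 4)

  fit2 <- active_learning_loop(p, cfg)
  expect_identical(fit$records, fit2$records)

  # proposals (iterations >= 1) lie strictly inside the domain
  acq <- fit$records[fit$records$iteration > 0, ]
  expect_true(all(acq$fall_angle > -90 & acq$fall_angle < 90))
  expect_true(all(acq$impact_velocity > 0.5 & acq$impact_velocity < 4.5))

  # budget = n_initial -> no acquisition rounds
  cfg0 <- surrogate_config(budget = 4, n_initial = 4, seed = 21)
  fit0 <- active_learning_loop(p, cfg0)
  expect_equal(fit0$n_oracle_calls, 4)
  expect_true(all(fit0$records$iteration == 0))
})

test_that("acquisitions concentrate near the 10 mm contour on the synthetic oracle", {
  p <- fracture_response_params(v_c0 = 1.8, angle_curvature = 0.6, slope = 10)
  cfg <- surrogate_config(budget = 14, n_initial = 4, seed = 5)
  fit <- active_learning_loop(p, cfg)
  acq <- fit$records[fit$records$iteration > 0, ]
  expect_lt(median(abs(acq$fracture_length - 10)), 1)
})

test_that("critical-velocity extraction finds the smallest root and its sentinels", {
  cfg <- surrogate_config()
  # exact linear surrogate FxL = 10 * (v - 1.5): root at 2.5 m/s at every angle
  lin <- mock_surrogate(function(a, v) 10 * (v - 1.5), config = cfg)
  curve <- extract_critical_velocity(lin, cfg, angle_grid = seq(-90, 90, 10))
  expect_true(all(abs(curve$v_crit - 2.5) < 1e-3))

  # mean capped below threshold -> +Inf sentinel everywhere
  low <- mock_surrogate(function(a, v) pmin(10 * (v - 1.5), 9), config = cfg)
  curve_low <- extract_critical_velocity(low, cfg, angle_grid = seq(-90, 90, 10))
  expect_true(all(is.infinite(curve_low$v_crit)))

  # mean above threshold at the lower bound -> lower-bound sentinel
  hot <- mock_surrogate(function(a, v) rep(12, length(a)), config = cfg)
  curve_hot <- extract_critical_velocity(hot, cfg, angle_grid = seq(-90, 90, 10))
  expect_true(all(curve_hot$v_crit == 0.5))

  # non-monotone mean with two roots: the smallest is returned
  wavy <- mock_surrogate(function(a, v) 15 - 10 * abs(v - 2.5), config = cfg)
  curve_wavy <- extract_critical_velocity(wavy, cfg, angle_grid = c(0))
  expect_equal(curve_wavy$v_crit, 2.0, tolerance = 1e-3)

  expect_error(extract_critical_velocity(lin, cfg, angle_grid = c(-100, 0)),
               "angle bounds")
})

test_that("the 20-budget surrogate reproduces the analytic curve of the reference oracle", {
  p <- fracture_response_params(v_c0 = 1.8, angle_curvature = 0.6, slope = 10)
  cfg <- surrogate_config(seed = 17)
  fit <- active_learning_loop(p, cfg)
  curve <- extract_critical_velocity(fit$model, cfg)
  ref <- brute_force_critical_velocity(p)
  expect_lt(curve_rmse(curve, ref), 0.15)
  # analytic cross-check of the reference itself
  expect_equal(ref$v_crit[ref$fall_angle == 0],
               true_critical_velocity(p, 0), tolerance = 1e-5)
})

test_that("a weaker subject yields a pointwise-not-lower extracted curve", {
  cfg <- surrogate_config(seed = 9)
  weak <- fracture_response_params(v_c0 = 1.5, angle_curvature = 0.6, slope = 10)
  strong <- fracture_response_params(v_c0 = 1.9, angle_curvature = 0.6, slope = 10)
  c_weak <- extract_critical_velocity(active_learning_loop(weak, cfg)$model, cfg)
  c_strong <- extract_critical_velocity(active_learning_loop(strong, cfg)$model, cfg)
  vb <- c(0.5, 4.5)
  cl <- function(v) pmin(pmax(v, vb[1]), vb[2])
  expect_true(all(cl(c_strong$v_crit) >= cl(c_weak$v_crit) - 0.05))
})
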