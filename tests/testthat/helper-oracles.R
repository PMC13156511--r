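# Independent oracles and mock objects used across the suite.

# Two-sided Fisher exact p by full hypergeometric enumeration of all tables
# with the observed margins (the probability-ordering definition).
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  x <- max(0, k - n2):min(k, m)
  probs <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Smallest fracturing speed of the noiseless oracle found by naive grid+bisect
# directly on oracle_fracture_length (independent of the closed form).
bisect_oracle_vcrit <- function(params, angle, protector = FALSE,
                                lo = 0.01, hi = 20, tol = 1e-7) {
  fxl <- function(v) {
    oracle_fracture_length(params, angle, v, protector = protector)$fracture_length
  }
  if (fxl(lo) >= FXL_THRESHOLD_MM) return(lo)
  if (fxl(hi) < FXL_THRESHOLD_MM) return(Inf)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fxl(mid) >= FXL_THRESHOLD_MM) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Mock surrogate with analytic mean/sd surfaces; carries a config so the
# default-config arguments of the surrogate operations work.
mock_surrogate <- function(mean_fn, sd_fn = function(a, v) rep(1, length(a)),
                           config = surrogate_config()) {
  structure(list(mean_fn = mean_fn, sd_fn = sd_fn, config = config),
            class = "mock_surrogate")
}

surrogate_predict.mock_surrogate <- function(model, fall_angle, impact_velocity, ...) {
  n <- max(length(fall_angle), length(impact_velocity))
  a <- rep_len(fall_angle, n); v <- rep_len(impact_velocity, n)
  list(mean = model$mean_fn(a, v), sd = model$sd_fn(a, v))
}
registerS3method("surrogate_predict", "mock_surrogate",
                 surrogate_predict.mock_surrogate,
                 envir = asNamespace("hipfxsim"))
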