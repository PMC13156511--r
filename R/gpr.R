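# Gaussian-process regression with the composite kernel
#   k = C * RBF * DotProduct + WhiteKernel
# over scaled (fall angle, impact velocity) inputs. Hyperparameters are fitted
# by marginal-likelihood maximization (L-BFGS-B on log parameters, random
# restarts within bounds).

# kernel cross-covariance (no white term); par = list(constant, length_scale, sigma0)
.kernel_cross <- function(X1, X2, par) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  rbf <- exp(-d2 / (2 * par$length_scale^2))
  dot <- par$sigma0^2 + tcrossprod(X1, X2)
  par$constant * rbf * dot
}

.gpr_nll <- function(log_par, X, y) {
  par <- list(constant = exp(log_par[1]), length_scale = exp(log_par[2]),
              sigma0 = exp(log_par[3]))
  noise <- exp(log_par[4])
  K <- .kernel_cross(X, X, par)
  diag(K) <- diag(K) + noise + 1e-10
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

# map raw (angle, velocity) to the scaled GP input space:
# angle / 90 in [-1, 1]; velocity centred at the domain midpoint and divided
# by the half-range, also [-1, 1] over the velocity bounds.
.scale_inputs <- function(fall_angle, impact_velocity, config) {
  vb <- config$velocity_bounds
  mid <- mean(vb)
  half <- diff(vb) / 2
  cbind(fall_angle / 90, (impact_velocity - mid) / half)
}

#' Fit the Gaussian-process surrogate of fracture length
#'
#' Fits a GP regression of fracture length (mm) on (fall angle, impact
#' velocity) with the composite kernel
#' `C * RBF * DotProduct + WhiteKernel`: a constant kernel scaling overall
#' variance, an isotropic radial-basis kernel for smooth nonlinearity, a
#' dot-product kernel for linear trends, and a white kernel absorbing
#' simulation noise. Inputs are scaled internally (angle by 90 degrees,
#' velocity by the domain midpoint/half-range); fracture lengths stay in mm.
#' Hyperparameters are optimised by log-marginal-likelihood maximisation with
#' `config$n_restarts` random restarts inside the bounds of
#' `config$hyper_bounds`, seeded from `config$seed`. The same kernel structure
#' is reused for every subject; only the hyperparameters are refitted.
#'
#' @param records Data.frame of fall-simulation records with columns
#'   `fall_angle`, `impact_velocity`, `fracture_length` (>= 3 rows).
#' @param config A [surrogate_config()].
#' @return An object of class `gpr_model`.
#' @export
fit_gpr <- function(records, config = surrogate_config()) {
  if (!is.data.frame(records) || nrow(records) < 3) {
    stop("at least 3 simulation records are required to fit the surrogate")
  }
  y <- records$fracture_length
  if (any(!is.finite(y))) stop("non-finite fracture lengths in records")
  X <- .scale_inputs(records$fall_angle, records$impact_velocity, config)

  hb <- config$hyper_bounds
  lower <- log(c(hb$constant[1], hb$length_scale[1], hb$sigma0[1], hb$noise[1]))
  upper <- log(c(hb$constant[2], hb$length_scale[2], hb$sigma0[2], hb$noise[2]))
  start0 <- pmin(pmax(log(c(1, 1, 1, 1e-5)), lower), upper)

  set.seed(as.integer(config$seed))
  starts <- rbind(
    start0,
    matrix(stats::runif(4 * config$n_restarts, rep(lower, each = config$n_restarts),
                        rep(upper, each = config$n_restarts)),
           ncol = 4)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], .gpr_nll, X = X, y = y, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("marginal-likelihood optimisation failed at all starts")

  par <- list(constant = exp(best$par[1]), length_scale = exp(best$par[2]),
              sigma0 = exp(best$par[3]))
  noise <- exp(best$par[4])
  K <- .kernel_cross(X, X, par)
  diag(K) <- diag(K) + noise + 1e-10
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  structure(
    list(X = X, y = y, records = records, par = par, noise = noise,
         L = L, alpha = alpha, log_marginal_likelihood = -best$value,
         config = config),
    class = "gpr_model"
  )
}

#' Predict from a fitted surrogate
#'
#' Posterior mean and predictive standard deviation of fracture length at the
#' given fall configurations. The predictive variance includes the fitted
#' white-noise level, so the uncertainty never collapses exactly to zero at
#' training points.
#'
#' @param model A fitted surrogate (class `gpr_model`, or any object with a
#'   `surrogate_predict` method).
#' @param fall_angle,impact_velocity Vectors (recycled to equal length).
#' @param ... Passed to methods.
#' @return A list with numeric vectors `mean` and `sd` (mm).
#' @export
surrogate_predict <- function(model, fall_angle, impact_velocity, ...) {
  UseMethod("surrogate_predict")
}

#' @rdname surrogate_predict
#' @export
surrogate_predict.gpr_model <- function(model, fall_angle, impact_velocity, ...) {
  n <- max(length(fall_angle), length(impact_velocity))
  fall_angle <- rep_len(fall_angle, n)
  impact_velocity <- rep_len(impact_velocity, n)
  Xs <- .scale_inputs(fall_angle, impact_velocity, model$config)
  Ks <- .kernel_cross(Xs, model$X, model$par)
  mu <- as.numeric(Ks %*% model$alpha)
  v <- forwardsolve(t(model$L), t(Ks))
  prior_var <- model$par$constant * (model$par$sigma0^2 + rowSums(Xs^2)) +
    model$noise
  var <- prior_var - colSums(v^2)
  list(mean = mu, sd = sqrt(pmax(var, 0)))
}

#' @export
print.gpr_model <- function(x, ...) {
  cat("Gaussian-process fracture-length surrogate\n")
  cat(sprintf("  training simulations: %d\n", length(x$y)))
  cat(sprintf("  kernel: C=%.3g * RBF(l=%.3g) * DotProduct(sigma0=%.3g) + White(%.3g)\n",
              x$par$constant, x$par$length_scale, x$par$sigma0, x$noise))
  cat(sprintf("  log marginal likelihood: %.3f\n", x$log_marginal_likelihood))
  invisible(x)
}
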