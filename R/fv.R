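# Force-velocity analysis: sweeping the molecular model over external force
# and fitting the hyperbolic Hill relation
#   v_hill(f) = v0 (fs - f) / (fs + f / beta)
# by nonlinear least squares.

#' Hill hyperbolic force-velocity relation
#'
#' `v_hill(f) = v0 * (fs - f) / (fs + f / beta)`: the shortening velocity at
#' external force `f`, equal to the unloaded velocity `v0` at `f = 0` and
#' zero at the stall force `fs`, with dimensionless curvature `beta`.
#'
#' @param f external force (vectorized), same units as `fs`.
#' @param v0 unloaded shortening velocity (> 0).
#' @param fs stall force (> 0).
#' @param beta curvature parameter (> 0).
#' @return Velocity, same units as `v0`.
#' @examples
#' hill_velocity(c(0, 10, 20), v0 = 1000, fs = 20, beta = 2)
#' @export
hill_velocity <- function(f, v0, fs, beta) {
  if (fs <= 0 || beta <= 0) stop("'fs' and 'beta' must be > 0", call. = FALSE)
  denom <- fs + f / beta
  if (any(denom == 0)) stop("singular denominator: fs + f/beta = 0", call. = FALSE)
  v0 * (fs - f) / denom
}

#' Force-velocity sweep of the parallel cluster model
#'
#' Evaluates the mean bound-ensemble velocity on a grid of external forces,
#' either deterministically from the master-equation stationary solution or
#' stochastically from Gillespie trajectories.
#'
#' @param params a [pcm_params()] object.
#' @param forces strictly increasing grid of external forces, pN.
#' @param method `"master_eq"` (default) or `"gillespie"`.
#' @param n_events events per Gillespie run (gillespie method only).
#' @param seed integer seed, required for the gillespie method; run `k` of
#'   the sweep uses `seed + k - 1`.
#' @return An object of class `fv_curve`: a data frame with columns
#'   `force_pN`, `velocity_nm_s`, `velocity_se` (`NA` for the deterministic
#'   method), with attributes `params`, `method`, `seed`.
#' @examples
#' fv <- pcm_fv_sweep(pcm_params(N = 2), forces = c(0, 5, 10))
#' fv
#' @export
pcm_fv_sweep <- function(params, forces, method = c("master_eq", "gillespie"),
                         n_events = 2e4, seed = NULL) {
  method <- match.arg(method)
  if (length(forces) == 0) stop("empty force grid", call. = FALSE)
  if (is.unsorted(forces, strictly = TRUE))
    stop("'forces' must be strictly increasing", call. = FALSE)
  if (method == "gillespie" && is.null(seed))
    stop("'seed' is required for the gillespie method", call. = FALSE)
  if (method == "master_eq") {
    v <- vapply(forces, function(f) {
      tryCatch(pcm_mean_bound_velocity(f, params),
               error = function(e) {
                 warning("master equation degenerate at f = ", f, ": ",
                         conditionMessage(e), call. = FALSE)
                 NA_real_
               })
    }, numeric(1))
    se <- rep(NA_real_, length(forces))
  } else {
    res <- lapply(seq_along(forces), function(k) {
      traj <- pcm_simulate(forces[k], params, n_events = n_events,
                           seed = seed + k - 1L)
      pcm_empirical_velocity(traj)
    })
    v <- vapply(res, `[[`, numeric(1), "velocity")
    se <- vapply(res, `[[`, numeric(1), "se")
  }
  out <- data.frame(force_pN = forces, velocity_nm_s = v, velocity_se = se)
  attr(out, "params") <- params
  attr(out, "method") <- method
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(out) <- c("fv_curve", "data.frame")
  out
}

#' Fit the Hill force-velocity relation to a force-velocity curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the hyperbolic Hill
#' relation to a sampled force-velocity curve. Points with nonpositive
#' velocity (at or beyond stall) are excluded, since the relation describes
#' shortening. Starting values: `v0` at the velocity of the smallest force,
#' `fs` at the interpolated zero crossing (or the largest force), `beta` at
#' 1; `beta` is constrained to (0, 100] to keep the fit away from the
#' degenerate linear limit.
#'
#' @param curve an `fv_curve` from [pcm_fv_sweep()], or a data frame with
#'   columns `force_pN` and `velocity_nm_s`.
#' @param beta_max upper bound for `beta` during fitting.
#' @return An object of class `hill_fit` with components `coefficients`
#'   (named `v0`, `fs`, `beta`), `r_squared`, `fitted.values`, `residuals`,
#'   `data` (the points used), `curve` (the full input), `method`, `seed`,
#'   `nls` (the underlying fit object).
#' @examples
#' f <- seq(0, 19, length.out = 10)
#' fit <- fit_hill(data.frame(force_pN = f,
#'                            velocity_nm_s = hill_velocity(f, 1000, 20, 2)))
#' coef(fit)
#' @export
fit_hill <- function(curve, beta_max = 100) {
  if (!all(c("force_pN", "velocity_nm_s") %in% names(curve)))
    stop("'curve' must have columns 'force_pN' and 'velocity_nm_s'", call. = FALSE)
  ok <- is.finite(curve$velocity_nm_s) & curve$velocity_nm_s > 0
  if (any(!ok))
    message(sum(!ok), " point(s) with nonpositive or missing velocity excluded from the fit")
  pts <- curve[ok, , drop = FALSE]
  if (nrow(pts) < 4)
    stop("need at least 4 points with positive velocity to fit the Hill relation",
         call. = FALSE)
  f <- pts$force_pN
  v <- pts$velocity_nm_s
  v0_init <- v[which.min(f)]
  # fs start: linear interpolation of the first zero crossing of the input
  # curve, falling back to just beyond the largest fitted force
  vc <- curve$velocity_nm_s
  fc <- curve$force_pN
  cross <- which(is.finite(vc) & vc <= 0 & seq_along(vc) > 1)[1]
  fs_init <- if (!is.na(cross) && is.finite(vc[cross - 1]) && vc[cross - 1] > 0) {
    fc[cross - 1] + (fc[cross] - fc[cross - 1]) *
      vc[cross - 1] / (vc[cross - 1] - vc[cross])
  } else max(f) * 1.05
  fit <- minpack.lm::nlsLM(
    v ~ v0 * (fs - f) / (fs + f / beta),
    data = data.frame(f = f, v = v),
    start = list(v0 = v0_init, fs = fs_init, beta = 1),
    lower = c(v0 = 1e-9, fs = 1e-9, beta = 1e-9),
    upper = c(v0 = Inf, fs = Inf, beta = beta_max),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  fitted <- hill_velocity(f, cf[["v0"]], cf[["fs"]], cf[["beta"]])
  res <- v - fitted
  r2 <- 1 - sum(res^2) / sum((v - mean(v))^2)
  structure(list(coefficients = cf, r_squared = r2,
                 fitted.values = fitted, residuals = res,
                 data = pts, curve = curve,
                 method = attr(curve, "method"), seed = attr(curve, "seed"),
                 nls = fit),
            class = "hill_fit")
}

#' Coefficient of determination of a Hill fit on a restricted force range
#'
#' Recomputes R-squared of a fitted Hill relation using only curve points
#' with forces inside `f_range`, e.g. the sub-stall range
#' `[0, 0.95 * fs]` on which the hyperbola is compared with the molecular
#' model.
#'
#' @param fit a [fit_hill()] object.
#' @param f_range length-2 numeric range of forces, pN.
#' @return R-squared over the restricted points.
#' @export
hill_fit_r2 <- function(fit, f_range) {
  d <- fit$data
  keep <- d$force_pN >= f_range[1] & d$force_pN <= f_range[2]
  if (sum(keep) < 3) stop("fewer than 3 points in 'f_range'", call. = FALSE)
  v <- d$velocity_nm_s[keep]
  pred <- predict(fit, newdata = data.frame(force_pN = d$force_pN[keep]))
  1 - sum((v - pred)^2) / sum((v - mean(v))^2)
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("Hill force-velocity fit\n")
  cat(sprintf("  v0 = %.*g nm/s, fs = %.*g pN, beta = %.*g\n",
              digits, x$coefficients[["v0"]], digits, x$coefficients[["fs"]],
              digits, x$coefficients[["beta"]]))
  cat(sprintf("  R-squared = %.*g on %d points\n", digits, x$r_squared,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  s <- summary(object$nls)
  structure(list(fit = object, nls_summary = s), class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates (nonlinear least squares):\n")
  stats::printCoefmat(x$nls_summary$coefficients)
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
              x$nls_summary$sigma, x$nls_summary$df[2]))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' Predicted Hill velocities
#'
#' @param object a [fit_hill()] object.
#' @param newdata optional data frame with a `force_pN` column; defaults to
#'   the fitted points.
#' @param ... unused.
#' @return Predicted velocities, nm/s.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$data$force_pN else newdata$force_pN
  cf <- object$coefficients
  hill_velocity(f, cf[["v0"]], cf[["fs"]], cf[["beta"]])
}

#' @export
plot.hill_fit <- function(x, n_grid = 200, ...) {
  d <- x$curve
  graphics::plot(d$force_pN, d$velocity_nm_s, pch = 19,
                 xlab = "external force f (pN)",
                 ylab = expression(V[b] ~ "(nm/s)"), ...)
  fg <- seq(min(d$force_pN), max(d$force_pN), length.out = n_grid)
  graphics::lines(fg, predict(x, data.frame(force_pN = fg)),
                  lty = 2, lwd = 2)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", bty = "n",
                   legend = c("molecular model", "Hill fit"),
                   pch = c(19, NA), lty = c(NA, 2), lwd = c(NA, 2))
  invisible(x)
}

#' @export
print.fv_curve <- function(x, ...) {
  cat(sprintf("Force-velocity curve (%s method, %d forces)\n",
              attr(x, "method"), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
plot.fv_curve <- function(x, ...) {
  graphics::plot(x$force_pN, x$velocity_nm_s, type = "b", pch = 19,
                 xlab = "external force f (pN)",
                 ylab = expression(V[b] ~ "(nm/s)"), ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
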