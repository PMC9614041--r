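# Gillespie stochastic simulation of the effective bound-count process,
# with ensemble-position bookkeeping. Waiting times by inversion of the
# exponential CDF; events by rate ratio. Because the external force is
# constant, every state-dependent quantity depends on i alone and is
# precomputed before the event loop.

#' Simulate a stochastic trajectory of the myosin ensemble
#'
#' Exact stochastic simulation of the one-step process in the bound count
#' `i` at constant external force. Waiting times are drawn by Monte-Carlo
#' inversion from the exponential distribution with total rate
#' `g(i) + r(i)`; the event type is chosen by rate ratio. Position
#' bookkeeping follows the model's displacement rules: a binding from `i`
#' bound motors shifts the ensemble by `dZ_on(i)`; the unbinding of the last
#' bound motor (`i`: 1 to 0) shifts it by minus the strain of the departing
#' head, whose power-stroke state is sampled from the unbinding-channel
#' probabilities (Boltzmann occupancy weighted by the per-state unbinding
#' rate); power strokes and all other unbindings leave the position
#' unchanged.
#'
#' @param f external force, pN.
#' @param params a [pcm_params()] object.
#' @param n_events number of reaction events to simulate (>= 1).
#' @param seed integer RNG seed; required, so that the same
#'   `(seed, params, f)` always yields a bit-identical trajectory.
#' @param i0 initial bound count (default 1: trajectories start bound, as
#'   the bound-ensemble average conditions on `i >= 1`).
#' @param lte must be `TRUE`; the explicit non-equilibrium power-stroke
#'   dynamics (rates `k12`, `k21`) are not implemented.
#' @return An object of class `pcm_trajectory`: a data frame with columns
#'   `time_s`, `i`, `Z_nm`, `event_type` (`"bind"`, `"unbind"`, `"detach"`
#'   for the 1-to-0 transition), one row per event, plus attributes `f`,
#'   `params`, `seed`, `i0`.
#' @examples
#' traj <- pcm_simulate(0, pcm_params(N = 2), n_events = 100, seed = 1)
#' head(traj)
#' @export
pcm_simulate <- function(f, params, n_events, seed, i0 = 1L, lte = TRUE) {
  if (!isTRUE(lte))
    stop("explicit non-LTE power-stroke dynamics (k12/k21) are not implemented; ",
         "the power-stroke occupancy is always treated in local thermodynamic ",
         "equilibrium", call. = FALSE)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' is required for reproducibility", call. = FALSE)
  if (length(n_events) != 1L || !is.finite(n_events) || n_events < 1)
    stop("'n_events' must be >= 1", call. = FALSE)
  n_events <- as.integer(n_events)
  if (length(f) != 1L || !is.finite(f))
    stop("'f' must be a single finite number", call. = FALSE)
  if (f < 0)
    warning("negative external force: the model is formulated for tensile loads",
            call. = FALSE)
  N <- params$N
  if (i0 < 0 || i0 > N) stop("'i0' must be in 0..N", call. = FALSE)

  rates <- pcm_effective_rates(f, params)
  g <- c(rates$forward, 0)        # g[i + 1] = g(i), i = 0..N
  r <- c(0, rates$reverse)        # r[i + 1] = r(i), i = 0..N
  dz_on <- c(0, vapply(seq_len(N - 1), pcm_delta_z_on, numeric(1),
                       f = f, params = params))  # dz_on[i + 1], i = 0..N-1
  # last-unbinding channels at i = 1: weight Pr(j|1) * rate_j, displacement -eps_1j
  b1 <- pcm_boltzmann(1, f, params)
  eps1 <- pcm_strain(1, 0:1, f, params)
  w1 <- b1$prob * c(params$k10, pcm_unbinding_rate(1, 1, f, params))
  p_detach_pre <- if (sum(w1) > 0) w1[1] / sum(w1) else 1

  set.seed(as.integer(seed))
  times <- numeric(n_events)
  counts <- integer(n_events)
  pos <- numeric(n_events)
  type <- integer(n_events)  # 1 bind, 2 unbind, 3 detach

  i <- as.integer(i0); z <- 0; t <- 0
  for (k in seq_len(n_events)) {
    tot <- g[i + 1L] + r[i + 1L]
    if (tot <= 0)
      stop("frozen state: total rate is zero at i = ", i, call. = FALSE)
    t <- t - log(stats::runif(1)) / tot
    if (stats::runif(1) < g[i + 1L] / tot) {
      z <- z + if (i < N) dz_on[i + 1L] else 0
      i <- i + 1L
      type[k] <- 1L
    } else {
      if (i == 1L) {
        jj <- if (stats::runif(1) < p_detach_pre) 1L else 2L
        z <- z - eps1[jj]
        type[k] <- 3L
      } else {
        type[k] <- 2L
      }
      i <- i - 1L
    }
    times[k] <- t; counts[k] <- i; pos[k] <- z
  }

  out <- data.frame(time_s = times, i = counts, Z_nm = pos,
                    event_type = c("bind", "unbind", "detach")[type],
                    stringsAsFactors = FALSE)
  attr(out, "f") <- f
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  attr(out, "i0") <- as.integer(i0)
  class(out) <- c("pcm_trajectory", "data.frame")
  out
}

# dwell times and state occupied during each inter-event interval,
# optionally discarding an initial burn-in fraction of events
traj_segments <- function(traj, burn_in = 0.1) {
  n <- nrow(traj)
  t_all <- c(0, traj$time_s)
  i_all <- c(attr(traj, "i0"), traj$i)
  z_all <- c(0, traj$Z_nm)
  keep <- seq.int(floor(burn_in * n) + 1L, n)
  list(dt = diff(t_all)[keep],
       state = i_all[keep],            # state during the interval
       dz = diff(z_all)[keep])         # displacement at the closing event
}

#' Time-weighted occupancy of the bound count
#'
#' Fraction of simulated time spent at each bound count `i = 0..N`, after
#' discarding an initial burn-in fraction of events.
#'
#' @param traj a [pcm_simulate()] trajectory.
#' @param burn_in fraction of initial events discarded (default 0.1).
#' @return Named numeric vector of occupancies over `i = 0..N`, summing
#'   to 1.
#' @export
pcm_occupancy <- function(traj, burn_in = 0.1) {
  N <- attr(traj, "params")$N
  seg <- traj_segments(traj, burn_in)
  occ <- vapply(0:N, function(i) sum(seg$dt[seg$state == i]), numeric(1))
  names(occ) <- 0:N
  occ / sum(occ)
}

#' Empirical bound-ensemble velocity of a trajectory
#'
#' Net displacement divided by time spent bound (`i >= 1`), after burn-in,
#' with a nonparametric bootstrap standard error obtained by resampling the
#' inter-event (dwell, displacement) pairs.
#'
#' @param traj a [pcm_simulate()] trajectory.
#' @param burn_in fraction of initial events discarded (default 0.1).
#' @param n_boot number of bootstrap replicates for the standard error.
#' @return A list with `velocity` (nm/s), `se`, `bound_time` (s) and
#'   `n_boot`.
#' @export
pcm_empirical_velocity <- function(traj, burn_in = 0.1, n_boot = 200) {
  seg <- traj_segments(traj, burn_in)
  # all displacement events occur from bound states, so the numerator can
  # keep every dz while the denominator counts bound dwell time only
  dt_b <- ifelse(seg$state >= 1, seg$dt, 0)
  if (sum(dt_b) <= 0) stop("no bound segments in trajectory", call. = FALSE)
  v <- sum(seg$dz) / sum(dt_b)
  n <- length(seg$dt)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- sum(dt_b[idx])
    if (tb <= 0) return(NA_real_)
    sum(seg$dz[idx]) / tb
  }, numeric(1))
  list(velocity = v, se = stats::sd(boot, na.rm = TRUE),
       bound_time = sum(dt_b), n_boot = n_boot)
}

#' @export
print.pcm_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("PCM Gillespie trajectory: N = %d, f = %g pN, %d events, seed = %d\n",
              p$N, attr(x, "f"), nrow(x), attr(x, "seed")))
  cat(sprintf("  duration %.4g s, final Z = %.4g nm\n",
              x$time_s[nrow(x)], x$Z_nm[nrow(x)]))
  invisible(x)
}

#' @export
plot.pcm_trajectory <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$time_s, x$i, type = "s", xlab = "time (s)",
                 ylab = "bound motors i", ...)
  graphics::plot(x$time_s, x$Z_nm, type = "s", xlab = "time (s)",
                 ylab = "ensemble position Z (nm)", ...)
  invisible(x)
}
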