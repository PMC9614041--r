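# Effective one-step (birth-death) master equation in the bound count i.
#
# With the power-stroke occupancy in local thermodynamic equilibrium, the
# slow dynamics reduce to a birth-death chain on i = 0..N with
#   g(i) = (N - i) k01                          (binding)
#   r(i) = sum_j Pr(j|i) [(i-j) k10 + j Tr20(i,j)]   (LTE-averaged unbinding)

#' Effective binding and unbinding rates of the bound-count process
#'
#' @param f external force, pN.
#' @param params a [pcm_params()] object.
#' @return A list with `forward` (`g(i)`, `i = 0..N-1`) and `reverse`
#'   (`r(i)`, `i = 1..N`), both in 1/s.
#' @export
pcm_effective_rates <- function(f, params) {
  N <- params$N
  g <- (N - (0:(N - 1))) * params$k01
  r <- vapply(seq_len(N), function(i) {
    j <- 0:i
    prob <- pcm_boltzmann(i, f, params)$prob
    tr20 <- pcm_unbinding_rate(i, j, f, params)
    sum(prob * ((i - j) * params$k10 + j * tr20))
  }, numeric(1))
  list(forward = g, reverse = r)
}

#' Stationary distribution of the bound-count chain
#'
#' Detailed-balance solution of the one-step process:
#' `Pr_{i+1} / Pr_i = g(i) / r(i+1)`, accumulated in log space and
#' normalized.
#'
#' @inheritParams pcm_effective_rates
#' @return Numeric vector of stationary probabilities over `i = 0..N`.
#' @export
pcm_stationary <- function(f, params) {
  rates <- pcm_effective_rates(f, params)
  g <- rates$forward
  r <- rates$reverse
  bad <- which(r == 0 & g > 0)
  if (length(bad))
    stop("degenerate chain: reverse rate is zero at i = ", bad[1],
         " while binding continues", call. = FALSE)
  logw <- c(0, cumsum(log(g) - log(r)))
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

#' Solve the parallel cluster model at a fixed external force
#'
#' Computes the effective one-step rates, the stationary distribution over
#' the bound count, its renormalization over bound states (`i >= 1`), the
#' state-conditional drift velocities `V_i`, and the mean bound-ensemble
#' velocity `V_b = sum_i V_i Pr_hat_i`.
#'
#' @param f external force on the ensemble, pN. Negative values are
#'   permitted mathematically but flagged with a warning, since the model is
#'   formulated for tensile loads.
#' @param params a [pcm_params()] object.
#' @return An object of class `pcm_master`: a list with `f`, `params`,
#'   `forward_rates`, `reverse_rates`, `stationary` (over `i = 0..N`),
#'   `bound_stationary` (over `i = 1..N`), `velocities` (`V_i`, `i = 1..N`)
#'   and `v_bound` (nm/s).
#' @examples
#' sol <- pcm_master(0, pcm_params(N = 4))
#' sol$v_bound
#' @export
pcm_master <- function(f, params) {
  if (length(f) != 1L || !is.finite(f))
    stop("'f' must be a single finite number", call. = FALSE)
  if (f < 0)
    warning("negative external force: the model is formulated for tensile loads",
            call. = FALSE)
  rates <- pcm_effective_rates(f, params)
  stat <- pcm_stationary(f, params)
  bound <- stat[-1] / sum(stat[-1])
  v_i <- vapply(seq_len(params$N), pcm_ensemble_velocity, numeric(1),
                f = f, params = params)
  structure(list(f = f, params = params,
                 forward_rates = rates$forward, reverse_rates = rates$reverse,
                 stationary = stat, bound_stationary = bound,
                 velocities = v_i, v_bound = sum(v_i * bound)),
            class = "pcm_master")
}

#' @export
print.pcm_master <- function(x, ...) {
  N <- x$params$N
  cat(sprintf("PCM master-equation solution (N = %d, f = %g pN)\n", N, x$f))
  cat(sprintf("  mean bound-ensemble velocity V_b = %.4g nm/s\n", x$v_bound))
  cat("  stationary Pr(i), i = 0..N:\n")
  print(round(x$stationary, 4))
  invisible(x)
}

#' Mean bound-ensemble velocity at a fixed force
#'
#' Convenience wrapper around [pcm_master()] returning only `V_b`.
#'
#' @inheritParams pcm_master
#' @return Velocity in nm/s.
#' @export
pcm_mean_bound_velocity <- function(f, params) {
  pcm_master(f, params)$v_bound
}

#' Empirical stall force of the molecular model
#'
#' Smallest tensile force at which the mean bound-ensemble velocity drops to
#' zero, located by bisection on `V_b(f)` (the Hill-fit stall force is a
#' separate, fitted quantity).
#'
#' @param params a [pcm_params()] object.
#' @param f_upper upper bracket for the search, pN; extended by doubling if
#'   `V_b(f_upper) > 0`.
#' @param tol force tolerance of the bisection, pN.
#' @return Stall force in pN.
#' @export
pcm_stall_force <- function(params, f_upper = 100, tol = 0.01) {
  lo <- 0
  v_lo <- pcm_mean_bound_velocity(lo, params)
  if (v_lo <= 0) return(0)
  hi <- f_upper
  while (pcm_mean_bound_velocity(hi, params) > 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("no stall force found below 1e6 pN", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pcm_mean_bound_velocity(mid, params) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
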