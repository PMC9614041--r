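# Per-state mechanics and kinetics of the parallel cluster model.
#
# State (i, j): i bound motors, j of them post-power-stroke. Motors in the
# same state bear the same load, so all per-motor quantities depend on the
# state only. External force f is in pN, lengths in nm, energies in pN nm.

check_state <- function(i, j, N) {
  if (length(i) != 1L || !is.finite(i) || i != round(i))
    stop("'i' must be a single integer", call. = FALSE)
  if (i == 0) stop("strain undefined for unbound ensemble (i = 0)", call. = FALSE)
  if (i < 0 || i > N) stop("'i' must satisfy 1 <= i <= N", call. = FALSE)
  if (any(!is.finite(j)) || any(j != round(j)) || any(j < 0) || any(j > i))
    stop("'j' must satisfy 0 <= j <= i", call. = FALSE)
  invisible(TRUE)
}

#' Strain of a pre-power-stroke motor
#'
#' Strain of the neck-linker spring of each pre-power-stroke motor when `i`
#' bound motors (of which `j` post-power-stroke) balance the constant
#' external force `f`: `eps_ij = (f / k_m - j * d) / i`. A post-power-stroke
#' motor carries strain `eps_ij + d`.
#'
#' @param i number of bound motors (1..N).
#' @param j number of post-power-stroke motors (0..i); may be a vector.
#' @param f external force on the ensemble, pN.
#' @param params a [pcm_params()] object.
#' @return Strain in nm (vectorized over `j`). May be negative (compressed
#'   pre-stroke heads at low force and high `j`).
#' @examples
#' p <- pcm_params()
#' pcm_strain(2, 1, 0, p)  # -d/2
#' @export
pcm_strain <- function(i, j, f, params) {
  check_state(i, j, params$N)
  if (length(f) != 1L || !is.finite(f)) stop("'f' must be a single finite number", call. = FALSE)
  (f / params$k_m - j * params$d) / i
}

#' Reconstruct the external force from the shared-load balance
#'
#' Evaluates `k_m * (i * eps_ij + j * d)`, the total elastic force the bound
#' motors exert on the backbone. By construction of the strain it equals the
#' applied force `f` identically; exposed for identity checking.
#'
#' @inheritParams pcm_strain
#' @return Force in pN, equal to `f` up to round-off.
#' @export
pcm_force_balance <- function(i, j, f, params) {
  eps <- pcm_strain(i, j, f, params)
  params$k_m * (i * eps + j * params$d)
}

#' Elastic force on one post-power-stroke motor
#'
#' `f_pp = k_m * (eps_ij + d)`: the load borne by a single motor whose lever
#' arm has swung, entering the catch-bond unbinding rate.
#'
#' @inheritParams pcm_strain
#' @return Force in pN (vectorized over `j`).
#' @export
pcm_post_stroke_force <- function(i, j, f, params) {
  params$k_m * (pcm_strain(i, j, f, params) + params$d)
}

#' Catch-bond unbinding rate of a post-power-stroke motor
#'
#' Reaction-rate (Bell-type) form with inverted sign, describing a catch
#' bond: `Tr20(i, j) = k20_0 * exp(-f_pp / f0_unbind)`. Tension makes the
#' bond stronger, so the rate decreases with the per-motor load `f_pp`.
#'
#' @inheritParams pcm_strain
#' @return Unbinding rate in 1/s (vectorized over `j`).
#' @examples
#' p <- pcm_params()
#' pcm_unbinding_rate(1, 1, 0, p)  # load-free stroke: f_pp = 0, rate = k20_0
#' @export
pcm_unbinding_rate <- function(i, j, f, params) {
  params$k20_0 * exp(-pcm_post_stroke_force(i, j, f, params) / params$f0_unbind)
}

#' Total energy of the bound motors in state (i, j)
#'
#' `e_ij = j * e_pp + (k_m / 2) * ((i - j) * eps^2 + j * (eps + d)^2)`:
#' the power-stroke bias plus the elastic energy stored in the pre- and
#' post-power-stroke neck linkers. The external-force contribution is
#' position-independent under constant load and drops out of the
#' conditional Boltzmann weights.
#'
#' @inheritParams pcm_strain
#' @return Energy in pN nm (vectorized over `j`); the elastic part is
#'   nonnegative, the total may be negative when `e_pp < 0`.
#' @export
pcm_bound_energy <- function(i, j, f, params) {
  eps <- pcm_strain(i, j, f, params)
  j * params$e_pp +
    (params$k_m / 2) * ((i - j) * eps^2 + j * (eps + params$d)^2)
}

#' Boltzmann occupancy of the power-stroke states
#'
#' Under local thermodynamic equilibrium the fast power-stroke degree of
#' freedom equilibrates between slow (un)binding events, so for a given
#' bound count `i` the number `j` of post-power-stroke motors follows
#' `Pr(j | i) = exp(-e_ij / kBT) / Q_i` with partition sum
#' `Q_i = sum_j exp(-e_ij / kBT)`. Weights are computed by max-shift
#' (log-sum-exp), since `e_ij / kBT` spans hundreds of units at realistic
#' `e_pp`; `partition` may overflow to `Inf` in extreme regimes while
#' `log_partition` stays finite.
#'
#' @param i number of bound motors (1..N).
#' @param f external force, pN.
#' @param params a [pcm_params()] object.
#' @return A list with `prob` (vector of `Pr(j|i)`, `j = 0..i`),
#'   `partition` (`Q_i`) and `log_partition` (`log Q_i`).
#' @examples
#' p <- pcm_params()
#' b <- pcm_boltzmann(2, 0, p)
#' sum(b$prob)  # 1
#' @export
pcm_boltzmann <- function(i, f, params) {
  if (length(i) != 1L || !is.finite(i) || i != round(i) || i < 1)
    stop("no bound states: 'i' must be an integer >= 1", call. = FALSE)
  if (i > params$N) stop("'i' must satisfy 1 <= i <= N", call. = FALSE)
  x <- -pcm_bound_energy(i, 0:i, f, params) / params$kBT
  m <- max(x)
  w <- exp(x - m)
  s <- sum(w)
  list(prob = w / s, partition = exp(m + log(s)), log_partition = m + log(s))
}

#' Ensemble position change on a new binding
#'
#' A free motor binds at zero strain where the backbone currently sits, and
#' the ensemble position (average position of the bound heads) shifts by
#' `dZ_on = -(1 / (i + 1)) * sum_j eps_ij * Pr(j | i)`, with `i` the bound
#' count before the binding. The first binding of an unbound ensemble
#' (`i = 0`) occurs at zero strain and moves nothing: `dZ_on(0) = 0`.
#'
#' @param i bound count before the binding event (0..N-1).
#' @inheritParams pcm_boltzmann
#' @return Position change in nm; positive values move the ensemble in the
#'   contraction direction (toward the F-actin barbed end).
#' @export
pcm_delta_z_on <- function(i, f, params) {
  if (length(i) != 1L || !is.finite(i) || i != round(i) || i < 0)
    stop("'i' must be a single nonnegative integer", call. = FALSE)
  if (i >= params$N) stop("no free motor available to bind (i = N)", call. = FALSE)
  if (i == 0) return(0)
  eps <- pcm_strain(i, 0:i, f, params)
  b <- pcm_boltzmann(i, f, params)
  -sum(eps * b$prob) / (i + 1)
}

#' Mean drift velocity of the ensemble in bound state i
#'
#' Only events that relocate the backbone move the ensemble: new bindings
#' (each shifting the position by `dZ_on(i)` at rate `(N - i) * k01`) and,
#' when exactly one motor is bound, its unbinding (shifting the position by
#' minus the strain of the departing head). Power strokes and other
#' unbindings leave the ensemble position unchanged:
#' `V_i = (N - i) k01 dZ_on(i)
#'        - [k10 eps_10 Pr(0|1) + Tr20(1,1) eps_11 Pr(1|1)] delta_{i,1}`.
#'
#' @param i bound count (1..N).
#' @inheritParams pcm_boltzmann
#' @return Velocity in nm/s; positive means contraction.
#' @export
pcm_ensemble_velocity <- function(i, f, params) {
  check_state(i, 0, params$N)
  v <- if (i < params$N) (params$N - i) * params$k01 * pcm_delta_z_on(i, f, params) else 0
  if (i == 1L) {
    b1 <- pcm_boltzmann(1, f, params)
    eps1 <- pcm_strain(1, 0:1, f, params)
    tr20 <- pcm_unbinding_rate(1, 1, f, params)
    v <- v - (params$k10 * eps1[1] * b1$prob[1] + tr20 * eps1[2] * b1$prob[2])
  }
  v
}
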