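# Macroscopic Hill muscle model: contractile (CC), series-elastic (SEC) and
# parallel-elastic (PEC) components with pennation geometry. Forces in N,
# lengths in m, pennation angle in degrees.

cos_alpha <- function(params) {
  if (params$alpha >= 90)
    stop("singular geometry: pennation angle alpha must be < 90 degrees",
         call. = FALSE)
  cos(params$alpha * pi / 180)
}

#' Contractile-component force
#'
#' `f_cc = f0_iso * a * f_fl * f_fv`: the active force is the maximum
#' isometric force scaled by three multiplicative, independent factors —
#' the activation level, the force-length factor, and the force-velocity
#' factor.
#'
#' @param a activation level, in `[0, 1]`.
#' @param fl force-length factor (>= 0), see [force_length()].
#' @param fv force-velocity factor (>= 0), see [force_velocity_factor()].
#' @param params a [hill_params()] object.
#' @return Force in N.
#' @examples
#' contractile_force(1, 1, 1, hill_params(f0_iso = 100))  # 100 N
#' @export
contractile_force <- function(a, fl, fv, params) {
  if (any(a < 0 | a > 1)) stop("activation 'a' must be in [0, 1]", call. = FALSE)
  if (any(fl < 0) || any(fv < 0))
    stop("'fl' and 'fv' must be >= 0", call. = FALSE)
  params$f0_iso * a * fl * fv
}

#' Force-length factor of the contractile component
#'
#' Dimensionless Gaussian bump over normalized CC length, maximal at the
#' optimum (`l_norm = 1`) and symmetric about it:
#' `f_fl = exp(-((l_norm - 1) / width)^2)`.
#'
#' @param l_norm CC length normalized by its optimum (> 0, vectorized).
#' @param width curve width (default 0.45), in units of optimal length.
#' @return Factor in `(0, 1]`.
#' @export
force_length <- function(l_norm, width = 0.45) {
  if (any(l_norm <= 0)) stop("'l_norm' must be > 0", call. = FALSE)
  exp(-((l_norm - 1) / width)^2)
}

#' Force-velocity factor of the contractile component
#'
#' Normalized Hill relation, bridging the molecular force-velocity curve
#' into the contractile component: inverting the hyperbola
#' `v = v0 (fs - f) / (fs + f / beta)` gives the force sustained at
#' shortening velocity `v`, and dividing by the stall force yields
#' `f_fv(v) = (v0 - v) / (v0 + v / beta)`, clamped to `[0, 1]`.
#'
#' @param v shortening velocity (vectorized), same units as `v0`.
#' @param v0 unloaded shortening velocity (> 0).
#' @param beta Hill curvature parameter (> 0).
#' @return Factor in `[0, 1]`.
#' @export
force_velocity_factor <- function(v, v0, beta) {
  if (v0 <= 0 || beta <= 0) stop("'v0' and 'beta' must be > 0", call. = FALSE)
  pmin(1, pmax(0, (v0 - v) / (v0 + v / beta)))
}

#' Series-elastic component force
#'
#' The SEC is slack below its unloaded length `l_u` and develops force
#' nonlinearly above it. The default quadratic law
#' `f_sec = gamma * (l_sec - l_u)^2` with `gamma = f0_iso / (u0 * l_u)^2`
#' reaches the maximum isometric force at strain `u0` above slack; the
#' alternative linear law (`sec_form = "linear"` in [hill_params()]) does
#' the same with `f_sec = f0_iso * (l_sec - l_u) / (u0 * l_u)`.
#'
#' @param l_sec SEC length, m (vectorized).
#' @param params a [hill_params()] object.
#' @return Force in N; 0 for `l_sec <= l_u`, continuous at `l_u`.
#' @examples
#' h <- hill_params(f0_iso = 1000, l_u = 0.2, u0 = 0.04)
#' sec_force(c(0.19, 0.2, 0.2 * 1.04), h)
#' @export
sec_force <- function(l_sec, params) {
  if (any(l_sec <= 0)) stop("'l_sec' must be > 0", call. = FALSE)
  ext <- pmax(0, l_sec - params$l_u)
  if (params$sec_form == "quadratic") {
    params$f0_iso / (params$u0 * params$l_u)^2 * ext^2
  } else {
    params$f0_iso / (params$u0 * params$l_u) * ext
  }
}

#' Parallel-elastic component force
#'
#' Force balance of the pennate geometry: the fiber-direction forces
#' project onto the line of action as `f_pec * cos(alpha) =
#' f_sec - f_cc * cos(alpha)`, so
#' `f_pec = (f_sec - f_cc * cos(alpha)) / cos(alpha)`.
#'
#' @param f_cc contractile-component force, N.
#' @param f_sec series-elastic component force, N.
#' @param params a [hill_params()] object.
#' @return PEC force in N.
#' @export
pec_force <- function(f_cc, f_sec, params) {
  ca <- cos_alpha(params)
  (f_sec - f_cc * ca) / ca
}

#' Total force on the muscle tendon
#'
#' `f_t = f_pec + f_cc * cos(alpha)`; substituting the PEC balance gives
#' the equivalent closure `f_t = f_pec + f_sec`.
#'
#' @param f_pec parallel-elastic component force, N.
#' @param f_cc contractile-component force, N.
#' @param params a [hill_params()] object.
#' @return Tendon force in N.
#' @export
tendon_force <- function(f_pec, f_cc, params) {
  f_pec + f_cc * cos_alpha(params)
}

#' Evaluate the full Hill muscle force chain
#'
#' Convenience wrapper composing the component force laws: activation,
#' force-length and force-velocity factors give the CC force, the SEC
#' length gives the SEC force, and the pennate force balance yields the PEC
#' and tendon forces.
#'
#' @param a activation level in `[0, 1]`.
#' @param l_norm normalized CC length.
#' @param v shortening velocity, nm/s (molecular scale of the
#'   force-velocity factor).
#' @param l_sec SEC length, m.
#' @param params a [hill_params()] object.
#' @return A one-row data frame with columns `a`, `l_norm`, `v`, `l_sec`,
#'   `f_fl`, `f_fv`, `f_cc`, `f_sec`, `f_pec`, `f_t`.
#' @export
hill_evaluate <- function(a, l_norm, v, l_sec, params) {
  fl <- force_length(l_norm, params$fl_width)
  fv <- force_velocity_factor(v, params$v0, params$beta)
  f_cc <- contractile_force(a, fl, fv, params)
  f_sec <- sec_force(l_sec, params)
  f_pec <- pec_force(f_cc, f_sec, params)
  f_t <- tendon_force(f_pec, f_cc, params)
  data.frame(a = a, l_norm = l_norm, v = v, l_sec = l_sec,
             f_fl = fl, f_fv = fv, f_cc = f_cc, f_sec = f_sec,
             f_pec = f_pec, f_t = f_t)
}
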