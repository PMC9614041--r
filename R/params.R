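#' Parameters of the parallel cluster model
#'
#' Constructs and validates the parameter set of the parallel cluster model
#' (PCM) of a myosin-II ensemble: `N` motors in parallel share a constant
#' external load; each motor is free, bound pre-power-stroke, or bound
#' post-power-stroke, and bound motors are connected to the backbone through
#' a linear neck-linker spring.
#'
#' The defaults are literature values for skeletal-muscle myosin-II taken
#' from the PCM source literature; none of them is fitted here, and every one
#' can be overridden. `k12` and `k21` (the explicit power-stroke transition
#' rates) are stored for completeness but unused: the power-stroke degree of
#' freedom is treated in local thermodynamic equilibrium, so its occupancy is
#' Boltzmann-distributed rather than simulated.
#'
#' @param N integer, number of myosin-II motors in the ensemble (>= 1).
#' @param k_m neck-linker stiffness, pN/nm.
#' @param d power-stroke strain increment, nm.
#' @param e_pp energy bias of the post- relative to the pre-power-stroke
#'   state, pN nm (typically negative: the stroke is downhill).
#' @param kBT thermal energy, pN nm.
#' @param k01 binding rate of a free motor, 1/s.
#' @param k10 unbinding rate of a pre-power-stroke motor, 1/s.
#' @param k12,k21 power-stroke forward/reverse rates, 1/s (stored, unused
#'   under local thermodynamic equilibrium).
#' @param k20_0 zero-force unbinding rate of a post-power-stroke motor, 1/s.
#' @param f0_unbind catch-bond force scale of post-power-stroke unbinding, pN.
#'
#' @return An object of class `pcm_params` (a validated named list).
#' @examples
#' p <- pcm_params(N = 4)
#' p$k_m
#' @export
pcm_params <- function(N = 4, k_m = 2.5, d = 8, e_pp = -60, kBT = 4.14,
                       k01 = 40, k10 = 2, k12 = 1000, k21 = 1000,
                       k20_0 = 80, f0_unbind = 12.6) {
  p <- list(N = N, k_m = k_m, d = d, e_pp = e_pp, kBT = kBT,
            k01 = k01, k10 = k10, k12 = k12, k21 = k21,
            k20_0 = k20_0, f0_unbind = f0_unbind)
  validate_pcm_params(p)
  p[] <- lapply(p, as.double)  # stable types regardless of input representation
  p$N <- as.integer(p$N)
  structure(p, class = "pcm_params")
}

validate_pcm_params <- function(p) {
  chk_scalar <- function(key) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", key, "' must be a single finite number", call. = FALSE)
  }
  for (key in names(p)) chk_scalar(key)
  if (p$N < 1 || p$N != round(p$N))
    stop("'N' must be a positive integer", call. = FALSE)
  if (p$k_m <= 0) stop("'k_m' must be > 0", call. = FALSE)
  if (p$kBT <= 0) stop("'kBT' must be > 0", call. = FALSE)
  if (p$d < 0) stop("'d' must be >= 0", call. = FALSE)
  if (p$f0_unbind <= 0) stop("'f0_unbind' must be > 0", call. = FALSE)
  for (key in c("k01", "k10", "k12", "k21", "k20_0"))
    if (p[[key]] < 0) stop("'", key, "' must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.pcm_params <- function(x, ...) {
  cat("Parallel cluster model parameters\n")
  cat(sprintf("  N = %d motors\n", x$N))
  cat(sprintf("  mechanics: k_m = %g pN/nm, d = %g nm, e_pp = %g pN nm, kBT = %g pN nm\n",
              x$k_m, x$d, x$e_pp, x$kBT))
  cat(sprintf("  kinetics:  k01 = %g, k10 = %g, k20_0 = %g /s; f0_unbind = %g pN\n",
              x$k01, x$k10, x$k20_0, x$f0_unbind))
  cat(sprintf("  (k12 = %g, k21 = %g /s stored; unused under LTE)\n", x$k12, x$k21))
  invisible(x)
}

#' Parameters of the Hill muscle model
#'
#' Constructs and validates the macroscopic Hill muscle-model parameter set:
#' a contractile component (CC) in series with a series-elastic component
#' (SEC), both in parallel with a parallel-elastic component (PEC), with
#' pennation angle `alpha` between the fiber direction and the muscle's line
#' of action.
#'
#' @param f0_iso maximum isometric force of the contractile component, N.
#' @param l_u unloaded (slack) length of the SEC, m.
#' @param u0 SEC strain constant (dimensionless); the SEC carries `f0_iso`
#'   at strain `u0` above slack. Commonly 0.04.
#' @param alpha pennation angle, degrees, in `[0, 90)`.
#' @param fl_width width of the Gaussian force-length factor (dimensionless,
#'   in units of optimal CC length).
#' @param sec_form `"quadratic"` (default) or `"linear"` force-extension law
#'   for the SEC above slack.
#' @param v0 unloaded shortening velocity of the Hill force-velocity
#'   relation, nm/s (molecular scale, used by the force-velocity factor).
#' @param fs stall force of the Hill force-velocity relation, pN.
#' @param beta dimensionless curvature of the Hill force-velocity relation.
#' @param l_pec PEC reference length, m (stored, unused by the force laws).
#'
#' @return An object of class `hill_params`.
#' @examples
#' h <- hill_params(f0_iso = 1000, l_u = 0.2)
#' sec_force(0.2 * 1.04, h)  # equals f0_iso at strain u0
#' @export
hill_params <- function(f0_iso = 1000, l_u = 0.2, u0 = 0.04, alpha = 0,
                        fl_width = 0.45, sec_form = c("quadratic", "linear"),
                        v0 = 1000, fs = 20, beta = 2, l_pec = NA_real_) {
  sec_form <- match.arg(sec_form)
  p <- list(f0_iso = f0_iso, l_u = l_u, u0 = u0, alpha = alpha,
            fl_width = fl_width, sec_form = sec_form,
            v0 = v0, fs = fs, beta = beta, l_pec = l_pec)
  validate_hill_params(p)
  num <- setdiff(names(p), "sec_form")
  p[num] <- lapply(p[num], as.double)
  structure(p, class = "hill_params")
}

validate_hill_params <- function(p) {
  num1 <- function(key, allow_na = FALSE) {
    v <- p[[key]]
    ok <- is.numeric(v) && length(v) == 1L && (is.finite(v) || (allow_na && is.na(v)))
    if (!ok) stop("'", key, "' must be a single finite number", call. = FALSE)
  }
  for (key in c("f0_iso", "l_u", "u0", "alpha", "fl_width", "v0", "fs", "beta"))
    num1(key)
  num1("l_pec", allow_na = TRUE)
  if (p$f0_iso <= 0) stop("'f0_iso' must be > 0", call. = FALSE)
  if (p$l_u <= 0) stop("'l_u' must be > 0", call. = FALSE)
  if (p$u0 <= 0 || p$u0 >= 1) stop("'u0' must be in (0, 1)", call. = FALSE)
  if (p$alpha < 0 || p$alpha >= 90)
    stop("'alpha' must be in [0, 90) degrees", call. = FALSE)
  if (p$fl_width <= 0) stop("'fl_width' must be > 0", call. = FALSE)
  if (p$v0 <= 0) stop("'v0' must be > 0", call. = FALSE)
  if (p$fs <= 0) stop("'fs' must be > 0", call. = FALSE)
  if (p$beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.hill_params <- function(x, ...) {
  cat("Hill muscle model parameters\n")
  cat(sprintf("  f0_iso = %g N, l_u = %g m, u0 = %g (SEC: %s), alpha = %g deg\n",
              x$f0_iso, x$l_u, x$u0, x$sec_form, x$alpha))
  cat(sprintf("  force-length width = %g; force-velocity: v0 = %g nm/s, fs = %g pN, beta = %g\n",
              x$fl_width, x$v0, x$fs, x$beta))
  invisible(x)
}
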