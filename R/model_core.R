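#' Water-renormalized Boltzmann weight
#'
#' Summing the two water spins at each broken-bond site out of the
#' partition function replaces the helix-propagation weight `W = e^(U/T)`
#' by the effective weight
#' \deqn{\tilde W = q^2 W / (q + K - 1)^2,}
#' where `K = e^(E/T)` is the water-peptide bond weight and `q` the
#' orientational degeneracy. `K = 1` (no water-peptide bond) leaves `W`
#' untouched; stronger water binding (`K > 1`) suppresses helix stability.
#'
#' @param W Helix-propagation Boltzmann weight (`> 0`), vectorized.
#' @param K Water-peptide Boltzmann weight (`>= 1`), vectorized.
#' @param q Water-orientation degeneracy (`>= 1`).
#' @return Effective weight, same length as the recycled inputs.
#' @examples
#' effective_weight(3, 1, 16)       # 3: water cannot renormalize when E = 0
#' effective_weight(1, 2, 2)        # q^2/(2q-1)^2 = 4/9
#' @export
effective_weight <- function(W, K, q) {
  if (!is.numeric(W) || any(W <= 0)) stop("W must be > 0")
  if (!is.numeric(K) || any(K < 1)) stop("K must be >= 1")
  if (!is.numeric(q) || any(q < 1)) stop("q must be >= 1")
  q^2 * W / (q + K - 1)^2
}

# log(q - 1 + e^x), stable for large x
.log_qm1_plus_exp <- function(x, q) {
  out <- numeric(length(x))
  big <- x > 30
  out[big] <- x[big] + log1p((q - 1) * exp(-x[big]))
  out[!big] <- log(q - 1 + exp(x[!big]))
  out
}

# log W-tilde for microscopic parameters, stable against overflow of e^(U/T)
.log_effective_weight <- function(U, E, q, T) {
  2 * log(q) + U / T - 2 * .log_qm1_plus_exp(E / T, q)
}

#' Effective temperature-dependent H-bond energy
#'
#' The implicit-solvent reduction is equivalent to replacing the bare
#' H-bond energy `U` in the water-free Hamiltonian by
#' \deqn{\tilde U(T) = T \ln \tilde W(T),}
#' which decreases with the strength of water-peptide binding and reduces
#' to `U` when `E = 0`.
#'
#' @param params A [zb_params()] object.
#' @return Effective energy in the same units as `U`.
#' @examples
#' effective_energy(zb_params(Q = 2, q = 16, U = 1, E = 0, T = 0.5))  # 1
#' @export
effective_energy <- function(params) {
  stopifnot(inherits(params, "zb_params"))
  params$T * .log_effective_weight(params$U, params$E, params$q, params$T)
}

#' Renormalized stability parameter in reduced units
#'
#' Evaluates, exactly as written in reduced units,
#' \deqn{\tilde s(\tau,\alpha,Q,q) = \frac{1}{Q}\left[
#'   \frac{q^2 e^{1/\tau}}{(q - 1 + e^{(1+\alpha)/(2\tau)})^2} - 1\right].}
#' The computation is done in log space so that small `tau` yields the
#' analytic limit (`+Inf` for `alpha < 0`, `-1/Q` for `alpha > 0`) rather
#' than overflow.
#'
#' @param p An [internal_params()] object (`tau` may be a vector).
#' @return `s~` values, one per `tau`.
#' @export
s_tilde_internal <- function(p) {
  stopifnot(inherits(p, "internal_params"))
  logw <- 2 * log(p$q) + 1 / p$tau -
    2 * .log_qm1_plus_exp((1 + p$alpha) / (2 * p$tau), p$q)
  s <- ifelse(logw > 709, Inf, expm1(pmin(logw, 709)) / p$Q)
  s
}

#' Renormalized stability parameter in laboratory units
#'
#' The fit-facing form of the stability parameter,
#' \deqn{\tilde s = \frac{1}{Q}\left[\left(e^{-h/d} +
#'   \frac{e^{(h_{ps}-h)/d} - e^{-h/d}}{q}\right)^{-2} - 1\right],
#'   \quad d = R(T - t_0),}
#' with `h`, `h_ps` in J/mol and `t0`, `T` in Kelvin. Algebraically this
#' equals `(effective_weight(e^{2h/d}, e^{h_ps/d}, q) - 1)/Q`; the log-space
#' evaluation used here keeps `T` close to `t0` finite (`+Inf` when
#' `h > h_ps`, `-1/Q` when `h < h_ps`).
#'
#' @param T Temperature(s) in Kelvin, all `> p$t0`.
#' @param p A [lab_params()] object.
#' @param R Gas constant (J mol^-1 K^-1), default [R_GAS].
#' @return `s~` values, one per temperature.
#' @examples
#' p <- lab_params(t0 = 260.6, h = 2134, h_ps = 2141, Q = 233)
#' s_tilde_lab(300, p)
#' @export
s_tilde_lab <- function(T, p, R = R_GAS) {
  stopifnot(inherits(p, "lab_params"), is.numeric(T))
  if (any(T <= p$t0))
    stop(sprintf("all temperatures must exceed t0 = %g K (offending: %s)",
                 p$t0, paste(format(T[T <= p$t0]), collapse = ", ")))
  d <- R * (T - p$t0)
  logw <- 2 * log(p$q) + 2 * p$h / d - 2 * .log_qm1_plus_exp(p$h_ps / d, p$q)
  ifelse(logw > 709, Inf, expm1(pmin(logw, 709)) / p$Q)
}

#' Helicity degree (order parameter) in the thermodynamic limit
#'
#' The average fraction of intact intramolecular H-bonds of an infinite
#' chain, from the largest transfer-matrix eigenvalue:
#' \deqn{\theta(\tilde s,\sigma) = \frac{\tilde s+\sigma}
#'   {1+\tilde s+r}\left(1+\frac{2\sigma-1+\tilde s}{r}\right),
#'   \quad r = \sqrt{(1-\tilde s)^2 + 4\sigma\tilde s}.}
#' `theta` runs from `sigma^2` at `s~ = 0` through `(1+sigma)/2` at the
#' transition point `s~ = 1` to 1 as `s~ -> Inf`.
#'
#' @param s_tilde Stability parameter(s); values down to `-sigma` are
#'   mathematically admissible (deep coil), `+Inf` gives 1.
#' @param sigma Cooperativity parameter in `(0, 1]`.
#' @return Helicity values in `[0, 1]`.
#' @examples
#' order_parameter(1, 0.25)   # (1 + sigma)/2 = 0.625
#' order_parameter(0, 0.04)   # sigma^2 = 0.0016
#' @export
order_parameter <- function(s_tilde, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0) || any(sigma > 1))
    stop("sigma must lie in (0, 1]")
  if (!is.numeric(s_tilde) || any(is.nan(s_tilde)))
    stop("s_tilde must be numeric")
  if (any(s_tilde < -sigma - 1e-12))
    stop("s_tilde below -sigma is outside the model's range (W~ < 0)")
  s <- pmax(s_tilde, -sigma)
  # (1-s)^2 would overflow above ~1e154; theta is 1 to 1e-100 there anyway
  huge <- !is.finite(s) | s > 1e100
  s_safe <- ifelse(huge, 1, s)
  r <- sqrt((1 - s_safe)^2 + 4 * sigma * s_safe)
  th <- (s_safe + sigma) / (1 + s_safe + r) * (1 + (2 * sigma - 1 + s_safe) / r)
  th[huge] <- 1
  pmin(pmax(th, 0), 1)
}

#' Model melt curve on a temperature grid
#'
#' Composes [s_tilde_lab()] and [order_parameter()] element-wise to give
#' the noiseless helicity-vs-temperature curve for a laboratory parameter
#' set.
#'
#' @param T_grid Strictly increasing Kelvin temperatures, all above
#'   `p$t0`.
#' @param p A [lab_params()] object.
#' @param R Gas constant, default [R_GAS].
#' @return A [melt_curve()] data frame with columns `temperature_K`,
#'   `theta`.
#' @export
theta_curve <- function(T_grid, p, R = R_GAS) {
  stopifnot(inherits(p, "lab_params"), is.numeric(T_grid))
  if (length(T_grid) && any(diff(T_grid) <= 0))
    stop("T_grid must be strictly increasing")
  s <- s_tilde_lab(T_grid, p, R)
  melt_curve(T_grid, order_parameter(s, 1 / p$Q),
             label = "model theta_curve")
}
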