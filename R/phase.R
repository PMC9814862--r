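#' Reduced energy balance alpha
#'
#' `alpha = (h_ps - h)/h`, the balance between water-peptide and
#' intramolecular H-bond energies. Cold denaturation requires `alpha > 0`
#' (water-peptide bonds stronger than intramolecular ones); `alpha = -1`
#' is the water-free reference (`h_ps = 0`).
#'
#' @param p A [lab_params()] object.
#' @return Scalar `alpha`.
#' @examples
#' compute_alpha(lab_params(t0 = 215.9, h = 1771, h_ps = 2292, Q = 24))
#' @export
compute_alpha <- function(p) {
  stopifnot(inherits(p, "lab_params"))
  if (p$h <= 0) stop("h must be > 0")
  (p$h_ps - p$h) / p$h
}

#' Stability-parameter trace over a temperature grid
#'
#' Vectorized [s_tilde_lab()], returned as a two-column data frame; used
#' to draw stability curves for fitted parameter sets.
#'
#' @param p A [lab_params()] object.
#' @param T_grid Kelvin temperatures above `p$t0` (may be empty).
#' @param R Gas constant, default [R_GAS].
#' @return Data frame with columns `temperature_K`, `s_tilde`.
#' @export
stability_trace <- function(p, T_grid, R = R_GAS) {
  stopifnot(inherits(p, "lab_params"))
  data.frame(temperature_K = as.numeric(T_grid),
             s_tilde = s_tilde_lab(as.numeric(T_grid), p, R))
}

#' Locate conformational transitions and classify the phase behavior
#'
#' Scans `s~(T)` on a dense grid, brackets every crossing of the
#' transition condition `s~ = 1`, polishes each root by bisection to
#' 1e-6 K, and classifies the regime:
#' \describe{
#'   \item{cold_and_heat}{two roots (re-entrant cold denaturation below,
#'     heat denaturation above), or a single rising crossing — since
#'     `s~(T) -> 0` as `T -> Inf` the heat root then lies above the scan
#'     window.}
#'   \item{heat_only}{one falling crossing, `s~ > 1` at the low end.}
#'   \item{always_denatured}{no root and `max s~ < 1`.}
#'   \item{always_ordered}{no root and `s~ > 1` throughout.}
#' }
#' The `s~ = 1` definition of the transition temperature differs from the
#' `theta = 1/2` midpoint at finite `sigma`: at a crossing the helicity is
#' `(1 + sigma)/2`.
#'
#' @param p A [lab_params()] object.
#' @param T_range Kelvin interval to scan; default
#'   `c(max(t0 + 5, 230), 400)`, the physiological window.
#' @param resolution Number of grid points (`>= 100`), default 2000.
#' @param R Gas constant, default [R_GAS].
#' @return An object of class `phase_report`: a list with `alpha`,
#'   `transition_temperatures` (ascending), `regime`, `s_max`, and the
#'   `scan` trace.
#' @export
find_transitions <- function(p, T_range = NULL, resolution = 2000,
                             R = R_GAS) {
  stopifnot(inherits(p, "lab_params"))
  if (is.null(T_range)) T_range <- c(max(p$t0 + 5, 230), 400)
  if (length(T_range) != 2 || diff(T_range) <= 0)
    stop("T_range must be an increasing Kelvin interval")
  if (T_range[1] <= p$t0)
    stop(sprintf("scan range must lie above t0 = %g K", p$t0))
  if (resolution < 100) stop("resolution must be >= 100 grid points")
  grid <- seq(T_range[1], T_range[2], length.out = resolution)
  scan <- stability_trace(p, grid, R)
  f <- scan$s_tilde - 1
  roots <- numeric(0)
  sgn <- sign(f)
  for (i in which(sgn[-length(sgn)] * sgn[-1] < 0)) {
    root <- stats::uniroot(function(T) s_tilde_lab(T, p, R) - 1,
                           lower = grid[i], upper = grid[i + 1],
                           tol = 1e-6)$root
    roots <- c(roots, root)
  }
  roots <- c(roots, grid[f == 0])  # exact grid hits
  roots <- sort(unique(roots))
  s_max <- max(scan$s_tilde)
  regime <- if (length(roots) >= 2) {
    "cold_and_heat"
  } else if (length(roots) == 1) {
    if (f[1] > 0) "heat_only" else "cold_and_heat"
  } else if (s_max < 1) {
    "always_denatured"
  } else {
    "always_ordered"
  }
  structure(list(alpha = compute_alpha(p),
                 transition_temperatures = roots,
                 regime = regime,
                 s_max = s_max,
                 scan = scan,
                 params = p),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat("Helix-coil phase report\n")
  cat(sprintf("  alpha  = %.5f\n", x$alpha))
  cat(sprintf("  regime = %s\n", x$regime))
  cat(sprintf("  max s~ over scan = %.4g\n", x$s_max))
  if (length(x$transition_temperatures))
    cat(sprintf("  transition temperature(s): %s K\n",
                paste(sprintf("%.2f", x$transition_temperatures),
                      collapse = ", ")))
  else cat("  no s~ = 1 crossing in the scanned window\n")
  invisible(x)
}

#' Phase boundary in reduced units
#'
#' For each reduced energy balance `alpha`, the reduced temperatures at
#' which [s_tilde_internal()] crosses 1 (0, 1, or 2 roots), tracing the
#' dome-shaped boundary between native and denatured regions. At
#' `alpha = -1` the single root has the closed form
#' `tau* = 1/log(Q + 1)`.
#'
#' @param alpha_grid Vector of `alpha` values (`>= -1`).
#' @param Q Conformational states per unit (`> 1`).
#' @param q Water-orientation degeneracy (`>= 1`), default 16.
#' @param tau_range Reduced-temperature scan interval, default
#'   `c(0.01, 10)` (log-spaced).
#' @param resolution Scan points per `alpha`, default 1000.
#' @return Data frame with one row per `alpha`: `alpha`, `n_roots`,
#'   `tau1`, `tau2` (NA where absent), roots ascending.
#' @export
phase_boundary_internal <- function(alpha_grid, Q, q = 16,
                                    tau_range = c(0.01, 10),
                                    resolution = 1000) {
  if (Q <= 1) stop("Q must be > 1")
  if (q < 1) stop("q must be >= 1")
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                  length.out = resolution))
  out <- lapply(alpha_grid, function(a) {
    f <- s_tilde_internal(internal_params(taus, a, Q, q)) - 1
    f[!is.finite(f)] <- sign(f[!is.finite(f)]) * 1e300
    roots <- numeric(0)
    sgn <- sign(f)
    for (i in which(sgn[-length(sgn)] * sgn[-1] < 0)) {
      r <- stats::uniroot(function(tt)
        s_tilde_internal(internal_params(tt, a, Q, q)) - 1,
        lower = taus[i], upper = taus[i + 1], tol = 1e-10)$root
      roots <- c(roots, r)
    }
    roots <- sort(roots)
    data.frame(alpha = a, n_roots = length(roots),
               tau1 = if (length(roots) >= 1) roots[1] else NA_real_,
               tau2 = if (length(roots) >= 2) roots[2] else NA_real_)
  })
  do.call(rbind, out)
}
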