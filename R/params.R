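#' Gas constant
#'
#' CODATA value of the molar gas constant, used to convert Kelvin
#' temperatures into molar energy units (`t = R*T`).
#'
#' @format Numeric scalar, J mol^-1 K^-1.
#' @export
R_GAS <- 8.314462618

#' Microscopic parameters of the explicit-water Zimm-Bragg model
#'
#' Bundles the parameters of the spin Hamiltonian: each of the `N` peptide
#' units carries a conformational spin with `Q` states (one helical,
#' `Q - 1` coil) and, when its intramolecular H-bond is broken, two water
#' spins with `q` orientations each (one orientation H-bonds to the
#' peptide). Energies are in units of temperature (`k_B = 1`).
#'
#' @param Q Conformational states per peptide unit (`>= 1`; integer for
#'   enumeration, may be real elsewhere).
#' @param q Water orientations per binding site (`>= 1`). Default 16, the
#'   entropic cost implied by a ~40 degree H-bond acceptance cone
#'   (see [q_from_angle()]).
#' @param U Intramolecular plus solvent-solvent H-bond energy sum (`> 0`).
#' @param E Water-polypeptide H-bond energy (`>= 0`).
#' @param T Temperature in energy units (`> 0`).
#' @return An object of class `zb_params`.
#' @examples
#' zb_params(Q = 2, q = 2, U = 1, E = 0.5, T = 1)
#' @export
zb_params <- function(Q, q = 16, U, E, T) {
  stopifnot(is.numeric(Q), is.numeric(q), is.numeric(U), is.numeric(E),
            is.numeric(T))
  if (Q < 1) stop("Q must be >= 1 (one helical + Q-1 coil states)")
  if (q < 1) stop("q must be >= 1 (water orientations per site)")
  if (U <= 0) stop("U must be > 0")
  if (E < 0) stop("E must be >= 0")
  if (T <= 0) stop("T must be > 0")
  structure(list(Q = Q, q = q, U = U, E = E, T = T), class = "zb_params")
}

#' Reduced-unit parameters of the stability surface
#'
#' Theoretical units used for the stability-parameter surface: reduced
#' temperature `tau = T*ln(Q)/U` and reduced energy balance
#' `alpha = (E - U)/U`. `alpha = -1` is the water-free reference (`E = 0`).
#'
#' @param tau Reduced temperature (`> 0`), may be a vector.
#' @param alpha Reduced energy balance (`>= -1`).
#' @param Q Conformational states per unit (`> 1`).
#' @param q Water orientations per site (`>= 1`), default 16.
#' @return An object of class `internal_params`.
#' @export
internal_params <- function(tau, alpha, Q, q = 16) {
  stopifnot(is.numeric(tau), is.numeric(alpha))
  if (any(tau <= 0)) stop("tau must be > 0")
  if (alpha < -1) stop("alpha must be >= -1 (alpha = -1 is the water-free reference)")
  if (Q <= 1) stop("Q must be > 1")
  if (q < 1) stop("q must be >= 1")
  structure(list(tau = tau, alpha = alpha, Q = Q, q = q),
            class = "internal_params")
}

#' Laboratory-unit fit parameters
#'
#' The four quantities estimated from a thermal melt curve: the
#' temperature-shift `t0` (K, a glass-transition-like offset entering
#' every denominator as `R*(T - t0)`), the single intramolecular H-bond
#' energy `h = U/2` (J/mol), the polypeptide-solvent H-bond energy `h_ps`
#' (J/mol), and the entropic cost `Q` of helix nucleation
#' (`sigma = 1/Q`). The water degeneracy `q` is a fixed model constant.
#'
#' @param t0 Temperature shift (Kelvin).
#' @param h Intramolecular H-bond energy (J/mol, `> 0`).
#' @param h_ps Polypeptide-solvent H-bond energy (J/mol, `>= 0`).
#' @param Q Entropic cost of a H-bond (`> 1`).
#' @param q Water-orientation degeneracy, default 16 (not fitted).
#' @return An object of class `lab_params`.
#' @examples
#' lab_params(t0 = 260.6, h = 2134, h_ps = 2141, Q = 233)
#' @export
lab_params <- function(t0, h, h_ps, Q, q = 16) {
  stopifnot(is.numeric(t0), is.numeric(h), is.numeric(h_ps), is.numeric(Q))
  if (h <= 0) stop("h must be > 0")
  if (h_ps < 0) stop("h_ps must be >= 0")
  if (Q <= 1) stop("Q must be > 1 (sigma = 1/Q must lie in (0,1))")
  if (q < 1) stop("q must be >= 1")
  structure(list(t0 = t0, h = h, h_ps = h_ps, Q = Q, q = q),
            class = "lab_params")
}

#' @export
print.lab_params <- function(x, ...) {
  cat(sprintf(
    "Lab-unit helix-coil parameters:\n  t0 = %.1f K, h = %.0f J/mol, h_ps = %.0f J/mol, Q = %.4g (sigma = %.4g), q = %g\n",
    x$t0, x$h, x$h_ps, x$Q, 1 / x$Q, x$q))
  invisible(x)
}

#' Water-orientation degeneracy from the H-bond acceptance angle
#'
#' The number of distinguishable water orientations at a binding site is
#' taken as the square of the number of acceptance cones fitting into a
#' full turn: `floor(360 / (2*angle))^2`. With the ~40 degree limit on the
#' H-O...O angle this gives `floor(4.5)^2 = 16`, the package default for
#' `q`.
#'
#' @param angle_deg Maximal deviation of the donor-acceptor axis from
#'   linearity, in degrees. Default 40.
#' @return Integer degeneracy `q`.
#' @examples
#' q_from_angle(40)  # 16
#' q_from_angle(35)  # 25
#' @export
q_from_angle <- function(angle_deg = 40) {
  if (!is.numeric(angle_deg) || angle_deg <= 0)
    stop("angle_deg must be a positive number of degrees")
  floor(360 / (2 * angle_deg))^2
}
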