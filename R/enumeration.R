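# Exact finite-chain oracles for the explicit-water spin model.
#
# The chain has N peptide units with conformational spins gamma_i in 1..Q
# (1 = helical) and two water spins mu_i^(1,2) in 1..q per unit. The bond
# indicator delta_i = [gamma_i = 1][gamma_{i+1} = 1] runs over i = 1..N
# (periodic, gamma_{N+1} = gamma_1) or i = 1..N-1 (open; the terminal unit
# then counts as broken for water binding, keeping all 2N water spins).

.ENUM_CAP_CONF <- 2^24   # conformation-space enumeration cap
.ENUM_CAP_JOINT <- 2^22  # joint conformation x water cap

.match_boundary <- function(boundary) match.arg(boundary, c("periodic", "open"))

# all Q^N conformation configurations, rows = configs
.conf_space <- function(N, Q) {
  as.matrix(expand.grid(rep(list(seq_len(Q)), N), KEEP.OUT.ATTRS = FALSE))
}

# per-unit broken/intact indicator and helical bond count for each config
.bond_counts <- function(G, boundary) {
  N <- ncol(G)
  H <- G == 1
  if (boundary == "periodic") {
    nxt <- c(2:N, 1)
    D <- H & H[, nxt, drop = FALSE]
  } else {
    D <- H[, -N, drop = FALSE] & H[, -1, drop = FALSE]
  }
  rowSums(D)
}

.check_enum_size <- function(states, cap, what) {
  if (states > cap)
    stop(sprintf(
      "state space too large for %s enumeration: ~%.3g states exceeds the cap of %.3g",
      what, states, cap))
}

#' Total energy of one explicit-water configuration
#'
#' Evaluates the full Hamiltonian
#' `H = -U * sum_i delta_i - E * sum_i (1 - delta_i) * ([mu_i1 = 1] + [mu_i2 = 1])`
#' for a single assignment of conformational and water spins. Under the
#' open boundary the bond sum drops the `i = N` term and the terminal unit
#' counts as broken in the water term.
#'
#' @param gamma Integer vector of N conformational spins in `1..Q`.
#' @param mu N x 2 integer matrix of water spins in `1..q`.
#' @param p A [zb_params()] object (integral `Q`, `q`).
#' @param boundary `"periodic"` (default) or `"open"`.
#' @return Scalar energy (same units as `U`, `E`).
#' @export
energy_total <- function(gamma, mu, p, boundary = c("periodic", "open")) {
  boundary <- .match_boundary(boundary)
  stopifnot(inherits(p, "zb_params"))
  N <- length(gamma)
  if (N < 2) stop("chain length must be >= 2")
  mu <- as.matrix(mu)
  if (!all(dim(mu) == c(N, 2))) stop("mu must be an N x 2 matrix")
  if (any(gamma < 1 | gamma > p$Q | gamma != round(gamma)))
    stop("conformational spins out of range 1..Q")
  if (any(mu < 1 | mu > p$q | mu != round(mu)))
    stop("water spins out of range 1..q")
  helix <- gamma == 1
  if (boundary == "periodic") {
    delta <- helix & helix[c(2:N, 1)]
  } else {
    delta <- c(helix[-N] & helix[-1], FALSE)  # terminal unit broken
    }
  n_bonds <- if (boundary == "periodic") sum(delta) else sum(delta[-N])
  -p$U * n_bonds - p$E * sum((1 - delta) * ((mu[, 1] == 1) + (mu[, 2] == 1)))
}

#' Exact partition function of the explicit-water model
#'
#' Brute-force partition function `Z = sum exp(-H/T)` over all
#' configurations of the finite chain. With `water_sum = "site"` (default)
#' the conformation space is enumerated exhaustively and each water spin is
#' summed exactly over its `q` orientations (the spins are independent
#' given the conformation, so the per-spin sum `K + q - 1` at a broken site
#' and `q` at an intact site is an identity, not an approximation). With
#' `water_sum = "joint"` every one of the `Q^N * q^(2N)` joint states is
#' visited through [energy_total()] — the literal Hamiltonian sum, capped
#' at 2^22 states.
#'
#' @param N Chain length (`>= 2`).
#' @param p A [zb_params()] object with integral `Q`, `q`.
#' @param boundary `"periodic"` (default) or `"open"`.
#' @param water_sum `"site"` or `"joint"` (see Details).
#' @return Scalar partition function.
#' @examples
#' p <- zb_params(Q = 2, q = 2, U = 1e-12, E = 0, T = 1)
#' partition_explicit(2, p)  # ~ Q^N * q^(2N) = 64 at zero energies
#' @export
partition_explicit <- function(N, p, boundary = c("periodic", "open"),
                               water_sum = c("site", "joint")) {
  boundary <- .match_boundary(boundary)
  water_sum <- match.arg(water_sum)
  stopifnot(inherits(p, "zb_params"))
  if (N < 2) stop("chain length must be >= 2")
  if (p$Q != round(p$Q) || p$q != round(p$q))
    stop("enumeration requires integral Q and q")
  if (water_sum == "joint") return(.partition_joint(N, p, boundary))
  .check_enum_size(p$Q^N, .ENUM_CAP_CONF, "conformation-space")
  G <- .conf_space(N, p$Q)
  nhel <- .bond_counts(G, boundary)
  W <- exp(p$U / p$T)
  K <- exp(p$E / p$T)
  # intact unit: both water spins free (q each); broken: K + q - 1 each
  sum(W^nhel * (p$q^2)^nhel * ((K + p$q - 1)^2)^(N - nhel))
}

# literal sum over all Q^N * q^(2N) joint states via energy_total
.partition_joint <- function(N, p, boundary) {
  n_states <- p$Q^N * p$q^(2 * N)
  .check_enum_size(n_states, .ENUM_CAP_JOINT, "joint")
  G <- .conf_space(N, p$Q)
  M <- as.matrix(expand.grid(rep(list(seq_len(p$q)), 2 * N),
                             KEEP.OUT.ATTRS = FALSE))
  z <- 0
  for (g in seq_len(nrow(G))) {
    for (m in seq_len(nrow(M))) {
      mu <- matrix(M[m, ], ncol = 2)
      z <- z + exp(-energy_total(G[g, ], mu, p, boundary) / p$T)
    }
  }
  z
}

#' Partition function via the implicit-water reduction
#'
#' The exact solvent summation factors the water contribution out of the
#' partition function:
#' \deqn{Z = (K + q - 1)^{2N} \sum_{\{\gamma\}} \prod_i
#'   [1 + \tilde V \delta_i], \quad \tilde V = \tilde W - 1,}
#' with the effective weight from [effective_weight()]. Must agree with
#' [partition_explicit()] to machine precision — that identity is the
#' correctness guarantee of the implicit model.
#'
#' @inheritParams partition_explicit
#' @return Scalar partition function.
#' @export
partition_implicit <- function(N, p, boundary = c("periodic", "open")) {
  boundary <- .match_boundary(boundary)
  stopifnot(inherits(p, "zb_params"))
  if (N < 2) stop("chain length must be >= 2")
  if (p$Q != round(p$Q) || p$q != round(p$q))
    stop("enumeration requires integral Q and q")
  .check_enum_size(p$Q^N, .ENUM_CAP_CONF, "conformation-space")
  G <- .conf_space(N, p$Q)
  nhel <- .bond_counts(G, boundary)
  W <- exp(p$U / p$T)
  K <- exp(p$E / p$T)
  Vt <- effective_weight(W, K, p$q) - 1
  (K + p$q - 1)^(2 * N) * sum((1 + Vt)^nhel)
}

#' Finite-chain helicity degree by exact enumeration
#'
#' Boltzmann average of the fraction of intact intramolecular bonds,
#' `<(1/n_b) sum_i delta_i>`, where `n_b = N` bonds for the periodic chain
#' and `N - 1` for the open chain. `model = "explicit"` weights
#' configurations with the site-summed explicit water factors;
#' `model = "implicit"` uses the reduced weights `W~^(n_helical)` — the
#' water prefactor cancels, so both give identical helicity.
#'
#' @inheritParams partition_explicit
#' @param model `"explicit"` (default) or `"implicit"` weighting.
#' @return Helicity degree in `[0, 1]`.
#' @export
theta_finite <- function(N, p, boundary = c("periodic", "open"),
                         model = c("explicit", "implicit")) {
  boundary <- .match_boundary(boundary)
  model <- match.arg(model)
  stopifnot(inherits(p, "zb_params"))
  if (N < 2) stop("chain length must be >= 2")
  if (p$Q != round(p$Q) || p$q != round(p$q))
    stop("enumeration requires integral Q and q")
  .check_enum_size(p$Q^N, .ENUM_CAP_CONF, "conformation-space")
  if (p$Q == 1) return(1)  # only helical states exist
  G <- .conf_space(N, p$Q)
  nhel <- .bond_counts(G, boundary)
  W <- exp(p$U / p$T)
  K <- exp(p$E / p$T)
  w <- if (model == "explicit") {
    W^nhel * (p$q^2)^nhel * ((K + p$q - 1)^2)^(N - nhel)
  } else {
    effective_weight(W, K, p$q)^nhel
  }
  n_bonds <- if (boundary == "periodic") N else N - 1
  sum(nhel * w) / (n_bonds * sum(w))
}

#' Finite-chain helicity from the reduced transfer matrix
#'
#' Helicity of the implicit-water Zimm-Bragg chain computed from the
#' 2 x 2 reduced transfer matrix `B = [[W~, Q-1], [1, Q-1]]` (coil states
#' aggregated), with `W~ = Q*s~ + 1` and `Q = 1/sigma`. For the periodic
#' chain `Z = lambda1^N + lambda2^N` and the bond density follows from the
#' analytic eigenvalue derivatives; the open chain uses an exact 2 x 2
#' recursion. Reaches chain lengths far beyond enumeration range and
#' converges to [order_parameter()] as `N` grows.
#'
#' @param N Chain length (up to ~1e5).
#' @param s_tilde Stability parameter (`>= 0`).
#' @param sigma Cooperativity parameter in `(0, 1]`.
#' @param boundary `"periodic"` (default) or `"open"`.
#' @return Helicity degree in `[0, 1]`.
#' @examples
#' transfer_matrix_theta(1e4, 1, 0.01)  # ~ (1 + sigma)/2
#' @export
transfer_matrix_theta <- function(N, s_tilde, sigma,
                                  boundary = c("periodic", "open")) {
  boundary <- .match_boundary(boundary)
  if (!is.numeric(s_tilde) || s_tilde < 0) stop("s_tilde must be >= 0")
  if (!is.numeric(sigma) || sigma <= 0 || sigma > 1)
    stop("sigma must lie in (0, 1]")
  if (N < 2) stop("chain length must be >= 2")
  Q <- 1 / sigma
  Wt <- Q * s_tilde + 1
  if (boundary == "periodic") {
    a <- Wt - (Q - 1)
    disc <- sqrt(a^2 + 4 * (Q - 1))
    l1 <- (Wt + Q - 1 + disc) / 2
    l2 <- (Wt + Q - 1 - disc) / 2
    dl1 <- (1 + a / disc) / 2
    dl2 <- (1 - a / disc) / 2
    r <- l2 / l1
    # theta = W~ dZ/dW~ / (N Z), Z = l1^N + l2^N
    Wt * (dl1 + r^(N - 1) * dl2) / (l1 * (1 + r^N))
  } else {
    B <- matrix(c(Wt, 1, Q - 1, Q - 1), 2, 2)
    dB <- matrix(c(1, 0, 0, 0), 2, 2)
    v <- c(1, Q - 1)   # first-spin class weights
    dv <- c(0, 0)
    for (k in seq_len(N - 1)) {
      dv <- dv %*% B + v %*% dB
      v <- v %*% B
      sc <- max(abs(v))
      v <- v / sc
      dv <- dv / sc
    }
    z <- sum(v)
    Wt * sum(dv) / ((N - 1) * z)
  }
}
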