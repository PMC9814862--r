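# shared fixtures and random-draw helpers

p_1a_dark <- function() table1_params("a:darkgreen")
p_1c_dark <- function() table1_params("c:darkgreen")
p_1d_lime <- function() table1_params("d:limegreen")

# random microscopic parameter draw for enumeration identities
draw_zb_params <- function(Q, q) {
  zb_params(Q = Q, q = q,
            U = runif(1, 0.1, 2),
            E = runif(1, 0, 2),
            T = runif(1, 0.5, 2))
}

# random lab-unit draw with exponents kept far from overflow
draw_lab_params <- function() {
  lab_params(t0 = runif(1, 180, 280),
             h = runif(1, 500, 8000),
             h_ps = runif(1, 0, 9000),
             Q = runif(1, 5, 500))
}

# (s~, sigma) implied by microscopic parameters through the exact mapping
map_to_zb_state <- function(p) {
  Wt <- effective_weight(exp(p$U / p$T), exp(p$E / p$T), p$q)
  list(s_tilde = (Wt - 1) / p$Q, sigma = 1 / p$Q)
}

# count of interior maxima from finite-difference sign changes (+ to -)
n_interior_maxima <- function(y) {
  s <- sign(diff(y))
  s <- s[s != 0]
  sum(s[-length(s)] > 0 & s[-1] < 0)
}
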