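# zbwater

Analysis of protein and polypeptide helix–coil transitions with a
Zimm–Bragg model in which water is present in the Hamiltonian — and then
summed out *exactly*.

## Who this is for

Anyone fitting thermal denaturation (CD-style) melt curves who wants the
fit to return physically meaningful H-bond energetics — including the
energy of the water–polypeptide bond, which conventional two-state or
bare Zimm–Bragg analyses cannot provide — and an explanation of why some
proteins cold-denature and others never do.

## The model in brief

Each peptide unit carries a conformational spin with `Q` states (one
helical, `Q−1` coil; σ = 1/Q is the nucleation parameter). An
intramolecular H-bond of energy `U` forms between neighbouring helical
units. Every *broken* bond exposes two water binding sites, each holding
a water spin with `q = 16` orientations of which one donates an H-bond of
energy `E`. Because the water spins are independent given the chain
conformation, they sum out of the partition function without
approximation, leaving the classical model with a renormalized
propagation weight:

    W̃ = q² W / (q + K − 1)²,    W = exp(U/T),  K = exp(E/T)

so only the stability parameter s̃ = (W̃ − 1)/Q changes — σ is untouched.
In laboratory units (energies per mole, `h = U/2`, `h_ps = E`, and a
glass-like temperature shift `t0` so that denominators read
`R(T − t0)`), the helicity degree θ(T) is a closed-form function of four
fitting parameters `(t0, h, h_ps, Q)`. The balance
`α = (h_ps − h)/h` controls the phase behavior: monotone (heat-only)
stability for α < 0, re-entrant cold + heat denaturation for α > 0, and
denatured at all temperatures when water binding is too strong.

The package provides:

* `effective_weight()`, `effective_energy()`, `s_tilde_lab()`,
  `s_tilde_internal()`, `order_parameter()`, `theta_curve()` — the
  closed-form core;
* `partition_explicit()`, `partition_implicit()`, `theta_finite()`,
  `transfer_matrix_theta()` — exact finite-chain oracles proving the
  solvent summation identity;
* `find_transitions()`, `stability_trace()`, `phase_boundary_internal()`
  — transition temperatures (roots of s̃ = 1) and regime classification;
* `fit_melt_curve()`, `fit_without_shift()`, `goodness_report()` —
  bounded multi-start least squares with percent errors, R², σ and α;
* `generate_melt_curve()`, `table1_params()`, `read_melt_csv()`,
  `write_melt_csv()` — synthetic data, reference parameter fixtures, and
  the CSV dialect;
* a CLI (`inst/cli/zbwater`) with `fit`, `simulate`, `phase`, and
  `verify` subcommands.

## Worked example

Simulate a noisy melt curve from the reference heat+cold parameter set
(an intrinsically disordered protein that denatures both on heating and
on cooling), then recover the parameters and classify the phases:

```r
library(zbwater)

p <- table1_params("c:darkgreen")
print(p)
#> Lab-unit helix-coil parameters:
#>   t0 = 260.6 K, h = 2134 J/mol, h_ps = 2141 J/mol, Q = 233 (sigma = 0.004292), q = 16

mc <- generate_melt_curve(generator_spec(p, 265, 330, n_points = 60,
                                         noise_sd = 0.01, seed = 0))
fit <- fit_melt_curve(mc, fit_config(n_starts = 20, seed = 0))
print(fit)
#> Melt-curve fit (theta(T; t0, h, h_ps, Q), q fixed at 16 )
#> t0 = 260.0(0.194) K  h = 2158(0.76) J/mol  h_ps = 2165(0.781) J/mol  Q = 232(0.456)  sigma = 0.004  R2 = 0.998
#>   alpha = 0.0035, converged = TRUE, successful starts = 29

ph <- find_transitions(lab_params(fit$estimates[["t0"]], fit$estimates[["h"]],
                                  fit$estimates[["h_ps"]], fit$estimates[["Q"]]))
print(ph)
#> Helix-coil phase report
#>   alpha  = 0.00351
#>   regime = cold_and_heat
#>   max s~ over scan = 1.029
#>   transition temperature(s): 279.45, 300.65 K
```

Reading the output: the generating energies (2134/2141 J/mol) come back
within ~1% with sub-percent standard errors, `h_ps` is recovered
*slightly above* `h` (α > 0), and exactly that small positive balance
produces the two transition temperatures — cold denaturation near 279 K
and heat denaturation near 301 K. The same workflow from a shell, using
the wrapper script the package installs (put it on your PATH or call it
via `system.file("cli", "zbwater", package = "zbwater")`):

```sh
zbwater simulate --out melt.csv --fixture c:darkgreen --t-start 265 --t-stop 330 --noise-sd 0.01
zbwater fit --data melt.csv --out report.json
zbwater phase --fixture d:limegreen
zbwater verify            # exact solvent-summation self-checks
```

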