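# coopnet — a cooperative voter model of ecological communities

How can many species coexist on few resources, and why are diverse
communities often *more* stable, when classical random-matrix theory says
complexity destabilizes?  `coopnet` implements a stochastic community model
built to answer that question, for theoretical ecologists and systems
biologists who work with interaction networks (microbial consortia,
mutualistic webs) and want a tested, reproducible implementation of the
whole pipeline: exact simulation, mean-field analysis, stability theory,
fluctuation theory, and abundance patterns.

## The model

A community of `N` individuals over `S` species evolves by voter-type
replacement: a random individual dies and is replaced by an offspring of
species *j* at rate

    omega_j = eta_j + eps1 * sum_k eta_k M_kj * theta(eta_j)
                    + eps2 * sum_k eta_k L_kj * eta_j
                    + eps3 * sum_k eta_k H_kj * theta(eta_j)

where `eta_j` is the relative abundance of species *j* and `theta(x) = 1`
for `x > 0`, else 0.  `M >= 0` is *mediated cooperation* (habitat
modification, cross-feeding — linear in the benefactor's abundance),
`L` is exploitation (mass action, antisymmetric signs:
`L_ij * L_ji < 0` or both zero) and `H <= 0` is one-directional harm
(e.g. antibiotics).  With all intensities zero the model is the neutral
voter model.

As `N -> infinity` the abundances follow the mean field
`d eta_s/dt = omega_s - eta_s * sum_i omega_i`.  For purely cooperative
communities with an irreducible `M` (strongly connected positive-entry
graph), the stationary state is the normalized left Perron–Frobenius
eigenvector `m = v / sum(v)` — every species coexists.  Species without
incoming support must go extinct, triggering pruning cascades.  At a random
cooperative equilibrium the Jacobian is, to leading order,
`J = eps1 * (-S*mu_M * I + (M - mu_M))`, so its spectrum fills an ellipse
centered at `-eps1*S*mu_M` with semi-axes `eps1*sqrt(S)*sigma_M*(1 ± rho_M)`:
the damping grows like `S` while the bulk grows like `sqrt(S)`, hence
stability *increases* with diversity — cooperation inverts the classical
complexity–stability paradox.  Around a stable equilibrium the scaled
fluctuations `x = sqrt(N) * (eta - m)` form an Ornstein–Uhlenbeck process
whose stationary covariance solves `A V + V A' + D = 0`.

## Worked example

```r
library(coopnet)
set.seed(7)
spec <- ensemble_spec(S = 30, c_M = 0.4, c_L = 0.1,
                      family = "abs-normal", mu = 1, sigma = 0.3)
com <- sample_community(spec, eps1 = 1, eps2 = 1, eps3 = 0)
com
#> Community of 30 species (eps1 = 1, eps2 = 1, eps3 = 0)
#>   nonzero links: M 328, L 92, H 0

fit <- coop_equilibrium(com)
summary(fit)
#> Stationary community state (integrate method)
#>   S = 30, survivors = 30, fraction extinct = 0, residual = 1.67e-16
#>   abundances: 0.04735, 0.03317, 0.03438, 0.02631, 0.04604, ...
#>   linear stability (tangent subspace): max Re = -6.88899 -> stable
```

All 30 species coexist (the cooperative web is irreducible, so exploitation
cannot drive extinctions), the residual shows the state is stationary to
machine precision, and the equilibrium is linearly stable with a comfortable
spectral margin.  The random-matrix prediction puts that margin in context:

```r
st <- effective_stats(com$M)
jacobian_spectrum(community_jacobian(com, fit$m, check = FALSE), stats = st)
#> Jacobian spectrum (S = 30): max Re on tangent subspace = -6.88899
#>   ellipse prediction: center -11.2699, semi-axes (5.371, 0.2981), predicted max -5.89846

rsa_curve(fit)
#> RSA curve: 30 species, populations in [1, 2.243]
```

The observed leading eigenvalue (−6.89) sits inside the predicted ellipse
support, whose center `-S*mu_M` deepens linearly with `S`.  Stochastic
realizations around the equilibrium come from `simulate(fit, N = 10000)`,
and `stationary_covariance(build_ou(com, fit$m))` gives the matching
analytic fluctuation covariance.

Experiment drivers reproduce the standard in-silico studies:
`run_motif()` (coexistence cycle and extinction cascade),
`run_harm_scan()` (extinction fraction versus harmful connectivity),
`run_spectrum()` (eigenvalue clouds with ellipse overlays) and `run_rsa()`
(CV-invariance of the cumulative relative species abundance).  Each writes
TSV/JSON outputs plus a manifest sufficient to re-run identically; the
thin CLI in `exec/coopnet` drives them from a shell
(`coopnet rsa --config cfg.yaml --seed 1 --out results/`).

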