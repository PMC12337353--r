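# panhgt

Stochastic simulation and ensemble theory of bacteria–phage coevolution with
horizontal gene transfer (HGT) over combinatorial toxin/antitoxin genotypes.

## The problem

Bacterial pan-genomes hold far more phage-defense systems than any single
genome can carry. The *panimmunity* hypothesis proposes that a community
maintains its full defense repertoire collectively: individual strains carry
small subsets of the gene pool and keep exchanging them by HGT, so genes
survive even while the strains carrying them constantly go extinct. `panhgt`
implements a minimal model of this process for people studying microbial
eco-evolutionary dynamics: it answers how large an HGT rate is needed to
keep `L` defense genes, or all `K` genotypes, alive in a community of fixed
size `N`.

## The model

Each bacterial genotype is an unordered pair (or triple) of distinct
toxin/antitoxin (TA) genes from a pool of `L`, giving `K = choose(L, g)`
genotypes; phage genotypes carry the matching antitoxins, and in the default
matched mode phage *ij* infects only bacterium *ij*. Abundances `B_ij`,
`V_ij` follow antisymmetric Lotka–Volterra pair dynamics with per-capita
fitnesses

    f_B = s (1 − V/n_V*),   f_V = ω (B/n_B* − 1),   n* = N/K,

discretized as a Poisson reproduction process (each individual leaves
`Pois(1 + f·dt)` descendants), with total population sizes held at `N_B`,
`N_V` by a regulator. Three HGT channels move single genes between genomes
at per-capita rates `r_B` (bacteria→bacteria) and `r_V` (bacteria→phage, or
phage→phage in the mean-field coinfection mode).

The statistical-mechanics analysis treats the pair Lyapunov energy
`E(B,V) = (B − n* log B/n*) + (V − n* log V/n*)` as the energy of a particle
in a canonical ensemble: demographic noise pumps E up, HGT re-injection
cools it, and abundances settle into Gamma distributions
`n_G ~ Γ(mean N/K, scale Θ)`, `n_g ~ Γ(mean 2N/L, scale θ)` with effective
temperatures

    Θ = 1/(2r)             (both regimes)
    θ = 1/(2r)  (boom-bust, Regime II)   θ = 2/r  (oscillations, Regime III)

Requiring interior modes of these Gammas (shape > 1) yields the critical
HGT rates `r_cg ∝ L/N` (below: Regime I, genes die) and `r_cG ∝ K/N`
(below: Regime II, genotype turnover with gene persistence — the
panimmunity regime), equivalently diversity carrying capacities
`L_max ∝ rN`, `K_max ∝ rN`, and at saturating `r_V` the inter-bacteria
escape boundary `r_B > L/N_B`.

## Worked example: the boom-bust (panimmunity) regime

`L = 10` genes (`K = 45` genotypes), `N = 1e5` per side, and an HGT rate
`r = 2e-4` between the two critical rates `L/N = 1e-4` and `K/N = 4.5e-4`:

```r
library(panhgt)
params <- sim_params(L = 10, NB = 1e5, r = 2e-4, T = 2e4, seed = 1)
traj <- run_simulation(params)
classify_regime(traj)
#> regime II: no gene lost; 2505 genotype zero-touch events after burn-in (t > 2000)
fit_gamma(sample_abundances(traj)$genotype)
#> gamma_fit: mean = 2244, theta (scale) = 3161, shape = 0.71 | n = 4095, zero fraction = 0.010
boom_peaks(traj)
#> peak_stats: 54 booms above 1.111e+04, exponential tail rate = 0.0004085
theory_prediction(L = 10, g = 2, N = 1e5, r = 2e-4, regime = "II")
#> theory_prediction (regime II): Theta = 2500, theta = 2500 | rcg = 0.0001, rcG = 0.00045 | Lmax = 20, Kmax = 20
```

Reading the numbers: no gene was ever lost while thousands of genotype
extinction-and-rebirth events occurred — panimmunity at work. Strain
abundances are Gamma-distributed with shape < 1 (mode at zero: most strains
rare, a few booming). The boom peak heights have an exponential tail with
fitted rate 4.09e-4 ≈ 2r = 4e-4, the kill-the-winner prediction.

Other entry points: `find_boundary()` bisects the I/II or II/III phase
boundary in any rate parameter; `scan_parameter()` produces persistence-time
curves; `temperature_sweep()` compares fitted and predicted effective
temperatures across `r`; `build_interaction(..., "random_sparse")` replaces
the matched infection matrix with a repaired random sparse one.

A command-line interface wraps the same functionality:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "panhgt", package = "panhgt"))') \
    simulate --config config.yaml --seed 1 --out out/
```

with subcommands `simulate`, `scan`, `find-boundary`, `temperature-sweep`,
`fit-gamma`, `classify`, `peaks`, `theory`.

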