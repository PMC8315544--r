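# cptcoord

Risk-sensitive coordination games with cumulative prospect theory and
level-k theory of mind.

`cptcoord` is for computational cognitive scientists and behavioral game
theorists who want to ask how two human-like cognitive mechanisms —
**risk sensitivity** and a **bounded theory of mind** — shape
coordination between two self-regarding agents. It implements:

* **CPT valuation** of discrete prospects: reference-dependent power
  utility (`u(x) = x^γ` for gains, `−λ|x|^γ` for losses), Prelec
  probability weighting `w(p) = exp{−α(−log p)^δ}` (plus the original
  1992 form and the identity), and rank-dependent decision weights
  `ψ⁺(r) = w(P(R ≥ r)) − w(P(R > r))`, so that
  `V = Σ u(r − b) ψ(r)`. Expected utility theory is the
  identity-parameter special case (`eut_params()`).
* **Symmetric 2×2 games under CPT**: action values against a mixing
  opponent, mixed-equilibrium solving by grid bracketing plus bisection,
  pure equilibria, and two-parameter equilibrium sweeps. The stag hunt
  (`R, S, T, P = 5, −1, 1, 1`) is built in.
* **A 16-position Markov stag hunt**: a canyon with hares at position 3
  (reward 1, obtainable alone) and stags at position 11 (reward 5, paid
  only when both hunters stand there), with noisy movement (intended
  step 0.6 / stay 0.2 / opposite 0.2) and joint dynamics
  `P^{a₁,a₂} = (I ⊗ P^{a₁} + P^{a₂} ⊗ I)/2`.
* **CPT planning**: policy evaluation and greedy best response via a CPT
  Bellman recursion with exact rank-dependent backups, and **level-k
  policy towers** anchored at the uniform stereotype — including
  heterogeneous pairs (EUT vs CPT agents).
* **Stationary analysis**: policy-conditioned chains, stationary
  distributions `ρ = ρP` with verified irreducibility and residuals
  below 1e-10, coordination summaries, and ready-made sweeps over
  sophistication levels, reference points, discount factors, utility
  concavity, and agent mixes.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` heatmaps. See `vignettes/methods.Rmd` for the model, the
numerical choices (including how the solver handles the CPT backup's
lack of a contraction guarantee), and the reward-calibration caveats.

## Worked example

A certainty of 900 against a 95% shot at 1000. Expected value says
gamble (950 > 900); a CPT agent with `γ = 0.85, λ = 2, α = 1, δ = 0.75`
prefers the certainty:

```r
library(cptcoord)
params <- cpt_params(utility_spec("power", gamma = 0.85, lambda = 2),
                     weighting_spec("prelec", alpha = 1, delta = 0.75))
p <- prospect(c(1000, 0), c(0.95, 0.05))
cpt_value(p, eut_params())
#> [1] 950
cpt_value(p, params)
#> [1] 318.5598
certainty_value(900, params)
#> [1] 324.4189
```

The same risk profile moves the stag hunt's mixed equilibrium: the
classical Nash indifference sits at 1/3, the CPT agent needs the partner
to hunt stag with probability 0.52 before stag hunting looks as good as
the safe hare:

```r
mixed_equilibrium(stag_hunt(), eut_params())
#> <mixed_equilibrium> interior
#>   p* = 0.3333333333
mixed_equilibrium(stag_hunt(), params)
#> <mixed_equilibrium> interior
#>   p* = 0.521515849
```

In the Markov canyon, level-k recursion with the study's weighting
(`w(x) = exp{−0.5(−log x)^0.9}`, `b = 0`, `β = 0.9`) drives the hunters
toward the joint stag state — its value grows with sophistication, and
at level 2 the pair spends a quarter of its time there (the theoretical
ceiling is 0.25 plus slip leakage, since only one agent moves per step):

```r
tw <- level_k_tower(2, canyon_spec(), markov_cpt_params())
glance(tw)
#> # A tibble: 6 × 6
#>   agent level iterations      residual approximate stag_value
#>   <int> <int>      <int>         <dbl> <lgl>            <dbl>
#> 1     1     0        181 0.00000000991 FALSE             23.5
#> 2     1     1        185 0.00000000917 FALSE             28.9
#> 3     1     2        187 0.00000000979 FALSE             34.8
#> ...
rho <- tower_stationary(tw, 2, 2)
m <- coordination_metrics(rho, canyon_spec())
c(stag = m$stag_mass, hare = m$hare_mass)
#>        stag        hare
#> 0.250520043 0.003170566
autoplot(rho)  # 16 x 16 occupancy heatmap
```

`run_sweep()` and `run_experiment()` package the recurring study designs
(sophistication grids, reference-point and discount sweeps, EUT/CPT
comparisons) into tibbles and tab-separated tables; a thin command-line
wrapper lives at `inst/cli/cptcoord.R`.

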