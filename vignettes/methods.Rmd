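---
title: "Risk-sensitive coordination: models and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-sensitive coordination: models and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptcoord)
```

`cptcoord` studies how two cognitive mechanisms — risk sensitivity and a
bounded theory of mind — shape coordination between two self-regarding
agents. Risk sensitivity is modelled with cumulative prospect theory
(CPT); theory of mind with level-k best-response recursion. Both are
exercised on the stag hunt, in its one-shot normal form and as a Markov
game on a 16-position "canyon" hunting ground.

## Valuing uncertain outcomes

A *prospect* is a finite random variable $R$ over real outcomes. A CPT
agent is described by three ingredients, bundled in `cpt_params()`:

* a **reference point** $b$ splitting outcomes into gains ($r \ge b$) and
  losses ($r < b$);
* a **utility function** $u(x) = x^\gamma$ for gains and
  $u(x) = -\lambda |x|^\gamma$ for losses ($x = r - b$), with concavity
  $\gamma$ and loss aversion $\lambda$;
* a **probability weighting function** $w$, by default Prelec's
  $w(p) = \exp\{-\alpha(-\log p)^\delta\}$. Small $\alpha$ overweights
  small probabilities (possibility effect); large $\alpha$ underweights
  large ones (certainty effect). The original 1992 form
  $p^g/(p^g + (1-p)^g)^{1/g}$ is available for comparison.

The CPT value applies $w$ to *cumulative* probabilities of the ranked
outcomes. With outcomes sorted increasingly, a gain $r$ receives decision
weight $\psi^+(r) = w(P(R \ge r)) - w(P(R > r))$ and a loss
$\psi^-(r) = w(P(R \le r)) - w(P(R < r))$, and

$$V_{\mathrm{CPT}}(R) = \sum_{r \ge b} u(r - b)\,\psi^+(r)
  + \sum_{r < b} u(r - b)\,\psi^-(r).$$

With identity utility, identity weighting and $b = 0$ this is the plain
expectation — expected utility theory (EUT) is the identity-parameter
special case, available as `eut_params()`.

```{r}
p <- prospect(c(1000, 0), c(0.95, 0.05))
cpt_value(p, eut_params())
cpt_value(p, cpt_params(utility_spec("power", 0.85, 2),
                        weighting_spec("prelec", 1, 0.75)))
```

Two conventions matter and are fixed once:

* **$w(0) = 0$ by continuity.** The Prelec form is undefined at $p = 0$;
  zero-probability outcomes are dropped at construction, which realizes
  the same limit.
* **Outcomes exactly at $b$ count as gains**, matching the $r \ge b$
  definition of the gain set; since $u(0) = 0$ the choice only affects
  which cumulative direction weights the boundary outcome.
* **Duplicate outcomes are merged** (probabilities summed) when a
  `prospect()` is built, so rank weights are well defined. Rank-dependent
  weights are invariant to splitting an outcome into tied copies, which
  the internal vectorized kernel exploits.

`cpt_value_integral()` recomputes the value as the difference of two
tail-probability integrals $\int_0^\infty w(P(u^+ > \varepsilon))\,
d\varepsilon - \int_0^\infty w(P(|u^-| > \varepsilon))\,d\varepsilon$,
summing the step function exactly. It shares no code with the
rank-weight path and serves as a permanent cross-check; the suite holds
the two equal to $10^{-9}$ over a thousand random prospects.

## The normal-form stag hunt

The symmetric game `stag_hunt()` pays $(R, S, T, P) = (5, -1, 1, 1)$:
hunting stag together pays 5 each, hunting stag alone pays $-1$ against
the hare hunter's 1, and hare hunting pays 1 regardless. Against an
opponent who hunts stag with probability $p$, each action is a
two-outcome prospect; `mixed_equilibrium()` finds every $p^*$ at which
the two actions' CPT values coincide. Under EUT the indifference point
is the classical $p^*_{\mathrm{Nash}} = (P - S)/(R - S - T + P) = 1/3$.

Numerics: the indifference gap is evaluated on a 2001-point grid (it is
cheap and resolves roots at least $5 \times 10^{-4}$ apart) and every
sign change is bisected to an interval of $10^{-10}$. CPT can create
several indifference points; `equilibrium_sweep()` reports the smallest
root (a deterministic, reproducible convention) and warns with the full
list, which remains available from `mixed_equilibrium()`. When the gap
never changes sign the dominating pure strategy (0 or 1) is reported, so
sweep surfaces stay continuous across region boundaries. Sweeps default
to $b = 0$, $\alpha = 1$, $\lambda = 1$, $\gamma = 1$ with $\delta =
0.75$ held fixed; $\delta = 0.75$ follows the certainty/gamble analyses,
while the Markov experiments below use $\delta = 0.9$ — both appear in
the corresponding published parameterizations and both are plain
arguments, with each default following its own experiment family.

## The canyon Markov game

`canyon_spec()` defines the dynamic environment: 16 positions on a
canyon floor, hares at position 3, stags at position 11. Each hunter
picks Left, Stay or Right; the intended displacement succeeds with
probability 0.6, the agent slips and stays with 0.2, and slips the
opposite way with 0.2 (Stay sends its two slip masses one step each
way). Displacements that would leave the grid are folded onto staying.
This is the simplest clamped-slip model whose kernel entries take
exactly the five values $\{0, 0.2, 0.4, 0.6, 0.8\}$, with 0.4 and 0.8
only at the corners, and it leaves no degenerate (absorbing) rows. All
of it is configurable.

Joint dynamics couple the two single-agent kernels as
$P^{a_1,a_2} = \tfrac12 (I \otimes P^{a_1} + P^{a_2} \otimes I)$: per
step exactly one agent moves, so neither agent's action can change the
other's position and the dynamics are independent of who acts first.
Internally joint state $(s_1, s_2)$ is flattened as $s_2 n + s_1$; the
public interface always speaks in position pairs.

Rewards: a hunter on the hare position earns 1 unconditionally; both
hunters on the stag position earn 5 each; a lone stag hunter earns 0
(configurable `lone_stag_reward`). The published environment does not
print its reward magnitudes; 1 and 5 mirror the normal-form payoffs, and
the normal form's $-1$ for lone stag hunting has no stated Markov
analogue, so 0 is the default. Every qualitative reproduction below is
conditional on this calibration.

## CPT planning and level-k towers

The value of a joint state under policies $(\pi_1, \pi_2)$ satisfies a
CPT Bellman equation: the one-step prospect at $s$ is the distribution
of $r_i(s) + \beta V(s')$ over successors, with the agent's own action
mixture pooled *inside* the probability weighting, and
$V(s)$ is its CPT value. The tail-probability integrals of the backup
are evaluated exactly as rank-dependent sums over the (at most
five-point) successor support — under the joint kernel at most one agent
moves one step, so every successor distribution lives on the stencil
$\{s_1 \pm 1, s_2 \pm 1, \text{stay}\}$. The reward enters at the
*current* state, not on arrival, and iteration starts from $V \equiv 0$.

`best_response()` runs greedy CPT value iteration
($V(s) \leftarrow \max_a$ over the per-action backups) and returns a
policy uniform over all actions within `tie_tol` ($10^{-9}$) of the
per-state maximum — preserving exact ties rather than committing to an
arbitrary argmax. `level_k_tower()` anchors both agents at the uniform
stereotype (level 0) and lets each level best-respond to the opponent's
previous level under its own parameters; heterogeneous pairs (an EUT
agent facing a CPT agent) are supported. When the two agents share
parameters the tower is computed once and mirrored through the
agent-swap permutation, which is exact by induction from the
swap-invariant stereotype; a test verifies the shortcut against the
direct computation.

### When the backup has no fixed point

The CPT backup is not a sup-norm contraction. For an all-gain prospect
the decision weights telescope to 1 and the usual $\beta$-contraction
argument applies — with $b \le 0$ and nonnegative rewards every backup
is in this regime and iteration converges as fast as classical value
iteration. But when one-step outcomes straddle the reference point, the
gain and loss weights sum to $w(p) + w(1-p)$, which exceeds 1 for the
weighting used here (about 1.4 at $p = 0.5$ for $\alpha = 0.5,
\delta = 0.9$), making the map locally expansive with Lipschitz constant
$\beta\,(w(p) + w(1-p)) > 1$. In that regime an exact fixed point need
not exist: freezing the outcome ordering makes the backup affine, and
solving the frozen systems shows adjacent affine pieces with distinct
fixed points, neither inside its own region. The iterates then settle
into a limit cycle of tiny amplitude (about $3 \times 10^{-5}$ on
values of order 20 at $b = 1$) that no damping can remove.

The solver therefore watches the residual trace: if it plateaus below
`approx_tol` (default $10^{-4}$) the minimal-residual iterate is
accepted and flagged `approximate = TRUE`, with the achieved residual
reported in the result, `glance()` output and experiment manifests.
Genuine divergence — no plateau below `approx_tol` within `max_iter` —
remains an error carrying the full residual trace. Setting
`approx_tol = 0` enforces strict convergence. The 1992 weighting
function is accepted by the Markov solver but triggers a warning, as it
is known to make these instabilities much worse.

Whether the per-state greedy scheme is optimal among *mixed* policies
under CPT (where value is nonlinear in the own mixture) is not settled;
the greedy recursion is implemented as the model's evident intent, and
the EUT limit — where greediness is provably optimal — is held to
classical oracles in the tests.

## Stationary analysis

Conditioning the joint kernel on a policy pair gives a Markov chain
$P^{\pi_1,\pi_2}_{s,s'} = \sum_{a_1,a_2} P^{a_1,a_2}_{s,s'}
\pi_1(a_1|s)\pi_2(a_2|s)$; its stationary distribution $\rho = \rho P$
summarizes where the hunters live in the long run.
`stationary_distribution()` first verifies irreducibility by
strong-connectivity search on the positive-entry graph (the slip noise
makes every policy-conditioned canyon chain irreducible; a reducible
chain is a diagnosed error naming the communicating classes), then
solves by eigen-decomposition of $P^\top$ polished with power iteration
until the sup-norm residual is below $10^{-10}$, falling back to pure
power iteration from the uniform vector if the eigen-decomposition is
degenerate. Because the chains are irreducible, the starting state of
the original story is irrelevant to the stationary summary.

`coordination_metrics()` reduces $\rho$ to a stag mass (both hunters on
the stag position), a hare mass (at least one hunter on the hare
position) and per-agent marginal occupancies. `run_sweep()` packages the
recurring study designs — sophistication grids, reference points,
discount factors, utility concavity, and EUT/CPT agent mixes — into
tibbles of settings, masses and full distributions.

```{r, eval = FALSE}
sw <- run_sweep("levels_grid", k_max = 4)
autoplot(sw)
```

## What the defaults reproduce

Under the default calibration the package reproduces, and the test
suite asserts, the qualitative findings of the study conditions: the
value of the joint stag state grows with sophistication $k$;
coordination peaks already at asymmetric levels $(2, 1)$; raising the
reference point moves the hunters from stags to hares (with $b \le 0$
behaviorally identical, since all outcomes are then gains and the value
shifts by a constant), while at $b = 1$ higher sophistication restores
stag hunting; CPT agents out-coordinate EUT agents at equal $k$;
patience ($\beta = 0.95$ vs $0.85$) favors stags; and even mild utility
concavity ($\gamma = 0.99$) erodes coordination.

These are properties of the model under this package's reward
calibration, not quantitative reproductions: the published environment
leaves the reward magnitudes unprinted, and no human or behavioral data
enter anywhere. The canyon itself is a deliberately stylized habitat —
one-dimensional, two prey sites, independent slip noise — so passing
tests speak to the mechanism (framing, weighting and recursion steering
coordination), not to ecological realism.

## Problem sizes and tolerances

The tests run the full 256-joint-state game for the oracle equivalences
and the qualitative sweeps (towers to $k = 4$; levels $k \le 2$ for the
discount/concavity/mix comparisons, where the effects are already
unambiguous), and 2-to-4-position fixtures wherever an exhaustive or
brute-force oracle is the point — small enough that all $3^4$
deterministic policies can be enumerated and every kernel entry checked
by explicit loops. Value iteration runs at `tol = 1e-8` (sup-norm),
equilibrium bisection at $10^{-10}$, stationary residuals at
$10^{-10}$, and the EUT-limit comparisons against linear solves at
$10^{-6}$.

## Limitations

* The greedy CPT best response may not be optimal among mixed policies;
  see above.
* At reference points inside the reward range, planner results are
  approximate fixed points with reported residuals (about $10^{-5}$
  here), not exact solutions — a property of the model, made explicit
  rather than hidden.
* Level-0 stereotypes are uniform; richer stereotypes (e.g. learned by
  self-play), populations beyond two agents, and inference of CPT
  parameters from choice data are out of scope.
* Continuous-outcome prospects are not supported; everything is finite
  and discrete.
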