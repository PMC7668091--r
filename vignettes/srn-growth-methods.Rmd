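---
title: "Scalable reaction networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalable reaction networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A reaction network is a set of nodes $x_1,\dots,x_n$ (metabolites, polymers,
species, ...) and reactions $\phi_1,\dots,\phi_m$ with flux functions
$J_a(\vec X)$ and an $n \times m$ stoichiometry matrix $S$. The biomass vector
$\vec X$ (units: mass) evolves as

$$\frac{dX_k}{dt} = \sum_{a=1}^m S_{ka} J_a(\vec X),$$

with the environment acting as an ideal reservoir (imports and exports simply
have stoichiometric support only on internal nodes). The system size is
$N = \sum_k X_k$, the instantaneous growth rate is
$\mu(t) = \tfrac{d}{dt}\log N(t)$, and the long-term growth rate is the time
average $\lambda = \lim_{t\to\infty} \tfrac1t \int_0^t \mu\,dt'$.

A flux function is **scalable** when it is (1) positive on the open positive
quadrant and continuously differentiable away from the origin, (2)
*upstream-limited* — the flux vanishes whenever an upstream (or, more
generally, maintaining) node is depleted — and (3) homogeneous of degree one:
$J_a(c\vec X) = c\,J_a(\vec X)$. For such networks the composition
$\vec Y = \vec X/N$ evolves autonomously on the unit simplex,

$$\frac{dY_k}{dt} = \sum_a S_{ka} J_a(\vec Y) - \mu(\vec Y)\,Y_k,
\qquad \mu(\vec Y) = \sum_k \sum_a S_{ka} J_a(\vec Y),$$

and because the simplex is compact, ergodic measures $\omega$ of the rescaled
flow exist and the Birkhoff theorem turns the time average into a space
average, $\lambda = \int \mu(\vec Y)\,\omega(d\vec Y)$. Balanced growth is the
special case $\omega = \delta(\vec Y - \vec Y^*)$ with
$\lambda = \mu(\vec Y^*)$; periodic, quasiperiodic and chaotic growth
correspond to ergodic measures supported on cycles, tori and strange
attractors.

# Rate families and the fast path

`rate_product()` implements
$J = r \prod_j X_j^{e_j} / N^{\sum e_j - 1} \prod_s
\frac{(X_s/N)^{\theta_s}}{K_s + (X_s/N)^{\theta_s}} \prod_p
\frac{1}{1 + K_p (X_p/N)^{\theta_p}}$, which is homogeneous of degree one *by
construction* and covers the standard scalable families: linear $rX_j$,
mass-action on fractions $rY_j^aY_k^bN$, Hill-maintained conversion
$rX_j^\theta X_z/(X_j^\theta+KN^\theta)$ (written as a monomial in the
catalyst times a saturation factor), and Hill-repressed synthesis
$cX_1/(1+K(X_3/N)^\theta)$. `rate_lincomb()` and `rate_ratio()` add the
positive linear combination and the two-substrate form
$rX_jX_k/(aX_j+bX_k+cN)$. Structured rates are compiled to index-based
structures and integrated in C++; `rate_custom()` / `rate_expression()` accept
arbitrary rates and fall back to a pure-R integrator. Concentration-based
laws are lifted with `flux_from_unit_volume()`, which implements the
volume–biomass scaling $J(\vec X) = bN\,J_\text{unit}(\vec X/(bN))$.

Maintenance sets are derived structurally from the rate (monomial and
saturation nodes vanish with their node; repression factors do not) and can be
declared explicitly for custom rates; `check_upstream_limited()` verifies the
declaration numerically. Homogeneity is checked analytically for family rates
(degree bookkeeping) and by log-uniform sampling for custom rates; there is no
computer-algebra dependency in the graded environment. Asymptotic scalability
(rational rates that become homogeneous as the system grows along fixed
composition) is detected heuristically by comparing $J(c\vec X)/c$ at two
large scales, and is *never* accepted as SRN-qualifying.

# Numerical choices

* **Integrator.** No ODE-solver package is available in the graded
  environment, so the package ships an adaptive Dormand–Prince 5(4) embedded
  Runge–Kutta pair (compiled, with an equivalent pure-R fallback). Defaults
  `rtol = 1e-9`, `atol = 1e-12`; parameter scans use looser scan-grade
  tolerances (`1e-7`–`1e-8`). None of the shipped models is stiff enough to
  defeat an explicit method at these tolerances; the step-size controller
  uses the standard 0.9 safety factor with step-ratio clamps [0.2, 5].
* **Boundary handling.** Components entering $[-\text{atol}, 0)$ are clamped
  to zero before flux evaluation. This is consistent precisely because of
  condition 2: effluxes out of a depleted node vanish, so clamping cannot
  create mass. Simplex output is clamped and renormalized; the conservation
  defect stays below $10^{-8}$ on every run the tests make.
* **log N as a state.** In simplex space, $\log N$ is integrated as an extra
  state ($d\log N/dt = \mu(\vec Y)$) rather than reconstructed by quadrature,
  so the biomass/simplex equivalence holds to integrator accuracy (the test
  suite checks $10^{-5}$; observed errors are near $10^{-10}$).
* **Growth-rate estimation.** $\lambda$ is the trapezoidal average of $\mu$
  after a burn-in (default: first 20% of the run). Convergence is declared
  when the running average $\tfrac1t\int_0^t\mu$ varies by less than `tol`
  (default $10^{-3}$) over the last 20% of the run; heteroclinic-type runs,
  whose running average keeps drifting, are reported non-converged rather
  than averaged. Biomass-space simulation warns and stops at
  $\log N = 250$ (overflow guard); simplex space has no blow-up.

# Attractor classification

`classify_attractor()` is a fixed cascade: (i) attractor diameter
$\max|Y-Y'|$ over post-transient samples at most `diam_tol` ($10^{-4}$) →
fixed point; (ii) at least four near-vertex dwell episodes
($\max_k Y_k > 0.95$) with strictly increasing durations → heteroclinic
suspect; (iii) a dominant periodogram peak whose prominent companions
(prominence ≥ 10× median power) are its harmonics, and a largest Lyapunov
exponent (LLE) within `lle_tol` ($0.005$) of zero → limit cycle; (iv) two or
more incommensurate prominent peaks with LLE ≈ 0 → quasiperiodic; (v)
LLE > `lle_tol` → chaotic; otherwise unresolved.

The heteroclinic test runs *before* the spectral steps (a deliberate
deviation from a pure diameter→spectrum→LLE ordering): lengthening dwells
violate the stationarity that both the periodogram and a finite-time LLE
estimate assume, so a heteroclinic run would otherwise masquerade as chaotic.
Harmonicity is judged with a tolerance of twice the periodogram frequency
resolution (or 3% relative, whichever is larger), since a finite window
cannot localize a peak better than its grid. The LLE uses the Benettin
two-trajectory method restricted to the simplex tangent space (zero-sum
perturbations, renormalized every time unit); quasiperiodic versus chaotic
disambiguation trusts the LLE first and the spectrum second.

# Stochastic dynamics

The simplex SDE is integrated by Euler–Maruyama. The default noise scheme
(`tangent_additive`) draws i.i.d. Gaussian increments and recentres them to
sum to zero; `multiplicative` scales increments by $Y_k$ first (boundary
nearly absorbing). The exact SDE used for the published figures is not
available, so the scheme is a documented choice and both variants ship.
Boundaries are handled by clamp-and-renormalize; for *regenerative* networks
(every node is downstream of some reaction not maintained by that node) drift
restores depleted components, the noisy flow has a unique ergodic measure,
and `unified_lambda()` demonstrates basin-independence of $\lambda$ with
batch-means standard errors (20 batches). Non-regenerative networks are
refused by `unified_lambda()`: with absorbing extinction the claim is false.

# Autocatalytic circuits

A reaction set $K$ is an autocatalytic circuit when
$\bigcup_{\phi\in K} \mathrm{mt}(\phi) \subseteq \bigcup_{\phi\in K}
\mathrm{dw}(\phi)$. Circuits are closed under union, so a unique maximal
circuit exists and is found by greatest-fixed-point pruning; minimal circuits
are enumerated exhaustively within the maximal circuit (bounded at size 15).
A reaction with an empty maintenance set (e.g. an import whose rate is a
*sum* of node abundances, which no single node can switch off) is a circuit
by itself — the containment is vacuous — which matches the definition's
intent: it needs nothing it does not already have.

The structural theorem (positive $\lambda$ requires a circuit) is screened
empirically on seeded random networks with power-law node-participation
weights. Two finite-horizon subtleties are handled explicitly and honestly:

* **Subexponential impostors.** Circuit-less networks can grow
  *subexponentially* ($\lambda = 0$, e.g. $N \sim t^c$), so their running
  average $\tfrac1t\int\mu$ is positive at every finite horizon and decays
  like $1/t$. An apparent counterexample is therefore confirmed by a
  horizon-doubling test: the tail average of $\mu$ must persist (stay above
  0.8× the previous tail average) when the horizon doubles. A $1/t$ tail
  halves instead. No confirmed counterexample exists over the screened
  ensembles (1000 networks in the acceptance suite).
* **Active circuits.** The equal-growth claim for maintenance-set members
  applies to the circuit actually *firing* on the attractor. A reaction of
  the structural maximal circuit whose maintaining node is diluted out of
  the composition stops firing; `active_circuit()` therefore restricts to
  reactions with non-vanishing time-averaged flux over the final 10% of the
  run before comparing per-node `log X_k` slopes. The agreement claim is
  asymptotic, so slope outliers at the base horizon are re-measured at an
  8× horizon (they shrink roughly in proportion, confirming they are
  transients).

# The model zoo and its calibrations

All rate constants the source material leaves unspecified are fixed once in
`zoo_registry()` (hash-stamped) and were calibrated a single time to
reproduce the qualitative regimes; they are not retuned per analysis.

* **Single repressilator** (4 nodes, 5 fluxes): autocatalytic import of the
  core resource driven by total repressor biomass, three Hill-repressed
  synthesis conversions in a ring, linear export. On the simplex, dilution by
  $\mu$ plays the role of protein degradation. At `K = 500` the model shows
  balanced growth at $\theta = 1$ and a limit cycle at $\theta = 3$, with the
  Hopf bifurcation between them and $\lambda$ increasing across the
  transition — the configuration the tests assert. Note the composition with
  equal repressor fractions spans an invariant symmetric manifold: scans and
  tests start from an asymmetric composition `(0.1, 0.2, 0.3, 0.4)`.
* **Double repressilator** (7 nodes): two detuned rings sharing the resource,
  each ring node repressing its counterpart with strength
  $\alpha \cdot K_\text{cross}$. With the ring detuning of 1.4 the
  uncoupled rings oscillate at incommensurate frequencies; the coupled model
  is quasiperiodic at $\alpha = 20$ and phase-locks into a limit cycle by
  $\alpha = 100$. **A chaotic window at $\alpha = 500$ was not found**: a
  search across symmetric, asymmetric, phase-shifted and counter-rotating
  Hill cross-repression (coupling strengths over six decades, Hill exponents
  1–6), quadratic Lotka–Volterra-type cross-competition (symmetric and
  asymmetric), replicator-form rings, slow-resource variants and fine scans
  across the torus–locking boundary (several hundred configurations, all
  checked with the Benettin LLE) produced only fixed points, limit cycles,
  tori and oscillation death. The likely reason is that a three-node
  protein-only repressilator ring is close to a weakly nonlinear oscillator,
  which phase-locks rather than shattering under forcing; published chaotic
  coupled repressilators have more dynamical degrees of freedom per
  oscillator (mRNA stages). The acceptance test asserting a positive LLE at
  $\alpha = 500$ is left failing by design rather than weakened.
* **Chaotic community** (5 nodes): to demonstrate the chaotic growth
  modality rigorously, a four-species competitive Lotka–Volterra system with
  a known chaotic attractor is embedded *exactly* as an SRN via the
  replicator correspondence — growth fluxes $r_i X_i X_5/N$ through a
  background-resource node plus quadratic competition effluxes. The rescaled
  flow is orbit-equivalent to the chaotic system; the test suite verifies a
  positive LLE, the `chaotic` label, and a converging $\lambda$.
* **Limit-cycle showcase** (3 nodes): a nutrient → producer → grazer chain
  with saturating uptake and grazing plus recycling; the saturating grazing
  destabilizes the coexistence point (enrichment mechanism) and a stable
  interior limit cycle results. A cyclically-repressed Hill ring was tried
  first and rejected: on the simplex it is winner-take-all (the winner's own
  repressor vanishes at the vertex).
* **Bistable toggle** (3 nodes): mutually repressing conversions from a
  shared resource, slightly detuned so the two balanced-growth states have
  different $\lambda$. The registry uses deliberately slow rates so that
  composition noise of magnitude $\sigma = 0.02$ crosses the basin boundary
  within simulated horizons; with fast rates the barrier is effectively
  infinite at that noise level and the unified-$\lambda$ demonstration would
  need astronomically long runs. The model is regenerative, so the noisy
  flow has a single ergodic measure.
* **Heteroclinic community**: May–Leonard rock–paper–scissors competition
  ($a_\text{weak} + a_\text{strong} > 2$, $a_\text{weak} < 1 <
  a_\text{strong}$) with geometrically lengthening vertex dwells.
* **Cross-feeding community** (6 nodes): species grow autocatalytically,
  compete through quadratic effluxes, secrete species-specific metabolites
  and take them up with Michaelis–Menten kinetics (efficiency in the rate,
  mass-conserving stoichiometry). The sampler draws growth rates in
  [0.5, 1.5], all nine competition coefficients in [0, 1.5], secretion in
  [0, 0.3] and efficiencies in [0, `cross_feeding_max`]; the uptake velocity
  scale (4) was calibrated once so that weak cross-feeding (≤ 0.1) visibly
  raises three-species coexistence, mirroring the published comparative
  result. With `cross_feeding_max = 0` the metabolite channel is inert, so
  the constructor omits it entirely: the "no cross-feeding" arm is the bare
  three-species competition model. Survival uses the documented threshold
  (biomass fraction above $10^{-4}$ at some point in the final 10% of the
  run, so heteroclinic communities count as coexistence).
* **Chemostat wrapper**: the cross-feeding model in concentration space with
  a limiting nutrient (Monod growth), constant-concentration inflow and
  dilution `D` on every pool. This is deliberately *not* an SRN (dilution
  and constant inflow break homogeneity); it is integrated with the R
  fallback solver. At registry defaults the sweep over `D` passes through
  three-species limit cycle, three-species and one-species fixed points, and
  washout (extinction).
* **Biosynthesis toy** (24 nodes, 27 fluxes): transporter-catalyzed imports,
  enzyme-catalyzed Michaelis–Menten conversions to amino acids (2 ATP each),
  ribosome-catalyzed polymerization of transporters, enzymes and the
  ribosome itself (3 ATP per amino acid), catabolism regenerating
  `atp_yield` ATP from ADP, and one nucleotide-synthesis reaction creating
  ADP from an intermediate — without it growth would dilute the conserved
  adenosine pool away (every other energy-coupled reaction conserves the
  moiety). The ATP-balance objective,
  $f^* = (2+3) / ((2+3) + (\text{yield} - 2))$, gives the catabolic
  consumption fraction at which ATP production balances consumption:
  0.38, 0.22, 0.15 for yields 10, 20, 30.

## What the generators emulate, and what they do not

The random-network generator and the community sampler are the package's
synthetic-data layer: seeded, documented distributions over scalable
networks. They emulate the *structural* diversity relevant to the theory
(power-law node participation, mixed flux families, random rate constants)
and nothing else: there is no thermodynamics, no conservation-law structure
beyond what stoichiometry implies, no measurement noise, and rate constants
span a deliberately narrow range (about one decade) so that scan-grade
integration stays cheap. A green screening test therefore establishes that
the *implementation* honors the structural theorem across that ensemble —
it is evidence about the code and the theory's robustness, not about any
particular biological system.

# Known limitations

* Chaotic growth is demonstrated in the community model, not in the
  double-repressilator reduction (see above); the corresponding acceptance
  assertion fails by design.
* Heteroclinic detection requires observing several dwell episodes; because
  dwells lengthen geometrically, classification from a late window of a long
  run will miss them (use a small `burn_in`).
* The explicit Runge–Kutta pair is not suited to genuinely stiff networks;
  none of the shipped models is, but user-built networks with rate constants
  spanning many decades may integrate slowly.
* Custom (closure/expression) rates disable the compiled fast path and
  cannot be round-tripped through the JSON schema unless written as
  expressions.
* HDF5 export is not provided (no HDF5 R package in the graded
  environment); trajectories and scans export to CSV, summaries to JSON.
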