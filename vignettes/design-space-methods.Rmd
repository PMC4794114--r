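---
title: "Design space analysis of power-law biochemical models: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design space analysis of power-law biochemical models: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(designspacer)
```

## The problem

Nonlinear biochemical models carry many rate constants and binding
constants whose values are unknown and hard to measure. `designspacer`
analyzes such models *without* prior parameter values, starting only from
their architecture. It applies the system design space idea: partition
log-parameter space into regions, each characterized by a *qualitatively
distinct phenotype* — a tractable power-law subsystem obtained by keeping
the dominant production and the dominant consumption term of every
equation — and then enumerate, realize, classify and co-visualize those
phenotypes automatically.

## Model class and recasting

The native model class is the **generalized mass action (GMA)** system:
ordered differential and algebraic equations whose two sides are sums of
power-law terms, each term a positive constant times a product of
parameters and variables raised to real exponents. Saturable rational
rate laws (sums of power laws over sums of power laws) are recast exactly
into GMA form by `recast_to_gma()`: each distinct multi-term denominator
becomes one auxiliary variable `d` with the algebraic equation
`0 = (denominator terms) - d`, and the ratio becomes the numerator times
`d^-1`. Single-term denominators are folded directly. Recasting changes
the representation, not the values: the recast right-hand sides equal the
original ones identically, which the test suite verifies to relative
1e-10 and, for trajectories, 1e-6.

## Cases, signatures and numbering

With $P_i$ positive and $N_i$ negative terms in equation $i$, a *case*
selects one term of each sign per equation; there are $\prod_i P_i N_i$
potential cases. The per-equation pairs form the system signature (e.g.
`[311121113121]` for the relaxation oscillator circuit below), a case's
selections form its case signature, and cases are numbered $1..\prod P_iN_i$
by digital counting with the first equation most significant and the
negative index cycling fastest — the convention that reproduces the
published case numbering of this circuit family.

## Validity by linear programming

Keeping only the selected terms yields an S-system, whose steady state is
linear in the logarithms: equating the log of the dominant production and
consumption terms per equation gives $M y = b_0 + B_z z$ with $y$ the
log10 dependent variables and $z$ the log10 parameters. When $M$ is
nonsingular (smallest singular value at least $10^{-10}$ of the largest;
otherwise the case is *unresolvable* and excluded, sub-case resolution
being out of scope), the steady state is affine in $z$, and each
*dominance condition* — selected term at least as large as each competing
term of the same sign, evaluated at that steady state — becomes one affine
inequality in $z$ alone. The case's region is the polytope where all rows
hold.

Validity is decided by a slack-maximization LP: maximize $\delta$ subject
to every dominance row $\ge \delta$ and every parameter at least $\delta$
inside its box. A case is valid iff the optimum exceeds
$\varepsilon_{slack} = 10^{-6}$ log10 units — "valid somewhere in
parameter space" is read as "has nonempty interior", so exact boundary
ties do not count. The optimizer doubles as the automatically determined
parameter set for the phenotype (with zero rows it is the Chebyshev
center of the box). Default bounds are $\pm 6$ decades per parameter; the
enumerated counts for the circuit family are unchanged from $\pm 3$
through $\pm 9$ decades, which the suite asserts as a regression.

The LPs are solved by a dense two-phase primal simplex implemented in the
package (Dantzig pricing, Bland's rule on stalls). It is validated in the
tests against exhaustive vertex enumeration on low-dimensional problems.

## Local dynamics and oscillatory potential

For a valid case, the fixed point is the exponentiated log-linear
solution. The Jacobian of the S-system over all dependent variables has
entries $(g_{ij}T^+_i - h_{ij}T^-_i)/X_j$; auxiliary variables are
eliminated by the implicit function theorem, $J = A - BC^{-1}D$.
Counting eigenvalues with real part above $10^{-9}$ classifies the
phenotype: stable, exponentially unstable, or oscillatory unstable when a
complex-conjugate pair has positive real parts (an unstable focus,
consistent with limit cycles born in Hopf bifurcations).

*Oscillatory potential* asks whether an unstable focus occurs anywhere in
the region, not merely at the witness. Two structural facts make this
decidable rather than a matter of luck. First, the reduced Jacobian of an
S-system factors as $\mathrm{diag}(\varphi)K$ where $K$ is the constant
matrix of reduced net kinetic orders and $\varphi_i > 0$ is the turnover
rate of dynamic equation $i$. Second, $\log_{10}\varphi$ is affine in
$z$. The detector therefore (i) scans a deterministic grid of turnover
log-ratios (default $\pm 3$ decades in steps of 0.5, refined by
Nelder–Mead ascent of the largest complex-pair real part within a 0.75
decade trust region), and (ii) checks each focus-positive candidate for
*realizability* inside the region with an exact LP whose equality rows
pin the turnover ratios (preferring, when feasible, a solution with unit
geometric-mean turnover — the growth-rate time normalization). A
realizable candidate returns a concrete parameter point with an unstable
focus. Seeded hit-and-run probing of the region polytope (budget 200)
remains as a fallback; pure probing alone is not relied on because the
focus-bearing subregions can occupy well under 1% of a region's volume.
The whole classification is deterministic for a fixed seed, and in
practice seed-independent because the scan precedes the probes.

## The two-gene circuit family

`build_circuit()` constructs the 16-member activator–repressor family:
activator mRNA $X_1$, activator $X_2$, repressor mRNA $X_3$, repressor
$X_4$, with binding polynomials $d_1, d_3$ for the two promoters, so each
design recasts to 6 equations in the order $X_1, X_2, X_3, X_4, d_1,
d_3$. Nascent proteins are absorbed into the effective translation
rates $k_2, k_4$, and degradation plus dilution into the lumped
inactivation rates $\gamma_1..\gamma_4$ — the 6-pair signature admits
exactly this lumping. Binary indices per gene choose the transcription
mode: dual control ($\delta=1$) places both regulators on the promoter,
**mutually exclusively**, with only the primary regulator ($\pi$)
carrying a free fold-change (activator-primary:
$\alpha(1+\rho_A A + R)/(1+A+R)$ with $\rho_A \ge 1$; repressor-primary:
$\alpha(1+A+\rho_R R)/(1+A+R)$ with $\rho_R \le 1$; the non-primary
regulator antagonizes purely by competitive occupancy). Single control
($\delta=0$) keeps one site — the repressor for gene 1, the activator for
gene 3 — and constitutive control is the single-mode site with its fold
pinned to 1. The fold constraints are part of the model (encoded as
bounds $\log_{10}\rho_A \in [0,6]$, $\log_{10}\rho_R \in [-6,0]$), which
is what makes each dual gene contribute exactly 5 valid dominance
combinations, each single gene 3, and each constitutive gene 2; the
valid count of every design is the product of its two gene factors.

Occupancies are $A_i = (X_2/K_{Ai})^{n_A}$ and $R_i = (X_4/K_{Ri})^{n_R}$.
Default cooperativities are per-promoter: $n_A = 2$ at the autogenous
activator promoter, $n_A = 4$ at the repressor-gene promoter (a steeper
response, as produced by tandem cooperative activator sites), and
$n_R = 2$ at both. These defaults were fixed once from the loop-gain
requirements of the family itself: a four-step negative feedback loop is
unstable only if its gain exceeds 4 (the secant condition), so the
negative-only architecture needs $n_A n_R > 4$ across the loop, while the
maximal-interaction phenotype (simultaneous autoactivation and
self-repression) loses its *focus* — the instability becomes real — if
the autogenous activation order is 3 or more. $n_A = (2, 4)$, $n_R = 2$
is the choice satisfying both constraints with the self-repression order
held at 2.

Time is in hours; simulations and reported witnesses can be normalized so
the geometric mean of $\gamma_1..\gamma_4$ is 1/h (a 1 h doubling-time
dilution scale), via an equality constraint on `g1..g4`.

## Slices, ensembles, ordering

`rasterize_slice()` maps a two-parameter slice: since every case's rows
and turnover logs are affine in the two axis coordinates, region
membership and eigenvalue counts are evaluated directly per grid point
(no LP), and each point gets a color class — monostable (blue), bistable
(three cases with eigenvalue counts 0/0/1, red), unstable focus (yellow),
mixed 0/1/2 (orange), other (grey). The default resolution is 301×301;
the test suite uses 21–81 per axis, which is ample for the qualitative
class assertions it makes.

`co_localize()` realizes several phenotypes in one slice: one joint LP
with a shared copy of all non-axis parameters, per-case copies of the
axis coordinates, maximizing the minimum slack over all cases' rows.
`maximal_coexistent_subset()` searches subsets in decreasing size and
lexicographic order with monotone pruning (any candidate containing a
known-infeasible subset — including precomputed infeasible pairs — is
skipped); the first feasible subset is a maximum, with ties resolved
toward the lexicographically smallest list. Multiple maximum subsets can
exist; for the relaxation oscillator on the inactivation-rate axes the
search returns one of several 11-member maxima. `ordered_ensemble()`
adds hard rows phasing the cases along a single axis with a configurable
margin (default 0.5 decades).

## Synthetic fixtures and what passing tests show

`random_gma_fixture()` generates small seeded GMA systems for the
property suites. The default structural class is the **cascade**:
acyclic regulation with own-variable turnover, for which the dominant
case at any parameter point can be chosen equation by equation
downstream and is therefore always self-consistent — the valid regions
provably tile the box, and the suite checks thousands of sampled points
for coverage. The `feedback` class (production terms may reference any
variable) exercises enumeration, steady states and Jacobians more
broadly, but for it dominance can cycle: a sampled point may belong to no
valid region, a documented limitation of dominance analysis that this
package does not attempt to resolve (no sub-case or cyclical-case
machinery). Feedback behavior is instead covered by the circuit family,
whose analyzed slices are verified gap-free. Fixture tests, being built
on power-law systems with unit rate constants and exponents in
$\{-2,-1,1,2\}$, say nothing about stiffness or scale ranges beyond the
$\pm 6$ decade box.

The sampling oracle used against the LP is one-sided by design: a sampled
point satisfying all dominance rows certifies validity, but sampling can
never prove invalidity, so the suite only asserts the sound direction.

## Numerical choices

* Logarithms are base 10 throughout; LP coordinates are log10 parameters.
* Singularity tolerance for steady-state matrices: smallest singular
  value below $10^{-10}$ of the largest; such cases are reported
  unresolvable, never raised as errors during enumeration.
* Validity threshold $\varepsilon_{slack} = 10^{-6}$ log10 units; exact
  ties (e.g. between proportional terms with equal constants) give zero
  slack and are invalid.
* Eigenvalue positivity tolerance $10^{-9}$.
* Trajectory classification inspects the final 50% of the time span and
  requires at least 6 extrema; the last-to-first peak-to-trough amplitude
  ratio within [0.95, 1.05] is sustained, below 0.95 with at least 3
  cycles damped, anything else (including still-growing transients)
  monotone/none. These thresholds are package choices; only the
  qualitative labels are inherent.
* Simulations use `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`;
  oscillator demonstrations integrate 1000 h so slow limit cycles (growth
  rates of order 0.1/h) saturate within the analyzed window.

## Known limitations

* No sub-case ("cyclical case") resolution: singular dominance
  subsystems are excluded from the repertoire.
* Coverage of parameter space by valid regions is guaranteed only for
  acyclic architectures; feedback systems can have points in no region.
* The maximal co-visualizable subset is exact in size, but its membership
  is one of possibly several maxima.
* Oscillatory-potential detection is complete only up to the resolution
  of the turnover-ratio scan; the trust-region refinement makes misses
  unlikely but not impossible for extremely thin focus bands.
* No continuation or Floquet analysis: classification is local, from
  eigenvalues of the dominance-restricted model, with full-system
  simulation as the qualitative check.
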