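# designspacer

Automated design space analysis of nonlinear biochemical models written
as generalized mass action (GMA) systems — enumeration of every
qualitatively distinct phenotype a model architecture can express,
without prior parameter values.

## The problem and who this is for

Mechanistic gene-circuit and metabolic models carry dozens of rate
constants, binding constants and fold-changes that are rarely known.
This package is for modelers and synthetic-biology designers who want
global, parameter-free answers to questions like: *which behaviors can
this architecture produce at all? what parameter values realize each
behavior? can several behaviors be placed side by side in one
two-parameter plane, or phased in a chosen order along an induction
axis?*

It implements the system design space strategy. Any model whose rates
are sums of power-law terms — or ratios of such sums, which are recast
exactly into GMA form with auxiliary variables for each binding
polynomial — is decomposed into *cases*: one dominant production and one
dominant consumption term per equation. A case's S-system has an
analytic, log-linear steady state, so the dominance conditions become
affine inequalities in the log10 parameters, and each case's validity
region is a convex polytope tested by linear programming:

* a case with $P_i, N_i$ terms per equation contributes to
  $\prod_i P_i N_i$ potential phenotypes (the *system signature*);
* `enumerate_repertoire()` solves one slack-maximizing LP per case; the
  valid set is the *phenotypic repertoire* and each valid case gets an
  automatically determined interior parameter set (the LP witness);
* `classify_case_dynamics()` computes reduced-Jacobian eigenvalues
  (auxiliary variables eliminated via $J = A - BC^{-1}D$) and decides
  *oscillatory potential* — whether an unstable focus exists anywhere in
  the region — by a deterministic scan over turnover-rate ratios with an
  exact LP realizability check;
* `rasterize_slice()`, `co_localize()`, `maximal_coexistent_subset()`
  and `ordered_ensemble()` map and combine phenotypes in
  two-dimensional slices of design space.

A built-in application reproduces a published screen of 16 two-gene
activator–repressor circuit designs (binary transcription-mode indices
π₁, δ₁, π₃, δ₃), including the relaxation oscillator.

## Worked example: the two-gene relaxation oscillator

```r
library(designspacer)

circ <- relaxation_oscillator()          # design D.14: pi1=1, delta1=1, pi3=1, delta3=0
compute_system_signature(circ$system)$flat
#> [1] "311121113121"
total_case_count(circ$system)
#> [1] 36

rep <- enumerate_repertoire(circ$system)
rep
#> Phenotypic repertoire: 15 valid of 36 potential phenotypes
#>   valid cases: 1, 7, 8, 13, 15, 17, 19, 20, 21, 22, 23, 24, 29, 35, 36
```

Of 36 potential phenotypes only 15 have a nonempty region anywhere in
the ±6-decade parameter box. Classifying each valid phenotype's local
dynamics at (and around) its automatically determined parameter set
singles out one phenotype capable of oscillation:

```r
norm <- linear_constraints(   # 1/h geometric-mean inactivation (time units)
  eq_A = matrix(0.25, 1, 4, dimnames = list(NULL, c("g1","g2","g3","g4"))),
  eq_b = 0)
cd <- classify_case_dynamics(circ$system, 23, constraints = norm, seed = 24)
cd
#> Dynamics at witness: exponentially_unstable (2 positive eigenvalue(s)); oscillatory potential: TRUE
```

Case 23 — activator-driven transcription repressed through the promoter
binding polynomial — is the unique case whose region contains a
complex-conjugate eigenvalue pair with positive real parts (an unstable
focus); `cd$focus_point` is a parameter set realizing it. Simulating the
full (pre-dominance) model there:

```r
tr <- simulate_full_system(circ$rational, cd$focus_point, t_end = 1000,
                           case = 23, gma = circ$system)
classify_trajectory(tr, "X4")
#> [1] "sustained_oscillation"
```

Eleven of the fifteen phenotypes can be shown together in a single slice
whose axes are the two regulator inactivation rates:

```r
ms <- maximal_coexistent_subset(circ$system, rep, axes = c("g2", "g4"))
length(ms$subset)
#> [1] 11
```

And the full 16-design screen (valid counts, oscillatory counts and
case numbers per design):

```r
sc <- screen_designs(seed = 1)
sc$table[sc$table$design %in% c("D.9", "D.12", "D.14"),
         c("design", "valid", "total", "n_oscillatory", "oscillatory_cases")]
#>  design valid total n_oscillatory oscillatory_cases
#>     D.9     9    16             1                 7
#>    D.12    25    81             4       16;18;43;45
#>    D.14    15    36             1                23
```

A thin command-line front end over the same functions ships in
`inst/cli/designspace` (subcommands `enumerate`, `params`, `stability`,
`screen`, `slice`, `colocalize`, `order`, `simulate`), and
`parse_model_file()` / `write_model_file()` define a plain-text model
format for user-supplied GMA systems.

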