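# qconcept

Quantum interference models for concept combination data.

## The problem

When people judge the membership of items in combined concepts, the
judgements systematically violate classical (fuzzy-set / Kolmogorov)
probability. For a disjunction such as *Fruits or Vegetables*, a single
classical probability space forces

```
max(mu_A, mu_B)  <=  mu(A or B)  <=  min(1, mu_A + mu_B)
```

yet measured membership weights routinely fall below the lower bound
(underextension — below both components: double underextension) or above
the upper one (overextension). Quantum cognition models such data by
representing each concept as a unit vector in a complex Hilbert space and
the combination as their normalised superposition
`(|A> + |B>)/sqrt(2)`, so that per item *k*

```
mu_k(A or B) = (mu_k(A) + mu_k(B))/2 + c_k sqrt(mu_k(A) mu_k(B)) cos(phi_k)
```

The second term is *interference*: `phi_k` is the phase difference between
the two concept waves at item *k* and `c_k` the overlap of the two item
basis vectors. The package fits this model to per-item collapse
probabilities (the relative frequencies with which each item is chosen as
the best member of a concept), with the orthogonality of the two concept
vectors enforced by a greedy partial-sum scheme over the per-item
interference budgets

```
lambda_k = sqrt( mu_k(A) mu_k(B) - (mu_k(A or B) - (mu_k(A)+mu_k(B))/2)^2 )
```

which assigns each phase a sign and fixes a single overlap coefficient
`c_m < 1` on the top-ranked item. For n items the model lives in C^(n+1).

The package also ships two companion analyses: a two-dimensional
*interfering prototype* illustration — each concept a Gaussian wave packet
over a plane of items, with a 24-coefficient polynomial phase field
`theta(x, y)` interpolated so the superposition density reproduces the
disjunction data at the item locations — and the conjunction/negation
compatibility statistic

```
I = 1 - mu(A and B) - mu(A and B') - mu(A' and B) - mu(A' and B')
```

which is 0 under any classical joint, -1 for a pure quantum conjunction
model, and empirically near -0.81, motivating the quantum-informed
prediction `mu(A' and B') = 1.81 - (sum of the other three)`.

It is intended for researchers in mathematical psychology / quantum
cognition who want to fit, diagnose and visualise interference structure
in two-concept membership data.

## Worked example

The 24-item *Fruits* / *Vegetables* disjunction dataset ships with the
package:

```r
library(qconcept)

tab <- fruits_vegetables_table()
fit <- disjunction_model(tab)
fit
#> Two-concept disjunction interference model
#>   24 items embedded in C^25
#>   final partial sum S_24 = 0.0154
#>   basis overlap c_m = 0.8020 on rank-1 item 'Tomato'
#>   |<A|B>| = 2.00e-04
```

The final partial sum `S_24` is the residual of the sine-sum
orthogonality constraint after the greedy sign assignment; the overlap
coefficient `c_m = 0.802` on *Tomato* (the item with the largest
interference budget) absorbs it exactly, making the two concept vectors
orthogonal up to the 4-decimal rounding of the inputs (`|<A|B>| = 2e-4`).

Per-item parameters and diagnostics:

```r
head(coef(fit), 3)
#>     item     lambda rank epsilon   phi_deg c
#> 1 Almond 0.02172970   16       1  83.95797 1
#> 2  Acorn 0.02135269   17      -1 -94.68531 1
#> 3 Peanut 0.02847999   10      -1 -95.41565 1

classicality_report(tab)$counts
#> labels
#>             classical        underextension double-underextension
#>                     3                    19                     2
#>         overextension  double-overextension
#>                     0                     0
```

Almond's phase of 84 degrees means its disjunction weight sits slightly
above the classical average of its component weights (cos 84 > 0), while
21 of the 24 items fall below the classical lower bound
`max(mu_A, mu_B)` for a disjunction. The
fitted model reconstructs the observed `mu(A or B)` column to machine
precision (`fitted(fit)`), and `plot(fit, items = "Almond")` draws the
item's two concept waves and their interfering superposition.

The wave-field illustration, on the published item coordinates:

```r
coords <- wavefield_coordinates()
pair <- wavefield_pair()
field <- solve_phase_field(coords, theta_targets(tab))
field$coefficients[["1"]]
#> [1] 87.52493
0.1 * interference_density(pair, 0, 0, field)
#> [1] 0.0688196
```

Apple sits at the origin, so the constant coefficient of the phase field
is its phase target (about 87.6 degrees), and the superposition density
there, times the effective cell weight 0.1, returns Apple's observed
disjunction probability 0.0688.

A shell interface wrapping the same functions is installed as
`exec/qconcept` (subcommands `build`, `diagnose`, `wavefield`, `predict`,
`simulate`).

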