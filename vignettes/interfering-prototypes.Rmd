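---
title: "Interfering prototypes: the disjunction model, the wave field, and the negation statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interfering prototypes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qconcept)
```

## The data and what they violate

The package works with *membership collapse probabilities*: for a concept
and a fixed list of $n$ items, the probability $\mu_k$ that item $k$ is
chosen as the concept's best member, so each concept column sums to 1.
The packaged 24-item dataset gives these for *Fruits* ($A$),
*Vegetables* ($B$) and *Fruits or Vegetables*, derived from 7-point
membership ratings: ratings in $\{-3,\dots,3\}$ are shifted by $+3$,
averaged over participants per item, and renormalised over items
(`likert_to_collapse()`). This substitute correlates with — but was not
measured as — a forced-choice collapse experiment, which is why the model
below never depends on the exact values being collapse frequencies.

A single classical probability space forces
$\max(\mu_A,\mu_B)\le\mu_{A\lor B}\le\min(1,\mu_A+\mu_B)$ per item.
`classicality_report()` labels each item against these bounds
(`underextension`, `double-underextension`, `overextension`, else
`classical`; a `double-overextension` level is kept for symmetry with
conjunction data but is unreachable under the disjunction rule, since
exceeding the additive bound is already the strongest violation). One
caveat is documented rather than enforced: the classical bounds are
stated for membership weights of a single item, whereas the packaged
columns are collapse probabilities over items; the diagnostic is exposed
generically and applies verbatim to either input.

## The Hilbert-space disjunction model

`disjunction_model()` represents each concept as a unit vector in
$\mathbb{C}^{n+1}$ and the disjunction as the normalised superposition
$(|A\rangle+|B\rangle)/\sqrt2$, giving per item

$$\mu_k(A\lor B)=\tfrac12(\mu_k(A)+\mu_k(B))
  + c_k\sqrt{\mu_k(A)\mu_k(B)}\cos\phi_k ,$$

with interference phase $\phi_k$ and basis overlap $c_k\in(0,1]$. The fit
is a finite construction, not an optimisation:

1. **Budgets.** $\lambda_k=\sqrt{\mu_A\mu_B-(\mu_{A\lor B}-\bar\mu)^2}$,
   where $\bar\mu$ is the component average — the largest interference
   magnitude item $k$ can carry at $c_k=1$. A negative radicand means no
   phase exists; the fit aborts naming the offending items rather than
   clamping, since the construction has no provision for $c_k>1$.
2. **Signs.** Orthogonality $\langle A|B\rangle=0$ splits into a cosine
   sum, satisfied automatically when all three columns are normalised,
   and a sine sum $\sum_k \epsilon_k c_k \lambda_k = 0$ over unknown signs.
   `partial_sum_signs()` ranks the budgets descending (ties broken by
   original item order; the first sign is $+1$) and greedily subtracts
   whenever the running sum stays nonnegative, else adds. The running sum
   never goes negative, and the final residual $S_n$ is small.
3. **Overlap.** The single coefficient
   $c_m=\sqrt{((S_n-\lambda_m)^2+(\mu_{A\lor B}-\bar\mu)^2)/(\mu_A\mu_B)}$
   on the top-ranked item closes the sine sum exactly, so only that item
   needs a two-dimensional subspace — hence dimension $n+1$.
4. **Vectors.** With the free global phases set to zero
   ($\alpha_k=\gamma_k=0$, so $\beta_k=\phi_k$, and the extra coordinate
   of $|A\rangle$ set to 0), $|A\rangle$ has real coordinates
   $\sqrt{\mu_A}$ and $|B\rangle$ carries the phases; the top-ranked
   item's B-coordinate splits as $b_m c_m$ (phase $\phi_m$) and
   $b_m\sqrt{1-c_m^2}$ on coordinate $n+1$.

On the packaged table: $S_{24}=0.0154$, $c_m=0.802$ on *Tomato*, and
$|\langle A|B\rangle|=2\times10^{-4}$ — the residual is entirely the
4-decimal rounding of the inputs (the three column sums are 1.0001,
1.0001, 0.9999); on exactly normalised synthetic tables the residual is
at machine precision. Note that one published rendering of the B-vector
prints Tomato's coordinate as $b_m$ with the unit-overlap phase
(96.8°), which is not unit-norm as written; the package follows the
construction ($b_m c_m \approx 0.209$ at $98.5°$).

Reported conventions: phases are stored internally in radians but
exposed in signed degrees (one decimal matches the published table);
regression tolerances against the published per-item values are
$\pm 3\times10^{-4}$ on $\lambda$ and $\pm0.5°$ on $\phi$, absorbing the
up-to-0.3° drift that 4-decimal input rounding produces.

The model object supports the standard verbs: `fitted()`/`predict()`
evaluate the interference decomposition (reconstructing the training
disjunction column to machine precision — the construction is exact, so
"reconstruction residuals" are a sanity check, and
`residuals(type = "interference")` returns the scientifically meaningful
deviation from the classical average); `simulate()` resamples the
component columns as multinomial relative frequencies of a finite number
of forced choices and recomputes the disjunction from the fitted phases;
`plot()` draws the one-dimensional wave picture
$\sqrt{\mu_A}\cos x$, $\sqrt{\mu_B}\cos(x+\phi)$ and their half-sum.

## The two-dimensional wave field

The wave-field module renders the same interference structure as a
spatial illustration. Each concept is a Gaussian wave packet over a
plane of items,

$$|\psi(x,y)|^2 = D\,e^{-\left(\frac{(x-x_0)^2}{2\sigma_x^2}
  +\frac{(y-y_0)^2}{2\sigma_y^2}\right)},$$

with $D$ the *peak density* (this reading of the published parameters,
rather than an amplitude to be squared, is what reproduces the packaged
numbers). A small cell of effective weight $\delta_{\text{eff}}$ around
each item location converts density to probability:
$\delta_{\text{eff}}\,|\psi|^2(x_k,y_k)=\mu_k$. The packaged solution
uses $\delta_{\text{eff}}=0.1$, calibrated so that
$\delta_{\text{eff}} D_A$ equals the peak item's probability
($0.1\times1.18412=0.1184$, Apple) and likewise for $D_B$ (Broccoli); a
printed value of $0.01$ in the source account is inconsistent with its
own parameter table and is treated as an erratum.

`locate_item()` inverts the two constraints: each fixes an axis-aligned
ellipse, intersected by parameterising the A-ellipse by angle and
root-finding the B-constraint on a 720-point bracketing scan (up to four
real intersections; a `hint` selects a branch; a zero A-radius forces
the packet center). `solve_phase_field()` interpolates the per-item
phase targets — unit-overlap phases
$\epsilon_k\arccos((\mu_{A\lor B}-\bar\mu)/\sqrt{\mu_A\mu_B})$, *not*
the overlap-corrected model phases, which is the choice that makes the
superposition density reproduce $\mu(A\lor B)$ at the nodes — with a
fixed basis of 24 monomials up to $x^6$, solving the $24\times24$ linear
system directly (condition estimate ≈ $4\times10^9$ at the packaged
coordinates, checked and reported; the solve is refused above
$10^{14}$). The field is an exact interpolator (node residuals below
$10^{-6}$ degrees); *between* nodes it depends on the sign convention
of the targets, which the data do not pin down (cosine is even), so the
greedy-scheme signs are the default and only the constant coefficient is
regression-tested against the published value. The interference density

$$|\psi_{A\lor B}|^2=\tfrac12(|\psi_A|^2+|\psi_B|^2)
  +|\psi_A\psi_B|\cos\theta(x,y)$$

is sampled by `wave_grid()` (default extent $x\in[-12,16]$,
$y\in[-4,12]$ covering all packaged coordinates, $600\times400$ samples;
tests use coarser grids) and rendered by `render_grid()`. No uniqueness
is claimed for the coordinates or Gaussian parameters: they are packaged
constants of one published solution, not refitted.

## The negation statistic

For conjunction/negation quadruples,
$I = 1-\mu(A\,\&\,B)-\mu(A\,\&\,B')-\mu(A'\,\&\,B)-\mu(A'\,\&\,B')$
vanishes identically under any single classical joint, equals $-1$ for a
pure quantum conjunction model (a result of a companion two-sector
model, documented here but not computed), and is empirically stable
near $-0.81$. `predict_fourth_quantum()` therefore predicts the fourth
weight as $1.81$ minus the other three; the constant is an exposed
parameter defaulting to the printed value, the offset from the classical
complement rule is $0.81$ identically, and out-of-range predictions are
flagged rather than clamped — the overflow is itself diagnostic.

## Synthetic data generators

All generators are deterministic under a seed and exist to give the
tests known ground truth:

* `gen_quantum_table()` draws normalised component columns (normalised
  Gamma(2) draws, a realistic mildly-skewed profile), phases uniform on
  $[30°,150°]$ in magnitude with random signs — kept away from $0°/180°$
  so the arccos recovery stays well-conditioned — and sets the
  disjunction by the interference formula at unit overlap. The
  disjunction column's sum is reported, not forced; `balanced = TRUE`
  recentres the interference terms so all three columns sum to 1 exactly
  (used to exercise machine-precision orthogonality), and
  `rescale_disjunction = TRUE` instead renormalises (breaking exactness).
  Phase recovery through the pipeline is exact in magnitude; signs are
  assigned by the greedy scheme and are not identifiable from the data.
* `gen_classical_table()` draws a latent $2\times2$ joint per item, so
  every classical bound holds by construction and every quadruple has
  $I=0$.
* `gen_likert()` draws shifted ratings as Binomial(6, $w_k/\max w$),
  the simplest integer mechanism whose shift-and-renormalise expectation
  is the target weight vector; with $10^5$ participants the conversion
  recovers the targets within 0.01 in sup norm.

What the generators deliberately do **not** emulate: response styles,
participant heterogeneity, item-order effects, and the sampling noise of
real Likert panels on the *joint* of three columns (each column is
generated independently of the others given the phases). Passing
recovery tests therefore shows the estimator inverts its own generative
model, not that real rating data satisfy it.

## Numerical choices and limitations

* Normalisation tolerance 0.003 by default (4-decimal rounding of a
  24-row table); fitting unnormalised tables requires an explicit
  `check_normalization = FALSE`.
* Items with $\mu_A=0$ or $\mu_B=0$ are flagged at construction and
  refuse to fit: their phase is undefined.
* Budget ties in the ranking are broken by original item order (the
  published scheme is silent); the rank-1 sign is always $+1$.
* Test problem sizes: property tests run 5–50 seeded replicates at
  10–40 items; the classical $I$ property suite draws $10^4$ quadruples;
  Likert recovery uses $10^5$ participants over 24 items.
* The model is exactly identified — one phase per item — so it cannot be
  falsified by a single table it can represent; its empirical content is
  the feasibility of the construction (all radicands nonnegative,
  $c_m\le1$) plus the stability of phases across datasets, which is out
  of scope here.
* Only two-concept disjunctions are implemented: no $n$-concept
  combinations, and no Fock-space conjunction model.
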