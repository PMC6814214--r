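---
title: "Margin-invariant proportional coordinates for 2x2 tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-invariant proportional coordinates for 2x2 tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proptab)
```

## The model

A 2×2 contingency table of counts $(a, b, c, d)$ has four marginal sums
that act as sample-size parameters: the row sums $(a+b, c+d)$ and column
sums $(a+c, b+d)$. Because the margins are set (directly or indirectly)
by the data-acquisition design, an association measure that mixes
proportional structure with marginal structure cannot be compared across
studies with different sampling balance. The package's core operation
factors the table as a product of a diagonal marginal-sum matrix and a
proportion matrix,

$$
\begin{pmatrix} a & b \\ c & d \end{pmatrix}
= \begin{pmatrix} n_1 & 0 \\ 0 & n_2 \end{pmatrix}
  \begin{pmatrix} \tfrac{a}{n_1(a+c)} & \tfrac{b}{n_1(b+d)} \\[2pt]
                  \tfrac{c}{n_2(a+c)} & \tfrac{d}{n_2(b+d)} \end{pmatrix}
  \begin{pmatrix} a+c & 0 \\ 0 & b+d \end{pmatrix},
$$

and symmetrically for row sums. Two normalizer choices matter:

* **unit** ($n_1 = n_2 = 1$): the columns of the proportion matrix are
  simplex points (the familiar conditional distributions);
* **dual** ($n_1 = \tfrac{a}{a+c} + \tfrac{b}{b+d}$,
  $n_2 = \tfrac{c}{a+c} + \tfrac{d}{b+d}$): the *rows* become simplex
  points — the column-scaling-invariant representation of row
  composition. Only the unit and dual normalizers are implemented; no
  other choice makes an axis of the proportion matrix a simplex system.

Each factorization contributes two forms, so a 2×2 table carries four
margin-invariant forms of proportional variation (`csum_rows`,
`csum_cols`, `rsum_rows`, `rsum_cols` in `simplex_pair()`). A form is a
pair of points in the one-simplex, reduced to center-of-mass
coordinates $\delta = (p_\beta - p_\alpha)/2$,
$\mu = (p_\alpha + p_\beta)/2$, with
$0 \le \mu \pm \delta \le 1$. The classical effect sizes are perspective
(linear-fractional) functions of $(\delta, \mu)$:

$$
\omega = \frac{\delta^2 + \mu(1-\mu) + \delta}{\delta^2 + \mu(1-\mu) - \delta},
\qquad
Q = \frac{\delta}{\delta^2 + \mu(1-\mu)},
\qquad
\rho = \frac{\mu + \delta}{\mu - \delta},
\qquad
\beta - \alpha = \frac{2\delta}{1 + \mu(\mu - 2) - \delta^2}.
$$

Two corollaries drive the rest of the package. First, a scalar effect
size always collapses the two degrees of freedom $(\delta, \mu)$ to
one, so fixing, say, $Q$ leaves a curve of compatible $(\delta, \mu)$
values — the residual identities
$\delta^2 - \delta/Q + \mu(1-\mu) = 0$ and
$\delta(\rho + 1) - \mu(\rho - 1) = 0$ are asserted as property tests.
Second, the margin-dependent $\phi$ coefficient factors as
$\phi = M \cdot D$ where $D$ is a margin-invariant displacement of a
dual form and $M$ a positive function of the margins alone, with $M = 1$
exactly for diagonally symmetric tables. Gini information gain at a
binary CART node obeys $IG_G = G(S)\,\phi^2$ with $G(S)$ constant
across the scan, so IG-ranked splits are $\phi^2$-ranked splits and
inherit the margin dependence; the scan's $M_c^2$ and $\omega_M$
columns quantify how much of an IG curve is margin artifact.

### A note on the ratio-difference denominator

The definitional ratio difference
$\beta - \alpha = p_\beta/(1-p_\beta) - p_\alpha/(1-p_\alpha)$ equals
$2\delta/((1-\mu)^2 - \delta^2) = 2\delta/(1 + \mu(\mu-2) - \delta^2)$
under the halved-$\delta$ convention. Some presentations drop the
factor 2 by writing the displacement un-halved; `proptab` keeps
$\delta$ halved everywhere (so that $|\delta| \le 1/2$ and the
$(\delta, \mu)$ constraints are symmetric), exposes the un-halved
quantity as `displacement`, and tests the perspective form against the
definitional form on random tables.

## Conventions (fixed once, used everywhere)

* **Cell order** is row-major $(a, b / c, d)$, rows first.
* **Halving**: `delta` is always the center-of-mass half-difference;
  `displacement` is the un-halved difference. The $\phi = M D$
  factorizations use displacements.
* **Orientation**: `com_coords(simplex_pair(t, "csum_rows"))` reports
  the c-minus-a direction (so the canonical example table
  $(10,30,30,20)$ gives $\delta_c = +0.179$, $\mu_c = 0.473$);
  `phi_factorization()` uses the a-first direction, for which the
  closed-form margin factors are positive. The two labels are exact
  negations; both are exposed rather than silently choosing one.
* **Relative risk**: the table-level `relative_risk()` reports
  first-category-over-second (the epidemiological convention, e.g.
  $[a/(a+b)]/[c/(c+d)]$ for `rsum_rows`); the com-coordinate
  $\rho = (\mu+\delta)/(\mu-\delta)$ inside `perspective_measures()` is
  oriented $p_\beta/p_\alpha$, which is the form satisfying the
  $\rho$ residual identity.
* **Zero cells** are allowed everywhere; only a zero marginal sum (or a
  zero dual normalizer, i.e. an empty row/column of the relevant kind)
  raises an error, because the corresponding simplex point is then
  undefined. No continuity (0.5) corrections are applied anywhere.
* **Counts are nonnegative reals**, so rescaled and Yule-symmetrized
  tables are first-class; the Monte Carlo sampler rounds to integers
  with a warning since its distributions are discrete.

## Monte Carlo confidence intervals

`mc_scheme()` represents the stochastic model of the acquisition
process: fixed column sums (each column an independent binomial of its
observed size), fixed row sums, or fixed total (multinomial over the
four cells). Defaults are 10000 tables per run and 64 runs; per-run
substreams are derived from `(seed, run_index)` so runs are independent
and order-insensitive. Draws for which a statistic is undefined (e.g.
an odds ratio on an all-zero diagonal) are excluded and counted — never
imputed. Summaries include per-run and pooled moments (both are
reported because pooling convention is a genuine choice), a fixed-width
histogram (0.01 bins by default), the percentile interval (asymmetric
by construction) and the mean ± 2 sd normal interval alongside, with
the sd of per-run means as the convergence diagnostic. For the
canonical table the two interval types agree to about 0.004, and fixing
only the total adds visible scatter to the $\mu$ coordinate relative to
fixing the column sums — both are regression-tested.

Out of scope by design: delta-method analytic intervals, bootstrap of
raw data, and richer error models (misclassification, heteroscedastic
measurement error) that the scheme abstraction could in principle
carry.

## The CART association scan

`association_scan(x, y)` forms, for every midpoint threshold $t$
between distinct covariate values (leaving at least `min_node = 5`
samples per side — the conventional guard; the value is a default, not
a claim), the 2×2 table with rows $S_1 = \{x \le t\}$, $S_2$ and the
two response classes as columns, and records IG (Gini and entropy,
natural log), $\phi^2$, $Q$, $(\delta_c, \mu_c)$, $\delta_r$,
$\omega_M$ and $M_c^2$. Both deltas are oriented subnode-2 minus
subnode-1 so they are directly comparable. The headline property,
asserted per record to $10^{-12}$: duplicating every sample of one
response class (doubling one column of every table) leaves the
$\delta_c$ curve unchanged while IG, $\phi^2$ and entropy gain all
move. `select_splits(..., mode = "two_sided")` reports the maximizing
and minimizing thresholds of the signed $\delta_c$ curve — on
overlapping class distributions these bracket the covariate range where
class composition flips, while the IG maximum sits near the pooled
median because the margin factor $\omega_M$ peaks at equal subnode
sizes. The two-sided rule is a signed-extremes rule; on a multimodal
$\delta_c$ curve a local-maxima search could select differently, which
is out of scope.

## Sample-size-adjusted logistic curves

For a binary response on one covariate, `fit_logistic()` (two-parameter
Newton–Raphson, score tolerance $10^{-10}$, 100-iteration cap,
cross-checked against `glm` in the tests; perfect separation along the
single covariate is detected directly and refused) yields
$(a_0, b)$. The intercept absorbs the class imbalance: writing
$a_0 = -b x_0 - \log(n_{neg}/n_{pos})$ defines the midpoint $x_0$ at
which the fitted curve passes through the sample-size proportion
$n_{pos}/(n_{neg}+n_{pos})$, leaving $(b, x_0)$ as the
class-balance-independent parameters. `reweighted_proportion()` is the
matching transformation of an observed proportion
($p \mapsto p\,n_{neg}/(p\,n_{neg} + (1-p)\,n_{pos})$, our reading of
"normalized for unequal sample sizes": the unique inverse-class-size
reweighting that sends the sample-size proportion to 1/2), and
`moving_average_proportion()` provides the nonparametric reference
curve (window is a required, logged choice; default $\approx n/20$,
odd).

One subtlety, discovered in testing and worth recording: the synthetic
generator draws labels from
$P(y{=}1\,|\,x) = 1/(1 + (n_{neg}/n_{pos})e^{-b(x - x_0)})$ over a
covariate grid, but the class ratio *realized* by such a draw matches
the nominal one only if the covariate design integrates the curve to
that ratio. The midpoint recoverable from a sample is therefore the one
implied by the realized class balance, which the generator records as
`x0_realized`; recovery tests compare against it, and the
balance-independence of $(b, x_0)$ is tested directly by class
duplication, where it is exact up to refit noise.

## What the synthetic data does and does not establish

`random_tables()` draws cell probabilities from a symmetric
Dirichlet(1,1,1,1), totals uniform on $[20, 200]$, and rejects zero
margins — a deliberately broad prior that exercises the algebraic
identities over the whole table simplex, not a model of any particular
study. `two_class_dataset()` emulates the structure of real screening
data — two broad, largely overlapping Gaussian class-conditionals with
unequal class sizes — and records the analytic density crossings
(midpoint of means for equal sds, quadratic roots otherwise) as ground
truth for split recovery. Green tests on these fixtures establish the
algebraic identities exactly and the statistical behaviors
qualitatively (split locations to within a stated tolerance of ~4
covariate units at the tested sizes); they do not establish performance
on any real data set, whose class-conditional shapes, ties and
rounding are not emulated.

## Numerical choices

* Reconstruction and simplex-sum tolerances: $10^{-12}$ relative (pure
  arithmetic identities); $\phi = M D$ and the perspective round-trips:
  $10^{-10}$ (one extra division); these are test tolerances, not
  fuzz factors in the implementation.
* Yule's $Q$ is computed as $(ad-bc)/(ad+bc)$, never via $\omega$, so
  boundary tables give $\pm 1$ without $\infty - \infty$.
* Degenerate inputs raise classed conditions
  (`proptab_domain_error`, `proptab_zero_margin_error`,
  `proptab_degenerate_error`, `proptab_undefined_error`,
  `proptab_convergence_error`) rather than returning NaN.
* Selection ties go to the smallest threshold, making scans
  deterministic.
* The ratio-difference identity is only asserted away from the simplex
  boundary ($p < 1 - 10^{-6}$): both expressions diverge there and
  their floating-point quotients become meaningless.

## Known limitations

* Only single-node scans: no recursive tree growth, pruning, or
  categorical covariates.
* The $r \times c$ module stops at $\chi^2$, Cramér's V and
  Goodman–Kruskal $\tau$ with their 2×2 equivalences; choosing a full
  basis of proportional variation for $r \times c$ tables has no unique
  solution and is intentionally not attempted.
* Monte Carlo schemes cover binomial/multinomial sampling only.
* The qualitative 0.1/0.3/0.5 effect-size labels ignore the $\mu$
  coordinate and are attached only on request, with that caveat.
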