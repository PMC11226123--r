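---
title: "Liability-threshold twin models with unknown zygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models with unknown zygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinliab)
```

## The problem

Twin designs decompose the population variance of a phenotype into an
additive-genetic share $a^2$ (heritability), a shared-environment share
$c^2$ (everything siblings reared together have in common), and a
unique-environment share $e^2$ (everything they do not, including
measurement error), using the contrast between monozygotic (MZ) twins,
who share all segregating genes, and dizygotic (DZ) twins, who share
half on average. Administrative registries often record twin status but
not zygosity. twinliab implements the standard workaround: opposite-sex
twin pairs are necessarily DZ, while the same-sex group is a mixture of
MZ and DZ pairs, and the mixture weight can be estimated from the group
sizes themselves.

The phenotypes handled here are binary indicators (for instance,
"borrowed at least one book of some genre in a year"), modelled with a
liability threshold: individual $i$ has a latent standard-normal
liability $L_i$ and expresses the trait when $L_i > \tau$, where
$\tau = \Phi^{-1}(1 - K)$ is fixed by the prevalence $K$. All variance
components live on the liability scale.

## The model

For a pair in group $g$ the two liabilities are bivariate normal with
correlation

$$r_g = \kappa_g\, a^2 + c^2 \quad (\text{ACE}) \qquad\text{or}\qquad
  r_g = \kappa_g\, a^2 + \delta_g\, d^2 \quad (\text{ADE}),$$

where $\kappa_g$ is the genetic correlation of the pair type (1 for MZ,
0.5 for DZ and full siblings) and $\delta_g$ the dominance analogue
(1 for MZ, 0.25 for DZ/siblings). $C$ and $D$ are not jointly
identifiable from twin data, so the two decompositions are fitted as
alternatives.

**Unknown zygosity.** Assuming DZ co-twin sexes assort independently,
same-sex and opposite-sex DZ pairs are equally frequent, so the MZ
proportion among same-sex pairs is $p_{MZ} = (N_{ss} - N_{os})/N_{ss}$
(Weinberg's rule) and the same-sex group behaves as if its genetic
correlation were the mixture

$$\gamma = p_{MZ} + 0.5\,(1 - p_{MZ}),$$

with dominance analogue $\delta_{ss} = p_{MZ} + 0.25\,(1 - p_{MZ})$.
`weinberg()` computes these; with pair counts 22,331 same-sex and
11,619 opposite-sex, $\gamma \approx 0.74$. Treating the mixed group as
a single group with averaged coefficients is a first-order
approximation to the true two-component mixture likelihood; it is the
standard practice in this design and is what the package implements.

**Estimation.** Each group's data reduce to a $2\times 2$ concordance
table. Because twin order is arbitrary, tables are symmetrized (each
pair contributes half a count to $(y_1,y_2)$ and half to $(y_2,y_1)$),
which justifies a single threshold for both members. The fit maximizes
the summed multinomial log-likelihood over path coefficients $(a, c)$
— components are their squares, so they are non-negative and
$a^2 + c^2 + e^2 = 1$ holds identically — and the threshold $\tau$
(shared across groups by default; `tau_by_group = TRUE` frees it).
This is direct maximum likelihood on the tables rather than a
structural-equation-model fit on polychoric correlations; the
closed-form method-of-moments solver `mom_decompose()`,

$$a^2 = \frac{r_{ss} - r_{os}}{\gamma - 0.5}, \qquad
  c^2 = r_{os} - 0.5\,a^2,$$

provides the bridge between the two routes and is used as an
independent cross-check in the test suite. On tables generated exactly
from model probabilities the two agree to about $10^{-3}$.

## Numerical choices

* The bivariate-normal orthant probability
  $P(L_1 > \tau, L_2 > \tau)$ dominates estimation accuracy. It is
  computed by adaptive 1-D quadrature of the conditional-normal
  integrand $\int_\tau^\infty \phi(x)\,
  \bar\Phi\big((\tau - \rho x)/\sqrt{1-\rho^2}\big)\,dx$ with relative
  tolerance $10^{-12}$; $\rho = \pm 1$ uses closed forms. Against an
  independent Gauss–Legendre product rule the error is below
  $10^{-12}$.
* Tetrachoric and biometric likelihoods are maximized by bounded
  quasi-Newton (L-BFGS-B); the tetrachoric fit works on
  $(\mathrm{atanh}\,\rho, \tau)$ so $\rho$ stays interior, with
  $|\rho| \le 0.9999$. A line-search failure near a bound triggers one
  restart from the best point.
* Zero cells receive no continuity correction — the multinomial
  likelihood handles them, and corrections bias $\rho$; degenerate
  tables yield a flagged boundary estimate instead. A table with an
  empty cell leaves the likelihood essentially flat in $\rho$ beyond
  the last occupied configuration, which is why oracle comparisons in
  the tests are restricted to fully occupied tables.
* Standard errors come from the numerically observed information,
  delta-method-transformed to the squared-component scale; 95% Wald
  intervals are truncated to $[0,1]$.

## Boundary behaviour

Shared-environment estimates frequently sit at the zero boundary (for
many adult behavioural phenotypes the truth appears to be near zero).
There, Wald SEs are conditional on the boundary and too small, and
likelihood-ratio quantities have mixture distributions. The package
flags boundary components, `confint(fit, type = "profile")` offers
profile-likelihood intervals, and `compare_strata()` attaches a
reliability warning to any Z test built from a boundary-flagged fit.
Two practical consequences, both visible in the validation suite:

* In parameter-recovery simulations at registry scale (22,331 same-sex
  plus 11,619 opposite-sex pairs, $K = 0.17$, true $a^2 = 0.57$,
  $c^2 = 0$), $\hat c^2$ is biased upward by about 0.02 and $\hat a^2$
  downward by the mirror amount, and Wald coverage for $a^2$ runs at
  roughly 0.92–0.93 rather than 0.95. Both are the expected footprint
  of the non-negativity constraint when the truth is on the boundary.
* The two-sample Z test for a heritability difference is calibrated
  only in the regular regime. Its type-I study therefore uses strata
  large enough that $\hat c^2$ stays interior (7,000 MZ plus 15,000 DZ
  pairs per stratum with true $a^2 = 0.5$, $c^2 = 0.15$); there the
  empirical size is about 0.05–0.07. With small strata and a weak
  shared-environment signal the boundary cases inflate the size — the
  reliability warning exists precisely for that situation.

## The synthetic registry generator

`simulate_pairs()` draws pair liabilities from the exact model the
estimator assumes: bivariate normal via the Cholesky factor
($L_2 = \rho L_1 + \sqrt{1-\rho^2} Z$, Mersenne-Twister, inversion
normals, so seeds are portable), dichotomized at $\tau(K)$. MZ pairs
are hidden inside the same-sex group; each DZ pair is opposite-sex with
probability 0.5 (independent sex assortment), matching the registry
design in expectation. Defaults emulate the motivating study's
conditions: prevalence $K = 0.17$, registry-scale pair counts
(10,712 MZ and 23,238 DZ reproduce the printed group sizes of 22,331
same-sex and 11,619 opposite-sex pairs in expectation), and truths such
as $a^2 = 0.57$, $c^2 = 0$ for the headline phenotype. The MZ:DZ ratio
is a free parameter, since registries only identify it through
Weinberg's rule.

What the generator deliberately omits: assortative mating,
gene–environment correlation and interaction, sex-limitation of
genetic effects, zygosity misclassification, and any structure in how
the binary indicators arise from underlying behaviour. Passing tests
therefore show that the estimator inverts its own generative model,
and that the pipeline is calibrated under those assumptions — not that
the assumptions hold in real registry data.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `prevalence` | 0.17 | trait prevalence $K$; sets $\tau$ (unitless, liability scale) |
| `gamma` | from counts | same-sex genetic correlation; `"global"`, `"stratum"` or fixed numeric |
| `dz_opposite_sex_prob` | 0.5 | DZ sex-assortment probability |
| `sibling_c` | 1 | shared-environment coefficient for non-twin siblings |
| `tau_by_group` | FALSE | free threshold per group |
| `min_pairs` | 10 | smallest per-group stratum size attempted |

The `twin_sibling` design replaces the opposite-sex group with same-sex
non-twin sibling pairs ($\kappa = 0.5$), which makes single-sex fits
identifiable; such models are known to return smaller $C$ estimates
when siblings share less environment than twins, so `sibling_c` is
exposed as a sensitivity knob (default 1). Per-stratum fits default to
a single global $\gamma$, recomputation within strata being available
via `gamma = "stratum"` because same-sex/opposite-sex composition can
differ across strata.

## Worked example

```{r example, eval = FALSE}
d <- simulate_pairs(n_mz = 10712, n_dz = 23238, a2 = 0.57, c2 = 0,
                    prevalence = 0.17, seed = 42)
fit <- fit_biometric(d, model = "ACE", design = "twin")
summary(fit)
confint(fit, parm = "a2", type = "profile")

# stratified heritability and Z tests
ds <- simulate_pairs(12000, 26000, a2 = 0.5, c2 = 0.05, prevalence = 0.17,
                     strata = list(low_income = list(a2 = 0.7),
                                   high_income = list(a2 = 0.4)),
                     seed = 1)
fits <- fit_stratified(ds, "stratum")
compare_all_strata(fits)
```

## Validation problem sizes

The test suite validates the pipeline with: exact-table inversions at
$N = 10^5$ pairs per group (agreement with the closed form to
$5\times 10^{-3}$); 200 Monte-Carlo replicates at registry scale for
bias and coverage; 50 random tables against a coarse-to-fine
grid-search oracle for the tetrachoric ML (agreement to $10^{-3}$);
and 500 null comparisons for the Z-test size. The same studies are
rerun end to end by `scripts/acceptance.R`.

## Limitations

* Binary indicators only; no ordinal or continuous phenotypes.
* One phenotype at a time; no multivariate or cross-trait models.
* Sex differences are handled by stratification, not by sex-limitation
  models with distinct male/female genetic parameters in a joint fit.
* The Weinberg adjustment treats the mixed same-sex group with averaged
  coefficients rather than an explicit two-component mixture; with
  moderate $\gamma$ the difference is far below sampling noise at
  realistic sizes, but it is an approximation.
* No multiple-testing correction across phenotypes; comparisons are
  reported at per-test $\alpha = 0.05$.
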