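---
title: "Predicting the precision of genomic breeding values: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the precision of genomic breeding values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsacc)
```

## The problem

When a breeding organisation weighs up a genomic selection scheme — how many
animals to genotype and phenotype for the reference population, which SNP
panel to buy — the decisive quantity is the **reliability** of the genomic
estimated breeding values (GEBV): the squared accuracy
$r^2 = v(\hat g)/v(g)$ of the predicted genetic merit $\hat g$ of a selection
candidate. `gsacc` predicts this reliability *a priori*, from design
parameters alone, before any genotyping is done.

The model is the idealised SNP-BLUP setting: $M$ biallelic SNPs in linkage
equilibrium carry all of the genetic variance; the reference population of
$N$ unrelated individuals is phenotyped ($y = X\beta + e$, phenotypic
variance normalised to 1 so $\sigma_g^2 = h^2$, $\sigma_e^2 = 1-h^2$); SNP
effects are estimated by ridge regression
$(X'X + \Lambda)\hat\beta = X'y$; candidates are unrelated to the reference
individuals. Under these assumptions the marginal reliability is exactly

$$ r^2 \;=\; 1 - \lambda\, \mathrm{tr}\!\left[ F\, E_X\!\big[(X'X +
\Lambda)^{-1}\big] \right], \qquad \lambda = \frac{1-h^2}{h^2}, $$

with $F = \mathrm{diag}(\sigma_k^2)$, $\sigma_k^2 = 2 f_k (1-f_k)$ the
genotype variance at SNP $k$. The expected inverse has no closed form; the
package provides (i) a Monte-Carlo evaluation of it
(`true_precision_mc()`), and (ii) Taylor-expansion closed forms that a
scheme designer can evaluate in microseconds.

## The closed forms

Splitting $X'X + \Lambda = D + E$ with $D = E[X'X] + \Lambda$ (diagonal
under linkage equilibrium) and $E$ zero-mean, the expansion
$(D+E)^{-1} = D^{-1}(I - ED^{-1} + ED^{-1}ED^{-1} - \cdots)$ yields:

* **first order** (`first_order()`, tag `eq5`):
  $r^2 \approx N/(N+M\lambda)$ under the *equal-contribution* prior
  ($\sigma_k^2\sigma_{\beta_k}^2 = \sigma_g^2/M$). Optimistic at finite
  $N$ — it behaves as if all other SNP effects were estimated perfectly.
* **second order** (`second_order_from_variances()`, `eq6`):
  subtracts $\lambda N M (N+M\lambda)^{-3}\big(M - 2 +
  \overline{1/\sigma_k^2}\big)$. The mean inverse genotype variance can come
  from realised panel variances, or from a moment of the assumed
  allele-frequency law:
  * uniform on $[f_{min}, 1-f_{min}]$ (`second_order_uniform()`, `eq7`):
    $E[1/\sigma_k^2] = \log\!\big(\tfrac{1-f_{min}}{f_{min}}\big) /
    (1 - 2f_{min})$;
  * U-shaped, density $\propto 1/(2f(1-f))$ (`second_order_ushape()`,
    `eq8`): the moment term is replaced by the compact approximation
    $\lambda (M/N)^2 (N/(N+M\lambda))^3$.
* **comparators**: the two classical single-SNP-regression formulas
  (`daetwyler_basic()` `eq2`, conservative, and `daetwyler_corrected()`
  `eq3`, its error-variance-corrected quadratic root), and Goddard's 2009
  closed form (`goddard_comparator()`) parameterised with
  $\lambda_G = \lambda M / (-\log f_{min})$ and effective loci $= M$.
* **single-prior variance** (`single_variance_first_order()`, `eq9`): when
  all SNP effects share one prior variance (the GBLUP prior,
  $\sigma_\beta^2 = \sigma_g^2/\sum_k \sigma_k^2$) the shrinkage diagonal is
  constant and the first-order formula involves
  $\hat\lambda_\beta = M\,\frac{1-6f_{min}^2+2f_{min}^3}{3(1-2f_{min})}\lambda$.
  This formula *always overestimates* the true reliability; the package's
  simulator demonstrates this property rather than asserting point values.
* **marker coverage** (`adjust_for_marker_coverage()`): when markers capture
  only a fraction $b$ of the genetic variance, heritability is reduced to
  $b h^2$ and the resulting precision regressed by $b$.

The generic engine behind the second-order forms is exposed in
`expected_P_diagonal()` / `precision_second_order_general()`: the diagonal
of $E_X[D^{-1}ED^{-1}E]$ is
$\tfrac{N\sigma_k^2}{\delta_k}\{\tfrac{1-2\sigma_k^2}{\delta_k} +
\sum_t \sigma_t^2/\delta_t\}$, valid for *any* positive shrinkage diagonal
$\lambda_k$, with $\delta_k = N\sigma_k^2 + \lambda_k$. With the
equal-contribution shrinkage $\lambda_k = M\lambda\sigma_k^2$ it collapses
algebraically to the scalar `eq6` (a regression test asserts the identity to
1e-12).

## Parameters that matter

| parameter | meaning | default / range used |
|---|---|---|
| `N` | reference population size | swept 1000–10000 |
| `M` | SNPs on the panel (all causal, unlinked) | 500 or 1000 |
| `h2` | heritability (unit phenotypic variance) | 0.1–0.7; `h2 = 1` allowed, short-circuits to $r^2 = 1$ |
| `f_min` | minimum minor allele frequency after panel filtering | 0.025–0.10 |
| frequency law | `uniform` or `ushape` on $[f_{min}, 1-f_{min}]$ | uniform |
| variance model | `equal_contribution` or `single_prior` | equal contribution |
| `N_cand` | candidates per simulation replicate | 1000 (not part of the published protocol; chosen so candidate-side sampling noise stays below reference-side noise at these scales) |
| `replicates` | Monte-Carlo replicates | 100 |

A drift-derived MAF bound $\alpha = 1/(2N_e)$ is obtained by passing
`f_min = 1/(2*Ne)`; there is no separate effective-population-size
parameter.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws allele frequencies from the assumed law, then
Hardy–Weinberg genotype counts $n_{ik}\sim\mathrm{Binomial}(2, f_k)$,
independent across SNPs and individuals, centred by the *true* frequency
(frequencies are treated as known). `empirical_precision()` additionally
draws SNP effects as independent zero-mean normal variables with the
variance-model variances — the BLUP theory uses only the first two moments,
so the normal family is a documented convenience, not an assumption of the
formulas — and evaluates candidates genotyped at the same frequencies.
Frequencies are redrawn every replicate; `freeze_freqs = TRUE` isolates the
genotype-sampling variance component.

Real data violate these assumptions in known ways: linkage disequilibrium
between SNPs (effective number of segments $< M$), related individuals
within and with the reference population, genetic variance not fully
captured by the panel, frequency estimation error. None of these are
modelled, so a green test here establishes the *internal* correctness of
the formulas under their stated assumptions, not their field accuracy.
LD-aware extensions and relationship-aware reference designs are explicitly
out of scope.

## Multi-trait selection indices

For $n_c$ traits with genetic and residual covariance matrices $V_g$,
$V_e$ and economic weights $a$, the first-order GEBV covariance is

$$ \widehat{v(\hat{\mathbf g})} = N V_g (N V_g + M V_e)^{-1} V_g, $$

and the index reliability is the ratio of quadratic forms
$(a'\hat V a)/(a' V_g a)$ (`index_precision()`). The reduction of the
published $r^2 = \mathrm{cov}(\gamma,\hat\gamma)^2/(v(\gamma)v(\hat\gamma))$
to this ratio uses the best-linear-predictor identity
$\mathrm{cov}(\gamma,\hat\gamma) = v(\hat\gamma)$. The validating simulator
(`empirical_index_precision()`) draws the effect vector of SNP $k$ from a
zero-mean multivariate normal with covariance $V_g/(M\sigma_k^2)$ — the
natural multi-trait extension of the equal-contribution rule; the source
derivation does not fix this scaling, so it is our documented
interpretation — and solves the full multivariate mixed-model equations.
Because the analytic formula is first order, it overestimates slightly at
finite $N$ (exactly as the single-trait first-order formula does), which is
why the consistency test works at 20 replicates and checks both agreement
within 3 MC standard errors and the direction of the bias. Single-trait
evaluation of multi-trait data does not reduce to these equations and is out
of scope.

## Numerical choices

* **Root choice** in the corrected single-SNP-regression quadratic: the
  "$-$" root, the only one at or below 1 (the "+" root exceeds 1 for every
  valid design; verified symbolically at $h^2 = 1$ and numerically on the
  reference grid).
* **No dense inverses on the analytic path**: traces are sums over
  diagonals; the Monte-Carlo evaluation extracts the inverse diagonal from
  a Cholesky factorisation, and the multi-trait inverse is a symmetric
  solve.
* **$h^2 = 1$** ($\lambda = 0$) short-circuits to 1 everywhere, avoiding a
  $0\cdot\infty$ ambiguity; the empirical simulator then uses a $10^{-8}$
  ridge for numerical definiteness.
* **Seeding**: one master seed spawns an independent sub-seed per
  replicate, so replicate results are order-independent.
* **U-shape sampling** uses the exact inverse CDF
  $f = \mathrm{logistic}(\mathrm{logit}(f_{min}) + 2u/C)$ — no rejection
  step.
* **`f_min = 0` is rejected**: the inverse-variance moment diverges.
* **Degenerate guard** in the single-prior formula: the log argument
  $(2f_{min}-1+s)/(1-2f_{min}+s)$ with $s = \sqrt{1+2\hat\lambda_\beta/N}$
  is provably positive for valid inputs, but is checked and reported by
  name anyway.

Two constants are implemented *as published* even though direct
integration disagrees at third order in $f_{min}$: the mean-variance factor
in $\hat\lambda_\beta$ uses $(1-6f_{min}^2+2f_{min}^3)/3$, while
$\int 2f(1-f)\,df$ over the truncated support gives
$(1-6f_{min}^2+4f_{min}^3)/3$. `expected_variance_uniform()` returns the
published constant; `expected_variance_quadrature()` the exact integral;
a test pins their difference to $-2f_{min}^3/(3(1-2f_{min}))$. We do not
silently "correct" the published formula — at $f_{min}\le 0.1$ the effect on
$r^2$ is below $10^{-4}$.

## Tolerances in the validation suite

Reference table cells are printed to 3 decimals. The suite therefore
compares closed forms to printed cells within **one unit in the last
printed place** (0.001): the printed tables are internally inconsistent at
that digit (the U-shape second-order column, which has no $f_{min}$
dependence, is printed as 0.902 in one $f_{min}$ block and 0.901 in the
other), so exact round-to-3 matching is unattainable for at least one cell.
For the Monte-Carlo column the standard error at 100 replicates is
$\sim 10^{-5}$ — far below the printing granularity — so the comparison is
$|\mathrm{MC} - \mathrm{printed}| \le 0.0005 + 3\,\mathrm{se}$, and the
sharper check is against the second-order closed forms directly
($|\mathrm{MC} - \hat r^2_{(2)}| \le 0.002$), which the suite asserts on
the full grid at a scaled-down size (N = 2000, M = 200, 50 replicates) and
at the published scale on representative cells (runtime budget; the full
published protocol runs in `scripts/acceptance.R`).

## Worked example

```{r example, eval = FALSE}
d <- design_spec(N = 5000, M = 500, h2 = 0.3)
first_order(d)                    # r2 = 0.8108  [eq5]
second_order_uniform(d, 0.05)     # r2 = 0.7983  [eq7]
true_precision_mc(d, freq_dist("uniform", 0.05),
                  replicates = 100, seed = 1)
                                  # r2 = 0.7977 (mc_se = 1.5e-05)  [eq1_mc]
```

## Known limitations

* All approximations are derived for unrelated individuals, unlinked loci
  and panel-captured genetic variance; outside this regime they bound
  rather than predict observed reliabilities.
* The Goddard comparator's functional form is pinned by reproducing its
  published comparison column (the source comparison does not print the
  formula it evaluated); its agreement there is its only calibration.
* The second-order U-shape form drops the $E[1/\sigma_k^2]$ moment in
  favour of a $(M/N)^2$ term; at small $N/M$ ratios the full moment form
  with `second_order_from_variances()` is preferable.
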