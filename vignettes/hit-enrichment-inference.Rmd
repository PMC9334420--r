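---
title: "Statistical inference for hit enrichment curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical inference for hit enrichment curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(hitenrich)
```

## The problem

A virtual screen scores every ligand in a library and proposes testing
the top-scoring fraction. The natural performance summary is the *hit
enrichment curve*: estimated recall $\hat\theta_r$ — the fraction of the
truly active ligands captured — plotted against the testing fraction
$r$. Screening libraries are large (often $10^5$–$10^6$ ligands) and
extremely imbalanced (active fractions of $10^{-3}$–$10^{-2}$), and
practical interest concentrates on very small $r$, where only a handful
of ligands are tested. Two statistical complications make naive
binomial reasoning wrong:

1. the score threshold $\hat t_r$ that defines "tested" is estimated
   from the same data, inducing correlation among the tested
   indicators *within* one scoring method, and
2. competing scoring methods score the same ligands and are usually
   positively correlated, inducing correlation *between* methods.

This package provides estimation and inference that accounts for both.

## Estimation

With scores $S_i$ and labels $X_i$, the empirical cdfs of all scores
and of active scores give
$\hat t_r = \min\{t : \hat F(t) \ge 1 - r\}$ and
$\hat\theta_r = 1 - \hat F_+(\hat t_r) = Q_r / (n\hat\pi_+)$, where
$Q_r$ counts actives with $S_i > \hat t_r$. Restricting candidate
thresholds to observed score values and using a strict inequality for
"tested" makes tie handling deterministic: ligands tied at the
threshold are never tested, so no arbitrary ordering can flatter a
method. The enrichment factor curve is the same object rescaled,
$EF_r = \hat\theta_r / r$.

```{r}
d <- simulate_scores(20000, pi_plus = 0.01, binormal_pair(),
                     rho = 0.9, seed = 1)
hit_enrichment_curve(d, "alg1", testing_fraction_grid(d$n, counts = c(20, 200, 2000)))
```

## Variance model

The asymptotic variance of $\hat\theta_r$ is
$$
Var_{JZ}(\hat\theta_r) = \frac{\theta_r(1-\theta_r)}{n\pi_+}
\Big[1 - 2\Lambda_r +
\frac{\Lambda_r^2 (1-r) r}{\pi_+\theta_r(1-\theta_r)}\Big],
$$
where $\Lambda_r = P(+\mid S = t_r)$ is the threshold-specific activity
rate. The bracket is the correction for threshold estimation; with
$\Lambda_r = 0$ the plain binomial variance is recovered. The
covariance between two methods' recalls at a common fraction, between
the same curve at two fractions, and between two methods at two
different fractions all share the same structure and are implemented in
an expanded (cancelled) form so that an independent pair
($\theta_{12} = \theta_1\theta_2$) causes no 0/0
(`cov_emproc()`, `cov_within_curve()`, `cov_cross_alg_frac()`).

### Estimating the threshold-specific activity rate

$\Lambda_r$ is estimated by Nadaraya-Watson kernel regression of the
labels on the pooled scores at $\hat t_r$, with a Gaussian kernel and
rule-of-thumb bandwidth $h = 1.06\,\hat\sigma_S\,n^{-1/5}$ (the
literature the estimator comes from does not pin down one specific
rule; the bandwidth is an explicit argument everywhere, so other
selectors can be substituted). Two numerical safeguards matter in this
application and are deliberate design choices:

* **Minimum-neighborhood bandwidth.** At testing fractions around
  $10^{-4}$ the threshold sits in a score region holding only a couple
  of (mostly active) ligands, and a fixed bandwidth lets
  $\hat\Lambda$ spike toward 1, which can annihilate the variance
  bracket. The bandwidth is therefore floored so the kernel window
  spans at least 20 observations (`min_neighbors`). This biases
  $\hat\Lambda$ downward only in the sparse tail; the effect on the
  variance is conservative (wider intervals and bands).
* **Flooring.** Plug-in estimates can still drive a raw variance
  negative; such values are floored at zero and flagged
  (`attr(x, "floored")`), and downstream code treats a zero standard
  error with a nonzero difference as degenerate rather than as
  $p = 0$.

## Pointwise two-method inference

`compare_recall()` tests $H_0: \theta_{1r} = \theta_{2r}$ with
$Z_r = (\hat\theta_{1r}-\hat\theta_{2r})/SE$ and offers four standard
errors: **EmProc** (both correlation sources; the default and the
recommended test), **IndJZ** (methods treated as independent;
conservative when scores correlate positively), **CorrBinom**
(correlated binomial counts, no threshold correction), and **McNemar**
(discordant active counts only). Two modifiers mirror common practice
for paired proportions:

* `pooled` replaces both marginal recalls with their average inside the
  variance (null-enforced tests only). McNemar is *identical* to pooled
  non-plus CorrBinom — asserted to machine precision in the tests.
* `plus` applies the Bonett-Price shift — one pseudo-active tested by
  each method, two added to the active total — to every count-based
  plug-in. For CorrBinom this reproduces the Bonett-Price interval
  exactly, which is also what the McNemar procedure reports as its
  interval. How the shift should enter the empirical-process variance
  is genuinely open; this package applies it *coherently*: the
  pseudo-actives also enlarge the tested count and the library, so
  every plug-in describes one consistent shifted 2x2 table. A useful
  consequence (provable from the Frechet-type inequalities
  $r \ge \pi\theta$, $1-r \ge \pi(1-\theta)$ on the shifted table) is
  that the Jiang-Zhao bracket stays $\ge (1-\Lambda)^2 \ge 0$, so
  plus-adjusted variances can never go negative.

Defaults follow the simulation evidence: tests are EmProc, unpooled,
non-plus; intervals should use `plus = TRUE`. Families of comparisons
are adjusted with Benjamini-Hochberg (`compare_table()`, `bh_adjust()`).

```{r}
compare_recall(d, "alg1", "alg2", r = 0.01)
```

## Simultaneous bands

For a fraction grid $r_1 < \dots < r_k$, `curve_covariance()` builds
the $k \times k$ plug-in covariance of the recall vector (Jiang-Zhao
diagonal, within-curve covariances off-diagonal), symmetrises it, and
clips negative eigenvalues to zero when plug-in noise leaves it
indefinite (flagged via `repaired`). Three rectanguloid bands
$\hat\theta_i \pm q\,SE_i$ are available:

* **sup-t** (default): $q$ is the Monte-Carlo $(1-\alpha)$ quantile of
  $\max_i |Z_i|$ under the estimated correlation matrix — the smallest
  rectanguloid with simultaneous coverage. 100,000 draws by default,
  seeded and reproducible; zero-variance grid points are excluded from
  the max and flagged.
* **Bonferroni**: $q = \sqrt{\chi^2_{1,1-\alpha/k}}$.
* **theta-projection**: $q = \sqrt{\chi^2_{k,1-\alpha}}$, the smallest
  rectanguloid containing the Wald ellipsoid; never narrower than
  Bonferroni, included for completeness.

The plus adjustment for a single curve is the familiar "add two
successes and add two failures", again applied coherently to all
plug-ins. The band is *centred at the raw estimate*; the shifted recall
enters only the variance. (Shifting the centre by $+2/(n\hat\pi_++4)$
sounds innocuous but is several standard errors wide at tested counts
of 2-8 under heavy imbalance, and destroyed coverage in our
simulations.) Difference bands (`confidence_band_diff()`) combine both
within-curve matrices with the two cross-method cross-fraction terms
and use the Bonett-Price shift, whose symmetric centring
$(Q_1-Q_2)/(n\hat\pi_++2)$ has no such directional bias.

The default grid mirrors common band practice: tested counts
$\{2^k\}_{k\le13} \cup \{3^k\}_{k\le8} \cup \{105, 300, 1500, 15000\}$
intersected with $[1, n]$ — 25 points for libraries of 150,000+.

```{r}
b <- confidence_band(d, "alg1",
                     testing_fraction_grid(d$n, counts = 2^(2:10)),
                     draws = 2e4, seed = 2)
b
```

## The synthetic-data generator

`simulate_scores()` emulates a MUV-style benchmark: $n = 150{,}000$
ligands with Bernoulli($\pi_+ = 0.002$) labels by default (skew 499),
class-conditional score distributions from three families, and a
Gaussian copula with parameter $\rho$ linking two methods' scores
within each class (classes independent). For normal marginals the
copula construction is exactly a bivariate normal with correlation
$\rho$; for the beta and uniform families $\rho$ is the copula
parameter, not the achieved Pearson correlation. The shipped presets
are the benchmark pairs (`binormal_pair()`: actives
$N(0.8\sqrt2, 1)$ vs $N(0.6\sqrt2, 1)$, Cohen's D 0.8 vs 0.6, shared
$N(0,1)$ inactives; `bibeta_pair()`: Beta(5,2) vs Beta(4,2) actives
over Beta(2,5) inactives) and five single-curve cases
(`single_curve_case()`) spanning weak to near-perfect separation.

Population oracles (`true_recall()`, `true_lambda()`,
`true_paired_prob()`) solve the mixture quantile by monotone root
finding (tolerance $10^{-10}$) and evaluate bivariate-normal orthant
probabilities by one-dimensional quadrature; the test suite uses them
as the independent reference for every variance formula.

What the generator does *not* emulate: benchmark pathologies of real
collections (analogue bias, artificial enrichment, untested decoys),
heavy-tailed or discretised docking scores, and score ties. Passing
simulation studies therefore validate the *estimators under their
assumptions*, not robustness to those artefacts; with real score
tables, ties are at least handled deterministically by construction.

## Study scale and what the checks show

The packaged Monte-Carlo studies (`run_power_study()`,
`run_coverage_study()` and the test suite) run at a reduced scale
chosen so the full suite completes in minutes on one core:
$n = 20{,}000$, $\pi_+ = 0.01$ (200 expected actives, matching the
order of magnitude of actives in the full-size design), 500–2,000
replicates, sup-t draws 20,000. At this scale, with fixed seeds:

* EmProc, CorrBinom and McNemar hold their 5% type-I level across the
  tested-count grid; IndJZ is strongly conservative under $\rho=0.9$.
* EmProc's power envelope dominates IndJZ, CorrBinom and McNemar on the
  bibeta pair at $\rho = 0.9$ at every grid point.
* Plus-adjusted sup-t bands achieve ~95% simultaneous coverage on
  binormal case 1 over tested counts 2–1024, unadjusted bands
  undercover badly (the zero-width points at tiny counts), and
  plus-Bonferroni covers at least as well while being wider.

## Known limitations

* All inference is asymptotic in $n$ with $n\pi_+$ effectively the
  sample size for recall; below a few dozen actives the normal
  approximation (and the kernel $\Lambda$ estimate) should not be
  trusted, plus adjustment or not.
* The unbiasedness of the empirical curve requires the score densities
  to be positive and smooth near the threshold. Where that fails — the
  uniform case has a density kink at the edge of the inactive support —
  the estimator is measurably biased at thresholds straddling the kink;
  the test suite demonstrates this as a negative control rather than
  hiding it.
* The empirical-process variance of a *difference* assumes both methods
  are evaluated on the same ligands of one sample; nothing here applies
  to comparisons across different libraries.
* Pooling is available for tests only; there is no justification for
  pooling in interval construction, and `plus` is ignored by the
  McNemar statistic itself (its interval is Bonett-Price, which is
  already plus-adjusted).
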