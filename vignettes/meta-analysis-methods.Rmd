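---
title: "Methods: pooling case-control SNP association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling case-control SNP association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasnp)
```

This vignette is the package's own account of the statistical machinery:
the models, the parameter choices and their defaults, the numerical
decisions, what the simulator does and does not emulate, and the known
limitations.

## The effect model

Every analysis reduces a study to a log odds ratio and its standard error.
Three routes exist, recorded in the `source` column of the effects table:

1. **Genotype counts** (`genotype_counts`). The per-arm counts of CC, CT
   and TT genotypes (C the effect allele) are collapsed into a 2×2 table
   under the additive contrast (allele counts: a = 2·CC + CT cases exposed,
   etc.), the dominant contrast (CC+CT vs TT carriers) or the recessive
   contrast (CC vs CT+TT). The Woolf estimator gives
   $\ln\widehat{OR} = \ln(ad/bc)$ and
   $se = \sqrt{1/a + 1/b + 1/c + 1/d}$.
2. **Reconstruction** (`reconstructed`). Summary-level rosters report only
   arm sizes, a minor-allele frequency and an odds ratio. Writing $p_1$
   and $p_0$ for the case and control allele-C frequencies, the pair is
   pinned down by two constraints: the odds relation
   $p_1 = \mathrm{OR}\,p_0 / (1 - p_0 + \mathrm{OR}\,p_0)$ and the
   combined-frequency identity
   $(N_1 p_1 + N_0 p_0)/(N_1 + N_0) = \mathrm{MAF}$. The left side of the
   second equation is strictly increasing in $p_0$, so the root is unique
   and is isolated numerically in $(0,1)$ to absolute tolerance $10^{-12}$.
   The implied allele table $a = 2N_1p_1,\; b = 2N_1(1-p_1),\;
   c = 2N_0p_0,\; d = 2N_0(1-p_0)$ keeps its fractional cells: rounding
   would inject avoidable error relative to the reported odds ratio, which
   the reconstruction reproduces exactly by construction (the tests verify
   $\ln\widehat{OR} = \ln(\mathrm{OR}_{\text{reported}})$ to $10^{-9}$ on
   every bundled row).
3. **Reported confidence interval** (`summary_ci`).
   $\ln\widehat{OR} = \ln(\mathrm{OR})$ and
   $se = (\ln \mathrm{CI}_{hi} - \ln \mathrm{CI}_{lo}) / (2 \times 1.959964)$.

Two interpretation switches deserve comment.

* **MAF interpretation.** A roster's frequency column may be the combined
  case+control frequency or the control-arm frequency; rosters rarely say.
  The default reads it as combined (the conservative choice when the
  column is not arm-specific); `maf_interpretation = "control"` takes it
  as the control frequency directly, with $p_1$ derived from the odds
  relation. Both interpretations reproduce the reported odds ratio
  exactly; they differ only in the implied standard errors, and on the
  bundled roster the difference is small (overall I² 84.5 % vs 84.3 %).
* **Effect direction.** Allele C is treated as the exposure throughout:
  OR > 1 means C increases disease odds. The package applies no per-study
  re-orientation, because a summary column alone cannot reveal whether a
  source article reported its odds ratio for the minor allele, the risk
  allele or the alternate allele. This is a real limitation of
  summary-level meta-analysis — transcribed odds-ratio columns that mix
  direction conventions will pool toward the null or away from the
  harmonized answer — and it is why analyses built on genotype counts
  (which fix the direction mechanically) are preferable whenever counts
  are available. The `policy` argument ranks the routes per study;
  `genotype_first` is the default.

Zero cells receive the Haldane–Anscombe correction: 0.5 is added to all
four cells, only when a zero occurs (never pre-emptively), and the event
is flagged in `correction_applied`. Two zero cells on a diagonal with the
correction disabled is an error, not a silent `Inf`.

## Heterogeneity and pooling

With inverse-variance weights $w_i = 1/se_i^2$ and fixed-effect mean
$\hat\theta = \sum w_i \theta_i / \sum w_i$:

$$Q = \sum_i w_i (\theta_i - \hat\theta)^2, \qquad
I^2 = \max\!\left(0, \frac{Q - (k-1)}{Q}\right) \times 100\,\%$$

$Q$ is referred to $\chi^2_{k-1}$; $I^2$ is reported on the 0–100 scale
and is 0 by convention when $Q = 0$. The DerSimonian–Laird between-study
variance is the untruncated moment estimator clamped at zero,

$$\hat\tau^2 = \max\!\left(0,
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

followed by re-weighting with $w_i^* = 1/(se_i^2 + \hat\tau^2)$. When
$Q \le k-1$ the estimate collapses exactly to the inverse-variance fixed
effect, and the tests assert this boundary identity. The Mantel–Haenszel
fixed-effect estimator is available for count-level studies, with the
Robins–Breslow–Greenland variance for $\ln \mathrm{OR}_{MH}$; on large
homogeneous tables it agrees with inverse variance to well within 2 %.

**Model selection.** The pooling rule joins its two thresholds with AND:
random effects when the Q-test $p < 0.05$ *and* $I^2 > 50\,\%$, fixed
effects otherwise. Declaring *heterogeneity* is often done on either
indicator alone, so when exactly one fires the package pools fixed (per
the AND rule) and emits a message carrying both flags; both raw values
are always present in the output, so a user can apply a different rule
without re-fitting. Thresholds are arguments (`p_threshold`,
`i2_threshold`), not constants.

All 95 % intervals use the fixed normal quantile 1.959964 on the log-odds
scale — fixed rather than computed so that a summary-CI round trip
(interval → se → interval) is bit-stable.

## Sensitivity and publication bias

`leave_one_out()` always re-fits the random-effects model with $\tau^2$
re-estimated on each $k-1$ subset, so each row's heterogeneity columns
describe that subset, not the full set.

`egger_test()` defaults to the classic unweighted formulation: OLS of the
standard normal deviate $\theta_i/se_i$ on precision $1/se_i$, intercept
tested against $t_{k-2}$. The weighted variant (regression of $\theta_i$
on $se_i$ with weights $1/se_i^2$) sits behind `weighted = TRUE`. A
numerically exact fit with a near-zero intercept is reported as
$t = 0, p = 1$ (no asymmetry evidence) rather than dividing two zeros; a
design with all precisions equal is a singular-fit error.

`begg_test()` standardises deviations from the fixed-effect mean by
$v_i = se_i^2 - 1/\sum w$ (falling back to $se_i^2$ with a warning if any
$v_i \le 0$, which cannot occur for $k \ge 2$ with finite weights) and
correlates them with $v_i$ by Kendall's tau. The normal deviate uses the
exact variance of Kendall's S, $k(k-1)(2k+5)/18$, with the tau-b tie
adjustment when ranks tie (noted via a message) and a continuity
correction of 1. Significance for both bias tests is conventionally read
at $\alpha = 0.01$; the raw p-values are always reported.

`welch_t()` uses the unequal-variance form with Welch–Satterthwaite
degrees of freedom, two-sided, treating studies as units. The
equal-variance pooled form is deliberately not offered: on study-level
frequency comparisons with unbalanced group sizes it can differ
substantially (on the bundled roster's MAF columns, pooled-variance t ≈
4.4 vs Welch ≈ 5.8), and the unequal-variance form is the defensible
default.

## The simulator

`simulate_studies()` draws, per study $i$:
$\theta_i \sim N(\ln \mathrm{OR}_{\text{true}}, \tau^2)$;
$p_{0i} \sim U(p_{0,\min}, p_{0,\max})$;
$p_{1i} = \operatorname{logit}^{-1}(\operatorname{logit}(p_{0i}) + \theta_i)$;
per-arm sizes uniform integers over `n_range`; and genotype counts
multinomially under Hardy–Weinberg proportions at the arm's allele
frequency. The roster row then summarises its own counts exactly (combined
empirical MAF, empirical allelic OR), so the reconstruction path closes
the loop on simulated data to machine precision — a property the tests
exercise directly.

Defaults, chosen once to mirror the bundled roster's conditions:
`k = 37` studies, true OR 1.12, $\tau^2 = 0.02$ (log-odds², about the
magnitude the roster itself exhibits within its less heterogeneous
stratum), per-arm sizes 300–3000 persons (the central range of the
roster's arms) and control allele frequencies 0.2–0.4 (the roster's
observed MAF band). `simulate_null_funnel()` fixes OR = 1 and
$\tau^2 = 0$ for type-I-error checks. A Hardy–Weinberg disequilibrium
coefficient is available (`hwe_d`) but defaults to 0.

What the generator deliberately does **not** emulate: covariate-adjusted
odds ratios (real studies often report logistic-regression estimates, not
raw allele-table ratios), genotyping error, case-arm departure from HWE
induced by strong risk loci, population stratification within a study,
and publication-selection mechanisms. Calibration results on synthetic
data therefore certify the estimators' arithmetic and sampling behaviour,
not robustness to those real-data complications.

Calibration checks run at 1,000 replicates with a fixed seed: recovery of
the true effect by DL at $k = 37$, and null behaviour of the Q and Egger
tests at $k = 20$. Recovery bias is assessed on the estimation (log-odds)
scale, the standard practice for log-linear estimators: the arithmetic
mean of exponentiated estimates carries a Jensen term of order
$se^2/2 \approx 3 \times 10^{-4}$ that is an artifact of the scale change,
not an estimator defect. Observed behaviour at these settings: log-scale
bias within two Monte-Carlo standard errors of zero, mean $\hat\tau^2$
within a few percent of truth, Q-test rejection near 4 % at the nominal
5 %, Egger rejection below 1 % at the nominal 1 %, mean null $I^2$ under
10.

## Numerical choices, in one place

* Normal quantile 1.959964 for every 95 % interval; 0.5 continuity
  correction only on zero cells; fractional reconstructed cells never
  rounded.
* Frequency reconstruction by bracketed root-finding on $(0,1)$, absolute
  tolerance $10^{-12}$; the `or = 1` case short-circuits to
  $p_1 = p_0 = \mathrm{MAF}$ exactly.
* $\hat\tau^2$ clamped at 0; $I^2$ clamped to $[0, 100]$; p-values kept in
  double precision and never truncated to zero in output.
* Results CSVs serialise doubles at 17 significant digits, which
  guarantees an exact binary round trip (base R's parser is exact at this
  precision).
* All randomness flows through a single seed; `simulate_studies(seed = )`
  uses a scoped seed that leaves the caller's random state untouched.

## Known limitations

* Per-study effect-direction conventions cannot be audited from summary
  columns; see the effect-model section. Roster columns transcribed from
  many source articles should be treated as potentially mixed-direction
  until checked against genotype counts.
* DL is the only random-effects estimator offered (no REML,
  Paule–Mandel or Hartung–Knapp); it is the conventional choice this
  pipeline standardises on, and its small-$k$ undercoverage is inherited.
* The biallelic model is hard-wired; multi-allelic variants and haplotypes
  are out of scope.
* Dominant and recessive contrasts require genotype counts; no
  approximation from allele-level summaries is attempted, because carrier
  frequencies are not identified by (MAF, allelic OR) without HWE
  assumptions the data may violate.
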