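---
title: "Models and methods for population-scale gene constraint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for population-scale gene constraint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(constraintkit)
```

This vignette is the package's account of its science: the models it
assumes, the parameters that matter, what the synthetic-exome generator
does and does not emulate, the numerical choices, and the known limits of
what passing tests demonstrate.

## The frequency model

Everything rests on one parametric family. A site with per-generation
mutation rate $\mu$ whose carriers suffer a heterozygous fitness cost
$s$ has an equilibrium population frequency approximated by a gamma
distribution,

$$ q \sim \mathrm{Gamma}\!\left(\text{shape} = 4N_e\mu,\;
   \text{rate} = 4N_e s_{\mathrm{eff}}\right), \qquad
   s_{\mathrm{eff}} = \max\{s,\, 1/(2N_e)\}, $$

the classical mutation–selection–drift spectrum. The *drift floor*
$1/(2N_e)$ stands in for $s = 0$ so a single family covers neutral and
selected sites; for small shape the density behaves as $q^{-1}e^{-4N_e s q}$,
the familiar neutral $1/q$ spectrum truncated at $q \sim 1/(4N_e s)$.
Sampling $n$ chromosomes with $\mathrm{AC} \mid q \sim \mathrm{Poisson}(nq)$
gives a negative binomial allele count with size $4N_e\mu$ and success
probability $n/(n + 4N_e s_{\mathrm{eff}})$, and the closed forms the
package uses throughout:

- `prob_segregating()`:
  $P(\mathrm{AC}\ge 1) = 1 - (1 + n/(4N_e s_{\mathrm{eff}}))^{-4N_e\mu}$;
- `expected_oe_curve()`: the ratio of that probability under selection to
  its value at the drift floor — the analytic observed/expected curve,
  which starts well below one for constrained genes and closes towards one
  as cohorts grow, making constraint metrics sample-size dependent by
  construction;
- `selection_pmf()`: the negative binomial conditioned on
  $\mathrm{AC}\ge 1$, the selected component of the mixture model.

**Assumptions.** Sites are independent (no linkage), the population is at
equilibrium at a single effective size, and selection acts additively on
heterozygotes. None of these hold exactly for humans — recent explosive
growth in particular makes real rare-variant spectra far more
singleton-rich than any equilibrium spectrum. The package treats $N_e$ as
a modelling dial: $10^4$ (the default) describes common variation;
analyses that live in the ultra-rare, strong-selection regime are better
described by larger $N_e$, and the identified composite is always
$4N_e s$ (doubling $N_e$ halves every inferred $s$).

## Recurrence: the simulator and the estimators share one law

The generator does not draw the negative binomial directly. It uses the
exact compound representation

$$ M \sim \mathrm{Poisson}(\lambda), \quad
   \lambda = 4N_e\mu\,\ln\!\left(1 + \tfrac{n}{4N_e s_{\mathrm{eff}}}\right),
   \qquad k_j \sim \mathrm{Logarithmic}(\pi), \quad
   \pi = \tfrac{n}{n + 4N_e s_{\mathrm{eff}}}, $$

with $\mathrm{AC} = \sum_{j\le M} k_j$ capped at $n$. $M$ is the number of
mutational origins observed in the sample (recorded per site in the truth
table) and each origin contributes a logarithmic-distributed count
$g(k) \propto \pi^k/k$ — for $\pi \to 1$ exactly the $1/k$ per-origin
spectrum the recurrence estimator assumes. Because the compound of a
Poisson with a logarithmic distribution *is* the negative binomial, the
simulator, `prob_segregating()`, `selection_pmf()` and the recurrence
machinery (`fit_recurrence_rate()`, `prob_recurrent_doubleton()`) are
mutually consistent by construction, not by tuning. Saturation
(`saturation_by_class()`) inverts as $\hat\lambda = -\ln(1-\text{saturation})$,
and the probability that a doubleton is recurrent is
$\lambda g(1)^2 / (2g(2) + \lambda g(1)^2)$.

## LOEUF and its power

`loeuf_upper(o, e)` is the upper limit of the exact two-sided 90% Poisson
interval for the mean, divided by the expectation:
$Q_\Gamma(0.95;\, o+1, 1)/e$. The level is configurable; 90% two-sided
(95th percentile upper limit) is the package convention. `loeuf_mis()`
pools pLoF with top-percentile predicted-deleterious missense counts
before applying the same bound — pooling keeps the interval exact, and
with an empty missense class it reduces to plain LOEUF. The top slice is
a union across predictors (a variant counts if any selected predictor
ranks it in the top percent exome-wide).

`loeuf_power()` is simulation-based: counts are drawn under a null and an
alternative selection strength, the critical value is the $\alpha$
quantile of the null LOEUF distribution, and power is the fraction of
alternative replicates below it. Within the equilibrium model a caveat is
worth stating plainly: the neutral expectation grows only logarithmically
in $n$ while the observed/expected gap $1 - \mathrm{oe}(n)$ closes as
constrained genes saturate, so power rises while the alternative remains
unsaturated ($n \lesssim 4N_e s_{\mathrm{alt}}$) and then declines slowly;
the Poisson discreteness of the critical value adds jaggedness on top.
The package's tests therefore assert the test's size, the near-complete
power for strong selection at large cohorts, and the rising
pre-saturation branch — not global monotonicity, which the model does not
possess.

A second artifact the model makes explicit: at equal selection and equal
*expected* counts, genes built from more mutable sites have higher
observed/expected ratios (their sites saturate even under selection) and
hence higher LOEUF. The effect is small but systematic, and it reverses
if expectations are not controlled, because higher $\mu$ also means more
expected variants and a tighter confidence bound.

## The probability-of-neutrality mixture

Per gene, the allele counts of *observed* pLoF variants are modelled as a
two-component mixture: with probability $w$ a variant is misannotated and
its count follows a neutral spectrum learned from exome-wide synonymous
variants (class-conditional empirical distribution, pseudocount 0.5,
log-uniform tail bins above AC 100); otherwise it follows the selected
negative binomial with the gene's $s_{het}$. A grid posterior —
$s_{het}$ on 40 log-spaced points in $[10^{-4}, 1]$, $w$ on 41 uniform
points (41 rather than a coarser grid so that refining the grid moves no
per-variant probability by more than 0.01) — with a log-uniform prior on
$s_{het}$ and uniform prior on $w$ yields the posterior mean $s_{het}$
and, per variant,
$p_{\mathrm{neutral}} = E_{\text{posterior}}\!\left[\frac{w P_N}{w P_N + (1-w) P_S}\right].$

Variants with $\mathrm{AC} = 0$ are excluded and both components are
conditioned on $\mathrm{AC} \ge 1$: the model sees only observed
variants, so all information about $s_{het}$ comes from the *shape* of
the allele-count distribution, not from the deficit of observed variants.
Two practical consequences, verified in the test suite:

- $s_{het}$ recovery needs well-powered genes. With ~40 expected pLoF
  variants per gene the posterior mean recovers $\log_{10} s_{het}$ with
  RMSE ≈ 0.38 and rank correlation ≈ 0.87; at ~10 expected (a handful
  observed in constrained genes) the posterior is prior-dominated and the
  RMSE roughly doubles.
- misannotation separation is a strong-selection phenomenon. The
  achievable AUROC is capped by the overlap of the neutral and selected
  count distributions; with the package's own Bayes oracle (true
  parameters) the cap is ≈ 0.92 at $4N_e s \approx 0.1\,n$ and exceeds
  0.95 only in the ultra-rare regime $4N_e s \gtrsim n$, where selected
  variants are essentially singletons. This mirrors the method's intended
  domain — strongly constrained genes — and the package's acceptance
  experiment measures separation there (AUROC 0.98).

## Loss-of-function rules and calibration

`compute_features()` derives, per variant: signed distance to the last
exon–exon junction (the junction sits at the first base of the final
exon; positive = upstream, where a premature termination codon triggers
NMD), CDS-start distance, a single-exon flag, distance to the transcript
end, and the splicing-impact score. `annotate_loftee2()` applies the rule
set in a relaxed and a strict mode; strict thresholds are at least as
exclusive, so the strict high-confidence set is always a subset of the
relaxed one, and a variant missing a needed feature is `unscorable`,
never silently high-confidence. Shipped defaults (junction 50 nt;
CDS-start 100/150 nt; single-exon end 1000 nt and start 100/150 nt;
splice score 0.2/0.5) are runnable placeholders; the recommended path is
`calibrate_threshold()`, which sorts variants by a feature, computes the
cumulative mean of $1 - p_{\mathrm{neutral}}$, places a single
least-squares changepoint on the per-variant sequence, and gates it on a
permutation test (1000 shuffles, $\alpha = 0.05$) so pure noise returns
no threshold. The threshold is the feature value of the last point in the
lower segment; on a cohort of strongly constrained genes the junction
calibration recovers the generator's 50 nt escape window to within a few
nucleotides.

`evaluate_truthset()` reports precision, recall and $F_{0.5}$ (precision
weighted twice as heavily as recall, the curation-relevant trade-off)
with case-bootstrap confidence intervals.

## Allelic expression

Read counts over heterozygous sites are modelled as beta-binomial
mixtures — beta-binomial rather than binomial to absorb overdispersion
from mapping bias and tissue mixing. The background, fit by EM on
synonymous variants, has a balanced component (mean fixed at the
reference-bias offset, default exactly 0.5, concentration ≥ 50), a
symmetric two-sided monoallelic component (one mean parameter shared by
both sides), and a random-imbalance component (same mean, concentration
constrained below 50 — the concentration ranges are what separate the two
mean-0.5 components). The NMD component is added on pLoF variants with
the background frozen: its mean is constrained below 0.5 because decay
depletes the transcript carrying the variant allele. M-steps use
box-constrained quasi-Newton updates that are only accepted when they
improve the weighted likelihood, so the EM log-likelihood is
non-decreasing by construction (asserted at every iteration in tests).
`separation_ratio()` compares classifications by the ratio of
geometric-mean posterior NMD probabilities (pLoF vs non-pLoF, floored at
$10^{-6}$).

## Integrating literature with constraint

`omelet_score()` places the latent *depletion* $\theta \in [0,1]$ of
high-impact variation at the centre: the literature percentile maps to a
beta prior with mean $\varepsilon + (1-2\varepsilon)\,\mathrm{pct}/100$
(floor $\varepsilon = 0.02$ keeps extreme percentiles proper) and
concentration $k = 4$ effective prior observations; the constraint counts
enter as $o \sim \mathrm{Poisson}(e(1-\theta))$; the score is the 5th
percentile of the posterior (the lower bound of the 95% credible level).
Parameterising depletion rather than rate makes "higher = more clinically
significant" hold simultaneously for prior, likelihood and posterior.
Numerically, the $\theta$ grid carries exact beta prior masses per bin
(from the beta CDF) modulated by the likelihood at bin midpoints, with
quantiles interpolated within a bin proportionally to the prior — this
stays accurate even for sub-1 beta shapes whose densities diverge at the
endpoints, where a naive midpoint-density grid fails. Against an exact
series representation of the posterior (a beta mixture), the grid is
within $2\times 10^{-5}$ at high resolution and $\sim 10^{-3}$ at the
default 501 points.

Two properties worth knowing: the prior's influence fades as expected
counts grow (but a *vanishing* prior strength does not recover a flat
prior — a beta with concentration $\to 0$ degenerates to endpoint atoms;
flat is $k = 2$ at mean 0.5); and the combination outperforms either
source alone only when both carry comparable information — with an
uninformative constraint arm the posterior simply tracks the prior.

`dispo_score()` is the percentile-point difference between constraint
rank (rank of $-$LOEUF) and the literature LoF-impact percentile;
`delta_pepper()` is the percentile rank (average-rank ties,
$100(r - 0.5)/n$) of the feature-minus-literature score difference; and
`flag_candidates()` applies the rule: feature score at or above the 95th
percentile, no established disease association, difference percentile
above 25.

## The synthetic exome: what it emulates, and what it does not

`simulate_exome()` builds per-gene transcript models (2–8 exons by
default, internal exons 120–240 nt, a longer final exon of 300–900 nt,
coding throughout), places up to three modelled sites per spliced
position (one per alternate allele), assigns mutational classes with
realistic frequencies (CpG transitions rare but an order of magnitude
more mutable), and draws allele counts from the recurrence-explicit model
above. Misannotation is injected three ways: stop-gained variants within
50 nt of the final junction (NMD escape), stop-gained variants within
100 nt of the CDS start (start-proximal rescue), and a random 5% of the
remaining pLoF sites — all drawn with neutral frequencies and flagged in
the truth table. Missense sites carry two correlated predictor scores
whose top percentile experiences the gene's selection; splice sites carry
an impact score coupled to their truth status (Beta(8,2) for genuine,
Beta(2,8) for misannotated). Gene-level literature scores are noisy
monotone transforms of the true $s_{het}$, with a 10% "understudied"
fraction forced low regardless of selection — the truth substrate for the
discovery-potential analyses.

What it does **not** emulate: linkage and haplotype structure, demography
and growth (so real singleton-heavy spectra are outside the model),
sequencing depth and call quality, transcript isoform complexity
(single-transcript genes, fully coding), and real trinucleotide-level
mutation-rate variation (four class-level rates instead). Passing tests
therefore demonstrate internal consistency and estimator correctness
under the stated model, not performance on real cohort data.

## Experiment designs used by the test suite

Sizes were chosen for the precision each check needs (all run on one CPU
in a few minutes):

- *Neutral observed/expected*: 500 genes × ~5000 sites at the drift
  floor, 1e5 individuals — about 2.5 million sites so the Monte-Carlo
  standard deviation of the aggregate ratio is ~1%, inside the ±2% band.
- *NMD-window recovery*: 1000 genes with $s_{het}$ log-uniform on
  [0.05, 0.5] — the strongly constrained regime where
  $p_{\mathrm{neutral}}$ carries signal; mixed-selection cohorts blur the
  cliff below detectability.
- *$s_{het}$ recovery*: 200 long, pLoF-heavy genes (~40 expected pLoF
  each), geometric escape windows disabled so the measurement isolates
  the estimator.
- *Misannotation AUROC*: 200 genes at $N_e = 10^6$, $s_{het}$ in
  [0.1, 0.5] — the ultra-rare regime ($4N_e s \gtrsim n$) the method
  targets.
- *Mode orderings*: a cohort with a 150 nt start-proximal escape zone and
  a splice-heavy consequence mix, so the relaxed (100 nt) and strict
  (150 nt) thresholds both face genuine escapes; with the escape zone
  equal to the relaxed threshold, extra stringency could only remove true
  positives and the comparison would be vacuous.
- *Score integration*: ~9 expected pLoF per gene and literature noise of
  40 percentile points, balancing the two sources so synergy is
  measurable.

## Known limitations

- All $s_{het}$ inference is conditioned on observed variants; the
  observed-count deficit (the heart of LOEUF) is deliberately not reused
  by the mixture, so the two views of constraint are independent but the
  mixture is underpowered for small genes.
- The equilibrium spectrum understates singleton fractions and recurrence
  at biobank scale; absolute saturation percentages from real data are
  outside the model's reach (only the estimators that produce them are
  implemented).
- The changepoint calibration fits a single breakpoint; features whose
  neutrality profile has two transitions (e.g. CDS-start distance
  combined with junction escape at the far end) are calibrated feature by
  feature, not jointly.
- Beta-binomial component identifiability relies on the concentration
  boxes; data genuinely intermediate between balanced and random
  imbalance are split by the 50-concentration boundary, which is a
  convention.
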