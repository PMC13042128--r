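# constraintkit

Gene constraint analysis at population scale: saturation and recurrence
under recurrent mutation, LOEUF-family observed/expected statistics with
power theory, a Bayesian mixture model for per-variant probabilities of
neutrality, an NMD-informed loss-of-function rule engine, an
allelic-expression beta-binomial mixture, and Bayesian integration of
literature-derived gene scores with constraint counts — together with a
synthetic-exome simulator that generates allele counts from the same
population-genetic model the estimators assume.

## Who this is for

Statistical and population geneticists working with site-level variant
summaries (allele counts over sampled chromosomes) who need: constraint
metrics whose sample-size and mutation-rate dependence is made explicit;
principled loss-of-function curation informed by nonsense-mediated decay
(NMD) biology; and gene prioritisation scores that combine population
constraint with literature-derived evidence.

## The models in brief

**Frequency model.** At a site with per-generation mutation rate μ and
heterozygous selection coefficient s, the population frequency follows the
gamma approximation of the equilibrium site frequency spectrum,
q ~ Gamma(shape 4·N_e·μ, rate 4·N_e·s_eff), with a drift floor
s_eff = max(s, 1/(2·N_e)) standing in for neutrality. Sampling n
chromosomes with AC | q ~ Poisson(n·q) makes the allele count negative
binomial, giving closed forms for the probability a site is polymorphic,

    P(AC ≥ 1) = 1 − (1 + n / (4·N_e·s_eff))^(−4·N_e·μ),

for the analytic observed/expected curve oe(n) = P_s(n) / P_drift(n), and
for the allele-count distribution under selection used by the mixture
model. The simulator draws the same law through its exact compound
representation — Poisson mutational origins with logarithmic per-origin
counts — so recurrence (multiple independent origins per site) is explicit
and simulated saturation matches `prob_segregating()` by construction.

**Constraint statistics.** `loeuf_upper(o, e)` is the upper limit of the
exact two-sided Poisson confidence interval for the mean at the configured
level (default 90%), divided by the expectation — the LOEUF convention
(lower = more constrained). `loeuf_mis()` pools pLoF with top-percentile
predicted-deleterious missense counts; `missense_vs_plof_test()` is the
conditional binomial comparison of depletion between the two classes.

**p_neutral mixture.** Per gene, observed pLoF allele counts are modelled
as a two-component mixture: a neutral spectrum learned from exome-wide
synonymous variants (misannotated variants) and the gamma/negative-binomial
spectrum under selection. A grid posterior over (s_het, mixture weight w)
yields the posterior-mean selection coefficient and, per variant, the
posterior probability of neutrality p_neutral.

**LOFTEE-style rules.** Transcript geometry (distance to the last
exon–exon junction, CDS-start distance, single-exon end distance) plus a
splicing-impact score drive a relaxed and a strict classification of pLoF
variants into high/low confidence; thresholds can be calibrated from data
by least-squares changepoint detection on 1 − p_neutral curves (the ~50 nt
NMD rule emerges from the calibration).

**Allelic expression.** Read counts over heterozygous sites follow a
beta-binomial mixture — balanced, monoallelic (symmetric pair), random
imbalance — fit by EM on synonymous variants, plus an NMD-depletion
component (mean < 0.5) fit on pLoF variants with the background frozen;
`separation_ratio()` benchmarks classifications by the geometric-mean
posterior NMD probability of pLoF versus non-pLoF variants.

**Integration.** `omelet_score()` treats the literature percentile as a
beta prior on the depletion θ of high-impact variation, the constraint
counts as a Poisson likelihood o ~ Poisson(e·(1−θ)), and reports the 95%
lower bound of the posterior. `dispo_score()` (constraint percentile minus
literature LoF percentile) and `delta_pepper()` (percentile rank of the
feature-minus-literature score difference) contrast the two sources;
`flag_candidates()` applies the published rule (feature score ≥ 95th
percentile, no established disease association, score-difference
percentile > 25).

## Worked example

```r
library(constraintkit)

cfg <- simulation_config(n_genes = 60, sites_per_gene = c(300L, 400L),
                         n_samples = 5e4, seed = 7)
ex <- simulate_exome(cfg)
ex
#> <synthetic_exome> 60 genes, 21004 sites (57 segregating), n_chrom = 100000

# per-gene constraint from observed vs expected counts
counts <- gene_counts_from_exome(ex$variants, n_chrom = cfg$n_chrom)
head(constraint_table(counts), 3)
#>   gene_id oe    loeuf loeuf_mis p_mis_vs_lof
#> 1   g0001  0 12.41703  12.21987            1
#> 2   g0002  0 16.03668  15.60330            1
#> 3   g0003  0 19.57132  19.08595            1

# saturation by mutational class
round(saturation_by_class(build_sfs(ex$variants)), 4)
#>   methyl_cpg_transition unmethyl_cpg_transition      non_cpg_transition
#>                  0.0424                  0.0026                  0.0024
#>            transversion
#>                  0.0008
```

Zero observed pLoF with a small expectation still leaves a wide LOEUF
bound (`-log(0.05)/e`); the bound tightens as expectations grow. The
saturation ordering tracks the mutation-rate hierarchy of the classes —
methylated CpG transitions are observed at many times the rate of
transversions at the same cohort size.

The full pipeline (simulate → p_neutral → LoF rules → allelic expression →
constraint → integration → benchmarks) runs as

```r
run_pipeline("out/", seed = 11,
             config = list(n_genes = 250L, sites_per_gene = c(300L, 400L),
                           n_samples = 5e4))
```

writing TSV artifacts plus a manifest with per-stage seeds and checksums;
reruns are byte-identical. A thin command-line wrapper is installed as
`exec/ckit` (`ckit pipeline --seed 11 --out-dir out/`, `ckit saturation`,
`ckit constraint`, ...).

## Input formats

- Variant TSV: `chrom, pos (1-based), ref, alt, context, methylation, mu,
  consequence, ac, an` plus optional per-predictor score columns.
- Minimal sites-VCF dialect: INFO keys `AC`, `AN` (mandatory), `MU`,
  `METHYL`, `SPLICE_SCORE`, `CSQ`, `CONTEXT` (optional).
- Transcripts: GTF (`exon` + `CDS` features) or a TSV with comma-separated
  0-based half-open exon bounds.
- Allelic expression TSV: `variant_id, ref_reads, alt_reads`.
- Gene scores TSV: literature/feature percentiles in [0, 100] per gene.

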