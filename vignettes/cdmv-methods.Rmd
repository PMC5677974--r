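---
title: "Quantifying inter-individual DNA methylation variability and selecting EWAS targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-individual DNA methylation variability and selecting EWAS targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmv)
```

## The problem

Epigenome-wide association studies (EWAS) scan CpG sites for associations
between DNA methylation (DNAm) and exposures, traits or disease. Most
published EWASs interrogate a fixed probe set (typically the
HumanMethylation450 array, ~480k of the ~27 million autosomal CpGs), and
most array probes sit at CpGs whose methylation barely varies between
people. A CpG that is (say) fully methylated in every individual cannot
correlate with anything; only CpGs that *commonly vary* across individuals
can become biomarkers. `cdmv` implements the analysis pipeline behind this
idea: quantify per-CpG inter-individual variability from whole-genome
bisulfite sequencing (WGBS) methylation calls, show that previously
reported EWAS biomarkers concentrate among highly variable CpGs, and
construct *commonly variable DNAm* (CDMV) target sets for future studies.

## The variability statistic

For CpG $i$ with methylation levels (betas, percent scale) $M_{i,1}, \dots,
M_{i,n}$ across $n$ individuals, the **reference interval** is

$$\mathrm{RI}_i = Q_{95}(M_{i,\cdot}) - Q_{5}(M_{i,\cdot}),$$

the difference between the 95th and 5th percentiles across individuals.
Percentiles use linear interpolation between order statistics (the
quantile "type 7" default); this choice is exposed because RI values shift
slightly under nearest-rank quantiles and the convention used upstream of
any given dataset may differ. The median of the same values classifies the
CpG's **status**: hypomethylated (median $\le 20$%), hypermethylated
(median $\ge 80$%), intermediate otherwise; boundary medians go to the
extreme classes because the defining inequalities are inclusive. A CpG is
**commonly variable** when $\mathrm{RI} \ge 30$% (inclusive). Status and
RI are logically independent — a CpG constant at 50% in everyone is
intermediate with RI 0 — but empirically intermediate CpGs carry most of
the inter-individual variability.

## QC pipeline

Per-sample CpG calls (Bismark-style coverage files; counts are
authoritative, the file's percent column is ignored) pass through a fixed
order of filters before any statistic is computed:

1. **Depth**: calls with depth $<6$ or $>300$ are removed (boundaries
   retained). Low depth makes betas unstable; extreme depth flags
   collapsed repeats.
2. **Variant masking**: per sample, a call is set to missing when that
   sample carries a non-reference allele at either base of the CpG
   dinucleotide, since the variant destroys the CpG unit itself. Any
   ALT-carrying genotype masks, regardless of zygosity — heterozygotes
   already measure a mixture of a CpG and a non-CpG allele.
3. **Call rate**: after assembling the cohort matrix over the union of
   CpGs, sites observed in fewer than 50% of samples (inclusive
   threshold) are dropped.

Strand merging (reverse-strand G calls added to the forward C at
`pos + 1`) is on by default but optional, since per-CpG exchange formats
differ in whether strands arrive pre-merged. Non-autosomal records are
dropped by default. No extra minimum-`n` rule is applied to RI beyond the
call-rate filter; `n_obs` is recorded per CpG so users can filter post
hoc.

## Enrichment statistics

The **biomarker likelihood** of a CpG set is the fraction of its members
previously reported in EWAS catalogs (matching by exact coordinate; probe
manifests map array IDs to coordinates). Sets are compared by 2×2 odds
ratios: $\mathrm{OR} = ad/bc$ with the Woolf log-scale 95% CI
$\exp(\ln\mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$ and a
two-sided Fisher exact p-value (point-probability rule). Zero cells take
the Haldane–Anscombe correction (+0.5 to every cell, flagged in the
result); only an empty *group* (a whole zero row) is treated as undefined,
since a zero column — an outcome absent from both groups — is still
correctable. The Woolf/Haldane pair was chosen as the standard closed form
when the upstream convention is unstated.

Two framings exist for decile profiles, because "compare each decile with
the whole probe set" nests a group inside its own baseline: the package
reports both the proper group-vs-complement OR (with CI and p) and the
literal likelihood-to-average ratio, clearly labelled. Efficacy
comparisons between target sets (e.g. a CDMV set vs an array probe set)
treat the sets as independent groups, each counted in full, because real
candidate sets overlap their references substantially and conditioning on
the overlap would change the estimand.

## Annotations and coordinates

Interval annotations use BED 0-based half-open coordinates; CpGs are
1-based forward-strand C positions; the single conversion (`pos - 1`)
lives in one function to prevent off-by-one drift. Promoters span 2 kb
upstream to 500 bp downstream of the TSS, strand-aware and clipped at the
chromosome start; the default window contains the 2,000 upstream bases,
the TSS base and 500 downstream bases (width 2,501), with a
`tss_in_downstream` switch giving the 2,500-width reading where the TSS
counts as the first downstream base — the prose definition is genuinely
ambiguous on that base. CGI shores are the 2-kb flanks of each island;
shore bases overlapping another island are kept by default (a
`subtract_cgi` option implements the common alternative). Membership of a
CpG in an element is decided at the C position alone; `both_bases` extends
it to any overlap of the dinucleotide. Repeat regions are ordinary
interval sets consumed by the selection step.

## CDMV target selection

A CDMV set keeps CpGs with $\mathrm{RI} \ge$ `min_ri` (default 30%,
inclusive) that fall outside repeat intervals; repeats are excluded
because microarray and capture measurement is unreliable there. An
optional cap removes CpGs with $\mathrm{RI} >$ `max_ri` (customarily 70%,
strict), reflecting the signal-to-noise argument that extremely variable
sites need implausibly large case–control differences to reach
significance. Per-criterion removal counts are attached to the result so
the accounting is reproducible on any input.

## Smoking and trait association

Per CpG, the model is ordinary least squares on the percent scale,

$$M_{i,j} = \beta_{i,0} + \beta_{i,S} S_j + \beta_{i,\mathrm{age}}
\mathrm{Age}_j + \beta_{i,\mathrm{sex}} \mathrm{Sex}_j,$$

with $S_j = 1$ for current and $0$ for never smokers; former and unknown
smokers are excluded, missing responses are dropped listwise, and
$\beta_{i,S}$ is tested two-sided. No logit or M-value transform is
applied — the estimand is the adjusted difference in percentage points.
Sex is coded female = 0, male = 1 (affects only the sign of
$\beta_{\mathrm{sex}}$). CpGs with fewer usable samples than parameters
plus one, or with collinear designs, are skipped with the reason recorded.
Nominal p-values are reported without genome-wide correction, matching the
regional-profile use case where a 0.05 guide line is customary; a
correction can be applied downstream. The quantitative-trait engine
regresses the trait on DNAm with the same age/sex covariates by default
(configurable, since conventions for expression models vary). Regional
profiles around an anchor CpG add the squared Pearson correlation with the
anchor (pairwise-complete, requiring at least 10 shared samples) and
per-group means and SDs.

## Power of the efficacy comparison

For a design with $N$ probes of which $K$ are previously associated, a
targeted fraction $f$ and a planted odds ratio $\theta$, membership
probabilities $(p_1, p_0)$ solve $\mathrm{odds}(p_1)/\mathrm{odds}(p_0) =
\theta$ and $(K p_1 + (N-K) p_0)/N = f$ (solved by `uniroot` to residual
$< 10^{-12}$; an alternative reading pins $p_0 = f$ directly and is
available via `marginal = "nonassoc"` — at $K \ll N$ the two differ
negligibly). Each Monte-Carlo replicate draws $a \sim \mathrm{Bin}(K,
p_1)$, $c \sim \mathrm{Bin}(N - K, p_0)$, forms the 2×2 table and applies
the Fisher exact test; power is the rejection fraction at $\alpha$, with
its Monte-Carlo standard error reported. The default alternative is
directional (enrichment), which is the hypothesis an efficacy improvement
states; the two-sided test is available. A normal-approximation path
(two-proportion score test) serves as a large-count cross-check and agrees
with the exact path within 0.01 at array-scale counts. At $N = 473{,}814$,
$K = 269$, $f = 0.10$, $\theta = 2.0$, $\alpha = 0.05$ the directional
power is 98.6%; the two-sided variant gives ~97.0%.

## The synthetic cohort generator

Real WGBS cohorts of purified blood cells are access-restricted, so every
pipeline stage is validated on synthetic cohorts with known ground truth.
The generative model, per CpG: a class (hypo / hyper / intermediate, mix
0.11 / 0.80 / 0.09), a true mean beta drawn uniformly from the class's
centre range (hypo U(0, 5), hyper U(88, 100), intermediate U(20, 80)),
per-individual true betas as a clipped normal around the mean with
class-specific SD (1.5 / 3 / 15 percentage points), Poisson read depths
(mean 15, per-sample means varying with SD 1, minimum 1) and binomially
sampled methylated counts — together a beta-binomial-style observation
model. The clipped normal was preferred over a Beta distribution for the
inter-individual layer because it gives direct control of the spread → RI
mapping; a practitioner can still obtain Beta-like shapes through the
centre ranges. The centre and spread values were fixed once so that the
observed per-class reference intervals reproduce the qualitative ordering
seen in purified monocytes (intermediate ≫ hyper > hypo, with the narrow
classes peaking near 10–20% RI at 15× depth): unmethylated CpGs sit at
tightly constrained CpG islands, while the methylated bulk genome is
slightly more dispersed.

Metadata mirror an adult cohort: ages uniform on [34, 74], balanced sexes,
smoking mix 0.3 / 0.6 / 0.1 (current / never / former). No age–methylation
coupling is generated by default so smoking tests are unconfounded unless
requested. Smoking effects are planted at intermediate CpGs (the only
class where a multi-point shift is observable without clipping). Note a
power fact that the generator makes explicit: at 15× depth the binomial
read noise alone contributes ~12 percentage points of within-group SD at
intermediate methylation, so a 10-point smoking effect at $n = 100$ has a
noncentrality of only ~2.5 and is *not* reliably detectable at stringent
thresholds; the detection tests therefore plant 25-point effects, the
scale of the strongest published smoking biomarkers.

Planted biomarker catalogs draw "associated" CpGs so that the odds of
catalog membership for broad-RI versus narrow-RI CpGs equal a requested
odds ratio, reusing the power module's probability solver; design labels
follow the published 47 : 225 : 3 population/case-control/both structure,
rescaled. Two planting modes matter for validation: planting on the
*measured* variability strata makes the efficacy estimator target exactly
the planted odds ratio (this mirrors reality — published EWAS hits were
discovered from measured methylation — and is the mode under which CI
coverage is checked: a planted OR of 3.0 is covered by the 95% CI in
≥ 90 of 100 cohorts of 100 samples × 20,000 CpGs), while planting on the
latent true-beta strata attenuates the estimate (to ~2.8 at these sizes)
through read-noise misclassification of CpGs near the RI threshold — a
genuine property of threshold-based selection on noisy estimates, checked
qualitatively. Synthetic annotation tracks (CpG islands, repeats,
DHS-like intervals, TSS records) and an array-style probe manifest with a
configurable bias toward low-variability CpGs complete the inputs, so the
full pipeline — coverage files → QC → matrix → variability → selection →
enrichment — runs end to end on generated data.

What passing these tests shows, and what it does not: the synthetic
cohorts validate the statistics and the plumbing under a known generative
model; they do not reproduce chromatin co-structure, methylation
haplotypes, mQTL genetics, cell-type mixtures or the real genome's CpG
spatial layout, so they say nothing about the biological claim that
variability predicts biomarker status in any particular tissue — only
that, where such structure exists, this pipeline measures it correctly.

## Numerical choices and problem sizes

Betas are carried on the percent scale throughout; conversions happen at
I/O edges only. Decile bins on an analysis subset are near-equal (sizes
differ by at most one, extras to the narrowest bins) with ties broken by
genomic order, so re-runs are deterministic. All simulation routines take
a mandatory seed and restore the caller's RNG state; identical seeds give
byte-identical output files. Test problem sizes (e.g. 100 cohorts of
100 × 20,000 for coverage checks, 10,000–20,000 replicates for power)
were chosen as the smallest sizes at which the binomial/Monte-Carlo error
bands in the assertions are decisive.

## Known limitations

- Catalog matching is coordinate-exact; liftover between genome builds is
  out of scope and must happen upstream.
- The reference-interval estimator confounds inter-individual variation
  with sequencing noise at low depth; at 15× a zero-variance CpG still
  shows an RI of roughly 10–20%. Comparisons between groups of CpGs at
  similar depth are unaffected, but absolute RI values should be read
  with the depth in mind.
- The smoking model is a per-CpG OLS with age and sex only; batch,
  cell-composition and genetic covariates are the user's responsibility.
- `estimate_power` models the catalog as fixed and the targeting as
  random, which is the natural reading of the published design but not
  the only one; the `marginal` option covers the main alternative.
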