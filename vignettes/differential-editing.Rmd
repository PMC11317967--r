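---
title: "Detecting differential A-to-I RNA editing from allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential A-to-I RNA editing from allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aied)
library(dplyr)
```

## The problem

Adenosine-to-inosine RNA editing appears in RNA-seq as A→G mismatches: at a
given transcriptomic site, some reads carry the genomic A and some carry G.
The data unit is therefore a pair of counts per site and sample —
`ref_count` unedited reads and `alt_count` edited reads — and the *editing
level* is the proportion `alt / (ref + alt)`. `aied` answers, from a long
table of such counts plus sample metadata:

1. Which candidate sites are credible editing sites at all?
2. Which sites change editing level between experimental groups
   (e.g. control vs two post-sepsis time points)?
3. Are those changes modulated by age or sex, coupled to host-gene
   expression, shared between independent datasets, or reversed by a
   treatment?

Upstream read processing (trimming, alignment, variant calling, VEP-style
consequence annotation) is out of scope: consequence classes, known-site
catalogues and repeat intervals are consumed as inputs.

## Site cataloguing

Candidate calls are first oriented to the sense strand: A→G on "+" is kept,
T→C on "−" is rewritten as sense A→G, and every other substitution is
rejected. A T→C call without a known strand cannot be oriented and is an
error rather than a silent guess.

The high-confidence filter retains a site if it is **known** (present in a
catalogue such as REDIportal, matched exactly on chromosome and 1-based
position) **or** its mean editing level is ≥ 5% in at least one design
subgroup **and** editing is observed in at least two samples. Choices worth
making explicit, since the verbal rule leaves them open:

- *Grouping of the disjunction.* We read the rule as
  `known OR (level AND observed)`: a catalogued site is kept regardless of
  level. The `retained_reason` column records which branch fired.
- *"Observed".* A record counts as an observation when it has ≥ 1 edited
  read at ≥ `min_coverage` (default 10) total reads. The coverage floor
  prevents single-read artifacts; the same floor is used whenever a level is
  computed, so a cell with < 10 reads is *missing*, not zero.
- *Sample counting.* The ≥ 2-sample observation rule is applied study-wide,
  not within the qualifying subgroup; with four-replicate subgroups a
  within-subgroup rule would make retention hinge on a single extra sample.
- *Subgroups* are the design cells (group × age × sex when available,
  group alone otherwise). A subgroup with no covered sample simply
  contributes no mean — it never propagates `NaN`.
- *Known-site matching ignores strand*: public catalogues are
  sense-oriented and candidates are canonicalised before matching, so
  strand adds no information and would only create false negatives at
  annotation disagreements.

Repeat context is annotated from a 0-based half-open BED: a site at 1-based
position *p* overlaps `[start, end)` iff `start ≤ p − 1 < end`, and when
repeat intervals themselves overlap, the first interval in file order wins
(a deterministic, reproducible tie-break). Coordinate conversion lives in
this one function only.

## Quantification

The sample-wide average editing level is the unweighted mean over
non-missing catalog sites. Weighting by coverage would couple the statistic
to library size; under coverage-missing-at-random the unweighted mean is
unbiased. "Edited", for the per-sample site and gene counts, means level
> 0 at adequate coverage. The association of the average level with those
counts is summarised by Pearson correlation with two-sided p. A one-way
ANOVA + Tukey HSD comparison of per-sample averages across groups is
provided as a convenience report; the per-site inference below is the
primary analysis.

## The two-stage differential test

For each site whose level reaches 5% in some subgroup (the inclusion mask),
stage one fits a binomial GLM with logit link on the per-sample
(alt, ref) counts,

$$\operatorname{logit} \pi_{is} = \beta_0 + \beta_{g(s)} \,(+\, \beta_{\text{age}} + \beta_{\text{sex}}),$$

and tests the group term by a likelihood-ratio chi-square with
`#groups − 1` df (`p_glm`). The binomial family respects the precision of
each sample's counts — a 50-read sample constrains the fit more than a
10-read one — which a Gaussian test on levels would ignore. The GLM family
is a deliberate choice; "empirical P" is taken to be the analytic LRT
p-value, with a label-permutation p available per site (`n_perm`) for users
who want a resampling calibration.

Stage two, computed only where `p_glm < 0.05`, pools counts within groups
and applies a Fisher exact test to the 2×K table (`p_fisher`): K = 2 uses
the two-sided hypergeometric test, K > 2 exact enumeration while the table
total is within `exact_total` (default 500) and a seeded Monte-Carlo
approximation with 10⁵ draws beyond it (the reported `fisher_method` column
says which). `p_glm` is BH-adjusted across tested sites — missing p-values
are excluded from the adjustment and reinserted as missing — and the final
call is `fdr < 0.05 AND p_fisher < 0.05`. The composition of the two
statistics into one call set is our operationalisation; both thresholds are
exposed. For cross-dataset comparison the caller supports
`fdr_mode = "off"` (calls at raw `p_glm < 0.05`), because BH within each of
several independent datasets over-corrects the *intersection* of calls; the
Venn machinery (`overlap_dre_sets()`) then reports exclusive cells,
all-shared sites, and per-set shared-with-any counts.

Temporal trends are classified by explicit rules on the three group means
rather than unsupervised clustering — the cluster descriptions are verbal
("up at D1 then back down", "up at D4", "down at both") and rules
transcribe them exactly, with ties falling into `unclassified`:
early_up_then_down iff `D1 > control` and `D4 < D1`; late_up iff
`D4 > control` and `D4 ≥ D1`; down iff both time points sit below control.
Labels are assigned only to significant sites.

Covariate effects at individual sites are 1-df LRT drops of age and of sex
from the full model `group + age + sex`; a covariate constant in the design
is reported as missing with a note, never fitted.

### Calibration limits under overdispersion

Real allele counts are overdispersed relative to binomial. Under
beta-binomial noise with intra-class correlation ρ the binomial LRT
statistic is inflated by roughly the factor `1 + (m − 1)ρ` (m = coverage):
at coverage 50 even ρ = 0.01 gives ≈ 1.5× inflation, and the test suite
measures the resulting raw false-positive rate at ≈ 0.13 instead of 0.05.
The pooled Fisher stage does *not* repair this — the pooled table inherits
the same variance inflation and its statistic is nearly collinear with the
GLM's — so the two-stage false-positive rate is essentially the GLM's.
A quasi-binomial F-test (`dispersion_correction = TRUE`), which scales the
LRT by the Pearson dispersion of the full model, restores near-nominal
calibration in the same simulation. It is off by default to keep the
default procedure the plain two-stage binomial test; analysts of real
(overdispersed) data should turn it on or treat borderline calls with
caution.

## Expression integration and rescue

TPM is computed per sample as `1e6 · (count/length) / Σ(count/length)`;
columns sum to one million and the statistic is invariant to rescaling all
lengths. Differential expression of (edited) genes uses a per-gene
negative-binomial GLM with log link and log-library-size offset, testing
the group term by LRT with the null refit at the full model's estimated
dispersion (family is a knob; Poisson is available). Cis-regulation is
tested by Spearman rank correlation (mid-rank ties, two-sided p) between a
site's editing levels and its host gene's TPM across samples, requiring
≥ 5 paired observations; monotone association is the claim being tested, so
the rank statistic is the right level of commitment.

Rescue calling in a control/challenge/pre-treated design declares a site
rescued iff (i) challenge vs control is significant (two-group GLM LRT,
p < 0.05), (ii) pre-treated vs challenge is significant in the opposite
direction, and (iii) the pre-treated mean is closer to control than the
challenge mean. The three conditions operationalise "restored toward
control"; each is reported separately so alternative rules can be composed.

## The synthetic-study generator

`simulate_study()` draws, per site: a baseline level uniform on
\[0.02, 0.40\] (the range where hippocampal editing sites typically sit,
away from the 5% filter only at the low end so the filter is actually
exercised); group effects of +0.10 on the proportion scale at a `frac_dre`
(default 0.2) subset, applied to the second group, third group, or both —
effects are additive on the proportion scale with clamping to
\[0.001, 0.999\], because the field reports differences in percentage
points, not log-odds; age and sex shifts of 0.15 at configurable subsets;
coverage Poisson with mean 50 floored at one read (no per-site coverage
law is available to emulate, so the simplest law with realistic
missingness is used); and edited-read counts beta-binomial with intra-class
correlation ρ (default 0.01; ρ = 0 is exactly binomial). Expression for a
subset of host genes is Poisson–log-normal with the log-mean shifted by
`coupling × (observed editing level)`, which makes cis-correlation
recoverable without asserting any particular functional form beyond
monotonicity. The default design is the fully crossed 3 groups × 2 ages ×
2 sexes × 4 replicates layout; a 3 × n treatment design without covariates
is provided for rescue studies. A given seed reproduces every table
byte-for-byte.

What the generator does **not** emulate: alignment artifacts, strand
bleed-through, positional coverage bias, correlated sites within a gene,
ADAR-expression-driven global shifts, and batch effects. Passing recovery
tests therefore demonstrates that the statistics do what they claim under
their own assumptions — not that those assumptions hold in any particular
real dataset.

## Numerical choices and problem sizes

Degenerate per-site data (identical proportions everywhere, or no edited —
or no unedited — read anywhere) carry no group information and are reported
as p = 1 with a `degenerate` flag; non-convergent fits give a missing p
with a flag; neither throws. BH ties share adjusted values via the standard
cummin from the largest rank. The Monte-Carlo Fisher fallback is seeded
through the caller for reproducibility and agrees with enumeration to the
Monte-Carlo error at its default 10⁵ draws.

The simulation-based checks in the test suite and acceptance script use
2000 null sites for calibration (standard error of a 5% rate ≈ 0.5%),
500 sites for power/recovery, 200 sites for covariate power, and 100 sites
for rescue recovery — sizes at which Monte-Carlo error is small relative to
the tolerances being asserted while a full run stays comfortably
interactive.

## Known limitations

- The default test is anti-conservative under overdispersion (measured and
  discussed above); the quasi-binomial option is the mitigation.
- Consequence annotation is trusted as given; one category per site is
  required, duplicates are an error rather than a silent merge.
- Site identity across datasets is by `gene:chrom:pos` string equality;
  genome builds are assumed identical and are not checked beyond that.
- The sample-average editing statistic ignores missingness structure; under
  coverage that is informative about editing it would be biased.
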