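---
title: "Models and methods for clustered de novo mutation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for clustered de novo mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdnmkit)
```

## The scientific problem

Ionizing radiation damages DNA largely through reactive oxygen species,
whose reach is a few nanometres. When such lesions arise in the paternal
germline and are repaired by error-prone end joining, the expected
footprint is a *cluster* of de novo mutations (cDNMs) within a few tens
of base pairs — unlike the isolated DNMs that accumulate with paternal
age. cdnmkit implements the full analysis path for testing this
hypothesis in whole-genome-sequenced parent–offspring trio cohorts:
calling DNMs from joint genotype likelihoods, assembling clusters under
a window rule, assigning parental origin from read evidence, matching
cohorts on parental age, and relating per-offspring counts to cohort
membership and paternal dose with negative binomial regression.

Because real trio WGS cohorts of this kind are controlled-access, the
package ships a synthetic cohort generator with the same statistical
structure, so every stage is testable end to end.

## DNM scoring and filtering

A candidate site is a trio record where the child's genotype call is
heterozygous. The de novo posterior compares the de novo configuration
(child het, both parents hom-ref) against all parental configurations
carrying at least one alternate allele. With per-member normalized
likelihoods $L(g) = 10^{-PL_g/10}$ and a per-site prior $\pi$:

$$
\mathrm{score} \;=\;
\frac{L_c(\mathrm{het})\,L_f(RR)\,L_m(RR)\,\pi}
{L_c(\mathrm{het})\,L_f(RR)\,L_m(RR)\,\pi +
 \frac{1-\pi}{8} L_c(\mathrm{het}) \sum_{(g_f,g_m)\ne(RR,RR)} L_f(g_f)\,L_m(g_m)}
$$

The alternative parental configurations are weighted uniformly (8
configurations), and the default prior is $\pi = 10^{-5}$ per candidate
site; with ~$10^8$ callable candidate sites per genome and under 100
true DNMs this is the right order of magnitude, and the score is
insensitive to $\pi$ within a couple of orders of magnitude because the
likelihood ratio of a clean trio is much larger. The functional form is
our own fixed, fully specified completion of the trio-likelihood scoring
idiom used by the common toolkits: confident child het plus confident
hom-ref parents scores near 1; any parental alt evidence drives it down
monotonically (a property the test suite checks against an exhaustive
nine-configuration enumeration).

The filter stack retains a candidate iff

* de novo score > 0.85 (exclusive),
* child depth > 10 (exclusive),
* alt-supporting reads < 2 in *each* parent (applied per parent — the
  stricter, unambiguous reading),
* joint allele count AC ≤ 1 (inclusive); this is the decisive filter
  that removes inherited variation and recurrent artifacts, and we use
  the per-alt AC after multiallelic decomposition,
* optional extra predicates (GQ floor, child allele-balance window),
  off by default.

Boundary semantics follow the inequality symbols exactly as printed
above; a depth of exactly 10 fails. Rejections are audited mutually
exclusively in threshold order (score, depth, parental reads, AC,
extras), so audit counts always sum to the candidate count. Non-
autosomal records are excluded by default (a flagged choice; the
analysis of sex chromosomes needs ploidy-aware genotypes we do not
model).

## Cluster assembly

DNMs of one offspring are sorted by chromosome and position and chained:
a DNM joins the open cluster iff its distance to the direct predecessor
is strictly less than the window (default 20 bp, matching the physical
range of ROS-induced damage; 10, 30, 10\,000 and 47\,000 bp are scanned
in the sensitivity analysis, each recomputed from scratch rather than by
splitting or merging). Runs of length 1 are discarded. A cluster of
more than two members may span more than one window. Distances are
differences of 1-based anchor positions; indels use their left-aligned
VCF POS (the convention is ours; nothing in the method depends on it
beyond consistency). Cluster assembly is order-invariant and idempotent,
and is tested against a brute-force maximal-run oracle.

Target masking (repeats, 36-mer mapability < 1.0) is evaluated per
member position against 0-based half-open BED intervals, not per cluster
span — the conservative reading of "overlaps a repeat"; a `by = "span"`
switch is provided. Masks are merged on load, and a 1-based point $p$
is inside $[s, e)$ iff $s < p \le e$.

## Phasing

Read evidence arrives as a pre-extracted table (one row per read per
DNM with the allele observed at a nearby informative site and the
parental genotypes there), keeping the module independent of alignment
machinery; the extraction contract is documented in `?phase_dnm` so a
BAM adapter can be added later. A read carrying the DNM alt allele
votes for the parent *uniquely* able to transmit the informative allele
it carries; sites transmissible by both or neither parent are ignored
and counted. A DNM is assigned an origin only on unanimous votes — the
conservative completion, since the cluster-level rule is the only one
the field fixes. Clusters inherit the origin of any phased member;
members phased to different parents make the cluster contradictory.
Origin ratios across cohorts are compared with a Pearson chi-squared
homogeneity test (no continuity correction, df = k − 1), with unknowns
excluded and a flag raised when expected cells drop below 1.

## Age matching

Cohorts differing in parental age cannot be compared on raw counts, so
subcohorts are selected by minimum-weight bipartite matching: the cost
of pairing two offspring is
$|f_{ref}-f_{other}| + |m_{ref}-m_{other}|$ in years (absolute
differences; the only sensible metric for an unsigned "age difference").
1:n matching is reduced to standard assignment by replicating each
reference node n times. The implementation delegates the assignment to
igraph's maximum-weight bipartite matching on transformed weights
$w = C_{max} - c + 1$, which preserves the optimum; optimality is
verified in the tests against exhaustive enumeration on small
instances. Inputs are sorted by sample id before graph construction so
runs are reproducible; among exactly tied optima the deterministic
solver order decides. Ages enter at stated precision, unbinned.

## Count models

All count outcomes use NB2 regression with log link: mean
$\mu_i = \exp(x_i^\top\beta)$, variance $\mu + \mu^2/\theta$, $\theta$
estimated by maximum likelihood (initialised from a Poisson fit, the
`MASS::glm.nb` behaviour), Wald 95% intervals
$\hat\beta \pm 1.96\,\mathrm{SE}$ — chosen because the symmetric
intervals reported in this literature are Wald-type. The Poisson limit
is reached as $\hat\theta \to \infty$ and is exercised in tests.

* **Paternal age effect**: `n_dnm ~ father_age`; reported as
  $100(e^{\hat\beta}-1)$ percent per year and as absolute DNMs/year at
  a reference mean. Paternal age serves as the single age covariate —
  parental ages correlate at about $r = 0.71$, so it proxies both;
  maternal age can be added for sensitivity.
* **Cohort contrasts**: `n_cdnm ~ cohort + father_age` against the
  control cohort reference level, with Bonferroni adjustment
  $p_{adj} = \min(1, m\,p_{nom})$, default $m = 9$ (the study-wide test
  count; a parameter because the full enumeration of the nine tests is
  not fixed by the method). The same machinery serves
  Exposed/Unexposed subgroup contrasts.
* **Dose response**: `n_cdnm ~ dose` on the exposed subgroup
  (dose > 0, missing doses dropped), reported as
  $f(n) = e^{\hat\beta_0} e^{\hat\beta n}$ per mGy with transformed
  Wald CI for the baseline.
* **Inverse model** (dose from count): a Gamma GLM with log link on the
  positive-dose subgroup — our choice of family; doses are positive,
  continuous and right-skewed, which the Gamma handles naturally.

Validation arithmetic uses the exact Clopper–Pearson interval through
the Beta quantile identity (cross-checked against `binom.test`).
Descriptive summaries report mean, sample SD, median, and the
PPV-adjusted mean (mean × PPV), rounded only at presentation.

**PPV robustness.** An imperfect positive predictive value is modelled
by binomial thinning: each offspring's cluster count $c$ is replaced by
a $\mathrm{Binomial}(c, \mathrm{PPV})$ draw and the contrast model is
refitted. Thinning at the count level (rather than relabelling
individual clusters) is the minimal faithful model of "each called
cluster is independently true with probability PPV"; it preserves
$E[\text{thinned}] = \mathrm{PPV}\cdot E[c]$, which the tests verify.
The summary is the fraction of replicates whose adjusted p-value stays
below the significance level; refit failures are counted, not fatal.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes:

* **Three cohorts** — a large control (`inova`-like) with fathers ~5 and
  mothers ~5.5 years older, and two exposed cohorts (`radar`-like,
  `cru`-like). Default desk-scale sizes are 120/60/60 offspring
  (the source design was 1275/110/130); sizes are per-cohort
  parameters.
* **Parental ages** from a bivariate normal with correlation 0.71 —
  only the observed correlation is fixed by the field, the copula is
  our choice.
* **Doses** as a point mass at 0 mGy plus an exponential tail: the
  radar-like cohort 70% unexposed with a 34 mGy tail (2.7% of dose
  estimates missing), the CRU-like cohort 10% unexposed with a 365 mGy
  tail. Exact distributions are unstated in the field; this mixture
  reproduces the zero-median/heavy-tail shape.
* **Isolated DNMs** per offspring: NB2 with mean
  $70\,e^{\log(1.02)(A-30)}$ (the ~2%/yr paternal-age effect around
  60–80 DNMs per generation) and dispersion 20 (chosen so the count SD
  at the mean matches the ~18 observed in such cohorts).
* **True clusters**: NB2 with mean
  $\mathrm{base}\cdot e^{5\times10^{-4}\,\mathrm{dose}}$ and dispersion
  1.5; **artifact clusters**: Poisson. The published per-offspring
  cluster means (0.88/1.48/2.65) describe *called* clusters, of which
  a PPV of 0.23 are true — the validated set is the full called set —
  so the defaults split each target mean into a true-cluster base rate
  (0.23 of it, deflated by the cohort's expected dose factor) and an
  artifact rate (0.77 of it). The generated PPV consequently converges
  to 0.23, which a test checks.
* **Cluster geometry**: member gaps uniform on $[1, w-1]$; sizes
  $2 + \mathrm{Poisson}(0.25)$; distinct events of one offspring are
  spaced ≥ 200 bp apart so the truth clusters are exactly what the
  window rule recovers. Cross-sample position collisions are resampled
  so the joint AC of each de novo record stays 1.
* **Origins** paternal with probability 2/3 — a configurable guess; no
  reliable population estimate of the paternal:maternal cluster ratio
  exists.
* **Fixtures**: each mutation becomes a clean joint-VCF record (child
  confidently het, parents confidently hom-ref, AC=1). Per offspring,
  spiked negatives each fail exactly one filter (borderline parental
  likelihood; child depth 8; a parent with 2 alt reads; an AC=2 site
  carried by an unrelated sample), plus inherited background hets —
  so filter recall and specificity are separately observable.
  Read-evidence rows exist for a true DNM iff its informative site
  lies within the cohort read length (100 bp control, 150 bp cases),
  reproducing the lower phaseable fraction of the short-read control
  cohort. Artifact clusters receive no phasing evidence and are placed
  inside the repeat mask with probability 0.6 (and the low-mapability
  mask with probability 0.2), mirroring the concentration of false
  calls in repetitive sequence.

What the generator does **not** emulate: read-level alignment artifacts
and device-specific error spectra, mutation-type composition (tandems,
indels, GG>TT classes), structural variation, mosaicism, and the
correlation structure of real genotype-likelihood errors. Passing
tests therefore demonstrate that the *pipeline logic and statistics*
behave as specified under the assumed generative model — not that the
filters would achieve the same operating point on real sequencing data.

## Numerical and degenerate-input choices

* Coordinates: VCF positions 1-based; BED masks 0-based half-open; all
  internal positions 1-based.
* Records missing a required FORMAT field are skipped and counted per
  field, never imputed; a pedigree sample missing from the VCF is a
  hard error.
* All-zero responses, rank-deficient designs, constant doses and
  too-small subgroups abort model fits with explicit errors; NB
  non-convergence is flagged on the fit object, never silently replaced.
* The thinning simulation tolerates `ppv = 0` as a degenerate case
  (every refit fails and is counted).
* Determinism: every stochastic stage takes a seed; the pipeline
  derives stage seeds from the config seed, and two runs with the same
  config produce byte-identical tables (tested).

## Problem sizes

The bundled pipeline configuration runs 20/12/12 offspring
(~3,500 joint-VCF records, ~100 samples) in well under a minute;
parameter-recovery checks use 500–2,000 offspring per fit and 20
replicate seeds, sizes at which the Wald CIs are narrow enough to be
informative while a full run of the test suite stays around a minute.
These sizes are the package's choice of demonstration scale; all of
them are parameters.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(cohorts = default_cohorts(40, 25, 25), seed = 7)
bundle <- run_pipeline(cfg, "cdnm_demo")
bundle$fits$cohort_contrast
bundle$descriptives$cdnm
```

## Known limitations

* The de novo posterior is a fixed trio model, not a re-implementation
  of any specific caller; concordance with other callers' scores is
  not guaranteed beyond the qualitative behaviour.
* The complete filter stack of production pipelines includes further
  heuristics; here they are optional predicates with documented
  defaults off.
* The inverse dose model's Gamma family is a modelling choice; with
  few exposed offspring its CIs are wide.
* Phasing consumes pre-extracted evidence; errors upstream of that
  table (alignment, informative-site selection) are out of scope.
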