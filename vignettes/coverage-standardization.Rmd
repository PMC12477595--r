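---
title: "Coverage-aware comparative metagenomics with npcstand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-aware comparative metagenomics with npcstand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shotgun metagenomes are random samples of a community's DNA, and two
metagenomes rarely capture the same fraction of their communities' genomic
diversity. That fraction — the *diversity coverage*, estimated here as
Nonpareil coverage (Npc) — is a biological quantity: at a fixed number of
reads it depends on the richness and evenness of the community. When
metagenomes of unequal Npc are compared, the comparison is silently biased
for any *multi-member feature* (a taxon aggregating several genomes, a gene
family aggregating several alleles): the relative abundance of each detected
member is stable across subsamples, but the *number of detected members*
grows with coverage, so the feature's aggregated abundance grows with
coverage too. Richness comparisons suffer the same way. npcstand packages
the machinery to demonstrate this effect on fully synthetic data and to
correct it by standardizing samples to a common Npc.

## The coverage model

Npc is estimated from read redundancy. For subsets of the read set of
increasing size $E$ (reads), a query read is called *redundant* iff at least
a fraction $L$ of its canonical $k$-mers (the lexicographic minimum of each
$k$-mer and its reverse complement) occurs elsewhere in the subset. The mean
redundancy $r(E)$ forms the redundancy curve, which is fitted as a gamma CDF
in log effort:

$$C(E) = F_\Gamma\!\big(\log(1+E);\ a, \theta\big),$$

with shape $a$ and scale $\theta$. This form is bounded in $[0,1]$,
nondecreasing, and exactly $0$ at $E = 0$ (the "+1" exists solely to pin
that endpoint). The estimated coverage of the full dataset is
$\mathrm{Npc} = C(R)$ at the total read count $R$, and the model inverts in
closed form: the effort needed for a target coverage $t$ is
$E(t) = \exp(F_\Gamma^{-1}(t; a, \theta)) - 1$.

Fitting is weighted nonlinear least squares (weights $1/\mathrm{sd}$ across
subset replicates where available): a multi-start grid of BFGS runs on
log-parameters ($a_0 \in \{0.5,1,2,4,8\}$, $\theta_0 \in \{0.1,0.3,1,3\}$;
ties broken toward the smaller shape) followed by a Levenberg–Marquardt
polish. Noiseless forward-generated curves are recovered to better than
$10^{-3}$ relative error; an all-zero curve is flagged degenerate rather
than fitted.

Key estimation parameters, all exposed in `redundancy_params()`:

* `k = 24` — canonical k-mer length. Chosen so that shared k-mers imply
  roughly species-level sequence identity; reads shorter than `k` or windows
  with non-ACGT characters contribute nothing and are counted as skipped.
* `min_shared_fraction = 0.5` — fraction of a read's k-mers that must occur
  elsewhere in the subset. With 150 bp reads and `k = 24` this corresponds
  to an overlapping read covering about 87 bp, i.e. a genuine local overlap.
* `subset_fractions` — 12 geometrically spaced subset sizes from 0.001 to 1,
  3 replicates each; `query_cap = 10000` queries per subset. These defaults
  trade precision for desk-scale runtime and can be raised for production
  use.

```{r}
library(npcstand)
rc <- redundancy_curve("reads.fastq.gz", redundancy_params(seed = 1))
model <- fit_npc(rc)
summary(model)
plot(model)
effort_for_npc(model, 0.9)   # reads needed for Npc = 0.9
```

## Standardization to a common Npc

`plan_for_target()` implements the analytic estimator in three steps: (1)
per sample, the read fraction needed for the target coverage is
$f = E(t)/R$, clipped to 1; (2) SD (sequencing depth in X), GEQ (genome
equivalents = total bp / average genome size) and read counts are multiplied
by $f$ (counts rounded half-to-even); (3) features whose rescaled depth
falls below `min_sd = 0.1` X are zeroed. Under the Lander–Waterman model the
expected breadth at 0.1X is $1 - e^{-0.1} \approx 9.5\%$, so the filter
corresponds to requiring roughly 10% coverage breadth.

Two consequences shape everything downstream. First, $f$ cancels in SD/GEQ,
so standardization never changes the relative abundance of a feature that
remains detected — it only changes *which* features are detected. Second,
detected sets are nested in the target coverage, so aggregated taxon
abundances are nondecreasing in Npc; that is exactly the mechanism that
biases unequal-coverage comparisons.

Targets cannot exceed any sample's achieved `npc_total`: a sample cannot be
up-sampled, and extrapolating the fitted curve beyond the observed effort
would report model speculation as data. A warning is emitted below Npc 0.3
(results there are unreliable) and a note below 0.6 (a commonly used
adequacy threshold). The manual route — actually subsampling reads without
replacement and recomputing depths — is available via `subsample_reads()`,
and `estimator_vs_oracle()` runs both routes and reports their agreement
(squared Pearson correlation and mean absolute relative deviation over
features detected by both).

## The maximum acceptable coverage difference

`delta_npc_max()` answers "how different may two samples' coverages be
before comparisons of this feature break?". Replicate samples are
standardized to a reference coverage (default 0.7); the target is then
lowered in steps of 0.01 and at each step the feature's aggregated SD/GEQ
across replicates is compared to the reference vector with a Welch
two-sample t-test. The first significant step (`p < alpha`, default 0.05)
is the break point; `delta_npc_max` is the distance from the reference, and
`delta_pct` its fraction of the reference. Features that never break are
censored at the grid floor (0.1, below which the model is typically
unreliable). Design choices made where the procedure was open:

* the reference abundance vector is computed once at the reference coverage
  and held fixed during the descent;
* the t-test is the unpaired Welch test (pooled-variance optional); no
  multiplicity correction is applied inside the sequential stop-at-first-
  significance loop — Benjamini–Hochberg is reserved for the group-wise
  differential-abundance tests;
* when both sides of the test are constant, equal means are treated as "not
  significant" (the step is skipped) and unequal means as an unambiguous
  difference;
* single-member features cannot be distorted by composition, only by
  detectability, so their break point is the lowest grid coverage at which
  the member stays at or above 0.1X in *every* replicate; a member
  undetected at the reference is flagged not comparable.

`fit_delta_vs_abundance()` regresses `delta_pct` on log10 mean abundance;
abundant features tolerate larger coverage differences, so the slope is
positive. `comparability_check()` wires the results into a decision rule:
all samples at Npc ≥ 0.9 → compare directly; otherwise compare the observed
ΔNpc with the feature's ΔNpc_max and either standardize to the lowest Npc or
proceed with caution.

## The synthetic-data generator

`sample_abundances()` draws species abundances from a log-normal model
(location μ on the natural-log scale, scale σ) and rescales them affinely in
log space so the max/min abundance ratio is hit exactly; the two standard
designs are μ = 2 with ratio 10,000 (uneven) and μ = 5 with ratio 500
(even). σ is not separately constrained by those designs; it defaults to 1
and matters little because the ratio rescale dominates realized evenness.
`make_genomes()` builds uniform-random genomes with within-species variants
at controlled pairwise identity (default band 95–99.5%, i.e. species-level
microdiversity); substitution positions are drawn disjointly across
variants, which makes every pairwise identity exact by construction.
`simulate_reads()` allocates reads by largest-remainder rounding of
`total_reads × abundance` (equal-length genomes make cell and read fractions
equivalent), places 150 bp reads uniformly on a uniformly chosen variant and
strand, and applies i.i.d. substitutions (default rate 0.001, an
Illumina-like error level). Labels carry 0-based half-open coordinates, and
identical seeds give byte-identical FASTQ.

What the generator does *not* emulate: indels, quality-score profiles,
GC-content and k-mer composition biases of real genomes, paired-end
fragments, strain-level gene content variation. Passing tests therefore
demonstrate the coverage arithmetic — detection thresholds, redundancy
scaling, standardization algebra — not sequencing-platform realism.

## Problem sizes used in the checks

The richness-ratio experiment uses two even communities (1000 vs 100
species, 5 kb genomes) at 320,000 and 40,000 reads — about 10X mean depth
each, enough for both to exceed Npc 0.9 so they can be standardized down to
0.9. Counting species with estimated SD ≥ 0.1X recovers the true 10-fold
richness ratio; at a low common sequencing effort of 500 reads — the scaled
analog of comparing such communities at a fixed, shallow read count, where
only the most abundant members clear the detection threshold — the observed
ordering inverts, illustrating why equal-effort comparisons mislead.
The estimator-versus-subsampling check uses a 30-species community at
100,000 reads standardized to the coverage reached at half its reads
(f = 0.5). The differential-abundance accuracy experiment contrasts even
(μ = 5, ratio 500) and uneven (μ = 2, ratio 10,000) 100-species communities,
three replicates each at 30,000 reads, aggregated into nine phyla, with
tests at Npc 0.3/0.5/0.7 scored against the full-data tests. 5 kb genomes
keep these designs fast; they make *detection* noisier than with
megabase-scale genomes (1X on 5 kb is only ~33 reads), which the tests
account for by asserting directional properties and scale-appropriate
tolerances.

## Known limitations

* The log-gamma parameterization is a declared modelling choice; other
  redundancy-curve parameterizations exist and will give slightly different
  Npc values, so comparisons should use one implementation consistently.
* GEQ is computed as total bp over (known or user-supplied) average genome
  size; marker-gene estimation of average genome size is out of scope.
* Read mapping is replaced by truth labels for simulated data; real data
  enter as externally computed feature tables (TSV).
* Standardization assumes SD, GEQ and counts scale linearly with the read
  fraction; at very low fractions GEQ may scale sublinearly in real data.
* ΔNpc_max depends on the (usually unknown) abundance distribution of a
  feature's members; it is a per-dataset diagnostic, not a universal cutoff.
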