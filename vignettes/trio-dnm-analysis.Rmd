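---
title: "Trio de novo mutation detection and rate estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio de novo mutation detection and rate estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodnm)
library(dplyr)
```

# The problem

A de novo mutation (DNM) is a variant carried by a child but absent from
both parents' germline genomes. In a sequenced father–mother–child trio it
shows up as a *Mendelian violation*: a trio genotype configuration that no
combination of inherited alleles can produce. Counting such events, and
dividing by how much of the genome could have revealed them, yields the
germline mutation rate per position per generation (PPPG) — a quantity of
order 10⁻⁸ in human exomes, meaning a typical trio contributes only a
handful of true events against a large background of genotyping error. The
entire design of this package follows from that asymmetry: strict filters on
the numerator, and a probabilistic correction of the denominator so the
filters do not bias the rate.

# Candidate detection

With genotypes coded `HomR` (homozygous reference), `Het`, `HomA`
(homozygous alternate), exactly three trio configurations are treated as
candidate DNMs:

1. child `Het`, both parents `HomR` — the child gained an alternate allele;
2. child `Het`, both parents `HomA` — the child gained a *reference* allele
   (a back-mutation relative to the parents);
3. child `HomR`, both parents `HomA`, indel allele — the "reversible" indel
   configuration, in which the parents carry a non-reference indel and the
   child reverts to the reference.

An exhaustive check over all 27 genotype triples (one of the acceptance
tests) confirms that these three are the only configurations the detector
fires on, and that the first two are the only ones possible for single
nucleotides. Configuration 2 is detected and reported under its own label
(`het_child_homalt_parents`): it is formally implied by the detection model
even though back-mutations at polymorphic sites are expected to be rare, and
keeping it separate lets users exclude it explicitly rather than silently.

Records with any missing member genotype are excluded from both detection
and the callable denominator (`drop_missing_records()`): a trio with an
uncallable member can neither show a violation nor have revealed one.

# Filters

Three thresholds, all overridable through `filter_thresholds()`:

| parameter | default | meaning |
|---|---|---|
| `min_gq` | 50 | phred-scaled genotype quality, inclusive (`>= 50`), every member |
| `min_depth_exclusive` | 20 reads | strict (`> 20`), every member |
| `ab_low`, `ab_high` | 0.3, 0.7 | allele-balance interval, endpoints inclusive |

The boundary semantics are deliberate and tested: GQ 49 fails and 50 passes;
depth 20 fails and 21 passes; allele balance exactly 0.30 or 0.70 passes.

The allele-balance rule needs one interpretive decision. Allele balance (the
fraction of reads carrying the alternate allele) is a heterozygote
diagnostic: somatic/mosaic artifacts sit below the interval, and a
heterozygous call with balanced reads sits inside it. But the filter is
meant to protect the *trio* call, and the most dangerous failure mode is a
parent called homozygous whose reads say otherwise — a parent labelled
`HomR` with 40% alternate reads is almost certainly a missed heterozygote,
which would turn an inherited variant into a fake DNM. We therefore apply
the interval to heterozygous members and the *complement* to homozygous
members: `HomR` members must fall below `ab_low` and `HomA` members above
`ab_high`. The child is always checked under whichever rule matches its
called genotype, including the `HomR` child of the reversible-indel
configuration. Members with zero informative reads skip the allele-balance
check (it is undefined); they are caught by the depth filter instead. The
first failing rule is recorded (`min_gq`, then `min_depth`, then
`allele_balance`) so filter attrition can be audited.

Manual inspection steps (genome-browser review, Sanger validation) are
intrinsically non-computational; the pipeline instead emits a per-candidate
evidence table (`candidate_evidence.tsv`) to support external review.

# The callable-site probability model

Counting filtered DNMs over raw genome positions would understate the rate,
because many positions could never have yielded a passing call. Each site
`j` in trio `i` therefore contributes a probability `P_ji` that a de novo
event there *would have been observed*:

* **Parental certainty.** Genotype posteriors are computed from each
  parent's reference/alternate read counts under a per-read error model
  with error probability ε: likelihoods `(1−ε)^r ε^a` for `HomR`,
  `0.5^(r+a)` for `Het`, `ε^r (1−ε)^a` for `HomA`, normalised with a
  uniform prior (the binomial coefficient cancels). The uniform prior keeps
  the posterior interpretable without population information; a
  Hardy–Weinberg prior would sharpen it where allele frequencies are known,
  but no frequency input is assumed here.
* **Child detectability.** `het_detection_probability(d)` enumerates all
  `d + 1` read outcomes of a true heterozygote (alternate reads
  `~ Binomial(d, 0.5)`) and sums the probability of those called `Het` by
  maximum likelihood with genotype quality ≥ `min_gq` and allele balance
  inside the interval. Genotype quality is the phred-scaled gap between the
  best and second-best genotype likelihood, capped at 99 — the same
  definition the simulator writes into its VCFs, so model and data agree.
  `homref_detection_probability()` is the analogue for the reversible-indel
  child (`alt reads ~ Binomial(d, ε)`, called `HomR`, balance below
  `ab_low`).

The per-site probabilities mirror the three configurations:

```
p_snv   = [P(M=HomR) P(F=HomR) + P(M=HomA) P(F=HomA)] · d_het(child depth)
p_indel =  P(M=HomA) P(F=HomA) · d_homref(child depth)
```

Sites where any member fails the strict depth filter contribute zero: the
"callable regardless of depth" reading of the denominator and the
"probability computed from coverage" reading are reconciled by letting the
probability itself vanish where the filters would have vetoed any call.
Both detection probabilities are exact finite sums — an independent
enumeration oracle in the test suite agrees to below 10⁻¹² for every depth
up to 60 — and are memoised over unique depths, since they depend on depth
only.

# The rate estimator and its interval

```
rate = Σᵢ nᵢ / ( 2 Σᵢ Σⱼ P_ji )
```

The factor 2 counts transmitted haplotypes: the simulator injects mutations
per transmitted haplotype at rate μ, and with perfect evidence (`P_ji = 1`)
the estimator recovers μ directly — across 100 seeded replicates of 20
trios × 10⁵ sites the relative bias is under 5% (acceptance test, and the
figure written by `scripts/acceptance.R`).

Confidence intervals are **Wilson score** intervals on
`(Σnᵢ, round(2ΣΣP))`. The method choice matters: for rare events (tens of
successes over ~10⁹ trials) the Wald interval is anti-conservative and
Clopper–Pearson is conservative, while the Wilson interval reproduces the
published bounds for this study design — 95 events at 2.74 × 10⁻⁸ give
(2.24, 3.35) × 10⁻⁸, and 3 events at 1.77 × 10⁻⁸ give
(0.60, 5.2) × 10⁻⁸ — which the acceptance suite checks at printed
precision (0.5% relative for the 3-event pair, whose trial count inherits
the rounding of the printed point estimate). Rounding the denominator to an
integer trial count is negligible at these magnitudes. The test suite also
cross-checks against an independent score-interval implementation
(`prop.test` without continuity correction) and verifies the Wald limit at
N = 10¹⁰.

Trios with anomalously many candidates (non-paternity, sample swaps,
contamination) are flagged — not excluded — by `flag_outlier_trios()`, which
puts a Poisson upper-tail threshold (default α = 10⁻⁶) around the expected
per-trio mean; exclusion is left to the analyst because the decisive
evidence (e.g. paternity testing) is external to the sequence data.

# The synthetic trio generator

`simulate_trio_dataset()` emulates a 48-trio exome study and is the
package's test bed. Defaults encode the study conditions the package
targets; the main knobs:

| parameter | default | rationale |
|---|---|---|
| `n_trios` | 48 | the target study's final trio count |
| `mean_depth` | 38.5 | the target study's mean exome depth (Poisson per sample-site) |
| `mu` | 2.74 × 10⁻⁸ | per haplotype-position per generation; the headline estimate |
| `n_sites` | 10⁴ | a contiguous exome slice; a full exome (~3.6 × 10⁷ callable sites/trio) is generated the same way but is not a sensible in-memory default |
| `error_rate` | 0.01 | typical post-filter per-read error; affects posterior sharpness only |
| `maf_alpha`, `maf_beta` | 0.5, 5 | Beta allele-frequency shape, skewed to rare variants as site-frequency spectra are |
| `ts_tv_weight` | 1.5 | odds of a transition alternate allele = expected de novo Ts/Tv |
| `indel_fraction` | 3/98 | indel share among de novo events (3 indels alongside 95 SNVs) |
| `feature_tracks` | 7 tracks, multipliers 1 | coverages loosely modelled on exome footprints of ENCODE-style annotations |

Generation proceeds per trio: Hardy–Weinberg parental genotypes at each
site's allele frequency; one transmitted allele per parent; each transmitted
haplotype mutates (ref→alt or alt→ref) with probability μ times the product
of feature multipliers at that site; read depth is Poisson, alternate reads
binomial at ε / 0.5 / 1−ε; genotypes are re-called by maximum likelihood
and GQ is the capped phred gap. `clean_evidence = TRUE` replaces the read
layer with noiseless evidence (fixed even depth, exact allele counts,
GQ 99) for tests that isolate the genotype-level logic, and
`simulate_dnm_counts()` draws only the per-trio mutation counts
(stratum-exact binomial sampling) for large replicate studies where
evidence is taken as perfect. An optional `mosaic_fraction` gives a portion
of truly `HomR` child sites a low-allele-balance read mixture, to exercise
the allele-balance filter against somatic-like artifacts; there is no
field-calibrated default, so it is off.

What the generator deliberately does **not** model: read-level artifacts
(mapping error, strand bias, indel realignment), linkage and recombination,
sex chromosomes (all simulated chromosomes are autosomal diploid), mutation
clustering, and parental mosaicism. Passing tests therefore demonstrate
correctness of the *estimators* under the stated sampling model, not
robustness to every artifact of real exome data — on real data the filters
confront error modes the simulator never produces.

Test and acceptance problem sizes (e.g. 100 replicates of 20 × 10⁵ for
recovery, 50 replicates of 10 × 10⁴ for enrichment, a few thousand sites
for end-to-end runs) are the package's chosen balance between Monte-Carlo
resolution and a test suite that stays pleasant to run; the tolerances
asserted are derived from the binomial sampling error at those sizes.

# Context models

Annotation is point-in-interval membership against BED tracks (0-based
half-open, converted once at the read boundary; a BED interval
`start end` contains 1-based position `pos` iff `start < pos ≤ end`), plus
a conservation flag `score > 12` — a score of exactly 12 is classified
non-conserved, since the convention defines only the two open half-lines —
and a per-position expression-specificity label. Stratified rates restrict
numerator and denominator to the same stratum, so a feature with rate
multiplier *m* is recovered as a ratio of stratified rates ≈ *m* (the
acceptance suite recovers a 3× open-chromatin enrichment within ±20% as a
median over 50 replicates).

The per-feature regression regresses each trio's DNM rate on that trio's
count of feature-carrying DNM positions — the only reading of
"positions with each parameter" that is observable per trio — via ordinary
least squares (`lm()`), reporting β ± SE, the two-sided t-test on the
slope, and R². A flat response returns slope 0 with R² 0 rather than the
undefined 0/0. Published per-feature coefficients from the real study are
not reproduction targets: they depend on the underlying restricted-access
exomes. Parental-age correlations are Pearson tests of per-trio counts
against each parent's age; a configurable log-linear paternal-age effect in
the simulator lets the sign-recovery property be tested.

# Impact aggregation

Ten categorical predictors are counted per DNM; `unknown` calls never count
as damaging. Two selection rules: at least 6 damaging/probably-damaging
votes, or at least half of the *informative* (non-unknown) predictors —
computing "half" over informative tools is a choice, made because treating
absent predictions as denominators would punish DNMs that simply lack
annotations. A conservation score is listed alongside these tools in some
annotation pipelines but is not a damaging/tolerated caller; it is supported
as an optional extra vote (`score > 2`), default off, so the ten categorical
tools alone decide by default. Call vocabularies are normalised through an
editable mapping table (`default_call_mapping()`).

# Concordance and reporting conventions

Call sets are compared on (trio, chromosome, position, ref, alt) after
left-aligning indel representations (trim shared suffix, then shared prefix,
advancing the position), which removes representation-dependent mismatches.
Because published overlap percentages do not always state their denominator,
`concordance()` reports the shared count under every normalisation (Jaccard,
percent of union, percent of each set). Similarly `per_person_mean()` is a
plain division — callers choosing truncation or a different trio denominator
can apply their own convention to the returned value.

# Known limitations

* The genotype model is biallelic per record; multiallelic VCF rows are
  decomposed per alternate allele, which double-counts depth across the
  resulting records at truly triallelic sites.
* `P_ji` treats members independently; correlated errors (shared mapping
  artifacts) violate that and would inflate the denominator on real data.
* The paternal-age model in the simulator is a convenience for sign-recovery
  testing, not a calibrated mutational model.
* The pipeline's `context` stage fits regressions on simulated data whose
  per-trio feature counts may be nearly constant at demo scale; degenerate
  fits are reported as `NA` rows rather than errors.
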