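---
title: "Methods: case-control association on a hemizygous region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association on a hemizygous region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiassoc)
```

## The problem

Carriers of a large hemizygous deletion — the motivating case is the 3 Mb
22q11.2 deletion of velo-cardio-facial syndrome (VCFS) — retain a single
allele over the deleted interval. Any variant on that remaining allele is
fully exposed: there is no second copy to mask a recessive or
loss-of-function allele. A natural hypothesis for the incomplete
penetrance of the deletion's neuropsychiatric phenotype is therefore that
risk variants on the *non-deleted* allele modify outcome. Testing it
amounts to a case-control comparison (affected vs unaffected deletion
carriers) of the variants each sample exposes on its remaining allele.

Hemizygosity simplifies the statistics considerably. Each sample
contributes exactly one allele per locus, so "genotype" collapses to a
binary carrier indicator, every tested unit reduces to a 2x2 table of
carrier status by diagnostic group, and Fisher's exact test is the
uniformly applicable engine:

|          | carrier | non-carrier |
|----------|---------|-------------|
| case     | a       | b           |
| control  | c       | d           |

`hemiassoc` implements this design end to end: retention filtering of the
call set, three association families (per-variant, per-gene burden,
variant-centred sliding windows), a per-nucleotide coverage-based CNV
test, simulation-based power analysis, and a synthetic-cohort generator
that makes the whole pipeline testable without access to patient-level
sequence data (which, for the motivating study, was never deposited).

## The exact test

`fisher_exact()` computes the classical conditional two-sided p-value:
with both margins fixed, the probability of every table at most as
probable as the observed one (probability-ordering convention, identical
to `stats::fisher.test`; ties are compared with a 1e-7 relative guard
against floating-point noise). The reported odds ratio is the sample
estimate `ad/bc`, with 0.5 added to every cell only when some cell is
zero (Haldane-Anscombe) and only for the odds ratio — never for the
p-value. Because all units in a family share the margins
(n cases, n controls), the implementation precomputes the full
`(n_case+1) x (n_control+1)` p-value grid once per family; a scan over
thousands of variants then costs a table lookup per unit. The test suite
verifies the p-values against an independent binomial-coefficient
enumeration for every margin configuration up to 60 per group, at 1e-12.

## Retention filters

`filter_variants()` retains a call iff all three hold:

* caller quality score at or above the caller-specific cutoff —
  defaults 50 for SNVs and 600 for indels, both inclusive, dispatched on
  the `CALLER` INFO key with a fallback to allele-length inference;
* population (database) allele frequency at or below 0.30, inclusive.
  The ceiling excludes common polymorphism while keeping everything
  rare; variants *absent* from the population annotation are retained,
  since novel variants are precisely the hypothesis class (each such
  decision is recorded in the per-variant audit log);
* at least 2 carriers in the dataset — dataset-singletons cannot
  replicate within the cohort and are removed.

Filtering is idempotent, order-independent and monotone in each
threshold; all three properties are tested. Genotype dialects are
normalized at parse time: callers run in default diploid mode on a
hemizygous region emit `1/1` or `0/1`, which are collapsed to "carrier",
and `./.` to non-carrier. Multi-allelic records are split into one unit
per ALT allele with carrier attribution by allele index. How the original
study handled multi-allelic sites and missing database frequencies is not
documented; both choices here are explicit package decisions.

## The three association families

**Variant family.** One exact test per retained variant. The Bonferroni
threshold is `alpha/m` for `m` retained variants; because such cutoffs
are conventionally quoted as powers of ten, results carry both the exact
threshold and its order of magnitude (`1e-5` for m near 4,000-5,000 at
alpha 0.05). Benjamini-Hochberg q-values are reported for reference but
never drive the significance flag: Bonferroni is the stated correction.

**Gene burden family.** `classify_variants()` assigns each (variant,
gene) pair one class against gene models loaded from GFF3: `coding`
(inside a CDS interval), `splice_site` (within 6 nt of an exon boundary
on the intronic side, at either end of an *internal* intron — transcript
ends are not splice sites; the definition is strand-symmetric), or
`other`. Coding takes precedence where a splice window touches a CDS
edge, so each pair has exactly one class. Without transcript sequence
there is no synonymous/missense distinction: every CDS-overlapping
variant counts. A sample is a gene's burden carrier iff it carries at
least one coding or splice-site variant of that gene — a union, never a
sum. The family threshold divides alpha by the number of *loaded* gene
models (73 by default here), counting genes with no qualifying variants,
which are reported untestable with p = 1. Indels are classified by their
leftmost base (VCF left-alignment convention).

**Window family.** For each window size w (1, 5, 10 kb by default) and
each retained variant, the unit is the length-w interval centred on the
variant; a sample is a burden carrier iff it carries any retained variant
within w/2 of the centre. Anchoring windows on variants makes the number
of windows equal the number of variants for every size — the only
reading under which "corrected for the number of windows (= number of
variants)" is arithmetically true — and each size forms its own
Bonferroni family. Whether the three sizes should instead be corrected
jointly is unstated in the motivating design; per-size correction is
implemented and the choice is visible in the output (`family` column).

`run_association_suite()` runs all three, emits a per-position
`-log10(p)` track (BED for browser display) and supports the sensitivity
analysis of dropping controls younger than a cutoff (controls may not yet
have passed the phenotype's risk window; cases are never dropped, and the
retained variant set is kept fixed for comparability of the two runs).

## The coverage-based CNV test

Per sample, normalized coverage at a nucleotide is reads overlapping the
nucleotide divided by the sample's total read count. When genome-wide
totals are unavailable the track sum is used, which preserves the scale
invariance that matters (multiplying any sample's depths and total by a
constant changes nothing downstream) but slightly attenuates contrasts
when an event occupies a large fraction of the track — another reason the
default depth window pads an injected event by three times its length.

The exact test needs a dichotomy, and the motivating description (a
Fisher test "independently for each nucleotide" on normalized coverage)
does not say how the continuous value was discretized; the reconstruction
here is therefore explicit and fully parameterized. At each position the
cross-sample median is the reference; a sample is `loss` strictly below
`loss_ratio x reference` and `gain` strictly above
`gain_ratio x reference` (defaults 0.5/1.5, the standard single-copy
heuristics: a complete loss of the remaining copy sits near ratio 0, far
below 0.5). Two practical caveats, both visible in the tests:

* an *attenuated* event of expected fold f sits exactly on a threshold
  equal to f and is flagged at chance level; the decision boundary for a
  directed scan should sit midway between states,
  `loss_ratio = (1+f)/2` (0.75 for a half-depth event);
* when a large fraction of one group carries the same event the
  positional median slides toward the carriers, and samples on the other
  side acquire spurious opposite-direction flags; `position_association()`
  therefore accepts `direction = "loss"`/`"gain"` to restrict the
  aberrant class during a directed scan. The default (`"both"`) is the
  neutral two-sided definition.

Positions with zero reference or with under 80% of samples covered
(capture gaps) are skipped and logged. Per position, aberrant-vs-normal
by group feeds the exact test with threshold `alpha / positions tested`;
runs of adjacent significant positions are merged into intervals (BED
output). An ingestion hook (`external_cnv_association()`) applies the
same carrier test to per-sample CNV calls from an external read-depth
caller supplied as BED, replacing any re-implementation of such callers.

## Power analysis

With carrier probability `p0` in controls, an odds ratio `OR` implies the
case carrier probability

p1 = OR * p0 / (1 - p0 + OR * p0),

(`case_carrier_freq()`, verified against the odds identity at 1e-12).
`simulate_power()` draws case carriers ~ Binomial(n_case, p1) and control
carriers ~ Binomial(n_control, p0) per replicate and counts two-sided
rejections at alpha — the hemizygous design makes the "one individual,
one allele" binomial sampling exact, and coincides with the classical
two-proportion Fisher power simulation. `exact_power()` is the
deterministic companion (full binomial-grid enumeration), used as the
noise-free reference in tests. `min_detectable_or()` bisects the OR axis
with common random numbers — one fixed set of per-individual uniforms
thresholded at each candidate p1 — so estimated power is exactly monotone
in OR and the bisection is well defined; it reports the bracketing
interval. The per-test alpha for the headline design is 0.05 (the
per-variant, uncorrected scale on which such power statements are made),
with any other alpha accepted.

Two numerical notes, both established by the deterministic enumeration
and asserted in the tests. First, at the motivating design (p0 = 0.01,
OR = 22, 40 vs 48, alpha = 0.05) the exact power is 0.848; the
often-quoted round "80% to detect OR of 22 or more" is the conservative
reading of the curve, whose 80% crossing sits near OR = 20 — comfortably
inside the [18, 26] bracket the package's minimum-detectable-OR check
uses. Second, a 30% vs 1% prevalence contrast is a 30-fold *risk* ratio;
the corresponding odds ratio is (0.30/0.70)/(0.01/0.99), about 42.4. The
two scales are often conflated in prose; `risk_ratio()` and
`odds_ratio_from_props()` keep them apart.

## The synthetic cohort generator

`cohort_config()` defaults *are* the emulated study conditions: 40 cases
vs 48 controls over chr22:18,400,394-22,600,038, a background rate
targeting ~4,600 variants per sample, manifest ages ~ Normal(22.2, 6.0)
truncated at 15 for controls (the study's control inclusion minimum), and
quality-score distributions straddling the 50/600 cutoffs so the quality
filter is genuinely exercised.

The site-frequency spectrum of the motivating cohort was never published,
so the default mixture is a modeling choice, calibrated once against the
two dataset-level observables that *were* published: the per-sample yield
(~4,600) and the dataset-wide retained count after all filters (~4,200,
which also pins the variant family's order-of-magnitude threshold at
1e-5). Those two jointly require a spectrum whose per-sample yield is
dominated by common polymorphism that the frequency filter then removes:
70% "rare" loci with population AF uniform on (0.0005, 0.010) and 30%
"common" on (0.05, 0.95), with mass on both sides of the 0.30 ceiling. A
configurable 10% of loci are forced dataset-singletons (the singleton
filter's target), 5% lack the population-AF annotation (novel variants),
and 10% are emitted as indels with the indel quality scale. Carrier
status is independent across loci and samples at the locus AF.

An injected risk variant gets carrier probability p0 in controls and
`case_carrier_freq(p0, OR)` in cases. Injected CNVs multiply read depth
by a fold over an interval in a configurable fraction of cases. Baseline
depth is negative-binomial with mean 50 and size 200 (variance/mean
about 1.25): mild extra-Poisson noise that keeps essentially every base
at or above the 20x floor characteristic of targeted capture data.
Per-base tracks for 88 samples over the full 4.2 Mb region are supported
but bulky, so tracks default to the injected interval padded by three
times its length (or the region's first 20 kb); the analysis is
windowed and scales linearly.

What the generator deliberately does **not** model: linkage
disequilibrium between background loci, positional capture bias and
capture gaps, alignment artifacts, raw reads. Consequently, passing tests
demonstrate the statistical machinery — error control, calibration,
recovery of injected signals — under idealized independence, not
robustness to the correlated structure of real capture data. All
randomness flows from one master seed through deterministic per-stage
substreams, so every artifact is byte-reproducible.

## Problem sizes used by the checks

The package's own verification runs use: 20,000 Monte-Carlo replicates
for power estimates (MC s.e. about 0.0028 at power 0.8); 200 null
full-design cohorts for the family-wise error check of the three
association families (bound 0.05 plus two binomial standard errors), with
the CNV family's null behaviour checked on 5 independent depth
simulations; 50 seeded cohorts for the OR = 60 risk-variant recovery
rate; one 5 kb half-depth CNV carried by all cases for interval recovery
(calling with the midpoint boundary 0.75, direction-restricted, as
derived above); and the exhaustive exact-test cross-check over all margin
configurations up to 60 per group. Unit fixtures run on a 100 kb
sub-region with proportional variant yield.

## Known limitations

* The coverage dichotomy is a reconstruction; the motivating study's
  actual discretization is undocumented, and all CNV outputs should be
  read with that caveat.
* The positional-median reference degrades as the carrier fraction of a
  shared event approaches half the cohort (see above); the direction
  restriction mitigates but does not remove this.
* Burden tests are dominance-coded by design (carrier yes/no); allele
  counts would be meaningless with one allele per sample, but this also
  means recurrent carriers contribute no extra weight.
* Bonferroni across heavily overlapping windows is conservative; the
  per-size families are not independent and no attempt is made to model
  their correlation.
* Power statements are for a single variant at per-test alpha; the
  design is underpowered for multi-variant architectures of small
  effects, and no burden/window power calculation is provided.
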