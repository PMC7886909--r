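---
title: "Methods: immune-monitoring analytics in tilmonitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-monitoring analytics in tilmonitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilmonitor)
```

`tilmonitor` implements the correlative analyses of a neoadjuvant
immunotherapy trial — sorted-subset TCRβ repertoire statistics, a composite
CD8 TIL activation index, a somatic-variant-to-neoepitope chain, multiplex-IHC
and ELISpot quantification rules, and survival endpoints — plus a synthetic
cohort generator that plants known structure so each stage can be validated
end to end. This vignette documents the models, defaults, numerical choices
and limitations.

## Repertoire metrics

A repertoire is a table of unique TCRβ rearrangements with template counts.
Two identity keys are available: the nucleotide CDR3 (`cdr3_nt`, the default,
appropriate for clone tracking since independent rearrangements rarely
collide at the nucleotide level) and the amino-acid CDR3 (`cdr3_aa`, for
convergence-style analyses). Non-productive rearrangements (out-of-frame or
containing stop codons) carry no receptor and are removed by
`filter_productive()` before any statistic; frequencies are always recomputed
from counts after filtering — stored frequencies are never trusted.

**Clonality** is the complement of Pielou evenness,
$C = 1 - H/\ln R$ with $H = -\sum_i p_i \ln p_i$ over the $R$ unique
rearrangements. This normalization maps any repertoire onto $[0,1]$ with 1
for a monoclonal population and values near 0 for diverse polyclonal ones,
matching how clonality scores are read in repertoire studies. The
single-clone case is defined as $C = 1$ (the monoclonal limit of the $0/0$
expression). Clonality is invariant to clone relabeling and strictly
increases when mass moves from a rarer to a more common clone; both
properties are tested on random perturbations.

**Morisita–Horn overlap** between count vectors $x$ and $y$ is
$MH = 2\sum_i x_i y_i \,/\, ((d_x + d_y)XY)$ with $X=\sum x_i$,
$d_x = \sum x_i^2/X^2$ (likewise $y$). It is symmetric, invariant to uniform
scaling of either repertoire, 0 for disjoint clone sets and 1 for identical
relative abundances. Floating-point excursions beyond $[0,1]$ are clamped
within $10^{-12}$. Whether overlap should be computed on all clones or only
the top 30 is genuinely open in this kind of analysis; both are supported via
`top_n`, and all clones is the default because truncation discards exactly
the low-frequency mass that distinguishes "shared but rare" from "absent".
Tests cross-check both metrics against independent single-pass oracle
implementations (tolerance $10^{-12}$) and against
`vegan::vegdist(method = "horn")`.

**Top-N and tracking.** `top_n_clones()` sorts by count descending with ties
broken lexicographically on `cdr3_nt`, making results identical across
platforms. `track_clones()` reports, for the top-N clones of a reference
sample (e.g. DOS DP TIL), the frequency in each comparator (0 when absent)
and the shared-clone count — the "how many tumor clones were already in
blood" question. `call_reactive_clones()` uses a *strict* frequency cutoff
(default 2%): a uniform 50-clone repertoire at exactly 2% each yields no
calls, by design.

## The CD8 TIL activation index

Three baseline→day-of-surgery (DOS) fold changes summarise CD8 TIL
activation: %CD8 among T cells, %CD103⁺CD39⁺ (DP) among CD8, and %Ki-67⁺
among DP. The exact published combination of the three categories is not
fully specified in the available text, so the rule is configurable and the
default is the most conservative reading: the index is their geometric mean
(symmetric in the components, scale-consistent — multiplying all three fold
changes by $k$ multiplies the index by $k$) and a responder must have index
> 1 **and** every component > 1, i.e. a concordant increase in all three
categories. `rule = "geom_only"` thresholds the composite alone; the
threshold itself is adjustable.

Percentages live on the 0–100 scale throughout (matching flow-cytometry
axes); 0–1 proportions are reserved for clone frequencies. Fold changes use a
detection floor (default 0.01 percentage points): $FC = \max(post, f)/\max(pre,
f)$, which keeps ratios finite when a subset is undetectable at one timepoint
and flags the event (`floored`) instead of dropping the patient. Without
flooring, $FC(a,b)\cdot FC(b,a) = 1$ exactly.

`timecourse_summary()` computes each patient's fold change versus their own
baseline per subset and timepoint, then means, SDs and the peak timepoint per
subset — used to locate the peak of peripheral proliferation.

## Neoepitope candidate chain

The variant filters follow standard somatic-calling practice for
FFPE exome data: tumor depth > 10 reads (strict), normal depth > 10 (strict),
tumor VAF ≥ 10% (inclusive), and tumor/normal VAF ratio ≥ 5. The ratio
criterion with a normal VAF of exactly 0 *passes* by definition — the only
reading under which germline-clean variants (infinite ratio) survive; it is
overridable. Caller concordance requires ≥ 2 of the four supported callers
(mutect, somaticsniper, strelka, varscan). The depth/VAF and caller filters
commute, which is tested. Every rejection lists all violated criteria.

Windows are built by taking up to 12 residues either side of the mutated
position (25-mer when possible) and substituting the alternate residue.
Centering maximises the number of 8–11mers that can span the mutation;
truncation at the protein termini shortens the window but never drops the
mutated residue. Only single amino-acid substitutions are in scope —
indels/frameshifts are rejected with an explicit message, because a
substitution-centred window is not defined for them.

`enumerate_peptides()` emits all distinct 8–11mer substrings covering the
mutated index, deduplicated on sequence in deterministic (start, length)
order: a centred mutation in a full 25-mer gives exactly 8+9+10+11 = 38
peptides; a mutation at a window edge gives 4 (one per length). Transcript
prioritization flags candidates with FPKM strictly above 100.

Binding prediction is deliberately *not* implemented: `rank_candidates()`
takes any vectorized peptide→score function and keeps candidates with at
least one peptide scoring ≤ cutoff (inclusive). The default cutoff 0.5 is
unit-agnostic — it applies to whatever scale the plugged-in predictor emits
(nM affinity or percentile rank; a 0.5 nM affinity cutoff and a 0.5% rank
cutoff are both in use in the field and the package asserts neither). A
deterministic hash-based stub scorer ships for tests and dry runs; it
carries no biology.

## Tissue and ELISpot rules

ROI aggregation averages cell densities (cells/mm², from six 0.36 mm² ROIs
per section) per patient × timepoint × compartment × phenotype. When fewer
than six ROIs exist the mean is over the available ones with `n_roi`
reported — densities are per-area, so a missing image is missing data, not
zero cells. `counts_to_density()` converts raw per-ROI counts. Tumor-vs-stroma
contrasts reuse the floored fold-change contract. Flow–IHC concordance is an
OLS fit of IHC density on flow percentage with $R^2$ the squared Pearson
correlation (undefined — an error, not 0 — when either vector has zero
variance; per-patient means are the intended input, one point per patient).

ELISpot positivity is the strict rule: > 100 spot-forming cells per well
(at the conventional 10⁵ cells/well plating). Background subtraction is not
applied by default because the positivity rule is stated on raw counts; an
optional `mock_sfc` argument subtracts a matched negative-control well first.

## Survival endpoints

Kaplan–Meier estimation, the Mantel–Cox log-rank test and reverse-KM median
follow-up are standard statistics, so they are delegated to the `survival`
package behind this package's interface; the tests validate them against
hand product-limit and observed-minus-expected arithmetic computed
independently. Conventions: events precede censorings at tied times
(censored subjects count as at risk for that event); survival times are
months from the day of surgery, asserted non-negative by the loader;
confidence intervals use the Greenwood variance with a log–log transform.
Reverse KM flips the censoring indicator so the curve describes follow-up;
the median is the smallest time with $S(t) \le 0.5$, and a curve that never
reaches 0.5 signals an explicit undefined-median condition rather than
returning a number.

## The synthetic cohort generator

The generator's role is to emulate the *statistical structure* the analyses
assume, with known ground truth, at configured effect sizes:

- **Clone abundance** is a discrete power law over ranks
  ($p_i \propto i^{-\alpha}$, default $\alpha = 2$) sampled multinomially at
  the configured depth — the simplest heavy-tailed model consistent with top
  clones dominating sorted tumor-resident subsets. Defaults
  (`repertoire_config()`): 1000 clones, depth $10^5$, 5% non-productive.
- **Planted sharing**: blood, draining lymph node, DN and SP draw
  `shared_pool_fraction` (default 0.8) of their mass from one shared clone
  pool with a common rank assignment, so bystander subsets overlap strongly;
  DP places `dp_private_fraction` (default 0.95) of its mass on private
  clones, reproducing the "tumor-reactive subset with a unique repertoire"
  pattern. The expected overlap ordering MH(DN,SP) > MH(DP,DN), MH(DP,SP) is
  verified over 20 seeds.
- **Flow cohort** (`cohort_config()`): responders (fraction 0.25, the
  observed responder rate in this trial setting) receive multiplicative
  lifts — 3.4-fold on %DP of CD8 and on %Ki-67 of DP, 2-fold ("modest") on
  %CD8 — relative to uniform baselines; non-responders receive fold 1. Noise
  is a single unbiased lognormal multiplier per fold-change component with
  coefficient of variation `noise_cv` (default 0.2, a modelling choice — no
  dispersion is published for these fold changes): sdlog
  $=\sqrt{\ln(1+cv^2)}$, meanlog $=-\mathrm{sdlog}^2/2$ so the expected fold
  equals the configured lift. The time-course generator plants peripheral
  proliferation peaks at D12 (6.8-fold CD4 Ki-67, 5-fold CD8, 10-fold
  plasmablasts) decaying by D34–D55.
- **Variants**: exactly `round(n × pass_fraction)` records satisfy every
  filter; the rest violate 1–3 named criteria, recorded in a sidecar truth
  table, with contexts of length 15–80 so terminal truncation is exercised.
- **Survival**: exponential event times per group (non-responders at
  `base_hazard` = 0.02/month; responders at `base_hazard × hazard_ratio`,
  with 0 allowed for an event-free group) under independent exponential
  censoring — analytically tractable, so KM at the distribution median can
  be checked against 0.5.
- **ROI / ELISpot fixtures** plant stroma CD3 > tumor CD3, a
  responder-restricted 3.4-fold post-treatment rise of proliferating
  CD103⁺CD8⁺ cells confined to tumor (stroma ≈ 1.12), and a DP-restricted
  ELISpot response.

Ground-truth labels always live in sidecar tables, never in the measurement
files, keeping the analysis blind. All generators run under
`withr::with_seed`, so identical configs and seeds reproduce outputs exactly
and global RNG state is untouched.

What the generator does **not** emulate: raw flow events or gating,
sequencing reads and their error modes, PCR amplification bias in template
counts, batch effects, correlated assay noise across panels, image pixels,
or non-exponential survival shapes. Passing tests therefore demonstrate the
*computations* are correct under the assumed structure, not that the assumed
structure captures all features of real trial data.

## Pipeline and determinism

`write_cohort_fixtures()` materializes a complete toy cohort directory;
`run_cohort_analysis()` (config as YAML or list, unknown keys rejected) runs
every stage with configured inputs and writes per-stage CSVs, `summary.json`,
a plain-text report and a run log with the resolved config and an MD5
checksum of every input file. Outputs contain no timestamps and numbers are
serialized at fixed precision, so a rerun with the same config and inputs is
byte-identical — tested end to end.

## Problem sizes and verification

The test-suite scales were chosen to make each property decisive while
keeping the suite quick: 100 random repertoires for the metric-vs-oracle
comparisons (tolerance $10^{-12}$), 50 random protein contexts for the
peptide-enumeration oracle, 100 generated variants for filter fidelity,
200-patient cohorts for responder recovery (100% at zero noise, ≥ 90%
at cv 0.2), 500 subjects/group for the planted hazard-ratio detection
(log-rank p < 0.001 at HR 3), and 20 seeds for the overlap-ordering
property. `scripts/acceptance.R` recomputes all of these from scratch at any
seed.

## Known limitations

- Clone identity ignores V/D/J gene segments; two rearrangements with
  identical CDR3 nucleotide sequence but different V genes would merge.
- The activation-index rule is a documented default, not a published
  formula; conclusions sensitive to the gate should be re-run under
  `geom_only`.
- The binding-scorer stub makes pipeline output runnable but biologically
  meaningless; real use requires an external predictor behind the scorer
  interface.
- Only single amino-acid substitutions generate windows; frameshift-derived
  neoantigens are out of scope.
- Survival helpers cover two-group comparisons; no Cox regression or
  competing risks.
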