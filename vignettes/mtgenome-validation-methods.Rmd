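---
title: "Methods: threshold-based whole-mtGenome haplotyping, QC and mixture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based whole-mtGenome haplotyping, QC and mixture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovalr)
```

## The problem

Forensic mitochondrial DNA analysis reports a *haplotype*: the list of
differences between a sample's mtGenome and the revised Cambridge Reference
Sequence (rCRS), a 16,569-nt circle. Short-amplicon massively parallel
sequencing (MPS) panels tile the whole circle with ~160-bp amplicons in two
PCR pools, producing per-position read counts from which variants are
called by simple frequency thresholds rather than by a probabilistic
genotyper. The quantitative read counts also enable analyses that
electrophoretic sequencing could not support: detecting two-person mixtures
by counting positions with two allele states, and splitting the
contributors by allele frequency.

This package implements that analysis chain — circular coordinates, pileup
primitives, threshold calling, run QC, replicate concordance, NUMT
flagging, and mixture deconvolution — together with a seedable synthetic
pileup generator that reproduces the statistical structure the analyses
assume, so the whole chain can be exercised and tested end to end without
sequencing data.

## Coordinates and nomenclature

All positions are 1-based on the circle. For work spanning the origin the
reference is extended by repeating its first 80 nucleotides after the last
position ("circularized" axis); `canonical_position()` folds extended
positions back. Variants are rendered in the field's difference-coded
style: `263G` (substitution), `11562R` (point heteroplasmy, two-base IUPAC
code), `309.1C` (first inserted base after position 309), `16193del`, and
`8943N` for a position deliberately left uninterpreted. Indels in
homopolymer tracts are right-aligned (3'-most tract position), which is how
the familiar control-region names arise.

## The calling model

Calling is purely threshold-based on the per-position stranded counts; no
error model or quality recalibration is applied. With total depth $D$ at a
position (spanning reads over A/C/G/T/deletion; insertion-carrying reads
are a subset of these and are never double-counted):

* a non-reference base at frequency $\ge 1 - t_{php}$ is a substitution;
* at $t_{php} \le f < 1 - t_{php}$ it is a point heteroplasmy, coded by
  the two most frequent alleles (a third allele above threshold adds a
  multi-allele flag);
* deletion-supporting reads at $\ge t_{del}$ of $D$ give a deletion;
* pooled insertion reads at $\ge t_{ins}$ of $D$ give an insertion named
  by the *dominant* inserted sequence — the inserted run with the most
  insertion reads, whose dominant fraction is taken over insertion reads
  only. Ties go to the lexicographically smaller run and are flagged,
  never silently resolved.

Defaults are $t_{php} = 10\%$, $t_{ins} = 30\%$, $t_{del} = 40\%$, with a
20X minimum depth below which positions enter the coverage mask and are
excluded from interpretation. **All thresholds are inclusive** — a minor
allele at exactly 10% is called. This matters at the mixture-detection
boundary: a 9:1 mixture puts the minor contributor at exactly 10% of reads
and must still be detected, while 10:1 (9.09%) must not be.

Strand bias for an allele is $1 - \min(f,r)/\max(f,r)$ over its supporting
reads. Calls exceeding the review bound (default 0.89) are flagged
`status = "review"` rather than suppressed: automated suppression of
strand-biased calls is known to discard true variants that an analyst
would rescue, so suppression is never silent here. The bound itself is a
configurable choice — commercial software has suppressed calls at 0.97
while labelling anything above 0.89 "extreme" — and we default to the
stricter 0.89. Whether bias should be computed from allele-supporting
reads or from all reads at the position is not settled in practice; both
are exposed (`mode = "allele"` is the default, being the stricter and more
informative).

Two further post-filters mirror analyst practice. Deletions at the 3' ends
of the long HVI/HVII C-stretches (`309del`, `315del`, `16193del` by
default) recur as false positives above the 40% threshold and are resolved
by external concordance, not by any computable rule, so
`apply_suspect_deletions()` marks them `suppressed_suspect` — excluded
from exports, retained for audit. `flag_nav()` re-labels heteroplasmies
whose minor allele matches a catalogued nuclear-insert (NUMT) allele as
`posN`: such calls cannot be distinguished from co-amplified nuclear reads
at pileup level. A catalogued allele that is the *dominant* allele
(≥ 90%) is a real variant and is never flagged.

## QC and contamination metrics

* **Amplicon balance**: each amplicon's median depth over its span divided
  by the median of all amplicons' medians (1.0 = balanced). Even-length
  spans use the mean of the two middle values; overlap positions count for
  both amplicons, since apportioning them would need read-level data.
  "Median of all amplicons" is interpreted as the median of per-amplicon
  medians, which reproduces the worked 100X/150X = 0.67 ratio.
* **Coverage breadth**: fraction of all 16,569 positions at or above the
  depth minimum.
* **Relative read depth**: a negative control's depth as a percentage of a
  paired positive's depth per position (50X/2000X = 2.5%). Positions where
  the positive has no reads are *undefined*, never 0 or infinite.
  `contamination_summary()` averages this over negatives, reports the
  fraction of the genome below a bound (default 10%) and flags the spans
  above it with their overlapping amplicons — on real data those spans are
  short non-spanning products concentrated in amplicon overlaps.

## Replicate concordance

`max_pairwise_difference()` is $100(\max - \min)$ over replicate
frequencies, identical to the maximum over all pairs.
`replicate_summary()` applies it per variant, grouped into substitutions /
PHPs / indels (indels additionally summarised by dominant-variant
fraction), and counts replicates where a variant is present in the reads
but below threshold. `compare_haplotypes()` classifies every discordance
into exactly one category, applied in order: suspect deletion; same
insertion anchor with a different dominant run; homopolymer indel (tract
of ≥ 4 identical reference bases containing or abutting the variant — the
problem tracts at 303–315, 16,183–16,194 and 568–573 all qualify);
threshold miss (present in the partner pileup below threshold, when the
pileup is available); heteroplasmy in one source only; other. The percent
discordant uses the union of both sources' calls as denominator.

## Mixtures

A *mixed variant site* (MV) is a position with two or more A/C/G/T states
each at ≥ 10% (indels are excluded from all mixture work: their error
rates and thresholds differ too much). Three or more MVs flag a mixture —
fewer could be personal heteroplasmies. Deconvolution assigns, at each MV,
the higher-frequency state to the major contributor; without read phasing
that per-site ordering is exactly the nearest-cluster assignment to the
two global frequency clusters, which collapse as the mixture approaches
1:1 — in that case (`major_mean - minor_mean` under 10 percentage points
by default) the result is flagged unresolvable rather than guessed. MVs
whose minor frequency lies more than 3 sample-SDs from the minor mean are
audited out as possible stochastic drop-in or NUMT signal. The minor
haplotype is the retained minor alleles plus all non-MV consensus
substitutions (shared by both contributors); means, SDs (sample SD, n−1,
over the MVs of the one mixture) and the effective ratio
`major_mean/minor_mean` are reported in percent.
`mixture_design()` provides the input-mass arithmetic of a
constant-plus-variable two-person series (2 pg constant: 20:1 → 42 pg
total, 1:10 → 2.2 pg total).

## The synthetic-data generator

`sim_scenario()` + `simulate_pileup()` draw, per position: total depth
Poisson around the panel-implied expectation (per-amplicon level =
target median × log-normal balance factor, summed over covering
amplicons, so overlaps are deeper); allele counts multinomial over the
mixture of contributor models plus error; strands binomial (default
forward fraction 0.5). The error model is deliberately minimal:

* substitution errors at rate 0.002 per read-base, uniform over the other
  three bases — the order of magnitude of a well-behaved amplicon MPS run;
* homopolymer indel noise at a tract's 3' end at rate
  `0.005 × tract length`, split evenly between one-base insertion and
  deletion reads. No published per-tract rates exist for this chemistry,
  so these defaults are calibrated only to reproduce the qualitative
  ordering: indels noisier than substitutions, and noise growing with
  tract length.

NUMT reads are a *fixed absolute count* of the catalogued allele per
catalog position — nuclear copy number does not dilute with mtDNA input —
which mechanically produces the rising NAV count across a dilution series
(`dilution_series()` scales the depth model while the NUMT count stays
put). Negative controls are background at a percent of the paired
positive's depth with optional hotspot spans. Every generator is
deterministic under its seed, and `exact = TRUE` replaces all draws with
expectation rounding for boundary analyses that must be noise-free (e.g.
the 9:1 vs 10:1 detection boundary).

What the generator does **not** emulate: read lengths and read-level
phasing, flowgram/homopolymer signal chemistry, alignment and mapping
artifacts, primer-binding-site SNP dropout dynamics, degraded-DNA
fragmentation, and real NUMT sequence homology (a catalog stands in for
homology search). Passing tests therefore demonstrate the correctness and
calibration of the *analysis chain*, not platform-level performance on
real libraries.

## Numerical and design choices

* Deletion-supporting reads count toward total depth, so the 40% deletion
  threshold is a fraction of spanning reads; whether insertion-carrying
  reads belong in that denominator is unstated in practice — here they do,
  via the total-depth definition.
* Even-count medians are the mean of the middle two; amplicon medians are
  taken over full spans.
* Dominant-insertion ties: lexicographic winner + explicit flag.
* The panel generator treats printed panel geometry (n, mean length, mean
  overlap) as descriptive, not as joint constraints — on a 16,569-nt
  circle they are mutually over-determined for any simple tiling. It
  enforces the feasibility inequality
  `n × (mean_length − overlap) ≥ L`, tiles evenly with the target
  junction overlap, and reports achieved means. Study scenarios use 110
  amplicons (achieved mean length ≈ 162 bp, overlap 11 bp).
* Degenerate inputs: zero-depth positions give *undefined* frequencies
  (`NA` with a warning), never 0; empty pileups yield a fully masked
  haplotype with zero calls; multi-record FASTAs error; non-rCRS lengths
  warn and extend by `min(80, L)`.

## Problem sizes

The test suite and analysis scripts run full-genome scenarios at 500–2000X
with 8 replicates × 3 donors, a 7-step dilution series, and 11 mixture
ratios; property checks use 1,000-iteration oracles where cheap (pairwise
differences) and 2–4 seeds where each case costs a full simulation. The
full suite completes in a few minutes on one CPU.

## Limitations

Calling is threshold-only by design; there is no base-quality weighting,
no realignment, and no likelihood-based mixture weighing (probabilistic
genotyping is explicitly out of scope). Haplogroup assignment and database
(EMPOP) queries are not performed; exported difference-coded text is
intended for such downstream tools. Mixture deconvolution is limited to
two contributors and to substitution sites.
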