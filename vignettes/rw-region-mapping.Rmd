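---
title: "Exclusion mapping and allelism analysis for balancer-region lethal screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exclusion mapping and allelism analysis for balancer-region lethal screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwmapkit)
```

## The problem

Regional ENU mutagenesis screens in the mouse recover collections of
recessive lethal mutations maintained over a balancer chromosome — here
modeled on the rump-white (*Rw*) inversion of proximal chromosome 5, which
suppresses recombination across the region, carries a dominant coat marker,
and is itself homozygous-lethal. Before any candidate gene can be sequenced,
each lethal must be localized. Two complementary sources of evidence do
this without ever observing the mutation directly:

* **Recessive-lethal exclusion from F2 intercrosses.** Carriers are
  outcrossed to a *M. castaneus*-derived chromosome and F1s intercrossed.
  A live F2 animal cannot be homozygous for the lethal, so wherever a live
  animal is proven homozygous for the mutagenized (B6) haplotype, the
  mutation cannot be.
* **Deletion complementation.** Crossing a carrier to a nested deficiency
  either yields no trans-heterozygous offspring (failure to complement: the
  mutation lies in removable DNA) or viable ones (complementation: the
  mutation is outside the DNA known to be deleted).

Both reduce to interval exclusion, and the surviving territory — the
critical region — is where candidate genes are sequenced.

## The exclusion model

All mapping logic runs on normalized interval sets (disjoint, sorted,
adjacent spans merged) in 0-based half-open coordinates; file I/O and all
printed positions use the 1-based inclusive convention of marker maps and
genome browsers, converted only at the boundary. With an initial search
region $R_0$ (the balancer footprint), deletions $D$ with minimal extent
$\min(D)$ (known absent) and maximal extent $\max(D)$ (breakpoint
uncertainty bounds), and live animals $i$ with proven-B6/B6 spans $S_i$:

$$R \;=\; \Bigl(R_0 \cap \bigcap_{D\,\in\,\text{FAILS}} \max(D)\Bigr)
\;\setminus\; \bigcup_{D\,\in\,\text{COMPLEMENTS}} \min(D)
\;\setminus\; \bigcup_i S_i .$$

Because every operation only removes territory, $R$ shrinks monotonically
in the evidence and the result is independent of the order in which tests
and animals are applied; `map_mutation()` additionally records each step in
a replayable evidence log and refuses (with the replay) to return an empty
region, which can only arise from inconsistent evidence.

Two design choices in `homozygous_b6_spans()` were genuinely open and were
resolved for soundness over power:

* A B6/B6 run excludes only the closed span from its first to its last
  marker, never extending into flanking heterozygous intervals: the
  crossover position between markers is unknown, and extending the span
  could exclude the true locus. A single-marker run excludes a 1 bp point
  span — the only provably homozygous DNA is the marker itself.
* Missing genotypes are uninformative and break runs; bridging across them
  would again risk unsound exclusions.

For non-complementation we intersect with the deletion's *maximal* extent,
and for complementation we subtract only the *minimal* extent, mirroring
the rectangle/thin-line semantics of deletion maps: conservative in both
directions.

## Allelism analysis

With $n$ mutations there are $n(n-1)$ potential complementation crosses
(ordered accounting, the default, since either carrier can serve as sire or
dam; 37 mutations give 1332). Pairs whose critical regions are disjoint
cannot be allelic — unless a gene spans adjacent intervals, which is why a
recorded failure to complement between disjoint-mapped mutations raises an
error instead of being silently resolved. `plan_tests()` classifies every
unordered pair (disjoint-inferred-complement, overlap with a recorded
outcome, or overlap-untested) and `allelic_groups()` partitions mutations
into allelic classes as connected components over failure-to-complement
edges (union-find; an igraph-based implementation serves as an independent
oracle in the test suite, not as the implementation).

For a viability test of one cross, the model is an
$m_1/\mathrm{Bal} \times m_2/\mathrm{Bal}$ intercross in which balancer
homozygotes die before genotyping, so weanable classes are 1
trans-heterozygote : 2 balancer carriers. `expected_weaned()` returns exact
thirds of the *weaned* total (pre-wean deaths are ungenotyped and excluded),
and `complementation_chisq()` applies the df = 1 Pearson statistic without
Yates continuity correction — with the correction the 0/21 cross would give
9.04 rather than the canonical 10.5. The statistic's null calibration is
checked by simulation (below).

## Candidate-variant filtering

`filter_candidates()` implements the capture-sequencing triage: keep mutant
calls that are (i) heterozygous — carrier DNA; a flag admits homozygous-alt
calls when homozygous embryo DNA was sequenced — (ii) inside the critical
region, (iii) absent (or homozygous-reference) at the same
(chrom, pos, alt) in every control sample, and (iv) absent from the
known-variant catalog. Multi-allelic records are decomposed per alternate
allele before filtering; matching across samples is by exact
(chrom, pos, alt). Quality thresholds are deliberately out of scope: read
filtering belongs upstream of this table-level module. Every rejection is
logged with its first failing criterion. `classify_putative()` triages a
re-sequenced site into strain SNP (present in a non-mutagenized strain
sample), artifact suspect (unreplicated across repeat sequencing of the
same DNA), or mutation (present only in mutant-lineage samples).

## The synthetic screen

The simulator exists so that every stage above can be validated against
known truth. Its generative model:

* **Meiosis** follows the Haldane model: crossover count
  $\sim$ Poisson(genetic length), breakpoints uniform on the region, no
  interference, starting phase a fair coin. Two loci $d$ Morgans apart then
  recombine with frequency $(1-e^{-2d})/2$, giving a closed form the tests
  check at 50,000 gametes. Kosambi-style interference is deliberately
  omitted in favor of testability.
* **F2 cohorts**: each of `n_f2` conceptuses draws two F1 gametes;
  conceptuses homozygous for the mutation-bearing haplotype die before
  genotyping and never enter the live table. Default `n_f2 = 100` — panel
  sizes per mutation were not recorded in the screen this emulates, so the
  default is an explicit, documented choice of a realistic mapping panel.
* **Markers**: by default every 0.5 Mb across a 60.9 Mb region, the
  SNP-scale density of the fine-mapping stage (the smallest published
  critical interval, 289 kb, is bounded by SNP markers). Recombination rate
  defaults to 0.5 cM/Mb, the order of the mouse genome average; both are
  configurable. Genotyping error and missingness default to 0 so soundness
  checks are deterministic knobs, not noise.
* **Deletion panels**: true breakpoints are drawn uniformly inside the
  uncertainty zones; a cross fails to complement exactly when the planted
  mutation falls in the sampled deleted segment. The packaged
  `rw_example_deletions()` catalog is synthetic (invented coordinates in
  the published panel's nested style), not the published extents.
* **Variant tables**: one heterozygous causative record at the true
  position in the mutant sample, plus configurable confounders — strain
  SNPs shared with a carrier control, background variants shared by all
  samples, and mutant-unique sites present in the known catalog.
* Everything is a pure function of the configuration including its seed.

What passing simulation tests do **not** show about real data: real mouse
meiosis shows strong positive interference at sub-5 Mb scales, so the
Haldane model is anti-conservative about double crossovers. Under Haldane,
a live animal can (with probability on the order of $10^{-6}$ per animal at
the default marker spacing) be B6/B6 at both markers flanking the lethal
through a double crossover, in which case the conservative marker-span rule
would excise the true position — a limitation of the no-interference model,
not of the exclusion logic, and one reason the marker-span rule refuses to
extend exclusions beyond genotyped markers. Real screens also face
genotyping error, segregation distortion, and incomplete penetrance of
lethality, none of which the default configuration injects.

## Numerical conventions and degenerate inputs

* Kilobase widths round half away from zero (fixed for determinism; base R
  `round()` is round-half-even). The 288,969 bp interval between the two
  published SNP coordinates prints as 289 kb under either convention.
* Empty interval sets are represented by zero rows, never by zero-width
  intervals; adjacent intervals merge on construction so set equality is
  representation equality.
* `expected_weaned()` returns exact rationals; the chi-square refuses a
  zero weaned total (zero expected counts).
* An empty genotype table yields an empty exclusion set with a warning; a
  deletion test that contradicts the candidate region, or evidence that
  excludes everything, is an error carrying the evidence replay.

## Problem sizes used in the packaged checks

The test suite and `scripts/acceptance.R` exercise: 1,000 randomized
interval-algebra instances against a per-basepair bitmap oracle; 200
simulated screens for critical-region soundness (the truth was contained in
200/200); 100 seeds each at 20 and 200 F2 conceptuses for the resolution
comparison (mean width ~32 Mb vs ~5 Mb); 50,000 gametes for the Haldane
check (max absolute error ~0.002); 100 screens for planted-variant recovery
(100/100); and 10,000 null weanling draws at a weaned total of 60 for
chi-square calibration (empirical type-I error ~3.9% at nominal 5% — the
exact discrete-binomial rate is 3.89%, inside the 5% ± 2% band the
calibration asserts). These sizes are the package's chosen validation
scale; all run on one CPU.

## Known limitations

* Single-chromosome model; the chromosome label is carried for format
  fidelity only.
* No likelihood-based or multipoint linkage mapping, no cM-map estimation:
  the exclusion calculus is deliberately deterministic and conservative.
* Penetrance, litter effects, and Fisher's exact alternative to the
  chi-square are out of scope.
* The balancer is modeled as fully recombination-suppressed and its
  homozygotes as dying before genotyping; partial suppression is not
  modeled.
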