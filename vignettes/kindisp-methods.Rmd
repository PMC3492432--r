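---
title: "Inferring dispersal from kin structure: methods and design choices"
author: "kindisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring dispersal from kin structure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindisp)
```

## The problem

In group-living mammals, which sex disperses and how often shapes the kin
composition of social groups and, through it, the opportunity for kin-based
social bonds. In populations where dispersal is facultative — some females
leave, some stay, and emigrants sometimes travel together with kin — the
dispersal status of an animal that was already resident when observation
began cannot be read from demographic records. `kindisp` implements a
complete analysis chain for this situation:

1. estimate pairwise relatedness *R* from microsatellite (STR) genotypes;
2. calibrate a close-kin threshold from dyads whose relationship is known;
3. build a genetic-tie network and assign *likely natal* / *likely
   immigrant* status from how each animal's close kin are distributed
   across groups;
4. score dyadic proximity from instantaneous scan samples;
5. test observed class means (e.g. female–female relatedness or proximity)
   against dyadic resampling nulls with percentile confidence bands;
6. compare group tenure between the sexes with Kaplan–Meier curves,
   log-rank tests, and expected-frequency count tests.

Because field genotype and scan data of this kind are rarely released, the
package ships a synthetic multigroup population generator with full ground
truth, and every stage is validated against it.

## Relatedness estimation

Two moment estimators are provided, both driven by reference allele
frequencies estimated by direct allele counting.

The default is the Queller–Goodnight regression estimator. For a dyad
(*x*, *y*) at one locus, with *x* carrying alleles *a*, *b* at frequencies
$p_a, p_b$ and $S_{uv}$ the allele-identity indicator, the per-locus terms
are

$$\mathrm{num}_{xy} = \tfrac12 (S_{ac}+S_{ad}+S_{bc}+S_{bd}) - p_a - p_b,
  \qquad
  \mathrm{den}_{xy} = 1 + S_{ab} - p_a - p_b .$$

Numerators and denominators are summed over loci and over both reference
directions before the ratio is taken, so loci that are uninformative for one
direction (zero denominator) contribute nothing instead of producing
indeterminate terms. The alternative estimator is Lynch–Ritland, combined
across loci with its published locus weights and symmetrized the same way.
We chose these two closed-form moment estimators over likelihood or MCMC
approaches because they are deterministic, auditable line by line, and
entirely adequate for threshold-based kin calling; the recovery tests show
both are unbiased (mean $\hat R$ within ±0.05 of 0, 0.25, 0.5, 0.5 for
unrelated, half-sib, parent–offspring and full-sib dyads at 20 loci).
Lynch–Ritland was preferred to Wang's estimator as the second option because
its closed form is compact enough to verify by hand against the original
equations; with Queller–Goodnight as the default, the second estimator
serves as a cross-check rather than a primary tool.

A dyad receives an estimate only when both members are typed at
`min_shared_loci` loci (default 10). The default mirrors the per-individual
filter used when evaluating classification accuracy: estimates over very few
loci are noisy enough to corrupt threshold-based kin calls.

## The close-kin threshold

`calibrate_threshold()` sets the threshold to the *minimum* R observed
among known first-degree dyads (parent–offspring and full siblings), and
records the maximum R among known non-kin. When the two ranges overlap the
`overlap` flag is raised — threshold-based kin calling is then unreliable
and the user should treat ties with caution. Classification is strict:
a dyad is a *genetic tie* only when $R$ is strictly **above** the
threshold; a dyad exactly at the threshold is not close kin. Dyads without
an estimate are "unevaluable" and never ties.

The threshold is a property of the genotyping panel and the known-dyad
sample, not a universal constant: with the default synthetic panel
(20 loci × 10 alleles) and a 55-dyad known-kin panel it calibrates to
roughly 0.33–0.42, bracketing the value a comparable field panel produces.

## Dispersal status from the kin network

For each animal passing the per-individual locus filter, its close kin
(network neighbors) are counted per group, with one exclusion: the focal's
own offspring co-residing in its current group are not counted, because a
parent may have immigrated before the offspring was born — a co-residing
offspring is not evidence of natality. The rules are then:

* strictly fewer counted kin in the current group than in some other group
  → *likely immigrant*;
* strictly more counted kin in the current group than in every other group
  → *likely natal*;
* a tie with exactly one other group is broken by the statuses of the tied
  kin themselves: all current-group kin known-or-likely natal **and** all
  other-group kin known-or-likely immigrant → *likely natal*; the mirror
  case → *likely immigrant*;
* no counted kin at all → *unknown* (`no_close_kin`); ties among three or
  more groups, or tie rules that never fire → *unknown* (`unresolved`).

Because the tie rules reference "known or likely" status, assignment
iterates: each sweep classifies every open case from the statuses settled
so far, updates synchronously, and repeats until nothing changes (bounded
by the node count). Synchronous updates make the fixed point independent
of iteration order, which the test suite verifies by permuting vertex
order. Known statuses are never overwritten; animals with known status
additionally receive a *shadow* assignment from the same rules, and
`evaluate_assignments()` compares shadow against known status to measure
accuracy (correct / incorrect / unassigned percentages partitioning the
evaluation set).

Two behaviors of these rules are worth knowing. First, an immigrant whose
mother or sister co-resides (after a parallel move) can be counted natal by
the majority rule — the method's documented failure mode, reproduced in the
tests. Second, a matriarch whose only close kin are her own offspring has,
after the exclusion, zero counted kin at home; if some offspring have
dispersed she can even appear to have a kin majority elsewhere. In field
designs such females are typically the ones whose status is unknown anyway
(they predate observation), so they rarely enter accuracy evaluations, but
users applying the classifier to complete populations should expect this
bias for founder-generation mothers.

## Proximity scores

The proximity score of dyad (A, B) is the arithmetic mean of two directed
proportions: the share of A's scans with B within one meter, and the share
of B's scans with A within one meter. Scans flagged as not fully identified
are dropped first (unidentifiable neighbors would silently deflate
co-occurrence), and individuals with fewer than `min_scans` retained scans
(default 10) receive no scores: proportions over a handful of scans are too
unstable to compare against resampling bands. Scores are computed only for
dyads co-resident in a group — the within-group nulls are only defined
there — and scans are pooled over the co-residence window without time
weighting.

## Resampling nulls

`within_group_null()` compares the observed mean of one dyad class (say,
female–female) in a group against simulated groups assembled by drawing,
in each of 10,000 iterations, the same number of dyads *without
replacement* from all dyads of that group regardless of class. Dyads are
sampled as units: two sampled dyads may share an individual. This literal
design keeps the null exhaustively enumerable — on any group with few
dyads the Monte-Carlo mean and every percentile bound can be checked
against all $\binom{n}{k}$ subsets, which the acceptance tests do.

The 95% and 99% bands are equal-tailed percentile intervals (order
statistics 2.5/97.5 and 0.5/99.5 with linear interpolation, R's default
quantile type 7); at 10,000 iterations the difference between
interpolation conventions is below reporting precision. Results always
carry a direction (above / below / inside) at both levels, since both
excesses and deficits are scientifically meaningful, and the 99% band
always contains the 95% band, so a 99%-level flag implies the 95%-level
flag.

`population_null()` works at the population scale: every real group is
replaced, per iteration, by an equal number of same-sex individuals drawn
without replacement from the population-wide pool; the across-group average
of simulated group means forms the null distribution for the "mean of group
means" of relatedness. Draws are independent across the simulated groups of
one iteration (an individual may appear in two simulated groups), since a
global partition is an equally defensible but stricter convention; the
choice only matters at second order for the across-group average.

Calibration: with exchangeable synthetic scans (no sex assortment), the
female–female class falls outside the 95% band in close to 5% of replicate
groups (two-sided), verified over 200 seeded replicates.

## Tenure analyses

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package, wrapped to the package's tenure-table format. The
median tenure is the smallest time at which survival reaches 0.5 or below,
with no interpolation; when fewer than half of a stratum's subjects
disperse before the study ends the median is undefined, which the curves
report as `NA` rather than a number. Censoring tied with events at the same
time is processed after the events (the standard convention). The sex-bias
count tests compute expected events per sex as total events × the sex's
share of the population; the chi-square version applies Yates' continuity
correction $(|O-E|-0.5)^2/E$ with 1 df (floored so over-correction cannot
flip the sign), and the Fisher version tests the 2×2 sex-by-outcome table
by the two-sided point-probability rule. When group composition changes
over the study, the proportion-based expected counts depend on the census
convention used for the denominators; both corrected and uncorrected
statistics are exposed so users can report either.

## The synthetic population generator

`simulate_population()` builds a pedigree over discrete breeding rounds in
a fixed set of groups, then derives genotypes, scans, and tenures from it.
What it emulates, and the defaults:

* **Demography.** 8 groups × 6 founders (alternating sexes), 3 breeding
  rounds of 2 offspring per breeding female — about 175 subadults and
  adults at analysis time, comparable to a mid-sized field study. Breeding
  rounds are 84 months apart so that conception (9 months before birth)
  falls *after* male natal dispersal at 74 months: sires are immigrant
  males, as obligate male dispersal requires. Parents are always drawn
  from the previous generation's co-resident pool at conception; a female
  with no co-resident male that round simply does not breed.
* **Dispersal.** Males all leave at 74 months. Each female decides at
  birth (probability 0.5 by default) whether she will disperse, at an age
  drawn from 55–80 months — late subadulthood to early adulthood, before
  first breeding, where female natal dispersal concentrates. Half of the
  dispersing females (by default) move in parallel: each co-resident
  daughter or maternal sister joins the cohort with probability 0.5,
  giving partial cohorts of realistic size rather than whole matrilines.
  Groups also fission along matrilines (probability 0.05 per group per
  round), each matriline assigned wholly to one daughter group.
* **Genetics.** 20 unlinked STR loci with 10 alleles each; founder allele
  frequencies are one symmetric Dirichlet draw per locus (concentration 3,
  keeping loci highly polymorphic, as marker panels selected for
  informativeness are). Inheritance is strictly Mendelian; missingness
  (5% per individual-locus call, emulating fecal-DNA dropout) is applied
  independently, after inheritance.
* **Known status.** A 60-month demographic observation window ends at the
  analysis time: a female's status is known when her birth or her
  immigration into her current group fell inside the window; females
  already resident at the window start are unknown. Males are always
  known. This reproduces the typical field situation in which the
  known-status set consists of young animals and observed transfers while
  the matriarchs are precisely the animals the genetic classifier is
  needed for.
* **Scans.** Every subadult/adult receives a fixed number of scans
  (default 46); each co-resident appears within one meter independently
  with a baseline probability, plus an additive female–female assortment
  effect when one is configured, and a small fraction of scans (0.9%) is
  flagged not fully identified. With the assortment effect at zero all
  dyad classes are exchangeable by construction — the null used for
  type-I calibration.

What it does **not** emulate: mortality (individuals persist to the
analysis time; censoring arises from the observation window only), age- or
rank-dependent fertility, extra-group paternity, genotyping error beyond
missingness, spatial structure or dispersal distances, and overlapping
generations within a breeding round. Passing tests therefore demonstrate
that the analysis chain recovers truth when its structural assumptions
hold; they do not certify robustness to genotyping artifacts or to
demographic processes outside this model.

## Numerical and testing choices

* All randomness flows through explicit integer seeds; identical
  configuration and seed reproduce every output byte for byte, including
  the pipeline's CSV files and manifest digests.
* Degenerate inputs are surfaced, not patched: empty known-kin lists,
  groups with a single dyad (degenerate CI, flagged), strata with no
  subjects, and ties referencing unknown individuals all raise errors or
  flags.
* Problem sizes in the test suite were chosen to keep every oracle exact
  or tightly bounded: enumeration checks run on groups with at most 12
  dyads (so all subsets can be listed), estimator recovery uses 500 dyads
  per category, and the type-I calibration uses 200 replicate groups at
  10,000 resampling iterations.
* The classifier-recovery check runs on the default generator
  configuration. Across seeds it attains 88–97% correct among known-status
  animals with at least one genetic tie, with 1–4% incorrect; occasional
  unresolved ties (when the kin on both sides of a tie have unknown
  status, so the tie rule cannot fire — faithful behavior of the published
  rules) account for the remainder.

## Known limitations

* The matriarch bias described above: founder-generation mothers whose
  only close kin are their own (excluded) offspring are systematically
  pushed toward *likely immigrant* when some offspring have dispersed.
* The tie rules only resolve two-group ties; three-way ties are left
  unknown by design.
* The close-kin threshold treats kin calling as a hard cut; no attempt is
  made to propagate relatedness uncertainty into the network.
* Group labels for dispersal patterns (philopatric / facultative /
  dispersed) use explicit natal-proportion cutoffs (≥ 2/3, ≤ 1/3) that are
  configurable because any such verbal classification is ultimately a
  convention.
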