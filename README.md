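# kindisp

Dispersal, kin composition, and proximity in multigroup animal populations.

## What it is for

In many group-living mammals one sex disperses and the other stays, so
groups are built around resident kin. But in populations with *facultative*
dispersal — where some females leave, some stay, and emigrants may travel
together with kin — the dispersal status of animals that were already
resident when a study began cannot be read from demographic records, and
the link between dispersal, the kin composition of groups, and social
bonds becomes an empirical question. `kindisp` is an R toolkit for that
question, aimed at behavioral ecologists and primatologists working with
microsatellite genotypes, demographic records, and scan-sample proximity
data from multigroup populations.

## The core methods

* **Pairwise relatedness.** Moment estimators (Queller–Goodnight by
  default, Lynch–Ritland as an alternative) give each dyad an estimate
  *R* from STR genotypes, combined over loci by summing numerators and
  denominators across both reference directions.
* **Close-kin threshold.** The threshold is calibrated as the minimum *R*
  over known parent–offspring and full-sibling dyads; a dyad is a
  *genetic tie* only when *R* is strictly above it, and the known non-kin
  range is checked for overlap.
* **Network-based dispersal status.** Counting each animal's genetic ties
  per group (excluding co-residing offspring from the home count), the
  classifier calls *likely immigrant* when the current group holds
  strictly fewer close kin than some other group, *likely natal* on a
  strict home majority, and breaks two-group ties with the known-or-likely
  statuses of the tied kin, iterating to an order-independent fixed point.
  Accuracy is evaluated against animals of known status.
* **Proximity scores.** For dyad (A, B), the mean of the proportion of A's
  scans with B within one meter and the proportion of B's scans with A
  within one meter, after dropping scans with unidentified neighbors.
* **Dyadic resampling nulls.** Observed class means (e.g. female–female
  *R* or proximity in a group) are compared against 10,000 simulated
  groups of dyads drawn without replacement from the same group (or, at
  the population level, simulated groups of same-sex individuals drawn
  from the population), with equal-tailed 95%/99% percentile bands and a
  direction attached.
* **Tenure analyses.** Kaplan–Meier curves and log-rank tests (via the
  `survival` package) for natal and breeding tenure, plus
  expected-frequency sex-bias tests (Yates-corrected chi-square, exact
  Fisher).
* **Synthetic populations.** A generator with Mendelian STR inheritance,
  obligate male dispersal, facultative/parallel female dispersal, group
  fission, scan sampling, and right-censored tenures provides ground truth
  for every stage; all tests run against it.

## Worked example

```r
library(kindisp)

pop <- simulate_population(population_config(seed = 1))
pop
#> <kd_population> 192 individuals in 8 groups (analysis time 288 mo)
#>     immigrant natal
#>   F        43    55
#>   M        74    20

rmat  <- estimate_relatedness(pop$genotypes)
known <- known_dyads_from_pedigree(pop$individuals, rmat)
thr   <- calibrate_threshold(known$R[known$relation != "non_kin"],
                             known$R[known$relation == "non_kin"])
thr
#> <kd_threshold> close kin iff R > 0.359 (calibrated)
#>   known-kin min 0.359; known non-kin max 0.1131; overlap: FALSE
```

The threshold is the lowest *R* among 55 pedigree-known first-degree dyads;
the known non-kin range (max 0.11) does not overlap it, so threshold-based
kin calling is safe here.

```r
ties <- classify_genetic_ties(rmat, thr)
net  <- build_kin_network(ties, subset(pop$individuals, age_class != "juvenile"),
                          n_loci_typed = attr(rmat, "n_loci_typed"))
asg  <- assign_dispersal_status(net, offspring = pedigree_offspring(pop$individuals))
evaluate_assignments(asg)
#> <kd_confusion> 134 known-status individuals evaluated
#>   correct 91%, incorrect 1%, unassigned 7%
#>            assigned
#> known       likely_natal likely_immigrant unknown
#>   immigrant            2               78       8
#>   natal               44                0       2
```

91% of known-status animals are classified correctly by the kin network
alone; the unassigned ones mostly lack close kin among the genotyped
animals.

```r
scans <- simulate_scans(pop, assortment_effect = 0.02, seed = 2)
prox  <- compute_proximity(scans, min_scans = 10)
nulls <- run_group_nulls(prox, value = "score", iterations = 10000, seed = 3)
head(summarize_significance(nulls[nulls$class == "FF", ]), 3)
#>   group class observed_mean sig95 sig99 direction label
#> 1   G01    FF    0.03765528  TRUE  TRUE     above    **
#> 2   G02    FF    0.03621640  TRUE  TRUE     above    **
#> 3   G03    FF    0.05450886  TRUE  TRUE     above    **
```

With a female–female assortment effect in the scan generator, the observed
female–female proximity means sit above the 99% band of the within-group
null (`**`), the package's analogue of a "female-bonded" group.

```r
tenures <- simulate_tenures(pop)
kaplan_meier(tenures, context = "natal_group", sex = "M")
#> <kd_survcurve> n = 94, events = 74, median = 74 months
logrank_test(tenures, by = "sex", context = "natal_group")
#> <kd_counttest> log_rank: chi-square = 8.8, df = 1, p = 0.00301
#>   observed: F 43, M 74
#>   expected: F 53.89, M 63.11
```

Males' median natal tenure is 74 months (the configured obligate dispersal
age) and males disperse from the natal group significantly more than
females.

`run_pipeline(population_config(seed = 1), out_dir = "run1")` executes the
whole chain and writes every stage table plus a deterministic
`manifest.json`; `inst/scripts/kindisp.R` wraps `simulate` and `run-all`
for shell use.

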