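Package: kindisp
Title: Dispersal, Kin Composition, and Proximity in Multigroup Animal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking dispersal, the kin composition of social groups,
    and proximity patterns in multigroup animal populations. Estimates pairwise
    relatedness from microsatellite (STR) genotypes with moment estimators
    (Queller-Goodnight, Lynch-Ritland), calibrates a close-kin threshold from
    known dyads, builds genetic-tie networks and assigns likely dispersal status
    from the distribution of close kin across groups, computes dyadic proximity
    scores from scan samples, runs within-group and population-level dyadic
    resampling nulls with percentile confidence intervals, and performs survival
    (Kaplan-Meier, log-rank) and sex-bias count analyses of group tenure. A
    synthetic multigroup population generator with Mendelian STR inheritance,
    obligate male dispersal, facultative and parallel female dispersal, and
    group fission provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
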