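#' Within-group dyadic table from a relatedness matrix
#'
#' Restricts a long dyadic table to pairs co-resident in the same group and
#' annotates each dyad with its group and sex class, the shape the
#' within-group resampling nulls consume.
#'
#' @param rmat A `kd_relmat` (or any `id1`/`id2`/value data.frame).
#' @param members Data.frame (`id`, `sex`, `current_group`).
#' @param value Name of the value column (default `"R"`).
#' @param adults_only Keep only dyads of adults (requires `age_class` in
#'   `members`).
#' @return Data.frame `id1`, `id2`, value, `group`, `class`.
#' @export
group_dyads <- function(rmat, members, value = "R", adults_only = FALSE) {
  d <- as.data.frame(rmat)
  if (adults_only) {
    ad <- members$id[members$age_class == "adult"]
    d <- d[d$id1 %in% ad & d$id2 %in% ad, ]
  }
  g1 <- members$current_group[match(d$id1, members$id)]
  g2 <- members$current_group[match(d$id2, members$id)]
  s1 <- members$sex[match(d$id1, members$id)]
  s2 <- members$sex[match(d$id2, members$id)]
  keep <- !is.na(g1) & !is.na(g2) & g1 == g2
  out <- d[keep, c("id1", "id2", value)]
  out$group <- g1[keep]
  out$class <- dyad_class(s1[keep], s2[keep])
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Orchestrates every stage in dependency order: population simulation, scan
#' and tenure simulation, allele-frequency and relatedness estimation,
#' close-kin threshold calibration from pedigree-known dyads, genetic-tie
#' network and dispersal-status assignment with accuracy evaluation,
#' proximity scores, within-group and population-level resampling nulls for
#' relatedness and proximity, tenure survival and sex-bias analyses, and a
#' per-group summary. Stage outputs are written as CSV files into `out_dir`
#' together with a deterministic JSON manifest (seeds, settings, file
#' digests); rerunning with an identical configuration and seed reproduces
#' every file byte for byte.
#'
#' @param config A `kd_config`; its `seed` drives the population stage, and
#'   per-stage seeds are derived from `seed` by fixed offsets.
#' @param out_dir Output directory (created if needed).
#' @param iterations Resampling iterations for all nulls.
#' @param estimator Relatedness estimator passed to
#'   [estimate_relatedness()].
#' @param min_shared_loci,min_loci_typed,min_scans Filters for relatedness,
#'   assignment, and proximity.
#' @param threshold `NULL` to calibrate the close-kin threshold from
#'   pedigree-known first-degree dyads, or a `kd_threshold` (e.g.
#'   [fixed_threshold()]).
#' @param assortment_effect Extra female-female per-scan co-occurrence
#'   probability used when simulating scans.
#' @param genetics Run the genetic stages (relatedness, network,
#'   assignments, relatedness nulls); when `FALSE`, proximity and demography
#'   outputs are still produced.
#' @param adults_only Also rerun the within-group nulls on adults only.
#' @return Invisibly, a list with all stage objects (`population`, `scans`,
#'   `tenures`, `freqs`, `rmat`, `threshold`, `ties`, `network`,
#'   `assignments`, `confusion`, `proximity`, `r_nulls`, `prox_nulls`,
#'   `pop_nulls`, `survival`, `count_tests`, `group_summary`, `manifest`).
#' @export
run_pipeline <- function(config = population_config(), out_dir,
                         iterations = 10000L,
                         estimator = "queller_goodnight",
                         min_shared_loci = 10L, min_loci_typed = 10L,
                         min_scans = 10L, threshold = NULL,
                         assortment_effect = 0.02, genetics = TRUE,
                         adults_only = FALSE) {
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()
  emit <- function(x, name) {
    write_table_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }

  ## simulate
  pop <- simulate_population(config)
  res$population <- pop
  emit(pop$individuals, "individuals")
  emit(pop$membership, "membership")
  write_genotypes_csv(pop$genotypes, file.path(out_dir, "genotypes.csv"))
  scans <- simulate_scans(pop, assortment_effect = assortment_effect,
                          seed = seed + 1L)
  res$scans <- scans
  write_scans_csv(scans, file.path(out_dir, "scans.csv"))
  tenures <- simulate_tenures(pop)
  res$tenures <- tenures
  emit(tenures, "tenures")
  subjects <- attr(scans, "subjects")
  members <- pop$individuals[pop$individuals$age_class != "juvenile", ]

  if (genetics) {
    ## relatedness and threshold
    freqs <- estimate_allele_frequencies(pop$genotypes)
    rmat <- estimate_relatedness(pop$genotypes, freqs, estimator = estimator,
                                 min_shared_loci = min_shared_loci)
    res$freqs <- freqs
    res$rmat <- rmat
    emit(rmat, "relatedness")
    known <- known_dyads_from_pedigree(pop$individuals, rmat)
    emit(known, "known_dyads")
    if (is.null(threshold)) {
      threshold <- calibrate_threshold(
        known$R[known$relation != "non_kin"],
        known$R[known$relation == "non_kin"])
    }
    res$threshold <- threshold

    ## network and status assignment
    ties <- classify_genetic_ties(rmat, threshold)
    res$ties <- ties
    emit(ties, "ties")
    net <- build_kin_network(ties, members,
                             n_loci_typed = attr(rmat, "n_loci_typed"))
    res$network <- net
    assignments <- assign_dispersal_status(
      net, offspring = pedigree_offspring(pop$individuals),
      min_loci_typed = min_loci_typed)
    res$assignments <- assignments
    emit(assignments, "assignments")
    res$confusion <- evaluate_assignments(assignments)

    ## relatedness nulls
    rdy <- group_dyads(rmat, members)
    res$r_nulls <- run_group_nulls(rdy, value = "R",
                                   iterations = iterations,
                                   seed = seed + 20L)
    emit(res$r_nulls, "relatedness_nulls")
    pn <- list()
    for (sx in c("F", "M")) {
      p <- try(population_null(rmat, members, sx, iterations = iterations,
                               seed = seed + 40L + (sx == "M")),
               silent = TRUE)
      if (!inherits(p, "try-error")) pn[[sx]] <- p
    }
    res$pop_nulls <- if (length(pn)) do.call(rbind, pn) else NULL
    if (!is.null(res$pop_nulls)) emit(res$pop_nulls, "population_nulls")
  }

  ## proximity and its nulls
  prox <- compute_proximity(scans, min_scans = min_scans,
                            subjects = subjects)
  res$proximity <- prox
  emit(prox, "proximity")
  res$prox_nulls <- run_group_nulls(prox, value = "score",
                                    iterations = iterations,
                                    seed = seed + 60L)
  emit(res$prox_nulls, "proximity_nulls")
  if (adults_only) {
    pad <- prox[prox$id1 %in% members$id[members$age_class == "adult"] &
                  prox$id2 %in% members$id[members$age_class == "adult"], ]
    if (nrow(pad))
      res$prox_nulls_adults <- run_group_nulls(pad, value = "score",
                                               iterations = iterations,
                                               seed = seed + 61L)
  }

  ## demography
  km <- list(natal_male = kaplan_meier(tenures, "natal_group", "M"),
             natal_female = kaplan_meier(tenures, "natal_group", "F"))
  res$survival <- km
  emit(as.data.frame(km$natal_male), "km_natal_male")
  emit(as.data.frame(km$natal_female), "km_natal_female")
  res$logrank_natal <- logrank_test(tenures, by = "sex",
                                    context = "natal_group")
  ev <- tenures[tenures$event_observed, ]
  n_m <- sum(members$sex == "M")
  n_f <- sum(members$sex == "F")
  res$count_tests <- list(
    emigration = sex_bias_count_test(sum(ev$sex == "M"), sum(ev$sex == "F"),
                                     n_m, n_f, method = "chi_square_yates"))

  ## per-group summary
  if (genetics) {
    res$group_summary <- summarize_groups(
      res$assignments, pop$individuals,
      r_nulls = res$r_nulls, prox_nulls = res$prox_nulls,
      r_dyads = group_dyads(res$rmat, members),
      prox_dyads = prox)
    emit(res$group_summary, "group_summary")
  }

  ## manifest
  files <- sort(list.files(out_dir, pattern = "\\.csv$"))
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(package = "kindisp",
                   version = as.character(utils::packageVersion("kindisp")),
                   seed = seed, iterations = iterations,
                   estimator = if (genetics) estimator else NULL,
                   threshold = if (genetics) res$threshold$threshold else NULL,
                   config = unclass(config), files = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Per-group dispersal, kin-composition, and bondedness summary
#'
#' Combines status assignments with the within-group resampling results into
#' one row per group: a dispersal-pattern label from the proportion of adult
#' females that are known or likely natal (at least `cutoffs[1]` natal is
#' philopatric, at most `cutoffs[2]` is dispersed, otherwise facultative), a
#' kin-based flag (female-female relatedness above the 95% within-group
#' band), a bonded flag (female-female proximity above the 95% band), and the
#' group means of female-female relatedness and proximity.
#'
#' @param assignments A `kd_assignments`.
#' @param individuals The individual table (for age classes).
#' @param r_nulls,prox_nulls `kd_null` tables from [run_group_nulls()] (may
#'   be `NULL`; flags are then `NA`).
#' @param r_dyads,prox_dyads Within-group dyad tables ([group_dyads()] /
#'   [compute_proximity()]) used for the group means (may be `NULL`).
#' @param cutoffs Numeric pair: natal-proportion cutoffs for the
#'   philopatric / dispersed labels.
#' @return Data.frame: `group`, `n_adult_females`, `prop_natal`,
#'   `dispersal_pattern`, `kin_based`, `mean_R_ff`, `bonded`,
#'   `mean_proximity_ff`.
#' @export
summarize_groups <- function(assignments, individuals, r_nulls = NULL,
                             prox_nulls = NULL, r_dyads = NULL,
                             prox_dyads = NULL, cutoffs = c(2 / 3, 1 / 3)) {
  af <- individuals$id[individuals$sex == "F" &
                         individuals$age_class == "adult"]
  a <- assignments[assignments$id %in% af, ]
  status <- ifelse(a$known_status != "unknown", a$known_status,
                   ifelse(a$assigned == "likely_natal", "natal",
                          ifelse(a$assigned == "likely_immigrant",
                                 "immigrant", "unknown")))
  groups <- sort(unique(assignments$group))
  flag_of <- function(nulls, g) {
    if (is.null(nulls)) return(NA)
    r <- nulls[nulls$group == g & nulls$class == "FF", ]
    if (!nrow(r)) return(NA)
    r$direction95 == "above"
  }
  mean_of <- function(dy, g, value) {
    if (is.null(dy)) return(NA_real_)
    v <- dy[[value]][dy$group == g & dy$class == "FF"]
    if (!length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }
  rows <- lapply(groups, function(g) {
    st <- status[a$group == g]
    n_cls <- sum(st != "unknown")
    prop <- if (n_cls) sum(st == "natal") / n_cls else NA_real_
    lab <- if (is.na(prop)) NA_character_
    else if (prop >= cutoffs[1]) "philopatric"
    else if (prop <= cutoffs[2]) "dispersed"
    else "facultative"
    data.frame(group = g, n_adult_females = sum(a$group == g),
               prop_natal = prop, dispersal_pattern = lab,
               kin_based = flag_of(r_nulls, g),
               mean_R_ff = mean_of(r_dyads, g, "R"),
               bonded = flag_of(prox_nulls, g),
               mean_proximity_ff = mean_of(prox_dyads, g, "score"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
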