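#' Configuration for the synthetic multigroup population generator
#'
#' Builds and validates the parameter set used by [simulate_population()].
#' The defaults describe a population of eight uni-/multi-male multi-female
#' groups with obligate male natal dispersal, facultative female dispersal
#' (half of the females disperse), parallel female cohort moves, occasional
#' group fission along matrilines, and 20 microsatellite (STR) loci inherited
#' Mendelianly with fecal-DNA-style genotype dropout.
#'
#' @param n_groups Number of social groups founded at time zero.
#' @param founders_per_group Total founders seeded per group, with alternating
#'   sexes (female, male, female, ...). Must be at least 2 so that every group
#'   starts with at least one founder of each sex.
#' @param n_generations Number of breeding rounds after the founders. Each
#'   round produces one offspring generation whose parents belong to the
#'   previous generation and co-reside at conception.
#' @param n_loci Number of unlinked autosomal STR loci.
#' @param alleles_per_locus Number of distinct alleles segregating per locus.
#' @param allele_freq_concentration Symmetric Dirichlet concentration used to
#'   draw the founder allele frequencies of each locus (larger values give
#'   more even frequencies; the default keeps most loci highly polymorphic,
#'   as human-derived STR panels selected for informativeness are).
#' @param female_dispersal_prob Probability that a female ever disperses from
#'   her current group (decided once, at birth).
#' @param parallel_dispersal_prob Given that a female disperses, probability
#'   that the move is a parallel cohort move in which her co-resident
#'   daughters and maternal sisters may join her.
#' @param cohort_join_prob In a parallel move, the probability that each
#'   co-resident daughter or maternal sister joins the cohort (cohorts are
#'   partial: a few kin travel together, others stay behind).
#' @param fission_prob_per_generation Per-group, per-generation probability of
#'   a fission that splits the group along matrilines.
#' @param male_dispersal_age_months Age (months) at which every male leaves
#'   his current group (obligate natal dispersal).
#' @param genotype_missing_rate Probability that a (individual, locus) genotype
#'   call is missing, applied independently after inheritance.
#' @param seed Integer seed; identical configurations yield byte-identical
#'   populations.
#' @param generation_interval_months Months between successive birth cohorts.
#'   The default (84) places conception after male natal dispersal, so that
#'   sires are immigrant males.
#' @param offspring_per_female Offspring produced by each breeding female per
#'   round (a female breeds only when a male of her parents' generation
#'   co-resides at conception).
#' @param female_dispersal_age_range Two-element numeric vector (months); a
#'   dispersing female's departure age is drawn uniformly from this interval.
#'   The default spans late subadulthood through early adulthood, before
#'   first breeding, the age band in which female natal dispersal
#'   concentrates.
#' @param observation_window_months Length (months) of the demographic
#'   observation window ending at the analysis time. A female's dispersal
#'   status is known when her birth or her immigration into the current
#'   group fell inside the window (her history was observed); females
#'   already resident when observation started have unknown status. Male
#'   status is always known, as obligate male dispersal makes it certain.
#' @param scan_unidentified_rate Probability that a scan sample is flagged as
#'   not fully identified (such scans are dropped by default downstream).
#'
#' @return An object of class `kd_config` (a validated named list).
#' @export
#' @examples
#' cfg <- population_config(n_groups = 3, founders_per_group = 4,
#'                          n_generations = 2, seed = 7)
#' cfg$n_groups
population_config <- function(n_groups = 8,
                              founders_per_group = 6,
                              n_generations = 3,
                              n_loci = 20,
                              alleles_per_locus = 10,
                              allele_freq_concentration = 3,
                              female_dispersal_prob = 0.5,
                              parallel_dispersal_prob = 0.5,
                              cohort_join_prob = 0.5,
                              fission_prob_per_generation = 0.05,
                              male_dispersal_age_months = 74,
                              genotype_missing_rate = 0.05,
                              seed = 1L,
                              generation_interval_months = 84,
                              offspring_per_female = 2,
                              female_dispersal_age_range = c(55, 80),
                              observation_window_months = 60,
                              scan_unidentified_rate = 0.009) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    founders_per_group = as.integer(founders_per_group),
    n_generations = as.integer(n_generations),
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    allele_freq_concentration = allele_freq_concentration,
    female_dispersal_prob = female_dispersal_prob,
    parallel_dispersal_prob = parallel_dispersal_prob,
    cohort_join_prob = cohort_join_prob,
    fission_prob_per_generation = fission_prob_per_generation,
    male_dispersal_age_months = male_dispersal_age_months,
    genotype_missing_rate = genotype_missing_rate,
    seed = as.integer(seed),
    generation_interval_months = generation_interval_months,
    offspring_per_female = as.integer(offspring_per_female),
    female_dispersal_age_range = female_dispersal_age_range,
    observation_window_months = observation_window_months,
    scan_unidentified_rate = scan_unidentified_rate
  )
  validate_config(cfg)
  class(cfg) <- "kd_config"
  cfg
}

validate_config <- function(cfg) {
  probs <- c("female_dispersal_prob", "parallel_dispersal_prob",
             "cohort_join_prob",
             "fission_prob_per_generation", "genotype_missing_rate",
             "scan_unidentified_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", p), call. = FALSE)
  }
  counts <- c("n_groups", "n_generations", "n_loci", "alleles_per_locus",
              "offspring_per_female")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop(sprintf("`%s` must be a count >= 1", p), call. = FALSE)
  }
  if (is.na(cfg$founders_per_group) || cfg$founders_per_group < 2)
    stop("`founders_per_group` must be >= 2 (at least one founder of each sex)",
         call. = FALSE)
  pos <- c("allele_freq_concentration", "male_dispersal_age_months",
           "generation_interval_months", "observation_window_months")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("`%s` must be a positive real", p), call. = FALSE)
  }
  r <- cfg$female_dispersal_age_range
  if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 0)
    stop("`female_dispersal_age_range` must be an increasing pair of non-negative months",
         call. = FALSE)
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [population_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `kd_config` object.
#' @export
read_population_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(population_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(population_config, vals)
}

#' @export
print.kd_config <- function(x, ...) {
  cat("<kd_config> synthetic population generator settings\n")
  cat(sprintf("  %d groups x %d founders, %d offspring generations\n",
              x$n_groups, x$founders_per_group, x$n_generations))
  cat(sprintf("  %d STR loci, %d alleles each (Dirichlet conc. %.2f), dropout %.1f%%\n",
              x$n_loci, x$alleles_per_locus, x$allele_freq_concentration,
              100 * x$genotype_missing_rate))
  cat(sprintf("  male dispersal at %.0f mo; P(female disperses) = %.2f, P(parallel) = %.2f\n",
              x$male_dispersal_age_months, x$female_dispersal_prob,
              x$parallel_dispersal_prob))
  cat(sprintf("  P(fission)/group/generation = %.2f; seed %d\n",
              x$fission_prob_per_generation, x$seed))
  invisible(x)
}
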