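#' Simulate a multigroup population with known dispersal ground truth
#'
#' Generates a pedigree over discrete, non-overlapping breeding rounds in a
#' set of social groups, together with Mendelian STR genotypes, a full
#' group-membership history, and known/true dispersal status per individual.
#' Males always leave their group at `male_dispersal_age_months`; each female
#' decides once (at birth) whether she will disperse, and a dispersing female
#' may take her co-resident daughters and maternal sisters along as a parallel
#' cohort. Groups may also fission along matrilines. Every downstream stage of
#' the package (relatedness estimation, kin networks, proximity, resampling
#' nulls, tenure analyses) can be validated against the ground truth recorded
#' here.
#'
#' Parents of a breeding round are always members of the previous generation
#' that co-reside at conception (nine months before the birth cohort); a
#' female with no co-resident male of the parental generation at conception
#' produces no offspring that round.
#'
#' @param config A `kd_config` from [population_config()].
#' @return An object of class `kd_population`: a list with elements
#'   \describe{
#'     \item{individuals}{data.frame of one row per individual: `id`, `sex`
#'       (`"F"`/`"M"`), `generation`, `age_class`
#'       (`juvenile`/`subadult`/`adult`), `birth_time`, `birth_group`,
#'       `current_group`, `entry_time` (entry into the current group),
#'       `exit_time` (`NA`, right-censored at the analysis time),
#'       `mother_id`, `father_id`, `true_status` (`natal`/`immigrant`),
#'       `known_status` (`natal`/`immigrant`/`unknown`).}
#'     \item{genotypes}{long data.frame (`id`, `locus`, `allele1`, `allele2`)
#'       with `NA` alleles where the call is missing.}
#'     \item{genotypes_true}{the same table before missingness was applied.}
#'     \item{membership}{data.frame of residence spells (`id`, `group`,
#'       `start`, `end`).}
#'     \item{allele_freqs_truth}{list per locus of the founder allele
#'       frequencies the genotypes were drawn from.}
#'     \item{groups}{character vector of all group ids (including fission
#'       products).}
#'     \item{t_end}{the analysis time (months) at which states are reported.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' pop <- simulate_population(population_config(n_groups = 3,
#'   founders_per_group = 4, n_generations = 2, seed = 42))
#' table(pop$individuals$sex, pop$individuals$true_status)
simulate_population <- function(config) {
  if (!inherits(config, "kd_config")) stop("`config` must be a kd_config")
  validate_config(config)
  set.seed(config$seed)

  gi <- config$generation_interval_months
  t_end <- gi * config$n_generations + 36
  n_loci <- config$n_loci
  loci <- sprintf("L%02d", seq_len(n_loci))
  allele_labels <- 100L + 2L * (seq_len(config$alleles_per_locus) - 1L)

  # founder allele frequencies: one symmetric Dirichlet draw per locus
  freqs <- lapply(seq_len(n_loci), function(l) {
    g <- stats::rgamma(config$alleles_per_locus,
                       shape = config$allele_freq_concentration)
    p <- g / sum(g)
    names(p) <- allele_labels
    p
  })
  names(freqs) <- loci

  ## -- mutable simulation state ----------------------------------------
  ind <- list(id = character(), sex = character(), generation = integer(),
              birth_time = numeric(), birth_group = character(),
              mother_id = character(), father_id = character())
  geno <- matrix(integer(), nrow = 0, ncol = 2L * n_loci)
  cur_group <- character()        # named by id
  move_log <- list()              # rows: id, time, group (includes birth)
  pending <- data.frame(id = character(), time = numeric(),
                        parallel = logical(), stringsAsFactors = FALSE)
  groups <- sprintf("G%02d", seq_len(config$n_groups))
  counter <- 0L

  log_move <- function(ids, time, group) {
    move_log[[length(move_log) + 1L]] <<- data.frame(
      id = ids, time = time, group = group, stringsAsFactors = FALSE)
  }

  new_id <- function() {
    counter <<- counter + 1L
    sprintf("I%04d", counter)
  }

  schedule_dispersal <- function(id, sex, birth_time) {
    if (sex == "M") {
      pending[nrow(pending) + 1L, ] <<- list(
        id, birth_time + config$male_dispersal_age_months, FALSE)
    } else if (stats::runif(1) < config$female_dispersal_prob) {
      age <- stats::runif(1, config$female_dispersal_age_range[1],
                          config$female_dispersal_age_range[2])
      par <- stats::runif(1) < config$parallel_dispersal_prob
      pending[nrow(pending) + 1L, ] <<- list(id, birth_time + age, par)
    }
  }

  add_individual <- function(sex, generation, birth_time, group,
                             mother, father, genotype_row) {
    id <- new_id()
    ind$id <<- c(ind$id, id)
    ind$sex <<- c(ind$sex, sex)
    ind$generation <<- c(ind$generation, generation)
    ind$birth_time <<- c(ind$birth_time, birth_time)
    ind$birth_group <<- c(ind$birth_group, group)
    ind$mother_id <<- c(ind$mother_id, mother)
    ind$father_id <<- c(ind$father_id, father)
    geno <<- rbind(geno, genotype_row)
    cur_group[id] <<- group
    log_move(id, birth_time, group)
    schedule_dispersal(id, sex, birth_time)
    id
  }

  # execute all scheduled dispersal moves with time <= t, in time order;
  # a parallel female move relocates her co-resident daughters and maternal
  # sisters as one cohort and cancels their own scheduled moves
  apply_moves_until <- function(t) {
    repeat {
      due <- which(pending$time <= t)
      if (!length(due)) break
      i <- due[order(pending$time[due], pending$id[due])][1L]
      mv <- pending[i, ]
      pending <<- pending[-i, , drop = FALSE]
      from <- cur_group[[mv$id]]
      dest_pool <- setdiff(groups, from)
      if (!length(dest_pool)) next  # single-group population: nowhere to go
      dest <- resample(dest_pool, 1L)
      movers <- mv$id
      if (mv$parallel) {
        idx <- match(mv$id, ind$id)
        mom <- ind$mother_id[idx]
        co <- ind$id[ind$sex == "F" & ind$id != mv$id &
                       cur_group[ind$id] == from &
                       ((!is.na(ind$mother_id) & ind$mother_id == mv$id) |
                          (!is.na(mom) & !is.na(ind$mother_id) &
                             ind$mother_id == mom))]
        co <- co[stats::runif(length(co)) < config$cohort_join_prob]
        movers <- c(movers, co)
      }
      cur_group[movers] <<- dest
      log_move(movers, mv$time, dest)
      pending <<- pending[!(pending$id %in% movers), , drop = FALSE]
    }
  }

  matriline_root <- function(id) {
    repeat {
      m <- ind$mother_id[match(id, ind$id)]
      if (is.na(m)) return(id)
      id <- m
    }
  }

  fission_group <- function(group, time) {
    members <- names(cur_group)[cur_group == group]
    if (length(members) < 2L) return(invisible())
    roots <- vapply(members, matriline_root, character(1))
    uroots <- unique(roots)
    if (length(uroots) < 2L) return(invisible())
    go <- uroots[stats::runif(length(uroots)) < 0.5]
    if (!length(go)) go <- resample(uroots, 1L)
    if (length(go) == length(uroots)) go <- go[-resample(seq_along(go), 1L)]
    if (!length(go)) return(invisible())
    new_gid <- sprintf("G%02d", length(groups) + 1L)
    groups <<- c(groups, new_gid)
    movers <- members[roots %in% go]
    cur_group[movers] <<- new_gid
    log_move(movers, time, new_gid)
  }

  ## -- founders ---------------------------------------------------------
  for (g in groups) {
    for (k in seq_len(config$founders_per_group)) {
      sex <- if (k %% 2L == 1L) "F" else "M"
      row <- unlist(lapply(seq_len(n_loci), function(l)
        resample(as.integer(names(freqs[[l]])), 2L, replace = TRUE,
                 prob = freqs[[l]])))
      add_individual(sex, 0L, 0, g, NA_character_, NA_character_, row)
    }
  }

  ## -- breeding rounds --------------------------------------------------
  for (gen in seq_len(config$n_generations)) {
    t_birth <- gi * gen
    t_conc <- t_birth - 9
    apply_moves_until(t_conc)
    snapshot <- cur_group  # residence at conception
    apply_moves_until(t_birth)
    parents <- ind$generation == gen - 1L
    mothers <- ind$id[parents & ind$sex == "F"]
    males <- ind$id[parents & ind$sex == "M"]
    for (mom in mothers) {
      pool <- males[snapshot[males] == snapshot[[mom]]]
      if (!length(pool)) next
      mom_row <- geno[match(mom, ind$id), ]
      for (k in seq_len(config$offspring_per_female)) {
        dad <- resample(pool, 1L)
        dad_row <- geno[match(dad, ind$id), ]
        child <- transmit_alleles(mom_row, dad_row, n_loci)
        sex <- resample(c("F", "M"), 1L)
        add_individual(sex, gen, t_birth, cur_group[[mom]], mom, dad, child)
      }
    }
    t_fis <- t_birth + 42
    if (t_fis <= t_end) {
      apply_moves_until(t_fis)
      for (g in groups) {
        if (stats::runif(1) < config$fission_prob_per_generation)
          fission_group(g, t_fis)
      }
    }
  }
  apply_moves_until(t_end)

  ## -- assemble outputs -------------------------------------------------
  individuals <- data.frame(ind, stringsAsFactors = FALSE)
  individuals$current_group <- unname(cur_group[individuals$id])
  individuals$true_status <- ifelse(
    individuals$current_group == individuals$birth_group, "natal", "immigrant")
  age <- t_end - individuals$birth_time
  individuals$age_class <- age_class_of(individuals$sex, age)

  moves <- do.call(rbind, move_log)
  moves <- moves[order(moves$id, moves$time), ]
  spells <- do.call(rbind, lapply(split(moves, moves$id), function(d) {
    data.frame(id = d$id, group = d$group, start = d$time,
               end = c(d$time[-1L], t_end), stringsAsFactors = FALSE)
  }))
  rownames(spells) <- NULL
  last <- spells[!duplicated(spells$id, fromLast = TRUE), ]
  individuals$entry_time <- last$start[match(individuals$id, last$id)]
  individuals$exit_time <- NA_real_

  # status is known when the individual's birth or its immigration into the
  # current group was observed inside the demographic window; males are
  # always known (obligate dispersal makes male status certain)
  w_start <- t_end - config$observation_window_months
  known <- individuals$sex == "M" |
    individuals$birth_time >= w_start |
    (individuals$true_status == "immigrant" &
       individuals$entry_time >= w_start)
  individuals$known_status <- ifelse(known, individuals$true_status,
                                     "unknown")
  individuals <- individuals[, c("id", "sex", "generation", "age_class",
                                 "birth_time", "birth_group", "current_group",
                                 "entry_time", "exit_time", "mother_id",
                                 "father_id", "true_status", "known_status")]

  geno_true <- genotype_long(individuals$id, geno, loci)
  miss <- matrix(stats::runif(nrow(geno) * n_loci) < config$genotype_missing_rate,
                 nrow = nrow(geno))
  geno_obs <- geno
  for (l in seq_len(n_loci)) {
    geno_obs[miss[, l], c(2L * l - 1L, 2L * l)] <- NA_integer_
  }
  genotypes <- genotype_long(individuals$id, geno_obs, loci)

  structure(list(individuals = individuals,
                 genotypes = genotypes,
                 genotypes_true = geno_true,
                 membership = spells,
                 allele_freqs_truth = freqs,
                 groups = groups,
                 t_end = t_end,
                 config = config),
            class = "kd_population")
}

# one Mendelian meiosis per locus from each parent; alleles stored as
# consecutive column pairs per locus
transmit_alleles <- function(mom_row, dad_row, n_loci) {
  out <- integer(2L * n_loci)
  pick <- stats::runif(2L * n_loci) < 0.5
  for (l in seq_len(n_loci)) {
    i <- 2L * l - 1L
    out[i] <- if (pick[i]) mom_row[i] else mom_row[i + 1L]
    out[i + 1L] <- if (pick[i + 1L]) dad_row[i] else dad_row[i + 1L]
  }
  out
}

age_class_of <- function(sex, age_months) {
  adult_at <- ifelse(sex == "M", 84, 60)
  ifelse(age_months < 36, "juvenile",
         ifelse(age_months <= adult_at, "subadult", "adult"))
}

genotype_long <- function(ids, geno, loci) {
  n_loci <- length(loci)
  data.frame(
    id = rep(ids, each = n_loci),
    locus = rep(loci, times = length(ids)),
    allele1 = as.integer(t(geno[, 2L * seq_len(n_loci) - 1L, drop = FALSE])),
    allele2 = as.integer(t(geno[, 2L * seq_len(n_loci), drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

# sample() without the length-1 surprise
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' @export
print.kd_population <- function(x, ...) {
  cat(sprintf("<kd_population> %d individuals in %d groups (analysis time %g mo)\n",
              nrow(x$individuals), length(unique(x$individuals$current_group)),
              x$t_end))
  tab <- table(x$individuals$sex, x$individuals$true_status)
  print(tab)
  invisible(x)
}
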