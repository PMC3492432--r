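test_that("degenerate configurations are rejected", {
  expect_error(population_config(founders_per_group = 0), "founders_per_group")
  expect_error(population_config(female_dispersal_prob = 1.2), "probability")
  expect_error(population_config(n_loci = 0), "count")
  expect_error(population_config(female_dispersal_age_range = c(90, 55)),
               "increasing")
})

test_that("identical config and seed reproduce the population byte for byte", {
  a <- simulate_population(small_config(seed = 7))
  b <- simulate_population(small_config(seed = 7))
  expect_identical(a, b)
  c <- simulate_population(small_config(seed = 8))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("with dispersal and fission disabled every female is natal", {
  pop <- simulate_population(small_config(
    seed = 3, female_dispersal_prob = 0, fission_prob_per_generation = 0))
  f <- pop$individuals[pop$individuals$sex == "F", ]
  expect_true(all(f$true_status == "natal"))
})

test_that("male dispersal is obligate: no adult male resides in his birth group", {
  for (s in 1:3) {
    pop <- simulate_population(population_config(
      seed = s, male_dispersal_age_months = 84))
    am <- pop$individuals[pop$individuals$sex == "M" &
                            pop$individuals$age_class == "adult", ]
    expect_true(all(am$current_group != am$birth_group))
  }
})

test_that("dispersal status is recomputable from birth and current group", {
  pop <- simulate_population(population_config(seed = 5))
  expect_identical(pop$individuals$true_status,
                   ifelse(pop$individuals$current_group ==
                            pop$individuals$birth_group,
                          "natal", "immigrant"))
  # known status, when present, agrees with the truth
  k <- pop$individuals$known_status != "unknown"
  expect_identical(pop$individuals$known_status[k],
                   pop$individuals$true_status[k])
})

test_that("every non-founder has co-resident opposite-sex parents of the prior generation", {
  pop <- simulate_population(small_config(seed = 11))
  ind <- pop$individuals
  kids <- ind[ind$generation > 0, ]
  mo <- ind[match(kids$mother_id, ind$id), ]
  fa <- ind[match(kids$father_id, ind$id), ]
  expect_true(all(mo$sex == "F"))
  expect_true(all(fa$sex == "M"))
  expect_true(all(mo$generation == kids$generation - 1L))
  expect_true(all(fa$generation == kids$generation - 1L))
  t_conc <- kids$birth_time - 9
  for (i in seq_len(nrow(kids))) {
    expect_identical(group_at(pop$membership, kids$mother_id[i], t_conc[i]),
                     group_at(pop$membership, kids$father_id[i], t_conc[i]))
  }
})

test_that("offspring genotypes are Mendelian before missingness", {
  pop <- simulate_population(small_config(seed = 13))
  g <- pop$genotypes_true
  ind <- pop$individuals
  kids <- ind$id[ind$generation > 0]
  for (id in kids) {
    gk <- g[g$id == id, ]
    gm <- g[g$id == ind$mother_id[match(id, ind$id)], ]
    gf <- g[g$id == ind$father_id[match(id, ind$id)], ]
    expect_true(all(gk$allele1 == gm$allele1 | gk$allele1 == gm$allele2))
    expect_true(all(gk$allele2 == gf$allele1 | gk$allele2 == gf$allele2))
  }
})

test_that("per-locus transmission frequency matches one half", {
  # 10,000 meioses from a heterozygous {A, B} parent at one locus
  set.seed(42)
  mom <- c(1L, 2L)   # alleles A = 1, B = 2
  dad <- c(3L, 3L)
  got <- vapply(seq_len(10000),
                function(i) kindisp:::transmit_alleles(mom, dad, 1L)[1L],
                integer(1))
  p_hat <- mean(got == 1L)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("allele labels stay within each locus's founder allele set", {
  pop <- simulate_population(small_config(seed = 17))
  g <- pop$genotypes_true
  for (l in names(pop$allele_freqs_truth)) {
    legal <- as.integer(names(pop$allele_freqs_truth[[l]]))
    gl <- g[g$locus == l, ]
    expect_true(all(c(gl$allele1, gl$allele2) %in% legal))
  }
})

test_that("scan samples respect co-residence and exclude the focal", {
  pop <- simulate_population(small_config(seed = 19))
  scans <- simulate_scans(pop, n_scans_per_individual = 12, baseline = 0.1,
                          seed = 2)
  subj <- attr(scans, "subjects")
  expect_true(all(table(scans$focal_id) == 12))
  nb <- strsplit(scans$neighbors, ";", fixed = TRUE)
  for (i in seq_len(nrow(scans))) {
    v <- nb[[i]]
    if (!length(v)) next
    expect_false(scans$focal_id[i] %in% v)
    fg <- subj$current_group[match(scans$focal_id[i], subj$id)]
    expect_true(all(subj$current_group[match(v, subj$id)] == fg))
  }
})

test_that("a dyad with affinity one co-occurs in every scan of both members", {
  subjects <- data.frame(id = c("a", "b", "c", "d"),
                         sex = c("F", "F", "M", "M"),
                         current_group = "G1", stringsAsFactors = FALSE)
  sc <- simulate_scans(subjects, n_scans_per_individual = 30, baseline = 0,
                       dyad_affinity = data.frame(id1 = "a", id2 = "b",
                                                  affinity = 1),
                       unidentified_rate = 0, seed = 4)
  ab <- sc[sc$focal_id %in% c("a", "b"), ]
  expect_true(all(vapply(strsplit(ab$neighbors, ";", fixed = TRUE),
                         function(v) any(v %in% c("a", "b")), logical(1))))
  pr <- compute_proximity(sc, min_scans = 10, subjects = subjects)
  expect_equal(pr$score[pr$id1 == "a" & pr$id2 == "b"], 1)
})

test_that("configured assortment excess is recovered from scan counts", {
  # female-female dyads get baseline + effect; directed co-occurrence counts
  # across many dyads are binomial with that rate
  subjects <- data.frame(id = sprintf("i%03d", 1:40),
                         sex = rep(c("F", "M"), 20),
                         current_group = "G1", stringsAsFactors = FALSE)
  eff <- 0.05
  sc <- simulate_scans(subjects, n_scans_per_individual = 50,
                       baseline = 0.03, assortment_effect = eff,
                       unidentified_rate = 0, seed = 9)
  nb <- strsplit(sc$neighbors, ";", fixed = TRUE)
  sex <- stats::setNames(subjects$sex, subjects$id)
  ff_hits <- 0L; ff_trials <- 0L; other_hits <- 0L; other_trials <- 0L
  for (i in seq_len(nrow(sc))) {
    fs <- sex[[sc$focal_id[i]]]
    partners <- subjects$id[subjects$id != sc$focal_id[i]]
    hit <- partners %in% nb[[i]]
    is_ff <- fs == "F" & sex[partners] == "F"
    ff_hits <- ff_hits + sum(hit[is_ff]); ff_trials <- ff_trials + sum(is_ff)
    other_hits <- other_hits + sum(hit[!is_ff])
    other_trials <- other_trials + sum(!is_ff)
  }
  p_ff <- ff_hits / ff_trials
  p_other <- other_hits / other_trials
  se <- sqrt(p_ff * (1 - p_ff) / ff_trials +
               p_other * (1 - p_other) / other_trials)
  expect_lt(abs((p_ff - p_other) - eff), 3 * se)
})

test_that("tenure records censor correctly at the window end", {
  pop <- simulate_population(small_config(seed = 23))
  ten <- simulate_tenures(pop)
  expect_true(all(ten$duration > 0))
  # a window before any move leaves every record censored
  first_move <- min(pop$membership$start[pop$membership$start > 0])
  early <- simulate_tenures(pop, window = c(0, first_move - 1))
  expect_true(all(!early$event_observed))
  # censored records at the full window are exactly the spells that reach it
  sp <- pop$membership
  expect_equal(sum(!ten$event_observed), sum(sp$end >= pop$t_end))
})

test_that("a male dispersing at 74 months leaves a natal tenure of 74 with an event", {
  pop <- simulate_population(population_config(seed = 1))
  ten <- simulate_tenures(pop)
  ind <- pop$individuals
  moved_males <- ind$id[ind$sex == "M" & ind$true_status == "immigrant"]
  nat <- ten[ten$id %in% moved_males & ten$context == "natal_group", ]
  expect_true(all(nat$duration == 74))
  expect_true(all(nat$event_observed))
})
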