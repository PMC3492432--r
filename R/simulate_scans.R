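#' Simulate instantaneous proximity scan samples
#'
#' Draws scan samples for every subadult and adult member of a simulated
#' population at the analysis time. During each of a focal's scans, every
#' co-resident subject is recorded within one meter independently with a
#' dyad-specific probability: `baseline` for all dyads, plus
#' `assortment_effect` for dyads of class `assort_class` (female-female by
#' default). Explicit per-dyad affinities may override both. With
#' `assortment_effect = 0` all within-group dyad classes are exchangeable, the
#' null the resampling calibration tests rely on. A small fraction of scans is
#' flagged as not fully identified, mirroring field scans in which some
#' neighbors could not be recognized.
#'
#' @param population A `kd_population`, or a data.frame of subjects with
#'   columns `id`, `sex`, `current_group`.
#' @param n_scans_per_individual Scans collected per focal.
#' @param baseline Per-scan probability that a given co-resident is within one
#'   meter of the focal.
#' @param assortment_effect Added to `baseline` for dyads of `assort_class`
#'   (result capped at 1). Must be non-negative.
#' @param assort_class Dyad class (`"FF"`, `"MM"`, or `"MF"`) receiving the
#'   assortment effect.
#' @param dyad_affinity Optional data.frame (`id1`, `id2`, `affinity`) of
#'   per-dyad co-occurrence probabilities overriding the class model.
#' @param unidentified_rate Probability a scan is flagged not fully
#'   identified; defaults to the population's configured rate (or 0).
#' @param seed Integer seed.
#' @return A `kd_scans` data.frame: `focal_id`, `scan_id`, `neighbors`
#'   (`;`-separated ids, `""` when nobody was within one meter), and
#'   `all_identified` (logical). The subject table is attached as attribute
#'   `"subjects"`.
#' @export
simulate_scans <- function(population, n_scans_per_individual = 46,
                           baseline = 0.02, assortment_effect = 0,
                           assort_class = "FF", dyad_affinity = NULL,
                           unidentified_rate = NULL, seed = 1L) {
  if (inherits(population, "kd_population")) {
    subjects <- population$individuals
    subjects <- subjects[subjects$age_class != "juvenile", ]
    if (is.null(unidentified_rate))
      unidentified_rate <- population$config$scan_unidentified_rate
  } else {
    subjects <- as.data.frame(population)
  }
  if (is.null(unidentified_rate)) unidentified_rate <- 0
  stopifnot(all(c("id", "sex", "current_group") %in% names(subjects)))
  if (nrow(subjects) == 0L) stop("no subjects to scan (empty group)")
  if (assortment_effect < 0) stop("`assortment_effect` must be >= 0")
  set.seed(seed)

  aff_key <- character()
  if (!is.null(dyad_affinity)) {
    aff_key <- dyad_key(dyad_affinity$id1, dyad_affinity$id2)
    aff_val <- dyad_affinity$affinity
  }

  rows <- vector("list", nrow(subjects))
  scan0 <- 0L
  for (i in seq_len(nrow(subjects))) {
    focal <- subjects$id[i]
    grp <- subjects$current_group[i]
    co <- subjects[subjects$current_group == grp & subjects$id != focal, ]
    p <- rep(baseline, nrow(co))
    cls <- dyad_class(subjects$sex[i], co$sex)
    p[cls == assort_class] <- pmin(1, baseline + assortment_effect)
    if (length(aff_key)) {
      k <- match(dyad_key(focal, co$id), aff_key)
      p[!is.na(k)] <- aff_val[k[!is.na(k)]]
    }
    n <- n_scans_per_individual
    if (nrow(co)) {
      hits <- matrix(stats::runif(n * nrow(co)) < rep(p, each = n), nrow = n)
      nb <- apply(hits, 1L, function(h) paste(co$id[h], collapse = ";"))
    } else {
      nb <- rep("", n)
    }
    rows[[i]] <- data.frame(
      focal_id = focal,
      scan_id = scan0 + seq_len(n),
      neighbors = nb,
      all_identified = stats::runif(n) >= unidentified_rate,
      stringsAsFactors = FALSE)
    scan0 <- scan0 + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subjects") <- subjects[, c("id", "sex", "current_group")]
  class(out) <- c("kd_scans", "data.frame")
  out
}

#' Dyad class from two sexes
#'
#' @param sex1,sex2 Character vectors of `"F"`/`"M"`.
#' @return `"FF"`, `"MM"`, or `"MF"` (unordered).
#' @export
dyad_class <- function(sex1, sex2) {
  ifelse(sex1 == sex2, ifelse(sex1 == "F", "FF", "MM"), "MF")
}

# canonical unordered dyad key
dyad_key <- function(id1, id2) {
  paste(pmin(id1, id2), pmax(id1, id2), sep = "|")
}

#' Extract right-censorable tenure records from a simulated population
#'
#' Converts the residence spells of a population into tenure records within an
#' observation window. A spell in the individual's birth group is a
#' `natal_group` tenure (duration runs from birth); spells in any other group
#' are `breeding_group` tenures. A record's event is observed when the spell
#' ended (by a group change) inside the window; spells still running at the
#' window end are right-censored there. Spells ending before the window starts
#' are not observed and are dropped.
#'
#' @param population A `kd_population`.
#' @param window Numeric `c(start, end)` observation window in months;
#'   defaults to the full simulated timeline.
#' @return A `kd_tenures` data.frame: `id`, `sex`, `age_class`, `context`
#'   (`natal_group`/`breeding_group`), `group`, `duration` (months),
#'   `event_observed` (logical).
#' @export
simulate_tenures <- function(population, window = NULL) {
  stopifnot(inherits(population, "kd_population"))
  if (is.null(window)) window <- c(0, population$t_end)
  stopifnot(length(window) == 2L, window[1] < window[2])
  sp <- population$membership
  indiv <- population$individuals
  i <- match(sp$id, indiv$id)
  sp$sex <- indiv$sex[i]
  sp$age_class <- indiv$age_class[i]
  sp$context <- ifelse(sp$group == indiv$birth_group[i],
                       "natal_group", "breeding_group")
  # drop spells with no overlap past the window start
  sp <- sp[sp$end > window[1] & sp$start < window[2], ]
  ended <- sp$end <= window[2] & sp$end < population$t_end
  out <- data.frame(id = sp$id, sex = sp$sex, age_class = sp$age_class,
                    context = sp$context, group = sp$group,
                    duration = pmin(sp$end, window[2]) - sp$start,
                    event_observed = ended,
                    stringsAsFactors = FALSE)
  out <- out[out$duration > 0, ]
  rownames(out) <- NULL
  class(out) <- c("kd_tenures", "data.frame")
  out
}
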