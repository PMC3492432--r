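#' Within-group dyadic resampling null
#'
#' Compares the observed mean value of one dyad class (e.g. female-female) in
#' a group against simulated groups built by drawing, in each iteration, the
#' same number of dyads without replacement from all dyads of the group,
#' irrespective of class. Dyads are sampled as units (two sampled dyads may
#' share an individual). Equal-tailed percentile intervals of the simulated
#' means give the 95% and 99% confidence bands; the observed mean is placed
#' above, below, or inside each band.
#'
#' @param values Numeric vector of dyadic values for one group (relatedness
#'   or proximity scores), one entry per unordered within-group dyad.
#' @param classes Character vector of dyad classes (`FF`/`MM`/`MF`) parallel
#'   to `values`.
#' @param target_class The dyad class whose observed mean is tested.
#' @param iterations Number of resampling iterations.
#' @param seed Integer seed.
#' @param group Optional group label carried into the result.
#' @return A `kd_null` one-row data.frame: `group`, `class`, `observed_mean`,
#'   `n_class_dyads`, `n_dyads`, `iterations`, `seed`, `ci95_lower`,
#'   `ci95_upper`, `ci99_lower`, `ci99_upper`, `direction95`, `direction99`
#'   (`above`/`below`/`inside`), `degenerate` (single-dyad group or constant
#'   values), or `NULL` when the group has no dyad of the target class.
#' @export
within_group_null <- function(values, classes, target_class,
                              iterations = 10000L, seed = 1L, group = NA) {
  stopifnot(length(values) == length(classes), iterations >= 1L)
  ok <- !is.na(values)
  values <- values[ok]
  classes <- classes[ok]
  n_dyads <- length(values)
  idx <- which(classes == target_class)
  n_t <- length(idx)
  if (n_t == 0L) return(NULL)
  if (n_t > n_dyads) stop("target class larger than the dyad set")
  observed <- mean(values[idx])
  set.seed(seed)
  sims <- vapply(seq_len(iterations), function(i)
    mean(values[sample.int(n_dyads, n_t)]), numeric(1))
  null_result(group, target_class, observed, n_t, n_dyads,
              iterations, seed, sims,
              degenerate = n_dyads == 1L || diff(range(values)) == 0)
}

null_result <- function(group, class, observed, n_class, n_total,
                        iterations, seed, sims, degenerate = FALSE) {
  q <- stats::quantile(sims, c(0.005, 0.025, 0.975, 0.995), names = FALSE,
                       type = 7)
  dir_of <- function(lo, hi)
    if (observed > hi) "above" else if (observed < lo) "below" else "inside"
  out <- data.frame(group = group, class = class, observed_mean = observed,
                    n_class_dyads = n_class, n_dyads = n_total,
                    iterations = iterations, seed = seed,
                    ci95_lower = q[2L], ci95_upper = q[3L],
                    ci99_lower = q[1L], ci99_upper = q[4L],
                    direction95 = dir_of(q[2L], q[3L]),
                    direction99 = dir_of(q[1L], q[4L]),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("kd_null", "data.frame")
  out
}

#' Run within-group nulls for every group and dyad class
#'
#' @param dyads Data.frame with columns `group`, `class`, and a value column
#'   (`score` or `R`), e.g. a `kd_proximity` table or a relatedness table
#'   augmented with `group`/`class`.
#' @param value Name of the value column.
#' @param classes Dyad classes to test in each group.
#' @param iterations,seed Passed to [within_group_null()]; the seed is offset
#'   deterministically per (group, class) so runs are reproducible yet
#'   independent.
#' @return A `kd_null` data.frame with one row per (group, class) for which a
#'   result exists (classes with no dyads in a group are skipped, like the
#'   empty cells of a results table).
#' @export
run_group_nulls <- function(dyads, value = "score",
                            classes = c("FF", "MM", "MF"),
                            iterations = 10000L, seed = 1L) {
  stopifnot(all(c("group", "class", value) %in% names(dyads)))
  res <- list()
  groups <- sort(unique(dyads$group))
  for (gi in seq_along(groups)) {
    d <- dyads[dyads$group == groups[gi], ]
    for (ci in seq_along(classes)) {
      r <- within_group_null(d[[value]], d$class, classes[ci],
                             iterations = iterations,
                             seed = seed + 131L * gi + ci,
                             group = groups[gi])
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("kd_null", "data.frame")
  out
}

#' Population-level relatedness null for one sex
#'
#' Tests whether the average within-group relatedness for one sex (the mean
#' across groups of each group's mean same-sex dyadic R) exceeds that of
#' simulated groups: in each iteration, every real group is replaced by an
#' equal number of same-sex individuals drawn without replacement from the
#' population-wide pool (draws are independent across simulated groups), the
#' simulated group's mean dyadic R is computed, and the across-group average
#' recorded. Percentile intervals over the iterations give the confidence
#' bands.
#'
#' @param rmat A `kd_relmat` (long dyadic R table).
#' @param members Data.frame (`id`, `sex`, `current_group`) of the
#'   individuals included in the analysis (the pool is all rows of the
#'   requested sex).
#' @param sex `"F"` or `"M"`.
#' @param iterations,seed As in [within_group_null()].
#' @param min_group_size Groups with fewer same-sex members are excluded.
#' @return A `kd_null` one-row data.frame (`group = "population"`, `class` =
#'   `FF` or `MM`), as in [within_group_null()].
#' @export
population_null <- function(rmat, members, sex, iterations = 10000L,
                            seed = 1L, min_group_size = 2L) {
  stopifnot(sex %in% c("F", "M"))
  pool <- members$id[members$sex == sex]
  m <- rel_matrix(rmat)
  pool <- pool[pool %in% rownames(m)]
  grp <- members$current_group[match(pool, members$id)]
  sizes <- table(grp)
  sizes <- sizes[sizes >= min_group_size]
  if (length(sizes) < 2L)
    stop("need at least two groups with >= ", min_group_size,
         " genotyped individuals of sex ", sex)
  if (max(sizes) > length(pool)) stop("a group is larger than the pool")
  mm <- m[pool, pool]
  by_group <- lapply(names(sizes), function(g) which(grp == g))
  grp_mean <- function(ix) {
    sub <- mm[ix, ix]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  observed <- mean(vapply(by_group, grp_mean, numeric(1)))
  k <- as.integer(sizes)
  set.seed(seed)
  sims <- vapply(seq_len(iterations), function(i)
    mean(vapply(k, function(n) grp_mean(sample.int(length(pool), n)),
                numeric(1))), numeric(1))
  n_class <- sum(vapply(k, function(n) n * (n - 1L) / 2L, numeric(1)))
  null_result("population", paste0(sex, sex), observed, n_class,
              length(pool) * (length(pool) - 1L) / 2L,
              iterations, seed, sims,
              degenerate = diff(range(mm[upper.tri(mm)], na.rm = TRUE)) == 0)
}

#' Significance summary of resampling nulls
#'
#' Flags each (group, class) result at the 95% and 99% confidence levels with
#' its direction, in the layout of a results table: one asterisk for a mean
#' outside the 95% band, two for a mean outside the 99% band.
#'
#' @param results A `kd_null` data.frame (rows from [within_group_null()],
#'   [run_group_nulls()] or [population_null()]).
#' @return Data.frame: `group`, `class`, `observed_mean`, `sig95`, `sig99`
#'   (logical), `direction` (`above`/`below`/`none`), `label` (`""`, `"*"`,
#'   or `"**"`).
#' @export
summarize_significance <- function(results) {
  stopifnot(inherits(results, "data.frame"))
  sig95 <- results$direction95 != "inside"
  sig99 <- results$direction99 != "inside"
  data.frame(group = results$group, class = results$class,
             observed_mean = results$observed_mean,
             sig95 = sig95, sig99 = sig99,
             direction = ifelse(sig95, results$direction95, "none"),
             label = ifelse(sig99, "**", ifelse(sig95, "*", "")),
             stringsAsFactors = FALSE)
}
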