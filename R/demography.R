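#' Kaplan-Meier survival curve for group tenure
#'
#' Product-limit estimate of the probability of remaining in the group as a
#' function of tenure length. Censored records (tenures still running at the
#' end of the observation window) reduce the risk set without contributing
#' events; censoring tied with events at the same time is processed after the
#' events. The median tenure is the smallest time at which survival drops to
#' 0.5 or below, and is undefined (`NA`) when survival never reaches 0.5 --
#' as happens when fewer than half of the subjects disperse before the study
#' ends.
#'
#' @param tenures A `kd_tenures` data.frame (`duration`, `event_observed`,
#'   ...), or any data.frame with those columns.
#' @param context Optional filter on the `context` column
#'   (`"natal_group"`/`"breeding_group"`).
#' @param sex Optional filter on the `sex` column.
#' @return A `kd_survcurve` list: `time` (ordered event/censoring times),
#'   `n_risk`, `n_event`, `n_censor`, `survival` (estimate after each time),
#'   `median` (months or `NA`), `n`, `n_events`.
#' @export
kaplan_meier <- function(tenures, context = NULL, sex = NULL) {
  d <- filter_tenures(tenures, context, sex)
  if (!nrow(d)) stop("no tenure records in the requested stratum")
  if (any(d$duration <= 0)) stop("durations must be positive")
  fit <- survival::survfit(
    survival::Surv(d$duration, d$event_observed) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- {
    at <- s$time[s$surv <= 0.5 + 1e-12]
    if (length(at)) min(at) else NA_real_
  }
  structure(list(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                 n_censor = s$n.censor, survival = s$surv,
                 median = med, n = nrow(d), n_events = sum(d$event_observed)),
            class = "kd_survcurve")
}

#' @export
print.kd_survcurve <- function(x, ...) {
  cat(sprintf("<kd_survcurve> n = %d, events = %d, median = %s months\n",
              x$n, x$n_events,
              if (is.na(x$median)) "undefined" else format(x$median)))
  invisible(x)
}

#' Coerce a survival curve to a data.frame
#'
#' @param x A `kd_survcurve`.
#' @param ... Unused.
#' @return Data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
as.data.frame.kd_survcurve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             n_censor = x$n_censor, survival = x$survival)
}

#' Log-rank test between tenure strata
#'
#' Compares the survival (tenure) curves of two or more strata by summing
#' observed and expected dispersal events per stratum over the event times.
#'
#' @param tenures A tenure data.frame.
#' @param by Name of the stratifying column (default `"sex"`).
#' @param context Optional filter on the `context` column.
#' @return A `kd_counttest` list: `observed`, `expected` (per stratum),
#'   `statistic` (chi-square), `df`, `p`, `method = "log_rank"`, `n`.
#' @export
logrank_test <- function(tenures, by = "sex", context = NULL) {
  d <- filter_tenures(tenures, context, NULL)
  stopifnot(by %in% names(d))
  strata <- factor(d[[by]])
  if (nlevels(strata) < 2L) stop("need at least two strata")
  if (any(table(strata) == 0L)) stop("a stratum has zero subjects")
  if (!any(d$event_observed)) stop("no events observed")
  sd <- survival::survdiff(
    survival::Surv(d$duration, d$event_observed) ~ strata)
  df <- length(sd$n) - 1L
  structure(list(observed = stats::setNames(as.vector(sd$obs),
                                            levels(strata)),
                 expected = stats::setNames(as.vector(sd$exp),
                                            levels(strata)),
                 statistic = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 method = "log_rank", n = nrow(d)),
            class = "kd_counttest")
}

#' Sex-bias tests on dispersal event counts
#'
#' Tests whether one sex immigrated to (or emigrated from) groups more often
#' than expected from its share of the population. Expected events for each
#' sex are the total events multiplied by that sex's proportion of the
#' population. `"chi_square_yates"` applies the continuity-corrected
#' goodness-of-fit statistic sum((|O - E| - 0.5)^2 / E) with 1 df (the
#' correction term is floored at zero); `"chi_square"` is the uncorrected
#' version; `"fisher_exact"` tests the 2x2 table of sex by event/non-event by
#' two-sided hypergeometric point-probability enumeration (so population
#' sizes must be at least the event counts).
#'
#' @param events_male,events_female Observed event counts per sex.
#' @param n_male,n_female Number of males and females in the population (the
#'   denominators of the expected proportions).
#' @param method `"chi_square_yates"`, `"chi_square"`, or `"fisher_exact"`.
#' @return A `kd_counttest` list: `observed`, `expected`, `statistic` (`NA`
#'   for Fisher), `df`, `p`, `method`.
#' @export
#' @examples
#' sex_bias_count_test(42, 34, 77, 92, method = "chi_square_yates")
sex_bias_count_test <- function(events_male, events_female, n_male, n_female,
                                method = c("chi_square_yates", "chi_square",
                                           "fisher_exact")) {
  method <- match.arg(method)
  stopifnot(events_male >= 0, events_female >= 0, n_male > 0, n_female > 0)
  tot <- events_male + events_female
  expected <- c(male = tot * n_male / (n_male + n_female),
                female = tot * n_female / (n_male + n_female))
  observed <- c(male = events_male, female = events_female)
  if (method == "fisher_exact") {
    if (events_male > n_male || events_female > n_female)
      stop("event counts exceed population sizes")
    tab <- matrix(c(events_male, n_male - events_male,
                    events_female, n_female - events_female),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(sex = c("male", "female"),
                                  outcome = c("event", "no_event")))
    p <- stats::fisher.test(tab)$p.value
    stat <- NA_real_
  } else {
    if (any(expected == 0)) stop("an expected count is zero")
    dev <- abs(observed - expected)
    if (method == "chi_square_yates") dev <- pmax(dev - 0.5, 0)
    stat <- sum(dev^2 / expected)
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  structure(list(observed = observed, expected = expected,
                 statistic = stat, df = 1L, p = p, method = method),
            class = "kd_counttest")
}

#' @export
print.kd_counttest <- function(x, ...) {
  cat(sprintf("<kd_counttest> %s: ", x$method))
  if (!is.na(x$statistic))
    cat(sprintf("chi-square = %.3g, df = %d, ", x$statistic, x$df))
  cat(sprintf("p = %.3g\n", x$p))
  cat("  observed:", paste(sprintf("%s %g", names(x$observed), x$observed),
                           collapse = ", "), "\n")
  cat("  expected:", paste(sprintf("%s %.2f", names(x$expected), x$expected),
                           collapse = ", "), "\n")
  invisible(x)
}

filter_tenures <- function(tenures, context, sex) {
  d <- as.data.frame(tenures)
  stopifnot(all(c("duration", "event_observed") %in% names(d)))
  if (!is.null(context)) d <- d[d$context %in% context, ]
  if (!is.null(sex)) d <- d[d$sex %in% sex, ]
  d
}
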