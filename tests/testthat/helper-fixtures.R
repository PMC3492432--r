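# shared fixture builders and independent oracles used across test files

# small default population for structural tests
small_config <- function(seed = 1L, ...) {
  population_config(n_groups = 3, founders_per_group = 4, n_generations = 2,
                    n_loci = 12, seed = seed, ...)
}

# group an individual belonged to at time t, from the membership spells
group_at <- function(membership, id, t) {
  sp <- membership[membership$id == id & membership$start <= t &
                     membership$end > t, ]
  if (!nrow(sp)) NA_character_ else sp$group[1L]
}

# long genotype table from a named list: ids -> list of c(a1, a2) per locus
make_genotypes <- function(geno_list, loci = NULL) {
  n_loci <- length(geno_list[[1L]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(n_loci))
  do.call(rbind, lapply(names(geno_list), function(id) {
    g <- geno_list[[id]]
    data.frame(id = id, locus = loci,
               allele1 = vapply(g, `[`, 0L, 1L),
               allele2 = vapply(g, `[`, 0L, 2L),
               stringsAsFactors = FALSE)
  }))
}

# independent single-dyad Queller-Goodnight oracle: plain transcription of
# the published per-locus terms, summed over loci and both directions
qg_oracle <- function(gx, gy, freqs) {
  num <- den <- 0
  for (l in seq_along(freqs)) {
    p <- freqs[[l]]
    a <- gx[[l]][1L]; b <- gx[[l]][2L]
    c_ <- gy[[l]][1L]; d <- gy[[l]][2L]
    pa <- p[[as.character(a)]]; pb <- p[[as.character(b)]]
    pc <- p[[as.character(c_)]]; pd <- p[[as.character(d)]]
    S <- function(u, v) as.numeric(u == v)
    num <- num + (0.5 * (S(a, c_) + S(a, d) + S(b, c_) + S(b, d)) - pa - pb) +
      (0.5 * (S(a, c_) + S(a, d) + S(b, c_) + S(b, d)) - pc - pd)
    den <- den + (1 + S(a, b) - pa - pb) + (1 + S(c_, d) - pc - pd)
  }
  num / den
}

# independent product-limit oracle: step through distinct times, events
# processed before censorings tied at the same time
km_oracle <- function(duration, event) {
  times <- sort(unique(duration))
  s <- 1
  out <- data.frame(time = times, survival = NA_real_)
  at_risk <- length(duration)
  for (i in seq_along(times)) {
    t <- times[i]
    d <- sum(duration == t & event)
    c_ <- sum(duration == t & !event)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$survival[i] <- s
    at_risk <- at_risk - d - c_
  }
  out
}

# independent log-rank oracle: sum of per-time hypergeometric (O - E) and
# variances for stratum 1, chi-square = (sum O - sum E)^2 / sum V
logrank_oracle <- function(duration, event, stratum) {
  times <- sort(unique(duration[event]))
  O <- E <- V <- 0
  for (t in times) {
    at1 <- sum(duration >= t & stratum == levels(factor(stratum))[1L])
    at2 <- sum(duration >= t & stratum != levels(factor(stratum))[1L])
    n <- at1 + at2
    d <- sum(duration == t & event)
    o1 <- sum(duration == t & event &
                stratum == levels(factor(stratum))[1L])
    O <- O + o1
    E <- E + d * at1 / n
    if (n > 1) V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# two-sided Fisher oracle: exhaustive hypergeometric point-probability rule
fisher_oracle <- function(tab) {
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

# minimal tenure-table builder
ten <- function(duration, event, sex = "M", context = "natal_group") {
  data.frame(id = sprintf("t%02d", seq_along(duration)), sex = sex,
             age_class = "adult", context = context, group = "G1",
             duration = duration, event_observed = event,
             stringsAsFactors = FALSE)
}

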