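#' Estimate allele frequencies from a genotype table
#'
#' Frequencies are simple allele counts over all non-missing calls per locus.
#' Loci with no non-missing call are excluded and reported in the
#' `"excluded_loci"` attribute.
#'
#' @param genotypes Long genotype data.frame (`id`, `locus`, `allele1`,
#'   `allele2`), as produced by [simulate_population()] or
#'   [read_genotypes_csv()].
#' @return A `kd_allele_freqs`: a named list, one named numeric vector of
#'   frequencies per locus (summing to 1).
#' @export
estimate_allele_frequencies <- function(genotypes) {
  stopifnot(all(c("id", "locus", "allele1", "allele2") %in% names(genotypes)))
  loci <- unique(genotypes$locus)
  out <- list()
  excluded <- character()
  for (l in loci) {
    d <- genotypes[genotypes$locus == l, ]
    alleles <- c(d$allele1, d$allele2)
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) {
      excluded <- c(excluded, l)
      next
    }
    tab <- table(alleles)
    out[[l]] <- as.numeric(tab) / sum(tab)
    names(out[[l]]) <- names(tab)
  }
  if (length(excluded))
    warning("loci with zero genotype calls excluded: ",
            paste(excluded, collapse = ", "))
  structure(out, excluded_loci = excluded, class = "kd_allele_freqs")
}

#' Pairwise relatedness from STR genotypes
#'
#' Computes dyadic relatedness R for every pair of genotyped individuals with
#' a moment estimator: the symmetrized multilocus Queller-Goodnight estimator
#' (default) or the weighted Lynch-Ritland estimator. For each dyad only loci
#' typed in both members contribute; dyads sharing fewer than
#' `min_shared_loci` typed loci carry no estimate (`NA`).
#'
#' For Queller-Goodnight, per-locus numerators and denominators are summed
#' across loci and across both reference directions before taking the ratio,
#' so uninformative loci (zero denominator) contribute nothing rather than
#' producing indeterminate terms. For Lynch-Ritland, per-locus estimates are
#' combined with the locus weights of the published estimator, again
#' symmetrized over the two reference directions.
#'
#' @param genotypes Long genotype data.frame (`id`, `locus`, `allele1`,
#'   `allele2`).
#' @param freqs A `kd_allele_freqs` (reference allele frequencies); defaults
#'   to frequencies estimated from `genotypes` itself.
#' @param estimator `"queller_goodnight"` or `"lynch_ritland"`.
#' @param min_shared_loci Minimum number of loci typed in both members for a
#'   dyad to receive an estimate.
#' @param dyads Optional data.frame (`id1`, `id2`) restricting the
#'   computation to those dyads; by default every pair of genotyped
#'   individuals is estimated.
#' @return A `kd_relmat` data.frame with one row per unordered dyad: `id1`,
#'   `id2` (with `id1 < id2`), `R`, `n_loci` (shared typed loci). Per
#'   individual counts of typed loci are attached as attribute
#'   `"n_loci_typed"` (named integer vector); the estimator name and the
#'   locus filter as attributes `"estimator"` and `"min_shared_loci"`.
#' @export
estimate_relatedness <- function(genotypes, freqs = NULL,
                                 estimator = c("queller_goodnight",
                                               "lynch_ritland"),
                                 min_shared_loci = 10L, dyads = NULL) {
  estimator <- match.arg(estimator)
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(genotypes)
  loci <- names(freqs)
  ids <- unique(genotypes$id)
  n <- length(ids)
  if (n < 2L) stop("need at least two genotyped individuals")

  # per-locus allele index matrices (n x 2), NA = missing
  a1 <- a2 <- p1 <- p2 <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    d <- genotypes[genotypes$locus == loci[k], ]
    i <- match(ids, d$id)
    x1 <- d$allele1[i]
    x2 <- d$allele2[i]
    pl <- freqs[[loci[k]]]
    q1 <- pl[as.character(x1)]
    q2 <- pl[as.character(x2)]
    if (any(!is.na(x1) & is.na(q1)) || any(!is.na(x2) & is.na(q2)))
      stop("allele frequencies do not cover all observed alleles at locus ",
           loci[k])
    a1[[k]] <- x1; a2[[k]] <- x2
    p1[[k]] <- unname(q1); p2[[k]] <- unname(q2)
  }
  typed <- sapply(seq_along(loci), function(k) !is.na(a1[[k]]))
  n_loci_typed <- as.integer(rowSums(typed))
  names(n_loci_typed) <- ids

  if (is.null(dyads)) {
    ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  } else {
    ii <- match(dyads$id1, ids)
    jj <- match(dyads$id2, ids)
    if (anyNA(ii) || anyNA(jj)) stop("`dyads` reference ungenotyped ids")
  }
  nd <- length(ii)
  num <- den <- numeric(nd)       # QG: summed components; LR: weighted sums
  wsum <- numeric(nd)
  shared <- integer(nd)

  for (k in seq_along(loci)) {
    xa <- a1[[k]][ii]; xb <- a2[[k]][ii]
    yc <- a1[[k]][jj]; yd <- a2[[k]][jj]
    ok <- !is.na(xa) & !is.na(yc)
    if (!any(ok)) next
    shared[ok] <- shared[ok] + 1L
    pa <- p1[[k]][ii]; pb <- p2[[k]][ii]
    pc <- p1[[k]][jj]; pd <- p2[[k]][jj]
    Sac <- (xa == yc); Sad <- (xa == yd)
    Sbc <- (xb == yc); Sbd <- (xb == yd)
    Sab <- (xa == xb); Scd <- (yc == yd)
    if (estimator == "queller_goodnight") {
      nxy <- 0.5 * (Sac + Sad + Sbc + Sbd) - pa - pb
      dxy <- 1 + Sab - pa - pb
      nyx <- 0.5 * (Sac + Sad + Sbc + Sbd) - pc - pd
      dyx <- 1 + Scd - pc - pd
      num[ok] <- num[ok] + (nxy + nyx)[ok]
      den[ok] <- den[ok] + (dxy + dyx)[ok]
    } else {
      rxy <- lr_terms(pa, pb, Sac, Sad, Sbc, Sbd, Sab)
      ryx <- lr_terms(pc, pd, Sac, Sbc, Sad, Sbd, Scd)
      num[ok] <- num[ok] + (rxy$num + ryx$num)[ok]
      wsum[ok] <- wsum[ok] + (rxy$w + ryx$w)[ok]
    }
  }

  R <- if (estimator == "queller_goodnight") num / den else num / wsum
  R[shared < min_shared_loci] <- NA_real_
  out <- data.frame(id1 = pmin(ids[ii], ids[jj]),
                    id2 = pmax(ids[ii], ids[jj]),
                    R = R, n_loci = shared, stringsAsFactors = FALSE)
  structure(out, n_loci_typed = n_loci_typed, estimator = estimator,
            min_shared_loci = as.integer(min_shared_loci),
            class = c("kd_relmat", "data.frame"))
}

# Lynch-Ritland per-locus estimate for reference individual (a,b) vs partner:
# numerator already divided by the common factor so that num/w is the
# weighted multilocus estimate. S* are allele identity indicators.
lr_terms <- function(pa, pb, Sac, Sad, Sbc, Sbd, Sab) {
  numer <- pa * (Sbc + Sbd) + pb * (Sac + Sad) - 4 * pa * pb
  denom <- (1 + Sab) * (pa + pb) - 4 * pa * pb
  w <- denom / (2 * pa * pb)
  list(num = numer / (2 * pa * pb), w = w)
}

#' Symmetric relatedness matrix from a long dyadic table
#'
#' @param rmat A `kd_relmat` (or any data.frame with `id1`, `id2` and a value
#'   column).
#' @param value Name of the value column.
#' @return A symmetric numeric matrix with `NA` diagonal.
#' @export
rel_matrix <- function(rmat, value = "R") {
  ids <- sort(unique(c(rmat$id1, rmat$id2)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(rmat$id1, ids)
  j <- match(rmat$id2, ids)
  m[cbind(i, j)] <- rmat[[value]]
  m[cbind(j, i)] <- rmat[[value]]
  m
}

#' Calibrate the close-kin threshold from known dyads
#'
#' The close-kin threshold is the lowest relatedness estimate observed among
#' known parent-offspring and full-sibling dyads; dyads with R strictly above
#' it are treated as close kin. The maximum known non-kin R is recorded to
#' check whether the two distributions overlap (when they do, threshold-based
#' kin calling is unreliable and the `overlap` flag is set).
#'
#' @param known_kin_R Numeric vector of R estimates for known first-degree kin
#'   dyads (must be non-empty).
#' @param known_nonkin_R Numeric vector of R estimates for known non-kin
#'   dyads (may be empty).
#' @return A `kd_threshold` list: `threshold`, `source` (`"calibrated"`),
#'   `known_kin_min`, `known_nonkin_max` (`-Inf` when no non-kin supplied),
#'   `overlap` (logical).
#' @export
#' @examples
#' calibrate_threshold(c(0.43, 0.51, 0.73), c(0, 0.12, 0.20))$threshold
calibrate_threshold <- function(known_kin_R, known_nonkin_R = numeric()) {
  known_kin_R <- known_kin_R[!is.na(known_kin_R)]
  if (!length(known_kin_R)) stop("`known_kin_R` must be non-empty")
  known_nonkin_R <- known_nonkin_R[!is.na(known_nonkin_R)]
  thr <- min(known_kin_R)
  nk_max <- if (length(known_nonkin_R)) max(known_nonkin_R) else -Inf
  structure(list(threshold = thr, source = "calibrated",
                 known_kin_min = thr, known_nonkin_max = nk_max,
                 overlap = nk_max >= thr),
            class = "kd_threshold")
}

#' Use a fixed close-kin threshold
#'
#' @param threshold Numeric threshold; dyads with R strictly above it are
#'   close kin.
#' @return A `kd_threshold` with `source = "fixed"`.
#' @export
fixed_threshold <- function(threshold) {
  stopifnot(is.finite(threshold))
  structure(list(threshold = threshold, source = "fixed",
                 known_kin_min = NA_real_, known_nonkin_max = -Inf,
                 overlap = FALSE),
            class = "kd_threshold")
}

#' @export
print.kd_threshold <- function(x, ...) {
  cat(sprintf("<kd_threshold> close kin iff R > %.4g (%s)\n",
              x$threshold, x$source))
  if (x$source == "calibrated")
    cat(sprintf("  known-kin min %.4g; known non-kin max %.4g; overlap: %s\n",
                x$known_kin_min, x$known_nonkin_max, x$overlap))
  invisible(x)
}

#' Classify dyads as genetic ties
#'
#' A dyad is a genetic tie when its relatedness estimate is present and
#' strictly above the close-kin threshold. Dyads with no estimate (too few
#' shared typed loci) are unevaluable and never ties; they are returned in
#' the `"unevaluable"` attribute.
#'
#' @param rmat A `kd_relmat`.
#' @param threshold A `kd_threshold`, or a single finite number.
#' @return A `kd_ties` data.frame (`id1`, `id2`, `R`) of genetic ties, with
#'   the unevaluable dyads (`id1`, `id2`) as attribute `"unevaluable"` and
#'   the threshold as attribute `"threshold"`.
#' @export
classify_genetic_ties <- function(rmat, threshold) {
  if (inherits(threshold, "kd_threshold")) threshold <- threshold$threshold
  stopifnot(is.finite(threshold))
  uneval <- rmat[is.na(rmat$R), c("id1", "id2")]
  ties <- rmat[!is.na(rmat$R) & rmat$R > threshold, c("id1", "id2", "R")]
  rownames(ties) <- rownames(uneval) <- NULL
  structure(ties, unevaluable = uneval, threshold = threshold,
            class = c("kd_ties", "data.frame"))
}
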