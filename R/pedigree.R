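#' Offspring map from a pedigree
#'
#' @param individuals Data.frame with `id`, `mother_id`, `father_id`.
#' @return Named list: for each parent id, the character vector of its
#'   offspring ids.
#' @export
pedigree_offspring <- function(individuals) {
  links <- rbind(
    data.frame(parent = individuals$mother_id, child = individuals$id,
               stringsAsFactors = FALSE),
    data.frame(parent = individuals$father_id, child = individuals$id,
               stringsAsFactors = FALSE))
  links <- links[!is.na(links$parent), ]
  split(links$child, links$parent)
}

#' Pedigree relationship of a dyad
#'
#' Classifies a dyad from pedigree links: `parent_offspring`, `full_sib`
#' (both parents shared), `half_sib` (exactly one parent shared), `non_kin`
#' (no shared ancestor at any depth and neither is an ancestor of the other),
#' or `other_kin`.
#'
#' @param individuals Pedigree data.frame (`id`, `mother_id`, `father_id`).
#' @param id1,id2 Individual ids (vectorized, equal length).
#' @return Character vector of relationship labels.
#' @export
pedigree_relationship <- function(individuals, id1, id2) {
  mo <- stats::setNames(individuals$mother_id, individuals$id)
  fa <- stats::setNames(individuals$father_id, individuals$id)
  anc <- ancestor_sets(individuals)
  vapply(seq_along(id1), function(k) {
    a <- id1[k]; b <- id2[k]
    if ((!is.na(mo[a]) && mo[a] == b) || (!is.na(fa[a]) && fa[a] == b) ||
        (!is.na(mo[b]) && mo[b] == a) || (!is.na(fa[b]) && fa[b] == a))
      return("parent_offspring")
    sm <- !is.na(mo[a]) && !is.na(mo[b]) && mo[a] == mo[b]
    sf <- !is.na(fa[a]) && !is.na(fa[b]) && fa[a] == fa[b]
    if (sm && sf) return("full_sib")
    if (sm || sf) return("half_sib")
    if (!length(intersect(c(a, anc[[a]]), c(b, anc[[b]])))) return("non_kin")
    "other_kin"
  }, character(1))
}

ancestor_sets <- function(individuals) {
  mo <- stats::setNames(individuals$mother_id, individuals$id)
  fa <- stats::setNames(individuals$father_id, individuals$id)
  anc <- list()
  get_anc <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    out <- character()
    for (p in c(mo[[id]], fa[[id]])) {
      if (!is.na(p)) out <- c(out, p, get_anc(p))
    }
    out <- unique(out)
    anc[[id]] <<- out
    out
  }
  for (id in individuals$id) get_anc(id)
  anc
}

#' Known-kin and known-non-kin dyads from pedigree truth
#'
#' Collects the relatedness estimates of pedigree parent-offspring and
#' full-sibling dyads (the known close kin used to calibrate the close-kin
#' threshold) and of a sample of pedigree non-kin dyads.
#'
#' A field study only ever has a modest panel of demographically confirmed
#' dyads, so both lists are subsampled deterministically (first in dyad
#' order) to panel sizes typical of such studies; the close-kin threshold is
#' the minimum R over the kin panel, and panel size governs how far that
#' minimum sits below the expected first-degree relatedness of 0.5.
#'
#' @param individuals Pedigree data.frame.
#' @param rmat A `kd_relmat`.
#' @param n_kin,n_nonkin Panel sizes for known first-degree kin and known
#'   non-kin dyads.
#' @return Data.frame: `id1`, `id2`, `relation`, `R` (estimated dyads only).
#' @export
known_dyads_from_pedigree <- function(individuals, rmat, n_kin = 55L,
                                      n_nonkin = 45L) {
  d <- rmat[!is.na(rmat$R), ]
  rel <- pedigree_relationship(individuals, d$id1, d$id2)
  kin <- d[rel %in% c("parent_offspring", "full_sib"), c("id1", "id2", "R")]
  kin$relation <- rel[rel %in% c("parent_offspring", "full_sib")]
  if (nrow(kin) > n_kin) kin <- kin[seq_len(n_kin), ]
  nk <- d[rel == "non_kin", c("id1", "id2", "R")]
  if (nrow(nk) > n_nonkin) nk <- nk[seq_len(n_nonkin), ]
  if (nrow(nk)) nk$relation <- "non_kin"
  out <- rbind(kin, nk)
  rownames(out) <- NULL
  out[, c("id1", "id2", "relation", "R")]
}

#' Simulate genotyped dyads of a fixed pedigree category
#'
#' Draws independent dyads of a single relationship category (unrelated,
#' parent-offspring, full siblings, half siblings) from Dirichlet-drawn
#' allele frequencies, for estimator-recovery checks. Each dyad is founded
#' independently; the returned table genotypes the two members of every dyad
#' at every locus with no missingness.
#'
#' @param n_dyads Number of dyads.
#' @param category `"unrelated"`, `"parent_offspring"`, `"full_sib"`, or
#'   `"half_sib"`.
#' @param n_loci,alleles_per_locus,concentration Locus model as in
#'   [population_config()].
#' @param seed Integer seed.
#' @return List: `genotypes` (long table), `dyads` (data.frame `id1`, `id2`),
#'   `freqs` (true allele frequencies, a `kd_allele_freqs`).
#' @export
simulate_kin_dyads <- function(n_dyads, category = c("unrelated",
                                                     "parent_offspring",
                                                     "full_sib", "half_sib"),
                               n_loci = 20L, alleles_per_locus = 8L,
                               concentration = 1, seed = 1L) {
  category <- match.arg(category)
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  labels <- 100L + 2L * (seq_len(alleles_per_locus) - 1L)
  freqs <- lapply(loci, function(l) {
    g <- stats::rgamma(alleles_per_locus, shape = concentration)
    stats::setNames(g / sum(g), labels)
  })
  names(freqs) <- loci
  draw <- function() unlist(lapply(freqs, function(p)
    resample(as.integer(names(p)), 2L, replace = TRUE, prob = p)))
  child_of <- function(a, b) transmit_alleles(a, b, n_loci)
  g1 <- g2 <- matrix(0L, n_dyads, 2L * n_loci)
  for (i in seq_len(n_dyads)) {
    switch(category,
           unrelated = {
             g1[i, ] <- draw(); g2[i, ] <- draw()
           },
           parent_offspring = {
             p <- draw(); q <- draw()
             g1[i, ] <- p; g2[i, ] <- child_of(p, q)
           },
           full_sib = {
             p <- draw(); q <- draw()
             g1[i, ] <- child_of(p, q); g2[i, ] <- child_of(p, q)
           },
           half_sib = {
             p <- draw(); q1 <- draw(); q2 <- draw()
             g1[i, ] <- child_of(p, q1); g2[i, ] <- child_of(p, q2)
           })
  }
  ids1 <- sprintf("D%04da", seq_len(n_dyads))
  ids2 <- sprintf("D%04db", seq_len(n_dyads))
  geno <- rbind(genotype_long(ids1, g1, loci), genotype_long(ids2, g2, loci))
  list(genotypes = geno,
       dyads = data.frame(id1 = ids1, id2 = ids2, stringsAsFactors = FALSE),
       freqs = structure(freqs, class = "kd_allele_freqs"))
}
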