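#' Build the genetic-tie network
#'
#' Nodes are individuals annotated with sex, current group, generation,
#' known dispersal status, and the number of loci at which they were typed;
#' undirected edges are genetic ties (close-kin dyads) weighted by R.
#'
#' @param ties A `kd_ties` data.frame (`id1`, `id2`, `R`) from
#'   [classify_genetic_ties()].
#' @param individuals Data.frame with columns `id`, `sex`, `current_group`,
#'   and optionally `generation`, `known_status`, `age_class`.
#' @param n_loci_typed Optional named integer vector (per-individual typed
#'   locus counts, e.g. `attr(rmat, "n_loci_typed")`).
#' @param adults_only If `TRUE`, keep only adults (requires an `age_class`
#'   column); subadults and their edges are dropped.
#' @return An [igraph::igraph] object (class also `kd_network`).
#' @export
build_kin_network <- function(ties, individuals, n_loci_typed = NULL,
                              adults_only = FALSE) {
  stopifnot(all(c("id", "sex", "current_group") %in% names(individuals)))
  missing_ids <- setdiff(c(ties$id1, ties$id2), individuals$id)
  if (length(missing_ids))
    stop("ties reference unknown individuals: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  v <- data.frame(name = individuals$id,
                  sex = individuals$sex,
                  group = individuals$current_group,
                  stringsAsFactors = FALSE)
  v$generation <- if ("generation" %in% names(individuals))
    individuals$generation else NA_integer_
  v$known_status <- if ("known_status" %in% names(individuals))
    individuals$known_status else "unknown"
  v$age_class <- if ("age_class" %in% names(individuals))
    individuals$age_class else NA_character_
  v$n_loci_typed <- if (!is.null(n_loci_typed))
    as.integer(n_loci_typed[v$name]) else NA_integer_
  if (adults_only) {
    if (all(is.na(v$age_class)))
      stop("`adults_only` requires an `age_class` column")
    v <- v[v$age_class == "adult", ]
    ties <- ties[ties$id1 %in% v$name & ties$id2 %in% v$name, ]
  }
  e <- data.frame(from = ties$id1, to = ties$id2, R = ties$R,
                  stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
  class(g) <- c("kd_network", class(g))
  g
}

#' Genetic clusters of a kin network
#'
#' Clusters are the connected components of the genetic-tie graph.
#'
#' @param network A `kd_network` from [build_kin_network()].
#' @return Named integer vector mapping each individual to a cluster label;
#'   component sizes are attached as attribute `"sizes"`.
#' @export
find_clusters <- function(network) {
  comp <- igraph::components(network)
  structure(comp$membership, sizes = comp$csize)
}

#' Assign likely dispersal status from the distribution of close kin
#'
#' For every individual that passes the per-individual locus filter, counts
#' its close kin (network neighbors) per group, excluding the focal's own
#' co-residing offspring from the current-group count (a parent may have
#' immigrated before the offspring was born, so a co-residing offspring is
#' not evidence of natality). An individual whose current group holds strictly
#' fewer counted close kin than some other group is a likely immigrant; one
#' whose current group holds strictly more than every other group is likely
#' natal. When the current group ties with exactly one other group, the tie is
#' broken by the known-or-likely statuses of the tied kin themselves: all
#' current-group kin natal and all other-group kin immigrant makes the focal
#' likely natal, and vice versa. Because the tie rules reference "known or
#' likely" status, assignment sweeps to a fixed point: likely statuses settled
#' in one sweep feed tie rules in the next, with synchronous updates so the
#' result does not depend on iteration order. Individuals with no counted
#' close kin are unassigned (`no_close_kin`); ties among three or more groups
#' and tie rules that never resolve are unassigned (`unresolved`).
#'
#' Individuals with known status keep it for propagation (they are never
#' reassigned), but each also receives a shadow assignment computed by the
#' same rules, which [evaluate_assignments()] compares against the known
#' status to measure the method's accuracy.
#'
#' @param network A `kd_network`; vertex attributes `group`, `known_status`
#'   and `n_loci_typed` are used.
#' @param offspring Optional named list mapping an individual id to the ids
#'   of its offspring (pedigree truth in synthetic data; an age/maternity
#'   table for field data).
#' @param min_loci_typed Per-individual locus filter; vertices typed at fewer
#'   loci are not evaluated (`NA` typed counts pass).
#' @param max_sweeps Upper bound on propagation sweeps (defaults to the node
#'   count).
#' @return A `kd_assignments` data.frame: `id`, `sex`, `group`,
#'   `known_status`, `assigned` (`likely_natal` / `likely_immigrant` /
#'   `unknown`), `basis` (`count_majority` / `tie_rule` / `no_close_kin` /
#'   `unresolved`, `NA` for unevaluated individuals), `eligible`, and
#'   `kin_counts` (per-group counted close kin, serialized `group:count;...`).
#' @export
assign_dispersal_status <- function(network, offspring = NULL,
                                    min_loci_typed = 10L, max_sweeps = NULL) {
  ids <- igraph::V(network)$name
  grp <- igraph::V(network)$group
  sex <- igraph::V(network)$sex
  known <- igraph::V(network)$known_status
  if (is.null(known)) known <- rep("unknown", length(ids))
  known[is.na(known)] <- "unknown"
  nlt <- igraph::V(network)$n_loci_typed
  if (is.null(nlt)) nlt <- rep(NA_integer_, length(ids))
  eligible <- is.na(nlt) | nlt >= min_loci_typed
  names(grp) <- names(known) <- names(eligible) <- ids
  if (is.null(max_sweeps)) max_sweeps <- length(ids)

  adj <- igraph::as_adj_list(network)
  nbrs <- lapply(adj, function(v) ids[as.integer(v)])
  names(nbrs) <- ids

  # static per-focal counted kin (offspring excluded from current group)
  counted <- lapply(ids, function(f) {
    nb <- nbrs[[f]]
    if (!is.null(offspring) && length(offspring[[f]]))
      nb <- nb[!(nb %in% offspring[[f]] & grp[nb] == grp[[f]])]
    nb
  })
  names(counted) <- ids
  counts <- lapply(ids, function(f) {
    nb <- counted[[f]]
    if (!length(nb)) return(integer())
    tab <- table(grp[nb])
    stats::setNames(as.integer(tab), names(tab))
  })
  names(counts) <- ids

  eff_status <- function(state, who) {
    s <- state[who]
    ifelse(s %in% c("natal", "likely_natal"), "natal",
           ifelse(s %in% c("immigrant", "likely_immigrant"), "immigrant",
                  "unknown"))
  }

  # returns c(assigned, basis) or NULL when the tie rule cannot fire yet
  classify_one <- function(f, state) {
    ct <- counts[[f]]
    if (!sum(ct)) return(c("unknown", "no_close_kin"))
    cur <- if (grp[[f]] %in% names(ct)) ct[[grp[[f]]]] else 0L
    others <- ct[setdiff(names(ct), grp[[f]])]
    maxo <- if (length(others)) max(others) else 0L
    if (cur < maxo) return(c("likely_immigrant", "count_majority"))
    if (cur > maxo) return(c("likely_natal", "count_majority"))
    tied <- names(others)[others == maxo]
    if (length(tied) != 1L) return(c("unknown", "unresolved"))
    nb <- counted[[f]]
    cur_kin <- eff_status(state, nb[grp[nb] == grp[[f]]])
    oth_kin <- eff_status(state, nb[grp[nb] == tied])
    if (all(cur_kin == "natal") && all(oth_kin == "immigrant"))
      return(c("likely_natal", "tie_rule"))
    if (all(cur_kin == "immigrant") && all(oth_kin == "natal"))
      return(c("likely_immigrant", "tie_rule"))
    NULL
  }

  state <- known                       # propagation state
  assigned <- stats::setNames(rep("unknown", length(ids)), ids)
  basis <- stats::setNames(rep(NA_character_, length(ids)), ids)
  open <- ids[eligible & known == "unknown"]
  for (sweep in seq_len(max_sweeps)) {
    res <- lapply(open, classify_one, state = state)
    names(res) <- open
    settled <- open[!vapply(res, is.null, logical(1))]
    for (f in settled) {
      assigned[f] <- res[[f]][1L]
      basis[f] <- res[[f]][2L]
    }
    # synchronous update: state changes only after the whole sweep
    firm <- settled[assigned[settled] != "unknown"]
    progressed <- length(firm) > 0L
    state[firm] <- assigned[firm]
    open <- setdiff(open, settled)
    if (!length(open) || !progressed) break
  }
  if (length(open)) {           # tie rules that never fired
    assigned[open] <- "unknown"
    basis[open] <- "unresolved"
  }

  # shadow assignments for known-status individuals, using others' statuses
  for (f in ids[eligible & known != "unknown"]) {
    res <- classify_one(f, state)
    if (is.null(res)) res <- c("unknown", "unresolved")
    assigned[f] <- res[1L]
    basis[f] <- res[2L]
  }

  serial <- vapply(ids, function(f) {
    ct <- counts[[f]]
    if (!length(ct)) return("")
    paste(sprintf("%s:%d", names(ct), ct), collapse = ";")
  }, character(1))

  out <- data.frame(id = ids, sex = sex, group = unname(grp),
                    known_status = unname(known),
                    assigned = unname(assigned), basis = unname(basis),
                    eligible = unname(eligible), kin_counts = unname(serial),
                    stringsAsFactors = FALSE)
  out$assigned[!out$eligible] <- "unknown"
  out$basis[!out$eligible] <- NA_character_
  class(out) <- c("kd_assignments", "data.frame")
  out
}

#' Accuracy of network-based status assignment
#'
#' Compares the shadow assignments of individuals whose dispersal status is
#' known from the demographic record with that known status, over the
#' individuals that pass the locus filter. An assignment is correct when
#' `likely_natal` meets `natal` or `likely_immigrant` meets `immigrant`,
#' incorrect when crossed, and unassigned when `unknown`. The three
#' percentages partition the evaluation set.
#'
#' @param assignments A `kd_assignments` from [assign_dispersal_status()].
#' @return A `kd_confusion` list: `table` (known status x assigned cell
#'   counts), `n`, `correct_pct`, `incorrect_pct`, `unassigned_pct`.
#' @export
evaluate_assignments <- function(assignments) {
  ev <- assignments[assignments$eligible &
                      assignments$known_status != "unknown", ]
  if (!nrow(ev)) stop("no individuals with known status to evaluate")
  tab <- table(known = ev$known_status,
               assigned = factor(ev$assigned,
                                 levels = c("likely_natal",
                                            "likely_immigrant", "unknown")))
  correct <- sum(ev$known_status == "natal" & ev$assigned == "likely_natal") +
    sum(ev$known_status == "immigrant" & ev$assigned == "likely_immigrant")
  incorrect <- sum(ev$known_status == "natal" &
                     ev$assigned == "likely_immigrant") +
    sum(ev$known_status == "immigrant" & ev$assigned == "likely_natal")
  unassigned <- sum(ev$assigned == "unknown")
  n <- nrow(ev)
  structure(list(table = tab, n = n,
                 correct_pct = 100 * correct / n,
                 incorrect_pct = 100 * incorrect / n,
                 unassigned_pct = 100 * unassigned / n),
            class = "kd_confusion")
}

#' @export
print.kd_confusion <- function(x, ...) {
  cat(sprintf("<kd_confusion> %d known-status individuals evaluated\n", x$n))
  cat(sprintf("  correct %.0f%%, incorrect %.0f%%, unassigned %.0f%%\n",
              x$correct_pct, x$incorrect_pct, x$unassigned_pct))
  print(x$table)
  invisible(x)
}
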