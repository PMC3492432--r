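#' Dyadic proximity scores from scan samples
#'
#' The proximity score of a dyad (A, B) is the mean of two directed
#' proportions: the proportion of A's retained scans in which B was within
#' one meter, and the proportion of B's retained scans in which A was within
#' one meter. Scans flagged as not fully identified are dropped first (when
#' `drop_unidentified`), and individuals with fewer than `min_scans` retained
#' scans receive no scores. Scores are computed only for dyads co-resident in
#' the same group when a subject table with group membership is available.
#'
#' @param scans A `kd_scans` data.frame (`focal_id`, `scan_id`, `neighbors`
#'   as a `;`-separated string, `all_identified`), e.g. from
#'   [simulate_scans()] or [read_scans_csv()].
#' @param min_scans Minimum retained scans for an individual to enter the
#'   score matrix.
#' @param drop_unidentified Drop scans whose neighbors were not all
#'   identified.
#' @param subjects Optional data.frame (`id`, `sex`, `current_group`)
#'   restricting scores to within-group dyads and supplying dyad classes;
#'   defaults to the scan set's `"subjects"` attribute.
#' @return A `kd_proximity` data.frame with one row per scored dyad: `id1`,
#'   `id2`, `score`, `p12` (proportion of id1's scans containing id2), `p21`,
#'   and, when sexes are known, `class` (`FF`/`MM`/`MF`) and `group`.
#'   Retained scan counts per individual are attached as attribute
#'   `"n_scans_used"`.
#' @export
compute_proximity <- function(scans, min_scans = 10L,
                              drop_unidentified = TRUE, subjects = NULL) {
  stopifnot(all(c("focal_id", "scan_id", "neighbors") %in% names(scans)))
  if (is.null(subjects)) subjects <- attr(scans, "subjects")
  if (min_scans < 1L) stop("`min_scans` must be >= 1")
  sc <- as.data.frame(scans)
  if (drop_unidentified && "all_identified" %in% names(sc))
    sc <- sc[as.logical(sc$all_identified), ]

  n_scans <- table(sc$focal_id)
  keep <- names(n_scans)[n_scans >= min_scans]
  sc <- sc[sc$focal_id %in% keep, ]
  if (!nrow(sc)) stop("no individuals retain enough scans")

  nb_list <- strsplit(sc$neighbors, ";", fixed = TRUE)
  len <- lengths(nb_list)
  pairs <- data.frame(focal = rep(sc$focal_id, len),
                      nbr = unlist(nb_list), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$nbr != "", ]
  if (any(pairs$focal == pairs$nbr))
    stop("a focal appears in its own neighbor set")
  # directed co-occurrence counts among retained individuals
  pairs <- pairs[pairs$nbr %in% keep, ]

  if (nrow(pairs)) {
    key <- paste(pairs$focal, pairs$nbr, sep = "\r")
    cnt <- table(key)
    uk <- strsplit(names(cnt), "\r", fixed = TRUE)
    directed <- data.frame(focal = vapply(uk, `[`, "", 1L),
                           nbr = vapply(uk, `[`, "", 2L),
                           n = as.integer(cnt), stringsAsFactors = FALSE)
  } else {
    directed <- data.frame(focal = character(), nbr = character(),
                           n = integer(), stringsAsFactors = FALSE)
  }

  # all unordered dyads among retained individuals (within-group if known)
  ids <- sort(keep)
  if (!is.null(subjects)) {
    ids <- ids[ids %in% subjects$id]
    grp <- subjects$current_group[match(ids, subjects$id)]
    sexv <- subjects$sex[match(ids, subjects$id)]
    split_ids <- split(ids, grp)
  } else {
    split_ids <- list(ids)
    grp <- sexv <- NULL
  }
  dy <- do.call(rbind, lapply(split_ids, function(v) {
    if (length(v) < 2L) return(NULL)
    cmb <- utils::combn(v, 2L)
    data.frame(id1 = cmb[1L, ], id2 = cmb[2L, ], stringsAsFactors = FALSE)
  }))
  if (is.null(dy) || !nrow(dy)) stop("no within-group dyads to score")
  rownames(dy) <- NULL

  nsc <- as.integer(n_scans[ids])
  names(nsc) <- ids
  dkey <- paste(directed$focal, directed$nbr, sep = "\r")
  c12 <- directed$n[match(paste(dy$id1, dy$id2, sep = "\r"), dkey)]
  c21 <- directed$n[match(paste(dy$id2, dy$id1, sep = "\r"), dkey)]
  c12[is.na(c12)] <- 0L
  c21[is.na(c21)] <- 0L
  dy$p12 <- c12 / nsc[dy$id1]
  dy$p21 <- c21 / nsc[dy$id2]
  dy$score <- (dy$p12 + dy$p21) / 2
  if (!is.null(sexv)) {
    s1 <- sexv[match(dy$id1, ids)]
    s2 <- sexv[match(dy$id2, ids)]
    dy$class <- dyad_class(s1, s2)
    dy$group <- grp[match(dy$id1, ids)]
  }
  dy <- dy[, c("id1", "id2", "score", "p12", "p21",
               intersect(c("class", "group"), names(dy)))]
  structure(dy, n_scans_used = nsc,
            class = c("kd_proximity", "data.frame"))
}
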