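#' Read and write the package's plain-text data formats
#'
#' All tables are plain CSV with a header row. Missing genotype calls are
#' empty fields; scan neighbor sets are `;`-separated id lists;
#' `all_identified` and `event_observed` are 0/1.
#'
#' @param genotypes,path,scans,x Tables and file paths.
#' @return Readers return data.frames (with the classes used elsewhere in the
#'   package); writers return the path invisibly.
#' @name kindisp_io
NULL

#' @rdname kindisp_io
#' @export
write_genotypes_csv <- function(genotypes, path) {
  d <- genotypes[, c("id", "locus", "allele1", "allele2")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname kindisp_io
#' @export
read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character", locus = "character"))
  d$allele1 <- suppressWarnings(as.integer(d$allele1))
  d$allele2 <- suppressWarnings(as.integer(d$allele2))
  d
}

#' @rdname kindisp_io
#' @export
write_scans_csv <- function(scans, path) {
  d <- as.data.frame(scans)[, c("focal_id", "scan_id", "neighbors",
                                "all_identified")]
  d$all_identified <- as.integer(d$all_identified)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname kindisp_io
#' @export
read_scans_csv <- function(path, subjects = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(focal_id = "character",
                                      neighbors = "character"))
  d$neighbors[is.na(d$neighbors)] <- ""
  d$all_identified <- as.logical(d$all_identified)
  attr(d, "subjects") <- subjects
  class(d) <- c("kd_scans", "data.frame")
  d
}

#' @rdname kindisp_io
#' @export
write_table_csv <- function(x, path) {
  d <- as.data.frame(x)
  if ("event_observed" %in% names(d))
    d$event_observed <- as.integer(d$event_observed)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname kindisp_io
#' @export
read_known_dyads_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id1", "id2", "relation") %in% names(d)))
  ok <- d$relation %in% c("parent_offspring", "full_sib", "non_kin")
  if (!all(ok)) stop("unknown relation labels: ",
                     paste(unique(d$relation[!ok]), collapse = ", "))
  d
}

#' Export genotypes as GenePop-style text
#'
#' Two-column-per-locus text export (three-digit allele codes, one population
#' block) for interoperability with population-genetics software. Missing
#' calls are written as `000000`.
#'
#' @param genotypes Long genotype data.frame.
#' @param path Output file.
#' @param title Header line.
#' @return The path, invisibly.
#' @export
write_genepop <- function(genotypes, path, title = "kindisp export") {
  loci <- sort(unique(genotypes$locus))
  ids <- unique(genotypes$id)
  lines <- c(title, loci, "POP")
  code <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a %% 1000L))
  for (id in ids) {
    d <- genotypes[genotypes$id == id, ]
    g <- vapply(loci, function(l) {
      r <- d[d$locus == l, ]
      if (!nrow(r)) "000000"
      else paste0(code(r$allele1[1L]), code(r$allele2[1L]))
    }, character(1))
    lines <- c(lines, paste0(id, " ,  ", paste(g, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
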