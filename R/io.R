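## Plain-text I/O for interaction networks.
## Edge lists are TSV with header `source target weight class`, `#` comments,
## 1-based species ids and class tokens M / L / H.  Adjacency matrices are
## headerless CSV, one row per source species.

#' Write a community as a TSV edge list
#'
#' Emits one line per nonzero directed entry, ordered by class (M, L, H),
#' then source, then target, with weights printed at full double precision so
#' that write -> read -> write is byte-identical.
#'
#' @param com a \code{\link{coop_community}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edgelist <- function(com, path) {
  stopifnot(inherits(com, "coop_community"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# coopnet edge list",
               sprintf("# S = %d", com$S),
               "source\ttarget\tweight\tclass"), con)
  for (cls in c("M", "L", "H")) {
    Q <- com[[cls]]
    nz <- which(Q != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
      writeLines(sprintf("%d\t%d\t%s\t%s", nz[, 1], nz[, 2],
                         sprintf("%.17g", Q[nz]), cls), con)
    }
  }
  invisible(path)
}

#' Read a community from a TSV edge list
#'
#' Parses the format written by \code{\link{write_edgelist}} and validates
#' all interaction-matrix constraints on load; a load with any violation is
#' rejected with an itemized report.
#'
#' @param path input file path.
#' @param S number of species (ids must lie in \code{1..S}).
#' @param eps1,eps2,eps3 intensities for the returned community.
#' @return a \code{\link{coop_community}}.
#' @export
read_edgelist <- function(path, S, eps1 = 1, eps2 = 1, eps3 = 1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^source\\b", lines[[1]])) lines <- lines[-1]
  S <- as.integer(S)
  M <- matrix(0, S, S); L <- matrix(0, S, S); H <- matrix(0, S, S)
  errs <- character(0)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      if (length(p) != 4L) { errs <- c(errs, sprintf("line %d: expected 4 fields", k)); next }
      i <- suppressWarnings(as.integer(p[1])); j <- suppressWarnings(as.integer(p[2]))
      w <- suppressWarnings(as.numeric(p[3])); cls <- p[4]
      if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > S || j > S) {
        errs <- c(errs, sprintf("line %d: species ids must be in 1..%d", k, S)); next
      }
      if (is.na(w)) { errs <- c(errs, sprintf("line %d: non-numeric weight", k)); next }
      if (!cls %in% c("M", "L", "H")) {
        errs <- c(errs, sprintf("line %d: unknown interaction class '%s'", k, cls)); next
      }
      Q <- switch(cls, M = M, L = L, H = H)
      if (Q[i, j] != 0) {
        errs <- c(errs, sprintf("line %d: duplicate directed edge %d->%d in class %s",
                                k, i, j, cls)); next
      }
      if (cls == "M") M[i, j] <- w else if (cls == "L") L[i, j] <- w else H[i, j] <- w
    }
  }
  if (length(errs)) stop("edge list rejected:\n  ", paste(errs, collapse = "\n  "))
  com <- structure(list(M = M, L = L, H = H, eps1 = eps1, eps2 = eps2,
                        eps3 = eps3, S = S), class = "coop_community")
  bad <- validate_interactions(com)
  if (length(bad)) stop("edge list rejected (constraint violations):\n  ",
                        paste(bad, collapse = "\n  "))
  com
}

#' Write / read a single matrix as headerless CSV
#'
#' @param Q square matrix.
#' @param path file path.
#' @return \code{write_adjacency}: \code{path} invisibly;
#'   \code{read_adjacency}: the matrix.
#' @export
write_adjacency <- function(Q, path) {
  .check_square(Q, "Q")
  utils::write.table(Q, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
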