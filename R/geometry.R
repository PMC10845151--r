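## Geometry construction and XYZ input/output.

#' Create a Geometry
#'
#' @param symbols character vector of element symbols (H, C, N, O).
#' @param coords numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @return A \linkS4class{Geometry}.
#' @export
#' @examples
#' Geometry(c("O", "H", "H"),
#'          rbind(c(0, 0, 0.119), c(0, 0.763, -0.477), c(0, -0.763, -0.477)))
Geometry <- function(symbols, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  new("Geometry", symbols = as.character(symbols), coords = coords)
}

#' Read molecular geometries from an XYZ file
#'
#' Standard multi-record XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom, repeated for each record.
#'
#' @param path file path.
#' @return A list of \linkS4class{Geometry} objects, named by the comment
#'   lines where non-empty.
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  out <- list(); nm <- character(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    if (i + 1L + n > length(lines))
      stop("malformed XYZ: truncated record at line ", i, call. = FALSE)
    comment <- trimws(lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    sym <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    out[[length(out) + 1L]] <- Geometry(sym, xyz)
    nm <- c(nm, comment)
    i <- i + 2L + n
  }
  if (any(nzchar(nm))) names(out) <- nm
  out
}

#' Write geometries to an XYZ file
#'
#' @param geoms a \linkS4class{Geometry} or list of them.
#' @param path output file path.
#' @param comments optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(geoms, path, comments = NULL) {
  if (is(geoms, "Geometry")) geoms <- list(geoms)
  if (is.null(comments)) comments <- names(geoms)
  if (is.null(comments)) comments <- rep("", length(geoms))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(geoms)) {
    g <- geoms[[k]]
    writeLines(as.character(nAtoms(g)), con)
    writeLines(comments[k], con)
    writeLines(sprintf("%-2s %15.8f %15.8f %15.8f", g@symbols,
                       g@coords[, 1], g@coords[, 2], g@coords[, 3]), con)
  }
  invisible(path)
}

## All-pairs Euclidean distances for one geometry.
.distanceMatrix <- function(geom) {
  as.matrix(stats::dist(geom@coords))
}
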