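## Dataset curation: keep a reaction only if its low-level TS optimization
## succeeded and both IRC endpoints match the dataset reactant/product in
## connectivity (adjacency-eigenvalue fingerprints) and conformation
## (weighted-adjacency fingerprints on the low-level optimized structures).

#' Create a RawRecord
#'
#' @param id identifier.
#' @param dftReactant,dftProduct dataset geometries at the reference level.
#' @param tsOptOk did the low-level TS optimization succeed.
#' @param ircFwd,ircRev IRC endpoint geometries (forward / reverse direction).
#' @param optEndpointFwd,optEndpointRev low-level optimized IRC endpoints.
#' @param optDatasetReactant,optDatasetProduct low-level optimized dataset
#'   structures.
#' @return A \linkS4class{RawRecord}.
#' @export
RawRecord <- function(id, dftReactant, dftProduct, tsOptOk,
                      ircFwd, ircRev, optEndpointFwd, optEndpointRev,
                      optDatasetReactant, optDatasetProduct) {
  new("RawRecord", id = as.character(id), dftReactant = dftReactant,
      dftProduct = dftProduct, tsOptOk = tsOptOk, ircFwd = ircFwd,
      ircRev = ircRev, optEndpointFwd = optEndpointFwd,
      optEndpointRev = optEndpointRev,
      optDatasetReactant = optDatasetReactant,
      optDatasetProduct = optDatasetProduct)
}

.CURATION_REASONS <- c("ok", "ts_opt_failed", "connectivity_mismatch",
                       "conformation_mismatch")

#' Curate one raw record
#'
#' Decision flow: (1) discard if the TS optimization failed; (2) build graphs
#' for both IRC endpoints and both dataset structures and try both direction
#' assignments (forward endpoint as reactant, then the swap) — if neither
#' assignment matches connectivity for both pairs, discard; (3) for the
#' matched assignment, compare the low-level optimized endpoint against the
#' low-level optimized dataset structure with the weighted fingerprint — any
#' mismatch discards the record as a different conformer. Ties between the two
#' assignments break in favor of forward-as-reactant.
#'
#' @param r a \linkS4class{RawRecord}.
#' @param connectivity_tol eigenvalue tolerance for connectivity (default
#'   1e-4).
#' @param conformation_tol eigenvalue tolerance for conformation (default
#'   1e-3).
#' @param scale bond-detection scale.
#' @return A list with `id`, `kept` (logical), `reason` (one of ok,
#'   ts_opt_failed, connectivity_mismatch, conformation_mismatch) and
#'   `direction` ("fwd_is_reactant", "rev_is_reactant" or NA).
#' @export
curateRecord <- function(r, connectivity_tol = 1e-4, conformation_tol = 1e-3,
                         scale = 1.2) {
  stopifnot(is(r, "RawRecord"))
  res <- function(kept, reason, direction = NA_character_)
    list(id = r@id, kept = kept, reason = reason, direction = direction)
  if (!r@tsOptOk) return(res(FALSE, "ts_opt_failed"))

  gR <- buildGraph(r@dftReactant, scale)
  gP <- buildGraph(r@dftProduct, scale)
  gF <- buildGraph(r@ircFwd, scale)
  gV <- buildGraph(r@ircRev, scale)

  fwd_ok <- sameConnectivity(gF, gR, connectivity_tol) &&
            sameConnectivity(gV, gP, connectivity_tol)
  rev_ok <- sameConnectivity(gV, gR, connectivity_tol) &&
            sameConnectivity(gF, gP, connectivity_tol)
  if (!fwd_ok && !rev_ok) return(res(FALSE, "connectivity_mismatch"))
  direction <- if (fwd_ok) "fwd_is_reactant" else "rev_is_reactant"

  if (direction == "fwd_is_reactant") {
    pairs <- list(list(r@optEndpointFwd, r@optDatasetReactant),
                  list(r@optEndpointRev, r@optDatasetProduct))
  } else {
    pairs <- list(list(r@optEndpointRev, r@optDatasetReactant),
                  list(r@optEndpointFwd, r@optDatasetProduct))
  }
  conf_ok <- all(vapply(pairs, function(pr)
    sameConformation(pr[[1]], pr[[2]], conformation_tol, scale), logical(1)))
  if (!conf_ok) return(res(FALSE, "conformation_mismatch", direction))
  res(TRUE, "ok", direction)
}

#' Curate a list of raw records
#'
#' Applies \code{\link{curateRecord}} to every record, preserving order.
#'
#' @param records list of \linkS4class{RawRecord} objects.
#' @param ... tolerances passed to \code{\link{curateRecord}}.
#' @return A list with `reports` (data.frame: id, kept, reason, direction),
#'   `kept_ids` (character) and `summary` (named integer counts per reason,
#'   always covering all four reasons and summing to the input size).
#' @export
curateDataset <- function(records, ...) {
  reports <- lapply(records, curateRecord, ...)
  df <- data.frame(
    id = vapply(reports, `[[`, "", "id"),
    kept = vapply(reports, `[[`, NA, "kept"),
    reason = vapply(reports, `[[`, "", "reason"),
    direction = vapply(reports, `[[`, "", "direction"),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(df$reason, levels = .CURATION_REASONS))
  summary <- stats::setNames(as.integer(counts), .CURATION_REASONS)
  stopifnot(sum(summary) == length(records))
  list(reports = df, kept_ids = df$id[df$kept], summary = summary)
}

#' Write a curation report to disk
#'
#' Writes the per-record table as TSV and the per-reason summary as JSON.
#'
#' @param curation result of \code{\link{curateDataset}}.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @return `curation`, invisibly.
#' @export
writeCurationReport <- function(curation, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(curation$reports, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(curation$summary), json_path,
                         auto_unbox = TRUE)
  invisible(curation)
}
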