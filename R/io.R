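## JSON record schema: one object per reaction, with species blocks carrying
## energy/zpe/frequencies/homo/lumo/bond_orders/self_polarizability plus the
## geometry (symbols + coordinates), and top-level smiles and bh_dft.

.speciesToList <- function(sp) {
  list(energy = sp@energy, zpe = sp@zpe, frequencies = sp@frequencies,
       homo = sp@homo, lumo = sp@lumo,
       bond_orders = unname(sp@bondOrders),
       self_polarizability = sp@selfPolarizability,
       symbols = sp@geometry@symbols,
       coords = unname(sp@geometry@coords))
}

.speciesFromList <- function(x) {
  SQMSpecies(energy = x$energy, zpe = x$zpe,
             frequencies = unlist(x$frequencies),
             homo = x$homo, lumo = x$lumo,
             bondOrders = .asMatrix(x$bond_orders),
             selfPolarizability = x$self_polarizability,
             geometry = Geometry(unlist(x$symbols), .asMatrix(x$coords)))
}

.asMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, unlist))
}

#' Write reaction records to JSON
#'
#' @param records list of \linkS4class{ReactionRecord} objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path) {
  objs <- lapply(records, function(r)
    list(id = r@id, smiles_reactant = r@smilesReactant,
         smiles_product = r@smilesProduct, bh_dft = r@bhDft,
         reactant = .speciesToList(r@reactant),
         ts = .speciesToList(r@ts),
         product = .speciesToList(r@product)))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reaction records from JSON
#'
#' @param path path to a file written by \code{\link{writeRecords}}.
#' @return List of \linkS4class{ReactionRecord} objects.
#' @export
readRecords <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(objs, function(x)
    ReactionRecord(x$id, .speciesFromList(x$reactant),
                   .speciesFromList(x$ts), .speciesFromList(x$product),
                   x$bh_dft, x$smiles_reactant, x$smiles_product))
}

#' Export a feature matrix
#'
#' CSV of the matrix plus a JSON sidecar with column names and families.
#'
#' @param m a \linkS4class{FeatureMatrix}.
#' @param csv_path CSV output path; the sidecar is `<csv_path>.json`.
#' @return `csv_path`, invisibly.
#' @export
writeFeatures <- function(m, csv_path) {
  utils::write.csv(as.data.frame(featureValues(m)), csv_path,
                   row.names = TRUE)
  jsonlite::write_json(list(names = featureNames(m),
                            family = featureFamilies(m)),
                       paste0(csv_path, ".json"))
  invisible(csv_path)
}
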