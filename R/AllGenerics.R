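#' Accessors for cfmdock data classes
#'
#' Number of heavy atoms, residues and fragments; Laplacian and C-alpha
#' coordinate extraction. Prefer these over direct slot access.
#'
#' @param x a cfmdock S4 object.
#' @return `nAtoms`, `nResidues`, `nFragments` return integer counts;
#'   `laplacian` the Laplacian matrix; `caCoords` the residue C-alpha
#'   coordinate matrix; `resolvedSequence` the per-chain resolved sequence
#'   strings.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))
#' @rdname accessors
#' @export
setGeneric("laplacian", function(x) standardGeneric("laplacian"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("resolvedSequence", function(x) standardGeneric("resolvedSequence"))

#' @rdname accessors
setMethod("nAtoms", "LigandGraph", function(x) length(x@elements))
#' @rdname accessors
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atomCoords))
#' @rdname accessors
setMethod("nResidues", "ProteinStructure", function(x) length(x@sequence))
#' @rdname accessors
setMethod("nFragments", "LigandGraph", function(x) length(unique(x@fragmentId)))
#' @rdname accessors
setMethod("laplacian", "LigandGraph", function(x) x@laplacian)
#' @rdname accessors
setMethod("caCoords", "ProteinStructure", function(x)
  x@atomCoords[x@caIndex, , drop = FALSE])

#' @rdname accessors
setMethod("resolvedSequence", "ProteinStructure", function(x) {
  vapply(split(x@sequence, x@chainId), paste0, character(1), collapse = "")
})

setMethod("show", "LigandGraph", function(object) {
  cat(sprintf(
    "LigandGraph: %d heavy atoms, %d bonds, %d fragment(s)%s\n",
    nAtoms(object), nrow(object@bonds), nFragments(object),
    if (nzchar(object@smiles)) sprintf(" [%s]", object@smiles) else ""
  ))
  cat("  elements:", paste(object@elements, collapse = " "), "\n")
})

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf(
    "ProteinStructure: %d residue(s) in %d chain(s), %d heavy atoms\n",
    nResidues(object), length(unique(object@chainId)), nAtoms(object)
  ))
  sq <- paste(object@sequence, collapse = "")
  if (nchar(sq) > 60) sq <- paste0(substr(sq, 1, 57), "...")
  cat("  sequence:", sq, "\n")
})

setMethod("show", "ComplexState", function(object) {
  cat(sprintf(
    "ComplexState at t = %.4f: %d protein / %d ligand heavy atoms\n",
    object@time, nrow(object@proteinCoords), nrow(object@ligandCoords)
  ))
})

setMethod("show", "PairRecord", function(object) {
  m <- object@metrics
  cat(sprintf(
    "PairRecord '%s': %d residues, %d ligand atoms, affinity %s pK\n",
    object@id, nResidues(object@holo), nAtoms(object@ligand),
    ifelse(is.na(object@affinityPk), "NA", sprintf("%.2f", object@affinityPk))
  ))
  if (length(m))
    cat(sprintf("  tm = %.3f, caRmsd = %.3f A, accepted = %s\n",
                m$tm, m$caRmsd, object@accepted))
})

setMethod("show", "Prediction", function(object) {
  cat(sprintf(
    "Prediction: %d protein / %d ligand atoms, mean confidence %.3f, affinity %.2f pK\n",
    nrow(object@predProtein), nrow(object@predLigand),
    mean(object@confidence), object@affinityPk
  ))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d states from t=0 to t=1, mean confidence %.3f\n",
    length(object@states), mean(object@final@confidence)
  ))
})
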