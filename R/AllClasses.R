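#' @import methods
NULL

#' Ligand bond-graph with Laplacian
#'
#' Heavy-atom bond topology of one or more ligand fragments ("."-separated
#' SMILES components). Holds the binary adjacency matrix \eqn{A}, the diagonal
#' degree matrix \eqn{D} and the graph Laplacian \eqn{L = D - A} that defines
#' the harmonic conformational prior, together with a deterministic reference
#' 3D conformer used for bond-length bookkeeping.
#'
#' @slot elements character vector, element symbol per heavy atom.
#' @slot bonds integer matrix with two columns, unordered atom-index pairs
#'   (1-based), no self-loops, no duplicates.
#' @slot fragmentId integer vector, connected-component label per atom.
#' @slot adjacency,degree,laplacian numeric matrices \eqn{A}, \eqn{D},
#'   \eqn{L = D - A}.
#' @slot refCoords numeric matrix (atoms x 3), reference conformer in Angstrom.
#' @slot smiles the SMILES string the graph was built from ("" if none).
#'
#' @seealso [parseSmiles()], [buildLaplacian()], [sampleHarmonicLigand()]
#' @export
setClass("LigandGraph", representation(
  elements = "character",
  bonds = "matrix",
  fragmentId = "integer",
  adjacency = "matrix",
  degree = "matrix",
  laplacian = "matrix",
  refCoords = "matrix",
  smiles = "character"
))

setValidity("LigandGraph", function(object) {
  n <- length(object@elements)
  msgs <- character(0)
  if (n < 1L) msgs <- c(msgs, "ligand must contain at least one heavy atom")
  b <- object@bonds
  if (nrow(b) > 0) {
    if (any(b[, 1] == b[, 2])) msgs <- c(msgs, "bonds contain self-loops")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key)) msgs <- c(msgs, "bonds contain duplicates")
    if (any(b < 1L) || any(b > n)) msgs <- c(msgs, "bond indices out of range")
  }
  A <- object@adjacency; D <- object@degree; L <- object@laplacian
  if (!all(dim(A) == c(n, n)) || !all(dim(L) == c(n, n)))
    msgs <- c(msgs, "matrix dimensions inconsistent with atom count")
  else {
    if (max(abs(L - (D - A))) > 1e-12) msgs <- c(msgs, "L != D - A")
    if (max(abs(L - t(L))) > 1e-12) msgs <- c(msgs, "L not symmetric")
    if (max(abs(rowSums(L))) > 1e-9) msgs <- c(msgs, "L rows do not sum to 0")
  }
  if (length(object@fragmentId) != n)
    msgs <- c(msgs, "fragmentId length mismatch")
  if (nrow(object@refCoords) != n || ncol(object@refCoords) != 3)
    msgs <- c(msgs, "refCoords must be atoms x 3")
  if (length(msgs)) msgs else TRUE
})

#' Protein structure with heavy-atom coordinates
#'
#' Residue sequence plus heavy-atom coordinates for one or more chains, with
#' per-residue C-alpha indexing. Residue indices are 0-based internally and
#' 1-based in files; atom order is file order.
#'
#' @slot sequence character vector of one-letter residue codes (length
#'   \eqn{S_P}).
#' @slot chainId character vector, chain identifier per residue.
#' @slot atomCoords numeric matrix (\eqn{N_P} x 3), Angstrom.
#' @slot atomToResidue integer vector, residue index (1-based into
#'   \code{sequence}) per heavy atom.
#' @slot caIndex integer vector, heavy-atom row of the C-alpha of each residue.
#' @slot atomNames character vector, PDB atom name per heavy atom.
#' @slot resNumbers integer vector, author residue numbers per residue.
#'
#' @seealso [readProteinPDB()]
#' @export
setClass("ProteinStructure", representation(
  sequence = "character",
  chainId = "character",
  atomCoords = "matrix",
  atomToResidue = "integer",
  caIndex = "integer",
  atomNames = "character",
  resNumbers = "integer"
))

setValidity("ProteinStructure", function(object) {
  sp <- length(object@sequence)
  np <- nrow(object@atomCoords)
  msgs <- character(0)
  if (sp < 1L) msgs <- c(msgs, "at least one residue required")
  if (np < sp) msgs <- c(msgs, "fewer heavy atoms than residues")
  if (!all(is.finite(object@atomCoords))) msgs <- c(msgs, "non-finite coordinates")
  if (length(object@caIndex) != sp)
    msgs <- c(msgs, "every residue needs exactly one C-alpha index")
  else if (any(object@caIndex < 1L) || any(object@caIndex > np))
    msgs <- c(msgs, "caIndex out of range")
  if (length(object@atomToResidue) != np)
    msgs <- c(msgs, "atomToResidue length mismatch")
  else if (!setequal(unique(object@atomToResidue), seq_len(sp)))
    msgs <- c(msgs, "atomToResidue must be surjective onto residues")
  if (length(object@chainId) != sp) msgs <- c(msgs, "chainId length mismatch")
  if (length(msgs)) msgs else TRUE
})

#' Joint protein/ligand coordinates at a flow time
#'
#' State of the complex along the conditional path: protein and ligand
#' heavy-atom coordinates plus the flow time \eqn{t \in [0, 1]} (0 = prior,
#' 1 = bound).
#'
#' @slot proteinCoords numeric matrix (\eqn{N_P} x 3), Angstrom.
#' @slot ligandCoords numeric matrix (\eqn{N_L} x 3), Angstrom.
#' @slot time scalar flow time in \eqn{[0, 1]}.
#' @export
setClass("ComplexState", representation(
  proteinCoords = "matrix",
  ligandCoords = "matrix",
  time = "numeric"
))

setValidity("ComplexState", function(object) {
  msgs <- character(0)
  if (ncol(object@proteinCoords) != 3 || ncol(object@ligandCoords) != 3)
    msgs <- c(msgs, "coordinates must have 3 columns")
  if (length(object@time) != 1L || object@time < -1e-12 || object@time > 1 + 1e-12)
    msgs <- c(msgs, "time must be a scalar in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Apo/holo training pair
#'
#' One curated example: an unbound (apo) structure, the bound (holo) crystal
#' structure of the same sequence, the ligand bond graph with its holo pose,
#' and an optional binding affinity label in pK units (-log10 Kd/Ki).
#'
#' @slot apo,holo [ProteinStructure-class] objects sharing a sequence.
#' @slot ligand a [LigandGraph-class].
#' @slot holoLigandCoords numeric matrix (\eqn{N_L} x 3), bound ligand pose.
#' @slot affinityPk scalar pK label (NA when unlabeled).
#' @slot fullSequence intended complete chain sequence(s) for gap checking,
#'   named by chain.
#' @slot id identifier used in manifests.
#' @slot accepted logical, set by [acceptPair()]/[curateDataset()].
#' @slot metrics list with tm / caRmsd once assessed.
#' @export
setClass("PairRecord", representation(
  apo = "ProteinStructure",
  holo = "ProteinStructure",
  ligand = "LigandGraph",
  holoLigandCoords = "matrix",
  affinityPk = "numeric",
  fullSequence = "character",
  id = "character",
  accepted = "logical",
  metrics = "list"
))

setValidity("PairRecord", function(object) {
  msgs <- character(0)
  if (!identical(object@apo@sequence, object@holo@sequence))
    msgs <- c(msgs, "apo and holo must share a residue sequence")
  if (nrow(object@holoLigandCoords) != length(object@ligand@elements))
    msgs <- c(msgs, "holo ligand coordinates inconsistent with bond graph")
  if (length(msgs)) msgs else TRUE
})

#' Model output for one complex
#'
#' Predicted holo coordinates, per-residue confidence in \eqn{[0, 1]}
#' (plDDT-style) and predicted binding affinity in pK units.
#'
#' @slot predProtein numeric matrix (\eqn{N_P} x 3).
#' @slot predLigand numeric matrix (\eqn{N_L} x 3).
#' @slot confidence numeric vector, one value per residue, in \eqn{[0, 1]}.
#' @slot affinityPk scalar, pK units.
#' @export
setClass("Prediction", representation(
  predProtein = "matrix",
  predLigand = "matrix",
  confidence = "numeric",
  affinityPk = "numeric"
))

setValidity("Prediction", function(object) {
  msgs <- character(0)
  if (!all(is.finite(object@predProtein)) || !all(is.finite(object@predLigand)))
    msgs <- c(msgs, "non-finite predicted coordinates")
  if (any(object@confidence < -1e-9) || any(object@confidence > 1 + 1e-9))
    msgs <- c(msgs, "confidence must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Generation trajectory
#'
#' Ordered [ComplexState-class] list from \eqn{t = 0} to \eqn{t = 1}
#' (\eqn{i + 1} entries for an \eqn{i}-step solver) plus the final
#' [Prediction-class] used for ranking.
#'
#' @slot states list of [ComplexState-class], times strictly increasing,
#'   first 0, last 1.
#' @slot final a [Prediction-class].
#' @export
setClass("Trajectory", representation(
  states = "list",
  final = "Prediction"
))

setValidity("Trajectory", function(object) {
  times <- vapply(object@states, function(s) s@time, numeric(1))
  msgs <- character(0)
  if (length(times) < 2L) msgs <- c(msgs, "trajectory needs at least 2 states")
  else {
    if (any(diff(times) <= 0)) msgs <- c(msgs, "times must be strictly increasing")
    if (abs(times[1]) > 1e-12 || abs(times[length(times)] - 1) > 1e-12)
      msgs <- c(msgs, "trajectory must run from t=0 to t=1")
  }
  if (length(msgs)) msgs else TRUE
})
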