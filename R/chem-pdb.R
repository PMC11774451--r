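## Protein structure I/O. Single-model parsing goes through bio3d; the
## multi-MODEL complex/trajectory writer emits fixed-width PDB records itself
## because bio3d writes one model per file.

#' Read a protein structure from a PDB file
#'
#' Keeps heavy atoms of standard amino-acid residues only. Alternate locations
#' are resolved by highest occupancy, then first seen. Residues without a
#' C-alpha and non-standard residues are dropped with a warning. Multiple
#' chains are concatenated into one structure with per-residue chain ids.
#'
#' @param path PDB file path.
#' @return a [ProteinStructure-class].
#' @export
readProteinPDB <- function(path) {
  if (!file.exists(path)) stop_input("no such PDB file: %s", path)
  ## pre-scan for malformed coordinate fields so errors carry a line number
  raw <- readLines(path)
  atomLines <- grep("^(ATOM  |HETATM)", raw)
  for (ln in atomLines) {
    fields <- c(substr(raw[ln], 31, 38), substr(raw[ln], 39, 46),
                substr(raw[ln], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop_input("malformed coordinates at line %d of %s", ln, path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop_input("cannot parse PDB %s: %s",
                                                 path, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop_input("no parseable residues in %s", path)
  ## standard residues only
  nonstd <- unique(at$resid[!(at$resid %in% names(AA3TO1))])
  if (length(nonstd)) {
    warning(sprintf("dropping non-standard residue type(s): %s",
                    paste(nonstd, collapse = ", ")))
    at <- at[at$resid %in% names(AA3TO1), , drop = FALSE]
  }
  ## heavy atoms only
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(gsub("[0-9]", "", at$elety), 1, 1)[
    is.na(elem) | elem == ""]
  at <- at[toupper(elem) != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop_input("no parseable residues in %s", path)
  ## altloc: per (chain, resno, insert, atom name) keep highest occupancy,
  ## then first seen
  at$.fileOrder <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, at$.fileOrder)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$.fileOrder), , drop = FALSE]  # restore file order
  ## group into residues (file order)
  rkey <- paste(at$chain, at$resno, at$insert)
  rid <- match(rkey, unique(rkey))
  hasCA <- tapply(at$elety == "CA", rid, any)
  if (any(!hasCA)) {
    warning(sprintf("dropping %d residue(s) lacking a C-alpha", sum(!hasCA)))
    keep <- hasCA[as.character(rid)]
    at <- at[keep, , drop = FALSE]
    rkey <- paste(at$chain, at$resno, at$insert)
    rid <- match(rkey, unique(rkey))
  }
  if (nrow(at) == 0L) stop_input("no parseable residues in %s", path)
  sp <- max(rid)
  firstOfRes <- match(seq_len(sp), rid)
  seqv <- unname(AA3TO1[at$resid[firstOfRes]])
  new("ProteinStructure",
      sequence = seqv,
      chainId = at$chain[firstOfRes],
      atomCoords = cbind(at$x, at$y, at$z),
      atomToResidue = as.integer(rid),
      caIndex = vapply(seq_len(sp), function(r)
        which(rid == r & at$elety == "CA")[1], integer(1)),
      atomNames = at$elety,
      resNumbers = as.integer(at$resno[firstOfRes]))
}

.AA1TO3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

.pdbAtomLine <- function(record, serial, name, resid, chain, resno, xyz, elem) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000, name4, resid, chain, resno %% 10000,
          xyz[1], xyz[2], xyz[3], 1, 0, elem)
}

## PDB records for one complex state (protein ATOM + ligand HETATM).
.complexModelLines <- function(structure, graph, proteinCoords, ligandCoords) {
  np <- nAtoms(structure)
  res3 <- .AA1TO3[structure@sequence]
  lines <- character(0)
  for (i in seq_len(np)) {
    r <- structure@atomToResidue[i]
    lines <- c(lines, .pdbAtomLine(
      "ATOM", i, structure@atomNames[i], res3[r], structure@chainId[r],
      structure@resNumbers[r], proteinCoords[i, ],
      substr(gsub("[0-9]", "", structure@atomNames[i]), 1, 1)))
  }
  lines <- c(lines, "TER")
  for (j in seq_len(nAtoms(graph))) {
    lines <- c(lines, .pdbAtomLine(
      "HETATM", np + j, paste0(graph@elements[j], j), "LIG", "X", 1,
      ligandCoords[j, ], graph@elements[j]))
  }
  lines
}

#' Write a protein-ligand complex (or trajectory) to PDB + SDF
#'
#' The protein is written as ATOM records, the ligand as HETATM records, and a
#' ligand SDF is written alongside (same path with extension `.sdf`). A list of
#' states is written as a MODEL/ENDMDL multi-model trajectory.
#'
#' @param structure a [ProteinStructure-class].
#' @param graph a [LigandGraph-class].
#' @param state a [ComplexState-class] or a list of them (trajectory).
#' @param path output PDB path.
#' @return the PDB path, invisibly.
#' @export
writeComplex <- function(structure, graph, state, path) {
  states <- if (is(state, "ComplexState")) list(state) else state
  for (s in states) {
    if (nrow(s@proteinCoords) != nAtoms(structure) ||
        nrow(s@ligandCoords) != nAtoms(graph))
      stop_input("state atom counts inconsistent with structure/graph")
  }
  lines <- character(0)
  for (k in seq_along(states)) {
    lines <- c(lines, sprintf("MODEL     %4d", k),
               .complexModelLines(structure, graph,
                                  states[[k]]@proteinCoords,
                                  states[[k]]@ligandCoords),
               "ENDMDL")
  }
  lines <- c(lines, "END")
  atomic_write_lines(lines, path)
  last <- states[[length(states)]]
  writeLigandSDF(graph, last@ligandCoords, sub("\\.pdb$", ".sdf", path))
  invisible(path)
}

#' Check a resolved structure against its intended full sequence
#'
#' TRUE iff, chain by chain and in order, the structure's resolved residue
#' sequence equals the supplied full sequence exactly. Any unresolved residue
#' (gap) or mismatch yields FALSE; used to drop gapped crystal structures
#' during curation.
#'
#' @param fullSequence a character vector of complete chain sequences. Either
#'   unnamed in chain order or named by chain id.
#' @param structure a [ProteinStructure-class].
#' @return logical scalar.
#' @export
checkSequenceGaps <- function(fullSequence, structure) {
  resolved <- resolvedSequence(structure)
  if (!is.null(names(fullSequence)) && all(nzchar(names(fullSequence)))) {
    if (!setequal(names(fullSequence), names(resolved))) return(FALSE)
    fullSequence <- fullSequence[names(resolved)]
  } else if (length(fullSequence) != length(resolved)) {
    return(FALSE)
  }
  all(unname(fullSequence) == unname(resolved))
}

#' Read chain sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop_input("no such FASTA file: %s", path)
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
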