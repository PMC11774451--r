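## Shared fixtures, generated in code at test time.

## A random connected-or-not bond graph on n atoms (Erdos-Renyi-ish, then
## bonds deduplicated); used for Laplacian/harmonic property tests.
randomBondGraph <- function(n, pEdge = 0.3) {
  bonds <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(bonds)) < pEdge
  bonds <- bonds[keep, , drop = FALSE]
  elements <- sample(c("C", "N", "O"), n, replace = TRUE)
  cfmdock:::.makeLigandGraph(elements, bonds)
}

## Small deterministic protein for I/O and alignment tests.
tinyProtein <- function(nRes = 5L, seed = 11L) {
  withr::with_seed(seed, {
    p <- makeToyComplex(toyComplexSpec(nResidues = nRes, seed = seed))
    p@holo
  })
}

## Write a minimal hand-crafted PDB file; returns the path.
writeTinyPDB <- function(path, withHydrogens = FALSE, gapped = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  CYS A   2       3.300   1.700   0.700  1.00  0.00           C",
    if (withHydrogens)
      "ATOM      5  H   CYS A   2       3.400   2.000   1.700  1.00  0.00           H",
    if (!gapped)
      "ATOM      6  CA  ASP A   3       5.100   2.100   1.200  1.00  0.00           C",
    "END")
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  path
}

## Pair with controlled TM/RMSD used for boundary tests: apo differs from holo
## by a calibrated deformation.
syntheticPairAt <- function(seed = 1L) {
  makeToyComplex(toyComplexSpec(seed = seed))
}
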