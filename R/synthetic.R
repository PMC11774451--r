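## Deterministic toy apo/holo protein-ligand complexes: an ideal helix with
## one pseudo side-chain atom per residue, a pocket near the helix midpoint,
## a ligand posed deterministically in the local pocket frame, an apo state
## generated by a hinge motion of the C-terminal half, and affinity labels
## that are an exact linear function of protein-ligand contacts (before
## clipping).

#' The fixed toy ligand library
#'
#' Ten small SMILES strings (mostly high-symmetry fragments, including one
#' multi-fragment entry) used by the toy-complex generator.
#'
#' @return character vector of 10 SMILES.
#' @export
toyLigandLibrary <- function() {
  c("O", "C", "N", "CC", "CO", "C=O", "OCO", "C1CC1", "CC.O", "c1ccccc1")
}

#' Toy complex specification
#'
#' @param nResidues helix length (default 24).
#' @param ligandSpec SMILES from [toyLigandLibrary()]; by default chosen from
#'   the library by `seed %% 10`.
#' @param hingeAngle apo-vs-holo hinge rotation of the C-terminal half, in
#'   degrees. The default is calibrated so that generated pairs satisfy the
#'   coupling-filter thresholds (TM-score >= 0.7, C-alpha RMSD < 5 Angstrom).
#' @param noiseScale Gaussian jitter applied to apo atoms, Angstrom.
#' @param seed integer seed; drives the sequence, jitter and ligand choice.
#' @return a list of class `"ToyComplexSpec"`.
#' @export
toyComplexSpec <- function(nResidues = 24L, ligandSpec = NULL,
                           hingeAngle = 8, noiseScale = 0.1, seed = 0L) {
  if (is.null(ligandSpec))
    ligandSpec <- toyLigandLibrary()[(seed %% 10) + 1]
  structure(list(nResidues = as.integer(nResidues), ligandSpec = ligandSpec,
                 hingeAngle = hingeAngle, noiseScale = noiseScale,
                 seed = as.integer(seed)),
            class = "ToyComplexSpec")
}

## Ideal helix C-alpha trace plus one pseudo side-chain atom (CB) per residue.
.helixProtein <- function(nRes, sequence) {
  i <- seq_len(nRes) - 1
  ang <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  cb <- cbind(3.8 * cos(ang), 3.8 * sin(ang), 1.5 * i)
  coords <- matrix(0, 2 * nRes, 3)
  coords[2 * i + 1, ] <- ca
  coords[2 * i + 2, ] <- cb
  center <- colMeans(coords)
  coords <- sweep(coords, 2, center)
  new("ProteinStructure",
      sequence = sequence, chainId = rep("A", nRes),
      atomCoords = coords,
      atomToResidue = rep(seq_len(nRes), each = 2L),
      caIndex = as.integer(2 * i + 1),
      atomNames = rep(c("CA", "CB"), nRes),
      resNumbers = seq_len(nRes))
}

## Rotation matrix for angle (rad) about unit axis u (Rodrigues).
.axisRotation <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  Kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * Kx + (1 - cos(angle)) * Kx %*% Kx
}

## Deterministic principal-axis frame of a point cloud with canonical signs.
.canonicalFrame <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  eg <- eigen(crossprod(cc) + diag(1e-9, 3), symmetric = TRUE)
  V <- eg$vectors
  for (k in 1:3) {
    s <- sum((cc %*% V[, k])^3)
    if (abs(s) < 1e-9) s <- V[which.max(abs(V[, k])), k]
    if (s < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Generate one toy apo/holo complex
#'
#' Builds the holo helix, defines the pocket as the 6 residues nearest the
#' helix midpoint, poses the ligand with its fragment centroids at the pocket
#' center (stacked along the helix axis for multi-fragment ligands) and its
#' principal axes aligned to the local pocket frame, derives the apo state by
#' a hinge rotation of the C-terminal half about the midpoint plus Gaussian
#' jitter, and labels affinity as
#' \eqn{pK = \mathrm{clip}(2 + 0.25 \cdot \#\{\mathrm{contacts} < 4\ \AA\},
#' 2, 12)}.
#'
#' @param spec a `"ToyComplexSpec"` from [toyComplexSpec()].
#' @return a [PairRecord-class]; bit-identical for identical specs.
#' @export
makeToyComplex <- function(spec = toyComplexSpec()) {
  seed <- spec$seed
  nRes <- spec$nResidues
  sequence <- with_seed_(derive_seed(seed, "seq"),
                         sample(AA1, nRes, replace = TRUE))
  holo <- .helixProtein(nRes, sequence)
  ca <- caCoords(holo)
  ## pocket: 6 residues nearest the helix midpoint (axis point at mean z)
  axisMid <- c(0, 0, mean(holo@atomCoords[, 3]))
  dMid <- sqrt(rowSums(sweep(ca, 2, axisMid)^2))
  pocketRes <- order(dMid)[1:6]
  ## pocket direction: radial direction of the closest residue's side chain
  nearest <- pocketRes[1]
  cb <- holo@atomCoords[holo@caIndex[nearest] + 1L, ]
  d1 <- cb - c(0, 0, cb[3])
  d1 <- d1 / sqrt(sum(d1^2))
  pocketCenter <- axisMid + 3.5 * d1
  axis <- c(0, 0, 1)
  e3 <- c(d1[2] * axis[3] - d1[3] * axis[2],
          d1[3] * axis[1] - d1[1] * axis[3],
          d1[1] * axis[2] - d1[2] * axis[1])
  e3 <- e3 / sqrt(sum(e3^2))
  frame <- cbind(axis, e3, d1)  # pocket frame (long axis along helix axis)
  ## ligand: reference conformer posed deterministically in the pocket frame
  graph <- parseSmiles(spec$ligandSpec, seed = 7L)
  nl <- nAtoms(graph)
  ligCoords <- matrix(0, nl, 3)
  frags <- sort(unique(graph@fragmentId))
  for (f in frags) {
    idx <- which(graph@fragmentId == f)
    conf <- graph@refCoords[idx, , drop = FALSE]
    conf <- sweep(conf, 2, colMeans(conf))
    if (length(idx) > 1L) {
      V <- .canonicalFrame(conf)
      conf <- conf %*% V %*% t(frame)
    }
    offset <- (which(frags == f) - (length(frags) + 1) / 2) * 3
    ligCoords[idx, ] <- sweep(conf, 2, pocketCenter + offset * axis, "+")
  }
  ## apo: hinge the C-terminal half about the midpoint, then jitter
  apoCoords <- holo@atomCoords
  hinge <- which(holo@atomToResidue > nRes / 2)
  R <- .axisRotation(e3, spec$hingeAngle * pi / 180)
  apoCoords[hinge, ] <- sweep(sweep(apoCoords[hinge, , drop = FALSE], 2,
                                    axisMid) %*% t(R), 2, axisMid, "+")
  apoCoords <- apoCoords + with_seed_(
    derive_seed(seed, "jitter"),
    matrix(stats::rnorm(length(apoCoords), sd = spec$noiseScale),
           nrow(apoCoords), 3))
  apo <- holo
  apo@atomCoords <- apoCoords
  ## affinity: exact linear function of <4 A protein-ligand contacts, clipped
  contacts <- sum(cross_dist(holo@atomCoords, ligCoords) < 4)
  pk <- clamp_scalar(2 + 0.25 * contacts, 2, 12)
  new("PairRecord", apo = apo, holo = holo, ligand = graph,
      holoLigandCoords = ligCoords, affinityPk = pk,
      fullSequence = c(A = paste(sequence, collapse = "")),
      id = sprintf("toy%05d", seed), accepted = NA, metrics = list())
}

#' Generate a toy dataset with a deterministic train/test split
#'
#' Complexes are generated with seeds `baseSeed .. baseSeed + n - 1` and split
#' 80/20 by ordering an integer hash of each seed (parity-free, so consecutive
#' seeds do not alternate systematically).
#'
#' @param n number of complexes (>= 2).
#' @param baseSeed first seed.
#' @param spec base `"ToyComplexSpec"` whose seed/ligand fields are overridden
#'   per complex.
#' @return list with `pairs`, `trainIdx`, `testIdx` (disjoint, covering all).
#' @export
makeToyDataset <- function(n, baseSeed = 0L, spec = toyComplexSpec()) {
  if (n < 2L) stop_input("need n >= 2")
  seeds <- baseSeed + seq_len(n) - 1L
  pairs <- lapply(seeds, function(s)
    makeToyComplex(toyComplexSpec(nResidues = spec$nResidues,
                                  hingeAngle = spec$hingeAngle,
                                  noiseScale = spec$noiseScale, seed = s)))
  h <- (as.numeric(seeds) * 2654435761) %% 2147483647
  nTest <- max(1L, floor(0.2 * n))
  testIdx <- order(h)[seq_len(nTest)]
  list(pairs = pairs, trainIdx = sort(setdiff(seq_len(n), testIdx)),
       testIdx = sort(testIdx))
}
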