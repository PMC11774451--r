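## Initial (t = 0) complex states: harmonic Gaussian ligand conformations with
## the bond-graph Laplacian as precision, noised apo protein structures, and
## training-time target noising.

#' Sample ligand coordinates from the harmonic bond-graph prior
#'
#' Draws zero-mean Gaussian coordinates with precision matrix \eqn{L = D - A}
#' restricted to its strictly positive eigenspace: along each eigenvector with
#' eigenvalue \eqn{\lambda_k > 10^{-9}} an independent coefficient
#' \eqn{c_k \sim N(0, 1/\lambda_k)} is drawn per spatial dimension; the
#' null-space (per-fragment translation) components are set to zero and each
#' fragment centroid is then translated to its requested center. Bonded atoms
#' therefore stay close (fluctuations of order one Angstrom for unit bond
#' weights) while unbonded fragments are independent.
#'
#' @param graph a [LigandGraph-class].
#' @param centers numeric matrix (fragments x 3), one center per fragment; a
#'   single 3-vector is recycled for all fragments.
#' @param seed integer seed (sampling is bit-reproducible under it).
#' @param nSamples number of independent draws. The default 1 returns an
#'   atoms x 3 matrix; larger values return an atoms x 3 x nSamples array
#'   drawn in a single seeded block (used for distributional checks).
#' @return numeric matrix (atoms x 3) in Angstrom, or an array for
#'   `nSamples > 1`.
#' @export
sampleHarmonicLigand <- function(graph, centers, seed = 0L, nSamples = 1L) {
  n <- nAtoms(graph)
  if (n == 0L) stop_input("empty ligand graph")
  nf <- nFragments(graph)
  if (is.vector(centers)) centers <- matrix(centers, nrow = nf, ncol = 3,
                                            byrow = TRUE)
  if (nrow(centers) != nf)
    stop_input("need one center per fragment (%d), got %d", nf, nrow(centers))
  nS <- as.integer(nSamples)
  out <- array(0, dim = c(n, 3, nS))
  with_seed_(derive_seed(seed, "harmonic"), {
    for (f in sort(unique(graph@fragmentId))) {
      idx <- which(graph@fragmentId == f)
      m <- length(idx)
      if (m == 1L) {
        xyz <- matrix(0, 1, 3 * nS)
      } else {
        eig <- .laplacianEigen(graph, idx)
        pos <- which(eig$values > 1e-9)
        ## coefficients c_k ~ N(0, 1/lambda_k), independent per dimension
        ## and per draw
        cf <- matrix(stats::rnorm(length(pos) * 3 * nS), length(pos)) /
          sqrt(eig$values[pos])
        xyz <- eig$vectors[, pos, drop = FALSE] %*% cf     # m x (3 nS)
        ## exact per-draw centroid at the origin
        xyz <- sweep(xyz, 2, colMeans(xyz))
      }
      for (s in seq_len(nS))
        out[idx, , s] <- sweep(xyz[, 3 * (s - 1) + 1:3, drop = FALSE], 2,
                               centers[f, ], "+")
    }
  })
  if (nS == 1L) matrix(out[, , 1], n, 3) else out
}

## memoized eigendecomposition of a fragment's Laplacian block (topology is
## immutable, so the bond list is a safe cache key)
.eigenCache <- new.env(parent = emptyenv())
.laplacianEigen <- function(graph, idx) {
  key <- paste(nAtoms(graph), paste(t(graph@bonds), collapse = ","),
               paste(idx, collapse = "."), sep = "|")
  hit <- .eigenCache[[key]]
  if (!is.null(hit)) return(hit)
  eig <- eigen(graph@laplacian[idx, idx, drop = FALSE], symmetric = TRUE)
  .eigenCache[[key]] <- eig
  eig
}

#' Sample from the noised apo protein prior
#'
#' Returns the apo coordinates plus i.i.d. isotropic Gaussian noise of scale
#' `noise$sigma` per coordinate (the unbound-structure distribution used as
#' the protein prior; sigma defaults to 1e-4 Angstrom).
#'
#' @param apo a [ProteinStructure-class].
#' @param noise a `NoiseConfig` (see [noiseConfig()]).
#' @return numeric matrix (\eqn{N_P} x 3).
#' @export
sampleApoProtein <- function(apo, noise = noiseConfig()) {
  x <- apo@atomCoords
  if (noise$sigma == 0) return(x)
  with_seed_(derive_seed(noise$seed, "apo"), {
    x + matrix(stats::rnorm(length(x), sd = noise$sigma), nrow(x), 3)
  })
}

#' Apply training-time noise to a holo target state
#'
#' Adds independent isotropic Gaussian noise (scale `noise$sigma`) to both the
#' protein and ligand target coordinates of a \eqn{t = 1} state. Used only
#' during training as a regularizer against computational/experimental
#' coordinate noise; never applied at inference.
#'
#' @param state a [ComplexState-class] with `time == 1`.
#' @param noise a `NoiseConfig`.
#' @return a noised [ComplexState-class] at \eqn{t = 1}.
#' @export
noiseHoloTargets <- function(state, noise = noiseConfig()) {
  if (abs(state@time - 1) > 1e-12)
    stop("noiseHoloTargets requires a t = 1 state", call. = FALSE)
  if (noise$sigma == 0) return(state)
  with_seed_(derive_seed(noise$seed, "holo"), {
    new("ComplexState",
        proteinCoords = state@proteinCoords +
          matrix(stats::rnorm(length(state@proteinCoords), sd = noise$sigma),
                 nrow(state@proteinCoords), 3),
        ligandCoords = state@ligandCoords +
          matrix(stats::rnorm(length(state@ligandCoords), sd = noise$sigma),
                 nrow(state@ligandCoords), 3),
        time = 1)
  })
}

#' Assemble a full prior (t = 0) complex state
#'
#' Combines [sampleApoProtein()] and [sampleHarmonicLigand()]. Fragment
#' centers follow the centering policy: `"centroid"` (default, blind docking)
#' places every fragment at the apo protein heavy-atom centroid; `"pocket"`
#' places them at a user-supplied pocket center.
#'
#' @param apo a [ProteinStructure-class].
#' @param graph a [LigandGraph-class].
#' @param noise a `NoiseConfig`; its seed drives both draws.
#' @param centering `"centroid"` or `"pocket"`.
#' @param pocketCenter 3-vector, required when `centering = "pocket"`.
#' @return list with `state` (a [ComplexState-class] at time 0) and
#'   `logContext` (centers and seed used).
#' @export
assemblePriorState <- function(apo, graph, noise = noiseConfig(),
                               centering = c("centroid", "pocket"),
                               pocketCenter = NULL) {
  centering <- match.arg(centering)
  center <- if (centering == "centroid") colMeans(apo@atomCoords) else {
    if (is.null(pocketCenter)) stop_input("pocket centering needs pocketCenter")
    as.numeric(pocketCenter)
  }
  prot <- sampleApoProtein(apo, noise)
  lig <- sampleHarmonicLigand(graph, center, seed = noise$seed)
  list(state = new("ComplexState", proteinCoords = prot, ligandCoords = lig,
                   time = 0),
       logContext = list(centering = centering, center = center,
                         seed = noise$seed))
}
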