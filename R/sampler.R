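## Bound-structure generation: integrate the learned map from t = 0 to t = 1
## with the variance-diminishing ODE (default) or the plain x1-parametrized
## Euler solver; rank samples by predicted confidence.

#' One variance-diminishing ODE step
#'
#' With \eqn{t = n/i}, \eqn{s = (n+1)/i} and \eqn{r = (1-s)/(1-t)}:
#' \deqn{x_{n+1} = \mathrm{clamp}(r \eta) x_n +
#'       \mathrm{clamp}((1 - r) \eta) \hat{x}_1,}
#' where both scalar coefficients are clamped to
#' `[config$clampLo, config$clampHi]` (defaults 1e-6 and 1 - 1e-6). With
#' \eqn{\eta = 1} each step is a convex combination of the current state and
#' the model's holo estimate that weights the estimate more heavily at late
#' timesteps; the clamp keeps an epsilon-memory of the state at the final
#' step.
#'
#' @param xn current coordinates (matrix or vector).
#' @param predX1 the model's holo estimate, same shape.
#' @param n current integer timestep, `0 <= n < i`.
#' @param config a `SamplerConfig`.
#' @return the updated coordinates.
#' @export
vdOdeStep <- function(xn, predX1, n, config = samplerConfig()) {
  i <- config$nSteps
  if (n < 0 || n >= i) stop("vdOdeStep: n must satisfy 0 <= n < i",
                            call. = FALSE)
  t <- n / i; s <- (n + 1) / i
  r <- (1 - s) / (1 - t)
  cA <- clamp_scalar(r * config$eta, config$clampLo, config$clampHi)
  cB <- clamp_scalar((1 - r) * config$eta, config$clampLo, config$clampHi)
  cA * xn + cB * predX1
}

#' One Euler step in the x1-parametrization
#'
#' The flow velocity reconstructed from the holo estimate is
#' \eqn{u = (\hat{x}_1 - x_n)/(1 - t)}, giving
#' \eqn{x_{n+1} = x_n + (1/i) u}. At the final step (\eqn{t = 1 - 1/i}) this
#' reduces exactly to \eqn{\hat{x}_1}.
#'
#' @inheritParams vdOdeStep
#' @return the updated coordinates.
#' @export
eulerStep <- function(xn, predX1, n, config = samplerConfig()) {
  i <- config$nSteps
  if (n < 0 || n >= i) stop("eulerStep: n must satisfy 0 <= n < i",
                            call. = FALSE)
  t <- n / i
  xn + (1 / i) * (predX1 - xn) / (1 - t)
}

#' Generate ranked bound-structure samples
#'
#' Draws `config$nSamples` independent prior states ([assemblePriorState()]),
#' integrates each from \eqn{t = 0} to \eqn{t = 1} with the configured solver,
#' calling the model at every step with \eqn{t = n/i}, then evaluates the
#' confidence and affinity heads on the final state and returns trajectories
#' ranked by descending mean per-residue confidence. The final state is taken
#' as the holo estimate. Deterministic under `config$seed`; no noise is
#' injected during integration (stochasticity comes from the prior draw only).
#'
#' @param model a `"flowModel"` (an untrained model yields prior-like output
#'   through its identity coordinate map).
#' @param apo a [ProteinStructure-class], used as-is (no noise at inference).
#' @param graph a [LigandGraph-class].
#' @param config a `SamplerConfig`.
#' @param centering,pocketCenter prior centering policy, see
#'   [assemblePriorState()].
#' @param predictFn the per-step predictor, by default [predictComplex()];
#'   replaceable by an oracle in tests.
#' @return list of [Trajectory-class] objects, best-ranked first.
#' @export
generateSamples <- function(model, apo, graph, config = samplerConfig(),
                            centering = "centroid", pocketCenter = NULL,
                            predictFn = NULL) {
  if (is.null(predictFn))
    predictFn <- function(state, t) predictComplex(model, state, t = t,
                                                   graph = graph,
                                                   structure = apo)
  stepFn <- if (config$solver == "vd_ode") vdOdeStep else eulerStep
  i <- config$nSteps
  trajs <- vector("list", config$nSamples)
  for (smp in seq_len(config$nSamples)) {
    nz <- noiseConfig(sigma = 0,
                      seed = derive_seed(config$seed, paste0("sample", smp)))
    prior <- assemblePriorState(apo, graph, nz, centering = centering,
                                pocketCenter = pocketCenter)
    state <- prior$state
    states <- vector("list", i + 1L)
    states[[1]] <- state
    for (n in 0:(i - 1L)) {
      t <- n / i
      pred <- predictFn(state, t)
      newProt <- stepFn(state@proteinCoords, pred@predProtein, n, config)
      newLig <- stepFn(state@ligandCoords, pred@predLigand, n, config)
      state <- new("ComplexState", proteinCoords = newProt,
                   ligandCoords = newLig, time = (n + 1) / i)
      states[[n + 2L]] <- state
    }
    finalPred <- predictFn(state, 1)
    final <- new("Prediction", predProtein = state@proteinCoords,
                 predLigand = state@ligandCoords,
                 confidence = finalPred@confidence,
                 affinityPk = finalPred@affinityPk)
    trajs[[smp]] <- new("Trajectory", states = states, final = final)
  }
  conf <- vapply(trajs, function(tr) mean(tr@final@confidence), numeric(1))
  trajs[order(-conf)]
}

#' Symmetry-corrected ligand RMSD
#'
#' Heavy-atom RMSD between a predicted and a reference ligand pose in the
#' receptor frame (no superposition), minimized over the automorphisms of the
#' element-labeled bond graph so chemically equivalent atoms are
#' interchangeable. Automorphisms are enumerated exhaustively (VF2) for
#' ligands of at most `maxAtoms` atoms; beyond that the identity mapping is
#' used with a warning.
#'
#' @param predLigand,refLigand coordinate matrices (N x 3), same atom order.
#' @param graph the [LigandGraph-class].
#' @param maxAtoms automorphism enumeration cap (default 40).
#' @return RMSD in Angstrom.
#' @export
ligandRmsdToReference <- function(predLigand, refLigand, graph,
                                  maxAtoms = 40L) {
  n <- nAtoms(graph)
  if (nrow(predLigand) != n || nrow(refLigand) != n)
    stop("ligand atom-count mismatch", call. = FALSE)
  perms <- list(seq_len(n))
  if (n <= maxAtoms) {
    g <- igraph::graph_from_adjacency_matrix(graph@adjacency,
                                             mode = "undirected")
    colors <- match(graph@elements, unique(graph@elements))
    maps <- igraph::subgraph_isomorphisms(g, g, method = "vf2",
                                          vertex.color1 = colors,
                                          vertex.color2 = colors)
    if (length(maps)) perms <- lapply(maps, as.integer)
  } else {
    warning("ligand larger than maxAtoms; symmetry correction skipped")
  }
  best <- Inf
  for (pm in perms) {
    r <- sqrt(mean(rowSums((predLigand[pm, , drop = FALSE] - refLigand)^2)))
    best <- min(best, r)
  }
  best
}
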