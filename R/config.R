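#' Configuration constructors
#'
#' Validated parameter bundles for the prior, coupling filter, network,
#' training loop and sampler. Defaults follow the published settings where one
#' exists: target noise sigma 1e-4 Angstrom, apo-holo acceptance thresholds
#' TM-score >= 0.7 and C-alpha RMSD < 5 Angstrom, sampler i = 40 timesteps with
#' eta = 1 and coefficient clamp bounds (1e-6, 1 - 1e-6).
#'
#' @param sigma standard deviation in Angstrom of the isotropic Gaussian noise
#'   applied per coordinate.
#' @param seed integer RNG seed.
#' @param tmMin minimum TM-score for an apo-holo pair to be accepted.
#' @param rmsdMax C-alpha RMSD (Angstrom) at or above which a pair is rejected.
#' @param maxResidues,maxLigandAtoms length-based acceptance caps.
#' @param hiddenDim number of radial basis functions per edge class.
#' @param nLayers number of coordinate-update applications per model call.
#' @param neighborCutoff radius-graph cutoff in Angstrom (ligand bond edges are
#'   always included).
#' @param steps,batchSize,learningRate training schedule.
#' @param ligandWeight weight of the ligand term in the flow-matching loss.
#' @param confWeight,affWeight weights of the confidence / affinity head losses.
#' @param inputNoise standard deviation (Angstrom) of the Gaussian
#'   perturbation applied to the interpolated input coordinates during
#'   training (not to the regression target). This smooths the learned map in
#'   a neighborhood of the conditional path, which keeps the sampler's
#'   self-generated states — never exactly on the path — inside the region
#'   where the model is accurate. Set 0 to disable.
#' @param coupling a `CouplingConfig` used to filter training pairs.
#' @param nSteps number of solver timesteps i.
#' @param eta VD-ODE coefficient scale.
#' @param clampLo,clampHi clamp bounds applied to the two step coefficients.
#' @param solver `"vd_ode"` or `"euler"`.
#' @param nSamples number of independent trajectories to generate.
#' @return a named list with class `"NoiseConfig"`, `"CouplingConfig"`,
#'   `"ModelConfig"`, `"TrainConfig"` or `"SamplerConfig"`.
#' @name configs
NULL

#' @rdname configs
#' @export
noiseConfig <- function(sigma = 1e-4, seed = 0L) {
  if (!is.numeric(sigma) || sigma < 0) stop_input("sigma must be >= 0")
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "NoiseConfig")
}

#' @rdname configs
#' @export
couplingConfig <- function(tmMin = 0.7, rmsdMax = 5.0,
                           maxResidues = 2000L, maxLigandAtoms = 400L) {
  if (tmMin <= 0 || tmMin > 1) stop_input("tmMin must be in (0, 1]")
  if (rmsdMax <= 0) stop_input("rmsdMax must be > 0")
  structure(list(tmMin = tmMin, rmsdMax = rmsdMax,
                 maxResidues = as.integer(maxResidues),
                 maxLigandAtoms = as.integer(maxLigandAtoms)),
            class = "CouplingConfig")
}

#' @rdname configs
#' @export
modelConfig <- function(hiddenDim = 12L, nLayers = 1L,
                        neighborCutoff = 10.0, seed = 0L) {
  if (nLayers < 1) stop_input("nLayers must be >= 1")
  if (neighborCutoff <= 0) stop_input("neighborCutoff must be > 0")
  structure(list(hiddenDim = as.integer(hiddenDim), nLayers = as.integer(nLayers),
                 neighborCutoff = neighborCutoff, seed = as.integer(seed)),
            class = "ModelConfig")
}

#' @rdname configs
#' @export
trainConfig <- function(steps = 1500L, batchSize = 8L, learningRate = 0.02,
                        sigma = 1e-4, seed = 0L, ligandWeight = 1.0,
                        confWeight = 0.25, affWeight = 0.05,
                        inputNoise = 0.3, coupling = couplingConfig()) {
  if (steps < 1) stop_input("steps must be >= 1")
  if (inputNoise < 0) stop_input("inputNoise must be >= 0")
  structure(list(steps = as.integer(steps), batchSize = as.integer(batchSize),
                 learningRate = learningRate, sigma = sigma,
                 seed = as.integer(seed), ligandWeight = ligandWeight,
                 confWeight = confWeight, affWeight = affWeight,
                 inputNoise = inputNoise, coupling = coupling),
            class = "TrainConfig")
}

#' @rdname configs
#' @export
samplerConfig <- function(nSteps = 40L, eta = 1.0, clampLo = 1e-6,
                          clampHi = 1 - 1e-6, solver = c("vd_ode", "euler"),
                          nSamples = 5L, seed = 0L) {
  solver <- match.arg(solver)
  if (nSteps < 1) stop_input("nSteps must be >= 1")
  if (!(clampLo > 0 && clampLo < clampHi && clampHi < 1))
    stop_input("require 0 < clampLo < clampHi < 1")
  structure(list(nSteps = as.integer(nSteps), eta = eta, clampLo = clampLo,
                 clampHi = clampHi, solver = solver,
                 nSamples = as.integer(nSamples), seed = as.integer(seed)),
            class = "SamplerConfig")
}
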