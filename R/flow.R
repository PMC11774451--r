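## CondOT conditional path, flow-matching regression loss, and the training
## loop wiring priors, coupling and the network together.

#' CondOT interpolation between prior and target states
#'
#' The conditional probability path: \eqn{x_t = (1 - t) x_0 + t x_1},
#' applied jointly to protein and ligand coordinates.
#'
#' @param x0,x1 [ComplexState-class] objects of equal shapes.
#' @param t scalar in \eqn{[0, 1]}.
#' @return a [ComplexState-class] at time `t`.
#' @export
condotInterpolate <- function(x0, x1, t) {
  if (!all(dim(x0@proteinCoords) == dim(x1@proteinCoords)) ||
      !all(dim(x0@ligandCoords) == dim(x1@ligandCoords)))
    stop("condotInterpolate: shape mismatch", call. = FALSE)
  if (t < 0 || t > 1) stop_input("t must be in [0, 1]")
  new("ComplexState",
      proteinCoords = (1 - t) * x0@proteinCoords + t * x1@proteinCoords,
      ligandCoords = (1 - t) * x0@ligandCoords + t * x1@ligandCoords,
      time = t)
}

#' Flow-matching regression loss
#'
#' Squared error between the predicted and target holo coordinates, reduced as
#' the mean over atoms and spatial dimensions separately for protein and
#' ligand, combined as `protein + ligandWeight * ligand`. The mean reduction
#' keeps loss magnitudes comparable across complex sizes.
#'
#' @param predProt,predLig predicted coordinates.
#' @param targetProt,targetLig target (holo) coordinates.
#' @param ligandWeight weight of the ligand term (default 1).
#' @return scalar loss.
#' @export
cfmLoss <- function(predProt, predLig, targetProt, targetLig,
                    ligandWeight = 1) {
  if (!all(is.finite(predProt)) || !all(is.finite(predLig)))
    stop("cfmLoss: non-finite predictions", call. = FALSE)
  if (!all(dim(predProt) == dim(targetProt)) ||
      !all(dim(predLig) == dim(targetLig)))
    stop("cfmLoss: shape mismatch", call. = FALSE)
  mean((predProt - targetProt)^2) + ligandWeight * mean((predLig - targetLig)^2)
}

#' Build a training batch of conditional-path samples
#'
#' For each element: a pair is drawn (uniformly with replacement), a flow time
#' \eqn{t \sim U(0, 1)}, a prior state via [assemblePriorState()], a noised
#' holo target via [noiseHoloTargets()], and the CondOT interpolation
#' [condotInterpolate()]. Deterministic under `seed`.
#'
#' @param pairs list of accepted [PairRecord-class] objects.
#' @param config a `TrainConfig`.
#' @param seed integer seed for this batch.
#' @return list of path samples, each a list with `pairIndex`, `t`, `x0`,
#'   `x1` (noised target), `xt`.
#' @export
makeTrainingBatch <- function(pairs, config = trainConfig(), seed = 0L) {
  if (length(pairs) == 0L) stop_input("empty pair list")
  with_seed_(derive_seed(seed, "batch"), {
    idx <- sample.int(length(pairs), config$batchSize, replace = TRUE)
    ts <- stats::runif(config$batchSize)
    subSeeds <- sample.int(2^30, config$batchSize)
    lapply(seq_len(config$batchSize), function(b) {
      p <- pairs[[idx[b]]]
      nz <- noiseConfig(sigma = config$sigma, seed = subSeeds[b])
      x0 <- assemblePriorState(p@apo, p@ligand, nz)$state
      holo <- new("ComplexState", proteinCoords = p@holo@atomCoords,
                  ligandCoords = p@holoLigandCoords, time = 1)
      x1 <- noiseHoloTargets(holo, nz)
      list(pairIndex = idx[b], t = ts[b], x0 = x0, x1 = x1,
           xt = condotInterpolate(x0, x1, ts[b]))
    })
  })
}

## Adam update for one parameter array; st carries (m, v, step).
.adam <- function(par, grad, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(st)) st <- list(m = par * 0, v = par * 0, k = 0L)
  st$k <- st$k + 1L
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mh <- st$m / (1 - b1^st$k)
  vh <- st$v / (1 - b2^st$k)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the flow model
#'
#' Stochastic gradient descent on the flow-matching loss plus the weighted
#' confidence and affinity head losses. Only pairs passing [acceptPair()]
#' under `config$coupling` are consumed; rejected pairs never influence the
#' loss history. The coordinate head is linear in its weights, so its
#' gradients are exact in closed form and the per-batch loss is quadratic;
#' it is optimized by preconditioned steepest descent with an exact line
#' search, using a fixed damped inverse-curvature preconditioner estimated
#' once from a probe batch (the natural choice for a linear head, and far
#' better conditioned than a diagonal adaptive method on these radial
#' features). The scalar heads use Adam with `config$learningRate`. Fully
#' seed-deterministic on CPU.
#'
#' @param pairs list of [PairRecord-class] objects (filtered internally).
#' @param model a `"flowModel"` (default: fresh zero-initialized model).
#' @param config a `TrainConfig`.
#' @param checkpointDir optional directory; a checkpoint is written after each
#'   epoch (one pass-equivalent over the accepted pairs).
#' @param verbose print progress every 100 steps.
#' @return list with `model` (trained) and `history` (data.frame of per-step
#'   total / flow / confidence / affinity losses).
#' @export
trainFlowModel <- function(pairs, model = flowModel(), config = trainConfig(),
                           checkpointDir = NULL, verbose = FALSE) {
  assessed <- lapply(pairs, function(p)
    if (length(p@metrics)) p else acceptPair(p, config$coupling))
  accepted <- Filter(function(p) isTRUE(p@accepted), assessed)
  if (length(accepted) == 0L) stop_input("no accepted pairs to train on")
  K <- model$config$hiddenDim
  psiDim <- .BERNSTEIN_M
  stConf <- NULL; stAff <- NULL
  hist <- matrix(NA_real_, config$steps, 4,
                 dimnames = list(NULL, c("total", "flow", "conf", "aff")))
  epochSteps <- max(1L, ceiling(length(accepted) / config$batchSize))
  ## input perturbation: regressing x1 from a Gaussian neighborhood of xt
  ## (target untouched) smooths the learned map off the exact CondOT path,
  ## which the sampler's self-generated states never lie on exactly
  perturbBatch <- function(batch, tag) {
    if (config$inputNoise == 0) return(batch)
    with_seed_(derive_seed(config$seed, paste0("aug", tag)), {
      lapply(batch, function(s) {
        s$xt@proteinCoords <- s$xt@proteinCoords +
          matrix(stats::rnorm(length(s$xt@proteinCoords),
                              sd = config$inputNoise),
                 nrow(s$xt@proteinCoords), 3)
        s$xt@ligandCoords <- s$xt@ligandCoords +
          matrix(stats::rnorm(length(s$xt@ligandCoords),
                              sd = config$inputNoise),
                 nrow(s$xt@ligandCoords), 3)
        s
      })
    })
  }
  ## probe-batch curvature of the (quadratic) coordinate-head loss
  QM <- model$Q * .BERNSTEIN_M
  probeCfg <- config; probeCfg$batchSize <- 32L
  probe <- perturbBatch(
    makeTrainingBatch(accepted, probeCfg,
                      seed = derive_seed(config$seed, "probe")), "probe")
  H <- matrix(0, QM, QM)
  for (s in probe) {
    p <- accepted[[s$pairIndex]]
    fw <- .forward(model, s$xt@proteinCoords, s$xt@ligandCoords, s$t,
                   p@ligand, p@holo)
    np <- nrow(fw$predProt); nl <- nrow(fw$predLig)
    w3 <- rep(c(rep(1 / (3 * np), np),
                rep(config$ligandWeight / (3 * nl), nl)), 3)
    D <- do.call(cbind, lapply(seq_len(.BERNSTEIN_M), function(m)
      fw$layers[[1]]$Fm * fw$psi[m]))
    H <- H + crossprod(D * sqrt(w3))
  }
  H <- 2 * H / length(probe)
  W <- solve(H + diag(1e-3 * sum(diag(H)) / QM, QM))
  for (step in seq_len(config$steps)) {
    batch <- perturbBatch(
      makeTrainingBatch(accepted, config,
                        seed = derive_seed(config$seed, step)), step)
    gTheta <- lapply(model$Theta, function(th) th * 0)
    gConf <- model$wConf * 0
    gAff <- model$wAff * 0
    lFlow <- 0; lConf <- 0; lAff <- 0
    caches <- vector("list", length(batch))
    for (bi in seq_along(batch)) {
      s <- batch[[bi]]
      p <- accepted[[s$pairIndex]]
      fw <- .forward(model, s$xt@proteinCoords, s$xt@ligandCoords, s$t,
                     p@ligand, p@holo)
      np <- nrow(fw$predProt); nl <- nrow(fw$predLig)
      rProt <- fw$predProt - s$x1@proteinCoords
      rLig <- fw$predLig - s$x1@ligandCoords
      lFlow <- lFlow + mean(rProt^2) + config$ligandWeight * mean(rLig^2)
      ## closed-form coordinate gradient: d loss / d Theta_l = F_l' (w r) psi'
      ## (exact for one layer; for stacked layers the identity-plus-update
      ## structure makes this the first-order gradient per layer)
      wR <- as.vector(rbind(rProt * (2 / (3 * np)),
                            rLig * (2 * config$ligandWeight / (3 * nl))))
      for (l in seq_along(model$Theta))
        gTheta[[l]] <- gTheta[[l]] +
          (t(fw$layers[[l]]$Fm) %*% wR) %*% t(fw$psi)
      caches[[bi]] <- list(Fm = fw$layers[[1]]$Fm, psi = fw$psi,
                           w3 = rep(c(rep(1 / (3 * np), np),
                                      rep(config$ligandWeight / (3 * nl), nl)),
                                    3))
      ## confidence labels: pose-sensitive lDDT of the current prediction
      ## against the holo target (interface pairs take precedence)
      lddt <- .confidenceLabels(fw$predProt, fw$predLig,
                                s$x1@proteinCoords, s$x1@ligandCoords,
                                p@holo, p@ligand)
      ok <- !is.na(lddt)
      if (any(ok)) {
        lConf <- lConf + mean((fw$conf[ok] - lddt[ok])^2)
        dEta <- numeric(length(fw$conf))
        dEta[ok] <- 2 * (fw$conf[ok] - lddt[ok]) *
          fw$conf[ok] * (1 - fw$conf[ok]) / sum(ok)
        gConf <- gConf + as.numeric(t(fw$Zconf) %*% dEta)
      }
      if (!is.na(p@affinityPk)) {
        lAff <- lAff + (fw$aff - p@affinityPk)^2
        gAff <- gAff + 2 * (fw$aff - p@affinityPk) * fw$zAff
      }
    }
    ## negative-pose samples for the confidence head only: the generated
    ## final state can carry an escaped ligand, a regime the conditional
    ## path never visits, so the head must be shown displaced poses with
    ## their (near-zero) interface lDDT labels or it cannot rank samples
    with_seed_(derive_seed(config$seed, paste0("esc", step)), {
      for (e in 1:4) {
        p <- accepted[[sample.int(length(accepted), 1)]]
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        shift <- dir * stats::runif(1, 0.5, 8)
        xl <- sweep(p@holoLigandCoords, 2, shift, "+") +
          matrix(stats::rnorm(length(p@holoLigandCoords), sd = 0.2),
                 nrow(p@holoLigandCoords), 3)
        fwh <- .forwardHeads(model, p@holo@atomCoords, xl, 1,
                             p@ligand, p@holo)
        lab <- .confidenceLabels(p@holo@atomCoords, xl,
                                 p@holo@atomCoords, p@holoLigandCoords,
                                 p@holo, p@ligand)
        ok <- !is.na(lab)
        if (any(ok)) {
          lConf <- lConf + mean((fwh$conf[ok] - lab[ok])^2)
          dEta <- numeric(length(fwh$conf))
          dEta[ok] <- 2 * (fwh$conf[ok] - lab[ok]) *
            fwh$conf[ok] * (1 - fwh$conf[ok]) / sum(ok)
          gConf <- gConf + as.numeric(t(fwh$Zconf) %*% dEta)
        }
      }
    })
    B <- length(batch)
    lFlow <- lFlow / B; lConf <- lConf / B; lAff <- lAff / B
    total <- lFlow + config$confWeight * lConf + config$affWeight * lAff
    if (!is.finite(total))
      stop(sprintf("training diverged at step %d (loss %g)", step, total),
           call. = FALSE)
    hist[step, ] <- c(total, lFlow, lConf, lAff)
    ## preconditioned steepest descent with exact line search on the
    ## quadratic batch loss: direction P = W g, step length
    ## alpha = <g, P> / P' H_batch P (guarantees monotone batch descent)
    for (l in seq_along(model$Theta)) {
      g <- gTheta[[l]] / B
      Pd <- matrix(W %*% as.vector(g), model$Q, .BERNSTEIN_M)
      denom <- 0
      for (cc in caches) {
        v <- cc$Fm %*% (Pd %*% cc$psi)
        denom <- denom + 2 * sum(cc$w3 * v^2)
      }
      denom <- denom / B
      if (denom > 0) {
        alpha <- sum(g * Pd) / denom
        model$Theta[[l]] <- model$Theta[[l]] - alpha * Pd
      }
    }
    up <- .adam(model$wConf, (config$confWeight / B) * gConf, stConf,
                config$learningRate)
    model$wConf <- up$par; stConf <- up$st
    up <- .adam(model$wAff, (config$affWeight / B) * gAff, stAff,
                config$learningRate)
    model$wAff <- up$par; stAff <- up$st
    if (verbose && step %% 100 == 0)
      message(sprintf("step %d: total %.4f flow %.4f conf %.4f aff %.4f",
                      step, total, lFlow, lConf, lAff))
    if (!is.null(checkpointDir) && step %% epochSteps == 0)
      saveFlowModel(model, file.path(checkpointDir,
                                     sprintf("checkpoint_%06d.rds", step)))
  }
  model$trained <- TRUE
  list(model = model, history = as.data.frame(hist))
}
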