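## Compact rotation-equivariant stand-in network. Coordinate updates are
## linear combinations of radial-basis-filtered relative-position vectors on a
## radius graph (ligand bond edges always included), so the coordinate map
## commutes with rigid motions by construction and the flow-matching loss is
## exactly quadratic in the coordinate-head weights. Scalar heads (per-residue
## confidence, binding affinity) consume rotation-invariant distance features.

.BERNSTEIN_M <- 4L

## Bernstein basis of degree 3 in the flow time t.
.timeBasis <- function(t) {
  c((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
}

.elemClass <- function(elements) {
  cls <- match(elements, c("C", "N", "O"))
  cls[is.na(cls)] <- 4L
  cls
}

.rbfCenters <- function(cfg) seq(0.75, cfg$neighborCutoff - 0.25,
                                 length.out = cfg$hiddenDim)

.rbf <- function(d, centers, width) {
  exp(-outer(d, centers, "-")^2 / (2 * width^2))
}

.N_POSFEAT <- 5L

## Fourier positional encoding of residue index: the sequence-conditioning
## channel of the stand-in (the published backbone conditions on per-residue
## language-model embeddings; we use smooth positional features instead).
.posFeatures <- function(residueIndex, nRes) {
  u <- (residueIndex - 1) / max(nRes - 1, 1)
  cbind(1, sin(2 * pi * outer(u, 1:2)), cos(2 * pi * outer(u, 1:2)))
}

## Per-ligand-atom chemical context features: constant, bonded degree,
## fragment size, bonded-oxygen count and total fragment count. They cross
## the ligand basis blocks so atoms of the same element in different chemical
## environments get distinct update fields.
.N_LIGFEAT <- 3L
.ligFeatures <- function(graph) {
  deg <- rowSums(graph@adjacency)
  fragSize <- as.numeric(table(graph@fragmentId))[graph@fragmentId]
  cbind(1, deg / 2, fragSize / 4)
}

## Radial basis resolution of the ligand blocks.
.K_LIG <- 10L

## Coordinate-basis column count: protein receivers get senderRole x RBF x
## receiver-position blocks (P<-P) plus RBF x receiver-position (P<-L);
## ligand receivers get element x ligfeat x RBF x sender-position (L<-P)
## plus element x {bond, nonbond} x ligfeat x RBF (L<-L).
.qDim <- function(K) {
  3L * K * .N_POSFEAT +
    4L * .N_LIGFEAT * .K_LIG * .N_POSFEAT +
    4L * 2L * .N_LIGFEAT * .K_LIG
}

#' Initialize a flow model
#'
#' The coordinate head is zero-initialized so the untrained network is the
#' identity on coordinates (a no-op flow, which stabilizes early sampling);
#' the confidence head starts at 0.5 and the affinity head at 0 pK.
#'
#' @param config a `ModelConfig` (see [modelConfig()]).
#' @return an object of class `"flowModel"`.
#' @export
flowModel <- function(config = modelConfig()) {
  K <- config$hiddenDim
  Q <- .qDim(K)
  centers <- .rbfCenters(config)
  width <- if (K > 1) diff(centers[1:2]) else 1
  centersLig <- seq(0.75, config$neighborCutoff - 0.25,
                    length.out = .K_LIG)
  widthLig <- diff(centersLig[1:2])
  nConf <- 1L + 2L * K + .BERNSTEIN_M + 20L
  nAff <- 1L + .BERNSTEIN_M + K * .BERNSTEIN_M + 6L
  structure(list(
    config = config,
    Theta = replicate(config$nLayers, matrix(0, Q, .BERNSTEIN_M),
                      simplify = FALSE),
    wConf = numeric(nConf),
    wAff = numeric(nAff),
    centers = centers, width = width,
    centersLig = centersLig, widthLig = widthLig, Q = Q,
    trained = FALSE
  ), class = "flowModel")
}

#' @export
print.flowModel <- function(x, ...) {
  cat(sprintf(
    "flowModel: %d RBFs, %d basis columns x %d time basis, %d layer(s)%s\n",
    x$config$hiddenDim, x$Q, .BERNSTEIN_M, x$config$nLayers,
    if (x$trained) " [trained]" else " [untrained: identity flow]"))
  invisible(x)
}

## Geometry shared by the basis and the scalar heads.
.edgeLists <- function(xProt, xLig, graph, structure, cutoff) {
  np <- nrow(xProt); nl <- nrow(xLig)
  X <- rbind(xProt, xLig)
  list(D = cross_dist(X, X), X = X, np = np, nl = nl,
       role = ifelse(structure@atomNames == "CA", 1L, 2L),
       elem = .elemClass(graph@elements))
}

## Equivariant basis tensor, returned as a (3N x Q) matrix with rows in
## as.vector(coords) order. Each column is a mean over a neighbor set of
## phi_k(d_ij) (x_j - x_i), modulated by a positional feature:
##   block A (P<-P): sender role x RBF x receiver residue position
##   block B (P<-L): RBF x receiver residue position
##   block C (L<-P): receiver element x RBF x sender residue position
##   block D (L<-L): receiver element x {bond, non-bond} x RBF
## Ligand bond edges are always included regardless of the cutoff.
.coordBasis <- function(model, ed, graph, structure, cutoff) {
  K <- model$config$hiddenDim
  P <- .N_POSFEAT
  LF <- .N_LIGFEAT
  np <- ed$np; nl <- ed$nl; N <- np + nl
  Fm <- matrix(0, 3L * N, model$Q)
  nRes <- nResidues(structure)
  posAtom <- .posFeatures(structure@atomToResidue, nRes)  # np x P
  ligF <- if (nl > 0) .ligFeatures(graph) else NULL       # nl x LF
  D <- ed$D
  colB0 <- 2L * K * P
  colC0 <- 3L * K * P
  colD0 <- colC0 + 4L * LF * .K_LIG * P
  ## block A: protein receivers from protein senders, split by sender role
  pp <- which(D[seq_len(np), seq_len(np), drop = FALSE] < cutoff,
              arr.ind = TRUE)
  pp <- pp[pp[, 1] != pp[, 2], , drop = FALSE]
  if (nrow(pp)) {
    phi <- .rbf(D[pp], model$centers, model$width)
    rel <- ed$X[pp[, 2], , drop = FALSE] - ed$X[pp[, 1], , drop = FALSE]
    for (sRole in 1:2) {
      sel <- which(ed$role[pp[, 2]] == sRole)
      if (!length(sel)) next
      rc <- pp[sel, 1]
      cnt <- tabulate(rc, nbins = np)
      for (a in 1:3) {
        M <- matrix(0, np, K)
        agg <- rowsum(phi[sel, , drop = FALSE] * rel[sel, a], rc)
        ri <- as.integer(rownames(agg))
        M[ri, ] <- agg / cnt[ri]
        for (m in seq_len(P)) {
          cols <- (sRole - 1L) * K * P + (seq_len(K) - 1L) * P + m
          Fm[(a - 1L) * N + seq_len(np), cols] <- M * posAtom[, m]
        }
      }
    }
  }
  if (nl > 0) {
    ## block B: protein receivers from ligand senders
    pl <- which(D[seq_len(np), np + seq_len(nl), drop = FALSE] < cutoff,
                arr.ind = TRUE)
    if (nrow(pl)) {
      phi <- .rbf(D[cbind(pl[, 1], np + pl[, 2])], model$centers, model$width)
      rel <- ed$X[np + pl[, 2], , drop = FALSE] - ed$X[pl[, 1], , drop = FALSE]
      rc <- pl[, 1]
      cnt <- tabulate(rc, nbins = np)
      for (a in 1:3) {
        M <- matrix(0, np, K)
        agg <- rowsum(phi * rel[, a], rc)
        ri <- as.integer(rownames(agg))
        M[ri, ] <- agg / cnt[ri]
        for (m in seq_len(P)) {
          cols <- colB0 + (seq_len(K) - 1L) * P + m
          Fm[(a - 1L) * N + seq_len(np), cols] <- M * posAtom[, m]
        }
      }
    }
    ## block C: ligand receivers from protein senders, sender-position
    ## modulated inside the aggregation
    KL <- .K_LIG
    lp <- which(D[np + seq_len(nl), seq_len(np), drop = FALSE] < cutoff,
                arr.ind = TRUE)
    if (nrow(lp)) {
      phi <- .rbf(D[cbind(np + lp[, 1], lp[, 2])], model$centersLig,
                  model$widthLig)
      pos <- posAtom[lp[, 2], , drop = FALSE]
      W <- phi[, rep(seq_len(KL), each = P), drop = FALSE] *
        pos[, rep(seq_len(P), KL), drop = FALSE]          # E x (KL*P)
      rel <- ed$X[lp[, 2], , drop = FALSE] -
        ed$X[np + lp[, 1], , drop = FALSE]
      cnt <- tabulate(lp[, 1], nbins = nl)
      for (e in 1:4) {
        sel <- which(ed$elem[lp[, 1]] == e)
        if (!length(sel)) next
        rc <- lp[sel, 1]
        for (a in 1:3) {
          agg <- rowsum(W[sel, , drop = FALSE] * rel[sel, a], rc)
          ri <- as.integer(rownames(agg))
          rows <- (a - 1L) * N + np + ri
          for (lf in seq_len(LF)) {
            cols <- colC0 + ((e - 1L) * LF + (lf - 1L)) * KL * P +
              seq_len(KL * P)
            Fm[rows, cols] <- (agg / cnt[ri]) * ligF[ri, lf]
          }
        }
      }
    }
    ## block D: ligand receivers from ligand senders (bond / non-bond)
    if (nl > 1) {
      bondAdj <- graph@adjacency > 0
      ll <- which(D[np + seq_len(nl), np + seq_len(nl), drop = FALSE] < cutoff,
                  arr.ind = TRUE)
      ll <- ll[ll[, 1] != ll[, 2], , drop = FALSE]
      ll <- unique(rbind(ll, which(bondAdj, arr.ind = TRUE)))
      if (nrow(ll)) {
        isBond <- bondAdj[ll]
        phi <- .rbf(D[cbind(np + ll[, 1], np + ll[, 2])], model$centersLig,
                    model$widthLig)
        rel <- ed$X[np + ll[, 2], , drop = FALSE] -
          ed$X[np + ll[, 1], , drop = FALSE]
        for (e in 1:4) for (bnd in c(TRUE, FALSE)) {
          sel <- which(ed$elem[ll[, 1]] == e & isBond == bnd)
          if (!length(sel)) next
          rc <- ll[sel, 1]
          cnt <- tabulate(rc, nbins = nl)
          for (a in 1:3) {
            agg <- rowsum(phi[sel, , drop = FALSE] * rel[sel, a], rc)
            ri <- as.integer(rownames(agg))
            rows <- (a - 1L) * N + np + ri
            for (lf in seq_len(LF)) {
              cols <- colD0 + (((e - 1L) * 2L + (!bnd)) * LF + (lf - 1L)) *
                KL + seq_len(KL)
              Fm[rows, cols] <- (agg / cnt[ri]) * ligF[ri, lf]
            }
          }
        }
      }
    }
  }
  Fm
}

## Invariant features for the scalar heads.
.headFeatures <- function(model, ed, graph, structure, t) {
  K <- model$config$hiddenDim
  np <- ed$np; nl <- ed$nl
  sp <- nResidues(structure)
  psi <- .timeBasis(t)
  ## per-residue: RBF sums from residue atoms to ligand atoms and to protein
  ## atoms of other residues (within 15 A)
  uAtom <- matrix(0, np, K); vAtom <- matrix(0, np, K)
  if (nl > 0) {
    dpl <- ed$D[seq_len(np), np + seq_len(nl), drop = FALSE]
    for (i in seq_len(np)) {
      dd <- dpl[i, ][dpl[i, ] < 15]
      if (length(dd)) uAtom[i, ] <- colSums(.rbf(dd, model$centers, model$width))
    }
  }
  dpp <- ed$D[seq_len(np), seq_len(np), drop = FALSE]
  res <- structure@atomToResidue
  for (i in seq_len(np)) {
    ok <- which(dpp[i, ] < 15 & res != res[i])
    if (length(ok)) vAtom[i, ] <- colSums(.rbf(dpp[i, ok], model$centers,
                                               model$width))
  }
  nAtomsRes <- tabulate(res, nbins = sp)
  u <- rowsum(uAtom, res) / nAtomsRes
  v <- rowsum(vAtom, res) / nAtomsRes
  resType <- matrix(0, sp, 20L)
  ti <- match(structure@sequence, AA1); ti[is.na(ti)] <- 1L
  resType[cbind(seq_len(sp), ti)] <- 1
  Zconf <- cbind(1, u, v, matrix(psi, sp, .BERNSTEIN_M, byrow = TRUE), resType)
  ## affinity: global RBF contact sums crossed with the time basis, plus
  ## ligand composition descriptors
  S <- if (nl > 0) colSums(matrix(uAtom, np, K)) else numeric(K)
  elemCnt <- tabulate(ed$elem, nbins = 4L)
  zAff <- c(1, psi, as.numeric(outer(S, psi)), nl, elemCnt,
            if (nl > 0) mean(rowSums(graph@adjacency)) else 0)
  list(Zconf = Zconf, zAff = zAff)
}

## Full forward pass; keeps the caches needed for closed-form gradients.
.forward <- function(model, xProt, xLig, t, graph, structure) {
  cutoff <- model$config$neighborCutoff
  psi <- .timeBasis(t)
  xs <- list()   # layer inputs
  Fs <- list()
  xp <- xProt; xl <- xLig
  for (l in seq_along(model$Theta)) {
    ed <- .edgeLists(xp, xl, graph, structure, cutoff)
    Fm <- .coordBasis(model, ed, graph, structure, cutoff)
    upd <- Fm %*% (model$Theta[[l]] %*% psi)
    N <- ed$np + ed$nl
    xNew <- matrix(as.vector(rbind(xp, xl)) + upd, N, 3)
    xs[[l]] <- list(ed = ed, Fm = Fm)
    xp <- xNew[seq_len(ed$np), , drop = FALSE]
    xl <- if (ed$nl > 0) xNew[ed$np + seq_len(ed$nl), , drop = FALSE] else xl
  }
  ## scalar heads read the (final) input-state geometry, not the prediction
  edH <- xs[[1]]$ed
  hf <- .headFeatures(model, edH, graph, structure, t)
  eta <- as.numeric(hf$Zconf %*% model$wConf)
  conf <- stats::plogis(eta)
  aff <- sum(hf$zAff * model$wAff)
  list(predProt = xp, predLig = xl, conf = conf, aff = aff,
       psi = psi, layers = xs, Zconf = hf$Zconf, zAff = hf$zAff, eta = eta)
}

#' Predict holo coordinates, confidence and affinity for a complex state
#'
#' One evaluation of the stand-in network \eqn{v_\theta(x_t, t)}: message
#' passing on a radius graph over all heavy atoms (ligand bond edges always
#' included), with coordinate updates built from relative-position vectors so
#' the coordinate map commutes with rigid motions; the flow time enters as a
#' scalar feature through a Bernstein basis. The untrained (zero-initialized)
#' model returns the input coordinates unchanged.
#'
#' @param model a `"flowModel"`.
#' @param state a [ComplexState-class].
#' @param t flow time in \eqn{[0, 1]} (defaults to `state@time`).
#' @param graph the [LigandGraph-class] of the ligand.
#' @param structure the [ProteinStructure-class] (sequence + atom typing).
#' @return a [Prediction-class].
#' @export
predictComplex <- function(model, state, t = state@time, graph, structure) {
  if (t < 0 || t > 1) stop_input("t must be in [0, 1]")
  if (nrow(state@proteinCoords) != nAtoms(structure) ||
      nrow(state@ligandCoords) != nAtoms(graph))
    stop_input("state shapes inconsistent with structure/graph")
  fw <- .forward(model, state@proteinCoords, state@ligandCoords, t,
                 graph, structure)
  new("Prediction", predProtein = fw$predProt, predLigand = fw$predLig,
      confidence = fw$conf, affinityPk = fw$aff)
}

#' Local distance difference test (lDDT)
#'
#' Fraction of reference inter-atomic distances (below the inclusion radius,
#' between atoms of different residues) preserved within each threshold,
#' averaged over the thresholds \{0.5, 1, 2, 4\} Angstrom and aggregated per
#' residue. Used to generate the labels the confidence head regresses.
#'
#' @param pred,reference coordinate matrices (N x 3) under the same atom
#'   correspondence.
#' @param residueIndex integer vector, residue label per atom.
#' @param inclusionRadius reference-distance cutoff in Angstrom (default 15).
#' @param thresholds preservation thresholds in Angstrom.
#' @return numeric vector, one score in \eqn{[0, 1]} per residue label (NA for
#'   residues with no scored pair).
#' @export
computeLDDT <- function(pred, reference, residueIndex, inclusionRadius = 15,
                        thresholds = c(0.5, 1, 2, 4)) {
  nres <- length(unique(residueIndex))
  if (nres < 2L) stop_input("lDDT needs at least 2 residues")
  dRef <- cross_dist(reference, reference)
  dPred <- cross_dist(pred, pred)
  sameRes <- outer(residueIndex, residueIndex, "==")
  use <- dRef < inclusionRadius & !sameRes
  use[lower.tri(use, diag = TRUE)] <- FALSE
  pairs <- which(use, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(rep(NA_real_, max(residueIndex)))
  diffs <- abs(dPred[pairs] - dRef[pairs])
  score <- rowMeans(outer(diffs, thresholds, "<"))
  nres <- max(residueIndex)
  num <- numeric(nres); den <- numeric(nres)
  for (col in 1:2) {
    r <- residueIndex[pairs[, col]]
    tab <- tapply(score, r, sum)
    cnt <- table(r)
    idx <- as.integer(names(tab))
    num[idx] <- num[idx] + as.numeric(tab)
    den[idx] <- den[idx] + as.numeric(cnt)
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

## Heads-only forward pass (no coordinate basis): scalar-head features and
## outputs for a given state. Used to train the confidence head on
## displaced-ligand states cheaply.
.forwardHeads <- function(model, xProt, xLig, t, graph, structure) {
  ed <- .edgeLists(xProt, xLig, graph, structure, model$config$neighborCutoff)
  hf <- .headFeatures(model, ed, graph, structure, t)
  eta <- as.numeric(hf$Zconf %*% model$wConf)
  list(conf = stats::plogis(eta), Zconf = hf$Zconf, zAff = hf$zAff,
       aff = sum(hf$zAff * model$wAff))
}

## Per-protein-residue lDDT over protein-ligand (interface) pairs only.
## NA for residues with no reference interface contact inside the inclusion
## radius.
.lddtInterface <- function(pred, reference, residueIndex, isLigand,
                           inclusionRadius = 15,
                           thresholds = c(0.5, 1, 2, 4)) {
  dRef <- cross_dist(reference, reference)
  use <- dRef < inclusionRadius & outer(isLigand, isLigand, "!=")
  use[lower.tri(use, diag = TRUE)] <- FALSE
  pairs <- which(use, arr.ind = TRUE)
  nres <- max(residueIndex[!isLigand])
  if (nrow(pairs) == 0L) return(rep(NA_real_, nres))
  dPred <- cross_dist(pred, pred)
  score <- rowMeans(outer(abs(dPred[pairs] - dRef[pairs]), thresholds, "<"))
  num <- numeric(nres); den <- numeric(nres)
  for (col in 1:2) {
    sel <- !isLigand[pairs[, col]]
    if (!any(sel)) next
    r <- residueIndex[pairs[sel, col]]
    tab <- tapply(score[sel], r, sum); cnt <- table(r)
    idx <- as.integer(names(tab))
    num[idx] <- num[idx] + as.numeric(tab)
    den[idx] <- den[idx] + as.numeric(cnt)
  }
  ifelse(den > 0, num / den, NA_real_)
}

## Confidence labels: interface lDDT where the residue has reference
## protein-ligand contacts (pose-sensitive), all-pair lDDT elsewhere. A
## confidence head trained on all-pair lDDT alone is dominated by
## protein-internal distances and cannot rank ligand poses.
.confidenceLabels <- function(predP, predL, refP, refL, structure, graph) {
  sp <- nResidues(structure)
  resIdx <- c(structure@atomToResidue, sp + graph@fragmentId)
  pred <- rbind(predP, predL)
  ref <- rbind(refP, refL)
  allPair <- computeLDDT(pred, ref, resIdx)[seq_len(sp)]
  isLig <- c(rep(FALSE, nrow(predP)), rep(TRUE, nrow(predL)))
  iface <- .lddtInterface(pred, ref, resIdx, isLig)[seq_len(sp)]
  ifelse(is.na(iface), allPair, iface)
}

#' Affinity head loss (masked squared error in pK units)
#'
#' @param predPk predicted affinity, pK units.
#' @param labelPk label, pK units; `NA` masks the example (contributes 0).
#' @return scalar loss.
#' @export
affinityHeadLoss <- function(predPk, labelPk) {
  if (is.na(labelPk)) return(0)
  (predPk - labelPk)^2
}

#' Confidence head loss (mean squared error against lDDT labels)
#'
#' @param predConf predicted per-residue confidence in \eqn{[0, 1]}.
#' @param lddtLabels per-residue lDDT of the predicted structure against the
#'   holo target (NA entries are dropped).
#' @return scalar loss.
#' @export
confidenceHeadLoss <- function(predConf, lddtLabels) {
  if (length(predConf) != length(lddtLabels))
    stop_input("confidence/label length mismatch")
  ok <- !is.na(lddtLabels)
  if (!any(ok)) return(0)
  mean((predConf[ok] - lddtLabels[ok])^2)
}

#' Save / load a flow model
#'
#' @param model a `"flowModel"`.
#' @param path file path (RDS).
#' @return `loadFlowModel` returns the model; `saveFlowModel` the path,
#'   invisibly.
#' @export
saveFlowModel <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveFlowModel
#' @export
loadFlowModel <- function(path) {
  if (!file.exists(path)) stop_input("no such checkpoint: %s", path)
  m <- readRDS(path)
  if (!inherits(m, "flowModel")) stop_input("checkpoint is not a flowModel")
  m
}
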