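## Apo-to-holo pair assessment: weighted structural alignment, RMSD, TM-score,
## and the unbalanced-coupling acceptance rule used for dataset curation.

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation R and translation t minimizing the weighted
#' least-squares objective \eqn{\sum_i w_i \| R m_i + t - y_i \|^2} via SVD of
#' the weighted cross-covariance, with the usual sign correction enforcing
#' det(R) = +1. Intended for C-alpha coordinates; apply the returned transform
#' to all atoms for a full-structure superposition.
#'
#' @param mobile,target numeric matrices (M x 3), M >= 3.
#' @param weights non-negative weights, not all zero (default uniform).
#' @return list with class `"AlignmentResult"`: `rotation` (3 x 3),
#'   `translation` (3-vector), `weightedRmsd` and `caRmsd` (unweighted RMSD
#'   after alignment), both in Angstrom.
#' @export
weightedKabschAlign <- function(mobile, target,
                                weights = rep(1, nrow(mobile))) {
  M <- nrow(mobile)
  if (M < 3L || nrow(target) != M)
    stop_input("need matching coordinate sets with at least 3 points")
  if (any(weights < 0) || sum(weights) <= 0)
    stop_input("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  mc <- colSums(mobile * w)
  tc <- colSums(target * w)
  A <- sweep(mobile, 2, mc)
  B <- sweep(target, 2, tc)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (!is.finite(d) || d == 0 || min(sv$d) < 1e-12 * max(sv$d, 1e-300)) {
    ## rank-deficient cross-covariance: collinear/degenerate weighted sets
    if (sum(sv$d > 1e-10 * max(sv$d, 1e-300)) < 2)
      stop_input("degenerate point configuration: weighted Kabsch undefined")
    if (d == 0) d <- 1
  }
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- tc - as.numeric(R %*% mc)
  fitted <- mobile %*% t(R) + matrix(tr, M, 3, byrow = TRUE)
  dev2 <- rowSums((fitted - target)^2)
  structure(list(rotation = R, translation = tr,
                 weightedRmsd = sqrt(sum(w * dev2)),
                 caRmsd = sqrt(mean(dev2))),
            class = "AlignmentResult")
}

#' Ligand-proximity residue weights for pocket-focused alignment
#'
#' \eqn{w_i = \exp(-d_i / \tau)} with \eqn{d_i} the minimum distance from
#' residue i's C-alpha to any ligand heavy atom, normalized to sum to one.
#' Concentrates the apo-to-holo alignment on the binding pocket.
#'
#' @param apoCa C-alpha coordinates (M x 3) in the frame of `ligandCoords`.
#' @param ligandCoords ligand heavy-atom coordinates (N x 3).
#' @param tau decay length in Angstrom (default 5).
#' @return numeric vector of M weights summing to 1.
#' @export
ligandProximityWeights <- function(apoCa, ligandCoords, tau = 5) {
  if (is.null(dim(ligandCoords)) || nrow(ligandCoords) == 0L)
    stop_input("empty ligand")
  if (tau <= 0) stop_input("tau must be > 0")
  d <- apply(cross_dist(apoCa, ligandCoords), 1, min)
  w <- exp(-d / tau)
  w / sum(w)
}

#' C-alpha RMSD without superposition
#'
#' \eqn{\sqrt{\mathrm{mean}_i \|a_i - b_i\|^2}}. The caller aligns first; no
#' superposition is performed here.
#'
#' @param a,b coordinate matrices of equal dimension (M x 3), M >= 1.
#' @return RMSD in Angstrom.
#' @export
caRMSD <- function(a, b) {
  if (!all(dim(a) == dim(b)) || nrow(a) < 1L)
    stop_input("coordinate sets must have equal non-zero dimensions")
  sqrt(mean(rowSums((a - b)^2)))
}

#' TM-score under fixed residue correspondence
#'
#' \eqn{TM = \frac{1}{M}\sum_i \frac{1}{1 + (d_i/d_0)^2}} with
#' \eqn{d_0 = \max(1.24 (M - 15)^{1/3} - 1.8,\ 0.5)} Angstrom, evaluated under
#' the superposition that maximizes the score. Residue correspondence is given
#' by the shared sequence, so no alignment search is performed; the
#' superposition is refined iteratively (start from the all-residue Kabsch
#' fit, re-fit on residues closer than a d0-scaled cutoff until the subset is
#' stable, at most 20 iterations, keeping the best score seen). Normalization
#' is by the (holo) target length.
#'
#' @param mobile,target C-alpha coordinate matrices (M x 3).
#' @return TM-score in (0, 1].
#' @export
tmScore <- function(mobile, target) {
  M <- nrow(mobile)
  if (M == 0L || nrow(target) != M) stop_input("need matched non-empty sets")
  d0 <- if (M > 15) max(1.24 * (M - 15)^(1 / 3) - 1.8, 0.5) else 0.5
  tmOf <- function(fit) mean(1 / (1 + (rowSums((fit - target)^2)) / d0^2))
  applyFit <- function(al) mobile %*% t(al$rotation) +
    matrix(al$translation, M, 3, byrow = TRUE)
  al <- weightedKabschAlign(mobile, target)
  fit <- applyFit(al)
  best <- tmOf(fit)
  subset <- seq_len(M)
  cutoff <- max(2 * d0, 1.0)
  for (it in seq_len(20L)) {
    d <- sqrt(rowSums((fit - target)^2))
    newSubset <- which(d < cutoff)
    if (length(newSubset) < 3L || identical(newSubset, subset)) break
    subset <- newSubset
    al <- tryCatch(weightedKabschAlign(mobile[subset, , drop = FALSE],
                                       target[subset, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(al)) break
    fit <- applyFit(al)
    best <- max(best, tmOf(fit))
  }
  best
}

#' Apply the apo-holo coupling acceptance rule to a pair
#'
#' Aligns apo to holo C-alphas with ligand-proximity weights (initial
#' unweighted fit to place the apo structure in the holo frame, weights from
#' distances to the bound ligand, then the weighted re-fit), computes the
#' TM-score and post-alignment C-alpha RMSD, and accepts iff
#' `tm >= tmMin` and `rmsd < rmsdMax` and both length caps hold — i.e. pairs
#' are rejected exactly when `tm < tmMin` or `rmsd >= rmsdMax` (defaults 0.7
#' and 5 Angstrom).
#'
#' @param pair a [PairRecord-class] (apo/holo sequences must match).
#' @param config a `CouplingConfig`.
#' @return the pair with `accepted` and `metrics` (tm, caRmsd) filled in.
#' @export
acceptPair <- function(pair, config = couplingConfig()) {
  if (!identical(pair@apo@sequence, pair@holo@sequence))
    stop("acceptPair requires residue-indexed pairing (equal sequences)",
         call. = FALSE)
  apoCa <- caCoords(pair@apo)
  holoCa <- caCoords(pair@holo)
  al0 <- weightedKabschAlign(apoCa, holoCa)
  M <- nrow(apoCa)
  apoCa0 <- apoCa %*% t(al0$rotation) + matrix(al0$translation, M, 3, byrow = TRUE)
  w <- ligandProximityWeights(apoCa0, pair@holoLigandCoords)
  al <- weightedKabschAlign(apoCa, holoCa, w)
  apoFit <- apoCa %*% t(al$rotation) + matrix(al$translation, M, 3, byrow = TRUE)
  metrics <- list(tm = tmScore(apoCa, holoCa), caRmsd = caRMSD(apoFit, holoCa))
  pair@metrics <- metrics
  pair@accepted <- metrics$tm >= config$tmMin &&
    metrics$caRmsd < config$rmsdMax &&
    nResidues(pair@holo) <= config$maxResidues &&
    nAtoms(pair@ligand) <= config$maxLigandAtoms
  pair
}

#' Curate an apo-holo pair dataset
#'
#' Applies the sequence-gap check (when a full sequence is attached) and then
#' [acceptPair()] to every pair, returning a manifest table with one row per
#' pair and per-category rejection counts.
#'
#' @param pairs list of [PairRecord-class] objects.
#' @param config a `CouplingConfig`.
#' @param manifestPath optional CSV output path (written atomically).
#' @return list with `pairs` (assessed records), `manifest` (data.frame with
#'   columns apo_id, holo_id, ligand_id, tm, ca_rmsd, n_residues,
#'   n_ligand_atoms, accepted, reject_reason) and `counts` (per-reason table).
#' @export
curateDataset <- function(pairs, config = couplingConfig(),
                          manifestPath = NULL) {
  if (length(pairs) == 0L) {
    warning("curateDataset called with no pairs; empty manifest")
    manifest <- data.frame(apo_id = character(0), holo_id = character(0),
                           ligand_id = character(0), tm = numeric(0),
                           ca_rmsd = numeric(0), n_residues = integer(0),
                           n_ligand_atoms = integer(0), accepted = logical(0),
                           reject_reason = character(0))
    if (!is.null(manifestPath)) atomic_write_csv(manifest, manifestPath)
    return(list(pairs = pairs, manifest = manifest,
                counts = table(character(0))))
  }
  rows <- vector("list", length(pairs))
  out <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    reason <- ""
    if (length(p@fullSequence) && any(nzchar(p@fullSequence)) &&
        !checkSequenceGaps(p@fullSequence, p@holo)) {
      p@accepted <- FALSE
      p@metrics <- list(tm = NA_real_, caRmsd = NA_real_)
      reason <- "sequence_gap"
    } else {
      p <- acceptPair(p, config)
      if (!p@accepted) {
        reason <- if (nResidues(p@holo) > config$maxResidues) "n_residues"
        else if (nAtoms(p@ligand) > config$maxLigandAtoms) "n_ligand_atoms"
        else if (p@metrics$tm < config$tmMin) "tm"
        else "rmsd"
      }
    }
    rows[[k]] <- data.frame(
      apo_id = paste0(p@id, "_apo"), holo_id = paste0(p@id, "_holo"),
      ligand_id = if (nzchar(p@ligand@smiles)) p@ligand@smiles else p@id,
      tm = round(p@metrics$tm, 6), ca_rmsd = round(p@metrics$caRmsd, 6),
      n_residues = nResidues(p@holo), n_ligand_atoms = nAtoms(p@ligand),
      accepted = p@accepted, reject_reason = reason)
    out[[k]] <- p
  }
  manifest <- do.call(rbind, rows)
  counts <- table(manifest$reject_reason[manifest$reject_reason != ""])
  message(sprintf("curated %d pairs: %d accepted, %d rejected (%s)",
                  nrow(manifest), sum(manifest$accepted),
                  sum(!manifest$accepted),
                  if (length(counts)) paste(names(counts), counts, sep = "=",
                                            collapse = ", ") else "none"))
  if (!is.null(manifestPath)) atomic_write_csv(manifest, manifestPath)
  list(pairs = out, manifest = manifest, counts = counts)
}
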