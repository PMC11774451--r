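mkState <- function(prot, lig, t) {
  new("ComplexState", proteinCoords = prot, ligandCoords = lig, time = t)
}

test_that("CondOT interpolation hits its endpoints and midpoint exactly", {
  p <- makeToyComplex(toyComplexSpec(seed = 1L))
  x0 <- mkState(p@apo@atomCoords, p@holoLigandCoords + 5, 0)
  x1 <- mkState(p@holo@atomCoords, p@holoLigandCoords, 1)
  expect_identical(condotInterpolate(x0, x1, 0)@proteinCoords,
                   x0@proteinCoords)
  expect_identical(condotInterpolate(x0, x1, 1)@ligandCoords,
                   x1@ligandCoords)
  z <- mkState(matrix(0, 2, 3), matrix(0, 1, 3), 0)
  w <- mkState(matrix(2, 2, 3), matrix(2, 1, 3), 1)
  expect_equal(condotInterpolate(z, w, 0.5)@proteinCoords, matrix(1, 2, 3))
  bad <- mkState(matrix(0, 3, 3), matrix(0, 1, 3), 0)
  expect_error(condotInterpolate(bad, w, 0.5), "shape")
})

test_that("cfm loss reduction is the stated mean with ligand weighting", {
  a <- matrix(0, 4, 3); b <- matrix(0, 2, 3)
  expect_equal(cfmLoss(a, b, a, b), 0)
  ## unit error on one axis of every atom: mean over 3 dims = 1/3 per block
  expect_equal(cfmLoss(a + c(1, 0, 0)[col(a)] * 0 + rep(c(1, 0, 0), each = 4),
                       b + rep(c(1, 0, 0), each = 2), a, b),
               1 / 3 + 1 / 3)
  ## homogeneity: doubling errors quadruples the loss
  e1 <- matrix(rnorm(12), 4, 3); e2 <- matrix(rnorm(6), 2, 3)
  l1 <- cfmLoss(a + e1, b + e2, a, b)
  l2 <- cfmLoss(a + 2 * e1, b + 2 * e2, a, b)
  expect_equal(l2, 4 * l1)
  ## ligand weight scales only the ligand term
  expect_equal(cfmLoss(a, b + 1, a, b, ligandWeight = 2), 2 * 1)
})

test_that("cfm loss gradient matches finite differences", {
  withr::with_seed(71, {
    pred <- matrix(rnorm(12), 4, 3)
    tgt <- matrix(rnorm(12), 4, 3)
    lw <- 1.7
    predL <- matrix(rnorm(6), 2, 3); tgtL <- matrix(rnorm(6), 2, 3)
    analytic <- 2 * (pred - tgt) / length(pred)
    analyticL <- 2 * lw * (predL - tgtL) / length(predL)
    eps <- 1e-6
    for (k in sample(12, 4)) {
      bumped <- pred; bumped[k] <- bumped[k] + eps
      fd <- (cfmLoss(bumped, predL, tgt, tgtL, lw) -
               cfmLoss(pred, predL, tgt, tgtL, lw)) / eps
      expect_equal(fd, analytic[k], tolerance = 1e-5)
    }
    for (k in sample(6, 3)) {
      bumped <- predL; bumped[k] <- bumped[k] + eps
      fd <- (cfmLoss(pred, bumped, tgt, tgtL, lw) -
               cfmLoss(pred, predL, tgt, tgtL, lw)) / eps
      expect_equal(fd, analyticL[k], tolerance = 1e-5)
    }
  })
})

test_that("training batches respect endpoints, uniform times, determinism", {
  pairs <- lapply(1:3, function(s)
    acceptPair(makeToyComplex(toyComplexSpec(seed = s))))
  cfg <- trainConfig(batchSize = 6L, sigma = 0)
  b1 <- makeTrainingBatch(pairs, cfg, seed = 5L)
  b2 <- makeTrainingBatch(pairs, cfg, seed = 5L)
  expect_identical(b1, b2)
  for (s in b1) {
    manual <- condotInterpolate(s$x0, s$x1, s$t)
    expect_equal(s$xt@proteinCoords, manual@proteinCoords, tolerance = 1e-10)
    ## endpoints: rebuild with forced t
    expect_equal(condotInterpolate(s$x0, s$x1, 1)@ligandCoords,
                 s$x1@ligandCoords)
    expect_equal(condotInterpolate(s$x0, s$x1, 0)@proteinCoords,
                 s$x0@proteinCoords)
  }
  ## t ~ U(0,1): Kolmogorov-Smirnov on pooled draws
  big <- trainConfig(batchSize = 2000L)
  ts <- vapply(makeTrainingBatch(pairs, big, seed = 7L), function(s) s$t,
               numeric(1))
  ks <- suppressWarnings(stats::ks.test(ts, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(makeTrainingBatch(list(), cfg, 1L), "empty")
})

test_that("training memorizes a single pair (overfit contract)", {
  p <- makeToyComplex(toyComplexSpec(seed = 10L))
  evalFlowLoss <- function(model) {
    batch <- makeTrainingBatch(list(p), trainConfig(batchSize = 64L,
                                                    seed = 999L), seed = 999L)
    mean(vapply(batch, function(s) {
      pr <- predictComplex(model, s$xt, t = s$t, graph = p@ligand,
                           structure = p@holo)
      cfmLoss(pr@predProtein, pr@predLigand,
              s$x1@proteinCoords, s$x1@ligandCoords)
    }, numeric(1)))
  }
  initial <- evalFlowLoss(flowModel())
  ## memorization is checked under the exact flow-matching objective
  ## (inputNoise = 0): the default input perturbation deliberately trades
  ## on-path bias for off-path robustness and is assessed elsewhere
  fit <- trainFlowModel(list(p), flowModel(),
                        trainConfig(steps = 500L, seed = 1L, inputNoise = 0))
  ## the flow loss on a fixed held-out batch of path samples falls below 1%
  ## of its value under the untrained model
  expect_lt(evalFlowLoss(fit$model) / initial, 0.01)
  expect_true(fit$model$trained)
})

test_that("training history is finite and seed-deterministic", {
  pairs <- lapply(41:44, function(s) makeToyComplex(toyComplexSpec(seed = s)))
  cfg <- trainConfig(steps = 30L, seed = 9L)
  f1 <- trainFlowModel(pairs, flowModel(), cfg)
  f2 <- trainFlowModel(pairs, flowModel(), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$Theta, f2$model$Theta)
  expect_true(all(is.finite(as.matrix(f1$history))))
})

test_that("rejected pairs never influence training", {
  pairs <- lapply(51:54, function(s) makeToyComplex(toyComplexSpec(seed = s)))
  ## a pair that fails the coupling filter: apo grossly deformed
  bad <- pairs[[1]]
  bad@apo@atomCoords <- bad@apo@atomCoords +
    outer(seq_len(nAtoms(bad@apo)), c(0.4, 0.2, 0.1))
  bad@id <- "bad"
  stopifnot(!acceptPair(bad)@accepted)
  cfg <- trainConfig(steps = 25L, seed = 3L)
  fClean <- trainFlowModel(pairs, flowModel(), cfg)
  fInjected <- trainFlowModel(c(pairs, list(bad)), flowModel(), cfg)
  expect_identical(fClean$history, fInjected$history)
})

test_that("checkpoints are written and reloadable", {
  pairs <- lapply(61:62, function(s) makeToyComplex(toyComplexSpec(seed = s)))
  dir <- withr::local_tempdir()
  fit <- trainFlowModel(pairs, flowModel(),
                        trainConfig(steps = 4L, batchSize = 2L, seed = 1L),
                        checkpointDir = dir)
  cks <- list.files(dir, pattern = "checkpoint_.*rds")
  expect_gt(length(cks), 0L)
  m <- loadFlowModel(file.path(dir, cks[length(cks)]))
  expect_s3_class(m, "flowModel")
})
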