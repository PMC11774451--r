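test_that("VD-ODE steps match hand-evaluated coefficients at i = 2", {
  cfg <- samplerConfig(nSteps = 2L)
  x0 <- matrix(c(0, 0, 0), 1)
  pred <- matrix(c(2, 2, 2), 1)
  ## n = 0: r = (1 - 1/2)/(1 - 0) = 1/2 -> midpoint
  x1 <- vdOdeStep(x0, pred, 0L, cfg)
  expect_equal(x1, (x0 + pred) / 2)
  ## n = 1: r = 0 -> clamped coefficients (1e-6, 1 - 1e-6)
  x2 <- vdOdeStep(x1, pred, 1L, cfg)
  expect_equal(x2, 1e-6 * x1 + (1 - 1e-6) * pred, tolerance = 1e-15)
  expect_lt(max(abs(x2 - pred)) / max(abs(pred)), 1e-5)
  ## fixed point
  expect_equal(vdOdeStep(pred, pred, 0L, cfg), pred)
  expect_error(vdOdeStep(x0, pred, 2L, cfg), "0 <= n < i")
})

test_that("VD-ODE coefficients sum to eta before clamping", {
  cfg <- samplerConfig(nSteps = 40L)
  for (n in 0:39) {
    t <- n / 40; s <- (n + 1) / 40
    r <- (1 - s) / (1 - t)
    expect_equal(r * cfg$eta + (1 - r) * cfg$eta, cfg$eta, tolerance = 1e-12)
  }
})

test_that("Euler steps follow the x1-parametrized velocity exactly", {
  cfg <- samplerConfig(nSteps = 4L, solver = "euler")
  x1 <- matrix(c(1, 2, 3), 1)
  x <- matrix(0, 1, 3)
  ## constant oracle: straight-line path hitting x1 at n = i (telescoping)
  for (n in 0:3) {
    x <- eulerStep(x, x1, n, cfg)
    expect_equal(x, x1 * (n + 1) / 4, tolerance = 1e-12)
  }
  expect_equal(x, x1)
  ## i = 1: single step returns the prediction
  cfg1 <- samplerConfig(nSteps = 1L)
  expect_equal(eulerStep(matrix(5, 1, 3), x1, 0L, cfg1), x1)
  ## stationarity
  expect_equal(eulerStep(x1, x1, 1L, cfg), x1)
})

test_that("constant-oracle generation converges to holo under the VD-ODE", {
  p <- makeToyComplex(toyComplexSpec(seed = 17L))
  holoProt <- p@holo@atomCoords
  holoLig <- p@holoLigandCoords
  oracle <- function(state, t)
    new("Prediction", predProtein = holoProt, predLigand = holoLig,
        confidence = rep(0.9, nResidues(p@holo)), affinityPk = 5)
  cfg <- samplerConfig(nSteps = 40L, nSamples = 2L, seed = 3L)
  trajs <- generateSamples(flowModel(), p@apo, p@ligand, cfg,
                           predictFn = oracle)
  for (tr in trajs) {
    fin <- tr@states[[length(tr@states)]]
    expect_lt(max(abs(fin@proteinCoords - holoProt)), 1e-5)
    expect_lt(max(abs(fin@ligandCoords - holoLig)), 1e-5)
    times <- vapply(tr@states, function(s) s@time, numeric(1))
    expect_equal(times, seq(0, 1, length.out = 41))
  }
})

test_that("generation is ranked by confidence, deterministic under seed", {
  p <- makeToyComplex(toyComplexSpec(seed = 18L))
  cfg <- samplerConfig(nSteps = 5L, nSamples = 5L, seed = 9L)
  t1 <- generateSamples(flowModel(), p@apo, p@ligand, cfg)
  t2 <- generateSamples(flowModel(), p@apo, p@ligand, cfg)
  expect_identical(t1, t2)
  expect_equal(length(t1), 5L)
  confs <- vapply(t1, function(tr) mean(tr@final@confidence), numeric(1))
  expect_true(all(diff(confs) <= 0))
})

test_that("trajectory displacement decreases toward late steps for a constant oracle", {
  p <- makeToyComplex(toyComplexSpec(seed = 19L))
  oracle <- function(state, t)
    new("Prediction", predProtein = p@holo@atomCoords,
        predLigand = p@holoLigandCoords,
        confidence = rep(0.5, nResidues(p@holo)), affinityPk = 5)
  cfg <- samplerConfig(nSteps = 40L, nSamples = 1L, seed = 1L)
  tr <- generateSamples(flowModel(), p@apo, p@ligand, cfg,
                        predictFn = oracle)[[1]]
  disp <- vapply(seq_len(40), function(n) {
    max(sqrt(rowSums((tr@states[[n + 1]]@ligandCoords -
                        tr@states[[n]]@ligandCoords)^2)))
  }, numeric(1))
  expect_true(all(is.finite(disp)))
  ## late-step displacements shrink (compare first and last quarter)
  expect_lt(mean(disp[31:40]), mean(disp[1:10]))
})

test_that("variance-diminishing: VD-ODE final variance < Euler under a noisy oracle", {
  ## common random numbers: both solvers see the same noise sequence per
  ## repetition, making the comparison exact and seed-controlled
  p <- makeToyComplex(toyComplexSpec(seed = 23L))
  holoProt <- p@holo@atomCoords; holoLig <- p@holoLigandCoords
  nRep <- 500L
  cfgV <- samplerConfig(nSteps = 40L, nSamples = 1L)
  finals <- withr::with_seed(71, {
    vapply(seq_len(nRep), function(rep) {
      noises <- lapply(0:40, function(n)
        matrix(rnorm(length(holoLig), sd = 0.5), nrow(holoLig), 3))
      runSolver <- function(stepFn) {
        x <- holoLig + matrix(rnorm(length(holoLig), sd = 2), nrow(holoLig), 3)
        for (n in 0:39) x <- stepFn(x, holoLig + noises[[n + 1]], n, cfgV)
        x[1, 1]
      }
      set.seed(rep)  # same prior perturbation for both solvers
      vd <- runSolver(vdOdeStep)
      set.seed(rep)
      eu <- runSolver(eulerStep)
      c(vd, eu)
    }, numeric(2))
  })
  varVd <- stats::var(finals[1, ])
  varEuler <- stats::var(finals[2, ])
  expect_lt(varVd, varEuler)
})

test_that("symmetry-corrected ligand RMSD handles automorphisms", {
  ## identical
  g <- parseSmiles("CC")
  x <- g@refCoords
  expect_equal(ligandRmsdToReference(x, x, g), 0)
  ## uniform 2 A shift
  expect_equal(ligandRmsdToReference(x + 2 / sqrt(3), x, g), 2,
               tolerance = 1e-9)
  ## benzene-like 6-cycle rotated by one position: zero after correction
  ring <- cfmdock:::.makeLigandGraph(rep("C", 6),
                                     cbind(1:6, c(2:6, 1)))
  ang <- (0:5) * pi / 3
  pose <- cbind(cos(ang), sin(ang), 0) * 1.39
  rotated <- pose[c(2:6, 1), ]
  expect_gt(sqrt(mean(rowSums((rotated - pose)^2))), 1)  # raw RMSD is large
  expect_equal(ligandRmsdToReference(rotated, pose, ring), 0,
               tolerance = 1e-9)
  ## element labels restrict the automorphism group
  hetero <- cfmdock:::.makeLigandGraph(c("C", "O", "C", "O", "C", "O"),
                                       cbind(1:6, c(2:6, 1)))
  shifted2 <- pose[c(3:6, 1, 2), ]
  expect_equal(ligandRmsdToReference(shifted2, pose, hetero), 0,
               tolerance = 1e-9)
  shifted1 <- pose[c(2:6, 1), ]
  expect_gt(ligandRmsdToReference(shifted1, pose, hetero), 0.5)
  expect_error(ligandRmsdToReference(x, matrix(0, 3, 3), g), "mismatch")
})
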