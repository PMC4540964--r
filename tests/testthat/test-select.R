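test_that("LR test reproduces the chi-squared(1) worked examples", {
  r1 <- lrTest(0, 28.99 / 2)
  expect_equal(r1$LR, 28.99)
  expect_equal(r1$p, 7.25e-8, tolerance = 0.01)
  r2 <- lrTest(0, 8.23 / 2)
  expect_equal(r2$p, 0.0041, tolerance = 0.01)
  expect_equal(lrTest(5, 5)$p, 1)          # LR = 0, null boundary
})

test_that("LR clips below-null alternatives and rejects non-nested pairs", {
  expect_warning(r <- lrTest(10, 10 - 1e-3), "clipped")
  expect_equal(r$LR, 0)
  mkFit <- function(model, ll, k) new("ModelFit", model = model,
    params = list(), logLik = ll, k = k, AIC = 2 * k - 2 * ll,
    nTips = 12L, degenerate = FALSE, untestable = FALSE)
  expect_error(lrTest(mkFit("M0", -3, 3), mkFit("BM", -2, 2)),
               "not nested")
})

test_that("Akaike weights normalize, are symmetric and never overflow", {
  expect_equal(akaikeWeights(c(10, 10)), c(0.5, 0.5))
  expect_equal(akaikeWeights(c(100, 102)),
               c(1 / (1 + exp(-1)), 1 - 1 / (1 + exp(-1))),
               tolerance = 1e-9)
  w <- akaikeWeights(c(0, 1000))
  expect_equal(w[1], 1, tolerance = 1e-12)
  expect_lt(w[2], 1e-200)
  expect_true(all(is.finite(w)))
  expect_error(akaikeWeights(c(1, Inf)), "non-finite")
  expect_error(akaikeWeights(3), "at least 2")
})

mkShiftFit <- function(model, aic, thetaShift = 5, thetaBase = 2) {
  ll <- (2 * 4 - aic) / 2
  new("ModelFit", model = model,
      params = list(alpha = 1, sigmaSq = 1,
                    theta = c(base = thetaBase, shift = thetaShift),
                    x0 = thetaBase),
      logLik = ll, k = 4, AIC = aic, nTips = 12L,
      degenerate = FALSE, untestable = FALSE)
}
mkPlainFit <- function(model, aic, k) {
  ll <- (2 * k - aic) / 2
  new("ModelFit", model = model,
      params = if (model == "BM") list(x0 = 0, sigmaSq = 1) else
        list(alpha = 1, sigmaSq = 1, theta = c(base = 2), x0 = 2),
      logLik = ll, k = k, AIC = aic, nTips = 12L,
      degenerate = FALSE, untestable = FALSE)
}

test_that("divergence calls follow the Akaike-weight comparison rules", {
  ## AICs chosen so the triple reproduces weights like (0.99, 3.7e-6, 4.3e-5)
  aM10 <- 10
  aM0 <- aM10 - 2 * log(3.73e-6 / 0.99)
  aBM <- aM10 - 2 * log(4.31e-5 / 0.99)
  fits <- list(M0 = mkPlainFit("M0", aM0, 3), BM = mkPlainFit("BM", aBM, 2),
               M10 = mkShiftFit("M10", aM10, thetaShift = 1))
  w <- akaikeWeights(vapply(fits[c("M10", "M0", "BM")], AIC, 0))
  expect_equal(unname(w), c(0.99, 3.73e-6, 4.31e-5), tolerance = 0.02)
  call <- callDivergence(fits, mode = "triple")
  expect_equal(call$model, "M10")
  expect_true(call$divergent)
  expect_equal(call$direction, "loss")    # theta_shift 1 < theta_base 2

  ## pairwise: wAIC pair {Mx: 0.89, M0: 0.11} -> divergent
  fits2 <- list(M0 = mkPlainFit("M0", 2 * log(0.89 / 0.11), 3),
                M10 = mkShiftFit("M10", 0))
  call2 <- callDivergence(fits2, mode = "pairwise")
  expect_equal(call2$wAIC, 0.89, tolerance = 1e-6)
  expect_true(call2$divergent)

  ## equal AICs: tie broken toward the simpler model, not divergent
  fits3 <- list(M0 = mkPlainFit("M0", 10, 3), M10 = mkShiftFit("M10", 10))
  expect_false(callDivergence(fits3, mode = "pairwise")$divergent)
  expect_error(callDivergence(list(BM = mkPlainFit("BM", 1, 2))), "M0")
})

test_that("shift direction is the sign of theta_shift - theta_base", {
  expect_equal(classifyDirection(mkShiftFit("M10", 10, 6.9, 2.62)), "gain")
  expect_equal(classifyDirection(mkShiftFit("M10", 10, 1, 2)), "loss")
  expect_equal(classifyDirection(mkShiftFit("M10", 10, 2, 2)),
               "indeterminate")
})

test_that("BH adjustment matches the hand computation and is monotone", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(31)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "0,1")
})

test_that("pairwise wAIC and the LR decision agree whenever LR > 2", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(32)
  for (i in 1:10) {
    gen <- sample(c("M0", "M10"), 1)
    params <- list(alpha = 1.5, sigmaSq = 1,
                   theta = c(base = 2, shift = if (gen == "M0") 2 else 5))
    x <- simulateTrait(tr, regs[[gen]], params)
    fits <- fitRegion(tr, x, regs[c("M0", "M10")])
    call <- callDivergence(fits, mode = "pairwise")
    if (call$LR > 2) expect_true(call$divergent)
    if (call$LR < 2) expect_false(call$divergent)
  }
})

test_that("divergence tables stack calls and the database round-trips", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  ds <- genTraitDataset(tr, regs$M10,
                        list(alpha = 2, sigmaSq = 1,
                             theta = c(base = 2, shift = 7)),
                        nRegions = 4, seed = 33)
  calls <- divergenceTable(ds$traits, tr, regs[c("BM", "M0", "M10")],
                           pwm = "toy")
  expect_true(all(c("pwm", "region", "model", "wAIC", "p", "p_adj",
                    "direction", "divergent") %in% names(calls)))
  expect_equal(nrow(calls), 4L)            # one shift model x 4 regions
  dir <- tempfile()
  writeDivergenceDb(calls, dir)
  back <- readDivergenceDb(dir)
  expect_equal(nrow(back), nrow(calls))
  expect_setequal(back$region, calls$region)
  gainFile <- file.path(dir, "toy", "M10_gain.txt")
  expect_true(file.exists(gainFile))
})
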