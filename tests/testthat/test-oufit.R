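test_that("BM log-likelihood matches the closed-form normal density", {
  st <- parseNewick("(A:1,B:1);")
  expect_equal(bmLoglik(st, c(A = 0, B = 0), 0, 1), -log(2 * pi),
               tolerance = 1e-12)
  expect_equal(bmLoglik(st, c(A = 1, B = -1), 0, 1), -log(2 * pi) - 1,
               tolerance = 1e-12)
  expect_error(bmLoglik(st, c(A = 0, B = 0), 0, -1), "sigmaSq")
})

test_that("sister-tip BM covariance equals sigma^2 times the shared stem", {
  tr <- parseNewick("((A:0.5,B:0.5):0.75,C:1.25);")
  p <- paintUniform(tr, "BM")
  set.seed(21)
  sims <- t(vapply(1:10000, function(i)
    simulateTrait(tr, p, list(sigmaSq = 1), seed = NULL), numeric(3)))
  v <- stats::cov(sims[, "A"], sims[, "B"])
  se <- sqrt((0.75^2 + 1.25 * 1.25) / 10000)  # var of sample cov, Gaussian
  expect_lt(abs(v - 0.75), 3 * se)
})

test_that("Hansen log-likelihood matches the scalar closed form on a 2-tip star", {
  st <- parseNewick("(A:1,B:1);")
  p0 <- paintUniform(st, "M0")
  v <- (2 / 2) * (1 - exp(-2))     # sigma^2/(2 alpha) (1 - e^{-2 alpha t})
  expect_equal(hansenLoglik(st, p0, c(A = 0, B = 0), alpha = 1,
                            sigmaSq = 2, theta = 0),
               -log(2 * pi * v), tolerance = 1e-9)
  expect_error(hansenLoglik(st, p0, c(A = 0, B = 0), alpha = 0,
                            sigmaSq = 1, theta = 0), "bmLoglik")
})

test_that("alpha -> 0 recovers BM; alpha large reaches the stationary limit", {
  t5 <- fiveTipTree()
  p <- paintUniform(t5)
  set.seed(22)
  for (i in 1:5) {
    x <- setNames(rnorm(5, 1, 2), t5$tip.label)
    expect_lt(abs(hansenLoglik(t5, p, x, 1e-10, 1.3, theta = 0.7,
                               x0 = 0.7) -
                  bmLoglik(t5, x, 0.7, 1.3)), 1e-5)
  }
  ## strong selection: tip distribution ~ N(theta, sigma^2/(2 alpha))
  st <- parseNewick("(A:1,B:1);")
  c0 <- 3.7
  ll <- hansenLoglik(st, paintUniform(st), c(A = c0, B = c0), alpha = 50,
                     sigmaSq = 1, theta = c0)
  expect_equal(ll, -log(2 * pi * 1 / 100), tolerance = 1e-6)
})

test_that("likelihood equals a naive MVN oracle on random painted trees", {
  set.seed(23)
  for (i in 1:20) {
    rp <- randomPaintedTree(sample(4:8, 1))
    n <- length(rp$tree$tip.label)
    x <- setNames(rnorm(n, 2, 1.5), rp$tree$tip.label)
    a <- runif(1, 0.2, 3); s2 <- runif(1, 0.3, 2)
    th <- c(base = rnorm(1), shift = rnorm(1, 2))
    expect_equal(hansenLoglik(rp$tree, rp$painting, x, a, s2, th),
                 oracleHansenLoglik(rp$tree, rp$painting, x, a, s2, th),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to tip order and serialization", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(24)
  x <- setNames(rnorm(12, 3), tr$tip.label)
  ll <- hansenLoglik(tr, regs$M3, x, 1.5, 1, c(base = 2, shift = 5))
  tr2 <- readNewick({f <- tempfile(); writeNewick(ape::rotate(tr, 14), f); f})
  regs2 <- builtinRegimes(tr2)
  expect_equal(hansenLoglik(tr2, regs2$M3, x[tr2$tip.label], 1.5, 1,
                            c(base = 2, shift = 5)), ll, tolerance = 1e-9)
})

test_that("constant traits fit with theta at the constant and a degeneracy flag", {
  t5 <- fiveTipTree()
  f <- fitModel(t5, paintUniform(t5), setNames(rep(3.3, 5), t5$tip.label))
  expect_true(f@degenerate)
  expect_equal(unname(fitParams(f)$theta["base"]), 3.3, tolerance = 1e-6)
  expect_equal(AIC(f), 2 * 3 - 2 * logLik(f))
})

test_that("fits report the exact AIC identity and parameter counts", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(25)
  x <- simulateTrait(tr, regs$M2, list(alpha = 2, sigmaSq = 1,
                                       theta = c(base = 2, shift = 5)))
  fits <- fitRegion(tr, x, regs[c("BM", "M0", "M2", "M6")])
  expect_equal(fits$BM@k, 2); expect_equal(fits$M0@k, 3)
  expect_equal(fits$M2@k, 4); expect_equal(fits$M6@k, 4)
  for (f in fits)
    expect_equal(AIC(f), 2 * f@k - 2 * logLik(f), tolerance = 1e-10)
})

test_that("branch-shift models never fall below M0 (nesting invariant)", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(26)
  for (i in 1:8) {
    gen <- sample(c("M0", "M2", "M10", "BM"), 1)
    params <- if (gen == "BM") list(sigmaSq = 1) else
      list(alpha = 1.5, sigmaSq = 1, theta = c(base = 2, shift = 4))
    x <- simulateTrait(tr, regs[[gen]], params)
    fits <- fitRegion(tr, x, regs)
    for (m in paste0("M", 1:10))
      expect_gte(logLik(fits[[m]]), logLik(fits$M0) - 1e-6)
  }
})

test_that("alpha is weakly identified on BM-generated traits (boundary collapse)", {
  ## under drift-generated data the M0 selection strength is barely
  ## identified on 12 tips: a large fraction of fits collapse to the lower
  ## optimizer bound (the single most common outcome) and the remainder
  ## scatter widely
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(27)
  fitsInfo <- vapply(1:200, function(i) {
    x <- simulateTrait(tr, regs$BM, list(sigmaSq = 1))
    p <- fitParams(fitModel(tr, regs$M0, x))
    c(p$alpha, p$alphaAtBound)
  }, numeric(2))
  expect_gt(mean(fitsInfo[2, ] == 1), 0.25)
  expect_gt(stats::IQR(fitsInfo[1, ]) / max(1e-8, median(fitsInfo[1, ])), 1)
})

test_that("theta_shift is recovered across seeded replicates under a strong shift", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(28)
  est <- vapply(1:200, function(i) {
    x <- simulateTrait(tr, regs$M10, list(alpha = 2, sigmaSq = 1,
                                          theta = c(base = 2, shift = 7)))
    unname(fitParams(fitModel(tr, regs$M10, x))$theta["shift"])
  }, numeric(1))
  qs <- quantile(est, c(0.025, 0.975))
  expect_lt(qs[1], 7); expect_gt(qs[2], 7)
  expect_equal(median(est), 7, tolerance = 0.15)
})

test_that("missing species prune the tree; a fully missing shift clade is untestable", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(29)
  x <- simulateTrait(tr, regs$M0, list(alpha = 1, sigmaSq = 1, theta = 2))
  x["Dmoj"] <- NA
  f4 <- fitModel(tr, regs$M4, x)            # shift clade reduced to Dvir
  expect_false(f4@untestable)
  expect_equal(f4@nTips, 11L)
  x["Dvir"] <- NA
  f4b <- fitModel(tr, regs$M4, x)
  expect_true(isUntestable(f4b))
  expect_true(is.na(logLik(f4b)))
})

test_that("near-duplicate tips give a singular-covariance error suggesting jitter", {
  tr <- parseNewick("((A:0.000000000000000001,B:0.000000000000000001):1,C:1);")
  expect_error(bmLoglik(tr, c(A = 1, B = 2, C = 3), 0, 1), "jitter")
})

test_that("fit tables serialize one row per region and model", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  set.seed(30)
  x <- simulateTrait(tr, regs$M0, list(alpha = 1, sigmaSq = 1, theta = 2))
  fits <- list(regA = fitRegion(tr, x, regs[c("BM", "M0", "M10")]))
  f <- tempfile(fileext = ".tsv")
  df <- writeFitTable(fits, f)
  expect_equal(nrow(df), 3L)
  back <- utils::read.delim(f)
  expect_equal(back$model, c("BM", "M0", "M10"))
  expect_equal(back$AIC, df$AIC, tolerance = 1e-12)
})
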