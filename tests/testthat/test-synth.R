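test_that("trait datasets are reproducible and carry their generating model", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  p <- list(alpha = 2, sigmaSq = 1, theta = c(base = 2, shift = 7))
  d1 <- genTraitDataset(tr, regs$M10, p, nRegions = 20, seed = 61)
  d2 <- genTraitDataset(tr, regs$M10, p, nRegions = 20, seed = 61)
  expect_identical(scoreValues(d1$traits), scoreValues(d2$traits))
  expect_equal(unique(d1$truth$model), "M10")
  expect_equal(dim(scoreValues(d1$traits)), c(20L, 12L))
})

test_that("pairwise calls on null (M0) data stay near the nominal false-positive rate", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  ds <- genTraitDataset(tr, regs$M0,
                        list(alpha = 2, sigmaSq = 1, theta = 2),
                        nRegions = 100, seed = 62)
  calls <- divergenceTable(ds$traits, tr, regs[c("M0", "M10")],
                           adjust = FALSE)
  ## pairwise wAIC(M10) > 0.5 <=> LR > 2; null expectation P(chisq1 > 2)
  expected <- pchisq(2, 1, lower.tail = FALSE)
  se <- sqrt(expected * (1 - expected) / 100)
  expect_lte(mean(calls$divergent), expected + 3 * se)
})

test_that("a strong mixed shift is recovered for most regions", {
  tr <- drosophilaTree()
  regs <- builtinRegimes(tr)
  ## shift of 5 stationary sd: sd = sqrt(1/(2*2)) = 0.5
  null <- genTraitDataset(tr, regs$M0,
                          list(alpha = 2, sigmaSq = 1, theta = 2),
                          nRegions = 25, seed = 63, prefix = "null")
  alt <- genTraitDataset(tr, regs$M2,
                         list(alpha = 2, sigmaSq = 1,
                              theta = c(base = 2, shift = 4.5)),
                         nRegions = 25, seed = 64, prefix = "alt")
  traits <- rbind(scoreValues(null$traits), scoreValues(alt$traits))
  calls <- divergenceTable(traits, tr, regs[c("M0", "M2")], adjust = FALSE)
  hit <- calls$divergent[match(alt$truth$region, calls$region)]
  expect_gt(mean(hit), 0.8)
})

test_that("sequence panels plant clusters only in the designated clade", {
  tr <- drosophilaTree()
  pwm <- tinyConsensusPwm(counts = 100, len = 8,
                          bases = c(1, 2, 3, 4, 1, 2, 3, 4)) # high IC
  clade <- c("Dmoj", "Dvir")
  panel <- genSequencePanel(tr, pwm,
                            list(cladeTips = clade, direction = "gain",
                                 nSites = 3, regionLength = 500,
                                 nRegions = 15), seed = 65)
  sm <- scoreValues(scoreOrthologs(panelSequences(panel), pwm))
  inClade <- rowMeans(sm[, clade, drop = FALSE])
  outClade <- rowMeans(sm[, setdiff(colnames(sm), clade)])
  expect_gte(mean(inClade - outClade > 0), 0.95)
})

test_that("without planted sites the clades are statistically indistinguishable", {
  tr <- parseNewick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  pwm <- tinyConsensusPwm(counts = 100, len = 6,
                          bases = c(1, 2, 3, 1, 2, 3))
  panel <- genSequencePanel(tr, pwm,
                            list(cladeTips = c("A", "B"),
                                 direction = "gain", nSites = 0,
                                 regionLength = 300, nRegions = 200),
                            seed = 66)
  sm <- scoreValues(scoreOrthologs(panelSequences(panel), pwm))
  tt <- t.test(rowMeans(sm[, c("A", "B")]), rowMeans(sm[, c("C", "D")]))
  expect_gt(tt$p.value, 0.01)
})

test_that("panels are byte-identical under a fixed seed and round-trip FASTA", {
  tr <- parseNewick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  pwm <- tinyConsensusPwm()
  sc <- list(cladeTips = "A", direction = "gain", nSites = 2,
             regionLength = 120, nRegions = 4)
  p1 <- genSequencePanel(tr, pwm, sc, seed = 67)
  p2 <- genSequencePanel(tr, pwm, sc, seed = 67)
  d1 <- tempfile(); d2 <- tempfile()
  writeFastaPanel(panelSequences(p1), d1)
  writeFastaPanel(panelSequences(p2), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  back <- readFastaPanel(setNames(file.path(d1, paste0(tr$tip.label, ".fa")),
                                  tr$tip.label))
  expect_equal(as.character(back$A), as.character(panelSequences(p1)$A))
})

test_that("loss and conserved scenarios, dropout, and packing errors behave", {
  tr <- parseNewick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  pwm <- tinyConsensusPwm()
  loss <- genSequencePanel(tr, pwm,
                           list(cladeTips = "A", direction = "loss",
                                nSites = 2, regionLength = 150,
                                nRegions = 6), seed = 68)
  expect_equal(unique(panelTruth(loss)$label), "loss")
  cons <- genSequencePanel(tr, pwm,
                           list(direction = "conserved", nSites = 2,
                                regionLength = 150, nRegions = 6),
                           seed = 68)
  expect_equal(unique(panelTruth(cons)$label), "conserved")
  drop <- genSequencePanel(tr, pwm,
                           list(cladeTips = "A", direction = "gain",
                                nSites = 1, regionLength = 150,
                                nRegions = 40, dropout = 0.2), seed = 69)
  expect_lt(sum(lengths(panelSequences(drop))), 160L)
  expect_error(genSequencePanel(tr, pwm,
                                list(cladeTips = "A", direction = "gain",
                                     nSites = 40, regionLength = 20,
                                     nRegions = 1), seed = 70),
               "packing")
})

test_that("enrichment benchmarks respect the universe size and recover the truth", {
  tr <- drosophilaTree()
  pwm <- tinyConsensusPwm(counts = 100, len = 8,
                          bases = c(1, 2, 3, 4, 4, 3, 2, 1))
  panel <- genSequencePanel(tr, pwm,
                            list(cladeTips = "Dvir", direction = "gain",
                                 nSites = 3, regionLength = 500,
                                 nRegions = 10), seed = 71)
  bench <- genEnrichmentBenchmark(list(panel), nBackground = 90, seed = 72)
  expect_length(bench$universe, 100L)
  expect_true(all(bench$input %in% bench$universe))
  expect_equal(bench$truth$direction, "gain")

  ## end-to-end: score, fit, call, discover -> planted combination on top
  regs <- builtinRegimes(tr)
  sm <- scoreOrthologs(panelSequences(panel), pwm)
  calls <- divergenceTable(sm, tr, regs[c("M0", "M4", "M10")],
                           pwm = pwm@id, adjust = FALSE)
  res <- discoverMotifs(bench$input, calls, bench$universe)
  truthRow <- res[res$model == "M10" & res$direction == "gain", ]
  expect_equal(truthRow$rank[1], 1L)  # ties with an enclosing clade allowed
  expect_lt(truthRow$p_adj[1], 0.05)

  ## 100% label noise: truth should not be significant in most runs
  benchN <- genEnrichmentBenchmark(list(panel), nBackground = 90,
                                   noise = 1, seed = 73)
  resN <- discoverMotifs(benchN$input, calls, benchN$universe)
  row <- resN[resN$model == "M10" & resN$direction == "gain", ]
  expect_gt(row$p_adj[1], 0.0001)  # no longer overwhelming
})
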