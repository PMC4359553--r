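test_that("toy genomes are reproducible with disjoint, consistent genes", {
  a <- makeToyGenome(20, 2000, seed = 1)
  b <- makeToyGenome(20, 2000, seed = 1)
  expect_identical(as.character(a$genome), as.character(b$genome))
  regs <- assignCisRegions(a$genes, 2000L, a$chromSizes)
  expect_length(regs, 20L)
  ov <- GenomicRanges::findOverlaps(regs, regs)
  expect_true(all(S4Vectors::queryHits(ov) == S4Vectors::subjectHits(ov)))
  m <- S4Vectors::mcols(a$genes)
  expect_true(all(m$tss >= IRanges::start(a$genes) &
                  m$tss <= IRanges::end(a$genes)))
  c2 <- makeToyGenome(20, 2000, seed = 2)
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("planted instances are recovered by scanning and labeled by peaks", {
  base <- makeToyGenome(6, 800, seed = 8)
  regions <- assignCisRegions(base$genes, 800L, base$chromSizes)
  pwms <- makeToyPwms(c("TFA", "TFB"), seed = 9)
  planted <- plantMotifInstances(base$genome, regions, pwms, density = 0.15,
                                 peakFraction = 0.7, seed = 10)
  expect_gt(nrow(planted$truth), 5)
  ## every planted instance scores 1.0 under its own PWM at its locus
  hits <- scanRegions(pwms, planted$genome, regions, threshold = 0.9)
  key <- paste(S4Vectors::mcols(hits)$tf, IRanges::start(hits))
  expect_true(all(paste(planted$truth$tf, planted$truth$start) %in% key))
  ## positives per TF follow the peak fraction
  for (tf in c("TFA", "TFB")) {
    n <- sum(planted$truth$tf == tf)
    expect_equal(sum(planted$truth$positive[planted$truth$tf == tf]),
                 round(0.7 * n))
  }
  ## labeling planted hits against the emitted peaks reproduces the truth
  hits <- resolveOverlappingHits(hits, by = "tf")
  hits <- labelAllHits(hits, planted$peaks)
  m <- S4Vectors::mcols(hits)
  truthKey <- paste(planted$truth$tf, planted$truth$start)
  labKey <- paste(m$tf, IRanges::start(hits))
  sel <- match(truthKey, labKey)
  expect_equal(m$label[sel] == "positive", planted$truth$positive)
})

test_that("signal bumps have flat tops, dips, and planted contrast", {
  cs <- c(chrT = 20000L)
  site <- 10000L
  stages <- c("S1", "S2")
  ## noise-free, dip depth 0: the 100-bp and 1-kb window means at the
  ## center are equal (flat bump top)
  tr0 <- simulateSignalTracks(cs, site, stages, seed = 1, dipDepth = 0,
                              noise = FALSE)
  v <- tr0$H3K27ac$S1@values$chrT
  ctr <- (site - 1) %/% 10 + 1
  m100 <- mean(v[(ctr - 5):(ctr + 4)])
  m1k <- mean(v[(ctr - 50):(ctr + 49)])
  ## the outermost 1-kb bins touch the Gaussian shoulder; agreement is to
  ## a few parts in 1e5 of the plateau height
  expect_equal(m100, m1k, tolerance = 1e-4)
  ## with a dip the local mean drops below the broad mean
  trD <- simulateSignalTracks(cs, site, stages, seed = 1, dipDepth = 0.6,
                              noise = FALSE)
  vD <- trD$H3K27ac$S1@values$chrT
  expect_lt(mean(vD[(ctr - 2):(ctr + 2)]), mean(vD[(ctr - 50):(ctr + 49)]))
  ## noise-free profile equals the generative kernel at the bin centers
  d <- abs((seq_along(v) - 0.5) * 10 - site)
  kern <- 1 + 8 * 1 * ifelse(d <= 500, 1, exp(-(d - 500)^2 / (2 * 150^2)))
  expect_equal(v[d <= 400], kern[d <= 400], tolerance = 1e-9)
  ## planted sites carry more H3K27ac than random bases (with noise)
  trN <- simulateSignalTracks(cs, c(3000L, 9000L, 15000L), stages, seed = 2)
  vn <- asinhTransform(trN$H3K27ac$S1)@values$chrT
  siteBins <- (c(3000, 9000, 15000) - 1) %/% 10 + 1
  set.seed(3)
  bgBins <- sample(setdiff(seq_along(vn),
                           unlist(lapply(siteBins, function(b) (b - 60):(b + 60)))),
                   200)
  expect_gt(mean(vn[siteBins]), mean(vn[bgBins]))
})

test_that("expression simulation follows the linear dynamical system", {
  A <- matrix(c(0.9, 0.2, 0, 0.8), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  X1 <- c(a = 2, b = 3)
  ex <- simulateExpressionDynamics(A, X1, sigma = 0, T = 4, seed = 1)
  X <- logExpr(ex)
  for (t in 1:3)
    expect_equal(unname(X[, t + 1]), unname(drop(A %*% X[, t])),
                 tolerance = 1e-10)
  ## identity dynamics with no noise are constant
  exI <- simulateExpressionDynamics(diag(2), X1, 0, 4, seed = 1)
  expect_true(all(abs(logExpr(exI) - X1) < 1e-10))
  ## residual sd over many genes approximates sigma within 5%
  p <- 1000
  Ai <- diag(p); dimnames(Ai) <- list(paste0("g", 1:p), paste0("g", 1:p))
  Xi <- stats::setNames(rep(3, p), paste0("g", 1:p))
  exN <- simulateExpressionDynamics(Ai, Xi, sigma = 0.2, T = 2, seed = 5)
  resid <- logExpr(exN)[, 2] - 3
  expect_lt(abs(sd(resid) - 0.2) / 0.2, 0.05)
  expect_error(simulateExpressionDynamics(diag(2) * 20, X1, 0, 4, seed = 1),
               "diverge")
})

test_that("perturbation truth is the thresholded one-step response", {
  A <- matrix(c(0, 0, 0.5, 0, 0, -0.3, 0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fp <- matrix(10, 3, 2, dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  expr <- newStageExpression(fp)
  pt <- makePerturbationTruth(A, expr, fold = 5)
  ## column of a regulator with no outgoing weights is empty
  expect_equal(sum(pt$P[, "a"]), 0)
  expect_equal(unname(pt$P["a", "c"]), 1L)
  expect_equal(unname(pt$calls$c["a"]), "up")
  expect_equal(unname(pt$calls$c["b"]), "down")
  ## self-consistency: calls match computationalPerturbation on the truth
  net <- methods::new("DynamicNetwork", genes = rownames(A),
                      stages = c("S1", "S2"), weights = list(),
                      segments = list(), bindings = list(), A = list(A),
                      edges = data.frame(), config = dbnConfig(),
                      objectives = numeric(0))
  pred <- computationalPerturbation(net, expr, "c", fold = 5, stage = 1L)
  dir <- pt$calls$c
  comparable <- names(dir)[dir != "none"]
  expect_equal(pred$direction[comparable], dir[comparable])
})

test_that("the composite network dataset is self-consistent", {
  ds <- simulateGrnDataset(seed = 1, nGenes = 8, nTf = 3, regionLen = 600)
  ## A* reproduces the u*' B* construction on every true edge
  cfgSim <- ds$config
  for (g in rownames(ds$truth$A)) {
    regs <- ds$truth$edges[ds$truth$edges$target == g, ]
    uMat <- ds$truth$u[[g]]
    ri <- match(g, S4Vectors::mcols(ds$regions)$geneId)
    segs <- segmentCisRegion(ds$regions[ri])
    expect_equal(nrow(uMat), length(segs))
  }
  ## expression follows X^{t+1} = A X^t within the noise scale
  X <- logExpr(ds$expr)
  for (t in 1:3) {
    resid <- X[, t + 1] - drop(ds$truth$A %*% X[, t])
    expect_lt(max(abs(resid)), 5 * 0.05 + 1e-6)
  }
  ## reproducibility
  ds2 <- simulateGrnDataset(seed = 1, nGenes = 8, nTf = 3, regionLen = 600)
  expect_identical(as.character(ds$genome), as.character(ds2$genome))
  expect_identical(ds$truth$edges, ds2$truth$edges)
  expect_identical(fpkm(ds$expr), fpkm(ds2$expr))
})
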