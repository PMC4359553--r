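test_that("intercept-only fit returns the exact logit of the base rate", {
  F <- matrix(0, 8, 69)
  tab <- tableFromMatrix(F, c(1, 1, 0, 0, 0, 0, 0, 0))   # 25% positives
  fit <- fitLogistic(tab)
  expect_true(fit@converged)
  expect_equal(unname(fit@coefficients[1]), qlogis(0.25), tolerance = 1e-10)
  expect_equal(unname(fit@coefficients[-1]), rep(0, 69))
})

test_that("IRLS coefficients match a BFGS maximizer of the likelihood", {
  set.seed(101)
  n <- 500
  F <- cbind(rnorm(n), rnorm(n))
  eta <- -0.5 + 1.2 * F[, 1] - 0.8 * F[, 2]
  y <- rbinom(n, 1, plogis(eta))
  tab <- tableFromMatrix(F, y)
  fit <- fitLogistic(tab)
  expect_true(fit@converged)
  negll <- function(b) {
    e <- b[1] + F %*% b[2:3]
    -sum(y * e - log1p(exp(e)))
  }
  o <- optim(c(0, 0, 0), negll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(fit@coefficients[1:3]), o$par, tolerance = 1e-6)
  ## duplicating every row leaves the optimum unchanged
  tab2 <- tableFromMatrix(rbind(F, F), c(y, y))
  fit2 <- fitLogistic(tab2)
  expect_equal(fit2@coefficients, fit@coefficients, tolerance = 1e-7)
  expect_error(fitLogistic(tableFromMatrix(F, rep(1, n))), "single class")
})

test_that("perfect separation is flagged instead of silently accepted", {
  F <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), 6)
  tab <- tableFromMatrix(F, c(0, 0, 0, 1, 1, 1))
  expect_warning(fit <- fitLogistic(tab, maxit = 60),
                 "separation|finite maximum")
  expect_false(fit@converged)
})

test_that("Wald tests give two-sided normal p-values with star binning", {
  set.seed(102)
  n <- 400
  F <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * F[, 1]))
  fit <- fitLogistic(tableFromMatrix(F, y))
  wt <- waldTests(fit)
  se <- sqrt(diag(fit@vcov))
  expect_equal(wt$z[2], unname(fit@coefficients[2] / se[2]))
  expect_equal(wt$p[2], 2 * pnorm(-abs(wt$z[2])))
  expect_equal(wt$direction[2], if (fit@coefficients[2] >= 0) "+" else "-")
  ## binning: z = 1.959964 corresponds to p ~ 0.05 (boundary of "*")
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
  starFor <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else ""
  for (i in seq_len(nrow(wt)))
    if (!is.na(wt$p[i])) expect_equal(wt$stars[i], starFor(wt$p[i]))
  ## constant (excluded) features are flagged with NA p
  expect_true(all(is.na(wt$p[4:70])))
})

test_that("regularized fits shrink to zero and recover the MLE at zero", {
  set.seed(103)
  n <- 300
  F <- matrix(rnorm(n * 5), n)
  y <- rbinom(n, 1, plogis(1.5 * F[, 1] - F[, 2]))
  tab <- tableFromMatrix(F, y)
  big <- fitRegularized(tab, lambda = 10)
  expect_equal(unname(big@coefficients[-1]), rep(0, 69))
  zero <- fitRegularized(tab, lambda = 0)
  mle <- fitLogistic(tab)
  expect_equal(unname(zero@coefficients[1:6]),
               unname(mle@coefficients[1:6]), tolerance = 1e-4)
})

test_that("LASSO and ML coefficients correlate on planted sparse signal", {
  set.seed(104)
  n <- 600
  F <- matrix(rnorm(n * 10), n)
  beta <- c(1.5, -1.2, 0.8, rep(0, 7))
  y <- rbinom(n, 1, plogis(drop(F %*% beta)))
  tab <- tableFromMatrix(F, y)
  mle <- fitLogistic(tab)
  lasso <- fitRegularized(tab, alpha = 1, seed = 104)
  idx <- 2:11
  expect_gt(cor(mle@coefficients[idx], lasso@coefficients[idx]), 0.8)
})

test_that("AUC equals the pairwise Mann-Whitney average", {
  expect_equal(computeAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(computeAuc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  set.seed(50)
  scores <- round(runif(50), 2)   # rounding forces some ties
  labels <- rbinom(50, 1, 0.4)
  expect_equal(computeAuc(scores, labels), pairwiseAuc(scores, labels))
  ## invariant under strictly monotone transforms
  expect_equal(computeAuc(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
               computeAuc(pmin(pmax(scores, 0.01), 0.99), labels))
  expect_error(computeAuc(scores, rep(0, 50)), "both classes")
})

test_that("leave-one-TF-out folds are exact partitions without leakage", {
  set.seed(105)
  n <- 90
  F <- matrix(rnorm(n * 3), n)
  y <- rbinom(n, 1, plogis(2 * F[, 1]))
  tfs <- rep(c("TFA", "TFB", "TFC"), each = 30)
  tab <- tableFromMatrix(F, y, tf = tfs)
  cv <- lotfoCV(tab)
  expect_setequal(cv$tf, c("TFA", "TFB", "TFC"))
  ## manual fold oracle: train on the other two TFs, score the held-out one
  for (tf in cv$tf) {
    test <- tfs == tf
    trainTab <- tableFromMatrix(F[!test, , drop = FALSE], y[!test],
                                tf = tfs[!test])
    trainStd <- suppressWarnings(standardizeFeatures(trainTab))
    fit <- suppressWarnings(fitLogistic(trainStd))
    z <- applyScaler(tableFromMatrix(F[test, , drop = FALSE], y[test])@features,
                     fit@scaler)
    sc <- plogis(drop(cbind(1, z) %*% fit@coefficients))
    expect_equal(cv$auc[cv$tf == tf], computeAuc(sc, y[test]),
                 tolerance = 1e-10)
  }
  expect_error(lotfoCV(tableFromMatrix(F, y, tf = rep("TFA", n))), ">= 2")
})

test_that("LR tracks stay in (0,1) and respond monotonically to features", {
  fx <- featureFixture()
  gid <- S4Vectors::mcols(fx$regions)$geneId
  ## a known model: intercept -1, positive weight on the H3K27ac 1-kb mean
  coefs <- stats::setNames(numeric(70), c("(Intercept)", featureNames()))
  coefs[1] <- -1; coefs["H3K27ac_t_w1000"] <- 0.8
  scaler <- list(center = stats::setNames(numeric(69), featureNames()),
                 scale = stats::setNames(rep(1, 69), featureNames()),
                 constant = stats::setNames(rep(FALSE, 69), featureNames()))
  fit <- methods::new("LogisticModel", coefficients = coefs,
                      vcov = matrix(numeric(0), 0, 0), fittedOn = 0L,
                      converged = TRUE, iterations = 0L, scaler = scaler,
                      lambda = 0)
  tr <- predictLrTrack(fit, fx$ctx, fx$regions, gid[2], 1L)
  expect_true(all(tr$score > 0 & tr$score < 1))
  expect_length(tr$score, IRanges::width(fx$regions)[2])
  ## all-zero standardized features score sigma(beta0)
  expect_equal(unname(predictLrScores(fit, matrix(0, 2, 69))),
               rep(plogis(-1), 2), tolerance = 1e-12)
  ## raising the positively-weighted feature raises the score
  base <- matrix(0, 1, 69)
  up <- base; up[1, which(featureNames() == "H3K27ac_t_w1000")] <- 1
  expect_gt(predictLrScores(fit, up), predictLrScores(fit, base))
})

test_that("enhancer scores are compared by the documented Wilcoxon rules", {
  mkTracks <- function(score) list(g1 = list(t1 = list(gene = "g1",
    transition = 1L, chrom = "chrT", start = 1L, score = score)))
  ## identical samples: normal approximation gives p = 1
  tr <- mkTracks(rep(0.5, 40))
  enh <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 11), width = 10))
  res <- compareRegionScores(tr, 1L, enh, nRandom = 30, seed = 1)
  expect_equal(res$p, 1)
  ## exact two-sided p for (1,2,3) vs (4,5,6) is 0.1
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(wt$p.value, 0.1)
  ## shifting sample 1 upward can only strengthen the one-sided evidence
  set.seed(2)
  x <- runif(12); yv <- runif(12)
  pBase <- wilcox.test(x, yv, alternative = "greater", exact = FALSE,
                       correct = FALSE)$p.value
  pUp <- wilcox.test(x + 1, yv, alternative = "greater", exact = FALSE,
                     correct = FALSE)$p.value
  expect_lte(pUp, pBase)
  expect_error(compareRegionScores(tr, 1L,
    GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 5)), 10, 1),
    "enhancer")
})

test_that("high-LR enrichment uses binomial tails and the min-p PWM rule", {
  ## 10% of scored bases are high-LR; one TF has all 20 hit centers there
  score <- c(rep(0.5, 100), rep(0.01, 900))
  tracks <- list(g1 = list(t1 = list(gene = "g1", transition = 1L,
    chrom = "chrT", start = 1L, score = score)))
  mkHits <- function(centers, tf, motif) {
    gr <- GenomicRanges::GRanges("chrT",
      IRanges::IRanges(centers - 3L, width = 8L), strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(tf = tf, motif = motif,
      normScore = 1, center = as.integer(centers), label = "unlabeled")
    gr
  }
  hits <- c(mkHits(seq(5, 100, 5), "TFA", "A.m1"),
            mkHits(seq(105, 1000, 45), "TFB", "B.m1"))
  fp <- matrix(c(50, 50, 50, 50), 2, 2,
               dimnames = list(c("TFA", "TFB"), c("S1", "S2")))
  expr <- newStageExpression(fp)
  res <- tfEnrichmentHighLr(tracks, 1L, hits, expr, threshold = 0.1)
  pa <- res[res$tf == "TFA", ]
  expect_equal(pa$nHits, 20L)
  expect_equal(pa$nHigh, 20L)
  expect_equal(pa$p, 0.1^20, tolerance = 1e-6)
  ## background-rate TF is not enriched
  expect_gt(res$p[res$tf == "TFB"], 0.05)
  ## multiple PWMs: the lowest p is reported for the TF
  hits2 <- c(hits, mkHits(seq(205, 1000, 45), "TFA", "A.m2"))
  res2 <- tfEnrichmentHighLr(tracks, 1L, hits2, expr, threshold = 0.1)
  expect_equal(res2[res2$tf == "TFA", "motif"], "A.m1")
  expect_equal(res2[res2$tf == "TFA", "p"], pa$p)
})

test_that("model JSON persistence preserves coefficients and scaler", {
  set.seed(107)
  F <- matrix(rnorm(40 * 69), 40)
  tab <- suppressWarnings(standardizeFeatures(
    tableFromMatrix(F, rbinom(40, 1, 0.5))))
  fit <- suppressWarnings(fitLogistic(tab))
  f <- tempfile(fileext = ".json")
  writeLogisticModel(fit, f)
  back <- readLogisticModel(f)
  expect_equal(back@coefficients, fit@coefficients, tolerance = 1e-12)
  expect_equal(back@scaler$center, fit@scaler$center, tolerance = 1e-12)
  expect_equal(back@converged, fit@converged)
})
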