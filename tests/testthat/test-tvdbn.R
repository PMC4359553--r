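test_that("cis-segment tiling follows the 50/5 convention", {
  expect_equal(length(segmentCisRegion(IRanges::IRanges(1, 40000))), 7991L)
  expect_equal(length(segmentCisRegion(IRanges::IRanges(1, 50))), 1L)
  segs <- segmentCisRegion(IRanges::IRanges(1, 60))
  expect_equal(IRanges::start(segs), c(1L, 6L, 11L))
  expect_equal(IRanges::end(segs), c(50L, 55L, 60L))
  ## adjacent segments overlap by 45 nt
  expect_equal(IRanges::width(IRanges::pintersect(segs[-3], segs[-1]))[1], 45L)
  expect_error(segmentCisRegion(IRanges::IRanges(1, 49)), "shorter")
})

## Shared scaffolding for binding-matrix tests: one gene, one TF, constant
## LR score over a 60-nt region.
bindingFixture <- function(lr = 0.2, P1 = 0, tfFpkm = 50) {
  fp <- matrix(c(5, 5, 5, 5, tfFpkm, tfFpkm, tfFpkm, tfFpkm), 2, 4,
               byrow = TRUE, dimnames = list(c("g1", "tf1"), paste0("S", 1:4)))
  expr <- newStageExpression(fp)
  P <- matrix(0L, 2, 2, dimnames = list(c("g1", "tf1"), c("g1", "tf1")))
  P["g1", "tf1"] <- as.integer(P1)
  region <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 60))
  track <- list(gene = "g1", chrom = "chrT", start = 1L, score = rep(lr, 60))
  hit <- GenomicRanges::GRanges("chrT", IRanges::IRanges(20, 27),
                                strand = "+")
  S4Vectors::mcols(hit) <- S4Vectors::DataFrame(tf = "tf1", motif = "m",
    normScore = 1, center = 23L, label = "positive", geneId = "g1")
  list(expr = expr, P = P, region = region, track = track, hit = hit)
}

test_that("binding potentials are segment-mean LR times the pi adjustment", {
  fx <- bindingFixture(lr = 0.2, P1 = 0)
  b <- buildBindingMatrix("g1", 1L, fx$track, fx$hit, fx$P, fx$expr,
                          fx$region, "tf1")
  ## segments [1,50],[6,55],[11,60] all overlap the hit at [20,27]
  expect_equal(dim(b@B), c(3L, 1L))
  expect_equal(unname(b@B[, 1]), rep(0.2 * 0.25, 3))
  ## perturbation-supported pair: pi = 1
  fx1 <- bindingFixture(lr = 0.2, P1 = 1)
  b1 <- buildBindingMatrix("g1", 1L, fx1$track, fx1$hit, fx1$P, fx1$expr,
                           fx1$region, "tf1")
  expect_equal(unname(b1@B[, 1]), rep(0.2, 3))
  ## no hit in a segment -> 0
  fx2 <- bindingFixture()
  noHit <- fx2$hit[0]
  b2 <- buildBindingMatrix("g1", 1L, fx2$track, noHit, fx2$P, fx2$expr,
                           fx2$region, "tf1")
  expect_equal(sum(b2@B), 0)
  ## TF below the abundance filter is dropped from the columns
  fx3 <- bindingFixture(tfFpkm = 10)
  b3 <- buildBindingMatrix("g1", 1L, fx3$track, fx3$hit, fx3$P, fx3$expr,
                           fx3$region, "tf1")
  expect_equal(ncol(b3@B), 0L)
  ## entries are bounded by the maximum segment-mean LR (pi <= 1)
  set.seed(12)
  fx4 <- bindingFixture()
  fx4$track$score <- runif(60, 0, 0.9)
  b4 <- buildBindingMatrix("g1", 1L, fx4$track, fx4$hit, fx4$P, fx4$expr,
                           fx4$region, "tf1")
  pos <- b4@B[b4@B > 0]
  cs <- c(0, cumsum(fx4$track$score))
  maxSeg <- max(vapply(1:3, function(k)
    (cs[IRanges::end(b4@segments)[k] + 1] - cs[IRanges::start(b4@segments)[k]]) / 50,
    numeric(1)))
  expect_true(all(pos <= maxSeg + 1e-12))
})

test_that("the one-segment least-squares solution matches the closed form", {
  ## K = 1, single TF with B = 1, (x^t, x^{t+1}) = (2, 1) at every
  ## transition: u = x^{t+1} x^t / (x^t)^2 = 0.5
  ## c_t = B %*% X[tf1, t] = 2 and y_t = X[g1, t+1] = 1 at every transition
  X <- matrix(c(0, 1, 1, 1,
                2, 2, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "tf1"), NULL))
  bindings <- lapply(1:3, function(t)
    toyBinding(matrix(1, 1, 1, dimnames = list(NULL, "tf1")), t))
  res <- solveGeneWeights("g1", X, bindings, 0, 0)
  expect_true(res$converged)
  expect_equal(unname(res$u), matrix(0.5, 1, 3), tolerance = 1e-6)
  ## a huge L1 penalty forces u = 0 with the data term as objective
  resBig <- solveGeneWeights("g1", X, bindings, 1e4, 0)
  expect_equal(unname(resBig$u), matrix(0, 1, 3))
  expect_equal(resBig$objective, sum(X["g1", 2:4]^2), tolerance = 1e-8)
})

test_that("solver objectives match an independent interior-point QP solver", {
  skip_if_not_installed("kernlab")
  worst <- 0
  for (seed in 1:20) {
    inst <- randomGeneInstance(seed)
    res <- solveGeneWeights("g1", inst$X, inst$bindings, inst$lambda1,
                            inst$lambda2,
                            control = list(epsAbs = 1e-11, epsRel = 1e-9,
                                           maxit = 100000L))
    oracle <- ipopGeneSolve(inst$X, inst$bindings, inst$lambda1,
                            inst$lambda2)
    rel <- abs(res$objective - oracle$objective) /
      max(abs(oracle$objective), 1e-12)
    worst <- max(worst, rel)
    expect_lt(rel, 1e-5)
    ## the reported objective is reproduced by direct evaluation
    expect_equal(res$objective,
                 geneObjective(res$u, inst$X, inst$bindings, inst$lambda1,
                               inst$lambda2), tolerance = 1e-10)
  }
})

test_that("objective is monotone in the penalties and sparsity in lambda1", {
  inst <- randomGeneInstance(99)
  ctl <- list(epsAbs = 1e-11, epsRel = 1e-9, maxit = 100000L)
  l1s <- c(0, 0.05, 0.2, 0.8)
  objs <- numeric(0); l1norm <- numeric(0)
  for (l1 in l1s) {
    r <- solveGeneWeights("g1", inst$X, inst$bindings, l1, 0.1, control = ctl)
    objs <- c(objs, r$objective); l1norm <- c(l1norm, sum(abs(r$u)))
  }
  expect_true(all(diff(objs) >= -1e-7))
  expect_true(all(diff(l1norm) <= 1e-7))
  objs2 <- vapply(c(0, 0.05, 0.2, 0.8), function(l2)
    solveGeneWeights("g1", inst$X, inst$bindings, 0.1, l2,
                     control = ctl)$objective, numeric(1))
  expect_true(all(diff(objs2) >= -1e-7))
})

test_that("a large fusion penalty equalizes the edge rows across transitions", {
  inst <- randomGeneInstance(7)
  r <- solveGeneWeights("g1", inst$X, inst$bindings, 0.01, 1e4,
                        control = list(epsAbs = 1e-11, epsRel = 1e-9,
                                       maxit = 100000L))
  rows <- lapply(1:3, function(t)
    drop(crossprod(r$u[, t], inst$bindings[[t]]@B)))
  expect_lt(max(abs(rows[[1]] - rows[[2]])), 1e-4)
  expect_lt(max(abs(rows[[2]] - rows[[3]])), 1e-4)
})

test_that("K = 0 and empty-TF problems degrade gracefully", {
  X <- matrix(c(1, 2, 1, 2, 3, 3, 3, 3), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "tf1"), NULL))
  b0 <- methods::new("BindingMatrix", geneId = "g1", transition = 1L,
                     B = matrix(0, 0, 1, dimnames = list(NULL, "tf1")),
                     segments = IRanges::IRanges())
  res <- solveGeneWeights("g1", X, list(b0, b0, b0), 0.1, 0.1)
  expect_equal(nrow(res$u), 0L)
  expect_equal(res$objective, sum(X["g1", 2:4]^2))
})

test_that("hyperparameter CV returns the grid arg-min with documented ties", {
  inst <- randomGeneInstance(13)
  bb <- list(g1 = inst$bindings)
  one <- selectHyperparameters(inst$X, bb,
                               data.frame(lambda1 = 0.3, lambda2 = 0.2))
  expect_equal(one$lambda1, 0.3)
  expect_equal(one$lambda2, 0.2)
  grid <- expand.grid(lambda1 = c(0, 0.1), lambda2 = c(0, 0.5))
  sel <- selectHyperparameters(inst$X, bb, grid)
  ## recompute the CV error of each grid point independently
  for (g in seq_len(nrow(grid))) {
    tot <- 0
    for (t0 in 1:3) {
      keep <- setdiff(1:3, t0)
      fit <- suppressWarnings(solveGeneWeights("g1", inst$X, inst$bindings,
        grid$lambda1[g], grid$lambda2[g], include = keep))
      near <- keep[which.min(abs(keep - t0))]
      B0 <- inst$bindings[[t0]]@B
      pred <- sum(fit$u[, match(near, keep)] *
                    drop(B0 %*% inst$X[colnames(B0), t0]))
      tot <- tot + unname(inst$X["g1", t0 + 1] - pred)^2
    }
    expect_equal(sel$cvError[g], unname(tot) / 3, tolerance = 1e-6)
  }
  best <- which.min(sel$cvError)
  expect_equal(sel$lambda1, grid$lambda1[best])
  expect_error(selectHyperparameters(inst$X, list(g1 = inst$bindings[1]),
                                     grid), "transitions")
})

test_that("sparsity helps under noise on a planted sparse instance", {
  ## the true segment reads a stably expressed TF; decoy segments read a
  ## volatile TF, so a dense (unpenalized) fit that spreads weight over
  ## decoys generalizes worse across transitions than the sparse truth
  set.seed(77)
  K <- 10
  tfs <- c("tf1", "tf2")
  B <- matrix(0, K, 2, dimnames = list(NULL, tfs))
  B[4, 1] <- 0.3
  B[-4, 2] <- runif(K - 1, 0.1, 0.3)
  bindings <- lapply(1:3, function(t) toyBinding(B, t))
  X <- matrix(0, 3, 4, dimnames = list(c("g1", tfs), NULL))
  X["tf1", ] <- 4
  X["tf2", ] <- runif(4, 1, 3.5)
  uTrue <- numeric(K); uTrue[4] <- 2
  for (t in 1:3)
    X["g1", t + 1] <- sum(uTrue * drop(B %*% X[tfs, t])) + rnorm(1, 0, 0.1)
  sel <- selectHyperparameters(X, list(g1 = bindings),
    data.frame(lambda1 = c(0, 0.05, 0.2), lambda2 = 0))
  expect_gt(sel$lambda1, 0)
  expect_lt(min(sel$cvError[-1]), sel$cvError[1])
})

test_that("assembled networks equal the dense matrix product", {
  inst <- randomGeneInstance(31)
  r <- solveGeneWeights("g1", inst$X, inst$bindings, 0.05, 0.05)
  cfg <- dbnConfig(lambda1 = 0.05, lambda2 = 0.05)
  nets <- assembleNetworks(list(g1 = r$u), list(g1 = inst$bindings),
                           rownames(inst$X), paste0("S", 1:4),
                           config = cfg)
  for (t in 1:3) {
    row <- drop(crossprod(r$u[, t], inst$bindings[[t]]@B))
    expect_equal(nets$A[[t]]["g1", colnames(inst$bindings[[t]]@B)], row,
                 ignore_attr = TRUE)
    e <- nets$edges[nets$edges$transition == t, ]
    expect_setequal(e$regulator, names(row)[row > cfg$edgeTol])
  }
  ## u = 0 everywhere -> no edges
  zero <- assembleNetworks(list(g1 = r$u * 0), list(g1 = inst$bindings),
                           rownames(inst$X), paste0("S", 1:4), config = cfg)
  expect_equal(nrow(zero$edges), 0L)
  ## one segment with u = 1 against a single binding entry
  b1 <- toyBinding(matrix(0.05, 1, 1, dimnames = list(NULL, "tf1")), 1)
  one <- assembleNetworks(list(g1 = matrix(1, 1, 1)), list(g1 = list(b1)),
                          c("g1", "tf1"), c("S1", "S2"), config = cfg)
  expect_equal(one$edges$weight, 0.05)
})

test_that("variance explained matches a hand-worked three-gene example", {
  X <- matrix(c(1, 2, 3,
                2, 1, 2), 3, 2,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  A <- list(matrix(c(0.5, 0, 0, 0, 0.5, 0, 0, 0, 0.5), 3, 3,
                   dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  pred <- 0.5 * X[, 1]
  obs <- X[, 2]
  expected <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(varianceExplained(X, A)[1], expected)
  ## perfect reconstruction
  Aperf <- list(diag(3))
  dimnames(Aperf[[1]]) <- dimnames(A[[1]])
  Xc <- cbind(S1 = c(1, 2, 3), S2 = c(1, 2, 3))
  rownames(Xc) <- c("a", "b", "c")
  expect_equal(varianceExplained(Xc, Aperf)[1], 1)
  ## null model against a centered target
  Azero <- list(matrix(0, 3, 3, dimnames = dimnames(A[[1]])))
  Xz <- cbind(S1 = c(1, 2, 3), S2 = c(-1, 0, 1))
  rownames(Xz) <- c("a", "b", "c")
  expect_equal(varianceExplained(Xz, Azero)[1], 0)
})

test_that("common links count the shared directed edges", {
  edges <- data.frame(
    transition = c(1, 1, 2, 2, 3),
    regulator = c("a", "b", "a", "c", "x"),
    target = c("t1", "t2", "t1", "t3", "t9"),
    weight = 1)
  cl <- commonLinks(edges)
  expect_equal(cl$common[cl$transitionA == 1 & cl$transitionB == 2], 1L)
  expect_equal(cl$common[cl$transitionA == 1 & cl$transitionB == 3], 0L)
  same <- commonLinks(rbind(edges[edges$transition == 1, ],
                            transform(edges[edges$transition == 1, ],
                                      transition = 2)))
  expect_equal(same$common, 2L)
})
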