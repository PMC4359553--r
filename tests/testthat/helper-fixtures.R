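## Shared fixture builders; everything is generated in code at test time.

tmpFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## The 3-mer toy PWM used across the scanning tests (consensus ACG).
toyPwm <- function() {
  counts <- matrix(c(10, 0, 0, 0,
                     0, 10, 0, 0,
                     0, 0, 10, 0), 4)
  newPwm(counts, tf = "T1", name = "T1.m1")
}

## Deterministic pseudo-random DNA string.
randomSeq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Construct a FeatureTable directly from a feature matrix (tests of the
## model fitting do not need genomic context).
tableFromMatrix <- function(F, y, tf = rep("TFA", nrow(F))) {
  if (ncol(F) < 69L)
    F <- cbind(F, matrix(0, nrow(F), 69L - ncol(F)))
  colnames(F) <- featureNames()
  methods::new("FeatureTable", features = F, response = as.integer(y),
               meta = S4Vectors::DataFrame(
                 gene = rep("g", nrow(F)), tf = tf,
                 chrom = rep("chrT", nrow(F)), pos = seq_len(nrow(F)),
                 stagePair = rep("S1->S2", nrow(F))),
               scaler = list())
}

## Minimal BindingMatrix with arbitrary entries (validity: B >= 0).
toyBinding <- function(B, t = 1L, gene = "g1") {
  methods::new("BindingMatrix", geneId = gene, transition = as.integer(t),
               B = B, segments = IRanges::IRanges(
                 start = seq_len(nrow(B)), width = 50L))
}

## Small genome + tracks + context shared by the feature tests (built once
## per test run).
.fixtureCache <- new.env(parent = emptyenv())

featureFixture <- function() {
  if (!is.null(.fixtureCache$feat)) return(.fixtureCache$feat)
  base <- makeToyGenome(4, 400, seed = 3)
  regions <- assignCisRegions(base$genes, 400L, base$chromSizes)
  stages <- c("S1", "S2", "S3")
  sites <- c(150L, 950L)
  tracks <- simulateSignalTracks(base$chromSizes, sites, stages, seed = 4)
  tracksT <- lapply(tracks, function(b) lapply(b, asinhTransform))
  set.seed(5)
  fp <- matrix(stats::rexp(4 * 3, 1 / 20), 4, 3,
               dimnames = list(S4Vectors::mcols(base$genes)$geneId, stages))
  fp[1, ] <- c(0, 3, 10)                       # exercises the f16 = 0 case
  fp[2, ] <- c(exp(1) - 1, 10, 1)              # f16 = 1 exactly
  expr <- newStageExpression(fp)
  ctx <- prepareFeatureContext(base$genome, base$genes, base$annTracks,
                               tracksT, expr, regions)
  .fixtureCache$feat <- list(base = base, regions = regions, ctx = ctx,
                             expr = expr, tracks = tracksT, stages = stages)
  .fixtureCache$feat
}

## Random per-gene weight problem instance (K <= 5, p <= 4, T = 4) used by
## the solver oracle tests.
randomGeneInstance <- function(seed) {
  set.seed(seed)
  K <- sample(1:5, 1); p <- sample(1:4, 1); T <- 4
  tfs <- paste0("tf", seq_len(p))
  X <- matrix(stats::rnorm((p + 1) * T), p + 1, T,
              dimnames = list(c("g1", tfs), NULL))
  bindings <- lapply(1:(T - 1), function(t)
    toyBinding(matrix(stats::runif(K * p), K, p,
                      dimnames = list(NULL, tfs)), t))
  list(X = X, bindings = bindings, K = K, p = p, T = T,
       lambda1 = stats::runif(1, 0, 0.5), lambda2 = stats::runif(1, 0, 0.5))
}

## Objective value of the per-gene problem at a weight matrix u.
geneObjective <- function(u, X, bindings, lambda1, lambda2,
                          loss = "squared") {
  nT <- length(bindings)
  dataTerm <- 0; fuse <- 0
  rows <- list()
  for (t in seq_len(nT)) {
    B <- bindings[[t]]@B
    c_t <- drop(B %*% X[colnames(B), t])
    r <- X["g1", t + 1] - sum(u[, t] * c_t)
    dataTerm <- dataTerm + if (loss == "squared") r^2 else abs(r)
    rows[[t]] <- drop(crossprod(u[, t], B))
  }
  for (t in seq_len(nT - 1))
    fuse <- fuse + sum(abs(rows[[t]] - rows[[t + 1]]))
  unname(dataTerm + lambda1 * sum(abs(u)) + lambda2 * fuse)
}
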