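#' Bootstrap p-values for cis-segment weights
#'
#' For each of N replicates the gene's per-base LR values are resampled
#' with replacement (bases keep their positions; values are drawn from the
#' empirical LR distribution of the cis-region at the same transition), the
#' binding matrices are rebuilt, and the weight problem is re-solved with
#' the point-estimate hyperparameters.  The p-value of segment k at
#' transition t is (sum_n H(nu > u) + 1) / (N + 1), where nu is the n-th
#' bootstrap estimate, u the point estimate, and H the strict-positivity
#' indicator of the difference; the smallest attainable p is 1 / (N + 1).
#' A replicate whose solve fails is retried once and then counted as an
#' exceedance for every segment (conservative), with a warning.
#'
#' @param geneId gene.
#' @param geneTracks the gene's LR tracks (list over transitions, as in one
#'   element of \code{\link{predictLrTracks}}).
#' @param hits the gene's resolved hit GRanges.
#' @param P perturbation matrix.
#' @param expr StageExpression.
#' @param region the gene's cis-region GRanges.
#' @param tfCandidates TF gene ids.
#' @param config list from \code{\link{dbnConfig}} (hyperparameters reused
#'   in every replicate).
#' @param N bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param unit "base" (default) or "segment" for block resampling in
#'   segment-width blocks.
#' @param control solver control.
#' @return data.frame(gene, transition, segStart, segEnd, u, p).
#' @export
bootstrapSegmentPvalues <- function(geneId, geneTracks, hits, P, expr, region,
                                    tfCandidates, config = dbnConfig(),
                                    N = 100L, seed = 1L,
                                    unit = c("base", "segment"),
                                    control = list()) {
  unit <- match.arg(unit)
  stopIfNot(N >= 1L, "N must be >= 1")
  X <- logExpr(expr)
  nT <- length(stageLabels(expr)) - 1L
  solveOne <- function(bindings)
    suppressWarnings(solveGeneWeights(geneId, X, bindings, config$lambda1,
                                      config$lambda2, config$loss,
                                      control = control))
  pointBindings <- lapply(seq_len(nT), function(t)
    buildBindingMatrix(geneId, t, geneTracks[[paste0("t", t)]], hits, P,
                       expr, region, tfCandidates, config))
  point <- solveOne(pointBindings)
  u <- point$u
  exceed <- matrix(0L, nrow(u), ncol(u))
  ## replicates only change the segment-mean LR: the hit-coverage /
  ## perturbation structure piCov = B / meanLr is fixed, so each replicate
  ## rescales the rows of B instead of rebuilding it from ranges
  segs <- pointBindings[[1L]]@segments
  offset <- geneTracks[[1L]]$start - 1L
  nBase <- length(geneTracks[[1L]]$score)
  lo <- pmax(1L, IRanges::start(segs) - offset)
  hi <- pmin(nBase, IRanges::end(segs) - offset)
  meanLr0 <- lapply(seq_len(nT), function(t) {
    cs <- c(0, cumsum(geneTracks[[paste0("t", t)]]$score))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  piCov <- lapply(seq_len(nT), function(t) {
    B <- pointBindings[[t]]@B
    if (ncol(B)) B / meanLr0[[t]] else B
  })
  rebuilt <- function(scores) lapply(seq_len(nT), function(t) {
    cs <- c(0, cumsum(scores[[t]]))
    ml <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    b <- pointBindings[[t]]
    if (ncol(b@B)) b@B <- piCov[[t]] * ml
    b
  })
  resample <- function(score) {
    if (unit == "base") return(sample(score, length(score), replace = TRUE))
    w <- config$segmentWidth
    nBlocks <- ceiling(length(score) / w)
    starts <- (sample.int(nBlocks, nBlocks, replace = TRUE) - 1L) * w + 1L
    idx <- unlist(lapply(starts, function(s) s:(s + w - 1L)))
    idx <- idx[idx <= length(score)][seq_along(score)]
    idx[is.na(idx)] <- sample.int(length(score), sum(is.na(idx)), replace = TRUE)
    score[idx]
  }
  set.seed(seed)
  for (n in seq_len(N)) {
    scoresRep <- lapply(seq_len(nT), function(t)
      resample(geneTracks[[paste0("t", t)]]$score))
    res <- NULL
    for (try in 1:2) {
      res <- tryCatch(solveOne(rebuilt(scoresRep)), error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      warning("bootstrap replicate ", n, " failed twice; counted as exceedance")
      exceed <- exceed + 1L
    } else {
      exceed <- exceed + (res$u > u)
    }
  }
  segs <- segmentCisRegion(region, config$segmentWidth, config$segmentStep)
  data.frame(gene = geneId,
             transition = rep(seq_len(ncol(u)), each = nrow(u)),
             segStart = rep(IRanges::start(segs), ncol(u)),
             segEnd = rep(IRanges::end(segs), ncol(u)),
             u = as.vector(u),
             p = as.vector((exceed + 1L) / (N + 1L)))
}

#' In-silico perturbation of a transcription factor
#'
#' The TF's expression is multiplied by \code{fold} on the FPKM scale and
#' re-logged; the change is propagated one step through the stage's
#' transition matrix, and each gene's response direction is the sign of the
#' change of its predicted next-stage expression (|change| <= tol counts as
#' unchanged).
#'
#' @param net DynamicNetwork.
#' @param expr StageExpression.
#' @param tf TF gene id to perturb.
#' @param fold fold induction on the FPKM scale (default 5).
#' @param stage stage index at which the TF is induced (the transition
#'   stage -> stage + 1 is used).
#' @param tol absolute change below which a gene counts as unchanged.
#' @return list(tf, fold, stage, direction = named character vector,
#'   delta = named numeric vector).
#' @export
computationalPerturbation <- function(net, expr, tf, fold = 5, stage = 1L,
                                      tol = 1e-8) {
  X <- logExpr(expr)
  stopIfNot(tf %in% rownames(X), "unknown TF: ", tf)
  A <- net@A[[stage]]
  if (all(A[, tf] == 0))
    warning("TF ", tf, " has no outgoing weight in transition ", stage,
            "; all predictions unchanged")
  xNew <- log(fold * fpkm(expr)[tf, stage] + 1)
  delta <- A[, tf] * (xNew - X[tf, stage])
  direction <- ifelse(delta > tol, "up", ifelse(delta < -tol, "down",
                                                "unchanged"))
  list(tf = tf, fold = fold, stage = stage,
       direction = stats::setNames(direction, rownames(A)),
       delta = stats::setNames(delta, rownames(A)))
}

#' Fisher agreement test between predicted and experimental directions
#'
#' Genes with a non-unchanged prediction and an up/down experimental call
#' enter a 2 x 2 table (predicted up/down x experimental up/down), tested
#' by a two-sided Fisher's exact test.
#'
#' @param predicted named character vector ("up"/"down"/"unchanged").
#' @param experimental named character vector ("up"/"down"; other values
#'   and missing genes are ignored).
#' @return list(p, table, n).
#' @export
directionAgreementTest <- function(predicted, experimental) {
  genes <- intersect(names(predicted)[predicted %in% c("up", "down")],
                     names(experimental)[experimental %in% c("up", "down")])
  stopIfNot(length(genes) > 0,
            "no gene has both a directional prediction and an experimental call")
  tab <- table(factor(predicted[genes], levels = c("up", "down")),
               factor(experimental[genes], levels = c("up", "down")),
               dnn = c("predicted", "experimental"))
  list(p = stats::fisher.test(tab)$p.value, table = tab, n = length(genes))
}
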