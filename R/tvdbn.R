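#' Default configuration of the time-varying network model
#'
#' @param lambda1 sparsity penalty on the cis-segment weights.
#' @param lambda2 fused-L1 penalty smoothing the edge weights of adjacent
#'   transitions.
#' @param loss data-term loss, "squared" (default) or "abs".
#' @param tfFpkmMin minimum FPKM for a TF to enter the binding matrix at a
#'   stage (default 25: only abundantly expressed TFs regulate).
#' @param segmentWidth,segmentStep cis-segment tiling (default 50 / 5 nt,
#'   adjacent segments overlapping by 45 nt).
#' @param piDefault perturbation adjustment for pairs without perturbation
#'   support (default 0.25; pairs with P = 1 get 1).
#' @param edgeTol threshold above which an assembled edge weight counts as a
#'   positive edge (default 1e-8, the solver noise floor).
#' @return named list.
#' @export
dbnConfig <- function(lambda1 = 0.01, lambda2 = 0.1, loss = c("squared", "abs"),
                      tfFpkmMin = 25, segmentWidth = 50L, segmentStep = 5L,
                      piDefault = 0.25, edgeTol = 1e-8) {
  loss <- match.arg(loss)
  stopIfNot(lambda1 >= 0 && lambda2 >= 0, "penalties must be non-negative")
  list(lambda1 = lambda1, lambda2 = lambda2, loss = loss,
       tfFpkmMin = tfFpkmMin, segmentWidth = as.integer(segmentWidth),
       segmentStep = as.integer(segmentStep), piDefault = piDefault,
       edgeTol = edgeTol)
}

#' Tile a cis-region into overlapping cis-segments
#'
#' Segments of \code{width} nt are placed every \code{step} nt starting at
#' the region start, giving K = floor((L - width) / step) + 1 segments for a
#' region of length L >= width.
#'
#' @param region GRanges of length 1 (or an IRanges of length 1).
#' @param width segment width (default 50).
#' @param step step size (default 5).
#' @return IRanges of the K segments, in the region's coordinates.
#' @export
segmentCisRegion <- function(region, width = 50L, step = 5L) {
  if (methods::is(region, "GRanges")) region <- IRanges::ranges(region)
  stopIfNot(length(region) == 1L, "one region at a time")
  L <- IRanges::width(region)
  if (L < width)
    stop("region of length ", L, " is shorter than the segment width ", width)
  K <- (L - width) %/% step + 1L
  IRanges::IRanges(start = IRanges::start(region) + (seq_len(K) - 1L) * step,
                   width = width)
}

#' Build the binding profile matrix of one gene at one transition
#'
#' Entry (k, j) is the mean LR score over the bases of cis-segment k times
#' the perturbation adjustment pi_ij (1 when the perturbation matrix
#' records target i responding to regulator j, else \code{piDefault}),
#' provided TF j has a surviving PWM hit overlapping segment k; otherwise 0.
#' Columns are restricted to TFs whose FPKM exceeds \code{tfFpkmMin} at
#' stage t; candidate TFs without any PWM are excluded with a warning.
#'
#' @param geneId target gene.
#' @param t transition index (stage t -> t+1).
#' @param lrTrack LR track of the gene at transition t
#'   (\code{\link{predictLrTrack}} or any list with chrom/start/score).
#' @param hits overlap-resolved GRanges of PWM hits.
#' @param P perturbation matrix (targets x regulators).
#' @param expr StageExpression.
#' @param region the gene's cis-region (GRanges of length 1).
#' @param tfCandidates character vector of TF gene ids considered by the
#'   model.
#' @param config list from \code{\link{dbnConfig}}.
#' @param pwmTfs TFs with a known PWM (default \code{tfCandidates});
#'   candidates outside this set are excluded with a warning.  A TF with a
#'   PWM but no hit in this region simply gets a zero column.
#' @return a \linkS4class{BindingMatrix}.
#' @export
buildBindingMatrix <- function(geneId, t, lrTrack, hits, P, expr, region,
                               tfCandidates, config = dbnConfig(),
                               pwmTfs = tfCandidates) {
  f <- fpkm(expr)
  tfs <- tfCandidates[f[tfCandidates, t] > config$tfFpkmMin]
  noPwm <- setdiff(tfs, pwmTfs)
  if (length(noPwm)) {
    warning("TF(s) without a known PWM excluded from binding matrix: ",
            paste(noPwm, collapse = ", "))
    tfs <- intersect(tfs, pwmTfs)
  }
  segs <- segmentCisRegion(region, config$segmentWidth, config$segmentStep)
  K <- length(segs)
  B <- matrix(0, K, length(tfs), dimnames = list(NULL, tfs))
  ## segment-mean LR via cumulative sums over the region's bases
  offset <- lrTrack$start - 1L
  cs <- c(0, cumsum(lrTrack$score))
  n <- length(lrTrack$score)
  lo <- pmax(1L, IRanges::start(segs) - offset)
  hi <- pmin(n, IRanges::end(segs) - offset)
  stopIfNot(all(lo <= hi), "LR track does not cover the cis-region")
  meanLr <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  chrom <- as.character(GenomicRanges::seqnames(region))
  segGr <- GenomicRanges::GRanges(chrom, segs)
  for (j in seq_along(tfs)) {
    hj <- hits[S4Vectors::mcols(hits)$tf == tfs[j]]
    if (!length(hj)) next
    covered <- IRanges::overlapsAny(segGr, hj, ignore.strand = TRUE)
    pi_ij <- if (!is.na(P[geneId, tfs[j]]) && P[geneId, tfs[j]] == 1) 1
             else config$piDefault
    B[covered, j] <- meanLr[covered] * pi_ij
  }
  methods::new("BindingMatrix", geneId = geneId, transition = as.integer(t),
               B = B, segments = segs)
}

## ---------------------------------------------------------------------------
## ADMM solver for the per-gene generalized-lasso objective
##   sum_t loss(y_t - c_t' u_t) + l1 sum_t |u_t|_1
##   + l2 sum_pairs |Ba' u_a - Bb' u_b|_1
## Splitting z = G u with G = [I; D] (squared loss keeps the quadratic in
## the u-update) or G = [M; I; D] (abs loss).  The u-update solves a
## ridge-plus-low-rank system by the Woodbury identity, so each iteration
## costs O(n * rank).

admmGenLasso <- function(y, clist, pairs, lambda1, lambda2,
                         loss = "squared", control = list()) {
  ctrl <- utils::modifyList(list(rho = 1, maxit = 20000L, epsAbs = 1e-9,
                                 epsRel = 1e-7, adaptEvery = 50L), control)
  nT <- length(clist)
  K <- if (nT) length(clist[[1L]]) else 0L
  n <- K * nT
  blk <- function(t) ((t - 1L) * K + 1L):(t * K)
  ## dense M (nT x n) and D (fusion rows x n)
  M <- matrix(0, nT, n)
  for (t in seq_len(nT)) M[t, blk(t)] <- clist[[t]]
  Drows <- sum(vapply(pairs, function(p) ncol(p$Ba), integer(1)))
  D <- matrix(0, Drows, n)
  r0 <- 0L
  for (p in pairs) {
    pr <- r0 + seq_len(ncol(p$Ba))
    D[pr, blk(p$a)] <- t(p$Ba)
    D[pr, blk(p$b)] <- -t(p$Bb)
    r0 <- r0 + ncol(p$Ba)
  }
  squared <- loss == "squared"
  ## G = [I; D] (squared) or [M; I; D] (abs); never formed densely --
  ## products use the block structure.
  if (squared) {
    lam <- c(rep(lambda1, n), rep(lambda2, Drows))
    uBlock <- seq_len(n)
    Gmul <- function(u) c(u, drop(D %*% u))
    Gtmul <- function(v) v[seq_len(n)] + drop(crossprod(D, v[n + seq_len(Drows)]))
    mz <- n + Drows
  } else {
    lam <- c(rep(0, nT), rep(lambda1, n), rep(lambda2, Drows))
    uBlock <- nT + seq_len(n)
    Gmul <- function(u) c(drop(M %*% u), u, drop(D %*% u))
    Gtmul <- function(v) drop(crossprod(M, v[seq_len(nT)])) +
      v[nT + seq_len(n)] + drop(crossprod(D, v[nT + n + seq_len(Drows)]))
    mz <- nT + n + Drows
  }
  z <- numeric(mz); w <- numeric(mz)
  rho <- ctrl$rho
  ## u-update system: (2 M'M + rho (I + D'D)) u = rhs   [squared]
  ##                  (rho (M'M + I + D'D)) u = rhs      [abs]
  ## both are rho*I + E E' with low-rank E.
  makeSolver <- function(rho) {
    E <- if (squared) rbind(sqrt(2) * M, sqrt(rho) * D)
         else sqrt(rho) * rbind(M, D)
    E <- t(E)                                   # n x m
    m <- ncol(E)
    if (m == 0L) return(function(v) v / rho)
    S <- diag(m) * rho + crossprod(E)
    R <- chol(S)
    function(v) {
      t1 <- crossprod(E, v)
      (v - E %*% backsolve(R, forwardsolve(t(R), t1))) / rho
    }
  }
  solver <- makeSolver(rho)
  proxZ <- function(v, rho) {
    out <- softThreshold(v, lam / rho)
    if (!squared) {
      ## data block: prox of |y - z| at the first nT entries
      d <- v[seq_len(nT)]
      out[seq_len(nT)] <- y - softThreshold(y - d, 1 / rho)
    }
    out
  }
  rhsBase <- if (squared) drop(crossprod(M, 2 * y)) else numeric(n)
  u <- numeric(n)
  converged <- FALSE
  for (it in seq_len(ctrl$maxit)) {
    rhs <- rhsBase + rho * Gtmul(z - w)
    u <- drop(solver(rhs))
    Gu <- Gmul(u)
    zOld <- z
    z <- proxZ(Gu + w, rho)
    w <- w + Gu - z
    if (it %% 10L == 0L || it == 1L) {
      rPri <- sqrt(sum((Gu - z)^2))
      sDual <- rho * sqrt(sum(Gtmul(z - zOld)^2))
      epsPri <- sqrt(mz) * ctrl$epsAbs +
        ctrl$epsRel * max(sqrt(sum(Gu^2)), sqrt(sum(z^2)))
      epsDual <- sqrt(n) * ctrl$epsAbs + ctrl$epsRel * rho * sqrt(sum(w^2))
      if (rPri <= epsPri && sDual <= epsDual) { converged <- TRUE; break }
      if (it %% ctrl$adaptEvery == 0L) {
        if (rPri > 10 * sDual) {
          rho <- rho * 2; w <- w / 2; solver <- makeSolver(rho)
        } else if (sDual > 10 * rPri) {
          rho <- rho / 2; w <- w * 2; solver <- makeSolver(rho)
        }
      }
    }
  }
  if (anyNA(u) || any(!is.finite(u)))
    stop("ADMM solver failed: non-finite iterate (status: diverged)")
  ## report the soft-thresholded copy of u (exactly sparse at the optimum)
  uOut <- z[uBlock]
  resid <- y - drop(M %*% uOut)
  dataTerm <- if (squared) sum(resid^2) else sum(abs(resid))
  obj <- dataTerm + lambda1 * sum(abs(uOut)) +
    lambda2 * sum(abs(drop(D %*% uOut)))
  list(u = matrix(uOut, K, nT), objective = obj, iterations = it,
       converged = converged, rho = rho)
}

#' Solve the segment-weight problem of one gene
#'
#' Minimizes, over the segment-weight vectors u^t of all included
#' transitions, the sum of the per-transition data loss
#' (x_i^{t+1} - (u^t)' B^t X^t)^2 (or its absolute value), an L1 penalty
#' lambda1 on the weights, and a fused-L1 penalty lambda2 on the change of
#' the implied edge-weight rows (u^t)' B^t between adjacent transitions.
#' The problem is convex; it is solved by ADMM to the control tolerances.
#'
#' @param geneId target gene (a row of X).
#' @param X p x T expression matrix on the log(FPKM + 1) scale, with gene
#'   rownames.
#' @param bindings list of \linkS4class{BindingMatrix}, one per transition.
#' @param lambda1,lambda2 penalties (>= 0).
#' @param loss "squared" (default) or "abs".
#' @param include integer vector of transitions whose data terms are fitted
#'   (default all); fusion pairs are restricted to adjacent included
#'   transitions.  Weights are returned only for included transitions.
#' @param control solver control list (rho, maxit, epsAbs, epsRel).
#' @return list(u = K x length(include) matrix, objective, iterations,
#'   converged, include).
#' @export
solveGeneWeights <- function(geneId, X, bindings, lambda1, lambda2,
                             loss = c("squared", "abs"), include = NULL,
                             control = list()) {
  loss <- match.arg(loss)
  stopIfNot(lambda1 >= 0 && lambda2 >= 0, "penalties must be non-negative")
  nT <- length(bindings)
  if (is.null(include)) include <- seq_len(nT)
  K <- nrow(bindings[[1L]]@B)
  y <- vapply(include, function(t) X[geneId, t + 1L], numeric(1))
  if (K == 0L) {
    dataTerm <- if (loss == "squared") sum(y^2) else sum(abs(y))
    return(list(u = matrix(0, 0L, length(include)), objective = dataTerm,
                iterations = 0L, converged = TRUE, include = include))
  }
  tfUnion <- unique(unlist(lapply(bindings[include],
                                  function(b) colnames(b@B))))
  expand <- function(b) {
    out <- matrix(0, K, length(tfUnion), dimnames = list(NULL, tfUnion))
    if (ncol(b@B)) out[, colnames(b@B)] <- b@B
    out
  }
  clist <- lapply(include, function(t)
    if (ncol(bindings[[t]]@B))
      drop(bindings[[t]]@B %*% X[colnames(bindings[[t]]@B), t])
    else numeric(K))
  pairs <- list()
  for (i in seq_along(include)[-1L]) {
    if (include[i] == include[i - 1L] + 1L)
      pairs[[length(pairs) + 1L]] <-
        list(a = i - 1L, b = i,
             Ba = expand(bindings[[include[i - 1L]]]),
             Bb = expand(bindings[[include[i]]]))
  }
  res <- admmGenLasso(y, clist, pairs, lambda1, lambda2, loss, control)
  res$include <- include
  if (!res$converged)
    warning("solver for gene ", geneId, " stopped at maxit without meeting ",
            "tolerances (status: maxit)")
  res
}

#' Select the penalty pair by leave-one-transition-out cross-validation
#'
#' For every grid point, each transition t0 is held out in turn: the
#' weights are refitted on the remaining transitions (fusion restricted to
#' adjacent fitted pairs), the held-out transition is predicted with the
#' temporally nearest fitted weight vector, and the squared prediction
#' error is averaged over held-out transitions and the gene subset.  The
#' arg-min is returned, ties going to the lexicographically smaller
#' (lambda1, lambda2).
#'
#' @param X expression matrix (log scale).
#' @param bindingsByGene named list: gene -> list of BindingMatrix per
#'   transition.
#' @param grid data.frame with columns lambda1, lambda2.
#' @param genes genes to evaluate (default: all in bindingsByGene; a seeded
#'   subsample is the caller's choice).
#' @param loss data loss.
#' @param control solver control.
#' @return list(lambda1, lambda2, cvError = per-grid-point mean error).
#' @export
selectHyperparameters <- function(X, bindingsByGene, grid,
                                  genes = names(bindingsByGene),
                                  loss = "squared", control = list()) {
  stopIfNot(nrow(grid) >= 1L, "empty hyperparameter grid")
  nT <- length(bindingsByGene[[1L]])
  stopIfNot(nT >= 2L,
            "leave-one-transition-out needs >= 3 stages (>= 2 transitions)")
  err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    tot <- 0; cnt <- 0L
    for (gene in genes) {
      bindings <- bindingsByGene[[gene]]
      for (t0 in seq_len(nT)) {
        keep <- setdiff(seq_len(nT), t0)
        fit <- suppressWarnings(solveGeneWeights(
          gene, X, bindings, grid$lambda1[g], grid$lambda2[g], loss,
          include = keep, control = control))
        ## temporally nearest fitted transition (earlier wins a tie)
        near <- keep[which.min(abs(keep - t0))]
        uNear <- fit$u[, match(near, keep)]
        b0 <- bindings[[t0]]
        pred <- if (ncol(b0@B) && nrow(fit$u))
          sum(uNear * drop(b0@B %*% X[colnames(b0@B), t0])) else 0
        tot <- tot + (X[gene, t0 + 1L] - pred)^2
        cnt <- cnt + 1L
      }
    }
    err[g] <- tot / cnt
  }
  ord <- order(err, grid$lambda1, grid$lambda2)
  best <- ord[1L]
  ## explicit tie-break: smallest error, then lexicographic (lambda1, lambda2)
  ties <- which(abs(err - err[best]) <= 1e-12)
  if (length(ties) > 1L)
    best <- ties[order(grid$lambda1[ties], grid$lambda2[ties])][1L]
  list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
       cvError = err)
}

#' Assemble per-transition networks from solved segment weights
#'
#' Row i of the transition matrix A^t is (u^{i,t})' B^{i,t}; a positive
#' regulator -> target edge (j -> i) is recorded when A^t_{ij} exceeds
#' \code{config$edgeTol}.  Cis-segments with weight above the tolerance
#' become TFBS records listing the overlapping TF hits.
#'
#' @param weightsByGene named list: gene -> K x (T-1) weight matrix.
#' @param bindingsByGene named list: gene -> list of BindingMatrix.
#' @param genes gene universe (rows/columns of A).
#' @param stages stage labels.
#' @param hits resolved hit GRanges (for the TFBS table; may be NULL).
#' @param config list from \code{\link{dbnConfig}}.
#' @return list(A, edges, tfbs).
#' @export
assembleNetworks <- function(weightsByGene, bindingsByGene, genes, stages,
                             hits = NULL, config = dbnConfig()) {
  nT <- length(stages) - 1L
  p <- length(genes)
  A <- lapply(seq_len(nT), function(t)
    matrix(0, p, p, dimnames = list(genes, genes)))
  edges <- list(); tfbs <- list()
  for (gene in names(weightsByGene)) {
    u <- weightsByGene[[gene]]
    bindings <- bindingsByGene[[gene]]
    for (t in seq_len(nT)) {
      b <- bindings[[t]]
      if (!nrow(u) || !ncol(b@B)) next
      row <- drop(crossprod(u[, t], b@B))
      A[[t]][gene, colnames(b@B)] <- row
      pos <- which(row > config$edgeTol)
      if (length(pos))
        edges[[length(edges) + 1L]] <- data.frame(
          transition = t, regulator = colnames(b@B)[pos], target = gene,
          weight = unname(row[pos]))
      segPos <- which(u[, t] > config$edgeTol)
      if (length(segPos)) {
        segs <- b@segments[segPos]
        tfList <- rep("", length(segPos))
        if (!is.null(hits)) {
          hg <- hits[!is.na(S4Vectors::mcols(hits)$geneId) &
                     S4Vectors::mcols(hits)$geneId == gene]
          if (length(hg)) {
            ov <- IRanges::findOverlaps(segs, IRanges::ranges(hg))
            tfList <- vapply(seq_along(segPos), function(k) {
              idx <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]
              paste(unique(S4Vectors::mcols(hg)$tf[idx]), collapse = ",")
            }, character(1))
          }
        }
        tfbs[[length(tfbs) + 1L]] <- data.frame(
          gene = gene, transition = t, start = IRanges::start(segs),
          end = IRanges::end(segs), u = unname(u[segPos, t]), tfs = tfList)
      }
    }
  }
  list(A = A,
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(transition = integer(), regulator = character(),
                    target = character(), weight = numeric()),
       tfbs = if (length(tfbs)) do.call(rbind, tfbs) else
         data.frame(gene = character(), transition = integer(),
                    start = integer(), end = integer(), u = numeric(),
                    tfs = character()))
}

#' Infer the full dynamic network
#'
#' Builds each gene's binding matrices at every transition, solves the
#' per-gene convex weight problem, and assembles the transition networks.
#'
#' @param expr StageExpression over the gene universe.
#' @param lrTracks nested LR track list from \code{\link{predictLrTracks}}.
#' @param hits resolved, gene-assigned hit GRanges.
#' @param P perturbation matrix.
#' @param regions cis-region GRanges.
#' @param tfCandidates TF gene ids with PWMs.
#' @param config list from \code{\link{dbnConfig}}.
#' @param genes genes to solve (default: all with regions).
#' @param control solver control.
#' @return a \linkS4class{DynamicNetwork}.
#' @export
inferNetwork <- function(expr, lrTracks, hits, P, regions, tfCandidates,
                         config = dbnConfig(), genes = NULL,
                         control = list()) {
  X <- logExpr(expr)
  stages <- stageLabels(expr)
  nT <- length(stages) - 1L
  if (is.null(genes)) genes <- S4Vectors::mcols(regions)$geneId
  bindingsByGene <- lapply(genes, function(gene) {
    hg <- hits[!is.na(S4Vectors::mcols(hits)$geneId) &
               S4Vectors::mcols(hits)$geneId == gene]
    lapply(seq_len(nT), function(t)
      buildBindingMatrix(gene, t, lrTracks[[gene]][[paste0("t", t)]], hg, P,
                         expr, regions[S4Vectors::mcols(regions)$geneId == gene],
                         tfCandidates, config))
  })
  names(bindingsByGene) <- genes
  sols <- lapply(genes, function(gene)
    solveGeneWeights(gene, X, bindingsByGene[[gene]], config$lambda1,
                     config$lambda2, config$loss, control = control))
  names(sols) <- genes
  weightsByGene <- lapply(sols, `[[`, "u")
  nets <- assembleNetworks(weightsByGene, bindingsByGene,
                           rownames(X), stages, hits, config)
  methods::new("DynamicNetwork", genes = rownames(X), stages = stages,
               weights = weightsByGene, segments = lapply(bindingsByGene,
                 function(b) b[[1L]]@segments),
               bindings = bindingsByGene, A = nets$A, edges = nets$edges,
               config = config,
               objectives = vapply(sols, `[[`, numeric(1), "objective"))
}

#' Fraction of expression variance explained per target stage
#'
#' R^2 of the one-step prediction X-hat^{t+1} = A^t X^t against the
#' observed X^{t+1}, relative to the stage-mean baseline.
#'
#' @param X p x T expression matrix (log scale).
#' @param A list of transition matrices (as in a DynamicNetwork).
#' @return numeric vector, one R^2 per target stage (t = 2..T).
#' @export
varianceExplained <- function(X, A) {
  vapply(seq_along(A), function(t) {
    obs <- X[, t + 1L]
    pred <- drop(A[[t]] %*% X[, t])
    denom <- sum((obs - mean(obs))^2)
    if (denom == 0) {
      warning("zero variance at target stage ", t + 1L, "; R^2 undefined")
      return(NA_real_)
    }
    1 - sum((obs - pred)^2) / denom
  }, numeric(1))
}

#' Shared positive edges between transition pairs
#'
#' @param edges edge data.frame (transition, regulator, target, weight).
#' @return data.frame(transitionA, transitionB, common) for every pair.
#' @export
commonLinks <- function(edges) {
  ts <- sort(unique(edges$transition))
  stopIfNot(length(ts) >= 2L, "need >= 2 transitions with edges")
  keys <- lapply(ts, function(t)
    paste(edges$regulator[edges$transition == t],
          edges$target[edges$transition == t]))
  combos <- utils::combn(seq_along(ts), 2L)
  data.frame(transitionA = ts[combos[1L, ]], transitionB = ts[combos[2L, ]],
             common = apply(combos, 2L, function(ij)
               length(intersect(keys[[ij[1L]]], keys[[ij[2L]]]))))
}

#' Write the positive-edge list as TSV
#' @param net DynamicNetwork (or an edge data.frame).
#' @param path output path.
#' @export
writeNetworkEdges <- function(net, path) {
  edges <- if (methods::is(net, "DynamicNetwork")) net@edges else net
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the predicted TFBS (weighted cis-segments) as TSV
#' @param net DynamicNetwork.
#' @param hits resolved hit GRanges used in the inference.
#' @param path output path.
#' @export
writeTfbsTable <- function(net, hits, path) {
  nets <- assembleNetworks(net@weights, net@bindings, net@genes, net@stages,
                           hits, net@config)
  utils::write.table(nets$tfbs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
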