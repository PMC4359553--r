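#' Fit the logistic occupancy model by IRLS
#'
#' Maximizes the Bernoulli log-likelihood of the 69-feature logistic
#' regression (plus intercept) by Newton iterations with step halving,
#' stopping when the gradient max-norm falls below 1e-8 or after
#' \code{maxit} iterations.  Zero-variance feature columns (e.g. constant
#' columns zeroed by standardization) are excluded from the fit and get
#' coefficient 0 with NA standard error.  Under perfect separation the fit
#' does not converge; the last iterate is returned with a warning and the
#' convergence flag unset.
#'
#' @param table FeatureTable with both response classes present.
#' @param maxit maximum Newton iterations (default 100).
#' @param tol gradient max-norm tolerance (default 1e-8).
#' @return a \linkS4class{LogisticModel}.
#' @export
fitLogistic <- function(table, maxit = 100L, tol = 1e-8) {
  y <- table@response
  if (length(unique(y)) < 2L)
    stop("response has a single class; cannot fit")
  F <- table@features
  X <- cbind(`(Intercept)` = 1, F)
  active <- c(TRUE, apply(F, 2L, function(v) diff(range(v)) > 0))
  Xa <- X[, active, drop = FALSE]
  beta <- numeric(ncol(Xa))
  loglik <- function(b) {
    eta <- drop(Xa %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xa, y - mu))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xa * w, Xa)
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, ncol(H)), grad))
    ## step halving keeps the likelihood non-decreasing
    s <- 1
    repeat {
      cand <- beta + s * step
      llNew <- loglik(cand)
      if (llNew >= ll - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- cand; ll <- llNew
  }
  if (!converged) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xa, y - mu))
    converged <- max(abs(grad)) < tol
  }
  ## under perfect separation the gradient vanishes as the probabilities
  ## saturate, so a small gradient alone does not certify a maximum;
  ## runaway coefficients are the telltale
  mu <- stats::plogis(drop(Xa %*% beta))
  if (converged && max(abs(beta)) > 25) converged <- FALSE
  if (!converged)
    warning("IRLS did not reach a finite maximum in ", maxit,
            " iterations (perfect separation is the usual cause); ",
            "returning the last iterate")
  w <- pmax(mu * (1 - mu), 1e-12)
  Ha <- crossprod(Xa * w, Xa)
  Va <- tryCatch(solve(Ha), error = function(e) matrix(NA_real_, ncol(Xa), ncol(Xa)))
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  coefs[active] <- beta
  V <- matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  V[active, active] <- Va
  methods::new("LogisticModel", coefficients = coefs, vcov = V,
               fittedOn = length(y), converged = converged,
               iterations = it, scaler = table@scaler, lambda = 0)
}

#' Wald tests for the fitted coefficients
#'
#' Two-sided normal test z = beta / se per coefficient, with the
#' significance stars binned as *: 0.01 <= p < 0.05, **: 0.001 <= p < 0.01,
#' ***: p < 0.001.  Coefficients with undefined standard error (excluded
#' columns) are flagged with NA p-values.
#'
#' @param model converged LogisticModel.
#' @return data.frame(feature, estimate, direction, z, p, stars).
#' @export
waldTests <- function(model) {
  stopIfNot(model@converged, "Wald tests require a converged model")
  se <- sqrt(diag(model@vcov))
  z <- model@coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(is.na(p), "",
           ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
           ifelse(p < 0.05, "*", ""))))
  data.frame(feature = names(model@coefficients),
             estimate = unname(model@coefficients),
             direction = ifelse(model@coefficients >= 0, "+", "-"),
             z = unname(z), p = unname(p), stars = stars,
             row.names = NULL)
}

#' Elastic-net regularized fit of the occupancy model
#'
#' Penalized likelihood with mixing parameter \code{alpha} (1 = LASSO);
#' the penalty weight lambda is chosen on a log grid by seeded k-fold
#' cross-validation minimizing the binomial deviance, unless a fixed
#' \code{lambda} is supplied.
#'
#' @param table FeatureTable.
#' @param alpha elastic-net mixing in [0, 1] (default 1, LASSO).
#' @param nFolds CV folds (default 3).
#' @param lambda optional fixed penalty (skips CV; 0 reproduces the
#'   unregularized fit).
#' @param seed RNG seed for the fold assignment.
#' @return a \linkS4class{LogisticModel} (vcov empty; lambda recorded).
#' @export
fitRegularized <- function(table, alpha = 1, nFolds = 3L, lambda = NULL,
                           seed = 1L) {
  y <- table@response
  if (length(unique(y)) < 2L) stop("response has a single class; cannot fit")
  F <- table@features
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nFolds), length(y)))
    cv <- glmnet::cv.glmnet(F, y, family = "binomial", alpha = alpha,
                            foldid = foldid, standardize = FALSE,
                            thresh = 1e-10)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    ## a decreasing path ending at the requested lambda stabilizes the
    ## coordinate-descent solution (glmnet warm starts along the path)
    lmax <- max(abs(crossprod(F, y - mean(y)))) / length(y)
    path <- sort(unique(c(exp(seq(log(max(lmax, 1e-3)), log(1e-7), length.out = 60)),
                          lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(F, y, family = "binomial", alpha = alpha,
                          lambda = path, standardize = FALSE, thresh = 1e-12,
                          maxit = 1e6)
  }
  cf <- as.numeric(stats::coef(fit, s = lambda))
  names(cf) <- c("(Intercept)", colnames(F))
  methods::new("LogisticModel", coefficients = cf,
               vcov = matrix(numeric(0), 0, 0), fittedOn = length(y),
               converged = TRUE, iterations = 0L, scaler = table@scaler,
               lambda = lambda)
}

#' Train the occupancy model, falling back to regularization under separation
#'
#' Fits the maximum-likelihood model; when the fit does not converge
#' (perfect separation, which is routine when the candidate rows are few
#' relative to the 69 features), refits with the LASSO path instead, whose
#' penalized optimum is always well defined.
#'
#' @param table standardized FeatureTable.
#' @param method "auto" (default), "ml" or "lasso".
#' @param seed seed for the regularization CV folds.
#' @return a \linkS4class{LogisticModel}.
#' @export
trainOccupancyModel <- function(table, method = c("auto", "ml", "lasso"),
                                seed = 1L) {
  method <- match.arg(method)
  if (method != "lasso") {
    ml <- withCallingHandlers(fitLogistic(table),
                              warning = function(w) invokeRestart("muffleWarning"))
    if (method == "ml" || ml@converged) return(ml)
  }
  fitRegularized(table, alpha = 1, seed = seed)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in [0, 1].
#' @export
computeAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  stopIfNot(n1 > 0 && n0 > 0, "AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-TF-out cross-validation
#'
#' For each TF, a model is trained on all other TFs' rows (with the feature
#' standardization refit on the training rows only) and evaluated on the
#' held-out TF's rows by AUC.  TFs whose held-out rows contain a single
#' class are skipped with a warning (AUC undefined).
#'
#' @param table raw (unstandardized) FeatureTable with >= 2 TFs.
#' @return data.frame(tf, auc, nPos, nNeg).
#' @export
lotfoCV <- function(table) {
  stopIfNot(!length(table@scaler),
            "provide the raw table; standardization is refit per fold")
  tfs <- unique(table@meta$tf)
  stopIfNot(length(tfs) >= 2L, "leave-one-TF-out needs >= 2 TFs")
  out <- lapply(tfs, function(tf) {
    test <- table@meta$tf == tf
    yTest <- table@response[test]
    if (length(unique(yTest)) < 2L) {
      warning("held-out TF ", tf, " has a single class; AUC undefined")
      return(data.frame(tf = tf, auc = NA_real_, nPos = sum(yTest == 1L),
                        nNeg = sum(yTest == 0L)))
    }
    train <- methods::new("FeatureTable",
                          features = table@features[!test, , drop = FALSE],
                          response = table@response[!test],
                          meta = table@meta[!test, , drop = FALSE],
                          scaler = list())
    ## constant columns and saturation inside a fold are routine at small n
    train <- suppressWarnings(standardizeFeatures(train))
    fit <- suppressWarnings(fitLogistic(train))
    z <- applyScaler(table@features[test, , drop = FALSE], fit@scaler)
    scores <- stats::plogis(drop(cbind(1, z) %*% fit@coefficients))
    data.frame(tf = tf, auc = computeAuc(scores, yTest),
               nPos = sum(yTest == 1L), nNeg = sum(yTest == 0L))
  })
  do.call(rbind, out)
}

#' Score a model on a raw feature matrix
#' @param model LogisticModel with a stored scaler.
#' @param features raw n x 69 matrix.
#' @return per-row occupancy probability in (0, 1).
#' @export
predictLrScores <- function(model, features) {
  stopIfNot(length(model@scaler) > 0, "model has no stored scaler")
  z <- applyScaler(features, model@scaler)
  p <- stats::plogis(drop(cbind(1, z) %*% model@coefficients))
  ## keep scores strictly inside (0, 1) even when the fit saturates
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Per-base LR score track over a gene's cis-region
#'
#' Computes the 69 features for every base of the gene's cis-region at the
#' requested stage transition, applies the training scaler, and evaluates
#' the fitted model, giving the stage-specific occupancy probability per
#' base.
#'
#' @param model converged LogisticModel.
#' @param ctx feature context from \code{\link{prepareFeatureContext}}.
#' @param regions cis-region GRanges.
#' @param geneId gene id.
#' @param t transition index.
#' @return list(gene, transition, chrom, start, score) where \code{score[i]}
#'   is the LR score of base \code{start + i - 1}.
#' @export
predictLrTrack <- function(model, ctx, regions, geneId, t) {
  stopIfNot(model@converged, "model must be converged")
  ri <- ctx$regionByGene[[geneId]]
  stopIfNot(!is.null(ri), "gene has no cis-region: ", geneId)
  chrom <- as.character(GenomicRanges::seqnames(regions))[ri]
  pos <- IRanges::start(regions)[ri]:IRanges::end(regions)[ri]
  feats <- featureMatrix(ctx, chrom, pos, rep(geneId, length(pos)), t)
  list(gene = geneId, transition = t, chrom = chrom, start = pos[1L],
       score = predictLrScores(model, feats))
}

#' LR tracks for all genes and transitions
#' @inheritParams predictLrTrack
#' @param transitions integer vector of transitions (default all).
#' @return nested list \code{tracks[[geneId]][[t]]}.
#' @export
predictLrTracks <- function(model, ctx, regions,
                            transitions = seq_len(length(ctx$stages) - 1L)) {
  genes <- S4Vectors::mcols(regions)$geneId
  out <- lapply(genes, function(g)
    stats::setNames(lapply(transitions, function(t)
      predictLrTrack(model, ctx, regions, g, t)), paste0("t", transitions)))
  stats::setNames(out, genes)
}

#' Write one LR track as bedGraph
#' @param track list from \code{\link{predictLrTrack}}.
#' @param path output path.
#' @export
writeLrTrack <- function(track, path) {
  con <- openOut(path); on.exit(close(con))
  pos0 <- track$start - 1L + seq_along(track$score) - 1L
  writeLines(paste(track$chrom, pos0, pos0 + 1L,
                   format(track$score, digits = 8), sep = "\t"), con)
  invisible(path)
}

#' Compare LR scores on candidate enhancers against random scored bases
#'
#' Sample 1 is the mean LR score per enhancer interval (over the bases of
#' the interval covered by the score tracks); sample 2 is the LR score of
#' \code{nRandom} uniformly sampled scored bases.  The two samples are
#' compared by a two-sided Wilcoxon rank-sum test (exact when both samples
#' have at most 10 observations and no ties; otherwise the normal
#' approximation with tie correction).
#'
#' @param lrTracks nested track list from \code{\link{predictLrTracks}}.
#' @param t transition index.
#' @param enhancers GRanges of enhancer intervals.
#' @param nRandom number of random background bases (default 1000).
#' @param seed RNG seed for the background sample.
#' @return list(p, medianEnhancer, medianRandom, nEnhancer).
#' @export
compareRegionScores <- function(lrTracks, t, enhancers, nRandom = 1000L,
                                seed = 1L) {
  key <- paste0("t", t)
  scored <- lapply(lrTracks, function(g) g[[key]])
  scored <- scored[!vapply(scored, is.null, logical(1))]
  stopIfNot(length(scored) > 0, "no scored tracks for transition ", t)
  enhMeans <- vapply(seq_along(enhancers), function(i) {
    ch <- as.character(GenomicRanges::seqnames(enhancers))[i]
    lo <- IRanges::start(enhancers)[i]; hi <- IRanges::end(enhancers)[i]
    vals <- unlist(lapply(scored, function(tr) {
      if (tr$chrom != ch) return(numeric(0))
      iLo <- max(lo, tr$start); iHi <- min(hi, tr$start + length(tr$score) - 1L)
      if (iLo > iHi) return(numeric(0))
      tr$score[(iLo - tr$start + 1L):(iHi - tr$start + 1L)]
    }))
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
  enhMeans <- enhMeans[!is.na(enhMeans)]
  stopIfNot(length(enhMeans) > 0, "no enhancer overlaps any scored base")
  allScores <- unlist(lapply(scored, `[[`, "score"), use.names = FALSE)
  set.seed(seed)
  bg <- sample(allScores, nRandom, replace = nRandom > length(allScores))
  p <- if (length(unique(c(enhMeans, bg))) == 1L) {
    1   # fully tied samples carry no evidence either way
  } else {
    exact <- length(enhMeans) <= 10L && length(bg) <= 10L &&
      !anyDuplicated(c(enhMeans, bg))
    stats::wilcox.test(enhMeans, bg, alternative = "two.sided",
                       exact = exact, correct = FALSE)$p.value
  }
  list(p = p, medianEnhancer = stats::median(enhMeans),
       medianRandom = stats::median(bg), nEnhancer = length(enhMeans))
}

#' TF enrichment in high-LR regions
#'
#' For each PWM of the expressed TF panel, tests whether its hit centers
#' fall in high-LR bases (score > \code{threshold}) more often than the
#' genome-wide fraction of high-LR bases would predict, by a one-sided
#' binomial test.  Per TF the lowest p-value over its PWMs is reported, with
#' Benjamini-Hochberg correction across TFs.  TFs with zero hits get p = 1
#' and are flagged.
#'
#' @param lrTracks nested track list.
#' @param t transition index.
#' @param hits resolved GRanges of PWM hits (any number of TFs/motifs).
#' @param expr StageExpression (for the expressed-TF panel filter).
#' @param threshold high-LR cutoff (default 0.1).
#' @param exprMin minimum FPKM (in any modeled stage) for a TF to enter the
#'   panel (default 1).
#' @return data.frame(tf, motif, nHits, nHigh, p, padj, flag), one row per TF.
#' @export
tfEnrichmentHighLr <- function(lrTracks, t, hits, expr, threshold = 0.1,
                               exprMin = 1) {
  key <- paste0("t", t)
  scored <- lapply(lrTracks, function(g) g[[key]])
  scored <- scored[!vapply(scored, is.null, logical(1))]
  allScores <- unlist(lapply(scored, `[[`, "score"), use.names = FALSE)
  p0 <- mean(allScores > threshold)
  lookup <- function(chrom, pos) {
    for (tr in scored) {
      if (tr$chrom == chrom && pos >= tr$start &&
          pos <= tr$start + length(tr$score) - 1L)
        return(tr$score[pos - tr$start + 1L])
    }
    NA_real_
  }
  f <- fpkm(expr)
  mStages <- seq_len(ncol(f) - 1L)  # stages entering the model
  m <- S4Vectors::mcols(hits)
  panel <- intersect(unique(m$tf), rownames(f))
  panel <- panel[apply(f[panel, mStages, drop = FALSE] > exprMin, 1L, any)]
  rows <- lapply(panel, function(tf) {
    motifs <- unique(m$motif[m$tf == tf])
    per <- lapply(motifs, function(mo) {
      sel <- which(m$tf == tf & m$motif == mo)
      lr <- vapply(sel, function(i)
        lookup(as.character(GenomicRanges::seqnames(hits))[i], m$center[i]),
        numeric(1))
      lr <- lr[!is.na(lr)]
      n <- length(lr)
      if (n == 0L)
        return(data.frame(tf = tf, motif = mo, nHits = 0L, nHigh = 0L,
                          p = 1, flag = "no_hits"))
      k <- sum(lr > threshold)
      data.frame(tf = tf, motif = mo, nHits = n, nHigh = k,
                 p = stats::pbinom(k - 1L, n, p0, lower.tail = FALSE),
                 flag = "")
    })
    per <- do.call(rbind, per)
    per[which.min(per$p), , drop = FALSE]   # lowest p over the TF's PWMs
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
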