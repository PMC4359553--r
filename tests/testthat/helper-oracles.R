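## Independent oracles used by the solver and statistics tests.

## Brute-force both-strand window scoring of a sequence with a PWM,
## written independently of the package scanner: every window is scored by
## summing per-column log-odds over the window's bases (and over the
## reverse complement for the minus strand), then min-max scaled.
bruteForceScan <- function(pwm, seq, threshold) {
  bases <- strsplit(seq, "")[[1L]]
  L <- ncol(pwm@probs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scoreWindow <- function(win) {
    s <- 0
    for (l in seq_along(win)) {
      col <- pwm@logOdds[, l]
      s <- s + if (win[l] %in% names(comp)) col[win[l]] else min(col)
    }
    (s - pwm@rawMin) / (pwm@rawMax - pwm@rawMin)
  }
  out <- list()
  for (i in seq_len(length(bases) - L + 1L)) {
    win <- bases[i:(i + L - 1L)]
    fs <- scoreWindow(win)
    rs <- scoreWindow(rev(unname(comp[win])))
    if (!is.na(fs) && fs >= threshold - 1e-12)
      out[[length(out) + 1L]] <- data.frame(start = i, strand = "+",
                                            score = fs)
    if (!is.na(rs) && rs >= threshold - 1e-12)
      out[[length(out) + 1L]] <- data.frame(start = i, strand = "-",
                                            score = rs)
  }
  if (!length(out)) return(data.frame(start = integer(), strand = character(),
                                      score = numeric()))
  do.call(rbind, out)
}

## Pairwise Mann-Whitney AUC oracle: average over all pos x neg pairs.
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

## Generic QP solve of the per-gene generalized-lasso objective via
## kernlab's interior-point solver on the positive-part splitting
## u = u+ - u-, z = D u = z+ - z-.
ipopGeneSolve <- function(X, bindings, lambda1, lambda2) {
  nT <- length(bindings)
  K <- nrow(bindings[[1L]]@B)
  n <- K * nT
  blk <- function(t) ((t - 1L) * K + 1L):(t * K)
  M <- matrix(0, nT, n)
  for (t in seq_len(nT)) {
    B <- bindings[[t]]@B
    M[t, blk(t)] <- drop(B %*% X[colnames(B), t])
  }
  p <- ncol(bindings[[1L]]@B)
  D <- matrix(0, p * (nT - 1L), n)
  for (t in seq_len(nT - 1L)) {
    pr <- ((t - 1L) * p + 1L):(t * p)
    D[pr, blk(t)] <- t(bindings[[t]]@B)
    D[pr, blk(t + 1L)] <- -t(bindings[[t + 1L]]@B)
  }
  y <- vapply(seq_len(nT), function(t) X["g1", t + 1L], numeric(1))
  dD <- nrow(D)
  H11 <- 2 * crossprod(M)
  H <- rbind(cbind(H11, -H11), cbind(-H11, H11))
  nz <- 2L * dD
  Hfull <- matrix(0, 2L * n + nz, 2L * n + nz)
  Hfull[seq_len(2L * n), seq_len(2L * n)] <- H
  diag(Hfull) <- diag(Hfull) + 1e-8
  cc <- c(-2 * crossprod(M, y) + lambda1, 2 * crossprod(M, y) + lambda1,
          rep(lambda2, nz))
  A <- cbind(D, -D, -diag(dD), diag(dD))
  sol <- kernlab::ipop(cc, Hfull, A, rep(0, dD), rep(0, 2L * n + nz),
                       rep(10, 2L * n + nz), rep(0, dD), sigf = 7,
                       maxiter = 300, margin = 0.05)
  x <- kernlab::primal(sol)
  u <- x[seq_len(n)] - x[n + seq_len(n)]
  list(u = matrix(u, K, nT),
       objective = sum((y - drop(M %*% u))^2) + lambda1 * sum(abs(u)) +
         lambda2 * sum(abs(drop(D %*% u))),
       status = kernlab::how(sol))
}

## Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
## probabilities of all tables with the same margins whose probability does
## not exceed the observed one's.
enumFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; nTot <- a + b + c + d
  probOf <- function(x) stats::dhyper(x, c1, nTot - c1, r1)
  pObs <- probOf(a)
  xs <- max(0, r1 + c1 - nTot):min(r1, c1)
  sum(vapply(xs, probOf, numeric(1))[
    vapply(xs, probOf, numeric(1)) <= pObs * (1 + 1e-7)])
}
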