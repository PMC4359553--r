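#' Toy PWM panel with distinct consensus motifs
#'
#' Each motif is a near-deterministic count matrix (85 counts for the
#' consensus base, 5 for each alternative), informative enough that at the
#' default 0.9 scan threshold only exact consensus matches score above
#' threshold.
#'
#' @param tfs character vector of TF names (one motif per TF).
#' @param motifLen motif length (default 8).
#' @param seed RNG seed.
#' @return named list of \linkS4class{PwmModel}.
#' @export
makeToyPwms <- function(tfs, motifLen = 8L, seed = 1L) {
  set.seed(seed)
  seen <- character(0)
  pwms <- lapply(tfs, function(tf) {
    repeat {
      cons <- sample(1:4, motifLen, replace = TRUE)
      key <- paste(cons, collapse = "")
      if (!key %in% seen) { seen <<- c(seen, key); break }
    }
    counts <- matrix(5, 4, motifLen)
    counts[cbind(cons, seq_len(motifLen))] <- 85
    newPwm(counts, tf = tf, name = paste0(tf, ".m1"))
  })
  stats::setNames(pwms, vapply(pwms, function(p) p@tf, character(1)))
}

#' Generate a toy genome with gene annotations
#'
#' One chromosome of i.i.d. uniform nucleotides carrying \code{nGenes}
#' genes whose TSSs are spaced \code{regionLen} apart (plus a small gap),
#' so the nominal cis-regions of width \code{regionLen} are disjoint.
#' Genes alternate strand and carry a 2-exon structure with an internal
#' CDS.  Conservation tracks (with an availability mask), CpG islands near
#' TSSs and scattered repeats give the sequence features realistic
#' marginals.
#'
#' @param nGenes number of genes.
#' @param regionLen nominal cis-region width (and TSS spacing), nt.
#' @param seed RNG seed.
#' @param gc GC fraction of the background sequence (default 0.5).
#' @return list(genome = DNAStringSet, genes = GRanges, chromSizes,
#'   annTracks = \linkS4class{AnnotationTracks}).
#' @export
makeToyGenome <- function(nGenes = 20L, regionLen = 1000L, seed = 1L,
                          gc = 0.5) {
  stopIfNot(regionLen >= 50L, "regionLen must be >= 50")
  set.seed(seed)
  gap <- 10L
  chromLen <- as.integer(nGenes * (regionLen + gap) + regionLen)
  if (chromLen < nGenes * regionLen)
    stop("cis-regions cannot fit on the chromosome")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- paste(sample(BASES, chromLen, replace = TRUE, prob = probs),
               collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chrT"))
  tss <- as.integer(regionLen / 2 + (seq_len(nGenes) - 1L) * (regionLen + gap) +
                    regionLen / 4)
  strand <- rep(c("+", "-"), length.out = nGenes)
  geneLen <- as.integer(pmin(stats::runif(nGenes, 0.3, 0.5) * regionLen,
                             regionLen / 2))
  geneId <- sprintf("g%02d", seq_len(nGenes))
  txS <- ifelse(strand == "+", tss, tss - geneLen + 1L)
  txE <- ifelse(strand == "+", tss + geneLen - 1L, tss)
  exon1 <- as.integer(geneLen * 0.25); exon2 <- as.integer(geneLen * 0.3)
  exons <- IRanges::IRangesList(lapply(seq_len(nGenes), function(i)
    IRanges::IRanges(start = c(txS[i], txE[i] - exon2[i] + 1L),
                     end = c(txS[i] + exon1[i] - 1L, txE[i]))))
  genes <- GenomicRanges::GRanges("chrT", IRanges::IRanges(txS, txE),
                                  strand = strand)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    geneId = geneId, tss = as.integer(tss),
    cdsStart = as.integer(txS + exon1 %/% 2L),
    cdsEnd = as.integer(txE - exon2 %/% 2L), exons = exons)
  names(genes) <- geneId
  avail <- stats::runif(chromLen) < 0.9
  consV <- ifelse(avail, round(stats::rbeta(chromLen, 0.6, 2.5), 3), NA)
  avail2 <- stats::runif(chromLen) < 0.85
  consP <- ifelse(avail2, round(stats::rbeta(chromLen, 0.6, 2.5), 3), NA)
  cpg <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(pmax(1L, tss[stats::runif(nGenes) < 0.7] - 100L),
                     width = 200L))
  nRep <- max(1L, chromLen %/% 5000L)
  repStart <- sort(sample.int(chromLen - 200L, nRep))
  repeats <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(repStart, width = sample(80:200, nRep, replace = TRUE)))
  ann <- methods::new("AnnotationTracks",
                      phastVert = list(chrT = consV),
                      phastPlac = list(chrT = consP),
                      cpgIslands = IRanges::reduce(cpg),
                      repeats = IRanges::reduce(repeats))
  list(genome = genome, genes = genes,
       chromSizes = c(chrT = chromLen), annTracks = ann)
}

## Elevate conservation around positive binding sites (both tracks).
boostConservation <- function(annTracks, centers, halfWidth = 10L,
                              level = 0.85) {
  for (slot in c("phastVert", "phastPlac")) {
    v <- methods::slot(annTracks, slot)[["chrT"]]
    for (c0 in centers) {
      idx <- max(1L, c0 - halfWidth):min(length(v), c0 + halfWidth)
      v[idx] <- level
    }
    methods::slot(annTracks, slot)[["chrT"]] <- v
  }
  annTracks
}

#' Plant motif instances into a genome
#'
#' Writes consensus instances of the given PWMs into the sequence at random
#' positions (or at caller-chosen positions), respecting a minimum spacing;
#' a colliding random position is re-drawn up to 100 times.  A ChIP-like
#' peak (center +/- \code{peakPad}) is emitted around a \code{peakFraction}
#' of each TF's instances; those instances are the ground-truth positives,
#' the remainder stay unmarked (negatives).
#'
#' @param genome DNAStringSet (single chromosome).
#' @param regions cis-region GRanges (random positions are drawn within
#'   these, \code{pad} nt away from region edges).
#' @param pwms named list of PwmModel.
#' @param density per-slot planting probability in (0, 1): each (region,
#'   TF) pair plants Binomial(floor(width / minSpacing), density) instances.
#' @param peakFraction fraction of each TF's instances that get a peak.
#' @param minSpacing minimum distance between instance starts (default 100).
#' @param seed RNG seed.
#' @param positions optional data.frame(tf, pos, strand) of exact plants
#'   (overrides density; peakFraction still applies unless a
#'   \code{positive} column is supplied).
#' @param peakPad peak half-width around the instance (default 30).
#' @return list(genome = mutated DNAStringSet, truth = data.frame(tf, chrom,
#'   start, strand, positive), peaks = named list of peak GRanges).
#' @export
plantMotifInstances <- function(genome, regions, pwms, density = 0.2,
                                peakFraction = 0.7, minSpacing = 100L,
                                seed = 1L, positions = NULL, peakPad = 30L) {
  set.seed(seed)
  chrom <- names(genome)[1L]
  seqChars <- strsplit(as.character(genome[[1L]]), "")[[1L]]
  planted <- integer(0)
  rows <- list()
  plantOne <- function(tf, pos, strand) {
    cons <- pwmConsensus(pwms[[tf]])
    L <- nchar(cons)
    inst <- if (strand == "+") cons else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    seqChars[pos:(pos + L - 1L)] <<- strsplit(inst, "")[[1L]]
    planted <<- c(planted, pos)
    data.frame(tf = tf, chrom = chrom, start = pos, strand = strand,
               width = L)
  }
  if (is.null(positions)) {
    stopIfNot(density > 0 && density < 1, "density must be in (0, 1)")
    for (ri in seq_along(regions)) {
      lo <- IRanges::start(regions)[ri] + 20L
      hi <- IRanges::end(regions)[ri] - 40L
      for (tf in names(pwms)) {
        slots <- max(0L, (hi - lo) %/% minSpacing)
        nInst <- stats::rbinom(1L, slots, density)
        for (k in seq_len(nInst)) {
          for (try in seq_len(100L)) {
            pos <- sample(lo:hi, 1L)
            if (!length(planted) || min(abs(planted - pos)) >= minSpacing) {
              rows[[length(rows) + 1L]] <-
                plantOne(tf, pos, sample(c("+", "-"), 1L))
              break
            }
            if (try == 100L)
              stop("could not place a motif instance after 100 tries")
          }
        }
      }
    }
  } else {
    for (i in seq_len(nrow(positions)))
      rows[[length(rows) + 1L]] <- plantOne(positions$tf[i], positions$pos[i],
                                            positions$strand[i] %||% "+")
  }
  truth <- do.call(rbind, rows)
  if (!is.null(positions) && !is.null(positions$positive)) {
    truth$positive <- positions$positive
  } else {
    truth$positive <- FALSE
    for (tf in unique(truth$tf)) {
      idx <- which(truth$tf == tf)
      nPos <- round(peakFraction * length(idx))
      truth$positive[sample(idx, nPos)] <- TRUE
    }
  }
  genomeOut <- Biostrings::DNAStringSet(
    stats::setNames(paste(seqChars, collapse = ""), chrom))
  peaks <- lapply(stats::setNames(nm = names(pwms)), function(tf) {
    sel <- truth[truth$tf == tf & truth$positive, , drop = FALSE]
    gr <- if (nrow(sel))
      GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pmax(1L, sel$start - peakPad),
                         sel$start + sel$width - 1L + peakPad))
    else GenomicRanges::GRanges()
    newPeakSet(gr, tf = tf, cellType = "toy")
  })
  list(genome = genomeOut, truth = truth, peaks = peaks)
}

#' Simulate enhancer-like signal tracks around bound sites
#'
#' Active marks get a flat-topped bump (constant over +/- plateau, Gaussian
#' shoulders) centered on each positive site, minus a centered local dip
#' (Gaussian of sd \code{dipSd}, truncated at +/- 50 nt) whose relative
#' depth is \code{dipDepth} -- the binding-site signature.  Amplitudes vary
#' by stage; Poisson noise is added per bin unless \code{noise = FALSE}.
#'
#' @param chromSizes named chromosome lengths.
#' @param positiveCenters integer vector of bound-site center positions
#'   (single chromosome).
#' @param stages character vector of stage labels (>= 2).
#' @param seed RNG seed.
#' @param marks mark names (default the five modeled marks).
#' @param bumpAmp named numeric: bump amplitude per mark (0 = no bump).
#' @param background baseline intensity per bin.
#' @param plateau bump flat-top half-width, nt (default 500).
#' @param shoulderSd Gaussian shoulder sd beyond the plateau (default 150).
#' @param dipDepth relative dip depth in [0, 1) (default 0.6).
#' @param dipSd dip Gaussian sd, nt (default 20; truncated at +/- 50).
#' @param stageScale multiplicative amplitude per stage (default mildly
#'   increasing).
#' @param binSize bin width (default 10).
#' @param noise add Poisson noise (default TRUE).
#' @return nested list tracks[[mark]][[stage]] of raw SignalTracks.
#' @export
simulateSignalTracks <- function(chromSizes, positiveCenters, stages,
                                 seed = 1L, marks = FEATURE_MARKS,
                                 bumpAmp = c(H3K27ac = 8, H3K4me1 = 5,
                                             H3K4me3 = 0, H3K27me3 = 0,
                                             RNAP = 0),
                                 background = 1, plateau = 500L,
                                 shoulderSd = 150, dipDepth = 0.6,
                                 dipSd = 20, stageScale = NULL,
                                 binSize = 10L, noise = TRUE) {
  stopIfNot(length(stages) >= 2L, "need >= 2 stages")
  set.seed(seed)
  if (is.null(stageScale))
    stageScale <- stats::setNames(seq(1, 1.2, length.out = length(stages)),
                                  stages)
  chrom <- names(chromSizes)[1L]
  nb <- (chromSizes[[1L]] + binSize - 1L) %/% binSize
  binCenter <- (seq_len(nb) - 0.5) * binSize
  shape <- numeric(nb)   # unit bump-with-dip profile accumulated over sites
  for (c0 in positiveCenters) {
    d <- abs(binCenter - c0)
    idx <- which(d <= plateau + 4 * shoulderSd)
    bump <- ifelse(d[idx] <= plateau, 1,
                   exp(-(d[idx] - plateau)^2 / (2 * shoulderSd^2)))
    dip <- ifelse(d[idx] <= 50, dipDepth * exp(-d[idx]^2 / (2 * dipSd^2)), 0)
    shape[idx] <- shape[idx] + bump * (1 - dip)
  }
  out <- lapply(stats::setNames(nm = marks), function(mk) {
    amp <- if (mk %in% names(bumpAmp)) bumpAmp[[mk]] else 0
    lapply(stats::setNames(nm = stages), function(st) {
      lam <- background + amp * stageScale[[st]] * shape
      v <- if (noise) stats::rpois(nb, lam) else lam
      methods::new("SignalTrack", mark = mk, stage = st,
                   binSize = as.integer(binSize),
                   values = stats::setNames(list(as.numeric(v)), chrom),
                   transformed = FALSE)
    })
  })
  out
}

#' Simulate expression trajectories from a linear dynamical system
#'
#' Forward-simulates X^{t+1} = A X^t + eps with eps ~ N(0, sigma^2 I) on
#' the log(FPKM + 1) scale, recovering FPKM as exp(X) - 1 clipped at 0.
#'
#' @param A p x p transition matrix (time-invariant ground truth) or a list
#'   of T-1 matrices.
#' @param X1 initial expression vector (log scale), named by gene.
#' @param sigma noise standard deviation.
#' @param T number of stages.
#' @param seed RNG seed.
#' @param stages stage labels (default S1..ST).
#' @return a \linkS4class{StageExpression}.
#' @export
simulateExpressionDynamics <- function(A, X1, sigma, T, seed = 1L,
                                       stages = paste0("S", seq_len(T))) {
  stopIfNot(sigma >= 0 && T >= 2L, "need sigma >= 0 and T >= 2")
  set.seed(seed)
  Alist <- if (is.list(A)) A else rep(list(A), T - 1L)
  p <- length(X1)
  X <- matrix(0, p, T, dimnames = list(names(X1), stages))
  X[, 1L] <- X1
  for (t in seq_len(T - 1L)) {
    X[, t + 1L] <- drop(Alist[[t]] %*% X[, t]) + stats::rnorm(p, 0, sigma)
    if (max(abs(X[, t + 1L])) > 50)
      stop("expression trajectories diverge; rescale the spectral radius of A")
  }
  fpkmMat <- pmax(exp(X) - 1, 0)
  newStageExpression(fpkmMat)
}

#' Ground-truth perturbation matrix and experimental call table
#'
#' Simulates a \code{fold}-fold induction of every gene j through the true
#' network: gene i responds with A_ij * (log(fold * FPKM_j + 1) - X_j).
#' P_ij = 1 when |response| exceeds \code{threshold}; the call table
#' records the response directions.
#'
#' @param A true transition matrix (targets x regulators).
#' @param expr StageExpression.
#' @param fold induction fold (default 5).
#' @param threshold absolute response threshold for P (default 1e-8).
#' @param stage stage at which genes are induced (default 1).
#' @return list(P = binary matrix, calls = list per regulator of named
#'   direction vectors "up"/"down"/"none").
#' @export
makePerturbationTruth <- function(A, expr, fold = 5, threshold = 1e-8,
                                  stage = 1L) {
  X <- logExpr(expr); f <- fpkm(expr)
  genes <- rownames(A)
  P <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  calls <- list()
  for (j in genes) {
    delta <- A[, j] * (log(fold * f[j, stage] + 1) - X[j, stage])
    P[abs(delta) > threshold, j] <- 1L
    calls[[j]] <- stats::setNames(
      ifelse(delta > threshold, "up",
             ifelse(delta < -threshold, "down", "none")), genes)
  }
  list(P = P, calls = calls)
}

#' Complete synthetic dataset with a known dynamic regulatory network
#'
#' Generates a toy genome with \code{nGenes} genes, designates the first
#' \code{nTf} as transcription factors (each with a distinct 8-mer motif
#' and a self-loop), wires every other gene to 1-2 TF regulators with a
#' chosen positive weight, plants the regulators' consensus motifs at
#' ChIP-confirmed sites in the targets' cis-regions (plus unbound decoy
#' instances elsewhere, the negative training examples), simulates
#' enhancer-like signal bumps with binding-site dips around the bound
#' sites, and forward-simulates expression from the true time-invariant
#' network.  The true segment weights u* are chosen so that the designed
#' edge weights satisfy A* = u*' B* exactly, with B* built from the true
#' LR track (high at bound sites) and the true perturbation matrix.
#'
#' @param seed RNG seed (every output is a pure function of it).
#' @param nGenes,nTf gene and TF counts.
#' @param T number of stages.
#' @param sigma expression noise sd.
#' @param regionLen cis-region width, nt.
#' @param decoysPerGene unbound decoy instances per gene (default 2).
#' @param pPerturbObserved fraction of true edges with perturbation support
#'   (default 0.6; the rest exercise the pi = 0.25 path).
#' @param lrHigh,lrLow true LR score at/away from bound sites.
#' @return list with genome, genes, chromSizes, annTracks, regions, pwms,
#'   peaks, tracks (raw), expr, P, expCalls, truth (edges, sites, u, A,
#'   lrTracks), stages, config.
#' @export
simulateGrnDataset <- function(seed = 42L, nGenes = 20L, nTf = 5L, T = 4L,
                               sigma = 0.05, regionLen = 1000L,
                               decoysPerGene = 2L, pPerturbObserved = 0.6,
                               lrHigh = 0.8, lrLow = 0.02) {
  base <- makeToyGenome(nGenes, regionLen, seed = seed)
  stages <- paste0("S", seq_len(T))
  genes <- base$genes
  geneIds <- S4Vectors::mcols(genes)$geneId
  tfIds <- geneIds[seq_len(nTf)]
  regions <- assignCisRegions(genes, width = regionLen, base$chromSizes)
  pwms <- makeToyPwms(tfIds, motifLen = 8L, seed = seed + 1L)
  motifLen <- 8L
  set.seed(seed + 2L)
  ## --- true network design: self-loops for TFs, 1-2 TF regulators per gene
  edges <- list()
  for (i in seq_along(geneIds)) {
    g <- geneIds[i]
    ## TF self-loops stay near 1 so TFs remain abundantly expressed
    ## (above the FPKM filter) across all stages; two-regulator genes can
    ## carry one repressive (negative-weight) edge, keeping trajectories
    ## positive
    regs <- if (g %in% tfIds) g else
      sample(tfIds, sample(1:2, 1L))
    w <- if (g %in% tfIds) {
      stats::runif(1, 0.97, 1.03)
    } else if (length(regs) == 1L) {
      stats::runif(1, 0.7, 1.2)
    } else {
      c(stats::runif(1, 0.6, 0.9),
        stats::runif(1, 0.15, 0.3) * sample(c(1, -1), 1, prob = c(0.55, 0.45)))
    }
    edges[[i]] <- data.frame(regulator = regs, target = g, weight = w)
  }
  edges <- do.call(rbind, edges)
  ## --- site placement: one site per true edge, spaced >= 120 nt
  sites <- list()
  for (g in geneIds) {
    regs <- edges$regulator[edges$target == g]
    lo <- IRanges::start(regions)[match(g, geneIds)] + 30L
    hi <- IRanges::end(regions)[match(g, geneIds)] - 40L
    offs <- seq(lo, hi, by = 140L)
    pos <- sample(offs, length(regs))
    sites[[g]] <- data.frame(tf = regs, gene = g, pos = pos,
                             strand = sample(c("+", "-"), length(regs),
                                             replace = TRUE),
                             positive = TRUE)
  }
  sites <- do.call(rbind, sites)
  ## --- decoys: instances of non-regulators, no peak, away from true sites
  decoys <- list()
  for (g in geneIds) {
    lo <- IRanges::start(regions)[match(g, geneIds)] + 30L
    hi <- IRanges::end(regions)[match(g, geneIds)] - 40L
    trueHere <- sites$pos[sites$gene == g]
    cand <- setdiff(seq(lo + 70L, hi, by = 140L), trueHere)
    cand <- cand[vapply(cand, function(p) min(abs(p - trueHere)) >= 120L,
                        logical(1))]
    nd <- min(decoysPerGene, length(cand))
    if (nd > 0L) {
      nonRegs <- setdiff(tfIds, edges$regulator[edges$target == g])
      if (!length(nonRegs)) nonRegs <- tfIds
      decoys[[g]] <- data.frame(tf = sample(nonRegs, nd, replace = TRUE),
                                gene = g, pos = sample(cand, nd),
                                strand = "+", positive = FALSE)
    }
  }
  decoys <- do.call(rbind, decoys)
  plantDf <- rbind(sites, decoys)
  planted <- plantMotifInstances(base$genome, regions, pwms,
                                 seed = seed + 3L, positions = plantDf)
  annTracks <- boostConservation(base$annTracks,
                                 sites$pos + (motifLen - 1L) %/% 2L)
  tracks <- simulateSignalTracks(base$chromSizes,
                                 sites$pos + (motifLen - 1L) %/% 2L,
                                 stages, seed = seed + 4L)
  ## --- expression from the true network
  A <- matrix(0, nGenes, nGenes, dimnames = list(geneIds, geneIds))
  A[cbind(edges$target, edges$regulator)] <- edges$weight
  set.seed(seed + 5L)
  X1 <- stats::setNames(stats::runif(nGenes, 3.6, 4.6), geneIds)
  X1[tfIds] <- stats::runif(nTf, 4.2, 4.8)
  expr <- simulateExpressionDynamics(A, X1, sigma, T, seed = seed + 6L,
                                     stages = stages)
  ## --- perturbation truth; observed subset enters P
  pt <- makePerturbationTruth(A, expr, fold = 5)
  set.seed(seed + 7L)
  P <- pt$P
  onIdx <- which(P == 1L)
  hide <- sample(onIdx, round((1 - pPerturbObserved) * length(onIdx)))
  P[hide] <- 0L
  ## --- true LR tracks (time-invariant) and true segment weights
  config <- dbnConfig()
  lrTracks <- lapply(stats::setNames(nm = geneIds), function(g) {
    ri <- match(g, geneIds)
    startPos <- IRanges::start(regions)[ri]
    n <- IRanges::width(regions)[ri]
    score <- rep(lrLow, n)
    for (pcenter in sites$pos[sites$gene == g] + (motifLen - 1L) %/% 2L) {
      idx <- pmax(1L, pcenter - 25L - startPos + 1L):
        pmin(n, pcenter + 25L - startPos + 1L)
      score[idx] <- lrHigh
    }
    tr <- list(gene = g, chrom = "chrT", start = startPos, score = score)
    stats::setNames(rep(list(tr), T - 1L), paste0("t", seq_len(T - 1L)))
  })
  ## hits restricted to the planted instances (the scan recovers these)
  truthHits <- GenomicRanges::GRanges(planted$truth$chrom,
    IRanges::IRanges(planted$truth$start, width = planted$truth$width),
    strand = planted$truth$strand)
  S4Vectors::mcols(truthHits) <- S4Vectors::DataFrame(
    tf = planted$truth$tf,
    motif = paste0(planted$truth$tf, ".m1"), normScore = 1,
    center = as.integer(planted$truth$start + (motifLen - 1L) %/% 2L),
    label = ifelse(planted$truth$positive, "positive", "negative"),
    geneId = plantDf$gene)
  uStar <- list()
  for (g in geneIds) {
    ri <- match(g, geneIds)
    segs <- segmentCisRegion(regions[ri], config$segmentWidth,
                             config$segmentStep)
    bm <- suppressWarnings(buildBindingMatrix(g, 1L, lrTracks[[g]][["t1"]],
                             truthHits[S4Vectors::mcols(truthHits)$geneId == g &
                                       S4Vectors::mcols(truthHits)$label ==
                                         "positive"],
                             P, expr, regions[ri], tfIds, config))
    u <- matrix(0, length(segs), T - 1L)
    sg <- sites[sites$gene == g, , drop = FALSE]
    for (k in seq_len(nrow(sg))) {
      center <- sg$pos[k] + (motifLen - 1L) %/% 2L
      segIdx <- which(IRanges::start(segs) <= center &
                      IRanges::end(segs) >= center)
      segIdx <- segIdx[which.min(abs(IRanges::start(segs)[segIdx] +
                                     IRanges::end(segs)[segIdx] - 2 * center))]
      wgt <- edges$weight[edges$target == g & edges$regulator == sg$tf[k]]
      b <- bm@B[segIdx, sg$tf[k]]
      if (b > 0) u[segIdx, ] <- wgt / b
    }
    uStar[[g]] <- u
  }
  list(genome = planted$genome, genes = genes, chromSizes = base$chromSizes,
       annTracks = annTracks, regions = regions, pwms = pwms,
       peaks = planted$peaks, tracks = tracks, expr = expr, P = P,
       expCalls = pt$calls, stages = stages, config = config,
       truth = list(edges = edges, sites = sites, decoys = decoys,
                    u = uStar, A = A, lrTracks = lrTracks,
                    plantTruth = planted$truth))
}

#' Synthetic training benchmark for the occupancy model
#'
#' Plants \code{perRegion} motif instances of each of \code{nTf} TFs per
#' cis-region; a \code{peakFraction} of each TF's instances are
#' ChIP-confirmed positives that carry elevated conservation and an
#' enhancer-like H3K27ac bump with a local dip, while the rest stay
#' unbound negatives on background signal.  Returns the labeled,
#' overlap-resolved hits and the raw design matrix, ready for
#' leave-one-TF-out evaluation.
#'
#' @param seed RNG seed.
#' @param nGenes,regionLen,nTf,perRegion,peakFraction dataset shape.
#' @param scanThreshold PWM scan threshold (default 0.9).
#' @return list(table = raw FeatureTable, hits, ctx, regions, pwms, peaks,
#'   model inputs...).
#' @export
makeLrBenchmark <- function(seed = 42L, nGenes = 100L, regionLen = 2000L,
                            nTf = 5L, perRegion = 4L, peakFraction = 0.7,
                            scanThreshold = 0.9) {
  base <- makeToyGenome(nGenes, regionLen, seed = seed)
  geneIds <- S4Vectors::mcols(base$genes)$geneId
  regions <- assignCisRegions(base$genes, width = regionLen, base$chromSizes)
  tfs <- paste0("TF", LETTERS[seq_len(nTf)])
  pwms <- makeToyPwms(tfs, motifLen = 8L, seed = seed + 1L)
  ## deterministic slot layout, random TF assignment per slot
  set.seed(seed + 2L)
  plantDf <- do.call(rbind, lapply(seq_along(regions), function(ri) {
    lo <- IRanges::start(regions)[ri] + 40L
    hi <- IRanges::end(regions)[ri] - 60L
    nSlots <- nTf * perRegion
    spacing <- (hi - lo) %/% nSlots
    slots <- as.integer(lo + spacing * (seq_len(nSlots) - 1L))
    data.frame(tf = sample(rep_len(tfs, length(slots))),
               pos = slots, strand = sample(c("+", "-"), length(slots),
                                            replace = TRUE))
  }))
  planted <- plantMotifInstances(base$genome, regions, pwms,
                                 peakFraction = peakFraction,
                                 seed = seed + 3L, positions = plantDf)
  posCenters <- planted$truth$start[planted$truth$positive] + 3L
  annTracks <- boostConservation(base$annTracks, posCenters)
  stages <- c("S1", "S2")
  tracks <- simulateSignalTracks(base$chromSizes, posCenters, stages,
                                 seed = seed + 4L)
  tracksT <- lapply(tracks, function(byStage) lapply(byStage, asinhTransform))
  set.seed(seed + 5L)
  fpkmMat <- matrix(stats::rexp(nGenes * 2L, 1 / 20), nGenes, 2L,
                    dimnames = list(geneIds, stages))
  expr <- newStageExpression(fpkmMat)
  ctx <- prepareFeatureContext(planted$genome, base$genes, annTracks,
                               tracksT, expr, regions)
  hits <- scanRegions(pwms, planted$genome, regions, threshold = scanThreshold)
  hits <- resolveOverlappingHits(hits, by = "tf")
  hits <- assignHitsToGenes(hits, regions)
  hits <- labelAllHits(hits, planted$peaks)
  stageMap <- stats::setNames(rep(1L, nTf), tfs)
  table <- assembleDesignMatrix(hits, ctx, stageMap)
  list(table = table, hits = hits, ctx = ctx, regions = regions,
       pwms = pwms, peaks = planted$peaks, truth = planted$truth,
       expr = expr, stageMap = stageMap, annTracks = annTracks,
       genome = planted$genome, genes = base$genes,
       chromSizes = base$chromSizes, tracks = tracksT)
}

#' Scan all cis-regions with a PWM panel
#'
#' @param pwms named list of PwmModel.
#' @param genome DNAStringSet.
#' @param regions cis-region GRanges.
#' @param threshold scan threshold.
#' @return GRanges of hits across all regions and PWMs.
#' @export
scanRegions <- function(pwms, genome, regions, threshold = 0.9) {
  out <- list()
  for (ri in seq_along(regions)) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[ri]
    lo <- IRanges::start(regions)[ri]; hi <- IRanges::end(regions)[ri]
    seq <- Biostrings::subseq(genome[[chrom]], lo, hi)
    for (p in pwms) {
      h <- scanSequence(p, seq, threshold, chrom = chrom, shift = lo - 1L)
      if (length(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(scanSequence(pwms[[1L]], "", threshold))
  do.call(c, out)
}

#' Label hits per TF against a list of peak sets
#'
#' @param hits GRanges of hits (multiple TFs).
#' @param peaksList named list of peak GRanges (per TF, from
#'   \code{\link{newPeakSet}}); TFs without a peak set get all-negative
#'   labels.
#' @return labeled hits.
#' @export
labelAllHits <- function(hits, peaksList) {
  m <- S4Vectors::mcols(hits)
  for (tf in unique(m$tf)) {
    sel <- which(m$tf == tf)
    if (tf %in% names(peaksList)) {
      sub <- labelHitsWithPeaks(hits[sel], peaksList[[tf]])
      S4Vectors::mcols(hits)$label[sel] <- S4Vectors::mcols(sub)$label
    } else {
      S4Vectors::mcols(hits)$label[sel] <- "negative"
    }
  }
  hits
}
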