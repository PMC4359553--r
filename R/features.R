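FEATURE_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3", "RNAP")
FEATURE_WINDOWS <- c(1000L, 500L, 100L, 50L, 10L)

#' Names of the 69 occupancy-model features, in fixed column order
#'
#' Columns 1-15 are sequence/annotation features (conservation, CpG, TSS
#' distance, repeat, gene structure, GC content), 16-19 nearby-gene
#' expression features at stages t and t+1, and 20-69 signal features: for
#' each of the five marks, the mean asinh intensity in centered windows of
#' total width 1000/500/100/50/10 nt at stage t, followed by the five
#' t+1 minus t differences.
#'
#' @return character vector of length 69.
#' @export
featureNames <- function() {
  seqf <- c("phast_vert", "phast_plac", "phast_vert_zero", "phast_plac_zero",
            "phast_vert_avail", "phast_plac_avail", "cpg_island",
            "log_tss_dist", "repeat_element", "transcribed", "cds_span",
            "exon", "coding_exon", "intron", "gc_content")
  exprf <- c("expr_t", "expr_t1", "de_up", "de_down")
  sigf <- unlist(lapply(FEATURE_MARKS, function(mk)
    c(paste0(mk, "_t_w", FEATURE_WINDOWS),
      paste0(mk, "_d_w", FEATURE_WINDOWS))))
  c(seqf, exprf, sigf)
}

## Per-base boolean mask over a chromosome from a GRanges.
maskFromRanges <- function(gr, chrom, len) {
  m <- logical(len)
  sel <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(sel)) {
    lo <- max(1L, IRanges::start(sel)[i]); hi <- min(len, IRanges::end(sel)[i])
    if (lo <= hi) m[lo:hi] <- TRUE
  }
  m
}

#' Precompute everything the per-base feature functions need
#'
#' Builds per-chromosome cumulative sums (GC, signal bins), gene-structure
#' masks, conservation arrays and the DE-call table, so that features for
#' thousands of bases are computed by vectorized lookups.
#'
#' @param genome DNAStringSet.
#' @param genes GRanges from \code{\link{readGeneAnnotation}}.
#' @param annTracks \linkS4class{AnnotationTracks}.
#' @param tracks nested list \code{tracks[[mark]][[stage]]} of
#'   asinh-transformed \linkS4class{SignalTrack}s.
#' @param expr \linkS4class{StageExpression}.
#' @param regions cis-region GRanges from \code{\link{assignCisRegions}}.
#' @param deCalls optional gene x transition character matrix with values
#'   "up"/"down"/"none"; defaults to \code{\link{defaultDeCalls}(expr)}.
#' @return an opaque context list for \code{\link{featureMatrix}}.
#' @export
prepareFeatureContext <- function(genome, genes, annTracks, tracks, expr,
                                  regions, deCalls = NULL) {
  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  names(lens) <- chroms
  gcCum <- lapply(chroms, function(ch) {
    v <- strsplit(as.character(genome[[ch]]), "")[[1L]] %in% c("G", "C", "g", "c")
    c(0, cumsum(v))
  })
  names(gcCum) <- chroms
  m <- S4Vectors::mcols(genes)
  geneChrom <- as.character(GenomicRanges::seqnames(genes))
  tssSorted <- lapply(chroms, function(ch) sort(m$tss[geneChrom == ch]))
  names(tssSorted) <- chroms
  exonGr <- GenomicRanges::GRanges(rep(geneChrom, lengths(m$exons)),
                                   unlist(m$exons))
  cdsIdx <- which(!is.na(m$cdsStart))
  cdsGr <- GenomicRanges::GRanges(geneChrom[cdsIdx],
             IRanges::IRanges(m$cdsStart[cdsIdx], m$cdsEnd[cdsIdx]))
  masks <- lapply(chroms, function(ch) list(
    transcribed = maskFromRanges(granges(genes), ch, lens[[ch]]),
    cds = maskFromRanges(cdsGr, ch, lens[[ch]]),
    exon = maskFromRanges(exonGr, ch, lens[[ch]]),
    cpg = maskFromRanges(annTracks@cpgIslands, ch, lens[[ch]]),
    rpt = maskFromRanges(annTracks@repeats, ch, lens[[ch]])))
  names(masks) <- chroms
  ## mark/stage bin cumsums
  for (mk in names(tracks)) for (st in names(tracks[[mk]])) {
    tr <- tracks[[mk]][[st]]
    stopIfNot(tr@transformed, "signal tracks must be asinh-transformed ",
              "before feature extraction (", mk, " @ ", st, ")")
  }
  sigCum <- lapply(tracks, function(byStage) lapply(byStage, function(tr)
    lapply(tr@values, function(v) c(0, cumsum(v)))))
  binSize <- tracks[[1L]][[1L]]@binSize
  if (is.null(deCalls)) deCalls <- defaultDeCalls(expr)
  regIdx <- match(S4Vectors::mcols(regions)$geneId, S4Vectors::mcols(regions)$geneId)
  list(chromLens = lens, gcCum = gcCum, tssSorted = tssSorted, masks = masks,
       cons = list(vert = annTracks@phastVert, plac = annTracks@phastPlac),
       sigCum = sigCum, binSize = binSize, expr = expr, deCalls = deCalls,
       stages = stageLabels(expr),
       regions = regions,
       regionByGene = stats::setNames(seq_along(regions),
                                      S4Vectors::mcols(regions)$geneId))
}

#' Default differential-expression caller for the up/down features
#'
#' A gene is called up between stages t and t+1 when (FPKM_{t+1} + 1) is at
#' least \code{fold} times (FPKM_t + 1) and the absolute FPKM change is at
#' least \code{minDelta}; down symmetrically.  Up and down are mutually
#' exclusive by construction.
#'
#' @param expr StageExpression.
#' @param fold fold-change threshold on FPKM + 1 (default 2).
#' @param minDelta minimum absolute FPKM change (default 1).
#' @return gene x transition character matrix ("up"/"down"/"none").
#' @export
defaultDeCalls <- function(expr, fold = 2, minDelta = 1) {
  f <- fpkm(expr)
  nt <- ncol(f) - 1L
  out <- matrix("none", nrow(f), nt,
                dimnames = list(rownames(f), paste0("t", seq_len(nt))))
  for (t in seq_len(nt)) {
    up <- (f[, t + 1L] + 1) >= fold * (f[, t] + 1) &
      (f[, t + 1L] - f[, t]) >= minDelta
    dn <- (f[, t] + 1) >= fold * (f[, t + 1L] + 1) &
      (f[, t] - f[, t + 1L]) >= minDelta
    out[up, t] <- "up"; out[dn, t] <- "down"
  }
  out
}

#' Sequence and annotation features (columns 1-15)
#'
#' @param ctx context from \code{\link{prepareFeatureContext}}.
#' @param chrom chromosome name.
#' @param pos integer vector of 1-based positions.
#' @return n x 15 matrix.
#' @export
sequenceFeatures <- function(ctx, chrom, pos) {
  len <- ctx$chromLens[[chrom]]
  stopIfNot(all(pos >= 1L & pos <= len), "position outside the genome")
  cv <- ctx$cons$vert[[chrom]][pos]
  cp <- ctx$cons$plac[[chrom]][pos]
  availV <- !is.na(cv); availP <- !is.na(cp)
  msk <- ctx$masks[[chrom]]
  tss <- ctx$tssSorted[[chrom]]
  ins <- findInterval(pos, tss)
  dLeft <- ifelse(ins >= 1L, pos - tss[pmax(ins, 1L)], Inf)
  dRight <- ifelse(ins < length(tss), tss[pmin(ins + 1L, length(tss))] - pos, Inf)
  dist <- pmin(dLeft, dRight)
  lo <- pmax(1L, pos - 50L); hi <- pmin(len, pos + 50L)
  gc <- (ctx$gcCum[[chrom]][hi + 1L] - ctx$gcCum[[chrom]][lo]) / (hi - lo + 1L)
  cbind(ifelse(availV, cv, 0), ifelse(availP, cp, 0),
        as.numeric(availV & cv == 0 & !is.na(cv)),
        as.numeric(availP & cp == 0 & !is.na(cp)),
        as.numeric(availV), as.numeric(availP),
        as.numeric(msk$cpg[pos]), log(dist + 5),
        as.numeric(msk$rpt[pos]), as.numeric(msk$transcribed[pos]),
        as.numeric(msk$cds[pos]), as.numeric(msk$exon[pos]),
        as.numeric(msk$exon[pos] & msk$cds[pos]),
        as.numeric(msk$transcribed[pos] & !msk$exon[pos]), gc)
}

#' Nearby-gene expression features (columns 16-19)
#'
#' @param ctx feature context.
#' @param ownerGene character vector of owner gene ids (one per base).
#' @param t transition index (stage pair t, t+1).
#' @return n x 4 matrix.
#' @export
expressionFeatures <- function(ctx, ownerGene, t) {
  f <- fpkm(ctx$expr)
  stopIfNot(t >= 1L && t + 1L <= ncol(f), "transition index out of range")
  stopIfNot(all(ownerGene %in% rownames(f)),
            "owner gene absent from the expression matrix")
  calls <- ctx$deCalls[ownerGene, t]
  cbind(log(f[ownerGene, t] + 1), log(f[ownerGene, t + 1L] + 1),
        as.numeric(calls == "up"), as.numeric(calls == "down"))
}

#' Signal window features (columns 20-69)
#'
#' Mean asinh-transformed intensity in centered windows of total width w
#' (the window covers [pos - w/2, pos + w/2)), for each mark at stage t,
#' plus the t+1 minus t difference per window.  Windows are clipped at the
#' owner gene's cis-region and at chromosome ends, averaging over the
#' remaining bins.
#'
#' @param ctx feature context.
#' @param chrom chromosome.
#' @param pos integer positions (1-based).
#' @param ownerGene owner gene id per position (for region clipping).
#' @param t transition index.
#' @return n x 50 matrix.
#' @export
signalWindowFeatures <- function(ctx, chrom, pos, ownerGene, t) {
  bs <- ctx$binSize
  stages <- ctx$stages
  stopIfNot(t >= 1L && t + 1L <= length(stages), "transition index out of range")
  st0 <- stages[t]; st1 <- stages[t + 1L]
  nb <- (ctx$chromLens[[chrom]] + bs - 1L) %/% bs
  ri <- ctx$regionByGene[ownerGene]
  regS <- IRanges::start(ctx$regions)[ri]; regE <- IRanges::end(ctx$regions)[ri]
  out <- matrix(0, length(pos), 50L)
  j <- 0L
  for (mk in FEATURE_MARKS) {
    byStage <- ctx$sigCum[[mk]]
    if (is.null(byStage) || is.null(byStage[[st0]]) || is.null(byStage[[st1]]))
      stop("signal track missing for mark ", mk, " at stage ", st0, " or ", st1)
    c0 <- byStage[[st0]][[chrom]]; c1 <- byStage[[st1]][[chrom]]
    means <- matrix(0, length(pos), 10L)
    for (wi in seq_along(FEATURE_WINDOWS)) {
      w <- FEATURE_WINDOWS[wi]
      lo <- pmax(pmax(1L, regS), pos - w %/% 2L)
      hi <- pmin(pmin(ctx$chromLens[[chrom]], regE), pos + w %/% 2L - 1L)
      b1 <- pmax(1L, binOf(lo, bs)); b2 <- pmin(nb, binOf(hi, bs))
      means[, wi] <- rangeMean(c0, b1, b2)
      means[, wi + 5L] <- rangeMean(c1, b1, b2) - means[, wi]
    }
    out[, j + (1:10)] <- means
    j <- j + 10L
  }
  out
}

#' Full 69-column feature matrix for a set of bases
#'
#' @param ctx feature context.
#' @param chrom chromosome.
#' @param pos integer positions.
#' @param ownerGene owner gene per position.
#' @param t transition index.
#' @return n x 69 matrix with \code{\link{featureNames}} columns.
#' @export
featureMatrix <- function(ctx, chrom, pos, ownerGene, t) {
  out <- cbind(sequenceFeatures(ctx, chrom, pos),
               expressionFeatures(ctx, ownerGene, t),
               signalWindowFeatures(ctx, chrom, pos, ownerGene, t))
  colnames(out) <- featureNames()
  rownames(out) <- NULL
  out
}

#' Assign hit centers to their owner genes
#'
#' A hit belongs to the gene whose ownership interval contains the hit's
#' center base; hits whose center falls outside every ownership interval are
#' dropped.
#'
#' @param hits GRanges of hits.
#' @param regions cis-region GRanges from \code{\link{assignCisRegions}}.
#' @return hits with a \code{geneId} metadata column.
#' @export
assignHitsToGenes <- function(hits, regions) {
  if (!length(hits)) return(hits)
  owned <- S4Vectors::mcols(regions)$owned
  ownGr <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(regions)), lengths(owned)),
    unlist(owned))
  ownGene <- rep(S4Vectors::mcols(regions)$geneId, lengths(owned))
  centers <- GenomicRanges::GRanges(GenomicRanges::seqnames(hits),
               IRanges::IRanges(S4Vectors::mcols(hits)$center, width = 1L))
  ov <- GenomicRanges::findOverlaps(centers, ownGr, ignore.strand = TRUE)
  gid <- rep(NA_character_, length(hits))
  gid[S4Vectors::queryHits(ov)] <- ownGene[S4Vectors::subjectHits(ov)]
  S4Vectors::mcols(hits)$geneId <- gid
  hits[!is.na(gid)]
}

#' Assemble the training design matrix from labeled hits
#'
#' One row per surviving hit center; the response is 1 for
#' positive-labeled hits.  Each TF's rows use the stage transition assigned
#' to it by \code{stageMap} (the stage pair its ChIP data belongs to).
#'
#' @param hits labeled, overlap-resolved GRanges with \code{geneId}.
#' @param ctx feature context.
#' @param stageMap named integer vector: TF -> transition index t.
#' @return a raw (unstandardized) \linkS4class{FeatureTable}.
#' @export
assembleDesignMatrix <- function(hits, ctx, stageMap) {
  stopIfNot(length(hits) > 0, "no hits to assemble")
  m <- S4Vectors::mcols(hits)
  stopIfNot(!any(m$label == "unlabeled"), "all hits must be labeled first")
  unmapped <- setdiff(unique(m$tf), names(stageMap))
  if (length(unmapped))
    stop("no stage transition mapped for TF(s): ",
         paste(unmapped, collapse = ", "))
  chroms <- as.character(GenomicRanges::seqnames(hits))
  tvec <- stageMap[m$tf]
  feats <- matrix(NA_real_, length(hits), 69L)
  for (grp in split(seq_along(hits), paste(chroms, tvec))) {
    i <- grp[1L]
    feats[grp, ] <- featureMatrix(ctx, chroms[i], m$center[grp],
                                  m$geneId[grp], tvec[i])
  }
  colnames(feats) <- featureNames()
  stages <- ctx$stages
  meta <- S4Vectors::DataFrame(
    gene = m$geneId, tf = m$tf, chrom = chroms, pos = m$center,
    stagePair = paste0(stages[tvec], "->", stages[tvec + 1L]))
  methods::new("FeatureTable", features = feats,
               response = as.integer(m$label == "positive"),
               meta = meta, scaler = list())
}

#' Z-score the feature columns of a table
#'
#' Columns are centered and scaled to unit sample standard deviation
#' (denominator n - 1); constant columns are set to zero, flagged, and a
#' warning is issued.  The scaler is stored on the table for reuse on
#' prediction-time features via \code{\link{applyScaler}}.
#'
#' @param table raw FeatureTable (>= 2 rows).
#' @return standardized FeatureTable with a recorded scaler.
#' @export
standardizeFeatures <- function(table) {
  stopIfNot(nrow(table@features) >= 2L, "need >= 2 rows to standardize")
  stopIfNot(!length(table@scaler), "table is already standardized")
  ctr <- colMeans(table@features)
  sds <- apply(table@features, 2L, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant))
    warning("constant feature column(s) set to zero: ",
            paste(colnames(table@features)[constant], collapse = ", "))
  scaler <- list(center = ctr, scale = ifelse(constant, 1, sds),
                 constant = constant)
  methods::initialize(table,
    features = applyScaler(table@features, scaler), scaler = scaler)
}

#' Apply a stored feature scaler to a raw feature matrix
#' @param features n x 69 raw matrix.
#' @param scaler scaler list from \code{\link{standardizeFeatures}}.
#' @return standardized matrix (constant training columns forced to 0).
#' @export
applyScaler <- function(features, scaler) {
  out <- sweep(sweep(features, 2L, scaler$center), 2L, scaler$scale, "/")
  out[, scaler$constant] <- 0
  out
}

#' Persist a FeatureTable as TSV plus a JSON sidecar for the scaler
#' @param table FeatureTable.
#' @param tsvPath TSV output path.
#' @param jsonPath sidecar path (default: tsvPath with .json appended).
#' @export
writeFeatureTable <- function(table, tsvPath, jsonPath = paste0(tsvPath, ".json")) {
  df <- cbind(as.data.frame(table@meta), response = table@response,
              as.data.frame(table@features))
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(columns = featureNames(),
                            scaler = lapply(table@scaler, as.list)),
                       jsonPath, digits = NA, auto_unbox = TRUE)
  invisible(tsvPath)
}

#' Read a FeatureTable written by \code{\link{writeFeatureTable}}
#' @param tsvPath TSV path.
#' @param jsonPath sidecar path.
#' @return FeatureTable.
#' @export
readFeatureTable <- function(tsvPath, jsonPath = paste0(tsvPath, ".json")) {
  df <- utils::read.table(tsvPath, header = TRUE, sep = "\t", check.names = FALSE)
  side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  feats <- as.matrix(df[, side$columns, drop = FALSE])
  scaler <- side$scaler
  if (length(scaler)) scaler <- lapply(scaler, unlist)
  meta <- S4Vectors::DataFrame(df[, setdiff(colnames(df),
                                            c(side$columns, "response")),
                                  drop = FALSE])
  methods::new("FeatureTable", features = feats,
               response = as.integer(df$response), meta = meta,
               scaler = if (length(scaler)) scaler else list())
}
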