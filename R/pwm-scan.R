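## Sequence -> integer codes (A=1, C=2, G=3, T=4, anything else NA).
seqCodes <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet"))
    seq <- as.character(seq)
  match(strsplit(toupper(seq), "")[[1L]], BASES)
}

## Raw log-odds window scores at every start position of `codes` for the
## score matrix `lo` (4 x L).  N/unknown bases contribute the column minimum.
rawWindowScores <- function(codes, lo) {
  L <- ncol(lo); n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  idx <- ifelse(is.na(codes), 5L, codes)
  for (l in seq_len(L)) {
    lut <- c(lo[, l], min(lo[, l]))
    sc <- sc + lut[idx[l:(l + nw - 1L)]]
  }
  sc
}

#' Min-max normalized PWM score of L-mers
#'
#' The raw score (sum of per-column log2-odds) is rescaled by the best and
#' worst attainable raw scores: norm = (raw - rawMin) / (rawMax - rawMin),
#' so the consensus scores 1 and the anti-consensus 0.  N bases contribute
#' the column-minimum log-odds (conservative).
#'
#' @param pwm PwmModel.
#' @param seqs character vector of L-mers (or a single DNAString).
#' @return numeric vector of normalized scores in [0, 1].
#' @export
pwmNormalizedScore <- function(pwm, seqs) {
  if (methods::is(seqs, "DNAString")) seqs <- as.character(seqs)
  L <- ncol(pwm@probs)
  vapply(seqs, function(s) {
    codes <- seqCodes(s)
    stopIfNot(length(codes) == L, "sequence length must equal motif length")
    raw <- rawWindowScores(codes, pwm@logOdds)
    (raw - pwm@rawMin) / (pwm@rawMax - pwm@rawMin)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of length L is scored on the forward strand and on its
#' reverse complement (reported at the forward-strand coordinates); windows
#' with min-max normalized score >= \code{threshold} become hits.  The
#' center base of a hit is \code{start + floor((L - 1) / 2)}.
#'
#' @param pwm PwmModel.
#' @param seq character or DNAString; the (sub)sequence to scan.
#' @param threshold scan threshold in (0, 1] (default 0.90).
#' @param chrom chromosome name for the returned ranges.
#' @param shift genomic position of the first base of \code{seq} minus one,
#'   so returned coordinates are genomic.
#' @return GRanges of hits with metadata \code{tf}, \code{motif},
#'   \code{normScore}, \code{center}, \code{label} (initialized "unlabeled").
#' @export
scanSequence <- function(pwm, seq, threshold = 0.90, chrom = "seq", shift = 0L) {
  stopIfNot(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  codes <- seqCodes(seq)
  L <- ncol(pwm@probs)
  span <- pwm@rawMax - pwm@rawMin
  fwd <- (rawWindowScores(codes, pwm@logOdds) - pwm@rawMin) / span
  rcLo <- pwm@logOdds[4:1, ncol(pwm@logOdds):1, drop = FALSE]
  rev <- (rawWindowScores(codes, rcLo) - pwm@rawMin) / span
  mkHits <- function(scores, strand) {
    i <- which(scores >= threshold - 1e-12)
    if (!length(i)) return(NULL)
    data.frame(start = i, score = scores[i], strand = strand)
  }
  hits <- rbind(mkHits(fwd, "+"), mkHits(rev, "-"))
  if (is.null(hits) || nrow(hits) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(tf = character(),
      motif = character(), normScore = numeric(), center = integer(),
      label = character())
    return(gr)
  }
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(hits$start + shift, width = L),
          strand = hits$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tf = pwm@tf, motif = pwm@name, normScore = hits$score,
    center = as.integer(hits$start + shift + (L - 1L) %/% 2L),
    label = "unlabeled")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Greedy overlap resolution among PWM hits
#'
#' Among any cluster of mutually overlapping hits the highest-scoring hit
#' survives; resolution is greedy by descending score with ties going to the
#' 5'-most (smallest start) hit.  Grouping "tf" resolves within each TF's
#' hits independently; "all" resolves jointly across TFs.
#'
#' @param hits GRanges from \code{\link{scanSequence}}.
#' @param by "tf" (default) or "all".
#' @return GRanges of retained, pairwise non-overlapping hits.
#' @export
resolveOverlappingHits <- function(hits, by = c("tf", "all")) {
  by <- match.arg(by)
  if (length(hits) <= 1L) return(hits)
  groups <- if (by == "tf") {
    split(seq_along(hits), S4Vectors::mcols(hits)$tf)
  } else list(seq_along(hits))
  keepAll <- logical(length(hits))
  for (g in groups) {
    sub <- hits[g]
    ord <- order(-S4Vectors::mcols(sub)$normScore, IRanges::start(sub),
                 as.character(GenomicRanges::seqnames(sub)))
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) ||
          !any(IRanges::overlapsAny(sub[i], sub[kept], ignore.strand = TRUE)))
        kept <- c(kept, i)
    }
    keepAll[g[kept]] <- TRUE
  }
  GenomicRanges::sort(hits[keepAll], ignore.strand = TRUE)
}

#' Construct a ChIP peak set
#' @param gr GRanges of peak intervals.
#' @param tf transcription factor name.
#' @param cellType cell type label.
#' @return GRanges with \code{tf}/\code{cellType} in metadata().
#' @export
newPeakSet <- function(gr, tf, cellType = NA_character_) {
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$tf <- tf
  S4Vectors::metadata(gr)$cellType <- cellType
  gr
}

#' Label PWM hits by ChIP-peak overlap
#'
#' A hit is labeled positive when its interval overlaps at least one base of
#' a ChIP peak of the same TF (half-open abutment does not count), negative
#' otherwise.  The peak set's TF must match every hit's TF.
#'
#' @param hits GRanges of hits for one TF.
#' @param peaks peak GRanges from \code{\link{newPeakSet}}.
#' @return hits with the \code{label} column set.
#' @export
labelHitsWithPeaks <- function(hits, peaks) {
  tf <- S4Vectors::metadata(peaks)$tf
  if (length(hits)) {
    stopIfNot(all(S4Vectors::mcols(hits)$tf == tf),
              "peak set TF does not match the hits' TF")
    pos <- IRanges::overlapsAny(hits, peaks, ignore.strand = TRUE)
    S4Vectors::mcols(hits)$label <- ifelse(pos, "positive", "negative")
  }
  hits
}

#' Export hits as BED6 (and optionally a TSV with center and label)
#' @param hits GRanges of hits.
#' @param bedPath BED6 output path.
#' @param tsvPath optional TSV output path.
#' @export
exportHits <- function(hits, bedPath, tsvPath = NULL) {
  m <- S4Vectors::mcols(hits)
  con <- openOut(bedPath)
  writeLines(paste(as.character(GenomicRanges::seqnames(hits)),
                   IRanges::start(hits) - 1L, IRanges::end(hits),
                   paste0(m$tf, ":", m$motif),
                   round(m$normScore * 1000),
                   as.character(GenomicRanges::strand(hits)), sep = "\t"), con)
  close(con)
  if (!is.null(tsvPath)) {
    con <- openOut(tsvPath)
    writeLines(c("chrom\tstart0\tend\ttf\tmotif\tstrand\tnormScore\tcenter\tlabel\tgeneId",
      paste(as.character(GenomicRanges::seqnames(hits)),
            IRanges::start(hits) - 1L, IRanges::end(hits), m$tf, m$motif,
            as.character(GenomicRanges::strand(hits)),
            format(m$normScore, digits = 10), m$center, m$label,
            if (!is.null(m$geneId)) m$geneId else NA, sep = "\t")), con)
    close(con)
  }
  invisible(bedPath)
}

#' Read hits back from the TSV written by exportHits
#' @param path TSV path.
#' @return GRanges of hits.
#' @export
readHitsTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "")
  gr <- GenomicRanges::GRanges(tab$chrom,
          IRanges::IRanges(tab$start0 + 1L, tab$end), strand = tab$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tf = as.character(tab$tf), motif = as.character(tab$motif),
    normScore = tab$normScore, center = as.integer(tab$center),
    label = as.character(tab$label))
  if (!all(is.na(tab$geneId))) S4Vectors::mcols(gr)$geneId <- as.character(tab$geneId)
  gr
}
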