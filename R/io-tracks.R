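#' Read a bedGraph signal track onto a fixed bin grid
#'
#' Records that do not align to the bin grid are re-binned by
#' coverage-weighted mean: each bin's value is the per-base average of the
#' record values over the bin, with uncovered bases contributing 0.
#' The result is a dense per-bin vector for every chromosome in
#' \code{chromSizes}.
#'
#' @param path bedGraph file (plain or gzipped).
#' @param mark,stage labels stored on the track.
#' @param chromSizes named integer vector of chromosome lengths.
#' @param binSize bin width in nt (default 10).
#' @return a \linkS4class{SignalTrack} (raw, untransformed).
#' @export
readSignalTrack <- function(path, mark, stage, chromSizes, binSize = 10L) {
  binSize <- as.integer(binSize)
  values <- lapply(chromSizes, function(sz) numeric((sz + binSize - 1L) %/% binSize))
  p <- readFields(path, 0L, "bedGraph record")
  if (length(p$fields)) {
    p <- readFields(path, 4L, "bedGraph record")
    f <- p$fields; ln <- p$lines
    col <- function(i) vapply(f, `[[`, character(1), i)
    chrom <- col(1)
    start0 <- asInt(col(2), path, ln, "bedGraph record")
    end0 <- asInt(col(3), path, ln, "bedGraph record")
    val <- asNum(col(4), path, ln, "bedGraph record")
    if (any(val < 0))
      stop(sprintf("negative signal value at line %d of %s",
                   ln[val < 0][1L], basename(path)))
    if (any(start0 >= end0))
      stop(sprintf("empty interval at line %d of %s",
                   ln[start0 >= end0][1L], basename(path)))
    stopIfNot(all(chrom %in% names(chromSizes)),
              "bedGraph chromosome absent from chromSizes")
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      recs <- IRanges::IRanges(start0[sel] + 1L, end0[sel])
      nb <- length(values[[ch]])
      bins <- IRanges::IRanges(start = (seq_len(nb) - 1L) * binSize + 1L,
                               width = binSize)
      ov <- IRanges::findOverlaps(recs, bins)
      wid <- IRanges::width(IRanges::pintersect(
        recs[S4Vectors::queryHits(ov)], bins[S4Vectors::subjectHits(ov)]))
      contrib <- wid * val[sel][S4Vectors::queryHits(ov)]
      acc <- numeric(nb)
      agg <- tapply(contrib, S4Vectors::subjectHits(ov), sum)
      acc[as.integer(names(agg))] <- agg
      ## last bin may be truncated by the chromosome end
      binBases <- pmin(seq_len(nb) * binSize, chromSizes[[ch]]) -
        (seq_len(nb) - 1L) * binSize
      values[[ch]] <- acc / binBases
    }
  }
  methods::new("SignalTrack", mark = mark, stage = stage, binSize = binSize,
               values = values, transformed = FALSE)
}

#' Write a signal track as bedGraph (one record per non-zero bin)
#' @param track SignalTrack.
#' @param path output path.
#' @export
writeSignalTrack <- function(track, path) {
  con <- openOut(path); on.exit(close(con))
  bs <- track@binSize
  for (ch in names(track@values)) {
    v <- track@values[[ch]]
    nz <- which(v != 0)
    if (length(nz))
      writeLines(paste(ch, (nz - 1L) * bs, nz * bs, format(v[nz], digits = 10),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Inverse-hyperbolic-sine transform of a raw signal track
#'
#' Applies asinh to damp the influence of very high tag counts while
#' preserving the ordering of any two bins.  Transforming twice is an error.
#'
#' @param track raw SignalTrack.
#' @return transformed SignalTrack.
#' @export
asinhTransform <- function(track) {
  stopIfNot(methods::is(track, "SignalTrack"), "track must be a SignalTrack")
  if (track@transformed) stop("track is already asinh-transformed")
  methods::initialize(track, values = lapply(track@values, asinh),
                      transformed = TRUE)
}
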