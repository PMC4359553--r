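#' Read gene annotations (BED12 or minimal TSV)
#'
#' Parses gene models into a \code{GRanges} of transcript spans with metadata
#' columns \code{geneId}, \code{tss} (1-based position of the transcription
#' start site: the transcript start on the plus strand, the transcript end on
#' the minus strand), \code{cdsStart}/\code{cdsEnd} (1-based closed, NA when
#' the record has no coding span) and \code{exons} (an \code{IRangesList} of
#' 1-based closed exon intervals).
#'
#' The TSV format is a tab-delimited table with header
#' \code{gene_id chrom strand txStart txEnd cdsStart cdsEnd exonStarts exonEnds},
#' all coordinates 0-based half-open as in BED, exon columns comma-separated,
#' and \code{.} for an absent CDS.
#'
#' @param path file path (plain or gzipped).
#' @param format "bed12" or "tsv".
#' @return GRanges of transcript spans, one per gene.
#' @export
readGeneAnnotation <- function(path, format = c("bed12", "tsv")) {
  format <- match.arg(format)
  if (format == "bed12") readBed12(path) else readGeneTsv(path)
}

parseStrand <- function(s, path, lines) {
  bad <- !(s %in% c("+", "-"))
  if (any(bad))
    stop(sprintf("unknown strand '%s' at line %d of %s",
                 s[bad][1L], lines[bad][1L], basename(path)))
  s
}

buildGenes <- function(chrom, start0, end0, geneId, strand, cdsStart0, cdsEnd0,
                       exonStarts0, exonEnds0, path, lines) {
  if (any(start0 >= end0))
    stop(sprintf("empty transcript span at line %d of %s",
                 lines[start0 >= end0][1L], basename(path)))
  tss <- ifelse(strand == "+", start0 + 1L, end0)
  exons <- IRanges::IRangesList(mapply(function(s, e) {
    IRanges::IRanges(start = s + 1L, end = e)
  }, exonStarts0, exonEnds0, SIMPLIFY = FALSE))
  hasCds <- !is.na(cdsStart0) & cdsEnd0 > cdsStart0
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start0 + 1L, end0), strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    geneId = geneId, tss = as.integer(tss),
    cdsStart = ifelse(hasCds, cdsStart0 + 1L, NA_integer_),
    cdsEnd = ifelse(hasCds, cdsEnd0, NA_integer_),
    exons = exons)
  for (i in seq_along(gr)) {
    ex <- exons[[i]]
    if (length(ex) && (min(IRanges::start(ex)) < IRanges::start(gr)[i] ||
                       max(IRanges::end(ex)) > IRanges::end(gr)[i]))
      stop(sprintf("exons outside transcript span at line %d of %s",
                   lines[i], basename(path)))
    if (hasCds[i] && (cdsStart0[i] + 1L < IRanges::start(gr)[i] ||
                      cdsEnd0[i] > IRanges::end(gr)[i]))
      stop(sprintf("CDS outside transcript span at line %d of %s",
                   lines[i], basename(path)))
  }
  names(gr) <- geneId
  gr
}

readBed12 <- function(path) {
  p <- readFields(path, 12L, "BED12 record")
  f <- p$fields; ln <- p$lines
  col <- function(i) vapply(f, `[[`, character(1), i)
  start0 <- asInt(col(2), path, ln, "BED12 record")
  end0 <- asInt(col(3), path, ln, "BED12 record")
  strand <- parseStrand(col(6), path, ln)
  thickS <- asInt(col(7), path, ln, "BED12 record")
  thickE <- asInt(col(8), path, ln, "BED12 record")
  nBlocks <- asInt(col(10), path, ln, "BED12 record")
  splitNum <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v[v != ""]))
  sizes <- splitNum(col(11)); offs <- splitNum(col(12))
  if (any(lengths(sizes) != nBlocks | lengths(offs) != nBlocks))
    stop(sprintf("block count mismatch at line %d of %s",
                 ln[which(lengths(sizes) != nBlocks | lengths(offs) != nBlocks)[1L]],
                 basename(path)))
  exonStarts0 <- mapply(function(s, o) s + o, start0, offs, SIMPLIFY = FALSE)
  exonEnds0 <- mapply(`+`, exonStarts0, sizes, SIMPLIFY = FALSE)
  buildGenes(col(1), start0, end0, col(4), strand,
             ifelse(thickE > thickS, thickS, NA_integer_),
             ifelse(thickE > thickS, thickE, NA_integer_),
             exonStarts0, exonEnds0, path, ln)
}

readGeneTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "")
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonStarts", "exonEnds")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("TSV annotation missing columns: ",
                         paste(miss, collapse = ", "))
  ln <- seq_len(nrow(tab)) + 1L
  strand <- parseStrand(tab$strand, path, ln)
  num <- function(x) suppressWarnings(as.integer(x))
  splitNum <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v[v != ""]))
  cds0 <- ifelse(tab$cdsStart == ".", NA, tab$cdsStart)
  cds1 <- ifelse(tab$cdsEnd == ".", NA, tab$cdsEnd)
  buildGenes(tab$chrom, num(tab$txStart), num(tab$txEnd), tab$gene_id, strand,
             num(cds0), num(cds1),
             splitNum(tab$exonStarts), splitNum(tab$exonEnds), path, ln)
}

#' Write gene annotations as BED12
#'
#' Inverse of \code{\link{readGeneAnnotation}(format = "bed12")}; a write/read
#' round trip returns identical records.
#'
#' @param genes GRanges as returned by \code{readGeneAnnotation}.
#' @param path output path (gzipped on .gz suffix).
#' @export
writeGeneAnnotation <- function(genes, path) {
  m <- S4Vectors::mcols(genes)
  con <- openOut(path); on.exit(close(con))
  for (i in seq_along(genes)) {
    ex <- m$exons[[i]]
    s0 <- IRanges::start(genes)[i] - 1L
    hasCds <- !is.na(m$cdsStart[i])
    writeLines(paste(
      as.character(GenomicRanges::seqnames(genes)[i]),
      s0, IRanges::end(genes)[i], m$geneId[i], 0L,
      as.character(GenomicRanges::strand(genes)[i]),
      if (hasCds) m$cdsStart[i] - 1L else s0,
      if (hasCds) m$cdsEnd[i] else s0,
      0L, length(ex),
      paste0(paste(IRanges::width(ex), collapse = ","), ","),
      paste0(paste(IRanges::start(ex) - 1L - s0, collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' Returns a GRanges sorted within chromosomes; a fourth column, when
#' present, becomes the \code{name} metadata column.
#'
#' @param path BED file (plain or gzipped).
#' @return sorted GRanges.
#' @export
readIntervals <- function(path) {
  p <- readFields(path, 0L, "BED record")
  if (!length(p$fields))
    return(GenomicRanges::GRanges())
  p <- readFields(path, 3L, "BED record")
  f <- p$fields; ln <- p$lines
  col <- function(i) vapply(f, `[[`, character(1), i)
  start0 <- asInt(col(2), path, ln, "BED record")
  end0 <- asInt(col(3), path, ln, "BED record")
  if (any(start0 >= end0))
    stop(sprintf("empty or inverted interval at line %d of %s",
                 ln[start0 >= end0][1L], basename(path)))
  gr <- GenomicRanges::GRanges(col(1), IRanges::IRanges(start0 + 1L, end0))
  if (all(lengths(f) >= 4L))
    S4Vectors::mcols(gr)$name <- col(4)
  GenomicRanges::sort(gr)
}

#' Write intervals as BED3 (or BED4 when a name column exists)
#' @param gr GRanges.
#' @param path output path.
#' @export
writeIntervals <- function(gr, path) {
  con <- openOut(path); on.exit(close(con))
  nm <- S4Vectors::mcols(gr)$name
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 IRanges::start(gr) - 1L, IRanges::end(gr), sep = "\t")
  if (!is.null(nm)) lines <- paste(lines, nm, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Assign cis-regions around TSSs with nearest-gene ownership
#'
#' Each gene receives a window of nominal width \code{width} centered on its
#' TSS (clipped at chromosome ends).  Where windows of neighbouring genes
#' overlap, each base is owned by the gene with the nearest TSS; a base
#' exactly equidistant between two TSSs goes to the gene with the smaller
#' TSS coordinate.  Ownership intervals of different genes are disjoint.
#'
#' @param genes GRanges from \code{\link{readGeneAnnotation}}.
#' @param width nominal window width in nt (even).
#' @param chromSizes named integer vector of chromosome lengths.
#' @return GRanges of cis-region intervals with metadata \code{geneId},
#'   \code{tss} and \code{owned} (IRangesList of owned sub-intervals).
#' @export
assignCisRegions <- function(genes, width = 40000L, chromSizes) {
  stopIfNot(width %% 2 == 0, "cis-region width must be even")
  half <- width %/% 2
  m <- S4Vectors::mcols(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  stopIfNot(all(chrom %in% names(chromSizes)),
            "all genes must lie on chromosomes present in chromSizes")
  tss0 <- m$tss - 1L                      # 0-based tss
  ord <- order(chrom, m$tss, m$geneId)
  regStart <- pmax(m$tss - half, 1L)
  regEnd <- pmin(m$tss - 1L + half, chromSizes[chrom])
  ownLo <- regStart; ownHi <- regEnd
  for (i in seq_len(length(ord) - 1L)) {
    a <- ord[i]; b <- ord[i + 1L]
    if (chrom[a] != chrom[b]) next
    cut0 <- (tss0[a] + tss0[b]) %/% 2     # last 0-based base owned upstream
    ownHi[a] <- min(ownHi[a], cut0 + 1L)  # 1-based position of that base
    ownLo[b] <- max(ownLo[b], cut0 + 2L)
  }
  owned <- IRanges::IRangesList(lapply(seq_along(genes), function(i) {
    if (ownLo[i] > ownHi[i]) IRanges::IRanges() else
      IRanges::IRanges(ownLo[i], ownHi[i])
  }))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(regStart, regEnd))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(geneId = m$geneId, tss = m$tss,
                                               owned = owned)
  names(gr) <- m$geneId
  gr
}

#' Fraction of query intervals overlapping a reference set
#'
#' @param query,reference GRanges on the same chromosome namespace.
#' @return fraction in [0, 1] of query intervals with >= 1 bp overlap.
#' @export
intervalOverlapFraction <- function(query, reference) {
  stopIfNot(length(query) > 0, "overlap fraction is undefined for an empty query")
  mean(IRanges::overlapsAny(query, reference))
}
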