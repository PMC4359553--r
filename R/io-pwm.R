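BASES <- c("A", "C", "G", "T")

#' Construct a PwmModel from counts or probabilities
#'
#' Count matrices get a pseudocount added to every cell before column
#' normalization; matrices whose columns already sum to 1 (within 1e-6) are
#' taken as probabilities directly.  Log-odds are against the uniform
#' background, and the raw score range (sums of column minima / maxima)
#' defines the min-max normalized score.
#'
#' @param mat 4 x L numeric matrix, rows A, C, G, T.
#' @param tf transcription factor name.
#' @param name motif identifier (defaults to tf).
#' @param pseudocount value added to each cell of a count matrix (default 0.01).
#' @return a \linkS4class{PwmModel}.
#' @export
newPwm <- function(mat, tf, name = tf, pseudocount = 0.01) {
  stopIfNot(nrow(mat) == 4L, "PWM matrix must have 4 rows (A, C, G, T)")
  rownames(mat) <- BASES
  isProb <- all(abs(colSums(mat) - 1) < 1e-6)
  if (!isProb) {
    if (any(colSums(mat) == 0))
      stop("all-zero PWM column in motif ", name)
    mat <- mat + pseudocount
    mat <- sweep(mat, 2, colSums(mat), "/")
  }
  lo <- log2(mat / 0.25)
  methods::new("PwmModel", tf = tf, name = name, probs = mat, logOdds = lo,
               rawMin = sum(apply(lo, 2, min)), rawMax = sum(apply(lo, 2, max)))
}

#' Consensus sequence of a PWM (column-wise most probable base)
#' @param pwm PwmModel.
#' @return character string of length L.
#' @export
pwmConsensus <- function(pwm) {
  paste(BASES[apply(pwm@probs, 2, which.max)], collapse = "")
}

#' Read a set of motifs in JASPAR PFM text format
#'
#' Each motif is a header line \code{>identifier tfName} followed by four
#' rows (A, C, G, T) of equal length, with or without the JASPAR bracket
#' syntax \code{A [ 1 2 3 ]}.  Counts are converted to probabilities with a
#' pseudocount; rows that already form a column-stochastic matrix are used
#' as probabilities unchanged (so a write/read round trip is exact).
#'
#' @param path PFM text file (plain or gzipped).
#' @param pseudocount per-cell pseudocount for count matrices.
#' @return named list of \linkS4class{PwmModel}.
#' @export
readPwmSet <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- grep("^>", lines)
  stopIfNot(length(hdr) > 0, "no motif headers ('>') found in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  pwms <- lapply(seq_along(hdr), function(i) {
    block <- lines[(hdr[i] + 1L):ends[i]]
    if (length(block) != 4L)
      stop("motif block must have 4 rows (A, C, G, T) in ", path)
    toks <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1L]]
    id <- toks[1L]; tf <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
      if (anyNA(v)) stop("non-numeric PWM row in motif ", id, " of ", path)
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("unequal row lengths in motif ", id, " of ", path)
    newPwm(do.call(rbind, rows), tf = tf, name = id, pseudocount = pseudocount)
  })
  names(pwms) <- vapply(pwms, function(p) p@name, character(1))
  pwms
}

#' Write motifs in JASPAR PFM text format (probability rows)
#' @param pwms list of PwmModel.
#' @param path output path.
#' @export
writePwmSet <- function(pwms, path) {
  con <- openOut(path); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p@name, " ", p@tf), con)
    for (b in 1:4)
      writeLines(paste0(BASES[b], " [ ",
                        paste(format(p@probs[b, ], digits = 12), collapse = " "),
                        " ]"), con)
  }
  invisible(path)
}
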