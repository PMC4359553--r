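## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Read a (possibly gzipped) whitespace/tab-delimited file into a character
## matrix of fields, keeping the original line numbers so parse errors can
## name the offending line.  Comment/track lines and blank lines are skipped.
readFields <- function(path, minFields, what = "record") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(#|track|browser)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < minFields)) {
    bad <- idx[which(nf < minFields)[1L]]
    stop(sprintf("malformed %s at line %d of %s: expected >= %d fields, got %d",
                 what, bad, basename(path), minFields, nf[which(nf < minFields)[1L]]))
  }
  list(fields = fields, lines = idx)
}

asNum <- function(x, path, lines, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop(sprintf("malformed %s at line %d of %s: non-numeric value '%s'",
                 what, lines[which(is.na(v))[1L]], basename(path),
                 x[which(is.na(v))[1L]]))
  }
  v
}

asInt <- function(x, path, lines, what) {
  v <- asNum(x, path, lines, what)
  if (any(v != floor(v)))
    stop(sprintf("malformed %s at line %d of %s: non-integer coordinate",
                 what, lines[which(v != floor(v))[1L]], basename(path)))
  as.integer(v)
}

## Open a text connection for writing, transparently gzipping on .gz suffix.
openOut <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

## Soft-threshold operator, the proximal map of k * |x|.
softThreshold <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

## Bin index (1-based) of a 1-based genomic position on a fixed grid.
binOf <- function(pos, binSize) (pos - 1L) %/% binSize + 1L

## Mean of bin values over an inclusive bin range, via precomputed cumsum
## (csum[i] = sum of bins 1..i, csum[0] omitted; use c(0, cumsum(v))).
rangeMean <- function(csum, from, to) {
  (csum[to + 1L] - csum[from]) / (to - from + 1L)
}

stopIfNot <- function(cond, ...) if (!cond) stop(...)
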