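#' Construct a StageExpression object from an FPKM matrix
#' @param fpkm non-negative gene x stage matrix with dimnames.
#' @return a \linkS4class{StageExpression}.
#' @export
newStageExpression <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  methods::new("StageExpression", fpkm = fpkm, X = log(fpkm + 1))
}

#' @rdname newStageExpression
#' @param x StageExpression.
#' @export
fpkm <- function(x) x@fpkm

#' @rdname newStageExpression
#' @export
logExpr <- function(x) x@X

#' @rdname newStageExpression
#' @export
stageLabels <- function(x) colnames(x@fpkm)

#' Read a gene x stage FPKM table
#'
#' Tab-delimited, header row of stage labels (first column the gene id), one
#' row per gene.  Genes are optionally filtered to those exceeding an FPKM
#' threshold in at least one stage (the expressed-gene universe used
#' throughout the model; default threshold 1).
#'
#' @param path TSV file (plain or gzipped).
#' @param filterThreshold FPKM threshold; genes must exceed it in >= 1 stage.
#' @param filter apply the threshold filter (default TRUE).
#' @return a \linkS4class{StageExpression}.
#' @export
readExpressionTable <- function(path, filterThreshold = 1, filter = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", basename(path), ": ",
         genes[duplicated(genes)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(m < 0))
    stop("negative FPKM for gene ", genes[which(rowSums(m < 0) > 0)[1L]],
         " in ", basename(path))
  rownames(m) <- genes
  if (filter) m <- m[apply(m > filterThreshold, 1L, any), , drop = FALSE]
  newStageExpression(m)
}

#' Write a StageExpression FPKM table as TSV
#' @param expr StageExpression.
#' @param path output path.
#' @export
writeExpressionTable <- function(expr, path) {
  con <- openOut(path); on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr@fpkm)), collapse = "\t"), con)
  writeLines(paste(rownames(expr@fpkm),
                   apply(expr@fpkm, 1L, function(r)
                     paste(format(r, digits = 10), collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a perturbation edge list into a binary matrix
#'
#' The tab-delimited file has a header naming at least \code{target} and
#' \code{regulator} columns (an optional binary \code{affected} column keeps
#' only rows with value 1).  Entry \code{P[i, j] = 1} records that gene i
#' changed significantly when gene j was perturbed; unlisted pairs are 0 and
#' duplicate rows are idempotent.
#'
#' @param path TSV file.
#' @param genes character vector: the gene universe (matrix dimnames).
#' @return p x p binary matrix.
#' @export
readPerturbationEdges <- function(path, genes) {
  p <- length(genes)
  P <- matrix(0L, p, p, dimnames = list(genes, genes))
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                    colClasses = "character"),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) return(P)
  need <- c("target", "regulator")
  if (!all(need %in% colnames(tab))) {
    colnames(tab)[1:2] <- need
  }
  if ("affected" %in% colnames(tab))
    tab <- tab[tab$affected == "1", , drop = FALSE]
  unknown <- setdiff(unique(c(tab$target, tab$regulator)), genes)
  if (length(unknown))
    stop("perturbation edges reference unknown genes: ",
         paste(unknown, collapse = ", "))
  P[cbind(tab$target, tab$regulator)] <- 1L
  P
}

#' Write a perturbation matrix as an edge list TSV
#' @param P binary matrix with dimnames.
#' @param path output path.
#' @export
writePerturbationEdges <- function(P, path) {
  con <- openOut(path); on.exit(close(con))
  writeLines("target\tregulator\taffected", con)
  idx <- which(P != 0, arr.ind = TRUE)
  if (nrow(idx))
    writeLines(paste(rownames(P)[idx[, 1L]], colnames(P)[idx[, 2L]], 1L,
                     sep = "\t"), con)
  invisible(path)
}
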