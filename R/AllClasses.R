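#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges start end width
#' @importFrom GenomicRanges GRanges seqnames strand granges
NULL

#' Per-stage binned signal track for one chromatin mark
#'
#' Holds the binned tag intensity of one ChIP-seq mark (e.g. H3K27ac) at one
#' differentiation stage.  Values are stored per chromosome as dense vectors
#' on a fixed bin grid (default 10 bp); gaps in the source bedGraph are zero.
#' Tracks are either raw (non-negative) or asinh-transformed.
#'
#' @slot mark character, mark name (e.g. "H3K27ac", "RNAP").
#' @slot stage character, stage label.
#' @slot binSize integer, bin width in nt.
#' @slot values named list of per-chromosome numeric bin vectors.
#' @slot transformed logical, whether values are asinh(raw).
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(mark = "character", stage = "character",
                 binSize = "integer", values = "list",
                 transformed = "logical"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (is.null(names(object@values)) || any(names(object@values) == ""))
    msg <- c(msg, "values must be a named per-chromosome list")
  if (!object@transformed) {
    bad <- vapply(object@values, function(v) any(v < 0, na.rm = TRUE), logical(1))
    if (any(bad))
      msg <- c(msg, "raw signal values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignalTrack", function(object) {
  nb <- sum(vapply(object@values, length, integer(1)))
  cat("SignalTrack:", object@mark, "@", object@stage,
      sprintf("(%d chrom, %d bins of %d nt, %s)\n",
              length(object@values), nb, object@binSize,
              if (object@transformed) "asinh-transformed" else "raw"))
})

#' Position weight matrix with min-max normalized scoring
#'
#' A column-stochastic 4 x L probability matrix together with its log2-odds
#' form (against a uniform background) and the best/worst attainable raw
#' log-odds sums, which define the min-max normalized score in [0, 1].
#'
#' @slot tf character, transcription factor name.
#' @slot name character, motif identifier.
#' @slot probs 4 x L column-stochastic matrix (rows A, C, G, T).
#' @slot logOdds 4 x L matrix, log2(probs / 0.25).
#' @slot rawMin,rawMax numeric, worst/best attainable sums of log-odds.
#' @exportClass PwmModel
setClass("PwmModel",
  representation(tf = "character", name = "character", probs = "matrix",
                 logOdds = "matrix", rawMin = "numeric", rawMax = "numeric"))

setValidity("PwmModel", function(object) {
  msg <- character()
  if (nrow(object@probs) != 4L)
    msg <- c(msg, "probs must have 4 rows (A, C, G, T)")
  if (!isTRUE(all.equal(colSums(object@probs), rep(1, ncol(object@probs)),
                        tolerance = 1e-9, check.names = FALSE)))
    msg <- c(msg, "probs columns must sum to 1")
  if (object@rawMax <= object@rawMin)
    msg <- c(msg, "degenerate motif: rawMax must exceed rawMin")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PwmModel", function(object) {
  cat(sprintf("PwmModel %s (TF %s): %d nt, consensus %s\n",
              object@name, object@tf, ncol(object@probs),
              pwmConsensus(object)))
})

#' Stage-wise expression matrix
#'
#' Gene-by-stage FPKM values together with the model-scale expression
#' X = log(FPKM + 1) used throughout the network model.
#'
#' @slot fpkm p x T non-negative matrix, rownames = genes, colnames = stages.
#' @slot X p x T matrix, log(fpkm + 1).
#' @exportClass StageExpression
setClass("StageExpression",
  representation(fpkm = "matrix", X = "matrix"))

setValidity("StageExpression", function(object) {
  msg <- character()
  if (any(object@fpkm < 0)) msg <- c(msg, "FPKM values must be non-negative")
  if (!identical(dim(object@fpkm), dim(object@X)))
    msg <- c(msg, "fpkm and X must have identical dimensions")
  if (max(abs(object@X - log(object@fpkm + 1))) > 1e-8)
    msg <- c(msg, "X must equal log(fpkm + 1)")
  if (is.null(rownames(object@fpkm)) || is.null(colnames(object@fpkm)))
    msg <- c(msg, "fpkm needs gene rownames and stage colnames")
  if (anyDuplicated(rownames(object@fpkm)))
    msg <- c(msg, "duplicate gene identifiers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StageExpression", function(object) {
  cat(sprintf("StageExpression: %d genes x %d stages (%s)\n",
              nrow(object@fpkm), ncol(object@fpkm),
              paste(colnames(object@fpkm), collapse = " -> ")))
})

#' Static annotation tracks used by the sequence features
#'
#' Per-base conservation scores (with NA marking unavailable bases) and the
#' CpG-island / repeat interval sets.
#'
#' @slot phastVert,phastPlac named lists of per-chromosome numeric vectors in
#'   [0, 1]; NA where the score is unavailable.
#' @slot cpgIslands,repeats GRanges.
#' @exportClass AnnotationTracks
setClass("AnnotationTracks",
  representation(phastVert = "list", phastPlac = "list",
                 cpgIslands = "GRanges", repeats = "GRanges"))

setValidity("AnnotationTracks", function(object) {
  ok <- function(lst) all(vapply(lst, function(v) {
    v <- v[!is.na(v)]; !length(v) || (min(v) >= 0 && max(v) <= 1)
  }, logical(1)))
  if (!ok(object@phastVert) || !ok(object@phastPlac))
    "conservation scores must lie in [0, 1] where available" else TRUE
})

#' Candidate-base feature table for the occupancy model
#'
#' One row per candidate base (PWM hit center) with the 69 features, the
#' binary response (hit center inside a ChIP peak of the hit's TF), and
#' per-row metadata.  After standardization the scaler (per-column mean/sd)
#' is recorded so prediction-time features can reuse it.
#'
#' @slot features n x 69 numeric matrix, fixed column order (see
#'   \code{\link{featureNames}}).
#' @slot response integer vector in {0, 1}.
#' @slot meta DataFrame with at least gene, tf, chrom, pos, stagePair.
#' @slot scaler list(center, scale, constant) or empty list when the table
#'   holds raw (unstandardized) features.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(features = "matrix", response = "integer",
                 meta = "DataFrame", scaler = "list"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (ncol(object@features) != 69L)
    msg <- c(msg, "feature matrix must have exactly 69 columns")
  if (nrow(object@features) != length(object@response))
    msg <- c(msg, "response length must match row count")
  if (length(object@response) && !all(object@response %in% 0:1))
    msg <- c(msg, "response must be binary")
  if (length(object@scaler)) {
    std <- object@features[, !object@scaler$constant, drop = FALSE]
    if (nrow(std) > 1L && ncol(std) > 0L) {
      if (max(abs(colMeans(std))) > 1e-6)
        msg <- c(msg, "standardized columns must have mean 0")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d rows x 69 features, %d positives (%s)\n",
              nrow(object@features), sum(object@response),
              if (length(object@scaler)) "standardized" else "raw"))
})

#' Fitted logistic occupancy model
#'
#' Maximum-likelihood logistic regression over the 69 features (plus
#' intercept), fitted by iteratively reweighted least squares, with the
#' observed-information covariance used for Wald tests.
#'
#' @slot coefficients named numeric, intercept first.
#' @slot vcov covariance matrix from the observed information.
#' @slot fittedOn integer, number of training rows.
#' @slot converged logical.
#' @slot iterations integer.
#' @slot scaler the feature scaler the model was trained with.
#' @slot lambda regularization penalty (0 for the plain ML fit).
#' @exportClass LogisticModel
setClass("LogisticModel",
  representation(coefficients = "numeric", vcov = "matrix",
                 fittedOn = "integer", converged = "logical",
                 iterations = "integer", scaler = "list",
                 lambda = "numeric"),
  prototype(lambda = 0))

setValidity("LogisticModel", function(object) {
  if (object@converged && nrow(object@vcov)) {
    d <- abs(object@vcov - t(object@vcov))
    if (max(d[!is.na(d)], 0) > 1e-6)
      return("covariance must be symmetric")
  }
  TRUE
})

setMethod("show", "LogisticModel", function(object) {
  cat(sprintf("LogisticModel: %d coefficients, fitted on %d rows, %s (%d IRLS iterations)\n",
              length(object@coefficients), object@fittedOn,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

#' Per-gene, per-transition binding profile matrix
#'
#' Rows are the overlapping 50-bp cis-segments of one gene's cis-region,
#' columns the abundantly expressed TFs (FPKM above threshold at stage t
#' with a known PWM).  Entry (k, j) is the segment-mean LR score times the
#' perturbation adjustment pi_ij when TF j has a surviving PWM hit in
#' segment k, and 0 otherwise.
#'
#' @slot geneId character.
#' @slot transition integer, index t of the stage transition (t -> t+1).
#' @slot B K x nTF numeric matrix, colnames = TF gene ids.
#' @slot segments IRanges of the K cis-segments (genomic coordinates).
#' @exportClass BindingMatrix
setClass("BindingMatrix",
  representation(geneId = "character", transition = "integer",
                 B = "matrix", segments = "IRanges"))

setValidity("BindingMatrix", function(object) {
  msg <- character()
  if (nrow(object@B) != length(object@segments))
    msg <- c(msg, "B must have one row per cis-segment")
  if (length(object@B) && min(object@B) < 0)
    msg <- c(msg, "binding potentials must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BindingMatrix", function(object) {
  cat(sprintf("BindingMatrix %s (transition %d): %d segments x %d TFs, %d non-zero\n",
              object@geneId, object@transition, nrow(object@B), ncol(object@B),
              sum(object@B > 0)))
})

#' Inferred time-varying dynamic network
#'
#' The solved cis-segment weights for every gene, the assembled per-transition
#' gene x gene coefficient matrices A^t (row = target, column = regulator),
#' the positive-edge list, and the configuration used.
#'
#' @slot genes character, gene universe (rows/cols of A).
#' @slot stages character, stage labels (T of them; T-1 transitions).
#' @slot weights named list (per gene) of K x (T-1) segment-weight matrices.
#' @slot segments named list (per gene) of IRanges.
#' @slot bindings named list (per gene) of lists of BindingMatrix (per transition).
#' @slot A list of T-1 dense p x p matrices.
#' @slot edges data.frame(transition, regulator, target, weight) of positive edges.
#' @slot config list, the DbnConfig used (lambda1, lambda2, loss, ...).
#' @slot objectives named numeric, per-gene optimal objective values.
#' @exportClass DynamicNetwork
setClass("DynamicNetwork",
  representation(genes = "character", stages = "character",
                 weights = "list", segments = "list", bindings = "list",
                 A = "list", edges = "data.frame", config = "list",
                 objectives = "numeric"))

setMethod("show", "DynamicNetwork", function(object) {
  nt <- length(object@stages) - 1L
  cnt <- vapply(seq_len(nt), function(t) sum(object@edges$transition == t), integer(1))
  cat(sprintf("DynamicNetwork: %d genes, %d transitions (%s)\n",
              length(object@genes), nt, paste(object@stages, collapse = " -> ")))
  cat("  positive edges per transition:", paste(cnt, collapse = ", "), "\n")
  cat(sprintf("  lambda1 = %g, lambda2 = %g, loss = %s\n",
              object@config$lambda1, object@config$lambda2, object@config$loss))
})
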