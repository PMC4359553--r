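#' Persist a fitted occupancy model as JSON
#' @param model LogisticModel.
#' @param path JSON output path.
#' @export
writeLogisticModel <- function(model, path) {
  jsonlite::write_json(list(
    coefficients = as.list(model@coefficients),
    fittedOn = model@fittedOn, converged = model@converged,
    iterations = model@iterations, lambda = model@lambda,
    scaler = lapply(model@scaler, as.list)), path, digits = NA,
    auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by \code{\link{writeLogisticModel}}
#' @param path JSON path.
#' @return LogisticModel (without covariance; Wald tests need a refit).
#' @export
readLogisticModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- j$scaler
  if (length(scaler)) scaler <- lapply(scaler, unlist)
  methods::new("LogisticModel", coefficients = unlist(j$coefficients),
               vcov = matrix(numeric(0), 0, 0),
               fittedOn = as.integer(j$fittedOn), converged = j$converged,
               iterations = as.integer(j$iterations),
               scaler = if (length(scaler)) scaler else list(),
               lambda = j$lambda %||% 0)
}

## Per-base conservation bedGraph -> per-chromosome vectors, NA where absent.
readConservation <- function(path, chromSizes) {
  out <- lapply(chromSizes, function(sz) rep(NA_real_, sz))
  p <- readFields(path, 0L, "bedGraph record")
  if (length(p$fields)) {
    p <- readFields(path, 4L, "bedGraph record")
    f <- p$fields; ln <- p$lines
    col <- function(i) vapply(f, `[[`, character(1), i)
    chrom <- col(1)
    s0 <- asInt(col(2), path, ln, "bedGraph record")
    e0 <- asInt(col(3), path, ln, "bedGraph record")
    v <- asNum(col(4), path, ln, "bedGraph record")
    for (i in seq_along(v)) out[[chrom[i]]][(s0[i] + 1L):e0[i]] <- v[i]
  }
  out
}

writeConservation <- function(values, path) {
  con <- openOut(path); on.exit(close(con))
  for (ch in names(values)) {
    v <- values[[ch]]
    ok <- which(!is.na(v))
    if (length(ok))
      writeLines(paste(ch, ok - 1L, ok, v[ok], sep = "\t"), con)
  }
  invisible(path)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults (cis width 40000, scan threshold 0.90, gene
#' FPKM filter 1, TF FPKM filter 25, bootstrap N 100), checks that every
#' referenced file exists and that stage labels are consistent, and rejects
#' invalid values with an error naming the field.  Normalization is
#' idempotent.
#'
#' @param config a named list, or a path to a YAML/JSON config file.
#' @return normalized config list.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- list(cisWidth = 40000L, scanThreshold = 0.90, geneFpkmMin = 1,
                   tfFpkmMin = 25, bootstrapN = 100L, seed = 1L,
                   lambda1 = 0.01, lambda2 = 0.1, loss = "squared",
                   outdir = "dyngrn_out")
  config <- utils::modifyList(defaults, config)
  err <- function(field, why) stop("config field '", field, "': ", why)
  if (is.null(config$stages) || length(config$stages) < 2L)
    err("stages", "at least 2 stage labels required")
  for (fld in c("lambda1", "lambda2"))
    if (config[[fld]] < 0) err(fld, "must be non-negative")
  if (config$scanThreshold <= 0 || config$scanThreshold > 1)
    err("scanThreshold", "must be in (0, 1]")
  if (config$bootstrapN < 1) err("bootstrapN", "must be >= 1")
  fileFields <- c("genomeFasta", "genesBed", "expressionTsv",
                  "perturbationTsv", "pwmFile", "conservationVert",
                  "conservationPlac", "cpgBed", "repeatsBed")
  for (fld in fileFields)
    if (!is.null(config[[fld]]) && !file.exists(config[[fld]]))
      err(fld, paste("file not found:", config[[fld]]))
  for (grp in c("trackFiles", "peakBeds"))
    for (path in unlist(config[[grp]]))
      if (!file.exists(path)) err(grp, paste("file not found:", path))
  if (!is.null(config$stageMap)) {
    bad <- setdiff(unlist(config$stageMap), config$stages)
    if (length(bad)) err("stageMap", paste("unknown stage label:",
                                           paste(bad, collapse = ", ")))
  }
  config
}

pipelineLog <- function(outdir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

needArtifact <- function(path, producer) {
  if (!all(file.exists(path)))
    stop("missing artifact ", path[!file.exists(path)][1L],
         "; run the '", producer, "' step first")
}

loadPipelineInputs <- function(config) {
  chromSizes <- NULL
  genome <- Biostrings::readDNAStringSet(config$genomeFasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  chromSizes <- stats::setNames(Biostrings::width(genome), names(genome))
  genes <- readGeneAnnotation(config$genesBed, "bed12")
  expr <- readExpressionTable(config$expressionTsv,
                              filterThreshold = config$geneFpkmMin)
  regions <- assignCisRegions(genes, width = config$cisWidth, chromSizes)
  pwms <- readPwmSet(config$pwmFile)
  ann <- methods::new("AnnotationTracks",
    phastVert = readConservation(config$conservationVert, chromSizes),
    phastPlac = readConservation(config$conservationPlac, chromSizes),
    cpgIslands = readIntervals(config$cpgBed),
    repeats = readIntervals(config$repeatsBed))
  tracks <- lapply(config$trackFiles, function(byStage)
    lapply(stats::setNames(nm = names(byStage)), function(st)
      asinhTransform(readSignalTrack(byStage[[st]],
        mark = "", stage = st, chromSizes = chromSizes))))
  for (mk in names(tracks)) for (st in names(tracks[[mk]]))
    tracks[[mk]][[st]]@mark <- mk
  peaks <- lapply(stats::setNames(nm = names(config$peakBeds)), function(tf)
    newPeakSet(readIntervals(config$peakBeds[[tf]]), tf = tf))
  P <- readPerturbationEdges(config$perturbationTsv, rownames(fpkm(expr)))
  list(genome = genome, chromSizes = chromSizes, genes = genes, expr = expr,
       regions = regions, pwms = pwms, annTracks = ann, tracks = tracks,
       peaks = peaks, P = P)
}

#' Run the two-step workflow (or one of its steps)
#'
#' Subcommands: \code{simulate} writes a complete synthetic dataset (in the
#' exact file formats the readers accept) plus a config; \code{scan},
#' \code{features}, \code{train-lr}, \code{predict-lr},
#' \code{infer-network}, \code{bootstrap} and \code{perturb} run the
#' corresponding stage on disk artifacts; \code{all} chains every step.
#' Every run appends parameters and seeds to \code{run.log} and refreshes
#' \code{manifest.json} in the output directory.
#'
#' @param config config list or file path (see \code{\link{validateConfig}}).
#' @param step subcommand.
#' @return invisibly, the list of artifacts written.
#' @export
runPipeline <- function(config,
                        step = c("all", "simulate", "scan", "features",
                                 "train-lr", "predict-lr", "infer-network",
                                 "bootstrap", "perturb")) {
  step <- match.arg(step)
  if (step == "simulate" || (step == "all" && is.character(config) == FALSE &&
                             is.null(config$genomeFasta)))
    return(pipelineSimulate(config, chain = step == "all"))
  config <- validateConfig(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  addArt <- function(p) art <<- c(art, p)
  paths <- list(
    hits = file.path(outdir, "hits.tsv"),
    features = file.path(outdir, "features.tsv"),
    model = file.path(outdir, "lr_model.json"),
    lrDir = file.path(outdir, "lr_tracks"),
    edges = file.path(outdir, "network_edges.tsv"),
    tfbs = file.path(outdir, "network_tfbs.tsv"),
    weights = file.path(outdir, "segment_weights.tsv"),
    boot = file.path(outdir, "bootstrap_pvalues.tsv"),
    perturb = file.path(outdir, "perturbation.tsv"))
  steps <- if (step == "all")
    c("scan", "features", "train-lr", "predict-lr", "infer-network",
      "bootstrap", "perturb") else step
  inp <- loadPipelineInputs(config)
  pipelineLog(outdir, "steps=", paste(steps, collapse = ","),
              " seed=", config$seed, " scanThreshold=", config$scanThreshold,
              " cisWidth=", config$cisWidth, " lambda1=", config$lambda1,
              " lambda2=", config$lambda2, " tfFpkmMin=", config$tfFpkmMin,
              " bootstrapN=", config$bootstrapN)
  for (s in steps) {
    switch(s,
      "scan" = {
        hits <- scanRegions(inp$pwms, inp$genome, inp$regions,
                            threshold = config$scanThreshold)
        hits <- resolveOverlappingHits(hits, by = "tf")
        hits <- assignHitsToGenes(hits, inp$regions)
        hits <- labelAllHits(hits, inp$peaks)
        exportHits(hits, file.path(outdir, "hits.bed"), paths$hits)
        addArt(c(file.path(outdir, "hits.bed"), paths$hits))
      },
      "features" = {
        needArtifact(paths$hits, "scan")
        hits <- readHitsTsv(paths$hits)
        ctx <- prepareFeatureContext(inp$genome, inp$genes, inp$annTracks,
                                     inp$tracks, inp$expr, inp$regions)
        stageMap <- stats::setNames(
          match(unlist(config$stageMap), config$stages),
          names(config$stageMap))
        tab <- assembleDesignMatrix(hits, ctx, stageMap)
        writeFeatureTable(tab, paths$features)
        addArt(paths$features)
      },
      "train-lr" = {
        needArtifact(paths$features, "features")
        tab <- readFeatureTable(paths$features)
        tab <- suppressWarnings(standardizeFeatures(tab))
        model <- trainOccupancyModel(tab, config$lrMethod %||% "auto",
                                     seed = config$seed)
        writeLogisticModel(model, paths$model)
        addArt(paths$model)
      },
      "predict-lr" = {
        needArtifact(paths$model, "train-lr")
        model <- readLogisticModel(paths$model)
        ctx <- prepareFeatureContext(inp$genome, inp$genes, inp$annTracks,
                                     inp$tracks, inp$expr, inp$regions)
        lrTracks <- predictLrTracks(model, ctx, inp$regions)
        dir.create(paths$lrDir, showWarnings = FALSE)
        for (g in names(lrTracks)) for (t in names(lrTracks[[g]])) {
          f <- file.path(paths$lrDir, paste0(g, "_", t, ".bedGraph"))
          writeLrTrack(lrTracks[[g]][[t]], f)
          addArt(f)
        }
      },
      "infer-network" = {
        needArtifact(c(paths$hits, paths$model), "predict-lr")
        stopIfNot(dir.exists(paths$lrDir) &&
                  length(list.files(paths$lrDir)) > 0,
                  "missing LR tracks; run the 'predict-lr' step first")
        hits <- readHitsTsv(paths$hits)
        lrTracks <- readLrTrackDir(paths$lrDir, inp$regions,
                                   length(config$stages) - 1L)
        cfg <- dbnConfig(lambda1 = config$lambda1, lambda2 = config$lambda2,
                         loss = config$loss, tfFpkmMin = config$tfFpkmMin)
        tfCandidates <- intersect(config$tfCandidates %||%
                                    unique(S4Vectors::mcols(hits)$tf),
                                  rownames(fpkm(inp$expr)))
        net <- inferNetwork(inp$expr, lrTracks, hits, inp$P, inp$regions,
                            tfCandidates, cfg)
        writeNetworkEdges(net, paths$edges)
        writeTfbsTable(net, hits, paths$tfbs)
        wdf <- do.call(rbind, lapply(names(net@weights), function(g) {
          u <- net@weights[[g]]
          if (!nrow(u)) return(NULL)
          data.frame(gene = g, transition = rep(seq_len(ncol(u)),
                                                each = nrow(u)),
                     segment = rep(seq_len(nrow(u)), ncol(u)),
                     u = as.vector(u))
        }))
        utils::write.table(wdf, paths$weights, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        addArt(c(paths$edges, paths$tfbs, paths$weights))
      },
      "bootstrap" = {
        needArtifact(c(paths$hits, paths$weights), "infer-network")
        hits <- readHitsTsv(paths$hits)
        lrTracks <- readLrTrackDir(paths$lrDir, inp$regions,
                                   length(config$stages) - 1L)
        cfg <- dbnConfig(lambda1 = config$lambda1, lambda2 = config$lambda2,
                         loss = config$loss, tfFpkmMin = config$tfFpkmMin)
        tfCandidates <- intersect(config$tfCandidates %||%
                                    unique(S4Vectors::mcols(hits)$tf),
                                  rownames(fpkm(inp$expr)))
        bootGenes <- config$bootstrapGenes %||%
          S4Vectors::mcols(inp$regions)$geneId
        res <- do.call(rbind, lapply(bootGenes, function(g) {
          hg <- hits[!is.na(S4Vectors::mcols(hits)$geneId) &
                     S4Vectors::mcols(hits)$geneId == g]
          bootstrapSegmentPvalues(g, lrTracks[[g]], hg, inp$P, inp$expr,
            inp$regions[S4Vectors::mcols(inp$regions)$geneId == g],
            tfCandidates, cfg, N = config$bootstrapN, seed = config$seed)
        }))
        utils::write.table(res, paths$boot, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        addArt(paths$boot)
      },
      "perturb" = {
        needArtifact(paths$edges, "infer-network")
        stopIfNot(!is.null(config$perturbTf),
                  "config field 'perturbTf' required for the perturb step")
        edges <- utils::read.table(paths$edges, header = TRUE, sep = "\t")
        genes <- rownames(fpkm(inp$expr))
        nT <- length(config$stages) - 1L
        A <- lapply(seq_len(nT), function(t) {
          m <- matrix(0, length(genes), length(genes),
                      dimnames = list(genes, genes))
          e <- edges[edges$transition == t, , drop = FALSE]
          if (nrow(e)) m[cbind(e$target, e$regulator)] <- e$weight
          m
        })
        net <- methods::new("DynamicNetwork", genes = genes,
                            stages = config$stages, weights = list(),
                            segments = list(), bindings = list(), A = A,
                            edges = edges, config = dbnConfig(),
                            objectives = numeric(0))
        pred <- computationalPerturbation(net, inp$expr, config$perturbTf,
                                          fold = config$perturbFold %||% 5,
                                          stage = config$perturbStage %||% 1L)
        utils::write.table(
          data.frame(gene = names(pred$direction),
                     direction = unname(pred$direction),
                     delta = unname(pred$delta)),
          paths$perturb, sep = "\t", quote = FALSE, row.names = FALSE)
        addArt(paths$perturb)
      })
    pipelineLog(outdir, "completed step ", s)
  }
  jsonlite::write_json(list(steps = steps, artifacts = unique(art)),
                       file.path(outdir, "manifest.json"), auto_unbox = TRUE)
  invisible(unique(art))
}

#' Read back the LR track bedGraphs written by the predict-lr step
#' @param dir directory of per-gene/transition bedGraphs.
#' @param regions cis-region GRanges.
#' @param nT number of transitions.
#' @return nested track list as from \code{\link{predictLrTracks}}.
#' @export
readLrTrackDir <- function(dir, regions, nT) {
  genes <- S4Vectors::mcols(regions)$geneId
  out <- lapply(genes, function(g) {
    ri <- match(g, genes)
    chrom <- as.character(GenomicRanges::seqnames(regions))[ri]
    lo <- IRanges::start(regions)[ri]; hi <- IRanges::end(regions)[ri]
    stats::setNames(lapply(seq_len(nT), function(t) {
      f <- file.path(dir, paste0(g, "_t", t, ".bedGraph"))
      needArtifact(f, "predict-lr")
      tab <- utils::read.table(f, sep = "\t")
      score <- rep(NA_real_, hi - lo + 1L)
      score[tab[[2L]] + 1L - lo + 1L] <- tab[[4L]]
      list(gene = g, transition = t, chrom = chrom, start = lo, score = score)
    }), paste0("t", seq_len(nT)))
  })
  stats::setNames(out, genes)
}

## Write a full synthetic dataset to disk and (optionally) chain the rest
## of the pipeline on the generated files.
pipelineSimulate <- function(config, chain = FALSE) {
  stopIfNot(is.list(config), "simulate needs a config list (seed, outdir)")
  outdir <- config$outdir %||% "dyngrn_out"
  seed <- config$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulateGrnDataset(seed = seed,
                           nGenes = config$nGenes %||% 20L,
                           nTf = config$nTf %||% 5L,
                           T = config$T %||% 4L,
                           sigma = config$sigma %||% 0.05,
                           regionLen = config$regionLen %||% 1000L)
  inDir <- file.path(outdir, "inputs")
  dir.create(inDir, showWarnings = FALSE)
  dir.create(file.path(inDir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(inDir, "peaks"), showWarnings = FALSE)
  Biostrings::writeXStringSet(ds$genome, file.path(inDir, "genome.fa"))
  writeGeneAnnotation(ds$genes, file.path(inDir, "genes.bed"))
  writeExpressionTable(ds$expr, file.path(inDir, "expression.tsv"))
  writePerturbationEdges(ds$P, file.path(inDir, "perturbation.tsv"))
  writePwmSet(ds$pwms, file.path(inDir, "pwms.pfm"))
  writeConservation(ds$annTracks@phastVert, file.path(inDir, "cons_vert.bedGraph"))
  writeConservation(ds$annTracks@phastPlac, file.path(inDir, "cons_plac.bedGraph"))
  writeIntervals(ds$annTracks@cpgIslands, file.path(inDir, "cpg.bed"))
  writeIntervals(ds$annTracks@repeats, file.path(inDir, "repeats.bed"))
  trackFiles <- list()
  for (mk in names(ds$tracks)) {
    trackFiles[[mk]] <- list()
    for (st in names(ds$tracks[[mk]])) {
      f <- file.path(inDir, "tracks", paste0(mk, "_", st, ".bedGraph"))
      writeSignalTrack(ds$tracks[[mk]][[st]], f)
      trackFiles[[mk]][[st]] <- f
    }
  }
  peakBeds <- list()
  for (tf in names(ds$peaks)) {
    f <- file.path(inDir, "peaks", paste0(tf, ".bed"))
    writeIntervals(ds$peaks[[tf]], f)
    peakBeds[[tf]] <- f
  }
  tfIds <- names(ds$pwms)
  full <- utils::modifyList(config, list(
    outdir = outdir, seed = seed, stages = ds$stages,
    genomeFasta = file.path(inDir, "genome.fa"),
    genesBed = file.path(inDir, "genes.bed"),
    expressionTsv = file.path(inDir, "expression.tsv"),
    perturbationTsv = file.path(inDir, "perturbation.tsv"),
    pwmFile = file.path(inDir, "pwms.pfm"),
    conservationVert = file.path(inDir, "cons_vert.bedGraph"),
    conservationPlac = file.path(inDir, "cons_plac.bedGraph"),
    cpgBed = file.path(inDir, "cpg.bed"),
    repeatsBed = file.path(inDir, "repeats.bed"),
    trackFiles = trackFiles, peakBeds = peakBeds,
    cisWidth = config$regionLen %||% 1000L,
    stageMap = stats::setNames(as.list(rep(ds$stages[1L], length(tfIds))),
                               tfIds),
    tfCandidates = tfIds,
    perturbTf = config$perturbTf %||% tfIds[1L]))
  cfgPath <- file.path(outdir, "config.yaml")
  yaml::write_yaml(full, cfgPath)
  pipelineLog(outdir, "simulate: seed=", seed, " -> ", inDir)
  if (chain) runPipeline(cfgPath, "all") else invisible(cfgPath)
}
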