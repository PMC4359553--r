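test_that("BED12 gene records parse with correct TSS on both strands", {
  f <- tmpFile(c("chr1\t100\t500\tgA\t0\t+\t150\t450\t0\t2\t100,100,\t0,300,",
                 "chr1\t100\t500\tgB\t0\t-\t150\t450\t0\t2\t100,100,\t0,300,"))
  genes <- readGeneAnnotation(f, "bed12")
  m <- S4Vectors::mcols(genes)
  expect_equal(m$geneId, c("gA", "gB"))
  ## 0-based tss 100 -> 1-based 101 on +; 0-based 499 -> 1-based 500 on -
  expect_equal(m$tss, c(101L, 500L))
  expect_equal(length(m$exons[[1]]), 2L)
  expect_equal(IRanges::start(m$exons[[1]]), c(101L, 401L))
  expect_equal(IRanges::end(m$exons[[1]]), c(200L, 500L))
})

test_that("gene annotation write/read round trip is the identity", {
  f <- tmpFile(c("chr1\t100\t500\tgA\t0\t+\t150\t450\t0\t2\t100,100,\t0,300,",
                 "chr2\t20\t220\tgB\t0\t-\t20\t20\t0\t1\t200,\t0,"))
  genes <- readGeneAnnotation(f, "bed12")
  out <- tempfile(fileext = ".bed")
  writeGeneAnnotation(genes, out)
  back <- readGeneAnnotation(out, "bed12")
  expect_equal(S4Vectors::mcols(back)$tss, S4Vectors::mcols(genes)$tss)
  expect_equal(S4Vectors::mcols(back)$cdsStart, S4Vectors::mcols(genes)$cdsStart)
  expect_identical(as.character(GenomicRanges::strand(back)),
                   as.character(GenomicRanges::strand(genes)))
  expect_equal(S4Vectors::mcols(back)$exons, S4Vectors::mcols(genes)$exons)
})

test_that("malformed annotation lines raise errors naming the line", {
  f <- tmpFile(c("chr1\t100\t500\tgA\t0\t+\t150\t450\t0\t2\t100,100,\t0,300,",
                 "chr1\t100"))
  expect_error(readGeneAnnotation(f, "bed12"), "line 2")
  f2 <- tmpFile("chr1\t100\t500\tgA\t0\t?\t150\t450\t0\t1\t400,\t0,")
  expect_error(readGeneAnnotation(f2, "bed12"), "strand")
})

test_that("BED interval reading is half-open, sorted, and validated", {
  f <- tmpFile(c("chr1\t5\t10", "chr1\t2\t4"))
  gr <- readIntervals(f)
  expect_equal(IRanges::start(gr), c(3L, 6L))   # sorted, 1-based
  expect_equal(IRanges::width(gr), c(2L, 5L))   # [5,10) has length 5
  expect_error(readIntervals(tmpFile("chr1\t7\t7")), "interval")
  expect_length(readIntervals(tmpFile(character(0))), 0L)
})

test_that("bedGraph re-binning matches per-base averaging", {
  cs <- c(chrA = 100L)
  ## single record on one bin
  tr <- readSignalTrack(tmpFile("chrA\t10\t20\t4.0"), "H3K27ac", "S1", cs)
  expect_equal(tr@values$chrA[2], 4.0)
  expect_equal(tr@values$chrA[c(1, 3)], c(0, 0))
  ## record spanning two full bins
  tr2 <- readSignalTrack(tmpFile("chrA\t10\t30\t2.5"), "H3K27ac", "S1", cs)
  expect_equal(tr2@values$chrA[2:3], c(2.5, 2.5))
  ## 25-bp record not aligned to the grid: coverage-weighted mean equals
  ## the brute-force per-base average (uncovered bases count 0)
  tr3 <- readSignalTrack(tmpFile("chrA\t13\t38\t2.0"), "H3K27ac", "S1", cs)
  perBase <- numeric(100); perBase[14:38] <- 2.0
  expected <- vapply(1:10, function(b) mean(perBase[((b - 1) * 10 + 1):(b * 10)]),
                     numeric(1))
  expect_equal(tr3@values$chrA, expected)
  expect_error(readSignalTrack(tmpFile("chrA\t0\t10\t-1"), "x", "S1", cs),
               "negative")
})

test_that("asinh transform is exact, monotone, and single-use", {
  cs <- c(chrA = 30L)
  tr <- readSignalTrack(tmpFile(c("chrA\t0\t10\t0", "chrA\t10\t20\t1",
                                  "chrA\t20\t30\t7")), "m", "S1", cs)
  tt <- asinhTransform(tr)
  expect_equal(tt@values$chrA[1], 0)
  expect_equal(tt@values$chrA[2], log(1 + sqrt(2)))
  expect_true(all(diff(order(tt@values$chrA)) == diff(order(tr@values$chrA))))
  expect_error(asinhTransform(tt), "already")
})

test_that("PFM parsing applies the pseudocount and round-trips", {
  f <- tmpFile(c(">M1 TFA", "A [ 10 0 ]", "C [ 0 10 ]", "G [ 0 0 ]",
                 "T [ 0 0 ]"))
  pwms <- readPwmSet(f)
  expect_equal(unname(pwms$M1@probs["A", 1]), 10.01 / 10.04)
  ## a uniform count column becomes uniform probabilities
  f2 <- tmpFile(c(">M2 TFB", "A 10 1", "C 0 1", "G 0 1", "T 0 1"))
  expect_equal(unname(readPwmSet(f2)$M2@probs[, 2]), rep(0.25, 4))
  out <- tempfile()
  writePwmSet(pwms, out)
  back <- readPwmSet(out)
  expect_lt(max(abs(back$M1@probs - pwms$M1@probs)), 1e-9)
  expect_error(readPwmSet(tmpFile(c(">M3 T", "A 1 2", "C 1", "G 1 2",
                                    "T 1 2"))), "unequal")
  expect_error(newPwm(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4), "T"),
               "all-zero")
})

test_that("expression table filtering and log transform follow the rules", {
  f <- tmpFile(c("gene\tS1\tS2\tS3\tS4",
                 "gA\t0\t3\t10\t2",
                 "gB\t0.5\t0.2\t0\t0"))
  expr <- readExpressionTable(f)
  expect_equal(rownames(fpkm(expr)), "gA")       # gB never exceeds 1 FPKM
  expect_equal(logExpr(expr)["gA", "S2"], log(4))
  exprAll <- readExpressionTable(f, filter = FALSE)
  expect_equal(nrow(fpkm(exprAll)), 2L)
  expect_error(readExpressionTable(tmpFile(c("gene\tS1", "gA\t-1"))),
               "negative")
  expect_error(readExpressionTable(tmpFile(c("gene\tS1", "gA\t1", "gA\t2"))),
               "duplicate")
})

test_that("perturbation edge lists build idempotent binary matrices", {
  genes <- paste0("g", 1:5)
  f <- tmpFile(c("target\tregulator", "g1\tg2", "g3\tg2", "g4\tg5",
                 "g1\tg2"))
  P <- readPerturbationEdges(f, genes)
  expect_equal(sum(P), 3)
  expect_equal(P["g1", "g2"], 1L)
  expect_equal(sum(readPerturbationEdges(tmpFile("target\tregulator"),
                                         genes)), 0)
  expect_error(readPerturbationEdges(tmpFile(c("target\tregulator",
                                               "gX\tg1")), genes), "gX")
  out <- tempfile()
  writePerturbationEdges(P, out)
  expect_equal(readPerturbationEdges(out, genes), P)
})

test_that("cis-region assignment follows the nearest-TSS rule", {
  mkGenes <- function(tss) {
    gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(tss, tss + 99L), strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneId = paste0("g", seq_along(tss)), tss = as.integer(tss),
      cdsStart = NA_integer_, cdsEnd = NA_integer_,
      exons = IRanges::IRangesList(lapply(tss, function(t)
        IRanges::IRanges(t, t + 99L))))
    gr
  }
  cs <- c(chr1 = 60000L)
  ## two genes at 0-based TSS 10000 and 20000 (1-based 10001/20001):
  ## bases below the midpoint go to gene 1, the rest to gene 2
  regs <- assignCisRegions(mkGenes(c(10001L, 20001L)), 40000L, cs)
  owned <- S4Vectors::mcols(regs)$owned
  expect_equal(IRanges::end(owned[[1]]), 15001L)   # 0-based base 15000
  expect_equal(IRanges::start(owned[[2]]), 15002L)
  ## single mid-chromosome gene: exactly [tss - W/2, tss + W/2)
  r1 <- assignCisRegions(mkGenes(30001L), 40000L, cs)
  expect_equal(IRanges::start(r1), 10001L)
  expect_equal(IRanges::end(r1), 50000L)
  expect_equal(IRanges::width(r1), 40000L)
})

test_that("ownership equals per-base nearest-TSS brute force", {
  set.seed(11)
  for (rep in 1:5) {
    tss <- sort(sample(200:1800, 3))
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tss, tss + 49L),
                                 strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneId = paste0("g", 1:3), tss = as.integer(tss),
      cdsStart = NA_integer_, cdsEnd = NA_integer_,
      exons = IRanges::IRangesList(lapply(tss, function(t)
        IRanges::IRanges(t, t + 49L))))
    cs <- c(chr1 = 2000L)
    W <- 600L
    regs <- assignCisRegions(gr, W, cs)
    owned <- S4Vectors::mcols(regs)$owned
    ## brute force: each base goes to the nearest covering TSS (ties to
    ## the smaller TSS)
    ownerOf <- rep(NA_integer_, 2000L)
    for (b in 1:2000) {
      d <- abs(b - tss)
      cand <- which(d <= (W / 2) &
                    b >= pmax(1, tss - W / 2) & b <= tss - 1 + W / 2)
      if (length(cand)) ownerOf[b] <- cand[which.min(d[cand])]
    }
    for (g in 1:3) {
      mine <- which(ownerOf == g)
      got <- unlist(lapply(seq_along(owned[[g]]), function(i)
        IRanges::start(owned[[g]])[i]:IRanges::end(owned[[g]])[i]))
      expect_equal(sort(got), mine)
    }
    ## masks are pairwise disjoint
    allOwned <- unlist(lapply(owned, function(o)
      unlist(lapply(seq_along(o), function(i)
        IRanges::start(o)[i]:IRanges::end(o)[i]))))
    expect_false(any(duplicated(allOwned)))
  }
})

test_that("interval overlap fraction respects half-open abutment", {
  q <- readIntervals(tmpFile(c("chr1\t0\t5", "chr1\t20\t30")))
  refIn <- readIntervals(tmpFile("chr1\t0\t100"))
  expect_equal(intervalOverlapFraction(q, refIn), 1.0)
  refOut <- readIntervals(tmpFile("chr2\t0\t100"))
  expect_equal(suppressWarnings(intervalOverlapFraction(q, refOut)), 0.0)
  ## [0,5) and [5,9) do not overlap
  abut <- readIntervals(tmpFile("chr1\t5\t9"))
  expect_equal(intervalOverlapFraction(
    readIntervals(tmpFile("chr1\t0\t5")), abut), 0.0)
  expect_error(intervalOverlapFraction(GenomicRanges::GRanges(), refIn),
               "empty")
})
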