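writeBed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

test_that("BED12 fields map onto the gene model on both strands", {
  bed <- writeBed(c(
    "chr1\t100\t1000\tgplus\t0\t+\t150\t600\t0\t1\t900,\t0,",
    "chr1\t2000\t3000\tgminus\t0\t-\t2400\t2900\t0\t1\t1000,\t0,"))
  models <- loadAnnotation(bed, "bed12")
  info <- modelInfo(models)
  expect_equal(length(models), 2L)
  plus <- info[info$gene_id == "gplus", ]
  expect_equal(plus$txStart, 100)
  expect_equal(plus$txEnd, 1000)
  expect_equal(plus$cdsEnd3, 600)            # thickEnd on +
  minus <- info[info$gene_id == "gminus", ]
  expect_equal(minus$cdsEnd3, 2400)          # thickStart on -
  expect_equal(IRanges::start(exonRanges(models)[[1]]), 101)
  expect_equal(IRanges::end(exonRanges(models)[[1]]), 1000)
})

test_that("the same transcript parsed from GTF matches the BED12 parse", {
  bed <- writeBed("chr1\t100\t1000\tt1\t0\t+\t100\t600\t0\t1\t900,\t0,")
  gtf <- tempfile(fileext = ".gtf")
  # 1-based closed: exon [101,1000], CDS [101,600]
  writeLines(c(
    paste("chr1\tsrc\texon\t101\t1000\t.\t+\t.",
          "gene_id \"t1\"; transcript_id \"t1\";", sep = "\t"),
    paste("chr1\tsrc\tCDS\t101\t600\t.\t+\t.",
          "gene_id \"t1\"; transcript_id \"t1\";", sep = "\t")), gtf)
  mBed <- loadAnnotation(bed, "bed12")
  mGtf <- loadAnnotation(gtf, "gtf")
  expect_equal(as.data.frame(modelInfo(mBed)), as.data.frame(modelInfo(mGtf)))
  expect_equal(exonRanges(mBed)[[1]], exonRanges(mGtf)[[1]])
})

test_that("malformed lines are reported with their line number and
           CDS-less transcripts are skipped with a warning", {
  bad <- writeBed(c(
    "chr1\t100\t1000\tg1\t0\t+\t150\t600\t0\t1\t900,\t0,",
    "chr1\t100\t1000"))
  expect_error(loadAnnotation(bad, "bed12"), "line 2")
  noCds <- writeBed("chr1\t100\t1000\tg1\t0\t+\t500\t500\t0\t1\t900,\t0,")
  expect_warning(m <- loadAnnotation(noCds, "bed12"), "without CDS")
  expect_equal(length(m), 0L)
})

test_that("parse -> write -> re-parse yields an identical annotation", {
  bed <- writeBed(c(
    "chr1\t100\t1000\tgplus\t0\t+\t100\t600\t0\t2\t300,500,\t0,400,",
    "chr2\t2000\t3000\tgminus\t0\t-\t2400\t3000\t0\t1\t1000,\t0,"))
  m1 <- loadAnnotation(bed, "bed12")
  out <- tempfile(fileext = ".bed")
  writeAnnotationBed12(m1, out)
  m2 <- loadAnnotation(out, "bed12")
  expect_equal(as.data.frame(modelInfo(m1)), as.data.frame(modelInfo(m2)))
  expect_equal(exonRanges(m1), exonRanges(m2))
})

utrFixture <- function(neighborStart = 25000) {
  # plus-strand gene with 400 nt 3'UTR ending at 1000
  bed <- writeBed(c(
    sprintf("chr1\t100\t1000\tgA\t0\t+\t100\t600\t0\t1\t900,\t0,"),
    sprintf("chr1\t%d\t%d\tgB\t0\t+\t%d\t%d\t0\t1\t1000,\t0,",
            neighborStart, neighborStart + 1000, neighborStart,
            neighborStart + 500)))
  loadAnnotation(bed, "bed12")
}

test_that("3'UTR extension runs to the 10 kb cap with a distant neighbour", {
  m <- utrFixture(25000)
  reg <- extractUTR3(m[1], m[2])
  expect_equal(annotatedLen(reg), 400)
  expect_equal(extendedLen(reg), 400 + 10000)
  expect_equal(capHit(reg), "max")
})

test_that("a close neighbour truncates the extension", {
  m <- utrFixture(5000)
  reg <- extractUTR3(m[1], m[2])
  expect_equal(extendedLen(reg), 400 + 4000)
  expect_equal(capHit(reg), "neighbor")
})

test_that("minus-strand extension mirrors the plus-strand case", {
  # reflection of the close-neighbour fixture around coordinate 30000
  R <- 30000
  bed <- writeBed(c(
    sprintf("chr1\t%d\t%d\tgA\t0\t-\t%d\t%d\t0\t1\t900,\t0,",
            R - 1000, R - 100, R - 600, R - 100),
    sprintf("chr1\t%d\t%d\tgB\t0\t-\t%d\t%d\t0\t1\t1000,\t0,",
            R - 6000, R - 5000, R - 5500, R - 5000)))
  m <- loadAnnotation(bed, "bed12")
  gA <- m[modelInfo(m)$gene_id == "gA"]
  gB <- m[modelInfo(m)$gene_id == "gB"]
  reg <- extractUTR3(gA, gB)
  plusReg <- extractUTR3(utrFixture(5000)[1], utrFixture(5000)[2])
  expect_equal(annotatedLen(reg), annotatedLen(plusReg))
  expect_equal(extendedLen(reg), extendedLen(plusReg))
  expect_equal(capHit(reg), capHit(plusReg))
  expect_equal(reg@utrEnd3 - reg@utrStart3,
               plusReg@utrEnd3 - plusReg@utrStart3)
})

test_that("a zero-length 3'UTR is rejected with a typed no-UTR condition", {
  bed <- writeBed("chr1\t100\t1000\tg1\t0\t+\t100\t1000\t0\t1\t900,\t0,")
  m <- loadAnnotation(bed, "bed12")
  expect_error(extractUTR3(m[1]), class = "apaNoUTR")
})

test_that("extension length is always within [0, 10000] and reflection
           leaves transcript-relative lengths unchanged", {
  set.seed(11)
  for (rep in 1:20) {
    utr <- sample(50:2000, 1)
    gap <- sample(c(50, 500, 5000, 20000), 1)
    end1 <- 1000 + utr
    nStart <- end1 + gap
    bed <- writeBed(c(
      sprintf("chr1\t100\t%d\tgA\t0\t+\t100\t1000\t0\t1\t%d,\t0,",
              end1, end1 - 100),
      sprintf("chr1\t%d\t%d\tgB\t0\t+\t%d\t%d\t0\t1\t1000,\t0,",
              nStart, nStart + 1000, nStart, nStart + 400)))
    m <- loadAnnotation(bed, "bed12")
    reg <- extractUTR3(m[1], m[2])
    ext <- extendedLen(reg) - annotatedLen(reg)
    expect_gte(ext, 0)
    expect_lte(ext, 10000)
    expect_equal(ext, min(10000, gap))
  }
})

test_that("extractAllUTR3 picks the longest-UTR transcript per gene", {
  bed <- writeBed(c(
    "chr1\t100\t1000\ttxShort\t0\t+\t100\t900\t0\t1\t900,\t0,",
    "chr1\t100\t1200\ttxLong\t0\t+\t100\t600\t0\t1\t1100,\t0,"))
  m <- loadAnnotation(bed, "bed12")
  m@info$gene_id <- c("g1", "g1")
  regs <- extractAllUTR3(m)
  expect_equal(length(regs), 1L)
  expect_equal(annotatedLen(regs$g1), 600)
})
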