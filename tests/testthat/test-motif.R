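test_that("polyA-signal scan finds exact and overlapping occurrences", {
  h <- scanPolyASignal("GGAATAAACC")
  expect_equal(h$offset, 2L)
  expect_equal(h$motif_id, "AATAAA")
  h2 <- scanPolyASignal("AATAAATAAA")
  expect_equal(h2$offset, c(0L, 4L))
  # U spelling equivalent to T, transcript-strand only
  expect_equal(scanPolyASignal("GGAAUAAACC")$offset, 2L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGAATAAACC")))
  expect_equal(nrow(scanPolyASignal(rc)), 0L)
  expect_error(scanPolyASignal("GGAXTAAACC"), "non-IUPAC")
  expect_equal(nrow(scanPolyASignal("GGGGGG")), 0L)
})

test_that("a near-deterministic PWM hits its consensus at rel score 1", {
  cons <- "ACGTAC"
  m <- matrix(0.01, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:6) m[substr(cons, j, j), j] <- 0.97
  pwm <- PWMModel("p1", m)
  h <- scanPWM(pwm, cons)
  expect_equal(nrow(h), 1L)
  expect_equal(h$offset, 0L)
  expect_equal(h$rel_score, 1, tolerance = 1e-12)
})

test_that("a uniform PWM is rejected as degenerate", {
  pwm <- PWMModel("flat", matrix(0.25, 4, 5,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL)))
  expect_error(scanPWM(pwm, "ACGTACGTA"), class = "apaDegeneratePWM")
})

test_that("PWM hits equal brute-force window scoring on random pairs", {
  set.seed(17)
  for (rep in 1:10) {
    w <- sample(4:8, 1)
    pwm <- randomPWM(w, paste0("r", rep))
    seq <- randomSeq(sample(60:150, 1))
    thr <- runif(1, 0.6, 0.9)
    got <- scanPWM(pwm, seq, thr)
    want <- oracleScanPWM(pwm@matrix, pwm@background, seq, thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$score, want$score, tolerance = 1e-10)
    expect_true(all(diff(got$offset) > 0))
  }
})

test_that("N bases score as background (0 contribution)", {
  cons <- "AAAA"
  m <- matrix(0.01, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", ] <- 0.97
  pwm <- PWMModel("pa", m)
  hFull <- scanPWM(pwm, "AAAA", minRelScore = 0)
  hN <- scanPWM(pwm, "AANA", minRelScore = 0)
  lo <- log2(pwm@matrix / pwm@background)
  expect_equal(hN$score, hFull$score - unname(lo["A", 3]))
})

test_that("site-count comparison reports gains in the long variant", {
  set.seed(19)
  m <- matrix(0.01, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:6) m[substr("AATAAA", j, j), j] <- 0.97
  pwm <- PWMModel("pasig", m)
  shortU <- paste0(randomSeq(80), "AATAAA", randomSeq(20))
  longU <- paste0(shortU, randomSeq(30), "AATAAA", randomSeq(10))
  tab <- compareSiteCounts(shortU, longU, list(pwm), minRelScore = 0.99)
  nS <- nrow(scanPWM(pwm, shortU, 0.99))
  nL <- nrow(scanPWM(pwm, longU, 0.99))
  expect_equal(tab$n_short, nS)
  expect_equal(tab$n_long, nL)
  expect_equal(tab$delta, nL - nS)
  expect_gte(tab$delta, 1)
  expect_equal(tab$per_kb_short, 1000 * nS / nchar(shortU))
  same <- compareSiteCounts(shortU, shortU, list(pwm))
  expect_equal(same$delta, 0)
})

test_that("PWMs round-trip through the TSV and MEME-minimal readers", {
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25), 4, 3,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste(rownames(m), apply(m, 1, paste, collapse = "\t"),
                   sep = "\t"), tsv)
  p1 <- readPWMs(tsv, "tsv")[[1]]
  meme <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF motA", "letter-probability matrix: alength= 4 w= 3",
               apply(t(m), 1, function(r) paste(sprintf("%.6f", r),
                                                collapse = " "))), meme)
  p2 <- readPWMs(meme, "meme")[["motA"]]
  expect_equal(p1@matrix, p2@matrix, tolerance = 1e-5)
  expect_equal(colSums(p1@matrix), rep(1, 3), ignore_attr = TRUE)
})
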