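test_that("a sharp coverage cliff sets the distal end", {
  t <- makeTrack(c(rep(10, 400), rep(0, 200)))
  expect_equal(detectDistalEnd(t), 400L)
})

test_that("sub-threshold gaps up to gapTol are bridged, longer ones stop
           the scan", {
  t <- makeTrack(c(rep(10, 400), rep(0, 30), rep(10, 170), rep(0, 100)))
  expect_equal(detectDistalEnd(t), 600L)
  t2 <- makeTrack(c(rep(10, 400), rep(0, 60), rep(10, 140)))
  expect_equal(detectDistalEnd(t2), 400L)
  expect_true(is.na(detectDistalEnd(makeTrack(rep(0, 300)))))
})

test_that("distal end matches the literal run/gap definition on random
           piecewise tracks", {
  set.seed(7)
  for (rep in 1:20) {
    pieces <- sample(2:6, 1)
    v <- unlist(lapply(seq_len(pieces), function(i)
      rep(sample(c(0, 0, 2, 10, 30), 1), sample(20:150, 1))))
    v[seq_len(50)] <- v[seq_len(50)] + 10  # ensure anchor coverage
    t <- makeTrack(v)
    expect_equal(detectDistalEnd(t), oracleDistalEnd(v))
  }
})

test_that("an exact step function is fitted with zero residual", {
  t <- makeTrack(c(rep(10, 50), rep(4, 50)))
  f <- fitBreakpoint(list(t), 100, minFlank = 50)
  expect_equal(breakpoint(f), 49)
  expect_equal(unname(f@wLong), 4)
  expect_equal(unname(f@wShort), 6)
  expect_equal(unname(pdui(f)), 0.4)
  expect_equal(f@rss, 0)
  expect_false(f@degenerate)
})

test_that("uniform coverage is degenerate: smallest admissible P, PDUI 1", {
  t <- makeTrack(rep(7, 200))
  f <- fitBreakpoint(list(t), 200, minFlank = 50)
  expect_equal(breakpoint(f), 49)   # smallest admissible on ties
  expect_equal(unname(pdui(f)), 1)
  expect_true(f@degenerate)
})

test_that("too-short regions and all-zero samples are handled", {
  t <- makeTrack(rep(5, 80))
  f <- fitBreakpoint(list(t), 80, minFlank = 50)
  expect_false(isTestable(f))
  z <- makeTrack(rep(0, 200), sampleId = "z")
  t2 <- makeTrack(c(rep(9, 100), rep(3, 100)), sampleId = "ok")
  f2 <- fitBreakpoint(list(t2, z), 200, minFlank = 50)
  expect_true(isTestable(f2))
  expect_true(is.na(pdui(f2)["z"]))
  expect_false(is.na(pdui(f2)["ok"]))
})

test_that("joint fit equals exhaustive enumeration on random instances", {
  set.seed(13)
  for (rep in 1:15) {
    D <- sample(120:400, 1)
    nS <- sample(1:4, 1)
    P <- sample(40:(D - 40), 1)
    vals <- lapply(seq_len(nS), function(s) {
      pi <- runif(1, 0.1, 0.9)
      depth <- runif(1, 5, 40)
      simulateCoverage(D, P, pi, depth)
    })
    tracks <- lapply(seq_along(vals), function(s)
      makeTrack(vals[[s]], sampleId = paste0("s", s)))
    fit <- fitBreakpoint(tracks, D, minFlank = 30)
    want <- oracleFitBreakpoint(vals, D, minFlank = 30)
    expect_equal(breakpoint(fit), want$P)
    expect_equal(unname(fit@wLong), want$wL, tolerance = 1e-10)
    expect_equal(unname(fit@wShort), want$wS, tolerance = 1e-10)
    expect_equal(fit@rss, want$rss, tolerance = 1e-10)
  }
})

test_that("scaling every track by a constant leaves P* and PDUI unchanged", {
  set.seed(21)
  vals <- lapply(1:3, function(s) simulateCoverage(300, 150, 0.4, 20))
  t1 <- lapply(seq_along(vals), function(s)
    makeTrack(vals[[s]], sampleId = paste0("s", s)))
  t2 <- lapply(seq_along(vals), function(s)
    makeTrack(vals[[s]] * 7.5, sampleId = paste0("s", s)))
  f1 <- fitBreakpoint(t1, 300)
  f2 <- fitBreakpoint(t2, 300)
  expect_equal(breakpoint(f1), breakpoint(f2))
  expect_equal(pdui(f1), pdui(f2), tolerance = 1e-12)
})

test_that("bias correction: identity mode, variance reduction on a ramp,
           and reduced PDUI bias on simulated decayed coverage", {
  t <- makeTrack(rpois(200, 20))
  expect_identical(correctBias(t, "none"), t)
  ramp <- makeTrack(seq(100, 20, length.out = 200))
  out <- correctBias(ramp, "linear_detrend")
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(coverageValues(out)), cv(coverageValues(ramp)))
  expect_equal(mean(coverageValues(out)), mean(coverageValues(ramp)))
  # paired simulation: beta = 0.5 decay, true pi known
  set.seed(31)
  piTrue <- 0.5
  errRaw <- errCorr <- numeric(40)
  for (i in 1:40) {
    v <- simulateCoverage(500, 250, piTrue, 50, biasBeta = 0.5)
    tr <- makeTrack(v)
    fRaw <- fitBreakpoint(list(tr), 500)
    fCor <- fitBreakpoint(list(correctBias(tr, "linear_detrend")), 500)
    errRaw[i] <- pdui(fRaw) - piTrue
    errCorr[i] <- pdui(fCor) - piTrue
  }
  expect_lt(abs(mean(errCorr)), abs(mean(errRaw)))
  expect_warning(correctBias(makeTrack(rep(5, 50)), "linear_detrend"),
                 "shorter than 100")
})

mkFit <- function(wL, wS, D, P, ids = names(wL)) {
  tot <- wL + wS
  new("APAFit", geneId = "g1", distalEnd = D, breakpoint = P,
      wLong = setNames(wL, ids), wShort = setNames(wS, ids),
      pdui = setNames(ifelse(tot > 0, wL / tot, NA_real_), ids),
      rss = 0, testable = TRUE, degenerate = FALSE)
}

test_that("group comparison: DPDUI arithmetic and Fisher p equals the
           hypergeometric enumeration", {
  # weights chosen so pooled read-equivalents form (90,10) vs (30,70)
  f <- mkFit(wL = c(A1 = 45, B1 = 15), wS = c(A1 = 10, B1 = 70),
             D = 700, P = 349)
  cmp <- compareGroups(f, "A1", "B1", fragLen = 350)
  expect_equal(unname(cmp@counts["A", ]), c(90, 10))
  expect_equal(unname(cmp@counts["B", ]), c(30, 70))
  expect_equal(cmp@pValue, oracleFisherP(cmp@counts), tolerance = 1e-12)
  pduis <- c(0.9, 0.9, 0.9, 0.3, 0.3, 0.3)
  f2 <- mkFit(wL = pduis * 10, wS = (1 - pduis) * 10, D = 700, P = 349,
              ids = c("A1", "A2", "A3", "B1", "B2", "B3"))
  cmp2 <- compareGroups(f2, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  expect_equal(dpdui(cmp2), 0.6)
})

test_that("identical groups give DPDUI 0 and p 1; swapping groups negates
           DPDUI", {
  f <- mkFit(wL = c(A1 = 20, B1 = 20), wS = c(A1 = 20, B1 = 20),
             D = 400, P = 199)
  cmp <- compareGroups(f, "A1", "B1")
  expect_equal(dpdui(cmp), 0)
  expect_equal(cmp@pValue, 1)
  f2 <- mkFit(wL = c(A1 = 30, B1 = 5), wS = c(A1 = 5, B1 = 30),
              D = 400, P = 199)
  ab <- compareGroups(f2, "A1", "B1")
  ba <- compareGroups(f2, "B1", "A1")
  expect_equal(dpdui(ab), -dpdui(ba))
  expect_equal(ab@pValue, ba@pValue, tolerance = 1e-12)
})

test_that("an untestable fit or a zero-margin table propagates safely", {
  f <- new("APAFit", geneId = "g1", distalEnd = NA_real_,
           breakpoint = NA_real_, wLong = c(A1 = NA_real_),
           wShort = c(A1 = NA_real_), pdui = c(A1 = NA_real_),
           rss = NA_real_, testable = FALSE, degenerate = FALSE)
  expect_equal(apaLabel(compareGroups(f, "A1", "B1")), "untestable")
  fz <- mkFit(wL = c(A1 = 0, B1 = 0), wS = c(A1 = 20, B1 = 20),
              D = 400, P = 199)
  expect_equal(compareGroups(fz, "A1", "B1")@pValue, 1)
})

test_that("Benjamini-Hochberg step-up matches hand-computed values", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.2), 0.2)
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  expect_equal(adjustBH(numeric(0)), numeric(0))
  # order preserved with input
  p <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(adjustBH(p), rep(0.04, 4))
})

test_that("classification applies the q and DPDUI thresholds", {
  df <- data.frame(dpdui = c(0.6, -0.25, 0.5, 0.1, NA),
                   q = c(0.001, 0.04, 0.2, 0.001, 0.01))
  expect_equal(classifyAPA(df),
               c("lengthened", "shortened", "unchanged", "unchanged",
                 "untestable"))
})
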