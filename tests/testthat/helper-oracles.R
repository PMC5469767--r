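# Independent brute-force oracles and small fixture builders.

makeTrack <- function(values, sampleId = "s1", geneId = "g1",
                      libSize = 1e6, scale = 1) {
  new("CoverageTrack", sampleId = sampleId, geneId = geneId,
      values = as.numeric(values), libSize = libSize, scale = scale)
}

makeRegion <- function(geneId = "g1", chrom = "chr1", strand = "+",
                       start = 100, end = 120, annotatedLen = NULL) {
  len <- end - start
  if (is.null(annotatedLen)) annotatedLen <- len
  new("UTR3Region", geneId = geneId, chrom = chrom, strand = strand,
      utrStart3 = start, utrEnd3 = end, annotatedLen = annotatedLen,
      extendedLen = len, capHit = "none")
}

bedGraphGR <- function(chrom, start0, end0, score) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0))
  gr$score <- score
  gr
}

# Literal per-base accumulation of bedGraph intervals over a region.
oracleExpand <- function(chrom, start0, end0, score, rChrom, rStart0, rEnd0) {
  v <- numeric(rEnd0 - rStart0)
  for (pos in rStart0:(rEnd0 - 1)) {
    for (k in seq_along(start0)) {
      if (chrom[k] == rChrom && pos >= start0[k] && pos < end0[k])
        v[pos - rStart0 + 1] <- v[pos - rStart0 + 1] + score[k]
    }
  }
  v
}

# Literal run/gap scan for the distal end definition.
oracleDistalEnd <- function(v, anchorLen = 100, frac = 0.05, minAbs = 1,
                            gapTol = 50) {
  anchor <- v[seq_len(min(anchorLen, length(v)))]
  if (all(anchor == 0)) return(NA_integer_)
  thr <- max(minAbs, frac * mean(anchor))
  covered <- v >= thr
  D <- 0L
  gap <- 0L
  for (i in seq_along(v)) {
    if (covered[i]) {
      D <- i
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > gapTol) break
    }
  }
  D
}

# Exhaustive enumeration of every candidate breakpoint with per-sample
# closed-form weights; ties toward the smallest P.
oracleFitBreakpoint <- function(valuesList, D, minFlank = 50) {
  Pcand <- seq.int(minFlank - 1L, D - minFlank - 1L)
  best <- NULL
  for (P in Pcand) {
    rss <- 0
    wL <- wS <- numeric(length(valuesList))
    for (s in seq_along(valuesList)) {
      C <- valuesList[[s]][seq_len(D)]
      short <- C[1:(P + 1)]
      long <- C[(P + 2):D]
      wL[s] <- mean(long)
      wS[s] <- max(0, mean(short) - wL[s])
      pred <- c(rep(wL[s] + wS[s], P + 1), rep(wL[s], D - P - 1))
      rss <- rss + sum((C - pred)^2)
    }
    if (is.null(best) || rss < best$rss)
      best <- list(P = P, wL = wL, wS = wS, rss = rss)
  }
  best
}

# Window-by-window PWM scoring.
oracleScanPWM <- function(mat, background, seq, minRelScore) {
  lo <- log2(mat / background)
  w <- ncol(mat)
  maxS <- sum(apply(lo, 2, max))
  minS <- sum(apply(lo, 2, min))
  bases <- strsplit(seq, "")[[1]]
  hits <- data.frame(offset = integer(), score = numeric())
  for (i in seq_len(length(bases) - w + 1)) {
    sc <- 0
    for (j in seq_len(w)) {
      b <- bases[i + j - 1]
      if (b %in% rownames(lo)) sc <- sc + lo[b, j]
    }
    rel <- (sc - minS) / (maxS - minS)
    if (rel >= minRelScore)
      hits <- rbind(hits, data.frame(offset = i - 1L, score = sc))
  }
  hits
}

# Two-sided Fisher p by direct hypergeometric enumeration.
oracleFisherP <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

randomPWM <- function(width, id = "pwm") {
  m <- matrix(stats::runif(4 * width, 0.05, 1), 4, width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- sweep(m, 2, colSums(m), "/")
  PWMModel(id, m)
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
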