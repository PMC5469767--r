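#' @include AllClasses.R
NULL

#' Detect the distal polyA site from merged coverage
#'
#' The distal polyA site is the end point of the longest 3'UTR supported by
#' any sample, found on the sample-merged coverage. A base is covered when
#' its depth reaches `max(minAbs, frac * anchor mean)`, where the anchor
#' mean is taken over the first `anchorLen` bases after the stop codon.
#' Scanning 5' to 3', sub-threshold gaps of at most `gapTol` nt are bridged
#' (alignment gaps); a longer gap terminates the scan so separate
#' downstream genes are not absorbed. The returned offset `D` is exclusive:
#' the covered 3'UTR is `[0, D)`.
#'
#' @param merged a [CoverageTrack], normally from [mergeTracks()].
#' @param anchorLen anchor window length (nt) defining the reference depth.
#' @param frac relative threshold as a fraction of the anchor mean.
#' @param minAbs absolute floor of the threshold (coverage units).
#' @param gapTol longest sub-threshold run (nt) bridged during the scan.
#' @return Integer offset `D`, or `NA` when the anchor has no coverage
#'   (gene untestable).
#' @export
detectDistalEnd <- function(merged, anchorLen = 100, frac = 0.05,
                            minAbs = 1.0, gapTol = 50) {
  stopifnot(is(merged, "CoverageTrack"))
  v <- merged@values
  L <- length(v)
  anchor <- v[seq_len(min(anchorLen, L))]
  if (all(anchor == 0)) return(NA_integer_)
  thr <- max(minAbs, frac * mean(anchor))
  r <- rle(v >= thr)
  D <- 0L
  pos <- 0L
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) {
      D <- pos + r$lengths[k]
    } else if (r$lengths[k] > gapTol) {
      break
    }
    pos <- pos + r$lengths[k]
  }
  as.integer(min(D, L))
}

#' Fit the two-isoform breakpoint model
#'
#' Models each sample's coverage over `[0, D)` as the superposition of a
#' long (distal) isoform at constant per-base density `wLong` over the full
#' region and a short isoform adding `wShort` over `[0, P]`. For a
#' candidate breakpoint P the per-sample weights are closed-form:
#' `wLong = mean(C over (P, D))` and
#' `wShort = max(0, mean(C over [0, P]) - wLong)`. A single breakpoint is
#' shared by all samples (that is what makes their PDUIs comparable): P* is
#' the candidate minimizing the squared residual summed over every track,
#' found by exhaustive scan, ties broken toward the smallest P. Candidates
#' keep at least `minFlank` nt on each side of the breakpoint. The
#' per-sample PDUI is `wLong / (wLong + wShort)` at P*.
#'
#' @param tracks list of [CoverageTrack] of one gene (same length >= D).
#' @param distalEnd exclusive distal offset D from [detectDistalEnd()].
#' @param minFlank minimum segment length (nt) on each side of P.
#' @return An [APAFit]. Untestable when `D < 2 * minFlank`.
#' @export
fitBreakpoint <- function(tracks, distalEnd, minFlank = 50) {
  stopifnot(length(tracks) >= 1)
  g <- tracks[[1]]@geneId
  ids <- vapply(tracks, function(t) t@sampleId, "")
  D <- as.integer(distalEnd)
  if (is.na(D) || D < 2 * minFlank) {
    return(new("APAFit", geneId = g, distalEnd = as.numeric(D),
               breakpoint = NA_real_,
               wLong = stats::setNames(rep(NA_real_, length(ids)), ids),
               wShort = stats::setNames(rep(NA_real_, length(ids)), ids),
               pdui = stats::setNames(rep(NA_real_, length(ids)), ids),
               rss = NA_real_, testable = FALSE, degenerate = FALSE))
  }
  # candidate P: short segment [0,P] and long-only segment (P,D) both
  # keep >= minFlank bases
  P <- seq.int(minFlank - 1L, D - minFlank - 1L)
  n1 <- P + 1
  n2 <- D - n1
  nS <- length(tracks)
  rssP <- numeric(length(P))
  muLs <- matrix(0, nS, length(P))
  wSs <- matrix(0, nS, length(P))
  for (s in seq_len(nS)) {
    C <- tracks[[s]]@values[seq_len(D)]
    S1 <- cumsum(C)
    S2 <- cumsum(C * C)
    s1 <- S1[n1]; q1 <- S2[n1]
    s2 <- S1[D] - s1; q2 <- S2[D] - q1
    muL <- s2 / n2
    wS <- pmax(0, s1 / n1 - muL)
    m1 <- muL + wS
    rssP <- rssP + (q1 - 2 * m1 * s1 + n1 * m1 * m1) +
                   (q2 - 2 * muL * s2 + n2 * muL * muL)
    muLs[s, ] <- muL
    wSs[s, ] <- wS
  }
  best <- which.min(rssP)   # first minimum = smallest P on ties
  wL <- stats::setNames(muLs[, best], ids)
  wS <- stats::setNames(wSs[, best], ids)
  tot <- wL + wS
  pdui <- ifelse(tot > 0, wL / tot, NA_real_)
  names(pdui) <- ids
  new("APAFit", geneId = g, distalEnd = as.numeric(D),
      breakpoint = as.numeric(P[best]), wLong = wL, wShort = wS,
      pdui = pdui, rss = rssP[best], testable = TRUE,
      degenerate = all(wS == 0))
}

#' Correct 5' to 3' coverage non-uniformity
#'
#' Library preparation can impose a monotone coverage trend along the
#' transcript that biases the step fit. `linear_detrend` fits a
#' least-squares line to `log1p(coverage)` over the distal-only portion of
#' the region (beyond `distalFrom`, where a single isoform contributes, so
#' the isoform step cannot leak into the trend), re-expands the line to
#' the full region, divides the coverage by the implied relative trend
#' (floored at 0.25 of its mean so low-coverage tails do not blow up),
#' and rescales so the output mean equals the input mean. Default mode is
#' `none`: the correction is opt-in.
#'
#' @param track a [CoverageTrack].
#' @param mode `"none"` or `"linear_detrend"`.
#' @param distalFrom first offset of the trend-fitting window; default
#'   60\% of the region length, distal to typical proximal sites.
#' @return A [CoverageTrack].
#' @export
correctBias <- function(track, mode = c("none", "linear_detrend"),
                        distalFrom = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(track)
  v <- track@values
  L <- length(v)
  if (L < 100) {
    warning("track shorter than 100 nt; bias correction skipped")
    return(track)
  }
  if (is.null(distalFrom)) distalFrom <- floor(0.6 * L)
  x <- seq_len(L) - 1
  win <- x >= distalFrom
  fit <- stats::lm.fit(cbind(1, x[win]), log1p(v[win]))
  trend <- expm1(cbind(1, x) %*% fit$coefficients)[, 1]
  mt <- mean(trend)
  if (!is.finite(mt) || mt <= 0) return(track)
  rel <- pmax(trend, 0.25 * mt) / mt
  out <- v / rel
  mo <- mean(out)
  if (mo > 0) out <- out * mean(v) / mo
  new("CoverageTrack", sampleId = track@sampleId, geneId = track@geneId,
      values = out, libSize = track@libSize, scale = track@scale)
}

#' Compare distal polyA usage between two sample groups
#'
#' Computes group mean PDUIs and their difference (DPDUI; positive =
#' lengthening in group A), converts the fitted per-base densities to
#' read-equivalents (`long = round(wLong * D / fragLen)`,
#' `short = round(wShort * (P + 1) / fragLen)`), pools them within group
#' into a 2x2 long/short table, and tests it with a two-sided Fisher exact
#' test. `fragLen` defaults to the 350 bp library insert target.
#'
#' @param fit an [APAFit].
#' @param groupA,groupB character vectors of sample ids in each group.
#' @param fragLen mean fragment length (nt) for read-equivalent scaling.
#' @return An [APAComparison] (qValue `NA` until [adjustBH()] is applied
#'   across genes).
#' @export
compareGroups <- function(fit, groupA, groupB, fragLen = 350) {
  stopifnot(is(fit, "APAFit"))
  empty <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("long", "short")))
  untest <- function() new("APAComparison", geneId = fit@geneId,
    pduiMeanA = NA_real_, pduiMeanB = NA_real_, dpdui = NA_real_,
    pValue = NA_real_, qValue = NA_real_, counts = empty,
    label = "untestable")
  if (!fit@testable) return(untest())
  pd <- fit@pdui
  pA <- pd[intersect(groupA, names(pd))]
  pB <- pd[intersect(groupB, names(pd))]
  if (sum(!is.na(pA)) == 0 || sum(!is.na(pB)) == 0) return(untest())
  D <- fit@distalEnd
  P <- fit@breakpoint
  longEq <- round(fit@wLong * D / fragLen)
  shortEq <- round(fit@wShort * (P + 1) / fragLen)
  tab <- rbind(
    A = c(long = sum(longEq[intersect(groupA, names(longEq))], na.rm = TRUE),
          short = sum(shortEq[intersect(groupA, names(shortEq))], na.rm = TRUE)),
    B = c(long = sum(longEq[intersect(groupB, names(longEq))], na.rm = TRUE),
          short = sum(shortEq[intersect(groupB, names(shortEq))], na.rm = TRUE)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
       else stats::fisher.test(tab)$p.value
  mA <- mean(pA, na.rm = TRUE)
  mB <- mean(pB, na.rm = TRUE)
  new("APAComparison", geneId = fit@geneId, pduiMeanA = mA, pduiMeanB = mB,
      dpdui = mA - mB, pValue = p, qValue = NA_real_, counts = tab,
      label = "unchanged")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, order-preserving with the
#' input), applied across all tested genes.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
adjustBH <- function(pValues) {
  if (length(pValues) == 0) return(numeric(0))
  stopifnot(all(is.na(pValues) | (pValues >= 0 & pValues <= 1)))
  stats::p.adjust(pValues, method = "BH")
}

#' Classify an APA comparison as lengthened / shortened / unchanged
#'
#' A gene is called lengthened when `q < alpha` and `DPDUI >= minDpdui`,
#' shortened when `q < alpha` and `DPDUI <= -minDpdui`, otherwise
#' unchanged; untestable comparisons propagate.
#'
#' @param comparison an [APAComparison] with `qValue` set, or a data.frame
#'   with columns `dpdui` and `q`.
#' @param alpha adjusted significance level.
#' @param minDpdui minimum absolute DPDUI effect size.
#' @return Character label(s).
#' @export
classifyAPA <- function(comparison, alpha = 0.05, minDpdui = 0.2) {
  if (is(comparison, "APAComparison")) {
    if (comparison@label == "untestable") return("untestable")
    return(.labelAPA(comparison@dpdui, comparison@qValue, alpha, minDpdui))
  }
  mapply(.labelAPA, comparison$dpdui, comparison$q,
         MoreArgs = list(alpha = alpha, minDpdui = minDpdui))
}

.labelAPA <- function(dpdui, q, alpha, minDpdui) {
  if (is.na(dpdui) || is.na(q)) return("untestable")
  if (q < alpha && dpdui >= minDpdui) return("lengthened")
  if (q < alpha && dpdui <= -minDpdui) return("shortened")
  "unchanged"
}
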