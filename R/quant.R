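#' @include AllClasses.R
NULL

#' Fragments per kilobase per million mapped fragments
#'
#' @param fragments fragment count assigned to the feature.
#' @param lengthBp feature length (bp), > 0.
#' @param totalFragments library size (mapped fragments), > 0.
#' @return `fragments * 1e9 / (lengthBp * totalFragments)`.
#' @examples
#' fpkm(100, 1000, 1e6)  # 100
#' @export
fpkm <- function(fragments, lengthBp, totalFragments) {
  if (any(lengthBp <= 0)) stop("lengthBp must be > 0")
  if (any(totalFragments <= 0)) stop("totalFragments must be > 0")
  fragments * 1e9 / (lengthBp * totalFragments)
}

#' Decompose gene FPKM into long- and short-3'UTR isoform shares
#'
#' Only the long isoform contributes reads to the distal-most exon, while
#' both isoforms cover the common 3'UTR domain, so the ratio of per-base
#' densities estimates the long-isoform fraction:
#' `fLong = min(1, distalDensity / commonDensity)`. The gene-level FPKM is
#' split accordingly, conserving the total. Over-unity ratios (sampling
#' noise at low coverage) clip to 1 rather than erroring.
#'
#' @param commonDensity mean per-base coverage over the common 3'UTR
#'   segment shared by both isoforms; must be > 0.
#' @param distalDensity mean per-base coverage over the distal-most exon
#'   (long isoform only).
#' @param fpkmTotal gene-level FPKM.
#' @return List with `fLong`, `fpkmLong`, `fpkmShort`
#'   (`fpkmLong + fpkmShort == fpkmTotal`).
#' @examples
#' splitByDistalExon(20, 8, 10)  # fLong 0.4 -> long 4, short 6
#' @export
splitByDistalExon <- function(commonDensity, distalDensity, fpkmTotal) {
  if (commonDensity <= 0) {
    if (distalDensity > 0) {
      cond <- structure(
        class = c("apaUndefinedSplit", "error", "condition"),
        list(message = "common-domain density is 0 with distal coverage; long fraction undefined",
             call = sys.call(-1)))
      stop(cond)
    }
    fLong <- 0
  } else {
    fLong <- min(1, distalDensity / commonDensity)
  }
  fpkmLong <- fpkmTotal * fLong
  list(fLong = fLong, fpkmLong = fpkmLong, fpkmShort = fpkmTotal - fpkmLong)
}

#' Comparative CT fold change
#'
#' The 2^-ddCT model for RT-PCR: target CT normalized to a reference gene
#' within each of a test and a control condition, and the difference of
#' differences exponentiated.
#'
#' @param ctTargetTest,ctRefTest target and reference CT in the test
#'   condition.
#' @param ctTargetCtrl,ctRefCtrl target and reference CT in the control
#'   condition.
#' @return Fold change `2^-(dCT_test - dCT_ctrl)`.
#' @examples
#' ddctFold(24, 18, 25, 18)  # one cycle earlier in test -> 2.0
#' @export
ddctFold <- function(ctTargetTest, ctRefTest, ctTargetCtrl, ctRefCtrl) {
  vals <- c(ctTargetTest, ctRefTest, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(vals))) stop("all CT values must be finite")
  2^-((ctTargetTest - ctRefTest) - (ctTargetCtrl - ctRefCtrl))
}

#' Quantify isoform abundance for a fitted gene in one sample
#'
#' Derives the segment densities from a coverage track and an [APAFit]
#' (common domain `[0, commonEnd)`, distal segment `(P, D)`), computes the
#' gene FPKM from total regional coverage, and splits it with
#' [splitByDistalExon()].
#'
#' @param track a raw [CoverageTrack] of one sample.
#' @param fit an [APAFit] (testable).
#' @param fragLen mean fragment length (nt) converting coverage to
#'   fragments.
#' @param commonEnd exclusive end of the common-domain segment; defaults to
#'   `min(400, P + 1)` (the two isoforms of the motivating gene share their
#'   first 400 nt).
#' @return One-row data.frame: gene_id, sample_id, fpkm_total, f_long,
#'   fpkm_long, fpkm_short.
#' @export
quantifyIsoforms <- function(track, fit, fragLen = 350, commonEnd = NULL) {
  stopifnot(is(track, "CoverageTrack"), is(fit, "APAFit"), fit@testable)
  D <- as.integer(fit@distalEnd)
  P <- as.integer(fit@breakpoint)
  if (is.null(commonEnd)) commonEnd <- min(400L, P + 1L)
  v <- track@values
  common <- mean(v[seq_len(commonEnd)])
  distal <- mean(v[(P + 2):D])
  fragments <- sum(v[seq_len(D)]) / fragLen
  total <- fpkm(fragments, D, track@libSize)
  sp <- splitByDistalExon(common, distal, total)
  data.frame(gene_id = fit@geneId, sample_id = track@sampleId,
             fpkm_total = total, f_long = sp$fLong,
             fpkm_long = sp$fpkmLong, fpkm_short = sp$fpkmShort,
             stringsAsFactors = FALSE)
}
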