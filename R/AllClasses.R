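#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Gene models parsed from BED12 or GTF
#'
#' Holds one record per transcript. Genomic coordinates in the `info` table
#' are 0-based half-open (`txStart`, `txEnd`, `cdsEnd3`); the exon list is
#' stored as a standard 1-based closed [IRanges::IRangesList] parallel to
#' `info`. `cdsEnd3` is the 3' edge of the stop codon in transcription
#' direction: the half-open end of the CDS on `+` transcripts and the
#' half-open start of the CDS on `-` transcripts, so the 3'UTR always begins
#' at `cdsEnd3` and runs downstream.
#'
#' @slot info A [S4Vectors::DataFrame] with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `txStart`, `txEnd`, `cdsEnd3`.
#' @slot exons An [IRanges::IRangesList], one element per transcript,
#'   sorted, disjoint, 1-based closed genomic intervals.
#' @exportClass GeneModels
setClass("GeneModels",
  representation(info = "DataFrame", exons = "IRangesList"))

setValidity("GeneModels", function(object) {
  info <- object@info
  need <- c("gene_id", "transcript_id", "chrom", "strand",
            "txStart", "txEnd", "cdsEnd3")
  if (!all(need %in% colnames(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (length(object@exons) != nrow(info))
    return("exons must be parallel to info")
  if (!all(info$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  for (i in seq_len(nrow(info))) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) return("each transcript needs >= 1 exon")
    st <- IRanges::start(ex) - 1L   # to 0-based
    en <- IRanges::end(ex)
    if (is.unsorted(st) || any(st[-1] < en[-length(en)]))
      return(sprintf("exons of %s not sorted/disjoint", info$transcript_id[i]))
    if (st[1] < info$txStart[i] || en[length(en)] > info$txEnd[i])
      return(sprintf("exons of %s outside transcript bounds",
                     info$transcript_id[i]))
    ce <- info$cdsEnd3[i]
    if (!any(ce >= st & ce <= en))
      return(sprintf("cdsEnd3 of %s not within an exon", info$transcript_id[i]))
  }
  TRUE
})

#' 3'UTR search region for one gene
#'
#' The genomically contiguous terminal-exon 3'UTR plus a downstream
#' extension (up to `maxExtension`, stopping before the nearest annotated
#' neighbour), the search space for distal polyA site detection.
#' `utrStart3`/`utrEnd3` are 0-based half-open genomic bounds.
#'
#' @slot geneId character scalar.
#' @slot chrom character scalar.
#' @slot strand `"+"` or `"-"`.
#' @slot utrStart3,utrEnd3 numeric scalars, 0-based half-open genomic bounds.
#' @slot annotatedLen annotated 3'UTR length (nt).
#' @slot extendedLen total region length including extension (nt).
#' @slot capHit which bound limited the extension: `"max"`, `"neighbor"`, or
#'   `"none"` (extension ran to the cap without meeting a neighbour is
#'   `"max"`; `"none"` only when no extension was requested).
#' @exportClass UTR3Region
setClass("UTR3Region",
  representation(geneId = "character", chrom = "character",
                 strand = "character", utrStart3 = "numeric",
                 utrEnd3 = "numeric", annotatedLen = "numeric",
                 extendedLen = "numeric", capHit = "character"))

setValidity("UTR3Region", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (object@utrEnd3 < object@utrStart3) return("empty or inverted region")
  if (object@extendedLen != object@utrEnd3 - object@utrStart3)
    return("extendedLen inconsistent with bounds")
  if (object@extendedLen < object@annotatedLen)
    return("extendedLen < annotatedLen")
  if (!object@capHit %in% c("max", "neighbor", "none"))
    return("capHit must be 'max', 'neighbor' or 'none'")
  TRUE
})

#' Per-base coverage over an extended 3'UTR, transcript-oriented
#'
#' `values[1]` is the first base after the stop codon (transcript-relative
#' offset 0) and indices increase 5' to 3' along the transcript; minus-strand
#' regions are reversed at load time so this always holds.
#'
#' @slot sampleId character scalar.
#' @slot geneId character scalar.
#' @slot values non-negative numeric vector, length = region `extendedLen`.
#' @slot libSize total mapped fragments of the originating library.
#' @slot scale normalization factor already applied (1 when raw).
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(sampleId = "character", geneId = "character",
                 values = "numeric", libSize = "numeric", scale = "numeric"))

setValidity("CoverageTrack", function(object) {
  if (any(object@values < 0)) return("coverage values must be >= 0")
  if (length(object@libSize) != 1L || object@libSize < 0)
    return("libSize must be a single non-negative number")
  TRUE
})

#' Fitted two-isoform breakpoint model for one gene
#'
#' @slot geneId character scalar.
#' @slot distalEnd transcript-relative exclusive offset D of the distal
#'   polyA site (the fitted region is `[0, D)`).
#' @slot breakpoint transcript-relative 0-based inclusive offset P of the
#'   last base covered by the short isoform, or `NA` when untestable.
#' @slot wLong,wShort named per-sample per-base densities: `wLong` is the
#'   distal (long-isoform) density, `wShort` the extra density of the short
#'   isoform over `[0, P]`.
#' @slot pdui named per-sample PDUI, `wLong/(wLong + wShort)`; `NA` where
#'   both weights are zero.
#' @slot rss total squared residual of the joint fit at the chosen P.
#' @slot testable logical flag.
#' @slot degenerate `TRUE` when no sample shows any short-isoform excess
#'   (all `wShort` = 0), in which case PDUI is 1 by construction.
#' @exportClass APAFit
setClass("APAFit",
  representation(geneId = "character", distalEnd = "numeric",
                 breakpoint = "numeric", wLong = "numeric",
                 wShort = "numeric", pdui = "numeric", rss = "numeric",
                 testable = "logical", degenerate = "logical"))

setValidity("APAFit", function(object) {
  if (object@testable && !is.na(object@breakpoint)) {
    if (object@breakpoint <= 0 || object@breakpoint >= object@distalEnd - 1)
      return("breakpoint must satisfy 0 < P < D - 1")
    if (any(object@wLong < 0) || any(object@wShort < 0))
      return("weights must be non-negative")
    ok <- !is.na(object@pdui)
    tot <- object@wLong + object@wShort
    if (any(abs(object@pdui[ok] - object@wLong[ok] / tot[ok]) > 1e-8))
      return("pdui inconsistent with weights")
  }
  TRUE
})

#' Between-group APA comparison for one gene
#'
#' @slot geneId character scalar.
#' @slot pduiMeanA,pduiMeanB group mean PDUI.
#' @slot dpdui `pduiMeanA - pduiMeanB`, in `[-1, 1]`.
#' @slot pValue two-sided Fisher exact p on the pooled long/short
#'   read-equivalent 2x2 table.
#' @slot qValue BH-adjusted p across all tested genes (`NA` until adjusted).
#' @slot counts 2x2 matrix (rows = groups, cols = long/short pooled
#'   read-equivalents).
#' @slot label one of `lengthened`, `shortened`, `unchanged`, `untestable`.
#' @exportClass APAComparison
setClass("APAComparison",
  representation(geneId = "character", pduiMeanA = "numeric",
                 pduiMeanB = "numeric", dpdui = "numeric",
                 pValue = "numeric", qValue = "numeric",
                 counts = "matrix", label = "character"))

setValidity("APAComparison", function(object) {
  if (!is.na(object@dpdui) && abs(object@dpdui) > 1 + 1e-12)
    return("|dpdui| must be <= 1")
  if (!object@label %in% c("lengthened", "shortened", "unchanged",
                           "untestable"))
    return("invalid label")
  TRUE
})

#' Position weight matrix for motif scanning
#'
#' Column-stochastic base probabilities over A, C, G, T (U is mapped to T at
#' scan time), regularized by a pseudocount and scored as log2 odds against
#' the background.
#'
#' @slot pwmId character scalar.
#' @slot matrix 4 x width numeric matrix with rownames A, C, G, T; each
#'   column sums to 1 after pseudocount regularization.
#' @slot pseudocount probability mass added to every cell before
#'   renormalization.
#' @slot background length-4 base frequency vector (A, C, G, T).
#' @exportClass PWMModel
setClass("PWMModel",
  representation(pwmId = "character", matrix = "matrix",
                 pseudocount = "numeric", background = "numeric"))

setValidity("PWMModel", function(object) {
  m <- object@matrix
  if (nrow(m) != 4L || is.null(rownames(m)) ||
      !identical(rownames(m), c("A", "C", "G", "T")))
    return("matrix must be 4 x width with rownames A, C, G, T")
  if (ncol(m) < 1L) return("width must be >= 1")
  if (any(abs(colSums(m) - 1) > 1e-6))
    return("columns must sum to 1")
  if (length(object@background) != 4L || any(object@background <= 0))
    return("background must be 4 positive frequencies")
  TRUE
})
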