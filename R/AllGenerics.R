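#' @include AllClasses.R
NULL

#' @rdname GeneModels-class
#' @param object,x a `GeneModels` object
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneModels-class
#' @export
setMethod("geneIds", "GeneModels", function(object) object@info$gene_id)

#' @rdname GeneModels-class
#' @export
setGeneric("transcriptIds", function(object) standardGeneric("transcriptIds"))

#' @rdname GeneModels-class
#' @export
setMethod("transcriptIds", "GeneModels",
          function(object) object@info$transcript_id)

#' @rdname GeneModels-class
#' @export
setGeneric("modelInfo", function(object) standardGeneric("modelInfo"))

#' @rdname GeneModels-class
#' @export
setMethod("modelInfo", "GeneModels", function(object) object@info)

#' @rdname GeneModels-class
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))

#' @rdname GeneModels-class
#' @export
setMethod("exonRanges", "GeneModels", function(object) object@exons)

#' @rdname GeneModels-class
#' @export
setMethod("length", "GeneModels", function(x) nrow(x@info))

#' @rdname GeneModels-class
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "GeneModels", function(x, i, j, ..., drop = TRUE) {
  new("GeneModels", info = x@info[i, , drop = FALSE], exons = x@exons[i])
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d transcript(s) on %d chromosome(s)\n",
              length(object), length(unique(object@info$chrom))))
  if (length(object) > 0)
    print(utils::head(as.data.frame(object@info), 5))
})

#' @rdname UTR3Region-class
#' @param object a `UTR3Region`
#' @export
setGeneric("annotatedLen", function(object) standardGeneric("annotatedLen"))

#' @rdname UTR3Region-class
#' @export
setMethod("annotatedLen", "UTR3Region", function(object) object@annotatedLen)

#' @rdname UTR3Region-class
#' @export
setGeneric("extendedLen", function(object) standardGeneric("extendedLen"))

#' @rdname UTR3Region-class
#' @export
setMethod("extendedLen", "UTR3Region", function(object) object@extendedLen)

#' @rdname UTR3Region-class
#' @export
setGeneric("capHit", function(object) standardGeneric("capHit"))

#' @rdname UTR3Region-class
#' @export
setMethod("capHit", "UTR3Region", function(object) object@capHit)

setMethod("show", "UTR3Region", function(object) {
  cat(sprintf(
    "UTR3Region %s %s:%d-%d(%s) annotated %d nt, extended %d nt [cap: %s]\n",
    object@geneId, object@chrom, object@utrStart3, object@utrEnd3,
    object@strand, object@annotatedLen, object@extendedLen, object@capHit))
})

#' @rdname CoverageTrack-class
#' @param object,x a `CoverageTrack`
#' @export
setGeneric("coverageValues", function(object) standardGeneric("coverageValues"))

#' @rdname CoverageTrack-class
#' @export
setMethod("coverageValues", "CoverageTrack", function(object) object@values)

#' @rdname CoverageTrack-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname CoverageTrack-class
#' @export
setMethod("sampleId", "CoverageTrack", function(object) object@sampleId)

#' @rdname CoverageTrack-class
#' @export
setGeneric("libSize", function(object) standardGeneric("libSize"))

#' @rdname CoverageTrack-class
#' @export
setMethod("libSize", "CoverageTrack", function(object) object@libSize)

#' @rdname CoverageTrack-class
#' @export
setMethod("length", "CoverageTrack", function(x) length(x@values))

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf(
    "CoverageTrack %s/%s: %d nt, mean depth %.2f (libSize %g, scale %g)\n",
    object@geneId, object@sampleId, length(object@values),
    mean(object@values), object@libSize, object@scale))
})

#' @rdname APAFit-class
#' @param object an `APAFit`
#' @export
setGeneric("breakpoint", function(object) standardGeneric("breakpoint"))

#' @rdname APAFit-class
#' @export
setMethod("breakpoint", "APAFit", function(object) object@breakpoint)

#' @rdname APAFit-class
#' @export
setGeneric("pdui", function(object) standardGeneric("pdui"))

#' @rdname APAFit-class
#' @export
setMethod("pdui", "APAFit", function(object) object@pdui)

#' @rdname APAFit-class
#' @export
setGeneric("isTestable", function(object) standardGeneric("isTestable"))

#' @rdname APAFit-class
#' @export
setMethod("isTestable", "APAFit", function(object) object@testable)

setMethod("show", "APAFit", function(object) {
  if (!object@testable) {
    cat(sprintf("APAFit %s: untestable\n", object@geneId))
  } else {
    cat(sprintf(
      "APAFit %s: D = %d, P = %d, rss = %.3f%s\n  PDUI: %s\n",
      object@geneId, object@distalEnd, object@breakpoint, object@rss,
      if (object@degenerate) " (degenerate: no short isoform)" else "",
      paste(sprintf("%s=%.3f", names(object@pdui), object@pdui),
            collapse = ", ")))
  }
})

#' @rdname APAComparison-class
#' @param object an `APAComparison`
#' @export
setGeneric("dpdui", function(object) standardGeneric("dpdui"))

#' @rdname APAComparison-class
#' @export
setMethod("dpdui", "APAComparison", function(object) object@dpdui)

#' @rdname APAComparison-class
#' @export
setGeneric("apaLabel", function(object) standardGeneric("apaLabel"))

#' @rdname APAComparison-class
#' @export
setMethod("apaLabel", "APAComparison", function(object) object@label)

setMethod("show", "APAComparison", function(object) {
  cat(sprintf(
    "APAComparison %s: PDUI %.3f vs %.3f, DPDUI %+.3f, p = %.3g, q = %s [%s]\n",
    object@geneId, object@pduiMeanA, object@pduiMeanB, object@dpdui,
    object@pValue,
    if (is.na(object@qValue)) "NA" else sprintf("%.3g", object@qValue),
    object@label))
})

setMethod("show", "PWMModel", function(object) {
  cat(sprintf("PWMModel %s: width %d, pseudocount %g\n",
              object@pwmId, ncol(object@matrix), object@pseudocount))
})
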