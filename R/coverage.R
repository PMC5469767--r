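#' @include AllClasses.R
NULL

#' Import a bedGraph track into a plain interval table
#'
#' Parses via `rtracklayer` and flattens to plain vectors (chrom, start,
#' end in 1-based closed coordinates, score) so that repeated regional
#' extraction across many genes stays cheap.
#'
#' @param track path to a bedGraph file, or a `GRanges` with `score`.
#' @return A data.frame of class `bedGraphTable`.
#' @export
bedGraphTable <- function(track) {
  if (is.character(track)) {
    if (!file.exists(track)) stop("bedGraph not found: ", track)
    track <- rtracklayer::import(track, format = "bedGraph")
  }
  stopifnot(is(track, "GRanges"))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                    start = GenomicRanges::start(track),
                    end = GenomicRanges::end(track),
                    score = track$score, stringsAsFactors = FALSE)
  class(out) <- c("bedGraphTable", "data.frame")
  out
}

#' Read per-base coverage for a 3'UTR region from a bedGraph track
#'
#' Expands bedGraph intervals (UCSC dialect, 0-based half-open) to a
#' per-base vector over the region, fills uncovered positions with 0, and
#' reverses minus-strand regions so index 1 is always the first base after
#' the stop codon and the vector runs 5' to 3' along the transcript. Values
#' are raw counts; normalization is a separate, explicit step.
#'
#' @param track path to a bedGraph file, a `GRanges` with a `score`
#'   column, or a [bedGraphTable()] (pre-importing once is much faster
#'   when reading many regions).
#' @param region a [UTR3Region].
#' @param sampleId sample label carried into the track.
#' @param libSize total mapped fragments of the library (from the sample
#'   sheet, not from the track, which is a regional extract).
#' @return A [CoverageTrack].
#' @export
readCoverage <- function(track, region, sampleId, libSize) {
  if (!inherits(track, "bedGraphTable")) track <- bedGraphTable(track)
  stopifnot(is(region, "UTR3Region"))
  L <- as.integer(region@extendedLen)
  values <- numeric(L)
  onChrom <- track$chrom == region@chrom
  if (!any(onChrom)) {
    warning(sprintf("chromosome %s absent from track; coverage all zero",
                    region@chrom))
  } else {
    starts <- track$start[onChrom]
    ends <- track$end[onChrom]
    scores <- track$score[onChrom]
    # region in 1-based closed coordinates
    r1 <- region@utrStart3 + 1
    r2 <- region@utrEnd3
    keep <- ends >= r1 & starts <= r2
    hs <- starts[keep]; he <- ends[keep]; sc <- scores[keep]
    if (length(hs) > 1) {
      o <- order(hs)
      hs <- hs[o]; he <- he[o]; sc <- sc[o]
      ov <- which(hs[-1] <= he[-length(he)])
      if (length(ov) > 0)
        stop(sprintf(
          "overlapping bedGraph intervals on %s: [%d,%d) overlaps [%d,%d)",
          region@chrom, hs[ov[1]] - 1, he[ov[1]], hs[ov[1] + 1] - 1,
          he[ov[1] + 1]))
    }
    for (k in seq_along(hs)) {
      a <- max(hs[k], r1) - r1 + 1
      b <- min(he[k], r2) - r1 + 1
      values[a:b] <- sc[k]
    }
  }
  if (region@strand == "-") values <- rev(values)
  new("CoverageTrack", sampleId = sampleId, geneId = region@geneId,
      values = values, libSize = as.numeric(libSize), scale = 1)
}

#' Depth-normalize a coverage track
#'
#' Scales values to per-million-fragments units so samples of different
#' sequencing depth are comparable before joint fitting. Re-normalizing an
#' already scaled track is rejected.
#'
#' @param track a [CoverageTrack].
#' @param perMillion if `FALSE`, the track is returned unchanged
#'   (scale 1).
#' @return A [CoverageTrack] with `scale` recording the factor applied.
#' @export
normalizeDepth <- function(track, perMillion = TRUE) {
  stopifnot(is(track, "CoverageTrack"))
  if (!perMillion) return(track)
  if (track@scale != 1) stop("track already normalized (scale = ",
                             track@scale, ")")
  if (track@libSize <= 0) stop("libSize must be > 0 to normalize")
  f <- 1e6 / track@libSize
  new("CoverageTrack", sampleId = track@sampleId, geneId = track@geneId,
      values = track@values * f, libSize = track@libSize, scale = f)
}

#' Merge coverage tracks of one gene across samples
#'
#' Element-wise sum, the combined coverage used to define the distal polyA
#' site over all samples jointly.
#'
#' @param tracks list of [CoverageTrack] sharing gene and length.
#' @return A [CoverageTrack] with `sampleId = "merged"`.
#' @export
mergeTracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  g <- unique(vapply(tracks, function(t) t@geneId, ""))
  if (length(g) != 1) stop("tracks belong to different genes: ",
                           paste(g, collapse = ", "))
  lens <- vapply(tracks, function(t) length(t@values), 0L)
  if (length(unique(lens)) != 1)
    stop("track lengths differ: ", paste(unique(lens), collapse = ", "))
  vals <- Reduce(`+`, lapply(tracks, function(t) t@values))
  new("CoverageTrack", sampleId = "merged", geneId = g, values = vals,
      libSize = sum(vapply(tracks, function(t) t@libSize, 0)), scale = 1)
}

#' Read a sample sheet
#'
#' TSV with header `sample_id, group, compartment, path, lib_size`
#' describing each library's coverage track and size.
#'
#' @param path sample sheet file.
#' @return data.frame with those columns.
#' @export
readSampleSheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "compartment", "path", "lib_size")
  miss <- setdiff(need, colnames(ss))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  ss
}
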