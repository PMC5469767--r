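#' @include AllClasses.R
NULL

#' Load gene annotation from BED12 or GTF
#'
#' Parses transcript models and normalizes both dialects onto a single
#' 0-based half-open internal representation. BED12 `thickStart`/`thickEnd`
#' delimit the CDS; GTF `exon` and `CDS` features are grouped by
#' `transcript_id`. Transcripts without a CDS (non-coding, or BED records
#' with `thickStart == thickEnd`) carry no 3'UTR and are skipped with a
#' warning. The result is ordered by (chrom, txStart, transcript_id).
#'
#' @param path annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @return A [GeneModels] object.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t1000\tgeneA\t0\t+\t150\t600\t0\t1\t900,\t0,", bed)
#' loadAnnotation(bed, "bed12")
#' @export
loadAnnotation <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  checkAnnotationLines(path, format)
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    models <- bedToGeneModels(gr)
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    models <- gtfToGeneModels(gr)
  }
  ord <- order(models@info$chrom, models@info$txStart,
               models@info$transcript_id, method = "radix")
  models[ord]
}

# Cheap pre-scan so malformed input is reported with its line number,
# which rtracklayer does not always do.
checkAnnotationLines <- function(path, format) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  minf <- if (format == "bed12") 12L else 9L
  bad <- which(nfield < minf)
  if (length(bad) > 0) {
    lineno <- which(keep)[bad[1]]
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab fields, got %d",
                 format, lineno, path, minf, nfield[bad[1]]))
  }
  invisible(TRUE)
}

bedToGeneModels <- function(gr) {
  thick <- gr$thick
  hasCDS <- IRanges::width(thick) > 0L
  if (any(!hasCDS))
    warning(sum(!hasCDS), " transcript(s) without CDS skipped")
  gr <- gr[hasCDS]
  thick <- gr$thick
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("BED12 records must be stranded")
  # 0-based half-open genomic fields
  txStart <- GenomicRanges::start(gr) - 1L
  txEnd <- GenomicRanges::end(gr)
  cdsEnd3 <- ifelse(strand == "+", IRanges::end(thick),
                    IRanges::start(thick) - 1L)
  blocks <- gr$blocks  # 1-based, relative to range start
  exons <- IRanges::shift(blocks, GenomicRanges::start(gr) - 1L)
  new("GeneModels",
      info = S4Vectors::DataFrame(
        gene_id = gr$name, transcript_id = gr$name,
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = strand, txStart = as.numeric(txStart),
        txEnd = as.numeric(txEnd), cdsEnd3 = as.numeric(cdsEnd3)),
      exons = exons)
}

gtfToGeneModels <- function(gr) {
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  txs <- unique(ex$transcript_id)
  withCDS <- txs %in% unique(cds$transcript_id)
  if (any(!withCDS))
    warning(sum(!withCDS), " transcript(s) without CDS skipped")
  txs <- txs[withCDS]
  info <- vector("list", length(txs))
  exl <- vector("list", length(txs))
  for (i in seq_along(txs)) {
    e <- ex[ex$transcript_id == txs[i]]
    cc <- cds[cds$transcript_id == txs[i]]
    strand <- as.character(GenomicRanges::strand(e))[1]
    er <- IRanges::IRanges(GenomicRanges::start(e), GenomicRanges::end(e))
    er <- er[order(IRanges::start(er))]
    cdsEnd3 <- if (strand == "+") max(GenomicRanges::end(cc))
               else min(GenomicRanges::start(cc)) - 1L
    info[[i]] <- data.frame(
      gene_id = e$gene_id[1], transcript_id = txs[i],
      chrom = as.character(GenomicRanges::seqnames(e))[1], strand = strand,
      txStart = min(IRanges::start(er)) - 1, txEnd = max(IRanges::end(er)),
      cdsEnd3 = as.numeric(cdsEnd3), stringsAsFactors = FALSE)
    exl[[i]] <- er
  }
  new("GeneModels",
      info = S4Vectors::DataFrame(do.call(rbind, info)),
      exons = IRanges::IRangesList(exl))
}

#' Write gene models back to BED12
#'
#' Inverse of [loadAnnotation()] for the BED12 dialect; parsing, writing and
#' re-parsing yields an identical object.
#'
#' @param models a [GeneModels] object.
#' @param path output file.
#' @export
writeAnnotationBed12 <- function(models, path) {
  info <- models@info
  lines <- character(length(models))
  for (i in seq_along(lines)) {
    ex <- models@exons[[i]]
    st0 <- IRanges::start(ex) - 1L
    sizes <- IRanges::width(ex)
    strand <- info$strand[i]
    thickStart <- if (strand == "+") findCdsStart(models, i) else info$cdsEnd3[i]
    thickEnd <- if (strand == "+") info$cdsEnd3[i] else findCdsEnd(models, i)
    lines[i] <- sprintf(
      "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
      info$chrom[i], info$txStart[i], info$txEnd[i], info$transcript_id[i],
      strand, thickStart, thickEnd, length(ex),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(st0 - info$txStart[i], collapse = ","), ","))
  }
  writeLines(lines, path)
  invisible(path)
}

# CDS extent is not stored beyond its 3' edge; for round-tripping, the CDS
# is written as running from the transcript 5' end to cdsEnd3.
findCdsStart <- function(models, i) models@info$txStart[i]
findCdsEnd <- function(models, i) models@info$txEnd[i]

#' Derive the 3'UTR search region of one gene
#'
#' The region spans from the stop codon's 3' edge to the annotated
#' transcript end and is then extended downstream (strand-aware) by up to
#' `maxExtension` nt, stopping before the nearest annotated neighbouring
#' transcript on either strand. The extension creates the search space for
#' distal polyA sites beyond the annotated gene end.
#'
#' @param gene a single-transcript [GeneModels] (or an index into `models`).
#' @param neighbors a [GeneModels] with candidate neighbouring transcripts
#'   (the gene itself is excluded by `transcript_id`).
#' @param maxExtension cap on the downstream extension (nt), default 10000.
#' @return A [UTR3Region].
#' @export
extractUTR3 <- function(gene, neighbors = NULL, maxExtension = 10000) {
  stopifnot(is(gene, "GeneModels"), length(gene) == 1L)
  info <- gene@info
  strand <- info$strand[1]
  ex <- gene@exons[[1]]
  st0 <- IRanges::start(ex) - 1
  en0 <- IRanges::end(ex)
  last <- if (strand == "+") length(ex) else 1L
  ce <- info$cdsEnd3[1]
  inLast <- ce >= st0[last] && ce <= en0[last]
  utrLen <- if (strand == "+") info$txEnd[1] - ce else ce - info$txStart[1]
  if (!inLast || utrLen <= 0) {
    cond <- structure(
      class = c("apaNoUTR", "error", "condition"),
      list(message = sprintf("gene %s has no terminal-exon 3'UTR",
                             info$gene_id[1]),
           call = sys.call(-1)))
    stop(cond)
  }
  extAllowed <- Inf
  if (!is.null(neighbors) && length(neighbors) > 0) {
    ni <- neighbors@info
    keep <- ni$transcript_id != info$transcript_id[1] &
      ni$chrom == info$chrom[1]
    ni <- ni[keep, , drop = FALSE]
    if (nrow(ni) > 0) {
      if (strand == "+") {
        geneEnd <- info$txEnd[1]
        down <- ni[ni$txEnd > geneEnd, , drop = FALSE]
        if (nrow(down) > 0)
          extAllowed <- min(pmax(down$txStart, geneEnd)) - geneEnd
      } else {
        geneStart <- info$txStart[1]
        down <- ni[ni$txStart < geneStart, , drop = FALSE]
        if (nrow(down) > 0)
          extAllowed <- geneStart - max(pmin(down$txEnd, geneStart))
      }
    }
  }
  ext <- min(maxExtension, extAllowed)
  cap <- if (maxExtension == 0 && extAllowed > 0) "none"
         else if (ext == maxExtension) "max" else "neighbor"
  if (strand == "+") {
    utrStart3 <- ce
    utrEnd3 <- info$txEnd[1] + ext
  } else {
    utrEnd3 <- ce
    utrStart3 <- info$txStart[1] - ext
  }
  new("UTR3Region", geneId = info$gene_id[1], chrom = info$chrom[1],
      strand = strand, utrStart3 = utrStart3, utrEnd3 = utrEnd3,
      annotatedLen = utrLen, extendedLen = utrLen + ext,
      capHit = cap)
}

#' Derive 3'UTR regions for all genes of an annotation
#'
#' One region per gene: among a gene's transcripts the one with the longest
#' annotated 3'UTR represents the gene (the per-gene breakpoint regression
#' needs a single search space). All other genes' transcripts act as
#' neighbours limiting the extension. Genes without a usable 3'UTR are
#' dropped with a warning.
#'
#' @param models a [GeneModels].
#' @param maxExtension see [extractUTR3()].
#' @return Named list of [UTR3Region] (names = gene ids).
#' @export
extractAllUTR3 <- function(models, maxExtension = 10000) {
  info <- as.data.frame(models@info)
  utrLen <- ifelse(info$strand == "+", info$txEnd - info$cdsEnd3,
                   info$cdsEnd3 - info$txStart)
  # representative transcript per gene: longest annotated 3'UTR
  ord <- order(info$gene_id, -utrLen, info$transcript_id, method = "radix")
  rep_idx <- ord[!duplicated(info$gene_id[ord])]
  out <- list()
  skipped <- character()
  for (i in rep_idx) {
    gid <- info$gene_id[i]
    strand <- info$strand[i]
    ex <- models@exons[[i]]
    st0 <- IRanges::start(ex) - 1
    en0 <- IRanges::end(ex)
    last <- if (strand == "+") length(ex) else 1L
    ce <- info$cdsEnd3[i]
    inLast <- ce >= st0[last] && ce <= en0[last]
    if (!inLast || utrLen[i] <= 0) { skipped <- c(skipped, gid); next }
    nb <- info$gene_id != gid & info$chrom == info$chrom[i]
    extAllowed <- Inf
    if (strand == "+") {
      geneEnd <- info$txEnd[i]
      down <- nb & info$txEnd > geneEnd
      if (any(down))
        extAllowed <- min(pmax(info$txStart[down], geneEnd)) - geneEnd
    } else {
      geneStart <- info$txStart[i]
      down <- nb & info$txStart < geneStart
      if (any(down))
        extAllowed <- geneStart - max(pmin(info$txEnd[down], geneStart))
    }
    ext <- min(maxExtension, extAllowed)
    cap <- if (maxExtension == 0 && extAllowed > 0) "none"
           else if (ext == maxExtension) "max" else "neighbor"
    if (strand == "+") {
      b1 <- ce; b2 <- info$txEnd[i] + ext
    } else {
      b2 <- ce; b1 <- info$txStart[i] - ext
    }
    out[[gid]] <- new("UTR3Region", geneId = gid, chrom = info$chrom[i],
                      strand = strand, utrStart3 = b1, utrEnd3 = b2,
                      annotatedLen = utrLen[i],
                      extendedLen = utrLen[i] + ext, capHit = cap)
  }
  if (length(skipped) > 0)
    warning("no usable 3'UTR for gene(s): ", paste(skipped, collapse = ", "))
  out[order(names(out))]
}

#' Tabulate 3'UTR regions
#'
#' @param regions list of [UTR3Region].
#' @return data.frame with columns gene_id, chrom, strand, utr_start3,
#'   utr_end3, annotated_len, extended_len, extension_cap_hit.
#' @export
utr3Table <- function(regions) {
  data.frame(
    gene_id = vapply(regions, function(r) r@geneId, ""),
    chrom = vapply(regions, function(r) r@chrom, ""),
    strand = vapply(regions, function(r) r@strand, ""),
    utr_start3 = vapply(regions, function(r) r@utrStart3, 0),
    utr_end3 = vapply(regions, function(r) r@utrEnd3, 0),
    annotated_len = vapply(regions, function(r) r@annotatedLen, 0),
    extended_len = vapply(regions, function(r) r@extendedLen, 0),
    extension_cap_hit = vapply(regions, function(r) r@capHit, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
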