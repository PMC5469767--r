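#' @include AllClasses.R
NULL

#' Default APA analysis parameters
#'
#' @return Named list: alpha (adjusted significance level), minDpdui
#'   (absolute DPDUI effect floor), fragLen (mean fragment length, nt),
#'   anchorLen / frac / minAbs / gapTol (distal-end detection), minFlank
#'   (breakpoint flank, nt), biasMode, coverageGate (minimum anchor-window
#'   mean coverage required of every compared sample), maxExtension (nt),
#'   perMillion (depth-normalize before fitting).
#' @export
apaParams <- function() {
  list(alpha = 0.05, minDpdui = 0.2, fragLen = 350, anchorLen = 100,
       frac = 0.05, minAbs = 1.0, gapTol = 50, minFlank = 50,
       biasMode = "none", coverageGate = 20, maxExtension = 10000,
       perMillion = FALSE)
}

#' Run the APA analysis for two sample groups
#'
#' Per gene: derive the extended 3'UTR region, load per-sample coverage,
#' merge, detect the distal polyA site, fit the joint breakpoint model,
#' compute per-sample PDUIs and the group comparison; then BH-adjust the
#' Fisher p-values across genes and classify lengthening/shortening.
#'
#' @param models a [GeneModels] annotation.
#' @param sampleSheet data.frame as from [readSampleSheet()].
#' @param groupA,groupB group names (levels of `sampleSheet$group`);
#'   positive DPDUI means lengthening in `groupA`.
#' @param params list as from [apaParams()] (partial overrides allowed).
#' @return List with `results` (per-gene data.frame: gene_id, D, P,
#'   per-sample PDUI columns, pdui_mean_A, pdui_mean_B, dpdui, p, q,
#'   label), `fits` (list of [APAFit]), `regions`, and `counts`
#'   (per-stage gene bookkeeping).
#' @export
runAPA <- function(models, sampleSheet, groupA, groupB,
                   params = apaParams()) {
  params <- utils::modifyList(apaParams(), params)
  ss <- sampleSheet[sampleSheet$group %in% c(groupA, groupB), , drop = FALSE]
  if (nrow(ss) == 0) stop("no samples in groups ", groupA, "/", groupB)
  idsA <- ss$sample_id[ss$group == groupA]
  idsB <- ss$sample_id[ss$group == groupB]
  regions <- extractAllUTR3(models, maxExtension = params$maxExtension)
  tracksGR <- lapply(stats::setNames(ss$path, ss$sample_id),
                     bedGraphTable)
  fits <- list()
  comps <- list()
  untestable <- 0L
  for (g in names(regions)) {
    region <- regions[[g]]
    tr <- lapply(seq_len(nrow(ss)), function(k) {
      t <- readCoverage(tracksGR[[ss$sample_id[k]]], region,
                        ss$sample_id[k], as.numeric(ss$lib_size[k]))
      if (params$perMillion) t <- normalizeDepth(t)
      correctBias(t, params$biasMode)
    })
    anchor <- vapply(tr, function(t)
      mean(t@values[seq_len(min(params$anchorLen, length(t@values)))]), 0)
    if (any(anchor < params$coverageGate)) { untestable <- untestable + 1L; next }
    merged <- mergeTracks(tr)
    D <- detectDistalEnd(merged, params$anchorLen, params$frac,
                         params$minAbs, params$gapTol)
    fit <- fitBreakpoint(tr, D, params$minFlank)
    if (!fit@testable) { untestable <- untestable + 1L; next }
    fits[[g]] <- fit
    comps[[g]] <- compareGroups(fit, idsA, idsB, params$fragLen)
  }
  if (length(comps) == 0) {
    return(list(results = data.frame(), fits = fits, regions = regions,
                counts = c(loaded = length(regions),
                           untestable = untestable, tested = 0L,
                           significant = 0L)))
  }
  res <- do.call(rbind, lapply(names(comps), function(g) {
    cm <- comps[[g]]
    f <- fits[[g]]
    pd <- as.list(f@pdui)
    names(pd) <- paste0("pdui_", names(f@pdui))
    cbind(data.frame(gene_id = g, D = f@distalEnd, P = f@breakpoint,
                     stringsAsFactors = FALSE),
          as.data.frame(pd),
          data.frame(pdui_mean_A = cm@pduiMeanA, pdui_mean_B = cm@pduiMeanB,
                     dpdui = cm@dpdui, p = cm@pValue,
                     stringsAsFactors = FALSE))
  }))
  res$q <- adjustBH(res$p)
  res$label <- classifyAPA(res, params$alpha, params$minDpdui)
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  nsig <- sum(res$label %in% c("lengthened", "shortened"))
  list(results = res, fits = fits, regions = regions,
       counts = c(loaded = length(regions), untestable = untestable,
                  tested = nrow(res), significant = nsig))
}

#' Filter a differential-expression table for enriched genes
#'
#' Keeps genes with `log2fc > minLog2fc` and `q < maxQ` (up), and
#' symmetrically `log2fc < -minLog2fc` and `q < maxQ` (down): the at least
#' two-fold, FDR-controlled enrichment rule.
#'
#' @param deTable data.frame with columns `gene`, `log2fc`, `q`.
#' @param minLog2fc fold-change threshold (log2), default 1.
#' @param maxQ FDR threshold, default 0.05.
#' @return List with character vectors `up` and `down`.
#' @export
filterEnriched <- function(deTable, minLog2fc = 1, maxQ = 0.05) {
  need <- c("gene", "log2fc", "q")
  miss <- setdiff(need, colnames(deTable))
  if (length(miss) > 0)
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(deTable$q >= 0 & deTable$q <= 1))
  list(up = deTable$gene[deTable$log2fc > minLog2fc & deTable$q < maxQ],
       down = deTable$gene[deTable$log2fc < -minLog2fc & deTable$q < maxQ])
}

#' Cross-tabulate APA status against differential expression
#'
#' Counts genes by APA label (lengthened / shortened / unchanged) and DE
#' status (up / down / ns); genes absent from the DE sets count as ns.
#' Row percentages are computed over genes with alternative 3'UTRs
#' (lengthened or shortened rows).
#'
#' @param apaLabels named character vector, gene -> APA label.
#' @param deSets list with `up` and `down` gene id vectors (e.g. from
#'   [filterEnriched()]).
#' @return List with `counts` (3x3 integer matrix) and `percent` (same
#'   shape, row percentages for the APA rows).
#' @export
crosstabApaDe <- function(apaLabels, deSets) {
  apaLabels <- apaLabels[apaLabels %in%
                         c("lengthened", "shortened", "unchanged")]
  genes <- names(apaLabels)
  if (length(intersect(genes, c(deSets$up, deSets$down))) == 0 &&
      length(c(deSets$up, deSets$down)) > 0)
    warning("no overlap between APA genes and DE sets; all genes counted ns")
  de <- ifelse(genes %in% deSets$up, "up",
               ifelse(genes %in% deSets$down, "down", "ns"))
  counts <- matrix(0L, 3, 3,
                   dimnames = list(c("lengthened", "shortened", "unchanged"),
                                   c("up", "down", "ns")))
  for (i in seq_along(genes))
    counts[apaLabels[i], de[i]] <- counts[apaLabels[i], de[i]] + 1L
  percent <- counts * NA_real_
  for (r in rownames(counts)) {
    tot <- sum(counts[r, ])
    percent[r, ] <- if (tot > 0) 100 * counts[r, ] / tot else 0
  }
  list(counts = counts, percent = percent)
}

#' Run the full APA pipeline and write its result bundle
#'
#' Stage order: annotation -> coverage -> distal-end detection -> joint
#' breakpoint fit -> group comparison -> BH adjustment -> classification
#' -> isoform quantification -> polyA-signal scan (when sequences are
#' given) -> DE cross-tabulation (when a DE table is given). Outputs are
#' tab-separated with headers; a run log records parameters and per-stage
#' gene counts. Reruns on identical inputs produce identical files.
#'
#' @param annotation path to a BED12 (or GTF with `annotationFormat`)
#'   annotation.
#' @param sampleSheet path to the sample sheet TSV.
#' @param groupA,groupB sample groups to compare.
#' @param outDir output directory.
#' @param fasta optional FASTA of transcript 3'UTR sequences to scan.
#' @param deTable optional DE table TSV (columns gene, log2fc, q).
#' @param params [apaParams()] overrides.
#' @param annotationFormat `"bed12"` or `"gtf"`.
#' @return Invisibly, list with `results`, `quant`, `hits`, `crosstab`,
#'   `counts` and the output paths.
#' @export
runPipeline <- function(annotation, sampleSheet, groupA, groupB, outDir,
                        fasta = NULL, deTable = NULL, params = list(),
                        annotationFormat = "bed12") {
  params <- utils::modifyList(apaParams(), params)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLines <- c(sprintf("apaScope %s",
                        as.character(utils::packageVersion("apaScope"))),
                sprintf("groups: %s vs %s", groupA, groupB),
                sprintf("params: %s",
                        paste(names(params), unlist(params), sep = "=",
                              collapse = " ")))
  models <- loadAnnotation(annotation, annotationFormat)
  ss <- readSampleSheet(sampleSheet)
  apa <- runAPA(models, ss, groupA, groupB, params)
  res <- apa$results
  resPath <- file.path(outDir, "apa_results.tsv")
  .writeTsv(res, resPath)

  # isoform quantification per testable gene and sample (raw coverage)
  ssUse <- ss[ss$group %in% c(groupA, groupB), , drop = FALSE]
  tracksGR <- lapply(stats::setNames(ssUse$path, ssUse$sample_id),
                     bedGraphTable)
  qrows <- list()
  for (g in names(apa$fits)) {
    fit <- apa$fits[[g]]
    for (k in seq_len(nrow(ssUse))) {
      t <- readCoverage(tracksGR[[ssUse$sample_id[k]]], apa$regions[[g]],
                        ssUse$sample_id[k], as.numeric(ssUse$lib_size[k]))
      qrows[[length(qrows) + 1]] <-
        quantifyIsoforms(t, fit, params$fragLen)
    }
  }
  quant <- if (length(qrows) > 0) do.call(rbind, qrows) else data.frame()
  quantPath <- file.path(outDir, "quant.tsv")
  .writeTsv(quant, quantPath)

  hits <- data.frame()
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    hl <- lapply(names(seqs), function(nm)
      scanPolyASignal(as.character(seqs[[nm]]), seqId = nm))
    hits <- do.call(rbind, hl)
  }
  hitsPath <- file.path(outDir, "hits.tsv")
  .writeTsv(hits, hitsPath)

  ct <- NULL
  ctPath <- file.path(outDir, "crosstab.tsv")
  if (!is.null(deTable) && nrow(res) > 0) {
    de <- utils::read.delim(deTable, stringsAsFactors = FALSE)
    sets <- filterEnriched(de)
    labels <- stats::setNames(res$label, res$gene_id)
    ct <- crosstabApaDe(labels, sets)
    ctDf <- data.frame(apa_label = rownames(ct$counts), ct$counts,
                       pct_up = ct$percent[, "up"],
                       pct_down = ct$percent[, "down"],
                       pct_ns = ct$percent[, "ns"],
                       stringsAsFactors = FALSE)
    .writeTsv(ctDf, ctPath)
  }
  logLines <- c(logLines,
                sprintf("genes loaded=%d untestable=%d tested=%d significant=%d",
                        apa$counts["loaded"], apa$counts["untestable"],
                        apa$counts["tested"], apa$counts["significant"]))
  writeLines(logLines, logPath)
  invisible(list(results = res, quant = quant, hits = hits, crosstab = ct,
                 counts = apa$counts,
                 paths = list(results = resPath, quant = quantPath,
                              hits = hitsPath, crosstab = ctPath,
                              log = logPath)))
}

.writeTsv <- function(df, path) {
  if (is.null(df) || nrow(df) == 0) {
    writeLines(if (!is.null(df) && ncol(df) > 0)
                 paste(colnames(df), collapse = "\t") else "", path)
    return(invisible(path))
  }
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
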