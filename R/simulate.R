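#' @include AllClasses.R
NULL

#' Simulate per-base 3'UTR coverage for one sample of one gene
#'
#' Two-isoform mixture: the long isoform covers the whole region `[0, L)`
#' at relative density `pi` (the true PDUI), the short isoform adds
#' `1 - pi` over `[0, pTrue]`. Counts are independent Poisson per base,
#' optionally attenuated by a linear 5' to 3' decay
#' `b(i) = 1 - biasBeta * i / L` emulating library-preparation
#' non-uniformity.
#'
#' @param L region length (nt).
#' @param pTrue true breakpoint (0-based inclusive), `0 < pTrue < L`.
#' @param pi true long-isoform fraction in `[0, 1]`.
#' @param depth mean per-base coverage of the common segment.
#' @param biasBeta slope of the linear decay, in `[0, 1)`.
#' @return Integer-valued numeric vector of length `L`. Uses the current
#'   RNG state; seed upstream for reproducibility.
#' @export
simulateCoverage <- function(L, pTrue, pi, depth, biasBeta = 0) {
  if (!(pTrue > 0 && pTrue < L)) stop("need 0 < pTrue < L")
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  if (depth <= 0) stop("depth must be > 0")
  if (biasBeta < 0 || biasBeta >= 1) stop("biasBeta must be in [0, 1)")
  i <- seq_len(L) - 1
  lambda <- depth * (1 - biasBeta * i / L) *
    (pi + (1 - pi) * (i <= pTrue))
  stats::rpois(L, lambda)
}

#' Simulation configuration
#'
#' Captures the emulated study design: two compartments (axon, cell body)
#' by two conditions (injury-conditioned ipsi, control contra) with 3
#' replicates each, genes carrying a short- and a long-3'UTR isoform mixed
#' at group-dependent proportions, Poisson read noise, optional 5' to 3'
#' coverage bias, and a fraction of genes whose true 3' end lies beyond
#' the annotated end (a distal read cluster inside the extension).
#'
#' @param nGenes number of genes.
#' @param groups named integer vector, group -> replicate count.
#' @param utrLenRange annotated 3'UTR length range (nt).
#' @param breakpointRel range of the true breakpoint's relative position
#'   within the true 3'UTR.
#' @param pduiByGroup `NULL` for the class-based defaults (see
#'   [defaultSimClasses()]), or a named numeric vector group -> true PDUI
#'   applied to every gene.
#' @param depth mean per-base coverage at the common segment.
#' @param biasBeta linear 5' to 3' decay slope, `[0, 1)`.
#' @param fragLen mean fragment length (nt), recorded for downstream
#'   read-equivalent scaling.
#' @param distalClusterFrac fraction of genes whose true 3' end extends
#'   beyond the annotated end.
#' @param distalClusterRange extra length range (nt) of such extensions.
#' @param libSize per-sample library size written to the sample sheet.
#' @param seed RNG seed.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nGenes = 50,
                      groups = c(ipsi_axon = 3, contra_axon = 3,
                                 ipsi_body = 3, contra_body = 3),
                      utrLenRange = c(500, 1500),
                      breakpointRel = c(0.35, 0.65),
                      pduiByGroup = NULL,
                      depth = 50, biasBeta = 0, fragLen = 350,
                      distalClusterFrac = 0.1,
                      distalClusterRange = c(500, 1500),
                      libSize = 24e6, seed = 1) {
  stopifnot(nGenes >= 1, all(groups >= 1), depth > 0,
            biasBeta >= 0, biasBeta < 1)
  if (!is.null(pduiByGroup)) {
    stopifnot(all(names(groups) %in% names(pduiByGroup)),
              all(pduiByGroup >= 0 & pduiByGroup <= 1))
  }
  structure(list(nGenes = nGenes, groups = groups,
                 utrLenRange = utrLenRange, breakpointRel = breakpointRel,
                 pduiByGroup = pduiByGroup, depth = depth,
                 biasBeta = biasBeta, fragLen = fragLen,
                 distalClusterFrac = distalClusterFrac,
                 distalClusterRange = distalClusterRange,
                 libSize = libSize, seed = seed),
            class = "SimConfig")
}

#' Default gene classes of the simulated design
#'
#' Mirrors the qualitative findings the generator emulates: most genes use
#' their 3'UTR isoforms alike in all compartments, a minority lengthen in
#' axons relative to cell bodies, a smaller minority shorten.
#'
#' @return data.frame with columns class, frac, pi_axon, pi_body.
#' @export
defaultSimClasses <- function() {
  data.frame(class = c("stable", "lengthened", "shortened"),
             frac = c(0.6, 0.25, 0.15),
             pi_axon = c(0.5, 0.9, 0.2),
             pi_body = c(0.5, 0.3, 0.6),
             stringsAsFactors = FALSE)
}

.piForGene <- function(config, geneClass, group) {
  if (!is.null(config$pduiByGroup)) return(config$pduiByGroup[[group]])
  cls <- defaultSimClasses()
  row <- cls[cls$class == geneClass, ]
  if (grepl("axon", group)) row$pi_axon else row$pi_body
}

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.plantHexamer <- function(seq, offset, motif = "AATAAA") {
  substr(seq, offset + 1, offset + nchar(motif)) <- motif
  seq
}

#' Simulate a complete APA dataset on disk
#'
#' Writes the exact dialects the analysis consumes: a BED12 annotation, one
#' bedGraph coverage track per sample, a FASTA of the true 3'UTR sequences
#' with AATAAA hexamers planted at the proximal breakpoint and 6 nt before
#' the distal end, a sample sheet, and a ground-truth table. Genes
#' alternate between the + and - strand and are spaced so the 10 kb
#' downstream extension never reaches a neighbour unless the spacing is
#' reduced. Output is byte-identical for identical seeds.
#'
#' @param config a [simConfig()] list.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the file paths (`annotation`, `tracks`,
#'   `fasta`, `sampleSheet`, `truth`) and the truth data.frame.
#' @export
simulateDataset <- function(config, outDir) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$nGenes
  slot <- 40000
  geneIds <- sprintf("gene_%04d", seq_len(n))
  strand <- rep(c("+", "-"), length.out = n)
  utrLen <- sample(seq(config$utrLenRange[1], config$utrLenRange[2]), n,
                   replace = TRUE)
  cls <- defaultSimClasses()
  geneClass <- sample(cls$class, n, replace = TRUE, prob = cls$frac)
  hasCluster <- stats::runif(n) < config$distalClusterFrac
  extra <- ifelse(hasCluster,
                  sample(seq(config$distalClusterRange[1],
                             config$distalClusterRange[2]), n,
                         replace = TRUE), 0L)
  dTrue <- utrLen + extra
  rel <- stats::runif(n, config$breakpointRel[1], config$breakpointRel[2])
  pTrue <- pmin(pmax(round(rel * dTrue), 60L), dTrue - 60L)

  cdsLen <- 300L
  # genomic layout, 0-based half-open; the annotated transcript covers CDS
  # plus the annotated 3'UTR only, the distal cluster lies beyond txEnd
  txStart <- txEnd <- cdsEnd3 <- numeric(n)
  for (i in seq_len(n)) {
    anchor <- (i - 1) * slot + 12000
    if (strand[i] == "+") {
      txStart[i] <- anchor
      cdsEnd3[i] <- anchor + cdsLen
      txEnd[i] <- cdsEnd3[i] + utrLen[i]
    } else {
      txEnd[i] <- anchor + cdsLen + utrLen[i]
      cdsEnd3[i] <- anchor + utrLen[i]
      txStart[i] <- anchor
    }
  }
  models <- new("GeneModels",
    info = S4Vectors::DataFrame(
      gene_id = geneIds, transcript_id = geneIds, chrom = "chrS",
      strand = strand, txStart = txStart, txEnd = txEnd,
      cdsEnd3 = cdsEnd3),
    exons = IRanges::IRangesList(lapply(seq_len(n), function(i)
      IRanges::IRanges(txStart[i] + 1, txEnd[i]))))
  annotPath <- file.path(outDir, "annotation.bed")
  writeAnnotationBed12(models, annotPath)

  # FASTA of true 3'UTR sequences with planted polyA signals
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- .randomSeq(dTrue[i])
    s <- .plantHexamer(s, pTrue[i])
    s <- .plantHexamer(s, dTrue[i] - 6L)
    seqs[i] <- s
  }
  fastaPath <- file.path(outDir, "utr_sequences.fa")
  fa <- character(0)
  for (i in seq_len(n)) {
    body <- substring(seqs[i], seq(1, nchar(seqs[i]), 60),
                      pmin(seq(60, nchar(seqs[i]) + 59, 60), nchar(seqs[i])))
    fa <- c(fa, paste0(">", geneIds[i]), body)
  }
  writeLines(fa, fastaPath)

  samples <- data.frame(sample_id = character(), group = character(),
                        stringsAsFactors = FALSE)
  for (gname in names(config$groups))
    for (r in seq_len(config$groups[[gname]]))
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_rep%d", gname, r), group = gname,
        stringsAsFactors = FALSE))
  samples$compartment <- ifelse(grepl("axon", samples$group), "axon", "body")
  samples$path <- file.path(outDir, paste0(samples$sample_id, ".bedGraph"))
  samples$lib_size <- format(config$libSize, scientific = FALSE)

  truth <- list()
  for (s in seq_len(nrow(samples))) {
    lines <- character(0)
    for (i in seq_len(n)) {
      pi <- .piForGene(config, geneClass[i], samples$group[s])
      v <- simulateCoverage(dTrue[i], pTrue[i], pi, config$depth,
                            config$biasBeta)
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = geneIds[i], sample_id = samples$sample_id[s],
        pi_true = pi, p_true = pTrue[i], d_true = dTrue[i],
        depth_realized = mean(v[seq_len(pTrue[i] + 1)]),
        stringsAsFactors = FALSE)
      # transcript offsets to genomic per-base values
      gv <- if (strand[i] == "+") v else rev(v)
      gStart <- if (strand[i] == "+") cdsEnd3[i] else cdsEnd3[i] - dTrue[i]
      r <- rle(gv)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values > 0
      if (any(keep))
        lines <- c(lines, sprintf("chrS\t%d\t%d\t%d",
                                  gStart + starts[keep],
                                  gStart + ends[keep],
                                  r$values[keep]))
    }
    writeLines(lines, samples$path[s])
  }
  truth <- do.call(rbind, truth)

  sheetPath <- file.path(outDir, "samples.tsv")
  utils::write.table(samples, sheetPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truthPath <- file.path(outDir, "truth.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(annotation = annotPath, tracks = samples$path,
                 fasta = fastaPath, sampleSheet = sheetPath,
                 truth = truthPath, truthTable = truth, models = models))
}
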