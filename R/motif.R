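#' @include AllClasses.R
NULL

#' Construct a position weight matrix model
#'
#' @param pwmId identifier.
#' @param matrix 4 x width matrix of base probabilities (rows A, C, G, T or
#'   A, C, G, U; columns need not be exactly normalized — they are
#'   renormalized after adding the pseudocount).
#' @param pseudocount probability mass added to each cell before column
#'   renormalization.
#' @param background base frequencies (A, C, G, T); uniform by default.
#' @return A [PWMModel].
#' @export
PWMModel <- function(pwmId, matrix, pseudocount = 0.01,
                     background = rep(0.25, 4)) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rn <- rownames(m)
  if (!is.null(rn)) {
    rn <- sub("U", "T", toupper(rn))
    if (!setequal(rn, c("A", "C", "G", "T")))
      stop("PWM rownames must be A, C, G, T/U")
    rownames(m) <- rn
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  }
  m <- m + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  new("PWMModel", pwmId = pwmId, matrix = m, pseudocount = pseudocount,
      background = background)
}

.cleanSeq <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "RNAString"))
    seq <- as.character(seq)
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- regmatches(s, regexpr("[^ACGTN]", s))
  if (length(bad) > 0 && nchar(bad) > 0)
    stop("non-IUPAC character in sequence: '", bad, "'")
  s
}

#' Scan a transcript sequence for polyadenylation-signal hexamers
#'
#' Reports every exact occurrence of the canonical polyA signal (and any
#' further configured hexamers) on the given strand only: the sequence is
#' taken 5' to 3' as transcribed, so the reverse complement is deliberately
#' not searched. Overlapping occurrences are all reported. U is treated
#' as T.
#'
#' @param seq nucleotide string (character, `DNAString` or `RNAString`).
#' @param motifs character vector of signal hexamers; default the canonical
#'   AAUAAA only (add `"ATTAAA"` for the common variant).
#' @param seqId identifier carried into the hits.
#' @return data.frame with columns seq_id, motif_id, offset (0-based),
#'   score, rel_score; offsets strictly increasing.
#' @examples
#' scanPolyASignal("GGAATAAACC")  # one hit at offset 2
#' @export
scanPolyASignal <- function(seq, motifs = "AATAAA", seqId = "seq") {
  s <- .cleanSeq(seq)
  motifs <- chartr("U", "T", toupper(motifs))
  hits <- list()
  for (m in motifs) {
    mm <- Biostrings::matchPattern(m, Biostrings::DNAString(s))
    if (length(mm) > 0)
      hits[[m]] <- data.frame(
        seq_id = seqId, motif_id = m,
        offset = Biostrings::start(mm) - 1L,
        score = nchar(m), rel_score = 1.0, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(seq_id = character(), motif_id = character(),
                      offset = integer(), score = numeric(),
                      rel_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence with a position weight matrix
#'
#' Windows are scored as `sum_j log2(matrix[base_j, j] / background[base_j])`
#' on the pseudocount-regularized matrix; N bases score 0 (background).
#' A window is reported when its relative score — its position in the span
#' between the minimal and maximal attainable score — reaches
#' `minRelScore`.
#'
#' @param pwm a [PWMModel].
#' @param seq nucleotide string, length >= PWM width.
#' @param minRelScore relative score threshold in `[0, 1]`.
#' @param seqId identifier carried into the hits.
#' @return data.frame as in [scanPolyASignal()], offsets strictly
#'   increasing.
#' @export
scanPWM <- function(pwm, seq, minRelScore = 0.8, seqId = "seq") {
  stopifnot(is(pwm, "PWMModel"))
  s <- .cleanSeq(seq)
  w <- ncol(pwm@matrix)
  if (nchar(s) < w) stop("sequence shorter than PWM width")
  lo <- log2(pwm@matrix / pwm@background)
  maxS <- sum(apply(lo, 2, max))
  minS <- sum(apply(lo, 2, min))
  if (maxS - minS < 1e-12) {
    cond <- structure(
      class = c("apaDegeneratePWM", "error", "condition"),
      list(message = sprintf(
        "PWM %s is degenerate: max and min attainable scores coincide",
        pwm@pwmId), call = sys.call(-1)))
    stop(cond)
  }
  base <- strsplit(s, "")[[1]]
  idx <- match(base, c("A", "C", "G", "T"))   # N -> NA, scores 0
  nWin <- nchar(s) - w + 1L
  score <- numeric(nWin)
  for (j in seq_len(w)) {
    bj <- idx[j:(j + nWin - 1L)]
    sc <- lo[, j][bj]
    sc[is.na(sc)] <- 0
    score <- score + sc
  }
  rel <- (score - minS) / (maxS - minS)
  keep <- which(rel >= minRelScore)
  data.frame(seq_id = rep(seqId, length(keep)),
             motif_id = rep(pwm@pwmId, length(keep)),
             offset = keep - 1L, score = score[keep],
             rel_score = rel[keep], stringsAsFactors = FALSE)
}

#' Compare motif site counts between short and long 3'UTR variants
#'
#' Scans both sequences with each PWM and tabulates hit counts, per-kb
#' rates, the count difference, and whether a motif is found only in the
#' long variant — the comparison behind asking whether a lengthened 3'UTR
#' gains regulatory (RBP) binding capacity.
#'
#' @param shortUtr,longUtr nucleotide strings (both nonempty).
#' @param pwms list of [PWMModel].
#' @param minRelScore threshold passed to [scanPWM()].
#' @return data.frame: pwm_id, n_short, n_long, per_kb_short, per_kb_long,
#'   delta (long - short), long_only (logical).
#' @export
compareSiteCounts <- function(shortUtr, longUtr, pwms, minRelScore = 0.8) {
  stopifnot(nchar(shortUtr) > 0, nchar(longUtr) > 0)
  rows <- lapply(pwms, function(p) {
    hs <- tryCatch(nrow(scanPWM(p, shortUtr, minRelScore, "short")),
                   error = function(e) stop(e))
    hl <- nrow(scanPWM(p, longUtr, minRelScore, "long"))
    data.frame(pwm_id = p@pwmId, n_short = hs, n_long = hl,
               per_kb_short = 1000 * hs / nchar(shortUtr),
               per_kb_long = 1000 * hl / nchar(longUtr),
               delta = hl - hs, long_only = hl > 0 && hs == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read PWMs from a simple 4-row TSV or MEME-minimal file
#'
#' The TSV dialect holds one matrix per file: 4 rows labelled A, C, G, T
#' (or U) and one column per motif position. MEME-minimal files may hold
#' several motifs (`MOTIF` blocks with a letter-probability matrix, rows =
#' positions, columns = A, C, G, T).
#'
#' @param path input file.
#' @param format `"tsv"` or `"meme"`.
#' @param pseudocount,background passed to [PWMModel()].
#' @return List of [PWMModel].
#' @export
readPWMs <- function(path, format = c("tsv", "meme"), pseudocount = 0.01,
                     background = rep(0.25, 4)) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = FALSE, row.names = 1,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    id <- tools::file_path_sans_ext(basename(path))
    return(list(PWMModel(id, m, pseudocount, background)))
  }
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) stop("no MOTIF blocks in ", path)
  out <- list()
  for (k in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[k]]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > starts[k]][1]
    if (is.na(hdr)) stop("MOTIF ", id, " lacks a letter-probability matrix")
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    m <- t(do.call(rbind, rows))   # to 4 x width
    rownames(m) <- c("A", "C", "G", "T")
    out[[id]] <- PWMModel(id, m, pseudocount, background)
  }
  out
}
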