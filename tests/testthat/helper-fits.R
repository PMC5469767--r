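# APAFit builder with D = 700, P = 349 so read-equivalents at the default
# fragment length equal round(2 * wLong) and round(wShort).
mkAccFit <- function(wL, wS) {
  tot <- wL + wS
  new("APAFit", geneId = "g1", distalEnd = 700, breakpoint = 349,
      wLong = wL, wShort = wS,
      pdui = ifelse(tot > 0, wL / tot, NA_real_),
      rss = 0, testable = TRUE, degenerate = FALSE)
}
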