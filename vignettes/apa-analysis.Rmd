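---
title: "Detecting alternative polyadenylation from 3'UTR coverage"
author: "apaScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative polyadenylation from 3'UTR coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaScope)
```

## The problem

Alternative cleavage and polyadenylation (APA) lets one gene produce
transcript isoforms that differ only in 3'UTR length. The 3'UTR houses
the cis-elements — polyA signals, RBP and miRNA sites — that control
where an mRNA goes and how long it lives, which matters acutely in
highly polarized cells such as sensory neurons, where transcripts are
shipped from the cell body into axons. Standard RNA-Seq does not read
out polyA sites directly, but it leaves a footprint: per-base coverage
over a 3'UTR steps down at the proximal polyA site, because only the
long isoform contributes beyond it. apaScope turns that footprint into
per-gene APA calls.

## The model

For gene coverage $C_s(i)$ of sample $s$ at transcript offset $i$
(offset 0 = first base after the stop codon), over the region
$[0, D)$ ending at the distal polyA site $D$:

$$\hat C_s(i) = w_{L,s} + w_{S,s}\,\mathbf{1}(i \le P)$$

with $w_{L,s} \ge 0$ the per-base density of the long (distal) isoform,
$w_{S,s} \ge 0$ the extra density of the short isoform, and $P$ the
last base covered by the short isoform — the proximal polyA site. At a
fixed $P$ the least-squares weights are closed-form: $w_{L,s}$ is the
mean coverage over $(P, D)$ and $w_{S,s} = \max(0,\,
\text{mean}_{[0,P]} - w_{L,s})$ (the non-negativity clamp prevents
anti-physical negative isoform densities). A single $P^\*$ is chosen
for all samples jointly by exhaustive scan of the total residual sum of
squares — sharing the breakpoint is what makes the per-sample usage
indices comparable. Ties go to the smallest $P$ (the most proximal
site); if no sample shows any short-isoform excess the fit is flagged
degenerate and PDUI is 1 by construction.

The percentage of distal polyA site usage index is
$\text{PDUI}_s = w_{L,s}/(w_{L,s}+w_{S,s})$, and a two-group comparison
reports $\Delta\text{PDUI} = \overline{\text{PDUI}}_A -
\overline{\text{PDUI}}_B$, positive for 3'UTR lengthening in group A.

### Model assumptions

* Exactly two isoforms per gene (one proximal, one distal site). Genes
  using three or more sites are approximated by their dominant pair;
  multi-breakpoint segmentation is out of scope.
* Coverage is locally flat within an isoform segment apart from
  counting noise. The least-squares criterion is exact maximum
  likelihood under Gaussian noise and a good working approximation for
  Poisson counts at the depths where APA calls are sensible.
* The 3'UTR is genomically contiguous. Spliced long 3'UTRs (a distal
  exon separated by an intron) surface as a distal read cluster inside
  the extension and are detected as such; their intronic gap is
  tolerated by the gap rule below, but the intron structure itself is
  not modelled.

## Search region and distal end

The per-gene search space is the terminal-exon 3'UTR (stop codon to
annotated transcript end) extended downstream, strand-aware, by up to
10 kb — stopping before the nearest annotated neighbouring transcript
on either strand. Blocking on both strands is conservative: it costs
search space but never counts antisense coverage toward the wrong
gene. When a gene has several transcripts, the one with the longest
annotated 3'UTR represents it, since the regression needs one region
per gene.

The distal end $D$ is called on sample-merged coverage: a base is
"covered" when its depth reaches $\max(c_{min},\,f \cdot \bar a)$ where
$\bar a$ is the mean over the first `anchorLen` = 100 nt and defaults
are $f = 0.05$, $c_{min} = 1$. Scanning 5'→3', sub-threshold runs up to
`gapTol` = 50 nt are bridged — enough to cross mappability gaps and
short introns in spliced 3'UTRs, short enough not to absorb a separate
downstream gene; a longer gap ends the scan.

## Significance and classification

With three replicates per group there are too few samples for a
per-gene t-type test on PDUIs, so evidence is pooled: each sample's
fitted densities convert to read-equivalents
($\text{long} = \text{round}(w_L D / \ell)$,
$\text{short} = \text{round}(w_S (P{+}1)/\ell)$ at mean fragment length
$\ell = 350$ nt, the library insert target), the 2×2 long/short table
pooled within groups is tested two-sided by Fisher's exact test, and p
values are Benjamini–Hochberg adjusted across all tested genes. A gene
is called **lengthened** when $q < \alpha$ and
$\Delta\text{PDUI} \ge 0.2$, **shortened** for
$\Delta\text{PDUI} \le -0.2$ ($\alpha = 0.05$ by default; both are
configuration). The absolute-effect floor of 0.2 follows common APA
practice and is what keeps the null false-call rate far below nominal
at high depth — pooled-count tests alone grow anti-conservative as
depth increases because they ignore biological replicate variance.

A testability gate requires mean anchor-window coverage of at least 20
in every compared sample; below that the breakpoint scan degenerates
into noise-chasing and the gene is reported untestable rather than
wrongly called.

## Bias correction

Library chemistry can impose a monotone 5'→3' coverage decay that
pushes the fitted breakpoint and PDUI off. The opt-in
`linear_detrend` mode fits a least-squares line to
$\log(1{+}C)$ over the distal-only portion of the region (beyond 60%
of its length by default, so the isoform step cannot leak into the
trend), re-expands the line to the full region, divides the coverage
by the implied relative trend — floored at 0.25 of its mean so
low-coverage tails cannot blow up — and rescales to preserve the mean.
Fitting the trend on the full region instead demonstrably
over-corrects: the step itself would be absorbed into the slope. The
correction is off by default because it is a model choice, not a
measurement.

## Isoform abundance

Only the long isoform covers the distal-most segment, while both cover
the common domain, so the density ratio estimates the long fraction:
$f_L = \min(1,\, d_{distal}/d_{common})$, and gene FPKM splits as
$\text{FPKM}_L = f_L \cdot \text{FPKM}$,
$\text{FPKM}_S = (1-f_L)\cdot\text{FPKM}$. Densities are per-base
means over their segments (the common domain defaults to the first
400 nt, the shared region length of the motivating gene's isoform
pair); per-base means rather than raw sums keep the ratio
length-invariant. The ratio clips at 1 instead of erroring — at low
coverage the ratio estimator's variance makes over-unity values an
expected nuisance, not a data error. A 2^−ΔΔCT helper supports qPCR
cross-validation of calls.

## Motif scanning

PolyA signals are searched as exact hexamer matches (canonical AAUAAA
by default; the common AUUAAA variant is a configuration away),
overlapping hits allowed, on the transcribed strand only — 3'UTR
sequences are directional, so the reverse complement is deliberately
not scanned. PWM scanning scores windows as
$\sum_j \log_2(m_{b_j,j}/\pi_{b_j})$ on a pseudocount-regularized
matrix (pseudocount 0.01, uniform background), reporting windows whose
relative score — position within the span between minimal and maximal
attainable score — reaches 80%, the customary threshold for this
scoring function. N bases score 0 (background). Uniform matrices,
whose score span is empty, are rejected as degenerate rather than
returning everything.

## The simulator

`simulateDataset()` emulates the study design the analysis targets:
two compartments × two conditions × three replicates, ~50× common-
segment depth, annotated 3'UTRs of 500–1500 nt with the true breakpoint
at 35–65% of the region, and a 10% minority of genes whose true distal
end lies 500–1500 nt beyond the annotated end (the distal-read-cluster
situation that motivates the 10 kb extension). Gene classes default to
60% stable, 25% axon-lengthened (PDUI 0.9 axon vs 0.3 body) and 15%
axon-shortened (0.2 vs 0.6). Noise is independent Poisson per base —
the simplest model consistent with the fit's least-squares criterion;
overdispersion is a documented extension point, and its absence means
passing recovery tests bound estimation error under ideal counting
noise, not under biological replicate dispersion, mappability
artefacts, or annotation errors in real data. AATAAA hexamers are
planted at the proximal breakpoint and 6 nt before the distal end,
matching canonical signal geometry closely enough for scan tests.
Output is byte-deterministic given the seed.

## Numerical choices and degenerate inputs

* Breakpoint candidates keep at least `minFlank` = 50 nt on both sides
  of $P$; shorter segments make the segment means too noisy to
  localize anything. Regions with $D < 2\,\text{minFlank}$ are
  untestable.
* The scan computes all candidate residuals from prefix sums, so a
  gene costs $O(D)$ per sample; `which.min` returns the first minimum,
  implementing the smallest-$P$ tie-break exactly.
* All-zero samples get an undefined PDUI; a comparison lacking any
  defined PDUI in either group is untestable. Pooled tables with a
  zero margin return $p = 1$ rather than erroring.
* Fisher's test and BH adjustment use the stock `stats`
  implementations; tests cross-check them against direct
  hypergeometric enumeration and hand-computed step-up values.
* Coordinates are 0-based half-open internally (BED convention);
  1-based closed interfaces (GTF, IRanges) are converted at the
  boundary, and minus-strand coverage is reversed once at load so all
  downstream code thinks in transcript orientation.

## Problem sizes in the tests

The shipped suites run the breakpoint oracle on 50 random instances
(regions up to 400 nt, 1–6 samples), recovery on 200 simulated genes
at 50× and $D = 500$, null calibration on 300 genes, power on 200
genes (PDUI 0.9 vs 0.3), and an end-to-end determinism run on a
20-gene dataset — sizes at which each check is already statistically
decisive while the whole suite stays interactive.

## Known limitations

* Two isoforms per gene; no multi-site segmentation.
* Coverage input is bedGraph; BAM pileup is upstream of this package.
* The Fisher/pooling test treats read-equivalents as independent
  counts; the DPDUI effect floor compensates, but p values at extreme
  depth should be read as evidence ranks, not calibrated error rates.
* The annotation choice (which transcript set defines gene ends) is
  the user's; results inherit its quality.
* Differential expression is consumed as an external table
  (gene/log2FC/q) and only filtered and joined, never re-fitted.
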