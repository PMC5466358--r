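---
title: "Simulating and benchmarking back-splice junction detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking back-splice junction detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(circbench)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor is joined to an
upstream splice acceptor (back-splicing), yielding a covalently closed
transcript. In RNA-seq the only sequence-level evidence of circularity is a
read that crosses the back-splice junction — the point where the 3' end of
the spliced circle continues into its own 5' end. Detection tools differ
substantially in how they recover such reads, and comparing them requires
(i) reads with known junction content, and (ii) a consistent scoring
methodology. `circbench` provides both: a simulator that emits paired-end
reads from circularized spliced transcripts with exact truth accounting, a
linear-mRNA background generator, and the downstream evaluation machinery
(confusion metrics, PR curves, method overlap, RNase R classification,
read-level clustering, validated-circRNA recovery).

All coordinates, in memory and on disk, are BED-style 0-based half-open.
GTF input is converted on read. Junction identity is the tuple
(chrom, start, end); strand is carried but only enters matching in an
optional strict mode, because callers report strand with varying
reliability.

## The circular read model

For a junction `[start, end)` the simulator builds a *circular template*:
the exons of the annotated transcript with the largest exonic overlap with
the interval, each intersected with it, spliced together (reverse
complemented as a whole on the minus strand). Without any overlapping
transcript the interval itself is the single exon. The template of spliced
length $L$ is circular: position $L-1$ is followed by position 0, and that
seam is the back-splice junction.

A fragment of length $F$ (the insert) starts at a uniform offset
$s \in \{0, \dots, L-1\}$ and reads the circle with wrap-around; when
$F > L$ it traverses the template repeatedly (rolling circle). Mate 1 is the
first `read_len` bases of the fragment; mate 2 the reverse complement of its
last `read_len` bases (FR orientation). A mate *supports the junction* iff
its interval on the circle wraps across offset 0, i.e. $s + R > L$ for mate
start $s$ and read length $R$. A pair is counted **once** toward the truth
support however many of its mates cross — the convention used by roughly
half of published callers; `convert_pair_counting()` maps truth counts to
the counted-twice convention, exactly when per-pair flags are available and
by doubling small circles ($L <$ insert, where geometry forces both mates
across) as a documented approximation otherwise.

Two sampling modes are provided because realistic study designs pin down
either a coverage or a support target, not both:

* **coverage mode** — pairs per circle $= \mathrm{round}(c \cdot L / (2R))$,
  starts uniform on the circle. Circles whose realized support falls outside
  the admissible `[min_support, max_support]` window (default 2–24 pairs,
  the range a CircBase-derived positive set exhibits) are re-drawn in target
  mode with a support sampled uniformly from that window, which reproduces
  the range without distorting within-range geometry.
* **target-support mode** — fragment starts are drawn uniformly from the set
  of offsets whose fragment crosses the junction, until exactly the
  requested number of supporting pairs exists. In this mode every emitted
  pair supports the junction, so `support_pairs == total_pairs`; datasets
  that should also carry non-supporting circle-derived pairs are produced in
  coverage mode.

Defaults mirror the simulated positive-set conditions of published
benchmarks: 101-bp reads, fixed 350-bp inserts (`insert_sd = 0`), 1%
substitution errors, seed 20160830. Substitutions hit each base
independently, uniformly over the three alternatives, never touching `N`;
the quality string is the constant Phred character
$\mathrm{round}(-10\log_{10}\varepsilon)$ (Phred 20 at 1%, Phred 40 for
error-free reads). Indels are not modeled on circular reads.

## The linear background

`simulate_background()` re-expresses an ART-style mRNA simulation natively:
per transcript, $\mathrm{round}(c \cdot \ell / (2R))$ pairs, inserts
$\mathcal{N}(350, 10)$ rounded and truncated to $[R, \ell]$, fragment starts
uniform on $[0, \ell - F]$ so nothing wraps — by construction the background
contributes zero true junctions, which the tests verify by string-searching
reads against every circle's junction-straddling substring. The default
substitution rate derives from a quality shift: a Phred-30 baseline shifted
down 13 points gives $10^{-1.7} \approx 2\%$, emulating deliberately poor
base quality. An optional per-base indel model (geometric length, truncated
to 1–3 bp) is applied at the fragment level so read lengths stay fixed;
it is off by default. Transcripts not longer than the mean insert are
skipped with a warning.

## Evaluation choices

* **Matching** is exact by default (tolerance 0 bp): simulated truth makes
  exact junction coordinates well-defined. A `tolerance` argument exists for
  real-tool outputs whose boundary adjustment differs; each prediction
  matches at most once.
* **Metrics**: $S = TP/|truth|$, $P = TP/\#detected$,
  $F1 = 2PS/(P+S)$, computed at full precision and rounded only for display
  (two decimals, percent scale for $S$ and $P$). `delta_metrics()`
  differences the *rounded* operands, since published drop figures arise
  from rounded table entries. The default support filter is ≥ 2 junction
  reads.
* **PR-AUC**: thresholds sweep the integer support values; the integral is
  trapezoidal over points sorted by recall ascending, anchored on the left
  by carrying the highest-threshold precision horizontally to recall 0, and
  never extrapolated beyond the largest observed recall. The anchor is what
  makes a perfect caller's AUC equal its maximum recall — the behavior
  summary tables of near-perfect callers exhibit (AUC ≈ sensitivity when
  precision ≈ 1); without it the integral would subtract the recall of the
  highest threshold, an artifact of threshold granularity.
* **Duplicate prediction rows** (same junction, same strand) merge by
  summing support, with a warning — the conservative reading of a
  "supporting read count" column across tool output dialects.

## Comparative analyses

* **Overlap**: $P(i,j) = C(i,j)/N_i$ with $C(i,j)$ the common-candidate
  count; rows with $N_i = 0$ are reported absent. At tolerance 0 the
  identities $P(i,j) N_i = C(i,j) = C(j,i)$ and $P(i,i)=1$ hold exactly and
  are property-tested.
* **RNase R classification**: junction counts are normalized per million
  sequenced read pairs (the constant cancels in ratios; "per million" is
  the conventional unit). With treated/untreated ratio $r$: depleted
  ($r < 1$), not depleted ($r \ge 1$ — ties count as not depleted, since
  the counts were "not reduced"), enriched ($r \ge 5$). The domain is the
  untreated sample's candidates at support ≥ 2; treated-only candidates are
  outside it. Top-N summaries rank by the untreated normalized count,
  breaking ties by genomic coordinate for determinism.
* **Read-level clustering**: candidates detected by all methods, minus those
  with spliced length below the insert size (where counting conventions
  diverge mechanically), log2(support + 1), Euclidean distance between
  method rows, average linkage (UPGMA) via `stats::hclust`; newick export
  via `ape`.
* **Validated recovery** counts how many junctions from an experimentally
  validated list are matched at support ≥ 1 and ≥ 2.

## The fixture generator

`make_fixture()` emulates the inputs a real benchmark downloads: a random
genome, multi-exon gene models, exon-bounded circles and spliced mRNAs.
Circle spans default to 51 bp – 50 kb; real catalogues extend to hundreds of
kb, but the simulator itself has no span ceiling and the reduced ceiling
keeps desk-scale runs fast. Junction support defaults to 2–24 pairs. Exon
lengths (80–400 bp) and intron lengths (100–2000 bp) are typical of compact
vertebrate-like gene models. Everything is deterministic under the spec
seed; infeasible specifications fail naming the violated constraint.

What the fixtures do **not** emulate: real base-composition and repeat
structure, trained sequencing-error profiles (substitutions are uniform;
real error rates are position- and context-dependent), expression-weighted
support distributions (supports are uniform in-range), alternative
isoforms per gene, intronic/intergenic circle biogenesis, and RNase R
biochemistry. Passing tests therefore demonstrate the correctness of the
geometry, accounting and metric arithmetic — not that any caller's
performance on real libraries is predicted.

## A worked example

```{r demo}
fx <- make_fixture(fixture_spec(n_genes = 8, n_circles = 10,
                                chrom_length = 120000, seed = 7))
templates <- lapply(seq_len(nrow(fx$circles)), function(i)
  build_circular_template(fx$circles[i, ], fx$exons, fx$genome))
sim <- simulate_circ_reads(templates, sim_config(coverage = 1, seed = 8))
head(sim$truth[, c("circ_id", "spliced_length", "genomic_span",
                   "support_pairs", "total_pairs")])

preds <- data.frame(tool = "demo", circ_id = sim$truth$circ_id,
                    chrom = sim$truth$chrom, start = sim$truth$start,
                    end = sim$truth$end, strand = sim$truth$strand,
                    support = sim$truth$support_pairs)
confusion(preds, sim$truth, min_support = 2)
pr_curve(preds, sim$truth)$auc
```

`end_to_end_demo()` chains fixture → circular simulation → background →
mixing → evaluation → overlap/RNase-R pseudo-analyses and writes a JSON
report; the test suite asserts its invariants (perfect caller scores 1.0
everywhere, 1-bp perturbations cost exactly the perturbed fraction of
precision, background contributes zero true positives).

## Numerical and degenerate-input notes

* Problem sizes in the tests (genomes ≤ 0.3 Mb, ≤ 30 circles, ≤ 10^4
  background pairs, one 10^6-base error-rate check) were chosen as the
  smallest instances at which every stochastic assertion has ≥ 3σ headroom.
* Fragment lengths are `round(rnorm)` truncated below at `read_len` (and at
  transcript length for the background), so `insert_sd = 0` yields exactly
  constant inserts.
* An empty prediction set gives an empty PR curve with AUC 0, absent
  precision and F1; an empty truth set leaves sensitivity absent.
* Ties everywhere are broken deterministically (coordinates for top-N,
  `hclust`'s stable ordering for clustering), so fixed seeds give
  byte-identical FASTQ, truth and report files — itself a tested property.
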