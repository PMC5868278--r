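---
title: "Methods: stop-codon readthrough discovery and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stop-codon readthrough discovery and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthrough)
```

Stop codon readthrough is the decoding of a UGA/UAG/UAA stop codon by a
near-cognate tRNA, so that translation continues in frame and produces a
C-terminally extended proteoform. In mammals the tetranucleotide CUAG
immediately 3' of a UGA stop (the UGA_CUAG motif) marks contexts with
unusually efficient readthrough; the vitamin D receptor (VDR) carries this
motif and its readthrough extension yields the proteoform known as VDRx.
This package implements the computational side of that discovery route as a
reusable, testable pipeline: a transcriptome-wide motif census with a
depletion test, extension-ORF extraction and reporter-insert design, a
phylogenetic coding-potential score with frame-integrity event calling, and
dual-luciferase quantification — together with synthetic-data generators
that give every stage a known ground truth.

## The motif census and its null model

`census()` counts, over deduplicated stop contexts, how often a motif
(default `TGA:CTAG` — a TGA stop immediately followed by CTAG) occurs, and
compares the count with an independence null: the expected count is

$$E = N \prod_{i=1}^{4} f_i(m_i),$$

where $N$ is the number of eligible contexts (stop codon matching the
motif, at least four unambiguous downstream nucleotides) and $f_i$ is the
empirical frequency of nucleotide $m_i$ at downstream position $i$ across
those same contexts. Contexts with `N` bases inside the window are dropped
from both numerator and denominator so observed and expected are computed
on the same sample. The one-sided p-value is the exact binomial tail
(`exact_binomial`) or its Poisson limit (`poisson_limit`,
$\lambda = Np$); the direction defaults to whichever side of $E$ the
observed count falls on and is recorded in the result. With the printed
census numbers — 23 observed against a null mean of 39 — the Poisson-limit
lower tail is 0.0040, and the exact binomial at $N = 10{,}000$,
$p = 0.0039$ agrees within 2%.

Two counting conventions exist for $N$ (transcripts versus unique genomic
stops); `run_census()` reports both, and the test uses unique stops, the
natural census denominator once isoforms sharing a stop are collapsed by
`dedupe_stops()`.

## Extension ORFs and reporter inserts

`find_extension()` scans in-frame codons 3' of the annotated stop until the
next stop codon. The count of codons strictly between the two stops
(`between_stops_codons`) excludes both; the extension peptide additionally
includes the residue decoded at the recoded stop, so
`extension_aa_length = between_stops_codons + 1`. This convention
reconciles the two ways extension length is conventionally reported — a
66-codon between-stop region corresponds to a 67-residue appended peptide —
and both counts are returned. The recoded-stop residue is rendered as a
configurable symbol (default `X`), because the amino acid inserted at a
read-through UGA is determined by tRNA competition, not by the transcript.

`design_reporter_insert()` builds the dual-luciferase test insert: 6 nt 5'
of the stop, the stop codon, and up to 12 nt 3' of it. The downstream
segment is truncated to whole codons ending before the first in-frame stop
inside the window — a stop codon inside the fusion insert would terminate
the reporter frame — and further truncated at the transcript end. A context
whose first downstream in-frame stop sits at codon 4 therefore yields 9 nt
of 3' sequence. A control insert with the stop changed to TGG (tryptophan,
one transversion from TGA) is emitted alongside; the TGG construct decodes
the insert constitutively and anchors the efficiency denominator.

## The coding-potential score

`csf_score()` asks whether a reference-framed codon alignment evolves like
protein-coding sequence. It is a likelihood-ratio score in decibans,

$$S = 10 \log_{10} \frac{P(\text{alignment} \mid \text{coding model})}
{P(\text{alignment} \mid \text{noncoding model})},$$

with both likelihoods computed by Felsenstein pruning over the 64-codon
state space down a fixed tree. It deliberately follows the score and
region conventions of PhyloCSF-class methods (positive = coding-like,
region between the stops, neither stop included) while being an explicit
simplified surrogate, **not** a PhyloCSF reimplementation: the empirical
codon models and fitted parameter sets of that tool are not reproduced
here. Scores from this package and published PhyloCSF scores of real
readthrough regions are therefore comparison points on the same scale,
never expected to match numerically.

The two regimes are:

* **coding** — a GY94-style model on the 61 sense codons: single-nucleotide
  changes only, rate $\kappa$ for transitions, target-nucleotide stationary
  frequency as an HKY-style factor, and $\omega$ multiplying nonsynonymous
  changes. Stop codons carry zero stationary mass and no flow.
* **noncoding** — three independent HKY nucleotide processes, one per codon
  position, composed onto the codon space; its transition matrix is exactly
  the tensor product of three 4×4 HKY matrices, and stop codons are
  ordinary states.

Defaults are $\kappa = 2.5$, $\omega = 0.2$ and F3×4-style frequencies
estimated from the alignment (with a 0.5 pseudocount); all are
conventional starting points and overridable. Both generators are
reversible and scaled so one unit of branch length is one expected
nucleotide substitution per site (three per codon), keeping branch lengths
in the units trees are usually published in.

### Numerical choices

Transition matrices come from the symmetric-form eigendecomposition of the
reversible generator ($D^{1/2} Q D^{-1/2}$ with $D = \mathrm{diag}(\pi)$),
cached per model. Pruning uses per-column scaling by the column maximum to
avoid underflow on deep trees. Tiny negative entries from
eigendecomposition round-off are clipped to zero inside the pruning
recursion, so an impossible configuration (mismatched leaves joined by
zero-length branches) propagates as a log-sum with a zero partial —
reaching `-Inf` or a round-off-bounded value near it, never `NaN`. Codons
containing gaps or ambiguity codes are treated as missing data (all-ones
partials): indel signal is deliberately routed to the frame-integrity
caller rather than the likelihood.

Stop codons inside the scored region need special care. The coding model
assigns them probability zero, so they cannot simply be "missing under the
coding model only": that would hand the coding model a free pass on exactly
the cells where the noncoding model pays full probability, and inflates the
score of any stop-containing alignment. They are therefore masked — treated
as missing — under **both** models, so the ratio compares the regimes on
identical effective data; the number of masked reference-row stops is
reported in the result.

### Percentile ranking and frame integrity

`background_percentile()` ranks a score against an empirical background of
scores of same-sized regions, returning the fraction strictly below —
mirroring how a single region's coding signal is judged against the
transcriptome-wide distribution of 3'-of-stop regions. Whether that
background should span all transcripts or only UGA-stop transcripts is a
judgment call the package leaves to the caller (the background is simply a
numeric vector, built under either policy).

`frame_integrity()` reports, per species: frameshifting indels (cumulative
indel length relative to the reference not divisible by 3, localised to the
codon where frame is first lost — for a deletion the codon containing the
deleted reference base, for an insertion the codon starting after it);
in-frame premature stops read at reference codon positions while the
species is in frame; and loss of the reference second stop. Species codons
that overlap gaps are unreadable and skipped, and a species that is out of
frame at a codon is not scanned for premature stops there, since its codon
boundaries no longer align. Whole-codon and mutually compensating indels
produce no frameshift event. An in-frame stop in the reference row itself
is reported (under the reference species) rather than treated as fatal.

## Dual-luciferase quantification

Per-replicate readthrough efficiency is

$$\text{\%RT} = 100 \cdot
\frac{(F/R)_{\text{TGA}}}{\overline{(F/R)}_{\text{TGG}}},$$

the relative luciferase activity (firefly/Renilla) of a stop-codon test
well divided by the control activity of the same construct and batch. The
default divides by the **mean** of the same-batch TGG controls, which is
robust to unequal replicate counts; a `paired` mode dividing by the
same-index control replicate is also provided, since plate layouts differ
in whether test and control wells are meaningfully paired. Efficiencies
are summarised with R's default type-7 quantiles, whiskers at the most
extreme values within 1.5 interquartile ranges of the box, and values
beyond as outliers — the conventions of the standard box-whisker figure.
The statistic is invariant to rescaling either luminescence channel.

Transactivation fold-change is the mean stimulated relative activity over
the mean vehicle relative activity per construct, with a delta-method
standard error. Dose-response curves are fitted as four-parameter
logistics on log10 dose by Levenberg–Marquardt least squares
(`minpack.lm`), multi-started from data-derived initial values (extreme
per-dose means for floor/top, interpolated half-max crossing for EC50,
slopes 0.5/1/2), tolerance 1e-8, at most 500 iterations. `dose_shift()`
reports the fitted EC50 ratio plus a fit-free estimate by horizontal
interpolation of per-dose means at the shared half-maximal response; the
latter is flagged unavailable when the response ranges do not overlap.

## What the synthetic generators emulate — and what they do not

`sim_transcriptome()` emulates the census substrate: single-isoform
transcripts with a 5' UTR, an ATG-initiated CDS ending in a stop drawn
from a human-like stop usage mix (TGA 48%, TAA 28%, TAG 24%), and a 3'
UTR whose first four nucleotides follow position-specific frequencies,
with a multiplicative `motif_factor` applied to the joint motif
probability after TGA stops (the planted depletion or enrichment the
census must recover). The default post-stop frequencies mildly favour the
motif bases (0.4 at each own position; joint motif probability 2.56%):
real stop contexts are non-uniform, and a closed-form Poisson power
calculation shows that at 5,000 UGA stops a motif with the uniform-null
probability of 0.39% carries too few expected counts (≈20) for a 0.6-fold
depletion to be detectable at $\alpha = 0.01$ with 90% power, whereas at
2.56% (≈128 expected) power exceeds 99%. The generator does not simulate
multi-isoform genes, splicing, or ribosome-profiling coverage.

`sim_codon_alignment()` draws a root from the model's stationary
distribution and evolves it along every branch with the model's transition
probabilities. Indels are planted on terminal branches only, as deletions
of 1–3 nt (so frameshifting, non-multiple-of-3 events occur), never on the
reference row; full indel inheritance down the tree would require an
alignment engine and is irrelevant to what the downstream callers consume.
Real alignments additionally contain alignment error, lineage-specific
rate variation and selection heterogeneity that the simulator does not
model — so passing tests demonstrate correctness of the statistics, not
performance on real genomes.

`sim_plate()`, `sim_transactivation()` and `sim_dose_response()` apply
multiplicative lognormal noise (median 1, given CV) independently to every
luminescence reading, reflecting that luminescence is positive with noise
scaling with signal; systematic plate effects (edge wells, injector drift)
are not modelled. All generators take one integer seed and draw everything
from a single restored-afterwards RNG stream, so identical spec + seed
gives byte-identical output.

## Study-scale choices

The simulation experiments in the test suite use a fixed balanced 8-taxon
tree (`sim_tree()`, every branch 0.15 substitutions/site, total length
2.1) and 66-codon regions — the length of the VDR between-stop region —
with 200 alignments per regime for separation estimates and 100 seeds for
recovery-rate estimates; plates use 12 replicates at CV 0.1 and truths of
0.7, 1.3 and 6.7% readthrough; dose-response recovery uses a 100-fold EC50
ratio at CV 0.05 with 8 replicates on a 13-point grid. These sizes were
chosen as the smallest at which the planted effects are comfortably
identifiable, keeping the whole suite quick to run.

## Known limitations

* The scorer is a surrogate: it shares PhyloCSF's units and conventions
  but not its empirical codon models, so real-data scores are not
  reproduced, only the sign/separation behaviour that the discovery logic
  relies on.
* Branch lengths are taken as given; there is no branch-length or
  parameter estimation.
* `load_transcripts()` requires `exon` features to splice from genomic
  sequence and handles the two common CDS dialects (stop excluded, the
  default, or included via `stop_in_cds = TRUE`); selenoprotein UGA
  recoding annotations are out of scope.
* Frame-integrity calls are descriptive alignment features, not ancestral
  reconstructions: a deletion relative to the reference row is not
  evidence about which lineage the event occurred in.
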