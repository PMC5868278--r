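# readthrough

Tools for discovering and quantifying **stop codon readthrough** — the
decoding of a UGA/UAG/UAA stop codon by a near-cognate tRNA so that
translation continues in frame and appends a C-terminal extension to the
protein. In mammals, a UGA stop immediately followed by CUAG (the
UGA_CUAG motif) marks contexts with unusually efficient readthrough; the
vitamin D receptor mRNA carries this motif, and readthrough of its stop
codon produces the extended proteoform VDRx. This package implements the
computational pipeline behind that kind of discovery, end to end, for
anyone studying recoding in transcriptomes:

* **Motif census** — count a stop-context motif over deduplicated
  annotated stops and test depletion/enrichment against the independence
  null `E = N · ∏ᵢ fᵢ(mᵢ)` built from position-specific nucleotide
  frequencies, with an exact one-sided binomial (or Poisson-limit) tail.
* **Extension ORFs** — extract the region between the annotated stop and
  the next in-frame stop, translate it (`extension_aa_length =
  between_stops_codons + 1`, the extra residue being the one decoded at
  the recoded stop), and design dual-luciferase reporter inserts (6 nt 5',
  stop, ≤12 nt 3', truncated to whole codons before any in-frame stop).
* **Coding potential** — score a reference-framed codon alignment with a
  likelihood ratio of a GY94-style coding model versus a composed-HKY
  noncoding model, computed by Felsenstein pruning and reported in
  decibans (10·log₁₀ ratio, positive = coding-like); rank scores against
  an empirical background and call per-species frame-integrity events
  (frameshifting indels, premature stops, second-stop loss).
* **Reporter assays** — readthrough efficiency as 100 × (firefly/Renilla
  of the TGA construct) / (control TGG activity), box-whisker summaries
  (type-7 quantiles, 1.5·IQR whiskers), transactivation fold-changes, and
  EC50 dose-shift estimates from four-parameter logistic fits.
* **Synthetic data** — seeded generators for transcriptomes with a planted
  motif depletion, codon alignments simulated down a tree under either
  regime, luciferase plates with known true efficiencies, and sigmoidal
  dose-response curves, so every stage is testable with known ground
  truth.

All user-facing functions take and return tibbles (or small S3 result
objects with `tidy()`/`glance()`/`autoplot()` methods) and chain with the
pipe.

## Worked example

```r
library(readthrough)

# a 5000-transcript TGA-stop transcriptome with a planted 0.6x motif depletion
tx <- sim_transcriptome(5000, motif_factor = 0.6,
                        stop_codon_mix = c(TAA = 0, TAG = 0, TGA = 1),
                        cds_length_range = c(30, 60),
                        utr3_length_range = c(10, 20), seed = 42)
run_census(transcripts = tx)$result
#> Stop-context motif census (TGA:CTAG)
#>   observed 91 of 5000 trials; expected 121.0 (p_motif = 0.0242)
#>   one-sided depletion p-value (exact_binomial): 0.002395
```

The census recovered the planted depletion: 91 motif stops observed where
the position-frequency null expects 121 (ratio 0.75, truth 0.6 before
sampling noise), one-sided p = 0.0024.

```r
# a dual-luciferase plate with 6.7% true readthrough, 12 replicates, 10% CV
plate <- sim_plate(0.067, n_replicates = 12, cv = 0.1,
                   construct = "VDR", seed = 42)
readthrough_efficiency(plate)[, c("construct", "n", "median", "q25", "q75")]
#> # A tibble: 1 × 5
#>   construct     n median   q25   q75
#>   <chr>     <int>  <dbl> <dbl> <dbl>
#> 1 VDR          12   7.25  6.63  8.10
```

The per-replicate efficiencies (percent) summarise to a median of 7.25%
against a truth of 6.7% — within the dispersion expected at this noise
level. `autoplot()` on the result draws the box-whisker figure.

```r
# score a 66-codon region simulated under the coding regime on an 8-taxon tree
tree <- sim_tree()
aln  <- sim_codon_alignment(tree, 66, build_codon_model("coding"), seed = 42)
csf_score(aln, tree)
#> coding-potential score: 334.52 decibans over 66 codons, 8 species

# dose-response curves 100x apart in EC50, and the recovered shift
d <- sim_dose_response(c(VDR = 1e-10, VDRx = 1e-8), noise_cv = 0.05, seed = 42)
fits <- lapply(split(d, d$curve_id), fit_dose_response)
dose_shift(fits$VDR, fits$VDRx)
#> # A tibble: 1 × 3
#>   shift_fit shift_interp interp_available
#>       <dbl>        <dbl> <lgl>
#> 1      88.7         88.1 TRUE
```

A strongly positive score (in decibans) says the alignment evolves like
coding sequence; noncoding-simulated alignments score strongly negative.
The fitted and fit-free dose-shift estimators agree that the second curve
needs ~90× more ligand for the same response (truth 100×).

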