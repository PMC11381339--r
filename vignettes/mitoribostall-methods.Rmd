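---
title: "Methods: codon-resolution mitoribosome stalling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-resolution mitoribosome stalling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoribostall)
```

# The problem

The human mitochondrial genome encodes 13 membrane subunits of the
oxidative-phosphorylation complexes, translated by mitoribosomes on
leaderless, transcript-punctuated mRNAs. Several of these proteins carry
polyproline stretches. Proline's pyrrolidine ring makes it a poor
peptidyl donor (P-site) and acceptor (A-site), so consecutive prolines
slow peptide-bond formation; in bacteria and the cytosol dedicated
factors (EF-P, eIF5A) resolve the resulting stalls. Mitoribosome
profiling measures where mitoribosomes sit at codon resolution, and
comparing occupancy between genotypes (wild type, a factor knockout, and
a reconstituted rescue) localises factor-dependent stalling.

This package implements that comparison end to end, together with a
simulator that generates footprint data with known dwell-time structure
so every stage can be validated against ground truth.

# Transcriptome model

Coordinates are 0-based, half-open, on mRNA-sense transcript sequences;
the L-strand gene (ND6) is stored already reverse-complemented, so no
strand arithmetic exists downstream. Bicistronic units (ATP8/ATP6,
ND4L/ND4) are single transcripts carrying two ORF annotations; a
footprint whose A-site lies in the overlap contributes to both ORF
profiles, in each ORF's own reading frame.

Several mitochondrial mRNAs end in a partial stop codon completed by
polyadenylation; such ORFs are flagged `stop_completed_by_polyA`, their
trailing 1–2 nt are never translated, and each bundled transcript ends in
a 30-nt oligo(A) tail so that footprints over these stops remain
representable. Occupancy vectors have one position per codon *including*
the terminal stop (protein length + 1), because the offset calibration
anchors on termination peaks.

Translation uses the vertebrate mitochondrial code (table 2): `TGA` =
Trp, `ATA` = Met, `AGA`/`AGG` = stop. An internal stop during ORF
translation is a hard error: it indicates a broken annotation, not data.

The bundled human fixture was built once (`data-raw/build_fixtures.R`)
from the complete human mtDNA genome NC_001807.4 shipped with the seqinr
package, with every ORF validated by translation (no internal stops,
canonical protein lengths). The yeast proteome fixture is a clearly
labelled *synthetic* stand-in: real S. cerevisiae mtDNA-encoded protein
sequences were not available for redistribution, so eight proteins with
realistic lengths and amino-acid composition are sampled under a fixed
seed with the documented motif structure (2xPro runs only in COX1 and
COX3; proteome proline content about half the human value). Census
results on that fixture demonstrate the machinery and mirror the
documented biology; they are not measurements of the real yeast
sequences.

# A-site offset calibration

The A-site of a footprint is inferred as 5′ end + offset(read length).
Two diagnostics determine the offset per read length:

1. **Stop-codon metagene.** A terminating ribosome holds the stop codon
   in its A-site, so 5′ ends of footprints near the calibration gene's
   stop (default COX1, the best-covered ORF with a complete stop) pile up
   at −offset relative to the stop's first nucleotide. The histogram mode
   fixes the base offset; ties break toward the geometric expectation
   15 + (length − 32) nt, i.e. P-site at +12 nt for a 32-nt footprint and
   the A-site one codon downstream. A flat histogram (mode ≤ 1.5× the
   median bin) is flagged `no_clear_peak` and leaves the length
   unassigned.
2. **Triplet phasing.** Ribosome A-sites fall overwhelmingly in reading
   frame 0, so the base offset is adjusted by at most ±1 nt to maximise
   the frame-0 fraction of in-ORF A-sites. Adjusted offsets outside the
   plausible window (default 13–20 nt) are discarded and flagged.

On simulated data the recovered offsets equal the configured truth
exactly without noise, and stay within ±1 nt under Poisson noise at
depth ≥ 50 reads/codon. Frame-0 fractions plateau near 0.997 rather than
1.0 on the full transcriptome because the bicistronic overlaps are
mutually out of frame — a property of the annotation, not a calibration
error.

# Occupancy and normalisation

Counts are accumulated per ORF codon. Two normalisations are exposed:
`rel_within` (per-codon counts / ORF total; used for all stall
statistics) and `rel_across` (per-gene totals / all-ORF total). Both sum
to 1 by construction whenever signal exists, and both are invariant to
uniform depth scaling; the test suite asserts count conservation
(assigned + dropped = input) on every simulated dataset. Only
protein-coding ORF positions enter the analysis; footprints with
uncalibrated lengths or out-of-ORF A-sites are dropped and reported, not
silently discarded.

# Stall calling

For one gene, the per-codon statistic is the ratio
`(ko_rel + p) / (wt_rel + p)` with pseudocount `p = 0.1 / n_codons` on
the relative scale, so codons silent in both genotypes sit at 1. A codon
is called when the KO raw count reaches `min_cov` (default 10), the
ratio reaches `min_ratio` (default 2), and the codon is a ratio local
maximum within ±`flank` (default 5) codons; adjacent qualifying codons
merge into one event at the maximum. No published numeric criterion
exists for this call, so the defaults are deliberately conservative and
all are configuration.

**ORF-start mask.** Mitochondrial mRNAs are leaderless: a footprint
whose A-site lies in the first few codons would begin upstream of the
transcript and cannot exist, so occupancy there is censored and ratio
estimates unstable (a null simulation exhibited exactly this failure
mode). Codons reachable only by censored footprints — the largest
plausible offset, 20 nt, divided by the codon size, rounded up to 7 —
are therefore ineligible as events (`stall_params(edge_exclude = 7)`).

Under the recovery conditions (depth 100 reads/codon, KO/WT dwell 8 vs
2, defaults, 10 seeds) implanted stalls are recovered with sensitivity
and FDR far inside the 0.9 / 0.1 bounds, with truth sites projected into
overlapping ORFs before matching; null simulations yield zero events.
Replicates are pooled within genotype before calling — the alternative
(per-replicate calls + intersection) is stricter but needs a dispersion
model the data do not provide.

# Rolling-window proline statistic

Each protein position is labelled with the number of prolines in a
trailing 5-amino-acid window (positions i−4…i, clamped at the
N-terminus; labels ≥ 3 pooled into group 3). The trailing anchor
reflects the nascent-chain context at the peptidyl-transferase centre; a
centered window is selectable. Per genotype, `rel_within` is summed over
codons by label group across all genes, and each group sum is normalised
to WT. Stop positions carry no amino acid and are excluded, which keeps
the conservation identity exact: group sums add up to the total
in-window relative occupancy.

Because `rel_within` renormalises per ORF, occupancy gained by stalled
groups is necessarily lost elsewhere: under strong simulated stalling
group 0 sits slightly *below* 1 (≈0.87 in the acceptance run) rather
than exactly at it. This is a property of the statistic, not a bias.

# The simulator

`simulate_dwell()` assigns every codon dwell 1, multiplied by a
termination pause (default 8) at each stop codon — which is what makes
stop-codon metagene calibration possible — and by per-site genotype
factors at stall sites. Expected occupancy is `te × dwell / Σ dwell` per
gene; translation-initiation weights default to 3 for COX1, COX3 and
ND6, the mRNAs with the highest initiation rates. `sample_footprints()`
draws per-codon counts as Poisson with mean `depth × expected ×
n_codons` (or rounds the mean, noiselessly), splits them over the read
length distribution (default 31:0.15, 32:0.5, 33:0.25, 34:0.1) and
places 5′ ends at A-site − true offset (defaults 15–18 nt). Reads
crossing transcript bounds are dropped and logged — the source of the
ORF-start censoring discussed above, exactly as in real leaderless
libraries.

Two stall-site generators encode the two study conditions:

* `default_stall_sites()`: one site per maximal ≥2-proline run, at the
  run's last proline; KO factor 8 (16 for ≥3xPro, the strongest
  stallers), WT factor 2. This is the truth used for event-recovery
  checks.
* `window_stall_sites()`: a site at every codon whose trailing window
  holds ≥2 prolines, with factors growing with the proline count (KO
  base 5, WT base 1.5 per level), encoding stalling that strengthens
  with proline density. This is the condition under which the
  proline-group ratio is studied; it produces ratios near 1 for groups
  0–1 and monotonically increasing, clearly elevated ratios for groups
  2–3.

Poisson counts (not negative binomial) are the default because no
replicate-dispersion model is available; overdispersion would widen the
stall-calling bounds but not move their centres. All randomness is fixed
by the configuration seed; identical configurations produce
byte-identical datasets.

What the simulator does *not* emulate: rRNA contamination, nuclease and
ligation sequence biases, disome (collided-ribosome) footprints, and
mapping ambiguity. Passing recovery tests therefore demonstrates the
correctness of the analysis logic under the stated noise model, not
robustness to every artefact of real libraries.

# Problem sizes and numerical choices

Test and acceptance runs simulate the full 13-ORF transcriptome
(≈3 800 codons) at 50–100 reads/codon over 10 seeds — large enough for
stable Monte-Carlo bounds, small enough to run in minutes. Tolerances:
normalisation identities are asserted to 1e-12; offset recovery is exact
(noiseless) or ±1 nt (Poisson); metagene ties break deterministically
toward geometry; the census is fully deterministic and ordered by gene.

One counting convention deserves note: the proteome census reports the
PP-containing-triplet total as **one motif per maximal ≥2-proline run**
(15 on the bundled human proteome: 14 2xPro runs + the single 3xPro run
in COX1, whose context is (G)CPPP). Enumerating flanking triplets
instead gives 31 instances over 18 distinct tripeptides
(`pp_triplets(convention = "per_run")`), or 32 over 16 PP dimer sites
(`"per_pair"`); both enumerations remain available on the per-record
level, and the convention is a configuration choice.

# Known limitations

* Offsets are calibrated per read length globally, not per transcript or
  per sample-batch; strong transcript-specific biases would require
  stratified calibration.
* Stall calling has no replicate-level significance model; events are
  threshold calls, and the event count on real data is expected to be
  threshold-sensitive.
* The yeast fixture is synthetic (see above); conclusions about the real
  yeast proteome require the real sequences.
* Disome-mediated upstream pauses (queued ribosomes behind a strong
  stall) are visible in the occupancy profiles but are not modelled or
  classified separately.
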