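---
title: "Methods and design notes for clirms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for clirms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clirms)
```

This vignette documents the statistical model behind `clirms`, the
parameters that matter, the numerical choices made where the underlying
methodology leaves the design open, and what the synthetic-data generator
does and does not establish.

## The measurement model

A CLIR-MS sample contains peptides carrying RNA-derived adducts in 1:1
light/heavy isotopic forms. Each adduct species is characterized by three
things:

1. a **nucleotide composition** — an order-free multiset over A/C/G/U,
   because mass spectrometry identifies the adduct by mass, and all
   orderings of the same composition weigh the same;
2. a **neutral loss** — a fixed formula subtracted from the intact
   oligonucleotide (none, −H₂O, −HPO₃, −H₃PO₄ by default);
3. a **labeling scheme** — which atoms of the residue are heavy in the
   labeled form.

The light formula of an n-mer adduct is the sum of its
nucleoside-5′-monophosphate formulas minus (n−1) waters. We adopt the
**5′-phosphate / 3′-OH terminus convention** (mono-U = 324.0359 Da), which
matches typical nuclease digestion products; a 5′-OH variant (−HPO₃) is
available through `terminus = "5p_OH"`. The cross-link itself is modeled as
zero-mass: UV cross-linking adds the full adduct mass to the peptide, and
any formal mass changes are expressed only through the loss table, which is
user-extensible because the canonical set of nucleic-acid neutral losses is
an empirical, instrument-dependent matter.

Heavy formulas apply the scheme's per-residue substitutions (e.g. metabolic
labeling makes all 9 carbons and 2 nitrogens of a UMP heavy, Δ = 11.0243 Da)
plus optional per-adduct constants (the ¹⁸O-phosphate scheme substitutes one
O → ¹⁸O once per adduct, Δ ≈ 2.00425 Da; the count is configurable since
labeling chemistry varies). Substitutions are capped at the atoms remaining
**after** the loss, so a loss that removes labeled atoms reduces the delta
mass; for the default losses (no C or N) the metabolic delta is unchanged,
which is the behavior the search needs.

Atomic monoisotopic masses are an embedded CODATA/NIST table rather than an
external dependency: seven constants that never change, versus a runtime
dependency that can.

### Delta grouping and the covering sequence

Species are partitioned into parallel searches by delta mass with a
tolerance of **1e−4 Da** — far below instrument precision (a 10 ppm window
at 500 Da is 5e−3 Da) and far above double-precision noise, so the
partition is unambiguous. Groups are formed on the delta-sorted species
list, starting a new group when the running delta exceeds the group's first
member by more than the tolerance; this makes assignment independent of
input order.

`generate_covering_rna` builds a deterministic "universal" RNA whose
substrings realize every composition up to length k: greedy base-by-base
extension choosing the base that covers the most uncovered compositions
(ties alphabetical), with a fallback that appends the sorted bases of the
first uncovered composition whenever no single base helps (this guarantees
termination; the greedy step alone can stall). For k = 4 over 4 bases the
output covers all 69 compositions in 57 nt. Minimality is not claimed —
the sequence is an input generator, not a combinatorial result.

## Reranking and unique identifications

Parallel searches can assign the same scan several competing explanations.
`rerank_by_scan` orders candidates within each spectrum key by ld-score,
then **shorter RNA composition, lexicographic composition tag, target
before decoy**. The score dominates; the remaining tie-breaks exist only to
make the ranking a deterministic total order, and they prefer the simpler
explanation. Reranking happens **before** FDR estimation: unique-ID
counting requires one candidate per spectrum, so the order is forced even
though the upstream methodology does not state it.

An identification is a unique (protein, position, RNA composition, loss)
key; collapse keeps the best-scoring representative and records the number
of supporting spectrum matches.

## FDR control

**Observed FDR.** At threshold t, FDR(t) = D(t)/T(t) with D, T the decoy
and target unique-identification counts at score ≥ t — the monolink
target-decoy convention (not D/(T+D)) — clipped to [0, 1], with T = 0
reported as 1. The q-value is q(t) = min over t′ ≤ t of FDR(t′): the
smallest FDR at which an identification scoring t would be accepted, and by
construction non-increasing in score. Thresholds are evaluated at observed
scores only (the curve is a step function). The reported cutoff is the
score of the weakest **accepted target**: candidate cutoffs are target
scores, so the cutoff names an identification actually in the output rather
than a decoy score below it. The default α = 0.01 follows standard
stringency for cross-link identification and is user-adjustable.

**Transferred FDR.** Low-abundance composition bins rarely contain enough
decoys for a direct estimate. The transferred estimate apportions the
global decoy count: the bin's decoy share πᵦ is the slope of a
through-origin least-squares fit of the bin's cumulative unique-decoy count
against the global cumulative count, evaluated at thresholds spanning the
**lowest 80% of unique decoy scores globally** (the decoy-rich region; the
80% quantile is taken globally, not per bin, so every bin is fit on the
same score region). The bin's FDR at t is πᵦ·D(t)/Tᵦ(t). This
concretization of "linear approximation" is this package's own definition,
not a restatement of any published equation. Bins with fewer than
`min_bin_decoys = 10` decoys in the fit region — below which the slope is
noise — or an undefined/non-positive fit fall back to the global observed
cutoff (`method = "fallback_observed"`). A bin with a *valid* fit where no
threshold reaches α gets cutoff +∞: the fallback handles mathematically
invalid estimates, not stringency. With a single bin π = 1 exactly and the
transferred cutoff reduces to the observed one.

**PIN export.** For external semi-supervised rescoring, `export_pin`
writes the Percolator INput format: SpecId, Label (±1), ScanNr, a feature
block, Peptide (dotted), Proteins. The feature set — ld_score, every
ingested `subscore_*` column verbatim, the calculated RNA mass addition,
RNA length, mass error, charge, peptide length — is a documented
superset-compatible choice; the rescoring engine itself (Percolator,
mokapot) is deliberately outside the package.

## Mass-error refinement

Relative precursor mass errors of true identifications cluster tightly;
outliers betray false matches. `fit_mass_error_tolerance` fits a Gaussian
**robustly** (median center, 1.4826 × MAD spread, then mean/sd of the
values within 3 initial spreads) because the error cloud of an unfiltered
result list is contaminated by exactly the outliers we want to remove. The
spread is floored at **0.1 ppm** so a degenerate cloud (identical errors)
still yields a usable window, and the default window is ±3σ (≈ 99.7%
retention under the model). At least 20 targets are required; below that
the function refuses and asks for a manual window rather than fitting
noise. Filtering runs after FDR thresholding, matching the usual
postprocessing order, and is configurable.

## RNA positional profile

Each identification's composition is matched against all contiguous RNA
windows with the same base multiset (order-free, consistent with mass-level
identification; a strict-substring interpretation would claim sequence
information the spectra do not contain). Weight 1/#windows goes to each
compatible window. Two modes exist because two useful quantities do:

* `normalize = FALSE` (default): every position covered by a window gains
  the window's full share — a coverage-style profile in which one
  identification of a k-mer contributes k units in total;
* `normalize = TRUE`: shares are further divided by the adduct length, so
  each matched identification contributes exactly one unit — a
  probabilistic placement satisfying the conservation property
  `sum(weights) + #unmatched = #identifications`.

Identifications with no compatible window are returned in `unmatched`,
never dropped. The profile is most informative for short, non-repetitive
labeled RNAs; for long or redundant sequences the windows multiply and the
profile flattens toward uninformativeness.

## The synthetic-data generator

`simulate_xlsm_table` emulates the *statistical shape* of consolidated
CLIR-MS search results, with every parameter explicit in
`synthetic_config`:

* **Score mixture.** True targets draw from a Gaussian high mode whose mean
  falls with adduct length (base 34, −2 per extra nucleotide, sd 3);
  chance targets and decoys share one low mode (mean 18, sd 3.5). Gaussian
  mixtures are a modeling choice — real ld-score distributions have shapes,
  not named families — and the length-dependence mirrors the observed
  tendency of longer RNA adducts to score lower. Equal numbers of chance
  targets and decoys drawn from the same distribution make the decoy count
  an unbiased estimate of false targets, which is precisely the assumption
  target-decoy FDR needs; the realized false-discovery proportion at α =
  0.01 then lands inside the binomial interval around 0.01 (verified over
  100 seeds in the acceptance suite).
* **Default sizes** (900 true / 550 chance / 550 decoys ≈ 2000 records)
  give FDR estimation steps of ~1/900 ≈ 0.001, fine enough for a 1%
  threshold to be meaningful at desk scale.
* **Mass errors** are Normal(1.5, 1.0) ppm — a typical small positive
  calibration offset on a well-tuned Orbitrap-class instrument.
* **Subscores** are noisy monotone transforms of the ld-score, enough to
  exercise PIN export and feature finiteness, not to model engine
  internals.
* A 5% fraction of spectra receive a second, lower-scoring candidate so
  reranking has real work to do.

`simulate_precursor_run` writes genuine mzXML: MS1 scans interleaved with
MS2 precursors, n injected light/heavy pairs at the scheme's deltas (ppm
jitter ≤ 3 ppm = 0.3 × the 10 ppm matching tolerance, RT jitter ≤ 20 s ≤
one third of the 60 s window) and unpaired background precursors
rejection-sampled to sit at least twice the tolerance from any valid pair
offset. Under these separation conditions pair recovery must be exact, and
the acceptance suite demands 100% recall with zero spurious pairs across
50 seeds. A control run (no UV analog) injects no pairs.

**What a green test establishes** — that the statistics are implemented
correctly and control what they claim on data satisfying their assumptions.
**What it does not** — that real spectra behave this way: the generator has
no peptide-level score correlations, no retention-time structure, no
intensity model, no chimeric spectra, and its decoys are exchangeable with
false targets by construction rather than by the grace of a well-built
decoy database.

## Numerical and format notes

* Masses serialize at 6 decimal places (0.5 µDa, below any meaningful
  precision); parameter files and manifests are written with fixed formats
  so regeneration is byte-identical — orchestration output is treated as
  build artifacts, and artifacts should diff clean.
* The mzXML layer (base64, 64-bit network order) covers the subset of the
  format the precursor operations need; it exists because the R stack
  offers no raw-data reader, and is not a general-purpose converter.
* Isotope pairing considers equal-charge precursors only: a light/heavy
  pair of the same species shares a charge envelope, and cross-charge
  pairing multiplies candidates without a physical rationale. The pair ppm
  error is computed on the light neutral mass.
* FASTA decoys preserve residue multisets exactly in all modes
  (reverse/shuffle/both); shuffling is seed-deterministic and isolated from
  the caller's RNG state.

## Known limitations

* No search engine: ld-scores and subscores are consumed, never computed.
* No DNA, no modified nucleotides, no intensity/propensity model of which
  adducts actually form.
* The transferred-FDR linear approximation is this package's
  concretization; treat cross-package numerical comparisons accordingly.
* Protein-level FDR and 3D-structure validation are out of scope.
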