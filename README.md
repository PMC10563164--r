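# clirms

Analysis toolkit for protein–RNA cross-linking mass spectrometry with
stable-isotope-labeled RNA (CLIR-MS-style experiments).

## The problem

In a CLIR-MS experiment a protein–RNA complex is UV cross-linked with a 1:1
mixture of light and heavy isotope-labeled RNA, digested with nuclease and
protease, and analyzed by LC-MS/MS. Every true peptide–RNA adduct then
appears as a *pair* of precursors separated by a known delta mass. Unlike a
protein–protein cross-linking experiment, which has one cross-linker and one
delta mass, nuclease digestion leaves many different oligonucleotide adducts
(mono- to tetranucleotides, with neutral losses), each with its own delta
mass — so the data must be searched many times in parallel, once per delta,
and the parallel results must be consolidated, reranked and statistically
controlled together.

`clirms` provides that scaffolding for the search engine of your choice, and
the postprocessing statistics:

* **Adduct chemistry** — enumerate every RNA-derived modification a given
  RNA sequence can leave on a peptide (`enumerate_compositions`,
  `build_adduct_species`), with exact light/heavy monoisotopic masses under
  metabolic ¹³C/¹⁵N, ribose ¹³C, or phosphate ¹⁸O labeling, and group the
  species into parallel searches by delta mass (`group_by_delta`).
* **Search orchestration** — parameter file sets with an execution manifest
  (`generate_search_params`), a light-only (0 Da monolink) search
  definition, and reverse/shuffle decoy databases (`make_decoy_db`).
* **Precursor-level tools** — read mzXML, detect light/heavy scan pairs at
  expected deltas within ppm/RT tolerances (`find_isotope_pairs`), and
  build +10 m/z shifted negative-control datasets (`shift_mz_decoy`).
* **Consolidation** — ingest per-search result tables
  (`parse_search_results`), rerank so each spectrum yields one
  identification (`rerank_by_scan`), collapse to unique identifications
  (amino-acid position × RNA product, `collapse_to_unique_ids`), and refine
  by a fitted mass-error window (`fit_mass_error_tolerance`).
* **FDR control** — observed target–decoy FDR with q-values
  (`observed_fdr`: FDR(t) = D(t)/T(t) at the unique-identification level,
  q(t) = min over thresholds t′ ≤ t of FDR(t′)), a per-composition-bin
  *transferred* FDR with an observed-FDR fallback for sparse bins
  (`transferred_fdr`), and Percolator-compatible PIN export for external
  rescoring (`export_pin`).
* **Reporting** — protein-centric site × RNA-product matrices, an
  RNA-centric positional interaction profile, and a minimum-information
  summary CSV for structural modeling.
* **Synthetic data** — `simulate_xlsm_table` / `simulate_precursor_run`
  generate seeded fixtures with the statistical structure of real runs
  (bimodal target scores whose high mode falls with adduct length, unimodal
  decoys, injected isotope pairs), so the whole pipeline is testable without
  raw data.

## Worked example

Enumerate the adducts of the PTBP1-style RNA `UCUCU` under metabolic
¹³C/¹⁵N labeling and group them into parallel searches:

```r
library(clirms)
scheme  <- labeling_scheme("metabolic_13C15N")
species <- enumerate_adduct_species("UCUCU", scheme, losses = list(loss_spec("none")))
adduct_table(group_by_delta(species))
#>    composition   loss light_mass_da heavy_mass_da delta_mass_da group_id
#> 1:          U1   none      324.0359      335.0601      11.02426     G001
#> 2:          C1   none      323.0519      335.0731      12.02130     G002
#> 3:        C1U1   none      629.0772      652.1227      23.04556     G003
#> 4:        C1U2   none      935.1025      969.1723      34.06982     G004
#> 5:        C2U1   none      934.1184      969.1853      35.06686     G005
#> 6:        C2U2   none     1240.1437    1286.2349      46.09112     G006
```

Six distinct compositions, six delta masses, six parallel searches: a
mono-U adduct weighs 324.0359 Da and its heavy form is 11.0243 Da heavier
(9 × Δ¹³C + 2 × Δ¹⁵N).

Run the postprocessing pipeline on a simulated consolidated result table
(FOX1-like preset, RNA `UGCAUGU`):

```r
cfg  <- synthetic_config(seed = 7)
xlsm <- simulate_xlsm_table(cfg)
res  <- run_pipeline(xlsm, rna_sequence = cfg$rna_sequence, alpha = 0.01)
#> 2100 XLSMs -> 1889 unique ids -> ld-score cutoff 25.32 -> 854 pass 1% FDR
res$mass_error_model
#> <mass_error_model> center 1.495 ppm, spread 1.017 ppm, window [-1.555, 4.545] (n=855)
round(res$rna_profile$weights, 1)
#>     U     G     C     A     U     G     U
#>  58.2 118.0 211.7 201.8 114.6  94.1  55.8
```

The identifications passing 1% FDR survive a fitted ±3σ mass-error window,
and their RNA compositions are distributed over the input RNA: each
identification spreads one unit of weight over the contiguous windows
compatible with its composition, peaking here on the central `CA` of
`UGCAUGU`.

## Command line

```sh
clirms adducts --rna UCUCU --scheme metabolic_13C15N --out adducts.tsv
clirms decoydb --in target.fasta --mode reverse_then_shuffle --seed 42 --out td.fasta
clirms pairs --mzxml run.mzXML --adducts adducts.tsv
clirms mzshift --in a.mzXML --out a_decoy.mzXML --shift 10
clirms fdr --in unique_ids.tsv --alpha 0.01
clirms topin --in all_xlsms.tsv --out run.pin
```

(the `clirms` script is installed under `exec/` in the package library; or
call `clirms::clirms_cli()` directly.)
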