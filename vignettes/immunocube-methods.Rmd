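---
title: "ImmunoCube: dimensional warehousing and cube exploration of immunoassay results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ImmunoCube: dimensional warehousing and cube exploration of immunoassay results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImmunoCube)
```

## The problem and the model

Translational immunology studies measure the same participants with
several high-content assays: bead-based multiplex immunoassays reporting
median fluorescence intensity (MFI) or calibrated pg/ml per analyte,
electrochemiluminescence cytokine panels, and phosphoepitope flow
cytometry in which PBMC aliquots are stimulated with individual
cytokines and phosphorylated STAT levels are read out per stimulation
condition. The analysis bottleneck is rarely the statistics; it is
getting heterogeneous batch spreadsheets, inconsistently decorated
sample identifiers and free-text metadata into one queryable structure.

ImmunoCube models the data dimensionally. The grain of the fact table is
the *aliquot measurement*: one number (`readout`) with its verbatim
`units`, a `quantification` flag recording whether the value sat inside
the assay's calibrated range (`in_range`) or beyond its limit of
quantification (`below_loq` / `above_loq`), the `tissue` the aliquot was
processed into, and the `stim` condition (`"none"` for unstimulated).
Facts join to four dimensions: `analyte` (scoped per assay family, so an
IL-6 bead readout and an IL-6 electrochemiluminescence readout remain
distinct analytes that can still be compared by name at query time),
`person`, `sample`, and `source` (the uploaded document, carrying assay,
run date, operator, instrument, kit lot, PI and project).

Two modelling choices deserve justification:

* **Time points are ordinals, not dates.** The sample dimension carries
  `year, month, week, day, draw` as study-event ordinals. This keeps
  studies with different designs comparable in one cube (a "day 7" is a
  day 7 in any study) and avoids anchoring analyses to calendar
  artifacts.
* **Age is stored with a derived decade band.** Although person
  attributes are conceptually time-invariant, age at enrollment is
  needed for band-wise segregation, so `age_years` is banded
  deterministically into `<20`, `20-29`, ..., `80+`; both fields are
  null together or set together.
* **Kit lot lives on the source.** A batch file is run with one kit
  lot, so lot is a source attribute; re-tests of the same samples with a
  second lot arrive as a second document and remain distinct facts,
  never deduplicated.

The store is a single SQLite file: referential integrity and uniqueness
are enforced by the schema itself (`AUTOINCREMENT` surrogate keys are
never reused; the natural key of a fact is
`(aliquot_id_ext, analyte_key, source_key, stim)`), loads are
transactional, and a content-hash uniqueness constraint on
`(file_name, file_hash)` makes repeated loads of the same file a no-op
by rejection rather than silent duplication.

## Ingestion contracts

**Batch sheets.** Lab-native exports vary per instrument; ImmunoCube
defines one canonical layout and expects sheets to be pre-converted:
two header rows (analyte names; units per analyte), one row per aliquot,
the aliquot identifier in column one and, for stimulation assays, a
`stim` column in column two. The quantification markers are a cell-level
grammar: `123.4` is in range, `<3.2` is below the limit of
quantification with the numeric part retained as the readout, `>100` is
above it, and a blank cell emits no fact. Anything else is a format
error reported with row and column coordinates — there is no silent
coercion anywhere in the ingestion path. CSV (UTF-8, comma, quoted
fields) is the canonical dialect; XLSX is read through `readxl` when
available, with identical logical layout.

**Metadata sheets.** The only constraint is records-in-rows with a
header row. A `ColumnMapping` assigns sheet columns to attributes;
person attributes activate only when a person-ID column is mapped and
sample attributes only when a sample-ID column is. Vocabulary-controlled
attributes (globally scoped: condition, ethnicity, gender;
project-scoped: response, treatment, time-point labels) must resolve
completely before anything is written: an incoming value either equals a
valid value verbatim or is covered by an explicit mapping
(`"M"` to `male`, `"SLE"` to `lupus`). Auto-proposals are case-folded,
whitespace-trimmed exact matches only — no fuzzy matching, because a
silently wrong vocabulary assignment is worse than a rejected load.
Blank cells store the sentinel `unknown`, which is a real member in the
cube rather than a hole. Metadata and batch results may be loaded in
either order.

**Identifier linkage.** Aliquot identifiers are decorated sample
identifiers (`HIMC-P0123-D07_A`); sample identifiers may embed person
identifiers (`P0123-D07`). A `LinkSession` records an ordered list of
transforms (fixed-string phrase removal, applied per occurrence, plus an
optional case-fold) per side; working strings are always a replayable
function of the verbatim external IDs, which are never modified.
`mapEquals` proposes a pair only when a child's working string matches
*exactly one* parent; collisions are reported as ambiguous and left for
explicit `mapPair` assignment. Matching is case-sensitive by default
since lab IDs can legitimately differ only by case. Commits are atomic
— if any child in the session was mapped concurrently, the whole commit
aborts — and the transform list plus pair count goes to an audit table,
because silent ID rewrites are a provenance hazard.

## The cube

A `CubeQuery` places dimension levels on two axes, restricts members
with filters, and requests a subset of the measures
`N, mean, median, min, max, sd, cv` (the latter two are extensions
beyond the core five; `sd` uses the n-1 denominator and is undefined
below two values, `cv = sd/mean` is undefined at mean zero). The median
of an even-sized cell is the mean of the two central order statistics.
Aggregation materializes every populated cell at every roll-up prefix
depth: levels beyond the prefix carry the `"(all)"` member, so parent
subtotals are ordinary rows of the result, and drill-down is
re-aggregation with the child hierarchy level appended, detail shown
under the expanded member and subtotals retained elsewhere.

Two policies are enforced structurally rather than by convention:

* **Units are an implicit finest grouping.** Pooling `raw MFI` with
  `pg/ml` would produce a meaningless mean, so when `Units` is not on an
  axis it is carried as a hidden innermost grouping column of every
  cell, including all subtotals. A corollary is that no cell with
  `Units = "(all)"` ever exists; the roll-up identities (count
  additivity, N-weighted mean, elementwise extrema) hold within, never
  across, units.
* **Unmapped facts stay visible.** Facts not yet linked to a sample
  contribute to person and time levels under an `"(unmapped)"` member;
  null time-point ordinals roll into `"(unspecified)"`. Integrity
  problems therefore show up in the cube instead of silently shrinking
  N.

Drill-through inverts any cell into exactly its contributing facts with
person/sample/source context, and the package asserts in its tests that
the detail row count equals the cell's N and that re-aggregating the
detail reproduces the cell's mean bit-exact. Pivots export to a wide CSV
(nested column headers flattened with `/`) and to a lossless JSON that
validates against the schema shipped in `inst/extdata/pivot-schema.json`.
Exports are deterministic: the same store and query produce
byte-identical files. Pooling across lots when `Lot` is not displayed is
deliberate — lot is an ordinary level, and segregating by it is one
drill-down away.

## The synthetic study generator

The generator emulates the study design the package is exercised
against: `studySpec()` defaults to 434 healthy participants, each
sampled at days 0, 7 and 28 around an influenza vaccination; a 51-plex
serum bead panel run in two kit lots (`H51-1`, `H51-2`) with persons
alternately assigned to lots; a 4-plex panel (IL-1b, IL-6, IL-8, TNF);
and phospho-flow with pSTAT1/3/5 readouts under seven cytokine
stimulations plus an unstimulated baseline (24 facts per aliquot).

Readouts are log-normal around per-analyte baselines with multiplicative
effects, a standard model for positively skewed MFI-like intensities:

* baseline log-medians drawn once per analyte, uniform on
  log(500)-log(20000) for the bead panel — magnitudes chosen to look
  like raw MFI, with no claim of matching any real kit;
* noise sigma 0.3 on the log scale (a realistic between-sample
  coefficient of variation of roughly 30% for serum cytokines),
  configurable;
* a lot factor (default 1.3 on the second lot) multiplying all readouts
  of that lot — absolute values differ by lot while within-lot contrasts
  are preserved;
* a gender effect as a female/male fold-ratio per analyte. The default
  plants a fold of 1.4 on four analytes (ENA-78, GM-CSF, leptin,
  PDGFBB) and 1.0 elsewhere. The fold was fixed a priori by a power
  calculation: a screen at the ">20% mean difference" threshold with
  per-lot, per-gender group sizes near 325 samples and sigma 0.3 has a
  per-comparison z of about 6 at fold 1.4, so the planted set is
  recovered essentially always, while a fold at the screening threshold
  itself would make recovery a coin toss. Because the gender effect
  multiplies the log-mean, the fold equals the ratio of arithmetic
  means exactly, making `groundTruthScreen()` an exact answer key.
* about 1% of bead readouts fall below a per-analyte limit of
  quantification (the 1st percentile of the null log-normal) and are
  written with the `<` marker;
* an optional coupling (default off) makes persons with higher serum
  IL-6 show proportionally lower IL-6-stimulated pSTAT1 induction, for
  exercising cross-assay exploration.

Aliquot IDs are decorated (`HIMC-` prefix, `_A` suffix) and sample IDs
embed the person ID with a `-D07`-style visit suffix; the manifest
declares exactly these phrases, so the linkage workflow is exercised
end-to-end rather than bypassed. Everything is a pure function of the
seed; generated files are byte-identical across runs.

What the generator does *not* emulate: plate/position effects, carryover,
calibration-curve nonlinearity at the range edges, person-level random
effects (samples from one person are independent draws), missing
metadata patterns beyond blanks, and biologically realistic absolute
concentrations. Passing tests therefore demonstrate the correctness of
the warehouse, linkage and cube machinery under a clean generative
model — not robustness to every pathology of real instrument exports.

## Numerical and design choices

* Readouts survive the file round trip bit-exact: sheets are written
  with `%.17g` formatting and stored as SQLite REAL (IEEE doubles), so
  export-and-re-pivot equality is exact, not approximate.
* File identity is md5 of content; in-memory sheets hash a canonical
  serialization.
* Cube correctness is tested against an independently written flat
  filter-then-group reference (base-R merges, split and loops) on
  randomized stores: N exact, floating measures to 1e-9 relative.
* Degenerate inputs: empty sheets register their source and load zero
  facts; header-only metadata sheets are valid and load nothing; empty
  cells never become facts; an empty link session cannot be committed;
  expanding a leaf hierarchy level is a no-op with a message.
* Where a GUI warehouse would use interactive drag-and-drop for mapping
  decisions, ImmunoCube uses JSON directive files (column mappings,
  value mappings, serialized link sessions) so every decision is
  reviewable and replayable; the `exec/immunocube` script is a thin
  shell over the exported functions with no logic of its own.

Problem sizes used in the shipped checks: the default study
(434 x 3 = 1302 samples, 102,858 facts) for the end-to-end and roll-up
properties; 20 randomized stores of at most ~1000 facts with 50
randomized queries for the oracle comparison; 100 independent seeds at
full cohort size for the planted-effect recovery rate, which requires
the exact planted set pooled and within each lot, with the effect
direction agreeing across lots.

## Known limitations

* Single-writer, single-process: no concurrency control beyond SQLite's
  own locking; this is a desktop/workstation tool, not a service.
* No normalization or batch correction: lot effects are visible and
  segregable, not removed. Statistical testing is out of scope by
  design; pivots and drill-through tables export cleanly to downstream
  statistical environments.
* Cross-assay analyte identity is by name match at query time; there is
  no ontology service behind analyte names or vocabularies.
* XLSX reading uses the first worksheet only and requires `readxl`;
  the canonical interchange format is CSV.
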