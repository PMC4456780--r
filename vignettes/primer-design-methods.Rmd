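---
title: "Batch primer design in primap: model, algorithm and design choices"
author: "primap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch primer design in primap: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primap)
```

## The problem

Validation work downstream of RNA-seq projects, genotyping of newly sequenced
species, multi-gene-family studies, primer walking and assembly PCR all need
primers designed *en masse*: tens to thousands of target sequences, each
requiring forward and reverse primers under the same thermodynamic and
compositional constraints, plus a fast visual check that the designed primers
actually sit where they should on their targets. `primap` automates exactly
that: multi-FASTA in; filtered, specificity-screened primers out, as a TSV
report plus per-primer alignment panels and per-target distribution maps.

The package is a toolkit of small composable steps --

`read_fasta()` → `design_primers()` → `map_primer()` /
`build_alignment_view()` → `render_alignment_panel()` /
`render_distribution_map()`

-- with a command-line driver (`main()`, or the installed `exec/primap`
script) that wires them together, and a deterministic synthetic-FASTA
generator (`random_fasta()`) so every demo and test runs without downloading
data.

## The melting-temperature model

Primer Tm is computed with the two-state nearest-neighbor model: duplex
formation enthalpy and entropy are sums over stacked dinucleotides,

$$\Delta H = \Delta H_{init} + \sum_i \Delta H(s_i s_{i+1}), \qquad
  \Delta S = \Delta S_{init} + \sum_i \Delta S(s_i s_{i+1}) \; (+\,\Delta S_{sym}),$$

with initiation terms split by the identity of each terminal base pair
(G·C vs A·T) and a symmetry entropy penalty applied when the oligo equals
its own reverse complement.  The melting temperature is then

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/x)} - 273.15
       + 16.6 \log_{10}[\mathrm{Na}^+],$$

with $\Delta H$ in kcal/mol, $\Delta S$ in cal/(mol·K), $R$ = 1.987
cal/(mol·K), and $x = 4$ for non-self-complementary oligos ($x = 1$ for
self-complementary ones).

Choices behind this, all of them swappable:

* **Parameter set.**  The unified duplex parameters (SantaLucia 1998) ship as
  a plain-text TSV (`inst/extdata/nn_unified_1998.tsv`; schema in the file
  header).  The table is reverse-complement symmetric, which makes `calc_tm()`
  strand-invariant -- a property the test suite asserts.  `thermo_parameters()`
  accepts any table with the same schema.
* **Defaults** $C_T$ = 250 nM total strand concentration and
  [Na⁺] = 50 mM: conventional PCR-adjacent values.
* **Salt correction.**  The closed-form $16.6 \log_{10}[\mathrm{Na}^+]$ shift
  is used because it keeps the formula closed-form and is the convention the
  rest of the model's constants were tuned with.  The independent
  cross-validation route `calc_tm_reference()` implements the same model
  through a deliberately different code path (inlined integer-indexed
  matrices rather than the shared named-vector table) and also exposes
  `salt_correction = "santalucia"`, the entropy-based
  $\Delta S + 0.368\,(n-1)\ln[\mathrm{Na}^+]$ convention used by Primer3's
  `oligotm`, so users can quantify how much the published salt conventions
  alone move Tm (a few °C in level; rank order is essentially preserved --
  the acceptance script reports both the same-convention and the
  cross-convention $R^2$ over 400 designed primers).
* Oligos shorter than 8 nt are rejected as non-primers; shorter than 2 nt the
  NN sum itself is undefined.

## The design algorithm

For each record, with parameters from `design_params()`:

1. **Enumeration.**  Every substring with length in `[len_min, len_max]`
   whose span lies inside the 5′ window (positions `1..five_prime_window`,
   forward primers) or the 3′ window (the final `three_prime_window` bases,
   reverse primers) becomes a candidate.  All lengths per start are
   enumerated, not one fixed length -- the complete candidate space is cheap
   at these scales, and returning *all* passing candidates leaves ranking to
   the user.  Reverse candidates carry the reverse complement of the covered
   slice, i.e. their sequence in synthesis orientation.  Windows larger than
   the record are clamped to its length, so "scan everything" is expressed by
   setting both windows to the sequence length.  A window smaller than
   `len_min` logs a warning and yields no candidates; a short record is not
   an error.
2. **Filtering.**  Four pure predicates -- length range, GC% range, Tm range,
   and (optionally) the GC clamp, which requires the 3′-terminal base to be G
   or C.  Each failing rule is appended to the candidate's
   `rejection_reasons` audit trail (`passes_filters()` drops nothing, so the
   attrition table is fully reconstructable; the CLI `--audit` flag writes it
   out).
3. **Specificity.**  A primer is specific iff its total strand-aware exact
   occurrence count over the screening scope is exactly 1 (its own site).
   Both the oligo and its reverse complement are counted across every
   screened sequence, overlapping matches included; a palindromic oligo
   therefore counts each physical site twice and can never be specific --
   deliberate, since such a primer binds both strands.  The scope is the
   whole input file or the primer's own target, per
   `specificity_whole_file`.  Exact full-length matching is the match model;
   3′-seed/mismatch-tolerant binding models are out of scope.

Coordinates are 1-based inclusive throughout.  Accepted primers are named by
start position, the field convention for this kind of map.  Bare start
positions cannot be globally unique, so collisions are resolved
deterministically: an `F`/`R` suffix when forward and reverse primers share a
start, and a `.length` suffix when several accepted lengths share a start and
direction (e.g. `493R.22`).  Output order is
deterministic (target, then start, then direction, then length), and the
accepted set is invariant under permutation of the input records.

Default parameters (all overridable, echoed by `--help` and logged at run
time): windows 150/150 nt, lengths 18--24 nt, GC 40--60%, Tm 52--65 °C, GC
clamp on, whole-file specificity on.

## Mapping and verification

Because every accepted primer is by construction an exact substring (or
reverse-complement substring) of its target, mapping is coordinate
bookkeeping, and `map_primer()` re-extracts the covered slice and verifies it
equals the primer sequence (after reverse complementing for reverse primers).
That re-extraction is the correctness gate an alignment step would otherwise
provide; an external aligner here would add a dependency and nondeterminism
without information, and no gapped alignment is possible for exact
substrings.  A verification failure is an internal-consistency error, never
user error.

`build_alignment_view()` windows the target around the primer (`flank` nt
each side, clamped at the ends -- boundary primers at position 1 or L are
exercised in the tests), pads the primer line with `-` outside the span, and
shows reverse primers as the *complement* of the target slice on target
coordinates: the glyph arrowhead, not the text, carries orientation.

## Rendering and the sidecar contract

Panels are written as PNG, JPEG or GIF (format follows the file extension);
distribution maps show a scaled coordinate ruler over `1..L` with one labeled
arrow glyph per primer, forward glyphs pointing toward increasing
coordinates, reverse toward decreasing.  Overlapping glyphs are packed onto
rows by greedy first-fit in start order with a small coordinate gap -- the
simplest layout that provably never collides (asserted in the tests).

Every image gets a JSON sidecar (`<image>.json`) describing the ruler extent
and each glyph's name, span, direction and row.  Pixel-level golden-image
tests are brittle across rasterizer versions, so the sidecar is the testable
surface: rendering determinism is defined as byte-identical sidecars, and
the sidecar glyph list must equal the primer set exactly (including the
empty-set, ruler-only case).  GIF output is produced by a small built-in
GIF87a encoder (web-safe 216-color quantization; LZW stream with periodic
clear codes), since none of the package's raster back-ends write GIF.

## The synthetic generator: what it does and does not emulate

`random_fasta()` draws i.i.d. bases with a per-base GC probability
(`gc_target`), realistic record-length ranges, and optional planted oligos
that overwrite a chosen region -- the mechanism behind constructed
specificity cases (`planted_dataset()` plants the same 20-mer in two
records, so whole-file screening must reject any candidate containing it).
All randomness is confined to one explicitly seeded scope; the same spec
yields the same bytes, and the manifest records seed, spec and realized
stats.

It deliberately does **not** simulate repeats, low-complexity runs,
isochores or gene structure.  Consequences worth stating: on i.i.d. sequence
an 18--24-mer essentially never recurs by chance, so the specificity screen
is mostly exercised through planted duplicates and duplicated records, and
passing tests show the *screen* is correct -- not that primers designed here
would be specific against a real genome's repeat content.  Likewise the
filter pass-rate on 50%-GC i.i.d. sequence (roughly 10--20% of candidates
under defaults) says nothing about pass rates on biased real targets.

## Numerical choices and degenerate inputs

* GC% is formed from integer counts with a single final float division.
* Ambiguity codes (N, R, Y, ...) are rejected at load with the offending
  position -- primer design over ambiguous bases is undefined here, and
  failing loudly beats silently skipping.  `U` is folded to `T` so
  transcript-derived FASTA works; lowercase (soft-masking) information is
  discarded by the case fold.
* Duplicate record ids are rejected at load time; records that yield zero
  primers produce warnings and empty sets, not errors; the CLI exits 0 in
  that case and reserves nonzero codes for usage (2), malformed input (3)
  and unexpected (1) errors.
* Ties and ordering are resolved deterministically everywhere (sorted
  candidate grids, stable naming), so identical runs produce identical
  reports and sidecars.

## Validation problem sizes

The shipped suite validates against independent oracles at sizes chosen to
exercise the combinatorics thoroughly while keeping the default run quick:
the Tm cross-check over 400 primers designed from seeded synthetic records;
50 seeded end-to-end comparisons against a naive
enumerate/filter/count pipeline; 200 seeded filter-monotonicity runs
(tightening any single bound never increases the accepted count); and
re-extraction verification of every accepted primer on every seeded run.
`scripts/acceptance.R` recomputes the headline quantities from scratch at
any seed.

## Known limitations

No primer-pair construction or amplicon bookkeeping, no dimer/hairpin ΔG
screening, no mismatch/dangling-end or divalent-cation thermodynamics, no
degenerate-base primers, no penalty-based ranking: the package returns every
constraint-satisfying primer and leaves selection to downstream logic.
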