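---
title: "Tracking protein production: the data model and methods behind prolims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking protein production: the data model and methods behind prolims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolims)
```

## The problem and the model

Protein-production work — from PCR through cloning, expression, purification
and on to crystallography — resists rigid workflow definitions: researchers
improvise, repeat and branch. prolims therefore models the laboratory with
four interlocking concepts rather than predefined pipelines:

* A **Sample** is a typed physical sample ("PCR product", "Soluble
  protein", ...) with at most one *producing* experiment and any number of
  *consuming* experiments.
* A **Protocol** is a reusable experiment template: typed input and output
  sample slots (each with a multiplicity — "2x PCR product" means two
  distinct samples) plus setup/result parameter definitions. A protocol that
  has been used by any experiment becomes immutable and undeletable; the
  supported route to variation is copying it under a new name and editing
  the copy.
* An **Experiment** is one instantiation of a protocol with bound input
  samples and recorded values; instantiating it creates its output samples.
* A **Lab Notebook** groups records and carries access control.

Because slots are typed, the system can make only sensible suggestions: a
soluble-protein sample is offered chromatography, complexation or a crystal
screen, never PCR; and an experiment can only ever be bound to samples of
the declared input types. The store-wide audit (`lims_audit()`) re-derives
all of these invariants — referential integrity, the single-producer rule,
type-chain soundness, acyclicity — from the raw records, so any API sequence
can be checked end-to-end.

Type names compare case-insensitively after whitespace normalization, since
bench usage mixes capitalizations ("Template" vs "template"). Matching is
exact name equality; there is no subtype hierarchy.

The package ships a standard library of 26 protocols in five groups
(Processing DNA; Cell growth and protein expression; Processing protein
samples; Protein characterization; Crystallography), seeded into a PUBLIC
notebook readable by every user. Measurement-only protocols (DLS, mass
spectrometry, test diffraction, diffraction) have no output slots: they
characterize a sample without transforming it, and inputs are treated
non-destructively throughout (consuming a sample never removes it).
The slot structure of the library is fixed; the parameter sets attached to a
few protocols (PCR annealing temperature in °C, culture volume in mL, ...)
are deliberately minimal starters that laboratories are expected to
customize by copying.

## Construct design and primer suggestion

A **Target** is a full-length protein and/or its DNA; a **Construct** is the
engineered expression unit: a 1-based inclusive residue window
`start_aa..stop_aa` of the target protein, an optional N-terminal
methionine, and tags. The stored sequences are

* `expressed_protein` = `[Met] + N-tags + region + C-tags` (the Met only
  when requested and the region does not already begin with one), and
* `final_protein` = the expressed protein with cleavable tags removed.

Internally DNA is handled as 0-based half-open offsets; the residue window
maps to codons via `offset + 3*(start_aa-1)`. When a target carries both
protein and DNA, the coding frame is located by searching the three forward
frames for the protein as a translated substring.

Primer suggestion takes a user-selectable target melting temperature
(default 60 °C). Each annealing region starts at 18 nt — the forward one a
prefix of the coding region at the first codon of `start_aa`, the reverse
one the reverse complement of a suffix ending at the last codon of
`stop_aa` — and is extended 3'-wards in 1 nt steps until its Tm reaches the
target or 35 nt is hit, in which case the primer is flagged
`tm_reached = FALSE`. The first length meeting the target wins; there is no
GC-clamp or secondary-structure scoring (a documented non-goal). 5' add-ons
(Met codon, tag codons back-translated through a fixed one-codon-per-residue
table of high-usage E. coli codons, and a TAA stop appended by the reverse
primer when no C-tag is present) sit outside the annealing region and are
excluded from the Tm.

Two Tm estimators are provided, both strand-symmetric:

* **Wallace rule**: `2(A+T) + 4(G+C)` °C, for quick estimates on short
  oligos.
* **Nearest-neighbor** (the default): duplex ΔH/ΔS summed over the unified
  nearest-neighbor parameter set with terminal initiation terms, a salt
  correction of `0.368·(N−1)·ln[Na+]` on the entropy, and
  `Tm = ΔH/(ΔS + R·ln(CT/4)) − 273.15` evaluated at 50 mM monovalent salt
  and 500 nM total oligo. The defaults are tunable (`na_mM`, `oligo_nM`).
  The implementation is verified in the test suite against values frozen
  from an independent nearest-neighbor implementation at identical
  conditions, to 1e-5 °C.

Construct design is recorded as a special **hybrid experiment with no
inputs** whose three outputs — one Template sample and two Primers samples —
are exactly what a PCR needs next. `lims_layout_constructs()` fills an
8×12 plate row-major (A1, A2, ...), and `lims_derive_plates()` places each
construct's template and primers in the *same well label* on derived plates,
so externally ordered primers stay matched to their templates.

## Provenance, reporting and complexes

The provenance DAG is derived, never stored: samples feed experiments,
experiments produce samples, constructs derive their design outputs, targets
back their constructs. `lims_build_graph()` returns the breadth-first
neighborhood of radius `depth` edges (default 2, so a sample shows its
producing and consuming experiments and their other samples); frontier
nodes with unexplored neighbors are marked truncated. The DOT rendering
follows a fixed legend — experiments as ellipses, samples as diamonds, blue
`#A7C7E7` fill, truncation points green `#90EE90`, the centre white with a
red border (the named colours are fixed here as specific hex choices).

`lims_sample_history()` reports every ancestor experiment exactly once
(diamond-shaped provenance collapses to set semantics), topologically
ordered ancestors-first with ties broken by `(performed_at, id)`; sibling
outputs of ancestor experiments are included in each stage's summaries. The
text and XML renderings (schema in `inst/schema/sample-history.xsd`) embed
the DOT source of the sample's ancestry diagram. Cycles are impossible for
API-built stores and are additionally guarded at binding time; a cycle found
during traversal raises an integrity error signalling a corrupt store.

`lims_cohort_report()` tracks founder samples through staged experiments:
cell (i, j) is true iff founder i has a descendant sample produced by an
experiment whose protocol matches stage j. A stage selector matches the
protocol's group label or, failing that, its exact name — group labels give
the coarse view ("Processing DNA"), names the per-stage view ("PCR"), which
is what the per-stage survival statistics need.

A **Complex** is a biological assembly declared over two or more targets
(duplicates record homo-oligomer stoichiometry). Detection matches component
*sets*: a sample is a candidate for a complex when the complex's distinct
targets are a subset of the targets reachable through the sample's construct
link and its ancestors' construct links, and the sample is linked to at
least two distinct targets. Homo-oligomer complexes are the deliberate
exception: one distinct target cannot satisfy the two-target rule, so they
match only outputs of Complexation experiments over their target; the rule
is configurable (`match_homo_oligomers`) because either convention is
defensible.

## Access control

Authorization is separated from authentication: the caller asserts a
username (`--user` on the CLI) and the package decides visibility. Rights
are granted per notebook to user groups; write implies read. An entity's
governing notebook is its own override if set, else the notebook of the
*nearest target* in its provenance (breadth-first over construct/ancestry
links, ties to the oldest target), else its own notebook — so assigning a
target to a notebook controls all downstream work by default, while any
page can still be independently re-homed. Every query surface (search,
suggestions, shortlists, graphs, histories, recents) routes through one
read filter; graphs omit unreadable entities entirely, including as
truncation markers, so even the existence of hidden work does not leak.

## Persistence and exchange

The store is an in-memory entity registry with reference semantics whose
on-disk form is a single JSON file; integrity is enforced by the audit
rather than by database constraints. Bulk exchange between installations
uses an XML document (JSON mirror) with deterministic element order — by
kind, then id — so exports diff cleanly and an unchanged store exports
byte-identically. Import remaps colliding ids, merges an imported PUBLIC
notebook into the local one, skips entities already present (re-importing a
document is a no-op) and is atomic: a document that fails parsing or would
fail the audit leaves the store untouched. Scoped export covers one
notebook plus the protocols, targets and sample types its records reference.

Two id modes exist: `sequential` (deterministic ids and logical-clock
timestamps, the default — reproducible fixtures and diffable exports) and
`uuid` (random ids and wall-clock time for multi-session use).

## What the synthetic generator emulates — and what it does not

`lims_generate_workflow()` grows, per construct, the chain PCR → Ligation →
Transformation → Culture → Miniprep → Large-scale expression →
Solubilization, with an independent Bernoulli dropout at each stage. All
randomness comes from one PRNG stream seeded from the spec (draw order:
per target the ORF, per construct a tag coin, per stage a dropout coin), so
identical specs yield byte-identical exports. Two chain stages use lab
copies of default protocols with one input type changed ("Transformation
(ligated plasmid)", "Large-scale expression (purified plasmid)"), created
through the regular copy-then-edit route: the standard library's own types
do not chain exactly at those joins (Ligation yields "Ligated plasmid"
while Transformation asks for "Plasmid"), and resolving that by copying is
precisely the customization the protocol system exists for.

Synthetic targets are uniform-random ORFs. Real coding sequences have
codon-usage bias, GC structure and repeats that affect real primer design;
passing tests on these fixtures therefore demonstrates the correctness of
the bookkeeping, typing, provenance and statistics machinery, not the
wet-lab quality of suggested primers. Default generator sizes in the test
and acceptance runs (up to 200 founders, 7 stages, dropout 0.15, 60-residue
targets) were chosen once as a realistic plate-scale campaign; per-stage
survivors are then Binomial(n, (1−r)^j), which the suite checks within four
standard deviations.

## Numerical and degenerate-input choices

* Residue indices are validated as `1 ≤ start ≤ stop ≤ protein length`;
  windows shorter than 18 nt of coding sequence are rejected for primer
  design.
* `melting_temperature()` requires ≥ 4 unambiguous bases; translation drops
  incomplete trailing codons and resolves ambiguous codons to X.
* Suggestion lists order most-recently-used first (per user), then
  alphabetically; history ties break on `(performed_at, id)`; export order
  is `(kind, id)`. Every ordering is total, so outputs are reproducible.
* Multiplicity-2 slots require distinct sample ids (complexing a sample
  with itself is meaningless).
* Instantiation is atomic: all bindings and required setup parameters are
  validated before anything is persisted.

## Known limitations

* No network accession fetch: targets import from local FASTA/GenBank/EMBL
  files only; the GenBank/EMBL reader covers the common single-record case
  (header, accession, description, first CDS translation, sequence block),
  not the full feature-table grammar.
* The relational backend is a single JSON file; there is no concurrent
  multi-writer support and no schema migration beyond a version check.
* Permissions are read/write per notebook with a single optional per-entity
  override; there are no deny rules or per-field redaction.
* Plate-parallel experiment batches are ordinary experiments whose samples
  carry plate/well locations, not first-class batch objects.
* The sample-history XML follows this package's own schema; no external
  wire-format compatibility is claimed.
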