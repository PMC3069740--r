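# prolims

Sample, protocol and construct tracking for protein-production laboratories.

Structural-biology labs move material through long, improvised chains —
PCR, cloning, transformation, expression, purification, crystallography —
and the record of that work usually lives in paper notebooks that nobody
else can decipher later. `prolims` is an information-management core for
exactly this setting, aimed at labs (and tool builders) who want electronic
records without committing to rigid predefined workflows. Instead of
pipelines it models:

* **Samples**, each with a type ("PCR product", "Soluble protein", ...),
  at most one producing experiment and any number of consuming ones;
* **Protocols**, reusable experiment templates with typed input/output
  slots and parameter definitions — used protocols become immutable and are
  varied by copy-then-edit; a 26-protocol standard library covering the
  protein-production pipeline ships with every store;
* **Experiments**, instantiations of protocols that bind input samples and
  create typed output samples, building a provenance DAG as a side effect;
* **Targets and Constructs** for sequence work: a construct takes a residue
  window of a target, optional N-terminal Met and tags, stores the
  expressed/final protein sequences, and suggests a PCR primer pair driven
  by a target melting temperature (Wallace rule `2(A+T)+4(G+C)`, or a
  unified nearest-neighbor model with salt correction
  `Tm = ΔH/(ΔS + 0.368(N−1)ln[Na⁺] + R ln(C_T/4)) − 273.15`
  at 50 mM Na⁺, 500 nM oligo);
* **Workflow graphs and reports**: Graphviz DOT diagrams truncated around a
  centre entity, exhaustive per-sample history reports (text/XML), and
  cohort tracking of founder samples through staged experiments;
* **Complexes**, declared over two or more targets, with automatic
  detection of samples whose provenance links them to all components;
* **Notebook-scoped access control** (groups, read/write grants, and the
  rule that a target's notebook governs all work derived from it), and a
  single-file store with deterministic bulk XML/JSON export/import.

## Worked example

```r
library(prolims)

store <- lims_store()                     # deterministic ids, logical clock
invisible(lims_seed_default_protocols(store))
nb  <- lims_create_notebook(store, "His-tag pilot")$id
tgt <- lims_generate_target(store, nb, protein_len = 120, seed = 42,
                            name = "demo-target")

# residues 2..110, N-terminal Met, cleavable His6 tag, primers aimed at 60 C
des <- lims_design_construct(store, tgt$id, 2, 110, add_n_met = TRUE,
                             tags = list(tag_his6("N", cleavable = TRUE)),
                             target_tm = 60)
```

The construct stores both protein forms — the expressed sequence keeps the
tag, the final sequence is what remains after cleavage:

```
expressed: MHHHHHHTFALEVTRHEFQYVRDKEFPFYC ...
final    : MTFALEVTRHEFQYVRDKEFPFYCIDALMR ...
forward primer: ATGCATCATCATCATCATCATACCTTTGCGCTGGAGGTGAC
  anneal 20 nt, Tm 60.4 C
reverse primer: TTAGAACATCCGACCTCTCTGCTGTGT
  anneal 24 nt, Tm 61.2 C
```

The forward primer carries the Met and His6 codons as a 5' add-on ahead of a
20 nt annealing region whose Tm (60.4 °C) is the first to reach the 60 °C
target; the reverse primer prepends the stop codon. Design is itself a
no-input experiment whose outputs — one Template and two Primers samples —
feed straight into PCR:

```r
pcr <- Filter(function(p) p$name == "PCR",
              lims_search_protocols_by_type(store, "Processing DNA"))[[1]]
exp <- lims_instantiate_experiment(store, pcr$id,
         list(primers = des$samples[[2]]$id, template = des$samples[[1]]$id))
lims_suggest_protocols(store, des$samples[[1]]$id)  # type-filtered:
#> Clone verification, PCR        (never e.g. Chromatography)
```

and the product's history report reconstructs every stage:

```
Sample history: sample-0056 (PCR pcr product, PCR product)
Stages: 2
1. Construct design: demo-target (2-110) (protocol: Construct design, ...)
   outputs: sample-0052 [Template], sample-0053 [Primers], sample-0054 [Primers]
2. PCR (protocol: PCR, ...)
   setup: annealing temperature=55, cycles=30
   inputs: sample-0053 [Primers], sample-0052 [Template]
   outputs: sample-0056 [PCR product]
```

`lims_audit(store)` returns `character(0)`: referential integrity, the
single-producer rule, type-chain soundness and acyclicity all hold. See the
methods vignette (`vignettes/protein-production-tracking.Rmd`) for the full
model, parameter choices and limitations.

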