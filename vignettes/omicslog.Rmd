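---
title: "omicslog: data model, consistency rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omicslog: data model, consistency rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicslog)
```

## What the package models

`omicslog` is an experiment-management system for multi-omics research
laboratories: a typed, consistency-enforcing logbook of experimental design,
sample lineage and data-processing provenance. It deliberately stores
*metadata and file pointers only*. The assumption behind that choice is that
raw and processed omics files live wherever the lab keeps bulk storage; what
goes missing in practice is the connective tissue — which FASTQ belongs to
which replicate of which condition, which BAM it was mapped into with which
reference, and which processed signal file a figure was made from.

Three module families cover this:

* **Sample lineage.** `biological_condition()` describes a biomaterial
  (organism, tissue, cell type, a free-text variation such as
  cancer/normal) plus an *optional* experimental condition record
  (treatment, dose, time-point). Absence of treatment is modelled as the
  whole record being absent, not as three empty strings, so "untreated" is
  representable as a unit. Conditions are instantiated by numbered
  `biological_replicate()`s — the pair (condition, replicate number) is
  unique — optionally tagged with a shared `experimental_batch()` (a
  systematic-noise grouping factor). Replicates yield
  `analytical_sample()`s: extraction-protocol-processed material ready for
  measurement (a cytosolic mRNA prep, a sub-cellular protein fraction). All
  links are one-to-many, which lets complex sampling schemes be expressed
  without duplicating information.

* **Provenance DAGs.** An analysis is built on a draft: `add_raw_step()`
  (measured from an analytical sample; the only permitted first step),
  `add_intermediate_step()` (trimming, mapping, peak calling, merging, …;
  one or many inputs), `add_processed_step()` (exactly one per analysis).
  Edges are derived from each node's `input_node_ids`, never stored
  separately, so the graph cannot desynchronize from the nodes.
  `finalize_analysis()` admits a draft only if its graph is acyclic, weakly
  connected, has every root either a raw-data node or a processed-data
  result of another finalized analysis, and exactly one sink — the
  processed-data node. Finalized analyses are immutable except for their
  experiment associations; "modifying" a workflow means importing a prefix
  of it into a new draft (`import_steps()`), which shares nodes *by
  reference*.

* **Experiments and progress.** An experiment records planned measurements
  as (assay tag, done) pairs. The `done` flag is a pure function of the
  associated analyses' types; it is recomputed from scratch on every
  association, dissociation and analysis deletion, so incremental state can
  never drift from the definition.

## Access control

The acting user is asserted by the caller (a `--user` flag on the command
line); there is no authentication layer — in the original client–server
setting that concern belongs to the transport, and as an embedded library
the caller is trusted. The rules are deliberately minimal:

* users are registered by an administrator (an empty registry bootstraps its
  first admin);
* the creator of an element owns it, with exclusive delete and grant rights;
* grants confer edit rights only, are idempotent and revocable;
* every registered user can read everything (a lab logbook restricts
  modification, not reading).

Experiment membership is informational; rights flow solely from ownership
and grants. This was a genuinely open point (should members automatically
get edit rights on an experiment's samples?) and the conservative reading
was chosen: implicit rights are easy to add later, impossible to retract
quietly.

## Deletion and referential integrity

Deletion is RESTRICT, never cascade: cascade would silently destroy workflow
steps shared between analyses. Two classes of links are distinguished:

* *structural references* (replicate → condition, sample → replicate, node
  inputs, analysis/draft node sets, analysis → experiment, ownership, and a
  secondary analysis' dependence on the analysis whose processed data it
  reuses) block deletion of their target, with the referrers listed in the
  error;
* *membership associations* (an experiment's member/sample/analysis sets,
  grants) are bookkeeping on the container and are cleaned up when the
  member is deleted — deleting an analysis dissociates it from its
  experiments and recomputes their progress flags.

Without this split the package's own reuse semantics would be inconsistent:
an analysis must be deletable (so shared nodes can eventually be released),
yet a node shared with a surviving analysis must not be.

One related choice: dissociating an analysis from its last experiment is
allowed (its progress flag reverts), so "≥ 1 experiment" is enforced at
finalization rather than as a permanent structural invariant.

`ems_audit()` is the global safety net: it re-derives every invariant —
reference resolution and kind-correctness, replicate uniqueness, the
one-analysis-one-processed-data rule (counting only sinks, so foreign
processed-data roots of secondary analyses are legal), flag correctness,
bidirectional association mirroring, grant validity, counter monotonicity —
from the stored state alone.

## Identifiers

Identifiers are typed prefixes with a zero-padded counter (`BC-0001`,
`RD-0003`, `AN-0002`), one counter per kind, monotonically increasing and
never rewound: a deleted identifier is never reissued, which keeps exported
documents and downstream notes unambiguous forever. The prefix makes every
cross-reference self-describing in exports and error messages. Four digits
are a formatting minimum, not a cap — counters keep counting past 9999.

Assay tags are matched case-insensitively and whitespace-trimmed but stored
canonically: `"mrna-seq "` resolves to `mRNA-seq`, while distinct tags
(`mRNA-seq` vs `miRNA-seq`) never collapse. This prevents progress-flag
drift from letter-case variants without inventing tag aliasing.

## Storage and interchange

The registry lives in memory with reference semantics and persists as a
single canonical JSON file (`write_registry()` / `read_registry()`), the
same format as `export_registry()` / `import_document()`. Canonical means
byte-deterministic: kinds and records sorted by identifier, fields in schema
order, set-valued fields sorted, ISO-8601 dates, UTF-8. Two registries are
equal exactly when their exports are byte-identical, which turns round-trip
identity into a testable property and makes registry files diffable under
version control. A `schema_version` field versions the format; strict import
requires an empty target, materializes original identifiers, advances
counters beyond the largest imported identifier, and runs the full audit
before committing — any failure aborts with the target untouched. Merge
import (identifier collisions across labs) is intentionally out of scope for
this version: its semantics are underdetermined, and a wrong guess here
corrupts provenance.

A relational engine was considered for the store and rejected: the
integrity rules above must live in the library regardless (they span graph
structure and derived flags that SQL foreign keys cannot express), and a
single canonical text file keeps persistence, interchange and equality
testing one mechanism instead of three.

Writing is atomic (temp file + rename), and each library operation validates
completely before mutating state, so a rejected operation leaves the
registry byte-identical — asserted in the tests by snapshot comparison.

## The fixture and the random generator

`build_encode_usecase()` is the package's reference scenario and the single
source of its acceptance counts: an "ENCODE test" experiment (type
"multiple conditions", 2 planned replicates, four planned measurements),
the K562 and GM12878 cell lines (human, blood, lymphocyte; cancer/normal;
no experimental condition), nine K562 biological replicates, analytical
samples per assay (two mRNA-seq preps with the Caltech long mRNA extraction
protocol; four proteomics fractions — membrane fraction, cytosol, nucleus,
mitochondria; two each for ChIP-seq and DNase-seq), and seven finalized
analyses covering the stock workflow templates, including a step-reuse
analysis and a DNase-seq secondary analysis merging two per-sample DHR bed
files. Where the scenario fixes a value, the fixture reproduces it exactly;
where it does not, a choice was made once and recorded in the manifest
rather than asserted as ground truth:

* the nine replicates are attached to K562 (the sampling scheme they
  implement is a K562 scheme); GM12878 receives a mirrored, smaller scheme
  (2 replicates, mRNA-seq samples only);
* K562 replicates are spread over three culture batches of three;
* the secondary DNase-seq merge uses N = 2 samples — the minimal nontrivial
  merge.

All creation dates are fixed, so two builds export byte-identically; the
shipped copy (`inst/extdata/encode_usecase.ems.json`) is asserted equal to a
fresh build in the tests.

`random_registry()` generates seed-deterministic registries for property
testing: configurable counts of users, conditions, replicates, samples and
analyses, random workflow shapes (chains, two-root merges, secondary
analyses), random batch membership and grants. It emulates the *structural*
variety of real registries — it does not emulate realistic metadata text,
heterogeneous date patterns, or adversarial inputs, so passing property
suites demonstrate structural consistency, not robustness to malicious
documents. The generator restores the caller's RNG state on exit.

## Testing strategy and problem sizes

Every consistency mechanism is checked against an independently coded
oracle rather than against itself: the workflow validator (igraph-based)
against a brute-force matrix-closure/union-find verdict on 1000 random
graphs of up to 8 nodes; lineage tracing against a global backward BFS over
all stored input edges; progress flags against a from-scratch scan after
every one of 2 × 500 random operations; round-trip identity on 200 random
registries; the permission matrix exhaustively for three principals (owner,
grantee, other) across all ten element kinds. These sizes keep the full
suite under a minute on one CPU while exhausting the small-graph space where
validator disagreements would hide; the acceptance script repeats scaled
versions (30 round-trips, 300 operations) so its checks rerun from scratch
on any seed.

## Known limitations

* Free-text biomaterial fields: no controlled-vocabulary or ontology
  validation of organism/tissue/cell-type terms, and no
  completeness scoring against reporting checklists.
* No authentication, sessions, audit trail of edits (only creation dates),
  or soft deletes.
* Single-writer model: operations are atomic and serialized within one
  process; concurrent writers on one registry file are not coordinated.
* The system never verifies that file pointers resolve, checksums their
  targets, or executes any processing step.
* Strict (whole-registry) import only; no merge, no ISA-Tab/SRA export.
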