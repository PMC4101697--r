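# omicslog

An embeddable experiment-management system (EMS) for research laboratories
running multi-omics studies — a structured lab logbook, as an R package plus
a command-line tool.

As sequencing costs fall, a single lab project routinely combines several
sequencing assays (mRNA-seq, ChIP-seq, DNase-seq, Methyl-seq, miRNA-seq)
with proteomics and metabolomics, across dozens of samples and replicates.
Facility LIMS track wet-lab pipelines at sequencing centers; what the
*originating lab* needs instead is consistent annotation of its experimental
design, its samples, and the processing pipelines applied to the data files
it gets back. `omicslog` provides exactly that: metadata and provenance only
— it stores **pointers** (paths/URIs) to FASTQ/BAM/BED/GTF files and never
ingests their content.

## The data model

Three connected modules, mirroring the minimal-information reporting
standards for sequencing and proteomics experiments (MINSEQE/MIAME/MIAPE):

* **Experiment** — goals, design, planned omics measurements, each with a
  progress flag that the registry keeps equal to "≥ 1 associated analysis of
  this type exists".
* **Samples** — a three-level lineage with one-to-many links:
  *biological condition* (biomaterial + optional treatment/dose/time-point)
  → numbered *biological replicates* (optionally tagged with the
  *experimental batch* they were cultured in) → *analytical samples*
  (extraction-protocol-processed material ready for measurement).
* **Analysis** — a provenance DAG per processed result:
  `raw data → intermediate steps (trimming, mapping, peak calling, …) →
  exactly one processed data` node. Edges are derived from each node's
  recorded inputs, so structure cannot desynchronize. Completed analyses are
  immutable; their steps can be *reused by reference* in new workflows, and
  a processed result can root a *secondary analysis* (e.g. merging
  per-sample DNase-hypersensitivity beds and re-counting reads). Every
  analysis traces back to the analytical samples it measured.

Every element is owned by the user who created it; owners hold exclusive
delete/grant rights and can grant edit access to other registered users.
Deletion is RESTRICT — nothing that is still referenced (a condition with
replicates, a workflow step shared by two analyses) can be removed. The
whole registry round-trips losslessly through canonical, diffable JSON.

## A worked example

```r
library(omicslog)

reg   <- ems_registry()
admin <- ems_register_user(reg, "admin", role = "admin")   # bootstrap admin
ana   <- ems_register_user(reg, "ana", acting = admin)

exp <- ems_create(reg, experiment(
  name = "LPS time course", experiment_type = "time course",
  n_replicates_planned = 3, planned_measurements = c("mRNA-seq", "ChIP-seq")
), acting = ana)

bc  <- ems_create(reg, biological_condition(
  name = "B-cell LPS 2h", organism = "mouse", tissue = "spleen",
  cell_type = "B lymphocyte",
  experimental_condition = list(treatment = "LPS", time_point = "2h")
), acting = ana)
br  <- ems_create(reg, biological_replicate(bc, 1), acting = ana)
as1 <- ems_create(reg, analytical_sample(br, "cytosolic mRNA prep",
  extraction_protocol = "cytosolic mRNA extraction"), acting = ana)

dr  <- start_analysis(reg, "mRNA-seq", exp, acting = ana)
rd  <- add_raw_step(reg, dr, as1, "mRNA-seq",
                    file_pointer = "runs/lps_2h_r1.fastq", acting = ana)
is1 <- add_intermediate_step(reg, dr, rd, step_kind = "mapping",
                             software = "TopHat",
                             reference_resource = "GENCODE hg19",
                             file_pointer = "aln/lps_2h_r1.bam", acting = ana)
pd  <- add_processed_step(reg, dr, is1, signal_description = "FPKM table",
                          file_pointer = "quant/lps_2h_r1.gtf", acting = ana)
an  <- finalize_analysis(reg, dr, acting = ana)   # "AN-0001"

trace_to_samples(reg, an)
#> # A tibble: 1 × 6
#>   as_id   sample_name         br_id   replicate_number bc_id   condition_name
#> 1 AS-0001 cytosolic mRNA prep BR-0001                1 BC-0001 B-cell LPS 2h
```

Finalizing the analysis flipped the experiment's `mRNA-seq` progress flag to
`TRUE` (ChIP-seq stays `FALSE` until a matching analysis is associated), and
the workflow renders deterministically:

```r
cat(render_graph(reg, an, format = "dot"))
#> digraph "AN-0001" {
#>   rankdir=LR;
#>   "IS-0001" [label="IS-0001\nmapping", shape=box];
#>   "PD-0001" [label="PD-0001\nFPKM table", shape=hexagon];
#>   "RD-0001" [label="RD-0001\nraw: mRNA-seq", shape=ellipse];
#>   "IS-0001" -> "PD-0001";
#>   "RD-0001" -> "IS-0001";
#> }

glance(reg)
#> # A tibble: 1 × 6
#>   schema_version n_entities n_users n_analyses n_grants audit_clean
#> 1              1         10       2          1        0 TRUE
```

`write_registry(reg, "lab.ems.json")` persists everything as canonical JSON;
`read_registry()` restores it with all identifiers intact.
`build_encode_usecase()` populates a registry with the package's reference
scenario (two ENCODE cell lines, four omics types, nine K562 replicates) and
returns its count manifest. `plot_workflow(reg, an)` draws the DAG with
ggplot2.

## Command line

The same operations are scriptable through the `ems` tool in
`inst/exec/ems` (after installation: `$(R RHOME)/library/omicslog/exec/ems`):

```sh
ems --registry lab.ems.json init
ems --registry lab.ems.json user register --name admin --role admin
ems --registry lab.ems.json fixture build
ems --registry lab.ems.json experiment show EXP-0001 --json
ems --registry lab.ems.json analysis trace AN-0001
```

Exit codes are stable for scripting: 0 success, 2 validation/usage,
3 permission, 4 not found, 5 integrity.

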