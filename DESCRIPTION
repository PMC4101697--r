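Package: omicslog
Title: Annotation, Storage and Provenance Tracking for Multi-Omics
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embeddable experiment-management system for research
    laboratories running multi-omics studies. Provides typed annotation of
    experiments, biological conditions, replicates, batches and analytical
    samples; a registry with ownership and grant-based access control,
    referential integrity and automatic experiment-progress bookkeeping;
    analysis-workflow provenance as directed acyclic graphs of raw,
    intermediate and processed data steps with step reuse and sample-lineage
    tracing; lossless canonical JSON interchange; a deterministic fixture and
    random-registry generator for testing; and a command-line interface for
    scripted use. The system stores metadata and file pointers only, never
    omics data files themselves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
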