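#' Build the canonical multi-omics annotation fixture
#'
#' Populates an empty registry with the package's reference scenario: the
#' annotation of a subset of the public ENCODE human dataset — four omics
#' data types (mRNA-seq, ChIP-seq, DNase-seq, Proteomics) measured on the
#' K562 (chronic myelogenous leukemia) and GM12878 (lymphoblastoid) cell
#' lines. The build is fully deterministic (fixed creation dates), so two
#' builds into fresh registries export to byte-identical documents; it is
#' the single source for the package's acceptance counts.
#'
#' What gets created:
#'
#' * one experiment, "ENCODE test" ("STATegra EMS test experiment"), of type
#'   "multiple conditions" with 2 planned replicates and four planned
#'   measurements;
#' * the two biological conditions (human, blood, lymphocyte; K562 = cancer,
#'   GM12878 = normal; no experimental condition — untreated cell lines);
#' * nine biological replicates for K562, distributed over three culture
#'   batches of three, and two (mirrored, smaller scheme) for GM12878;
#' * analytical samples: one mRNA-seq sample per each of two replicates per
#'   condition ("Caltech long mRNA extraction protocol"); four proteomics
#'   samples on a designated K562 replicate, named after the sub-cellular
#'   fractions (membrane fraction, cytosol, nucleus, mitochondria); one
#'   ChIP-seq and one DNase-seq sample on two further K562 replicates each;
#' * finalized analyses following the stock workflow templates: an mRNA-seq
#'   primary workflow (raw -> TopHat mapping against GENCODE hg19 ->
#'   "Cufflinks gtf file with FPKMs"), a reuse analysis importing its first
#'   two steps and ending in "junction's bed file obtained by TopHat", a
#'   ChIP-seq workflow with exactly two intermediate steps (read mapping,
#'   peak calling), two DNase-seq primary workflows ending in per-sample DHR
#'   bed files, a DNase-seq secondary workflow merging the two DHR beds and
#'   counting reads into a per-sample signal file, and a proteomics workflow
#'   (raw -> protein quantification, zero intermediate steps).
#'
#' Afterwards all four experiment progress flags are true.
#'
#' @param registry An empty [ems_registry()], or one containing only users
#'   (at least one admin and one regular user). A brand-empty registry is
#'   bootstrapped with an admin ("admin") and a regular user ("rafa").
#' @return The fixture manifest: a tibble with columns `metric` and `value`
#'   holding every count the fixture guarantees.
#' @export
#' @examples
#' reg <- ems_registry()
#' manifest <- build_encode_usecase(reg)
build_encode_usecase <- function(registry) {
  check_registry(registry)
  non_user <- setdiff(ENTITY_KINDS, "user")
  if (any(vapply(registry$tables[non_user], length, integer(1)) > 0)) {
    abort_validation("the fixture requires a registry without entities")
  }
  d0 <- as.Date("2014-03-13")
  if (length(registry$tables$user) == 0) {
    ems_register_user(registry, "admin", role = "admin", created_on = d0)
    admin <- names(registry$tables$user)[[1]]
    ems_register_user(registry, "rafa", role = "regular", acting = admin,
                      created_on = d0)
  }
  roles <- vapply(registry$tables$user, function(u) u$role, character(1))
  if (!any(roles == "admin") || !any(roles == "regular")) {
    abort_validation("the fixture needs one admin and one regular user")
  }
  u <- names(roles)[roles == "regular"][[1]]

  exp_id <- ems_create(registry, experiment(
    name = "ENCODE test",
    description = "STATegra EMS test experiment",
    goals = "Annotate a subset of the ENCODE human dataset",
    experiment_type = "multiple conditions",
    n_replicates_planned = 2,
    planned_measurements = c("mRNA-seq", "ChIP-seq", "DNase-seq",
                             "Proteomics")
  ), acting = u, created_on = d0)

  k562 <- ems_create(registry, biological_condition(
    name = "K562", title = "Chronic myelogenous leukemia",
    organism = "human", tissue = "blood", cell_type = "lymphocyte",
    variation = "cancer"
  ), acting = u, created_on = d0)
  gm <- ems_create(registry, biological_condition(
    name = "GM12878", title = "Lymphoblastoid",
    organism = "human", tissue = "blood", cell_type = "lymphocyte",
    variation = "normal"
  ), acting = u, created_on = d0)
  ems_associate_sample(registry, k562, exp_id, acting = u)
  ems_associate_sample(registry, gm, exp_id, acting = u)

  batches <- vapply(1:3, function(i) {
    ems_create(registry, experimental_batch(sprintf("culture batch %d", i)),
               acting = u, created_on = d0)
  }, character(1))

  k_reps <- vapply(1:9, function(i) {
    ems_create(registry, biological_replicate(
      k562, replicate_number = i, batch_id = batches[[ceiling(i / 3)]]
    ), acting = u, created_on = d0)
  }, character(1))
  g_reps <- vapply(1:2, function(i) {
    ems_create(registry, biological_replicate(gm, replicate_number = i),
               acting = u, created_on = d0)
  }, character(1))

  mrna_protocol <- "Caltech long mRNA extraction protocol"
  k_mrna <- vapply(1:2, function(i) {
    ems_create(registry, analytical_sample(
      k_reps[[i]], name = sprintf("K562 cytosolic mRNA #%d", i),
      extraction_protocol = mrna_protocol
    ), acting = u, created_on = d0)
  }, character(1))
  g_mrna <- vapply(1:2, function(i) {
    ems_create(registry, analytical_sample(
      g_reps[[i]], name = sprintf("GM12878 cytosolic mRNA #%d", i),
      extraction_protocol = mrna_protocol
    ), acting = u, created_on = d0)
  }, character(1))
  fractions <- c("membrane fraction", "cytosol", "nucleus", "mitochondria")
  prot_as <- vapply(fractions, function(fr) {
    ems_create(registry, analytical_sample(
      k_reps[[3]], name = fr,
      extraction_protocol = "sub-cellular fractionation"
    ), acting = u, created_on = d0)
  }, character(1))
  chip_as <- vapply(1:2, function(i) {
    ems_create(registry, analytical_sample(
      k_reps[[3 + i]], name = sprintf("K562 chromatin IP #%d", i),
      extraction_protocol = "crosslinked chromatin immunoprecipitation"
    ), acting = u, created_on = d0)
  }, character(1))
  dnase_as <- vapply(1:2, function(i) {
    ems_create(registry, analytical_sample(
      k_reps[[5 + i]], name = sprintf("K562 DNase digest #%d", i),
      extraction_protocol = "DNase I digestion"
    ), acting = u, created_on = d0)
  }, character(1))

  # mRNA-seq primary workflow: raw -> mapping -> FPKM quantification
  dr <- start_analysis(registry, "mRNA-seq", exp_id, acting = u,
                       created_on = d0)
  rd1 <- add_raw_step(registry, dr, k_mrna[[1]], "mRNA-seq",
                      file_pointer = "runs/k562_rep1.fastq",
                      protocol_details = "Caltech long mRNA library prep",
                      acting = u, created_on = d0)
  is1 <- add_intermediate_step(registry, dr, rd1, step_kind = "mapping",
                               software = "TopHat",
                               reference_resource = "GENCODE hg19",
                               file_pointer = "aln/k562_rep1.bam",
                               acting = u, created_on = d0)
  add_processed_step(registry, dr, is1,
                     signal_description = "Cufflinks gtf file with FPKMs",
                     file_pointer = "quant/k562_rep1.gtf",
                     acting = u, created_on = d0)
  an_mrna <- finalize_analysis(registry, dr, acting = u, created_on = d0)

  # reuse analysis: import the first two steps, different processed result
  dr <- start_analysis(registry, "mRNA-seq", exp_id, acting = u,
                       created_on = d0)
  import_steps(registry, dr, an_mrna, c(rd1, is1), acting = u)
  add_processed_step(registry, dr, is1,
                     signal_description = "junction's bed file obtained by TopHat",
                     file_pointer = "aln/k562_rep1.junctions.bed",
                     acting = u, created_on = d0)
  finalize_analysis(registry, dr, acting = u, created_on = d0)

  # ChIP-seq workflow: exactly two intermediate steps
  dr <- start_analysis(registry, "ChIP-seq", exp_id, acting = u,
                       created_on = d0)
  rd <- add_raw_step(registry, dr, chip_as[[1]], "ChIP-seq",
                     file_pointer = "runs/k562_chip1.fastq",
                     protocol_details = "ChIP library prep",
                     acting = u, created_on = d0)
  m <- add_intermediate_step(registry, dr, rd, step_kind = "read mapping",
                             software = "Bowtie",
                             reference_resource = "hg19",
                             file_pointer = "aln/k562_chip1.bam",
                             acting = u, created_on = d0)
  pk <- add_intermediate_step(registry, dr, m, step_kind = "peak calling",
                              software = "MACS",
                              file_pointer = "peaks/k562_chip1_peaks.xls",
                              acting = u, created_on = d0)
  add_processed_step(registry, dr, pk,
                     signal_description = "ChIP peak regions bed file",
                     file_pointer = "peaks/k562_chip1.bed",
                     acting = u, created_on = d0)
  finalize_analysis(registry, dr, acting = u, created_on = d0)

  # DNase-seq primary workflows: per-sample DHR bed from peak calling
  dnase_pd <- character(2)
  dnase_an <- character(2)
  for (i in 1:2) {
    dr <- start_analysis(registry, "DNase-seq", exp_id, acting = u,
                         created_on = d0)
    rd <- add_raw_step(registry, dr, dnase_as[[i]], "DNase-seq",
                       file_pointer = sprintf("runs/k562_dnase%d.fastq", i),
                       protocol_details = "DNase-seq library prep",
                       acting = u, created_on = d0)
    m <- add_intermediate_step(registry, dr, rd, step_kind = "mapping",
                               software = "BWA", reference_resource = "hg19",
                               file_pointer = sprintf("aln/k562_dnase%d.bam",
                                                      i),
                               acting = u, created_on = d0)
    dnase_pd[[i]] <- add_processed_step(
      registry, dr, m,
      signal_description = "DHR bed file (peak calling)",
      file_pointer = sprintf("dhr/k562_dnase%d.DHR.bed", i),
      acting = u, created_on = d0
    )
    dnase_an[[i]] <- finalize_analysis(registry, dr, acting = u,
                                       created_on = d0)
  }

  # DNase-seq secondary workflow: merge the per-sample DHR beds, count reads
  dr <- start_analysis(registry, "DNase-seq", exp_id, acting = u,
                       created_on = d0)
  import_steps(registry, dr, dnase_an[[1]], dnase_pd[[1]], acting = u)
  import_steps(registry, dr, dnase_an[[2]], dnase_pd[[2]], acting = u)
  mg <- add_intermediate_step(registry, dr, dnase_pd, step_kind = "merging",
                              software = "bedtools merge",
                              file_pointer = "dhr/k562_consolidated.bed",
                              acting = u, created_on = d0)
  ct <- add_intermediate_step(registry, dr, mg, step_kind = "read counting",
                              software = "bedtools multicov",
                              file_pointer = "dhr/k562_counts.txt",
                              acting = u, created_on = d0)
  add_processed_step(registry, dr, ct,
                     signal_description = "per-sample signal value file",
                     file_pointer = "dhr/k562_signal.txt",
                     acting = u, created_on = d0)
  finalize_analysis(registry, dr, acting = u, created_on = d0)

  # proteomics workflow: zero intermediate steps is a valid analysis
  dr <- start_analysis(registry, "Proteomics", exp_id, acting = u,
                       created_on = d0)
  rd <- add_raw_step(registry, dr, prot_as[[1]], "Proteomics",
                     file_pointer = "ms/k562_membrane.raw",
                     protocol_details = "LC-MS/MS",
                     acting = u, created_on = d0)
  add_processed_step(registry, dr, rd,
                     signal_description = "protein quantification matrix",
                     file_pointer = "ms/k562_membrane_quant.txt",
                     acting = u, created_on = d0)
  finalize_analysis(registry, dr, acting = u, created_on = d0)

  fixture_manifest(registry, exp_id, k562, gm)
}

fixture_manifest <- function(registry, exp_id, k562, gm) {
  exp <- registry$tables$experiment[[exp_id]]
  n_done <- sum(vapply(exp$planned_measurements, function(m) m$done,
                       logical(1)))
  mrna_as <- function(bc) {
    reps <- replicates_of(registry, bc)$br_id
    smp <- ems_query(registry, "analytical_sample")
    sum(smp$br_id %in% reps &
          smp$extraction_protocol == "Caltech long mRNA extraction protocol")
  }
  prot_names <- {
    smp <- ems_query(registry, "analytical_sample")
    sort(smp$name[smp$extraction_protocol == "sub-cellular fractionation"])
  }
  tibble::tibble(
    metric = c(
      "experiments", "biological_conditions", "experimental_batches",
      "biological_replicates", "k562_replicates", "gm12878_replicates",
      "analytical_samples", "k562_mrna_seq_analytical_samples",
      "gm12878_mrna_seq_analytical_samples",
      "proteomics_analytical_samples", "planned_measurements",
      "planned_measurements_done", "analyses", "raw_data_nodes",
      "intermediate_step_nodes", "processed_data_nodes",
      "chipseq_intermediate_steps", "proteomics_fraction_names_match"
    ),
    value = c(
      length(registry$tables$experiment),
      length(registry$tables$biological_condition),
      length(registry$tables$experimental_batch),
      length(registry$tables$biological_replicate),
      nrow(replicates_of(registry, k562)),
      nrow(replicates_of(registry, gm)),
      length(registry$tables$analytical_sample),
      mrna_as(k562),
      mrna_as(gm),
      length(prot_names),
      length(exp$planned_measurements),
      n_done,
      length(registry$tables$analysis),
      length(registry$tables$raw_data),
      length(registry$tables$intermediate_step),
      length(registry$tables$processed_data),
      {
        chip <- Filter(function(a) a$analysis_type == "ChIP-seq",
                       registry$tables$analysis)
        if (length(chip) == 1) {
          sum(kind_of_id(chip[[1]]$node_ids) == "intermediate_step")
        } else {
          NA_integer_
        }
      },
      as.integer(identical(
        prot_names,
        sort(c("membrane fraction", "cytosol", "nucleus", "mitochondria"))
      ))
    )
  )
}

#' Workflow templates shipped with the package
#'
#' The stock step sequences for the supported sequencing assays (mRNA-seq:
#' raw -> mapping -> processed; ChIP-seq: raw -> read mapping -> peak
#' calling -> processed; DNase-seq primary and secondary). Templates are
#' data used by the fixture and the documentation, not enforced schemas —
#' processing-step forms are generic for high-throughput sequencing.
#'
#' @return A tibble with columns `template`, `assay_tag`, `position`,
#'   `step`, `step_kind`.
#' @export
workflow_templates <- function() {
  dir <- system.file("extdata", "templates", package = "omicslog")
  files <- sort(list.files(dir, pattern = "\\.template\\.json$",
                           full.names = TRUE))
  purrr::map_dfr(files, function(f) {
    t <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    tibble::tibble(
      template = t$name,
      assay_tag = t$assay_tag,
      position = seq_along(t$steps),
      step = vapply(t$steps, function(s) s$step, character(1)),
      step_kind = vapply(t$steps, function(s) s$step_kind %||% NA_character_,
                         character(1))
    )
  })
}
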