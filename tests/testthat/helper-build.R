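# small programmatic builders shared across tests

base_registry <- function() {
  reg <- ems_registry()
  admin <- ems_register_user(reg, "admin", role = "admin",
                             created_on = as.Date("2020-01-01"))
  u1 <- ems_register_user(reg, "ana", acting = admin,
                          created_on = as.Date("2020-01-01"))
  u2 <- ems_register_user(reg, "david", acting = admin,
                          created_on = as.Date("2020-01-01"))
  list(reg = reg, admin = admin, owner = u1, other = u2)
}

# experiment + condition + replicate + analytical sample owned by `owner`
with_lineage <- function(ctx) {
  reg <- ctx$reg
  d <- as.Date("2020-02-01")
  ctx$exp <- ems_create(reg, experiment(
    name = "test experiment", experiment_type = "multiple conditions",
    n_replicates_planned = 2,
    planned_measurements = c("mRNA-seq", "ChIP-seq")
  ), acting = ctx$owner, created_on = d)
  ctx$bc <- ems_create(reg, biological_condition(
    name = "K562", title = "Chronic myelogenous leukemia",
    organism = "human", tissue = "blood", cell_type = "lymphocyte",
    variation = "cancer"
  ), acting = ctx$owner, created_on = d)
  ctx$br <- ems_create(reg, biological_replicate(ctx$bc, 1),
                       acting = ctx$owner, created_on = d)
  ctx$as <- ems_create(reg, analytical_sample(
    ctx$br, name = "K562 mRNA #1",
    extraction_protocol = "Caltech long mRNA extraction protocol"
  ), acting = ctx$owner, created_on = d)
  ctx
}

# a finalized raw -> mapping -> processed chain; returns ids
simple_chain <- function(ctx, type = "mRNA-seq") {
  reg <- ctx$reg
  d <- as.Date("2020-02-02")
  dr <- start_analysis(reg, type, ctx$exp, acting = ctx$owner,
                       created_on = d)
  rd <- add_raw_step(reg, dr, ctx$as, type,
                     file_pointer = "runs/x.fastq", acting = ctx$owner,
                     created_on = d)
  is1 <- add_intermediate_step(reg, dr, rd, step_kind = "mapping",
                               software = "TopHat",
                               reference_resource = "GENCODE hg19",
                               file_pointer = "aln/x.bam",
                               acting = ctx$owner, created_on = d)
  pd <- add_processed_step(reg, dr, is1,
                           signal_description = "FPKM table",
                           file_pointer = "quant/x.gtf",
                           acting = ctx$owner, created_on = d)
  an <- finalize_analysis(reg, dr, acting = ctx$owner, created_on = d)
  list(an = an, rd = rd, is1 = is1, pd = pd)
}
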