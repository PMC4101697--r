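test_that("drafts start empty, with canonicalized, registered types only", {
  ctx <- with_lineage(base_registry())
  dr <- start_analysis(ctx$reg, " mrna-SEQ ", ctx$exp, acting = ctx$owner)
  d <- ems_get(ctx$reg, dr)
  expect_identical(d$analysis_type, "mRNA-seq")
  expect_identical(d$node_ids, character())
  err <- expect_error(
    start_analysis(ctx$reg, "HiC-seq", ctx$exp, acting = ctx$owner),
    class = "ems_validation_error"
  )
  expect_match(conditionMessage(err), "mRNA-seq")
  expect_error(start_analysis(ctx$reg, "mRNA-seq", "EXP-9999",
                              acting = ctx$owner),
               class = "ems_not_found_error")
})

test_that("raw data is the only option on an empty draft", {
  ctx <- with_lineage(base_registry())
  dr <- start_analysis(ctx$reg, "mRNA-seq", ctx$exp, acting = ctx$owner)
  expect_error(
    add_intermediate_step(ctx$reg, dr, "RD-0001", step_kind = "mapping",
                          file_pointer = "x.bam", acting = ctx$owner),
    "raw-data step", class = "ems_validation_error"
  )
  expect_error(
    add_processed_step(ctx$reg, dr, "RD-0001", signal_description = "s",
                       file_pointer = "x.txt", acting = ctx$owner),
    class = "ems_validation_error"
  )
  rd <- add_raw_step(ctx$reg, dr, ctx$as, "mRNA-seq",
                     file_pointer = "runs/k562_rep1.fastq",
                     acting = ctx$owner)
  expect_identical(ems_get(ctx$reg, rd)$as_id, ctx$as)
  # a second run of the same analytical sample is allowed: two roots
  rd2 <- add_raw_step(ctx$reg, dr, ctx$as, "mRNA-seq",
                      file_pointer = "runs/k562_rep1b.fastq",
                      acting = ctx$owner)
  expect_identical(sort(ems_get(ctx$reg, dr)$node_ids), sort(c(rd, rd2)))
  expect_error(
    add_raw_step(ctx$reg, dr, "AS-9999", "mRNA-seq", file_pointer = "f",
                 acting = ctx$owner),
    class = "ems_not_found_error"
  )
})

test_that("intermediate steps consume one or many in-draft nodes", {
  ctx <- with_lineage(base_registry())
  dr <- start_analysis(ctx$reg, "DNase-seq", ctx$exp, acting = ctx$owner)
  roots <- vapply(1:4, function(i) {
    add_raw_step(ctx$reg, dr, ctx$as, "DNase-seq",
                 file_pointer = sprintf("runs/r%d.fastq", i),
                 acting = ctx$owner)
  }, character(1))
  merge <- add_intermediate_step(ctx$reg, dr, roots, step_kind = "merging",
                                 file_pointer = "merged.bed",
                                 acting = ctx$owner)
  expect_identical(ems_get(ctx$reg, merge)$input_node_ids, roots)
  one <- add_intermediate_step(ctx$reg, dr, merge, step_kind = "filtering",
                               software = "bedtools",
                               file_pointer = "filtered.bed",
                               acting = ctx$owner)
  expect_identical(length(ems_get(ctx$reg, one)$input_node_ids), 1L)
  # inputs outside the draft are rejected
  expect_error(
    add_intermediate_step(ctx$reg, dr, "RD-9999", step_kind = "mapping",
                          file_pointer = "x.bam", acting = ctx$owner),
    class = "ems_validation_error"
  )
  expect_error(
    add_intermediate_step(ctx$reg, dr, character(), step_kind = "mapping",
                          file_pointer = "x.bam", acting = ctx$owner),
    class = "ems_validation_error"
  )
})

test_that("one processed-data step per draft; raw -> processed is valid", {
  ctx <- with_lineage(base_registry())
  dr <- start_analysis(ctx$reg, "Proteomics", ctx$exp, acting = ctx$owner)
  rd <- add_raw_step(ctx$reg, dr, ctx$as, "Proteomics",
                     file_pointer = "ms/run.raw", acting = ctx$owner)
  pd <- add_processed_step(ctx$reg, dr, rd,
                           signal_description = "protein quantification",
                           file_pointer = "ms/quant.txt",
                           acting = ctx$owner)
  expect_error(
    add_processed_step(ctx$reg, dr, rd, signal_description = "again",
                       file_pointer = "ms/quant2.txt", acting = ctx$owner),
    class = "ems_validation_error"
  )
  # zero intermediate steps still finalizes
  an <- finalize_analysis(ctx$reg, dr, acting = ctx$owner)
  expect_identical(sort(ems_get(ctx$reg, an)$node_ids), sort(c(rd, pd)))
})

test_that("finalization enforces every graph invariant by name", {
  ctx <- with_lineage(base_registry())
  # empty draft: no processed data
  dr <- start_analysis(ctx$reg, "mRNA-seq", ctx$exp, acting = ctx$owner)
  expect_error(finalize_analysis(ctx$reg, dr, acting = ctx$owner),
               "no processed-data step", class = "ems_validation_error")
  # orphan node: disconnected graph is rejected listing the orphan
  rd1 <- add_raw_step(ctx$reg, dr, ctx$as, "mRNA-seq",
                      file_pointer = "a.fastq", acting = ctx$owner)
  orphan <- add_raw_step(ctx$reg, dr, ctx$as, "mRNA-seq",
                         file_pointer = "b.fastq", acting = ctx$owner)
  add_processed_step(ctx$reg, dr, rd1, signal_description = "s",
                     file_pointer = "s.txt", acting = ctx$owner)
  err <- expect_error(finalize_analysis(ctx$reg, dr, acting = ctx$owner),
                      class = "ems_validation_error")
  expect_match(conditionMessage(err), orphan, fixed = TRUE)
  # a well-formed chain finalizes into a 3-node immutable analysis
  chain <- simple_chain(ctx)
  an <- ems_get(ctx$reg, chain$an)
  expect_identical(length(an$node_ids), 3L)
  expect_error(ems_update(ctx$reg, chain$an, list(analysis_type = "x"),
                          acting = ctx$owner),
               class = "ems_validation_error")
  # drafts are consumed on finalization; only the unfinalized one remains
  expect_identical(ems_query(ctx$reg, "draft")$draft_id, dr)
})

test_that("step reuse shares nodes by reference, requiring ancestor closure", {
  ctx <- with_lineage(base_registry())
  first <- simple_chain(ctx)
  count_nodes <- function() {
    nrow(ems_query(ctx$reg, "raw_data")) +
      nrow(ems_query(ctx$reg, "intermediate_step")) +
      nrow(ems_query(ctx$reg, "processed_data"))
  }
  n0 <- count_nodes()
  dr <- start_analysis(ctx$reg, "mRNA-seq", ctx$exp, acting = ctx$owner)
  # importing an intermediate step without its raw ancestor is rejected
  err <- expect_error(
    import_steps(ctx$reg, dr, first$an, first$is1, acting = ctx$owner),
    class = "ems_validation_error"
  )
  expect_match(conditionMessage(err), first$rd, fixed = TRUE)
  # prefix import shares the two nodes without copying
  import_steps(ctx$reg, dr, first$an, c(first$rd, first$is1),
               acting = ctx$owner)
  expect_identical(count_nodes(), n0)
  pd2 <- add_processed_step(ctx$reg, dr, first$is1,
                            signal_description = "junction's bed file",
                            file_pointer = "aln/x.junctions.bed",
                            acting = ctx$owner)
  an2 <- finalize_analysis(ctx$reg, dr, acting = ctx$owner)
  expect_identical(count_nodes(), n0 + 1L)
  shared <- intersect(ems_get(ctx$reg, first$an)$node_ids,
                      ems_get(ctx$reg, an2)$node_ids)
  expect_identical(sort(shared), sort(c(first$rd, first$is1)))
  # ownership of shared nodes is unchanged
  expect_identical(ems_get(ctx$reg, first$rd)$owner_id, ctx$owner)
  # importing the processed data together with other nodes is rejected
  dr2 <- start_analysis(ctx$reg, "mRNA-seq", ctx$exp, acting = ctx$owner)
  expect_error(
    import_steps(ctx$reg, dr2, first$an, c(first$is1, first$pd),
                 acting = ctx$owner),
    class = "ems_validation_error"
  )
  # nodes not in the source are reported
  expect_error(
    import_steps(ctx$reg, dr2, first$an, "RD-9999", acting = ctx$owner),
    class = "ems_not_found_error"
  )
})

test_that("secondary analyses root in foreign processed data and merge", {
  ctx <- with_lineage(base_registry())
  # two primary DNase-style chains on two samples
  br2 <- ems_create(ctx$reg, biological_replicate(ctx$bc, 2),
                    acting = ctx$owner)
  as2 <- ems_create(ctx$reg, analytical_sample(br2, "digest 2"),
                    acting = ctx$owner)
  p1 <- simple_chain(ctx, type = "DNase-seq")
  ctx2 <- ctx
  ctx2$as <- as2
  p2 <- simple_chain(ctx2, type = "DNase-seq")
  dr <- start_analysis(ctx$reg, "DNase-seq", ctx$exp, acting = ctx$owner)
  import_steps(ctx$reg, dr, p1$an, p1$pd, acting = ctx$owner)
  import_steps(ctx$reg, dr, p2$an, p2$pd, acting = ctx$owner)
  mg <- add_intermediate_step(ctx$reg, dr, c(p1$pd, p2$pd),
                              step_kind = "merging",
                              file_pointer = "consolidated.bed",
                              acting = ctx$owner)
  ct <- add_intermediate_step(ctx$reg, dr, mg, step_kind = "read counting",
                              file_pointer = "counts.txt",
                              acting = ctx$owner)
  add_processed_step(ctx$reg, dr, ct,
                     signal_description = "per-sample signal value file",
                     file_pointer = "signal.txt", acting = ctx$owner)
  an <- finalize_analysis(ctx$reg, dr, acting = ctx$owner)
  # lineage is the union of both primaries (checked against the BFS oracle)
  lin <- trace_to_samples(ctx$reg, an)
  expect_identical(lin$as_id, oracle_lineage(ctx$reg, an))
  expect_identical(lin$as_id, sort(c(ctx$as, as2)))
  expect_setequal(
    lin$as_id,
    union(trace_to_samples(ctx$reg, p1$an)$as_id,
          trace_to_samples(ctx$reg, p2$an)$as_id)
  )
  # replicate/condition ancestry is reported
  expect_identical(unique(lin$bc_id), ctx$bc)
  expect_identical(sort(lin$replicate_number), 1:2)
})

test_that("lineage of a primary chain is its single analytical sample", {
  ctx <- with_lineage(base_registry())
  chain <- simple_chain(ctx)
  lin <- trace_to_samples(ctx$reg, chain$an)
  expect_identical(nrow(lin), 1L)
  expect_identical(lin$as_id, ctx$as)
  expect_identical(lin$condition_name, "K562")
  expect_identical(lin$as_id, oracle_lineage(ctx$reg, chain$an))
})

test_that("graph rendering is deterministic, typed and well-formed", {
  ctx <- with_lineage(base_registry())
  chain <- simple_chain(ctx)
  dot <- render_graph(ctx$reg, chain$an, format = "dot")
  expect_identical(length(grep("label=", strsplit(dot, "\n")[[1]])), 3L)
  expect_identical(length(grep("->", strsplit(dot, "\n")[[1]])), 2L)
  expect_match(dot, "shape=ellipse")
  expect_match(dot, "shape=box")
  expect_match(dot, "shape=hexagon")
  expect_identical(dot, render_graph(ctx$reg, chain$an, format = "dot"))
  js <- jsonlite::fromJSON(render_graph(ctx$reg, chain$an, format = "json"),
                           simplifyVector = FALSE)
  expect_identical(length(js$nodes), 3L)
  expect_identical(length(js$edges), 2L)
  expect_error(render_graph(ctx$reg, chain$an, format = "svg"),
               class = "ems_validation_error")
})

test_that("finalized analyses always render and trace without error", {
  reg <- ems_registry()
  build_encode_usecase(reg)
  for (an in ems_query(reg, "analysis")$analysis_id) {
    expect_no_error(render_graph(reg, an, format = "dot"))
    expect_no_error(render_graph(reg, an, format = "json"))
    expect_gte(nrow(trace_to_samples(reg, an)), 1L)
  }
})

test_that("the incremental validator agrees with brute force on small graphs", {
  withr::local_seed(424242)
  for (i in 1:150) {
    case <- random_graph_case()
    verdict <- length(validate_workflow_graph(case$nodes,
                                              foreign_roots = case$foreign))
    expect_identical(
      verdict == 0L,
      oracle_graph_valid(case$nodes, foreign_roots = case$foreign),
      info = paste("case", i)
    )
  }
})
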