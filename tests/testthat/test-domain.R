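test_that("identifiers are typed, zero-padded and sequential", {
  reg <- ems_registry()
  expect_identical(new_identifier(reg, "biological_condition"), "BC-0001")
  drawn <- vapply(1:9, function(i) {
    new_identifier(reg, "biological_replicate")
  }, character(1))
  # independent enumeration of the counter
  expect_identical(drawn, sprintf("BR-%04d", 1:9))
  expect_identical(drawn[[9]], "BR-0009")
  expect_error(new_identifier(reg, "plasmid"),
               class = "ems_validation_error")
})

test_that("identifier generation is injective across kinds and draws", {
  reg <- ems_registry()
  kinds <- entity_kinds()
  draws <- unlist(lapply(1:10, function(i) {
    vapply(kinds, function(k) new_identifier(reg, k), character(1))
  }))
  expect_identical(anyDuplicated(draws), 0L)
})

test_that("deleted identifiers are never reissued", {
  ctx <- base_registry()
  b1 <- ems_create(ctx$reg, experimental_batch("b1"), acting = ctx$owner)
  ems_delete(ctx$reg, b1, acting = ctx$owner)
  b2 <- ems_create(ctx$reg, experimental_batch("b2"), acting = ctx$owner)
  expect_false(identical(b1, b2))
  expect_identical(b2, "BAT-0002")
})

test_that("kind_of_id decodes identifier prefixes", {
  expect_identical(kind_of_id(c("BC-0001", "AN-0002", "XX-1")),
                   c("biological_condition", "analysis", NA))
})

test_that("every structural invariant is caught on a minimal counterexample", {
  # replicate number must be >= 1
  expect_match(validate_entity(biological_replicate("BC-0001", 0)),
               "replicate_number must be >=1", all = FALSE)
  # raw data needs a non-empty file pointer
  expect_gt(length(validate_entity(
    raw_data("AS-0001", "mRNA-seq", file_pointer = "  ")
  )), 0)
  # condition name non-empty
  expect_gt(length(validate_entity(biological_condition(""))), 0)
  # experimental_condition only allows treatment/dose/time_point
  expect_gt(length(validate_entity(biological_condition(
    "K562", experimental_condition = list(ph = "7")
  ))), 0)
  # batch label non-empty
  expect_gt(length(validate_entity(experimental_batch(""))), 0)
  # analytical sample needs a name
  expect_gt(length(validate_entity(analytical_sample("BR-0001", ""))), 0)
  # intermediate steps need at least one input and a step kind
  expect_gt(length(validate_entity(intermediate_step(
    character(), "mapping", "f.bam"
  ))), 0)
  expect_gt(length(validate_entity(intermediate_step(
    "RD-0001", "", "f.bam"
  ))), 0)
  # processed data needs a signal description
  expect_gt(length(validate_entity(processed_data("IS-0001", "", "f.txt"))),
            0)
  # experiments need unique planned tags (case-insensitively)
  expect_gt(length(validate_entity(experiment(
    "e", planned_measurements = c("mRNA-seq", "MRNA-SEQ")
  ))), 0)
  expect_gt(length(validate_entity(experiment(
    "e", n_replicates_planned = 0
  ))), 0)
  # non-entities yield a report, not an error
  expect_identical(validate_entity(list(a = 1)),
                   "not a recognised entity (build it with a constructor)")
})

test_that("a fully annotated cell-line condition validates cleanly", {
  k562 <- biological_condition(
    name = "K562", title = "Chronic myelogenous leukemia",
    organism = "human", tissue = "blood", cell_type = "lymphocyte",
    variation = "cancer"
  )
  expect_identical(validate_entity(k562), character())
  # untreated cell line: the whole experimental-condition section is absent
  expect_false("experimental_condition" %in% names(k562))
})

test_that("validation is deterministic and side-effect free", {
  bad <- biological_replicate("BC-0001", 0)
  r1 <- validate_entity(bad)
  r2 <- validate_entity(bad)
  expect_identical(r1, r2)
})

test_that("assay tags are matched case-insensitively and stored canonically", {
  reg <- ems_registry()
  expect_identical(canonical_assay_tag(reg, " mrna-SEQ "), "mRNA-seq")
  expect_identical(canonical_assay_tag(reg, "proteomics"), "Proteomics")
  # distinct tags never collapse
  expect_identical(canonical_assay_tag(reg, "miRNA-seq"), "miRNA-seq")
  expect_error(canonical_assay_tag(reg, "HiC-seq"),
               "registered tags", class = "ems_validation_error")
})

test_that("the assay registry is user-extensible without collisions", {
  reg <- ems_registry()
  add_assay_type(reg, "ATAC-seq", "sequencing")
  expect_identical(canonical_assay_tag(reg, "atac-seq"), "ATAC-seq")
  expect_error(add_assay_type(reg, "ATAC-SEQ", "sequencing"),
               class = "ems_validation_error")
})
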