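test_that("user registration is admin-only with an admin bootstrap", {
  reg <- ems_registry()
  expect_error(ems_register_user(reg, "ana", role = "regular"),
               class = "ems_permission_error")
  admin <- ems_register_user(reg, "admin", role = "admin")
  expect_identical(admin, "USR-0001")
  u <- ems_register_user(reg, "rafa", acting = admin)
  expect_identical(u, "USR-0002")
  expect_error(ems_register_user(reg, "eve", acting = u),
               class = "ems_permission_error")
  more <- vapply(1:10, function(i) {
    ems_register_user(reg, "dup name", acting = admin)
  }, character(1))
  expect_identical(anyDuplicated(more), 0L)
})

test_that("create rejects dangling references, naming the missing id", {
  ctx <- base_registry()
  err <- expect_error(
    ems_create(ctx$reg, biological_replicate("BC-9999", 1),
               acting = ctx$owner),
    class = "ems_integrity_error"
  )
  expect_match(conditionMessage(err), "BC-9999")
  # reference fields must also point at the right kind of element
  bc <- ems_create(ctx$reg, biological_condition("K562"),
                   acting = ctx$owner)
  expect_error(
    ems_create(ctx$reg, biological_replicate(bc, 1, batch_id = bc),
               acting = ctx$owner),
    class = "ems_integrity_error"
  )
})

test_that("replicate numbers are unique within a condition", {
  ctx <- base_registry()
  bc <- ems_create(ctx$reg, biological_condition("K562"),
                   acting = ctx$owner)
  ids <- vapply(1:9, function(i) {
    ems_create(ctx$reg, biological_replicate(bc, i), acting = ctx$owner)
  }, character(1))
  got <- ems_query(ctx$reg, "biological_replicate")
  expect_identical(nrow(got), 9L)
  expect_identical(got$replicate_number, 1:9)
  expect_error(
    ems_create(ctx$reg, biological_replicate(bc, 5), acting = ctx$owner),
    class = "ems_validation_error"
  )
})

test_that("a failed create leaves the registry byte-identical", {
  ctx <- base_registry()
  before <- doc_to_json(export_registry(ctx$reg))
  expect_error(ems_create(ctx$reg, biological_replicate("BC-9999", 1),
                          acting = ctx$owner),
               class = "ems_integrity_error")
  expect_error(ems_create(ctx$reg, biological_condition(""),
                          acting = ctx$owner),
               class = "ems_validation_error")
  expect_identical(doc_to_json(export_registry(ctx$reg)), before)
})

test_that("ownership and grants gate editing; grants are idempotent", {
  ctx <- base_registry()
  bc <- ems_create(ctx$reg, biological_condition("K562", title = "t0"),
                   acting = ctx$owner)
  # stranger cannot edit or grant
  expect_error(ems_update(ctx$reg, bc, list(title = "x"),
                          acting = ctx$other),
               class = "ems_permission_error")
  expect_error(ems_grant(ctx$reg, bc, ctx$other, acting = ctx$other),
               class = "ems_permission_error")
  # owner grants; grantee can edit but not delete nor grant
  g1 <- ems_grant(ctx$reg, bc, ctx$other, acting = ctx$owner)
  g2 <- ems_grant(ctx$reg, bc, ctx$other, acting = ctx$owner)
  expect_identical(g1, g2)
  ems_update(ctx$reg, bc, list(title = "edited by grantee"),
             acting = ctx$other)
  expect_identical(ems_get(ctx$reg, bc)$title, "edited by grantee")
  expect_error(ems_delete(ctx$reg, bc, acting = ctx$other),
               class = "ems_permission_error")
  expect_error(ems_grant(ctx$reg, bc, ctx$admin, acting = ctx$other),
               class = "ems_permission_error")
  # unregistered grantee
  expect_error(ems_grant(ctx$reg, bc, "USR-9999", acting = ctx$owner),
               class = "ems_not_found_error")
  # revocation removes edit rights
  ems_revoke(ctx$reg, bc, ctx$other, acting = ctx$owner)
  expect_error(ems_update(ctx$reg, bc, list(title = "nope"),
                          acting = ctx$other),
               class = "ems_permission_error")
})

test_that("updates respect immutability, validation and uniqueness", {
  ctx <- base_registry()
  bc1 <- ems_create(ctx$reg, biological_condition("K562"),
                    acting = ctx$owner)
  bc2 <- ems_create(ctx$reg, biological_condition("GM12878"),
                    acting = ctx$owner)
  ems_create(ctx$reg, biological_replicate(bc1, 1), acting = ctx$owner)
  br2 <- ems_create(ctx$reg, biological_replicate(bc2, 1),
                    acting = ctx$owner)
  # owner edits persist
  ems_update(ctx$reg, bc1, list(title = "Chronic myelogenous leukemia"),
             acting = ctx$owner)
  expect_identical(ems_get(ctx$reg, bc1)$title,
                   "Chronic myelogenous leukemia")
  # identifier and owner are immutable
  expect_error(ems_update(ctx$reg, bc1, list(owner_id = ctx$other),
                          acting = ctx$owner),
               class = "ems_validation_error")
  expect_error(ems_update(ctx$reg, br2, list(br_id = "BR-9999"),
                          acting = ctx$owner),
               class = "ems_validation_error")
  # moving a replicate onto a condition where its number collides fails
  before <- doc_to_json(export_registry(ctx$reg))
  expect_error(ems_update(ctx$reg, br2, list(bc_id = bc1),
                          acting = ctx$owner),
               class = "ems_validation_error")
  expect_identical(doc_to_json(export_registry(ctx$reg)), before)
  # validation failures roll back too
  expect_error(ems_update(ctx$reg, br2, list(replicate_number = 0),
                          acting = ctx$owner),
               class = "ems_validation_error")
  expect_identical(doc_to_json(export_registry(ctx$reg)), before)
})

test_that("deletion is RESTRICT and lists the referrers", {
  ctx <- base_registry()
  bc <- ems_create(ctx$reg, biological_condition("K562"),
                   acting = ctx$owner)
  br <- ems_create(ctx$reg, biological_replicate(bc, 1),
                   acting = ctx$owner)
  err <- expect_error(ems_delete(ctx$reg, bc, acting = ctx$owner),
                      class = "ems_integrity_error")
  expect_match(conditionMessage(err), br, fixed = TRUE)
  # an unreferenced analytical sample deletes fine
  smp <- ems_create(ctx$reg, analytical_sample(br, "s1"),
                    acting = ctx$owner)
  expect_identical(ems_referrers(ctx$reg, smp), character())
  ems_delete(ctx$reg, smp, acting = ctx$owner)
  expect_error(ems_get(ctx$reg, smp), class = "ems_not_found_error")
  # deleting the leaf then the parent chain works
  ems_delete(ctx$reg, br, acting = ctx$owner)
  ems_delete(ctx$reg, bc, acting = ctx$owner)
  # a user owning elements cannot be deleted
  bc2 <- ems_create(ctx$reg, biological_condition("GM"),
                    acting = ctx$owner)
  expect_error(ems_delete(ctx$reg, ctx$owner, acting = ctx$admin),
               class = "ems_integrity_error")
  expect_gt(length(ems_referrers(ctx$reg, ctx$owner)), 0)
})

test_that("a raw node shared by two analyses stays protected until both go", {
  ctx <- with_lineage(base_registry())
  first <- simple_chain(ctx)
  # reuse the first two steps in a second analysis
  dr <- start_analysis(ctx$reg, "mRNA-seq", ctx$exp, acting = ctx$owner)
  import_steps(ctx$reg, dr, first$an, c(first$rd, first$is1),
               acting = ctx$owner)
  pd2 <- add_processed_step(ctx$reg, dr, first$is1,
                            signal_description = "junction bed",
                            file_pointer = "aln/x.junctions.bed",
                            acting = ctx$owner)
  an2 <- finalize_analysis(ctx$reg, dr, acting = ctx$owner)
  # reference-count oracle: the raw node is held by both analyses + consumer
  expect_true(all(c(first$an, an2, first$is1) %in%
                    ems_referrers(ctx$reg, first$rd)))
  ems_delete(ctx$reg, an2, acting = ctx$owner)
  # still referenced by the surviving analysis
  err <- expect_error(ems_delete(ctx$reg, first$rd, acting = ctx$owner),
                      class = "ems_integrity_error")
  expect_match(conditionMessage(err), first$an, fixed = TRUE)
})

test_that("an analysis whose result is reused cannot be deleted", {
  ctx <- with_lineage(base_registry())
  first <- simple_chain(ctx)
  dr <- start_analysis(ctx$reg, "mRNA-seq", ctx$exp, acting = ctx$owner)
  import_steps(ctx$reg, dr, first$an, first$pd, acting = ctx$owner)
  is2 <- add_intermediate_step(ctx$reg, dr, first$pd, step_kind = "merging",
                               file_pointer = "m.bed", acting = ctx$owner)
  add_processed_step(ctx$reg, dr, is2, signal_description = "signal",
                     file_pointer = "s.txt", acting = ctx$owner)
  an2 <- finalize_analysis(ctx$reg, dr, acting = ctx$owner)
  expect_true(an2 %in% ems_referrers(ctx$reg, first$an))
  expect_error(ems_delete(ctx$reg, first$an, acting = ctx$owner),
               class = "ems_integrity_error")
})

test_that("progress flags track associated analyses both ways", {
  ctx <- with_lineage(base_registry())
  expect_identical(stored_flags(ctx$reg, ctx$exp), c(FALSE, FALSE))
  chain <- simple_chain(ctx)  # mRNA-seq
  expect_identical(stored_flags(ctx$reg, ctx$exp),
                   oracle_flags(ctx$reg, ctx$exp))
  flags <- stored_flags(ctx$reg, ctx$exp)
  pm <- ems_get(ctx$reg, ctx$exp)$planned_measurements
  tags <- vapply(pm, function(m) m$assay_tag, character(1))
  expect_true(flags[tags == "mRNA-seq"])
  expect_false(flags[tags == "ChIP-seq"])
  # associating an analysis of an unplanned type changes no flags
  dn <- simple_chain(ctx, type = "DNase-seq")
  expect_identical(stored_flags(ctx$reg, ctx$exp), flags)
  # dissociating the only mRNA-seq analysis reverts its flag
  ems_dissociate_analysis(ctx$reg, chain$an, ctx$exp, acting = ctx$owner)
  expect_false(any(stored_flags(ctx$reg, ctx$exp)[tags == "mRNA-seq"]))
  expect_identical(stored_flags(ctx$reg, ctx$exp),
                   oracle_flags(ctx$reg, ctx$exp))
  # re-associate
  ems_associate_analysis(ctx$reg, chain$an, ctx$exp, acting = ctx$owner)
  expect_true(stored_flags(ctx$reg, ctx$exp)[tags == "mRNA-seq"])
})

test_that("queries are deterministic, filterable and kind-checked", {
  ctx <- base_registry()
  bc <- ems_create(ctx$reg, biological_condition("K562"),
                   acting = ctx$owner)
  bat <- ems_create(ctx$reg, experimental_batch("b1"), acting = ctx$owner)
  for (i in 1:3) {
    ems_create(ctx$reg, biological_replicate(
      bc, i, batch_id = if (i < 3) bat
    ), acting = ctx$owner)
  }
  expect_identical(nrow(replicates_of(ctx$reg, bc)), 3L)
  expect_identical(nrow(batch_members(ctx$reg, bat)), 2L)
  expect_identical(nrow(analytical_samples_of(ctx$reg, "BR-0001")), 0L)
  got <- ems_query(ctx$reg, "biological_replicate", replicate_number > 1)
  expect_identical(got$br_id, c("BR-0002", "BR-0003"))
  expect_error(ems_query(ctx$reg, "plasmid"),
               class = "ems_validation_error")
})

test_that("tidy and glance summarize registries and analyses", {
  ctx <- with_lineage(base_registry())
  chain <- simple_chain(ctx)
  td <- tidy(ctx$reg)
  expect_identical(td$n[td$kind == "biological_replicate"], 1L)
  gl <- glance(ctx$reg)
  expect_true(gl$audit_clean)
  expect_identical(gl$n_analyses, 1L)
  an <- ems_get(ctx$reg, chain$an)
  expect_identical(nrow(tidy(an)), 3L)
  expect_identical(glance(an)$n_samples, 1L)
})
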