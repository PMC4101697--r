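# random operation-sequence driver: applies n_ops randomly chosen store and
# workflow operations (some of which are legitimately rejected — duplicate
# replicate numbers, restricted deletions, ...) and, after every operation,
# compares the experiment progress flags with a from-scratch recomputation.

run_random_ops <- function(seed, n_ops = 500) {
  set.seed(seed)
  reg <- ems_registry()
  d <- as.Date("2021-01-01")
  admin <- ems_register_user(reg, "admin", role = "admin", created_on = d)
  users <- vapply(1:3, function(i) {
    ems_register_user(reg, sprintf("user%d", i), acting = admin,
                      created_on = d)
  }, character(1))
  tags <- assay_types(reg)$tag
  exp_owner <- users[[1]]
  exp <- ems_create(reg, experiment(
    name = "ops experiment", n_replicates_planned = 2,
    planned_measurements = sample(tags, 4)
  ), acting = exp_owner, created_on = d)

  st <- new.env()
  st$bcs <- character(); st$batches <- character()
  st$brs <- character(); st$smps <- character()
  st$analyses <- character()
  flags_ok <- TRUE
  n_rejected <- 0L

  all_elements <- function() {
    c(st$bcs, st$batches, st$brs, st$smps, st$analyses, exp)
  }
  try_op <- function(expr) {
    tryCatch(expr, ems_error = function(e) {
      n_rejected <<- n_rejected + 1L
      NULL
    })
  }

  mk_workflow <- function() {
    owner <- exp_owner
    type <- sample(tags, 1)
    dr <- start_analysis(reg, type, exp, acting = owner, created_on = d)
    if (length(st$analyses) > 0 && stats::runif(1) < 0.3) {
      src <- sample(st$analyses, 1)
      pd <- ems_get(reg, src)$processed_data_id
      import_steps(reg, dr, src, pd, acting = owner)
      tip <- add_intermediate_step(reg, dr, pd, step_kind = "merging",
                                   file_pointer = "ops/m.bed",
                                   acting = owner, created_on = d)
    } else {
      tip <- add_raw_step(reg, dr, sample(st$smps, 1), type,
                          file_pointer = "ops/run.fastq", acting = owner,
                          created_on = d)
      for (k in seq_len(sample(0:2, 1))) {
        tip <- add_intermediate_step(reg, dr, tip, step_kind = "mapping",
                                     file_pointer = "ops/i.bam",
                                     acting = owner, created_on = d)
      }
    }
    add_processed_step(reg, dr, tip, signal_description = "signal",
                       file_pointer = "ops/p.txt", acting = owner,
                       created_on = d)
    st$analyses <- c(st$analyses,
                     finalize_analysis(reg, dr, acting = owner,
                                       created_on = d))
  }

  for (i in seq_len(n_ops)) {
    who <- sample(users, 1)
    op <- sample(c("bc", "batch", "br", "as", "workflow", "grant",
                   "update", "delete", "assoc", "dissoc"), 1,
                 prob = c(.14, .05, .16, .16, .14, .08, .10, .07, .05, .05))
    switch(op,
      bc = {
        st$bcs <- c(st$bcs, ems_create(reg, biological_condition(
          sprintf("cond %d", i)
        ), acting = who, created_on = d))
      },
      batch = {
        st$batches <- c(st$batches, ems_create(
          reg, experimental_batch(sprintf("batch %d", i)), acting = who,
          created_on = d
        ))
      },
      br = if (length(st$bcs) > 0) {
        id <- try_op(ems_create(reg, biological_replicate(
          sample(st$bcs, 1), sample(1:6, 1),
          batch_id = if (length(st$batches) > 0 && stats::runif(1) < 0.5) {
            sample(st$batches, 1)
          }
        ), acting = who, created_on = d))
        if (!is.null(id)) st$brs <- c(st$brs, id)
      },
      as = if (length(st$brs) > 0) {
        st$smps <- c(st$smps, ems_create(reg, analytical_sample(
          sample(st$brs, 1), sprintf("sample %d", i)
        ), acting = who, created_on = d))
      },
      workflow = if (length(st$smps) > 0) try_op(mk_workflow()),
      grant = {
        el <- sample(all_elements(), 1)
        owner <- ems_get(reg, el)$owner_id
        grantee <- sample(c(users, admin), 1)
        try_op(ems_grant(reg, el, grantee, acting = owner))
      },
      update = {
        el <- sample(all_elements(), 1)
        owner <- ems_get(reg, el)$owner_id
        field <- switch(kind_of_id(el),
          biological_condition = list(title = sprintf("title %d", i)),
          experimental_batch = list(label = sprintf("label %d", i)),
          biological_replicate = list(replicate_number = sample(1:6, 1)),
          analytical_sample = list(name = sprintf("name %d", i)),
          experiment = list(goals = sprintf("goal %d", i)),
          analysis = list(analysis_type = "mRNA-seq")  # must be rejected
        )
        try_op(ems_update(reg, el, field, acting = owner))
      },
      delete = {
        el <- sample(all_elements(), 1)
        if (el != exp) {
          owner <- ems_get(reg, el)$owner_id
          deleted <- !is.null(try_op(ems_delete(reg, el, acting = owner)))
          if (deleted) {
            st$bcs <- setdiff(st$bcs, el)
            st$batches <- setdiff(st$batches, el)
            st$brs <- setdiff(st$brs, el)
            st$smps <- setdiff(st$smps, el)
            st$analyses <- setdiff(st$analyses, el)
          }
        }
      },
      assoc = if (length(st$analyses) > 0) {
        try_op(ems_associate_analysis(reg, sample(st$analyses, 1), exp,
                                      acting = exp_owner))
      },
      dissoc = if (length(st$analyses) > 0) {
        try_op(ems_dissociate_analysis(reg, sample(st$analyses, 1), exp,
                                       acting = exp_owner))
      }
    )
    if (!identical(stored_flags(reg, exp), oracle_flags(reg, exp))) {
      flags_ok <- FALSE
    }
  }
  list(reg = reg, flags_ok = flags_ok, n_rejected = n_rejected,
       experiment = exp)
}

# store-wide one-analysis-one-processed-data scan (independent of ems_audit)
one_pd_rule_holds <- function(reg) {
  ans <- ems_query(reg, "analysis")
  if (nrow(ans) == 0) return(TRUE)
  sink_of <- ans$processed_data_id
  if (anyDuplicated(sink_of) > 0) return(FALSE)
  for (i in seq_len(nrow(ans))) {
    nodes <- ans$node_ids[[i]]
    pds <- nodes[kind_of_id(nodes) == "processed_data"]
    own <- ans$processed_data_id[[i]]
    if (!own %in% pds) return(FALSE)
    if (!all(setdiff(pds, own) %in% sink_of)) return(FALSE)
  }
  TRUE
}
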