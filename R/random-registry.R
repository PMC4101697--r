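#' Seed-deterministic random registry generator
#'
#' Generates a valid registry of configurable size for property testing:
#' users, one experiment with randomly planned measurements, biological
#' conditions with batched replicates and analytical samples, and finalized
#' analyses with random workflow shapes (single chains, two-root merges,
#' variable numbers of intermediate steps, and — with probability
#' `p_secondary` — secondary analyses rooted in an earlier analysis'
#' processed data). Every registry this function returns passes the global
#' referential audit ([ems_audit()]); generated sizes are bounded by what is
#' available (an analysis needs at least one analytical sample).
#'
#' The generator restores the caller's RNG state on exit, so it is
#' reproducible from `seed` alone and side-effect free.
#'
#' @param seed Integer seed.
#' @param n_users Number of users (>= 2 whenever any other entity is
#'   requested: one admin plus regular users).
#' @param n_conditions Number of biological conditions.
#' @param replicates_per_condition Replicates created for each condition.
#' @param samples_per_replicate Analytical samples per replicate.
#' @param n_analyses Number of finalized analyses to attempt.
#' @param p_secondary Probability that an analysis is secondary (reuses a
#'   previous analysis' processed data as its root).
#' @return An [ems_registry()].
#' @export
#' @examples
#' reg <- random_registry(7, n_conditions = 3, replicates_per_condition = 4)
#' nrow(ems_query(reg, "biological_replicate"))
random_registry <- function(seed, n_users = 2, n_conditions = 2,
                            replicates_per_condition = 2,
                            samples_per_replicate = 1, n_analyses = 2,
                            p_secondary = 0.25) {
  reg <- ems_registry()
  sizes <- c(n_users, n_conditions, replicates_per_condition,
             samples_per_replicate, n_analyses)
  if (any(sizes < 0)) abort_validation("size parameters must be >= 0")
  if (all(sizes == 0)) return(reg)

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  d <- as.Date("2020-01-01")
  nxt_day <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      d + (i %% 60L)
    }
  })

  n_users <- max(n_users, 2L)
  admin <- ems_register_user(reg, "admin", role = "admin",
                             created_on = nxt_day())
  users <- vapply(seq_len(n_users - 1L), function(i) {
    ems_register_user(reg, sprintf("user%02d", i), role = "regular",
                      acting = admin, created_on = nxt_day())
  }, character(1))
  if (length(users) == 0) users <- admin
  pick_user <- function() sample(users, 1)

  tags <- reg$assay_types$tag
  exp_id <- ems_create(reg, experiment(
    name = "generated experiment",
    experiment_type = sample(c("multiple conditions", "time course"), 1),
    n_replicates_planned = sample(1:3, 1),
    planned_measurements = sample(tags, sample(2:4, 1))
  ), acting = pick_user(), created_on = nxt_day())

  organisms <- c("human", "mouse", "rat")
  all_as <- character()
  if (n_conditions > 0) {
    n_batches <- max(1L, ceiling(n_conditions * replicates_per_condition / 3))
    batch_ids <- vapply(seq_len(n_batches), function(i) {
      ems_create(reg, experimental_batch(sprintf("batch %02d", i)),
                 acting = pick_user(), created_on = nxt_day())
    }, character(1))
    for (ci in seq_len(n_conditions)) {
      owner <- pick_user()
      bc <- ems_create(reg, biological_condition(
        name = sprintf("COND-%02d", ci),
        title = sprintf("generated condition %d", ci),
        organism = sample(organisms, 1), tissue = "blood",
        cell_type = "lymphocyte",
        variation = sample(c("normal", "cancer"), 1),
        experimental_condition = if (stats::runif(1) < 0.4) {
          list(treatment = "LPS", dose = "10 ng/ml",
               time_point = sprintf("%dh", sample(c(0, 2, 6, 24), 1)))
        }
      ), acting = owner, created_on = nxt_day())
      ems_associate_sample(reg, bc, exp_id, acting = {
        e <- reg$tables$experiment[[exp_id]]
        e$owner_id
      })
      for (ri in seq_len(replicates_per_condition)) {
        br <- ems_create(reg, biological_replicate(
          bc, replicate_number = ri,
          batch_id = if (stats::runif(1) < 0.7) sample(batch_ids, 1)
        ), acting = owner, created_on = nxt_day())
        for (si in seq_len(samples_per_replicate)) {
          all_as <- c(all_as, ems_create(reg, analytical_sample(
            br, name = sprintf("%s rep%d sample%d", bc, ri, si),
            extraction_protocol = "generated extraction protocol"
          ), acting = owner, created_on = nxt_day()))
        }
      }
    }
  }

  seq_tags <- reg$assay_types$tag[reg$assay_types$category == "sequencing"]
  finalized <- character()
  if (length(all_as) > 0) {
    exp_owner <- reg$tables$experiment[[exp_id]]$owner_id
    for (ai in seq_len(n_analyses)) {
      owner <- exp_owner
      type <- sample(seq_tags, 1)
      dr <- start_analysis(reg, type, exp_id, acting = owner,
                           created_on = nxt_day())
      secondary <- length(finalized) > 0 && stats::runif(1) < p_secondary
      if (secondary) {
        src_id <- sample(finalized, 1)
        src <- reg$tables$analysis[[src_id]]
        import_steps(reg, dr, src_id, src$processed_data_id, acting = owner)
        tip <- add_intermediate_step(
          reg, dr, src$processed_data_id, step_kind = "merging",
          software = "gen-merge",
          file_pointer = sprintf("gen/sec%03d.bed", ai),
          acting = owner, created_on = nxt_day()
        )
      } else {
        n_roots <- if (length(all_as) > 1 && stats::runif(1) < 0.3) 2L else 1L
        roots <- vapply(seq_len(n_roots), function(ri) {
          add_raw_step(reg, dr, sample(all_as, 1), type,
                       file_pointer = sprintf("gen/run%03d_%d.fastq", ai, ri),
                       acting = owner, created_on = nxt_day())
        }, character(1))
        tip <- if (n_roots > 1) {
          add_intermediate_step(reg, dr, roots, step_kind = "merging",
                                software = "gen-merge",
                                file_pointer = sprintf("gen/m%03d.bam", ai),
                                acting = owner, created_on = nxt_day())
        } else {
          roots[[1]]
        }
        for (k in seq_len(sample(0:2, 1))) {
          tip <- add_intermediate_step(
            reg, dr, tip,
            step_kind = sample(c("mapping", "trimming", "filtering"), 1),
            software = "gen-tool",
            file_pointer = sprintf("gen/i%03d_%d.bam", ai, k),
            acting = owner, created_on = nxt_day()
          )
        }
      }
      add_processed_step(reg, dr, tip,
                         signal_description = "generated signal values",
                         file_pointer = sprintf("gen/p%03d.txt", ai),
                         acting = owner, created_on = nxt_day())
      finalized <- c(finalized,
                     finalize_analysis(reg, dr, acting = owner,
                                       created_on = nxt_day()))
    }
  }

  # a few random grants
  elems <- setdiff(unlist(lapply(reg$tables, names), use.names = FALSE),
                   names(reg$tables$user))
  elems <- elems[kind_of_id(elems) != "draft"]
  if (length(elems) > 0 && length(users) > 1) {
    for (el in sample(elems, min(3, length(elems)))) {
      owner <- reg_get(reg, el)$owner_id
      grantee <- sample(setdiff(c(users, admin), owner), 1)
      ems_grant(reg, el, grantee, acting = owner)
    }
  }
  reg
}
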