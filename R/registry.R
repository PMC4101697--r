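#' Create an empty registry
#'
#' The registry is the persistent heart of the system: an in-memory store of
#' all annotated elements (users, experiments, the sample lineage, workflow
#' nodes, analyses), their ownership and grants, per-kind identifier
#' counters, and the assay-type table. It has reference semantics (it is an
#' environment), so store operations mutate it in place — the model a lab
#' logbook needs. Persist it with [write_registry()] / [read_registry()],
#' which use the canonical JSON interchange format.
#'
#' A brand-new registry contains no users. The first user must be an
#' administrator and is registered without an acting user
#' (see [ems_register_user()]); from then on only administrators can
#' register users.
#'
#' @return An object of class `ems_registry`.
#' @export
#' @examples
#' reg <- ems_registry()
#' admin <- ems_register_user(reg, "admin", role = "admin")
ems_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$schema_version <- 1L
  reg$tables <- stats::setNames(
    lapply(ENTITY_KINDS, function(k) list()), ENTITY_KINDS
  )
  reg$counters <- stats::setNames(
    rep(0L, length(ENTITY_KINDS)), ENTITY_KINDS
  )
  reg$grants <- list()
  reg$assay_types <- default_assay_types()
  class(reg) <- "ems_registry"
  reg
}

check_registry <- function(registry) {
  if (!inherits(registry, "ems_registry")) {
    abort_validation("`registry` must be an ems_registry object")
  }
  invisible(registry)
}

#' @export
print.ems_registry <- function(x, ...) {
  cat("<ems_registry>\n")
  counts <- vapply(x$tables, length, integer(1))
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    cat("  (empty)\n")
  } else {
    for (k in names(counts)) cat(sprintf("  %-22s %d\n", k, counts[[k]]))
  }
  invisible(x)
}

# shallow copy: all stored values are immutable R objects
registry_clone <- function(registry) {
  out <- new.env(parent = emptyenv())
  for (f in ls(registry)) assign(f, get(f, envir = registry), envir = out)
  class(out) <- "ems_registry"
  out
}

registry_is_empty <- function(registry) {
  all(vapply(registry$tables, length, integer(1)) == 0L)
}

reg_get <- function(registry, id, what = "element") {
  kind <- if (length(id) == 1 && is.character(id) && !is.na(id)) {
    kind_of_id(id)
  } else {
    NA_character_
  }
  rec <- if (!is.na(kind)) registry$tables[[kind]][[id]] else NULL
  if (is.null(rec)) {
    abort_not_found(sprintf("%s '%s' not found", what, id), id = id)
  }
  rec
}

reg_exists <- function(registry, id) {
  kind <- kind_of_id(id)
  !is.na(kind) && !is.null(registry$tables[[kind]][[id]])
}

reg_put <- function(registry, record) {
  kind <- entity_kind(record)
  id <- record[[id_field(kind)]]
  tab <- registry$tables[[kind]]
  tab[[id]] <- record
  registry$tables[[kind]] <- tab[order(names(tab))]
  invisible(id)
}

reg_drop <- function(registry, id) {
  kind <- kind_of_id(id)
  tab <- registry$tables[[kind]]
  tab[[id]] <- NULL
  registry$tables[[kind]] <- tab
  invisible(id)
}

#' Fetch a stored element by identifier
#'
#' @param registry An [ems_registry()].
#' @param id Element identifier (any kind; the prefix routes the lookup).
#' @return The stored record as a classed list.
#' @export
ems_get <- function(registry, id) {
  check_registry(registry)
  rec <- reg_get(registry, id)
  # lets tidy()/glance()/autoplot() find the registry the record came from
  attr(rec, "registry") <- registry
  rec
}

check_acting <- function(registry, acting) {
  if (!is_nonempty_string(acting)) {
    abort_permission("an acting user id is required for this operation")
  }
  rec <- registry$tables$user[[acting]]
  if (is.null(rec)) {
    abort_permission(sprintf("acting user '%s' is not registered", acting))
  }
  rec
}

# ---- users --------------------------------------------------------------

#' Register a user
#'
#' Users must be registered by an administrator before they can work with
#' the registry. The single exception is bootstrap: an empty registry (no
#' users yet) accepts its first user without an acting user, and that first
#' user must be an administrator. Duplicate display names are allowed —
#' identifiers disambiguate.
#'
#' @param registry An [ems_registry()].
#' @param display_name Human-readable name.
#' @param role `"admin"` or `"regular"`.
#' @param acting Acting user id; must be an admin (omit only for the first,
#'   bootstrap admin).
#' @param created_on Registration date.
#' @return The new user's identifier (`USR-...`).
#' @export
ems_register_user <- function(registry, display_name, role = "regular",
                              acting = NULL, created_on = Sys.Date()) {
  check_registry(registry)
  first <- length(registry$tables$user) == 0
  if (first) {
    if (!identical(role, "admin")) {
      abort_permission("the first registered user must be an administrator")
    }
  } else {
    actor <- check_acting(registry, acting)
    if (actor$role != "admin") {
      abort_permission("only administrators may register users")
    }
  }
  user <- new_entity("user", list(
    display_name = display_name, role = role,
    created_on = as.Date(created_on)
  ))
  report <- validate_entity(user)
  if (length(report) > 0) {
    abort_validation(paste0("invalid user: ",
                            paste(report, collapse = "; ")),
                     report = report)
  }
  id <- new_identifier(registry, "user")
  user$user_id <- id
  user$owner_id <- if (first) id else acting
  reg_put(registry, user)
  id
}

# ---- reference checking -------------------------------------------------

REF_FIELD_KIND <- list(
  bc_id = "biological_condition",
  br_id = "biological_replicate",
  as_id = "analytical_sample",
  batch_id = "experimental_batch",
  input_node_ids = c("raw_data", "intermediate_step", "processed_data"),
  node_ids = c("raw_data", "intermediate_step", "processed_data"),
  processed_data_id = "processed_data",
  experiment_id = "experiment",
  experiment_ids = "experiment",
  owner_id = "user",
  member_ids = "user",
  sample_ids = "biological_condition",
  analysis_ids = "analysis"
)

check_ref <- function(registry, ids, field) {
  allowed <- REF_FIELD_KIND[[field]]
  for (id in ids) {
    if (!reg_exists(registry, id)) {
      abort_integrity(sprintf("%s not found (referenced by %s)", id, field))
    }
    if (!is.null(allowed) && !kind_of_id(id) %in% allowed) {
      abort_integrity(sprintf(
        "%s references %s, which is a %s, not a %s",
        field, id, kind_of_id(id), paste(allowed, collapse = "/")
      ))
    }
  }
  invisible(ids)
}

check_entity_refs <- function(registry, record, kind) {
  info <- kind_info(kind)
  for (f in info$hard_refs) {
    if (!is.null(record[[f]])) check_ref(registry, record[[f]], f)
  }
  for (f in info$soft_refs) {
    if (!is.null(record[[f]])) check_ref(registry, record[[f]], f)
  }
  invisible(record)
}

check_replicate_unique <- function(registry, record, exclude_id = NULL) {
  for (other in registry$tables$biological_replicate) {
    if (!is.null(exclude_id) && other$br_id == exclude_id) next
    if (other$bc_id == record$bc_id &&
        other$replicate_number == record$replicate_number) {
      abort_validation(sprintf(
        "replicate number %d already exists for %s (%s)",
        record$replicate_number, record$bc_id, other$br_id
      ))
    }
  }
  invisible(record)
}

# canonicalize assay tags stored inside an entity; errors on unregistered tags
canonicalize_entity_tags <- function(registry, record, kind) {
  if (kind == "raw_data") {
    record$assay_tag <- canonical_assay_tag(registry, record$assay_tag)
  }
  if (kind %in% c("analysis", "draft")) {
    record$analysis_type <- canonical_assay_tag(registry,
                                                record$analysis_type)
  }
  if (kind == "experiment") {
    record$planned_measurements <- lapply(
      record$planned_measurements,
      function(m) {
        m$assay_tag <- canonical_assay_tag(registry, m$assay_tag)
        m
      }
    )
  }
  record
}

assert_valid <- function(record, kind) {
  report <- validate_entity(record)
  if (length(report) > 0) {
    abort_validation(
      sprintf("invalid %s: %s", kind, paste(report, collapse = "; ")),
      report = report
    )
  }
  invisible(record)
}

normalize_record <- function(record, kind) {
  record <- record[!vapply(record, is.null, logical(1))]
  for (f in SET_FIELDS) {
    if (!is.null(record[[f]])) {
      record[[f]] <- sort(unique(as.character(record[[f]])))
    }
  }
  for (f in INTEGER_FIELDS) {
    if (!is.null(record[[f]])) record[[f]] <- as.integer(record[[f]])
  }
  if (!is.null(record$created_on)) {
    record$created_on <- as.Date(record$created_on)
  }
  structure(record, class = c(paste0("ems_", kind), "ems_entity"))
}

# ---- create -------------------------------------------------------------

#' Store a new entity
#'
#' Validates the entity structurally ([validate_entity()]), checks that
#' every reference it holds resolves in the registry (and points at the
#' right kind of element), enforces uniqueness rules (e.g. no two replicates
#' of a condition may share a replicate number), assigns a fresh identifier
#' and persists the record atomically. The acting user becomes the owner of
#' the element and thereby holds exclusive rights to delete it and to grant
#' edit access to others.
#'
#' Users, analyses and drafts are not created through this function: use
#' [ems_register_user()] and the workflow builders ([start_analysis()],
#' [finalize_analysis()]).
#'
#' @param registry An [ems_registry()].
#' @param entity An unpersisted entity from one of the constructors.
#' @param acting Acting (registered) user id; becomes the owner.
#' @param created_on Creation date stored on the record.
#' @return The new identifier.
#' @export
#' @examples
#' reg <- ems_registry()
#' admin <- ems_register_user(reg, "admin", role = "admin")
#' bc <- ems_create(reg, biological_condition("K562"), acting = admin)
ems_create <- function(registry, entity, acting, created_on = Sys.Date()) {
  check_registry(registry)
  check_acting(registry, acting)
  if (!inherits(entity, "ems_entity")) {
    abort_validation("`entity` must be built with an entity constructor")
  }
  kind <- entity_kind(entity)
  if (kind %in% c("user", "analysis", "draft")) {
    abort_validation(sprintf(
      "%s elements are created via %s", kind,
      if (kind == "user") "ems_register_user()" else "the workflow builders"
    ))
  }
  info <- kind_info(kind)
  if (!is.null(entity[[info$id]])) {
    abort_validation("entity already carries an identifier; create it once")
  }
  assert_valid(entity, kind)
  entity <- canonicalize_entity_tags(registry, entity, kind)
  check_entity_refs(registry, entity, kind)
  if (kind == "biological_replicate") {
    check_replicate_unique(registry, entity)
  }
  # all checks passed: only now touch registry state
  id <- new_identifier(registry, kind)
  entity[[info$id]] <- id
  entity$owner_id <- acting
  entity$created_on <- as.Date(created_on)
  reg_put(registry, normalize_record(entity, kind))
  id
}

# internal insert used by the workflow builders and the importer;
# the caller is responsible for checks
reg_insert <- function(registry, record, kind) {
  reg_put(registry, normalize_record(record, kind))
}

# ---- permissions --------------------------------------------------------

#' Grants held on an element
#'
#' @param registry An [ems_registry()].
#' @param element_id Element identifier.
#' @return Character vector of grantee user ids (sorted).
#' @export
ems_grants <- function(registry, element_id) {
  check_registry(registry)
  reg_get(registry, element_id)
  as.character(registry$grants[[element_id]] %||% character())
}

#' May a user edit / delete an element?
#'
#' Ownership confers edit, delete and grant rights; a grant confers edit
#' rights only; every other registered user can read but not modify.
#'
#' @param registry An [ems_registry()].
#' @param user_id A registered user id.
#' @param element_id Element identifier.
#' @return Logical scalar.
#' @export
ems_can_edit <- function(registry, user_id, element_id) {
  check_registry(registry)
  rec <- reg_get(registry, element_id)
  identical(rec$owner_id, user_id) ||
    user_id %in% (registry$grants[[element_id]] %||% character())
}

#' @rdname ems_can_edit
#' @export
ems_can_delete <- function(registry, user_id, element_id) {
  check_registry(registry)
  rec <- reg_get(registry, element_id)
  identical(rec$owner_id, user_id)
}

require_edit <- function(registry, acting, element_id) {
  check_acting(registry, acting)
  if (!ems_can_edit(registry, acting, element_id)) {
    abort_permission(sprintf(
      "user %s may not edit %s (owner or grantee required)",
      acting, element_id
    ))
  }
}

require_owner <- function(registry, acting, element_id, verb = "modify") {
  check_acting(registry, acting)
  rec <- reg_get(registry, element_id)
  if (!identical(rec$owner_id, acting)) {
    abort_permission(sprintf(
      "only the owner (%s) may %s %s", rec$owner_id, verb, element_id
    ))
  }
}

#' Grant or revoke edit access on an element
#'
#' The owner of an element can grant edit (but never delete) rights to any
#' other registered user; grants are additive, idempotent, and revocable by
#' the owner.
#'
#' @param registry An [ems_registry()].
#' @param element_id Element to share.
#' @param grantee Registered user id receiving (or losing) edit rights.
#' @param acting Acting user id; must own the element.
#' @return The updated grant set for the element (character vector).
#' @export
ems_grant <- function(registry, element_id, grantee, acting) {
  check_registry(registry)
  require_owner(registry, acting, element_id, verb = "grant access to")
  if (is.null(registry$tables$user[[grantee]])) {
    abort_not_found(sprintf("grantee '%s' is not a registered user", grantee))
  }
  registry$grants[[element_id]] <-
    sort(unique(c(registry$grants[[element_id]], grantee)))
  registry$grants <- registry$grants[order(names(registry$grants))]
  ems_grants(registry, element_id)
}

#' @rdname ems_grant
#' @export
ems_revoke <- function(registry, element_id, grantee, acting) {
  check_registry(registry)
  require_owner(registry, acting, element_id, verb = "revoke access to")
  g <- setdiff(registry$grants[[element_id]] %||% character(), grantee)
  if (length(g) == 0) {
    registry$grants[[element_id]] <- NULL
  } else {
    registry$grants[[element_id]] <- g
  }
  as.character(g)
}

# ---- update -------------------------------------------------------------

IMMUTABLE_FIELDS <- c("owner_id", "created_on",
                      vapply(KIND_INFO, function(k) k$id, character(1)))

#' Edit a stored element
#'
#' Applies a named list of field changes to an element, re-validates the
#' result (structure, references, uniqueness) and commits atomically: a
#' rejected update leaves the registry untouched. The acting user must be
#' the owner or hold a grant on the element. Identifiers, ownership and
#' creation dates are immutable, and finalized analyses cannot be edited at
#' all (associate them to further experiments with
#' [ems_associate_analysis()] instead).
#'
#' Setting a field to `NULL` removes an optional field (e.g. drop the
#' `batch_id` of a replicate). For experiments, `planned_measurements` may
#' be given as a character vector of assay tags; progress flags are then
#' recomputed from the associated analyses.
#'
#' @param registry An [ems_registry()].
#' @param element_id Element to edit.
#' @param changes Named list of field values.
#' @param acting Acting user id (owner or grantee).
#' @return The updated record, invisibly.
#' @export
ems_update <- function(registry, element_id, changes, acting) {
  check_registry(registry)
  rec <- reg_get(registry, element_id)
  kind <- entity_kind(rec)
  require_edit(registry, acting, element_id)
  if (kind == "analysis") {
    abort_validation(paste0(
      "finalized analyses are immutable; use ems_associate_analysis()/",
      "ems_dissociate_analysis() to change experiment associations"
    ))
  }
  if (length(changes) == 0) return(invisible(rec))
  if (is.null(names(changes)) || any(!nzchar(names(changes)))) {
    abort_validation("`changes` must be a fully named list")
  }
  info <- kind_info(kind)
  bad <- setdiff(names(changes), info$fields)
  if (length(bad) > 0) {
    abort_validation(sprintf("unknown field(s) for %s: %s", kind,
                             paste(bad, collapse = ", ")))
  }
  frozen <- intersect(names(changes), IMMUTABLE_FIELDS)
  if (length(frozen) > 0) {
    abort_validation(sprintf("immutable field(s): %s",
                             paste(frozen, collapse = ", ")))
  }
  if (kind == "experiment" && !is.null(changes$planned_measurements) &&
      is.character(changes$planned_measurements)) {
    changes$planned_measurements <- lapply(
      changes$planned_measurements,
      function(tag) list(assay_tag = tag, done = FALSE)
    )
  }
  if (kind == "biological_replicate" && !is.null(changes$replicate_number)) {
    changes$replicate_number <- as_count(changes$replicate_number)
  }
  if (kind == "experiment" && !is.null(changes$n_replicates_planned)) {
    changes$n_replicates_planned <- as_count(changes$n_replicates_planned)
  }
  candidate <- utils::modifyList(rec, changes)
  candidate <- structure(candidate, class = class(rec))
  assert_valid(candidate, kind)
  candidate <- canonicalize_entity_tags(registry, candidate, kind)
  check_entity_refs(registry, candidate, kind)
  if (kind == "biological_replicate") {
    check_replicate_unique(registry, candidate, exclude_id = element_id)
  }
  reg_put(registry, normalize_record(candidate, kind))
  if (kind == "experiment") recompute_progress(registry, element_id)
  invisible(registry$tables[[kind]][[element_id]])
}

# ---- delete -------------------------------------------------------------

#' Elements that reference an element
#'
#' Lists the identifiers of stored elements holding a structural reference
#' to `element_id` (lineage links, workflow inputs, analysis membership,
#' ownership). These references RESTRICT deletion. Experiment membership
#' sets and grants are associations, not structural references: they are
#' cleaned up when the member is deleted and are not reported here.
#'
#' @param registry An [ems_registry()].
#' @param element_id Element identifier.
#' @return Character vector of referrer identifiers (sorted).
#' @export
ems_referrers <- function(registry, element_id) {
  check_registry(registry)
  out <- character()
  for (kind in ENTITY_KINDS) {
    info <- KIND_INFO[[kind]]
    refs <- c(info$hard_refs, if (kind != "user") "owner_id")
    for (rec in registry$tables[[kind]]) {
      rid <- rec[[info$id]]
      if (rid == element_id) next
      for (f in refs) {
        if (element_id %in% (rec[[f]] %||% character())) {
          out <- c(out, rid)
          break
        }
      }
    }
  }
  # a secondary analysis that reuses this analysis' processed data as a
  # root depends on it even though it references the node, not the analysis
  if (kind_of_id(element_id) == "analysis") {
    pd <- registry$tables$analysis[[element_id]]$processed_data_id
    for (other in registry$tables$analysis) {
      if (other$analysis_id != element_id && pd %in% other$node_ids) {
        out <- c(out, other$analysis_id)
      }
    }
    for (dr in registry$tables$draft) {
      if (pd %in% dr$node_ids) out <- c(out, dr$draft_id)
    }
  }
  sort(unique(out))
}

#' Delete an element
#'
#' Only the owner may delete (grantees can edit but never delete). Deletion
#' is RESTRICT: if any stored element still structurally references the
#' target — a replicate of a condition, a workflow node consumed by another
#' node or contained in an analysis, an experiment referenced by an analysis,
#' a user who owns elements — the deletion is rejected listing the
#' referrers. Membership associations are cleaned up instead: deleting an
#' analysis removes it from its experiments' association sets and recomputes
#' their progress flags. A deleted identifier is never reissued.
#'
#' @param registry An [ems_registry()].
#' @param element_id Element to delete.
#' @param acting Acting user id; must be the owner.
#' @return The deleted identifier, invisibly.
#' @export
ems_delete <- function(registry, element_id, acting) {
  check_registry(registry)
  rec <- reg_get(registry, element_id)
  require_owner(registry, acting, element_id, verb = "delete")
  refs <- ems_referrers(registry, element_id)
  refs <- setdiff(refs, element_id)
  if (length(refs) > 0) {
    abort_integrity(
      sprintf("%s is still referenced by: %s", element_id,
              paste(refs, collapse = ", ")),
      referrers = refs
    )
  }
  kind <- entity_kind(rec)
  # clean up membership associations and grants
  touched_experiments <- character()
  for (exp in registry$tables$experiment) {
    changed <- FALSE
    for (f in c("member_ids", "sample_ids", "analysis_ids")) {
      if (element_id %in% exp[[f]]) {
        exp[[f]] <- setdiff(exp[[f]], element_id)
        changed <- TRUE
      }
    }
    if (changed) {
      reg_put(registry, exp)
      touched_experiments <- c(touched_experiments, exp$experiment_id)
    }
  }
  registry$grants[[element_id]] <- NULL
  if (kind == "user") {
    registry$grants <- lapply(registry$grants, function(g) {
      setdiff(g, element_id)
    })
    registry$grants <- registry$grants[
      vapply(registry$grants, length, integer(1)) > 0
    ]
  }
  reg_drop(registry, element_id)
  for (eid in touched_experiments) recompute_progress(registry, eid)
  invisible(element_id)
}

# ---- experiment associations & progress ---------------------------------

recompute_progress <- function(registry, experiment_id) {
  exp <- registry$tables$experiment[[experiment_id]]
  types <- vapply(
    exp$analysis_ids,
    function(aid) registry$tables$analysis[[aid]]$analysis_type,
    character(1)
  )
  exp$planned_measurements <- lapply(exp$planned_measurements, function(m) {
    m$done <- norm_tag(m$assay_tag) %in% norm_tag(types)
    m
  })
  reg_put(registry, exp)
  invisible(exp)
}

#' Associate or dissociate an analysis and an experiment
#'
#' Associating an analysis records it in the experiment's analysis set and
#' in the analysis' experiment set, then recomputes the experiment's
#' planned-measurement progress flags: the `done` flag of a planned assay
#' tag is true exactly when at least one associated analysis has that
#' analysis type. Dissociation recomputes the flags the same way, so
#' removing the only analysis of a planned type reverts its flag to false.
#'
#' @param registry An [ems_registry()].
#' @param analysis_id A finalized analysis id.
#' @param experiment_id An experiment id.
#' @param acting Acting user id; must be able to edit the experiment.
#' @return The updated experiment record, invisibly.
#' @export
ems_associate_analysis <- function(registry, analysis_id, experiment_id,
                                   acting) {
  check_registry(registry)
  an <- reg_get(registry, analysis_id, what = "analysis")
  exp <- reg_get(registry, experiment_id, what = "experiment")
  require_edit(registry, acting, experiment_id)
  exp$analysis_ids <- sort(unique(c(exp$analysis_ids, analysis_id)))
  an$experiment_ids <- sort(unique(c(an$experiment_ids, experiment_id)))
  reg_put(registry, exp)
  reg_put(registry, an)
  invisible(recompute_progress(registry, experiment_id))
}

#' @rdname ems_associate_analysis
#' @export
ems_dissociate_analysis <- function(registry, analysis_id, experiment_id,
                                    acting) {
  check_registry(registry)
  an <- reg_get(registry, analysis_id, what = "analysis")
  exp <- reg_get(registry, experiment_id, what = "experiment")
  require_edit(registry, acting, experiment_id)
  exp$analysis_ids <- setdiff(exp$analysis_ids, analysis_id)
  an$experiment_ids <- setdiff(an$experiment_ids, experiment_id)
  reg_put(registry, exp)
  reg_put(registry, an)
  invisible(recompute_progress(registry, experiment_id))
}

#' Associate a biological condition (sample) with an experiment
#'
#' @param registry An [ems_registry()].
#' @param bc_id Biological condition id.
#' @param experiment_id Experiment id.
#' @param acting Acting user id; must be able to edit the experiment.
#' @return The updated experiment record, invisibly.
#' @export
ems_associate_sample <- function(registry, bc_id, experiment_id, acting) {
  check_registry(registry)
  reg_get(registry, bc_id, what = "biological condition")
  exp <- reg_get(registry, experiment_id, what = "experiment")
  require_edit(registry, acting, experiment_id)
  if (kind_of_id(bc_id) != "biological_condition") {
    abort_validation("`bc_id` must identify a biological condition")
  }
  exp$sample_ids <- sort(unique(c(exp$sample_ids, bc_id)))
  reg_put(registry, exp)
  invisible(exp)
}

#' Add a member user to an experiment
#'
#' Membership is informational (who works on the experiment); edit rights
#' flow solely from ownership and grants.
#'
#' @inheritParams ems_associate_sample
#' @param user_id Registered user to add.
#' @export
ems_add_member <- function(registry, user_id, experiment_id, acting) {
  check_registry(registry)
  exp <- reg_get(registry, experiment_id, what = "experiment")
  require_edit(registry, acting, experiment_id)
  if (is.null(registry$tables$user[[user_id]])) {
    abort_not_found(sprintf("user '%s' is not registered", user_id))
  }
  exp$member_ids <- sort(unique(c(exp$member_ids, user_id)))
  reg_put(registry, exp)
  invisible(exp)
}

# ---- query --------------------------------------------------------------

LIST_FIELDS <- c(SET_FIELDS, ORDERED_LIST_FIELDS,
                 "planned_measurements", "attributes",
                 "experimental_condition")

empty_field_value <- function(field) {
  if (field %in% LIST_FIELDS) return(list())
  if (field %in% INTEGER_FIELDS) return(NA_integer_)
  if (field == "created_on") return(as.Date(NA))
  NA_character_
}

record_to_row <- function(rec, info) {
  vals <- lapply(info$fields, function(f) {
    v <- rec[[f]]
    if (f %in% LIST_FIELDS) return(list(v))
    if (is.null(v)) return(empty_field_value(f))
    v
  })
  names(vals) <- info$fields
  tibble::as_tibble(vals)
}

#' Query stored elements as a tibble
#'
#' Returns all elements of a kind, one row per element, deterministically
#' ordered by identifier, with multi-valued fields as list-columns. Extra
#' arguments are `dplyr::filter()` predicates evaluated on the result, so
#' the everyday lineage queries compose naturally:
#'
#' ```
#' ems_query(reg, "biological_replicate", bc_id == "BC-0001")
#' ems_query(reg, "analytical_sample", br_id == "BR-0003")
#' ```
#'
#' @param registry An [ems_registry()].
#' @param kind One of [entity_kinds()].
#' @param ... Optional filter predicates.
#' @return A tibble ordered by identifier.
#' @export
ems_query <- function(registry, kind, ...) {
  check_registry(registry)
  info <- kind_info(kind)
  recs <- registry$tables[[kind]]
  if (length(recs) == 0) {
    cols <- lapply(info$fields, empty_field_value)
    names(cols) <- info$fields
    out <- tibble::as_tibble(cols)[0, ]
  } else {
    out <- dplyr::bind_rows(lapply(recs, record_to_row, info = info))
    out <- dplyr::arrange(out, .data[[info$id]])
  }
  dots <- rlang::enquos(...)
  if (length(dots) > 0) out <- dplyr::filter(out, !!!dots)
  out
}

#' Convenience lineage queries
#'
#' Thin wrappers over [ems_query()] for the everyday questions: the
#' replicates of a condition, the analytical samples of a replicate, the
#' analyses associated to an experiment, and the replicates in a batch.
#'
#' @param registry An [ems_registry()].
#' @param bc_id,br_id,experiment_id,batch_id Parent identifiers.
#' @return A tibble ordered by identifier.
#' @name lineage-queries
NULL

#' @rdname lineage-queries
#' @export
replicates_of <- function(registry, bc_id) {
  target <- bc_id
  ems_query(registry, "biological_replicate", .data$bc_id == target)
}

#' @rdname lineage-queries
#' @export
analytical_samples_of <- function(registry, br_id) {
  target <- br_id
  ems_query(registry, "analytical_sample", .data$br_id == target)
}

#' @rdname lineage-queries
#' @export
analyses_of <- function(registry, experiment_id) {
  target <- experiment_id
  out <- ems_query(registry, "analysis")
  keep <- purrr::map_lgl(out$experiment_ids, function(x) target %in% x)
  out[keep, ]
}

#' @rdname lineage-queries
#' @export
batch_members <- function(registry, batch_id) {
  target <- batch_id
  out <- ems_query(registry, "biological_replicate")
  out[!is.na(out$batch_id) & out$batch_id == target, ]
}

# ---- audit --------------------------------------------------------------

#' Global consistency audit
#'
#' Scans the whole registry and reports every violation of store-wide
#' invariants: dangling structural or membership references, reference
#' fields pointing at the wrong kind of element, duplicate replicate numbers
#' within a condition, analyses whose processed-data sink is missing or
#' shared with another analysis, processed-data members that are no
#' analysis' sink, progress flags that disagree with a from-scratch
#' recomputation, grants on missing elements or to missing users, and
#' identifier counters behind the largest issued identifier.
#'
#' @param registry An [ems_registry()].
#' @return A tibble with columns `element_id` and `problem`; zero rows means
#'   the registry is consistent.
#' @export
ems_audit <- function(registry) {
  check_registry(registry)
  problems <- list()
  note <- function(id, msg) {
    problems[[length(problems) + 1]] <<- tibble::tibble(
      element_id = id, problem = msg
    )
  }
  for (kind in ENTITY_KINDS) {
    info <- KIND_INFO[[kind]]
    refs <- c(info$hard_refs, info$soft_refs,
              if (kind != "user") "owner_id")
    for (rec in registry$tables[[kind]]) {
      rid <- rec[[info$id]]
      rep <- validate_entity(rec)
      for (msg in rep) note(rid, msg)
      for (f in refs) {
        allowed <- REF_FIELD_KIND[[f]]
        for (target in rec[[f]] %||% character()) {
          if (!reg_exists(registry, target)) {
            note(rid, sprintf("dangling reference %s in %s", target, f))
          } else if (!is.null(allowed) &&
                     !kind_of_id(target) %in% allowed) {
            note(rid, sprintf("%s points at wrong kind: %s", f, target))
          }
        }
      }
    }
  }
  # replicate uniqueness
  reps <- registry$tables$biological_replicate
  if (length(reps) > 0) {
    key <- vapply(reps, function(r) {
      paste(r$bc_id, r$replicate_number)
    }, character(1))
    for (k in unique(key[duplicated(key)])) {
      ids <- names(key)[key == k]
      note(ids[[2]], sprintf("duplicate replicate number (%s)", k))
    }
  }
  # one analysis <-> one processed-data sink
  sink_claims <- list()
  for (an in registry$tables$analysis) {
    pd <- an$processed_data_id
    sink_claims[[pd]] <- c(sink_claims[[pd]], an$analysis_id)
  }
  for (pd in names(sink_claims)) {
    if (length(sink_claims[[pd]]) > 1) {
      note(pd, sprintf("processed data is the sink of several analyses: %s",
                       paste(sink_claims[[pd]], collapse = ", ")))
    }
  }
  for (an in registry$tables$analysis) {
    member_pds <- an$node_ids[kind_of_id(an$node_ids) == "processed_data"]
    for (pd in setdiff(member_pds, an$processed_data_id)) {
      owners <- sink_claims[[pd]]
      if (is.null(owners) || !any(owners != an$analysis_id)) {
        note(an$analysis_id, sprintf(
          "member processed data %s is not the sink of any other analysis",
          pd
        ))
      }
    }
  }
  # progress flags vs recomputation
  for (exp in registry$tables$experiment) {
    types <- character()
    for (aid in exp$analysis_ids) {
      an <- registry$tables$analysis[[aid]]
      if (!is.null(an)) types <- c(types, an$analysis_type)
      an2 <- registry$tables$analysis[[aid]]
      if (!is.null(an2) && !exp$experiment_id %in% an2$experiment_ids) {
        note(exp$experiment_id, sprintf(
          "association with %s is not mirrored on the analysis", aid
        ))
      }
    }
    for (m in exp$planned_measurements) {
      expected <- norm_tag(m$assay_tag) %in% norm_tag(types)
      if (!identical(m$done, expected)) {
        note(exp$experiment_id, sprintf(
          "progress flag for %s is %s but should be %s",
          m$assay_tag, m$done, expected
        ))
      }
    }
  }
  for (an in registry$tables$analysis) {
    for (eid in an$experiment_ids) {
      exp <- registry$tables$experiment[[eid]]
      if (!is.null(exp) && !an$analysis_id %in% exp$analysis_ids) {
        note(an$analysis_id, sprintf(
          "association with %s is not mirrored on the experiment", eid
        ))
      }
    }
  }
  # grants
  for (eid in names(registry$grants)) {
    if (!reg_exists(registry, eid)) {
      note(eid, "grant on a missing element")
    }
    for (u in registry$grants[[eid]]) {
      if (is.null(registry$tables$user[[u]])) {
        note(eid, sprintf("grant to missing user %s", u))
      }
    }
  }
  # counters never behind issued identifiers
  for (kind in ENTITY_KINDS) {
    ids <- names(registry$tables[[kind]])
    if (length(ids) > 0) {
      mx <- max(id_number(ids))
      if (registry$counters[[kind]] < mx) {
        note(kind, sprintf("counter for %s (%d) is behind max issued id (%d)",
                           kind, registry$counters[[kind]], mx))
      }
    }
  }
  if (length(problems) == 0) {
    tibble::tibble(element_id = character(), problem = character())
  } else {
    dplyr::bind_rows(problems)
  }
}
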