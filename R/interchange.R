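#' Canonical JSON interchange
#'
#' A registry (or the transitive closure of one experiment) can be exported
#' losslessly to a canonical JSON document and re-imported with identifiers
#' preserved. Canonical means byte-deterministic: entity kinds and records
#' are sorted by identifier, record fields follow the fixed schema order,
#' multi-valued set fields are sorted, dates are ISO-8601, and the encoding
#' is UTF-8 — so identical registries always serialize to identical bytes
#' and exports are diffable. The same format is the on-disk form of the
#' registry ([write_registry()] / [read_registry()]); `schema_version`
#' records the format generation.
#'
#' @name interchange
NULL

EMS_SCHEMA_VERSION <- 1L

serialize_value <- function(field, value) {
  if (is.null(value)) return(NULL)
  if (field == "created_on") return(format(as.Date(value), "%Y-%m-%d"))
  if (field %in% c(SET_FIELDS, ORDERED_LIST_FIELDS)) {
    return(as.character(value))
  }
  if (field == "planned_measurements") {
    return(lapply(value, function(m) {
      list(assay_tag = m$assay_tag, done = m$done)
    }))
  }
  if (field == "attributes") {
    if (length(value) == 0) return(NULL)
    return(value[order(names(value))])
  }
  if (field == "experimental_condition") {
    return(value[order(names(value))])
  }
  value
}

serialize_record <- function(rec, kind) {
  info <- KIND_INFO[[kind]]
  out <- list()
  for (f in info$fields) {
    v <- serialize_value(f, rec[[f]])
    if (!is.null(v)) out[[f]] <- v
  }
  out
}

materialize_value <- function(field, value) {
  if (field == "created_on") return(as.Date(unlist(value)))
  if (field %in% c(SET_FIELDS, ORDERED_LIST_FIELDS)) {
    return(as.character(unlist(value)))
  }
  if (field %in% INTEGER_FIELDS) return(as.integer(unlist(value)))
  if (field == "planned_measurements") {
    return(lapply(value, function(m) {
      list(assay_tag = as.character(m$assay_tag),
           done = as.logical(m$done))
    }))
  }
  if (field == "attributes") {
    return(lapply(value, function(v) as.character(unlist(v))))
  }
  if (field == "experimental_condition") {
    return(lapply(value, function(v) as.character(unlist(v))))
  }
  as.character(unlist(value))
}

materialize_record <- function(raw, kind) {
  info <- KIND_INFO[[kind]]
  rec <- list()
  for (f in info$fields) {
    if (!is.null(raw[[f]])) {
      rec[[f]] <- materialize_value(f, raw[[f]])
    } else if (f %in% SET_FIELDS && kind %in% c("experiment", "analysis",
                                                "draft")) {
      rec[[f]] <- character()
    } else if (f == "attributes" && kind == "experiment") {
      rec[[f]] <- list()
    } else if (f == "planned_measurements" && kind == "experiment") {
      rec[[f]] <- list()
    } else if (f == "node_ids" && kind == "draft") {
      rec[[f]] <- character()
    }
  }
  normalize_record(rec, kind)
}

#' Export a registry to an interchange document
#'
#' `scope = "all"` exports everything. `scope = "EXP-...."` exports the
#' transitive closure of one experiment: the experiment itself, its
#' associated biological conditions with their full lineage (replicates,
#' batches, analytical samples), its analyses with their complete workflow
#' graphs — following shared foreign processed-data roots into their source
#' analyses recursively — plus every user owning, member of, or granted on
#' an included element, and the grants on included elements. Associations
#' pointing outside the scope (an analysis also linked to another
#' experiment) are pruned so that the exported document is self-contained.
#' Drafts are exported only with `scope = "all"`.
#'
#' @param registry An [ems_registry()].
#' @param scope `"all"` or one experiment identifier.
#' @return An `ems_document`: a plain nested list with fields
#'   `schema_version`, `assay_types`, `counters`, `entities`, `grants`,
#'   `manifest`.
#' @export
export_registry <- function(registry, scope = "all") {
  check_registry(registry)
  if (identical(scope, "all")) {
    keep <- unlist(lapply(registry$tables, names), use.names = FALSE)
  } else {
    exp <- reg_get(registry, scope, what = "experiment")
    if (entity_kind(exp) != "experiment") {
      abort_not_found(sprintf("experiment '%s' not found", scope))
    }
    keep <- experiment_closure(registry, scope)
  }
  keep <- sort(unique(keep))
  entities <- list()
  for (kind in sort(ENTITY_KINDS)) {
    ids <- intersect(names(registry$tables[[kind]]), keep)
    recs <- lapply(registry$tables[[kind]][sort(ids)], function(rec) {
      if (!identical(scope, "all")) rec <- prune_to_scope(rec, kind, keep)
      serialize_record(rec, kind)
    })
    entities[[kind]] <- unname(recs)
  }
  grants <- registry$grants[names(registry$grants) %in% keep]
  grants <- lapply(grants, function(g) as.character(intersect(g, keep)))
  grants <- grants[vapply(grants, length, integer(1)) > 0]
  if (length(grants) == 0) grants <- stats::setNames(list(), character())
  doc <- list(
    schema_version = registry$schema_version,
    assay_types = {
      at <- dplyr::arrange(registry$assay_types, .data$tag)
      lapply(seq_len(nrow(at)), function(i) {
        list(tag = at$tag[[i]], category = at$category[[i]])
      })
    },
    counters = as.list(registry$counters[sort(names(registry$counters))]),
    entities = entities,
    grants = grants[order(names(grants))],
    manifest = lapply(entities, length)
  )
  structure(doc, class = "ems_document")
}

prune_to_scope <- function(rec, kind, keep) {
  fields <- intersect(
    c("member_ids", "sample_ids", "analysis_ids", "experiment_ids"),
    names(rec)
  )
  for (f in fields) rec[[f]] <- intersect(rec[[f]], keep)
  rec
}

experiment_closure <- function(registry, experiment_id) {
  exp <- registry$tables$experiment[[experiment_id]]
  keep <- c(experiment_id, exp$member_ids, exp$owner_id)
  # sample lineage
  for (bc_id in exp$sample_ids) {
    keep <- c(keep, bc_id)
    for (br in registry$tables$biological_replicate) {
      if (br$bc_id == bc_id) {
        keep <- c(keep, br$br_id, br$batch_id %||% character())
        for (smp in registry$tables$analytical_sample) {
          if (smp$br_id == br$br_id) keep <- c(keep, smp$as_id)
        }
      }
    }
  }
  # analyses and their graphs, recursing through foreign processed data
  sinks <- sink_owner_map(registry)
  pending <- exp$analysis_ids
  seen_an <- character()
  while (length(pending) > 0) {
    aid <- pending[[1]]
    pending <- pending[-1]
    if (aid %in% seen_an) next
    seen_an <- c(seen_an, aid)
    an <- registry$tables$analysis[[aid]]
    keep <- c(keep, aid, an$node_ids)
    for (n in an$node_ids) {
      kind <- kind_of_id(n)
      if (kind == "raw_data") {
        rd <- registry$tables$raw_data[[n]]
        smp <- registry$tables$analytical_sample[[rd$as_id]]
        br <- registry$tables$biological_replicate[[smp$br_id]]
        keep <- c(keep, rd$as_id, smp$br_id, br$bc_id,
                  br$batch_id %||% character())
      } else if (kind == "processed_data" && n != an$processed_data_id) {
        pending <- c(pending, sinks[[n]] %||% character())
      }
    }
  }
  keep <- unique(keep)
  # owners and grantees of everything included
  extra <- character()
  for (id in keep) {
    kind <- kind_of_id(id)
    if (is.na(kind)) next
    rec <- registry$tables[[kind]][[id]]
    if (!is.null(rec$owner_id)) extra <- c(extra, rec$owner_id)
    extra <- c(extra, registry$grants[[id]] %||% character())
  }
  unique(c(keep, extra))
}

doc_to_jsonlite <- function(doc) {
  ub <- jsonlite::unbox
  ents <- lapply(doc$entities, function(recs) {
    lapply(recs, function(rec) {
      out <- lapply(names(rec), function(f) {
        v <- rec[[f]]
        if (f %in% c(SET_FIELDS, ORDERED_LIST_FIELDS)) {
          return(as.character(v))
        }
        if (f == "planned_measurements") {
          return(lapply(v, function(m) {
            list(assay_tag = ub(m$assay_tag), done = ub(m$done))
          }))
        }
        if (f %in% c("attributes", "experimental_condition")) {
          return(lapply(v, ub))
        }
        ub(v)
      })
      names(out) <- names(rec)
      out
    })
  })
  grants <- lapply(doc$grants, as.character)
  if (length(grants) == 0) grants <- stats::setNames(list(), character())
  list(
    schema_version = ub(doc$schema_version),
    assay_types = lapply(doc$assay_types, function(a) {
      list(tag = ub(a$tag), category = ub(a$category))
    }),
    counters = lapply(doc$counters, function(x) ub(as.integer(x))),
    entities = ents,
    grants = grants,
    manifest = lapply(doc$manifest, function(x) ub(as.integer(x)))
  )
}

#' Serialize an interchange document to canonical JSON text
#'
#' @param doc An `ems_document` from [export_registry()].
#' @return A single JSON string.
#' @export
doc_to_json <- function(doc) {
  as.character(jsonlite::toJSON(doc_to_jsonlite(doc), pretty = TRUE,
                                digits = NA, null = "null"))
}

#' Write / read an interchange document
#'
#' Files use the `.ems.json` extension by convention. Writing is atomic:
#' the document is written to a temporary file in the same directory and
#' renamed into place.
#'
#' @param doc An `ems_document`.
#' @param path File path.
#' @return `write_ems_json()` returns `path` invisibly; `read_ems_json()`
#'   returns an `ems_document`.
#' @export
write_ems_json <- function(doc, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(doc_to_json(doc), tmp, useBytes = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_ems_json
#' @export
read_ems_json <- function(path) {
  if (!file.exists(path)) {
    abort_not_found(sprintf("file '%s' not found", path))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(raw, class = "ems_document")
}

#' @export
print.ems_document <- function(x, ...) {
  cat("<ems_document> schema_version", as.integer(x$schema_version), "\n")
  m <- unlist(x$manifest)
  m <- m[m > 0]
  for (k in names(m)) cat(sprintf("  %-22s %d\n", k, m[[k]]))
  invisible(x)
}

#' Import an interchange document
#'
#' Strict import: the target registry must be completely empty (import into
#' a fresh [ems_registry()]). All entities are materialized with their
#' original identifiers, identifier counters are advanced beyond the largest
#' imported identifier, and a full referential audit runs on the staged
#' result; any failure aborts atomically, leaving the target registry
#' unchanged.
#'
#' @param registry An empty [ems_registry()].
#' @param doc An `ems_document`.
#' @param mode Only `"strict"` is supported.
#' @return A load report: tibble with columns `kind` and `n_loaded`.
#' @export
import_document <- function(registry, doc, mode = "strict") {
  check_registry(registry)
  mode <- match.arg(mode, "strict")
  if (!registry_is_empty(registry)) {
    abort_validation("strict import requires an empty target registry")
  }
  sv <- as.integer(doc$schema_version %||% NA_integer_)
  if (is.na(sv) || sv != EMS_SCHEMA_VERSION) {
    abort_validation(sprintf(
      "unsupported schema_version %s (this build reads version %d)",
      doc$schema_version %||% "<missing>", EMS_SCHEMA_VERSION
    ))
  }
  staging <- ems_registry()
  if (!is.null(doc$assay_types) && length(doc$assay_types) > 0) {
    staging$assay_types <- tibble::tibble(
      tag = vapply(doc$assay_types, function(a) as.character(a$tag),
                   character(1)),
      category = vapply(doc$assay_types, function(a) {
        as.character(a$category)
      }, character(1))
    )
  }
  manifest <- lapply(doc$manifest %||% list(), as.integer)
  for (kind in names(doc$entities %||% list())) {
    if (!kind %in% ENTITY_KINDS) {
      abort_validation(sprintf("unknown entity kind in document: %s", kind))
    }
    recs <- doc$entities[[kind]]
    if (!is.null(manifest[[kind]]) && manifest[[kind]] != length(recs)) {
      abort_validation(sprintf(
        "manifest count for %s (%d) does not match record count (%d)",
        kind, manifest[[kind]], length(recs)
      ))
    }
    for (raw in recs) {
      rec <- materialize_record(raw, kind)
      id <- rec[[id_field(kind)]]
      if (is.null(id) || is.na(id)) {
        abort_validation(sprintf("a %s record has no identifier", kind))
      }
      if (!is.null(staging$tables[[kind]][[id]])) {
        abort_validation(sprintf("duplicate identifier in document: %s", id))
      }
      reg_insert(staging, rec, kind)
    }
  }
  for (eid in names(doc$grants %||% list())) {
    staging$grants[[eid]] <- sort(unique(as.character(
      unlist(doc$grants[[eid]])
    )))
  }
  if (length(staging$grants) > 0) {
    staging$grants <- staging$grants[order(names(staging$grants))]
  }
  for (kind in ENTITY_KINDS) {
    ids <- names(staging$tables[[kind]])
    from_doc <- as.integer(doc$counters[[kind]] %||% 0L)
    issued <- if (length(ids) > 0) max(id_number(ids)) else 0L
    staging$counters[[kind]] <- max(from_doc, issued, 0L, na.rm = TRUE)
  }
  audit <- ems_audit(staging)
  if (nrow(audit) > 0) {
    abort_integrity(
      paste0("document fails the referential audit: ",
             paste(sprintf("%s: %s", audit$element_id, audit$problem),
                   collapse = "; ")),
      referrers = audit$element_id
    )
  }
  # commit
  registry$schema_version <- EMS_SCHEMA_VERSION
  registry$tables <- staging$tables
  registry$counters <- staging$counters
  registry$grants <- staging$grants
  registry$assay_types <- staging$assay_types
  tibble::tibble(
    kind = sort(ENTITY_KINDS),
    n_loaded = vapply(sort(ENTITY_KINDS), function(k) {
      length(registry$tables[[k]])
    }, integer(1))
  )
}

#' Persist / load a registry as a single file
#'
#' The on-disk form of a registry is its full canonical interchange export,
#' so registry files are plain, diffable JSON.
#'
#' @param registry An [ems_registry()] (empty, for `read_registry()` the
#'   function creates its own).
#' @param path File path (conventionally `*.ems.json`).
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns a fresh registry.
#' @export
write_registry <- function(registry, path) {
  write_ems_json(export_registry(registry, scope = "all"), path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  reg <- ems_registry()
  import_document(reg, read_ems_json(path))
  reg
}

#' Are two registries identical?
#'
#' Compares the canonical serialization of both registries; `TRUE` means
#' field-by-field equality of every stored element, grant, counter and
#' assay type.
#'
#' @param a,b Registries.
#' @return Logical scalar.
#' @export
registries_equal <- function(a, b) {
  identical(doc_to_json(export_registry(a)), doc_to_json(export_registry(b)))
}
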