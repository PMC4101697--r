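#' Entity constructors
#'
#' These constructors build in-memory descriptions of the annotatable
#' elements of an omics study. They perform no persistence and no
#' cross-reference checking: pass the result to [ems_create()] (or the
#' workflow builders) to store it, at which point structural validation
#' ([validate_entity()]) and referential checks run and an identifier is
#' assigned.
#'
#' The three-level sample lineage is: a *biological condition* (a
#' biomaterial, e.g. the K562 cell line, plus an optional experimental
#' condition such as treatment/dose/time-point) is assessed through numbered
#' *biological replicates* (optionally tagged with the experimental batch
#' they were cultured in), each of which yields one or more
#' *analytical samples* — extraction-protocol-processed material ready to be
#' measured by a high-throughput assay.
#'
#' Workflow nodes (raw data, intermediate steps, processed data) carry a
#' `file_pointer`: a free-text path or URI to the data file, whose content
#' the system never ingests.
#'
#' @param name Short name (e.g. `"K562"`); required, non-empty.
#' @param title Extended description (e.g. `"Chronic myelogenous leukemia"`).
#' @param organism,tissue,cell_type Free-text biomaterial description.
#' @param variation Free text, e.g. `"cancer"` or `"normal"`.
#' @param experimental_condition Optional list with any of the fields
#'   `treatment`, `dose`, `time_point`; `NULL` (the default) represents the
#'   entire section being absent, as for untreated cell lines.
#' @return A classed list (an unpersisted entity).
#' @name entity-constructors
NULL

new_entity <- function(kind, fields) {
  fields <- fields[!vapply(fields, is.null, logical(1))]
  structure(fields, class = c(paste0("ems_", kind), "ems_entity"))
}

entity_kind <- function(entity) {
  sub("^ems_", "", class(entity)[[1]])
}

#' @rdname entity-constructors
#' @export
biological_condition <- function(name, title = "", organism = "",
                                 tissue = "", cell_type = "", variation = "",
                                 experimental_condition = NULL) {
  new_entity("biological_condition", list(
    name = name, title = title, organism = organism, tissue = tissue,
    cell_type = cell_type, variation = variation,
    experimental_condition = experimental_condition
  ))
}

#' @rdname entity-constructors
#' @param label Batch label, e.g. `"culture batch 1"`.
#' @export
experimental_batch <- function(label) {
  new_entity("experimental_batch", list(label = label))
}

#' @rdname entity-constructors
#' @param bc_id Identifier of the biological condition the replicate
#'   instantiates (exactly one).
#' @param replicate_number Positive integer; unique within the condition.
#' @param batch_id Optional identifier of the experimental batch the
#'   replicate belongs to.
#' @export
biological_replicate <- function(bc_id, replicate_number, batch_id = NULL) {
  new_entity("biological_replicate", list(
    bc_id = bc_id,
    replicate_number = as_count(replicate_number),
    batch_id = batch_id
  ))
}

#' @rdname entity-constructors
#' @param br_id Identifier of the parent biological replicate.
#' @param extraction_protocol Free text, e.g.
#'   `"Caltech long mRNA extraction protocol"`.
#' @export
analytical_sample <- function(br_id, name, extraction_protocol = "") {
  new_entity("analytical_sample", list(
    br_id = br_id, name = name, extraction_protocol = extraction_protocol
  ))
}

#' @rdname entity-constructors
#' @param as_id Identifier of the analytical sample the raw data was
#'   measured from.
#' @param assay_tag Registered assay type tag (case-insensitive).
#' @param protocol_details Library preparation / instrument characteristics.
#' @param file_pointer Path or URI of the data file (pointer only; content is
#'   never stored). Required, non-empty.
#' @export
raw_data <- function(as_id, assay_tag, file_pointer, protocol_details = "") {
  new_entity("raw_data", list(
    as_id = as_id, assay_tag = assay_tag,
    protocol_details = protocol_details, file_pointer = file_pointer
  ))
}

#' @rdname entity-constructors
#' @param input_node_ids Ordered list of input node identifiers (length >= 1).
#' @param step_kind Free text: mapping, trimming, peak calling, merging, ...
#' @param software,parameters Free-text processing description.
#' @param reference_resource Optional genome/annotation resource, e.g.
#'   `"GENCODE hg19"`.
#' @export
intermediate_step <- function(input_node_ids, step_kind, file_pointer,
                              software = "", parameters = "",
                              reference_resource = NULL) {
  new_entity("intermediate_step", list(
    input_node_ids = as.character(input_node_ids), step_kind = step_kind,
    software = software, parameters = parameters,
    reference_resource = reference_resource, file_pointer = file_pointer
  ))
}

#' @rdname entity-constructors
#' @param signal_description What the final signal file contains, e.g.
#'   `"Cufflinks gtf file with FPKMs"`.
#' @export
processed_data <- function(input_node_ids, signal_description, file_pointer) {
  new_entity("processed_data", list(
    input_node_ids = as.character(input_node_ids),
    signal_description = signal_description, file_pointer = file_pointer
  ))
}

#' @rdname entity-constructors
#' @param description,goals Free-text study description.
#' @param experiment_type E.g. `"multiple conditions"`, `"time course"`.
#' @param n_replicates_planned Positive integer.
#' @param planned_measurements Character vector of assay tags the experiment
#'   plans to measure; each gets a `done` progress flag that the registry
#'   keeps equal to "at least one associated analysis has this type".
#' @param attributes Named list of free-text extras.
#' @export
experiment <- function(name, description = "", goals = "",
                       experiment_type = "", n_replicates_planned = 1,
                       planned_measurements = character(),
                       attributes = list()) {
  new_entity("experiment", list(
    name = name, description = description, goals = goals,
    experiment_type = experiment_type,
    n_replicates_planned = as_count(n_replicates_planned),
    planned_measurements = lapply(planned_measurements, function(tag) {
      list(assay_tag = tag, done = FALSE)
    }),
    attributes = attributes,
    member_ids = character(), sample_ids = character(),
    analysis_ids = character()
  ))
}

as_count <- function(x) {
  if (length(x) == 1 && is.numeric(x) && !is.na(x) && x == as.integer(x)) {
    as.integer(x)
  } else {
    # leave malformed values for validate_entity to report
    x
  }
}

#' Structural validation of an entity
#'
#' Checks every structural invariant of the entity's type and returns a
#' report of violations; an empty report means the entity is structurally
#' valid. This is a pure function: it never consults a registry, so
#' referential rules (do `bc_id`, `input_node_ids`, ... resolve?) are
#' enforced separately by the store operations. Malformed structure yields
#' report entries, never an error.
#'
#' @param entity Any entity built by the constructors (or a stored record).
#' @return Character vector of violation messages (empty when valid).
#' @export
#' @examples
#' validate_entity(biological_replicate("BC-0001", 0))
validate_entity <- function(entity) {
  if (!inherits(entity, "ems_entity")) {
    return("not a recognised entity (build it with a constructor)")
  }
  UseMethod("validate_entity")
}

#' @export
validate_entity.default <- function(entity) {
  "not a recognised entity kind"
}

need_string <- function(entity, field, problems, nonempty = FALSE) {
  x <- entity[[field]]
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    return(c(problems, sprintf("%s must be a string", field)))
  }
  if (nonempty && !nzchar(trimws(x))) {
    return(c(problems, sprintf("%s must be non-empty", field)))
  }
  problems
}

need_count <- function(entity, field, problems) {
  x <- entity[[field]]
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) ||
      x < 1) {
    c(problems, sprintf("%s must be >=1", field))
  } else {
    problems
  }
}

need_inputs <- function(entity, problems) {
  x <- entity$input_node_ids
  if (!is.character(x) || length(x) < 1 || anyNA(x) || any(!nzchar(x))) {
    problems <- c(problems, "input_node_ids must list at least one node")
  } else if (!is.null(entity$node_id) && entity$node_id %in% x) {
    problems <- c(problems, "a node cannot take itself as input")
  }
  problems
}

#' @export
validate_entity.ems_user <- function(entity) {
  p <- need_string(entity, "display_name", character(), nonempty = TRUE)
  role <- entity$role
  if (!is_nonempty_string(role) || !role %in% c("admin", "regular")) {
    p <- c(p, "role must be 'admin' or 'regular'")
  }
  p
}

#' @export
validate_entity.ems_biological_condition <- function(entity) {
  p <- need_string(entity, "name", character(), nonempty = TRUE)
  for (f in c("title", "organism", "tissue", "cell_type", "variation")) {
    p <- need_string(entity, f, p)
  }
  ec <- entity$experimental_condition
  if (!is.null(ec)) {
    if (!is.list(ec) || is.null(names(ec)) ||
        !all(names(ec) %in% c("treatment", "dose", "time_point"))) {
      p <- c(p, paste0("experimental_condition may only contain treatment, ",
                       "dose and time_point"))
    }
  }
  p
}

#' @export
validate_entity.ems_experimental_batch <- function(entity) {
  need_string(entity, "label", character(), nonempty = TRUE)
}

#' @export
validate_entity.ems_biological_replicate <- function(entity) {
  p <- need_string(entity, "bc_id", character(), nonempty = TRUE)
  p <- need_count(entity, "replicate_number", p)
  if (!is.null(entity$batch_id)) {
    p <- need_string(entity, "batch_id", p, nonempty = TRUE)
  }
  p
}

#' @export
validate_entity.ems_analytical_sample <- function(entity) {
  p <- need_string(entity, "br_id", character(), nonempty = TRUE)
  p <- need_string(entity, "name", p, nonempty = TRUE)
  need_string(entity, "extraction_protocol", p)
}

#' @export
validate_entity.ems_raw_data <- function(entity) {
  p <- need_string(entity, "as_id", character(), nonempty = TRUE)
  p <- need_string(entity, "assay_tag", p, nonempty = TRUE)
  p <- need_string(entity, "protocol_details", p)
  need_string(entity, "file_pointer", p, nonempty = TRUE)
}

#' @export
validate_entity.ems_intermediate_step <- function(entity) {
  p <- need_inputs(entity, character())
  p <- need_string(entity, "step_kind", p, nonempty = TRUE)
  for (f in c("software", "parameters")) p <- need_string(entity, f, p)
  if (!is.null(entity$reference_resource)) {
    p <- need_string(entity, "reference_resource", p)
  }
  need_string(entity, "file_pointer", p, nonempty = TRUE)
}

#' @export
validate_entity.ems_processed_data <- function(entity) {
  p <- need_inputs(entity, character())
  p <- need_string(entity, "signal_description", p, nonempty = TRUE)
  need_string(entity, "file_pointer", p, nonempty = TRUE)
}

#' @export
validate_entity.ems_experiment <- function(entity) {
  p <- need_string(entity, "name", character(), nonempty = TRUE)
  for (f in c("description", "goals", "experiment_type")) {
    p <- need_string(entity, f, p)
  }
  p <- need_count(entity, "n_replicates_planned", p)
  pm <- entity$planned_measurements
  if (!is.list(pm)) {
    p <- c(p, "planned_measurements must be a list of (assay_tag, done)")
  } else {
    tags <- vapply(pm, function(m) {
      if (is.list(m) && is_nonempty_string(m$assay_tag) &&
          is.logical(m$done) && length(m$done) == 1) {
        m$assay_tag
      } else {
        NA_character_
      }
    }, character(1))
    if (anyNA(tags)) {
      p <- c(p, "each planned measurement needs an assay_tag and a done flag")
    } else if (anyDuplicated(norm_tag(tags))) {
      p <- c(p, "planned_measurements tags must be unique")
    }
  }
  if (!is.list(entity$attributes)) {
    p <- c(p, "attributes must be a named list")
  }
  p
}

#' @export
validate_entity.ems_analysis <- function(entity) {
  p <- character()
  if (!is_nonempty_string(entity$analysis_type)) {
    p <- c(p, "analysis_type must be a registered assay tag")
  }
  if (!is.character(entity$node_ids) || length(entity$node_ids) < 1) {
    p <- c(p, "an analysis must contain at least one node")
  }
  if (!is_nonempty_string(entity$processed_data_id)) {
    p <- c(p, "an analysis must reference exactly one processed-data node")
  } else if (is.character(entity$node_ids) &&
             !entity$processed_data_id %in% entity$node_ids) {
    p <- c(p, "processed_data_id must be one of the analysis nodes")
  }
  # >=1 experiment is required at finalization (enforced there); afterwards
  # dissociation down to zero must remain representable
  if (!is.character(entity$experiment_ids %||% character())) {
    p <- c(p, "experiment_ids must be a character vector")
  }
  p
}

#' @export
validate_entity.ems_draft <- function(entity) {
  p <- character()
  if (!is_nonempty_string(entity$analysis_type)) {
    p <- c(p, "analysis_type must be a registered assay tag")
  }
  if (!is_nonempty_string(entity$experiment_id)) {
    p <- c(p, "a draft must be assigned to an experiment")
  }
  if (!is.character(entity$node_ids)) {
    p <- c(p, "node_ids must be a character vector")
  }
  p
}
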