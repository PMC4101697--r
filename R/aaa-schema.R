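# Entity-kind schema: identifier prefixes, canonical field order, and which
# fields are references. This table is the single source of truth for
# identifier generation, tibble conversion, canonical serialization and the
# referential audit.

KIND_INFO <- list(
  user = list(
    prefix = "USR", id = "user_id",
    fields = c("user_id", "display_name", "role", "owner_id", "created_on")
  ),
  experiment = list(
    prefix = "EXP", id = "experiment_id",
    fields = c(
      "experiment_id", "name", "description", "goals", "experiment_type",
      "n_replicates_planned", "planned_measurements", "attributes",
      "member_ids", "sample_ids", "analysis_ids", "owner_id", "created_on"
    ),
    # membership sets: cleaned up when the member is deleted, do not RESTRICT
    soft_refs = c("member_ids", "sample_ids", "analysis_ids")
  ),
  biological_condition = list(
    prefix = "BC", id = "bc_id",
    fields = c(
      "bc_id", "name", "title", "organism", "tissue", "cell_type",
      "variation", "experimental_condition", "owner_id", "created_on"
    )
  ),
  experimental_batch = list(
    prefix = "BAT", id = "batch_id",
    fields = c("batch_id", "label", "owner_id", "created_on")
  ),
  biological_replicate = list(
    prefix = "BR", id = "br_id",
    fields = c(
      "br_id", "bc_id", "replicate_number", "batch_id", "owner_id",
      "created_on"
    ),
    hard_refs = c("bc_id", "batch_id")
  ),
  analytical_sample = list(
    prefix = "AS", id = "as_id",
    fields = c(
      "as_id", "br_id", "name", "extraction_protocol", "owner_id",
      "created_on"
    ),
    hard_refs = "br_id"
  ),
  raw_data = list(
    prefix = "RD", id = "node_id",
    fields = c(
      "node_id", "as_id", "assay_tag", "protocol_details", "file_pointer",
      "owner_id", "created_on"
    ),
    hard_refs = "as_id"
  ),
  intermediate_step = list(
    prefix = "IS", id = "node_id",
    fields = c(
      "node_id", "input_node_ids", "step_kind", "software", "parameters",
      "reference_resource", "file_pointer", "owner_id", "created_on"
    ),
    hard_refs = "input_node_ids"
  ),
  processed_data = list(
    prefix = "PD", id = "node_id",
    fields = c(
      "node_id", "input_node_ids", "signal_description", "file_pointer",
      "owner_id", "created_on"
    ),
    hard_refs = "input_node_ids"
  ),
  analysis = list(
    prefix = "AN", id = "analysis_id",
    fields = c(
      "analysis_id", "analysis_type", "node_ids", "processed_data_id",
      "experiment_ids", "owner_id", "created_on"
    ),
    hard_refs = c("node_ids", "processed_data_id", "experiment_ids")
  ),
  draft = list(
    prefix = "DRAFT", id = "draft_id",
    fields = c(
      "draft_id", "analysis_type", "experiment_id", "node_ids",
      "processed_data_id", "owner_id", "created_on"
    ),
    hard_refs = c("node_ids", "experiment_id", "processed_data_id")
  )
)

# every record also hard-references its owner
OWNER_REF_KINDS <- setdiff(names(KIND_INFO), "user")

ENTITY_KINDS <- names(KIND_INFO)

PREFIX_TO_KIND <- stats::setNames(
  names(KIND_INFO),
  vapply(KIND_INFO, function(k) k$prefix, character(1))
)

# fields holding multiple values; "set" fields are kept sorted, "ordered"
# fields preserve insertion order (workflow input order is meaningful)
SET_FIELDS <- c("member_ids", "sample_ids", "analysis_ids", "node_ids",
                "experiment_ids")
ORDERED_LIST_FIELDS <- c("input_node_ids")
INTEGER_FIELDS <- c("n_replicates_planned", "replicate_number")

kind_info <- function(kind) {
  info <- KIND_INFO[[kind]]
  if (is.null(info)) {
    abort_validation(sprintf(
      "unknown entity kind '%s'; known kinds: %s",
      kind, paste(ENTITY_KINDS, collapse = ", ")
    ))
  }
  info
}

id_field <- function(kind) kind_info(kind)$id

#' Entity kind encoded in an identifier
#'
#' Identifiers are self-describing: `BC-0001` is a biological condition,
#' `RD-0003` a raw-data node, and so on.
#'
#' @param id Character vector of identifiers.
#' @return Character vector of entity kinds (`NA` for unrecognized prefixes).
#' @export
#' @examples
#' kind_of_id(c("BC-0001", "AN-0002"))
kind_of_id <- function(id) {
  prefix <- sub("-.*$", "", id)
  unname(PREFIX_TO_KIND[prefix])
}

id_number <- function(id) {
  suppressWarnings(as.integer(sub("^[A-Z]+-", "", id)))
}

#' Generate the next identifier for an entity kind
#'
#' Identifiers are typed-prefix, zero-padded sequential strings
#' (`BC-0001`, `BR-0009`, ...). Counters are per-kind, monotonically
#' increasing, and never rewound: an identifier is never reused even after
#' the entity is deleted.
#'
#' @param registry An [ems_registry()].
#' @param kind One of the known entity kinds (see [entity_kinds()]).
#' @return A single identifier string.
#' @export
#' @examples
#' reg <- ems_registry()
#' new_identifier(reg, "biological_condition")
new_identifier <- function(registry, kind) {
  check_registry(registry)
  info <- kind_info(kind)
  n <- registry$counters[[kind]] + 1L
  registry$counters[[kind]] <- n
  sprintf("%s-%04d", info$prefix, n)
}

#' Known entity kinds
#'
#' @return Character vector of entity kind names with their identifier
#'   prefixes as names.
#' @export
entity_kinds <- function() {
  stats::setNames(names(KIND_INFO),
                  vapply(KIND_INFO, function(k) k$prefix, character(1)))
}
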