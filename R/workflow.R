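#' Analysis workflows
#'
#' An analysis is a provenance DAG describing how a processed signal file was
#' obtained: it starts at raw-data nodes measured from analytical samples (or
#' at processed-data results of earlier analyses, for secondary analyses such
#' as merging per-sample DNase hypersensitivity regions), passes through
#' zero or more intermediate steps (trimming, mapping, peak calling,
#' merging, ...) and ends in exactly one processed-data node. Workflows are
#' built step by step on a *draft*; [finalize_analysis()] checks the graph
#' invariants and turns the draft into an immutable analysis.
#'
#' Edges are never stored separately: they are derived from each node's
#' `input_node_ids`, so graph structure cannot desynchronize from the nodes.
#'
#' @name workflow
NULL

get_draft <- function(registry, draft_id) {
  rec <- reg_get(registry, draft_id, what = "analysis draft")
  if (entity_kind(rec) != "draft") {
    abort_validation(sprintf("%s is not an analysis draft", draft_id))
  }
  rec
}

#' Start a new analysis draft
#'
#' Creates an empty draft of the given analysis type, pre-assigned to the
#' currently active experiment. The tag is matched case-insensitively
#' against the registered assay types and stored canonically.
#'
#' @param registry An [ems_registry()].
#' @param analysis_type Assay tag (e.g. `"mRNA-seq"`).
#' @param experiment_id The active experiment the analysis will belong to.
#' @param acting Acting user id; becomes the draft owner.
#' @param created_on Creation date.
#' @return The draft identifier (`DRAFT-...`).
#' @export
start_analysis <- function(registry, analysis_type, experiment_id, acting,
                           created_on = Sys.Date()) {
  check_registry(registry)
  check_acting(registry, acting)
  reg_get(registry, experiment_id, what = "experiment")
  if (kind_of_id(experiment_id) != "experiment") {
    abort_validation("`experiment_id` must identify an experiment")
  }
  tag <- canonical_assay_tag(registry, analysis_type)
  id <- new_identifier(registry, "draft")
  draft <- new_entity("draft", list(
    draft_id = id, analysis_type = tag, experiment_id = experiment_id,
    node_ids = character(), owner_id = acting,
    created_on = as.Date(created_on)
  ))
  reg_insert(registry, draft, "draft")
  id
}

draft_append_node <- function(registry, draft, node_id) {
  draft$node_ids <- sort(unique(c(draft$node_ids, node_id)))
  reg_insert(registry, draft, "draft")
  node_id
}

check_inputs_in_draft <- function(draft, input_node_ids) {
  if (length(draft$node_ids) == 0) {
    abort_validation(paste0(
      "the draft is empty: a raw-data step (or imported steps) must come ",
      "first"
    ))
  }
  input_node_ids <- as.character(input_node_ids)
  if (length(input_node_ids) < 1) {
    abort_validation("at least one input node is required")
  }
  missing <- setdiff(input_node_ids, draft$node_ids)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "input node(s) not in the draft: %s (import or annotate them first)",
      paste(missing, collapse = ", ")
    ))
  }
  input_node_ids
}

persist_node <- function(registry, entity, kind, draft, acting, created_on) {
  assert_valid(entity, kind)
  entity <- canonicalize_entity_tags(registry, entity, kind)
  check_entity_refs(registry, entity, kind)
  id <- new_identifier(registry, kind)
  entity$node_id <- id
  entity$owner_id <- acting
  entity$created_on <- as.Date(created_on)
  reg_insert(registry, entity, kind)
  draft_append_node(registry, draft, id)
}

#' Annotate a raw-data step
#'
#' Adds a raw-data node measured from an existing analytical sample. On an
#' empty draft this (or [import_steps()]) is the only permitted first step.
#' The same analytical sample may feed several raw-data steps (multiple
#' sequencing runs), and a draft may hold several raw-data roots before a
#' merging step joins them.
#'
#' @param registry An [ems_registry()].
#' @param draft_id Draft to extend.
#' @param as_id Analytical sample the data was measured from.
#' @param assay_tag Registered assay tag.
#' @param file_pointer Path/URI of the raw data file (pointer only).
#' @param protocol_details Library preparation / instrument description.
#' @param acting Acting user id (owner or grantee of the draft).
#' @param created_on Creation date.
#' @return The new node identifier (`RD-...`).
#' @export
add_raw_step <- function(registry, draft_id, as_id, assay_tag, file_pointer,
                         protocol_details = "", acting,
                         created_on = Sys.Date()) {
  check_registry(registry)
  draft <- get_draft(registry, draft_id)
  require_edit(registry, acting, draft_id)
  if (!reg_exists(registry, as_id) ||
      kind_of_id(as_id) != "analytical_sample") {
    abort_not_found(sprintf("analytical sample '%s' not found", as_id))
  }
  node <- raw_data(as_id = as_id, assay_tag = assay_tag,
                   file_pointer = file_pointer,
                   protocol_details = protocol_details)
  persist_node(registry, node, "raw_data", draft, acting, created_on)
}

#' Annotate an intermediate processing step
#'
#' @inheritParams add_raw_step
#' @param input_node_ids Nodes already in the draft that this step consumes
#'   (length >= 1).
#' @param step_kind Free text: mapping, trimming, peak calling, merging, ...
#' @param software,parameters Processing description.
#' @param reference_resource Optional genome/annotation, e.g. `"GENCODE hg19"`.
#' @return The new node identifier (`IS-...`).
#' @export
add_intermediate_step <- function(registry, draft_id, input_node_ids,
                                  step_kind, file_pointer, software = "",
                                  parameters = "", reference_resource = NULL,
                                  acting, created_on = Sys.Date()) {
  check_registry(registry)
  draft <- get_draft(registry, draft_id)
  require_edit(registry, acting, draft_id)
  inputs <- check_inputs_in_draft(draft, input_node_ids)
  node <- intermediate_step(
    input_node_ids = inputs, step_kind = step_kind,
    file_pointer = file_pointer, software = software,
    parameters = parameters, reference_resource = reference_resource
  )
  persist_node(registry, node, "intermediate_step", draft, acting, created_on)
}

#' Annotate the processed-data step
#'
#' The final step of a workflow: the file holding the signal values of the
#' omics features (e.g. a Cufflinks gtf with FPKMs, a consolidated-region
#' count matrix). A draft may contain exactly one processed-data step; a
#' second one is rejected — start a new draft and [import_steps()] instead.
#'
#' @inheritParams add_intermediate_step
#' @param signal_description What the signal file contains.
#' @return The new node identifier (`PD-...`).
#' @export
add_processed_step <- function(registry, draft_id, input_node_ids,
                               signal_description, file_pointer, acting,
                               created_on = Sys.Date()) {
  check_registry(registry)
  draft <- get_draft(registry, draft_id)
  require_edit(registry, acting, draft_id)
  if (!is.null(draft$processed_data_id)) {
    abort_validation(paste0(
      "the draft already has a processed-data step (",
      draft$processed_data_id,
      "); an analysis is associated to exactly one processed data"
    ))
  }
  inputs <- check_inputs_in_draft(draft, input_node_ids)
  node <- processed_data(input_node_ids = inputs,
                         signal_description = signal_description,
                         file_pointer = file_pointer)
  assert_valid(node, "processed_data")
  check_entity_refs(registry, node, "processed_data")
  id <- new_identifier(registry, "processed_data")
  node$node_id <- id
  node$owner_id <- acting
  node$created_on <- as.Date(created_on)
  reg_insert(registry, node, "processed_data")
  draft$processed_data_id <- id
  draft$node_ids <- sort(unique(c(draft$node_ids, id)))
  reg_insert(registry, draft, "draft")
  id
}

# processed-data id -> analysis id that claims it as sink
sink_owner_map <- function(registry) {
  out <- list()
  for (an in registry$tables$analysis) {
    out[[an$processed_data_id]] <- c(out[[an$processed_data_id]],
                                     an$analysis_id)
  }
  out
}

#' Reuse steps of a completed analysis
#'
#' A completed analysis can be partially reused to build additional
#' workflows. Two forms are supported:
#'
#' * *Prefix import*: an ancestor-closed set of the source's raw/intermediate
#'   nodes (every ancestor of every member must be included), e.g. the
#'   raw-data and mapping steps of an RNA-seq analysis, to be continued
#'   toward a different processed result.
#' * *Secondary-analysis root*: exactly the source's processed-data node,
#'   used as a root of a higher-level workflow (e.g. merging per-sample DHR
#'   bed files).
#'
#' Nodes are shared by reference — the same node identifiers appear in both
#' analyses, nothing is copied, and ownership of the shared nodes is
#' unchanged. The RESTRICT deletion policy keeps shared steps safe.
#'
#' @param registry An [ems_registry()].
#' @param draft_id Destination draft.
#' @param source_analysis_id A finalized analysis.
#' @param node_ids Members of the source analysis to share.
#' @param acting Acting user id (owner or grantee of the draft).
#' @return The updated draft record, invisibly.
#' @export
import_steps <- function(registry, draft_id, source_analysis_id, node_ids,
                         acting) {
  check_registry(registry)
  draft <- get_draft(registry, draft_id)
  require_edit(registry, acting, draft_id)
  src <- reg_get(registry, source_analysis_id, what = "source analysis")
  if (entity_kind(src) != "analysis") {
    abort_validation(sprintf("%s is not a finalized analysis",
                             source_analysis_id))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) < 1) {
    abort_validation("select at least one node to import")
  }
  outside <- setdiff(node_ids, src$node_ids)
  if (length(outside) > 0) {
    abort_not_found(sprintf(
      "node(s) not in %s: %s", source_analysis_id,
      paste(outside, collapse = ", ")
    ))
  }
  if (src$processed_data_id %in% node_ids) {
    if (length(node_ids) != 1) {
      abort_validation(paste0(
        "the source's processed data may only be imported alone, as the ",
        "root of a secondary analysis"
      ))
    }
  } else {
    # ancestor closure within the source graph
    missing <- character()
    for (n in node_ids) {
      anc <- node_ancestors(registry, n, within = src$node_ids)
      missing <- c(missing, setdiff(anc, node_ids))
    }
    missing <- sort(unique(missing))
    if (length(missing) > 0) {
      abort_validation(sprintf(
        "import set is not ancestor-closed; missing ancestor(s): %s",
        paste(missing, collapse = ", ")
      ))
    }
  }
  draft$node_ids <- sort(unique(c(draft$node_ids, node_ids)))
  reg_insert(registry, draft, "draft")
  invisible(registry$tables$draft[[draft_id]])
}

# ancestors of node_id following input edges, restricted to `within`
node_ancestors <- function(registry, node_id, within) {
  seen <- character()
  frontier <- node_id
  while (length(frontier) > 0) {
    nxt <- character()
    for (n in frontier) {
      rec <- reg_get(registry, n)
      ins <- intersect(rec$input_node_ids %||% character(), within)
      nxt <- c(nxt, setdiff(ins, seen))
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setdiff(sort(unique(seen)), node_id)
}

#' Validate a workflow graph
#'
#' Checks the structural invariants every finalized analysis must satisfy:
#' the graph (edges derived from `inputs`, restricted to the listed nodes)
#' is acyclic and weakly connected; every root (in-degree 0) is a raw-data
#' node or a permitted foreign processed-data root; and there is exactly one
#' sink (out-degree 0), a processed-data node.
#'
#' This validator is independent of any draft bookkeeping; it is what
#' [finalize_analysis()] runs on the draft's induced subgraph.
#'
#' @param nodes A tibble (or data.frame) with columns `id` (character),
#'   `kind` (`"raw_data"`, `"intermediate_step"`, `"processed_data"`) and
#'   `inputs` (list of character vectors).
#' @param foreign_roots Identifiers of processed-data nodes allowed to act
#'   as roots (results of other analyses).
#' @return Character vector of violations; empty when the graph is valid.
#' @export
validate_workflow_graph <- function(nodes, foreign_roots = character()) {
  problems <- character()
  if (nrow(nodes) == 0) {
    return("the workflow is empty: no processed data")
  }
  ids <- nodes$id
  if (anyDuplicated(ids)) {
    problems <- c(problems, "duplicate node identifiers")
    return(problems)
  }
  edges <- purrr::map2(nodes$inputs, ids, function(ins, id) {
    ins <- intersect(as.character(ins), ids)
    if (length(ins) == 0) return(NULL)
    data.frame(from = ins, to = id, stringsAsFactors = FALSE)
  })
  edges <- dplyr::bind_rows(edges)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0) edges else data.frame(from = character(),
                                               to = character()),
    directed = TRUE,
    vertices = data.frame(name = ids)
  )
  if (!igraph::is_dag(g)) {
    problems <- c(problems, "the workflow contains a cycle")
  }
  if (igraph::count_components(g, mode = "weak") > 1) {
    comp <- igraph::components(g, mode = "weak")
    main <- which.max(comp$csize)
    orphans <- names(comp$membership)[comp$membership != main]
    problems <- c(problems, sprintf(
      "the workflow is disconnected; orphan node(s): %s",
      paste(sort(orphans), collapse = ", ")
    ))
  }
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  kinds <- stats::setNames(nodes$kind, ids)
  roots <- ids[indeg[ids] == 0]
  for (r in roots) {
    ok <- kinds[[r]] == "raw_data" ||
      (kinds[[r]] == "processed_data" && r %in% foreign_roots)
    if (!ok) {
      problems <- c(problems, sprintf(
        "root %s must be raw data or a foreign processed-data result", r
      ))
    }
  }
  sinks <- ids[outdeg[ids] == 0]
  if (length(sinks) != 1) {
    problems <- c(problems, sprintf(
      "the workflow must have exactly one final node, found %d (%s)",
      length(sinks), paste(sort(sinks), collapse = ", ")
    ))
  } else if (kinds[[sinks]] != "processed_data") {
    problems <- c(problems, sprintf(
      "the final node %s must be a processed-data step", sinks
    ))
  }
  problems
}

draft_graph_tbl <- function(registry, member_ids) {
  recs <- lapply(member_ids, function(n) reg_get(registry, n))
  tibble::tibble(
    id = vapply(recs, function(r) r$node_id, character(1)),
    kind = vapply(recs, entity_kind, character(1)),
    inputs = lapply(recs, function(r) r$input_node_ids %||% character())
  )
}

#' Finalize a draft into an immutable analysis
#'
#' Verifies the workflow invariants on the draft's graph — exactly one
#' processed-data sink, acyclicity, weak connectivity, roots that are raw
#' data or processed-data results of other finalized analyses — and, when
#' they hold, persists an immutable analysis associated to at least one
#' experiment. Experiment progress flags are updated through the
#' association. Every violated invariant is reported by name.
#'
#' @param registry An [ems_registry()].
#' @param draft_id Draft to finalize.
#' @param acting Acting user id; must be able to edit the draft and the
#'   target experiments.
#' @param experiment_ids Experiments to associate; defaults to the draft's
#'   pre-assigned experiment.
#' @param created_on Creation date of the analysis record.
#' @return The new analysis identifier (`AN-...`).
#' @export
finalize_analysis <- function(registry, draft_id, acting,
                              experiment_ids = NULL,
                              created_on = Sys.Date()) {
  check_registry(registry)
  draft <- get_draft(registry, draft_id)
  require_edit(registry, acting, draft_id)
  if (is.null(experiment_ids)) experiment_ids <- draft$experiment_id
  experiment_ids <- sort(unique(as.character(experiment_ids)))
  if (length(experiment_ids) < 1) {
    abort_validation("an analysis must be associated to >=1 experiment")
  }
  for (eid in experiment_ids) {
    reg_get(registry, eid, what = "experiment")
    require_edit(registry, acting, eid)
  }
  if (is.null(draft$processed_data_id)) {
    abort_validation("the draft has no processed-data step; cannot finalize")
  }
  sinks <- sink_owner_map(registry)
  member_pds <- draft$node_ids[kind_of_id(draft$node_ids) == "processed_data"]
  foreign <- setdiff(member_pds, draft$processed_data_id)
  not_foreign <- foreign[vapply(foreign, function(pd) {
    is.null(sinks[[pd]])
  }, logical(1))]
  if (length(not_foreign) > 0) {
    abort_validation(sprintf(
      "processed-data node(s) %s belong to no finalized analysis and are not
 this draft's result",
      paste(not_foreign, collapse = ", ")
    ))
  }
  tbl <- draft_graph_tbl(registry, draft$node_ids)
  violations <- validate_workflow_graph(tbl, foreign_roots = foreign)
  if (length(violations) > 0) {
    abort_validation(
      paste0("cannot finalize: ", paste(violations, collapse = "; ")),
      report = violations
    )
  }
  id <- new_identifier(registry, "analysis")
  an <- new_entity("analysis", list(
    analysis_id = id, analysis_type = draft$analysis_type,
    node_ids = sort(draft$node_ids),
    processed_data_id = draft$processed_data_id,
    experiment_ids = experiment_ids, owner_id = acting,
    created_on = as.Date(created_on)
  ))
  reg_insert(registry, an, "analysis")
  reg_drop(registry, draft_id)
  for (eid in experiment_ids) {
    exp <- registry$tables$experiment[[eid]]
    exp$analysis_ids <- sort(unique(c(exp$analysis_ids, id)))
    reg_put(registry, exp)
    recompute_progress(registry, eid)
  }
  id
}

#' Trace an analysis back to its analytical samples
#'
#' Walks the workflow's input edges backwards from the processed-data sink
#' to the raw-data roots and reports the analytical samples they were
#' measured from, together with their replicate/condition ancestry. For
#' secondary analyses rooted in foreign processed-data nodes, tracing
#' continues transitively into the source analyses, so the lineage of a
#' merge analysis is the union of the lineages of the analyses it reuses.
#'
#' @param registry An [ems_registry()].
#' @param analysis_id A finalized analysis.
#' @return A tibble, ordered by `as_id`, with columns `as_id`,
#'   `sample_name`, `br_id`, `replicate_number`, `bc_id`, `condition_name`.
#' @export
trace_to_samples <- function(registry, analysis_id) {
  check_registry(registry)
  an <- reg_get(registry, analysis_id, what = "analysis")
  if (entity_kind(an) != "analysis") {
    abort_validation(sprintf("%s is not a finalized analysis", analysis_id))
  }
  sinks <- sink_owner_map(registry)
  as_ids <- character()
  visited <- character()
  walk <- function(aid) {
    if (aid %in% visited) return(invisible(NULL))
    visited <<- c(visited, aid)
    a <- registry$tables$analysis[[aid]]
    for (n in a$node_ids) {
      kind <- kind_of_id(n)
      if (kind == "raw_data") {
        as_ids <<- c(as_ids, registry$tables$raw_data[[n]]$as_id)
      } else if (kind == "processed_data" && n != a$processed_data_id) {
        for (owner in sinks[[n]] %||% character()) {
          if (owner != aid) walk(owner)
        }
      }
    }
  }
  walk(analysis_id)
  as_ids <- sort(unique(as_ids))
  rows <- lapply(as_ids, function(s) {
    smp <- registry$tables$analytical_sample[[s]]
    br <- registry$tables$biological_replicate[[smp$br_id]]
    bc <- registry$tables$biological_condition[[br$bc_id]]
    tibble::tibble(
      as_id = s, sample_name = smp$name, br_id = br$br_id,
      replicate_number = br$replicate_number, bc_id = bc$bc_id,
      condition_name = bc$name
    )
  })
  if (length(rows) == 0) {
    tibble::tibble(
      as_id = character(), sample_name = character(), br_id = character(),
      replicate_number = integer(), bc_id = character(),
      condition_name = character()
    )
  } else {
    dplyr::bind_rows(rows)
  }
}

NODE_SHAPES <- c(raw_data = "ellipse", intermediate_step = "box",
                 processed_data = "hexagon")

node_label <- function(rec) {
  kind <- entity_kind(rec)
  detail <- switch(kind,
    raw_data = paste0("raw: ", rec$assay_tag),
    intermediate_step = rec$step_kind,
    processed_data = rec$signal_description
  )
  paste0(rec$node_id, "\\n", gsub("\"", "'", detail))
}

#' Render a workflow graph
#'
#' Deterministic serialization of an analysis (or draft) workflow: nodes
#' sorted by identifier with type-specific shapes and labels, edges as
#' input -> consumer. `"dot"` produces Graphviz DOT text; `"json"` produces
#' the canonical interchange-style node/edge document. Rendering the same
#' graph twice yields byte-identical output.
#'
#' @param registry An [ems_registry()].
#' @param id A finalized analysis (`AN-...`) or draft (`DRAFT-...`) id.
#' @param format `"dot"` or `"json"`.
#' @return A single string.
#' @export
render_graph <- function(registry, id, format = "dot") {
  check_registry(registry)
  if (!is_nonempty_string(format) || !format %in% c("dot", "json")) {
    abort_validation("`format` must be \"dot\" or \"json\"")
  }
  rec <- reg_get(registry, id, what = "analysis")
  kind <- entity_kind(rec)
  if (!kind %in% c("analysis", "draft")) {
    abort_validation(sprintf("%s is not an analysis or draft", id))
  }
  members <- sort(rec$node_ids)
  recs <- lapply(members, function(n) reg_get(registry, n))
  names(recs) <- members
  edges <- list()
  for (r in recs) {
    for (input in intersect(r$input_node_ids %||% character(), members)) {
      edges[[length(edges) + 1]] <- c(from = input, to = r$node_id)
    }
  }
  edge_tbl <- if (length(edges) > 0) {
    e <- dplyr::bind_rows(lapply(edges, as.list))
    dplyr::arrange(e, .data$from, .data$to)
  } else {
    tibble::tibble(from = character(), to = character())
  }
  if (format == "dot") {
    lines <- c(
      sprintf("digraph \"%s\" {", id),
      "  rankdir=LR;",
      vapply(recs, function(r) {
        sprintf("  \"%s\" [label=\"%s\", shape=%s];",
                r$node_id, node_label(r),
                NODE_SHAPES[[entity_kind(r)]])
      }, character(1)),
      if (nrow(edge_tbl) > 0) {
        sprintf("  \"%s\" -> \"%s\";", edge_tbl$from, edge_tbl$to)
      },
      "}"
    )
    paste(lines, collapse = "\n")
  } else {
    doc <- list(
      id = jsonlite::unbox(id),
      nodes = lapply(recs, function(r) {
        list(
          id = jsonlite::unbox(r$node_id),
          kind = jsonlite::unbox(entity_kind(r)),
          label = jsonlite::unbox(sub(".*\\\\n", "", node_label(r)))
        )
      }),
      edges = unname(apply(edge_tbl, 1, function(e) {
        list(from = jsonlite::unbox(unname(e["from"])),
             to = jsonlite::unbox(unname(e["to"])))
      }))
    )
    names(doc$nodes) <- NULL
    as.character(jsonlite::toJSON(doc, pretty = TRUE, digits = NA))
  }
}
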