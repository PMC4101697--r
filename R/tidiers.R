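#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a registry into an entity-count table
#'
#' @param x An [ems_registry()].
#' @param ... Unused.
#' @return A tibble with columns `kind` and `n`.
#' @export
tidy.ems_registry <- function(x, ...) {
  tibble::tibble(
    kind = ENTITY_KINDS,
    n = unname(vapply(x$tables, length, integer(1)))
  )
}

#' One-row summary of a registry
#'
#' @param x An [ems_registry()].
#' @param ... Unused.
#' @return A one-row tibble: schema version, entity/user/analysis/grant
#'   counts, and whether the global audit is clean.
#' @export
glance.ems_registry <- function(x, ...) {
  tibble::tibble(
    schema_version = x$schema_version,
    n_entities = sum(vapply(x$tables, length, integer(1))),
    n_users = length(x$tables$user),
    n_analyses = length(x$tables$analysis),
    n_grants = sum(vapply(x$grants, length, integer(1))),
    audit_clean = nrow(ems_audit(x)) == 0
  )
}

#' Tidy an analysis into its node table
#'
#' @param x An analysis record, e.g. `ems_get(reg, "AN-0001")`.
#' @param registry The registry holding the analysis; defaults to the one
#'   the record was fetched from.
#' @param ... Unused.
#' @return A tibble with one row per workflow node: `node_id`, `kind`,
#'   `detail` (assay tag / step kind / signal description), `file_pointer`
#'   and `inputs` (list-column).
#' @export
tidy.ems_analysis <- function(x, registry = attr(x, "registry"), ...) {
  check_registry(registry)
  nodes <- sort(x$node_ids)
  recs <- lapply(nodes, function(n) reg_get(registry, n))
  tibble::tibble(
    node_id = nodes,
    kind = vapply(recs, entity_kind, character(1)),
    detail = vapply(recs, function(r) {
      switch(entity_kind(r),
             raw_data = r$assay_tag,
             intermediate_step = r$step_kind,
             processed_data = r$signal_description)
    }, character(1)),
    file_pointer = vapply(recs, function(r) r$file_pointer, character(1)),
    inputs = lapply(recs, function(r) r$input_node_ids %||% character())
  )
}

#' @rdname tidy.ems_analysis
#' @export
glance.ems_analysis <- function(x, registry = attr(x, "registry"), ...) {
  check_registry(registry)
  lineage <- trace_to_samples(registry, x$analysis_id)
  kinds <- kind_of_id(x$node_ids)
  tibble::tibble(
    analysis_id = x$analysis_id,
    analysis_type = x$analysis_type,
    n_nodes = length(x$node_ids),
    n_raw = sum(kinds == "raw_data"),
    n_intermediate = sum(kinds == "intermediate_step"),
    n_processed = sum(kinds == "processed_data"),
    n_samples = nrow(lineage),
    n_experiments = length(x$experiment_ids)
  )
}

#' Plot an analysis workflow
#'
#' Draws the provenance DAG of an analysis (or draft) with a layered
#' left-to-right layout: raw data and foreign roots on the left, the
#' processed-data sink on the right.
#'
#' @param registry An [ems_registry()].
#' @param id Analysis or draft identifier.
#' @return A ggplot object.
#' @export
plot_workflow <- function(registry, id) {
  check_registry(registry)
  rec <- reg_get(registry, id)
  members <- sort(rec$node_ids)
  recs <- lapply(members, function(n) reg_get(registry, n))
  names(recs) <- members
  edges <- dplyr::bind_rows(lapply(recs, function(r) {
    ins <- intersect(r$input_node_ids %||% character(), members)
    if (length(ins) == 0) return(NULL)
    tibble::tibble(from = ins, to = r$node_id)
  }))
  g <- igraph::graph_from_data_frame(
    if (nrow(edges %||% tibble::tibble()) > 0) edges else
      tibble::tibble(from = character(), to = character()),
    directed = TRUE, vertices = data.frame(name = members)
  )
  lay <- igraph::layout_with_sugiyama(g)$layout
  nodes <- tibble::tibble(
    node_id = members,
    # sugiyama layers top-down; rotate to left-right
    x = -lay[, 2], y = lay[, 1],
    kind = vapply(recs, entity_kind, character(1)),
    label = vapply(recs, function(r) sub("\\\\n", "\n", node_label(r)),
                   character(1))
  )
  seg <- if (nrow(edges %||% tibble::tibble()) > 0) {
    dplyr::left_join(edges, nodes[, c("node_id", "x", "y")],
                     by = c(from = "node_id")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(nodes[, c("node_id", "x", "y")],
                       by = c(to = "node_id"))
  } else {
    NULL
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm")),
      colour = "grey40"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kind), size = 10,
                        alpha = 0.85) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.8,
                       vjust = -1.6) +
    ggplot2::scale_colour_manual(values = c(
      raw_data = "#66c2a5", intermediate_step = "#8da0cb",
      processed_data = "#fc8d62"
    )) +
    ggplot2::labs(title = id, colour = "node type") +
    ggplot2::theme_void()
}

#' @rdname plot_workflow
#' @param object An analysis record fetched with [ems_get()].
#' @param ... Unused.
#' @export
autoplot.ems_analysis <- function(object, registry = attr(object, "registry"),
                                  ...) {
  plot_workflow(registry, object$analysis_id)
}
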