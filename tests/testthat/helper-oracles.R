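# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms than the package code
# (matrix transitive closure instead of igraph, global backward BFS instead
# of membership recursion, from-scratch flag scans).

# brute-force workflow-graph verdict: TRUE iff the graph satisfies all
# invariants (acyclic, weakly connected, typed roots, one processed sink)
oracle_graph_valid <- function(nodes, foreign_roots = character()) {
  n <- nrow(nodes)
  if (n == 0) return(FALSE)
  ids <- nodes$id
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (inp in intersect(as.character(nodes$inputs[[i]]), ids)) {
      adj[inp, ids[[i]]] <- TRUE
    }
  }
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | ((reach %*% adj) > 0)
  }
  if (any(diag(reach))) return(FALSE)
  und <- adj | t(adj)
  seen <- 1L
  frontier <- 1L
  while (length(frontier) > 0) {
    nb <- which(apply(und[frontier, , drop = FALSE], 2, any))
    frontier <- setdiff(nb, seen)
    seen <- union(seen, frontier)
  }
  if (length(seen) < n) return(FALSE)
  indeg <- colSums(adj)
  outdeg <- rowSums(adj)
  roots <- ids[indeg == 0]
  for (r in roots) {
    k <- nodes$kind[ids == r]
    if (!(k == "raw_data" ||
          (k == "processed_data" && r %in% foreign_roots))) {
      return(FALSE)
    }
  }
  sinks <- ids[outdeg == 0]
  length(sinks) == 1 && nodes$kind[ids == sinks] == "processed_data"
}

# random graph case for the validator-equivalence property: half the draws
# are layered (mostly valid) DAG attempts, half fully random (cycles, loose
# parts, bad roots/sinks)
random_graph_case <- function() {
  n <- sample(1:8, 1)
  ids <- sprintf("N%d", seq_len(n))
  kinds <- sample(c("raw_data", "intermediate_step", "processed_data"),
                  n, replace = TRUE)
  inputs <- vector("list", n)
  if (stats::runif(1) < 0.5) {
    for (i in seq_len(n)) {
      inputs[[i]] <- if (i > 1 && kinds[[i]] != "raw_data") {
        k <- sample(0:min(3, i - 1), 1)
        sample(ids[seq_len(i - 1)], k)
      } else {
        character()
      }
    }
  } else {
    for (i in seq_len(n)) {
      inputs[[i]] <- sample(ids, sample(0:min(3, n), 1))
    }
  }
  list(
    nodes = tibble::tibble(id = ids, kind = kinds, inputs = inputs),
    foreign = sample(ids, sample(0:n, 1))
  )
}

# lineage oracle: global backward BFS over stored input edges from the
# analysis sink, independent of analysis membership bookkeeping
oracle_lineage <- function(reg, analysis_id) {
  an <- ems_get(reg, analysis_id)
  frontier <- an$processed_data_id
  seen <- character()
  as_ids <- character()
  while (length(frontier) > 0) {
    n <- frontier[[1]]
    frontier <- frontier[-1]
    if (n %in% seen) next
    seen <- c(seen, n)
    rec <- ems_get(reg, n)
    if (kind_of_id(n) == "raw_data") as_ids <- c(as_ids, rec$as_id)
    ins <- rec$input_node_ids
    if (!is.null(ins)) frontier <- c(frontier, ins)
  }
  sort(unique(as_ids))
}

# progress-flag oracle: recompute every done flag from scratch by scanning
# the associated analyses
oracle_flags <- function(reg, experiment_id) {
  exp <- ems_get(reg, experiment_id)
  types <- vapply(exp$analysis_ids, function(a) {
    tolower(ems_get(reg, a)$analysis_type)
  }, character(1))
  vapply(exp$planned_measurements, function(m) {
    tolower(m$assay_tag) %in% types
  }, logical(1))
}

stored_flags <- function(reg, experiment_id) {
  exp <- ems_get(reg, experiment_id)
  vapply(exp$planned_measurements, function(m) m$done, logical(1))
}
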