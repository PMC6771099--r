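#' Build the directed cross-border flow network
#'
#' Every displacement from a residence municipality to a different
#' hospitalization municipality is a directed edge weighted by the number
#' of patients who moved. Self-flows (treatment in the residence
#' municipality) are not edges; they are kept as the `self_flow` node
#' attribute so no information is lost. Each node also carries its
#' `resident_total` (row sum) and `hospitalized_total` (column sum).
#'
#' @param od An [od_matrix()].
#' @return A directed weighted [igraph][igraph::graph_from_data_frame]
#'   graph over all units of the matrix (units without cross-border flows
#'   are isolated nodes).
#' @export
build_flow_graph <- function(od) {
  stopifnot(inherits(od, "od_matrix"))
  counts <- od$counts
  off <- counts
  diag(off) <- 0L
  idx <- which(off > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = od$unit_ids[idx[, 1]],
    to = od$unit_ids[idx[, 2]],
    weight = off[idx]
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  vertices <- data.frame(
    name = od$unit_ids,
    self_flow = diag(counts),
    resident_total = rowSums(counts),
    hospitalized_total = colSums(counts)
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Node in- and out-strengths
#'
#' @param g Flow graph from [build_flow_graph()].
#' @return Data frame with `unit_id`, `in_strength` (patients received
#'   from other units) and `out_strength` (patients sent out).
#' @export
node_strengths <- function(g) {
  data.frame(
    unit_id = igraph::V(g)$name,
    in_strength = igraph::strength(g, mode = "in"),
    out_strength = igraph::strength(g, mode = "out"),
    row.names = NULL
  )
}

#' Identify attraction hubs
#'
#' Ranks nodes by in-strength (patients attracted from other units), ties
#' broken lexicographically by unit id, and returns the top `k`.
#'
#' @param g Flow graph.
#' @param k Number of hubs requested (truncated to the node count).
#' @return Character vector of unit ids, strongest attractor first.
#' @export
identify_hubs <- function(g, k = 1L) {
  stopifnot(k >= 1)
  s <- node_strengths(g)
  s <- s[order(-s$in_strength, s$unit_id), , drop = FALSE]
  head(s$unit_id, min(k, nrow(s)))
}

#' Remove a node and its incident flows
#'
#' Excluding the dominant hub and re-examining the remaining structure
#' exposes the peripheral sub-networks its gravity otherwise hides.
#'
#' @param g Flow graph.
#' @param unit Unit id to remove.
#' @return The flow graph without `unit` and its incident edges.
#' @export
remove_node_subnetwork <- function(g, unit) {
  if (!unit %in% igraph::V(g)$name) {
    stop("remove_node_subnetwork: unknown unit: ", unit, call. = FALSE)
  }
  igraph::delete_vertices(g, unit)
}

#' Weakly connected components
#'
#' Components with edge direction ignored, largest first: the natural
#' notion for asking which municipalities still exchange patients at all
#' once a hub is excluded.
#'
#' @param g Flow graph.
#' @return List of character vectors of unit ids, sorted by size
#'   (decreasing), ties by smallest member id.
#' @export
weak_components <- function(g) {
  comp <- igraph::components(g, mode = "weak")
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- lapply(groups, sort)
  first <- vapply(groups, `[`, character(1), 1L)
  groups <- groups[order(-lengths(groups), first)]
  names(groups) <- NULL
  groups
}

#' Per-origin destination entropy
#'
#' Shannon entropy of each origin's destination distribution,
#' `H_i = -sum_j p_j ln p_j` with `p_j` the share of origin i's cases
#' hospitalized in j. Low entropy means residents concentrate on a single
#' destination (well-ordered flows); high entropy means dispersal over
#' many destinations. With `normalize = TRUE` (default) the value is
#' divided by `ln(m)`, m the number of destinations actually used, giving
#' a 0-1 index (0 when m = 1). `include_self` controls whether treatment
#' in the residence municipality counts as a destination.
#'
#' The exact normalization conventions differ across the literature, so
#' absolute values are only comparable within one choice of flags.
#'
#' @param od An [od_matrix()].
#' @param include_self Count the origin itself as a destination (default
#'   `TRUE`).
#' @param normalize Divide by the maximum attainable entropy (default
#'   `TRUE`).
#' @return Named numeric vector, one value per origin; `NA` for origins
#'   with no cases.
#' @export
origin_entropy <- function(od, include_self = TRUE, normalize = TRUE) {
  stopifnot(inherits(od, "od_matrix"))
  counts <- od$counts
  if (!include_self) diag(counts) <- 0
  vapply(seq_along(od$unit_ids), function(i) {
    row <- counts[i, ]
    tot <- sum(row)
    if (tot == 0) return(NA_real_)
    p <- row[row > 0] / tot
    h <- -sum(p * log(p))
    if (normalize) {
      if (length(p) <= 1L) 0 else h / log(length(p))
    } else {
      h
    }
  }, numeric(1), USE.NAMES = FALSE) |> setNames(od$unit_ids)
}

#' Export a flow graph
#'
#' Writes the edge list as CSV (`origin`, `destination`, `weight`) and,
#' optionally, the full graph as GraphML and the per-node metrics
#' (strengths plus self-flow) as CSV.
#'
#' @param g Flow graph.
#' @param edges_csv Path for the edge-list CSV.
#' @param graphml Optional path for a GraphML export.
#' @param nodes_csv Optional path for the per-node metrics CSV.
#' @return `edges_csv`, invisibly.
#' @export
write_flow_graph <- function(g, edges_csv, graphml = NULL, nodes_csv = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("origin", "destination", "weight")
  write.csv(el, edges_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(nodes_csv)) {
    nm <- node_strengths(g)
    nm$self_flow <- igraph::V(g)$self_flow
    write.csv(nm, nodes_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(edges_csv)
}
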