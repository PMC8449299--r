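#' Build the HCW collaboration graph from co-session counts
#'
#' Edge weight between two HCWs is the number of concurrent sessions they
#' share, i.e. the off-diagonal of `hcw_session %*% t(hcw_session)` for the
#' 0/1 HCW-by-session participation matrix. Each session involves at least
#' two HCWs, so every session contributes at least one edge. Optional node
#' attributes (specialty, role, and `prop_time` — the proportion of EHR time
#' spent concurrently, used as node size when visualizing) are attached when
#' metadata is supplied.
#'
#' @param hcw_session Sparse 0/1 HCW-by-session matrix (see
#'   [build_matrices()]).
#' @param hcw_meta Optional tibble with `hcw_id`, `specialty`, `role`.
#' @param node_size Optional tibble with `hcw_id` and `prop_time` (e.g. from
#'   per-HCW means of [compute_intensity()] records).
#' @return An undirected `igraph` graph with edge attribute `weight`
#'   (integer co-session count, >= 1) and no self-loops.
#' @export
build_graph <- function(hcw_session, hcw_meta = NULL, node_size = NULL) {
  w <- Matrix::tcrossprod(hcw_session)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(hcw_meta)) {
    m <- match(igraph::V(g)$name, hcw_meta$hcw_id)
    igraph::V(g)$specialty <- ifelse(is.na(m), NA_character_,
                                     hcw_meta$specialty[m])
    role <- ifelse(is.na(m), "unknown", hcw_meta$role[m])
    role[is.na(role)] <- "unknown"
    igraph::V(g)$role <- role
  }
  if (!is.null(node_size)) {
    m <- match(igraph::V(g)$name, node_size$hcw_id)
    igraph::V(g)$prop_time <- node_size$prop_time[m]
  }
  g
}

#' Extract the k-core of a collaboration graph
#'
#' The k-core is the maximal subgraph in which every HCW is connected to at
#' least `k` other HCWs within the subgraph (plain degree; edge weights are
#' ignored). It isolates the densely collaborating core of the network and
#' may be empty.
#'
#' @param graph An `igraph` graph.
#' @param k Degree threshold (>= 1).
#' @return The induced subgraph on vertices with coreness >= `k`.
#' @export
k_core <- function(graph, k) {
  stopifnot(k >= 1)
  keep <- igraph::coreness(graph) >= k
  igraph::induced_subgraph(graph, which(keep))
}

#' Aggregate an HCW graph to role-level relationships
#'
#' Sums HCW-level co-session edge weights into unordered role pairs
#' (including within-role self-pairs), so total role-pair weight exactly
#' equals total HCW edge weight. HCWs without a role mapping count as
#' `"unknown"`.
#'
#' @param graph HCW graph from [build_graph()].
#' @param hcw_meta Tibble with `hcw_id`, `role`.
#' @return Tibble `role_a`, `role_b` (alphabetical within pair), `weight`.
#' @export
aggregate_roles <- function(graph, hcw_meta) {
  if (igraph::ecount(graph) == 0) {
    return(tibble::tibble(role_a = character(), role_b = character(),
                          weight = numeric()))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  m <- match(el$from, hcw_meta$hcw_id)
  ra <- ifelse(is.na(m), "unknown", hcw_meta$role[m])
  m <- match(el$to, hcw_meta$hcw_id)
  rb <- ifelse(is.na(m), "unknown", hcw_meta$role[m])
  pairs <- tibble::tibble(role_a = pmin(ra, rb), role_b = pmax(ra, rb),
                          weight = el$weight)
  out <- dplyr::summarise(
    dplyr::group_by(pairs, .data$role_a, .data$role_b),
    weight = sum(.data$weight), .groups = "drop")
  dplyr::arrange(out, .data$role_a, .data$role_b)
}

#' Label role pairs as high- or low-likelihood collaborations
#'
#' Sorts role pairs by aggregate co-session weight and labels the top
#' `n_top` as high-likelihood and the bottom `n_bottom` as low-likelihood
#' collaborative relationships — the two groups whose distinguishability is
#' then checked against expert survey scores. Within-role self-pairs are
#' excluded by default (8 roles then give 28 candidate pairs). Ties are
#' broken lexicographically by role names, so the labeling is deterministic.
#'
#' @param role_graph Tibble from [aggregate_roles()].
#' @param n_top,n_bottom Number of pairs to label high/low (default 6 each).
#' @param include_self Keep within-role pairs? Default `FALSE`.
#' @return Tibble `role_a`, `role_b`, `weight`, `likelihood`
#'   (`"high"`/`"low"`), `rank`; only labeled pairs are returned.
#' @export
rank_relationships <- function(role_graph, n_top = 6, n_bottom = 6,
                               include_self = FALSE) {
  pairs <- role_graph
  if (!include_self) {
    pairs <- pairs[pairs$role_a != pairs$role_b, , drop = FALSE]
  }
  if (nrow(pairs) < n_top + n_bottom) {
    stop("need at least ", n_top + n_bottom, " distinct role pairs, have ",
         nrow(pairs), call. = FALSE)
  }
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$weight),
                          .data$role_a, .data$role_b)
  pairs$rank <- seq_len(nrow(pairs))
  n <- nrow(pairs)
  lab <- rep(NA_character_, n)
  if (n_top > 0) lab[seq_len(n_top)] <- "high"
  if (n_bottom > 0) lab[(n - n_bottom + 1):n] <- "low"
  pairs$likelihood <- lab
  pairs[!is.na(pairs$likelihood), , drop = FALSE]
}

#' Export a graph as GraphML
#'
#' @param graph An `igraph` graph.
#' @param path Output path (`.graphml`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export a graph as GEXF
#'
#' Writes a minimal static GEXF 1.2 document (nodes with `label` and any
#' vertex attributes, undirected weighted edges) readable by Gephi-style
#' network tools.
#'
#' @param graph An `igraph` graph.
#' @param path Output path (`.gexf`).
#' @return `path`, invisibly.
#' @export
write_gexf <- function(graph, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  gr <- xml2::xml_add_child(doc, "graph", mode = "static",
                            defaultedgetype = "undirected")
  vattrs <- setdiff(igraph::vertex_attr_names(graph), "name")
  if (length(vattrs) > 0) {
    at <- xml2::xml_add_child(gr, "attributes", class = "node")
    for (i in seq_along(vattrs)) {
      xml2::xml_add_child(at, "attribute", id = as.character(i - 1),
                          title = vattrs[i], type = "string")
    }
  }
  nodes <- xml2::xml_add_child(gr, "nodes")
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  for (vi in seq_along(vnames)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[vi],
                              label = vnames[vi])
    if (length(vattrs) > 0) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattrs)) {
        val <- igraph::vertex_attr(graph, vattrs[i], vi)
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = as.character(val))
      }
    }
  }
  edges <- xml2::xml_add_child(gr, "edges")
  if (igraph::ecount(graph) > 0) {
    el <- igraph::as_data_frame(graph, what = "edges")
    w <- if ("weight" %in% names(el)) el$weight else rep(1, nrow(el))
    for (ei in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(ei - 1),
                          source = el$from[ei], target = el$to[ei],
                          weight = as.character(w[ei]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a graph as an edge-list CSV
#'
#' @param graph An `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  readr::write_csv(el, path, progress = FALSE)
  invisible(path)
}
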