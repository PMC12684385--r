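# Internal: adjacency representation of a weighted network, nodes sorted so
# that integer order == lexicographic order (the Dijkstra tie-break).
build_adjacency <- function(wnet) {
  nodes <- sort(attr(wnet, "nodes"))
  idx <- stats::setNames(seq_along(nodes), nodes)
  from <- idx[wnet$from]
  ord <- order(from, idx[wnet$to])
  from <- from[ord]
  to <- unname(idx[wnet$to])[ord]
  w <- wnet$weight[ord]
  adj_to <- split(to, factor(from, levels = seq_along(nodes)))
  adj_w <- split(w, factor(from, levels = seq_along(nodes)))
  list(nodes = nodes, idx = idx, adj_to = adj_to, adj_w = adj_w)
}

# Internal: Dijkstra from one source. Deterministic: the unvisited node with
# the smallest distance is popped with ties going to the lexicographically
# smallest node, and among equal-cost relaxations the lexicographically
# smallest predecessor is kept.
dijkstra_single <- function(adj, src) {
  n <- length(adj$nodes)
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  dist[src] <- 0
  repeat {
    d <- dist
    d[visited] <- Inf
    u <- which.min(d)            # ties -> smallest index == lexicographic
    if (!is.finite(d[u])) break
    visited[u] <- TRUE
    nbr <- adj$adj_to[[u]]
    if (length(nbr) > 0L) {
      nd <- dist[u] + adj$adj_w[[u]]
      for (k in seq_along(nbr)) {
        v <- nbr[k]
        if (nd[k] < dist[v]) {
          dist[v] <- nd[k]
          pred[v] <- u
        } else if (nd[k] == dist[v] && !is.na(pred[v]) && u < pred[v]) {
          pred[v] <- u
        }
      }
    }
    if (all(visited | !is.finite(dist))) break
  }
  list(dist = dist, pred = pred)
}

reconstruct_path <- function(pred, src, sink) {
  path <- sink
  v <- sink
  while (v != src) {
    v <- pred[v]
    if (is.na(v)) return(NULL)
    path <- c(v, path)
  }
  path
}

#' Mine least-cost shortest paths from a patient's mutated genes
#'
#' Runs Dijkstra's algorithm over the patient's contextualized network from
#' every mutated gene to all reachable nodes and emits the minimum-cost path
#' per (source, sink) pair when it spans at least `min_edges` edges. Path
#' cost is the sum of the traversed edge weights, so paths through
#' upregulated cascades surface with the lowest costs.
#'
#' @param wnet A `weighted_network` from [contextualize_network()].
#' @param sources Character vector of mutated genes; genes absent from the
#'   network are dropped with a warning.
#' @param min_edges Minimum number of edges for a path to qualify
#'   (default 3).
#' @return Tibble with columns `source`, `sink`, `cost`, `n_edges` and a
#'   list-column `path` (node sequences), sorted by cost then
#'   (source, sink). Empty (with a warning) when no source is in the
#'   network.
#' @export
patient_shortest_paths <- function(wnet, sources, min_edges = 3) {
  stopifnot(inherits(wnet, "weighted_network"))
  sources <- unique(sources)
  adj <- build_adjacency(wnet)
  present <- sources[sources %in% adj$nodes]
  if (length(present) < length(sources))
    warning(length(sources) - length(present),
            " mutated gene(s) absent from the network were dropped")
  empty <- tibble::tibble(source = character(), sink = character(),
                          cost = numeric(), n_edges = integer(),
                          path = list())
  if (length(present) == 0L) {
    warning("no mutated gene is present in the network; no paths computed")
    return(empty)
  }
  res <- lapply(sort(present), function(s) {
    si <- adj$idx[[s]]
    dj <- dijkstra_single(adj, si)
    sinks <- which(is.finite(dj$dist) & seq_along(dj$dist) != si)
    if (length(sinks) == 0L) return(empty)
    paths <- lapply(sinks, reconstruct_path, pred = dj$pred, src = si)
    n_edges <- vapply(paths, length, integer(1)) - 1L
    keep <- n_edges >= min_edges
    tibble::tibble(source = s,
                   sink = adj$nodes[sinks[keep]],
                   cost = dj$dist[sinks[keep]],
                   n_edges = n_edges[keep],
                   path = lapply(paths[keep], function(p) adj$nodes[p]))
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, .data$cost, .data$source, .data$sink)
}

#' Cost of a path in a weighted network
#'
#' @param path Character vector of nodes along the path.
#' @param wnet A `weighted_network`.
#' @return Sum of the edge weights along the path; errors if any consecutive
#'   pair is not an edge of the network.
#' @export
path_cost <- function(path, wnet) {
  if (length(path) < 2L) stop("a path needs at least one edge")
  key <- paste(wnet$from, wnet$to, sep = "\r")
  w <- stats::setNames(wnet$weight, key)
  steps <- paste(path[-length(path)], path[-1], sep = "\r")
  if (anyNA(w[steps]))
    stop("path uses edge(s) absent from the network: ",
         paste(gsub("\r", "->", steps[is.na(w[steps])]), collapse = ", "))
  sum(w[steps])
}

#' Select the top-percentile least-cost paths (Mutpaths)
#'
#' Sorts candidate paths ascending by cost (ties broken by source then sink)
#' and retains the top fraction given by `percentile`, with a `min_paths`
#' floor so that small networks still yield a usable subnetwork. The
#' retained paths are assembled into the Mutpaths union graph on which
#' driver scoring operates.
#'
#' @param paths Tibble from [patient_shortest_paths()].
#' @param percentile Fraction of candidate paths to retain
#'   (default 1e-4, i.e. the top 0.01%; the fallback for sparse patients
#'   doubles this to 0.02%).
#' @param min_paths Minimum number of retained paths (default 10).
#' @param deg_set Character vector of the sample's DEGs, used to annotate
#'   which DEGs appear in the union graph.
#' @return An object of class `mutpaths`: a list with `paths` (retained,
#'   ascending cost), `union_edges` (tibble `from`, `to`), `nodes`,
#'   `mutated_nodes`, `deg_nodes`, `percentile`, `n_candidates`.
#' @export
select_mutpaths <- function(paths, percentile = 1e-4, min_paths = 10,
                            deg_set = character()) {
  if (is.null(paths) || nrow(paths) == 0L)
    stop("no Mutpaths computable: the candidate path set is empty")
  ord <- dplyr::arrange(paths, .data$cost, .data$source, .data$sink)
  k <- min(nrow(ord), max(min_paths, ceiling(percentile * nrow(ord))))
  retained <- ord[seq_len(k), , drop = FALSE]
  edge_tbls <- lapply(retained$path, function(p) {
    tibble::tibble(from = p[-length(p)], to = p[-1])
  })
  union_edges <- dplyr::distinct(dplyr::bind_rows(edge_tbls))
  nodes <- sort(unique(c(union_edges$from, union_edges$to)))
  structure(list(paths = retained,
                 union_edges = union_edges,
                 nodes = nodes,
                 mutated_nodes = sort(unique(retained$source)),
                 deg_nodes = sort(intersect(deg_set, nodes)),
                 percentile = percentile,
                 n_candidates = nrow(ord)),
            class = "mutpaths")
}

#' @export
print.mutpaths <- function(x, ...) {
  cat("<mutpaths> ", nrow(x$paths), "/", x$n_candidates,
      " paths retained (top ", format(100 * x$percentile), "%), ",
      length(x$nodes), " nodes, ", length(x$mutated_nodes),
      " mutated sources, ", length(x$deg_nodes), " DEGs in subnetwork\n",
      sep = "")
  invisible(x)
}

#' @method tidy mutpaths
#' @export
#' @rdname mutpaths-tidiers
tidy.mutpaths <- function(x, ...) {
  tibble::tibble(source = x$paths$source, sink = x$paths$sink,
                 cost = x$paths$cost, n_edges = x$paths$n_edges,
                 path = vapply(x$paths$path, paste, character(1),
                               collapse = "|"))
}

#' Tidiers for Mutpaths objects
#'
#' `tidy()` returns the retained path table (node sequences collapsed with
#' `|`); `glance()` a one-row summary.
#'
#' @param x A `mutpaths` object.
#' @param ... Unused.
#' @name mutpaths-tidiers
#' @method glance mutpaths
#' @export
glance.mutpaths <- function(x, ...) {
  tibble::tibble(n_paths = nrow(x$paths), n_candidates = x$n_candidates,
                 percentile = x$percentile, n_nodes = length(x$nodes),
                 n_edges = nrow(x$union_edges),
                 n_mutated = length(x$mutated_nodes),
                 n_degs = length(x$deg_nodes))
}

# igraph view of the Mutpaths union graph
mutpaths_igraph <- function(mp) {
  igraph::graph_from_data_frame(as.data.frame(mp$union_edges),
                                directed = TRUE,
                                vertices = mp$nodes)
}

#' Write Mutpaths tables
#'
#' Serializes the retained-path table and the union-graph edge list as TSVs
#' loadable in standard graph viewers.
#'
#' @param mp A `mutpaths` object.
#' @param paths_file,edges_file Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written file paths.
#' @export
write_mutpaths <- function(mp, paths_file = NULL, edges_file = NULL) {
  if (!is.null(paths_file)) write_tsv_plain(tidy(mp), paths_file)
  if (!is.null(edges_file)) write_tsv_plain(mp$union_edges, edges_file)
  invisible(c(paths_file, edges_file))
}
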