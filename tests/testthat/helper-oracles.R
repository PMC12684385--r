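# Independent oracles used across the suite. These deliberately use naive
# exhaustive algorithms (DFS path enumeration, subset search, direct pairwise
# counting) so they share no code with the implementation they check.

# exhaustive minimum cost over simple paths with >= min_edges edges,
# for every (source, sink) pair reachable from `sources`
brute_min_paths <- function(edges, sources, min_edges = 3) {
  adj <- split(seq_len(nrow(edges)), edges$from)
  best <- list()
  dfs <- function(src, v, visited, cost, nsteps) {
    for (i in adj[[v]]) {
      t <- edges$to[i]
      if (t %in% visited) next
      c2 <- cost + edges$weight[i]
      if (nsteps + 1L >= min_edges) {
        key <- paste(src, t, sep = "|")
        if (is.null(best[[key]]) || c2 < best[[key]]) best[[key]] <<- c2
      }
      dfs(src, t, c(visited, t), c2, nsteps + 1L)
    }
  }
  for (s in sources) if (!is.null(adj[[s]])) dfs(s, s, s, 0, 0L)
  best
}

# unconstrained shortest-path edge count of the min-cost route (via igraph),
# used to decide which pairs the miner is expected to emit
igraph_shortest <- function(edges, source) {
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::distances(g, v = source, mode = "out", weights = edges$weight)[1, ]
}

# random weighted digraph as an edge tibble
random_wdigraph <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  tibble::tibble(from = paste0("n", sprintf("%02d", pairs$from[keep])),
                 to = paste0("n", sprintf("%02d", pairs$to[keep])),
                 weight = stats::runif(sum(keep), 0.1, 2))
}

# wrap an edge tibble as the weighted-network container the miner consumes
make_wnet <- function(edges) {
  out <- tibble::as_tibble(edges)
  attr(out, "nodes") <- sort(unique(c(out$from, out$to)))
  attr(out, "frac_defaulted") <- 0
  class(out) <- c("weighted_network", class(out))
  out
}

# smallest subset of covered-sets reaching `target` coverage of `universe`,
# by exhaustive search over subset sizes; returns Inf when unattainable
brute_min_cover_size <- function(covered, universe, target = 0.70) {
  need <- target * length(universe)
  for (k in seq_along(covered)) {
    for (idx in utils::combn(length(covered), k, simplify = FALSE)) {
      if (length(unique(unlist(covered[idx]))) >= need) return(k)
    }
  }
  Inf
}

# direct pairwise-majority count and Condorcet winner from ballot lists
# (ballots: list of character vectors, best first; unlisted genes tied last)
brute_condorcet_winner <- function(ballots) {
  genes <- sort(unique(unlist(ballots)))
  winner <- NULL
  for (a in genes) {
    beats_all <- TRUE
    for (b in setdiff(genes, a)) {
      a_over_b <- 0L; b_over_a <- 0L
      for (bl in ballots) {
        pa <- match(a, bl); pb <- match(b, bl)
        pa <- ifelse(is.na(pa), length(bl) + 1L, pa)
        pb <- ifelse(is.na(pb), length(bl) + 1L, pb)
        if (pa < pb) a_over_b <- a_over_b + 1L
        if (pb < pa) b_over_a <- b_over_a + 1L
      }
      if (a_over_b <= b_over_a) { beats_all <- FALSE; break }
    }
    if (beats_all) { winner <- a; break }
  }
  winner
}

ballots_to_tbl <- function(ballots) {
  dplyr::bind_rows(lapply(seq_along(ballots), function(i) {
    tibble::tibble(sample_id = paste0("S", i),
                   rank = seq_along(ballots[[i]]), gene = ballots[[i]])
  }))
}

# exponential survival with a binary carrier effect; the generating model is
# the oracle for Cox recovery
simulate_survival <- function(n, log_hr = log(2), frac_carrier = 0.5,
                              censoring = 0.2, base_rate = 0.02, seed = 1) {
  set.seed(seed)
  carrier <- stats::rbinom(n, 1, frac_carrier)
  t_true <- stats::rexp(n, rate = base_rate * exp(log_hr * carrier))
  cens <- stats::rbinom(n, 1, censoring) == 1
  tibble::tibble(sample_id = paste0("S", seq_len(n)),
                 time_months = ifelse(cens, t_true * stats::runif(n), t_true),
                 event = as.integer(!cens), carrier = carrier)
}
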