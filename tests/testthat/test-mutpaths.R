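unit_chain <- function(nodes) {
  n <- length(nodes)
  make_wnet(tibble::tibble(from = nodes[-n], to = nodes[-1], weight = 1))
}

test_that("path mining enforces the minimum path length", {
  w4 <- unit_chain(c("a", "b", "c", "d"))
  paths <- patient_shortest_paths(w4, "a")
  expect_equal(nrow(paths), 1L)
  expect_equal(paths$cost, 3.0)
  expect_equal(paths$path[[1]], c("a", "b", "c", "d"))

  w3 <- unit_chain(c("a", "b", "c"))
  expect_equal(nrow(patient_shortest_paths(w3, "a")), 0L)

  msgs <- testthat::capture_warnings(out <- patient_shortest_paths(w4, "zz"))
  expect_true(any(grepl("no mutated gene", msgs)))
  expect_equal(nrow(out), 0L)
  expect_warning(patient_shortest_paths(w4, c("a", "zz")), "dropped")
})

test_that("path costs sum the edge weights and reject missing edges", {
  w <- make_wnet(tibble::tibble(from = c("a", "b", "c"),
                                to = c("b", "c", "d"),
                                weight = c(0.5, 0.25, 1.0)))
  expect_equal(path_cost(c("a", "b", "c", "d"), w), 1.75)
  expect_equal(path_cost(c("a", "b"), w), 0.5)
  expect_error(path_cost(c("a", "d"), w), "absent")
})

test_that("mined costs match exhaustive enumeration on random digraphs", {
  for (s in 1:25) {
    edges <- random_wdigraph(n = sample(6:10, 1), p = 0.3, seed = s)
    if (nrow(edges) == 0L) next
    wnet <- make_wnet(edges)
    sources <- sample(attr(wnet, "nodes"), 2)
    mined <- suppressWarnings(patient_shortest_paths(wnet, sources))
    oracle <- brute_min_paths(edges, sources, min_edges = 3)
    for (i in seq_len(nrow(mined))) {
      key <- paste(mined$source[i], mined$sink[i], sep = "|")
      expect_equal(mined$cost[i], oracle[[key]], tolerance = 1e-12)
      # the reported node sequence re-costs to the reported cost
      expect_equal(path_cost(mined$path[[i]], wnet), mined$cost[i])
    }
    # pairs whose unconstrained shortest route already has >= 3 edges are
    # always emitted
    for (src in sources) {
      d <- igraph_shortest(edges, src)
      emitted <- mined[mined$source == src, ]
      for (snk in names(d)[is.finite(d) & names(d) != src]) {
        key <- paste(src, snk, sep = "|")
        if (!is.null(oracle[[key]]) &&
            isTRUE(all.equal(oracle[[key]], unname(d[snk]))))
          expect_true(snk %in% emitted$sink)
      }
    }
  }
})

test_that("Mutpaths selection keeps a deterministic ascending-cost prefix", {
  paths <- tibble::tibble(
    source = rep("m", 200), sink = sprintf("t%03d", 1:200),
    cost = seq(0.1, 20, length.out = 200), n_edges = 3L,
    path = replicate(200, c("m", "x", "y", "t"), simplify = FALSE))
  mp <- select_mutpaths(paths, percentile = 1e-4, min_paths = 10)
  expect_equal(nrow(mp$paths), 10L)          # floor applies
  expect_equal(mp$paths$cost, sort(paths$cost)[1:10])

  big <- dplyr::bind_rows(replicate(500, paths, simplify = FALSE))
  big$sink <- sprintf("t%05d", seq_len(nrow(big)))
  mp2 <- select_mutpaths(big, percentile = 1e-4, min_paths = 10)
  expect_equal(nrow(mp2$paths), ceiling(1e-4 * nrow(big)))

  # permutation invariance of the input order
  perm <- sample(nrow(paths))
  mp3 <- select_mutpaths(paths[perm, ], percentile = 1e-4, min_paths = 10)
  expect_equal(mp3$paths, mp$paths)

  # exact cost ties broken by (source, sink), count unchanged
  tied <- paths
  tied$cost <- rep(1, 200)
  mp4 <- select_mutpaths(tied, min_paths = 10)
  expect_equal(nrow(mp4$paths), 10L)
  expect_equal(mp4$paths$sink, sprintf("t%03d", 1:10))

  expect_error(select_mutpaths(paths[0, ]), "no Mutpaths")
})

test_that("Mutpaths assembles the union graph and annotates DEGs", {
  w <- make_wnet(tibble::tibble(
    from = c("m", "x", "y", "m", "p", "q"),
    to   = c("x", "y", "z", "p", "q", "r"),
    weight = c(0.1, 0.1, 0.1, 1, 1, 1)))
  paths <- patient_shortest_paths(w, "m")
  mp <- select_mutpaths(paths, min_paths = 1, percentile = 1e-4,
                        deg_set = c("y", "z", "nothere"))
  expect_equal(mp$mutated_nodes, "m")
  expect_setequal(mp$deg_nodes, c("y", "z"))
  expect_true(all(mp$union_edges$from %in% mp$nodes))
  expect_equal(nrow(mp$paths), 1L)           # min_paths floor of 1
  expect_equal(mp$paths$sink, "z")           # cheapest qualifying path
})

test_that("upregulating a path's nodes never worsens its cost rank", {
  for (s in 1:10) {
    edges <- random_wdigraph(10, p = 0.3, seed = 100 + s)
    if (nrow(edges) < 5) next
    net <- as_gene_network(edges[, c("from", "to")])
    nodes <- network_nodes(net)
    set.seed(s)
    nw <- stats::setNames(stats::runif(length(nodes), 0.5, 2), nodes)
    src <- sample(nodes, 1)
    mined <- suppressWarnings(
      patient_shortest_paths(contextualize_network(net, nw), src))
    if (nrow(mined) == 0L) next
    pick <- mined[sample(nrow(mined), 1), ]
    rank0 <- match(paste(pick$source, pick$sink),
                   paste(mined$source, mined$sink))
    nw2 <- nw
    nw2[pick$path[[1]]] <- nw2[pick$path[[1]]] * 4
    mined2 <- suppressWarnings(
      patient_shortest_paths(contextualize_network(net, nw2), src))
    rank1 <- match(paste(pick$source, pick$sink),
                   paste(mined2$source, mined2$sink))
    expect_true(rank1 <= rank0)
  }
})
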