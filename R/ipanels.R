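#' DEG reachability strata of a gene in the Mutpaths subnetwork
#'
#' Breadth-first search over the directed Mutpaths union graph from `gene`:
#' each DEG is counted once, at its minimum directed distance, up to
#' `max_hops`. The gene itself is never counted in its own strata.
#'
#' @param mp A `mutpaths` object.
#' @param gene Gene symbol; must be a node of the union graph.
#' @param deg_set DEG symbols; defaults to the DEGs recorded in `mp`.
#' @param max_hops Reachability horizon in edges (default 4).
#' @return Integer vector of length `max_hops`; element `n` is the number of
#'   DEGs first reached at distance `n`.
#' @export
deg_strata <- function(mp, gene, deg_set = mp$deg_nodes, max_hops = 4) {
  stopifnot(inherits(mp, "mutpaths"))
  if (!gene %in% mp$nodes)
    stop("gene ", gene, " is not a node of the Mutpaths union graph")
  g <- mutpaths_igraph(mp)
  d <- igraph::distances(g, v = gene, mode = "out")[1, ]
  degs <- setdiff(intersect(deg_set, mp$nodes), gene)
  dd <- d[degs]
  counts <- integer(max_hops)
  inreach <- dd[is.finite(dd) & dd >= 1 & dd <= max_hops]
  if (length(inreach) > 0L) {
    tab <- table(factor(inreach, levels = seq_len(max_hops)))
    counts <- as.integer(tab)
  }
  counts
}

#' Netscore: distance-discounted DEG reach of a driver gene
#'
#' `Netscore = sum over n of counts[n] / n`: a DEG adjacent to the gene
#' contributes 1, one reached in four hops contributes 1/4, so the score
#' measures both how many perturbed genes a mutated gene can influence and
#' how directly.
#'
#' @param strata Non-negative integer vector of per-distance DEG counts
#'   (position `n` = DEGs first reached at distance `n`).
#' @return Numeric score.
#' @examples
#' netscore(c(3, 2, 1, 0))  # 3 + 1 + 1/3
#' @export
netscore <- function(strata) {
  if (any(strata < 0)) stop("strata counts must be non-negative")
  sum(strata / seq_along(strata))
}

#' DEGs reachable from a gene within the hop horizon
#'
#' @inheritParams deg_strata
#' @return Character vector of DEG symbols within `max_hops` directed hops
#'   (the gene itself excluded).
#' @export
covered_degs <- function(mp, gene, deg_set = mp$deg_nodes, max_hops = 4) {
  g <- mutpaths_igraph(mp)
  d <- igraph::distances(g, v = gene, mode = "out")[1, ]
  degs <- setdiff(intersect(deg_set, mp$nodes), gene)
  dd <- d[degs]
  sort(degs[is.finite(dd) & dd >= 1 & dd <= max_hops])
}

#' Score all mutated candidate drivers of a Mutpaths subnetwork
#'
#' @param mp A `mutpaths` object.
#' @param deg_set DEG universe (default: DEGs in the union graph).
#' @param max_hops Hop horizon (default 4).
#' @return Tibble `gene`, `netscore`, `n_covered` with a list-column
#'   `covered` (DEGs within the horizon), sorted by netscore descending.
#' @export
candidate_drivers <- function(mp, deg_set = mp$deg_nodes, max_hops = 4) {
  cands <- intersect(mp$mutated_nodes, mp$nodes)
  rows <- lapply(sort(cands), function(g) {
    cov <- covered_degs(mp, g, deg_set, max_hops)
    tibble::tibble(gene = g,
                   netscore = netscore(deg_strata(mp, g, deg_set, max_hops)),
                   n_covered = length(cov),
                   covered = list(cov))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    return(tibble::tibble(gene = character(), netscore = numeric(),
                          n_covered = integer(), covered = list()))
  dplyr::arrange(out, dplyr::desc(.data$netscore), .data$gene)
}

#' Greedy maximum set cover over the DEG universe
#'
#' Starting from the candidates ranked by netscore, repeatedly picks the
#' candidate covering the most not-yet-covered DEGs (ties broken by higher
#' netscore, then lexicographic gene symbol) until the target coverage
#' fraction is reached or no candidate adds coverage. The resulting ordered
#' gene list is the patient's iPanel.
#'
#' @param candidates Tibble with columns `gene`, `netscore` and list-column
#'   `covered` (e.g. from [candidate_drivers()]).
#' @param universe Character vector: the DEG universe (must be non-empty).
#' @param target Coverage fraction to attain (default 0.70).
#' @return An object of class `ipanel`: list with `entries` (tibble `rank`,
#'   `gene`, `netscore`, `n_new`, `cumulative_coverage`, list-column
#'   `covered`), `coverage`, `attained`, `target`, `universe_size`.
#' @export
greedy_max_cover <- function(candidates, universe, target = 0.70) {
  if (length(universe) == 0L) stop("no DEG universe: cannot run set cover")
  universe <- unique(universe)
  cand <- dplyr::arrange(candidates, dplyr::desc(.data$netscore), .data$gene)
  cand$covered <- lapply(cand$covered, intersect, y = universe)
  covered <- character(0)
  entries <- list()
  remaining <- cand
  while (length(covered) / length(universe) < target && nrow(remaining) > 0L) {
    gain <- vapply(remaining$covered,
                   function(s) length(setdiff(s, covered)), integer(1))
    if (max(gain) == 0L) break
    # ties: larger gain, then higher netscore, then lexicographic gene
    best <- order(-gain, -remaining$netscore, remaining$gene)[1]
    new <- setdiff(remaining$covered[[best]], covered)
    covered <- c(covered, new)
    entries[[length(entries) + 1L]] <- tibble::tibble(
      gene = remaining$gene[best],
      netscore = remaining$netscore[best],
      n_new = length(new),
      cumulative_coverage = length(covered) / length(universe),
      covered = list(sort(remaining$covered[[best]])))
    remaining <- remaining[-best, , drop = FALSE]
  }
  entries <- dplyr::bind_rows(entries)
  if (nrow(entries) > 0L)
    entries <- dplyr::mutate(entries, rank = dplyr::row_number(),
                             .before = 1)
  else
    entries <- tibble::tibble(rank = integer(), gene = character(),
                              netscore = numeric(), n_new = integer(),
                              cumulative_coverage = numeric(),
                              covered = list())
  coverage <- length(covered) / length(universe)
  structure(list(entries = entries,
                 coverage = coverage,
                 attained = coverage >= target,
                 target = target,
                 universe_size = length(universe)),
            class = "ipanel")
}

#' Build a patient's iPanel from their Mutpaths
#'
#' Convenience wrapper: scores the mutated candidates with
#' [candidate_drivers()] and runs [greedy_max_cover()] over the DEGs of the
#' Mutpaths union graph.
#'
#' @param mp A `mutpaths` object with a non-empty `deg_nodes` set.
#' @param target Coverage target (default 0.70).
#' @param max_hops Hop horizon for reachability (default 4).
#' @return An `ipanel` object.
#' @export
build_ipanel <- function(mp, target = 0.70, max_hops = 4) {
  greedy_max_cover(candidate_drivers(mp, max_hops = max_hops),
                   universe = mp$deg_nodes, target = target)
}

#' @export
print.ipanel <- function(x, ...) {
  cat("<ipanel> ", nrow(x$entries), " gene(s), coverage ",
      sprintf("%.1f%%", 100 * x$coverage),
      if (x$attained) " (target attained)" else " (target NOT attained)",
      "\n", sep = "")
  if (nrow(x$entries) > 0L)
    print(dplyr::select(x$entries, -"covered"))
  invisible(x)
}

#' Tidiers for iPanel objects
#'
#' `tidy()` returns the panel entries (one row per driver, in greedy pick
#' order); `glance()` a one-row summary with coverage and attainment.
#'
#' @param x An `ipanel` object.
#' @param ... Unused.
#' @method tidy ipanel
#' @export
tidy.ipanel <- function(x, ...) {
  dplyr::mutate(dplyr::select(x$entries, -"covered"),
                n_covered_degs = vapply(x$entries$covered, length, integer(1)))
}

#' @rdname tidy.ipanel
#' @method glance ipanel
#' @export
glance.ipanel <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$entries), coverage = x$coverage,
                 attained = x$attained, target = x$target,
                 universe_size = x$universe_size)
}

#' Coverage curve of an iPanel
#'
#' Step plot of cumulative DEG coverage against panel rank, with the
#' coverage target as a dashed reference line.
#'
#' @param object An `ipanel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ipanel
#' @export
autoplot.ipanel <- function(object, ...) {
  df <- dplyr::select(object$entries, "rank", "gene", "cumulative_coverage")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$cumulative_coverage)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.8,
                       size = 3) +
    ggplot2::geom_hline(yintercept = object$target, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "panel rank", y = "cumulative DEG coverage") +
    ggplot2::theme_minimal()
}
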