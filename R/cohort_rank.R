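#' Pairwise-preference matrix from ranked ballots
#'
#' Each patient's driver panel is a truncated ballot: listed genes are
#' preferred in their listed order, and every gene absent from a ballot
#' ranks below all of its listed genes (absent genes mutually tied).
#' `d[a, b]` counts the ballots strictly preferring `a` over `b`.
#'
#' @param ballots Tibble with columns `sample_id`, `rank`, `gene`.
#' @return Square integer matrix with gene dimnames.
#' @export
pairwise_preferences <- function(ballots) {
  stopifnot(all(c("sample_id", "rank", "gene") %in% names(ballots)))
  genes <- sort(unique(ballots$gene))
  m <- length(genes)
  d <- matrix(0L, m, m, dimnames = list(genes, genes))
  for (sid in unique(ballots$sample_id)) {
    b <- ballots[ballots$sample_id == sid, , drop = FALSE]
    b <- b[order(b$rank), , drop = FALSE]
    if (anyDuplicated(b$gene)) stop("duplicate gene within ballot ", sid)
    pos <- stats::setNames(rep(length(b$gene) + 1L, m), genes)  # tied last
    pos[b$gene] <- seq_along(b$gene)
    cmp <- outer(pos, pos, "<")
    d <- d + cmp
  }
  d
}

# Schulze method: widest-path (strongest beatpath) strengths via
# Floyd-Warshall, candidates ordered by the number of opponents they beat.
schulze_order <- function(d) {
  genes <- rownames(d)
  m <- nrow(d)
  p <- matrix(0L, m, m, dimnames = dimnames(d))
  stronger <- d > t(d)
  p[stronger] <- d[stronger]
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
    pj <- pmin(p[, i], p[i, j])
    upd <- pj > p[, j]
    upd[c(i, j)] <- FALSE
    p[upd, j] <- pj[upd]
  }
  beats <- p > t(p)
  wins <- rowSums(beats)
  genes[order(-wins, genes)]
}

copeland_order <- function(d) {
  score <- rowSums(d > t(d)) - rowSums(d < t(d))
  rownames(d)[order(-score, rownames(d))]
}

#' Condorcet ranking of cohort driver genes
#'
#' Aggregates per-patient driver panels (ballots in greedy pick order) into
#' a single cohort-level ranking using a Condorcet-consistent rule. With the
#' default Schulze method, a gene beating every other gene in pairwise
#' majorities (the Condorcet winner) is always ranked first; majority cycles
#' are resolved by strongest beatpaths and flagged.
#'
#' @param ballots Tibble with columns `sample_id`, `rank`, `gene` (at least
#'   one non-empty ballot).
#' @param method `"schulze"` (default) or `"copeland"`.
#' @return Object of class `condorcet_ranking`: list with `ranking` (tibble
#'   `rank`, `gene`, `wins`, `losses`), `method`, `condorcet_winner`
#'   (symbol or `NA`), `has_cycle`, `preferences` (the pairwise matrix).
#' @export
condorcet_rank <- function(ballots, method = c("schulze", "copeland")) {
  method <- match.arg(method)
  if (nrow(ballots) == 0L) stop("no ballots supplied")
  d <- pairwise_preferences(ballots)
  ord <- switch(method, schulze = schulze_order(d), copeland = copeland_order(d))
  wins <- rowSums(d > t(d))
  losses <- rowSums(d < t(d))
  cw <- rownames(d)[wins == nrow(d) - 1L]
  cw <- if (length(cw) == 1L) cw else NA_character_
  has_cycle <- is.na(cw) && nrow(d) > 1L
  if (has_cycle)
    message("no Condorcet winner: pairwise-majority cycle resolved by ",
            method)
  ranking <- tibble::tibble(rank = seq_along(ord), gene = ord,
                            wins = unname(wins[ord]),
                            losses = unname(losses[ord]))
  structure(list(ranking = ranking, method = method,
                 condorcet_winner = cw, has_cycle = has_cycle,
                 preferences = d),
            class = "condorcet_ranking")
}

#' @export
print.condorcet_ranking <- function(x, ...) {
  cat("<condorcet_ranking> ", nrow(x$ranking), " genes, method = ",
      x$method,
      if (!is.na(x$condorcet_winner))
        paste0(", Condorcet winner = ", x$condorcet_winner)
      else ", majority cycle present", "\n", sep = "")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Tidiers for Condorcet rankings
#'
#' `tidy()` returns the ranking table with pairwise win counts; `glance()`
#' a one-row summary.
#'
#' @param x A `condorcet_ranking`.
#' @param ... Unused.
#' @method tidy condorcet_ranking
#' @export
tidy.condorcet_ranking <- function(x, ...) x$ranking

#' @rdname tidy.condorcet_ranking
#' @method glance condorcet_ranking
#' @export
glance.condorcet_ranking <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$ranking), method = x$method,
                 condorcet_winner = x$condorcet_winner,
                 has_cycle = x$has_cycle)
}

#' Benchmark a ranked gene list against a gold standard
#'
#' Precision = fraction of the top-k that are gold-standard genes; recall =
#' fraction of the gold standard recovered in the top-k; F1 their harmonic
#' mean (0 when both are 0).
#'
#' @param ranked Character vector of genes, best first, or a
#'   `condorcet_ranking`.
#' @param gold Non-empty character vector of gold-standard genes.
#' @param k Depth of the ranking to evaluate (default 20; must not exceed
#'   the ranking length).
#' @return One-row tibble: `k`, `n_hits`, `precision`, `recall`, `f1`.
#' @examples
#' benchmark_topk(c("A", "B", "C", "D"), gold = c("A", "C", "X"), k = 4)
#' @export
benchmark_topk <- function(ranked, gold, k = 20) {
  if (inherits(ranked, "condorcet_ranking")) ranked <- ranked$ranking$gene
  gold <- unique(gold)
  if (length(gold) == 0L) stop("gold-standard list is empty")
  if (k > length(ranked))
    stop("k = ", k, " exceeds ranking length ", length(ranked))
  hits <- length(intersect(ranked[seq_len(k)], gold))
  precision <- hits / k
  recall <- hits / length(gold)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  tibble::tibble(k = k, n_hits = hits, precision = precision,
                 recall = recall, f1 = f1)
}

#' Driver frequency across a cohort, with rare-driver flags
#'
#' @param panels Tibble `sample_id`, `gene` (cohort panel memberships).
#' @param n_patients Cohort size (default: number of distinct samples in
#'   `panels`).
#' @param rare_cut Strict frequency threshold below which a driver is
#'   flagged rare (default 0.02, i.e. present in < 2% of patients).
#' @return Tibble `gene`, `n_patients`, `frequency`, `rare`, sorted by
#'   frequency descending.
#' @export
driver_frequency <- function(panels, n_patients = dplyr::n_distinct(panels$sample_id),
                             rare_cut = 0.02) {
  if (nrow(panels) == 0L) stop("no panels supplied")
  counts <- dplyr::count(dplyr::distinct(panels[, c("sample_id", "gene")]),
                         .data$gene, name = "n_patients")
  out <- dplyr::mutate(counts,
                       frequency = .data$n_patients / !!n_patients,
                       rare = .data$frequency < rare_cut)
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$gene)
}
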