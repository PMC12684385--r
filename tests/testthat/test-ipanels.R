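# build a mutpaths object directly from an edge list (the container is a
# plain list; tests construct it to probe the scoring layer in isolation)
mp_from_edges <- function(from, to, mutated, degs) {
  nodes <- sort(unique(c(from, to)))
  structure(list(paths = tibble::tibble(),
                 union_edges = tibble::tibble(from = from, to = to),
                 nodes = nodes,
                 mutated_nodes = intersect(mutated, nodes),
                 deg_nodes = sort(intersect(degs, nodes)),
                 percentile = 1e-4, n_candidates = NA_integer_),
            class = "mutpaths")
}

test_that("reachability strata count DEGs at their minimum distance only", {
  # star: three DEGs at distance 1
  mp <- mp_from_edges(rep("g", 3), c("d1", "d2", "d3"), "g",
                      c("d1", "d2", "d3"))
  expect_equal(deg_strata(mp, "g"), c(3L, 0L, 0L, 0L))

  # chain through a non-DEG intermediate
  mp2 <- mp_from_edges(c("g", "x"), c("x", "d"), "g", "d")
  expect_equal(deg_strata(mp2, "g"), c(0L, 1L, 0L, 0L))

  # DEG at distance 5 is beyond the horizon
  chain <- c("g", "a", "b", "c", "e", "d5")
  mp3 <- mp_from_edges(chain[-6], chain[-1], "g", "d5")
  expect_equal(deg_strata(mp3, "g"), c(0L, 0L, 0L, 0L))

  # a DEG reachable at distances 1 and 3 is counted once, at 1
  mp4 <- mp_from_edges(c("g", "g", "x", "y"), c("d", "x", "y", "d"),
                       "g", "d")
  expect_equal(deg_strata(mp4, "g"), c(1L, 0L, 0L, 0L))
  expect_error(deg_strata(mp4, "nope"), "not a node")
})

test_that("netscore is the distance-discounted stratum sum", {
  expect_equal(netscore(c(3, 2, 1, 0)), 3 + 1 + 1/3)
  expect_equal(netscore(c(0, 0, 0, 0)), 0)
  expect_equal(netscore(c(4, 0, 0, 4)), 5)
  expect_error(netscore(c(-1, 0, 0, 0)), "non-negative")
})

test_that("netscore and strata agree on random subnetworks (disjoint strata)", {
  for (s in 1:10) {
    edges <- random_wdigraph(12, p = 0.2, seed = 200 + s)
    if (nrow(edges) == 0L) next
    nodes <- unique(c(edges$from, edges$to))
    set.seed(s)
    degs <- sample(nodes, min(5, length(nodes)))
    g <- sample(nodes, 1)
    mp <- mp_from_edges(edges$from, edges$to, g, degs)
    strata <- deg_strata(mp, g)
    expect_true(sum(strata) <= length(mp$deg_nodes))
    expect_equal(sum(strata), length(covered_degs(mp, g)))
    expect_equal(netscore(strata), sum(strata / 1:4))
  }
})

test_that("greedy cover handles single-cover, multi-step and exhaustion cases", {
  uni4 <- paste0("d", 1:4)
  cands <- tibble::tibble(gene = "G", netscore = 4,
                          covered = list(uni4))
  p1 <- greedy_max_cover(cands, uni4)
  expect_equal(p1$entries$gene, "G")
  expect_equal(p1$coverage, 1.0)
  expect_true(p1$attained)

  uni10 <- paste0("d", 1:10)
  cands2 <- tibble::tibble(
    gene = c("A", "B", "C"), netscore = c(6, 6, 2),
    covered = list(paste0("d", 1:6), paste0("d", 5:10), paste0("d", 1:2)))
  p2 <- greedy_max_cover(cands2, uni10)
  expect_equal(p2$entries$gene, c("A", "B"))
  expect_equal(p2$coverage, 1.0)
  # no single candidate reaches 70%: exhaustive confirmation
  expect_equal(brute_min_cover_size(cands2$covered, uni10, 0.70), 2)

  cands3 <- tibble::tibble(gene = c("A", "B"), netscore = c(1, 2),
                           covered = list("d1", "d1"))
  p3 <- greedy_max_cover(cands3, uni10)
  expect_equal(p3$entries$gene, "B")         # tie on gain -> higher netscore
  expect_equal(p3$coverage, 0.1)
  expect_false(p3$attained)

  expect_error(greedy_max_cover(cands, character(0)), "no DEG universe")
})

test_that("greedy coverage increases strictly and stays within the classic bound", {
  set.seed(77)
  for (rep in 1:40) {
    m <- sample(3:10, 1)
    uni <- paste0("d", 1:12)
    covered <- lapply(seq_len(m), function(i)
      sample(uni, sample(1:8, 1)))
    cands <- tibble::tibble(gene = sprintf("c%02d", seq_len(m)),
                            netscore = stats::runif(m, 0, 5),
                            covered = covered)
    panel <- greedy_max_cover(cands, uni, target = 0.70)
    expect_true(all(diff(c(0, panel$entries$cumulative_coverage)) > 0))
    expect_lte(nrow(panel$entries), m)
    opt <- brute_min_cover_size(covered, uni, 0.70)
    if (is.finite(opt)) {
      expect_true(panel$attained)
      expect_lte(nrow(panel$entries), (log(length(uni)) + 1) * opt)
    } else {
      expect_false(panel$attained)
    }
  }
})

test_that("a planted driver upstream of the DEG mass forms a one-gene panel", {
  spec <- synthetic_spec(n_genes = 120, n_patients = 1, seed = 99,
                         drivers_per_patient = 1, driver_reach_min = 20)
  net <- generate_network(spec)
  pat <- generate_patient(net, spec, seed = 123, sample_id = "P1")
  res <- run_sample(net, pat$mutations$gene,
                    pat$expression[, c("gene", "log2fc", "fdr")],
                    sample_id = "P1")
  driver <- pat$truth$gene[pat$truth$role == "driver"]
  expect_equal(res$ipanel$entries$gene, driver)
  expect_true(res$ipanel$attained)
})

test_that("ipanel tidiers and coverage plot expose the panel", {
  cands <- tibble::tibble(gene = c("A", "B"), netscore = c(3, 1),
                          covered = list(paste0("d", 1:5), paste0("d", 6:8)))
  panel <- greedy_max_cover(cands, paste0("d", 1:8))
  td <- tidy(panel)
  expect_equal(td$gene, c("A", "B"))
  expect_equal(td$n_covered_degs, c(5L, 3L))
  gl <- glance(panel)
  expect_equal(gl$coverage, 1.0)
  expect_s3_class(autoplot(panel), "ggplot")
})
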