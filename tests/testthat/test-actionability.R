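toy_roles <- tibble::tibble(gene = c("ONC", "TSG1", "TSG2", "ONCDOWN"),
                            role = c("oncogene", "tsg", "tsg", "oncogene"))
toy_drugs <- tibble::tibble(
  gene = c("ONC", "ONC", "TSG1", "TSG2"),
  drug = c("inhib_X", "activ_Y", "activ_Z", "inhib_W"),
  mode = c("inhibitor", "activator", "activator", "inhibitor"))

test_that("expression triage applies the strict fold-change boundary", {
  lfc <- c(kept = 1.5, boundary = 1.0, down = -2.0)
  tri <- triage_perturbed(names(lfc), lfc)
  expect_setequal(tri$gene, c("kept", "down"))
  expect_equal(tri$direction[tri$gene == "down"], "down")
  # missing expression passes with the flag set
  tri2 <- triage_perturbed(c("kept", "noexpr"), lfc)
  expect_true(tri2$missing_expression[tri2$gene == "noexpr"])
  expect_equal(tri2$direction[tri2$gene == "noexpr"], "unknown")
})

test_that("the actionability matrix pairs genes with matching-mode drugs", {
  up_onc <- classify_action("ONC", "up", "oncogene", toy_drugs)
  expect_equal(up_onc$recommended_mode, "inhibitor")
  expect_equal(up_onc$drugs, "inhib_X")

  down_tsg <- classify_action("TSG1", "down", "tsg", toy_drugs)
  expect_equal(down_tsg$recommended_mode, "activator")
  expect_equal(down_tsg$drugs, "activ_Z")

  up_tsg <- classify_action("TSG1", "up", "tsg", toy_drugs)
  expect_equal(up_tsg$recommended_mode, "activator")

  down_onc <- classify_action("ONCDOWN", "down", "oncogene", toy_drugs)
  expect_equal(down_onc$recommended_mode, "undetermined")
  expect_equal(down_onc$n_drugs, 0L)

  # actionable rule match but no drug of the recommended mode
  no_match <- classify_action("TSG2", "down", "tsg", toy_drugs)
  expect_equal(no_match$recommended_mode, "activator")
  expect_equal(no_match$n_drugs, 0L)
})

test_that("every recommended drug's mode matches the recommendation", {
  set.seed(23)
  for (i in 1:30) {
    g <- sample(toy_roles$gene, 1)
    dir <- sample(c("up", "down", "unknown"), 1)
    role <- toy_roles$role[toy_roles$gene == g]
    pair <- classify_action(g, dir, role, toy_drugs)
    if (pair$n_drugs > 0) {
      listed <- strsplit(pair$drugs, ",")[[1]]
      modes <- toy_drugs$mode[toy_drugs$gene == g & toy_drugs$drug %in% listed]
      expect_true(all(modes == pair$recommended_mode))
    }
  }
})

iacte_fixture <- function() {
  # panel gene PAN (not actionable) -> x -> ONC (actionable DEG at distance 2)
  # and a chain placing DEG FAR at distance 5
  from <- c("PAN", "x", "PAN", "a", "b", "c", "e")
  to   <- c("x", "ONC", "a", "b", "c", "e", "FAR")
  structure(list(paths = tibble::tibble(),
                 union_edges = tibble::tibble(from = from, to = to),
                 nodes = sort(unique(c(from, to))),
                 mutated_nodes = "PAN",
                 deg_nodes = c("FAR", "ONC"),
                 percentile = 1e-4, n_candidates = NA_integer_),
            class = "mutpaths")
}

test_that("iActE extends to 4-hop DEG neighbours and excludes panel genes", {
  mp <- iacte_fixture()
  panel <- tibble::tibble(gene = "PAN", netscore = 1)
  lfc <- c(PAN = 0.2, ONC = 2.5, FAR = 3)
  iact <- iact_pairs(panel, lfc, toy_roles, toy_drugs)
  # PAN triaged out (|log2fc| <= 1): no iAct pair
  expect_equal(nrow(iact), 0L)
  iacte <- extend_iacte(panel, mp, lfc, toy_roles, toy_drugs)
  expect_equal(iacte$gene, "ONC")            # FAR is beyond the horizon
  expect_equal(iacte$recommended_mode, "inhibitor")
  expect_equal(iacte$tier, "iActE")
  # tiers are disjoint by construction
  expect_length(intersect(iact$gene, iacte$gene), 0)

  # enlarging the drug reference never removes an emitted pair
  more_drugs <- dplyr::bind_rows(toy_drugs,
    tibble::tibble(gene = "ONC", drug = "inhib_new", mode = "inhibitor"))
  iacte2 <- extend_iacte(panel, mp, lfc, toy_roles, more_drugs)
  expect_true(all(iacte$gene %in% iacte2$gene))
  expect_true(grepl("inhib_X", iacte2$drugs[iacte2$gene == "ONC"]))
})

test_that("action reports serialize to JSON and round-trip losslessly", {
  cands <- tibble::tibble(gene = "PAN", netscore = 2.5,
                          covered = list(c("d1", "d2")))
  panel <- greedy_max_cover(cands, c("d1", "d2"))
  rep1 <- build_report("S1", panel,
                       iact = classify_action("ONC", "up", "oncogene",
                                              toy_drugs),
                       flags = "undefined HR for gene ZZZ")
  expect_true(is.na(rep1$pirs))
  expect_true(any(grepl("undefined HR", rep1$flags)))
  f <- tempfile(fileext = ".json")
  write_report(rep1, f)
  back <- read_report(f)
  expect_equal(back$sample_id, rep1$sample_id)
  expect_equal(back$panel, rep1$panel)
  expect_equal(back$iact, rep1$iact)
  expect_equal(back$flags, rep1$flags)
  expect_equal(back$coverage, rep1$coverage)
  # parse -> serialize -> parse is stable
  f2 <- tempfile(fileext = ".json")
  write_report(back, f2)
  expect_equal(read_report(f2)$panel, back$panel)

  # a report with no pairs flags the absence of actions
  rep2 <- build_report("S2", panel)
  expect_true("no action available" %in% rep2$flags)
  expect_error(build_report("S3", NULL), "iPanel is required")
})
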