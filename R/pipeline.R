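#' Pipeline configuration with standard defaults
#'
#' Collects every tunable of the per-sample and cohort pipelines. The
#' defaults are the method's standard settings: top 0.01% of paths (0.02%
#' fallback), minimum path length 3 edges, 4-hop reachability, 70% DEG
#' coverage, DEG thresholds |log2FC| >= 1 and FDR <= 0.05, hypermutation
#' cutoff 1000, actionability fold-change cutoff 2, rare-driver cutoff 2%,
#' benchmarking depth 20.
#'
#' @param percentile Mutpaths retention fraction (default 1e-4).
#' @param fallback_percentile Retention fraction used when the coverage
#'   target is not attained at `percentile` (default 2e-4).
#' @param min_paths Floor on retained paths (default 10).
#' @param min_edges Minimum path length in edges (default 3).
#' @param max_hops Reachability horizon (default 4).
#' @param coverage_target DEG coverage target for the iPanel (default 0.70).
#' @param lfc_cut,fdr_cut DEG thresholds (defaults 1.0, 0.05).
#' @param max_mutations Hypermutation exclusion cutoff (default 1000).
#' @param fold_cut Actionability triage fold-change cutoff (default 2.0).
#' @param rare_cut Rare-driver frequency cutoff (default 0.02).
#' @param top_k Benchmarking depth (default 20).
#' @param condorcet_method `"schulze"` or `"copeland"`.
#' @param hr_covariate `"ipanel"` (carrier = gene in the patient's panel,
#'   default) or `"mutated"` (carrier = gene mutated).
#' @param seed Seed for any stochastic step (permutation adjustment).
#' @return A list of class `run_config`.
#' @export
run_config <- function(percentile = 1e-4, fallback_percentile = 2e-4,
                       min_paths = 10, min_edges = 3, max_hops = 4,
                       coverage_target = 0.70, lfc_cut = 1.0,
                       fdr_cut = 0.05, max_mutations = 1000, fold_cut = 2.0,
                       rare_cut = 0.02, top_k = 20,
                       condorcet_method = "schulze",
                       hr_covariate = c("ipanel", "mutated"), seed = 1L) {
  hr_covariate <- match.arg(hr_covariate)
  structure(as.list(environment()), class = "run_config")
}

#' Run the per-sample pipeline
#'
#' Executes the four per-patient stages in order: contextualize the shared
#' network with the sample's expression, mine least-cost paths from its
#' mutated genes, select the Mutpaths subnetwork and extract the iPanel by
#' greedy set cover, then classify action pairs. When the coverage target is
#' not attained at the default path percentile the stage is retried once at
#' the fallback percentile.
#'
#' @param net A `gene_network` shared across the cohort.
#' @param mutated Character vector of the sample's mutated genes.
#' @param expression Tibble `gene`, `log2fc`, `fdr` for this sample.
#' @param config A [run_config()].
#' @param sample_id Sample identifier.
#' @param roles,drugs Optional actionability reference tables.
#' @return A list of class `sample_result`: `sample_id`, `status`
#'   (`"ok"` or `"no_panel"`), `mutpaths`, `ipanel`, `deg_set`, `iact`,
#'   `iacte`, `percentile_used`, `report` (an `action_report`, PiRS unset
#'   until the cohort stage), or a `status = "no_panel"` stub when no path
#'   or DEG universe exists even at the fallback percentile.
#' @export
run_sample <- function(net, mutated, expression, config = run_config(),
                       sample_id = "sample", roles = NULL, drugs = NULL) {
  deg_tbl <- call_degs(dplyr::mutate(expression, sample_id = sample_id),
                       lfc_cut = config$lfc_cut, fdr_cut = config$fdr_cut)
  deg_set <- deg_tbl$gene
  wnet <- contextualize_network(net, expression[, c("gene", "log2fc")])
  no_panel <- function(reason) {
    structure(list(sample_id = sample_id, status = "no_panel",
                   reason = reason, mutpaths = NULL, ipanel = NULL,
                   deg_set = deg_set, iact = empty_action_pairs(),
                   iacte = empty_action_pairs(),
                   percentile_used = NA_real_, report = NULL),
              class = "sample_result")
  }
  paths <- withCallingHandlers(
    patient_shortest_paths(wnet, mutated, min_edges = config$min_edges),
    warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(paths) == 0L) return(no_panel("no qualifying paths"))

  attempt <- function(pct) {
    mp <- select_mutpaths(paths, percentile = pct,
                          min_paths = config$min_paths, deg_set = deg_set)
    if (length(mp$deg_nodes) == 0L) return(NULL)
    panel <- build_ipanel(mp, target = config$coverage_target,
                          max_hops = config$max_hops)
    if (nrow(panel$entries) == 0L) return(NULL)
    list(mp = mp, panel = panel)
  }
  pct_used <- config$percentile
  fit <- attempt(pct_used)
  if (is.null(fit) || !fit$panel$attained) {
    fit2 <- attempt(config$fallback_percentile)
    if (!is.null(fit2) && (is.null(fit) || fit2$panel$attained)) {
      fit <- fit2
      pct_used <- config$fallback_percentile
    }
  }
  if (is.null(fit))
    return(no_panel("no DEG universe in Mutpaths even at fallback percentile"))

  lfc <- stats::setNames(expression$log2fc, expression$gene)
  iact <- if (!is.null(roles) && !is.null(drugs))
    iact_pairs(fit$panel, lfc, roles, drugs, fold_cut = config$fold_cut)
  else empty_action_pairs()
  iacte <- if (!is.null(roles) && !is.null(drugs))
    extend_iacte(fit$panel, fit$mp, lfc, roles, drugs,
                 max_hops = config$max_hops)
  else empty_action_pairs()

  flags <- character(0)
  if (pct_used > config$percentile)
    flags <- c(flags, sprintf("fallback percentile %g used", pct_used))
  report <- build_report(sample_id, fit$panel, iact = iact, iacte = iacte,
                         flags = flags, percentile_used = pct_used)
  structure(list(sample_id = sample_id, status = "ok", reason = NA_character_,
                 mutpaths = fit$mp, ipanel = fit$panel, deg_set = deg_set,
                 iact = iact, iacte = iacte, percentile_used = pct_used,
                 report = report),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat("<sample_result> ", x$sample_id, ": ", x$status, "\n", sep = "")
  if (x$status == "ok") print(x$ipanel)
  invisible(x)
}

#' Run the cohort pipeline
#'
#' Applies the hypermutation filter, runs every sample through
#' [run_sample()], then performs the cohort stages: per-gene Cox hazards,
#' PiRS scores and the stratifying cutoff scan (when survival data are
#' supplied), Condorcet ranking of the per-patient panels, rare-driver
#' flags, and gold-standard benchmarking (when a gold list is supplied).
#' The accounting identity `reports + hypermutation skips + no-panel
#' records = input samples` always holds.
#'
#' @param net A `gene_network`.
#' @param mutations Tibble `sample_id`, `gene` of retained somatic calls
#'   (e.g. from [read_maf()]).
#' @param expression Tibble `sample_id`, `gene`, `log2fc`, `fdr`.
#' @param config A [run_config()].
#' @param survival Optional tibble `sample_id`, `time_months`, `event`.
#' @param roles,drugs Optional actionability reference tables.
#' @param gold Optional gold-standard gene vector for benchmarking.
#' @param n_perm Permutations for the cutoff-scan adjustment (default 0).
#' @return List of class `cohort_result`: `samples` (named list of
#'   `sample_result`), `panels` (tibble `sample_id`, `rank`, `gene`,
#'   `netscore`), `hazards`, `pirs` (tibble with scores and groups),
#'   `cutoff` (a `pirs_cutoff` or `NULL`), `ranking`
#'   (`condorcet_ranking`), `frequency`, `benchmark`, `accounting`,
#'   `reports` (per-sample `action_report`s), `config`.
#' @export
run_cohort <- function(net, mutations, expression, config = run_config(),
                       survival = NULL, roles = NULL, drugs = NULL,
                       gold = NULL, n_perm = 0) {
  ids <- sort(unique(mutations$sample_id))
  if (length(ids) < 2L) stop("cohort pipeline needs >= 2 samples")
  n_mut <- table(mutations$sample_id)
  hyper <- names(n_mut)[n_mut > config$max_mutations]
  kept_ids <- setdiff(ids, hyper)

  samples <- lapply(kept_ids, function(sid) {
    run_sample(net,
               mutated = mutations$gene[mutations$sample_id == sid],
               expression = expression[expression$sample_id == sid,
                                       c("gene", "log2fc", "fdr")],
               config = config, sample_id = sid,
               roles = roles, drugs = drugs)
  })
  names(samples) <- kept_ids
  ok <- vapply(samples, function(s) s$status == "ok", logical(1))

  panels <- dplyr::bind_rows(lapply(samples[ok], function(s) {
    dplyr::mutate(tidy(s$ipanel)[, c("rank", "gene", "netscore")],
                  sample_id = s$sample_id, .before = 1)
  }))
  if (nrow(panels) == 0L) stop("no sample yielded an iPanel")

  carriers_tbl <- switch(config$hr_covariate,
                         ipanel = panels[, c("sample_id", "gene")],
                         mutated = mutations[mutations$sample_id %in% kept_ids,
                                             c("sample_id", "gene")])
  hazards <- NULL
  pirs_tbl <- NULL
  cutoff <- NULL
  if (!is.null(survival)) {
    records <- survival[survival$sample_id %in% kept_ids, , drop = FALSE]
    hazards <- gene_hazards(carriers_tbl, records)
    pirs_tbl <- pirs_scores(panels, hazards)
    scorable <- records[records$sample_id %in% pirs_tbl$sample_id, ,
                        drop = FALSE]
    cutoff <- tryCatch({
      set.seed(config$seed)
      scan_pirs_cutoff(pirs_tbl, scorable, n_perm = n_perm)
    }, error = function(e) {
      message("PiRS cutoff scan skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(cutoff))
      pirs_tbl <- dplyr::left_join(
        pirs_tbl, cutoff$groups[, c("sample_id", "group")], by = "sample_id")
  } else message("no survival table supplied: prognosis stage skipped")

  ranking <- condorcet_rank(panels[, c("sample_id", "rank", "gene")],
                            method = config$condorcet_method)
  frequency <- driver_frequency(panels, n_patients = length(kept_ids),
                                rare_cut = config$rare_cut)
  benchmark <- if (!is.null(gold))
    benchmark_topk(ranking, gold,
                   k = min(config$top_k, nrow(ranking$ranking)))
  else NULL

  reports <- lapply(samples[ok], function(s) {
    rep <- s$report
    if (!is.null(pirs_tbl) && s$sample_id %in% pirs_tbl$sample_id) {
      rep$pirs <- pirs_tbl$pirs[pirs_tbl$sample_id == s$sample_id]
      if ("group" %in% names(pirs_tbl))
        rep$pirs_group <- as.character(
          pirs_tbl$group[pirs_tbl$sample_id == s$sample_id])
    }
    rare <- frequency$gene[frequency$rare]
    rare_in_panel <- intersect(rep$panel$gene, rare)
    if (length(rare_in_panel) > 0L)
      rep$flags <- union(rep$flags,
                         paste0("rare driver(s): ",
                                paste(rare_in_panel, collapse = ",")))
    rep
  })

  accounting <- tibble::tibble(
    n_input = length(ids),
    n_hypermutated = length(hyper),
    n_no_panel = sum(!ok),
    n_reports = sum(ok))
  structure(list(samples = samples, panels = panels, hazards = hazards,
                 pirs = pirs_tbl, cutoff = cutoff, ranking = ranking,
                 frequency = frequency, benchmark = benchmark,
                 accounting = accounting, reports = reports,
                 hypermutated = hyper, config = config),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  acc <- x$accounting
  cat("<cohort_result> ", acc$n_input, " input samples: ", acc$n_reports,
      " reports, ", acc$n_hypermutated, " hypermutation skips, ",
      acc$n_no_panel, " no-panel records\n", sep = "")
  print(x$ranking)
  invisible(x)
}

#' Tidiers for cohort results
#'
#' `tidy()` returns the cohort panel table (one row per driver per
#' patient); `glance()` the accounting summary with the selected PiRS
#' cutoff when available.
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @method tidy cohort_result
#' @export
tidy.cohort_result <- function(x, ...) x$panels

#' @rdname tidy.cohort_result
#' @method glance cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  out <- x$accounting
  out$pirs_cutoff <- if (is.null(x$cutoff)) NA_real_ else x$cutoff$cutoff
  out$logrank_p <- if (is.null(x$cutoff)) NA_real_ else x$cutoff$logrank_p
  out
}

#' Write the cohort result tables as TSVs
#'
#' Emits deterministic TSVs: panels, gene hazards, PiRS scores with groups,
#' cohort ranking, driver frequencies, benchmark row and the per-patient
#' tier counts (iAct / iActE) echoing the actionability accounting.
#'
#' @param result A `cohort_result`.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv_plain(df, p)
    paths[[name]] <<- p
  }
  emit(result$panels, "ipanels.tsv")
  emit(tidy(result$ranking), "ranking.tsv")
  emit(result$frequency, "driver_frequency.tsv")
  if (!is.null(result$hazards)) emit(result$hazards, "gene_hazards.tsv")
  if (!is.null(result$pirs)) emit(result$pirs, "pirs.tsv")
  if (!is.null(result$benchmark)) emit(result$benchmark, "benchmark.tsv")
  tiers <- dplyr::bind_rows(lapply(result$reports, function(r) {
    tibble::tibble(sample_id = r$sample_id, n_iact = nrow(r$iact),
                   n_iacte = nrow(r$iacte),
                   actionable = nrow(r$iact) + nrow(r$iacte) > 0)
  }))
  if (nrow(tiers) > 0L) emit(tiers, "actionability_summary.tsv")
  emit(result$accounting, "accounting.tsv")
  invisible(paths)
}
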