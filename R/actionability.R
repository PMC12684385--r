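#' Triage panel genes by expression perturbation strength
#'
#' Keeps genes whose expression fold change exceeds `fold_cut` in magnitude
#' (strictly): with the default cutoff of 2, `|log2fc| > 1`. Genes with no
#' expression value are retained but flagged, so that downstream pairing can
#' exclude them from direction-dependent rules.
#'
#' @param genes Character vector of panel genes, or a tibble with a `gene`
#'   column.
#' @param log2fc Named numeric vector (gene -> log2 fold change) or a tibble
#'   with columns `gene`, `log2fc`.
#' @param fold_cut Linear fold-change cutoff (default 2.0, strict).
#' @return Tibble `gene`, `log2fc`, `direction` (`up`/`down`/`unknown`),
#'   `missing_expression`, restricted to genes passing the triage (missing
#'   expression passes with the flag set).
#' @export
triage_perturbed <- function(genes, log2fc, fold_cut = 2.0) {
  if (is.data.frame(genes)) genes <- genes$gene
  if (is.data.frame(log2fc))
    log2fc <- stats::setNames(log2fc$log2fc, log2fc$gene)
  lfc <- unname(log2fc[genes])
  missing <- is.na(lfc)
  keep <- missing | (abs(lfc) > log2(fold_cut))
  tibble::tibble(gene = genes[keep],
                 log2fc = lfc[keep],
                 direction = dplyr::case_when(
                   is.na(lfc[keep]) ~ "unknown",
                   lfc[keep] > 0 ~ "up",
                   TRUE ~ "down"),
                 missing_expression = missing[keep])
}

#' Classify a gene on the expression-by-function actionability matrix
#'
#' Two rules produce a recommendation: an upregulated oncogene is paired
#' with inhibitor-mode drugs, and a tumour suppressor (whether up- or
#' downregulated) with activator-mode drugs. Everything else — downregulated
#' oncogenes, unknown roles, unknown directions — is classified
#' undetermined with no recommendation. A gene matching a rule but with no
#' drug of the recommended mode is reported actionable-without-matched-drug.
#'
#' @param gene Gene symbol.
#' @param direction `"up"`, `"down"` or `"unknown"`.
#' @param role `"oncogene"`, `"tsg"` or `"unknown"`.
#' @param drugs Tibble with columns `gene`, `drug`, `mode` (the reference
#'   table; only rows for `gene` are used), or `NULL`.
#' @param tier `"iAct"` (panel gene) or `"iActE"` (extended DEG neighbour).
#' @return One-row tibble: `gene`, `direction`, `role`, `recommended_mode`
#'   (`inhibitor`/`activator`/`undetermined`), `drugs` (comma-separated
#'   matching-mode drugs, `""` when none), `n_drugs`, `tier`.
#' @export
classify_action <- function(gene, direction, role, drugs = NULL,
                            tier = "iAct") {
  mode <- if (direction == "up" && role == "oncogene") "inhibitor"
          else if (role == "tsg" && direction %in% c("up", "down")) "activator"
          else "undetermined"
  matched <- character(0)
  if (mode != "undetermined" && !is.null(drugs)) {
    matched <- sort(drugs$drug[drugs$gene == gene & drugs$mode == mode])
  }
  tibble::tibble(gene = gene, direction = direction, role = role,
                 recommended_mode = mode,
                 drugs = paste(matched, collapse = ","),
                 n_drugs = length(matched), tier = tier)
}

# role lookup with "unknown" default
lookup_role <- function(genes, roles) {
  r <- roles$role[match(genes, roles$gene)]
  ifelse(is.na(r), "unknown", r)
}

#' Action pairs for a patient's iPanel genes (iAct tier)
#'
#' Applies the expression triage ([triage_perturbed()]) and the
#' actionability matrix ([classify_action()]) to the panel genes. Genes with
#' missing expression are direction-unknown and therefore receive no
#' recommendation.
#'
#' @param panel An `ipanel` or tibble with a `gene` column.
#' @param log2fc Named vector or tibble (`gene`, `log2fc`) for this patient.
#' @param roles Tibble `gene`, `role`.
#' @param drugs Tibble `gene`, `drug`, `mode`.
#' @param fold_cut Triage fold-change cutoff (default 2.0).
#' @return Tibble of action-pair rows (see [classify_action()]), tier
#'   `iAct`, one row per triaged panel gene.
#' @export
iact_pairs <- function(panel, log2fc, roles, drugs, fold_cut = 2.0) {
  genes <- if (inherits(panel, "ipanel")) panel$entries$gene else panel$gene
  tri <- triage_perturbed(genes, log2fc, fold_cut)
  if (nrow(tri) == 0L) return(empty_action_pairs())
  dplyr::bind_rows(lapply(seq_len(nrow(tri)), function(i) {
    classify_action(tri$gene[i], tri$direction[i],
                    lookup_role(tri$gene[i], roles), drugs, tier = "iAct")
  }))
}

empty_action_pairs <- function() {
  tibble::tibble(gene = character(), direction = character(),
                 role = character(), recommended_mode = character(),
                 drugs = character(), n_drugs = integer(), tier = character())
}

#' Extended action pairs over downstream DEGs (iActE tier)
#'
#' When a patient's panel genes are not themselves targetable, their
#' perturbed downstream genes often are. Candidates are the DEGs within
#' `max_hops` directed hops of any panel gene in the Mutpaths union graph,
#' excluding the panel genes themselves; each is classified on the same
#' actionability matrix using its own expression direction, and only
#' candidates with a determined recommendation are emitted.
#'
#' @param panel An `ipanel` or tibble with a `gene` column.
#' @param mp The patient's `mutpaths` object.
#' @param log2fc Named vector or tibble (`gene`, `log2fc`).
#' @param roles,drugs Reference tables as in [iact_pairs()].
#' @param max_hops Hop horizon (default 4).
#' @return Tibble of action-pair rows, tier `iActE`.
#' @export
extend_iacte <- function(panel, mp, log2fc, roles, drugs, max_hops = 4) {
  genes <- if (inherits(panel, "ipanel")) panel$entries$gene else panel$gene
  genes <- intersect(genes, mp$nodes)
  if (length(genes) == 0L) return(empty_action_pairs())
  cand <- sort(setdiff(
    unique(unlist(lapply(genes, covered_degs, mp = mp, max_hops = max_hops))),
    genes))
  if (length(cand) == 0L) return(empty_action_pairs())
  if (is.data.frame(log2fc))
    log2fc <- stats::setNames(log2fc$log2fc, log2fc$gene)
  lfc <- log2fc[cand]
  dirs <- dplyr::case_when(is.na(lfc) ~ "unknown", lfc > 0 ~ "up",
                           TRUE ~ "down")
  rows <- dplyr::bind_rows(lapply(seq_along(cand), function(i) {
    classify_action(cand[i], dirs[i], lookup_role(cand[i], roles), drugs,
                    tier = "iActE")
  }))
  rows[rows$recommended_mode != "undetermined", , drop = FALSE]
}

#' Consolidated per-patient action report
#'
#' Bundles a patient's panel, risk score, action pairs and warnings into a
#' single list that serializes to JSON and round-trips losslessly.
#'
#' @param sample_id Sample identifier.
#' @param panel An `ipanel` object (required).
#' @param pirs Numeric risk score or `NULL` when no survival data.
#' @param pirs_group `"low"`, `"high"` or `NULL`.
#' @param iact,iacte Action-pair tibbles (default empty).
#' @param flags Character vector of warnings (rare drivers, unattained
#'   coverage, undefined hazards, ...).
#' @param percentile_used Mutpaths percentile the panel was built from.
#' @return List of class `action_report`.
#' @export
build_report <- function(sample_id, panel, pirs = NULL, pirs_group = NULL,
                         iact = empty_action_pairs(),
                         iacte = empty_action_pairs(),
                         flags = character(0), percentile_used = 1e-4) {
  if (is.null(panel) || !inherits(panel, "ipanel"))
    stop("an iPanel is required to build a report for sample ", sample_id)
  if (!panel$attained) flags <- union(flags, "coverage target not attained")
  if (nrow(iact) == 0L && nrow(iacte) == 0L)
    flags <- union(flags, "no action available")
  structure(list(
    sample_id = sample_id,
    panel = tidy(panel),
    coverage = panel$coverage,
    attained = panel$attained,
    pirs = if (is.null(pirs)) NA_real_ else pirs,
    pirs_group = if (is.null(pirs_group)) NA_character_
                 else as.character(pirs_group),
    iact = iact,
    iacte = iacte,
    flags = flags,
    percentile_used = percentile_used),
    class = "action_report")
}

#' @export
print.action_report <- function(x, ...) {
  cat("<action_report> sample ", x$sample_id, ": panel of ",
      nrow(x$panel), " gene(s) [", paste(x$panel$gene, collapse = ", "),
      "], coverage ", sprintf("%.0f%%", 100 * x$coverage),
      ", PiRS ", ifelse(is.na(x$pirs), "NA", format(round(x$pirs, 3))),
      ", ", nrow(x$iact), " iAct / ", nrow(x$iacte), " iActE pair(s)\n",
      sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize / parse an action report as JSON
#'
#' @param report An `action_report`.
#' @param path Output file.
#' @return `path` invisibly; [read_report()] returns the parsed
#'   `action_report`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$panel <- tibble::as_tibble(x$panel)
  x$iact <- if (length(x$iact)) tibble::as_tibble(x$iact)
            else empty_action_pairs()
  x$iacte <- if (length(x$iacte)) tibble::as_tibble(x$iacte)
             else empty_action_pairs()
  x$flags <- as.character(unlist(x$flags))
  x$pirs <- if (is.null(x$pirs)) NA_real_ else x$pirs
  x$pirs_group <- if (is.null(x$pirs_group)) NA_character_ else x$pirs_group
  class(x) <- "action_report"
  x
}
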