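#' Univariate Cox hazard ratio for a binary gene indicator
#'
#' Fits a Cox proportional-hazards model with a single binary covariate —
#' whether the gene belongs to the sample's driver panel — and reports the
#' hazard ratio `exp(beta)` with its Wald confidence interval. Degenerate
#' designs (no events, a single-level indicator, or too few events) yield an
#' undefined hazard with an explanatory flag instead of an error, so that
#' cohort-level scans can proceed.
#'
#' @param records Tibble with columns `sample_id`, `time_months`, `event`.
#' @param carriers Character vector of sample ids carrying the gene, or a
#'   logical/0-1 vector aligned with `records`.
#' @param gene Optional gene symbol echoed in the output.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return One-row tibble: `gene`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `n_carriers`, `n_events`, `flag` (`"ok"` or the reason the hazard is
#'   undefined, in which case `hr` is `NA`).
#' @export
fit_cox_hr <- function(records, carriers, gene = NA_character_,
                       conf_level = 0.95) {
  stopifnot(all(c("sample_id", "time_months", "event") %in% names(records)))
  x <- if (is.character(carriers)) as.integer(records$sample_id %in% carriers)
       else as.integer(carriers)
  base <- tibble::tibble(gene = gene, hr = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_,
                         n_carriers = sum(x), n_events = sum(records$event))
  if (sum(records$event) < 2)
    return(dplyr::mutate(base, flag = "fewer than 2 events"))
  if (length(unique(x)) < 2)
    return(dplyr::mutate(base, flag = "zero-variance carrier indicator"))
  fit <- tryCatch(
    survival::coxph(survival::Surv(records$time_months, records$event) ~ x),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(
        survival::coxph(survival::Surv(records$time_months, records$event) ~ x))
    })
  if (is.null(fit) || !is.finite(stats::coef(fit)[1]))
    return(dplyr::mutate(base, flag = "fit did not converge"))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  dplyr::mutate(base,
                hr = exp(beta),
                ci_low = exp(beta - z * se),
                ci_high = exp(beta + z * se),
                p = 2 * stats::pnorm(-abs(beta / se)),
                flag = "ok")
}

#' Per-gene hazard ratios across a cohort's iPanels
#'
#' For every gene appearing in at least one panel, fits [fit_cox_hr()] with
#' panel membership as the carrier indicator. When `joint = TRUE`, a joint
#' (multivariable) Cox fit over all panel genes is attempted first and
#' per-gene hazards are taken from it when it converges with finite
#' estimates, falling back to the univariate fits otherwise — joint fits on
#' rare genes frequently fail.
#'
#' @param panels Tibble with columns `sample_id`, `gene` (one row per panel
#'   membership).
#' @param records Survival tibble (`sample_id`, `time_months`, `event`).
#' @param joint Attempt a joint fit over all genes first (default FALSE).
#' @return Tibble of per-gene hazard rows (see [fit_cox_hr()]) plus a
#'   `source` column (`"joint"` or `"univariate"`).
#' @export
gene_hazards <- function(panels, records, joint = FALSE) {
  genes <- sort(unique(panels$gene))
  uni <- dplyr::bind_rows(lapply(genes, function(g) {
    fit_cox_hr(records, carriers = panels$sample_id[panels$gene == g],
               gene = g)
  }))
  uni$source <- "univariate"
  if (!joint || length(genes) < 2) return(uni)
  X <- vapply(genes, function(g)
    as.integer(records$sample_id %in% panels$sample_id[panels$gene == g]),
    integer(nrow(records)))
  ok_cols <- apply(X, 2, function(v) length(unique(v)) > 1)
  fit <- tryCatch(suppressWarnings(
    survival::coxph(survival::Surv(records$time_months, records$event) ~
                      X[, ok_cols, drop = FALSE])),
    error = function(e) NULL)
  if (is.null(fit)) return(uni)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  fine <- is.finite(beta) & is.finite(se) & se < 10
  jgenes <- genes[ok_cols][fine]
  uni[match(jgenes, uni$gene), c("hr", "ci_low", "ci_high", "p", "source")] <-
    tibble::tibble(hr = exp(beta[fine]),
                   ci_low = exp(beta[fine] - 1.96 * se[fine]),
                   ci_high = exp(beta[fine] + 1.96 * se[fine]),
                   p = 2 * stats::pnorm(-abs(beta[fine] / se[fine])),
                   source = "joint")
  uni
}

#' PiRS: panel-level prognosis risk score for one patient
#'
#' The risk score is the sum over the patient's iPanel of
#' `netscore * hazard ratio`, combining how central each driver is in the
#' patient's perturbed subnetwork with its cohort-level survival effect.
#' Panel genes with an undefined hazard are skipped with a warning rather
#' than imputed.
#'
#' @param panel An `ipanel` object, or a tibble with columns `gene`,
#'   `netscore`.
#' @param hazards Tibble from [gene_hazards()] (columns `gene`, `hr`).
#' @return Numeric risk score (0 for an empty panel, with a warning).
#' @examples
#' panel <- tibble::tibble(gene = c("A", "B"), netscore = c(2, 3))
#' hz <- tibble::tibble(gene = c("A", "B"), hr = c(1.5, 0.5))
#' pirs(panel, hz)  # 2*1.5 + 3*0.5 = 4.5
#' @export
pirs <- function(panel, hazards) {
  entries <- if (inherits(panel, "ipanel")) panel$entries else panel
  if (nrow(entries) == 0L) {
    warning("empty panel: PiRS is 0")
    return(0)
  }
  hr <- hazards$hr[match(entries$gene, hazards$gene)]
  bad <- is.na(hr)
  if (any(bad))
    warning("panel gene(s) without a defined hazard skipped from PiRS: ",
            paste(entries$gene[bad], collapse = ", "))
  sum(entries$netscore[!bad] * hr[!bad])
}

#' PiRS scores for a cohort
#'
#' @param panels Tibble `sample_id`, `gene`, `netscore` (cohort panel
#'   memberships).
#' @param hazards Tibble from [gene_hazards()].
#' @return Tibble `sample_id`, `pirs`.
#' @export
pirs_scores <- function(panels, hazards) {
  hr <- hazards$hr[match(panels$gene, hazards$gene)]
  ok <- !is.na(hr)
  dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(sample_id = panels$sample_id,
                     term = ifelse(ok, panels$netscore * hr, 0)),
      .data$sample_id),
    pirs = sum(.data$term), .groups = "drop")
}

# log-rank p for a low/high split of the cohort at `cutoff`
logrank_p_at <- function(scores, records, cutoff) {
  grp <- factor(ifelse(scores >= cutoff, "high", "low"),
                levels = c("low", "high"))
  sd <- survival::survdiff(
    survival::Surv(records$time_months, records$event) ~ grp)
  stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
}

#' Scan PiRS cutoffs for the best survival stratification
#'
#' Evaluates candidate cutoffs at score percentiles, splits the cohort into
#' PiRS-low / PiRS-high at each, and returns the cutoff minimizing the
#' log-rank p-value subject to both groups holding at least
#' `min_group_frac` of the cohort. Ties go to the cutoff nearest the median
#' score. Because the minimum over a grid is an optimistic statistic, an
#' optional permutation adjustment re-scans permuted scores and reports the
#' rank-based adjusted p.
#'
#' @param scores Tibble `sample_id`, `pirs` (or a numeric vector aligned
#'   with `records`).
#' @param records Survival tibble (`sample_id`, `time_months`, `event`).
#' @param grid Percentile grid for candidate cutoffs
#'   (default `seq(0.10, 0.90, by = 0.05)`).
#' @param min_group_frac Minimum fraction of the cohort per group
#'   (default 0.10).
#' @param n_perm Number of score permutations for the adjusted p
#'   (default 0 = skip).
#' @return List of class `pirs_cutoff`: `cutoff`, `logrank_p`,
#'   `adjusted_p` (NA when `n_perm = 0`), `perm_min_p` (numeric vector),
#'   `scan` (tibble `cutoff`, `percentile`, `n_low`, `n_high`, `p`),
#'   `groups` (tibble `sample_id`, `pirs`, `group`).
#' @export
scan_pirs_cutoff <- function(scores, records,
                             grid = seq(0.10, 0.90, by = 0.05),
                             min_group_frac = 0.10, n_perm = 0) {
  if (is.data.frame(scores)) {
    s <- scores$pirs[match(records$sample_id, scores$sample_id)]
  } else s <- scores
  if (length(s) != nrow(records) || anyNA(s))
    stop("every survival record needs a PiRS score")
  if (nrow(records) < 20) stop("cutoff scan needs >= 20 samples")
  if (length(unique(s)) < 2) stop("no stratification possible: all scores identical")

  scan_once <- function(sv) {
    cuts <- unique(stats::quantile(sv, probs = grid, type = 7))
    res <- lapply(cuts, function(ct) {
      n_high <- sum(sv >= ct)
      n_low <- length(sv) - n_high
      if (min(n_high, n_low) < min_group_frac * length(sv))
        return(NULL)
      tibble::tibble(cutoff = ct, n_low = n_low, n_high = n_high,
                     p = logrank_p_at(sv, records, ct))
    })
    dplyr::bind_rows(res)
  }

  scan <- scan_once(s)
  if (nrow(scan) == 0L)
    stop("no cutoff satisfies the minimum group-size constraint")
  best_p <- min(scan$p)
  cand <- scan[scan$p == best_p, , drop = FALSE]
  med <- stats::median(s)
  best <- cand[order(abs(cand$cutoff - med), cand$cutoff), ][1, ]

  perm_min_p <- numeric(0)
  adjusted_p <- NA_real_
  if (n_perm > 0) {
    perm_min_p <- vapply(seq_len(n_perm), function(i) {
      sp <- sample(s)
      ps <- scan_once(sp)
      if (nrow(ps) == 0L) return(NA_real_)
      min(ps$p)
    }, numeric(1))
    perm_min_p <- perm_min_p[!is.na(perm_min_p)]
    adjusted_p <- (1 + sum(perm_min_p <= best_p)) / (1 + length(perm_min_p))
  }

  groups <- tibble::tibble(
    sample_id = records$sample_id, pirs = s,
    group = factor(ifelse(s >= best$cutoff, "high", "low"),
                   levels = c("low", "high")))
  structure(list(cutoff = best$cutoff, logrank_p = best$p,
                 adjusted_p = adjusted_p, perm_min_p = perm_min_p,
                 scan = scan, groups = groups, records = records),
            class = "pirs_cutoff")
}

#' @export
print.pirs_cutoff <- function(x, ...) {
  cat("<pirs_cutoff> cutoff =", format(x$cutoff),
      " log-rank p =", format.pval(x$logrank_p),
      if (!is.na(x$adjusted_p))
        paste(" permutation-adjusted p =", format.pval(x$adjusted_p)),
      "\n")
  invisible(x)
}

#' Tidiers for the PiRS cutoff scan
#'
#' `tidy()` returns the scan table (one row per candidate cutoff);
#' `glance()` the selected cutoff with its p-values.
#'
#' @param x A `pirs_cutoff` object.
#' @param ... Unused.
#' @method tidy pirs_cutoff
#' @export
tidy.pirs_cutoff <- function(x, ...) x$scan

#' @rdname tidy.pirs_cutoff
#' @method glance pirs_cutoff
#' @export
glance.pirs_cutoff <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, logrank_p = x$logrank_p,
                 adjusted_p = x$adjusted_p,
                 n_low = sum(x$groups$group == "low"),
                 n_high = sum(x$groups$group == "high"))
}

#' Kaplan-Meier curves for the PiRS-low / PiRS-high split
#'
#' @param object A `pirs_cutoff` object.
#' @param ... Unused.
#' @return A ggplot object with one product-limit curve per group.
#' @method autoplot pirs_cutoff
#' @export
autoplot.pirs_cutoff <- function(object, ...) {
  rec <- object$records
  fit <- survival::survfit(
    survival::Surv(rec$time_months, rec$event) ~ object$groups$group)
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(time = fit$time, surv = fit$surv,
                       group = sub(".*=", "", strata))
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = unique(df$group)), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = "PiRS group",
                  subtitle = sprintf("log-rank p = %.2g", object$logrank_p)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
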