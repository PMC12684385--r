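test_that("Cox hazard is ~1 for identical groups and flagged when degenerate", {
  rec <- tibble::tibble(sample_id = paste0("S", 1:40),
                        time_months = rep(c(5, 10, 15, 20, 25, 30, 35, 40,
                                            45, 50), 4),
                        event = rep(c(1, 1, 0, 1), 10))
  carriers <- rec$sample_id[1:20]   # same time/event pattern as the rest
  fit <- fit_cox_hr(rec, carriers)
  expect_equal(fit$flag, "ok")
  expect_lt(abs(log(fit$hr)), 0.05)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # all-censored cohort
  rec0 <- dplyr::mutate(rec, event = 0)
  fit0 <- fit_cox_hr(rec0, carriers)
  expect_true(is.na(fit0$hr))
  expect_match(fit0$flag, "events")

  # single-level indicator
  fit1 <- fit_cox_hr(rec, rec$sample_id)
  expect_true(is.na(fit1$hr))
  expect_match(fit1$flag, "zero-variance")
})

test_that("Cox recovers a planted carrier log-hazard from simulated survival", {
  sim <- simulate_survival(500, log_hr = log(2), censoring = 0.2, seed = 31)
  fit <- fit_cox_hr(sim, sim$sample_id[sim$carrier == 1])
  expect_lt(abs(log(fit$hr) - log(2)), 0.15)
  # bias shrinks with n (checked at two sizes)
  sim_small <- simulate_survival(100, log_hr = log(2), seed = 32)
  fit_small <- fit_cox_hr(sim_small, sim_small$sample_id[sim_small$carrier == 1])
  expect_lt(abs(log(fit$hr) - log(2)) , 0.5)
  expect_true(is.finite(fit_small$hr))
})

test_that("PiRS is the netscore-weighted hazard sum with linearity", {
  panel <- tibble::tibble(gene = c("A", "B"), netscore = c(2, 3))
  hz <- tibble::tibble(gene = c("A", "B"), hr = c(1.5, 0.5))
  expect_equal(pirs(panel, hz), 4.5)
  expect_equal(pirs(tibble::tibble(gene = "G", netscore = 10),
                    tibble::tibble(gene = "G", hr = 2)), 20)
  expect_warning(p0 <- pirs(panel[0, ], hz), "empty panel")
  expect_equal(p0, 0)
  # undefined hazards are skipped with a warning, not imputed
  hz_na <- tibble::tibble(gene = c("A", "B"), hr = c(1.5, NA))
  expect_warning(p1 <- pirs(panel, hz_na), "skipped")
  expect_equal(p1, 3)
  # doubling all hazards doubles the score
  hz2 <- dplyr::mutate(hz, hr = hr * 2)
  expect_equal(pirs(panel, hz2), 2 * pirs(panel, hz))
  expect_gte(pirs(panel, hz), 0)
})

test_that("cohort PiRS scores aggregate per sample", {
  panels <- tibble::tibble(sample_id = c("S1", "S1", "S2"),
                           gene = c("A", "B", "A"),
                           netscore = c(2, 3, 1))
  hz <- tibble::tibble(gene = c("A", "B"), hr = c(1.5, 0.5))
  sc <- pirs_scores(panels, hz)
  expect_equal(sc$pirs[sc$sample_id == "S1"], 4.5)
  expect_equal(sc$pirs[sc$sample_id == "S2"], 1.5)
})

test_that("cutoff scan finds a planted split and respects group-size floors", {
  set.seed(41)
  n <- 300
  score <- stats::runif(n, 0, 100)
  high <- score > stats::median(score)
  t_true <- stats::rexp(n, rate = 0.02 * ifelse(high, 3, 1))
  cens <- stats::rbinom(n, 1, 0.2) == 1
  rec <- tibble::tibble(sample_id = paste0("S", 1:n),
                        time_months = ifelse(cens, t_true * stats::runif(n),
                                             t_true),
                        event = as.integer(!cens))
  scores <- tibble::tibble(sample_id = rec$sample_id, pirs = score)
  scan <- scan_pirs_cutoff(scores, rec)
  expect_lt(scan$logrank_p, 0.01)
  band <- stats::quantile(score, c(0.40, 0.60))
  expect_true(scan$cutoff >= band[1] && scan$cutoff <= band[2])
  expect_true(all(table(scan$groups$group) >= 0.1 * n))

  # selection is invariant under strictly monotone score transforms
  scan2 <- scan_pirs_cutoff(dplyr::mutate(scores, pirs = log1p(pirs)), rec)
  expect_equal(scan2$logrank_p, scan$logrank_p)
  expect_equal(as.character(scan2$groups$group),
               as.character(scan$groups$group))

  # two distinct score values force the single separating cutoff
  scores3 <- tibble::tibble(sample_id = rec$sample_id,
                            pirs = rep(c(1, 9), length.out = n))
  scan3 <- scan_pirs_cutoff(scores3, rec)
  expect_equal(sum(scan3$groups$group == "high"), sum(scores3$pirs == 9))

  expect_error(
    scan_pirs_cutoff(dplyr::mutate(scores, pirs = 1), rec),
    "no stratification")
  expect_error(scan_pirs_cutoff(scores[1:10, ], rec[1:10, ]), ">= 20")
})

test_that("joint hazard fits fall back to univariate estimates when needed", {
  sim <- simulate_survival(200, log_hr = log(2), seed = 55)
  panels <- tibble::tibble(
    sample_id = c(sim$sample_id[sim$carrier == 1], sim$sample_id[1:5]),
    gene = c(rep("CARRIER", sum(sim$carrier)), rep("RARE", 5)))
  hz <- gene_hazards(panels, sim, joint = TRUE)
  expect_setequal(hz$gene, c("CARRIER", "RARE"))
  expect_true(all(hz$hr[!is.na(hz$hr)] > 0))
  hz_uni <- gene_hazards(panels, sim, joint = FALSE)
  expect_true(all(hz_uni$source == "univariate"))
})

test_that("cutoff scan tidiers and KM plot summarize the stratification", {
  sim <- simulate_survival(100, log_hr = log(3), seed = 61)
  scores <- tibble::tibble(sample_id = sim$sample_id,
                           pirs = sim$carrier * 10 + stats::runif(100))
  scan <- scan_pirs_cutoff(scores, sim)
  expect_true(all(c("cutoff", "p") %in% names(tidy(scan))))
  expect_equal(nrow(glance(scan)), 1L)
  expect_s3_class(autoplot(scan), "ggplot")
})
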