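#' Specification for a synthetic cohort with planted ground truth
#'
#' Collects the generator's parameters: network size and density, per-patient
#' planted drivers and their downstream expression cascades, passenger
#' mutations, and the survival model. The defaults define a compact reference
#' cohort — a 200-gene directed network with heavy-tailed out-degree, 50
#' patients carrying 1–2 planted drivers with upregulated cascades reaching
#' at least 70% of their DEGs within 4 hops, and 5 passenger mutations drawn
#' from low-influence nodes — small enough to run the full pipeline in
#' seconds while exercising every stage.
#'
#' @param n_genes Number of network nodes (default 200, >= 20).
#' @param mean_out_degree Mean out-degree of the network (default 3).
#' @param degree_sdlog Log-sd of the lognormal out-degree law (default 0.8;
#'   heavier tails for larger values).
#' @param n_patients Cohort size (default 50).
#' @param drivers_per_patient Integer vector sampled uniformly for the number
#'   of planted drivers (default `1:2`).
#' @param n_passengers Passenger mutations per patient (default 5).
#' @param cascade_depth Hops of the planted expression cascade (default 3,
#'   must be <= 4 so the panel horizon can see it). The cascade has two
#'   tiers: all downstream nodes strictly closer than `cascade_depth`
#'   (nearest first, capped by `n_cascade`) plus `n_deep` nodes at exactly
#'   `cascade_depth` hops. The deep tier mimics the limited deep propagation
#'   of a signalling cascade and bounds the number of all-cascade least-cost
#'   paths each driver emits, so the mined top-path subnetwork samples every
#'   planted driver instead of being monopolized by one.
#' @param n_cascade Cap on cascade genes per driver (default 40).
#' @param n_deep Upregulated nodes at exactly `cascade_depth` hops per
#'   driver (default 5).
#' @param effect Mean log2 fold change of cascade genes (default 2, >= 1.5).
#' @param noise_sd Expression noise sd on the log2 scale (default 0.25).
#' @param driver_reach_min Minimum 4-hop reach for a node to be eligible as
#'   a planted driver (default 30 nodes).
#' @param passenger_reach_max Maximum 4-hop reach for passenger eligibility
#'   (default 10 nodes).
#' @param baseline_rate Baseline exponential hazard per month
#'   (default 0.02, median survival about 35 months).
#' @param driver_log_hazard Additive log-hazard per planted driver carried
#'   (default `log(2)`).
#' @param censoring Independent censoring fraction (default 0.3).
#' @param frac_role Fraction of genes annotated with a role in the synthetic
#'   actionability reference (default 0.4).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, mean_out_degree = 3,
                           degree_sdlog = 0.8, n_patients = 50,
                           drivers_per_patient = 1:2, n_passengers = 5,
                           cascade_depth = 3, n_cascade = 40, n_deep = 5,
                           effect = 2,
                           noise_sd = 0.25, driver_reach_min = 30,
                           passenger_reach_max = 10, baseline_rate = 0.02,
                           driver_log_hazard = log(2), censoring = 0.3,
                           frac_role = 0.4, seed = 20231) {
  stopifnot(n_genes >= 20, n_patients >= 1, cascade_depth <= 4,
            cascade_depth >= 1, noise_sd >= 0, censoring >= 0, censoring < 1,
            mean_out_degree > 0, all(drivers_per_patient >= 1))
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a directed gene network with heavy-tailed out-degree
#'
#' Out-degrees follow a lognormal law with the requested mean; edge targets
#' are sampled with lognormal attractiveness weights so in-degree is also
#' skewed. Self-loops and duplicate edges are excluded, and nodes outside
#' the weakly connected giant component are attached to it so that at least
#' 90% of nodes (in practice all) are mutually reachable ignoring direction.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `gene_network` tibble with gene symbols `g0001`, `g0002`, ...
#' @export
generate_network <- function(spec) {
  n <- spec$n_genes
  if (spec$mean_out_degree >= n - 1)
    stop("infeasible density: mean out-degree must be < n_genes - 1")
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(n))
  meanlog <- log(spec$mean_out_degree) - spec$degree_sdlog^2 / 2
  deg <- pmin(n - 1L,
              pmax(1L, round(stats::rlnorm(n, meanlog, spec$degree_sdlog))))
  attract <- stats::rlnorm(n, 0, 1)
  edges <- lapply(seq_len(n), function(i) {
    targets <- sample(genes[-i], size = deg[i], prob = attract[-i])
    tibble::tibble(from = genes[i], to = targets)
  })
  net <- as_gene_network(dplyr::bind_rows(edges))
  g <- as_igraph_network(net)
  comp <- igraph::components(g, mode = "weak")
  if (comp$no > 1L) {
    giant <- which.max(comp$csize)
    anchors <- names(comp$membership)[comp$membership == giant]
    stray <- names(comp$membership)[comp$membership != giant]
    extra <- tibble::tibble(from = sample(anchors, length(stray),
                                          replace = TRUE),
                            to = stray)
    net <- as_gene_network(dplyr::bind_rows(tibble::as_tibble(net), extra))
  }
  net
}

# 4-hop (or `order`-hop) downstream reach of every node, excluding itself
node_reach <- function(net, order = 4) {
  g <- as_igraph_network(net)
  sizes <- igraph::ego_size(g, order = order, mode = "out")
  stats::setNames(sizes - 1L, igraph::V(g)$name)
}

#' Generate one synthetic patient with planted drivers
#'
#' Planted drivers are sampled from nodes whose 4-hop downstream reach meets
#' `driver_reach_min` and that support a deep cascade tier; their cascade —
#' all downstream nodes strictly closer than `cascade_depth` hops (nearest
#' first, capped by `n_cascade`) plus `n_deep` nodes at exactly
#' `cascade_depth` hops — receives upregulated expression
#' (`log2fc ~ N(effect, noise_sd)`, FDR 0.001) so the DEG filter retains it,
#' while all other genes receive null expression (`log2fc ~ N(0, noise_sd)`,
#' FDR 0.5) and fail the filter. Passenger mutations are drawn uniformly
#' from low-reach nodes outside the cascades.
#'
#' @param net A `gene_network`.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for this patient.
#' @param sample_id Sample identifier.
#' @param reach Optional precomputed [node_reach] vector (recomputed when
#'   `NULL`).
#' @param dists Optional precomputed directed distance matrix
#'   (`igraph::distances(..., mode = "out")`); recomputed when `NULL`.
#' @return List: `sample_id`, `mutations` (tibble `sample_id`, `gene`),
#'   `expression` (tibble `sample_id`, `gene`, `log2fc`, `fdr` over all
#'   network genes), `truth` (tibble `sample_id`, `gene`, `role` in
#'   \{driver, passenger\}, `n_cascade`).
#' @export
generate_patient <- function(net, spec, seed, sample_id = "S1",
                             reach = NULL, dists = NULL) {
  set.seed(seed)
  genes <- network_nodes(net)
  g <- as_igraph_network(net)
  if (is.null(dists)) dists <- igraph::distances(g, mode = "out")
  if (is.null(reach)) reach <- node_reach(net, order = 4)
  deep_avail <- rowSums(dists == spec$cascade_depth)
  eligible <- names(reach)[reach >= spec$driver_reach_min &
                             deep_avail[names(reach)] >= spec$n_deep]
  if (length(eligible) == 0L)
    stop("no node has 4-hop reach >= ", spec$driver_reach_min,
         " with a deep cascade tier; cannot plant a driver")
  n_driver <- if (length(spec$drivers_per_patient) == 1L)
    spec$drivers_per_patient else sample(spec$drivers_per_patient, 1)

  # each driver's potential downstream region, used to keep planted cascades
  # disjoint: overlapping cascades would let one driver's least-cost paths
  # cover the other's DEGs, collapsing the ground truth to a single driver
  region_of <- function(dv) {
    d <- dists[dv, ]
    c(dv, names(d)[is.finite(d) & d >= 1 & d <= spec$cascade_depth])
  }
  drivers <- character(0)
  taken <- character(0)
  for (cand in sample(eligible)) {
    r <- region_of(cand)
    if (length(intersect(r, taken)) == 0L) {
      drivers <- c(drivers, cand)
      taken <- c(taken, r)
    }
    if (length(drivers) == n_driver) break
  }
  if (length(drivers) == 0L)
    stop("could not plant any driver with a disjoint cascade region")

  cascade_of <- lapply(drivers, function(dv) {
    d <- dists[dv, ]
    shallow <- names(d)[is.finite(d) & d >= 1 & d < spec$cascade_depth]
    shallow <- shallow[order(d[shallow], shallow)]   # nearest first, then name
    deep <- names(d)[d == spec$cascade_depth]
    deep <- sample(deep, min(spec$n_deep, length(deep)))
    c(utils::head(shallow, max(0L, spec$n_cascade - length(deep))), deep)
  })
  cascade <- unique(unlist(cascade_of))

  lfc <- stats::rnorm(length(genes), 0, spec$noise_sd)
  fdr <- rep(0.5, length(genes))
  names(lfc) <- names(fdr) <- genes
  lfc[cascade] <- stats::rnorm(length(cascade), spec$effect, spec$noise_sd)
  fdr[cascade] <- 0.001

  low <- setdiff(names(reach)[reach <= spec$passenger_reach_max],
                 c(drivers, cascade))
  if (length(low) < spec$n_passengers)
    low <- utils::head(setdiff(names(sort(reach)), c(drivers, cascade)),
                       max(spec$n_passengers, length(low)))
  passengers <- sample(low, min(spec$n_passengers, length(low)))

  list(sample_id = sample_id,
       mutations = tibble::tibble(sample_id = sample_id,
                                  gene = sort(c(drivers, passengers))),
       expression = tibble::tibble(sample_id = sample_id, gene = genes,
                                   log2fc = unname(lfc), fdr = unname(fdr)),
       truth = tibble::tibble(
         sample_id = sample_id,
         gene = c(drivers, passengers),
         role = c(rep("driver", length(drivers)),
                  rep("passenger", length(passengers))),
         n_cascade = c(vapply(cascade_of, length, integer(1)),
                       rep(0L, length(passengers)))))
}

#' Generate a full synthetic cohort with survival and actionability tables
#'
#' Builds the network, all patients, exponential survival times whose
#' log-hazard is the baseline plus `driver_log_hazard` per planted driver,
#' independent censoring at the stated fraction, and a synthetic
#' actionability reference (roles for a fraction of genes, 1–2 drugs per
#' annotated gene with random mode). Everything is a deterministic function
#' of `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_cohort`: `network`, `mutations`,
#'   `expression`, `survival` (tibbles), `truth` (planted drivers and
#'   per-patient hazard multiplier), `roles`, `drugs`, `spec`.
#' @export
generate_cohort <- function(spec) {
  net <- generate_network(spec)
  reach <- node_reach(net, order = 4)
  dists <- igraph::distances(as_igraph_network(net), mode = "out")
  set.seed(spec$seed + 1L)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_patients)
  ids <- sprintf("P%03d", seq_len(spec$n_patients))
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    generate_patient(net, spec, seed = patient_seeds[i],
                     sample_id = ids[i], reach = reach, dists = dists)
  })
  mutations <- dplyr::bind_rows(lapply(patients, `[[`, "mutations"))
  expression <- dplyr::bind_rows(lapply(patients, `[[`, "expression"))
  truth <- dplyr::bind_rows(lapply(patients, `[[`, "truth"))

  set.seed(spec$seed + 2L)
  n_drivers <- vapply(ids, function(s)
    sum(truth$role == "driver" & truth$sample_id == s), integer(1))
  hazard <- spec$baseline_rate * exp(spec$driver_log_hazard * n_drivers)
  t_true <- stats::rexp(spec$n_patients, rate = hazard)
  censored <- stats::rbinom(spec$n_patients, 1, spec$censoring) == 1
  time <- ifelse(censored, t_true * stats::runif(spec$n_patients), t_true)
  survival <- tibble::tibble(sample_id = ids,
                             time_months = round(time, 3),
                             event = as.integer(!censored))
  truth_hazard <- tibble::tibble(sample_id = ids, n_drivers = n_drivers,
                                 hazard_multiplier = exp(spec$driver_log_hazard * n_drivers))

  set.seed(spec$seed + 3L)
  genes <- network_nodes(net)
  annotated <- sort(sample(genes, round(spec$frac_role * length(genes))))
  roles <- tibble::tibble(gene = annotated,
                          role = sample(c("oncogene", "tsg"),
                                        length(annotated), replace = TRUE))
  with_drug <- sort(sample(annotated, round(0.7 * length(annotated))))
  drugs <- dplyr::bind_rows(lapply(with_drug, function(gn) {
    k <- sample(1:2, 1)
    tibble::tibble(gene = gn,
                   drug = paste0("drug_", gn, "_", seq_len(k)),
                   mode = sample(c("inhibitor", "activator"), k,
                                 replace = TRUE))
  }))

  structure(list(network = net, mutations = mutations,
                 expression = expression, survival = survival,
                 truth = truth, truth_hazard = truth_hazard,
                 roles = roles, drugs = drugs, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$spec$n_patients, " patients, network of ",
      length(network_nodes(x$network)), " genes / ", nrow(x$network),
      " edges, ", sum(x$truth$role == "driver"), " planted drivers\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits exactly the files the readers consume: a MAF, a DEG TSV, a network
#' edge list, a survival TSV, role/drug TSVs and the ground-truth table.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(maf = file.path(dir, "mutations.maf"),
             deg = file.path(dir, "expression.tsv"),
             network = file.path(dir, "network.tsv"),
             survival = file.path(dir, "survival.tsv"),
             roles = file.path(dir, "roles.tsv"),
             drugs = file.path(dir, "drugs.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_maf(cohort$mutations, paths["maf"])
  write_tsv_plain(cohort$expression, paths["deg"])
  utils::write.table(as.data.frame(cohort$network)[, c("from", "to")],
                     paths["network"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_plain(cohort$survival, paths["survival"])
  write_tsv_plain(cohort$roles, paths["roles"])
  write_tsv_plain(cohort$drugs, paths["drugs"])
  write_tsv_plain(cohort$truth, paths["truth"])
  invisible(paths)
}
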