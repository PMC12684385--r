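#' Read a directed gene-interaction network from an edge list
#'
#' Reads a TSV/SIF-style edge list (first two columns: source gene, target
#' gene; extra columns ignored) into a directed network. Duplicate edges are
#' collapsed and self-loops dropped; both are counted in the load summary
#' attached as an attribute.
#'
#' @param path Path to a tab-separated edge list with at least two columns.
#'   A header line is auto-detected: if the first line repeats no gene symbol
#'   found elsewhere it is still treated as data, so pass `header = TRUE` for
#'   files with column names.
#' @param header Logical; does the file carry a header line? Default `FALSE`
#'   (plain SIF-like lists usually do not).
#' @return A tibble of class `gene_network` with columns `from`, `to` (one
#'   row per unique directed edge) and attributes `nodes` (character vector)
#'   and `load_summary` (rows read, duplicates collapsed, self-loops
#'   dropped).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC", "A\tC", "A\tB", "D\tD"), f)
#' net <- read_network(f)
#' nrow(net)                      # 3 unique directed edges
#' attr(net, "load_summary")
#' @export
read_network <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (file.size(path) == 0L) stop("network file is empty: ", path)
  raw <- utils::read.table(path, sep = "\t", header = header,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  if (nrow(raw) == 0L) stop("network file is empty: ", path)
  if (ncol(raw) < 2L) stop("network edge list needs >= 2 columns, found ",
                           ncol(raw))
  edges <- tibble::tibble(from = trimws(raw[[1]]), to = trimws(raw[[2]]))
  edges <- dplyr::filter(edges, .data$from != "", .data$to != "")
  n_in <- nrow(edges)
  loops <- edges$from == edges$to
  edges <- edges[!loops, , drop = FALSE]
  dedup <- dplyr::distinct(edges)
  new_gene_network(dedup,
                   load_summary = list(rows_read = n_in,
                                       self_loops_dropped = sum(loops),
                                       duplicates_collapsed = nrow(edges) - nrow(dedup)))
}

#' Construct a gene network from an edge table
#'
#' @param edges Data frame with columns `from` and `to` (gene symbols).
#' @param load_summary Optional list recorded as the load summary.
#' @return A `gene_network` tibble (self-loops and duplicate edges removed).
#' @export
as_gene_network <- function(edges, load_summary = NULL) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- dplyr::distinct(edges[edges$from != edges$to, , drop = FALSE])
  new_gene_network(edges, load_summary = load_summary)
}

new_gene_network <- function(edges, load_summary = NULL) {
  out <- tibble::as_tibble(edges)
  attr(out, "nodes") <- sort(unique(c(out$from, out$to)))
  attr(out, "load_summary") <- load_summary
  class(out) <- c("gene_network", class(out))
  out
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(attr(x, "nodes")), " nodes, ",
      nrow(x), " directed edges\n", sep = "")
  NextMethod()
}

#' Nodes of a gene network
#' @param net A `gene_network`.
#' @return Character vector of gene symbols.
#' @export
network_nodes <- function(net) attr(net, "nodes")

# igraph view of a network (edge attribute `weight` kept when present)
as_igraph_network <- function(net) {
  igraph::graph_from_data_frame(as.data.frame(net), directed = TRUE)
}

#' Variant classes retained as non-synonymous driver candidates
#'
#' Missense, nonsense and frame-shift indel calls; splice-site and in-frame
#' classes are excluded by default but can be added via `keep_classes`.
#' @export
nonsynonymous_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                           "Frame_Shift_Ins", "Frame_Shift_Del")

#' Read somatic mutations from a MAF file
#'
#' Parses a Mutation Annotation Format table, retains non-synonymous variant
#' classes and drops hypermutated samples (more retained variants than
#' `max_mutations`). Only the columns `Hugo_Symbol`,
#' `Variant_Classification` and `Tumor_Sample_Barcode` are required; all
#' others are ignored.
#'
#' @param path Path to a tab-separated MAF (comment lines starting `#`
#'   skipped; header required).
#' @param max_mutations Hypermutation cutoff: samples with more retained
#'   variants are excluded (default 1000).
#' @param keep_classes Variant classes to retain
#'   (default [nonsynonymous_classes]).
#' @return A tibble with columns `sample_id`, `gene` (unique pairs over
#'   retained variants), and attributes `excluded_samples` (tibble
#'   `sample_id`, `n_retained`) and `n_raw_variants` (named count per input
#'   sample, before class filtering).
#' @export
read_maf <- function(path, max_mutations = 1000,
                     keep_classes = nonsynonymous_classes) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  maf <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE, fill = TRUE)
  required <- c("Hugo_Symbol", "Variant_Classification", "Tumor_Sample_Barcode")
  missing <- setdiff(required, names(maf))
  if (length(missing) > 0L)
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(maf) == 0L) {
    warning("MAF has no variant rows")
    out <- tibble::tibble(sample_id = character(), gene = character())
    attr(out, "excluded_samples") <-
      tibble::tibble(sample_id = character(), n_retained = integer())
    attr(out, "n_raw_variants") <- integer()
    return(out)
  }
  n_raw <- table(maf$Tumor_Sample_Barcode)
  kept <- maf[maf$Variant_Classification %in% keep_classes, , drop = FALSE]
  n_retained <- table(kept$Tumor_Sample_Barcode)
  hyper <- names(n_retained)[n_retained > max_mutations]
  excluded <- tibble::tibble(sample_id = hyper,
                             n_retained = as.integer(n_retained[hyper]))
  kept <- kept[!(kept$Tumor_Sample_Barcode %in% hyper), , drop = FALSE]
  out <- dplyr::distinct(tibble::tibble(sample_id = kept$Tumor_Sample_Barcode,
                                        gene = kept$Hugo_Symbol))
  out <- dplyr::arrange(out, .data$sample_id, .data$gene)
  attr(out, "excluded_samples") <- excluded
  attr(out, "n_raw_variants") <-
    stats::setNames(as.integer(n_raw), names(n_raw))
  out
}

#' Write a minimal MAF file
#'
#' Serializes a `(sample_id, gene)` mutation table as a MAF with the three
#' required columns, one `Missense_Mutation` row per pair. Used by the
#' synthetic generator and round-trip tests.
#'
#' @param mutations Tibble with `sample_id`, `gene` and optionally
#'   `variant_class`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  vc <- if ("variant_class" %in% names(mutations)) mutations$variant_class
        else rep("Missense_Mutation", nrow(mutations))
  df <- data.frame(Hugo_Symbol = mutations$gene,
                   Variant_Classification = vc,
                   Tumor_Sample_Barcode = mutations$sample_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample differential-expression table
#'
#' @param path TSV with columns `sample_id`, `gene`, `log2fc`, `fdr`.
#' @return Tibble with those columns; errors if any is missing or an FDR
#'   falls outside \[0, 1\].
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  tbl <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE))
  required <- c("sample_id", "gene", "log2fc", "fdr")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L)
    stop("DEG table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(tbl$fdr < 0 | tbl$fdr > 1, na.rm = TRUE))
    stop("DEG table has FDR values outside [0, 1]")
  tbl[, required]
}

#' Call differentially expressed genes from a fold-change table
#'
#' A gene is a DEG when `|log2fc| >= lfc_cut` and `fdr <= fdr_cut`; both
#' boundaries inclusive. Loosening either threshold can only grow the set.
#'
#' @param deg_table Tibble with columns `sample_id`, `gene`, `log2fc`,
#'   `fdr` (per-sample rows).
#' @param lfc_cut Absolute log2 fold-change threshold (default 1.0).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return Tibble `sample_id`, `gene`, `log2fc` restricted to DEGs.
#' @examples
#' tbl <- tibble::tibble(sample_id = "S1", gene = c("A", "B", "C"),
#'                       log2fc = c(1.0, 0.5, -2.0), fdr = c(0.05, 0.001, 0.01))
#' call_degs(tbl)$gene   # "A" and "C"
#' @export
call_degs <- function(deg_table, lfc_cut = 1.0, fdr_cut = 0.05) {
  stopifnot(all(c("sample_id", "gene", "log2fc", "fdr") %in% names(deg_table)))
  out <- dplyr::filter(deg_table,
                       abs(.data$log2fc) >= lfc_cut, .data$fdr <= fdr_cut)
  dplyr::select(out, "sample_id", "gene", "log2fc")
}

#' Read a plain-text gene list
#'
#' One symbol per line; whitespace stripped, duplicates removed, case
#' preserved, blank lines ignored.
#'
#' @param path Path to the list.
#' @return Character vector of unique symbols (empty with a warning for an
#'   empty file).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- unique(lines[lines != ""])
  if (length(genes) == 0L) warning("gene list is empty: ", path)
  genes
}

#' Read a survival table
#'
#' @param path TSV with columns `sample_id`, `time_months`, `event`
#'   (0 = censored, 1 = deceased).
#' @return Tibble with those columns; negative times or events outside
#'   \{0, 1\} raise an error.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival table not found: ", path)
  tbl <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE))
  required <- c("sample_id", "time_months", "event")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L)
    stop("survival table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(tbl$time_months < 0)) stop("negative survival times")
  if (!all(tbl$event %in% c(0, 1))) stop("event must be 0/1")
  tbl[, required]
}

#' Read a gene-role table (oncogene / tumour suppressor)
#'
#' @param path TSV with columns `gene`, `role`; roles other than
#'   `oncogene`/`tsg` raise an error.
#' @return Tibble `gene`, `role`.
#' @export
read_role_table <- function(path) {
  if (!file.exists(path)) stop("role table not found: ", path)
  tbl <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE))
  if (!all(c("gene", "role") %in% names(tbl)))
    stop("role table needs columns gene, role")
  bad <- setdiff(unique(tbl$role), c("oncogene", "tsg"))
  if (length(bad) > 0L)
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  dplyr::distinct(tbl[, c("gene", "role")])
}

#' Read a gene-drug table with mode of action
#'
#' @param path TSV with columns `gene`, `drug`, `mode`; modes other than
#'   `inhibitor`/`activator` raise an error.
#' @return Tibble `gene`, `drug`, `mode`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("drug table not found: ", path)
  tbl <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE))
  if (!all(c("gene", "drug", "mode") %in% names(tbl)))
    stop("drug table needs columns gene, drug, mode")
  bad <- setdiff(unique(tbl$mode), c("inhibitor", "activator"))
  if (length(bad) > 0L)
    stop("unknown drug mode(s): ", paste(bad, collapse = ", "))
  dplyr::distinct(tbl[, c("gene", "drug", "mode")])
}

# shared TSV writer: deterministic, no quoting, no row names
write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
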