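#' Node weight from tumour and control expression
#'
#' The node weight of a gene is the ratio of its expression in the tumour
#' sample to its expression in the matched control,
#' `NW = (a + pseudocount) / (b + pseudocount)`, clamped to `clamp`. The
#' pseudocount keeps the ratio defined when the control expression is zero.
#'
#' @param a Tumour expression value(s), >= 0.
#' @param b Control expression value(s), >= 0.
#' @param pseudocount Added to numerator and denominator (default 0.5).
#' @param clamp Two-element numeric bounds on NW (default `c(1e-4, 1e4)`).
#' @return Numeric vector of node weights, strictly positive.
#' @examples
#' node_weight(8, 2, pseudocount = 0)   # 4
#' node_weight(2, 0)                    # (2 + .5) / .5 = 5
#' @export
node_weight <- function(a, b, pseudocount = 0.5, clamp = c(1e-4, 1e4)) {
  if (any(a < 0) || any(b < 0)) stop("expression values must be non-negative")
  nw <- (a + pseudocount) / (b + pseudocount)
  pmin(pmax(nw, clamp[1]), clamp[2])
}

#' Node weight from a log2 fold change
#'
#' Equivalent entry point for users who have fold changes rather than raw
#' tumour/control pairs: `NW = 2^log2fc`, clamped.
#'
#' @param log2fc Numeric log2 fold change(s).
#' @inheritParams node_weight
#' @return Numeric node weights.
#' @export
nw_from_log2fc <- function(log2fc, clamp = c(1e-4, 1e4)) {
  pmin(pmax(2^log2fc, clamp[1]), clamp[2])
}

#' Edge weight from the node weights of its endpoints
#'
#' `EW = 1 / sqrt(NW_i * NW_j)`: an edge between two upregulated genes is
#' cheap to traverse, one between downregulated genes expensive, so
#' least-cost paths track upregulated cascades.
#'
#' @param nw_i,nw_j Positive node weights.
#' @return Numeric edge weights.
#' @examples
#' edge_weight(4, 4)  # 0.25
#' edge_weight(2, 8)  # 0.25
#' @export
edge_weight <- function(nw_i, nw_j) {
  if (any(nw_i <= 0) || any(nw_j <= 0)) stop("node weights must be positive")
  1 / sqrt(nw_i * nw_j)
}

#' Contextualize a network with one sample's expression
#'
#' Attaches an edge weight to every edge of the shared network using the
#' sample's node weights. Genes with no expression data default to a
#' cost-neutral `NW = 1`; the fraction defaulted is recorded in the result's
#' `frac_defaulted` attribute.
#'
#' @param net A `gene_network` (tibble `from`, `to`).
#' @param node_weights Either a named numeric vector (gene -> NW) or a data
#'   frame with columns `gene` and one of `nw` / `log2fc` (fold changes are
#'   converted via [nw_from_log2fc()]).
#' @return A tibble of class `weighted_network` with columns `from`, `to`,
#'   `weight`, plus attributes `nodes`, `node_weights` (named vector over
#'   all network nodes) and `frac_defaulted`.
#' @export
contextualize_network <- function(net, node_weights) {
  nodes <- network_nodes(net)
  nw <- stats::setNames(rep(1, length(nodes)), nodes)
  if (is.data.frame(node_weights)) {
    stopifnot("gene" %in% names(node_weights))
    vals <- if ("nw" %in% names(node_weights)) node_weights$nw
            else if ("log2fc" %in% names(node_weights))
              nw_from_log2fc(node_weights$log2fc)
            else stop("node_weights needs an `nw` or `log2fc` column")
    node_weights <- stats::setNames(vals, node_weights$gene)
  }
  if (any(node_weights <= 0)) stop("node weights must be positive")
  known <- intersect(names(node_weights), nodes)
  nw[known] <- node_weights[known]
  out <- tibble::tibble(from = net$from, to = net$to,
                        weight = unname(edge_weight(nw[net$from], nw[net$to])))
  attr(out, "nodes") <- nodes
  attr(out, "node_weights") <- nw
  attr(out, "frac_defaulted") <-
    if (length(nodes) > 0) 1 - length(known) / length(nodes) else 0
  class(out) <- c("weighted_network", class(out))
  out
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", length(attr(x, "nodes")), " nodes, ",
      nrow(x), " weighted edges (",
      round(100 * attr(x, "frac_defaulted")), "% nodes at neutral NW=1)\n",
      sep = "")
  NextMethod()
}
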