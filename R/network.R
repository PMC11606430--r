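#' Construct a metabolic network from a directed edge list
#'
#' A metabolic network here is simply the set of directed edges between
#' metabolites that are allowed to carry a Jacobian entry: an edge
#' `source -> target` permits the elasticity of the target's rate with
#' respect to the source metabolite (entry `J[target, source]`). Diagonal
#' entries (self-regulation / turnover) are always allowed and need not be
#' listed.
#'
#' @param edges Data frame with character columns `source` and `target`.
#'   Self-edges are accepted (the diagonal is allowed anyway).
#' @param nodes Optional character vector of node names; defaults to the
#'   names appearing in `edges`. Node order defines the matrix ordering.
#' @return A tibble of class `metabolic_network` with columns `source`,
#'   `target` and a `nodes` attribute.
#' @export
metabolic_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || !all(c("source", "target") %in% names(edges))) {
    stop_bad_arg("`edges` must have columns source and target")
  }
  edges <- tibble::tibble(source = as.character(edges$source),
                          target = as.character(edges$target))
  nodes <- nodes %||% unique(c(edges$source, edges$target))
  nodes <- as.character(nodes)
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(unknown) > 0L) {
    stop_bad_arg("edge list references unknown node(s): %s",
                 paste(unknown, collapse = ", "))
  }
  structure(edges, nodes = nodes,
            class = c("metabolic_network", class(edges)))
}

#' Structural mask of allowed Jacobian entries
#'
#' Converts a network into the boolean constraint matrix used by the
#' inverse Lyapunov solver: `mask[i, j]` is `TRUE` when entry `J[i, j]`
#' (response of metabolite i's rate to metabolite j) is structurally
#' allowed, i.e. when the network has edge `j -> i` or `i == j`.
#'
#' @param network A `metabolic_network` (or edge-list data frame).
#' @param nodes Character vector fixing the variable order; defaults to
#'   the network's node set. Network nodes must be a subset.
#' @return A logical `length(nodes)` square matrix with dimnames, diagonal
#'   all `TRUE`.
#' @export
jacobian_mask <- function(network, nodes = NULL) {
  if (!is.data.frame(network) || !all(c("source", "target") %in% names(network))) {
    stop_bad_arg("`network` must have columns source and target")
  }
  nodes <- as.character(nodes %||% attr(network, "nodes") %||%
                          unique(c(network$source, network$target)))
  unmatched <- setdiff(unique(c(network$source, network$target)), nodes)
  if (length(unmatched) > 0L) {
    stop_bad_arg("network node(s) absent from the variable set: %s",
                 paste(unmatched, collapse = ", "))
  }
  n <- length(nodes)
  mask <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(mask) <- TRUE
  if (nrow(network) > 0L) {
    mask[cbind(match(network$target, nodes), match(network$source, nodes))] <- TRUE
  }
  if (n > 1L && sum(mask) == n) {
    rlang::warn("mask has no off-diagonal freedom: network contributes no edges; Jacobian will be diagonal-only")
  }
  mask
}
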