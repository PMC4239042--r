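#' Participation coefficient of a node
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2`, where `k_im` is the number (or
#' weight) of links node `i` has with nodes in module `m` of the *hard*
#' partition and `k_i` its degree (or strength).  `P_i` is 0 when all
#' edges stay in one module and approaches `1 - 1/M` as they spread
#' evenly over `M` modules.  A self-loop counts once towards the node's
#' own-module term.
#'
#' @param net an `overmod_network`.
#' @param hp an `overmod_hard_partition` covering `net`.
#' @param node node identifier.
#' @param weighted use edge weights (strengths) instead of counts; the
#'   default `FALSE` matches the unweighted-degree reading used on
#'   unweighted interaction networks.
#' @return `P_i` in `[0, 1)`.
#' @examples
#' # a node with 4 edges split 1/1/1/1 over 4 modules has P = 0.75
#' @export
participation_coefficient <- function(net, hp, node, weighted = FALSE) {
  validate_partition(net, hp)
  v <- match(node, net$nodes)
  if (is.na(v)) stop("unknown node: ", node)
  hard <- unclass(hp)[net$nodes]
  nb <- net$adj_n[[v]]
  w <- if (weighted) net$adj_w[[v]] else rep(1, length(nb))
  loop <- if (weighted) net$loops[v] else as.numeric(net$loops[v] > 0)
  k_i <- sum(w) + loop
  if (k_i == 0) stop("participation coefficient undefined for degree-0 node: ", node)
  k_im <- rowsum(c(w, loop), c(hard[nb], hard[v]))[, 1]
  1 - sum((k_im / k_i)^2)
}

#' Per-node topological profiles
#'
#' One row per node: hard module, soft-partition role, degree and
#' strength, number of links into the own module and each foreign module
#' summarised as the inter-modular degree (count of distinct foreign
#' modules with at least one link), participation coefficient, and
#' betweenness / eigenvector centrality (delegated to igraph).  The table
#' supports the group contrasts of interest (isolated vs connector,
#' inter vs intra).
#'
#' @param net an `overmod_network`.
#' @param hp an `overmod_hard_partition`.
#' @param sp an `overmod_soft_partition` for `net` (provides roles and
#'   membership counts); may be `NULL` for hard-partition-only profiles.
#' @param weighted passed to [participation_coefficient()].
#' @return A `data.frame` with columns `node`, `hard_module`, `role`,
#'   `n_modules`, `degree`, `strength`, `inter_modular_degree`,
#'   `participation`, `betweenness`, `eigenvector`.
#' @export
node_profiles <- function(net, hp, sp = NULL, weighted = FALSE) {
  validate_partition(net, hp)
  nodes <- net$nodes
  hard <- unclass(hp)[nodes]
  n <- length(nodes)
  degree <- lengths(net$adj_n) + as.numeric(net$loops > 0)
  imd <- vapply(seq_len(n), function(v) {
    length(setdiff(unique(hard[net$adj_n[[v]]]), hard[v]))
  }, numeric(1))
  part <- vapply(seq_len(n), function(v) {
    if (degree[v] == 0) NA_real_
    else participation_coefficient(net, hp, nodes[v], weighted = weighted)
  }, numeric(1))
  g <- as_igraph(net)
  btw <- igraph::betweenness(g, weights = NA)
  eig <- igraph::eigen_centrality(g, weights = NA)$vector
  role <- rep(NA_character_, n)
  nmod <- rep(NA_integer_, n)
  if (!is.null(sp)) {
    role <- as.character(sp$roles[nodes])
    nmod <- lengths(sp$membership[nodes])
  }
  data.frame(
    node = nodes,
    hard_module = as.integer(hard),
    role = role,
    n_modules = nmod,
    degree = as.integer(degree),
    strength = as.numeric(net$strength[nodes]),
    inter_modular_degree = as.integer(imd),
    participation = part,
    betweenness = as.numeric(btw[nodes]),
    eigenvector = as.numeric(eig[nodes]),
    row.names = NULL
  )
}
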