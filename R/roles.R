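#' Classify nodes as isolated or connector relative to a hard partition
#'
#' A node is *isolated* when every neighbour (self-loops excluded) lies in
#' its own hard module; otherwise it is a *connector*.  For each module `m`
#' the connector set `CC_m` comprises the connectors assigned to `m` plus
#' any outside node with at least one neighbour in `m`.  Each connector's
#' *candidate* modules are its own hard module plus every foreign module it
#' has a neighbour in; these are the modules it may join during the
#' conversion to a soft partition.  Self-loops never create candidacy.
#'
#' @param net an `overmod_network`.
#' @param hp an `overmod_hard_partition` covering `net`.
#' @return An object of class `overmod_roles`: lists `isolated_by_module`
#'   and `connectors_by_module` of node-name vectors (`CI_m`, `CC_m`),
#'   `candidates` (named list: connector -> integer module ids), the
#'   logical vector `is_connector`, and the integer hard assignment `hard`
#'   aligned to `net$nodes`.
#' @export
classify_nodes <- function(net, hp) {
  validate_partition(net, hp)
  nodes <- net$nodes
  n <- length(nodes)
  hard <- unclass(hp)[nodes]
  M <- max(hard)

  is_connector <- vapply(seq_len(n), function(v) {
    nb <- net$adj_n[[v]]
    any(hard[nb] != hard[v])
  }, logical(1))

  candidates <- vector("list", n)
  names(candidates) <- nodes
  for (v in which(is_connector)) {
    cand <- sort(unique(c(hard[v], hard[net$adj_n[[v]]])))
    candidates[[v]] <- cand
  }
  candidates <- candidates[is_connector]

  isolated_by_module <- lapply(seq_len(M), function(m) {
    nodes[!is_connector & hard == m]
  })
  connectors_by_module <- lapply(seq_len(M), function(m) {
    inside <- nodes[is_connector & hard == m]
    outside <- nodes[vapply(seq_len(n), function(v) {
      hard[v] != m && any(hard[net$adj_n[[v]]] == m)
    }, logical(1))]
    sort(unique(c(inside, outside)))
  })

  structure(
    list(
      isolated_by_module = isolated_by_module,
      connectors_by_module = connectors_by_module,
      candidates = candidates,
      is_connector = setNames(is_connector, nodes),
      hard = setNames(as.integer(hard), nodes),
      n_modules = M
    ),
    class = "overmod_roles"
  )
}

#' @export
print.overmod_roles <- function(x, ...) {
  cat(sprintf("overmod roles: %d modules, %d connectors, %d isolated nodes\n",
              x$n_modules, sum(x$is_connector), sum(!x$is_connector)))
  invisible(x)
}

#' Jaccard index of two node sets
#'
#' `|A intersect B| / |A union B|`, the standard similarity used to compare
#' connector or inter-connector sets across partitioning methods.  Defined
#' as 1 when both sets are empty (identical sets).
#'
#' @param a,b character (or atomic) vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
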