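# Binary assignments are dense logical matrices x (nodes x modules) with
# rownames = net$nodes; x[i, m] == TRUE means node i belongs to module m.
# Isolated nodes carry exactly their hard module and are frozen; connector
# rows may only be TRUE on candidate modules and must keep >= 1 membership.

assignment_from_hard <- function(net, hard, M = max(hard)) {
  n <- length(net$nodes)
  x <- matrix(FALSE, n, M, dimnames = list(net$nodes, NULL))
  x[cbind(seq_len(n), hard[net$nodes])] <- TRUE
  x
}

assignment_from_membership <- function(net, membership, M) {
  x <- matrix(FALSE, length(net$nodes), M, dimnames = list(net$nodes, NULL))
  for (v in names(membership)) x[v, membership[[v]]] <- TRUE
  x
}

membership_from_assignment <- function(x) {
  out <- apply(x, 1, which, simplify = FALSE)
  lapply(out, as.integer)
}

# per-module strength sums S_m and internal edge weights W_m; an edge
# contributes to every module holding both endpoints, a self-loop a_ii to
# every module holding its node (once each)
module_aggregates <- function(net, x) {
  M <- ncol(x)
  e <- net$edges
  S <- as.numeric(crossprod(x, net$strength))
  W <- vapply(seq_len(M), function(m) {
    sum(e$w[x[e$i, m] & x[e$j, m]])
  }, numeric(1))
  list(S = S, W = W)
}

qov_from_aggregates <- function(S, W, L) {
  sum(W / L - (S / (2 * L))^2)
}

check_feasible <- function(net, roles, x) {
  if (any(rowSums(x) < 1L)) {
    stop("infeasible assignment: node with zero module memberships")
  }
  hard <- roles$hard
  iso <- names(which(!roles$is_connector))
  iso_ok <- all(rowSums(x[iso, , drop = FALSE]) == 1L) &&
    all(x[cbind(match(iso, rownames(x)), hard[iso])])
  if (!iso_ok) stop("infeasible assignment: isolated node moved or duplicated")
  for (v in names(roles$candidates)) {
    on <- which(x[v, ])
    if (length(setdiff(on, roles$candidates[[v]]))) {
      stop("infeasible assignment: connector '", v,
           "' assigned outside its candidate modules")
    }
  }
  invisible(TRUE)
}

#' Overlapping modularity of a binary node/module assignment
#'
#' Evaluates `Q_ov = sum_m [ W_m / L - (S_m / 2L)^2 ]`, where `S_m` is the
#' sum of strengths of the nodes assigned to module `m` and `W_m` the total
#' weight of edges with both endpoints in `m` (a self-loop counts once when
#' its node is a member; an edge may contribute to several modules when
#' both endpoints co-occur in them).  At a single-membership assignment
#' this reduces exactly to the classical (hard) modularity.
#'
#' @param net an `overmod_network`.
#' @param roles the `overmod_roles` from [classify_nodes()].
#' @param asg either a logical node-by-module matrix (rownames = node ids)
#'   or a named list mapping each node to its integer module set.
#' @param check validate feasibility (non-empty memberships, frozen
#'   isolated nodes, candidate-only connectors) before evaluating.
#' @return The objective value, a single real number.
#' @export
qov <- function(net, roles, asg, check = TRUE) {
  M <- roles$n_modules
  x <- if (is.matrix(asg)) asg else assignment_from_membership(net, asg, M)
  stopifnot(identical(rownames(x), net$nodes))
  if (check) check_feasible(net, roles, x)
  ag <- module_aggregates(net, x)
  qov_from_aggregates(ag$S, ag$W, net$L)
}

#' Modularity of a hard partition
#'
#' The per-module sum `sum_m [ W_m / L - (S_m / 2L)^2 ]` evaluated at the
#' disjoint indicator, i.e. classical Newman modularity on loop-free
#' graphs (self-loops, when present, count once in both `W_m` and `L`).
#'
#' @param net an `overmod_network`.
#' @param hp an `overmod_hard_partition` covering `net`.
#' @return Modularity `Q`, a single real number.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "a c", "b c", "c d", "d e", "d f", "e f"), f)
#' net <- read_edgelist(f)
#' hp <- new_hard_partition(c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L))
#' hard_modularity(net, hp) # 5/14
#' @export
hard_modularity <- function(net, hp) {
  validate_partition(net, hp)
  hard <- unclass(hp)[net$nodes]
  x <- assignment_from_hard(net, hard)
  ag <- module_aggregates(net, x)
  qov_from_aggregates(ag$S, ag$W, net$L)
}
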