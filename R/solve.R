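# CSR adjacency (0-based, self-loops excluded) for the compiled climber
csr_adjacency <- function(net) {
  n <- length(net$nodes)
  lens <- lengths(net$adj_n)
  ptr <- c(0L, cumsum(lens))
  list(ptr = as.integer(ptr),
       idx = as.integer(unlist(net$adj_n, use.names = FALSE) - 1L),
       w = as.numeric(unlist(net$adj_w, use.names = FALSE)))
}

# flippable (node, module) pairs in deterministic order: by node index,
# then module id
candidate_pairs <- function(net, roles) {
  conn <- names(roles$candidates)
  vi <- match(conn, net$nodes)
  o <- order(vi)
  node <- integer(0); mod <- integer(0)
  for (k in o) {
    cm <- roles$candidates[[k]]
    node <- c(node, rep(vi[k], length(cm)))
    mod <- c(mod, cm)
  }
  list(node = node, mod = mod)
}

soft_partition_from_assignment <- function(net, roles, x, qov_value) {
  membership <- membership_from_assignment(x)
  role <- ifelse(!roles$is_connector[net$nodes], "isolated",
                 ifelse(lengths(membership) >= 2L, "inter", "intra"))
  new_soft_partition(membership, qov_value, setNames(role, net$nodes))
}

#' Exact conversion to a soft partition by exhaustive enumeration
#'
#' Enumerates every feasible binary assignment (each connector takes any
#' non-empty subset of its candidate modules; isolated nodes stay frozen)
#' and returns the global maximiser of the overlapping modularity.  This
#' is the brute-force oracle used to validate [solve_multistart()] on
#' small instances.  Among equal optima the assignment with the fewest
#' total memberships wins, then the lexicographically smallest membership
#' sets.
#'
#' @param net an `overmod_network`.
#' @param roles output of [classify_nodes()].
#' @param hp the hard partition the roles were derived from.
#' @param budget refuse when the number of feasible assignments (the
#'   product over connectors of `2^|candidates| - 1`) exceeds this.
#' @return An `overmod_soft_partition` with the optimal `qov`.
#' @export
solve_exact <- function(net, roles, hp, budget = 4096) {
  validate_partition(net, hp)
  M <- roles$n_modules
  conn <- names(roles$candidates)
  sizes <- vapply(roles$candidates, function(cm) 2^length(cm) - 1, numeric(1))
  if (prod(sizes) > budget) {
    stop(sprintf(paste0("exact enumeration budget exceeded (%g feasible ",
                        "assignments > %g); use solve_multistart()"),
                 prod(sizes), budget))
  }
  hard <- roles$hard
  x_hard <- assignment_from_hard(net, hard, M)
  if (!length(conn)) {
    return(soft_partition_from_assignment(net, roles, x_hard,
                                          qov(net, roles, x_hard, check = FALSE)))
  }
  # per-connector non-empty candidate subsets, ordered by size then
  # lexicographically (so earlier = more parsimonious)
  subsets <- lapply(roles$candidates, function(cm) {
    out <- list()
    for (sz in seq_along(cm)) {
      combs <- utils::combn(cm, sz, simplify = FALSE)
      out <- c(out, combs[order(vapply(combs, paste, character(1), collapse = ","))])
    }
    out
  })
  radices <- lengths(subsets)
  counter <- rep(1L, length(conn))
  best <- NULL
  repeat {
    x <- x_hard
    for (k in seq_along(conn)) {
      v <- conn[k]
      x[v, ] <- FALSE
      x[v, subsets[[k]][[counter[k]]]] <- TRUE
    }
    q <- qov(net, roles, x, check = FALSE)
    cand <- list(q = q, x = x,
                 nmem = sum(x),
                 key = paste(vapply(seq_len(nrow(x)), function(i)
                   paste(which(x[i, ]), collapse = ","), character(1)),
                   collapse = ";"))
    if (is.null(best) || q > best$q + 1e-12 ||
        (abs(q - best$q) <= 1e-12 &&
         (cand$nmem < best$nmem ||
          (cand$nmem == best$nmem && cand$key < best$key)))) {
      best <- cand
    }
    # increment mixed-radix counter
    k <- 1L
    while (k <= length(counter)) {
      counter[k] <- counter[k] + 1L
      if (counter[k] <= radices[k]) break
      counter[k] <- 1L
      k <- k + 1L
    }
    if (k > length(counter)) break
  }
  soft_partition_from_assignment(net, roles, best$x, best$q)
}

#' Multi-start local search conversion to a soft partition
#'
#' The production solver for the conversion stage.  Each restart draws an
#' independent uniform 0/1 initial value for every connector/candidate
#' pair (isolated nodes stay frozen at their hard module), repairs any
#' connector left with zero memberships by activating its original hard
#' module, and then hill-climbs by steepest-ascent single-entry flips
#' (flips violating the at-least-one-membership constraint excluded)
#' until no flip improves the overlapping modularity by more than `tol`.
#' The best restart wins.  Fully deterministic given `(seed, restarts)`;
#' restart `r` uses a stream seed derived from `(seed, r)`, so increasing
#' `restarts` does not reshuffle earlier restarts.
#'
#' @param net an `overmod_network`.
#' @param roles output of [classify_nodes()].
#' @param hp the hard partition the roles were derived from.
#' @param restarts number of random restarts (>= 1); 100 is the reference
#'   setting.
#' @param seed master integer seed.
#' @param tol minimum accepted objective improvement per flip.
#' @return An `overmod_soft_partition`; attribute `"restart_qov"` carries
#'   the per-restart objective trace.
#' @export
solve_multistart <- function(net, roles, hp, restarts = 100, seed, tol = 1e-10) {
  stopifnot(restarts >= 1)
  if (missing(seed)) stop("a seed is required for the stochastic solver")
  validate_partition(net, hp)
  M <- roles$n_modules
  x_hard <- assignment_from_hard(net, roles$hard, M)
  pairs <- candidate_pairs(net, roles)
  if (!length(pairs$node)) {
    sp <- soft_partition_from_assignment(net, roles, x_hard,
                                         qov(net, roles, x_hard, check = FALSE))
    attr(sp, "restart_qov") <- rep(sp$qov, 0)
    return(sp)
  }
  csr <- csr_adjacency(net)
  conn_idx <- sort(unique(pairs$node))
  best <- NULL
  trace <- numeric(restarts)
  for (r in seq_len(restarts)) {
    x0 <- x_hard
    with_seed(derive_seed(seed, r), {
      draw <- runif(length(pairs$node)) < 0.5
      x0[conn_idx, ] <- FALSE
      on <- which(draw)
      x0[cbind(pairs$node[on], pairs$mod[on])] <- TRUE
      # repair: an all-zero connector re-activates its hard module
      zero <- conn_idx[rowSums(x0[conn_idx, , drop = FALSE]) == 0L]
      if (length(zero)) x0[cbind(zero, roles$hard[zero])] <- TRUE
    })
    res <- hill_climb_cpp(x0, csr$ptr, csr$idx, csr$w, net$loops,
                          net$strength, net$L,
                          as.integer(pairs$node - 1L),
                          as.integer(pairs$mod - 1L), tol)
    trace[r] <- res$qov
    if (is.null(best) || res$qov > best$qov) {
      best <- res
    }
  }
  x <- best$x
  dimnames(x) <- dimnames(x_hard)
  sp <- soft_partition_from_assignment(net, roles, x, best$qov)
  attr(sp, "restart_qov") <- trace
  sp
}

#' Re-derive node roles from a soft partition's memberships
#'
#' Sets `role(i)` to `isolated` for nodes that were isolated under the
#' hard partition, `inter` for connectors assigned to two or more modules
#' and `intra` for connectors remaining in exactly one.
#'
#' @param sp an `overmod_soft_partition`.
#' @param roles output of [classify_nodes()].
#' @return `sp` with consistent roles; attribute `"role_counts"` holds the
#'   isolated/intra/inter tally.
#' @export
classify_connectors <- function(sp, roles) {
  nodes <- names(sp$membership)
  role <- ifelse(!roles$is_connector[nodes], "isolated",
                 ifelse(lengths(sp$membership) >= 2L, "inter", "intra"))
  sp$roles <- setNames(role, nodes)
  attr(sp, "role_counts") <- c(
    isolated = sum(role == "isolated"),
    intra = sum(role == "intra"),
    inter = sum(role == "inter")
  )
  sp
}

#' Select strong inter-connectors
#'
#' Two selection rules for flagging the most strongly multi-clustered
#' nodes among the inter-connectors:
#' * `"threshold:k"` -- nodes assigned to at least `k` modules (the rule
#'   used on small networks, e.g. `k = 3`);
#' * `"top10range"` -- find the ten inter-connectors with the most
#'   memberships, take `r` = the smallest membership count among them, and
#'   return *all* nodes with at least `r` memberships (ties included, so
#'   more than ten nodes may qualify).
#'
#' With fewer than ten inter-connectors, `"top10range"` falls back to all
#' inter-connectors and flags the result with attribute
#' `"fallback" = TRUE`.
#'
#' @param sp a classified `overmod_soft_partition`.
#' @param rule selection rule string.
#' @return Character vector of node ids (possibly empty).
#' @export
strong_interconnectors <- function(sp, rule = "threshold:3") {
  inter <- names(sp$membership)[sp$roles == "inter"]
  if (!length(inter)) return(character(0))
  counts <- lengths(sp$membership[inter])
  if (grepl("^threshold:", rule)) {
    k <- as.integer(sub("^threshold:", "", rule))
    if (is.na(k) || k < 2L) stop("invalid threshold rule: ", rule)
    return(sort(names(counts)[counts >= k]))
  }
  if (rule == "top10range") {
    if (length(inter) < 10L) {
      out <- sort(inter)
      attr(out, "fallback") <- TRUE
      warning("fewer than 10 inter-connectors; returning all of them")
      return(out)
    }
    r <- sort(counts, decreasing = TRUE)[10]
    return(sort(names(counts)[counts >= r]))
  }
  stop("unknown strong-interconnector rule: ", rule)
}
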