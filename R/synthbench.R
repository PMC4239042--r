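#' Generate a synthetic network with planted overlapping communities
#'
#' A planted-partition generator with near-uniform degrees emulating the
#' benchmark design used to evaluate overlap recovery: `n` nodes split
#' evenly over `n_modules` modules; `O_n` randomly chosen nodes receive
#' `O_m - 1` extra distinct module memberships; each node targets
#' `avg_degree` edges of which an expected fraction `mu` (the mixing
#' parameter) go to nodes sharing no module and `1 - mu` to co-members,
#' with a multi-membership node's internal stubs split evenly across its
#' modules.  Stub pairing produces a simple unweighted graph (no loops or
#' multi-edges; the few conflicting stub pairs are dropped).  The largest
#' connected component is returned with the planted truth restricted
#' accordingly.  Fully determined by `seed`.
#'
#' This deliberately simplifies the LFR benchmark family: degree and
#' community-size distributions are near-uniform rather than power laws.
#'
#' @param n number of nodes.
#' @param avg_degree target mean degree.
#' @param n_modules number of planted modules.
#' @param O_n number of overlapping (multi-clustered) nodes.
#' @param O_m number of modules each overlapping node belongs to.
#' @param mu mixing parameter in `[0, 1)`: expected fraction of edges
#'   between non-co-members.
#' @param seed integer seed.
#' @return A list with components `network` (an `overmod_network`) and
#'   `truth` (class `overmod_benchmark_truth`: named list `membership`,
#'   character vector `multi` of planted overlapping nodes, and the
#'   generator parameters).
#' @export
generate_benchmark <- function(n = 500, avg_degree = 10, n_modules = 10,
                               O_n = 75, O_m = 4, mu = 0.05, seed) {
  if (missing(seed)) stop("a seed is required for the benchmark generator")
  stopifnot(O_m >= 1, O_m <= n_modules, O_n >= 0, O_n <= n,
            mu >= 0, mu < 1, n_modules >= 1, n_modules <= n)
  if (n / n_modules < 2) stop("modules too small for the requested degree targets")
  if (avg_degree >= n) stop("average degree must be below n")
  with_seed(seed, {
    nodes <- sprintf("n%04d", seq_len(n))
    primary <- sort(rep_len(seq_len(n_modules), n))
    membership <- lapply(primary, function(m) m)
    if (O_n > 0 && O_m > 1) {
      multi_idx <- sort(sample.int(n, O_n))
      for (v in multi_idx) {
        extra <- sample(setdiff(seq_len(n_modules), primary[v]), O_m - 1)
        membership[[v]] <- sort(c(primary[v], extra))
      }
    } else {
      multi_idx <- integer(0)
    }
    names(membership) <- nodes
    members_by_module <- lapply(seq_len(n_modules), function(m) {
      which(vapply(membership, function(ms) m %in% ms, logical(1)))
    })

    # per-node degree target and internal/external stub split
    deg <- rep(floor(avg_degree), n) +
      (runif(n) < (avg_degree - floor(avg_degree)))
    n_int <- rbinom(n, deg, 1 - mu)
    n_ext <- deg - n_int

    # internal stubs: round-robin over the node's modules from a random
    # offset, so multi-membership nodes split internal edges evenly
    int_stub_node <- vector("list", n_modules)
    for (v in seq_len(n)) {
      if (n_int[v] == 0) next
      ms <- membership[[v]]
      picks <- ms[((sample.int(length(ms), 1) + seq_len(n_int[v]) - 2) %%
                     length(ms)) + 1]
      for (m in unique(picks)) {
        int_stub_node[[m]] <- c(int_stub_node[[m]], rep(v, sum(picks == m)))
      }
    }
    pair_up <- function(stubs) {
      stubs <- stubs[sample.int(length(stubs))]
      if (length(stubs) < 2) return(NULL)
      if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
      cbind(stubs[c(TRUE, FALSE)], stubs[c(FALSE, TRUE)])
    }
    pairs <- list()
    for (m in seq_len(n_modules)) {
      pm <- pair_up(int_stub_node[[m]])
      if (!is.null(pm)) pairs[[length(pairs) + 1]] <- pm
    }
    ext_stubs <- rep(seq_len(n), n_ext)
    pe <- pair_up(ext_stubs)
    if (!is.null(pe)) {
      share <- vapply(seq_len(nrow(pe)), function(r) {
        length(intersect(membership[[pe[r, 1]]], membership[[pe[r, 2]]])) > 0
      }, logical(1))
      pairs[[length(pairs) + 1]] <- pe[!share, , drop = FALSE]
    }
    ep <- do.call(rbind, pairs)
    lo <- pmin(ep[, 1], ep[, 2])
    hi <- pmax(ep[, 1], ep[, 2])
    ok <- lo != hi
    lo <- lo[ok]; hi <- hi[ok]
    dup <- duplicated(paste(lo, hi))
    lo <- lo[!dup]; hi <- hi[!dup]
    edges <- data.frame(i = lo, j = hi, w = 1)
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    net <- new_network(nodes, edges)
    net <- main_component(net)
    membership <- membership[net$nodes]
    truth <- structure(
      list(
        membership = membership,
        multi = names(membership)[lengths(membership) >= 2L],
        params = list(n = n, avg_degree = avg_degree, n_modules = n_modules,
                      O_n = O_n, O_m = O_m, mu = mu, seed = seed)
      ),
      class = "overmod_benchmark_truth"
    )
    list(network = net, truth = truth)
  })
}

#' @export
print.overmod_benchmark_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("planted benchmark truth: %d nodes in component, ",
                     "%d multi-clustered (O_n=%d, O_m=%d, mu=%g)\n"),
              length(x$membership), length(x$multi), p$O_n, p$O_m, p$mu))
  invisible(x)
}

# realized fraction of edges joining nodes that share no planted module
realized_mixing <- function(net, truth) {
  e <- net$edges
  e <- e[e$i != e$j, , drop = FALSE]
  share <- vapply(seq_len(nrow(e)), function(r) {
    length(intersect(truth$membership[[net$nodes[e$i[r]]]],
                     truth$membership[[net$nodes[e$j[r]]]])) > 0
  }, logical(1))
  mean(!share)
}

#' Jaccard recovery of the planted multi-clustered nodes
#'
#' @param predicted_multi character vector of nodes predicted to be
#'   multi-clustered (e.g. the inter-connectors of a soft partition).
#' @param truth an `overmod_benchmark_truth`.
#' @return Jaccard index between the predicted set and the planted set of
#'   overlapping nodes.
#' @export
recovery_jaccard <- function(predicted_multi, truth) {
  jaccard(predicted_multi, truth$multi)
}

#' Run the recovery benchmark over a parameter grid
#'
#' For every grid cell and replicate: generate a planted benchmark
#' network, detect a hard partition with [greedy_hard_partition()],
#' classify nodes, convert with [solve_multistart()], take the
#' inter-connectors as the predicted multi-clustered set and score it
#' with [recovery_jaccard()].  Deterministic given `seed`.
#'
#' @param param_grid `data.frame` with any of the columns `n`,
#'   `avg_degree`, `n_modules`, `O_n`, `O_m`, `mu` (missing columns take
#'   the generator defaults).
#' @param replicates networks generated per cell.
#' @param restarts restarts for the conversion solver.
#' @param seed master integer seed.
#' @return `param_grid` with added columns `mean_jaccard`, `sd_jaccard`,
#'   `mean_pred_size` (mean size of the predicted multi-clustered set)
#'   and `replicates`.
#' @export
benchmark_suite <- function(param_grid, replicates = 10, restarts = 100, seed) {
  if (missing(seed)) stop("a seed is required for the benchmark suite")
  defaults <- list(n = 500, avg_degree = 10, n_modules = 10,
                   O_n = 75, O_m = 4, mu = 0.05)
  for (col in names(defaults)) {
    if (is.null(param_grid[[col]])) param_grid[[col]] <- defaults[[col]]
  }
  mean_j <- numeric(nrow(param_grid))
  sd_j <- numeric(nrow(param_grid))
  mean_size <- numeric(nrow(param_grid))
  for (r in seq_len(nrow(param_grid))) {
    vals <- vapply(seq_len(replicates), function(t) {
      cell_seed <- derive_seed(seed, r * 1009L + t)
      tryCatch(
        benchmark_replicate(param_grid[r, ], restarts, cell_seed),
        error = function(e) {
          stop(sprintf("benchmark cell %d (mu=%g, O_n=%d, O_m=%d), replicate %d: %s",
                       r, param_grid$mu[r], param_grid$O_n[r],
                       param_grid$O_m[r], t, conditionMessage(e)),
               call. = FALSE)
        })
    }, numeric(2))
    mean_j[r] <- mean(vals[1, ])
    sd_j[r] <- if (replicates > 1) sd(vals[1, ]) else NA_real_
    mean_size[r] <- mean(vals[2, ])
  }
  param_grid$mean_jaccard <- mean_j
  param_grid$sd_jaccard <- sd_j
  param_grid$mean_pred_size <- mean_size
  param_grid$replicates <- replicates
  param_grid
}

benchmark_replicate <- function(cell, restarts, cell_seed) {
  bench <- generate_benchmark(
    n = cell$n, avg_degree = cell$avg_degree, n_modules = cell$n_modules,
    O_n = cell$O_n, O_m = cell$O_m, mu = cell$mu, seed = cell_seed
  )
  net <- bench$network
  hp <- greedy_hard_partition(net, seed = derive_seed(cell_seed, 1L))
  roles <- classify_nodes(net, hp)
  sp <- solve_multistart(net, roles, hp, restarts = restarts,
                         seed = derive_seed(cell_seed, 2L))
  predicted <- names(sp$membership)[sp$roles == "inter"]
  c(jaccard = recovery_jaccard(predicted, bench$truth),
    pred_size = length(predicted))
}
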