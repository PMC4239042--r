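#' @useDynLib overmod, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif sd setNames aggregate
#' @importFrom utils head read.table write.table
NULL

# Internal constructor.  `edges` is a data.frame with integer columns i, j
# (indices into `nodes`, canonicalised so i <= j) and numeric w > 0, one row
# per unordered pair.  Self-loops (i == j) are permitted.
new_network <- function(nodes, edges) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  n <- length(nodes)
  if (nrow(edges)) {
    stopifnot(all(edges$i <= edges$j), all(edges$w > 0))
    key <- paste(edges$i, edges$j)
    if (anyDuplicated(key)) stop("duplicate edges after canonicalisation")
  }
  loops <- numeric(n)
  is_loop <- edges$i == edges$j
  loops[edges$i[is_loop]] <- edges$w[is_loop]

  # adjacency excluding self-loops
  nb <- edges[!is_loop, , drop = FALSE]
  adj_n <- vector("list", n)
  adj_w <- vector("list", n)
  for (v in seq_len(n)) {
    adj_n[[v]] <- integer(0)
    adj_w[[v]] <- numeric(0)
  }
  if (nrow(nb)) {
    ends <- c(nb$i, nb$j)
    other <- c(nb$j, nb$i)
    w2 <- c(nb$w, nb$w)
    o <- order(ends, other)
    ends <- ends[o]; other <- other[o]; w2 <- w2[o]
    idx <- split(seq_along(ends), ends)
    for (k in names(idx)) {
      v <- as.integer(k)
      adj_n[[v]] <- other[idx[[k]]]
      adj_w[[v]] <- w2[idx[[k]]]
    }
  }
  # strength: each incident non-loop edge once, the self-loop weight once
  s <- vapply(seq_len(n), function(v) sum(adj_w[[v]]), numeric(1)) + loops
  names(s) <- nodes

  structure(
    list(
      nodes = nodes,
      edges = edges,
      adj_n = adj_n,
      adj_w = adj_w,
      loops = loops,
      strength = s,
      L = sum(edges$w)
    ),
    class = "overmod_network"
  )
}

#' Read an undirected network from an edge-list file
#'
#' Parses a whitespace-separated edge list: two columns `node1 node2` for an
#' unweighted network, three columns `node1 node2 weight` for a weighted one.
#' Lines starting with `#` and blank lines are ignored.  The graph is
#' undirected: repeated `(i,j)` / `(j,i)` lines are collapsed by *summing*
#' their weights (conservative for interaction lists with repeated evidence
#' lines).  Self-loops `(i,i)` are accepted and their weight `a_ii` counts
#' once in both the node strength `s_i` and the total edge weight `L`, so
#' for a loop-free network `sum(s_i) == 2 * L`.
#'
#' @param path path to the edge-list file.
#' @param weighted logical; `TRUE` expects three columns, `FALSE` two.
#'   The default `NA` auto-detects from the first data line.
#' @return An object of class `overmod_network`: an undirected weighted
#'   graph with node identifiers (opaque strings), canonical edge table,
#'   per-node strengths and total edge weight `L`.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c"), f)
#' net <- read_edgelist(f)
#' net$L            # 2
#' net$strength["b"] # 2
#' @export
read_edgelist <- function(path, weighted = NA) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("edge-list file contains no data lines: ", path)
  toks <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(toks)
  if (is.na(weighted)) weighted <- nf[1] == 3L
  want <- if (weighted) 3L else 2L
  bad <- which(nf != want)
  if (length(bad)) {
    stop(sprintf("malformed edge line %d (expected %d fields, got %d): %s",
                 keep[bad[1]], want, nf[bad[1]], raw[keep[bad[1]]]))
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1]
      stop(sprintf("malformed weight on line %d: %s", keep[bad], raw[keep[bad]]))
    }
    if (any(w <= 0)) {
      bad <- which(w <= 0)[1]
      stop(sprintf("non-positive weight on line %d: %s", keep[bad], raw[keep[bad]]))
    }
  } else {
    w <- rep(1, length(a))
  }
  nodes <- sort(unique(c(a, b)))
  i <- match(a, nodes)
  j <- match(b, nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  agg <- rowsum(w, group = paste(lo, hi), reorder = TRUE)
  ij <- do.call(rbind, strsplit(rownames(agg), " "))
  edges <- data.frame(
    i = as.integer(ij[, 1]),
    j = as.integer(ij[, 2]),
    w = as.numeric(agg[, 1])
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new_network(nodes, edges)
}

#' @export
print.overmod_network <- function(x, ...) {
  cat(sprintf("overmod network: %d nodes, %d edges (L = %g, %d self-loops)\n",
              length(x$nodes), nrow(x$edges), x$L, sum(x$loops > 0)))
  invisible(x)
}

# induced subgraph on a subset of node names (order preserved as sorted names)
subset_network <- function(net, keep_names) {
  keep_names <- sort(keep_names)
  old_idx <- match(keep_names, net$nodes)
  stopifnot(!anyNA(old_idx))
  remap <- rep(NA_integer_, length(net$nodes))
  remap[old_idx] <- seq_along(keep_names)
  e <- net$edges
  sel <- !is.na(remap[e$i]) & !is.na(remap[e$j])
  e <- e[sel, , drop = FALSE]
  edges <- data.frame(i = remap[e$i], j = remap[e$j], w = e$w)
  lo <- pmin(edges$i, edges$j); hi <- pmax(edges$i, edges$j)
  edges <- data.frame(i = lo, j = hi, w = edges$w)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new_network(keep_names, edges)
}

#' Extract the main connected component of a network
#'
#' Returns the induced subgraph on the largest connected component.  When
#' several components tie for the largest size the one containing the
#' lexicographically smallest node identifier wins, so the result is
#' deterministic.
#'
#' @param net an `overmod_network`.
#' @return An `overmod_network` restricted to the main component.
#' @export
main_component <- function(net) {
  n <- length(net$nodes)
  if (n == 0L) stop("empty network")
  comp <- component_labels(net)
  sizes <- tabulate(comp)
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  # tie-break: component containing the lexicographically smallest member
  first_member <- vapply(cand, function(cc) min(net$nodes[comp == cc]), character(1))
  winner <- cand[order(first_member)][1]
  subset_network(net, net$nodes[comp == winner])
}

# connected-component labels (1-based) via breadth-first search
component_labels <- function(net) {
  n <- length(net$nodes)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- net$adj_n[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# igraph view of the network (used for centrality pass-throughs)
as_igraph <- function(net) {
  el <- cbind(net$nodes[net$edges$i], net$nodes[net$edges$j])
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], weight = net$edges$w),
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  g
}
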