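#' Monte-Carlo node-removal robustness curves
#'
#' For each node class (e.g. `isolated`, `intra`, `inter`), removes the
#' class's nodes one at a time in a seeded uniform random order and
#' records `sigma(N_r)`: the size of the largest connected component
#' after `N_r` removals divided by the initial main-component size (the
#' denominator stays fixed for the whole run).  Each class is evaluated
#' independently on a fresh copy of the network; curves are per-step
#' means over `n_runs` independent runs.
#'
#' @param net an `overmod_network`.
#' @param classes named character vector mapping node ids to class
#'   labels; nodes absent from `classes` are never removed.
#' @param n_runs number of independent runs averaged per class.
#' @param seed master integer seed.
#' @return A `data.frame` with columns `class`, `n_removed` (0 to class
#'   size), `sigma` (mean relative largest-component size) and `n_runs`.
#'   Empty classes are skipped with a warning.
#' @export
removal_simulation <- function(net, classes, n_runs = 100, seed) {
  if (missing(seed)) stop("a seed is required for the removal simulation")
  stopifnot(!is.null(names(classes)))
  unknown <- setdiff(names(classes), net$nodes)
  if (length(unknown)) stop("classes refer to unknown node(s): ",
                            paste(head(unknown, 5), collapse = ", "))
  n <- length(net$nodes)
  comp <- component_labels(net)
  denom <- max(tabulate(comp))
  # factor input may carry unused levels: these are empty classes
  labels <- if (is.factor(classes)) levels(classes) else sort(unique(classes))
  out <- list()
  for (ci in seq_along(labels)) {
    lbl <- labels[ci]
    members <- match(names(classes)[classes == lbl], net$nodes)
    s <- length(members)
    if (!s) {
      warning("class '", lbl, "' is empty; skipped")
      next
    }
    sums <- numeric(s + 1)
    for (run in seq_len(n_runs)) {
      ord <- with_seed(derive_seed(seed, ci * 100000L + run),
                       members[sample.int(s)])
      sums <- sums + removal_curve(net, ord) / denom
    }
    out[[length(out) + 1]] <- data.frame(
      class = lbl,
      n_removed = 0:s,
      sigma = sums / n_runs,
      n_runs = n_runs
    )
  }
  if (!length(out)) stop("all classes empty")
  do.call(rbind, out)
}

# largest-component sizes along one removal order, computed in reverse by
# adding nodes back into a union-find structure; returns sizes at
# N_r = 0, 1, ..., length(ord)
removal_curve <- function(net, ord) {
  n <- length(net$nodes)
  s <- length(ord)
  present <- rep(TRUE, n)
  present[ord] <- FALSE
  parent <- seq_len(n)
  csize <- rep(1L, n)
  curmax <- 0L
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      if (csize[ra] < csize[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      parent[rb] <<- ra
      csize[ra] <<- csize[ra] + csize[rb]
      if (csize[ra] > curmax) curmax <<- csize[ra]
    }
  }
  base <- which(present)
  if (length(base)) curmax <- 1L
  e <- net$edges
  keep <- e$i != e$j & present[e$i] & present[e$j]
  for (r in which(keep)) link(e$i[r], e$j[r])
  sizes <- integer(s + 1)
  sizes[s + 1] <- curmax
  for (k in rev(seq_len(s))) {
    v <- ord[k]
    present[v] <- TRUE
    if (curmax < 1L) curmax <- 1L
    nb <- net$adj_n[[v]]
    for (u in nb[present[nb]]) link(v, u)
    sizes[k] <- curmax
  }
  sizes
}
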