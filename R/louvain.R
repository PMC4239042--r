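# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived stream seed for sub-task r of a master seed; kept below 2^31
derive_seed <- function(seed, r) {
  as.integer((as.double(seed) %% 65011 + 1) * 31013 + 7 * r) %% 2147483647L
}

#' Greedy (Louvain-style) hard-partition optimiser
#'
#' Convenience modularity optimiser for stage one of the two-stage
#' procedure: repeated local moving of nodes to the neighbouring community
#' with the largest modularity gain, followed by community aggregation,
#' until no gain above `tol` remains.  Node visit order is shuffled by
#' `seed` and ties break to the lowest community id, so the result is
#' fully reproducible.  Any externally produced hard partition (read with
#' [read_partition()]) is an equally valid stage-one input.
#'
#' @param net an `overmod_network`; should be connected (run per component
#'   otherwise).
#' @param seed integer seed controlling node visit order.
#' @param tol minimum modularity gain for accepting a move.
#' @return An `overmod_hard_partition` covering `net`.
#' @export
greedy_hard_partition <- function(net, seed, tol = 1e-10) {
  with_seed(seed, {
    n0 <- length(net$nodes)
    # level-graph state: edge list (i, j, w) i < j, self-loop weights
    e <- net$edges
    lev <- list(
      n = n0,
      ei = e$i[e$i != e$j], ej = e$j[e$i != e$j], ew = e$w[e$i != e$j],
      self = {
        s <- numeric(n0)
        lp <- e$i == e$j
        s[e$i[lp]] <- e$w[lp]
        s
      }
    )
    node2comm <- seq_len(n0) # original node -> community at current level
    repeat {
      comm <- louvain_local_move(lev, tol)
      labels <- sort(unique(comm))
      cmap <- match(comm, labels) # densified community ids 1..k
      k <- length(labels)
      node2comm <- cmap[node2comm]
      if (k == lev$n) break # no aggregation progress: done
      lev <- louvain_aggregate(lev, cmap, k)
    }
    labels <- sort(unique(node2comm))
    assignment <- match(node2comm, labels)
    names(assignment) <- net$nodes
    new_hard_partition(assignment)
  })
}

# one level of local moving; standard degree convention (self-loops count
# twice in strength) so that aggregation preserves the objective exactly
louvain_local_move <- function(lev, tol) {
  n <- lev$n
  # adjacency (excluding self-loops)
  adj_n <- vector("list", n)
  adj_w <- vector("list", n)
  ends <- c(lev$ei, lev$ej); other <- c(lev$ej, lev$ei); w2 <- c(lev$ew, lev$ew)
  sp <- split(seq_along(ends), ends)
  for (v in seq_len(n)) { adj_n[[v]] <- integer(0); adj_w[[v]] <- numeric(0) }
  for (key in names(sp)) {
    v <- as.integer(key)
    adj_n[[v]] <- other[sp[[key]]]
    adj_w[[v]] <- w2[sp[[key]]]
  }
  k <- vapply(seq_len(n), function(v) sum(adj_w[[v]]), numeric(1)) + 2 * lev$self
  two_m <- sum(k)
  if (two_m == 0) return(seq_len(n))
  comm <- seq_len(n)
  stot <- k
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      a <- comm[v]
      nb <- adj_n[[v]]
      if (!length(nb)) next
      wtab <- rowsum(adj_w[[v]], comm[nb])
      cands <- as.integer(rownames(wtab))
      wts <- wtab[, 1]
      if (!(a %in% cands)) { cands <- c(cands, a); wts <- c(wts, 0) }
      stot_minus <- stot[cands]
      stot_minus[cands == a] <- stot_minus[cands == a] - k[v]
      score <- wts - k[v] * stot_minus / two_m
      o <- order(-score, cands) # tie-break: lowest community id
      best <- cands[o[1]]
      cur_score <- score[cands == a]
      if (best != a && score[o[1]] > cur_score + tol) {
        stot[a] <- stot[a] - k[v]
        stot[best] <- stot[best] + k[v]
        comm[v] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

louvain_aggregate <- function(lev, cmap, k) {
  ci <- cmap[lev$ei]; cj <- cmap[lev$ej]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  self <- numeric(k)
  in_self <- rowsum(c(lev$self, ifelse(lo == hi, lev$ew, 0)),
                    c(cmap, lo))
  self[as.integer(rownames(in_self))] <- in_self[, 1]
  keep <- lo != hi
  if (any(keep)) {
    agg <- rowsum(lev$ew[keep], paste(lo[keep], hi[keep]))
    ij <- do.call(rbind, strsplit(rownames(agg), " "))
    list(n = k,
         ei = as.integer(ij[, 1]), ej = as.integer(ij[, 2]),
         ew = as.numeric(agg[, 1]), self = self)
  } else {
    list(n = k, ei = integer(0), ej = integer(0), ew = numeric(0), self = self)
  }
}
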