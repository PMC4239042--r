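#' Construct a hard partition from a named assignment vector
#'
#' Hard partitions are named integer vectors (node -> module id in 1..M)
#' of class `overmod_hard_partition`.  Arbitrary module labels are
#' densified to consecutive integers `1..M` by sorted original label.
#'
#' @param assignment named integer vector mapping node ids to module ids.
#' @return An `overmod_hard_partition`.
#' @export
new_hard_partition <- function(assignment) {
  stopifnot(is.integer(assignment), !is.null(names(assignment)))
  m_ids <- sort(unique(assignment))
  if (!identical(m_ids, seq_along(m_ids))) {
    nm <- names(assignment)
    assignment <- match(assignment, m_ids)
    names(assignment) <- nm
  }
  structure(assignment, class = "overmod_hard_partition")
}

n_modules <- function(hp) max(unclass(hp))

#' Read a hard (disjoint) partition from a TSV file
#'
#' Expects two whitespace-separated columns: node identifier and module id.
#' Module labels are densified to consecutive integers `1..M` (sorted by
#' original label).  Lines starting with `#` and blank lines are ignored.
#'
#' @param path path to the partition file.
#' @return A named integer vector of class `overmod_hard_partition` mapping
#'   each node to its module.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("partition file contains no data lines: ", path)
  toks <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    stop(sprintf("malformed partition line %d: %s", keep[bad], raw[keep[bad]]))
  }
  node <- vapply(toks, `[[`, character(1), 1L)
  mod <- vapply(toks, `[[`, character(1), 2L)
  dup <- duplicated(node)
  if (any(dup)) {
    for (d in which(dup)) {
      prev <- mod[match(node[d], node)]
      if (!identical(prev, mod[d])) {
        stop(sprintf("node '%s' listed with conflicting modules '%s' and '%s'",
                     node[d], prev, mod[d]))
      }
    }
    node <- node[!dup]; mod <- mod[!dup]
  }
  labels <- sort(unique(mod))
  assignment <- match(mod, labels)
  names(assignment) <- node
  o <- order(node)
  new_hard_partition(assignment[o])
}

#' Write a hard partition to a TSV file
#'
#' @param hp an `overmod_hard_partition`.
#' @param path output path.
#' @param header optional extra comment lines (without leading `#`).
#' @export
write_partition <- function(hp, path, header = character(0)) {
  lines <- c(paste0("#", c("node\tmodule", header)),
             paste(names(hp), unclass(hp), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# check that a hard partition covers the network exactly
validate_partition <- function(net, hp) {
  missing <- setdiff(net$nodes, names(hp))
  if (length(missing)) {
    stop("partition does not cover network node(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  invisible(TRUE)
}

# Soft partitions: membership is a named list of sorted integer module-id
# vectors; roles is a parallel named character vector in
# {"isolated", "intra", "inter"}; qov the objective value attained.
new_soft_partition <- function(membership, qov, roles) {
  stopifnot(is.list(membership), !is.null(names(membership)),
            all(lengths(membership) >= 1L),
            identical(sort(names(membership)), sort(names(roles))))
  membership <- lapply(membership, function(m) sort(as.integer(m)))
  roles <- roles[names(membership)]
  structure(list(membership = membership, qov = qov, roles = roles),
            class = "overmod_soft_partition")
}

#' @export
print.overmod_soft_partition <- function(x, ...) {
  tab <- table(factor(x$roles, levels = c("isolated", "intra", "inter")))
  cat(sprintf(
    "overmod soft partition: %d nodes, Q_ov = %.6f (isolated=%d intra=%d inter=%d)\n",
    length(x$membership), x$qov, tab[["isolated"]], tab[["intra"]], tab[["inter"]]))
  invisible(x)
}

#' Write a soft (overlapping) partition to a TSV file
#'
#' Format: a `#node<TAB>modules<TAB>role` header followed by one line per
#' node with comma-joined sorted module ids and the node's role
#' (`isolated`, `intra` or `inter`).  Extra comment lines may carry run
#' metadata.  Round-trip stable with [read_soft_partition()].
#'
#' @param sp an `overmod_soft_partition`.
#' @param path output path.
#' @param header optional extra comment lines (without leading `#`).
#' @export
write_soft_partition <- function(sp, path, header = character(0)) {
  nodes <- sort(names(sp$membership))
  mods <- vapply(sp$membership[nodes],
                 function(m) paste(sort(m), collapse = ","), character(1))
  lines <- c(paste0("#", header),
             "#node\tmodules\trole",
             paste(nodes, mods, sp$roles[nodes], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a soft partition written by [write_soft_partition()]
#'
#' @param path path to the soft-partition TSV.
#' @param qov objective value to attach (the file stores memberships and
#'   roles only); defaults to `NA`.
#' @return An `overmod_soft_partition`.
#' @export
read_soft_partition <- function(path, qov = NA_real_) {
  if (!file.exists(path)) stop("soft-partition file not found: ", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  toks <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(toks)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1]
    stop(sprintf("malformed soft-partition line %d: %s", keep[bad], raw[keep[bad]]))
  }
  node <- vapply(toks, `[[`, character(1), 1L)
  mods <- lapply(strsplit(vapply(toks, `[[`, character(1), 2L), ",", fixed = TRUE),
                 as.integer)
  role <- vapply(toks, `[[`, character(1), 3L)
  if (!all(role %in% c("isolated", "intra", "inter"))) {
    stop("unknown role label in soft-partition file")
  }
  names(mods) <- node
  names(role) <- node
  new_soft_partition(mods, qov, role)
}
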