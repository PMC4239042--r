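pkg_version <- function() {
  as.character(utils::packageVersion("overmod"))
}

output_header <- function(cfg, extra = character(0)) {
  c(sprintf("overmod %s", pkg_version()),
    sprintf("seed=%s restarts=%s tol=%g",
            as.character(cfg$seed), as.character(cfg$restarts), cfg$tol),
    extra)
}

#' Run the full two-stage conversion pipeline
#'
#' Stage one reads the network (and a hard partition, or detects one with
#' the built-in greedy optimiser when `auto_partition` is set) and
#' classifies nodes as isolated or connector.  Stage two converts the
#' hard partition into a soft partition by maximising the overlapping
#' modularity, classifies connectors as inter or intra, and writes the
#' artifacts: the soft partition, a role-count summary, per-node
#' profiles, and a machine-readable JSON manifest recording every
#' parameter, the seed and the attained objective.  All text outputs
#' begin with `#` comment headers carrying version, seed and parameters,
#' and a rerun with the same configuration is byte-identical.
#'
#' @param cfg a list: `edges` (edge-list path; required), `weighted`
#'   (flag, default `NA` = auto), `partition` (hard-partition path) or
#'   `auto_partition = TRUE`, `restarts` (default 100), `seed`
#'   (required), `tol` (default 1e-10), `exact` (use the enumeration
#'   solver), `budget` (enumeration budget, default 4096), `strong_rule`
#'   (default `"threshold:3"`), `out_dir` (required), `verbose`.
#' @return Invisibly, a list with the in-memory results (`network`,
#'   `hard`, `roles`, `soft`, `profiles`, `strong`, `paths`).
#' @export
run_pipeline <- function(cfg) {
  defaults <- list(weighted = NA, restarts = 100L, tol = 1e-10,
                   exact = FALSE, budget = 4096, auto_partition = FALSE,
                   strong_rule = "threshold:3", verbose = FALSE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$edges)) stop("pipeline [input]: an --edges file is required")
  if (is.null(cfg$out_dir)) stop("pipeline [output]: an --out directory is required")
  if (is.null(cfg$seed)) stop("pipeline [input]: a --seed is required")
  if (cfg$restarts < 1) stop("pipeline [input]: restarts must be >= 1")
  if (cfg$tol <= 0) stop("pipeline [input]: tolerance must be > 0")
  if (is.null(cfg$partition) && !isTRUE(cfg$auto_partition)) {
    stop("pipeline [input]: supply --partition or set --auto-partition")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  net <- tryCatch(main_component(read_edgelist(cfg$edges, weighted = cfg$weighted)),
                  error = function(e) stop("pipeline [netio]: ",
                                           conditionMessage(e), call. = FALSE))
  say("network: %d nodes, %d edges (main component)",
      length(net$nodes), nrow(net$edges))

  paths <- list()
  hp <- tryCatch({
    if (!is.null(cfg$partition)) {
      read_partition(cfg$partition)
    } else {
      hp <- greedy_hard_partition(net, seed = derive_seed(cfg$seed, 101L))
      paths$partition <- file.path(cfg$out_dir, "partition.tsv")
      write_partition(hp, paths$partition, header = output_header(cfg))
      hp
    }
  }, error = function(e) stop("pipeline [partition]: ",
                              conditionMessage(e), call. = FALSE))

  roles <- tryCatch(classify_nodes(net, hp),
                    error = function(e) stop("pipeline [roles]: ",
                                             conditionMessage(e), call. = FALSE))
  q_hard <- hard_modularity(net, hp)
  say("hard partition: M=%d, Q=%.6f, %d connectors",
      roles$n_modules, q_hard, sum(roles$is_connector))

  sp <- tryCatch({
    if (isTRUE(cfg$exact)) {
      solve_exact(net, roles, hp, budget = cfg$budget)
    } else {
      solve_multistart(net, roles, hp, restarts = cfg$restarts,
                       seed = derive_seed(cfg$seed, 202L), tol = cfg$tol)
    }
  }, error = function(e) stop("pipeline [convert]: ",
                              conditionMessage(e), call. = FALSE))
  sp <- classify_connectors(sp, roles)
  if (isTRUE(cfg$verbose) && !is.null(attr(sp, "restart_qov"))) {
    for (r in seq_along(attr(sp, "restart_qov"))) {
      say("restart %d: Q_ov=%.9f", r, attr(sp, "restart_qov")[r])
    }
  }
  counts <- attr(sp, "role_counts")
  say("soft partition: Q_ov=%.6f isolated=%d intra=%d inter=%d",
      sp$qov, counts[["isolated"]], counts[["intra"]], counts[["inter"]])

  paths$soft <- file.path(cfg$out_dir, "soft.tsv")
  write_soft_partition(sp, paths$soft,
                       header = output_header(cfg, sprintf("qov=%.12g", sp$qov)))

  paths$summary <- file.path(cfg$out_dir, "summary.tsv")
  writeLines(c(paste0("#", output_header(cfg)),
               "#modules\tqov\tq_hard\tisolated\tintra\tinter",
               sprintf("%d\t%.12g\t%.12g\t%d\t%d\t%d",
                       roles$n_modules, sp$qov, q_hard,
                       counts[["isolated"]], counts[["intra"]],
                       counts[["inter"]])),
             paths$summary)

  profiles <- node_profiles(net, hp, sp)
  paths$profiles <- file.path(cfg$out_dir, "profiles.tsv")
  con <- file(paths$profiles, "w")
  writeLines(paste0("#", output_header(cfg)), con)
  suppressWarnings(write.table(format(profiles, digits = 12, trim = TRUE),
                               con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)

  strong <- strong_interconnectors(sp, rule = cfg$strong_rule)

  manifest <- list(
    version = pkg_version(),
    parameters = cfg[c("edges", "partition", "weighted", "restarts", "seed",
                       "tol", "exact", "budget", "auto_partition",
                       "strong_rule")],
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    n_modules = roles$n_modules,
    q_hard = q_hard,
    qov = sp$qov,
    role_counts = as.list(counts),
    strong_interconnectors = as.character(strong),
    outputs = paths
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(network = net, hard = hp, roles = roles, soft = sp,
                 profiles = profiles, strong = strong, paths = paths))
}
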