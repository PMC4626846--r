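#' Configuration of a multi-site key-player run
#'
#' @param tables named character vector or list: site label -> path of a
#'   tab-separated OTU table (see [read_otu_table]).
#' @param theta prevalence threshold; default 0.20.
#' @param n_resamples,n_permutations,exclusion_threshold,max_exclusions,alpha
#'   sparCC/network parameters (see [sparcc_correlation], [build_network]).
#' @param cutoffs top-rank fractions; default `c(0.05, 0.10, 0.20)`.
#' @param metrics centrality metrics; default degree and betweenness.
#' @param dominance_fraction see [dominant_groups]; default 0.10.
#' @param tie_policy see [top_set].
#' @param seed integer seed recorded in every output header.
#' @param out_dir output directory (one subdirectory per site is created).
#' @return A list of class `run_config`.
#' @export
run_config <- function(tables, theta = 0.20, n_resamples = 20,
                       n_permutations = 100, exclusion_threshold = 0.1,
                       max_exclusions = 10, alpha = 0.05,
                       cutoffs = c(0.05, 0.10, 0.20),
                       metrics = c("degree", "betweenness"),
                       dominance_fraction = 0.10,
                       tie_policy = "stable-order", seed = 1,
                       out_dir = "microkey_out") {
  tables <- unlist(tables)
  if (length(tables) == 0) stop("at least one site table is required")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be named by site label")
  if (any(cutoffs <= 0 | cutoffs > 1)) stop("cutoffs must lie in (0, 1]")
  structure(list(tables = tables, theta = theta, n_resamples = n_resamples,
                 n_permutations = n_permutations,
                 exclusion_threshold = exclusion_threshold,
                 max_exclusions = max_exclusions, alpha = alpha,
                 cutoffs = cutoffs, metrics = metrics,
                 dominance_fraction = dominance_fraction,
                 tie_policy = tie_policy, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON object mirrors [run_config] field for field; `tables` is an
#' object mapping site labels to file paths.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- j[intersect(names(j), names(formals(run_config)))]
  do.call(run_config, args)
}

# provenance header prepended to every TSV artifact
.provenance <- function(config, site) {
  sprintf(paste0("# microkey site=%s seed=%d theta=%g alpha=%g resamples=%d ",
                 "permutations=%d tie_policy=%s"),
          site, config$seed, config$theta, config$alpha, config$n_resamples,
          config$n_permutations, config$tie_policy)
}

.write_tsv <- function(d, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full key-player analysis for one body site
#'
#' Filter -> sparCC correlations + permutation p-values -> binary network ->
#' global statistics and centralities -> group enrichment and dominance.
#' Writes, under `out_dir/<site>/`: `filtered_table.tsv`,
#' `correlations.tsv`, `pvalues.tsv`, `edges.tsv`, `network.graphml`,
#' `global_stats.tsv`, `centrality.tsv`, `enrichment.tsv` — every TSV
#' carrying a provenance comment line with the configuration and seed.
#'
#' @param config a [run_config].
#' @param site one of `names(config$tables)`.
#' @return Invisibly, a list with the in-memory results (`table`, `sparcc`,
#'   `network`, `global`, `centrality`, `enrichment`, `files`).
#' @export
run_site <- function(config, site) {
  if (!site %in% names(config$tables)) stop("unknown site: ", site)
  dir <- file.path(config$out_dir, site)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .provenance(config, site)

  tab <- read_otu_table(config$tables[[site]], site = site)
  tab <- prevalence_filter(tab, config$theta)
  write_otu_table(tab, file.path(dir, "filtered_table.tsv"))

  cr <- sparcc_correlation(tab, n_resamples = config$n_resamples,
                           n_permutations = config$n_permutations,
                           seed = config$seed,
                           exclusion_threshold = config$exclusion_threshold,
                           max_exclusions = config$max_exclusions)
  .write_tsv(as.data.frame(cr$rho), file.path(dir, "correlations.tsv"), hdr)
  .write_tsv(as.data.frame(cr$pvals), file.path(dir, "pvalues.tsv"), hdr)

  gm <- group_map(tab)
  net <- build_network(cr$rho, cr$pvals, alpha = config$alpha,
                       nodes = gm$otu_id, groups = gm$group)
  el <- igraph::as_edgelist(net)
  .write_tsv(data.frame(otu_a = el[, 1], otu_b = el[, 2]),
             file.path(dir, "edges.tsv"), hdr)
  igraph::write_graph(net, file.path(dir, "network.graphml"),
                      format = "graphml")

  gs <- global_stats(net)
  .write_tsv(cbind(site = site, gs), file.path(dir, "global_stats.tsv"), hdr)
  ct <- centrality_table(net)
  .write_tsv(ct, file.path(dir, "centrality.tsv"), hdr)

  kp <- key_players(net, metrics = config$metrics, cutoffs = config$cutoffs,
                    alpha = config$alpha,
                    dominance_fraction = config$dominance_fraction,
                    tie_policy = config$tie_policy)
  .write_tsv(kp, file.path(dir, "enrichment.tsv"), hdr)

  files <- file.path(dir, c("filtered_table.tsv", "correlations.tsv",
                            "pvalues.tsv", "edges.tsv", "network.graphml",
                            "global_stats.tsv", "centrality.tsv",
                            "enrichment.tsv"))
  invisible(list(table = tab, sparcc = cr, network = net, global = gs,
                 centrality = ct, enrichment = kp, files = files))
}

#' Run every configured site and combine the reports
#'
#' Each site is analysed with [run_site]; a failure in one site is logged
#' and does not stop the others. The combined report concatenates the
#' per-site global-statistics rows and builds a groups-by-sites key/dominant
#' summary from the per-site enrichment tables (re-read from the files on
#' disk, so every combined number traces to exactly one per-site artifact).
#' The combined files `global_stats_all.tsv` and `key_summary.tsv` are
#' written under `config$out_dir`.
#'
#' @param config a [run_config].
#' @return A list with `global` (one row per successful site), `summary`
#'   (group x site key/dominant table), `failures` (named character vector
#'   of error messages), `n_ok`.
#' @export
run_all <- function(config) {
  sites <- names(config$tables)
  if (length(sites) == 0) stop("no sites configured")
  failures <- character(0)
  for (s in sites) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({run_site(config, s); NULL},
                    error = function(e) conditionMessage(e))
    if (is.null(res)) {
      message(sprintf("[microkey] site %s done in %.1fs (seed %d)",
                      s, proc.time()[["elapsed"]] - t0, config$seed))
    } else {
      message(sprintf("[microkey] site %s FAILED: %s", s, res))
      failures[s] <- res
    }
  }
  ok <- setdiff(sites, names(failures))
  if (length(ok) == 0) stop("all sites failed")
  read_artifact <- function(s, f)
    utils::read.table(file.path(config$out_dir, s, f), sep = "\t",
                      header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  global <- do.call(rbind, lapply(ok, read_artifact, "global_stats.tsv"))
  enr <- do.call(rbind, lapply(ok, function(s)
    cbind(site = s, read_artifact(s, "enrichment.tsv"))))
  qd <- if (0.20 %in% config$cutoffs) 0.20 else max(config$cutoffs)
  md <- if ("degree" %in% config$metrics) "degree" else config$metrics[1]
  base <- enr[enr$metric == md & enr$cutoff == qd, ]
  summary <- data.frame(site = base$site, group = base$group,
                        key = base$significant, dominant = base$dominant)
  hdr <- sprintf("# microkey combined seed=%d tie_policy=%s",
                 config$seed, config$tie_policy)
  .write_tsv(global, file.path(config$out_dir, "global_stats_all.tsv"), hdr)
  .write_tsv(summary, file.path(config$out_dir, "key_summary.tsv"), hdr)
  list(global = global, summary = summary, failures = failures,
       n_ok = length(ok))
}
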