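#' Write a panel to long-format CSV with a JSON sidecar
#'
#' @param panel a `panel_data` (or compatible data frame).
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json` when `truth` or `seed` is supplied.
#' @param truth optional ground-truth [weighted_digraph()].
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, truth = NULL, seed = NULL) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  if (!is.null(truth) || !is.null(seed)) {
    sidecar <- list(seed = seed)
    if (!is.null(truth)) {
      sidecar$truth <- list(labels = truth$labels,
                            weights = truth$weights,
                            edges = edge_list(truth))
    }
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read and validate a long-format panel CSV
#'
#' The file must provide `id`, `visit`, outcome columns `Y1..YQ` and
#' optionally covariates `X1..XS`.  Rows are sorted to canonical order
#' (id, then visit); individuals with fewer than two visits are dropped
#' with a warning; visits within an individual must be consecutive
#' integers starting at 1.
#'
#' @param path CSV file path.
#' @param on_gap `"error"` (default) rejects non-consecutive visits,
#'   `"drop"` removes the offending individuals with a warning.
#' @return a `panel_data` data frame.
#' @export
read_panel <- function(path, on_gap = c("error", "drop")) {
  on_gap <- match.arg(on_gap)
  df <- utils::read.csv(path)
  need <- c("id", "visit")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- panel_columns(df)
  num_cols <- c("visit", cols$y, cols$x)
  bad <- num_cols[!vapply(df[num_cols], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (cc in cols$y) {
    if (anyNA(df[[cc]])) {
      stop("missing outcome values in ", cc, " (rows ",
           paste(utils::head(which(is.na(df[[cc]])), 3L), collapse = ", "),
           ", ...)", call. = FALSE)
    }
  }
  df <- df[order(df$id, df$visit), , drop = FALSE]
  counts <- table(df$id)
  short <- names(counts)[counts < 2L]
  if (length(short)) {
    warning("dropping ", length(short),
            " individual(s) with fewer than two visits: ",
            paste(utils::head(short, 5L), collapse = ", "), call. = FALSE)
    df <- df[!(df$id %in% short), , drop = FALSE]
  }
  gap_ids <- unlist(lapply(split(df$visit, df$id), function(v) {
    if (!identical(as.integer(v), seq_along(v))) TRUE else FALSE
  }))
  bad_ids <- names(gap_ids)[gap_ids]
  if (length(bad_ids)) {
    if (on_gap == "error") {
      stop("non-consecutive visits for individual(s): ",
           paste(utils::head(bad_ids, 5L), collapse = ", "), call. = FALSE)
    }
    warning("dropping individual(s) with visit gaps: ",
            paste(utils::head(bad_ids, 5L), collapse = ", "), call. = FALSE)
    df <- df[!(df$id %in% bad_ids), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("panel_data", "data.frame")
  df
}

#' Configuration for a replicated simulate-fit-select experiment
#'
#' @param scenario 1 or 2 (the built-in generators).
#' @param n_replicates number of replicates (at least 1).
#' @param seed master seed; per-replicate seeds are derived from it
#'   deterministically.
#' @param scenario_args list of arguments to [scenario_one()] /
#'   [scenario_two()].
#' @param Ly,Lx lag orders used in the fit.
#' @param priors a [prior_config()].
#' @param mcmc list of MCMC control arguments for [fit_dcg()].
#' @param threshold edge-inclusion threshold for [select_graph()].
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(scenario, n_replicates, seed,
                              scenario_args = list(), Ly = 0L, Lx = 0L,
                              priors = prior_config(),
                              mcmc = list(n_iter = 5000L, burnin = 2500L,
                                          thin = 5L),
                              threshold = 0.5) {
  if (!scenario %in% c(1L, 2L)) stop("`scenario` must be 1 or 2",
                                     call. = FALSE)
  if (n_replicates < 1L) stop("`n_replicates` must be at least 1",
                              call. = FALSE)
  structure(list(scenario = as.integer(scenario),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), scenario_args = scenario_args,
                 Ly = as.integer(Ly), Lx = as.integer(Lx), priors = priors,
                 mcmc = mcmc, threshold = threshold),
            class = "experiment_config")
}

#' Run a replicated simulate-fit-select experiment
#'
#' For each replicate a fresh panel is simulated, the model fitted, and
#' the median-probability graph selected.  The report aggregates the
#' relative frequency of each distinct selected graph (identified by its
#' instantaneous-plus-lagged edge support) and the marginal detection
#' frequency of every edge.
#'
#' @param config an [experiment_config()].
#' @param progress print one line per replicate.
#' @return object of class `experiment_report` with `graph_modes`
#'   (data frame: key, count, frequency), `edge_freq` (data frame: edge,
#'   count, frequency), `replicates` (list of per-replicate summaries),
#'   `config`.
#' @export
run_replicated_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    res <- tryCatch({
      set.seed(seeds[r])
      sim <- if (config$scenario == 1L) {
        do.call(scenario_one, config$scenario_args)
      } else {
        do.call(scenario_two, config$scenario_args)
      }
      fit <- do.call(fit_dcg, c(list(panel = sim$panel, Ly = config$Ly,
                                     Lx = config$Lx,
                                     priors = config$priors),
                                config$mcmc))
      summ <- select_graph(fit, threshold = config$threshold)
      list(seed = seeds[r], key = summary_support_key(summ),
           edges = summ$edges, summary = summ)
    }, error = function(e) {
      stop("replicate ", r, " failed: ", conditionMessage(e), call. = FALSE)
    })
    reps[[r]] <- res
    if (progress) {
      cat(sprintf("replicate %d/%d: %d edge(s)\n", r, config$n_replicates,
                  nrow(res$edges)))
    }
  }
  keys <- vapply(reps, `[[`, character(1), "key")
  tab <- sort(table(keys), decreasing = TRUE)
  graph_modes <- data.frame(key = names(tab), count = as.integer(tab),
                            frequency = as.numeric(tab) / length(keys),
                            stringsAsFactors = FALSE)
  all_edges <- unlist(lapply(reps, function(r) {
    unique(paste0(r$edges$from, ">", r$edges$to))
  }))
  etab <- sort(table(all_edges), decreasing = TRUE)
  edge_freq <- data.frame(edge = names(etab), count = as.integer(etab),
                          frequency = as.numeric(etab) / length(keys),
                          stringsAsFactors = FALSE)
  structure(list(graph_modes = graph_modes, edge_freq = edge_freq,
                 replicates = reps, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", length(x$replicates), " replicate(s), ",
      nrow(x$graph_modes), " distinct graph mode(s)\n", sep = "")
  print(utils::head(x$graph_modes, 5L), row.names = FALSE)
  invisible(x)
}

#' Marginal detection frequency of an undirected outcome pair
#'
#' Relative frequency, across replicates, of selecting an instantaneous
#' edge between two vertices in either direction (the reporting unit of
#' the simulation studies).
#'
#' @param report an [run_replicated_experiment()] report.
#' @param a,b vertex labels.
#' @return a frequency in `[0, 1]`.
#' @export
pair_detection_frequency <- function(report, a, b) {
  hits <- vapply(report$replicates, function(r) {
    e <- r$edges[r$edges$lag == 0L, , drop = FALSE]
    any((e$from == a & e$to == b) | (e$from == b & e$to == a))
  }, logical(1))
  mean(hits)
}

#' Render an experiment report to files
#'
#' Writes the graph-mode frequency table and marginal edge frequencies as
#' CSV, a JSON summary, and one DOT figure per graph mode with edge
#' labels rounded to two decimals.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "graph_modes.csv")
  utils::write.csv(report$graph_modes, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "edge_frequencies.csv")
  utils::write.csv(report$edge_freq, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(n_replicates = length(report$replicates),
         seed = report$config$seed,
         scenario = report$config$scenario,
         package_version = as.character(utils::packageVersion("dcgiv")),
         graph_modes = report$graph_modes,
         edge_frequencies = report$edge_freq),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  for (k in seq_len(nrow(report$graph_modes))) {
    key <- report$graph_modes$key[k]
    rep1 <- report$replicates[[match(key, vapply(report$replicates, `[[`,
                                                 character(1), "key"))]]
    p <- file.path(dir, sprintf("mode_%02d.dot", k))
    write_mode_dot(rep1$edges, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_mode_dot <- function(edges, path) {
  verts <- unique(c(edges$from, edges$to))
  lines <- c("digraph mode {",
             paste0("  \"", verts, "\";"),
             if (nrow(edges)) {
               paste0("  \"", edges$from, "\" -> \"", edges$to,
                      "\" [label=\"", sprintf("%.2f", edges$weight), "\"];")
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}
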