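# End-to-end orchestration: load -> kinetics -> rank -> cluster + sensitivity
# -> ADOS -> HDP -> report, plus fixture generation for worked examples.

#' Default pipeline configuration
#'
#' Every tunable of the workflow, with the canonical defaults: cluster the
#' full panel at k = 6, flag poor clusterers over the 1 + S leave-one-out
#' dendrograms at threshold 6 (or take `drop_poor_clusterers` as given),
#' recluster the survivors at k = 4, score ADOS, drop the stability-family
#' variables, and fit the LASSO HDP (5-fold CV, 100 lambda values) against
#' the ranked absolute 25 C monomer-loss rate.
#'
#' @param matrix_csv,registry_csv,timeseries_csv optional input paths; when
#'   `NULL` the pipeline must be given in-memory objects.
#' @param k_full,k_reduced branch counts for the full and reduced clusterings.
#' @param poor_threshold leave-one-out flag threshold (default 6).
#' @param drop_poor_clusterers var_ids removed as difficult to cluster; the
#'   canonical panel uses `c(29, 30, 31, 32)`. Set to `NULL` to re-derive
#'   them via [identify_poor_clusterers()].
#' @param target list: `readout`, `temperature`, `absolute` (rank on the
#'   absolute rate).
#' @param lasso list: `folds`, `n_lambda`, `seed`.
#' @param rank_partition optional list with `fixed`, `tied`, `ambiguous`
#'   enabling the rank-uncertainty sweep (see [enumerate_rank_sets()]).
#' @param default_cv percent CV for [fit_rate_wls()].
#' @param out_dir optional directory; when set, stage outputs are written as
#'   CSV/JSON.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_csv = NULL, registry_csv = NULL,
                            timeseries_csv = NULL,
                            k_full = 6L, k_reduced = 4L,
                            poor_threshold = 6L,
                            drop_poor_clusterers = c(29L, 30L, 31L, 32L),
                            target = list(readout = "monomer", temperature = 25,
                                          absolute = TRUE),
                            lasso = list(folds = 5L, n_lambda = 100L, seed = 1L),
                            rank_partition = NULL,
                            default_cv = 0.036,
                            out_dir = NULL) {
  structure(list(matrix_csv = matrix_csv, registry_csv = registry_csv,
                 timeseries_csv = timeseries_csv,
                 k_full = as.integer(k_full), k_reduced = as.integer(k_reduced),
                 poor_threshold = as.integer(poor_threshold),
                 drop_poor_clusterers = drop_poor_clusterers,
                 target = target, lasso = lasso,
                 rank_partition = rank_partition,
                 default_cv = default_cv, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full developability workflow
#'
#' Stages, in order: load/validate the panel; fit CV-weighted degradation
#' rates from the stability time courses and rank the target attribute;
#' cluster the full variable set and remove the difficult-to-cluster
#' variables; recluster the survivors, compute ADOS (and its MLR-weighted
#' variant); remove the stability-family variables; fit the LASSO HDP on the
#' ranked remainder; optionally sweep the 2^m + 1 rank sets. Any stage error
#' aborts with the stage name; warnings are collected in the report.
#'
#' @param config a [pipeline_config()].
#' @param matrix optional in-memory `dev_matrix` (overrides the CSV paths).
#' @param series optional list of [stability_series()] (overrides the CSV).
#' @return A list of class `run_report`: stage results, the variable-count
#'   filter chain, selected HDP variables, correlations and warnings.
#' @export
run_full <- function(config, matrix = NULL, series = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        note(sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  m <- run_stage("load", {
    if (is.null(matrix)) matrix <- load_matrix(config$matrix_csv, config$registry_csv)
    matrix
  })
  counts <- c(initial = ncol(m$values))

  rates <- run_stage("kinetics", {
    if (is.null(series) && !is.null(config$timeseries_csv))
      series <- read_timeseries(config$timeseries_csv)
    if (is.null(series)) NULL else {
      sel <- Filter(function(s) s$readout == config$target$readout &&
                      s$temperature == config$target$temperature, series)
      lapply(sel, fit_rate_wls, default_cv = config$default_cv)
    }
  })

  target_ranks <- run_stage("target", {
    if (is.null(rates)) NULL else {
      vals <- vapply(rates, function(r) r$slope, 0)
      names(vals) <- vapply(rates, function(r) r$sample_id, "")
      vals <- vals[rownames(m$values)]
      if (isTRUE(config$target$absolute)) vals <- abs(vals)
      stats::setNames(avg_rank(vals), rownames(m$values))
    }
  })

  cluster_full <- run_stage("cluster_full", {
    cluster_variables(spearman_matrix(m), k = config$k_full)
  })

  poor <- run_stage("poor_clusterers", {
    if (is.null(config$drop_poor_clusterers))
      identify_poor_clusterers(m, k = config$k_full,
                               threshold = config$poor_threshold)
    else as.integer(config$drop_poor_clusterers)
  })
  m28 <- run_stage("drop_poor", drop_variables(m, poor))
  counts <- c(counts, after_poor_drop = ncol(m28$values))

  dend <- run_stage("cluster_reduced", {
    cluster_variables(spearman_matrix(m28), k = config$k_reduced)
  })
  loo <- run_stage("sensitivity", {
    pairing_stability(leave_one_out_dendrograms(m28, k = config$k_reduced))
  })

  groups <- stats::setNames(paste0("G", dend$branches), dend$var_ids)
  ados_res <- run_stage("ados", ados(m28, groups = groups))
  mlr_res <- if (!is.null(target_ranks))
    run_stage("ados_mlr", ados_mlr(ados_res, target_ranks)) else NULL

  m19 <- run_stage("drop_stability", drop_variables(m28, family_vars(m28, "stability")))
  counts <- c(counts, after_stability_drop = ncol(m19$values))

  lasso_res <- hdp_res <- sweep_res <- NULL
  if (!is.null(target_ranks)) {
    Xr <- rank_matrix(m19)
    lasso_res <- run_stage("lasso", {
      fit_lasso(Xr, target_ranks, folds = config$lasso$folds,
                n_lambda = config$lasso$n_lambda, seed = config$lasso$seed)
    })
    hdp_res <- run_stage("hdp", hdp(lasso_res, Xr, target_ranks))
    if (!is.null(config$rank_partition)) {
      sweep_res <- run_stage("sweep", {
        rp <- config$rank_partition
        sets <- enumerate_rank_sets(rates,
                                    fixed = unlist(rp$fixed),
                                    tied = rp$tied,
                                    ambiguous = rp$ambiguous)
        selection_sweep(Xr, sets, folds = config$lasso$folds,
                        n_lambda = config$lasso$n_lambda,
                        seed = config$lasso$seed,
                        groups = groups[colnames(Xr)])
      })
    }
  }

  report <- structure(list(
    counts = counts, poor_clusterers = poor,
    rates = rates, target_ranks = target_ranks,
    dendrogram_full = cluster_full, dendrogram = dend,
    pairing_stability = loo,
    ados = ados_res, ados_mlr = mlr_res,
    lasso = lasso_res, hdp = hdp_res, sweep = sweep_res,
    warnings = warnings_log, files = character(0)
  ), class = "run_report")
  if (!is.null(config$out_dir))
    report$files <- write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("devrank run report\n")
  cat("  variable filter chain:", paste(x$counts, collapse = " -> "), "\n")
  cat("  poor clusterers removed:", paste(x$poor_clusterers, collapse = ", "), "\n")
  if (!is.null(x$lasso))
    cat("  HDP variables:", paste(x$lasso$selected_vars, collapse = ", "),
        sprintf("(r = %.3f)\n", x$hdp$pearson_r))
  if (!is.null(x$sweep))
    cat("  rank-uncertainty sweep:", length(x$sweep$models), "LASSO fits\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(report$rates)) {
    put_csv(data.frame(
      sample_id = vapply(report$rates, function(r) r$sample_id, ""),
      readout = vapply(report$rates, function(r) r$readout, ""),
      temperature = vapply(report$rates, function(r) r$temperature, 0),
      slope = vapply(report$rates, function(r) r$slope, 0),
      stderr = vapply(report$rates, function(r) r$stderr, 0),
      method = vapply(report$rates, function(r) r$method, "")), "rates.csv")
  }
  put_csv(report$pairing_stability, "pairing_stability.csv")
  put_csv(as.data.frame(report$ados), "ados.csv")
  hc <- report$dendrogram$hclust
  dj <- file.path(out_dir, "dendrogram.json")
  jsonlite::write_json(list(merge = hc$merge, height = hc$height,
                            var_ids = report$dendrogram$var_ids,
                            branches = unname(report$dendrogram$branches)),
                       dj, auto_unbox = TRUE, digits = NA)
  files <- c(files, dj)
  if (!is.null(report$lasso)) {
    lj <- file.path(out_dir, "lasso_model.json")
    jsonlite::write_json(list(lambda_grid = report$lasso$lambda_grid,
                              lambda_star = report$lasso$lambda_star,
                              coefficients = as.list(report$lasso$coefficients),
                              intercept = report$lasso$intercept,
                              selected_vars = report$lasso$selected_vars,
                              pearson_r = report$hdp$pearson_r),
                         lj, auto_unbox = TRUE, digits = NA)
    files <- c(files, lj)
  }
  if (!is.null(report$sweep)) put_csv(report$sweep$by_var, "selection_frequency.csv")
  rj <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(counts = as.list(report$counts),
                            poor_clusterers = report$poor_clusterers,
                            selected_vars = if (is.null(report$lasso)) list()
                                            else report$lasso$selected_vars,
                            warnings = report$warnings,
                            files = files),
                       rj, auto_unbox = TRUE, digits = NA)
  c(files, rj)
}

#' Read stability time courses from long-format CSV
#'
#' Columns: `sample_id,readout,temperature,time_months,replicate,value_percent`.
#'
#' @param path CSV path.
#' @return List of [stability_series()], one per
#'   sample/readout/temperature combination.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "readout", "temperature", "time_months",
            "replicate", "value_percent")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("time-series CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  key <- interaction(d$sample_id, d$readout, d$temperature, drop = TRUE)
  lapply(split(d, key), function(g)
    stability_series(g$sample_id[1L], g$readout[1L], g$temperature[1L],
                     g$time_months, g$replicate, g$value_percent))
}

#' Write stability time courses to long-format CSV
#'
#' @param series list of [stability_series()].
#' @param path CSV destination.
#' @export
write_timeseries <- function(series, path) {
  rows <- lapply(series, function(s)
    data.frame(sample_id = s$sample_id, readout = s$readout,
               temperature = s$temperature, s$data,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complete synthetic example study to disk
#'
#' Wraps the synthetic-panel generator: emits the matrix CSV, registry CSV,
#' outcome CSV (true monomer-loss rates) and a long-format time-series CSV
#' covering every sample at each registered temperature.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param config optional [synth_config()]; its seed is overridden by `seed`.
#' @return Invisibly, a named list of file paths plus the generated objects.
#' @export
make_fixture <- function(seed = 1L, dir = tempfile("devrank_fixture_"),
                         config = NULL) {
  if (is.null(config)) config <- synth_config(seed = seed)
  else config$seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- generate_matrix(config)
  outcome <- generate_outcome(m, config)
  paths <- list(matrix = file.path(dir, "matrix.csv"),
                registry = file.path(dir, "registry.csv"),
                outcome = file.path(dir, "outcome.csv"),
                timeseries = file.path(dir, "timeseries.csv"))
  write_matrix(m, paths$matrix, paths$registry)
  utils::write.csv(data.frame(sample_id = names(outcome),
                              rate_percent_per_month = as.numeric(outcome)),
                   paths$outcome, row.names = FALSE, quote = FALSE)
  series <- list()
  for (i in seq_along(outcome)) {
    for (temp in names(config$time_grids)) {
      series[[length(series) + 1L]] <-
        generate_timeseries(abs(outcome[i]) * temp_rate_factor(temp), config,
                            temperature = temp,
                            sample_id = names(outcome)[i],
                            seed = config$seed + 3e6L + i * 100L +
                              as.integer(as.numeric(temp)))
    }
  }
  write_timeseries(series, paths$timeseries)
  invisible(c(paths, list(matrix_obj = m, outcome = outcome, series = series,
                          config = config)))
}

# Relative speed of degradation by storage temperature: 25 C is the reference
# attribute; 40 C runs ~30x faster and 5 C ~7x slower (accelerated vs
# long-term storage).
temp_rate_factor <- function(temperature) {
  switch(as.character(temperature), `40` = 30, `25` = 1, `5` = 1 / 7, 1)
}
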