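#' @section Plot tables and pipeline:
#' The package consumes plot-level tables in a fixed CSV schema
#' (`plot_id, treatment, cultivar, rep, blue, green, red, red_edge, nir,
#' yield_t_ha`) — the product of upstream orthomosaic zonal statistics —
#' and [run_pipeline()] reproduces the full workflow on such a table:
#' index computation, dual ranking, thresholding, set combination,
#' RFE per base model, and a cross-validated accuracy grid of six feature
#' subsets (all features, PC, RF, union, intersection, integrated
#' selection) by two base models.
#' @name io
NULL

.plot_schema <- c("plot_id", "treatment", "cultivar", "rep",
                  "blue", "green", "red", "red_edge", "nir", "yield_t_ha")

#' Read a plot-level band table
#'
#' Reads and validates the standard plot CSV. Malformed rows (non-numeric
#' bands, non-positive yield) are rejected with their line numbers.
#'
#' @param path CSV path with header
#'   `plot_id,treatment,cultivar,rep,blue,green,red,red_edge,nir,yield_t_ha`.
#' @return A validated data.frame, one row per plot.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) vi_stop(sprintf("file not found: %s", path), "viselect_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.plot_schema, names(raw))
  if (length(missing)) {
    vi_stop(sprintf("plot table is missing column(s): %s",
                    paste(missing, collapse = ", ")), "viselect_schema_error")
  }
  out <- raw[.plot_schema]
  num_cols <- c("rep", "blue", "green", "red", "red_edge", "nir", "yield_t_ha")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (length(bad)) {
      vi_stop(sprintf("non-numeric '%s' at line(s) %s", col,
                      paste(bad + 1L, collapse = ", ")), "viselect_schema_error")
    }
    out[[col]] <- v
  }
  bad_yield <- which(!is.finite(out$yield_t_ha) | out$yield_t_ha <= 0)
  if (length(bad_yield)) {
    vi_stop(sprintf("non-positive or missing yield at line(s) %s",
                    paste(bad_yield + 1L, collapse = ", ")), "viselect_schema_error")
  }
  validate_bands(out[c("blue", "green", "red", "red_edge", "nir")])
  out
}

#' Write a plot-level band table
#'
#' @param plots A data.frame in the standard plot schema (e.g.
#'   `simulate_experiment()$plots`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_plot_table <- function(plots, path) {
  missing <- setdiff(.plot_schema, names(plots))
  if (length(missing)) {
    vi_stop(sprintf("plot table is missing column(s): %s",
                    paste(missing, collapse = ", ")), "viselect_schema_error")
  }
  utils::write.csv(plots[.plot_schema], path, row.names = FALSE)
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' @param stage Free-text stage label (e.g. `"flowering"`,
#'   `"grain_filling"`); the two acquisition stages of a trial are treated
#'   as independent runs over separate tables.
#' @param dialect Index formula dialect.
#' @param pc_tau,rf_tau Ranking thresholds (defaults 0.53 and 1.9).
#' @param models Base model families to run (default both).
#' @param k Cross-validation folds for the accuracy grid (default 10).
#' @param seed Master seed; all stage seeds are derived from it.
#' @param patience,rfe_folds RFE patience and inner CV folds.
#' @param num_trees Trees for the ranking forest.
#' @param cubist,rnn Control lists for the base models
#'   ([cubist_control()], [rnn_control()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(stage = "flowering", dialect = "as_printed",
                       pc_tau = 0.53, rf_tau = 1.9,
                       models = c("cubist", "rnn"), k = 10, seed = 1,
                       patience = 10, rfe_folds = 10, num_trees = 500,
                       cubist = cubist_control(), rnn = rnn_control()) {
  models <- match.arg(models, c("cubist", "rnn"), several.ok = TRUE)
  structure(list(stage = stage, dialect = match_dialect(dialect),
                 pc_tau = pc_tau, rf_tau = rf_tau, models = models,
                 k = as.integer(k), seed = as.integer(seed),
                 patience = as.integer(patience),
                 rfe_folds = as.integer(rfe_folds),
                 num_trees = as.integer(num_trees),
                 cubist = cubist, rnn = rnn),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lapply(unclass(config), unclass), tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

spec_for <- function(config, family, seed) {
  ctrl <- config[[family]]
  spec <- model_spec(family, seed = seed)
  spec$control <- ctrl
  spec
}

#' Run the full feature-selection and evaluation pipeline
#'
#' Executes, on one plot table: index computation, Pearson and forest
#' rankings, thresholding, union/intersection, recursive feature
#' elimination per base model, and the cross-validated accuracy grid of six
#' feature subsets by the configured base models. Fully seeded and
#' reproducible: two runs with identical config produce identical reports.
#'
#' @param plots A plot table (data.frame in the standard schema) or a path
#'   to one.
#' @param config A [run_config()].
#' @param out_dir Optional output directory; if given, `report.json` and
#'   `summary.csv` are written there.
#' @return An object of class `yield_run`: `$results` (one row per model x
#'   subset with mean R² and RMSE), `$subsets`, `$selection` (per-model
#'   `pcrf_rfe` objects), `$provenance`.
#' @export
run_pipeline <- function(plots, config = run_config(), out_dir = NULL) {
  if (is.character(plots)) plots <- read_plot_table(plots)
  message(sprintf("stage [indices]: computing %d vegetation indices (%s)",
                  length(vi_names()), config$dialect))
  vit <- compute_all(plots, dialect = config$dialect)
  y <- plots$yield_t_ha

  message("stage [ranking]: Pearson correlation and forest importance")
  rk_pc <- pearson_ranking(vit, y)
  rk_rf <- rf_ranking(vit, y, num_trees = config$num_trees,
                      seed = mix_seed(config$seed, 1L))

  message(sprintf("stage [threshold]: |r| > %g, importance > %g",
                  config$pc_tau, config$rf_tau))
  sub_pc <- apply_threshold(rk_pc, config$pc_tau)
  sub_rf <- apply_threshold(rk_rf, config$rf_tau)

  message("stage [combine]: union and intersection of the retained sets")
  sub_union <- combine_subsets(sub_pc, sub_rf, "union")
  sub_inter <- combine_subsets(sub_pc, sub_rf, "intersection")
  if (length(sub_union$features) == 0L) {
    vi_stop("no feature exceeds either threshold; relax pc_tau and/or rf_tau",
            "viselect_empty_union_error")
  }

  message(sprintf("stage [rfe]: recursive elimination (patience %d) per base model",
                  config$patience))
  selection <- list()
  for (fam in config$models) {
    cfg <- rfe_config(base = spec_for(config, fam, seed = 0L),
                      patience = config$patience, folds = config$rfe_folds,
                      seed = mix_seed(config$seed, 2L))
    selection[[fam]] <- rfe_select(vit, y, sub_union, cfg)
  }

  message(sprintf("stage [cv]: %d-fold accuracy grid (%d subsets x %d models)",
                  config$k, 5L + 1L, length(config$models)))
  base_subsets <- list(all = vi_subset(vi_names()), pc = sub_pc, rf = sub_rf,
                       union = sub_union, intersection = sub_inter)
  results <- list()
  cv_detail <- list()
  for (fam in config$models) {
    subsets <- c(base_subsets, list(pcrf_rfe = selection[[fam]]))
    for (sname in names(subsets)) {
      sub <- subsets[[sname]]
      if (length(sub$features) == 0L) {
        results[[length(results) + 1]] <- data.frame(
          stage = config$stage, model = fam, subset = sname,
          n_features = 0L, mean_r2 = NA_real_, mean_rmse = NA_real_)
        next
      }
      cv <- kfold_cv(vit, y, subset = sub, spec = spec_for(config, fam, seed = 0L),
                     k = config$k, seed = mix_seed(config$seed, 3L))
      cv_detail[[paste(fam, sname, sep = ".")]] <- cv
      results[[length(results) + 1]] <- data.frame(
        stage = config$stage, model = fam, subset = sname,
        n_features = length(sub$features),
        mean_r2 = cv$mean_r2, mean_rmse = cv$mean_rmse)
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  message("stage [report]: assembling run report")
  run <- structure(list(
    stage = config$stage,
    results = results,
    rankings = list(pc = rk_pc, rf = rk_rf),
    subsets = c(base_subsets, list(pcrf_rfe = lapply(selection, `[[`, "features"))),
    selection = selection,
    cv = cv_detail,
    provenance = list(package = "viselect",
                      version = as.character(utils::packageVersion("viselect")),
                      config = config,
                      config_hash = config_hash(config),
                      seed = config$seed)
  ), class = "yield_run")
  if (!is.null(out_dir)) write_run_report(run, out_dir)
  run
}

#' @export
print.yield_run <- function(x, ...) {
  cat(sprintf("Pipeline run (stage: %s, seed %d)\n", x$stage,
              x$provenance$seed))
  df <- x$results
  df$mean_r2 <- round(df$mean_r2, 3)
  df$mean_rmse <- round(df$mean_rmse, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write the JSON report and CSV summary of a pipeline run
#'
#' The JSON report is the primary artifact (byte-stable across identical
#' runs); the CSV summary is a derived view of the accuracy grid. Both
#' record the package version, configuration hash and master seed.
#'
#' @param run A `yield_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report path.
#' @export
write_run_report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package = run$provenance$package,
    version = run$provenance$version,
    config_hash = run$provenance$config_hash,
    seed = run$provenance$seed,
    stage = run$stage,
    thresholds = list(pc = run$provenance$config$pc_tau,
                      rf = run$provenance$config$rf_tau),
    rankings = lapply(run$rankings, function(r)
      list(method = attr(r, "method"),
           scores = mapply(function(f, s) list(f, s), r$feature, r$score,
                           SIMPLIFY = FALSE, USE.NAMES = FALSE))),
    subsets = lapply(run$subsets[c("pc", "rf", "union", "intersection")],
                     function(s) s$features),
    pcrf_rfe = lapply(run$selection, function(s) s$features),
    results = run$results
  )
  path <- file.path(out_dir, "report.json")
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
  writeLines(json, path)
  utils::write.csv(run$results, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(path)
}
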