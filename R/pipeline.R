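#' Pipeline configuration
#'
#' Bundles the settings of every stage of the end-to-end run: the
#' synthetic-cohort simulator (or paths to existing profile/series CSV
#' files), the per-patient HMM, the association-table alpha, the tree
#' settings, the forecast levels and the train/test split seed.
#'
#' @param simulate a [cohort_config()], or `NULL` when reading from CSV.
#' @param profiles_path,series_path input CSVs when `simulate` is NULL.
#' @param hmm list of [fit_baum_welch()] settings (n_states, emission,
#'   tol, max_iter, n_restarts, seed).
#' @param assoc_alpha significance threshold of the association table.
#' @param tree list with alpha, max_depth, min_leaf.
#' @param levels nominal forecast levels of the coverage/width curve.
#' @param forecast_parameters parameters forecast by the trees.
#' @param split_seed patient-level train/test split seed.
#' @param out_dir output directory for the artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_config(),
                            profiles_path = NULL, series_path = NULL,
                            hmm = list(n_states = 2L, emission = "diagonal",
                                       tol = 1e-6, max_iter = 200L,
                                       n_restarts = 3L, seed = 1L),
                            assoc_alpha = 0.01,
                            tree = list(alpha = 0.1, max_depth = 5L,
                                        min_leaf = 20L),
                            levels = c(0.5, 0.6, 0.7, 0.8, 0.84, 0.9, 0.95),
                            forecast_parameters = c("mu", "sigma"),
                            split_seed = 1L,
                            out_dir = tempfile("icuprior_run_")) {
  structure(list(simulate = simulate, profiles_path = profiles_path,
                 series_path = series_path, hmm = hmm,
                 assoc_alpha = assoc_alpha, tree = tree, levels = levels,
                 forecast_parameters = forecast_parameters,
                 split_seed = split_seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation (or CSV ingest), rule-based
#' labelling, per-patient HMM fitting with failure alignment, parameter
#' extraction, per-patient AUC on multi-state patients, the association
#' table, one conditional inference tree per response column, and the
#' coverage/width curve. All artifacts are plain CSV/JSON under
#' `config$out_dir`, listed in `manifest.json` with MD5 content hashes;
#' the run is fully deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly: a data frame of artifact paths and
#'   hashes.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      icp_stop(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "pipeline_error")
    })
  }
  art <- character(0)
  put <- function(name, path) { art[name] <<- path; path }

  # --- simulate / ingest -------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$simulate)) {
      g <- generate_cohort(config$simulate)
      write_cohort(g$cohort, config$out_dir, truth = g$truth)
      put("ground_truth", file.path(config$out_dir, "ground_truth.csv"))
      g
    } else {
      list(cohort = read_cohort(config$profiles_path, config$series_path,
                                quiet = quiet),
           truth = NULL)
    }
  })
  cohort <- sim$cohort
  put("profiles", file.path(config$out_dir, "profiles.csv"))
  put("series", file.path(config$out_dir, "series.csv"))
  if (is.null(config$simulate)) {
    utils::write.csv(cohort$profiles, art[["profiles"]], row.names = FALSE)
    utils::write.csv(cohort$series, art[["series"]], row.names = FALSE)
  }
  say("simulate: %d patients, %d rows", nrow(cohort$profiles),
      nrow(cohort$series))

  # --- label -------------------------------------------------------------
  labels <- stage("label", label_states(cohort$series))
  utils::write.csv(labels, put("labels", file.path(config$out_dir,
                                                   "labels.csv")),
                   row.names = FALSE)
  cohort$labels <- labels

  # --- fit ---------------------------------------------------------------
  h <- config$hmm
  fitres <- stage("fit-hmm", fit_cohort(
    cohort, n_states = h$n_states, emission = h$emission, tol = h$tol,
    max_iter = h$max_iter, n_restarts = h$n_restarts, seed = h$seed))
  records <- fitres$records
  utils::write.csv(records, put("params", file.path(config$out_dir,
                                                    "params.csv")),
                   row.names = FALSE)
  post <- do.call(rbind, lapply(names(fitres$fits), function(pid) {
    p <- fitres$fits[[pid]]$posteriors
    d <- data.frame(patient_id = pid, time = seq_len(nrow(p)))
    for (s in seq_len(ncol(p))) d[[paste0("p_state", s)]] <- p[, s]
    d$decoded <- fitres$fits[[pid]]$decoded
    d
  }))
  utils::write.csv(post, put("posteriors", file.path(config$out_dir,
                                                     "posteriors.csv")),
                   row.names = FALSE)
  n_conv <- sum(vapply(fitres$fits, `[[`, logical(1), "converged"))
  say("fit-hmm: %d/%d fits converged", n_conv, length(fitres$fits))

  # --- evaluate ----------------------------------------------------------
  aucres <- stage("evaluate", evaluate_cohort_auc(fitres$fits, labels))
  utils::write.csv(aucres, put("auc", file.path(config$out_dir, "auc.csv")),
                   row.names = FALSE)
  utils::write.csv(attr(aucres, "summary")$hist,
                   put("auc_hist", file.path(config$out_dir,
                                             "auc_hist.csv")),
                   row.names = FALSE)
  say("evaluate: %d multi-state patients, median AUC %.3f",
      nrow(aucres), attr(aucres, "summary")$median)

  # --- association -------------------------------------------------------
  assoc <- stage("test-assoc",
                 build_association_table(records, cohort$profiles,
                                         alpha = config$assoc_alpha))
  utils::write.csv(as.data.frame(assoc),
                   put("assoc", file.path(config$out_dir, "assoc.csv")),
                   row.names = FALSE)
  say("test-assoc: %d/%d cells significant at %g", sum(assoc$significant),
      nrow(assoc), config$assoc_alpha)

  # --- trees + forecast --------------------------------------------------
  tr <- config$tree
  curve <- stage("forecast", coverage_width_curve(
    records, cohort$profiles, levels = config$levels,
    parameters = config$forecast_parameters, alpha = tr$alpha,
    max_depth = tr$max_depth, min_leaf = tr$min_leaf,
    train_frac = 0.7, split_seed = config$split_seed))
  utils::write.csv(curve, put("curve", file.path(config$out_dir,
                                                 "curve.csv")),
                   row.names = FALSE)
  utils::write.csv(attr(curve, "averages"),
                   put("curve_avg", file.path(config$out_dir,
                                              "curve_averages.csv")),
                   row.names = FALSE)
  stage("tree", {
    wide <- records_to_responses(records, cohort$profiles,
                                 config$forecast_parameters)
    resp_cols <- grep(":", names(wide), value = TRUE, fixed = TRUE)
    for (rc in resp_cols) {
      y <- wide[[rc]]
      keep <- !is.na(y)
      tree <- grow_tree(y[keep],
                        wide[keep, c("sex", "age", "weight", "height",
                                     "bmi"), drop = FALSE],
                        alpha = tr$alpha, max_depth = tr$max_depth,
                        min_leaf = tr$min_leaf)
      fn <- paste0("tree_", gsub(":", "_", rc, fixed = TRUE), ".json")
      tree_to_json(tree, put(paste0("tree:", rc),
                             file.path(config$out_dir, fn)))
    }
  })

  manifest <- data.frame(artifact = names(art), path = unname(art),
                         md5 = unname(tools::md5sum(unname(art))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  say("pipeline complete: %d artifacts in %s", nrow(manifest),
      config$out_dir)
  invisible(manifest)
}
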