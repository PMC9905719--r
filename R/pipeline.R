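#' End-to-end run configuration
#'
#' Bundles every setting of the assessment workflow: data schema, grey
#' relational selection, PSO-tuned SVM training and evaluation. All
#' randomness derives from `seed`: the train/test split uses `seed`, the
#' tuner `seed + 1` and the cross-validation folds `seed + 2`; the derived
#' seeds are recorded in the run manifest.
#'
#' @param input CSV path (re-runnable from a manifest) or a data frame
#'   already in canonical form.
#' @param schema A [water_schema()] (CSV input only).
#' @param grey A [grey_config()].
#' @param comparison Subjective [comparison_matrix()] or `NULL` for the
#'   neutral equal-weight matrix.
#' @param q Indicators to select.
#' @param kernel_kind `"rbf"`, `"linear"` or `"polynomial"`.
#' @param swarm_size,t_max,c1,c2,tol,patience PSO settings (see
#'   [pso_config()]).
#' @param search_bounds Hyperparameter box (see [pso_tune()]); `NULL` for
#'   the kernel's default.
#' @param folds Cross-validation folds inside tuning.
#' @param test_fraction Held-out proportion for the final evaluation.
#' @param select_on_all If `TRUE`, run indicator selection on the full
#'   dataset before splitting (the literal flowchart order) instead of on
#'   the training split only (the default, which avoids test leakage).
#' @param seed Master integer seed.
#' @param out_dir Directory for report artifacts, or `NULL` to skip
#'   writing.
#' @return A `run_config` list.
#' @export
run_config <- function(input, schema = water_schema(), grey = grey_config(),
                       comparison = NULL, q = 4L,
                       kernel_kind = c("rbf", "linear", "polynomial"),
                       swarm_size = 50L, t_max = 50L, c1 = 1.6, c2 = 2.0,
                       tol = 1e-4, patience = 10L, search_bounds = NULL,
                       folds = 5L, test_fraction = 0.2,
                       select_on_all = FALSE, seed = 1L, out_dir = NULL) {
  kernel_kind <- match.arg(kernel_kind)
  structure(list(input = input, schema = schema, grey = grey,
                 comparison = comparison, q = q, kernel_kind = kernel_kind,
                 swarm_size = swarm_size, t_max = t_max, c1 = c1, c2 = c2,
                 tol = tol, patience = patience,
                 search_bounds = search_bounds, folds = folds,
                 test_fraction = test_fraction,
                 select_on_all = isTRUE(select_on_all),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline aborted at stage '%s': %s", name, conditionMessage(e))
  })
}

#' Run the full assessment workflow
#'
#' Executes the five pipeline stages in order — clean, split, indicator
#' selection, PSO-tuned one-vs-one SVM training, evaluation — and
#' (optionally) persists the artifacts: indicator report, tuning history,
#' per-sample predictions, metrics report and a machine-readable manifest
#' holding every resolved setting and derived seed. Re-running from the
#' manifest reproduces all outputs byte-identically
#' (see [run_from_manifest()]).
#'
#' @param cfg A [run_config()].
#' @return A `wq_run` list: `selection` ([select_features()] result),
#'   `tuning` ([pso_tune()] result), `model` ([train_ovo()]), `metrics`
#'   ([evaluate_classification()]), `predictions`, `dropped` (cleaning
#'   count), `manifest` and the paths of any files written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))

  data <- stage("clean", {
    if (is.character(cfg$input)) {
      read_water_csv(cfg$input, cfg$schema)
    } else {
      df <- as.data.frame(cfg$input)
      keep <- rowSums(is.na(df[intersect(wq_indicators(), names(df))])) == 0L
      if (any(!keep)) wq_note("clean", sum(!keep), " row(s) dropped")
      structure(df[keep, , drop = FALSE], dropped = sum(!keep))
    }
  })
  if (!"label" %in% names(data)) {
    stopf("pipeline aborted at stage 'clean': input carries no labels")
  }

  split <- stage("split", stratified_split(data, cfg$test_fraction, cfg$seed))

  selection <- stage("select", {
    basis <- if (cfg$select_on_all) data else split$train
    select_features(basis[c(wq_indicators(), "label")], q = cfg$q,
                    comparison = cfg$comparison, cfg = cfg$grey)
  })
  feats <- selection$selected

  tuning <- stage("tune", {
    pso_cfg <- pso_config(bounds = cbind(c(0, 1)),  # replaced by pso_tune
                          swarm_size = cfg$swarm_size, t_max = cfg$t_max,
                          c1 = cfg$c1, c2 = cfg$c2, tol = cfg$tol,
                          patience = cfg$patience, seed = cfg$seed + 1L)
    pso_tune(split$train[feats], split$train$label, cfg$kernel_kind,
             pso_cfg = pso_cfg, search_bounds = cfg$search_bounds,
             folds = cfg$folds, cv_seed = cfg$seed + 2L)
  })

  model <- stage("train",
                 train_ovo(split$train[feats], split$train$label, tuning$kernel))

  metrics <- stage("evaluate", {
    pred <- predict(model, split$test[feats], votes = TRUE)
    votes <- attr(pred, "votes")
    attr(pred, "votes") <- NULL
    list(metrics = evaluate_classification(split$test$label, pred),
         pred = pred, votes = votes)
  })

  manifest <- list(
    package = "aquassess",
    input = if (is.character(cfg$input)) cfg$input else NA_character_,
    n_rows = nrow(data), dropped = attr(data, "dropped"),
    q = cfg$q, kernel_kind = cfg$kernel_kind,
    swarm_size = cfg$swarm_size, t_max = cfg$t_max,
    c1 = cfg$c1, c2 = cfg$c2, tol = cfg$tol, patience = cfg$patience,
    folds = cfg$folds, test_fraction = cfg$test_fraction,
    select_on_all = cfg$select_on_all,
    grey = unclass(cfg$grey),
    comparison = if (is.null(cfg$comparison)) NULL else unclass(cfg$comparison),
    search_bounds = cfg$search_bounds,
    seed = cfg$seed,
    seed_split = cfg$seed, seed_tune = cfg$seed + 1L, seed_cv = cfg$seed + 2L,
    selected = feats,
    tuned = list(C = tuning$kernel$C, r = tuning$kernel$r, d = tuning$kernel$d)
  )

  out <- structure(list(selection = selection, tuning = tuning, model = model,
                        metrics = metrics$metrics,
                        predictions = metrics$pred, votes = metrics$votes,
                        test_labels = split$test$label,
                        dropped = attr(data, "dropped"),
                        manifest = manifest, files = character(0)),
                   class = "wq_run")

  if (!is.null(cfg$out_dir)) {
    out$files <- stage("report", write_run_artifacts(out, cfg$out_dir))
  }
  out
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    features = file.path(dir, "feature_report.csv"),
    history = file.path(dir, "pso_history.csv"),
    predictions = file.path(dir, "predictions.csv"),
    metrics = file.path(dir, "metrics_report.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  rk <- run$selection$ranking
  rk[2:6] <- lapply(rk[2:6], fmt_num)
  write.csv(rk, paths["features"], row.names = FALSE, quote = FALSE)
  hist <- data.frame(t = seq_along(run$tuning$history) - 1L,
                     gbest_loss = fmt_num(run$tuning$history))
  write.csv(hist, paths["history"], row.names = FALSE, quote = FALSE)
  pred <- data.frame(sample = seq_along(run$predictions),
                     actual = run$test_labels,
                     predicted = run$predictions)
  if (!is.null(run$votes)) {
    v <- as.data.frame(run$votes)
    names(v) <- paste0("votes_", names(v))
    pred <- cbind(pred, v)
  }
  write.csv(pred, paths["predictions"], row.names = FALSE, quote = FALSE)
  mr <- metrics_report(run$metrics)
  mr[2:5] <- lapply(mr[2:5], fmt_num)
  write.csv(mr, paths["metrics"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  paths
}

#' Re-run a pipeline from its manifest
#'
#' Rebuilds the [run_config()] recorded in a manifest file and executes
#' [run_pipeline()] again; with the same input data this reproduces every
#' artifact byte-identically.
#'
#' @param path Path to a `manifest.json` written by [run_pipeline()].
#' @param data Optional data frame overriding the manifest's input path
#'   (required when the original run was fed a data frame directly).
#' @param out_dir Artifact directory for the re-run (`NULL` to skip).
#' @return A `wq_run`, as from [run_pipeline()].
#' @export
run_from_manifest <- function(path, data = NULL, out_dir = NULL) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  input <- if (!is.null(data)) data else man$input
  if (is.null(input) || (is.character(input) && is.na(input))) {
    stopf("manifest has no input path; supply `data`")
  }
  cfg <- run_config(
    input = input, q = man$q, kernel_kind = man$kernel_kind,
    grey = grey_config(man$grey$rho, man$grey$denominator_form,
                       man$grey$normalize_reference),
    comparison = if (is.null(man$comparison)) NULL else
      comparison_matrix(man$comparison),
    swarm_size = man$swarm_size, t_max = man$t_max, c1 = man$c1,
    c2 = man$c2, tol = man$tol, patience = man$patience,
    search_bounds = if (is.null(man$search_bounds)) NULL else
      as.matrix(man$search_bounds),
    folds = man$folds, test_fraction = man$test_fraction,
    select_on_all = man$select_on_all, seed = man$seed, out_dir = out_dir)
  run_pipeline(cfg)
}

#' @export
print.wq_run <- function(x, ...) {
  cat("Water-quality assessment run\n")
  cat("  selected indicators:", paste(x$selection$selected, collapse = ", "), "\n")
  k <- x$tuning$kernel
  cat(sprintf("  tuned kernel: %s (C = %.4g%s)\n", k$kind, k$C,
              if (!is.null(k$r)) sprintf(", r = %.4g", k$r)
              else if (!is.null(k$d)) sprintf(", d = %d", k$d) else ""))
  cat(sprintf("  CV loss at optimum: %.4f\n", x$tuning$loss))
  print(x$metrics)
  invisible(x)
}
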