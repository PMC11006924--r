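#' Random 80:20 train/validation split
#'
#' @param ds dataset with at least 5 rows.
#' @param seed integer seed; equal seeds give equal splits.
#' @return list with `train` and `validation`, disjoint and exhaustive; the
#'   training set holds `round(0.8 * n)` rows.
#' @export
split_80_20 <- function(ds, seed) {
  df <- as.data.frame(ds)
  n <- nrow(df)
  if (n < 5L) stop_validation("need at least 5 rows to split 80:20")
  set.seed(as.integer(seed))
  n_train <- round(0.8 * n)
  idx <- sample.int(n, n_train)
  restore <- function(sub) {
    if (inherits(ds, "rl_dataset")) rl_dataset(sub, attr(ds, "schema")) else sub
  }
  list(train = restore(df[idx, , drop = FALSE]),
       validation = restore(df[-idx, , drop = FALSE]))
}

#' Coefficient of determination
#'
#' @param pred predictions.
#' @param obs observations (not constant).
#' @return `1 - SS_res / SS_tot` (at most 1; can be negative).
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop_validation("pred and obs must have equal length")
  if (length(obs) < 2L) stop_validation("need at least 2 observations")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop_validation("constant observations: R^2 undefined")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Subset a production dataset by producer group
#'
#' `"general"` is the whole-database model and returns every row; the
#' producer-specific models are row subsets.
#'
#' @param ds a `production` [rl_dataset()].
#' @param group `"general"`, `"pseudomonas"` or `"burkholderia"`.
#' @return filtered [rl_dataset()]; empty result is an error.
#' @export
subset_by_producer <- function(ds, group) {
  stopifnot(inherits(ds, "rl_dataset"), attr(ds, "schema") == "production")
  group <- match.arg(group, .producer_groups)
  if (group == "general") return(ds)
  keep <- !is.na(ds$producer_group) & ds$producer_group == group
  if (!any(keep))
    stop_validation(sprintf("no rows for producer group '%s'", group))
  rl_dataset(as.data.frame(ds)[keep, , drop = FALSE], "production")
}

#' Repeated-split model fitting protocol
#'
#' The full model-building protocol: `n_splits` random 80:20 splits, each
#' fitted `n_runs` times with distinct evolution seeds (default 3 x 10 = 30
#' candidate models). Every candidate's frozen expression is scored on its own
#' training and validation sets (no refitting); the selected model is the one
#' with the lowest validation RMSE, ties broken by lower training RMSE and
#' then by run order. The selection is therefore stable under candidate
#' reordering.
#'
#' @param ds complete [rl_dataset()] (or data frame with a `target` column).
#' @param target target column; defaults to the schema target.
#' @param cfg a [gep_config()]; its `seed` acts as the protocol master seed.
#' @param n_splits,n_runs protocol repetitions.
#' @param descriptors descriptor set; defaults to the schema's model
#'   descriptors (set `include_MV_C = TRUE` to add `MV_C` for production).
#' @param include_MV_C include the carbon-source molecular volume descriptor.
#' @return an `rl_ensemble`: `candidates` (per-candidate metrics data frame),
#'   `models` (chromosomes), `selected` (an `rl_model` with applicability
#'   domain and pooled predicted-vs-observed pairs in its metrics).
#' @export
fit_protocol <- function(ds, target = NULL, cfg = NULL, n_splits = 3L,
                         n_runs = 10L, descriptors = NULL,
                         include_MV_C = FALSE) {
  df <- as.data.frame(ds)
  schema <- if (inherits(ds, "rl_dataset")) attr(ds, "schema") else "custom"
  if (is.null(descriptors)) {
    if (schema == "custom")
      stop_validation("descriptors must be given for plain data frames")
    sc <- rl_schema(schema)
    descriptors <- sc$model_descriptors
    if (schema == "production" && include_MV_C)
      descriptors <- c(descriptors, "MV_C")
    if (is.null(target)) target <- sc$target
  }
  if (is.null(target)) stop_validation("target must be given")
  if (anyNA(df[, c(descriptors, target)]))
    stop_validation("dataset must be complete; impute first")
  if (is.null(cfg)) cfg <- gep_config(terminals = descriptors)
  if (!all(descriptors %in% cfg$terminals))
    stop_validation("cfg terminals must cover the descriptor set")

  master_seed <- cfg$seed
  cand <- list()
  k <- 0L
  for (s in seq_len(n_splits)) {
    split <- split_80_20(df, seed = master_seed + s)
    for (r in seq_len(n_runs)) {
      k <- k + 1L
      run_cfg <- cfg
      run_cfg$seed <- (master_seed %% 100000L) * 1000L + s * 100L + r
      res <- tryCatch(evolve(split$train, target, run_cfg),
                      error = function(e) e)
      if (inherits(res, "error"))
        rl_abort(sprintf("fit protocol failed at split %d, run %d: %s",
                         s, r, conditionMessage(res)), "rl_validation_error")
      tree <- res$tree
      pred_tr <- evaluate(tree, split$train)
      pred_va <- evaluate(tree, split$validation)
      cand[[k]] <- list(
        split = s, run = r, seed = run_cfg$seed, chromosome = res$chromosome,
        train_idx = NULL,
        rmse_train = res$rmse,
        rmse_validation = sqrt(mean((pred_va - split$validation[[target]])^2)),
        r2_train = r_squared(pred_tr, split$train[[target]]),
        r2_validation = r_squared(pred_va, split$validation[[target]]),
        train = split$train, validation = split$validation)
    }
  }
  metrics <- data.frame(
    candidate = seq_along(cand),
    split = vapply(cand, `[[`, 0L, "split"),
    run = vapply(cand, `[[`, 0L, "run"),
    seed = vapply(cand, function(x) as.numeric(x$seed), 0),
    rmse_train = vapply(cand, `[[`, 0, "rmse_train"),
    rmse_validation = vapply(cand, `[[`, 0, "rmse_validation"),
    r2_train = vapply(cand, `[[`, 0, "r2_train"),
    r2_validation = vapply(cand, `[[`, 0, "r2_validation")
  )
  # lowest validation RMSE; ties -> lower train RMSE, then run index
  ord <- order(metrics$rmse_validation, metrics$rmse_train, metrics$candidate)
  best <- cand[[ord[1L]]]

  best_tree <- express(best$chromosome, cfg)
  pred_tr <- evaluate(best_tree, best$train)
  pred_va <- evaluate(best_tree, best$validation)
  pooled <- data.frame(
    observed = c(best$train[[target]], best$validation[[target]]),
    predicted = c(pred_tr, pred_va),
    set = c(rep("train", nrow(best$train)),
            rep("validation", nrow(best$validation))))
  domain <- fit_domain(best$train, descriptors = descriptors,
                       model_id = sprintf("%s/%s", schema, target))
  selected <- fitted_model(
    best$chromosome, cfg, schema = schema, descriptors = descriptors,
    target = target, domain = domain,
    metrics = list(
      split = best$split, run = best$run, seed = best$seed,
      rmse_train = best$rmse_train,
      rmse_validation = best$rmse_validation,
      r2_train = best$r2_train, r2_validation = best$r2_validation,
      r2_pooled = r_squared(pooled$predicted, pooled$observed),
      pooled = pooled))
  structure(list(candidates = metrics,
                 models = lapply(cand, `[[`, "chromosome"),
                 selected = selected, cfg = cfg,
                 n_splits = n_splits, n_runs = n_runs),
            class = "rl_ensemble")
}

#' @export
print.rl_ensemble <- function(x, ...) {
  cat(sprintf("<rl_ensemble %d candidates (%d splits x %d runs)>\n",
              nrow(x$candidates), x$n_splits, x$n_runs))
  cat(sprintf("  selected: split %d run %d, validation R^2 = %.3f\n",
              x$selected$metrics$split, x$selected$metrics$run,
              x$selected$metrics$r2_validation))
  invisible(x)
}
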