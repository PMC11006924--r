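#' Imputation settings
#'
#' Chained-equations imputation is only applied when the overall descriptor
#' missingness is at or below `max_missing_fraction` (default 10%, the rule
#' under which both databases qualify). Per-column models are ordinary linear
#' regressions on all other descriptors; targets are never imputed and never
#' used as predictors.
#'
#' @param max_missing_fraction refusal gate, in (0, 1].
#' @param n_cycles number of chained cycles (>= 1).
#' @param seed stored for provenance; the per-column least-squares predictions
#'   are deterministic, so equal seeds trivially give equal outputs.
#' @param model per-column model family; only `"linear_regression"`.
#' @return an `imputation_spec` list.
#' @export
imputation_spec <- function(max_missing_fraction = 0.10, n_cycles = 10L,
                            seed = 1L, model = "linear_regression") {
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1,
            n_cycles >= 1L)
  model <- match.arg(model)
  structure(list(max_missing_fraction = max_missing_fraction,
                 n_cycles = as.integer(n_cycles), seed = as.integer(seed),
                 model = model),
            class = "imputation_spec")
}

#' Impute missing descriptor cells by chained equations
#'
#' Multivariate imputation by chained equations with per-column linear
#' regressions: missing cells are initialized at column means, then columns
#' are revisited in order of increasing missingness; at each visit the column
#' is regressed on all other descriptors over its originally observed rows and
#' its missing cells are replaced by the fitted predictions. Observed cells
#' are never altered, and an already-complete dataset is returned unchanged.
#'
#' @param ds an [rl_dataset()] whose descriptor missingness is at or below the
#'   spec's gate (otherwise a refusal error citing the threshold).
#' @param spec an [imputation_spec()].
#' @return a complete [rl_dataset()] (no missing descriptor cells).
#' @export
mice_impute <- function(ds, spec = imputation_spec()) {
  stopifnot(inherits(ds, "rl_dataset"), inherits(spec, "imputation_spec"))
  sc <- rl_schema(attr(ds, "schema"))
  frac <- missing_fraction(ds)
  if (frac > spec$max_missing_fraction)
    stop_validation(sprintf(
      "missing descriptor fraction %.4f exceeds the %.0f%% imputation gate",
      frac, 100 * spec$max_missing_fraction))
  if (frac == 0) return(ds)

  desc <- sc$descriptors
  X <- as.data.frame(ds)[, desc, drop = FALSE]
  obs <- !is.na(X)
  n_obs <- colSums(obs)
  if (any(n_obs == 0L))
    stop_validation(sprintf("column(s) with no observed values: %s",
                            paste(desc[n_obs == 0L], collapse = ", ")))
  if (sum(n_obs > 0L) < 2L)
    stop_validation("need at least 2 informative descriptor columns")

  # mean initialization, then chained least-squares prediction
  for (j in seq_along(desc))
    X[[j]][!obs[, j]] <- mean(X[[j]][obs[, j]])
  visit <- order(colSums(!obs))
  visit <- visit[colSums(!obs)[visit] > 0L]
  for (cycle in seq_len(spec$n_cycles)) {
    for (j in visit) {
      others <- setdiff(seq_along(desc), j)
      dat <- X[, others, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, as.matrix(dat[obs[, j], , drop = FALSE])),
                           X[[j]][obs[, j]])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0  # collinear predictors drop out
      pred <- drop(cbind(1, as.matrix(dat[!obs[, j], , drop = FALSE])) %*% beta)
      X[[j]][!obs[, j]] <- pred
    }
  }
  # imputations stay within the observed range of their column so the
  # completed table cannot violate record invariants (e.g. negative
  # concentrations, pH outside (0, 14))
  for (j in seq_along(desc)) {
    observed <- as.data.frame(ds)[[desc[j]]]
    rng <- range(observed, na.rm = TRUE)
    filled <- pmin(pmax(X[[j]][!obs[, j]], rng[1]), rng[2])
    # ordinal columns (all observed values whole, e.g. the impurity scale)
    # round to the nearest observed level
    if (all(observed[!is.na(observed)] %% 1 == 0)) filled <- round(filled)
    X[[j]][!obs[, j]] <- filled
  }
  out <- as.data.frame(ds)
  out[, desc] <- X
  rl_dataset(out, sc$name)
}
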