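#' Positive/negative contribution of a descriptor
#'
#' At every data point the partial derivative of the model prediction with
#' respect to the descriptor is estimated by a central finite difference with
#' step `1e-4 *` the descriptor's standard deviation (scale-aware, and robust
#' for the piecewise-smooth protected primitives). The returned percentages
#' count points with positive, negative and (numerically) zero derivative;
#' they always sum to 100.
#'
#' @param model an `rl_model`.
#' @param ds complete dataset covering the model's descriptors.
#' @param descriptor descriptor name (must be in the model's schema).
#' @return named vector `c(positive_pct=, negative_pct=, zero_pct=)`.
#' @export
contribution_signs <- function(model, ds, descriptor) {
  stopifnot(inherits(model, "rl_model"))
  df <- as.data.frame(ds)
  if (!descriptor %in% model$descriptors)
    stop_validation(sprintf("'%s' is not a model descriptor", descriptor))
  if (anyNA(df[, model$descriptors, drop = FALSE]))
    stop_validation("dataset must be complete")
  x <- df[[descriptor]]
  h <- 1e-4 * stats::sd(x)
  if (!is.finite(h) || h == 0) h <- 1e-4
  hi <- df; hi[[descriptor]] <- x + h
  lo <- df; lo[[descriptor]] <- x - h
  d <- (predict(model, hi, check_domain = FALSE) -
          predict(model, lo, check_domain = FALSE)) / (2 * h)
  n <- length(d)
  c(positive_pct = 100 * sum(d > 0) / n,
    negative_pct = 100 * sum(d < 0) / n,
    zero_pct = 100 * sum(d == 0) / n)
}

#' Permutation importance of model descriptors
#'
#' Importance of a descriptor is the mean relative increase in RMSE when that
#' descriptor's column is randomly permuted (`n_perm` permutations), clipped
#' to \[0, 1\]. Descriptors absent from the expressed model score exactly 0.
#'
#' @param model an `rl_model`.
#' @param ds complete dataset including the target column.
#' @param n_perm permutations per descriptor.
#' @param seed seed for the permutations.
#' @return named numeric vector of scores in \[0, 1\], one per model
#'   descriptor.
#' @export
importance <- function(model, ds, n_perm = 30L, seed = 1L) {
  stopifnot(inherits(model, "rl_model"))
  df <- as.data.frame(ds)
  if (!model$target %in% names(df))
    stop_validation(sprintf("target '%s' not in data", model$target))
  if (anyNA(df[, c(model$descriptors, model$target), drop = FALSE]))
    stop_validation("dataset must be complete")
  obs <- df[[model$target]]
  base <- sqrt(mean((predict(model, df, check_domain = FALSE) - obs)^2))
  if (base == 0) base <- .Machine$double.eps
  set.seed(as.integer(seed))
  used <- model$tree$terminals
  scores <- vapply(model$descriptors, function(d) {
    if (!d %in% used) return(0)
    incr <- vapply(seq_len(n_perm), function(p) {
      perm <- df
      perm[[d]] <- sample(perm[[d]])
      r <- sqrt(mean((predict(model, perm, check_domain = FALSE) - obs)^2))
      (r - base) / base
    }, 0)
    min(max(mean(incr), 0), 1)
  }, 0)
  scores
}

#' Full sensitivity report for a fitted model
#'
#' Combines [importance()] and [contribution_signs()] for every model
#' descriptor, with ranks (1 = most important; ties broken by descriptor
#' order).
#'
#' @inheritParams importance
#' @return a `SensitivityReport` data frame: `descriptor`, `importance`,
#'   `rank`, `positive_pct`, `negative_pct`, `zero_pct`.
#' @export
sensitivity_report <- function(model, ds, n_perm = 30L, seed = 1L) {
  imp <- importance(model, ds, n_perm = n_perm, seed = seed)
  signs <- t(vapply(model$descriptors,
                    function(d) contribution_signs(model, ds, d),
                    c(positive_pct = 0, negative_pct = 0, zero_pct = 0)))
  out <- data.frame(descriptor = model$descriptors,
                    importance = unname(imp),
                    rank = rank(-imp, ties.method = "first"),
                    signs, row.names = NULL)
  out[order(out$rank), ]
}
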