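#' Applicability domain of a model
#'
#' Per-descriptor (min, max) training ranges. Predictions for descriptor
#' values outside these ranges are extrapolations and are flagged.
#'
#' @param bounds data frame with columns `descriptor`, `min`, `max`.
#' @param model_id optional model identifier.
#' @return an `rl_domain` data frame.
#' @export
applicability_domain <- function(bounds, model_id = NULL) {
  need <- c("descriptor", "min", "max")
  miss <- setdiff(need, names(bounds))
  if (length(miss) > 0L)
    stop_validation(sprintf("domain bounds need column(s): %s",
                            paste(miss, collapse = ", ")))
  if (any(bounds$min > bounds$max))
    stop_validation("domain: min > max")
  structure(as.data.frame(bounds[, need]),
            class = c("rl_domain", "data.frame"), model_id = model_id)
}

#' Fit an applicability domain from training data
#'
#' @param ds complete training data (data frame / [rl_dataset()]).
#' @param descriptors descriptor columns to bound; defaults to the schema's
#'   model descriptor set for an [rl_dataset()].
#' @param model_id optional identifier stored with the domain.
#' @return an [applicability_domain()] with componentwise min/max.
#' @export
fit_domain <- function(ds, descriptors = NULL, model_id = NULL) {
  df <- as.data.frame(ds)
  if (is.null(descriptors)) {
    if (!inherits(ds, "rl_dataset"))
      stop_validation("descriptors must be given for plain data frames")
    descriptors <- rl_schema(attr(ds, "schema"))$model_descriptors
  }
  if (nrow(df) == 0L) stop_validation("empty dataset")
  miss <- setdiff(descriptors, names(df))
  if (length(miss) > 0L)
    stop_validation(sprintf("missing descriptor(s): %s",
                            paste(miss, collapse = ", ")))
  sub <- df[, descriptors, drop = FALSE]
  if (anyNA(sub)) stop_validation("dataset must be complete; impute first")
  applicability_domain(data.frame(
    descriptor = descriptors,
    min = vapply(sub, min, 0),
    max = vapply(sub, max, 0),
    row.names = NULL
  ), model_id = model_id)
}

#' Check a descriptor point against an applicability domain
#'
#' Bounds are inclusive: training extremes are in-domain.
#'
#' @param x named list / one-row data frame covering the domain's descriptors.
#' @param ad an [applicability_domain()].
#' @return list with `in_domain` (logical) and `violations` (data frame with
#'   `descriptor`, `value`, `bound`, `limit`).
#' @export
in_domain <- function(x, ad) {
  stopifnot(inherits(ad, "rl_domain"))
  x <- as.list(as.data.frame(x))
  miss <- setdiff(ad$descriptor, names(x))
  if (length(miss) > 0L)
    stop_validation(sprintf("missing descriptor(s): %s",
                            paste(miss, collapse = ", ")))
  v <- vapply(ad$descriptor, function(d) as.numeric(x[[d]][1L]), 0)
  low <- v < ad$min
  high <- v > ad$max
  violations <- rbind(
    data.frame(descriptor = ad$descriptor[low], value = v[low],
               bound = rep("lower", sum(low)), limit = ad$min[low]),
    data.frame(descriptor = ad$descriptor[high], value = v[high],
               bound = rep("upper", sum(high)), limit = ad$max[high])
  )
  rownames(violations) <- NULL
  list(in_domain = nrow(violations) == 0L, violations = violations)
}

#' Normalized parallel-coordinates table
#'
#' Rescales each descriptor column of `ds` to \[0, 1\] using the domain's
#' bounds (the visualization used to present applicability domains). A
#' degenerate axis (min == max) maps to 0.5.
#'
#' @param ds data rows to plot.
#' @param ad an [applicability_domain()].
#' @return data frame with columns `row`, `descriptor`, `position`.
#' @export
parallel_coordinates_data <- function(ds, ad) {
  stopifnot(inherits(ad, "rl_domain"))
  df <- as.data.frame(ds)
  miss <- setdiff(ad$descriptor, names(df))
  if (length(miss) > 0L)
    stop_validation(sprintf("missing descriptor(s): %s",
                            paste(miss, collapse = ", ")))
  out <- do.call(rbind, lapply(seq_len(nrow(ad)), function(i) {
    d <- ad$descriptor[i]
    rng <- ad$max[i] - ad$min[i]
    pos <- if (rng == 0) rep(0.5, nrow(df)) else (df[[d]] - ad$min[i]) / rng
    data.frame(row = seq_len(nrow(df)), descriptor = d, position = pos)
  }))
  rownames(out) <- NULL
  out[order(out$row, match(out$descriptor, ad$descriptor)), ]
}
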