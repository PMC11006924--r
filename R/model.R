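#' Fitted QSPR model
#'
#' Bundles a selected GEP expression with everything needed to use it as a
#' calculator: the Karva chromosome and constants, the engine configuration,
#' the descriptor schema it expects, its applicability domain (per-descriptor
#' training ranges), and training metadata.
#'
#' @param chromosome a `gep_chromosome`.
#' @param cfg the [gep_config()] it was evolved under.
#' @param schema `"production"` or `"msr"` (or `"custom"`).
#' @param descriptors descriptor names the model consumes.
#' @param target target column name.
#' @param domain an [fit_domain()] result, or `NULL`.
#' @param metrics named list of training metadata (RMSEs, R-squared values,
#'   split/run indices, pooled predicted-vs-observed pairs, ...).
#' @return an `rl_model` object.
#' @export
fitted_model <- function(chromosome, cfg, schema, descriptors, target,
                         domain = NULL, metrics = list()) {
  structure(list(chromosome = chromosome, cfg = cfg,
                 tree = express(chromosome, cfg), schema = schema,
                 descriptors = descriptors, target = target,
                 domain = domain, metrics = metrics),
            class = "rl_model")
}

#' @export
print.rl_model <- function(x, ...) {
  cat(sprintf("<rl_model schema=%s target=%s descriptors=%s>\n",
              x$schema, x$target, paste(x$descriptors, collapse = ",")))
  if (!is.null(x$metrics$r2_validation))
    cat(sprintf("  validation R^2 = %.3f\n", x$metrics$r2_validation))
  invisible(x)
}

#' Predict from a fitted model
#'
#' Evaluates the stored expression on new descriptor rows. When the model
#' carries an applicability domain and `check_domain = TRUE`, out-of-domain
#' rows trigger a warning naming the violated bounds (the prediction is still
#' returned: forward calculators warn, they do not refuse).
#'
#' @param object an `rl_model`.
#' @param newdata data frame (or named list, one row) of descriptor values.
#' @param check_domain warn on applicability-domain violations.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rl_model <- function(object, newdata, check_domain = TRUE, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$descriptors, names(newdata))
  if (length(miss) > 0L)
    stop_validation(sprintf("missing descriptor(s): %s",
                            paste(miss, collapse = ", ")))
  if (check_domain && !is.null(object$domain)) {
    for (i in seq_len(nrow(newdata))) {
      chk <- in_domain(newdata[i, object$descriptors, drop = FALSE],
                       object$domain)
      if (!chk$in_domain)
        warning(sprintf(
          "row %d outside applicability domain: %s", i,
          paste(sprintf("%s=%.4g beyond %s bound %.4g",
                        chk$violations$descriptor, chk$violations$value,
                        chk$violations$bound, chk$violations$limit),
                collapse = "; ")), call. = FALSE)
    }
  }
  evaluate(object$tree, newdata)
}

#' Serialize a fitted model to JSON
#'
#' The JSON document is the package's "calculator" file format: Karva gene
#' strings, constant arrays, the engine configuration, descriptor names,
#' applicability domain and metrics, plus an md5 hash of the configuration for
#' provenance.
#'
#' @param model an `rl_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rl_model"))
  cfg <- model$cfg
  cfg_doc <- cfg[c("terminals", "functions", "genes", "head", "tail", "n_rnc",
                   "rnc_range", "linking", "pop_size", "generations", "rates",
                   "seed")]
  doc <- list(
    format = "rldesign-model",
    version = 1L,
    schema = model$schema,
    target = model$target,
    descriptors = model$descriptors,
    karva = lapply(model$chromosome$genes, paste, collapse = " "),
    rncs = model$chromosome$rncs,
    config = cfg_doc,
    config_hash = config_hash(cfg_doc),
    domain = if (is.null(model$domain)) NULL else
      list(model_id = attr(model$domain, "model_id"),
           bounds = as.data.frame(model$domain)),
    metrics = model$metrics
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_model()].
#' @return an `rl_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_validation(sprintf("malformed model file: %s",
                                            conditionMessage(e))))
  if (!identical(doc$format, "rldesign-model"))
    stop_validation("malformed model file: not an rldesign model document")
  cd <- doc$config
  cfg <- gep_config(terminals = cd$terminals, functions = cd$functions,
                    genes = cd$genes, head = cd$head, n_rnc = cd$n_rnc,
                    rnc_range = cd$rnc_range, linking = cd$linking,
                    pop_size = cd$pop_size, generations = cd$generations,
                    rates = as.list(cd$rates), seed = cd$seed)
  genes <- lapply(doc$karva, function(s) strsplit(s, " ", fixed = TRUE)[[1L]])
  rncs <- doc$rncs
  if (is.matrix(rncs)) rncs <- lapply(seq_len(nrow(rncs)), function(i) rncs[i, ])
  if (cfg$n_rnc == 0L) rncs <- replicate(cfg$genes, numeric(), simplify = FALSE)
  chrom <- structure(list(genes = genes, rncs = rncs),
                     class = "gep_chromosome")
  if (!chromosome_valid(chrom, cfg))
    stop_validation("malformed model file: chromosome violates head/tail discipline")
  domain <- NULL
  if (!is.null(doc$domain) && length(doc$domain) > 0L) {
    domain <- applicability_domain(doc$domain$bounds,
                                   model_id = doc$domain$model_id)
  }
  fitted_model(chrom, cfg, schema = doc$schema, descriptors = doc$descriptors,
               target = doc$target, domain = domain,
               metrics = as.list(doc$metrics))
}

config_hash <- function(cfg_doc) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg_doc, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
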