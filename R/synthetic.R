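# Synthetic emulation of the two databases. Descriptor ranges are anchored to
# values printed for real feedstocks/solubilizates (e.g. logP_C from -2.64 for
# glucose to 10.84 for brassica oil; solubilizate logP 2.7-10.8 and MV 94-985
# cubic angstroms; MSR spanning 1e-5 to about 7). Missingness is MCAR with an
# exact cell count so small tables still hit the nominal rate.

.truths <- list(
  production_linear = list(
    schema = "production",
    expr = quote(4.6 + 0.35 * logP_C - 0.004 * shaking),
    terminals = c("logP_C", "shaking"),
    signs = c(logP_C = "+", shaking = "-"),
    description = "linear: hydrophobic feedstocks give more hydrophobic RL, aeration pushes toward diRL"
  ),
  production_saturating = list(
    schema = "production",
    expr = quote(4.2 + 2.0 * (1 - exp(-conc_C / 30000)) +
                   0.2 * logP_C - 0.003 * shaking),
    terminals = c("conc_C", "logP_C", "shaking"),
    signs = c(conc_C = "+", logP_C = "+", shaking = "-"),
    description = "monotone-saturating in carbon concentration"
  ),
  # Solubilization effect sizes are anchored to the published relative
  # descriptor importances (0.384 : 0.312 : 0.252 : 0.013 for molecular
  # volume : solubilizate logP : impurity : CMC), scaled so the noiseless
  # target roughly fills the literature logMSR span.
  msr_linear = list(
    schema = "msr",
    expr = quote(-1.8 - 0.0032 * (MV_SOL - 540) + 0.29 * (logP_SOL - 6.75) +
                   0.32 * (impurity - 2.5) - 0.048 * (log10(CMC) - 1.7)),
    terminals = c("MV_SOL", "logP_SOL", "impurity", "CMC"),
    signs = c(MV_SOL = "-", logP_SOL = "+", impurity = "+", CMC = "-"),
    description = "linear solubilization efficiency"
  ),
  msr_interaction = list(
    schema = "msr",
    expr = quote(-1.8 - 0.0032 * (MV_SOL - 540) + 0.29 * (logP_SOL - 6.75) +
                   0.32 * (impurity - 2.5) - 0.048 * (log10(CMC) - 1.7) +
                   0.012 * (logP_SOL - 6.75) * (impurity - 2.5)),
    terminals = c("MV_SOL", "logP_SOL", "impurity", "CMC"),
    signs = c(MV_SOL = "-", logP_SOL = "+", impurity = "+", CMC = "-"),
    description = paste("interaction form: bulky solubilizates always hurt,",
                        "hydrophobicity and impurity always help (swelling)")
  )
)

#' Catalog of synthetic generating functions
#'
#' Each entry carries the schema it targets, a quoted expression over
#' descriptor names, the descriptors it uses, and its qualitative sign
#' structure (the solubilization truths are decreasing in solubilizate
#' molecular volume and increasing in solubilizate hydrophobicity and in
#' biosurfactant impurity).
#'
#' @return named list of truth definitions.
#' @export
truth_registry <- function() .truths

get_truth <- function(truth) {
  if (!truth %in% names(.truths))
    stop_validation(sprintf("unknown truth id '%s' (known: %s)", truth,
                            paste(names(.truths), collapse = ", ")))
  .truths[[truth]]
}

#' Evaluate a registered truth on descriptor rows
#'
#' @param truth truth id from [truth_registry()].
#' @param df descriptor data frame.
#' @return numeric vector of noiseless target values.
#' @export
truth_predict <- function(truth, df) {
  tr <- get_truth(truth)
  out <- eval(tr$expr, envir = as.data.frame(df), enclos = baseenv())
  rep_len(as.numeric(out), nrow(as.data.frame(df)))
}

#' Wrap a registered truth as a fitted model
#'
#' Useful for exercising sensitivity and calculator machinery against a known
#' ground truth (e.g. contribution signs of the generating function itself).
#'
#' @param truth truth id.
#' @param domain optional [applicability_domain()].
#' @return an `rl_model` whose expression is the truth.
#' @export
truth_as_model <- function(truth, domain = NULL) {
  tr <- get_truth(truth)
  sc <- rl_schema(tr$schema)
  structure(list(
    chromosome = NULL,
    cfg = NULL,
    tree = structure(list(expr = tr$expr, terminals = tr$terminals),
                     class = "gep_tree"),
    schema = tr$schema, descriptors = sc$model_descriptors,
    target = sc$target, domain = domain,
    metrics = list(truth = truth)
  ), class = "rl_model")
}

# exactly round(rate * cells) missing cells, MCAR over the descriptor block
punch_missing <- function(df, fields, rate, n_cells_override = NULL) {
  n <- nrow(df)
  total <- n * length(fields)
  n_miss <- if (is.null(n_cells_override)) round(rate * total)
            else n_cells_override
  if (n_miss == 0L) return(df)
  cells <- sample.int(total, n_miss)
  for (cell in cells) {
    col <- fields[(cell - 1L) %/% n + 1L]
    row <- (cell - 1L) %% n + 1L
    df[row, col] <- NA_real_
  }
  df
}

#' Generate a synthetic biosynthesis database
#'
#' Emulates the structure of the curated cultivation database: descriptors
#' drawn from literature-plausible ranges (feedstock logP in \[-2.64, 10.84\],
#' pH 5-8, temperature 25-37 C, shaking 0-250 rpm, time 24-240 h,
#' concentrations log-uniform), a registered generating function plus Gaussian
#' noise on the target, producer groups assigned by `group_mix`, and MCAR
#' missingness punched into exactly `round(missing_rate * n * 9)` descriptor
#' cells (default rate 9.6%).
#'
#' @param n rows (>= 10).
#' @param seed integer seed; equal seeds give identical tables.
#' @param truth truth id from [truth_registry()] (production schema).
#' @param noise_sd Gaussian noise on `logP_RL`; the default 1.0 reproduces the
#'   moderate explained variance typical of heterogeneous literature data.
#' @param missing_rate MCAR descriptor-cell missingness.
#' @param group_mix named probabilities over producer groups.
#' @return list with `data` (the punched [rl_dataset()]), `complete` (before
#'   missingness), `truth` (registry entry plus `noise_sd`).
#' @export
gen_production_dataset <- function(n = 213L, seed = 1L,
                                   truth = "production_linear",
                                   noise_sd = 1.0, missing_rate = 0.096,
                                   group_mix = c(pseudomonas = 0.55,
                                                 burkholderia = 0.25,
                                                 general = 0.20)) {
  if (n < 10L) stop_validation("need n >= 10")
  tr <- get_truth(truth)
  if (tr$schema != "production")
    stop_validation(sprintf("truth '%s' is not a production truth", truth))
  set.seed(as.integer(seed))
  group <- sample(names(group_mix), n, replace = TRUE, prob = group_mix)
  conc_C <- 10^stats::runif(n, log10(500), log10(1e5))
  conc_N <- 10^stats::runif(n, log10(50), log10(1e4))
  logP_C <- stats::runif(n, -2.64, 10.84)
  # molecular volume tracks hydrophobicity across feedstocks (sugars are
  # small and hydrophilic, plant oils large and hydrophobic); the residual
  # scatter keeps the pair informative for chained-equations imputation
  MV_C <- pmax(120 + 75 * (logP_C + 2.64) + stats::rnorm(n, 0, 40), 90)
  df <- data.frame(
    producer_taxon = paste0(group, "_strain_", seq_len(n)),
    producer_group = group,
    conc_C = conc_C,
    logP_C = logP_C,
    MV_C = MV_C,
    conc_N = conc_N,
    CN_ratio = conc_C / conc_N,
    pH = stats::runif(n, 5, 8),
    temperature = stats::runif(n, 25, 37),
    shaking = stats::runif(n, 0, 250),
    time = stats::runif(n, 24, 240),
    stringsAsFactors = FALSE
  )
  df$logP_RL <- truth_predict(truth, df) + stats::rnorm(n, 0, noise_sd)
  complete <- rl_dataset(df, "production")
  sc <- rl_schema("production")
  punched <- punch_missing(df, sc$descriptors, missing_rate)
  list(data = rl_dataset(punched, "production"), complete = complete,
       truth = c(tr, list(id = truth, noise_sd = noise_sd)))
}

#' Generate a synthetic solubilization database
#'
#' Emulates the curated solubilization database: solubilizate logP in
#' \[2.7, 10.8\], molecular volume in \[94, 985\] cubic angstroms, impurity an
#' ordinal 0-5, CMC log-uniform on \[5, 500\] mg/L; `logMSR` is the registered
#' truth plus Gaussian noise, clamped to the literature span \[-5, 0.9\].
#' Missingness defaults to 1.99% of descriptor cells.
#'
#' @param n rows (>= 10).
#' @param seed integer seed.
#' @param truth truth id (msr schema).
#' @param noise_sd Gaussian noise on `logMSR`; the default 0.6 mirrors the
#'   residual scatter of a model explaining about 80% of variance.
#' @param missing_rate MCAR descriptor-cell missingness.
#' @return list with `data`, `complete`, `truth` as in
#'   [gen_production_dataset()].
#' @export
gen_msr_dataset <- function(n = 74L, seed = 1L, truth = "msr_interaction",
                            noise_sd = 0.6, missing_rate = 0.0199) {
  if (n < 10L) stop_validation("need n >= 10")
  tr <- get_truth(truth)
  if (tr$schema != "msr")
    stop_validation(sprintf("truth '%s' is not an msr truth", truth))
  set.seed(as.integer(seed))
  df <- data.frame(
    impurity = sample(0:5, n, replace = TRUE),
    logP_RL = stats::runif(n, 4, 8.5),
    CMC = 10^stats::runif(n, log10(5), log10(500)),
    logP_SOL = stats::runif(n, 2.7, 10.8),
    MV_SOL = stats::runif(n, 94, 985),
    pH = stats::runif(n, 4, 9),
    temperature = stats::runif(n, 20, 40)
  )
  logmsr <- truth_predict(truth, df) + stats::rnorm(n, 0, noise_sd)
  df$logMSR <- pmin(pmax(logmsr, -5), 0.9)
  df$MSR <- 10^df$logMSR
  complete <- rl_dataset(df, "msr")
  sc <- rl_schema("msr")
  punched <- punch_missing(df, sc$descriptors, missing_rate)
  list(data = rl_dataset(punched, "msr"), complete = complete,
       truth = c(tr, list(id = truth, noise_sd = noise_sd)))
}
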