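#' Built-in congener descriptor table
#'
#' Reference table of rhamnolipid congeners with hydrophobicity (logP) and
#' molecular volume (MV, cubic angstroms) descriptors. It always contains the
#' two workhorse congeners used when literature reports only class shares:
#' Rha-C10-C10 (mono-rhamnolipid) and Rha-Rha-C10-C10 (di-rhamnolipid).
#'
#' The numeric logP/MV values shipped here are SYNTHETIC stand-ins: per-congener
#' descriptors are normally computed with a cheminformatics tool and are inputs
#' to this package, not outputs. The stand-ins only preserve the qualitative
#' structure (the mono congener is smaller and more hydrophobic than the di).
#' Supply your own table via [read_congener_table()] for real work.
#'
#' @return data frame with columns `name`, `class` (`"mono"`/`"di"`), `logP`,
#'   `MV`.
#' @export
congener_table <- function() {
  validate_congener_table(data.frame(
    name = c("Rha-C10-C10", "Rha-Rha-C10-C10"),
    class = c("mono", "di"),
    logP = c(5.2, 4.4),      # synthetic stand-in values
    MV = c(490.0, 630.0),    # synthetic stand-in values
    stringsAsFactors = FALSE
  ))
}

validate_congener_table <- function(tab) {
  need <- c("name", "class", "logP", "MV")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop_validation(sprintf("congener table: missing column(s): %s",
                            paste(miss, collapse = ", ")))
  if (anyDuplicated(tab$name))
    stop_validation("congener table: names must be unique")
  if (!all(tab$class %in% c("mono", "di")))
    stop_validation("congener table: class must be 'mono' or 'di'")
  for (ref in c("Rha-C10-C10", "Rha-Rha-C10-C10"))
    if (!ref %in% tab$name)
      stop_validation(sprintf("congener table must contain '%s'", ref))
  tab
}

#' Read a congener table from CSV
#'
#' @param path CSV with columns `name,class,logP,MV`.
#' @return validated congener table data frame.
#' @export
read_congener_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$logP <- as.numeric(tab$logP)
  tab$MV <- as.numeric(tab$MV)
  validate_congener_table(tab)
}

#' Mass-fraction weighted descriptors of a mixture
#'
#' Mixed carbon sources and multi-congener biosurfactants are described by the
#' fraction-weighted arithmetic mean of the components' logP and MV.
#'
#' @param components data frame (or list coercible to one) with columns
#'   `fraction`, `logP`, `MV`. Fractions must be positive and sum to 1
#'   (tolerance 1e-6).
#' @return named numeric vector `c(logP=, MV=)`.
#' @export
weighted_descriptor <- function(components) {
  comp <- as.data.frame(components)
  if (nrow(comp) == 0L) stop_validation("empty component list")
  need <- c("fraction", "logP", "MV")
  miss <- setdiff(need, names(comp))
  if (length(miss) > 0L)
    stop_validation(sprintf("components need column(s): %s",
                            paste(miss, collapse = ", ")))
  if (any(comp$fraction <= 0))
    stop_validation("component fractions must be > 0")
  if (abs(sum(comp$fraction) - 1) > 1e-6)
    stop_validation(sprintf("component fractions sum to %.8f, not 1",
                            sum(comp$fraction)))
  c(logP = sum(comp$fraction * comp$logP),
    MV = sum(comp$fraction * comp$MV))
}

#' Resolve a rhamnolipid composition from partial literature information
#'
#' Literature reports biosurfactant composition in several incomplete ways;
#' this resolves them to an explicit component list usable by
#' [weighted_descriptor()]:
#'
#' * Case A — only the mono/di class split is reported (`mono_share`): the
#'   representative congeners Rha-C10-C10 and Rha-Rha-C10-C10 carry the split.
#' * Case B — congeners are listed without shares: a default 35/65 mono/di
#'   mass split is assumed and divided equally within each listed class.
#' * Case C — congeners with explicit shares: passed through after
#'   normalization.
#'
#' @param mono_share mass fraction of mono-rhamnolipids, or `NULL`.
#' @param congeners character vector of congener names, or `NULL`.
#' @param shares numeric shares aligned with `congeners`, or `NULL`.
#' @param table congener descriptor table (default [congener_table()]).
#' @return data frame with columns `name`, `fraction`, `logP`, `MV`; fractions
#'   sum to 1.
#' @export
resolve_composition <- function(mono_share = NULL, congeners = NULL,
                                shares = NULL, table = congener_table()) {
  table <- validate_congener_table(table)
  if (is.null(mono_share) && is.null(congeners))
    stop_validation("need at least one of mono_share / congeners")
  if (!is.null(mono_share) &&
      (mono_share < 0 || mono_share > 1))
    stop_validation("mono_share must lie in [0, 1]")

  if (is.null(congeners)) {
    # Case A: class split carried by the two representative congeners.
    congeners <- c("Rha-C10-C10", "Rha-Rha-C10-C10")
    shares <- c(mono_share, 1 - mono_share)
  }
  unknown <- setdiff(congeners, table$name)
  if (length(unknown) > 0L)
    stop_validation(sprintf("unknown congener(s): %s",
                            paste(unknown, collapse = ", ")))
  rows <- table[match(congeners, table$name), , drop = FALSE]

  if (is.null(shares)) {
    split <- if (is.null(mono_share)) c(mono = 0.35, di = 0.65)
             else c(mono = mono_share, di = 1 - mono_share)
    n_mono <- sum(rows$class == "mono")
    n_di <- sum(rows$class == "di")
    for (cl in c("mono", "di")) {
      n_cl <- if (cl == "mono") n_mono else n_di
      if (n_cl == 0L && split[[cl]] > 0)
        stop_validation(sprintf(
          "no %sRL congener listed but default %sRL share is %.2f; supply explicit shares",
          cl, cl, split[[cl]]))
    }
    shares <- ifelse(rows$class == "mono",
                     split[["mono"]] / n_mono, split[["di"]] / n_di)
  }
  if (length(shares) != nrow(rows))
    stop_validation("shares must align with congeners")
  if (any(shares < 0)) stop_validation("shares must be >= 0")
  rows <- rows[shares > 0, , drop = FALSE]
  shares <- shares[shares > 0]
  if (length(shares) == 0L) stop_validation("all shares are zero")
  shares <- shares / sum(shares)
  data.frame(name = rows$name, fraction = shares,
             logP = rows$logP, MV = rows$MV,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Carbon-to-nitrogen mass ratio
#'
#' @param conc_C carbon source concentration, mg/L.
#' @param conc_N nitrogen source concentration, mg/L (> 0).
#' @return `conc_C / conc_N` (w/w). Vectorized.
#' @export
derive_cn_ratio <- function(conc_C, conc_N) {
  if (any(!is.na(conc_N) & conc_N == 0))
    stop_validation("conc_N = 0: C:N ratio undefined")
  conc_C / conc_N
}

#' Reconcile explicit and derived C:N ratios
#'
#' Where a record carries both concentrations and an explicitly reported C:N
#' ratio, the two are cross-checked; a relative discrepancy above 5% keeps the
#' explicit value but emits a warning naming the rows.
#'
#' @param conc_C,conc_N concentrations, mg/L.
#' @param explicit explicitly reported C:N ratio (may contain `NA`).
#' @return reconciled C:N vector: explicit where present, derived otherwise.
#' @export
reconcile_cn_ratio <- function(conc_C, conc_N, explicit) {
  derived <- ifelse(!is.na(conc_N) & conc_N > 0, conc_C / conc_N, NA_real_)
  both <- !is.na(explicit) & !is.na(derived)
  off <- both & abs(derived - explicit) > 0.05 * abs(explicit)
  if (any(off))
    warning(sprintf(
      "C:N ratio discrepancy > 5%% in row(s) %s; keeping explicit values",
      paste(which(off), collapse = ", ")), call. = FALSE)
  ifelse(is.na(explicit), derived, explicit)
}

#' Harmonize a production dataset in place
#'
#' Fills `CN_ratio` from concentrations where missing and cross-checks
#' explicit values (see [reconcile_cn_ratio()]).
#'
#' @param ds a `production` [rl_dataset()].
#' @return the harmonized dataset.
#' @export
harmonize_production <- function(ds) {
  stopifnot(inherits(ds, "rl_dataset"), attr(ds, "schema") == "production")
  if (nrow(ds) == 0L) return(ds)
  ds$CN_ratio <- reconcile_cn_ratio(ds$conc_C, ds$conc_N, ds$CN_ratio)
  rl_dataset(as.data.frame(ds), "production")
}
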