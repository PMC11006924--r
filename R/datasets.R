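#' Column schemas for the two experiment databases
#'
#' The package works with two tabular databases: cultivation experiments that
#' produced a rhamnolipid (RL) of measured hydrophobicity (`logP_RL`), and
#' micellar solubilization experiments with a measured molar solubilization
#' ratio (MSR). Each schema fixes column names, the descriptor subset, the
#' modelling target, and the default descriptor set used by the fitted models.
#'
#' Units: concentrations in mg/L, molecular volumes (`MV_*`) in cubic
#' angstroms, temperature in degrees Celsius, shaking speed in rpm,
#' cultivation time in hours, CMC in mg/L, MSR in mol solubilizate per mol
#' surfactant. `logP*` and pH are dimensionless.
#'
#' @format A named list with elements `columns` (column name -> type),
#'   `descriptors`, `target` and `model_descriptors`.
#' @name rl_schemas
NULL

.rl_schemas <- list(
  production = list(
    character = c("producer_taxon", "producer_group"),
    numeric = c("conc_C", "logP_C", "MV_C", "conc_N", "CN_ratio", "pH",
                "temperature", "shaking", "time", "logP_RL"),
    descriptors = c("conc_C", "logP_C", "MV_C", "conc_N", "CN_ratio", "pH",
                    "temperature", "shaking", "time"),
    target = "logP_RL",
    # MV_C is excluded from the default model descriptor set; it can be added
    # back with the `include_MV_C` flag of fit helpers.
    model_descriptors = c("conc_C", "logP_C", "conc_N", "CN_ratio", "pH",
                          "temperature", "shaking", "time")
  ),
  msr = list(
    character = character(),
    numeric = c("impurity", "logP_RL", "CMC", "logP_SOL", "MV_SOL", "pH",
                "temperature", "MSR", "logMSR"),
    descriptors = c("impurity", "logP_RL", "logP_SOL", "MV_SOL", "CMC",
                    "pH", "temperature"),
    target = "logMSR",
    model_descriptors = c("impurity", "logP_RL", "logP_SOL", "MV_SOL", "CMC",
                          "temperature", "pH")
  )
)

.producer_groups <- c("general", "pseudomonas", "burkholderia")
.provenance_levels <- c("literature", "experimental")

#' Look up a database schema
#'
#' @param schema `"production"` or `"msr"`.
#' @return The schema definition list (see [rl_schemas]).
#' @export
rl_schema <- function(schema) {
  schema <- match.arg(schema, names(.rl_schemas))
  c(.rl_schemas[[schema]], list(name = schema))
}

#' Construct a validated dataset
#'
#' Wraps a data frame as an `rl_dataset`: columns are reordered to the schema,
#' a per-row `provenance` tag (`"literature"` or `"experimental"`) is attached,
#' and all record invariants are checked. Missing cells are `NA`; targets may
#' not be missing for `production` (`logP_RL`) but any descriptor may be.
#'
#' @param df data frame with the schema's columns (plus optional `provenance`).
#' @param schema `"production"` or `"msr"`.
#' @param provenance default tag for rows lacking one.
#' @return A data frame of class `rl_dataset` with attribute `schema`.
#' @export
rl_dataset <- function(df, schema, provenance = "literature") {
  sc <- rl_schema(schema)
  cols <- c(sc$character, sc$numeric)
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop_validation(sprintf("schema '%s': missing column(s): %s",
                            sc$name, paste(miss, collapse = ", ")))
  if (!"provenance" %in% names(df)) {
    df$provenance <- rep(match.arg(provenance, .provenance_levels),
                         length.out = nrow(df))
  }
  df <- df[, c(cols, "provenance"), drop = FALSE]
  for (col in sc$numeric) df[[col]] <- as.numeric(df[[col]])
  validate_rl_rows(df, sc)
  rownames(df) <- NULL
  structure(df, class = c("rl_dataset", "data.frame"), schema = sc$name)
}

# Row-level invariants; errors name the row and the field.
validate_rl_rows <- function(df, sc) {
  bad <- function(idx, field, why) {
    if (any(idx, na.rm = TRUE))
      stop_validation(sprintf("row %d, field '%s': %s",
                              which(idx)[1L], field, why))
  }
  if (nrow(df) == 0L) return(invisible(df))
  bad(!df$provenance %in% .provenance_levels, "provenance",
      "must be 'literature' or 'experimental'")
  if (sc$name == "production") {
    bad(!is.na(df$producer_group) & !df$producer_group %in% .producer_groups,
        "producer_group",
        sprintf("must be one of %s", paste(.producer_groups, collapse = "/")))
    for (f in c("conc_C", "conc_N", "shaking", "time"))
      bad(df[[f]] < 0, f, "must be >= 0")
  } else {
    bad(!is.na(df$impurity) &
          (df$impurity < 0 | df$impurity > 5 |
             abs(df$impurity - round(df$impurity)) > 1e-9),
        "impurity", "must be an integer in 0..5")
    bad(df$MSR <= 0, "MSR", "must be > 0")
    bad(df$CMC <= 0, "CMC", "must be > 0")
    both <- !is.na(df$MSR) & !is.na(df$logMSR)
    bad(both & abs(df$logMSR - log10(df$MSR)) > 1e-12, "logMSR",
        "inconsistent with log10(MSR)")
  }
  bad(df$pH <= 0 | df$pH >= 14, "pH", "must lie strictly between 0 and 14")
  invisible(df)
}

#' @export
print.rl_dataset <- function(x, ...) {
  cat(sprintf("<rl_dataset schema=%s rows=%d>\n", attr(x, "schema"), nrow(x)))
  NextMethod()
}

#' Read a database from CSV
#'
#' CSV convention: UTF-8, `.` decimal separator, empty string = missing.
#' Header names are matched case-insensitively against the schema; unknown
#' columns raise a schema error listing the offending names, and unparseable
#' numeric cells raise a row-indexed error. Missing cells are preserved as
#' `NA`, never zero-filled.
#'
#' @param path CSV file path.
#' @param schema `"production"` or `"msr"`.
#' @return An [rl_dataset()].
#' @export
read_dataset <- function(path, schema) {
  sc <- rl_schema(schema)
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  known <- c(sc$character, sc$numeric, "provenance")
  idx <- match(tolower(names(raw)), tolower(known))
  if (anyNA(idx))
    stop_validation(sprintf("schema '%s': unknown column(s): %s", sc$name,
                            paste(names(raw)[is.na(idx)], collapse = ", ")))
  names(raw) <- known[idx]
  for (col in sc$numeric) {
    if (!col %in% names(raw)) next
    cell <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & nzchar(cell))
    if (length(bad) > 0L)
      stop_validation(sprintf("row %d, column '%s': unparseable numeric '%s'",
                              bad[1L], col, cell[bad[1L]]))
    raw[[col]] <- val
  }
  for (col in intersect(c(sc$character, "provenance"), names(raw))) {
    raw[[col]][!nzchar(trimws(raw[[col]]))] <- NA_character_
  }
  rl_dataset(raw, sc$name)
}

#' Write a database to CSV
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, p), schema)`
#' reproduces `ds`, including its missingness pattern and provenance tags.
#' Missing cells are written as empty fields.
#'
#' @param ds an [rl_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "rl_dataset"))
  out <- as.data.frame(ds)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      # full double precision so round-trips are lossless
      txt <- vapply(out[[col]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17L,
                                                scientific = FALSE), "")
      out[[col]] <- txt
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fraction of missing descriptor cells
#'
#' The databases' missingness is quoted as a fraction of descriptor cells
#' (rows x descriptor columns); targets are excluded.
#'
#' @param ds an [rl_dataset()].
#' @param fields descriptor subset (default: all schema descriptors).
#' @return A fraction in \[0, 1\].
#' @export
missing_fraction <- function(ds, fields = NULL) {
  stopifnot(inherits(ds, "rl_dataset"))
  sc <- rl_schema(attr(ds, "schema"))
  if (is.null(fields)) fields <- sc$descriptors
  if (length(fields) == 0L) stop_validation("empty descriptor field set")
  extra <- setdiff(fields, sc$descriptors)
  if (length(extra) > 0L)
    stop_validation(sprintf("not descriptor field(s): %s",
                            paste(extra, collapse = ", ")))
  if (nrow(ds) == 0L) return(0)
  cells <- as.matrix(as.data.frame(ds)[, fields, drop = FALSE])
  mean(is.na(cells))
}
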