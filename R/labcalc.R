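#' Critical micelle concentration from a surface-tension isotherm
#'
#' Fits two straight lines to the isotherm in (log10 concentration, surface
#' tension) space — the descending pre-micellar branch and the post-CMC
#' plateau — by exhaustive search over all interior breakpoints with at least
#' `min_points` points per segment, minimizing total squared error. The CMC is
#' the abscissa of the two lines' intersection, back-transformed to mg/L.
#' The plateau is fitted with a free slope (real post-CMC tension drifts
#' slightly); SSE ties are broken toward the flatter plateau.
#'
#' @param concentration surfactant concentrations, mg/L, strictly positive,
#'   at least 6 points.
#' @param tension surface tensions, mN/m.
#' @param min_points minimum points per segment (>= 3).
#' @return list with `cmc` (mg/L), `log10_cmc`, `breakpoint` (index of the
#'   last pre-micellar point), per-segment `slopes`, `intercepts`, and `sse`.
#'   Errors: "no CMC detectable" when the best descending branch has
#'   non-negative slope; intersection outside the data range is an error.
#' @export
cmc_from_isotherm <- function(concentration, tension, min_points = 3L) {
  if (is.data.frame(concentration)) {
    tension <- concentration[[2L]]
    concentration <- concentration[[1L]]
  }
  if (length(concentration) != length(tension))
    stop_validation("concentration and tension must have equal length")
  if (length(concentration) < 6L)
    stop_validation("need at least 6 isotherm points")
  if (any(concentration <= 0))
    stop_validation("concentrations must be strictly positive")
  min_points <- max(3L, as.integer(min_points))
  ord <- order(concentration)
  x <- log10(concentration[ord])
  y <- tension[ord]
  n <- length(x)
  if (n - 2L * min_points < 0L)
    stop_validation("too few points for two segments")

  line_fit <- function(xx, yy) {
    b <- stats::cov(xx, yy) / stats::var(xx)
    a <- mean(yy) - b * mean(xx)
    list(a = a, b = b, sse = sum((yy - a - b * xx)^2))
  }
  best <- NULL
  for (br in min_points:(n - min_points)) {
    f1 <- line_fit(x[1:br], y[1:br])
    f2 <- line_fit(x[(br + 1):n], y[(br + 1):n])
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && abs(f2$b) < abs(best$f2$b))) {
      best <- list(br = br, f1 = f1, f2 = f2, sse = sse)
    }
  }
  if (best$f1$b >= 0)
    stop_validation("no CMC detectable: pre-micellar branch is not descending")
  if (best$f1$b == best$f2$b)
    stop_validation("no CMC detectable: parallel segments")
  x_star <- (best$f2$a - best$f1$a) / (best$f1$b - best$f2$b)
  if (x_star < min(x) || x_star > max(x))
    stop_validation("line intersection falls outside the measured range")
  list(cmc = 10^x_star, log10_cmc = x_star, breakpoint = best$br,
       slopes = c(descending = best$f1$b, plateau = best$f2$b),
       intercepts = c(descending = best$f1$a, plateau = best$f2$a),
       sse = best$sse)
}

#' Molar solubilization ratio from a solubility curve
#'
#' The MSR is the ordinary-least-squares slope of solubilizate concentration
#' versus surfactant concentration (both mol/L) restricted to points above the
#' CMC. Inputs may instead be given in mg/L together with molar masses
#' (g/mol), in which case they are converted first; the MSR is invariant to
#' consistent unit changes.
#'
#' @param surfactant surfactant concentrations.
#' @param solubilizate solubilizate concentrations.
#' @param cmc the surfactant CMC, same units as `surfactant`.
#' @param molar_mass `NULL` for mol/L inputs, or
#'   `c(surfactant=, solubilizate=)` in g/mol for mg/L inputs (`cmc` then also
#'   mg/L).
#' @return list with `msr` (mol/mol), `log_msr` (base-10), `n_points` used,
#'   and `intercept` of the fitted line. Fewer than 3 points above the CMC or
#'   a non-positive slope are errors.
#' @export
msr_from_curve <- function(surfactant, solubilizate, cmc, molar_mass = NULL) {
  if (length(surfactant) != length(solubilizate))
    stop_validation("surfactant and solubilizate must have equal length")
  if (!is.null(molar_mass)) {
    need <- c("surfactant", "solubilizate")
    if (!all(need %in% names(molar_mass)))
      stop_validation("molar_mass needs named entries 'surfactant' and 'solubilizate'")
    surfactant <- surfactant / 1000 / molar_mass[["surfactant"]]
    solubilizate <- solubilizate / 1000 / molar_mass[["solubilizate"]]
    cmc <- cmc / 1000 / molar_mass[["surfactant"]]
  }
  above <- surfactant > cmc
  if (sum(above) < 3L)
    stop_validation("need at least 3 points above the CMC")
  xx <- surfactant[above]
  yy <- solubilizate[above]
  slope <- stats::cov(xx, yy) / stats::var(xx)
  if (slope <= 0)
    stop_validation("no measurable solubilization: non-positive slope above CMC")
  list(msr = slope, log_msr = log10(slope), n_points = sum(above),
       intercept = mean(yy) - slope * mean(xx))
}
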