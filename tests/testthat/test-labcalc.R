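# exact two-line isotherm: gamma = 70 - 20 log10(c) descending, plateau 40,
# intersecting at log10(c) = 1.5 i.e. CMC = 31.62 mg/L
two_line_isotherm <- function(n_per_side = 6, noise_sd = 0,
                              cmc_log10 = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lc <- c(seq(0.2, cmc_log10, length.out = n_per_side),
          seq(cmc_log10 + 0.15, 2.8, length.out = n_per_side))
  gamma <- ifelse(lc <= cmc_log10, 70 - 20 * lc, 40)
  gamma <- gamma + stats::rnorm(length(gamma), 0, noise_sd)
  data.frame(concentration = 10^lc, tension = gamma)
}

test_that("the two-line intersection recovers a constructed CMC", {
  iso <- two_line_isotherm()
  res <- cmc_from_isotherm(iso$concentration, iso$tension)
  expect_equal(res$cmc, 10^1.5, tolerance = 0.5 / 31.62)
  expect_lt(res$slopes[["descending"]], 0)
  expect_equal(res$slopes[["plateau"]], 0, tolerance = 1e-9)
})

test_that("degenerate isotherms are refused with clear errors", {
  flat <- data.frame(concentration = 10^seq(0.5, 2.5, length.out = 10),
                     tension = 50)
  expect_error(cmc_from_isotherm(flat$concentration, flat$tension),
               "no CMC detectable", class = "rl_validation_error")
  iso <- two_line_isotherm()
  expect_error(cmc_from_isotherm(iso$concentration[1:5], iso$tension[1:5]),
               class = "rl_validation_error")
  expect_error(cmc_from_isotherm(-iso$concentration, iso$tension),
               class = "rl_validation_error")
  # rising isotherm has no descending branch
  expect_error(cmc_from_isotherm(iso$concentration, rev(iso$tension)),
               "no CMC detectable", class = "rl_validation_error")
})

test_that("breakpoint search is globally optimal over admissible splits", {
  set.seed(12)
  for (i in 1:10) {
    iso <- two_line_isotherm(n_per_side = 7, noise_sd = 1)
    res <- cmc_from_isotherm(iso$concentration, iso$tension)
    x <- log10(sort(iso$concentration))
    y <- iso$tension[order(iso$concentration)]
    n <- length(x)
    sse_at <- function(br) {
      f <- function(idx) {
        fit <- stats::lm(y[idx] ~ x[idx])
        sum(stats::resid(fit)^2)
      }
      f(1:br) + f((br + 1):n)
    }
    all_sse <- vapply(3:(n - 3), sse_at, 0)
    expect_equal(res$sse, min(all_sse), tolerance = 1e-8)
  }
})

test_that("1% tension noise still recovers the CMC within 10% (median)", {
  cmcs <- vapply(1:50, function(i) {
    iso <- two_line_isotherm(n_per_side = 8, noise_sd = 0.01 * 55, seed = 100 + i)
    tryCatch(cmc_from_isotherm(iso$concentration, iso$tension)$cmc,
             error = function(e) NA_real_)
  }, 0)
  expect_lt(abs(stats::median(cmcs, na.rm = TRUE) - 31.6228) / 31.6228, 0.10)
})

test_that("MSR equals the slope of the solubility curve above the CMC", {
  surf <- seq(0.5e-3, 5e-3, length.out = 10)   # mol/L
  cmc <- 1.2e-3
  sol <- ifelse(surf > cmc, 1e-5 + 0.02 * (surf - cmc), 1e-5)
  res <- msr_from_curve(surf, sol, cmc)
  expect_equal(res$msr, 0.02, tolerance = 1e-12)
  expect_equal(res$log_msr, log10(0.02), tolerance = 1e-12)
  expect_identical(res$n_points, sum(surf > cmc))

  # all points below the CMC -> error
  expect_error(msr_from_curve(surf[surf <= cmc], sol[surf <= cmc], cmc),
               class = "rl_validation_error")
  # descending curve -> no measurable solubilization
  expect_error(msr_from_curve(surf, rev(sol), cmc),
               "no measurable", class = "rl_validation_error")
})

test_that("MSR is invariant under consistent unit conversion", {
  mm <- c(surfactant = 504.6, solubilizate = 302.4)  # g/mol
  surf_mol <- seq(1e-3, 8e-3, length.out = 12)
  cmc_mol <- 2e-3
  sol_mol <- ifelse(surf_mol > cmc_mol, 2e-6 + 0.015 * (surf_mol - cmc_mol),
                    2e-6)
  direct <- msr_from_curve(surf_mol, sol_mol, cmc_mol)
  converted <- msr_from_curve(surf_mol * 1000 * mm[["surfactant"]],
                              sol_mol * 1000 * mm[["solubilizate"]],
                              cmc_mol * 1000 * mm[["surfactant"]],
                              molar_mass = mm)
  expect_equal(converted$msr, direct$msr, tolerance = 1e-9)
  expect_equal(converted$log_msr, direct$log_msr, tolerance = 1e-9)
})
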