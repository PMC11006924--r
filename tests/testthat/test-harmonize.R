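test_that("weighted_descriptor averages by mass fraction", {
  # identity on a single component (tributyrin descriptors)
  expect_equal(
    weighted_descriptor(data.frame(fraction = 1, logP = 3.27, MV = 297.46)),
    c(logP = 3.27, MV = 297.46))
  # symmetry
  expect_equal(
    weighted_descriptor(data.frame(fraction = c(0.5, 0.5),
                                   logP = c(2, 4), MV = c(100, 300))),
    c(logP = 3, MV = 200))
  # 50/50 tributyrin/triolein blend, frozen from hand arithmetic:
  # logP = (3.27 + 10.78)/2 = 7.025; MV = (297.46 + 984.58)/2 = 641.02
  expect_equal(
    weighted_descriptor(data.frame(fraction = c(0.5, 0.5),
                                   logP = c(3.27, 10.78),
                                   MV = c(297.46, 984.58))),
    c(logP = 7.025, MV = 641.02))
})

test_that("weighted_descriptor validates fractions and is bounded", {
  expect_error(weighted_descriptor(data.frame(fraction = numeric(),
                                              logP = numeric(),
                                              MV = numeric())),
               class = "rl_validation_error")
  expect_error(
    weighted_descriptor(data.frame(fraction = c(0.6, 0.6),
                                   logP = c(1, 2), MV = c(1, 2))),
    "sum", class = "rl_validation_error")
  expect_error(
    weighted_descriptor(data.frame(fraction = c(-0.5, 1.5),
                                   logP = c(1, 2), MV = c(1, 2))),
    class = "rl_validation_error")

  # property: permutation-invariant and bounded by component extrema
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    f <- stats::runif(k)
    f <- f / sum(f)
    comp <- data.frame(fraction = f, logP = stats::runif(k, -3, 11),
                       MV = stats::runif(k, 90, 1000))
    w <- weighted_descriptor(comp)
    perm <- comp[sample(k), ]
    expect_equal(weighted_descriptor(perm), w)
    expect_gte(w[["logP"]], min(comp$logP))
    expect_lte(w[["logP"]], max(comp$logP))
    expect_gte(w[["MV"]], min(comp$MV))
    expect_lte(w[["MV"]], max(comp$MV))
  }
})

test_that("resolve_composition handles the three literature cases", {
  # Case A: a reported 25.65/74.35 mono/di split lands on the two
  # representative congeners
  comp <- resolve_composition(mono_share = 0.2565)
  expect_equal(comp$fraction[comp$name == "Rha-C10-C10"], 0.2565)
  expect_equal(comp$fraction[comp$name == "Rha-Rha-C10-C10"], 0.7435)

  # Case B: congeners listed without shares -> default 35/65 split
  comp <- resolve_composition(congeners = c("Rha-C10-C10",
                                            "Rha-Rha-C10-C10"))
  expect_equal(comp$fraction, c(0.35, 0.65))

  # Case C: fully specified composition is normalized passthrough
  comp <- resolve_composition(congeners = c("Rha-C10-C10",
                                            "Rha-Rha-C10-C10"),
                              shares = c(2, 6))
  expect_equal(comp$fraction, c(0.25, 0.75))

  # fractions always sum to 1
  for (c2 in list(resolve_composition(mono_share = 0.1),
                  resolve_composition(mono_share = 1),
                  resolve_composition(congeners = "Rha-C10-C10",
                                      mono_share = 1)))
    expect_equal(sum(c2$fraction), 1)

  # Case B with a missing class and nonzero default share refuses
  expect_error(resolve_composition(congeners = "Rha-C10-C10"),
               "explicit shares", class = "rl_validation_error")
  expect_error(resolve_composition(), class = "rl_validation_error")
})

test_that("congener tables validate and round-trip", {
  tab <- congener_table()
  expect_true(all(c("Rha-C10-C10", "Rha-Rha-C10-C10") %in% tab$name))
  # mono congener is smaller and more hydrophobic than the di
  expect_gt(tab$logP[tab$name == "Rha-C10-C10"],
            tab$logP[tab$name == "Rha-Rha-C10-C10"])
  expect_lt(tab$MV[tab$name == "Rha-C10-C10"],
            tab$MV[tab$name == "Rha-Rha-C10-C10"])

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_equal(read_congener_table(path), tab)

  bad <- tab[tab$class == "mono", ]
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_congener_table(path), class = "rl_validation_error")
})

test_that("C:N ratios derive, refuse zero nitrogen, and reconcile", {
  expect_equal(derive_cn_ratio(100, 100), 1)
  expect_equal(derive_cn_ratio(500, 25), 20)
  expect_error(derive_cn_ratio(100, 0), class = "rl_validation_error")

  # explicit value within 5% of the derived one passes silently
  expect_silent(out <- reconcile_cn_ratio(500, 25, 20.5))
  expect_equal(out, 20.5)
  # discrepancy beyond 5% keeps the explicit value but warns with the row
  expect_warning(out <- reconcile_cn_ratio(c(500, 100), c(25, 10), c(30, NA)),
                 "row\\(s\\) 1")
  expect_equal(out, c(30, 10))

  df <- tiny_production_df()
  df$CN_ratio[3] <- NA
  ds <- harmonize_production(rl_dataset(df, "production"))
  expect_equal(ds$CN_ratio[3], df$conc_C[3] / df$conc_N[3])
})
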