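test_that("Karva decoding matches hand-decoded examples", {
  cfg <- manual_cfg()
  # identity chromosome: head "a"
  tr <- express(manual_chromosome(cfg, c("a")), cfg)
  expect_equal(evaluate(tr, data.frame(a = 7, b = 0)), 7)

  # "+ a b" decodes to a + b
  tr <- express(manual_chromosome(cfg, c("+", "a", "b")), cfg)
  expect_equal(evaluate(tr, data.frame(a = 2, b = 3)), 5)

  # two genes a and b joined by multiplicative linking
  cfg2 <- manual_cfg(genes = 2L, linking = "*")
  tr <- express(manual_chromosome(cfg2, c("a"), c("b")), cfg2)
  expect_equal(evaluate(tr, data.frame(a = 2, b = 3)), 6)

  # unused tail symbols are ignored: "+ a b" with junk tail equals a + b
  tr <- express(manual_chromosome(cfg, c("+", "a", "b", "b", "b", "a", "a")),
                cfg)
  expect_equal(evaluate(tr, data.frame(a = 1, b = 10)), 11)

  # unknown symbol errors
  chrom <- manual_chromosome(cfg, c("q"))
  expect_error(express(chrom, cfg), "unknown symbol",
               class = "rl_validation_error")
})

test_that("protected operators keep every evaluation finite", {
  cfg <- manual_cfg(functions = c("+", "-", "*", "/", "sqrt", "ln", "exp"))
  div <- express(manual_chromosome(cfg, c("/", "a", "b")), cfg)
  expect_equal(evaluate(div, data.frame(a = 3, b = 0)), 1)  # x/0 -> 1
  expect_equal(evaluate(div, data.frame(a = 3, b = 2)), 1.5)

  lnx <- express(manual_chromosome(cfg, c("ln", "a")), cfg)
  expect_equal(evaluate(lnx, data.frame(a = -5, b = 0)), log1p(5))
  expect_equal(evaluate(lnx, data.frame(a = exp(2), b = 0)), 2)

  ex <- express(manual_chromosome(cfg, c("exp", "a")), cfg)
  expect_equal(evaluate(ex, data.frame(a = 1000, b = 0)), exp(50))

  # missing descriptor errors
  expect_error(evaluate(div, data.frame(a = 1)), "missing descriptor",
               class = "rl_validation_error")
})

test_that("expression/evaluation agrees with the recursive oracle", {
  set.seed(11)
  cfg <- gep_config(terminals = c("x1", "x2", "x3"), genes = 2L, head = 5L,
                    n_rnc = 3L, pop_size = 4L, generations = 1L, seed = 1L)
  data <- data.frame(x1 = stats::runif(4, -5, 5), x2 = stats::runif(4, -5, 5),
                     x3 = stats::runif(4, 0.1, 10))
  for (i in 1:120) {
    chrom <- random_chromosome(cfg)
    got <- evaluate(express(chrom, cfg), data)
    want <- oracle_evaluate(chrom, cfg, data)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rmse matches hand arithmetic and ignores row order", {
  cfg <- manual_cfg()
  perfect <- express(manual_chromosome(cfg, c("a")), cfg)
  df <- data.frame(a = c(3, 4), b = 0, y = c(3, 4))
  expect_equal(rmse(perfect, df, "y"), 0)

  zero <- express(manual_chromosome(cfg, c("-", "a", "a")), cfg)
  expect_equal(rmse(zero, df, "y"), sqrt(12.5))
  expect_equal(rmse(zero, df[2:1, ], "y"), sqrt(12.5))
  expect_error(rmse(zero, df[0, ], "y"), class = "rl_validation_error")
})

test_that("genetic operators preserve head/tail discipline", {
  set.seed(5)
  cfg <- gep_config(terminals = c("x1", "x2"), genes = 3L, head = 6L,
                    n_rnc = 4L, pop_size = 4L, generations = 1L,
                    rates = list(mutation = 0.3, rnc_mutation = 0.5))
  ops_unary <- list(rldesign:::op_mutate, rldesign:::op_mutate_rnc,
                    rldesign:::op_is_transpose, rldesign:::op_ris_transpose,
                    rldesign:::op_gene_transpose)
  chrom <- random_chromosome(cfg)
  for (i in 1:6000) {
    op <- ops_unary[[sample.int(length(ops_unary), 1)]]
    chrom <- op(chrom, cfg)
    if (i %% 100L == 0L) expect_true(chromosome_valid(chrom, cfg))
  }
  c1 <- random_chromosome(cfg)
  c2 <- random_chromosome(cfg)
  ops_binary <- list(rldesign:::op_one_point, rldesign:::op_two_point,
                     rldesign:::op_gene_recombine)
  for (i in 1:4000) {
    op <- ops_binary[[sample.int(length(ops_binary), 1)]]
    pair <- op(c1, c2, cfg)
    c1 <- pair[[1]]
    c2 <- pair[[2]]
    if (i %% 100L == 0L) {
      expect_true(chromosome_valid(c1, cfg))
      expect_true(chromosome_valid(c2, cfg))
    }
  }
})

test_that("evolution is elitist, deterministic, and can be exact", {
  set.seed(2)
  df <- data.frame(x1 = stats::runif(30, -3, 3), x2 = stats::runif(30, -3, 3))
  df$y <- df$x1 + df$x2
  cfg <- gep_config(terminals = c("x1", "x2"), functions = c("+", "-"),
                    genes = 2L, head = 4L, n_rnc = 0L, pop_size = 30L,
                    generations = 500L, seed = 17L)
  res <- evolve(df, "y", cfg)
  expect_lt(res$rmse, 1e-9)
  # elitism: best fitness never worsens
  expect_true(all(diff(res$trace) <= 0))
  # determinism: same seed, same best chromosome
  res2 <- evolve(df, "y", cfg)
  expect_identical(res$chromosome, res2$chromosome)

  # constant target approximated through random numerical constants
  df2 <- data.frame(x1 = stats::runif(20), y = 4.2)
  cfgc <- gep_config(terminals = "x1", functions = c("+", "-"),
                     genes = 2L, head = 3L, n_rnc = 3L, pop_size = 40L,
                     generations = 300L, seed = 3L)
  resc <- evolve(df2, "y", cfgc)
  expect_lt(resc$rmse, 0.05)

  expect_error(evolve(df[1:3, ], "y", cfg), class = "rl_validation_error")
})

test_that("models serialize to JSON and reload bit-for-bit", {
  set.seed(9)
  cfg <- gep_config(terminals = c("x1", "x2"), genes = 2L, head = 4L,
                    n_rnc = 2L, pop_size = 4L, generations = 1L)
  chrom <- random_chromosome(cfg)
  ad <- applicability_domain(data.frame(descriptor = c("x1", "x2"),
                                        min = c(0, -1), max = c(1, 1)))
  m <- fitted_model(chrom, cfg, schema = "custom",
                    descriptors = c("x1", "x2"), target = "y", domain = ad,
                    metrics = list(rmse_train = 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  df <- data.frame(x1 = stats::runif(5), x2 = stats::runif(5))
  expect_equal(predict(back, df, check_domain = FALSE),
               predict(m, df, check_domain = FALSE), tolerance = 1e-12)
  expect_equal(as.data.frame(back$domain), as.data.frame(m$domain))
  expect_equal(back$metrics$rmse_train, 0.5)

  junk <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", junk)
  expect_error(read_model(junk), "malformed", class = "rl_validation_error")
})
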