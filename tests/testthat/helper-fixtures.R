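# Small in-code fixtures shared across the suite.

# three-row production table, fully observed
tiny_production_df <- function() {
  data.frame(
    producer_taxon = c("Pseudomonas sp. A", "Burkholderia sp. B",
                       "Pseudomonas sp. C"),
    producer_group = c("pseudomonas", "burkholderia", "pseudomonas"),
    conc_C = c(20000, 40000, 10000),
    logP_C = c(-1.6, 10.72, -2.64),
    MV_C = c(160, 950, 120),
    conc_N = c(1000, 2000, 4000),
    CN_ratio = c(20, 20, 2.5),
    pH = c(7, 6.5, 7.2),
    temperature = c(30, 28, 37),
    shaking = c(180, 150, 200),
    time = c(96, 120, 48),
    logP_RL = c(4.69, 7.95, 4.80),
    stringsAsFactors = FALSE
  )
}

tiny_production <- function() rl_dataset(tiny_production_df(), "production")

tiny_msr_df <- function() {
  msr <- c(0.02, 0.5, 0.0031)
  data.frame(
    impurity = c(0, 3, 5),
    logP_RL = c(4.7, 6.0, 8.0),
    CMC = c(50, 120, 20),
    logP_SOL = c(3.27, 10.78, 4.5),
    MV_SOL = c(297.46, 984.58, 400),
    pH = c(7, 5.5, 8.5),
    temperature = c(25, 25, 30),
    MSR = msr,
    logMSR = log10(msr)
  )
}

tiny_msr <- function() rl_dataset(tiny_msr_df(), "msr")

# config for hand-built chromosomes: head 3 / tail 4, no constants
manual_cfg <- function(terminals = c("a", "b"),
                       functions = c("+", "-", "*", "/"),
                       genes = 1L, linking = "+", ...) {
  gep_config(terminals = terminals, functions = functions, genes = genes,
             head = 3L, n_rnc = 0L, linking = linking, pop_size = 4L,
             generations = 1L, ...)
}

# chromosome from explicit per-gene symbol vectors (padded with `pad`)
manual_chromosome <- function(cfg, ..., pad = cfg$terminals[1L]) {
  genes <- lapply(list(...), function(syms) {
    stopifnot(length(syms) <= cfg$head + cfg$tail)
    c(syms, rep(pad, cfg$head + cfg$tail - length(syms)))
  })
  stopifnot(length(genes) == cfg$genes)
  structure(list(genes = genes,
                 rncs = replicate(cfg$genes, numeric(), simplify = FALSE)),
            class = "gep_chromosome")
}

# single-descriptor identity model (prediction == the descriptor), with an
# optional applicability domain
identity_model <- function(descriptor, schema = "custom",
                           descriptors = descriptor, target = "y",
                           domain = NULL) {
  cfg <- gep_config(terminals = descriptors, functions = c("+", "-"),
                    genes = 1L, head = 1L, n_rnc = 0L, pop_size = 2L,
                    generations = 1L)
  chrom <- structure(list(
    genes = list(rep(descriptor, 1L + cfg$tail)),
    rncs = list(numeric())), class = "gep_chromosome")
  fitted_model(chrom, cfg, schema = schema, descriptors = descriptors,
               target = target, domain = domain)
}

# naive recursive Karva oracle, independent of the decode-to-call path:
# explicit breadth-first tree construction, then depth-first evaluation of
# scalars row by row.
oracle_evaluate <- function(chrom, cfg, data) {
  fns <- list(
    "+" = function(a, b) a + b, "-" = function(a, b) a - b,
    "*" = function(a, b) a * b,
    "/" = function(a, b) if (b == 0) 1 else a / b,
    "sqrt" = function(a) sqrt(abs(a)),
    "ln" = function(a) if (a > 0) log(a) else log1p(abs(a)),
    "exp" = function(a) exp(min(max(a, -50), 50)),
    "sq" = function(a) a * a)
  arity <- function(s) if (s %in% cfg$functions) {
    if (s %in% c("+", "-", "*", "/")) 2L else 1L
  } else 0L
  eval_gene <- function(syms, rnc, row) {
    build <- function() {
      nodes <- list(list(sym = syms[1L], kids = integer()))
      frontier <- 1L
      pos <- 2L
      while (length(frontier) > 0L) {
        cur <- frontier[1L]
        frontier <- frontier[-1L]
        k <- arity(nodes[[cur]]$sym)
        if (k > 0L) {
          for (j in seq_len(k)) {
            nodes[[length(nodes) + 1L]] <- list(sym = syms[pos],
                                                kids = integer())
            nodes[[cur]]$kids <- c(nodes[[cur]]$kids, length(nodes))
            frontier <- c(frontier, length(nodes))
            pos <- pos + 1L
          }
        }
      }
      nodes
    }
    nodes <- build()
    rec <- function(i) {
      s <- nodes[[i]]$sym
      if (s %in% cfg$functions)
        do.call(fns[[s]], lapply(nodes[[i]]$kids, rec))
      else if (s %in% cfg$const_syms)
        rnc[match(s, cfg$const_syms)]
      else row[[s]]
    }
    rec(1L)
  }
  link <- fns[[cfg$linking]]
  vapply(seq_len(nrow(data)), function(r) {
    row <- as.list(data[r, , drop = FALSE])
    vals <- lapply(seq_len(cfg$genes), function(g)
      eval_gene(chrom$genes[[g]], chrom$rncs[[g]], row))
    out <- vals[[1L]]
    if (cfg$genes > 1L)
      for (g in 2L:cfg$genes) out <- link(out, vals[[g]])
    out
  }, 0)
}

# dominant contribution sign per descriptor, with an importance floor below
# which a model is read as making no sign claim
dominant_signs <- function(model, ds, imp_floor = 0.05, seed = 99L) {
  imp <- importance(model, ds, seed = seed)
  vapply(model$descriptors, function(d) {
    if (imp[[d]] < imp_floor) return("0")
    s <- contribution_signs(model, ds, d)
    if (s[["positive_pct"]] > s[["negative_pct"]]) "+" else "-"
  }, "")
}
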