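# Gene expression programming: fixed-length linear chromosomes in Karva
# (breadth-first) notation, decoded into expression trees and evolved against
# a root-mean-squared-error fitness.

# Protected primitives: every function is total and finite on the reals so a
# candidate model can never produce an unusable fitness.
.gep_functions <- list(
  "+"    = list(arity = 2L, fn = function(a, b) a + b),
  "-"    = list(arity = 2L, fn = function(a, b) a - b),
  "*"    = list(arity = 2L, fn = function(a, b) a * b),
  "/"    = list(arity = 2L, fn = function(a, b) {
    out <- a / b
    out[rep_len(b == 0, length(out))] <- 1  # protected division: x/0 -> 1
    out
  }),
  "sqrt" = list(arity = 1L, fn = function(a) sqrt(abs(a))),
  "ln"   = list(arity = 1L, fn = function(a) {
    out <- a
    pos <- a > 0
    out[pos] <- log(a[pos])
    out[!pos] <- log1p(abs(a[!pos]))  # protected log: finite for all reals
    out
  }),
  "exp"  = list(arity = 1L, fn = function(a) exp(pmin(pmax(a, -50), 50))),
  "sq"   = list(arity = 1L, fn = function(a) a * a)
)

#' GEP engine configuration
#'
#' Defines the search space and evolution schedule for the symbolic-regression
#' engine. Chromosomes have `genes` genes of head length `head`; the tail
#' length is always computed as `head * (max_arity - 1) + 1` so that any head
#' content decodes to a complete expression tree. Heads may hold functions or
#' terminals, tails hold terminals only. Terminals are the descriptor names
#' plus `n_rnc` random-numerical-constant slots per gene, drawn uniformly from
#' `rnc_range`.
#'
#' Defaults (3 genes, head 8, additive linking, population 50, 1000
#' generations, mutation 0.044, transpositions 0.1, recombinations 0.3/0.3/0.1,
#' constant mutation 0.01) follow common GEP practice; all are exposed here.
#'
#' @param terminals character vector of descriptor names.
#' @param functions subset of the built-in protected function set
#'   `+ - * / sqrt ln exp sq`.
#' @param genes,head chromosome layout.
#' @param n_rnc random constants per gene (0 disables constants).
#' @param rnc_range range for uniform constant draws.
#' @param linking binary linking function joining the genes.
#' @param pop_size,generations evolution schedule.
#' @param rates named list of operator rates: `mutation` (per symbol),
#'   `is_transposition`, `ris_transposition`, `gene_transposition` (per
#'   chromosome), `one_point`, `two_point`, `gene_recombination` (per pair),
#'   `rnc_mutation` (per constant).
#' @param seed integer seed; evolution is deterministic given it.
#' @return a `gep_config` object.
#' @export
gep_config <- function(terminals,
                       functions = c("+", "-", "*", "/", "sqrt", "ln", "exp", "sq"),
                       genes = 3L, head = 8L, n_rnc = 5L,
                       rnc_range = c(-10, 10), linking = "+",
                       pop_size = 50L, generations = 1000L,
                       rates = list(), seed = 1L) {
  stopifnot(is.character(terminals), length(terminals) >= 1L,
            genes >= 1L, head >= 1L, n_rnc >= 0L, pop_size >= 2L,
            generations >= 1L, length(rnc_range) == 2L,
            rnc_range[1] < rnc_range[2])
  unknown <- setdiff(functions, names(.gep_functions))
  if (length(unknown) > 0L)
    stop_validation(sprintf("unknown function symbol(s): %s",
                            paste(unknown, collapse = ", ")))
  if (length(functions) > 0L) {
    if (!linking %in% functions || .gep_functions[[linking]]$arity != 2L)
      stop_validation("linking must be a binary function from the set")
  }
  default_rates <- list(mutation = 0.044, is_transposition = 0.1,
                        ris_transposition = 0.1, gene_transposition = 0.1,
                        one_point = 0.3, two_point = 0.3,
                        gene_recombination = 0.1, rnc_mutation = 0.01)
  bad <- setdiff(names(rates), names(default_rates))
  if (length(bad) > 0L)
    stop_validation(sprintf("unknown rate(s): %s", paste(bad, collapse = ", ")))
  default_rates[names(rates)] <- rates
  if (any(unlist(default_rates) < 0 | unlist(default_rates) > 1))
    stop_validation("operator rates must lie in [0, 1]")
  max_arity <- if (length(functions) == 0L) 1L
               else max(vapply(.gep_functions[functions], `[[`, 0L, "arity"))
  const_syms <- if (n_rnc > 0L) paste0(".c", seq_len(n_rnc)) else character()
  structure(list(
    terminals = terminals, functions = functions,
    const_syms = const_syms, term_pool = c(terminals, const_syms),
    genes = as.integer(genes), head = as.integer(head),
    tail = as.integer(head * (max_arity - 1L) + 1L),
    n_rnc = as.integer(n_rnc), rnc_range = as.numeric(rnc_range),
    linking = linking, pop_size = as.integer(pop_size),
    generations = as.integer(generations), rates = default_rates,
    seed = as.integer(seed)
  ), class = "gep_config")
}

gene_length <- function(cfg) cfg$head + cfg$tail

#' Draw a random chromosome
#'
#' @param cfg a [gep_config()].
#' @return a `gep_chromosome`: per-gene Karva symbol vectors plus per-gene
#'   constant arrays.
#' @export
random_chromosome <- function(cfg) {
  head_pool <- c(cfg$functions, cfg$term_pool)
  genes <- replicate(cfg$genes, c(
    sample(head_pool, cfg$head, replace = TRUE),
    sample(cfg$term_pool, cfg$tail, replace = TRUE)
  ), simplify = FALSE)
  rncs <- replicate(cfg$genes,
                    stats::runif(cfg$n_rnc, cfg$rnc_range[1], cfg$rnc_range[2]),
                    simplify = FALSE)
  structure(list(genes = genes, rncs = rncs), class = "gep_chromosome")
}

#' Check head/tail discipline of a chromosome
#'
#' @param chrom a `gep_chromosome`.
#' @param cfg its [gep_config()].
#' @return `TRUE` if every gene has the right length, heads hold only known
#'   symbols and tails hold terminals only.
#' @export
chromosome_valid <- function(chrom, cfg) {
  all(vapply(seq_len(cfg$genes), function(g) {
    syms <- chrom$genes[[g]]
    length(syms) == gene_length(cfg) &&
      all(syms[seq_len(cfg$head)] %in% c(cfg$functions, cfg$term_pool)) &&
      all(syms[cfg$head + seq_len(cfg$tail)] %in% cfg$term_pool) &&
      length(chrom$rncs[[g]]) == cfg$n_rnc
  }, TRUE))
}

# Breadth-first (Karva) decoding of one gene: returns symbol indices actually
# used and the children of each used node.
decode_gene <- function(syms, cfg) {
  is_fun <- syms %in% cfg$functions
  ar <- integer(length(syms))
  ar[is_fun] <- vapply(.gep_functions[syms[is_fun]], `[[`, 0L, "arity")
  child <- vector("list", length(syms))
  used <- 1L
  i <- 1L
  while (i <= used) {
    k <- ar[i]
    if (k > 0L) {
      child[[i]] <- seq.int(used + 1L, used + k)
      used <- used + k
    }
    i <- i + 1L
  }
  list(syms = syms, child = child, used = used)
}

gene_to_call <- function(dec, rnc, cfg) {
  build <- function(i) {
    s <- dec$syms[i]
    if (s %in% cfg$functions) {
      as.call(c(list(.gep_functions[[s]]$fn), lapply(dec$child[[i]], build)))
    } else if (s %in% cfg$const_syms) {
      rnc[match(s, cfg$const_syms)]
    } else {
      as.name(s)
    }
  }
  build(1L)
}

#' Decode a chromosome into an executable expression tree
#'
#' Karva decoding: each gene is read breadth-first from its first symbol;
#' symbols beyond the spanned tree are silently ignored. Genes are joined
#' left-to-right by the linking function.
#'
#' @param chrom a `gep_chromosome`.
#' @param cfg its [gep_config()].
#' @return a `gep_tree`: an evaluable R call plus the descriptor terminals it
#'   actually references.
#' @export
express <- function(chrom, cfg) {
  unknown <- setdiff(unique(unlist(chrom$genes)),
                     c(cfg$functions, cfg$term_pool))
  if (length(unknown) > 0L)
    stop_validation(sprintf("unknown symbol(s) in chromosome: %s",
                            paste(unknown, collapse = ", ")))
  terms_used <- character()
  calls <- vector("list", cfg$genes)
  for (g in seq_len(cfg$genes)) {
    dec <- decode_gene(chrom$genes[[g]], cfg)
    calls[[g]] <- gene_to_call(dec, chrom$rncs[[g]], cfg)
    terms_used <- c(terms_used,
                    intersect(dec$syms[seq_len(dec$used)], cfg$terminals))
  }
  expr <- calls[[1L]]
  if (cfg$genes > 1L) {
    link <- .gep_functions[[cfg$linking]]$fn
    for (g in 2L:cfg$genes) expr <- as.call(list(link, expr, calls[[g]]))
  }
  structure(list(expr = expr, gene_calls = calls,
                 terminals = unique(terms_used), chromosome = chrom),
            class = "gep_tree")
}

#' Evaluate an expression tree on descriptor data
#'
#' @param tree a `gep_tree` from [express()].
#' @param data data frame or named list covering every terminal the tree
#'   references; extra columns are ignored.
#' @return a finite numeric vector, one value per row (recycled for
#'   constant-only trees).
#' @export
evaluate <- function(tree, data) {
  stopifnot(inherits(tree, "gep_tree"))
  data <- as.data.frame(data)
  miss <- setdiff(tree$terminals, names(data))
  if (length(miss) > 0L)
    stop_validation(sprintf("missing descriptor(s): %s",
                            paste(miss, collapse = ", ")))
  out <- eval(tree$expr, envir = data, enclos = baseenv())
  out <- rep_len(as.numeric(out), max(nrow(data), 1L))
  # protected primitives are finite, but products can still overflow doubles
  out[is.nan(out)] <- 0
  out[out > 1e100] <- 1e100
  out[out < -1e100] <- -1e100
  out
}

#' Root-mean-squared error of a tree on a dataset
#'
#' RMSE is the fitness function of the evolutionary search.
#'
#' @param tree a `gep_tree`.
#' @param ds complete data frame / [rl_dataset()].
#' @param target target column name.
#' @return `sqrt(mean((prediction - observed)^2))`.
#' @export
rmse <- function(tree, ds, target) {
  ds <- as.data.frame(ds)
  if (nrow(ds) == 0L) stop_validation("empty dataset")
  if (!target %in% names(ds))
    stop_validation(sprintf("target '%s' not in data", target))
  pred <- evaluate(tree, ds)
  sqrt(mean((pred - ds[[target]])^2))
}

## ---- genetic operators (all preserve head/tail discipline) ----

op_mutate <- function(chrom, cfg) {
  head_pool <- c(cfg$functions, cfg$term_pool)
  rate <- cfg$rates$mutation
  for (g in seq_len(cfg$genes)) {
    syms <- chrom$genes[[g]]
    hit <- stats::runif(length(syms)) < rate
    for (i in which(hit)) {
      syms[i] <- if (i <= cfg$head) sample(head_pool, 1L)
                 else sample(cfg$term_pool, 1L)
    }
    chrom$genes[[g]] <- syms
  }
  chrom
}

# Constant mutation: half of the hits redraw uniformly (global exploration),
# half perturb the current value on a relative log scale (fine tuning) —
# plain uniform redraws almost never land on small coefficients.
op_mutate_rnc <- function(chrom, cfg) {
  if (cfg$n_rnc == 0L) return(chrom)
  rate <- cfg$rates$rnc_mutation
  for (g in seq_len(cfg$genes)) {
    hit <- which(stats::runif(cfg$n_rnc) < rate)
    for (i in hit) {
      if (stats::runif(1) < 0.5) {
        chrom$rncs[[g]][i] <- stats::runif(1, cfg$rnc_range[1],
                                           cfg$rnc_range[2])
      } else {
        v <- chrom$rncs[[g]][i]
        v <- v * 10^stats::rnorm(1, 0, 0.25) +
          stats::rnorm(1, 0, 1e-3 * diff(cfg$rnc_range))
        chrom$rncs[[g]][i] <- min(max(v, cfg$rnc_range[1]), cfg$rnc_range[2])
      }
    }
  }
  chrom
}

# Insertion-sequence transposition: copy a short subsequence into a head
# (never at the root), shifting right and truncating to head length.
op_is_transpose <- function(chrom, cfg) {
  if (cfg$head < 2L) return(chrom)
  src_g <- sample.int(cfg$genes, 1L)
  dst_g <- sample.int(cfg$genes, 1L)
  len <- sample.int(min(3L, cfg$head - 1L), 1L)
  glen <- gene_length(cfg)
  start <- sample.int(glen - len + 1L, 1L)
  seqn <- chrom$genes[[src_g]][start:(start + len - 1L)]
  at <- sample(2:cfg$head, 1L)
  head_syms <- chrom$genes[[dst_g]][seq_len(cfg$head)]
  new_head <- append(head_syms, seqn, after = at - 1L)[seq_len(cfg$head)]
  chrom$genes[[dst_g]][seq_len(cfg$head)] <- new_head
  chrom
}

# Root-insertion transposition: a subsequence starting at a function symbol in
# the head is copied to the head's root.
op_ris_transpose <- function(chrom, cfg) {
  g <- sample.int(cfg$genes, 1L)
  syms <- chrom$genes[[g]]
  scan_from <- sample.int(cfg$head, 1L)
  fun_pos <- which(syms[seq_len(cfg$head)] %in% cfg$functions)
  fun_pos <- fun_pos[fun_pos >= scan_from]
  if (length(fun_pos) == 0L) return(chrom)
  start <- fun_pos[1L]
  len <- sample.int(min(3L, cfg$head), 1L)
  len <- min(len, gene_length(cfg) - start + 1L)
  seqn <- syms[start:(start + len - 1L)]
  new_head <- c(seqn, syms[seq_len(cfg$head)])[seq_len(cfg$head)]
  chrom$genes[[g]][seq_len(cfg$head)] <- new_head
  chrom
}

op_gene_transpose <- function(chrom, cfg) {
  if (cfg$genes < 2L) return(chrom)
  g <- sample(2:cfg$genes, 1L)
  ord <- c(g, setdiff(seq_len(cfg$genes), g))
  chrom$genes <- chrom$genes[ord]
  chrom$rncs <- chrom$rncs[ord]
  chrom
}

flatten_chrom <- function(chrom) unlist(chrom$genes, use.names = FALSE)

unflatten_chrom <- function(flat, chrom, cfg) {
  glen <- gene_length(cfg)
  for (g in seq_len(cfg$genes))
    chrom$genes[[g]] <- flat[((g - 1L) * glen + 1L):(g * glen)]
  chrom
}

op_one_point <- function(c1, c2, cfg) {
  glen <- gene_length(cfg)
  total <- glen * cfg$genes
  p <- sample.int(total - 1L, 1L)
  f1 <- flatten_chrom(c1); f2 <- flatten_chrom(c2)
  n1 <- c(f1[seq_len(p)], f2[(p + 1L):total])
  n2 <- c(f2[seq_len(p)], f1[(p + 1L):total])
  # constant arrays follow the gene that donates its tail end
  cut_gene <- ceiling(p / glen)
  o1 <- c1; o2 <- c2
  if (cut_gene < cfg$genes) {
    swap <- (cut_gene + 1L):cfg$genes
    o1$rncs[swap] <- c2$rncs[swap]
    o2$rncs[swap] <- c1$rncs[swap]
  }
  list(unflatten_chrom(n1, o1, cfg), unflatten_chrom(n2, o2, cfg))
}

op_two_point <- function(c1, c2, cfg) {
  total <- gene_length(cfg) * cfg$genes
  pts <- sort(sample.int(total, 2L))
  f1 <- flatten_chrom(c1); f2 <- flatten_chrom(c2)
  mid <- pts[1L]:pts[2L]
  n1 <- f1; n1[mid] <- f2[mid]
  n2 <- f2; n2[mid] <- f1[mid]
  list(unflatten_chrom(n1, c1, cfg), unflatten_chrom(n2, c2, cfg))
}

op_gene_recombine <- function(c1, c2, cfg) {
  g <- sample.int(cfg$genes, 1L)
  tmp_g <- c1$genes[[g]]; tmp_r <- c1$rncs[[g]]
  c1$genes[[g]] <- c2$genes[[g]]; c1$rncs[[g]] <- c2$rncs[[g]]
  c2$genes[[g]] <- tmp_g; c2$rncs[[g]] <- tmp_r
  list(c1, c2)
}

tournament_select <- function(fitness, k = 3L) {
  cand <- sample.int(length(fitness), k, replace = TRUE)
  cand[which.min(fitness[cand])]
}

#' Evolve a symbolic-regression model
#'
#' Generational evolution with elitism: the best-so-far chromosome survives
#' each generation unmodified, so the fitness trace is non-increasing. Parents
#' are chosen by size-3 tournament on training RMSE; offspring pass through
#' point mutation, constant mutation, the three transpositions and the three
#' recombination operators at the configured rates. Deterministic given
#' `cfg$seed`.
#'
#' @param train complete training data (data frame / [rl_dataset()]).
#' @param target target column name.
#' @param cfg a [gep_config()].
#' @return list with `chromosome` (best by training RMSE), `tree`, `rmse`, and
#'   `trace` (best RMSE per generation).
#' @export
evolve <- function(train, target, cfg) {
  train <- as.data.frame(train)
  if (nrow(train) < 5L) stop_validation("need at least 5 training rows")
  if (anyNA(train[, cfg$terminals, drop = FALSE]))
    stop_validation("training data must be complete; impute first")
  set.seed(cfg$seed)

  score <- function(ch) {
    r <- rmse(express(ch, cfg), train, target)
    if (!is.finite(r)) 1e100 else r
  }
  pop <- replicate(cfg$pop_size, random_chromosome(cfg), simplify = FALSE)
  fit <- vapply(pop, score, 0)
  best_i <- which.min(fit)
  best <- pop[[best_i]]
  best_fit <- fit[best_i]
  trace <- numeric(cfg$generations)

  rates <- cfg$rates
  for (gen in seq_len(cfg$generations)) {
    newpop <- vector("list", cfg$pop_size)
    newpop[[1L]] <- best  # elitism
    for (i in 2:cfg$pop_size) {
      ch <- pop[[tournament_select(fit)]]
      ch <- op_mutate(ch, cfg)
      ch <- op_mutate_rnc(ch, cfg)
      if (stats::runif(1) < rates$is_transposition) ch <- op_is_transpose(ch, cfg)
      if (stats::runif(1) < rates$ris_transposition) ch <- op_ris_transpose(ch, cfg)
      if (stats::runif(1) < rates$gene_transposition) ch <- op_gene_transpose(ch, cfg)
      newpop[[i]] <- ch
    }
    if (cfg$pop_size >= 3L) {
      for (i in seq(2L, cfg$pop_size - 1L, by = 2L)) {
        pair <- list(newpop[[i]], newpop[[i + 1L]])
        if (stats::runif(1) < rates$one_point) pair <- op_one_point(pair[[1]], pair[[2]], cfg)
        if (stats::runif(1) < rates$two_point) pair <- op_two_point(pair[[1]], pair[[2]], cfg)
        if (stats::runif(1) < rates$gene_recombination)
          pair <- op_gene_recombine(pair[[1]], pair[[2]], cfg)
        newpop[[i]] <- pair[[1]]; newpop[[i + 1L]] <- pair[[2]]
      }
    }
    pop <- newpop
    fit <- c(best_fit, vapply(pop[-1L], score, 0))
    gen_best <- which.min(fit)
    if (fit[gen_best] < best_fit) {
      best_fit <- fit[gen_best]
      best <- pop[[gen_best]]
    }
    trace[gen] <- best_fit
  }
  list(chromosome = best, tree = express(best, cfg), rmse = best_fit,
       trace = trace)
}
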