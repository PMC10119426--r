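# Function set used by the symbolic-regression engine: four binary
# arithmetic operators plus three unary functions.  Maximum arity 2.
GEP_FUNCS <- c("+", "-", "*", "/", "Inv", "Cos", "Tan")
GEP_ARITY <- c(2L, 2L, 2L, 2L, 1L, 1L, 1L)
GEP_NMAX <- 2L
GEP_GUARD_EPS <- 1e-12
GEP_CLAMP <- 1e6

#' The GEP operational function set
#'
#' Addition, subtraction, multiplication and division (arity 2) plus the
#' unary inverse, cosine and tangent.
#'
#' @return data.frame with columns `symbol` and `arity`.
#' @export
gep_function_set <- function() {
  data.frame(symbol = GEP_FUNCS, arity = GEP_ARITY, stringsAsFactors = FALSE)
}

#' Karva tail length
#'
#' For a gene with head length `h` over a function set of maximum arity
#' `n_max`, the tail must hold `t = h * (n_max - 1) + 1` terminals so that
#' any head content decodes to a complete expression tree.
#'
#' @param h Head length (>= 1).
#' @param n_max Maximum function arity (>= 1).
#' @return Integer tail length.
#' @examples
#' tail_length(7, 2)  # 8
#' @export
tail_length <- function(h, n_max = GEP_NMAX) {
  if (h < 1L || n_max < 1L) stop("h and n_max must be >= 1")
  as.integer(h * (n_max - 1L) + 1L)
}

gep_terminals <- function(n_terminals) paste0("d", seq_len(n_terminals) - 1L)

arity_of <- function(sym) {
  a <- GEP_ARITY[match(sym, GEP_FUNCS)]
  a[is.na(a)] <- 0L
  a
}

#' Construct a Karva-encoded chromosome
#'
#' A chromosome is one or more fixed-length genes; each gene is a symbol
#' string whose first `head` positions may hold functions or terminals and
#' whose tail (length `head * (n_max - 1) + 1`) holds terminals only.
#' Multigene chromosomes are combined with the linking function.
#'
#' @param genes List of character vectors (one per gene), or a single
#'   character vector for a one-gene chromosome.
#' @param head Head length.
#' @param n_terminals Number of terminals `d0 ... d<n-1>` (default 5).
#' @param link Linking function for multigene chromosomes, `"+"` or `"*"`.
#' @return Object of class `gep_chromosome`.
#' @export
gep_chromosome <- function(genes, head, n_terminals = 5L, link = "+") {
  if (!is.list(genes)) genes <- list(genes)
  chrom <- structure(list(genes = genes, head = as.integer(head),
                          n_terminals = as.integer(n_terminals),
                          link = match.arg(link, c("+", "*"))),
                     class = "gep_chromosome")
  validate_chromosome(chrom)
  chrom
}

#' Validate chromosome invariants
#'
#' Checks fixed gene length, known symbols and the terminals-only tail;
#' errors on violation.  Used after every genetic operator in the test
#' suite's fuzzing harness.
#'
#' @param chrom A `gep_chromosome`.
#' @return Invisibly `TRUE`.
#' @export
validate_chromosome <- function(chrom) {
  stopifnot(inherits(chrom, "gep_chromosome"))
  h <- chrom$head
  glen <- h + tail_length(h)
  terms <- gep_terminals(chrom$n_terminals)
  for (g in chrom$genes) {
    if (length(g) != glen)
      stop("gene length ", length(g), " != head + tail = ", glen)
    if (!all(g %in% c(GEP_FUNCS, terms)))
      stop("unknown symbol(s): ",
           paste(setdiff(g, c(GEP_FUNCS, terms)), collapse = ", "))
    if (any(g[(h + 1L):glen] %in% GEP_FUNCS))
      stop("tail positions must contain terminals only")
  }
  invisible(TRUE)
}

#' @export
print.gep_chromosome <- function(x, ...) {
  cat("<gep_chromosome> head", x$head, "x", length(x$genes), "gene(s), link '",
      x$link, "'\n", sep = " ")
  for (g in x$genes) cat("  ", paste(g, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Random chromosome
#'
#' Head positions drawn uniformly from functions plus terminals, tail
#' positions from terminals.
#'
#' @inheritParams gep_chromosome
#' @param n_genes Number of genes.
#' @return A `gep_chromosome`.
#' @export
random_chromosome <- function(head, n_terminals = 5L, n_genes = 1L,
                              link = "+") {
  terms <- gep_terminals(n_terminals)
  t_len <- tail_length(head)
  genes <- lapply(seq_len(n_genes), function(i)
    c(sample(c(GEP_FUNCS, terms), head, replace = TRUE),
      sample(terms, t_len, replace = TRUE)))
  gep_chromosome(genes, head, n_terminals, link)
}

#' Decode a Karva gene into an expression tree
#'
#' Level-order (breadth-first) reading: the first symbol is the root, and
#' each function node consumes the next `arity` unread symbols as its
#' children.  Unused trailing symbols are ignored.  For a multigene
#' chromosome the gene trees are joined by the linking function.
#'
#' @param x A `gep_chromosome` or a bare character vector (single gene).
#' @return An expression tree: nested list with fields `sym` (symbol) and
#'   `args` (list of child trees; `NULL` for terminals), class `gep_tree`.
#' @export
decode_karva <- function(x) {
  if (inherits(x, "gep_chromosome")) {
    validate_chromosome(x)
    trees <- lapply(x$genes, decode_gene)
    if (length(trees) == 1L) return(trees[[1L]])
    out <- trees[[1L]]
    for (k in 2L:length(trees))
      out <- gep_node(x$link, list(out, trees[[k]]))
    return(out)
  }
  decode_gene(as.character(x))
}

gep_node <- function(sym, args = NULL) {
  structure(list(sym = sym, args = args), class = "gep_tree")
}

decode_gene <- function(gene) {
  ar <- arity_of(gene)
  if (is.na(ar[1L])) stop("unknown symbol at position 1")
  # how many symbols the tree actually uses
  needed <- 1L; i <- 1L
  while (i <= needed) {
    if (needed > length(gene))
      stop("malformed gene: runs out of symbols while decoding")
    needed <- needed + ar[i]
    i <- i + 1L
  }
  # children indices in level order
  kids <- vector("list", needed)
  nxt <- 2L
  for (j in seq_len(needed)) {
    if (ar[j] > 0L) {
      kids[[j]] <- seq.int(nxt, nxt + ar[j] - 1L)
      nxt <- nxt + ar[j]
    }
  }
  build <- function(j) {
    if (ar[j] == 0L) return(gep_node(gene[j]))
    gep_node(gene[j], lapply(kids[[j]], build))
  }
  build(1L)
}

#' Serialise an expression tree back to a Karva gene
#'
#' Level-order serialisation, the inverse of [decode_karva()] for trees that
#' fit the head: all function symbols must land within the head, and the
#' remaining positions are padded with the first terminal.
#'
#' @param tree A `gep_tree`.
#' @param head Head length of the target gene.
#' @param n_terminals Number of terminals.
#' @return Character vector of length `head + tail_length(head)`.
#' @export
encode_tree <- function(tree, head, n_terminals = 5L) {
  syms <- character(0)
  queue <- list(tree)
  while (length(queue) > 0L) {
    nd <- queue[[1L]]; queue <- queue[-1L]
    syms <- c(syms, nd$sym)
    if (!is.null(nd$args)) queue <- c(queue, nd$args)
  }
  if (any(grepl("^-?[0-9.]+$", syms)))
    stop("numeric constants cannot be Karva-encoded (no constant domain)")
  glen <- head + tail_length(head)
  if (length(syms) > glen)
    stop("tree needs ", length(syms), " symbols; gene holds ", glen)
  fun_pos <- which(syms %in% GEP_FUNCS)
  if (length(fun_pos) > 0L && max(fun_pos) > head)
    stop("tree has a function symbol beyond the head; increase head length")
  pad <- gep_terminals(n_terminals)[1L]
  c(syms, rep(pad, glen - length(syms)))
}

#' Infix rendering of an expression tree
#' @param tree A `gep_tree`.
#' @return Character scalar, fully parenthesised.
#' @export
tree_to_infix <- function(tree) {
  if (is.null(tree$args)) return(tree$sym)
  if (length(tree$args) == 1L)
    return(paste0(tree$sym, "(", tree_to_infix(tree$args[[1L]]), ")"))
  paste0("(", tree_to_infix(tree$args[[1L]]), tree$sym,
         tree_to_infix(tree$args[[2L]]), ")")
}

gep_clamp <- function(v) pmin(pmax(v, -GEP_CLAMP), GEP_CLAMP)

#' Evaluate an expression tree over terminal data
#'
#' Recursive evaluation, vectorised over observations.  Singularities are
#' guarded: division and inverse with |denominator| < 1e-12 return the
#' saturation value 1e6, and every node output is clamped to +/- 1e6 so that
#' tangent blow-ups cannot overflow downstream arithmetic.
#'
#' @param tree A `gep_tree` (from [decode_karva()] or
#'   [parse_model_expression()]).
#' @param data Named list, data.frame or matrix providing one numeric vector
#'   per terminal (`d0`, `d1`, ...).
#' @return Numeric vector of values.
#' @export
evaluate_tree <- function(tree, data) {
  data <- as.data.frame(data)
  ev <- function(nd) {
    s <- nd$sym
    if (is.null(nd$args)) {
      if (grepl("^-?[0-9.]+$", s)) return(as.numeric(s))
      if (is.null(data[[s]])) stop("terminal '", s, "' not bound in data")
      return(as.numeric(data[[s]]))
    }
    a <- ev(nd$args[[1L]])
    if (length(nd$args) == 2L) {
      b <- ev(nd$args[[2L]])
      if (length(a) != length(b)) {      # broadcast scalar constants
        len <- max(length(a), length(b))
        a <- rep_len(a, len); b <- rep_len(b, len)
      }
      return(switch(s,
        "+" = gep_clamp(a + b),
        "-" = gep_clamp(a - b),
        "*" = gep_clamp(a * b),
        "/" = gep_clamp(ifelse(abs(b) < GEP_GUARD_EPS, GEP_CLAMP, a / b)),
        stop("unknown binary function: ", s)))
    }
    switch(s,
      Inv = gep_clamp(ifelse(abs(a) < GEP_GUARD_EPS, GEP_CLAMP, 1 / a)),
      Cos = cos(a),
      Tan = gep_clamp(tan(a)),
      stop("unknown unary function: ", s))
  }
  out <- ev(tree)
  if (length(out) == 1L) out <- rep(out, max(1L, nrow(data)))
  out
}

#' GEP fitness of a prediction vector
#'
#' Default specification: `1000 / (1 + RMSE)`, bounded in (0, 1000] with
#' 1000 meaning a perfect fit.  Alternative: squared Pearson correlation.
#' Higher is better under both.
#'
#' @param predictions,y Equal-length numeric vectors.
#' @param spec `"rmse"` (default) or `"correlation"`.
#' @return Scalar fitness.
#' @export
gep_fitness <- function(predictions, y, spec = c("rmse", "correlation")) {
  spec <- match.arg(spec)
  if (length(predictions) != length(y)) stop("length mismatch")
  if (spec == "rmse") {
    rmse <- sqrt(mean((predictions - y)^2))
    return(1000 / (1 + rmse))
  }
  if (stats::sd(y) == 0)
    stop("zero-variance response under correlation fitness")
  if (stats::sd(predictions) == 0) return(0)
  stats::cor(predictions, y)^2
}

#' Elite roulette parent selection
#'
#' The top `elitism` individuals survive unchanged; the remaining slots are
#' filled by fitness-proportional sampling with replacement.  If every
#' fitness is zero, sampling degenerates to uniform with a warning.
#'
#' @param fitnesses Non-negative fitness vector.
#' @param n_select Number of individuals to select (default: population
#'   size).
#' @param elitism Number of elite copies (default 1).
#' @return Integer vector of selected indices; the first `elitism` entries
#'   are the elite.
#' @export
select_elite_roulette <- function(fitnesses, n_select = length(fitnesses),
                                  elitism = 1L) {
  n <- length(fitnesses)
  if (n == 0L) stop("empty population")
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  elitism <- min(as.integer(elitism), n_select)
  elite <- order(fitnesses, decreasing = TRUE)[seq_len(elitism)]
  rest <- n_select - elitism
  if (rest == 0L) return(elite)
  if (all(fitnesses == 0)) {
    warning("all-zero fitness: falling back to uniform sampling")
    picked <- sample.int(n, rest, replace = TRUE)
  } else {
    picked <- sample.int(n, rest, replace = TRUE, prob = fitnesses)
  }
  c(elite, picked)
}

#' Evolution configuration
#'
#' Hyperparameter defaults follow common gene-expression-programming
#' practice: population 500, single gene of head length 10, mutation rate
#' 0.044 (about two point mutations per chromosome), one-/two-point
#' recombination 0.3 each, gene recombination and the three transposition
#' operators 0.1 each, elitism 1.  All are configurable.
#'
#' @param population Population size (>= 2).
#' @param generations Maximum generations.
#' @param head Gene head length.
#' @param n_genes Genes per chromosome.
#' @param link Linking function for multigene chromosomes.
#' @param p_mutation Per-position mutation probability.
#' @param p_one_point,p_two_point,p_gene_recomb Per-individual recombination
#'   participation probabilities.
#' @param p_is,p_ris,p_gene_trans Transposition probabilities.
#' @param max_transposon Maximum transposon length (default 3).
#' @param elitism Number of elite individuals copied unchanged.
#' @param fitness `"rmse"` or `"correlation"` (see [gep_fitness()]).
#' @param stop_fitness Early-termination fitness threshold (default `Inf`,
#'   i.e. run all generations).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return List of class `gep_config`.
#' @export
gep_config <- function(population = 500L, generations = 200L, head = 10L,
                       n_genes = 1L, link = "+", p_mutation = 0.044,
                       p_one_point = 0.3, p_two_point = 0.3,
                       p_gene_recomb = 0.1, p_is = 0.1, p_ris = 0.1,
                       p_gene_trans = 0.1, max_transposon = 3L,
                       elitism = 1L, fitness = "rmse", stop_fitness = Inf,
                       seed = NULL) {
  rates <- c(p_mutation, p_one_point, p_two_point, p_gene_recomb, p_is,
             p_ris, p_gene_trans)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (population < 2L) stop("population must be >= 2")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 head = as.integer(head), n_genes = as.integer(n_genes),
                 link = match.arg(link, c("+", "*")),
                 p_mutation = p_mutation, p_one_point = p_one_point,
                 p_two_point = p_two_point, p_gene_recomb = p_gene_recomb,
                 p_is = p_is, p_ris = p_ris, p_gene_trans = p_gene_trans,
                 max_transposon = as.integer(max_transposon),
                 elitism = as.integer(elitism),
                 fitness = match.arg(fitness, c("rmse", "correlation")),
                 stop_fitness = stop_fitness, seed = seed),
            class = "gep_config")
}
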