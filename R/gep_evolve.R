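# ---- integer codec -------------------------------------------------------
# Internally the evolutionary loop works on integer codes: functions 1..7 in
# GEP_FUNCS order, terminals 8..(7 + n_terminals).  A chromosome is the
# concatenation of its genes.

n_funcs <- function() length(GEP_FUNCS)

chromosome_to_codes <- function(chrom) {
  terms <- gep_terminals(chrom$n_terminals)
  unlist(lapply(chrom$genes, function(g) match(g, c(GEP_FUNCS, terms))),
         use.names = FALSE)
}

codes_to_chromosome <- function(codes, head, n_terminals, n_genes, link) {
  terms <- gep_terminals(n_terminals)
  glen <- head + tail_length(head)
  genes <- lapply(seq_len(n_genes), function(g)
    c(GEP_FUNCS, terms)[codes[((g - 1L) * glen + 1L):(g * glen)]])
  gep_chromosome(genes, head, n_terminals, link)
}

# column indices of head/tail positions within the concatenated chromosome
head_positions <- function(head, glen, n_genes)
  unlist(lapply(seq_len(n_genes) - 1L, function(g) g * glen + seq_len(head)))

tail_positions <- function(head, glen, n_genes)
  unlist(lapply(seq_len(n_genes) - 1L,
                function(g) g * glen + seq.int(head + 1L, glen)))

# ---- genetic operators (integer-coded) -----------------------------------

#' Point mutation
#'
#' Each position flips with probability `rate`; head positions draw from the
#' full symbol set, tail positions from terminals only, so chromosome
#' validity is preserved by construction.
#'
#' @param chrom A `gep_chromosome`.
#' @param rate Per-position mutation probability.
#' @return Mutated `gep_chromosome`.
#' @export
mutate <- function(chrom, rate) {
  codes <- chromosome_to_codes(chrom)
  glen <- chrom$head + tail_length(chrom$head)
  codes <- mutate_codes(codes, chrom$head, glen, length(chrom$genes),
                        chrom$n_terminals, rate)
  codes_to_chromosome(codes, chrom$head, chrom$n_terminals,
                      length(chrom$genes), chrom$link)
}

mutate_codes <- function(codes, head, glen, n_genes, nt, rate) {
  if (rate <= 0) return(codes)
  hp <- head_positions(head, glen, n_genes)
  tp <- tail_positions(head, glen, n_genes)
  hit <- stats::runif(length(codes)) < rate
  hh <- intersect(which(hit), hp)
  tt <- intersect(which(hit), tp)
  if (length(hh) > 0L)
    codes[hh] <- sample.int(n_funcs() + nt, length(hh), replace = TRUE)
  if (length(tt) > 0L)
    codes[tt] <- n_funcs() + sample.int(nt, length(tt), replace = TRUE)
  codes
}

#' One-point recombination
#'
#' Swaps the suffixes of two parents after a random crossover point.
#' Because both parents share the head/tail layout, offspring remain valid.
#'
#' @param c1,c2 Parent `gep_chromosome`s with identical configuration.
#' @return List of two offspring chromosomes.
#' @export
recombine_one_point <- function(c1, c2) {
  v1 <- chromosome_to_codes(c1); v2 <- chromosome_to_codes(c2)
  L <- length(v1)
  p <- sample.int(L - 1L, 1L)
  o1 <- c(v1[1:p], v2[(p + 1L):L]); o2 <- c(v2[1:p], v1[(p + 1L):L])
  list(rebuild(c1, o1), rebuild(c2, o2))
}

#' Two-point recombination
#' @inheritParams recombine_one_point
#' @return List of two offspring chromosomes.
#' @export
recombine_two_point <- function(c1, c2) {
  v1 <- chromosome_to_codes(c1); v2 <- chromosome_to_codes(c2)
  L <- length(v1)
  pts <- sort(sample.int(L, 2L))
  seg <- pts[1L]:pts[2L]
  o1 <- v1; o2 <- v2
  o1[seg] <- v2[seg]; o2[seg] <- v1[seg]
  list(rebuild(c1, o1), rebuild(c2, o2))
}

#' Whole-gene recombination
#'
#' Exchanges one randomly chosen gene between the parents.
#'
#' @inheritParams recombine_one_point
#' @return List of two offspring chromosomes.
#' @export
recombine_gene <- function(c1, c2) {
  v1 <- chromosome_to_codes(c1); v2 <- chromosome_to_codes(c2)
  glen <- c1$head + tail_length(c1$head)
  g <- sample.int(length(c1$genes), 1L)
  seg <- ((g - 1L) * glen + 1L):(g * glen)
  o1 <- v1; o2 <- v2
  o1[seg] <- v2[seg]; o2[seg] <- v1[seg]
  list(rebuild(c1, o1), rebuild(c2, o2))
}

rebuild <- function(proto, codes)
  codes_to_chromosome(codes, proto$head, proto$n_terminals,
                      length(proto$genes), proto$link)

#' Insertion-sequence (IS) transposition
#'
#' Copies a short random segment of the chromosome and inserts it into a
#' gene head at a position other than the root; the head is truncated back
#' to its fixed length and the tail is untouched.
#'
#' @param chrom A `gep_chromosome`.
#' @param max_len Maximum transposon length (default 3).
#' @return Transposed `gep_chromosome`.
#' @export
transpose_is <- function(chrom, max_len = 3L) {
  h <- chrom$head
  if (h < 2L) return(chrom)
  codes <- chromosome_to_codes(chrom)
  glen <- h + tail_length(h)
  ng <- length(chrom$genes)
  src_start <- sample.int(length(codes), 1L)
  len <- sample.int(min(max_len, length(codes) - src_start + 1L), 1L)
  seg <- codes[src_start:(src_start + len - 1L)]
  gt <- sample.int(ng, 1L)
  off <- (gt - 1L) * glen
  ins <- sample.int(h - 1L, 1L) + 1L      # insertion site in 2..h
  head_old <- codes[off + seq_len(h)]
  head_new <- c(head_old[seq_len(ins - 1L)], seg,
                head_old[ins:h])[seq_len(h)]
  codes[off + seq_len(h)] <- head_new
  rebuild(chrom, codes)
}

#' Root insertion-sequence (RIS) transposition
#'
#' Scans a gene head from a random point for a function symbol; the segment
#' starting there (length at most `max_len`) is copied to the head start, and
#' the head is truncated to length.  Identity when no function is found.
#'
#' @inheritParams transpose_is
#' @return Transposed `gep_chromosome`.
#' @export
transpose_ris <- function(chrom, max_len = 3L) {
  h <- chrom$head
  codes <- chromosome_to_codes(chrom)
  glen <- h + tail_length(h)
  ng <- length(chrom$genes)
  g <- sample.int(ng, 1L)
  off <- (g - 1L) * glen
  head_old <- codes[off + seq_len(h)]
  start <- sample.int(h, 1L)
  fpos <- which(head_old[start:h] <= n_funcs())
  if (length(fpos) == 0L) return(chrom)
  s <- start + fpos[1L] - 1L
  len <- sample.int(min(max_len, h - s + 1L), 1L)
  seg <- head_old[s:(s + len - 1L)]
  codes[off + seq_len(h)] <- c(seg, head_old)[seq_len(h)]
  rebuild(chrom, codes)
}

#' Gene transposition
#'
#' Moves a randomly chosen non-leading gene to the front of the chromosome.
#' Identity for single-gene chromosomes.
#'
#' @param chrom A `gep_chromosome`.
#' @return Transposed `gep_chromosome`.
#' @export
transpose_gene <- function(chrom) {
  ng <- length(chrom$genes)
  if (ng < 2L) return(chrom)
  j <- sample.int(ng - 1L, 1L) + 1L
  chrom$genes <- chrom$genes[c(j, setdiff(seq_len(ng), j))]
  chrom
}

# ---- evolution loop ------------------------------------------------------

#' Evolve a symbolic-regression model by gene expression programming
#'
#' Standard GEP loop: random initial population of Karva chromosomes,
#' expression + fitness evaluation, elite roulette selection, then mutation,
#' transposition (IS, RIS, gene) and recombination (one-point, two-point,
#' gene) at the configured rates.  Elite individuals bypass the operators, so
#' best-so-far fitness is monotone non-decreasing.  Runs are reproducible
#' under `config$seed`.
#'
#' @param X Matrix or data.frame of terminal values; column `j` binds to
#'   terminal `d<j-1>`.
#' @param y Numeric response.
#' @param config A [gep_config()].
#' @return Object of class `gep_result`: `best` chromosome, `best_tree`,
#'   `best_fitness`, `history` (best-so-far fitness per generation),
#'   `predictions` of the best model, `terminal_binding`, `generations_run`,
#'   `config`.
#' @export
gep_evolve <- function(X, y, config = gep_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least two observations")
  if (length(y) != nrow(X)) stop("X and y dimensions disagree")
  nt <- ncol(X)
  run <- function() {
    h <- config$head
    glen <- h + tail_length(h)
    ng <- config$n_genes
    L <- glen * ng
    npop <- config$population
    link_code <- if (config$link == "+") 0L else 1L
    hp <- head_positions(h, glen, ng)
    tp <- tail_positions(h, glen, ng)
    # initial population: head from all symbols, tail from terminals
    pop <- matrix(0L, npop, L)
    pop[, hp] <- sample.int(n_funcs() + nt, npop * length(hp), replace = TRUE)
    pop[, tp] <- n_funcs() + sample.int(nt, npop * length(tp), replace = TRUE)
    best_codes <- NULL; best_fit <- -Inf
    history <- numeric(0)
    gen <- 0L
    while (gen < config$generations) {
      gen <- gen + 1L
      preds <- gep_eval_population(pop, X, GEP_ARITY, h, glen, ng, link_code)
      fit <- apply(preds, 2L, gep_fitness, y = y, spec = config$fitness)
      gb <- which.max(fit)
      if (fit[gb] > best_fit) {
        best_fit <- fit[gb]
        best_codes <- pop[gb, ]
      }
      history[gen] <- best_fit
      if (best_fit >= config$stop_fitness) break
      # selection (elites first), then variation on the non-elite block
      sel <- select_elite_roulette(fit, npop, config$elitism)
      pop <- pop[sel, , drop = FALSE]
      ne <- seq.int(config$elitism + 1L, npop)
      # mutation, vectorised across the non-elite block
      blk <- pop[ne, , drop = FALSE]
      hit <- matrix(stats::runif(length(blk)) < config$p_mutation,
                    nrow(blk), ncol(blk))
      hh <- which(hit[, hp, drop = FALSE])
      if (length(hh) > 0L)
        blk[, hp][hh] <- sample.int(n_funcs() + nt, length(hh), replace = TRUE)
      tt <- which(hit[, tp, drop = FALSE])
      if (length(tt) > 0L)
        blk[, tp][tt] <- n_funcs() + sample.int(nt, length(tt), replace = TRUE)
      pop[ne, ] <- blk
      # transpositions (per-individual)
      for (i in ne) {
        if (stats::runif(1) < config$p_is)
          pop[i, ] <- transpose_is_codes(pop[i, ], h, glen, ng,
                                         config$max_transposon)
        if (stats::runif(1) < config$p_ris)
          pop[i, ] <- transpose_ris_codes(pop[i, ], h, glen, ng,
                                          config$max_transposon)
        if (ng > 1L && stats::runif(1) < config$p_gene_trans)
          pop[i, ] <- transpose_gene_codes(pop[i, ], glen, ng)
      }
      # recombinations (random disjoint pairs among participants)
      pop <- crossover_block(pop, ne, config$p_one_point, function(a, b) {
        p <- sample.int(L - 1L, 1L)
        idx <- (p + 1L):L
        tmp <- a[idx]; a[idx] <- b[idx]; b[idx] <- tmp
        list(a, b)
      })
      pop <- crossover_block(pop, ne, config$p_two_point, function(a, b) {
        pts <- sort(sample.int(L, 2L))
        idx <- pts[1L]:pts[2L]
        tmp <- a[idx]; a[idx] <- b[idx]; b[idx] <- tmp
        list(a, b)
      })
      if (ng > 1L)
        pop <- crossover_block(pop, ne, config$p_gene_recomb, function(a, b) {
          g <- sample.int(ng, 1L)
          idx <- ((g - 1L) * glen + 1L):(g * glen)
          tmp <- a[idx]; a[idx] <- b[idx]; b[idx] <- tmp
          list(a, b)
        })
    }
    best <- codes_to_chromosome(best_codes, h, nt, ng, config$link)
    tree <- decode_karva(best)
    term_names <- if (!is.null(colnames(X))) colnames(X)
                  else gep_terminals(nt)
    dat <- as.data.frame(X)
    names(dat) <- gep_terminals(nt)
    structure(list(best = best, best_tree = tree, best_fitness = best_fit,
                   history = history, predictions = evaluate_tree(tree, dat),
                   terminal_binding = stats::setNames(term_names,
                                                      gep_terminals(nt)),
                   generations_run = gen, config = config),
              class = "gep_result")
  }
  if (!is.null(config$seed)) withr_seed(config$seed, run()) else run()
}

#' @export
print.gep_result <- function(x, ...) {
  cat("<gep_result> fitness ", format(x$best_fitness, digits = 6),
      " after ", x$generations_run, " generation(s)\n", sep = "")
  cat("  model: ", tree_to_infix(x$best_tree), "\n", sep = "")
  invisible(x)
}

# code-level transposition twins of the chromosome-level operators (kept in
# lockstep; the chromosome-level versions delegate to the same layout rules)
transpose_is_codes <- function(codes, h, glen, ng, max_len) {
  if (h < 2L) return(codes)
  src <- sample.int(length(codes), 1L)
  len <- sample.int(min(max_len, length(codes) - src + 1L), 1L)
  seg <- codes[src:(src + len - 1L)]
  off <- (sample.int(ng, 1L) - 1L) * glen
  ins <- sample.int(h - 1L, 1L) + 1L
  head_old <- codes[off + seq_len(h)]
  codes[off + seq_len(h)] <- c(head_old[seq_len(ins - 1L)], seg,
                               head_old[ins:h])[seq_len(h)]
  codes
}

transpose_ris_codes <- function(codes, h, glen, ng, max_len) {
  off <- (sample.int(ng, 1L) - 1L) * glen
  head_old <- codes[off + seq_len(h)]
  start <- sample.int(h, 1L)
  fpos <- which(head_old[start:h] <= n_funcs())
  if (length(fpos) == 0L) return(codes)
  s <- start + fpos[1L] - 1L
  len <- sample.int(min(max_len, h - s + 1L), 1L)
  codes[off + seq_len(h)] <- c(head_old[s:(s + len - 1L)],
                               head_old)[seq_len(h)]
  codes
}

transpose_gene_codes <- function(codes, glen, ng) {
  j <- sample.int(ng - 1L, 1L) + 1L
  ord <- c(j, setdiff(seq_len(ng), j))
  idx <- unlist(lapply(ord, function(g) ((g - 1L) * glen + 1L):(g * glen)))
  codes[idx]
}

crossover_block <- function(pop, ne, p, swap_fun) {
  if (p <= 0 || length(ne) < 2L) return(pop)
  cand <- ne[stats::runif(length(ne)) < p]
  if (length(cand) < 2L) return(pop)
  cand <- sample(cand)
  npair <- length(cand) %/% 2L
  for (k in seq_len(npair)) {
    i <- cand[2L * k - 1L]; j <- cand[2L * k]
    out <- swap_fun(pop[i, ], pop[j, ])
    pop[i, ] <- out[[1L]]; pop[j, ] <- out[[2L]]
  }
  pop
}

# ---- infix parser for printed models -------------------------------------

#' Parse an infix model expression into an expression tree
#'
#' Tokenises over the GEP function set (`+ - * /`, `Inv`, `Cos`, `Tan`),
#' terminals `d0, d1, ...`, numeric constants and parentheses, and parses
#' under the convention that unary functions bind tighter than `*` and `/`,
#' which bind tighter than `+` and `-`; binary operators associate left.
#' Under this convention `Cos d0 * d2` reads as `cos(d0) * d2` and
#' `Cos1/d3/d0` as `(cos(1) / d3) / d0`.
#'
#' @param text Expression text; whitespace is ignored and tokens may be
#'   juxtaposed (e.g. `"Tand0"`).
#' @return A `gep_tree`.
#' @export
parse_model_expression <- function(text) {
  s <- gsub("\\s+", "", text)
  s <- gsub("−", "-", s)   # typographic minus
  toks <- list(); pos <- integer(0)
  i <- 1L
  pats <- c(fun = "^(Inv|Cos|Tan)", term = "^d[0-9]+",
            num = "^[0-9]+\\.?[0-9]*", op = "^[-+*/()]")
  while (i <= nchar(s)) {
    rest <- substr(s, i, nchar(s))
    hit <- NULL
    for (p in pats) {
      m <- regmatches(rest, regexpr(p, rest, ignore.case = TRUE))
      if (length(m) == 1L) { hit <- m; break }
    }
    if (is.null(hit))
      stop("cannot tokenize expression at position ", i, ": '",
           substr(rest, 1, 8), "'")
    if (grepl("^(inv|cos|tan)$", hit, ignore.case = TRUE))
      hit <- paste0(toupper(substr(hit, 1, 1)), tolower(substr(hit, 2, 3)))
    toks[[length(toks) + 1L]] <- hit
    pos[length(pos) + 1L] <- i
    i <- i + nchar(hit)
  }
  toks <- unlist(toks)
  k <- 1L
  peek <- function() if (k <= length(toks)) toks[k] else NA_character_
  eat <- function() { t <- toks[k]; k <<- k + 1L; t }
  fail <- function(msg) stop("parse error near position ",
                             if (k <= length(pos)) pos[k] else nchar(s) + 1L,
                             ": ", msg)
  parse_expr <- function() {
    neg <- FALSE
    if (identical(peek(), "-")) { eat(); neg <- TRUE }
    node <- parse_term()
    if (neg) node <- gep_node("-", list(gep_node("0"), node))
    while (peek() %in% c("+", "-")) {
      op <- eat()
      node <- gep_node(op, list(node, parse_term()))
    }
    node
  }
  parse_term <- function() {
    node <- parse_unary()
    while (peek() %in% c("*", "/")) {
      op <- eat()
      node <- gep_node(op, list(node, parse_unary()))
    }
    node
  }
  parse_unary <- function() {
    t <- peek()
    if (t %in% c("Inv", "Cos", "Tan")) {
      eat()
      return(gep_node(t, list(parse_unary())))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "(") {
      eat()
      node <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      eat()
      return(node)
    }
    if (grepl("^d[0-9]+$", t) || grepl("^[0-9]+\\.?[0-9]*$", t))
      return(gep_node(eat()))
    fail(paste0("unexpected token '", t, "'"))
  }
  out <- parse_expr()
  if (k <= length(toks)) fail(paste0("trailing token '", peek(), "'"))
  out
}

#' The published non-linear (GEP) activity model
#'
#' Ships the printed symbolic model over the terminals d0-d4, parsed under
#' the documented left-associative, function-binds-tighter convention of
#' [parse_model_expression()].  The printed string carries no parentheses,
#' so this reconstruction is one convention among several possible readings;
#' the terminal binding maps d0-d4 to MREB, NN, YZS/YZR, MPCO(ZPC) and MSEC.
#'
#' @return List with `text`, `tree` (a `gep_tree`) and `binding` (named
#'   character vector d0..d4 to descriptor names).
#' @export
gep_published_model <- function() {
  text <- paste0("Cosd0*d2+Tand0+Tand3*d3*d0-d0+d3/Cos1/d3/d0+d3*d3",
                 "+TanTanTanTanCosd4/d1/d2+TanTanTanTanTand0+d0/d2")
  list(text = text,
       tree = parse_model_expression(text),
       binding = c(d0 = "MREB", d1 = "NN", d2 = "YZS_YZR",
                   d3 = "MPCO_ZPC", d4 = "MSEC"))
}
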