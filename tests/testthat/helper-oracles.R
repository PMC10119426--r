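# Independent oracles used throughout the suite.  These are deliberately
# written with different algorithms/styles than the package implementations
# so that agreement is evidence, not tautology.

# ---- naive Karva decoder: returns a nested unnamed list (sym, children) ----
oracle_decode <- function(gene) {
  arity_tbl <- c("+" = 2, "-" = 2, "*" = 2, "/" = 2,
                 Inv = 1, Cos = 1, Tan = 1)
  ar <- function(s) { a <- arity_tbl[s]; if (is.na(a)) 0 else a }
  nodes <- list()
  # pass 1: collect used symbols by simulating the level-order queue
  pending <- 1  # arguments still to fill
  used <- 0
  while (pending > 0) {
    used <- used + 1
    if (used > length(gene)) stop("oracle: gene exhausted")
    pending <- pending - 1 + ar(gene[used])
  }
  # pass 2: recursive build from the flat prefix in level order
  child_of <- vector("list", used)
  nxt <- 2
  for (i in seq_len(used)) {
    k <- ar(gene[i])
    if (k > 0) {
      child_of[[i]] <- nxt:(nxt + k - 1)
      nxt <- nxt + k
    }
  }
  rec <- function(i) {
    kids <- child_of[[i]]
    if (is.null(kids)) list(gene[i])
    else c(list(gene[i]), lapply(kids, rec))
  }
  rec(1)
}

# ---- naive guarded interpreter over the nested-list trees -----------------
oracle_eval <- function(node, env) {
  clip <- function(v) {
    v[v > 1e6] <- 1e6; v[v < -1e6] <- -1e6; v
  }
  s <- node[[1]]
  if (length(node) == 1) {
    if (grepl("^-?[0-9.]+$", s)) return(as.numeric(s))
    return(env[[s]])
  }
  a <- oracle_eval(node[[2]], env)
  if (length(node) == 3) {
    b <- oracle_eval(node[[3]], env)
    v <- switch(s,
                "+" = a + b, "-" = a - b, "*" = a * b,
                "/" = { r <- a / b; r[abs(b) < 1e-12] <- 1e6; r })
    return(clip(v))
  }
  v <- switch(s,
              Inv = { r <- 1 / a; r[abs(a) < 1e-12] <- 1e6; r },
              Cos = cos(a),
              Tan = tan(a))
  clip(v)
}

# convert the package's gep_tree to the oracle's nested-list form
as_oracle_tree <- function(tree) {
  if (is.null(tree$args)) return(list(tree$sym))
  c(list(tree$sym), lapply(tree$args, as_oracle_tree))
}

# ---- OLS through explicit normal equations --------------------------------
oracle_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd) %*% t(Xd) %*% y
  fitted <- drop(Xd %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- nrow(Xd); k <- ncol(Xd) - 1
  s2 <- rss / (n - k - 1)
  se <- sqrt(diag(solve(t(Xd) %*% Xd)) * s2)
  list(beta = drop(beta), fitted = fitted, r2 = 1 - rss / tss, s2 = s2,
       t = drop(beta) / se)
}

# ---- leave-one-out by explicit refits -------------------------------------
oracle_loo_press <- function(X, y, fit_fun, pred_fun) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    m <- fit_fun(X[-i, , drop = FALSE], y[-i])
    press <- press + (y[i] - pred_fun(m, X[i, , drop = FALSE]))^2
  }
  press
}

oracle_loo_r2cv <- function(X, y) {
  press <- oracle_loo_press(
    X, y,
    function(Xi, yi) lm.fit(cbind(1, Xi), yi)$coefficients,
    function(b, xi) drop(cbind(1, xi) %*% b))
  1 - press / sum((y - mean(y))^2)
}

# ---- PLS1 via the Krylov-subspace characterisation ------------------------
# The ncomp-component PLS1 coefficient vector is the least-squares solution
# restricted to the Krylov space span{s, As, ..., A^(a-1) s} with A = Xc'Xc
# and s = Xc'yc — an algebraically different construction from NIPALS.
oracle_pls_coefs <- function(X, y, ncomp) {
  Xc <- scale(as.matrix(X), scale = FALSE)
  yc <- y - mean(y)
  A <- t(Xc) %*% Xc
  s <- drop(t(Xc) %*% yc)
  K <- matrix(0, ncol(Xc), ncomp)
  v <- s
  for (a in seq_len(ncomp)) {
    K[, a] <- v
    v <- drop(A %*% v)
  }
  Q <- qr.Q(qr(K))
  drop(Q %*% solve(t(Q) %*% A %*% Q, t(Q) %*% s))
}

# ---- direct double-loop similarity fields ---------------------------------
oracle_fields <- function(mol, grid, probe, weights) {
  pw <- c(S = 1, E = probe$charge, H = probe$hydrophobic,
          D = probe$donor, A = probe$acceptor)
  out <- matrix(0, nrow(grid$points), 5)
  colnames(out) <- c("S", "E", "H", "D", "A")
  for (q in seq_len(nrow(grid$points))) {
    for (i in seq_len(nrow(mol$coords))) {
      r2 <- sum((grid$points[q, ] - mol$coords[i, ])^2)
      g <- exp(-probe$alpha * r2)
      for (k in 1:5) out[q, k] <- out[q, k] - pw[k] * weights[i, k] * g
    }
  }
  out
}

# ---- Monte-Carlo disc-union area ------------------------------------------
oracle_mc_area <- function(u, v, r, n_samples = 2e5) {
  lo_u <- min(u - r); hi_u <- max(u + r)
  lo_v <- min(v - r); hi_v <- max(v + r)
  pu <- runif(n_samples, lo_u, hi_u)
  pv <- runif(n_samples, lo_v, hi_v)
  inside <- rep(FALSE, n_samples)
  for (i in seq_along(u))
    inside <- inside | ((pu - u[i])^2 + (pv - v[i])^2 <= r[i]^2)
  mean(inside) * (hi_u - lo_u) * (hi_v - lo_v)
}

# ---- random tree generator over the GEP symbol set ------------------------
random_tree <- function(depth, n_terminals = 5) {
  terms <- paste0("d", seq_len(n_terminals) - 1)
  funcs <- c("+", "-", "*", "/", "Inv", "Cos", "Tan")
  arity <- c(2, 2, 2, 2, 1, 1, 1)
  if (depth == 0 || runif(1) < 0.3)
    return(structure(list(sym = sample(terms, 1), args = NULL),
                     class = "gep_tree"))
  k <- sample(length(funcs), 1)
  structure(list(sym = funcs[k],
                 args = lapply(seq_len(arity[k]), function(i)
                   random_tree(depth - 1, n_terminals))),
            class = "gep_tree")
}

# small deterministic test molecule
fixture_molecule <- function(id = "fix1") {
  molecule(id,
           elements = c("C", "N", "O", "H", "C"),
           coords = rbind(c(0, 0, 0), c(1.4, 0.2, -0.3), c(-1.2, 0.9, 0.4),
                          c(0.3, -1.1, 0.8), c(2.5, -0.7, 0.6)),
           charges = c(0.05, -0.3, -0.4, 0.25, 0.4))
}
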