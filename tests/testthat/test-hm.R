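test_that("fit_ols: exact fit, degenerate response, oracle agreement", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y_exact <- 2 * X[, 1] - 3 * X[, 2] + 1
  m <- fit_ols(X, y_exact)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$s2, 0, tolerance = 1e-12)
  expect_equal(unname(m$coefficients), c(2, -3, 0), tolerance = 1e-10)

  expect_warning(m0 <- fit_ols(X, rep(4, 10)), "zero-variance")
  expect_equal(m0$r2, 0)

  X2 <- matrix(rnorm(16), 8, 2)
  y2 <- rnorm(8)
  m2 <- fit_ols(X2, y2)
  orc <- oracle_ols(X2, y2)
  expect_equal(unname(c(m2$intercept, m2$coefficients)), unname(orc$beta),
               tolerance = 1e-10)
  expect_equal(m2$r2, orc$r2, tolerance = 1e-10)
  expect_equal(m2$s2, orc$s2, tolerance = 1e-10)
  expect_equal(unname(m2$t_values), unname(orc$t), tolerance = 1e-10)

  Xdup <- cbind(X2, X2[, 1])
  expect_error(fit_ols(Xdup, y2), "rank-deficient")
})

test_that("fit_ols t-values match the reference implementation", {
  set.seed(2)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 15, 4)
    y <- rnorm(15)
    m <- fit_ols(X, y)
    ref <- summary(lm(y ~ X))$coefficients[, "t value"]
    expect_equal(unname(m$t_values), unname(ref), tolerance = 1e-8)
  }
})

test_that("loo_r2cv equals explicit refits and behaves on noiseless data", {
  set.seed(3)
  X <- matrix(rnorm(100), 50, 2)
  y <- 1 + X[, 1] - 0.5 * X[, 2]
  expect_equal(loo_r2cv(X, y), 1, tolerance = 1e-10)

  for (i in 1:5) {
    Xr <- matrix(rnorm(45), 15, 3)
    yr <- rnorm(15)
    expect_equal(loo_r2cv(Xr, yr), oracle_loo_r2cv(Xr, yr),
                 tolerance = 1e-10)
  }
})

test_that("R2cv never exceeds R2 when y is independent of X", {
  set.seed(4)
  for (i in 1:100) {
    X <- matrix(rnorm(40), 20, 2)
    y <- rnorm(20)
    expect_lte(loo_r2cv(X, y), fit_ols(X, y)$r2)
  }
})

test_that("prefilter drops constant, missing and weak columns", {
  set.seed(5)
  n <- 30
  strong <- rnorm(n)
  y <- 3 * strong + rnorm(n, sd = 0.1)
  X <- cbind(const = rep(2, n), holey = c(NA, rnorm(n - 1)),
             noise = rnorm(n), strong = strong)
  out <- prefilter(X, y, t_min = 1)
  expect_true("strong" %in% colnames(out))
  expect_false(any(c("const", "holey") %in% colnames(out)))
  expect_true(all(c("const", "holey") %in% attr(out, "dropped")))
  expect_error(prefilter(cbind(a = rep(1, n)), y), "every column")
})

test_that("heuristic_search finds a planted noiseless pair exactly", {
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("x", 1:12)))
  y <- 2 * X[, 3] - 3 * X[, 7]
  tr <- heuristic_search(X, y, hm_config(max_size = 2, cap = 0.8))
  expect_setequal(tr$steps[[1]]$descriptors, c("x3", "x7"))
  expect_equal(tr$steps[[1]]$r2, 1, tolerance = 1e-12)
})

test_that("size-2 search equals the exhaustive best pair with cap off", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 25; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", 1:p)
    y <- rnorm(n)
    tr <- heuristic_search(X, y, hm_config(max_size = 2, cap = 1.0))
    best <- NULL; bestr2 <- -Inf
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      r2 <- oracle_ols(X[, c(i, j)], y)$r2
      if (r2 > bestr2) { bestr2 <- r2; best <- c(i, j) }
    }
    expect_setequal(tr$steps[[1]]$columns, best)
    expect_equal(tr$steps[[1]]$r2, bestr2, tolerance = 1e-10)
  }
})

test_that("collinearity cap vetoes duplicated descriptors", {
  set.seed(8)
  n <- 30
  x1 <- rnorm(n)
  X <- cbind(x1 = x1, dup = x1, x3 = rnorm(n), x4 = rnorm(n))
  y <- 2 * x1 + 0.5 * X[, "x3"] + rnorm(n, sd = 0.1)
  tr <- heuristic_search(X, y, hm_config(max_size = 3, cap = 0.8))
  for (st in tr$steps)
    expect_false(all(c("x1", "dup") %in% st$descriptors))
})

test_that("R2 is non-decreasing along the greedy path", {
  set.seed(9)
  gen <- gen_planted_linear(n = 40, p = 15, n_true = 3, seed = 99)
  tr <- heuristic_search(gen$X, gen$y, hm_config(max_size = 6, cap = 0.9))
  r2s <- vapply(tr$steps, `[[`, 0, "r2")
  expect_true(all(diff(r2s) >= -1e-12))
  expect_true(all(vapply(tr$steps, function(s) s$model$s2, 0) >= 0))
})

test_that("correlation_table is symmetric with unit diagonal", {
  set.seed(10)
  X <- matrix(rnorm(100), 20, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  ct <- correlation_table(paste0("x", 1:5), X)
  expect_equal(unname(diag(ct)), rep(1, 5))
  expect_equal(ct, t(ct))
  # textbook Pearson oracle
  pear <- function(a, b) {
    ac <- a - mean(a); bc <- b - mean(b)
    sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
  }
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(ct[i, j], pear(X[, i], X[, j]), tolerance = 1e-12)

  Xd <- cbind(X, x1b = X[, 1])
  ct2 <- correlation_table(c("x1", "x1b"), Xd)
  expect_equal(ct2[1, 2], 1)
  expect_error(correlation_table(c("x1", "zz"), X), "zz")
})

test_that("choose_model_size applies the diminishing-returns rule", {
  fake_trace <- function(r2s, sizes = seq_along(r2s) + 1L) {
    steps <- Map(function(r2, s) list(size = s, r2 = r2), r2s, sizes)
    structure(list(steps = steps, config = hm_config()), class = "hm_trace")
  }
  expect_equal(choose_model_size(fake_trace(c(0.5, 0.8, 0.81), 1:3), 0.05),
               2L)
  expect_equal(choose_model_size(fake_trace(c(0.2, 0.4, 0.6, 0.8), 1:4),
                                 0.05), 4L)
  # trace shaped like the published search: gains flatten after size 5
  r2s <- c(0.45, 0.60, 0.72, 0.80, 0.815, 0.825)   # sizes 2..7
  expect_equal(choose_model_size(fake_trace(r2s, 2:7), 0.02), 5L)
})

test_that("published five-descriptor equation evaluates term by term", {
  expect_identical(hm_published_predict(0, 0, 0, 0, 0), 49.779)
  base <- hm_published_predict(1, 2, 3, 4, 5)
  expect_equal(hm_published_predict(2, 2, 3, 4, 5) - base, -4.0867,
               tolerance = 1e-12)
  # independent term-by-term evaluation
  v <- c(0.3, 4, 0.77, -0.41, 2.2)
  expected <- 49.779 + sum(c(-4.0867, 6.6215e-2, 6.3779, 3.7446,
                             -1.0425e-1) * v)
  expect_equal(hm_published_predict(v[1], v[2], v[3], v[4], v[5]), expected,
               tolerance = 1e-12)
  expect_error(hm_published_predict(NA, 0, 0, 0, 0))
})
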