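rot3 <- function(th) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  Rx %*% Rz
}

test_that("alignment: identity, rotate-recover, error contracts", {
  m <- fixture_molecule("t")
  dup <- m; dup$id <- "same"
  al <- align_to_template(list(m, dup), "t")
  expect_lt(al$rmsd["same"], 1e-10)

  set.seed(21)
  m2 <- m; m2$id <- "moved"
  m2$coords <- m$coords %*% rot3(runif(2, 0, 2 * pi)) +
    matrix(c(3, -1, 2), n_atoms(m), 3, byrow = TRUE)
  al2 <- align_to_template(list(m, m2), "t")
  expect_lt(al2$rmsd["moved"], 1e-8)
  expect_equal(al2$molecules[[2]]$coords, m$coords, tolerance = 1e-8,
               ignore_attr = TRUE)

  map2 <- data.frame(molecule_id = "moved", molecule_atom_index = 1:2,
                     template_atom_index = 1:2)
  expect_error(align_to_template(list(m, m2), "t", map2), ">= 3")
  lin <- molecule("lin", c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  lin2 <- lin; lin2$id <- "lin2"
  expect_error(align_to_template(list(lin, lin2), "lin"), "collinear")
  expect_error(align_to_template(list(m), "nope"), "not among")
})

test_that("build_grid spans the bounding box plus margin", {
  a <- molecule("a", "C", matrix(0, 1, 3))
  g <- build_grid(list(a), spacing = 2, margin = 4)
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(unname(g$origin), c(-4, -4, -4))

  b <- molecule("b", c("C", "C"), rbind(c(0, 0, 0), c(4, 0, 0)))
  g0 <- build_grid(list(b), spacing = 2, margin = 0)
  expect_equal(g0$dims, c(3L, 1L, 1L))
  expect_equal(range(g0$points[, 1]), c(0, 4))

  c2 <- molecule("c", "C", matrix(c(10, 0, 0), 1))
  g2 <- build_grid(list(b, c2), spacing = 2, margin = 0)
  expect_equal(range(g2$points[, 1]), c(0, 10))
  expect_error(build_grid(list(a), spacing = 0), "spacing")
})

test_that("similarity fields match hand values and the naive oracle", {
  probe <- probe_params(alpha = 0.3)
  a <- molecule("a", "C", matrix(0, 1, 3), charges = 0.2)
  g1 <- build_grid(list(a), spacing = 1, margin = 0)  # single point at atom
  w <- matrix(1, 1, 5)
  f <- similarity_fields(a, g1, probe, w)
  expect_equal(unname(f[1, ]), rep(-1, 5), tolerance = 1e-15)

  # hand exponential at r = 2
  b <- molecule("b", "C", matrix(c(2, 0, 0), 1))
  gb <- build_grid(list(molecule("o", "C", matrix(0, 1, 3))),
                   spacing = 1, margin = 0)
  fb <- similarity_fields(b, gb, probe, w)
  expect_equal(unname(fb[1, "S"]), -exp(-1.2), tolerance = 1e-12)

  m <- fixture_molecule()
  gm <- build_grid(list(m), spacing = 2, margin = 3)
  wm <- atom_field_weights(m)
  fm <- similarity_fields(m, gm, probe)
  expect_equal(fm, oracle_fields(m, gm, probe, wm), tolerance = 1e-12)

  wbad <- wm; wbad[2, 3] <- NA
  expect_error(similarity_fields(m, gm, probe, wbad), "atom")
})

test_that("fields are invariant under joint rigid rotation", {
  set.seed(22)
  probe <- probe_params()
  m <- fixture_molecule()
  g <- build_grid(list(m), spacing = 2, margin = 3)
  w <- atom_field_weights(m)
  f0 <- similarity_fields(m, g, probe, w)
  R <- rot3(runif(2, 0, 2 * pi))
  m2 <- m; m2$coords <- m$coords %*% R
  g2 <- g; g2$points <- g$points %*% R
  f1 <- similarity_fields(m2, g2, probe, w)
  expect_equal(f1, f0, tolerance = 1e-10)
})

test_that("PLS: OLS limit, univariate slope, zero X, Krylov oracle", {
  set.seed(23)
  X <- matrix(rnorm(48), 12, 4)
  y <- rnorm(12)
  m <- pls_fit(X, y, 4)
  expect_equal(m$fitted, drop(cbind(1, X) %*% oracle_ols(X, y)$beta),
               tolerance = 1e-8)

  X1 <- matrix(rnorm(12), 12, 1)
  m1 <- pls_fit(X1, y, 1)
  expect_equal(m1$coefficients, cov(X1[, 1], y) / var(X1[, 1]),
               tolerance = 1e-12)

  m0 <- pls_fit(matrix(0, 10, 3), y[1:10], 1)
  expect_equal(m0$fitted, rep(mean(y[1:10]), 10))

  for (i in 1:5) {
    Xr <- matrix(rnorm(20 * 6), 20, 6)
    yr <- rnorm(20)
    nc <- sample(1:3, 1)
    expect_equal(pls_fit(Xr, yr, nc)$coefficients,
                 oracle_pls_coefs(Xr, yr, nc), tolerance = 1e-8)
  }
  expect_error(pls_fit(X, y, 12), "n - 1")
})

test_that("loo_q2 equals brute force and is 1 for noiseless relations", {
  set.seed(24)
  X <- matrix(rnorm(60), 20, 3)
  y <- 2 + X %*% c(1, -2, 0.5)
  expect_equal(loo_q2(X, drop(y), 3), 1, tolerance = 1e-8)

  yr <- rnorm(20)
  for (nc in 1:2) {
    press <- oracle_loo_press(
      X, yr,
      function(Xi, yi) pls_fit(Xi, yi, nc),
      function(m, xi) predict(m, xi))
    expect_equal(loo_q2(X, yr, nc),
                 1 - press / sum((yr - mean(yr))^2), tolerance = 1e-10)
  }
  # mean-only predictions give q2 = 0 by the defining identity
  press_mean <- sum((yr - mean(yr))^2)
  expect_equal(1 - press_mean / sum((yr - mean(yr))^2), 0)
})

test_that("select_onc maximises q2 with small-count tie-break", {
  set.seed(25)
  # two latent factors drive y: ONC should find 2
  hits <- 0
  for (i in 1:10) {
    t1 <- rnorm(24); t2 <- rnorm(24)
    X <- cbind(outer(t1, runif(6)), outer(t2, runif(6))) +
      matrix(rnorm(24 * 12, sd = 0.05), 24)
    y <- t1 - 0.8 * t2 + rnorm(24, sd = 0.05)
    sel <- select_onc(X, y, 5)
    hits <- hits + (sel$onc == 2L)
    expect_equal(sel$q2, max(sel$q2_trace))
  }
  expect_gte(hits, 8)
})

test_that("field contributions: degenerate and random cases", {
  set.seed(26)
  n_pts <- 4
  X <- matrix(rnorm(10 * n_pts * 5), 10)
  attr(X, "field") <- rep(c("S", "E", "H", "D", "A"), each = n_pts)
  y <- rnorm(10)
  m <- pls_fit(X, y, 2)
  contrib <- field_contributions(m, X)
  expect_equal(sum(contrib), 100, tolerance = 1e-9)
  # direct-formula oracle
  w <- abs(m$coefficients * apply(X, 2, sd))
  expected <- 100 * vapply(c("S", "E", "H", "D", "A"), function(f)
    sum(w[attr(X, "field") == f]), 0) / sum(w)
  expect_equal(contrib, expected, tolerance = 1e-12)

  m2 <- m
  m2$coefficients[attr(X, "field") != "S"] <- 0
  c2 <- field_contributions(m2, X)
  expect_equal(unname(c2["S"]), 100)
  m3 <- m
  m3$coefficients[] <- 0
  expect_error(field_contributions(m3, X), "zero")
})

test_that("column_filter masks by standard deviation", {
  set.seed(27)
  X <- cbind(rep(1, 10), rnorm(10), rnorm(10, sd = 0.01))
  expect_equal(column_filter(X, 0), rep(TRUE, 3))
  mask <- column_filter(X, 0.005)
  expect_equal(mask, apply(X, 2, sd) >= 0.005)
  expect_false(mask[1])
  expect_error(column_filter(X, 100), "every column")
})

test_that("contour_masks flag extreme influence points", {
  set.seed(28)
  n_pts <- 10
  X <- matrix(rnorm(12 * n_pts * 5), 12)
  attr(X, "field") <- rep(c("S", "E", "H", "D", "A"), each = n_pts)
  m <- pls_fit(X, rnorm(12), 2)
  masks <- contour_masks(m, X, 80, 20)
  for (f in names(masks)) {
    v <- masks[[f]]$influence
    expect_equal(sum(masks[[f]]$favored),
                 sum(v > quantile(v, 0.8, names = FALSE)))
    expect_equal(sum(masks[[f]]$disfavored),
                 sum(v < quantile(v, 0.2, names = FALSE)))
  }
  # uniform influence: strict inequalities empty both masks
  mu <- m
  mu$coefficients[] <- 0
  masks0 <- contour_masks(mu, X)
  expect_false(any(masks0$S$favored))
  expect_false(any(masks0$S$disfavored))
})

test_that("predict_comsia reproduces fitted values and flags outliers", {
  gen <- gen_toy_molecules(n = 12, seed = 31)
  fit <- comsia_fit(gen$molecules, gen$activities, max_comp = 4)
  p1 <- predict_comsia(fit, gen$molecules[[3]])
  expect_equal(as.numeric(p1), unname(fit$model$fitted[3]),
               tolerance = 1e-10)
  dup <- gen$molecules[[3]]
  dup$id <- "copy"
  expect_equal(as.numeric(predict_comsia(fit, dup)), as.numeric(p1))
  far <- dup
  far$coords[1, ] <- far$coords[1, ] + 100
  expect_warning(pf <- predict_comsia(fit, far), "outside")
  expect_true(attr(pf, "extrapolated")[1])
})

test_that("grid exports are readable and consistent", {
  gen <- gen_toy_molecules(n = 3, seed = 32)
  f <- similarity_fields(gen$molecules[[1]], gen$grid)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(gen$grid, f, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(gen$grid$points))
  expect_equal(back$S, unname(f[, "S"]), tolerance = 1e-6)
  dx <- withr::local_tempfile(fileext = ".dx")
  write_grid_dx(gen$grid, f[, "S"], dx)
  lines <- readLines(dx)
  expect_match(lines[1], "gridpositions counts")
  nums <- as.numeric(unlist(strsplit(
    paste(lines[8:(length(lines) - 1)], collapse = " "), " +")))
  expect_equal(sort(nums), sort(unname(f[, "S"])), tolerance = 1e-6)
})
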