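make_mol <- function(elements, coords = NULL, ...) {
  if (is.null(coords))
    coords <- matrix(seq_len(3 * length(elements)), ncol = 3)
  molecule("m", elements, coords, ...)
}

test_that("count_nitrogens counts exactly the N atoms", {
  methane <- make_mol(c("C", "H", "H", "H", "H"))
  expect_equal(count_nitrogens(methane), 0L)
  pyridine <- make_mol(c("N", rep("C", 5), rep("H", 5)))
  expect_equal(count_nitrogens(pyridine), 1L)
  piperazine <- make_mol(c("N", "C", "C", "N", "C", "C"))
  expect_equal(count_nitrogens(piperazine), 2L)
})

test_that("ee_charges: homonuclear zero, heteronuclear signs, hand value", {
  o2 <- make_mol(c("O", "O"))
  expect_equal(ee_charges(o2)$charges, c(0, 0))

  co <- make_mol(c("C", "O"))   # S_C < S_O so C is positive
  q <- ee_charges(co)$charges
  expect_gt(q[1], 0)
  expect_lt(q[2], 0)

  # hand arithmetic for water with the shipped table
  en <- sanderson_en_table()
  s <- unname(en[c("O", "H", "H")])
  smol <- prod(s)^(1 / 3)
  raw <- (smol - s) / (2.08 * sqrt(s))
  expected <- raw - mean(raw)       # shift to net charge 0
  w <- make_mol(c("O", "H", "H"))
  expect_equal(ee_charges(w)$charges, expected, tolerance = 1e-12)

  expect_error(ee_charges(make_mol(c("C", "Xe"), radii = c(1.7, 2.16))),
               "electronegativity table.*Xe")
})

test_that("ee_charges conserve net charge to 1e-12", {
  set.seed(5)
  els <- names(sanderson_en_table())
  for (i in 1:20) {
    k <- sample(2:12, 1)
    nc <- sample(-1:1, 1)
    m <- molecule("m", sample(els, k, replace = TRUE),
                  matrix(rnorm(3 * k), ncol = 3), net_charge = nc,
                  radii = rep(1.5, k))
    expect_equal(sum(ee_charges(m)$charges), nc, tolerance = 1e-12)
  }
})

test_that("min_o_charge picks the minimum oxygen charge and errors", {
  m <- make_mol(c("O", "C", "O"))
  expect_equal(min_o_charge(c(-0.30, 0.1, -0.42), m), -0.42)
  m1 <- make_mol(c("O", "C"))
  expect_equal(min_o_charge(c(-0.30, 0.3), m1), -0.30)
  expect_error(min_o_charge(c(0.1, 0.2), make_mol(c("C", "H"))),
               "no oxygen")
})

test_that("principal_frame: rod along x, rotate-then-recover, single atom", {
  rod <- molecule("rod", c("C", "C", "C"),
                  rbind(c(-2, 0, 0), c(0, 0, 0), c(2, 0, 0)))
  pf <- suppressWarnings(principal_frame(rod))
  expect_equal(abs(pf$coords[, 1]), c(2, 0, 2), tolerance = 1e-12)
  expect_equal(pf$coords[, 2], rep(0, 3), tolerance = 1e-12)

  set.seed(21)
  m <- fixture_molecule()
  base <- principal_frame(m)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    m2 <- m
    m2$coords <- m$coords %*% (Rx %*% Rz) +
      matrix(rnorm(3), nrow(m$coords), 3, byrow = TRUE)
    expect_equal(principal_frame(m2)$coords, base$coords, tolerance = 1e-8)
  }

  single <- make_mol("C", matrix(c(1, 2, 3), 1))
  expect_warning(out <- principal_frame(single), "single atom")
  expect_equal(unname(out$coords), matrix(0, 1, 3))
})

test_that("shadow: analytic circle, ratio pi/4, disjoint discs, errors", {
  m1 <- suppressWarnings(principal_frame(
    molecule("a", "C", matrix(0, 1, 3))))
  sh <- shadow(m1, "YZ", 0.05)
  expect_equal(sh$shadow_area, pi * 1.7^2, tolerance = 0.01)
  expect_equal(sh$ratio, pi / 4, tolerance = 0.01)

  # two x-separated carbons: projections on YZ coincide, on XY are disjoint
  m2 <- molecule("b", c("C", "C"), rbind(c(-4, 0, 0), c(4, 0, 0)))
  sh2 <- shadow(m2, "XY", 0.05)
  expect_equal(sh2$shadow_area, 2 * pi * 1.7^2, tolerance = 0.01)
  set.seed(31)
  mc <- oracle_mc_area(c(-4, 4), c(0, 0), c(1.7, 1.7))
  expect_equal(sh2$shadow_area, mc, tolerance = 0.02)

  expect_error(shadow(m1, "YZ", 0), "resolution")
})

test_that("shadow area grows with radius and converges in resolution", {
  m <- fixture_molecule()
  pf <- principal_frame(m)
  a0 <- shadow(pf, "YZ", 0.05)$shadow_area
  bigger <- pf
  bigger$radii[2] <- bigger$radii[2] + 0.5
  expect_gt(shadow(bigger, "YZ", 0.05)$shadow_area, a0)
  a_half <- shadow(pf, "YZ", 0.025)$shadow_area
  expect_lt(abs(a_half - a0) / a0, 0.005)
})

test_that("shadow ratio is invariant under rigid pre-rotation", {
  m <- fixture_molecule()
  r0 <- yzs_yzr(m, 0.05)
  set.seed(41)
  th <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  m2 <- m
  m2$coords <- m$coords %*% R
  expect_equal(yzs_yzr(m2, 0.05), r0, tolerance = 0.01)
})

test_that("resonance_energy: trivial, brute-force and symmetry", {
  ri0 <- resonance_input(matrix(0.5, 2, 2), matrix(0, 2, 2),
                         c(1, 2), c("C", "H"))
  expect_equal(resonance_energy(ri0, 1, 2), 0)

  ri1 <- resonance_input(matrix(c(1, 0.5, 0.5, 1), 2),
                         matrix(c(0, -2, -2, 0), 2),
                         c(1, 2), c("C", "H"))
  expect_equal(resonance_energy(ri1, 1, 2), -1.0)

  set.seed(51)
  P <- matrix(rnorm(16), 4); P <- (P + t(P)) / 2
  B <- matrix(rnorm(16), 4); B <- (B + t(B)) / 2
  ri <- resonance_input(P, B, c(1, 1, 2, 2), c("C", "C", "H", "H"))
  brute <- 0
  for (mu in 1:2) for (nu in 3:4) brute <- brute + P[mu, nu] * B[mu, nu]
  expect_equal(resonance_energy(ri, 1, 2), brute, tolerance = 1e-12)
  expect_equal(resonance_energy(ri, 1, 2), resonance_energy(ri, 2, 1),
               tolerance = 1e-12)
  expect_error(resonance_energy(ri, 1, 1), "distinct")
})

test_that("max_ch_resonance equals the exhaustive pairwise maximum", {
  set.seed(61)
  nb <- 8
  P <- matrix(rnorm(nb^2), nb); P <- (P + t(P)) / 2
  B <- matrix(rnorm(nb^2), nb); B <- (B + t(B)) / 2
  atoms <- c(1, 1, 2, 3, 3, 4, 5, 5)
  els <- c("C", "C", "H", "C", "C", "H", "N", "N")
  ri <- resonance_input(P, B, atoms, els)
  vals <- c()
  for (a in c(1, 3)) for (b in c(2, 4))
    vals <- c(vals, resonance_energy(ri, a, b))
  expect_equal(max_ch_resonance(ri), max(vals), tolerance = 1e-12)

  ri_noh <- resonance_input(P, B, atoms, rep("C", nb))
  expect_error(max_ch_resonance(ri_noh), "no C-H")
})

test_that("assemble_matrix merges computed and provided columns", {
  mols <- list(
    molecule("c1", c("C", "O", "N"), matrix(rnorm(9), 3)),
    molecule("c2", c("C", "O", "H"), matrix(rnorm(9), 3)),
    molecule("c3", c("N", "O", "C"), matrix(rnorm(9), 3)))
  df <- assemble_matrix(mols)
  expect_equal(nrow(df), 3L)
  expect_named(df, c("compound_id", "NN", "MPCO_ZPC", "YZS_YZR"))
  expect_equal(df$NN, c(1L, 0L, 1L))
  expect_equal(unname(attr(df, "provenance")["NN"]), "computed")

  prov <- data.frame(compound_id = c("c1", "c2", "c3"),
                     MREB = c(1.1, 1.2, 1.3))
  df2 <- assemble_matrix(mols, prov)
  expect_equal(ncol(df2), 5L)
  expect_equal(unname(attr(df2, "provenance")["MREB"]), "provided")

  bad <- data.frame(compound_id = c("c1", "c2"), MREB = c(1, 2))
  expect_error(assemble_matrix(mols, bad), "c3")
})

test_that("descriptor CSV export carries provenance comments", {
  mols <- list(molecule("c1", c("C", "O", "N"), matrix(rnorm(9), 3)))
  df <- assemble_matrix(mols)
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(df, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# provenance", lines)))
  back <- read.csv(f, comment.char = "#")
  expect_equal(back$YZS_YZR, df$YZS_YZR, tolerance = 1e-12)
})
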