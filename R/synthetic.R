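#' Generate a descriptor matrix with a planted sparse linear signal
#'
#' Emulates the statistical situation the stepwise heuristic search faces:
#' a small number of truly active descriptors hidden among many mutually
#' correlated nuisance columns.  Nuisance correlation is induced by a single
#' shared latent factor (`x_j = sqrt(rho) z + sqrt(1-rho) e_j`), giving
#' pairwise correlation `rho`; the true columns are drawn independently.
#' The response is the planted linear combination plus Gaussian noise.
#'
#' @param n Compounds (default 40, the usual training-set size).
#' @param p Descriptors (default 100).
#' @param n_true Number of truly active descriptors (default 5).
#' @param true_idx Optional indices of the true columns (default: random).
#' @param coefs Optional true coefficients (default: magnitudes 0.5-2 with
#'   random signs).
#' @param intercept True intercept (default 0).
#' @param rho Pairwise nuisance correlation (default 0.3).
#' @param noise_sd Noise standard deviation; with `noise_relative = TRUE`
#'   (default) it is interpreted as a fraction of the noise-free signal's
#'   standard deviation (default 0.1).
#' @param noise_relative Interpret `noise_sd` relative to `sd(signal)`.
#' @param seed Integer seed.
#' @return List: `X` (n x p, columns `x1..xp`), `y`, `true_idx`, `coefs`,
#'   `intercept`, `noise_sd_absolute`, `seed`.
#' @export
gen_planted_linear <- function(n = 40L, p = 100L, n_true = 5L,
                               true_idx = NULL, coefs = NULL, intercept = 0,
                               rho = 0.3, noise_sd = 0.1,
                               noise_relative = TRUE, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  withr_seed(seed, {
    if (is.null(true_idx)) true_idx <- sort(sample.int(p, n_true))
    true_idx <- as.integer(true_idx)
    if (length(true_idx) != n_true || any(true_idx < 1L | true_idx > p))
      stop("true_idx must be n_true valid column indices")
    if (is.null(coefs))
      coefs <- stats::runif(n_true, 0.5, 2) *
        sample(c(-1, 1), n_true, replace = TRUE)
    z <- stats::rnorm(n)
    X <- sqrt(rho) * z + sqrt(1 - rho) *
      matrix(stats::rnorm(n * p), n, p)
    X[, true_idx] <- matrix(stats::rnorm(n * n_true), n, n_true)
    colnames(X) <- paste0("x", seq_len(p))
    signal <- intercept + drop(X[, true_idx, drop = FALSE] %*% coefs)
    sd_abs <- if (noise_relative) noise_sd * stats::sd(signal) else noise_sd
    y <- signal + stats::rnorm(n, sd = sd_abs)
    list(X = X, y = y, true_idx = true_idx, coefs = coefs,
         intercept = intercept, noise_sd_absolute = sd_abs,
         seed = as.integer(seed))
  })
}

#' Generate a symbolic-regression dataset from a target expression
#'
#' Terminals are sampled uniformly within per-terminal ranges and the target
#' expression (over the GEP function set) is evaluated with the guarded
#' interpreter; Gaussian noise is added on top.  If any sampled point lands
#' in a guarded singular region (saturated value), generation aborts with a
#' suggestion to change the ranges, so noiseless datasets are exactly
#' reproducible by re-evaluating the returned tree.
#'
#' @param expression Target expression text (see
#'   [parse_model_expression()]), default `"d0*d1+Cos(d2)"`.
#' @param n Observations (default 50).
#' @param n_terminals Terminals d0.. (default 5; unused terminals become
#'   nuisance inputs).
#' @param ranges 2 x n_terminals matrix of lower/upper sampling bounds, or a
#'   length-2 vector recycled to all terminals (default `c(0.1, 2)`).
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return List: `X` (columns d0..), `y`, `tree` (ground truth),
#'   `expression`, `seed`.
#' @export
gen_symbolic <- function(expression = "d0*d1+Cos(d2)", n = 50L,
                         n_terminals = 5L, ranges = c(0.1, 2),
                         noise_sd = 0, seed = 1L) {
  tree <- parse_model_expression(expression)
  if (is.null(dim(ranges)))
    ranges <- matrix(rep(as.numeric(ranges), n_terminals), nrow = 2L)
  if (nrow(ranges) != 2L || ncol(ranges) != n_terminals)
    stop("ranges must be a 2 x n_terminals matrix")
  withr_seed(seed, {
    X <- vapply(seq_len(n_terminals), function(j)
      stats::runif(n, ranges[1L, j], ranges[2L, j]), numeric(n))
    colnames(X) <- gep_terminals(n_terminals)
    y0 <- evaluate_tree(tree, as.data.frame(X))
    if (any(abs(y0) >= GEP_CLAMP))
      stop("target expression hits a guarded singularity inside the ",
           "sampling ranges; choose ranges that avoid zero denominators ",
           "and tangent poles")
    y <- y0 + if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
    list(X = X, y = y, tree = tree, expression = expression,
         seed = as.integer(seed))
  })
}

# fixed scaffold shared by every toy molecule: a planar 6-ring of carbons
# with one para oxygen, hard-coded so no chemistry toolkit is needed
toy_scaffold <- function() {
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  coords <- rbind(ring, c(2.9, 0, 0))
  list(elements = c(rep("C", 6L), "O"), coords = coords,
       charges = c(rep(0.02, 6L), -0.35),
       sub_site = c(-2.6, 0, 0))
}

#' Generate aligned toy molecules with field-generated activities
#'
#' All molecules share a hard-coded rigid scaffold (perfect alignment by
#' construction) and differ only in one substituent atom whose van der
#' Waals radius and partial charge vary.  Activities are a fixed linear
#' functional of the molecules' true steric and electrostatic similarity
#' fields sampled at a few lattice points near the substituent, plus
#' optional Gaussian noise — so a CoMSIA refit can be checked against known
#' ground truth.
#'
#' @param n Number of molecules (default 20).
#' @param radius_range,charge_range Uniform sampling ranges for the
#'   substituent radius (Angstrom) and charge (default 1.2-2.2 and
#'   -0.5-0.5).
#' @param noise_sd Additive noise on the activities (default 0).
#' @param spacing,margin Lattice geometry used for the generating fields.
#' @param probe Probe parameters for the generating fields.
#' @param seed Integer seed.
#' @return List: `molecules`, `activities`, `grid`, `gen_points` (lattice
#'   indices used), `gen_weights` (named list with `S` and `E` weight
#'   vectors), `seed`.
#' @export
gen_toy_molecules <- function(n = 20L, radius_range = c(1.2, 2.2),
                              charge_range = c(-0.5, 0.5), noise_sd = 0,
                              spacing = 2, margin = 4,
                              probe = probe_params(), seed = 1L) {
  sc <- toy_scaffold()
  withr_seed(seed, {
    radii <- stats::runif(n, radius_range[1L], radius_range[2L])
    charges <- stats::runif(n, charge_range[1L], charge_range[2L])
    mols <- lapply(seq_len(n), function(i) {
      molecule(paste0("toy", i),
               elements = c(sc$elements, "C"),
               coords = rbind(sc$coords, sc$sub_site),
               charges = c(sc$charges, charges[i]),
               radii = c(vdw_radii_table()[sc$elements], radii[i]))
    })
    grid <- build_grid(mols, spacing, margin)
    # generating functional: S and E field values at the 3 lattice points
    # closest to the substituent site
    d2 <- rowSums(sweep(grid$points, 2L, sc$sub_site)^2)
    pts <- order(d2)[1:3]
    w_s <- c(2.0, -1.0, 0.5)
    w_e <- c(-1.5, 1.0, 0.8)
    acts <- vapply(mols, function(m) {
      f <- similarity_fields(m, grid, probe)
      sum(w_s * f[pts, "S"]) + sum(w_e * f[pts, "E"])
    }, 0)
    if (noise_sd > 0) acts <- acts + stats::rnorm(n, sd = noise_sd)
    names(acts) <- vapply(mols, function(m) m$id, "")
    list(molecules = mols, activities = acts, grid = grid,
         gen_points = pts, gen_weights = list(S = w_s, E = w_e),
         seed = as.integer(seed))
  })
}

#' The packaged 50-compound activity table
#'
#' IC50 values (micromolar) of the 50 VEGFR3 inhibitors used throughout the
#' package examples, with the 2D-QSAR test-set membership flags and the
#' transformed activity column.  The 3D-QSAR test-set flags (`test_3d`) are
#' `NA`: that annotation is typographic (underlining) in the original table
#' and is not recoverable from the available text, so the fixture takes no
#' position.
#'
#' @return data.frame: `compound_id`, `ic50_uM`, `test_2d`, `test_3d`,
#'   `activity`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_activity.csv", package = "qsarflow",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric", "logical",
                                       "logical"))
  df$activity <- transform_activity(df$ic50_uM)
  df
}
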