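#' Rigid alignment of molecules onto a template
#'
#' Least-squares (Kabsch) superposition: each molecule is rotated and
#' translated so that its mapped atoms best match the corresponding atoms of
#' the template's common substructure.  The template itself is returned
#' unchanged.
#'
#' @param molecules List of [molecule()] objects.
#' @param template_id Id of the template molecule (must be in `molecules`).
#' @param mapping data.frame with columns `molecule_id`,
#'   `molecule_atom_index`, `template_atom_index`; every non-template
#'   molecule needs at least 3 non-collinear mapped atoms.  Molecules whose
#'   atom order matches the template may omit the mapping (identity map).
#' @return List with `molecules` (aligned) and `rmsd` (named numeric vector
#'   of mapped-atom RMSD in Angstrom).
#' @export
align_to_template <- function(molecules, template_id, mapping = NULL) {
  ids <- vapply(molecules, function(m) m$id, "")
  ti <- match(as.character(template_id), ids)
  if (is.na(ti)) stop("template '", template_id, "' not among the molecules")
  tmpl <- molecules[[ti]]
  rmsd <- stats::setNames(numeric(length(molecules)), ids)
  for (k in seq_along(molecules)) {
    if (k == ti) next
    mol <- molecules[[k]]
    if (is.null(mapping)) {
      if (n_atoms(mol) != n_atoms(tmpl))
        stop("no mapping given and atom counts differ for '", mol$id, "'")
      mi <- seq_len(n_atoms(mol)); tix <- mi
    } else {
      rows <- mapping[mapping$molecule_id == mol$id, , drop = FALSE]
      mi <- rows$molecule_atom_index; tix <- rows$template_atom_index
    }
    if (length(mi) < 3L)
      stop("alignment of '", mol$id, "' needs >= 3 mapped atoms")
    A <- mol$coords[mi, , drop = FALSE]
    B <- tmpl$coords[tix, , drop = FALSE]
    if (collinear_points(B) || collinear_points(A))
      stop("mapped atoms of '", mol$id, "' are collinear; frame undefined")
    fit <- kabsch(A, B)
    molecules[[k]]$coords <- sweep(mol$coords, 2L, fit$cent_a) %*% fit$R +
      matrix(fit$cent_b, n_atoms(mol), 3L, byrow = TRUE)
    moved <- molecules[[k]]$coords[mi, , drop = FALSE]
    rmsd[k] <- sqrt(mean(rowSums((moved - B)^2)))
  }
  list(molecules = molecules, rmsd = rmsd)
}

collinear_points <- function(P) {
  if (nrow(P) < 3L) return(TRUE)
  Pc <- sweep(P, 2L, colMeans(P))
  sv <- svd(Pc)$d
  sv[2L] < 1e-8 * max(sv[1L], 1e-300)
}

# optimal rotation R (right-multiplied) mapping centred A onto centred B
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, cent_a = ca, cent_b = cb)
}

#' Build an empty field lattice around aligned molecules
#'
#' Axis-aligned rectangular grid covering the union bounding box of the
#' atom centres plus `margin` on every side, at the given spacing.
#'
#' @param molecules List of aligned [molecule()] objects.
#' @param spacing Grid spacing in Angstrom (default 2, the usual CoMSIA
#'   lattice).
#' @param margin Extra space beyond the bounding box on each side (default
#'   4 Angstrom).
#' @return Object of class `field_grid`: `origin`, `spacing`, `dims` (points
#'   per axis) and `points` (n_points x 3 coordinate matrix, x fastest).
#' @export
build_grid <- function(molecules, spacing = 2, margin = 4) {
  if (length(molecules) < 1L) stop("need at least one molecule")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (margin < 0) stop("margin must be >= 0")
  all_xyz <- do.call(rbind, lapply(molecules, function(m) m$coords))
  lo <- apply(all_xyz, 2L, min) - margin
  hi <- apply(all_xyz, 2L, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L)
  axes <- lapply(1:3, function(a) lo[a] + spacing * (seq_len(dims[a]) - 1L))
  pts <- as.matrix(expand.grid(x = axes[[1L]], y = axes[[2L]],
                               z = axes[[3L]]))
  structure(list(origin = lo, spacing = spacing, dims = dims, points = pts),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat("<field_grid> ", paste(x$dims, collapse = " x "), " points, spacing ",
      x$spacing, " A, origin (", paste(round(x$origin, 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' CoMSIA probe parameters
#'
#' @param alpha Gaussian attenuation factor in 1/Angstrom^2 (default 0.3,
#'   the conventional CoMSIA choice).
#' @param charge Probe charge in elementary units (default +1).
#' @param radius Probe radius in Angstrom (default 1).
#' @param hydrophobic,donor,acceptor Probe property weights (default +1).
#' @return List of class `probe_params`.
#' @export
probe_params <- function(alpha = 0.3, charge = 1, radius = 1,
                         hydrophobic = 1, donor = 1, acceptor = 1) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  structure(list(alpha = alpha, charge = charge, radius = radius,
                 hydrophobic = hydrophobic, donor = donor,
                 acceptor = acceptor),
            class = "probe_params")
}

FIELD_NAMES <- c("S", "E", "H", "D", "A")

#' Per-atom physico-chemical weights for the five similarity fields
#'
#' Steric weight is the cubed van der Waals radius, electrostatic weight the
#' partial charge (from the molecule, or computed by [ee_charges()] when
#' absent), and hydrophobic/donor/acceptor weights come from the shipped
#' element table [atom_type_weights()].
#'
#' @param mol A [molecule()].
#' @param type_table Atom-type weight table (see [atom_type_weights()]).
#' @return Numeric matrix n_atoms x 5 with columns S, E, H, D, A.
#' @export
atom_field_weights <- function(mol, type_table = atom_type_weights()) {
  q <- mol$charges
  if (is.null(q)) q <- ee_charges(mol)$charges
  idx <- match(mol$elements, type_table$element)
  hyd <- ifelse(is.na(idx), 0, type_table$hydrophobic[idx])
  don <- ifelse(is.na(idx), 0, type_table$donor[idx])
  acc <- ifelse(is.na(idx), 0, type_table$acceptor[idx])
  w <- cbind(S = mol$radii^3, E = q, H = hyd, D = don, A = acc)
  rownames(w) <- NULL
  w
}

#' Gaussian similarity-index fields of one molecule
#'
#' CoMSIA similarity index at lattice point q for property k:
#' `A_k(q) = - sum_i w_probe_k * w_ik * exp(-alpha * r_iq^2)`,
#' a distance-dependent Gaussian that avoids the singularities of
#' Lennard-Jones/Coulomb fields at the atom positions.
#'
#' @param mol An aligned [molecule()].
#' @param grid A [build_grid()] lattice.
#' @param probe A [probe_params()].
#' @param weights Optional n_atoms x 5 weight matrix (default
#'   [atom_field_weights()]); missing (NA) weights raise an error naming the
#'   atom.
#' @return Numeric matrix n_points x 5, columns S, E, H, D, A.
#' @export
similarity_fields <- function(mol, grid, probe = probe_params(),
                              weights = NULL) {
  stopifnot(inherits(grid, "field_grid"))
  if (is.null(weights)) weights <- atom_field_weights(mol)
  weights <- as.matrix(weights)
  if (nrow(weights) != n_atoms(mol) || ncol(weights) != 5L)
    stop("weights must be an n_atoms x 5 matrix")
  if (anyNA(weights))
    stop("missing field weight for atom(s) ",
         paste(which(rowSums(is.na(weights)) > 0), collapse = ", "))
  probe_w <- c(S = 1, E = probe$charge, H = probe$hydrophobic,
               D = probe$donor, A = probe$acceptor)
  # n_points x n_atoms squared-distance Gaussian kernel
  P <- grid$points
  d2 <- outer(rowSums(P^2), rowSums(mol$coords^2), `+`) -
    2 * P %*% t(mol$coords)
  K <- exp(-probe$alpha * d2)
  out <- -K %*% weights
  out <- sweep(out, 2L, probe_w, `*`)
  colnames(out) <- FIELD_NAMES
  out
}

#' Flatten per-molecule fields into a PLS data block
#'
#' @param molecules List of aligned molecules.
#' @param grid A [build_grid()] lattice.
#' @param probe A [probe_params()].
#' @param weights Optional list of per-molecule weight matrices.
#' @return Numeric matrix n_molecules x (n_points * 5); the `field` and
#'   `point` attributes give each column's field label and lattice index.
#' @export
field_block <- function(molecules, grid, probe = probe_params(),
                        weights = NULL) {
  n_pts <- nrow(grid$points)
  X <- matrix(0, length(molecules), n_pts * 5L)
  for (k in seq_along(molecules)) {
    w <- if (is.null(weights)) NULL else weights[[k]]
    X[k, ] <- as.vector(similarity_fields(molecules[[k]], grid, probe, w))
  }
  rownames(X) <- vapply(molecules, function(m) m$id, "")
  attr(X, "field") <- rep(FIELD_NAMES, each = n_pts)
  attr(X, "point") <- rep(seq_len(n_pts), times = 5L)
  X
}

#' Minimum-sigma column filter
#'
#' Drops field columns whose standard deviation across molecules falls below
#' the threshold, the usual variance pre-filter applied before PLS.
#'
#' @param X Field block (molecules x columns).
#' @param sigma_threshold Minimum column standard deviation (default 0 =
#'   keep everything with any variance when > 0; exactly 0 keeps all).
#' @return Logical mask of retained columns.
#' @export
column_filter <- function(X, sigma_threshold = 0) {
  sds <- apply(X, 2L, stats::sd)
  mask <- sds >= sigma_threshold
  if (!any(mask)) stop("column filter removed every column")
  mask
}

#' Partial least squares regression (univariate response)
#'
#' NIPALS latent-variable extraction with X deflation: components maximise
#' the covariance of X scores with y, and the coefficient vector is mapped
#' back to the original (centred) columns.  Statistics follow 3D-QSAR
#' conventions: `SEE = sqrt(RSS / (n - ncomp - 1))` and
#' `F = (r2/ncomp) / ((1 - r2)/(n - ncomp - 1))`.
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector.
#' @param ncomp Number of latent components (>= 1, <= n - 1).
#' @return Object of class `pls_model`: `coefficients` (p), `intercept`,
#'   `x_means`, `fitted`, `r2`, `see`, `f`, `ncomp`, plus the `field` /
#'   `point` column attributes when present on `X`.
#' @export
pls_fit <- function(X, y, ncomp) {
  fld <- attr(X, "field"); pt <- attr(X, "point")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1")
  if (ncomp > n - 1L) stop("ncomp must be <= n - 1")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); Pl <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); b <- numeric(ncomp)
  Xd <- Xc
  actual <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break            # X exhausted or orthogonal to y
    w <- w / wn
    t_sc <- Xd %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    pl <- crossprod(Xd, t_sc) / tt
    b_a <- sum(t_sc * yc) / tt
    W[, a] <- w; Pl[, a] <- pl; Tm[, a] <- t_sc; b[a] <- b_a
    Xd <- Xd - t_sc %*% t(pl)
    actual <- a
  }
  if (actual == 0L) {
    coefs <- numeric(p)
  } else {
    W <- W[, seq_len(actual), drop = FALSE]
    Pl <- Pl[, seq_len(actual), drop = FALSE]
    b <- b[seq_len(actual)]
    # R = W (P'W)^-1 maps X-space to scores
    coefs <- drop(W %*% solve(t(Pl) %*% W, b))
  }
  fitted <- drop(Xc %*% coefs) + ym
  rss <- sum((y - fitted)^2)
  tss <- sum(yc^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  dof <- n - ncomp - 1L
  see <- if (dof > 0) sqrt(rss / dof) else NA_real_
  f <- if (dof > 0 && r2 < 1) (r2 / ncomp) / ((1 - r2) / dof)
       else if (dof > 0) Inf else NA_real_
  structure(list(coefficients = coefs, intercept = ym, x_means = xm,
                 fitted = fitted, r2 = r2, see = see, f = f,
                 ncomp = ncomp, ncomp_used = actual,
                 field = fld, point = pt),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$ncomp, " component(s), r2 = ",
      format(x$r2, digits = 4), ", SEE = ", format(x$see, digits = 4),
      ", F = ", format(x$f, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Predict from a PLS model
#' @param object A `pls_model`.
#' @param newdata Matrix with the model's columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2L, object$x_means)
  drop(Xc %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validated q-squared
#'
#' `q2 = 1 - PRESS/TSS` where PRESS accumulates squared prediction errors
#' from n refits, each leaving one molecule out, at a fixed number of
#' components.
#'
#' @inheritParams pls_fit
#' @return Numeric q2 (at most 1; negative means worse than the mean).
#' @export
loo_q2 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 observations for leave-one-out")
  if (ncomp > n - 2L) stop("ncomp too large for leave-one-out refits")
  press <- 0
  for (i in seq_len(n)) {
    m <- pls_fit(X[-i, , drop = FALSE], y[-i], ncomp)
    press <- press + (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero-variance response")
  1 - press / tss
}

#' Select the optimal number of PLS components
#'
#' ONC = the component count maximising leave-one-out q2, ties resolved in
#' favour of the smaller count.
#'
#' @inheritParams pls_fit
#' @param max_comp Largest component count tried.
#' @return List with `onc`, `q2` (at ONC) and the full `q2_trace`.
#' @export
select_onc <- function(X, y, max_comp) {
  max_comp <- min(as.integer(max_comp), nrow(X) - 2L)
  if (max_comp < 1L) stop("max_comp must be >= 1")
  q2s <- vapply(seq_len(max_comp), function(a) loo_q2(X, y, a), 0)
  onc <- which.max(q2s)               # which.max takes the first maximum
  list(onc = as.integer(onc), q2 = q2s[onc], q2_trace = q2s)
}

#' Relative field contributions of a PLS model
#'
#' Each field's share of `sum_j |coef_j * sd(column_j)|`, normalised to
#' percentages — the standard decomposition reported for CoMSIA models.
#'
#' @param model A fitted `pls_model` (with field column labels).
#' @param X The field block the model was fitted on.
#' @return Named numeric vector of percentages over S, E, H, D, A (sums to
#'   100).
#' @export
field_contributions <- function(model, X) {
  fld <- model$field
  if (is.null(fld)) fld <- attr(X, "field")
  if (is.null(fld)) stop("no field labels available for the columns")
  w <- abs(model$coefficients * apply(as.matrix(X), 2L, stats::sd))
  if (sum(w) == 0) stop("all coefficients are zero; contributions undefined")
  shares <- vapply(FIELD_NAMES, function(f) sum(w[fld == f]), 0)
  100 * shares / sum(shares)
}

#' Favoured / disfavoured contour masks
#'
#' For each field, ranks lattice points by their `coef * sd` influence and
#' flags points strictly above the favoured percentile and strictly below
#' the disfavoured percentile — the data behind the classic green/yellow
#' (etc.) CoMSIA contour plots.
#'
#' @param model A fitted `pls_model` with field/point labels.
#' @param X The field block.
#' @param favored_pct,disfavored_pct Percentiles in (0, 100); defaults 80
#'   and 20.
#' @return Named list per field with logical `favored` / `disfavored`
#'   vectors over lattice points and the underlying `influence` values.
#' @export
contour_masks <- function(model, X, favored_pct = 80, disfavored_pct = 20) {
  fld <- model$field
  if (is.null(fld)) stop("model carries no field labels")
  infl <- model$coefficients * apply(as.matrix(X), 2L, stats::sd)
  out <- list()
  for (f in FIELD_NAMES) {
    v <- infl[fld == f]
    if (length(v) == 0L) stop("empty field: ", f)
    hi <- stats::quantile(v, favored_pct / 100, names = FALSE)
    lo <- stats::quantile(v, disfavored_pct / 100, names = FALSE)
    out[[f]] <- list(favored = v > hi, disfavored = v < lo, influence = v)
  }
  out
}

#' Fit a CoMSIA model end to end
#'
#' Aligns the molecules to the template, builds the lattice, computes the
#' five similarity-index fields, filters low-variance columns, selects the
#' component count by leave-one-out q2 and fits the final PLS model.
#'
#' @param molecules List of [molecule()] objects.
#' @param activities Named numeric vector (names = compound ids) or vector
#'   in molecule order.
#' @param template_id Template compound id (skip alignment with `NULL` if
#'   the molecules are already aligned).
#' @param mapping Atom correspondence table (see [align_to_template()]).
#' @param spacing,margin Lattice geometry (Angstrom).
#' @param probe A [probe_params()].
#' @param max_comp Largest PLS component count tried (default 10).
#' @param sigma_threshold Column filter threshold (default 0 = off).
#' @return Object of class `comsia_model` bundling the grid, probe, PLS
#'   model, q2/ONC, field contributions and the training ids.
#' @export
comsia_fit <- function(molecules, activities, template_id = NULL,
                       mapping = NULL, spacing = 2, margin = 4,
                       probe = probe_params(), max_comp = 10L,
                       sigma_threshold = 0) {
  ids <- vapply(molecules, function(m) m$id, "")
  y <- if (!is.null(names(activities))) as.numeric(activities[ids])
       else as.numeric(activities)
  if (anyNA(y)) stop("activities missing for some molecules")
  if (!is.null(template_id)) {
    al <- align_to_template(molecules, template_id, mapping)
    molecules <- al$molecules
  }
  grid <- build_grid(molecules, spacing, margin)
  X <- field_block(molecules, grid, probe)
  mask <- column_filter(X, sigma_threshold)
  Xf <- X[, mask, drop = FALSE]
  attr(Xf, "field") <- attr(X, "field")[mask]
  attr(Xf, "point") <- attr(X, "point")[mask]
  sel <- select_onc(Xf, y, max_comp)
  model <- pls_fit(Xf, y, sel$onc)
  structure(list(grid = grid, probe = probe, mask = mask, model = model,
                 q2 = sel$q2, onc = sel$onc, q2_trace = sel$q2_trace,
                 contributions = field_contributions(model, Xf),
                 ids = ids, activities = y,
                 template_id = template_id),
            class = "comsia_model")
}

#' @export
print.comsia_model <- function(x, ...) {
  cat("<comsia_model> q2 = ", format(x$q2, digits = 4), ", ONC = ", x$onc,
      ", r2 = ", format(x$model$r2, digits = 4), ", SEE = ",
      format(x$model$see, digits = 4), ", F = ",
      format(x$model$f, digits = 5), "\n  contributions (%): ",
      paste(names(x$contributions),
            sprintf("%.1f", x$contributions), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Predict activity of an aligned molecule with a CoMSIA model
#'
#' The molecule must already sit in the model's template frame.  Its fields
#' are computed on the stored lattice, the training column filter applied,
#' and the PLS scoring function evaluated.  Molecules reaching outside the
#' lattice are scored anyway but flagged as extrapolations.
#'
#' @param model A `comsia_model`.
#' @param mol An aligned [molecule()] (or list of molecules).
#' @param weights Optional per-molecule weight matrix (see
#'   [similarity_fields()]).
#' @return Numeric predictions; attribute `extrapolated` marks molecules
#'   outside the lattice.
#' @export
predict_comsia <- function(model, mol, weights = NULL) {
  mols <- if (inherits(mol, "molecule")) list(mol) else mol
  lo <- model$grid$origin
  hi <- lo + (model$grid$dims - 1L) * model$grid$spacing
  extra <- vapply(mols, function(m)
    any(sweep(m$coords, 2L, lo) < 0) || any(sweep(m$coords, 2L, hi) > 0),
    TRUE)
  if (any(extra))
    warning("molecule(s) outside the lattice: ",
            paste(vapply(mols[extra], function(m) m$id, ""), collapse = ", "),
            " (extrapolating)")
  wl <- if (is.null(weights)) NULL
        else if (is.list(weights)) weights else list(weights)
  X <- field_block(mols, model$grid, model$probe, wl)
  preds <- predict(model$model, X[, model$mask, drop = FALSE])
  attr(preds, "extrapolated") <- extra
  preds
}

#' Export a field lattice as a flat CSV table
#'
#' One row per lattice point: `point_index,x,y,z,S,E,H,D,A`.
#'
#' @param grid A [build_grid()] lattice.
#' @param fields n_points x 5 field matrix (e.g. [similarity_fields()]).
#' @param path Output CSV path.
#' @export
write_grid_csv <- function(grid, fields, path) {
  df <- data.frame(point_index = seq_len(nrow(grid$points)),
                   grid$points, fields)
  names(df) <- c("point_index", "x", "y", "z", FIELD_NAMES)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export one scalar field as an OpenDX grid file
#'
#' Minimal OpenDX "regularpositions / regularconnections" scalar export,
#' readable by the usual molecular-graphics tools.
#'
#' @param grid A [build_grid()] lattice.
#' @param values Numeric vector over lattice points (x fastest, as produced
#'   by [similarity_fields()]).
#' @param path Output file path.
#' @export
write_grid_dx <- function(grid, values, path) {
  d <- grid$dims
  if (length(values) != prod(d)) stop("value count does not match lattice")
  # OpenDX wants z fastest; our lattice stores x fastest
  idx <- expand.grid(z = seq_len(d[3]), y = seq_len(d[2]),
                     x = seq_len(d[1]))
  lin <- (idx$z - 1L) * d[1] * d[2] + (idx$y - 1L) * d[1] + idx$x
  out <- values[lin]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(out))), con)
  writeLines(apply(matrix(c(out, rep(NA, (3 - length(out) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1L,
                   function(r) paste(stats::na.omit(r), collapse = " ")),
             con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
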