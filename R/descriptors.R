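#' Count nitrogen atoms
#'
#' Constitutional descriptor NN: the number of N atoms in the structure.
#' More nitrogens typically mean more NO2/NH2-type groups capable of
#' hydrogen bonding to the target.
#'
#' @param mol A [molecule()].
#' @return Integer count.
#' @export
count_nitrogens <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sum(mol$elements == "N")
}

#' Electronegativity-equalization partial charges
#'
#' One-shot Sanderson equalization: with S_A the atomic Sanderson
#' electronegativity and S_mol the geometric mean over all atoms, the raw
#' charge is `q_A = (S_mol - S_A) / (2.08 * sqrt(S_A))`.  A uniform per-atom
#' shift is then applied so the charges sum exactly to the molecular net
#' charge (the one-shot formula does not conserve charge by itself).
#'
#' @param mol A [molecule()].
#' @param en_table Named electronegativity lookup, default
#'   [sanderson_en_table()].
#' @return Object of class `partial_charge_set`: list with `charges` (one per
#'   atom) and `q_min_O` (minimum charge over oxygen atoms, `NA` if the
#'   molecule has no oxygen).
#' @export
ee_charges <- function(mol, en_table = sanderson_en_table()) {
  stopifnot(inherits(mol, "molecule"))
  s <- unname(en_table[mol$elements])
  if (anyNA(s)) {
    bad <- unique(mol$elements[is.na(s)])
    stop("element(s) missing from the electronegativity table: ",
         paste(bad, collapse = ", "))
  }
  s_mol <- exp(mean(log(s)))
  q <- (s_mol - s) / (2.08 * sqrt(s))
  q <- q + (mol$net_charge - sum(q)) / length(q)
  is_o <- mol$elements == "O"
  structure(list(charges = q,
                 q_min_O = if (any(is_o)) min(q[is_o]) else NA_real_),
            class = "partial_charge_set")
}

#' Minimum partial charge over oxygen atoms (MPCO)
#'
#' The electrostatic descriptor Qmin = min over O atoms of the partial
#' charge.  Undefined (error) for oxygen-free structures.
#'
#' @param charges A `partial_charge_set` from [ee_charges()], or a bare
#'   numeric vector of per-atom charges.
#' @param mol The [molecule()] the charges belong to.
#' @return Minimum O charge (elementary-charge units).
#' @export
min_o_charge <- function(charges, mol) {
  stopifnot(inherits(mol, "molecule"))
  q <- if (inherits(charges, "partial_charge_set")) charges$charges
       else as.numeric(charges)
  if (length(q) != n_atoms(mol))
    stop("charge vector length does not match atom count")
  is_o <- mol$elements == "O"
  if (!any(is_o))
    stop("MPCO undefined: molecule '", mol$id, "' contains no oxygen atom")
  min(q[is_o])
}

#' Rotate a molecule into its principal frame
#'
#' Centres the coordinates on the centroid and rotates onto the principal
#' axes of the atomic coordinate spread, ordered by descending extent.  The
#' sign of each axis is fixed so that the atom farthest from the centroid has
#' non-negative coordinates (ties broken by atom index), which makes the
#' frame deterministic up to degenerate symmetry.
#'
#' @param mol A [molecule()].
#' @return The molecule with rotated coordinates.
#' @export
principal_frame <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  xyz <- mol$coords
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2L, ctr)
  if (n == 1L) {
    warning("single atom: principal frame is the identity")
    mol$coords <- xyz
    return(mol)
  }
  cv <- crossprod(xyz) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] < 1e-12 * max(eg$values[1L], 1e-300))
    warning("near-collinear atom set: principal frame is not unique")
  rot <- xyz %*% eg$vectors   # columns already ordered by descending eigenvalue
  # sign convention: farthest atom from centroid gets non-negative coordinates
  d2 <- rowSums(xyz^2)
  far <- which(d2 == max(d2))[1L]
  flip <- ifelse(rot[far, ] < 0, -1, 1)
  mol$coords <- sweep(rot, 2L, flip, `*`)
  colnames(mol$coords) <- c("x", "y", "z")
  mol
}

#' Shadow projection of the van der Waals surface
#'
#' Projects every atom as a disc (centre = projected coordinates, radius =
#' van der Waals radius) onto one of the three principal planes and measures
#' the area of the disc union by rasterisation at the given resolution.  The
#' enclosing rectangle spans the projected extents including the radii, so
#' the shadow/rectangle ratio lies in (0, 1].  The molecule should already be
#' in its principal frame (see [principal_frame()]); the classic shadow-ratio
#' descriptor YZS/YZR is the `"YZ"` plane ratio.
#'
#' @param mol A [molecule()], normally output of [principal_frame()].
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @param resolution Raster pixel size in Angstrom (default 0.05).
#' @return Object of class `shadow_result`: list with `plane`, `shadow_area`,
#'   `rectangle_area` (both Angstrom^2) and `ratio`.
#' @export
shadow <- function(mol, plane = c("YZ", "XY", "XZ"), resolution = 0.05) {
  stopifnot(inherits(mol, "molecule"))
  plane <- match.arg(plane)
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be > 0")
  ax <- switch(plane, XY = c(1L, 2L), XZ = c(1L, 3L), YZ = c(2L, 3L))
  u <- mol$coords[, ax[1L]]
  v <- mol$coords[, ax[2L]]
  r <- mol$radii
  lo_u <- min(u - r); hi_u <- max(u + r)
  lo_v <- min(v - r); hi_v <- max(v + r)
  rect <- (hi_u - lo_u) * (hi_v - lo_v)
  # pixel centres over the enclosing rectangle
  gu <- seq(lo_u + resolution / 2, hi_u, by = resolution)
  gv <- seq(lo_v + resolution / 2, hi_v, by = resolution)
  covered <- shadow_raster(gu, gv, u, v, r)
  area <- sum(covered) * resolution^2
  structure(list(plane = plane, shadow_area = area, rectangle_area = rect,
                 ratio = area / rect),
            class = "shadow_result")
}

# mark raster pixels covered by any disc; loops atoms, vectorized per atom
shadow_raster <- function(gu, gv, u, v, r) {
  covered <- matrix(FALSE, length(gu), length(gv))
  for (i in seq_along(u)) {
    iu <- which(abs(gu - u[i]) <= r[i])
    iv <- which(abs(gv - v[i]) <= r[i])
    if (length(iu) == 0L || length(iv) == 0L) next
    du2 <- (gu[iu] - u[i])^2
    dv2 <- (gv[iv] - v[i])^2
    covered[iu, iv] <- covered[iu, iv] | (outer(du2, dv2, `+`) <= r[i]^2)
  }
  covered
}

#' Shadow-ratio descriptor on the second/third principal axes (YZS/YZR)
#'
#' Convenience wrapper: principal-frame rotation followed by the YZ-plane
#' [shadow()] ratio.  With axes ordered by extent this is the molecular
#' cross-section perpendicular to the longest axis.
#'
#' @inheritParams shadow
#' @return Numeric shadow/rectangle ratio in (0, 1].
#' @export
yzs_yzr <- function(mol, resolution = 0.05) {
  sh <- shadow(principal_frame(mol), "YZ", resolution)
  sh$ratio
}

#' Resonance-energy contraction over two atoms
#'
#' Computes `E_R(A,B) = sum_{mu in A} sum_{nu in B} P_mu_nu * beta_mu_nu`,
#' the contraction of semi-empirical density-matrix elements with resonance
#' integrals over the basis functions owned by two atoms.  The wavefunction
#' matrices are supplied by the user (e.g. exported from a semi-empirical
#' code); see [resonance_input()].
#'
#' @param input A [resonance_input()].
#' @param atom_a,atom_b Distinct atom indices.
#' @return Energy in the units of `beta`.
#' @export
resonance_energy <- function(input, atom_a, atom_b) {
  stopifnot(inherits(input, "resonance_input"))
  if (atom_a == atom_b) stop("atoms must be distinct")
  mu <- which(input$basis_atom == atom_a)
  nu <- which(input$basis_atom == atom_b)
  if (length(mu) == 0L || length(nu) == 0L)
    stop("each atom must own at least one basis function")
  sum(input$P[mu, nu, drop = FALSE] * input$beta[mu, nu, drop = FALSE])
}

#' Bundle density matrix, resonance integrals and basis map
#'
#' @param P Symmetric numeric matrix of density-matrix elements over the
#'   atomic basis.
#' @param beta Numeric matrix of resonance integrals, same shape as `P`.
#' @param basis_atom Integer vector: owning atom index for each basis
#'   function.
#' @param basis_element Character vector: element symbol of the owning atom
#'   for each basis function.
#' @return Object of class `resonance_input`.
#' @export
resonance_input <- function(P, beta, basis_atom, basis_element) {
  P <- as.matrix(P); beta <- as.matrix(beta)
  if (!all(dim(P) == dim(beta)) || nrow(P) != ncol(P))
    stop("P and beta must be square matrices of identical shape")
  nb <- nrow(P)
  basis_atom <- as.integer(basis_atom)
  basis_element <- as.character(basis_element)
  if (length(basis_atom) != nb || length(basis_element) != nb)
    stop("every basis index must be mapped to an atom and element")
  if (anyNA(basis_atom) || anyNA(basis_element))
    stop("basis map contains unmapped entries")
  structure(list(P = P, beta = beta, basis_atom = basis_atom,
                 basis_element = basis_element),
            class = "resonance_input")
}

#' Read a resonance-energy input from plain-text files
#'
#' @param p_path,beta_path Whitespace-delimited square matrices.
#' @param map_path CSV `basis_index,atom_index,element`.
#' @return A [resonance_input()].
#' @export
read_resonance_input <- function(p_path, beta_path, map_path) {
  P <- as.matrix(utils::read.table(p_path))
  beta <- as.matrix(utils::read.table(beta_path))
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  req <- c("basis_index", "atom_index", "element")
  if (!all(req %in% names(map)))
    stop("basis map CSV must have columns: ", paste(req, collapse = ", "))
  map <- map[order(map$basis_index), ]
  if (!identical(map$basis_index, seq_len(nrow(P))))
    stop("basis map must cover basis indices 1..", nrow(P))
  resonance_input(P, beta, map$atom_index, map$element)
}

#' Maximum C-H bond resonance energy (MREB)
#'
#' The maximum of [resonance_energy()] over all carbon-hydrogen atom pairs.
#'
#' @param input A [resonance_input()].
#' @return MREB in the units of `beta`.
#' @export
max_ch_resonance <- function(input) {
  stopifnot(inherits(input, "resonance_input"))
  el_by_atom <- tapply(input$basis_element, input$basis_atom,
                       function(e) e[1L])
  atoms <- as.integer(names(el_by_atom))
  c_atoms <- atoms[el_by_atom == "C"]
  h_atoms <- atoms[el_by_atom == "H"]
  if (length(c_atoms) == 0L || length(h_atoms) == 0L)
    stop("MREB undefined: no C-H atom pair in the basis map")
  best <- -Inf
  for (a in c_atoms) for (b in h_atoms)
    best <- max(best, resonance_energy(input, a, b))
  best
}

#' Assemble a descriptor matrix
#'
#' Computes the locally available descriptors (NN nitrogen count, MPCO
#' minimum oxygen charge, YZS/YZR shadow ratio) for each molecule and merges
#' user-provided descriptor columns (e.g. quantum descriptors MREB, MSEC
#' exported from external software) by compound id.  Column provenance
#' (`computed` vs `provided`) is recorded in the `provenance` attribute.
#'
#' @param molecules List of [molecule()] objects.
#' @param provided Optional data.frame with `compound_id` plus descriptor
#'   columns, or a CSV path.
#' @param resolution Shadow raster resolution (Angstrom).
#' @return data.frame: `compound_id` plus descriptor columns, with attribute
#'   `provenance` (named character vector).
#' @export
assemble_matrix <- function(molecules, provided = NULL, resolution = 0.05) {
  stopifnot(length(molecules) >= 1L)
  ids <- vapply(molecules, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("duplicate molecule ids")
  nn <- vapply(molecules, count_nitrogens, 0L)
  mpco <- vapply(molecules, function(m) {
    cs <- ee_charges(m)
    if (is.na(cs$q_min_O)) NA_real_ else cs$q_min_O
  }, 0)
  yz <- vapply(molecules, yzs_yzr, 0, resolution = resolution)
  df <- data.frame(compound_id = ids, NN = nn, MPCO_ZPC = mpco,
                   YZS_YZR = yz, stringsAsFactors = FALSE)
  prov <- c(NN = "computed", MPCO_ZPC = "computed", YZS_YZR = "computed")
  if (!is.null(provided)) {
    if (is.character(provided))
      provided <- utils::read.csv(provided, comment.char = "#",
                                  stringsAsFactors = FALSE)
    if (is.null(provided$compound_id))
      stop("provided descriptor table must have a compound_id column")
    provided$compound_id <- as.character(provided$compound_id)
    orphan <- setdiff(ids, provided$compound_id)
    if (length(orphan) > 0L)
      stop("compound(s) missing from provided descriptors: ",
           paste(orphan, collapse = ", "))
    extra <- setdiff(names(provided), "compound_id")
    clash <- intersect(extra, names(df))
    if (length(clash) > 0L)
      stop("provided column(s) clash with computed columns: ",
           paste(clash, collapse = ", "))
    df <- merge(df, provided, by = "compound_id", sort = FALSE)
    df <- df[match(ids, df$compound_id), ]
    rownames(df) <- NULL
    prov <- c(prov, stats::setNames(rep("provided", length(extra)), extra))
  }
  attr(df, "provenance") <- prov
  df
}

#' Write a descriptor matrix with provenance header comments
#' @param df Output of [assemble_matrix()].
#' @param path CSV path.
#' @export
write_descriptor_csv <- function(df, path) {
  prov <- attr(df, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov))
    writeLines(paste0("# provenance: ", names(prov), " = ", prov), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
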