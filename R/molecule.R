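#' Bondi-style van der Waals radii (Angstrom)
#'
#' Default atomic radii used for shadow projections, steric field weights and
#' radius assignment when a structure file carries no radii.  Values follow the
#' Bondi compilation with the common extensions for main-group elements; any
#' entry can be overridden per call via the `radii` arguments of the consuming
#' functions.
#'
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
vdw_radii_table <- function() {
  c(H = 1.20, He = 1.40,
    Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
    F = 1.47, Ne = 1.54,
    Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80,
    Cl = 1.75, Ar = 1.88,
    K = 2.75, Ca = 2.31, Zn = 1.39, Ga = 1.87, Ge = 2.11, As = 1.85,
    Se = 1.90, Br = 1.85, Kr = 2.02,
    Rb = 3.03, Sr = 2.49, Cd = 1.58, In = 1.93, Sn = 2.17, Sb = 2.06,
    Te = 2.06, I = 1.98, Xe = 2.16)
}

#' Sanderson electronegativities
#'
#' Atomic electronegativities on the Sanderson scale, used by the one-shot
#' electronegativity-equalization partial charge scheme ([ee_charges()]).
#'
#' @return Named numeric vector, element symbol to Sanderson electronegativity.
#' @export
sanderson_en_table <- function() {
  c(H = 2.592, Li = 0.670, Be = 1.810, B = 2.275, C = 2.746, N = 3.194,
    O = 3.654, F = 4.000, Na = 0.560, Mg = 1.318, Al = 1.714, Si = 2.138,
    P = 2.515, S = 2.957, Cl = 3.475, K = 0.445, Ca = 0.946, Zn = 2.223,
    Ga = 2.419, Ge = 2.618, As = 2.816, Se = 3.014, Br = 3.219, Rb = 0.312,
    Sr = 0.721, I = 2.778, Sn = 2.298)
}

#' Construct a molecule
#'
#' The unit every descriptor and field operation consumes: a set of atoms with
#' element symbols, 3D coordinates, van der Waals radii and (optionally)
#' partial charges.
#'
#' @param id Compound identifier (coerced to character).
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param charges Optional numeric vector of partial charges (elementary
#'   charge units), or `NULL`.
#' @param net_charge Integer net molecular charge (default 0).
#' @param radii Optional numeric vector of per-atom van der Waals radii; when
#'   `NULL`, radii are looked up in `radius_table`.
#' @param radius_table Named vector mapping element to radius, default
#'   [vdw_radii_table()].
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule("mol1", c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)))
#' n_atoms(m)
#' @export
molecule <- function(id, elements, coords, charges = NULL, net_charge = 0L,
                     radii = NULL, radius_table = vdw_radii_table()) {
  elements <- as.character(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) < 1L) stop("molecule must contain at least one atom")
  if (nrow(coords) != length(elements))
    stop("coords must have one row per element")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(radii)) {
    radii <- unname(radius_table[elements])
    if (anyNA(radii)) {
      bad <- unique(elements[is.na(radii)])
      stop("unknown element(s) with no van der Waals radius: ",
           paste(bad, collapse = ", "))
    }
  } else {
    radii <- as.numeric(radii)
    if (length(radii) != length(elements))
      stop("radii must have one entry per atom")
  }
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("van der Waals radii must be positive and finite")
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != length(elements))
      stop("charges must have one entry per atom")
  }
  colnames(coords) <- c("x", "y", "z")
  structure(list(id = as.character(id), elements = elements, coords = coords,
                 radii = radii, charges = charges,
                 net_charge = as.integer(net_charge)),
            class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  length(mol$elements)
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, ": ", length(x$elements), " atoms (",
      paste(utils::head(x$elements, 8L), collapse = " "),
      if (length(x$elements) > 8L) " ..." else "", "), net charge ",
      x$net_charge, "\n", sep = "")
  invisible(x)
}

#' Element-based CoMSIA atom-type weights
#'
#' A small, documented table of hydrophobic, hydrogen-bond donor and acceptor
#' atom weights keyed on the element symbol.  The parameterisation is
#' deliberately coarse (no connectivity perception): carbon and sulfur carry
#' hydrophobic weight, nitrogen and oxygen carry donor/acceptor weight,
#' halogens act as weak acceptors.  Elements absent from the table default to
#' zero in all three properties.
#'
#' @return data.frame with columns `element`, `hydrophobic`, `donor`,
#'   `acceptor`.
#' @export
atom_type_weights <- function() {
  data.frame(
    element     = c("C", "S", "N", "O", "F", "Cl", "Br", "I", "H", "P"),
    hydrophobic = c(1.0, 0.6, 0.0, 0.0, 0.3, 0.5, 0.5, 0.5, 0.0, 0.2),
    donor       = c(0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    acceptor    = c(0.0, 0.3, 0.5, 1.0, 0.3, 0.2, 0.2, 0.2, 0.0, 0.3),
    stringsAsFactors = FALSE)
}
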