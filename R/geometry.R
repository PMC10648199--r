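#' Fixed peptide backbone geometry
#'
#' Bond lengths, bond angles and the peptide-bond torsion used when a backbone
#' is rebuilt from dihedral angles.  All bond lengths and bond angles are held
#' fixed, so a fragment's conformation is fully determined by its phi/psi
#' series.  Defaults are the standard trans-peptide values.
#'
#' @param n_ca,ca_c,c_n bond lengths in Angstrom (N-Calpha, Calpha-C, C-N).
#' @param n_ca_c,ca_c_n,c_n_ca bond angles in degrees.
#' @param omega peptide-bond dihedral in degrees (180 = trans).
#' @return an object of class `pb_geometry` (a named list).
#' @examples
#' backbone_geometry()
#' @export
backbone_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                              n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
                              omega = 180) {
  g <- list(n_ca = n_ca, ca_c = ca_c, c_n = c_n,
            n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca,
            omega = omega)
  if (any(unlist(g[1:6]) <= 0)) abort("bond lengths and angles must be positive")
  structure(g, class = "pb_geometry")
}

# place atom D given A, B, C so that |C-D| = bond, angle(B,C,D) = angle and
# dihedral(A,B,C,D) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build an L-residue N/CA/C backbone from per-residue phi/psi (degrees).
# phi[1] and psi[L] do not influence any atom and may be NA.
# Returns a 3L x 3 coordinate matrix, atoms ordered N, CA, C per residue.
nerf_chain <- function(phi, psi, geometry = backbone_geometry()) {
  L <- length(phi)
  if (length(psi) != L) abort("phi and psi must have equal length")
  if (L < 1) abort("need at least one residue")
  g <- geometry
  X <- matrix(0, 3 * L, 3)
  X[2, ] <- c(g$n_ca, 0, 0)
  th <- g$n_ca_c * pi / 180
  X[3, ] <- X[2, ] + c(-g$ca_c * cos(th), g$ca_c * sin(th), 0)
  if (L == 1) return(X)
  # torsions for atoms 4..3L cycle through psi_{i-1}, omega, phi_i
  lens <- rep(c(g$c_n, g$n_ca, g$ca_c), L - 1)
  angs <- rep(c(g$ca_c_n, g$c_n_ca, g$n_ca_c), L - 1)
  tors <- as.vector(rbind(psi[-L], g$omega, phi[-1]))
  for (i in 4:(3 * L)) {
    k <- i - 3
    X[i, ] <- place_atom(X[i - 3, ], X[i - 2, ], X[i - 1, ], lens[k], angs[k], tors[k])
  }
  X
}

#' Build a five-residue backbone fragment from its dihedral series
#'
#' A pentapeptide block is defined by the eight dihedral angles
#' psi1, phi2, psi2, phi3, psi3, phi4, psi4, phi5 (the terminal phi1 and psi5
#' do not affect the 15 N/Calpha/C atoms).  With bond lengths and angles fixed
#' by `geometry`, these angles determine the fragment up to a rigid motion.
#'
#' @param dihedrals numeric vector of 8 angles in degrees, ordered
#'   psi1, phi2, psi2, phi3, psi3, phi4, psi4, phi5; each in (-180, 180].
#' @param geometry a [backbone_geometry()] object.
#' @return a tibble with columns `res` (1-5), `atom` (N/CA/C), `x`, `y`, `z`.
#' @examples
#' helix <- build_backbone(rep(c(-47, -57), 4))
#' backbone_dihedrals(helix)
#' @export
build_backbone <- function(dihedrals, geometry = backbone_geometry()) {
  if (length(dihedrals) != 8) abort("expected 8 dihedral angles (psi1, phi2, ..., phi5)")
  if (any(!is.finite(dihedrals)) || any(dihedrals <= -180 - 1e-9) || any(dihedrals > 180 + 1e-9)) {
    abort("dihedral angles must be finite and in (-180, 180]")
  }
  psi <- c(dihedrals[c(1, 3, 5, 7)], NA)
  phi <- c(NA, dihedrals[c(2, 4, 6, 8)])
  X <- nerf_chain(phi, psi, geometry)
  tibble(
    res = rep(1:5, each = 3),
    atom = rep(c("N", "CA", "C"), 5),
    x = X[, 1], y = X[, 2], z = X[, 3]
  )
}

#' Back-compute the dihedral series of a backbone fragment
#'
#' Inverse of [build_backbone()]: given 15 backbone atoms (N, CA, C per
#' residue, chain order) returns the eight dihedrals
#' psi1, phi2, psi2, phi3, psi3, phi4, psi4, phi5 in degrees.
#'
#' @param coords a 15 x 3 coordinate matrix or the tibble returned by
#'   [build_backbone()].
#' @return named numeric vector of 8 angles in (-180, 180].
#' @export
backbone_dihedrals <- function(coords) {
  X <- as_coord_matrix(coords)
  if (nrow(X) != 15) abort("expected 15 backbone atoms (5 residues x N/CA/C)")
  # torsion of every consecutive atom quadruple: psi1, omega1, phi2, psi2, ...
  tors <- vapply(seq_len(12), function(k) {
    dihedral4(X[k, ], X[k + 1, ], X[k + 2, ], X[k + 3, ])
  }, numeric(1))
  out <- wrap_angle(tors[-seq(2, 12, by = 3)])
  names(out) <- c("psi1", "phi2", "psi2", "phi3", "psi3", "phi4", "psi4", "phi5")
  out
}

# full (2L - 2)-angle series psi_1, phi_2, psi_2, ..., psi_{L-1}, phi_L for an
# L-residue backbone matrix (3L x 3)
chain_dihedrals <- function(X) {
  L <- nrow(X) / 3
  tors <- vapply(seq_len(3 * L - 3), function(k) {
    dihedral4(X[k, ], X[k + 1, ], X[k + 2, ], X[k + 3, ])
  }, numeric(1))
  wrap_angle(tors[-seq(2, length(tors), by = 3)])
}
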