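# Torsion-angle chain building: sequential internal-to-Cartesian placement
# (natural extension reference frame), used directly by the torsion-angle
# polypeptide builder and to derive each helix class's reference geometry.

#' Default backbone bond geometry
#'
#' Standard peptide bond lengths (Å) and angles (degrees) used whenever a
#' builder is not given explicit values: N-CA 1.47, CA-C 1.53, C-N 1.33,
#' C=O 1.24; N-CA-C 110, CA-C-N 114, C-N-CA 121, CA-C-O 121 (the carbonyl
#' oxygen lies in the peptide plane, anti to the next amide nitrogen).
#'
#' @return A `BondGeometry` list.
#' @export
default_bond_geometry <- function() {
  structure(list(n_ca = 1.47, ca_c = 1.53, c_n = 1.33, c_o = 1.24,
                 n_ca_c = 110, ca_c_n = 114, c_n_ca = 121, ca_c_o = 121),
            class = "BondGeometry")
}

validate_bond_geometry <- function(geom) {
  lens <- unlist(geom[c("n_ca", "ca_c", "c_n", "c_o")])
  angs <- unlist(geom[c("n_ca_c", "ca_c_n", "c_n_ca", "ca_c_o")])
  if (length(lens) != 4 || length(angs) != 4 || anyNA(c(lens, angs))) {
    stop("bond geometry must supply lengths n_ca, ca_c, c_n, c_o and ",
         "angles n_ca_c, ca_c_n, c_n_ca, ca_c_o")
  }
  if (any(lens <= 0.8 | lens >= 2.0)) {
    stop("bond lengths must lie in (0.8, 2.0) Å")
  }
  if (any(angs <= 90 | angs >= 140)) {
    stop("bond angles must lie in (90, 140) degrees")
  }
  invisible(geom)
}

#' Place an atom from internal coordinates
#'
#' Given the three previously placed atoms A, B, C, places atom D such that
#' |C-D| = `length`, the B-C-D angle is `angle` and the A-B-C-D torsion is
#' `torsion` (degrees, IUPAC sign convention).
#'
#' @param a,b,c 3-vectors of the three reference atoms.
#' @param length bond length C-D in Å.
#' @param angle bond angle B-C-D in degrees.
#' @param torsion dihedral A-B-C-D in degrees.
#' @return 3-vector position of D.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- angle * pi / 180
  ta <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("cannot place atom: reference atoms are collinear")
  n <- n / nn
  m <- cross3(n, bc)
  c + length * (-cos(th) * bc + sin(th) * cos(ta) * m + sin(th) * sin(ta) * n)
}

#' Build a polypeptide backbone from torsion angles
#'
#' Constructs a glycine backbone atom-by-atom by sequential
#' internal-to-Cartesian placement. Residue i is described by the triple
#' (phi_i, psi_i, omega_i); phi of the first residue and omega of the last
#' are not used (they would require atoms outside the chain). Measured
#' torsions of the output reproduce the inputs.
#'
#' @param torsions data.frame or list of rows with fields `phi`, `psi`,
#'   `omega` in degrees, each in (-180, 180]; one row per residue, >= 2 rows.
#'   A single triple may be given together with `n_res` to repeat it.
#' @param geom a `BondGeometry`; default [default_bond_geometry()].
#' @param n_res optional: repeat a single torsion triple this many times.
#' @return A single-chain glycine `Assembly` (chain "A").
#' @export
build_ta_polypeptide <- function(torsions, geom = default_bond_geometry(),
                                 n_res = NULL) {
  tor <- as.data.frame(torsions)
  if (!is.null(n_res)) {
    if (nrow(tor) != 1) stop("n_res repetition requires a single triple")
    tor <- tor[rep(1, n_res), , drop = FALSE]
  }
  if (!all(c("phi", "psi", "omega") %in% names(tor))) {
    stop("torsions must have fields phi, psi, omega")
  }
  n <- nrow(tor)
  if (n < 2) stop("at least 2 torsion triples are required")
  if (any(abs(c(tor$phi, tor$psi, tor$omega)) > 180)) {
    stop("torsion angles must lie in (-180, 180] degrees")
  }
  validate_bond_geometry(geom)
  xyz <- matrix(0, 4 * n, 3)
  rowN <- function(i) 4L * (i - 1L) + 1L
  # seed the first residue in the xy-plane
  xyz[1, ] <- c(0, 0, 0)                      # N1
  xyz[2, ] <- c(geom$n_ca, 0, 0)              # CA1
  ang <- geom$n_ca_c * pi / 180
  xyz[3, ] <- xyz[2, ] + geom$ca_c * c(-cos(ang), sin(ang), 0)  # C1
  for (i in seq_len(n)) {
    iN <- rowN(i)
    if (i < n) {
      xyz[iN + 4L, ] <- place_atom(xyz[iN, ], xyz[iN + 1L, ], xyz[iN + 2L, ],
                                   geom$c_n, geom$ca_c_n, tor$psi[i])
      xyz[iN + 5L, ] <- place_atom(xyz[iN + 1L, ], xyz[iN + 2L, ],
                                   xyz[iN + 4L, ],
                                   geom$n_ca, geom$c_n_ca, tor$omega[i])
      xyz[iN + 6L, ] <- place_atom(xyz[iN + 2L, ], xyz[iN + 4L, ],
                                   xyz[iN + 5L, ],
                                   geom$ca_c, geom$n_ca_c, tor$phi[i + 1])
    }
    # carbonyl oxygen: in the peptide plane, anti to the next N
    xyz[iN + 3L, ] <- place_atom(xyz[iN, ], xyz[iN + 1L, ], xyz[iN + 2L, ],
                                 geom$c_o, geom$ca_c_o, tor$psi[i] + 180)
  }
  new_assembly(glycine_atom_table("A", n), xyz, id = "ta_polypeptide")
}

#' Measure backbone torsions of a chain
#'
#' @param chain a backbone-complete `Polymer` or single-chain `Assembly`.
#' @return data.frame with columns `phi`, `psi`, `omega` (degrees), one row
#'   per residue; entries that would need atoms beyond the chain ends are
#'   `NA` (phi of the first residue, psi/omega of the last).
#' @export
measure_torsions <- function(chain) {
  bb <- backbone_coords(chain)
  n <- nrow(bb) / 4L
  N <- bb[seq(1, by = 4, length.out = n), , drop = FALSE]
  CA <- bb[seq(2, by = 4, length.out = n), , drop = FALSE]
  C <- bb[seq(3, by = 4, length.out = n), , drop = FALSE]
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) phi[i] <- dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n) {
      psi[i] <- dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      omega[i] <- dihedral(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}
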