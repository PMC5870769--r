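# Helix classes and the path-following (Crick-style) helix builders.
#
# A helix class is defined by its canonical backbone torsions plus the
# default bond geometry. The derived constants (rise per residue, CA helix
# radius, residues per turn, handedness) and the cylindrical offsets of N,
# C and O relative to the CA helix are measured once from a torsion-built
# reference chain and cached, so the path-following builders and the
# torsion-angle builder realize exactly the same local geometry.

HELIX_CANONICAL_TORSIONS <- list(
  alpha = c(phi = -57.8, psi = -47.0, omega = 180),
  ppii  = c(phi = -75.0, psi = 145.0, omega = 180),
  pi    = c(phi = -57.0, psi = -70.0, omega = 180)
)

.helix_cache <- new.env(parent = emptyenv())

#' Helix class constants
#'
#' Returns the idealized geometric constants of a polypeptide helix class:
#' the right-handed alpha helix, the left-handed polyproline type-II (PPII)
#' helix adopted by collagen strands, or the pi helix. Each class is
#' generated from canonical backbone torsions (alpha: phi -57.8, psi -47.0;
#' PPII: -75, +145; pi: -57, -70; omega 180 throughout) with the default
#' bond geometry, and the constants reported here are measured from that
#' reference so the two construction routes agree.
#'
#' @param name one of "alpha", "ppii", "pi".
#' @return A `HelixClass` list: `name`, `torsions` (phi/psi/omega, degrees),
#'   `rise_per_residue` (Å), `helix_radius` (Å, CA radius),
#'   `residues_per_turn`, `handedness` ("right"/"left"), `twist_per_residue`
#'   (signed degrees, positive = right-handed) and `offsets` (3 x 3 matrix:
#'   rows N, C, O; columns radius (Å), dphi (degrees), dz (Å) relative to
#'   the CA helix).
#' @export
helix_class <- function(name = c("alpha", "ppii", "pi")) {
  name <- match.arg(name)
  if (!is.null(.helix_cache[[name]])) return(.helix_cache[[name]])
  tor <- HELIX_CANONICAL_TORSIONS[[name]]
  ref <- derive_helix_reference(tor[["phi"]], tor[["psi"]], tor[["omega"]])
  cls <- structure(c(list(name = name, torsions = tor), ref),
                   class = "HelixClass")
  .helix_cache[[name]] <- cls
  cls
}

# Build a long reference chain from the canonical torsions, align its axis
# to +z, and measure the helical parameters and per-atom-type offsets.
derive_helix_reference <- function(phi, psi, omega, n = 48) {
  ch <- build_ta_polypeptide(data.frame(phi = phi, psi = psi, omega = omega),
                             n_res = n)
  bb <- backbone_coords(ch)
  idx <- function(k) seq(k, by = 4, length.out = n)
  CA <- bb[idx(2), , drop = FALSE]
  ax <- fit_axis(CA)
  # rotate axis onto +z, centroid to origin
  X <- sweep(bb, 2, ax$point)
  v <- cross3(ax$direction, c(0, 0, 1))
  s <- sqrt(sum(v^2))
  if (s > 1e-12) {
    X <- rotate(X, v, atan2(s, ax$direction[3]) * 180 / pi)
  } else if (ax$direction[3] < 0) {
    X <- rotate(X, c(1, 0, 0), 180)
  }
  CA <- X[idx(2), , drop = FALSE]
  th <- atan2(CA[, 2], CA[, 1])
  dth <- ((diff(th) + pi) %% (2 * pi)) - pi
  interior <- 5:(n - 5)
  rise <- mean(diff(CA[, 3])[interior])
  twist <- mean(dth[interior]) * 180 / pi
  radius <- mean(sqrt(CA[, 1]^2 + CA[, 2]^2)[interior])
  offs <- t(vapply(c(N = 1, C = 3, O = 4), function(k) {
    M <- X[idx(k), , drop = FALSE]
    dphi <- ((atan2(M[, 2], M[, 1]) - th + pi) %% (2 * pi)) - pi
    c(radius = mean(sqrt(M[, 1]^2 + M[, 2]^2)[interior]),
      dphi = mean(dphi[interior]) * 180 / pi,
      dz = mean((M[, 3] - CA[, 3])[interior]))
  }, numeric(3)))
  list(rise_per_residue = rise,
       helix_radius = radius,
       residues_per_turn = 360 / abs(twist),
       twist_per_residue = twist,
       handedness = if (twist >= 0) "right" else "left",
       offsets = offs)
}

# Mirror image of a helix class: reflection negates the twist and the
# angular offsets (a right-handed alpha helix becomes left-handed). Used by
# symmetry checks: reflecting a supercoiled build through the xz plane
# yields the opposite-handedness supercoil of the mirrored minor class.
mirror_helix_class <- function(cls) {
  cls$twist_per_residue <- -cls$twist_per_residue
  cls$handedness <- if (cls$handedness == "right") "left" else "right"
  cls$offsets[, "dphi"] <- -cls$offsets[, "dphi"]
  cls$name <- paste0(cls$name, "_mirror")
  cls
}

# Backbone coordinates of one minor helix wound along a superhelical path
# about the global z axis (the generalized Crick construction). With
# r0 = 0 or pitch = Inf the path degenerates to a straight helix on the z
# axis / at radius r0. Returns a (4 * n_res) x 3 matrix in residue order
# N, CA, C, O.
#
# phase0: superhelical phase of the chain (degrees, angle in the xy plane).
# phi_ca: interface angle, the rotation of the minor helix about its own
#   path; 0 means the CA of residue 1 points toward the superhelix axis.
crick_backbone <- function(cls, n_res, r0, pitch, phase0 = 0,
                           superhelix_handedness = c("left", "right"),
                           phi_ca = 0) {
  superhelix_handedness <- match.arg(superhelix_handedness)
  d <- cls$rise_per_residue
  w_minor <- cls$twist_per_residue * pi / 180        # signed rad / residue
  if (is.finite(pitch)) {
    alpha <- atan2(2 * pi * r0, pitch)               # superhelix pitch angle
  } else {
    alpha <- 0
  }
  s_h <- if (superhelix_handedness == "right") 1 else -1
  w0 <- if (r0 > 0) s_h * d * sin(alpha) / r0 else 0 # rad / residue
  # minor frequency adjusted so local geometry is preserved on the curved path
  w1 <- w_minor - w0 * cos(alpha)
  phase0 <- phase0 * pi / 180
  phi_ca <- phi_ca * pi / 180
  labels <- c("N", "CA", "C", "O")
  out <- matrix(0, 4 * n_res, 3)
  t0 <- seq_len(n_res) - 1
  for (k in seq_along(labels)) {
    lab <- labels[k]
    if (lab == "CA") {
      rx <- cls$helix_radius; dphi <- 0; dz <- 0
    } else {
      o <- cls$offsets[lab, ]
      rx <- o[["radius"]]; dphi <- o[["dphi"]] * pi / 180; dz <- o[["dz"]]
    }
    tp <- t0 + dz / d                # arc-length advance along the path
    theta <- phase0 + w0 * tp
    Sx <- r0 * cos(theta); Sy <- r0 * sin(theta); Sz <- d * cos(alpha) * tp
    # moving frame: e1 toward the superhelix axis, T path tangent, e2 = T x e1
    e1 <- cbind(-cos(theta), -sin(theta), 0)
    Tg <- cbind(-s_h * sin(alpha) * sin(theta),
                s_h * sin(alpha) * cos(theta),
                rep(cos(alpha), length(theta)))
    e2 <- cbind(Tg[, 2] * e1[, 3] - Tg[, 3] * e1[, 2],
                Tg[, 3] * e1[, 1] - Tg[, 1] * e1[, 3],
                Tg[, 1] * e1[, 2] - Tg[, 2] * e1[, 1])
    # minor-helix phase, evaluated at the same arc-length parameter as the
    # frame; the offset is re-zeroed so the straight-helix case reproduces
    # the torsion-built reference exactly
    psi <- w1 * tp + (dphi - w_minor * dz / d) + phi_ca
    P <- cbind(Sx, Sy, Sz) + rx * (cos(psi) * e1 + sin(psi) * e2)
    out[seq(k, by = 4, length.out = n_res), ] <- P
  }
  out
}

#' Build an ideal straight helix between two points
#'
#' Winds a glycine backbone as an ideal helix of the given class about the
#' start-to-end axis: CA atoms lie on a circular helix of radius
#' `cls$helix_radius` with per-residue rise `cls$rise_per_residue` and twist
#' `360 / cls$residues_per_turn` (signed by handedness); N, C and O are
#' placed on their own coaxial helices using the class's reference offsets.
#' The first CA sits in the plane through `start` normal to the axis.
#'
#' @param cls a `HelixClass` (see [helix_class()]) or class name.
#' @param n_res number of residues (>= 2).
#' @param start,end 3-vectors defining the helix axis (must differ).
#' @return A single-chain glycine `Assembly` (chain "A").
#' @export
build_helix <- function(cls = "alpha", n_res, start = c(0, 0, 0),
                        end = c(0, 0, 1)) {
  if (is.character(cls)) cls <- helix_class(cls)
  if (n_res < 2) stop("a helix needs at least 2 residues, got ", n_res)
  u <- end - start
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("zero-length helix axis: start equals end")
  # straight-helix degenerate case of the Crick construction: r0 = 0 places
  # the minor helix on the z axis itself
  xyz <- crick_backbone(cls, n_res, r0 = 0, pitch = Inf)
  u <- u / nu
  v <- cross3(c(0, 0, 1), u)
  s <- sqrt(sum(v^2))
  if (s > 1e-12) {
    xyz <- rotate(xyz, v, atan2(s, u[3]) * 180 / pi)
  } else if (u[3] < 0) {
    xyz <- rotate(xyz, c(1, 0, 0), 180)
  }
  xyz <- translate(xyz, start)
  new_assembly(glycine_atom_table("A", n_res), xyz,
               id = paste0(cls$name, "_helix"))
}

#' Build a supercoiled (helical) helix
#'
#' Winds a minor helix of class `cls` along a superhelical path of radius
#' `r0` and pitch `pitch` about the global z axis, starting at superhelical
#' phase `phase`. The minor-helix angular frequency is adjusted for the
#' curvature of the path so the local rise and twist per residue are
#' preserved; as `pitch` tends to infinity the build reduces to a straight
#' helix at radius `r0`.
#'
#' @param cls a `HelixClass` or class name.
#' @param n_res number of residues (>= 2).
#' @param r0 superhelix radius in Å (> 0).
#' @param pitch superhelix pitch in Å (> 0; axial distance of one full
#'   superhelical turn). May be `Inf`.
#' @param phase starting superhelical phase in degrees.
#' @param handedness superhelix handedness, "left" (default; alpha coiled
#'   coils) or "right" (collagen).
#' @param phi_ca interface angle in degrees: rotation of the minor helix
#'   about its own path, zero meaning the CA of residue 1 points toward the
#'   superhelix axis.
#' @return A single-chain glycine `Assembly` (chain "A").
#' @export
build_helical_helix <- function(cls = "alpha", n_res, r0, pitch, phase = 0,
                                handedness = c("left", "right"), phi_ca = 0) {
  if (is.character(cls)) cls <- helix_class(cls)
  handedness <- match.arg(handedness)
  if (n_res < 2) stop("a helix needs at least 2 residues, got ", n_res)
  if (!isTRUE(r0 > 0)) stop("superhelix radius r0 must be positive")
  if (!isTRUE(pitch > 0)) stop("superhelix pitch must be positive")
  xyz <- crick_backbone(cls, n_res, r0 = r0, pitch = pitch, phase0 = phase,
                        superhelix_handedness = handedness, phi_ca = phi_ca)
  new_assembly(glycine_atom_table("A", n_res), xyz,
               id = paste0(cls$name, "_helical_helix"))
}
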