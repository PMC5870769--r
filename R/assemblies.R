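# Assembly-level fold specifications: coiled coils (and collagens),
# helix pairs, and solenoid repeat proteins. All builders are deterministic
# and emit glycine backbone models.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crick-style coiled-coil parameters
#'
#' The parameter set that fully determines a coiled-coil (or collagen)
#' backbone: number of chains, superhelix radius and pitch, the interface
#' angle, and per-chain z-shifts, rotational offsets, lengths and
#' orientations.
#'
#' @param n_chains number of chains (>= 2).
#' @param superhelix_radius distance of each helix axis from the bundle
#'   axis, Å (> 0).
#' @param pitch axial length of one full superhelical turn, Å (> 0; always
#'   positive, handedness is carried separately).
#' @param interface_angle rotation of each minor helix about its own
#'   superhelical path, degrees; zero means the CA of residue 1 points
#'   toward the bundle axis (a convention: fitted values are only
#'   comparable under this same convention).
#' @param z_shift per-chain translation along the bundle axis, Å (recycled).
#' @param chain_rotation per-chain rotational offset about the bundle axis,
#'   degrees (added to the k-th chain's symmetric phase; recycled).
#' @param n_residues per-chain residue count (recycled).
#' @param orientation per-chain "parallel"/"antiparallel" (recycled).
#' @param superhelix_handedness "left" (alpha coiled coils) or "right"
#'   (collagen).
#' @return A validated `CrickParams` list.
#' @export
crick_params <- function(n_chains, superhelix_radius, pitch,
                         interface_angle = 0, z_shift = 0, chain_rotation = 0,
                         n_residues = 28, orientation = "parallel",
                         superhelix_handedness = c("left", "right")) {
  superhelix_handedness <- match.arg(superhelix_handedness)
  if (!isTRUE(n_chains >= 2 && n_chains == round(n_chains))) {
    stop("parameter 'n_chains' must be an integer >= 2")
  }
  if (!isTRUE(superhelix_radius > 0)) {
    stop("parameter 'superhelix_radius' must be positive")
  }
  if (!isTRUE(pitch > 0)) stop("parameter 'pitch' must be positive")
  p <- list(n_chains = as.integer(n_chains),
            superhelix_radius = superhelix_radius, pitch = pitch,
            interface_angle = interface_angle,
            z_shift = rep_len(z_shift, n_chains),
            chain_rotation = rep_len(chain_rotation, n_chains),
            n_residues = as.integer(rep_len(n_residues, n_chains)),
            orientation = rep_len(orientation, n_chains),
            superhelix_handedness = superhelix_handedness)
  if (any(p$n_residues < 2)) stop("parameter 'n_residues' must be >= 2")
  if (!all(p$orientation %in% c("parallel", "antiparallel"))) {
    stop("parameter 'orientation' must be 'parallel' or 'antiparallel'")
  }
  structure(p, class = "CrickParams")
}

#' Build a coiled coil
#'
#' Places `n_chains` supercoiled helices (see [build_helical_helix()]) with
#' n-fold rotational symmetry about the z axis: chain k is phase-shifted by
#' k * 360 / n degrees plus its `chain_rotation`, z-shifted by its
#' `z_shift`, and spun about its own path by the common `interface_angle`.
#' Models use glycine residues only (backbone models).
#'
#' @param p a `CrickParams` (see [crick_params()]).
#' @param cls minor-helix class, default "alpha". Use "ppii" (via
#'   [build_tropocollagen()]) for collagens.
#' @return An `Assembly` with chains A, B, C, ...
#' @export
build_coiled_coil <- function(p, cls = "alpha") {
  if (!inherits(p, "CrickParams")) p <- do.call(crick_params, p)
  if (is.character(cls)) cls <- helix_class(cls)
  chains <- CHAIN_ALPHABET[seq_len(p$n_chains)]
  parts <- vector("list", p$n_chains)
  for (k in seq_len(p$n_chains)) {
    phase <- (k - 1) * 360 / p$n_chains + p$chain_rotation[k]
    xyz <- crick_backbone(cls, p$n_residues[k], r0 = p$superhelix_radius,
                          pitch = p$pitch, phase0 = phase,
                          superhelix_handedness = p$superhelix_handedness,
                          phi_ca = p$interface_angle)
    if (p$orientation[k] == "antiparallel") {
      # flip the chain end-over-end about the radial direction through its
      # own axial midpoint, so it occupies the same superhelical site
      phr <- phase * pi / 180
      mid <- c(0, 0, mean(range(xyz[, 3])))
      xyz <- rotate(xyz, c(cos(phr), sin(phr), 0), 180, point = mid)
    }
    xyz <- translate(xyz, c(0, 0, p$z_shift[k]))
    parts[[k]] <- xyz
  }
  # chains are emitted already in canonical label/numbering order
  new_assembly(glycine_atom_table(chains, p$n_residues),
               do.call(rbind, parts), id = "coiled_coil")
}

#' Build a collagen triple helix (tropocollagen)
#'
#' A right-handed superhelix of three left-handed polyproline type-II
#' strands, built with the same Crick-style construction as
#' [build_coiled_coil()]. The per-chain `z_shift` values produce the
#' characteristic one-residue stagger that creates leading and lagging
#' strands.
#'
#' @param p a `CrickParams` with `n_chains = 3`; `superhelix_handedness`
#'   should normally be "right" (the default used here when `p` is given as
#'   a plain list without one).
#' @return An `Assembly` with chains A, B, C.
#' @export
build_tropocollagen <- function(p) {
  if (!inherits(p, "CrickParams")) {
    p$superhelix_handedness <- p$superhelix_handedness %||% "right"
    p <- do.call(crick_params, p)
  }
  if (p$n_chains != 3) {
    stop("tropocollagen requires exactly 3 chains, got ", p$n_chains)
  }
  out <- build_coiled_coil(p, cls = "ppii")
  out$id <- "tropocollagen"
  out
}

#' Helix-pair repeat-unit parameters
#'
#' The repeating unit of a solenoid: two alpha helices built on a plane
#' relative to a reference axis (the z axis; the reference plane is the xz
#' plane). Each helix is described independently by five parameters. Helix
#' 1 is placed at x = -axis_distance[1] and helix 2 at x = +axis_distance[2]
#' so the two sit on opposite sides of the reference axis.
#'
#' @param axis_distance per-helix distance from the reference axis, Å
#'   (length 2).
#' @param z_shift per-helix shift along the reference axis, Å.
#' @param phi_ca per-helix spin about its own axis, degrees.
#' @param splay per-helix in-plane tilt (rotation about the y axis),
#'   degrees.
#' @param off_plane_rotation per-helix out-of-plane rotation (about the x
#'   axis), degrees; 180 flips a helix antiparallel.
#' @param helix_lengths per-helix residue counts (>= 2).
#' @return A validated `HelixPairParams` list.
#' @export
helix_pair_params <- function(axis_distance, z_shift = c(0, 0),
                              phi_ca = c(0, 0), splay = c(0, 0),
                              off_plane_rotation = c(0, 0),
                              helix_lengths = c(10, 10)) {
  p <- list(axis_distance = axis_distance, z_shift = z_shift,
            phi_ca = phi_ca, splay = splay,
            off_plane_rotation = off_plane_rotation,
            helix_lengths = as.integer(helix_lengths))
  bad <- names(p)[vapply(p, length, 1L) != 2L]
  if (length(bad)) {
    stop("helix-pair parameters must have length 2 (two helices): ",
         paste(bad, collapse = ", "))
  }
  if (any(p$helix_lengths < 2)) stop("helix_lengths must be >= 2")
  structure(p, class = "HelixPairParams")
}

#' Build a two-helix repeat unit
#'
#' @param p a `HelixPairParams` (see [helix_pair_params()]).
#' @return An `Assembly` with chains A and B, each an alpha helix centered
#'   on its own placement point.
#' @export
build_helix_pair <- function(p) {
  if (!inherits(p, "HelixPairParams")) p <- do.call(helix_pair_params, p)
  cls <- helix_class("alpha")
  side <- c(-1, 1)
  parts <- vector("list", 2)
  for (j in 1:2) {
    n <- p$helix_lengths[j]
    half <- (n - 1) * cls$rise_per_residue / 2
    xyz <- coords(build_helix(cls, n, start = c(0, 0, -half),
                              end = c(0, 0, half)))
    xyz <- rotate(xyz, c(0, 0, 1), p$phi_ca[j])            # spin on own axis
    xyz <- rotate(xyz, c(0, 1, 0), p$splay[j])             # in-plane tilt
    xyz <- rotate(xyz, c(1, 0, 0), p$off_plane_rotation[j])# out-of-plane
    xyz <- translate(xyz, c(side[j] * p$axis_distance[j], 0, p$z_shift[j]))
    parts[[j]] <- xyz
  }
  new_assembly(glycine_atom_table(c("A", "B"), p$helix_lengths),
               do.call(rbind, parts), id = "helix_pair")
}

#' Solenoid parameters
#'
#' Helical symmetry applied to a repeating unit: the unit is placed at
#' `radius` from the solenoid (z) axis and replicated by a fixed screw
#' transform of `rise_per_repeat` along and `twist_per_repeat` about the
#' axis.
#'
#' @param repeat_unit an `Assembly` to replicate, or a `HelixPairParams`
#'   (or plain list of its fields) from which the unit is built.
#' @param n_repeats number of repeats (>= 2).
#' @param radius distance of the unit centroid from the solenoid axis, Å
#'   (>= 0).
#' @param rise_per_repeat axial advance per repeat, Å.
#' @param twist_per_repeat rotation about the axis per repeat, degrees.
#' @param handedness "right" (default) or "left"; flips the sign of the
#'   applied twist.
#' @param unit_rotation rotation of the unit about the solenoid radial
#'   direction before replication, degrees (the unit's remaining rotational
#'   freedom).
#' @return A validated `SolenoidParams` list.
#' @export
solenoid_params <- function(repeat_unit, n_repeats, radius, rise_per_repeat,
                            twist_per_repeat, handedness = c("right", "left"),
                            unit_rotation = 0) {
  handedness <- match.arg(handedness)
  if (!isTRUE(n_repeats >= 2 && n_repeats == round(n_repeats))) {
    stop("parameter 'n_repeats' must be an integer >= 2")
  }
  if (!isTRUE(radius >= 0)) stop("parameter 'radius' must be >= 0")
  structure(list(repeat_unit = repeat_unit, n_repeats = as.integer(n_repeats),
                 radius = radius, rise_per_repeat = rise_per_repeat,
                 twist_per_repeat = twist_per_repeat, handedness = handedness,
                 unit_rotation = unit_rotation),
            class = "SolenoidParams")
}

# Orient a repeat unit into its canonical centroid frame: centroid at the
# origin, first principal axis along z, second along x, with deterministic
# sign fixing (z follows the first chain's CA direction, x the separation
# of chain centroids). Makes solenoid building independent of how the unit
# happened to be oriented.
canonicalize_unit <- function(unit) {
  X <- unit$xyz
  cen <- colMeans(X)
  X0 <- sweep(X, 2, cen)
  V <- svd(X0, nu = 0, nv = 3)$v
  v1 <- V[, 1]; v2 <- V[, 2]
  ch_col <- unit$atoms$chain
  ch1 <- ch_col == ch_col[1]
  ca1 <- X0[ch1 & unit$atoms$label == "CA", , drop = FALSE]
  dirz <- ca1[nrow(ca1), ] - ca1[1, ]
  if (sum(v1 * dirz) < 0) v1 <- -v1
  if (!all(ch1)) {
    sep <- colMeans(X0[!ch1, , drop = FALSE]) -
      colMeans(X0[ch1, , drop = FALSE])
    if (sum(v2 * sep) < 0) v2 <- -v2
  } else if (sum(v2 * X0[1, ]) < 0) {
    v2 <- -v2
  }
  v3 <- cross3(v1, v2)
  Q <- rbind(v2, v3, v1)          # rows: new x, y, z expressed in old frame
  unit$xyz <- X0 %*% t(Q)
  dimnames(unit$xyz) <- list(NULL, c("x", "y", "z"))
  unit
}

#' Build a solenoid repeat protein
#'
#' Canonicalizes the repeat unit (centroid frame, see details), applies the
#' `unit_rotation` about the radial direction, places the unit at `radius`
#' from the z axis, and replicates it `n_repeats` times by the screw
#' transform (`rise_per_repeat` along z, signed `twist_per_repeat` about z).
#' Chains are relabelled sequentially across repeats.
#'
#' @param p a `SolenoidParams` (see [solenoid_params()]).
#' @return An `Assembly` with `n_repeats` copies of the unit's chains.
#' @export
build_solenoid <- function(p) {
  if (!inherits(p, "SolenoidParams")) p <- do.call(solenoid_params, p)
  unit <- p$repeat_unit
  if (!inherits(unit, "Assembly")) {
    if (!inherits(unit, "HelixPairParams")) {
      unit <- do.call(helix_pair_params, unit)
    }
    unit <- build_helix_pair(unit)
  }
  unit <- canonicalize_unit(unit)
  xyz0 <- rotate(unit$xyz, c(1, 0, 0), p$unit_rotation)
  xyz0 <- translate(xyz0, c(p$radius, 0, 0))
  s <- if (p$handedness == "right") 1 else -1
  unit_ids <- chain_ids(unit)
  n_ch <- length(unit_ids)
  if (n_ch * p$n_repeats > length(CHAIN_ALPHABET)) {
    stop("solenoid would need ", n_ch * p$n_repeats,
         " chains; at most ", length(CHAIN_ALPHABET), " are supported")
  }
  parts <- vector("list", p$n_repeats)
  for (k in seq_len(p$n_repeats)) {
    xyz <- rotate(xyz0, c(0, 0, 1), s * (k - 1) * p$twist_per_repeat)
    parts[[k]] <- translate(xyz, c(0, 0, (k - 1) * p$rise_per_repeat))
  }
  # chains relabelled sequentially across repeats (A, B from repeat 1,
  # C, D from repeat 2, ...)
  atoms <- unit$atoms[rep(seq_len(nrow(unit$atoms)), p$n_repeats), ]
  rep_k <- rep(seq_len(p$n_repeats), each = nrow(unit$atoms))
  atoms$chain <- CHAIN_ALPHABET[(rep_k - 1L) * n_ch +
                                  match(atoms$chain, unit_ids)]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new_assembly(atoms, do.call(rbind, parts), id = "solenoid")
}
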