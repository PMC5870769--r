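# Rigid-body manipulation of assemblies and bare coordinate matrices.

#' Rotation matrix about an arbitrary axis
#'
#' Right-handed rotation by `angle` degrees about the direction `axis`
#' (Rodrigues construction).
#'
#' @param axis non-zero 3-vector (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle * pi / 180
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * ux + (1 - cos(th)) * (ux %*% ux)
}

#' Rotate an assembly, polymer or coordinate matrix
#'
#' Applies the right-handed rotation of `angle` degrees about the line
#' through `point` with direction `axis` to every atom. Topology and
#' hierarchy are unchanged.
#'
#' @param target an `Assembly`/`Polymer`, or an n x 3 coordinate matrix.
#' @param axis non-zero 3-vector.
#' @param angle degrees.
#' @param point a point on the rotation axis (default: origin).
#' @return Same type as `target`.
#' @export
rotate <- function(target, axis, angle, point = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle)
  if (is.matrix(target)) {
    return(sweep(sweep(target, 2, point) %*% t(R), 2, point, `+`))
  }
  target$xyz[] <- sweep(sweep(target$xyz, 2, point) %*% t(R), 2, point, `+`)
  target
}

#' Translate an assembly, polymer or coordinate matrix
#'
#' @param target an `Assembly`/`Polymer`, or an n x 3 coordinate matrix.
#' @param vector 3-vector shift in Å.
#' @return Same type as `target`.
#' @export
translate <- function(target, vector) {
  stopifnot(length(vector) == 3, all(is.finite(vector)))
  if (is.matrix(target)) return(sweep(target, 2, vector, `+`))
  target$xyz[] <- sweep(target$xyz, 2, vector, `+`)
  target
}

CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Relabel chains, residues and serials canonically
#'
#' Chains are relabelled A, B, C, ... (then a-z, 0-9), residues renumbered
#' from 1 within each chain (insertion codes dropped), and atom serials made
#' sequential from 1 across the assembly.
#'
#' @param assembly an `Assembly`.
#' @return The relabelled `Assembly`.
#' @export
relabel <- function(assembly) {
  ids <- chain_ids(assembly)
  if (length(ids) > length(CHAIN_ALPHABET)) {
    stop("cannot relabel more than ", length(CHAIN_ALPHABET),
         " chains with single-character ids (got ", length(ids), ")")
  }
  a <- assembly$atoms
  a$chain <- CHAIN_ALPHABET[match(a$chain, ids)]
  ridx <- residue_index(assembly)
  # renumber residues from 1 per chain
  first_in_chain <- !duplicated(a$chain)
  chain_first_res <- ridx[first_in_chain][match(a$chain, a$chain[first_in_chain])]
  a$res_seq <- ridx - chain_first_res + 1L
  a$ins_code <- ""
  a$serial <- seq_len(nrow(a))
  assembly$atoms <- a
  assembly
}
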