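#' @keywords internal
"_PACKAGE"

# Residue codes used to classify a chain's polymer type on input.
PROTEIN_CODES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HYP", "MSE", "SEC", "PYL"
)
NUCLEIC_CODES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U")

BACKBONE_LABELS <- c("N", "CA", "C", "O")

#' Construct an assembly
#'
#' An assembly is the top-level structure container: an ordered atom table
#' plus an n x 3 coordinate matrix in ångströms. Rows are atoms in file /
#' build order; chains are contiguous runs of the `chain` column, residues
#' contiguous runs of (`chain`, `res_seq`, `ins_code`). This flat layout
#' keeps building and scoring fast while the accessor functions
#' ([get_polymer()], [get_residue()], [get_atom()]) expose the hierarchical
#' assembly/polymer/residue/atom view with navigation in both directions.
#'
#' @param atoms data.frame with columns `serial` (integer), `label`
#'   (atom-name string, e.g. "CA"), `element`, `mol_code` (3-letter residue
#'   code), `res_seq` (integer residue number), `ins_code` (insertion code,
#'   "" when absent), `chain` (single-character chain id) and `polymer_type`
#'   ("protein" or "nucleic").
#' @param xyz numeric matrix, `nrow(atoms)` x 3, coordinates in Å.
#' @param id free-form assembly label.
#' @return An object of class `Assembly`.
#' @export
new_assembly <- function(atoms, xyz, id = "") {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), nrow(atoms) == nrow(xyz),
            ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("all atom coordinates must be finite")
  if (any(!nzchar(atoms$label))) stop("atom labels must be non-empty")
  # chain ids must be unique: a chain may not reappear after another chain
  ch <- rle(atoms$chain)$values
  if (anyDuplicated(ch)) {
    stop("chain ids must be unique within an assembly: ",
         paste(ch[duplicated(ch)], collapse = ", "))
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, atoms = atoms, xyz = xyz), class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("<Assembly '%s': %d chain(s), %d residue(s), %d atom(s)>\n",
              x$id, length(chain_ids(x)), n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Assembly coordinates
#'
#' @param assembly an `Assembly`.
#' @return The n x 3 coordinate matrix (Å).
#' @export
coords <- function(assembly) assembly$xyz

#' Number of atoms in an assembly
#' @param assembly an `Assembly`.
#' @export
n_atoms <- function(assembly) nrow(assembly$atoms)

#' Chain identifiers, in order
#' @param assembly an `Assembly`.
#' @export
chain_ids <- function(assembly) rle(assembly$atoms$chain)$values

# Integer residue index (1-based, global across the assembly) per atom.
residue_index <- function(assembly) {
  a <- assembly$atoms
  key <- paste(a$chain, a$res_seq, a$ins_code, sep = "\r")
  changed <- c(TRUE, key[-1] != key[-length(key)])
  cumsum(changed)
}

#' Number of residues
#' @param assembly an `Assembly`.
#' @param chain optional chain id; when given, counts that chain only.
#' @export
n_residues <- function(assembly, chain = NULL) {
  if (!is.null(chain)) assembly <- get_polymer(assembly, chain)
  max(residue_index(assembly))
}

#' Extract one polymer (chain) from an assembly
#'
#' @param assembly an `Assembly`.
#' @param chain chain id.
#' @return An object of class `c("Polymer", "Assembly")` containing that
#'   chain only; `$polymer_type` gives its type.
#' @export
get_polymer <- function(assembly, chain) {
  keep <- assembly$atoms$chain == chain
  if (!any(keep)) {
    stop("no chain '", chain, "' in assembly (chains: ",
         paste(chain_ids(assembly), collapse = ", "), ")")
  }
  p <- new_assembly(assembly$atoms[keep, , drop = FALSE],
                    assembly$xyz[keep, , drop = FALSE], id = assembly$id)
  p$chain_id <- chain
  p$polymer_type <- assembly$atoms$polymer_type[keep][1]
  class(p) <- c("Polymer", "Assembly")
  p
}

#' Extract one residue from a polymer or assembly
#'
#' @param polymer a `Polymer` (or single-chain `Assembly`).
#' @param i residue position (1-based, in chain order).
#' @return A `Residue`: list with `mol_code`, `insertion_id` (residue number
#'   as a string, including any insertion code), `atoms` (named list of
#'   `Atom`s keyed by label), and back-references `chain` and `res_index`.
#' @export
get_residue <- function(polymer, i) {
  ridx <- residue_index(polymer)
  rows <- which(ridx == i)
  if (!length(rows)) stop("no residue ", i, " (chain has ", max(ridx), ")")
  a <- polymer$atoms[rows, , drop = FALSE]
  if (anyDuplicated(a$label)) {
    stop("duplicate atom labels within residue ", a$res_seq[1])
  }
  atoms <- lapply(seq_len(nrow(a)), function(k) {
    structure(list(label = a$label[k], element = a$element[k],
                   coords = polymer$xyz[rows[k], ], serial = a$serial[k],
                   chain = a$chain[k], res_index = i,
                   mol_code = a$mol_code[k]),
              class = "Atom")
  })
  names(atoms) <- a$label
  structure(list(mol_code = a$mol_code[1],
                 insertion_id = paste0(a$res_seq[1], trimws(a$ins_code[1])),
                 atoms = atoms, chain = a$chain[1], res_index = i,
                 tags = list()),
            class = "Residue")
}

#' Extract one atom from a residue
#' @param residue a `Residue`.
#' @param label atom label, e.g. "CA".
#' @export
get_atom <- function(residue, label) {
  at <- residue$atoms[[label]]
  if (is.null(at)) {
    stop("residue ", residue$mol_code, " ", residue$insertion_id,
         " has no atom '", label, "'")
  }
  at
}

#' Smoothed C-alpha trace (primitive) of a polymer
#'
#' The primitive is the running average of the C-alpha positions along a
#' chain: the geometric path a polymer-level building specification
#' prescribes. A centered window of width 3 is used, truncated at the chain
#' ends (the first point averages CA 1-2, the last averages the final two),
#' so the primitive has one point per residue.
#'
#' @param chain a `Polymer` (or single-chain `Assembly`) in which every
#'   residue has a CA atom.
#' @return Object of class `Primitive`: list with `points`, an n x 3 matrix.
#' @export
primitive_of <- function(chain) {
  ca <- ca_coords(chain)
  n <- nrow(ca)
  if (n < 3) stop("primitive requires at least 3 residues, got ", n)
  lo <- pmax(seq_len(n) - 1L, 1L)
  hi <- pmin(seq_len(n) + 1L, n)
  pts <- t(vapply(seq_len(n),
                  function(i) colMeans(ca[lo[i]:hi[i], , drop = FALSE]),
                  numeric(3)))
  structure(list(points = pts), class = "Primitive")
}

# CA coordinates of a chain, erroring on any residue without one.
ca_coords <- function(chain) {
  ridx <- residue_index(chain)
  is_ca <- chain$atoms$label == "CA"
  nres <- max(ridx)
  has <- tabulate(ridx[is_ca], nres)
  if (any(has == 0)) {
    miss <- which(has == 0)[1]
    row1 <- which(ridx == miss)[1]
    stop("residue ", chain$atoms$mol_code[row1], " ",
         chain$atoms$res_seq[row1], " (chain ",
         chain$atoms$chain[row1], ") has no CA atom")
  }
  chain$xyz[is_ca, , drop = FALSE]
}

#' Backbone coordinates in canonical order
#'
#' Returns the N, CA, C, O coordinates of every protein residue, residues in
#' chain order and atoms in the fixed order N, CA, C, O. Errors if any
#' residue is not backbone-complete.
#'
#' @param assembly an `Assembly`.
#' @return A (4 * n_residues) x 3 matrix.
#' @export
backbone_coords <- function(assembly) {
  a <- assembly$atoms
  ridx <- residue_index(assembly)
  nres <- max(ridx)
  rows <- integer(4L * nres)
  for (k in seq_along(BACKBONE_LABELS)) {
    sel <- a$label == BACKBONE_LABELS[k]
    have <- tabulate(ridx[sel], nres)
    if (any(have != 1)) {
      bad <- which(have != 1)[1]
      r1 <- which(ridx == bad)[1]
      stop("residue ", a$mol_code[r1], " ", a$res_seq[r1], " (chain ",
           a$chain[r1], ") is not backbone-complete: atom '",
           BACKBONE_LABELS[k], "' ",
           if (have[bad] == 0) "missing" else "duplicated")
    }
    rows[seq(k, by = 4L, length.out = nres)] <- which(sel)
  }
  assembly$xyz[rows, , drop = FALSE]
}

# Build the standard atom table for a glycine backbone model.
# chains: character vector of chain ids; n_res: residues per chain (recycled).
# Memoized: builders construct the same small tables thousands of times
# inside optimization loops.
.atom_table_cache <- new.env(parent = emptyenv())

glycine_atom_table <- function(chains, n_res) {
  key <- paste(c(chains, "|", n_res), collapse = ",")
  hit <- .atom_table_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- glycine_atom_table_build(chains, n_res)
  .atom_table_cache[[key]] <- tab
  tab
}

glycine_atom_table_build <- function(chains, n_res) {
  n_res <- rep_len(n_res, length(chains))
  per_chain <- lapply(seq_along(chains), function(k) {
    n <- n_res[k]
    data.frame(
      label = rep(BACKBONE_LABELS, n),
      element = rep(c("N", "C", "C", "O"), n),
      mol_code = "GLY",
      res_seq = rep(seq_len(n), each = 4L),
      ins_code = "",
      chain = chains[k],
      polymer_type = "protein",
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, per_chain)
  tab$serial <- seq_len(nrow(tab))
  tab[, c("serial", "label", "element", "mol_code", "res_seq", "ins_code",
          "chain", "polymer_type")]
}

# Merge several single-chain assemblies into one, keeping chain order.
combine_assemblies <- function(parts, id = "") {
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  xyz <- do.call(rbind, lapply(parts, function(p) p$xyz))
  atoms$serial <- seq_len(nrow(atoms))
  new_assembly(atoms, xyz, id = id)
}
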