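# PDB coordinate-format input/output (v3.3 fixed-column dialect).

#' Read a PDB file into an assembly
#'
#' Parses ATOM and HETATM records of the coordinate section. Only the first
#' model of a multi-MODEL file is read; alternate locations other than blank
#' or "A" are dropped; header/REMARK and other records are ignored. One
#' polymer is created per chain id, with residues and atoms in file order.
#' Polymer type is inferred from residue codes (standard amino acids ->
#' protein, DA/DC/DG/DT/... -> nucleic).
#'
#' @param path path to a PDB file, or a character vector of PDB lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return An `Assembly`.
#' @export
read_pdb <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(sel)) stop("no ATOM/HETATM records found")
  al <- lines[sel]
  altloc <- substr(al, 17, 17)
  keep <- altloc == " " | altloc == "A" | altloc == ""
  al <- al[keep]
  sel <- sel[keep]
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("unparseable ", what, " field at line ", sel[bad], ": '",
           trimws(s[bad]), "'")
    }
    v
  }
  x <- num(substr(al, 31, 38), "x coordinate")
  y <- num(substr(al, 39, 46), "y coordinate")
  z <- num(substr(al, 47, 54), "z coordinate")
  serial <- as.integer(num(substr(al, 7, 11), "serial"))
  label <- trimws(substr(al, 13, 16))
  mol_code <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  res_seq <- as.integer(num(substr(al, 23, 26), "residue number"))
  ins_code <- trimws(substr(al, 27, 27))
  element <- trimws(substr(al, 77, 78))
  # fall back to the label's leading letter when the element column is empty
  # (common in hand-written or legacy files); for standard polymer atoms the
  # first alphabetic character of the name is the element
  miss <- element == ""
  element[miss] <- substr(sub("^[0-9']*", "", label[miss]), 1, 1)
  element[element == ""] <- "X"
  ptype <- ifelse(mol_code %in% NUCLEIC_CODES, "nucleic",
                  ifelse(mol_code %in% PROTEIN_CODES, "protein", "protein"))
  # chain type decided by majority of its residues
  for (ch in unique(chain)) {
    i <- chain == ch
    ptype[i] <- names(which.max(table(ptype[i])))
  }
  atoms <- data.frame(serial = serial, label = label, element = element,
                      mol_code = mol_code, res_seq = res_seq,
                      ins_code = ins_code, chain = chain,
                      polymer_type = ptype, stringsAsFactors = FALSE)
  id <- if (!is.null(path)) basename(path) else ""
  new_assembly(atoms, cbind(x, y, z), id = id)
}

#' Write an assembly as PDB text
#'
#' Emits fixed-column ATOM records (80 characters each, space padded) with
#' occupancy 1.00, B-factor 0.00 and the element column filled, a TER record
#' after each chain and END last. Coordinates are rendered with 3 decimals.
#'
#' @param assembly an `Assembly`.
#' @param path optional file path; when given the text is also written there.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(assembly, path = NULL) {
  a <- assembly$atoms
  xyz <- assembly$xyz
  if (any(abs(xyz) >= 10000 - 5e-4) || any(xyz <= -1000 + 5e-4)) {
    stop("coordinate magnitude overflows the fixed-column PDB format ",
         "(allowed range -999.999 to 9999.999 Å)")
  }
  name4 <- ifelse(nchar(a$label) >= 4, substr(a$label, 1, 4),
                  sprintf(" %-3s", a$label))
  rec <- ifelse(a$mol_code %in% c(PROTEIN_CODES, NUCLEIC_CODES),
                "ATOM  ", "HETATM")
  lines <- character(0)
  serial <- 0L
  for (ch in chain_ids(assembly)) {
    i <- which(a$chain == ch)
    serial_i <- serial + seq_along(i)
    body <- sprintf(
      "%s%5d %s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec[i], serial_i, name4[i], a$mol_code[i], ch, a$res_seq[i],
      substr(paste0(a$ins_code[i], " "), 1, 1),
      xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, a$element[i])
    last <- i[length(i)]
    ter <- sprintf("TER   %5d      %3s %s%4d",
                   serial_i[length(i)] + 1L, a$mol_code[last], ch,
                   a$res_seq[last])
    lines <- c(lines, body, ter)
    serial <- serial_i[length(i)] + 1L
  }
  lines <- c(lines, "END")
  lines <- sprintf("%-80s", lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
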