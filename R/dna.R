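# Idealized B-form DNA duplex builder. The base-pair template is a
# synthetic idealized geometry: planar Watson-Crick pairs with C1', a
# minimal sugar-phosphate backbone (P, O5', C5', C4', C3', O3') and planar
# base rings at canonical-looking positions. It reproduces the gross
# helical parameters (rise and twist per base pair) and strand topology;
# it is not a stereochemically refined nucleic-acid model.

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Reverse complement of a DNA sequence
#' @param sequence string over A, C, G, T.
#' @export
reverse_complement <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% names(DNA_COMPLEMENT))
  if (length(bad)) {
    stop("invalid nucleotide '", chars[bad[1]], "' at position ", bad[1])
  }
  paste(rev(unname(DNA_COMPLEMENT[chars])), collapse = "")
}

#' DNA duplex parameters
#'
#' @param sequence 5'-to-3' sequence of strand 1 (string over A, C, G, T,
#'   length >= 2). Strand 2 is its reverse complement.
#' @param rise_per_bp axial rise per base pair, Å (B-form default 3.38).
#' @param twist_per_bp right-handed twist per base pair, degrees (B-form
#'   default 34.3).
#' @return A validated `DnaDuplexParams` list.
#' @export
dna_duplex_params <- function(sequence, rise_per_bp = 3.38,
                              twist_per_bp = 34.3) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(DNA_COMPLEMENT))
  if (length(bad)) {
    stop("invalid nucleotide '", chars[bad[1]], "' at position ", bad[1])
  }
  if (length(chars) < 2) stop("sequence must have at least 2 bases")
  structure(list(sequence = sequence, rise_per_bp = rise_per_bp,
                 twist_per_bp = twist_per_bp),
            class = "DnaDuplexParams")
}

# Idealized strand-1 nucleotide template in the base-pair frame (helix axis
# = z through the origin, base-pair plane = z = 0, dyad along x). Cylindrical
# placements; the dyad rotation (180 degrees about x) generates strand 2.
dna_nucleotide_template <- function(base) {
  cyl <- function(r, az_deg, z) {
    a <- az_deg * pi / 180
    c(r * cos(a), r * sin(a), z)
  }
  backbone <- rbind(
    P     = cyl(8.9, 72, 2.0),
    `O5'` = cyl(8.7, 66, 1.3),
    `C5'` = cyl(8.3, 61, 0.8),
    `C4'` = cyl(7.6, 58, 0.4),
    `C3'` = cyl(7.2, 64, -0.2),
    `O3'` = cyl(6.9, 70, -0.8),
    `C1'` = cyl(5.9, 54, 0.0)
  )
  c1 <- backbone["C1'", ]
  u <- -c(c1[1], c1[2], 0)
  u <- u / sqrt(sum(u^2))           # inward, toward the helix axis
  w <- c(-u[2], u[1], 0)            # in-plane normal to u
  ring_at <- function(center, circum, n, phase, labels) {
    ang <- phase + seq(0, length.out = n, by = 2 * pi / n)
    pts <- t(vapply(ang, function(a) {
      center + circum * (cos(a) * u + sin(a) * w)
    }, numeric(3)))
    rownames(pts) <- labels
    pts
  }
  purine <- base %in% c("A", "G")
  glyco <- c1 + 1.48 * u            # N9 (purine) or N1 (pyrimidine)
  if (purine) {
    cen5 <- glyco + 1.17 * u
    five <- ring_at(cen5, 1.17, 5, pi, c("N9", "C8", "N7", "C5", "C4"))
    cen6 <- cen5 + 2.2 * u
    six <- ring_at(cen6, 1.39, 6, pi, c("C5x", "C6", "N1", "C2", "N3", "C4x"))
    ring <- rbind(five, six[c("C6", "N1", "C2", "N3"), , drop = FALSE])
  } else {
    cen6 <- glyco + 1.39 * u
    ring <- ring_at(cen6, 1.39, 6, pi,
                    c("N1", "C2", "N3", "C4", "C5", "C6"))
  }
  rbind(backbone, ring)
}

#' Build an idealized B-form DNA duplex
#'
#' Generates two antiparallel strands: base pair i is produced from the
#' planar idealized pair template, rotated by i * `twist_per_bp` about the
#' z axis and advanced i * `rise_per_bp` along it. Strand 2 (chain B) is
#' the reverse complement of the input sequence and its residues are
#' ordered 5' to 3'.
#'
#' @param p a `DnaDuplexParams` (see [dna_duplex_params()]), or a sequence
#'   string.
#' @return An `Assembly` with nucleic chains A and B.
#' @export
build_dna_duplex <- function(p) {
  if (is.character(p)) p <- dna_duplex_params(p)
  if (!inherits(p, "DnaDuplexParams")) p <- do.call(dna_duplex_params, p)
  bases1 <- strsplit(p$sequence, "")[[1]]
  n <- length(bases1)
  bases2 <- unname(DNA_COMPLEMENT[bases1])  # pair partner at each step
  step <- function(xyz, i) {
    translate(rotate(xyz, c(0, 0, 1), (i - 1) * p$twist_per_bp),
              c(0, 0, (i - 1) * p$rise_per_bp))
  }
  make_res <- function(base, i, strand2) {
    tmpl <- dna_nucleotide_template(base)
    if (strand2) tmpl <- rotate(tmpl, c(1, 0, 0), 180)  # dyad flip
    xyz <- step(tmpl, i)
    data.frame(label = rownames(tmpl), element = substr(rownames(tmpl), 1, 1),
               mol_code = paste0("D", base), pair = i,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  s1 <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_res(bases1[i], i, strand2 = FALSE)
  }))
  s2 <- do.call(rbind, lapply(rev(seq_len(n)), function(i) {
    make_res(bases2[i], i, strand2 = TRUE)   # 5'->3' of strand 2
  }))
  s1$chain <- "A"
  s2$chain <- "B"
  tab <- rbind(s1, s2)
  res_key <- paste(tab$chain, tab$pair)
  res_seq <- ave(seq_along(res_key), tab$chain,
                 FUN = function(i) cumsum(!duplicated(res_key[i])))
  atoms <- data.frame(serial = seq_len(nrow(tab)), label = tab$label,
                      element = tab$element, mol_code = tab$mol_code,
                      res_seq = as.integer(res_seq), ins_code = "",
                      chain = tab$chain, polymer_type = "nucleic",
                      stringsAsFactors = FALSE)
  new_assembly(atoms, as.matrix(tab[, c("x", "y", "z")]), id = "dna_duplex")
}

#' Sequence of a nucleic polymer
#'
#' @param assembly an `Assembly`.
#' @param chain chain id.
#' @return The chain's base sequence (5' to 3') as a string.
#' @export
dna_sequence <- function(assembly, chain) {
  p <- get_polymer(assembly, chain)
  ridx <- residue_index(p)
  codes <- p$atoms$mol_code[!duplicated(ridx)]
  paste(sub("^D", "", codes), collapse = "")
}
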