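# Shared fixtures, all generated in code.

# the standard noiseless trimer used by recovery checks
trimer_truth <- function(n_residues = 28) {
  crick_params(3, superhelix_radius = 6.5, pitch = 150,
               interface_angle = 10, n_residues = n_residues)
}

# collagen truth parameters, all inside the packaged collagen ranges
collagen_truth <- function(n_residues = 30) {
  crick_params(3, superhelix_radius = 3.0, pitch = 85, interface_angle = 40,
               z_shift = c(0, 2.8, 5.6), chain_rotation = c(-10, 0, 10),
               n_residues = n_residues, superhelix_handedness = "right")
}

# ankyrin-like repeat unit, all inside the packaged ankyrin unit ranges
ankyrin_unit_truth <- function(helix_lengths = c(10, 10)) {
  helix_pair_params(axis_distance = c(2.5, 2.5), z_shift = c(-1, 1),
                    phi_ca = c(30, -40), splay = c(-10, -20),
                    off_plane_rotation = c(100, 250),
                    helix_lengths = helix_lengths)
}

ankyrin_solenoid_truth <- function(n_repeats = 5) {
  solenoid_params(ankyrin_unit_truth(), n_repeats = n_repeats, radius = 32,
                  rise_per_repeat = 10, twist_per_repeat = 12)
}

# a random proper rotation matrix (uniform axis, uniform angle)
random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 360))
}

# hand-written single-atom PDB line: CA of GLY A 1 at (1, 2, 3)
one_atom_pdb <- function() {
  paste0("ATOM      1  CA  GLY A   1       1.000   2.000   3.000",
         "  1.00  0.00           C")
}

# hand-written two-chain PDB text: chain A with 3 GLY, chain B with 2 GLY
two_chain_pdb <- function() {
  mk <- function(serial, ch, res, x) {
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, ch, res, x, 0, 0)
  }
  c(mk(1, "A", 1, 0), mk(2, "A", 2, 3.8), mk(3, "A", 3, 7.6),
    "TER", mk(4, "B", 1, 0), mk(5, "B", 2, 3.8), "END")
}
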