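# Small constructed fixtures, built in code at test time.

# A tiny peptide structure with hand-set coordinates.
make_peptide <- function(n_residues = 5, jitter = 0) {
  h <- make_helix_structure(n_residues, sequence = c("ALA", "GLY", "SER"))
  if (jitter > 0) {
    set.seed(99)
    h$xyz <- h$xyz + matrix(rnorm(length(h$xyz), sd = jitter),
                            nrow(h$xyz), 3)
  }
  h
}

# Random well-conditioned point cloud for superposition tests.
random_coords <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * 3, -5, 5), n, 3)
}

# Random proper rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# A "cage" of single-atom residues on a sphere: a spherical cavity whose
# centre is the most contact-rich clash-free position.
make_cavity_frame <- function(radius = 5, n_wall = 14) {
  pts <- sphere_points(n_wall) * radius
  topo <- data.frame(serial = seq_len(n_wall),
                     name = "CA", element = "C",
                     resid = seq_len(n_wall), resname = "ALA",
                     chain = "A", stringsAsFactors = FALSE)
  structure3d(topo, pts)
}

single_atom_ligand <- function(element = "C") {
  structure3d(data.frame(serial = 1L, name = paste0(element, "1"),
                         element = element, resid = 1L, resname = "LIG",
                         chain = "L", stringsAsFactors = FALSE),
              matrix(0, 1, 3))
}
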