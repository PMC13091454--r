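# Fixtures are built in code; nothing binary ships with the tests.

# bare atom-table builder for toy models
toy_atoms <- function(xyz, name = "C", element = "C", res_name = "ALA",
                      chain_id = "A", res_seq = NULL, occupancy = 1,
                      alt_loc = "", is_hetero = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = rep_len(name, n), element = rep_len(element, n),
             alt_loc = rep_len(alt_loc, n), res_name = rep_len(res_name, n),
             chain_id = rep_len(chain_id, n),
             res_seq = if (is.null(res_seq)) seq_len(n) else rep_len(res_seq, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = rep_len(occupancy, n),
             is_hetero = rep_len(is_hetero, n),
             stringsAsFactors = FALSE)
}

toy_model <- function(...) fibril_model(toy_atoms(...))

# minimal 3-atom PDB text fixture (1 chain, 1 residue)
tiny_pdb_text <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "END")

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_text, path)
  path
}

# analytic SASA of one of two equal spheres of accessible radius r at
# centre distance d < 2r (outer surface minus the occluded spherical cap)
two_sphere_area <- function(r, d) 4 * pi * r^2 - 2 * pi * r * (r - d / 2)

# random proper rotation (uniform via QR of Gaussians)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

default_standin_points <- 240  # sphere points for stand-in energy tests (speed)
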