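# Deterministic synthetic fibril generator and independent brute-force
# oracles. Models carry the structural features the analysis assumes --
# beta-strand-like layers stacked by rise/twist, charged residues exposed on
# one face, optional paired protofilaments -- but side-chain geometry is an
# idealized internal template, not a rotamer library, and is documented as
# non-physical.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Side-chain templates: local coordinates (d, t, u) per atom, where d is the
# side-chain direction in the layer plane (alternating sides residue to
# residue), t the chain tangent, and u the fibril axis. Distances are
# bond-plausible; geometry is idealized.
.sidechain_templates <- list(
  GLY = NULL,
  ALA = list(CB = c(1.5, 0, 0)),
  SER = list(CB = c(1.5, 0, 0), OG = c(2.9, 0.3, 0)),
  CYS = list(CB = c(1.5, 0, 0), SG = c(2.9, 0.3, 0)),
  THR = list(CB = c(1.5, 0, 0), OG1 = c(2.8, 0.7, 0), CG2 = c(2.8, -0.7, 0)),
  VAL = list(CB = c(1.5, 0, 0), CG1 = c(2.8, 0.7, 0), CG2 = c(2.8, -0.7, 0)),
  LEU = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), CD1 = c(4.0, 0.8, 0),
             CD2 = c(4.0, -0.8, 0)),
  ILE = list(CB = c(1.5, 0, 0), CG1 = c(2.8, 0.5, 0), CG2 = c(2.5, -1.0, 0),
             CD1 = c(4.1, 0.8, 0)),
  PRO = list(CB = c(1.5, 0, 0), CG = c(2.7, 0.8, 0), CD = c(2.0, 1.9, 0)),
  MET = list(CB = c(1.5, 0, 0), CG = c(2.9, 0.3, 0), SD = c(4.2, 0, 0),
             CE = c(5.6, 0.4, 0)),
  PHE = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), CD1 = c(3.6, 1.2, 0),
             CD2 = c(3.6, -1.2, 0), CE1 = c(5.0, 1.2, 0),
             CE2 = c(5.0, -1.2, 0), CZ = c(5.7, 0, 0)),
  TYR = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), CD1 = c(3.6, 1.2, 0),
             CD2 = c(3.6, -1.2, 0), CE1 = c(5.0, 1.2, 0),
             CE2 = c(5.0, -1.2, 0), CZ = c(5.7, 0, 0), OH = c(7.1, 0, 0)),
  TRP = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), CD1 = c(3.6, 1.2, 0),
             CD2 = c(3.8, -1.1, 0), NE1 = c(4.9, 1.0, 0),
             CE2 = c(5.1, -0.3, 0), CE3 = c(3.9, -2.4, 0),
             CZ2 = c(6.4, -0.8, 0), CZ3 = c(5.2, -2.9, 0),
             CH2 = c(6.5, -2.1, 0)),
  ASP = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), OD1 = c(3.6, 1.1, 0),
             OD2 = c(3.6, -1.1, 0)),
  GLU = list(CB = c(1.5, 0, 0), CG = c(2.9, 0.3, 0), CD = c(4.3, 0, 0),
             OE1 = c(5.0, 1.1, 0), OE2 = c(5.0, -1.1, 0)),
  ASN = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), OD1 = c(3.6, 1.1, 0),
             ND2 = c(3.6, -1.1, 0)),
  GLN = list(CB = c(1.5, 0, 0), CG = c(2.9, 0.3, 0), CD = c(4.3, 0, 0),
             OE1 = c(5.0, 1.1, 0), NE2 = c(5.0, -1.1, 0)),
  LYS = list(CB = c(1.5, 0, 0), CG = c(2.9, 0.3, 0), CD = c(4.3, 0, 0),
             CE = c(5.7, 0.3, 0), NZ = c(7.0, 0, 0)),
  ARG = list(CB = c(1.5, 0, 0), CG = c(2.9, 0.3, 0), CD = c(4.3, 0, 0),
             NE = c(5.6, 0.3, 0), CZ = c(6.9, 0, 0), NH1 = c(7.6, 1.1, 0),
             NH2 = c(7.6, -1.1, 0)),
  HIS = list(CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), ND1 = c(3.6, 1.1, 0),
             CD2 = c(3.7, -1.1, 0), CE1 = c(4.9, 0.9, 0),
             NE2 = c(5.0, -0.6, 0))
)

#' Synthetic fibril recipe
#'
#' @param sequence one-letter amino-acid string (standard residues only)
#' @param path_shape in-plane backbone path: `straight`, `c_shape` (240
#'   degree arc), or `s_shape` (two opposed half-turns)
#' @param rise,twist helical parameters relating successive layers
#'   (defaults 4.8 A / -1.2 degrees, a generic left-handed amyloid)
#' @param n_layers number of layers in [make_fibril()]
#' @param protofilaments 1 or 2 (2: second chain by a 2-fold about the axis)
#' @param start_res author number of the first residue (default 1)
#' @param jitter_sd optional Gaussian coordinate noise (A; default 0 = off)
#' @param seed RNG seed for jitter; generation is fully deterministic given
#'   the seed, and with `jitter_sd = 0` the seed is irrelevant
#' @export
fibril_recipe <- function(sequence,
                          path_shape = c("straight", "c_shape", "s_shape"),
                          rise = 4.8, twist = -1.2, n_layers = 5,
                          protofilaments = 1, start_res = 1L,
                          jitter_sd = 0, seed = 1L) {
  path_shape <- match.arg(path_shape)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop("sequence must be non-empty")
  bad <- setdiff(letters1, names(AA1TO3))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  stopifnot(n_layers >= 1, protofilaments %in% c(1, 2))
  structure(list(sequence = letters1, path_shape = path_shape, rise = rise,
                 twist = twist, n_layers = n_layers,
                 protofilaments = protofilaments,
                 start_res = as.integer(start_res),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "fibril_recipe")
}

# In-plane path: positions and unit tangents at arc-length spacing `spacing`
# for n points. Paths are laid out in the xy plane and then translated so
# their centroid sits 15 A from the fibril (z) axis, keeping a 2-fold mate
# clash-free.
path_points <- function(n, shape, spacing = 4.8) {
  s <- (seq_len(n) - 1) * spacing
  if (shape == "straight") {
    pos <- cbind(s, 0)
    tan <- cbind(rep(1, n), 0)
  } else if (shape == "c_shape") {
    total_angle <- 240 * pi / 180
    Rc <- max(s) / total_angle
    th <- s / Rc
    pos <- cbind(Rc * cos(th), Rc * sin(th))
    tan <- cbind(-sin(th), cos(th))
  } else { # s_shape: two opposed half-turns
    half <- max(s) / 2
    Rc <- half / pi
    th <- pmin(s, half) / Rc
    pos1 <- cbind(Rc * sin(th), Rc * (1 - cos(th)))
    tan1 <- cbind(cos(th), sin(th))
    s2 <- pmax(s - half, 0)
    th2 <- s2 / Rc
    # continue from the end of arc 1 (at (0, 2Rc), tangent (-1, 0)) on a
    # circle curving the other way
    pos2 <- cbind(-Rc * sin(th2), 2 * Rc + Rc * (1 - cos(th2)))
    tan2 <- cbind(-cos(th2), sin(th2))
    first <- s <= half
    pos <- ifelse(cbind(first, first), pos1, pos2)
    tan <- ifelse(cbind(first, first), tan1, tan2)
  }
  ctr <- colMeans(pos)
  pos <- sweep(pos, 2, ctr)
  pos[, 1] <- pos[, 1] + 15
  list(pos = pos, tangent = tan)
}

#' Build one synthetic fibril layer
#'
#' Residues are placed along the recipe's 2D path at ~4.8 A CA-CA spacing in
#' the xy plane (the fibril axis is z), with full heavy-atom side chains
#' from idealized templates oriented alternately to either side of the path
#' normal. With `protofilaments = 2` the second chain is the first rotated
#' 180 degrees about the axis.
#'
#' @param recipe a [fibril_recipe()]
#' @return a [fibril_model()] with one chain per protofilament (ids "A", "B")
#' @export
make_layer <- function(recipe) {
  stopifnot(inherits(recipe, "fibril_recipe"))
  seq1 <- recipe$sequence
  n <- length(seq1)
  pp <- path_points(n, recipe$path_shape)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res3 <- AA1TO3[[seq1[i]]]
    t2 <- pp$tangent[i, ]
    n2 <- c(-t2[2], t2[1])              # in-plane normal
    d2 <- n2 * if (i %% 2L == 0L) -1 else 1
    ca <- pp$pos[i, ]
    place <- function(d_comp, t_comp, u_comp) {
      c(ca + d_comp * d2 + t_comp * t2, u_comp)
    }
    atoms <- list(N = place(0.3, -1.2, 0), CA = place(0, 0, 0),
                  C = place(0.3, 1.2, 0), O = place(0.3, 1.6, 1.1))
    tmpl <- .sidechain_templates[[res3]]
    for (nm in names(tmpl)) {
      lc <- tmpl[[nm]]
      atoms[[nm]] <- place(lc[1], lc[2], lc[3])
    }
    xyz <- do.call(rbind, atoms)
    rows[[i]] <- data.frame(
      serial = 0L, name = names(atoms),
      element = vapply(names(atoms), guess_element, character(1)),
      alt_loc = "", res_name = res3, chain_id = "A",
      res_seq = recipe$start_res + i - 1L,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, rows)
  if (recipe$protofilaments == 2L) {
    b <- a
    b$chain_id <- "B"
    b$x <- -a$x
    b$y <- -a$y
    a <- rbind(a, b)
  }
  a$serial <- seq_len(nrow(a))
  ci <- data.frame(chain_id = unique(a$chain_id),
                   layer = NA_integer_, protofilament = NA_integer_,
                   stringsAsFactors = FALSE)
  ci$protofilament <- seq_len(nrow(ci)) - 1L
  fibril_model(a, label = sprintf("synthetic_%s", recipe$path_shape),
               chain_info = ci)
}

#' Build a synthetic N-layer fibril
#'
#' [make_layer()] expanded by [apply_helical_symmetry()] with the recipe's
#' rise/twist, layers and protofilaments annotated. Optional seeded Gaussian
#' jitter is applied to the expanded stack (for robustness tests; default
#' off). A near-180-degree twist with a single protofilament per layer
#' yields the pseudo-2-fold-screw paired architecture.
#'
#' @param recipe a [fibril_recipe()]
#' @return a [fibril_model()]
#' @export
make_fibril <- function(recipe) {
  layer <- make_layer(recipe)
  params <- helical_params(recipe$rise, recipe$twist)
  stack <- apply_helical_symmetry(layer, params, recipe$n_layers)
  if (recipe$jitter_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(recipe$seed)
    xyz <- coords(stack) +
      matrix(stats::rnorm(3L * nrow(stack$atoms), sd = recipe$jitter_sd),
             ncol = 3)
    stack <- set_coords(stack, xyz)
  }
  stack
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Brute-force SASA oracle
#'
#' Independent re-implementation of the Shrake-Rupley estimate used by
#' [sasa()]: a different deterministic point lattice (equal-area latitude
#' bands rather than a golden-angle spiral), naive all-pairs occlusion, no
#' neighbour lists, pure R. Slow by design; intended for models of at most
#' a couple of thousand atoms.
#'
#' @param model a [fibril_model()] (hydrogens/heteroatoms removed as in
#'   [sasa()])
#' @param radii a [radius_set()]
#' @param n_points points per atom (>= 10000 recommended for oracle duty)
#' @return atom table with an `area` column
#' @export
brute_force_sasa <- function(model, radii = radius_set(), n_points = 10000) {
  m <- sasa_prep(model, include_hetero = FALSE)
  r <- atom_radii(m, radii)
  R <- r + radii$probe_radius
  xyz <- coords(m)
  n <- nrow(xyz)
  P <- latitude_band_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(P * R[i], 2, xyz[i, ], "+")
    alive <- rep(TRUE, nrow(P))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      alive <- alive & d2 >= R[j]^2
      if (!any(alive)) break
    }
    area[i] <- 4 * pi * R[i]^2 * mean(alive)
  }
  out <- m$atoms
  out$area <- area
  out
}

# Equal-area latitude-band lattice (Deserno construction), deterministic.
latitude_band_points <- function(n) {
  a <- 4 * pi / n
  d <- sqrt(a)
  m_theta <- round(pi / d)
  d_theta <- pi / m_theta
  d_phi <- a / d_theta
  pts <- list()
  for (mi in seq_len(m_theta) - 1) {
    theta <- pi * (mi + 0.5) / m_theta
    m_phi <- round(2 * pi * sin(theta) / d_phi)
    if (m_phi < 1) m_phi <- 1
    phi <- 2 * pi * (seq_len(m_phi) - 1) / m_phi
    pts[[mi + 1]] <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                           rep(cos(theta), m_phi))
  }
  do.call(rbind, pts)
}

#' End-to-end energy/compensation test fixture
#'
#' Builds a 5-layer lysine-ladder fibril, a compensation spec listing the
#' central chain's lysines, and the expected compensation delta computed by
#' direct re-summation of the nullified NZ terms from the area table -- an
#' independent bookkeeping path against which
#' [apply_charge_compensation()] can be checked exactly.
#'
#' @param asp an [asp_table()]
#' @param n_sphere_points see [sasa()]
#' @return list with `model` (the stack), `chain` (central chain id),
#'   `areas`, `spec`, and `expected_delta` (kcal/mol, <= 0): the expected
#'   change in dG per chain upon compensation
#' @export
make_energy_fixture <- function(asp = asp_table(), n_sphere_points = 240) {
  recipe <- fibril_recipe("ALKALKALKA", "straight", rise = 4.8, twist = -1.2,
                          n_layers = 5)
  stack <- make_fibril(recipe)
  chain <- central_chain_ids(stack)[1]
  areas <- buried_areas(stack, chain, n_sphere_points = n_sphere_points)
  kres <- unique(areas[areas$res_name == "LYS", c("chain_id", "res_seq")])
  spec <- compensation_spec(data.frame(chain_id = kres$chain_id,
                                       res_seq = kres$res_seq,
                                       res_name = "LYS"),
                            label = "lysine_ladder")
  # independent path: sum the positive NZ penalty terms straight off the
  # area table
  nz <- areas$res_name == "LYS" & areas$name == "NZ" &
        areas$res_seq %in% kres$res_seq
  sig <- asp$sigma[["charged_N_plus"]]
  penalty_terms <- -sig * areas$buried[nz]
  expected_delta <- -sum(penalty_terms[penalty_terms > 0])
  list(model = stack, chain = chain, areas = areas, spec = spec,
       expected_delta = expected_delta)
}
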