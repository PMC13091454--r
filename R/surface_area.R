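# Solvent-accessible surface area (Shrake-Rupley) and buried area of a
# designated chain within the fibril assembly.

#' Van der Waals radius set
#'
#' Radii used for SASA; implementation defaults, not literature-reproduced
#' constants. Unknown elements take `fallback` unless `fallback = NA`, in
#' which case they are an error.
#'
#' @param radii named numeric vector, element symbol -> radius (Angstrom)
#' @param probe_radius solvent probe radius (Angstrom, default 1.4, water)
#' @param fallback radius for unlisted elements (default 1.70; `NA` to forbid)
#' @export
radius_set <- function(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80),
                       probe_radius = 1.4, fallback = 1.70) {
  stopifnot(all(radii > 0), probe_radius >= 0)
  structure(list(radii = radii, probe_radius = probe_radius,
                 fallback = fallback), class = "radius_set")
}

# per-atom vdW radii for a model under a radius_set
atom_radii <- function(model, radii) {
  el <- toupper(model$atoms$element)
  r <- unname(radii$radii[el])
  if (anyNA(r)) {
    if (is.na(radii$fallback)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "))
    }
    r[is.na(r)] <- radii$fallback
  }
  r
}

# shared preprocessing: heavy protein atoms (hydrogens always removed;
# heteroatoms removed unless retained as occluders)
sasa_prep <- function(model, include_hetero = FALSE) {
  m <- drop_hydrogens(model)
  if (!include_hetero && any(m$atoms$is_hetero)) m <- drop_hetero(m)
  m
}

# Canonical orientation: rotate coordinates into the model's principal-axis
# frame (signs fixed by third moments, proper-rotation enforced). The sphere
# lattice is fixed in this frame, so a rigidly moved model sees an
# identically moved lattice and SASA is exactly invariant under rigid
# motion. Skipped for < 3 atoms (areas there are frame-independent anyway).
canonical_orient <- function(xyz) {
  if (nrow(xyz) < 3L) return(xyz)
  X <- sweep(xyz, 2, colMeans(xyz))
  ei <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- ei$vectors
  for (k in 1:2) {
    s <- sum((X %*% V[, k])^3)
    if (s < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  X %*% V
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, the fraction of a deterministic quasi-uniform point set on
#' the sphere of radius (r_vdw + probe) not inside any neighbour's expanded
#' sphere, times the sphere area. The point set is a golden-angle spiral
#' lattice; no randomness is involved, so results are exactly reproducible.
#'
#' @param model a [fibril_model()]; hydrogens are removed, heteroatoms are
#'   excluded unless `include_hetero = TRUE` (then they occlude and are
#'   scored like other atoms)
#' @param radii a [radius_set()]
#' @param n_sphere_points points per atom (>= 60; default 960, at which the
#'   total buried area of a fibril chain is converged to well under 0.5%)
#' @param include_hetero keep HETATM records as occluders
#' @param orient evaluate in the model's canonical principal-axis frame
#'   (default), which makes the estimate exactly invariant under rigid
#'   motion of the whole model; with `FALSE` the lattice is fixed in the lab
#'   frame, which instead makes area exactly monotone when comparing the
#'   same coordinates with occluders added
#' @return the model's (filtered) atom table with an `area` column (Angstrom^2)
#' @export
sasa <- function(model, radii = radius_set(), n_sphere_points = 960,
                 include_hetero = FALSE, orient = TRUE) {
  if (n_sphere_points < 60) stop("n_sphere_points must be >= 60")
  m <- sasa_prep(model, include_hetero)
  r <- atom_radii(m, radii)
  xyz <- if (orient) canonical_orient(coords(m)) else coords(m)
  area <- sasa_cpp(xyz, r, radii$probe_radius, as.integer(n_sphere_points))
  out <- m$atoms
  out$area <- area
  out
}

#' Per-atom reference (fully solvated) areas for one chain
#'
#' The reference state against which burial is measured: each residue is
#' scored in a minimal host context -- the residue plus its covalently
#' adjacent residues (author numbering +/- 1), extracted in situ -- standing
#' in for the unfolded, fully solvated chain. For an isolated one-residue
#' chain the reference is the isolated-residue SASA.
#'
#' @param chain_model a [fibril_model()] restricted to a single chain
#' @param radii a [radius_set()]
#' @param n_sphere_points see [sasa()]
#' @return atom table with a `reference` column (Angstrom^2)
#' @export
reference_areas <- function(chain_model, radii = radius_set(),
                            n_sphere_points = 960) {
  m <- sasa_prep(chain_model, include_hetero = FALSE)
  chs <- chain_ids(m)
  if (length(chs) != 1L) {
    stop("reference_areas expects a single chain, got: ",
         paste(chs, collapse = ", "))
  }
  a <- m$atoms
  res <- sort(unique(a$res_seq))
  ref <- numeric(nrow(a))
  for (rs in res) {
    host <- a$res_seq %in% c(rs - 1L, rs, rs + 1L)
    target <- which(a$res_seq[host] == rs)
    hm <- fibril_model(a[host, , drop = FALSE], "host")
    r <- atom_radii(hm, radii)
    area <- sasa_cpp(canonical_orient(coords(hm)), r, radii$probe_radius,
                     as.integer(n_sphere_points))
    ref[which(host)[target]] <- area[target]
  }
  out <- a
  out$reference <- ref
  out
}

#' Buried area of a target chain within a fibril stack
#'
#' Assembly areas come from [sasa()] on the full stack restricted to the
#' target chain; reference areas from [reference_areas()] on the target
#' chain alone (in situ). Buried area is `max(0, reference - assembly)` per
#' atom. For fibril use the stack should contain the chain's occluding
#' context (>= 3 layers, target in the middle).
#'
#' @param stack a [fibril_model()] containing the occluding assembly
#' @param target_chain chain id to score
#' @param radii a [radius_set()]
#' @param n_sphere_points see [sasa()]
#' @param include_hetero keep HETATM records as occluders (never scored)
#' @return data.frame of class `atom_areas`: chain_id, res_seq, res_name,
#'   name, element, reference, assembly, buried (Angstrom^2)
#' @export
buried_areas <- function(stack, target_chain, radii = radius_set(),
                         n_sphere_points = 960, include_hetero = FALSE) {
  if (!target_chain %in% stack$atoms$chain_id) {
    stop("target chain '", target_chain, "' absent from stack (chains: ",
         paste(utils::head(chain_ids(stack), 12), collapse = ", "), ")")
  }
  asm <- sasa(stack, radii, n_sphere_points, include_hetero = include_hetero)
  asm <- asm[asm$chain_id == target_chain & !asm$is_hetero, , drop = FALSE]
  chain_only <- fibril_model(
    stack$atoms[stack$atoms$chain_id == target_chain &
                !stack$atoms$is_hetero, , drop = FALSE],
    label = target_chain)
  ref <- reference_areas(chain_only, radii, n_sphere_points)
  key <- function(d) paste(d$res_seq, d$name)
  idx <- match(key(asm), key(ref))
  if (anyNA(idx)) stop("internal error: assembly/reference atom mismatch")
  out <- asm[, c("chain_id", "res_seq", "res_name", "name", "element")]
  out$reference <- ref$reference[idx]
  out$assembly <- asm$area
  out$buried <- pmax(0, out$reference - out$assembly)
  class(out) <- c("atom_areas", class(out))
  out
}
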