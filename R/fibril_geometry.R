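# Helical geometry: expansion of one fibril layer into an N-layer stack and
# recovery of rise/twist from a deposited stack via screw decomposition.

#' Helical parameters
#'
#' @param rise translation per subunit along the fibril axis (Angstrom, > 0).
#' @param twist rotation per subunit about the axis (degrees, in (-180, 180]).
#'   Amyloid fibrils are typically left-handed with small negative twist;
#'   paired protofilaments related by a pseudo-2-fold screw show twist near
#'   180 degrees with roughly halved rise.
#' @param symmetry_class `"C1_single"` or `"pseudo_21_paired"`.
#' @param pseudo21_tol how close |twist| must be to 180 degrees for
#'   `pseudo_21_paired` (degrees).
#' @export
helical_params <- function(rise, twist,
                           symmetry_class = c("C1_single", "pseudo_21_paired"),
                           pseudo21_tol = 5) {
  symmetry_class <- match.arg(symmetry_class)
  stopifnot(is.finite(rise), is.finite(twist))
  if (rise <= 0) stop("rise must be > 0")
  if (twist <= -180 || twist > 180) stop("twist must lie in (-180, 180]")
  if (symmetry_class == "pseudo_21_paired" && abs(abs(twist) - 180) > pseudo21_tol) {
    stop(sprintf("pseudo_21_paired requires |twist| within %g deg of 180 (got %g)",
                 pseudo21_tol, twist))
  }
  structure(list(rise = rise, twist = twist, symmetry_class = symmetry_class),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params rise=%.5g A, twist=%.5g deg, %s>\n",
              x$rise, x$twist, x$symmetry_class))
  invisible(x)
}

#' Axis frame for helical operations
#' @param origin point on the axis (3-vector, Angstrom)
#' @param direction axis direction (3-vector; normalised internally)
#' @export
axis_frame <- function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  stopifnot(length(origin) == 3, length(direction) == 3,
            all(is.finite(origin)), all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("degenerate axis frame: zero direction vector")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm),
            class = "axis_frame")
}

# Rodrigues rotation matrix about unit axis u by angle (radians)
rotation_about_axis <- function(u, angle) {
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * (u %o% u)
}

#' Expand one fibril layer into an N-layer helical stack
#'
#' Layer k (k = 0..n_layers-1) is the input layer rotated by k*twist about
#' the axis and translated by k*rise along it. By default the stack is
#' centred: the input layer sits at the middle layer index so the deposited
#' layer is the interior, fully occluded one. Chain ids gain a `_Lk` suffix
#' and the returned model carries layer/protofilament annotations.
#'
#' @param layer a [fibril_model()] holding a single layer (one chain per
#'   protofilament)
#' @param params a [helical_params()]
#' @param n_layers number of layers (>= 1)
#' @param frame an [axis_frame()]; default: z axis through the origin
#' @param center if `TRUE` (default) layers run from `-floor(n/2)` to
#'   `n - 1 - floor(n/2)` so the input layer is central; layer indices in the
#'   output are renumbered 0..n_layers-1 bottom to top.
#' @return a [fibril_model()] with `n_layers` copies of each input chain
#' @export
apply_helical_symmetry <- function(layer, params, n_layers,
                                   frame = axis_frame(), center = TRUE) {
  stopifnot(inherits(layer, "fibril_model"), inherits(params, "helical_params"),
            inherits(frame, "axis_frame"))
  if (n_layers < 1) stop("n_layers must be >= 1")
  base_chains <- chain_ids(layer)
  if (!length(base_chains)) stop("layer contains no chains")
  proto_of <- stats::setNames(seq_along(base_chains) - 1L, base_chains)
  if (!is.null(layer$chain_info) &&
      all(base_chains %in% layer$chain_info$chain_id)) {
    pf <- layer$chain_info$protofilament[match(base_chains,
                                               layer$chain_info$chain_id)]
    if (!anyNA(pf)) proto_of[] <- pf
  }
  offset <- if (center) -(n_layers %/% 2L) else 0L
  u <- frame$direction
  xyz0 <- sweep(coords(layer), 2, frame$origin, "-")
  pieces <- vector("list", n_layers)
  infos <- vector("list", n_layers)
  for (k in seq_len(n_layers) - 1L) {
    kk <- k + offset
    R <- rotation_about_axis(u, kk * params$twist * pi / 180)
    xyz <- xyz0 %*% t(R)
    xyz <- sweep(xyz, 2, frame$origin + kk * params$rise * u, "+")
    a <- layer$atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    new_ids <- sprintf("%s_L%d", a$chain_id, k)
    infos[[k + 1L]] <- data.frame(
      chain_id = sprintf("%s_L%d", base_chains, k),
      layer = k,
      protofilament = unname(proto_of[base_chains]),
      stringsAsFactors = FALSE)
    a$chain_id <- new_ids
    pieces[[k + 1L]] <- a
  }
  atoms <- do.call(rbind, pieces)
  atoms$serial <- seq_len(nrow(atoms))
  fibril_model(atoms,
               label = sprintf("%s_stack%d", layer$label, n_layers),
               chain_info = do.call(rbind, infos))
}

# layer annotations: explicit chain_info, `_Lk` chain-id suffixes, or --
# for deposited-style stacks with plain chain ids -- geometric inference
# (chains with identical residue content ordered along the principal axis
# of their centroids; one chain per layer).
layer_table <- function(stack) {
  if (!is.null(stack$chain_info)) return(stack$chain_info)
  ch <- chain_ids(stack)
  m <- regmatches(ch, regexec("_L([0-9]+)$", ch))
  lay <- vapply(m, function(g) if (length(g) == 2L) as.integer(g[2]) else NA_integer_,
                integer(1))
  if (!anyNA(lay)) {
    base <- sub("_L[0-9]+$", "", ch)
    return(data.frame(chain_id = ch, layer = lay,
                      protofilament = as.integer(factor(base)) - 1L,
                      stringsAsFactors = FALSE))
  }
  # geometric fallback
  a <- stack$atoms[!stack$atoms$is_hetero, , drop = FALSE]
  sig <- vapply(ch, function(cc) {
    aa <- a[a$chain_id == cc, , drop = FALSE]
    paste(sort(paste(aa$res_seq, aa$name)), collapse = "|")
  }, character(1))
  if (length(unique(sig)) != 1L) {
    stop("cannot infer layers: chains ", paste(ch, collapse = ", "),
         " do not share a common residue set")
  }
  ctr <- t(vapply(ch, function(cc) {
    colMeans(as.matrix(a[a$chain_id == cc, c("x", "y", "z")]))
  }, numeric(3)))
  C <- sweep(ctr, 2, colMeans(ctr))
  axis <- eigen(crossprod(C), symmetric = TRUE)$vectors[, 1]
  ord <- order(C %*% axis)
  data.frame(chain_id = ch[ord], layer = seq_along(ch) - 1L,
             protofilament = 0L, stringsAsFactors = FALSE)
}

#' Estimate helical rise and twist from a multi-layer stack
#'
#' For each pair of adjacent layers the rigid transform superposing layer k
#' onto layer k+1 is found by Kabsch superposition of CA atoms, then screw-
#' decomposed: the rotation angle comes from the rotation-matrix trace, the
#' axis from its +1 eigenvector (oriented so the rise is positive), and the
#' rise is the translation component along the axis. Rise and twist are
#' averaged over layer pairs.
#'
#' @param stack a [fibril_model()] with >= 2 annotated layers
#' @param atoms atom names used for superposition (default CA)
#' @return a [helical_params()] with attributes `axis` (an [axis_frame()])
#'   and `per_pair` (matrix of per-pair estimates)
#' @export
estimate_helical_params <- function(stack, atoms = "CA") {
  lt <- layer_table(stack)
  layers <- sort(unique(lt$layer))
  if (length(layers) < 2L) stop("need >= 2 layers to estimate helical parameters")
  layer_coords <- function(k) {
    chs <- lt$chain_id[lt$layer == k]
    a <- stack$atoms[stack$atoms$chain_id %in% chs &
                     stack$atoms$name %in% atoms & !stack$atoms$is_hetero, ,
                     drop = FALSE]
    pf <- lt$protofilament[match(a$chain_id, lt$chain_id)]
    ord <- order(pf, a$res_seq, a$name)
    a <- a[ord, , drop = FALSE]
    list(xyz = as.matrix(a[, c("x", "y", "z")]),
         key = paste(pf[ord], a$res_seq, a$name))
  }
  per <- NULL
  axes <- NULL
  origins <- NULL
  for (i in seq_len(length(layers) - 1L)) {
    A <- layer_coords(layers[i]); B <- layer_coords(layers[i + 1L])
    if (!identical(A$key, B$key)) {
      stop(sprintf("layers %d and %d have mismatched residue sets (%d vs %d %s atoms)",
                   layers[i], layers[i + 1L], nrow(A$xyz), nrow(B$xyz),
                   paste(atoms, collapse = ",")))
    }
    sp <- kabsch_superpose(B$xyz, A$xyz)  # transform mapping layer k -> k+1
    sd <- screw_decompose(sp$rotation, sp$translation)
    per <- rbind(per, c(rise = sd$rise, twist = sd$twist))
    axes <- rbind(axes, sd$axis)
    origins <- rbind(origins, sd$origin)
  }
  rise <- mean(per[, "rise"])
  # average twist on the circle to be safe near +/-180
  ang <- per[, "twist"] * pi / 180
  twist <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  cls <- if (abs(abs(twist) - 180) <= 5) "pseudo_21_paired" else "C1_single"
  hp <- helical_params(rise, twist, cls)
  attr(hp, "axis") <- axis_frame(colMeans(origins), colMeans(axes))
  attr(hp, "per_pair") <- per
  hp
}

# screw decomposition of y = R x + t: unit axis u (oriented so u.t >= 0),
# signed angle about u, rise u.t, and a point on the axis.
screw_decompose <- function(R, t) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  angle <- acos(ct)
  if (angle < 1e-9) {
    # pure translation: axis along t
    nt <- sqrt(sum(t^2))
    u <- if (nt < 1e-12) c(0, 0, 1) else t / nt
    return(list(axis = u, twist = 0, rise = sum(u * t), origin = c(0, 0, 0)))
  }
  if (abs(angle - pi) < 1e-9) {
    # 180 degrees: axis from R + I column space
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    u <- M[, j] / sqrt(sum(M[, j]^2))
  } else {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    u <- v / (2 * sin(angle))
  }
  # sign of angle is tied to u; orient u so the rise is positive
  if (sum(u * t) < 0) {
    u <- -u
    angle <- -angle
  }
  rise <- sum(u * t)
  # axis origin: solve (I - R) p = t_perp in the plane normal to u
  t_perp <- t - rise * u
  A <- diag(3) - R
  p <- tryCatch(qr.solve(A + u %o% u, t_perp), error = function(e) c(0, 0, 0))
  list(axis = u, twist = angle * 180 / pi, rise = rise, origin = as.numeric(p))
}

#' Chains of the central (fully occluded) layer
#'
#' Energies are evaluated on interior chains so both axial neighbours
#' occlude; the central layer is index `floor(n/2)` of a 0-based stack.
#' For paired protofilaments both chains of that layer are returned.
#'
#' @param stack a [fibril_model()] with >= 3 annotated layers
#' @return character vector of chain ids
#' @export
central_chain_ids <- function(stack) {
  lt <- layer_table(stack)
  layers <- sort(unique(lt$layer))
  if (length(layers) < 3L) {
    stop("no fully occluded layer: stack has ", length(layers),
         " layer(s), need >= 3")
  }
  mid <- layers[length(layers) %/% 2L + 1L]
  lt$chain_id[lt$layer == mid]
}
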