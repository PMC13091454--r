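#' @useDynLib fibrilstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a fibril model
#'
#' A `fibril_model` is the package's uniform hierarchical container for
#' atomic models: a flat atom table (one row per atom, author residue
#' numbering) plus optional per-chain layer/protofilament annotations.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `res_name`, `chain_id`, `res_seq`, `x`, `y`, `z`,
#'   `occupancy`, `is_hetero`. Coordinates in Angstrom; `res_seq` is the
#'   author (deposited) residue number and is authoritative throughout.
#' @param label provenance label (free text, e.g. a file name or recipe id).
#' @param chain_info optional data.frame with columns `chain_id`, `layer`,
#'   `protofilament` annotating fibril layers (0-based layer index).
#' @return object of class `fibril_model`.
#' @export
fibril_model <- function(atoms, label = "model", chain_info = NULL) {
  required <- c("serial", "name", "element", "alt_loc", "res_name",
                "chain_id", "res_seq", "x", "y", "z", "occupancy",
                "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates in atom table")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$is_hetero <- as.logical(atoms$is_hetero)
  rownames(atoms) <- NULL
  if (!is.null(chain_info)) {
    stopifnot(all(c("chain_id", "layer", "protofilament") %in% names(chain_info)))
    has_layer <- !is.na(chain_info$layer)
    if (any(has_layer & is.na(chain_info$protofilament))) {
      stop("every chain with a layer index needs a protofilament index")
    }
  }
  structure(list(atoms = atoms, label = label, chain_info = chain_info),
            class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[!a$is_hetero, c("chain_id", "res_seq")]))
  cat(sprintf("<fibril_model '%s': %d atoms, %d chains, %d protein residues>\n",
              x$label, nrow(a), length(unique(a$chain_id)), nres))
  if (!is.null(x$chain_info)) {
    cat(sprintf("  layers: %s\n",
                paste(sort(unique(x$chain_info$layer)), collapse = " ")))
  }
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param model a `fibril_model`
#' @return n x 3 numeric matrix (Angstrom)
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Chain identifiers present in a model
#' @param model a `fibril_model`
#' @export
chain_ids <- function(model) unique(model$atoms$chain_id)

#' Count ordered (modeled) residues
#'
#' Counts distinct non-hetero residues, optionally per chain. This is the
#' denominator used for per-residue stabilization energies.
#'
#' @param model a `fibril_model`
#' @param chain optional chain id
#' @export
n_residues <- function(model, chain = NULL) {
  a <- model$atoms[!model$atoms$is_hetero, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain_id %in% chain, , drop = FALSE]
  nrow(unique(a[, c("chain_id", "res_seq")]))
}

#' Drop hydrogen atoms
#'
#' Area and energy computations operate on heavy atoms only; deposited
#' cryo-EM fibril models are heavy-atom models, but uploaded or generated
#' files may carry hydrogens.
#'
#' @param model a `fibril_model`
#' @export
drop_hydrogens <- function(model) {
  keep <- !(toupper(model$atoms$element) %in% c("H", "D"))
  if (all(keep)) return(model)
  fibril_model(model$atoms[keep, , drop = FALSE], model$label, model$chain_info)
}

#' Drop hetero (non-polymer) atoms
#' @param model a `fibril_model`
#' @export
drop_hetero <- function(model) {
  keep <- !model$atoms$is_hetero
  if (!any(keep)) stop("model contains only hetero atoms")
  fibril_model(model$atoms[keep, , drop = FALSE], model$label, model$chain_info)
}

#' Replace coordinates of a model
#' @param model a `fibril_model`
#' @param xyz n x 3 matrix matching the atom table
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# internal: rigid transform y = R x + t applied to a model
transform_model <- function(model, R, t) {
  xyz <- coords(model) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  set_coords(model, xyz)
}

# internal: residues of one chain, ordered by res_seq
chain_residues <- function(model, chain) {
  a <- model$atoms[model$atoms$chain_id == chain & !model$atoms$is_hetero, ,
                   drop = FALSE]
  sort(unique(a$res_seq))
}
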