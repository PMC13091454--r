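# Rigid-body superposition (Kabsch) and segment RMSD between fibril folds.

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' sum_i ||A_i - (R B_i + t)||^2 over paired points, via SVD of the
#' covariance matrix with the usual determinant correction so a reflection
#' is never returned.
#'
#' @param coords_A,coords_B n x 3 matrices of paired coordinates (n >= 3)
#' @return object of class `superposition` with fields `rotation` (3 x 3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom), `n_atoms`, and
#'   `transformed` (B mapped onto A)
#' @export
kabsch_superpose <- function(coords_A, coords_B) {
  A <- as.matrix(coords_A); B <- as.matrix(coords_B)
  if (!all(dim(A) == dim(B))) {
    stop(sprintf("coordinate sets differ in size: %d vs %d points",
                 nrow(A), nrow(B)))
  }
  if (nrow(A) < 3L) stop("need >= 3 paired points")
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cA - R %*% cB)
  Bt <- B %*% t(R)
  Bt <- sweep(Bt, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((A - Bt)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_atoms = nrow(A), transformed = Bt, pairing = NULL),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.3f A over %d atoms>\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' RMSD between residue segments of two models
#'
#' Extracts the two closed residue ranges, filters to the named atoms
#' (default CA), pairs residues strictly by position (i-th onto i-th; the
#' segments may cover different sequence positions, so sequence-based
#' pairing is deliberately not offered), and superposes with
#' [kabsch_superpose()].
#'
#' @param model_A,model_B [fibril_model()] objects
#' @param range_A,range_B lists `list(chain=, start=, end=)`
#' @param atoms atom name filter (default `"CA"`)
#' @return a `superposition` with a `pairing` data.frame of matched residue
#'   numbers
#' @export
segment_rmsd <- function(model_A, range_A, model_B, range_B, atoms = "CA") {
  seg <- function(m, r) {
    s <- select_segment(m, r$chain, r$start, r$end, atom_filter = atoms)
    a <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
    a[order(a$res_seq, a$name), , drop = FALSE]
  }
  a <- seg(model_A, range_A)
  b <- seg(model_B, range_B)
  if (nrow(a) != nrow(b)) {
    stop(sprintf("segments yield unequal atom counts: %d (%s:%d-%d) vs %d (%s:%d-%d)",
                 nrow(a), range_A$chain, range_A$start, range_A$end,
                 nrow(b), range_B$chain, range_B$start, range_B$end))
  }
  res <- kabsch_superpose(as.matrix(a[, c("x", "y", "z")]),
                          as.matrix(b[, c("x", "y", "z")]))
  res$pairing <- data.frame(res_seq_A = a$res_seq, res_seq_B = b$res_seq)
  res
}
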