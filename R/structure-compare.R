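# Rigid-body structure superposition (Kabsch) and the Q-score metric used
# to compare catalytic-domain models.

#' Read a structure model from a PDB file
#'
#' Keeps one representative alpha-carbon per residue (residues lacking a CA
#' are dropped with a warning).
#'
#' @param path PDB-format file (ATOM records)
#' @param id model id (defaults to the file name)
#' @return a \code{structure_model}: data.frame of residues with
#'   \code{resno}, \code{resid}, \code{x}, \code{y}, \code{z}
#' @export
read_structure <- function(path, id = basename(path)) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  all_res <- unique(at$resno[at$type == "ATOM"])
  missing <- setdiff(all_res, ca$resno)
  if (length(missing))
    warning("residues without CA dropped: ", paste(missing, collapse = ", "))
  structure_model(ca$resno, ca$resid, as.matrix(ca[, c("x", "y", "z")]), id)
}

#' Construct a structure model from coordinates
#'
#' @param resno residue numbers
#' @param resid residue names
#' @param xyz numeric matrix n x 3 of representative-atom coordinates (A)
#' @param id model id
#' @return a \code{structure_model}
#' @export
structure_model <- function(resno, resid, xyz, id = "model") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 3L, all(is.finite(xyz)))
  structure(list(resno = resno, resid = resid, xyz = xyz, id = id),
            class = "structure_model")
}

#' Kabsch least-squares superposition of two structure models
#'
#' Finds the rigid transform (rotation with determinant +1 and translation;
#' reflections excluded) minimising the RMSD over the corresponded residue
#' pairs.
#'
#' @param a,b \code{structure_model}s (b is moved onto a)
#' @param correspondence integer matrix/data.frame of index pairs (rows:
#'   index in a, index in b); defaults to positional pairing of equal-length
#'   models
#' @return a \code{superposition} list: \code{rotation} (3x3, det +1),
#'   \code{translation}, \code{n_align}, \code{rmsd}, \code{q_score}
#'   (computed with the model sizes), and \code{b_transformed}
#' @export
kabsch_superpose <- function(a, b, correspondence = NULL) {
  if (is.null(correspondence)) {
    if (nrow(a$xyz) != nrow(b$xyz))
      stop("models differ in length; supply an explicit correspondence")
    correspondence <- cbind(seq_len(nrow(a$xyz)), seq_len(nrow(b$xyz)))
  }
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3L) stop("need at least 3 correspondence pairs")
  P <- a$xyz[correspondence[, 1L], , drop = FALSE]   # target
  Q <- b$xyz[correspondence[, 2L], , drop = FALSE]   # moving
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- t(Q0) %*% P0
  sv <- svd(H)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    stop("degenerate (collinear) point set: superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Qr - P0)^2)))
  translation <- cp - as.vector(R %*% cq)
  n_align <- nrow(correspondence)
  q <- q_score(n_align, rmsd, nrow(a$xyz), nrow(b$xyz))
  b_t <- sweep(b$xyz %*% t(R), 2L, translation, "+")
  structure(list(rotation = R, translation = translation,
                 n_align = n_align, rmsd = rmsd, q_score = q,
                 b_transformed = b_t, ids = c(a$id, b$id)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition %s onto %s: N_align=%d RMSD=%.3f A  Q=%.3f\n",
              x$ids[2], x$ids[1], x$n_align, x$rmsd, x$q_score))
  invisible(x)
}

#' Superposition Q-score
#'
#' Q = N_align^2 / ((1 + (RMSD/R0)^2) * N1 * N2) with R0 = 3 A, the usual
#' quality statistic combining aligned-residue count and RMSD; equals 1
#' only for a perfect full-length self-match.
#'
#' @param n_align aligned residue pairs
#' @param rmsd RMSD over the aligned pairs (A)
#' @param n1,n2 residue counts of the two models
#' @param r0 distance scale (A)
#' @return Q in (0, 1]
#' @export
q_score <- function(n_align, rmsd, n1, n2, r0 = 3.0) {
  stopifnot(n_align > 0, n1 > 0, n2 > 0, n_align <= min(n1, n2), rmsd >= 0)
  n_align^2 / ((1 + (rmsd / r0)^2) * n1 * n2)
}
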