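# Least-squares rigid-body superposition (Kabsch, SVD form with proper-
# rotation correction) and a residual-trimmed iterative variant for
# comparing conformational states.

#' Superpose two paired coordinate sets
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` (Kabsch algorithm; reflections are excluded
#' by the determinant correction).
#'
#' @param mobile,reference Paired n x 3 coordinate matrices, n >= 3.
#' @return An object of class `hw_superposition`: list with `rotation`
#'   (3 x 3), `translation` (length 3; the fitted mobile is
#'   `mobile %*% t(rotation) + translation`), `rmsd`, `n`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L)
    stop("mobile and reference must be paired n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 paired points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2L, cm); b <- sweep(reference, 2L, cr)
  if (min(svd(a)$d[2L], svd(b)$d[2L]) < 1e-8)
    stop("degenerate (collinear) point configuration")
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(r)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  out <- list(rotation = r, translation = as.numeric(cr - r %*% cm),
              rmsd = rmsd, n = n)
  class(out) <- "hw_superposition"
  out
}

#' @export
print.hw_superposition <- function(x, ...) {
  cat(sprintf("<hw_superposition> %d pairs, rmsd %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform
#'
#' @param x A [hw_structure] or an n x 3 coordinate matrix.
#' @param sp A `hw_superposition`.
#' @return The transformed object (same type as `x`).
#' @export
apply_transform <- function(x, sp) {
  tf <- function(xyz) sweep(xyz %*% t(sp$rotation), 2L, sp$translation, `+`)
  if (inherits(x, "hw_structure")) return(set_coords(x, tf(atom_coords(x))))
  tf(as.matrix(x))
}

#' Iterative superposition with residual trimming
#'
#' Alternates fitting and exclusion of pairs whose residual exceeds
#' `cutoff` until the retained set is stable (robust core fit for
#' inactive/active state comparisons).
#'
#' @param mobile,reference Paired n x 3 coordinate matrices.
#' @param cutoff Residual cutoff in Angstrom (`Inf` disables trimming).
#' @param max_cycles Maximum alternation cycles.
#' @return A `hw_superposition` with an extra logical element `retained`
#'   (pair mask) and `cycles`.
#' @export
iterative_superpose <- function(mobile, reference, cutoff = 3.5,
                                max_cycles = 10L) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  keep <- rep(TRUE, nrow(mobile))
  sp <- NULL
  for (cyc in seq_len(max_cycles)) {
    if (sum(keep) < 3L)
      stop("fewer than 3 pairs retained; trimming did not converge")
    sp <- superpose(mobile[keep, , drop = FALSE],
                    reference[keep, , drop = FALSE])
    resid <- sqrt(rowSums((apply_transform(mobile, sp) - reference)^2))
    new_keep <- resid <= cutoff
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 pairs retained; trimming did not converge")
  sp$retained <- keep
  sp$cycles <- cyc
  sp$rmsd <- {
    resid <- sqrt(rowSums((apply_transform(mobile, sp) - reference)^2))
    sqrt(mean(resid[keep]^2))
  }
  class(sp) <- "hw_superposition"
  sp
}
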