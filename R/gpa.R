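#' Generalized Procrustes alignment of outlines via their landmarks
#'
#' Superimposition parameters (translation, scaling to unit centroid
#' size, rotation; reflections disallowed) are estimated on the 5-landmark
#' configurations by iterative GPA -- align every configuration to the
#' consensus, recompute the consensus, repeat until the consensus moves
#' by less than `tol` -- and then applied to the full outlines.
#'
#' After convergence the whole set is rotated to a canonical pose: the
#' landmark 5 -> 4 axis (bottom to top of the seed) of the consensus is
#' made to point along +y. This makes the result invariant to arbitrary
#' rotation/translation/scaling of the inputs, so downstream coefficients
#' do not depend on acquisition pose.
#'
#' @param outlines list of [outline()] objects, all with the same point
#'   count (resample first).
#' @param landmarks list of [landmark_set()] objects, parallel to
#'   `outlines`.
#' @param tol convergence tolerance on the consensus displacement.
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`, not an error.
#' @return Object of class `gpa_alignment`: list with `outlines`
#'   (aligned), `landmarks` (aligned configurations), `mean_shape`
#'   (consensus landmark configuration), `iterations`, `converged`.
#' @export
gpa_align <- function(outlines, landmarks, tol = 1e-10, max_iter = 100) {
  n <- length(outlines)
  if (n < 2) stop2("gpa_align needs at least 2 outlines")
  if (length(landmarks) != n) stop2("outlines and landmarks differ in length")
  counts <- vapply(outlines, nrow, integer(1))
  if (length(unique(counts)) != 1L)
    stop2("all outlines must have the same point count; resample first")

  # center and scale each landmark configuration
  cents <- lapply(landmarks, function(l) colMeans(unclass(l)))
  sizes <- mapply(function(l, ce) sqrt(sum(sweep(unclass(l), 2, ce)^2)),
                  landmarks, cents)
  if (any(sizes <= 0)) stop2("degenerate landmark configuration (zero size)")
  confs <- mapply(function(l, ce, s) sweep(unclass(l), 2, ce) / s,
                  landmarks, cents, sizes, SIMPLIFY = FALSE)

  rots <- replicate(n, diag(2), simplify = FALSE)
  consensus <- confs[[1]]
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    aligned <- vector("list", n)
    for (i in seq_len(n)) {
      rots[[i]] <- procrustes_rotation(confs[[i]], consensus)
      aligned[[i]] <- confs[[i]] %*% rots[[i]]
    }
    new_cons <- Reduce(`+`, aligned) / n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge within ", max_iter, " iterations", call. = FALSE)

  # canonical pose: consensus ldk5 -> ldk4 axis along +y
  v <- consensus[4, ] - consensus[5, ]
  ang <- atan2(v[2], v[1])
  canon <- rot_mat(pi / 2 - ang)
  consensus <- consensus %*% t(canon)
  out_aligned <- vector("list", n)
  lmk_aligned <- vector("list", n)
  for (i in seq_len(n)) {
    R <- rots[[i]] %*% t(canon)  # config %*% R, applied as p %*% R
    p <- sweep(unclass(outlines[[i]]), 2, cents[[i]]) / sizes[i]
    out_aligned[[i]] <- rebuild_outline(p %*% R, outlines[[i]])
    lmk_aligned[[i]] <- landmark_set(confs[[i]] %*% R,
                                     image_id = attr(landmarks[[i]], "image_id"))
  }
  names(out_aligned) <- names(outlines)
  names(lmk_aligned) <- names(landmarks)
  structure(list(outlines = out_aligned, landmarks = lmk_aligned,
                 mean_shape = consensus, iterations = iter,
                 converged = converged),
            class = "gpa_alignment")
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat(sprintf("<gpa_alignment> %d outlines, %d iterations, %sconverged\n",
              length(x$outlines), x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

# Optimal rotation (no reflection) taking centered config X onto target Y,
# for use as X %*% R. Kabsch via SVD with determinant guard.
procrustes_rotation <- function(X, Y) {
  s <- svd(t(X) %*% Y)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
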