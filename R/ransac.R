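# RANSAC estimation of the affine transform between two matched frames.

# exact affine through 3 point pairs, batched over candidates via Cramer's
# rule; returns NULL rows (NA) for near-collinear samples
fit_affine_triples <- function(p, q, i1, i2, i3) {
  x1 <- p[i1, 1]; y1 <- p[i1, 2]
  x2 <- p[i2, 1]; y2 <- p[i2, 2]
  x3 <- p[i3, 1]; y3 <- p[i3, 2]
  det <- x1 * (y2 - y3) - y1 * (x2 - x3) + (x2 * y3 - x3 * y2)
  cr <- function(v1, v2, v3) {
    a <- (v1 * (y2 - y3) + v2 * (y3 - y1) + v3 * (y1 - y2)) / det
    b <- (v1 * (x3 - x2) + v2 * (x1 - x3) + v3 * (x2 - x1)) / det
    t <- (v1 * (x2 * y3 - x3 * y2) + v2 * (x3 * y1 - x1 * y3) +
          v3 * (x1 * y2 - x2 * y1)) / det
    cbind(a, b, t)
  }
  px <- cr(q[i1, 1], q[i2, 1], q[i3, 1])
  py <- cr(q[i1, 2], q[i2, 2], q[i3, 2])
  list(px = px, py = py, det = det)
}

ls_affine <- function(p, q) {
  X <- cbind(p[, 1], p[, 2], 1)
  beta <- tryCatch(qr.solve(X, q), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(NULL)
  m <- rbind(c(beta[1, 1], beta[2, 1], beta[3, 1]),
             c(beta[1, 2], beta[2, 2], beta[3, 2]),
             c(0, 0, 1))
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(d) || abs(d) <= 1e-8) return(NULL)
  affine_transform(m)
}

#' RANSAC affine estimation from point correspondences
#'
#' Robustly fits the 6-DOF affine transform mapping `src` points onto
#' `dst` points: minimal samples of 3 correspondences are drawn (all
#' triples exhaustively when there are no more than `max_iter` of them,
#' otherwise `max_iter` seeded random triples), inliers are counted at
#' `inlier_tol` pixels, and the transform is re-fit by least squares on
#' the largest consensus set.  Deterministic for a given `seed`.
#'
#' @param src,dst n x 2 matrices of `(x, y)` coordinates, n >= 3.
#' @param inlier_tol Inlier residual tolerance in pixels (default 3).
#' @param max_iter Maximum number of minimal samples (default 2000).
#' @param seed RNG seed for the sample draw.
#' @return List with `transform` (an [affine_transform()] mapping src
#'   coordinates into dst) and `inliers` (integer indices of the
#'   consensus correspondences).
#' @export
estimate_affine_points <- function(src, dst, inlier_tol = 3, max_iter = 2000L,
                                   seed = 1L) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 3L || nrow(dst) != n) {
    gg_stop("at least 3 correspondences are required", "gg_insufficient_correspondences")
  }
  if (max_iter < 1L) {
    gg_stop("max_iter must be >= 1", "gg_invalid_parameter")
  }
  n_triples <- choose(n, 3)
  if (n_triples <= max_iter) {
    combs <- utils::combn(n, 3L)
    i1 <- combs[1, ]; i2 <- combs[2, ]; i3 <- combs[3, ]
  } else {
    samp <- with_seed(seed, {
      vapply(seq_len(max_iter), function(k) sample.int(n, 3L), integer(3))
    })
    i1 <- samp[1, ]; i2 <- samp[2, ]; i3 <- samp[3, ]
  }
  fits <- fit_affine_triples(src, dst, i1, i2, i3)
  ok <- abs(fits$det) > 1e-6 &
    is.finite(rowSums(fits$px)) & is.finite(rowSums(fits$py))
  if (!any(ok)) {
    gg_stop("all minimal samples are degenerate (collinear points)",
            "gg_degenerate_geometry")
  }
  px <- fits$px[ok, , drop = FALSE]
  py <- fits$py[ok, , drop = FALSE]
  X <- cbind(src[, 1], src[, 2], 1)
  ex <- X %*% t(px) - dst[, 1]          # n x n_cand residuals
  ey <- X %*% t(py) - dst[, 2]
  e2 <- ex * ex + ey * ey
  inl <- e2 <= inlier_tol^2
  counts <- colSums(inl)
  errs <- colSums(e2 * inl)
  best <- order(-counts, errs)[1]
  if (counts[best] < 3L) {
    gg_stop("no consensus set of size >= 3 found", "gg_degenerate_geometry")
  }
  inliers <- which(inl[, best])
  tf <- ls_affine(src[inliers, , drop = FALSE], dst[inliers, , drop = FALSE])
  if (is.null(tf)) {
    gg_stop("consensus set is geometrically degenerate", "gg_degenerate_geometry")
  }
  list(transform = tf, inliers = inliers)
}

#' RANSAC affine estimation from a match set
#'
#' Convenience wrapper around [estimate_affine_points()] taking a
#' [match_features()] result: the returned transform maps coordinates of
#' frame `a` into frame `b` (the package-wide `H_ab` convention).
#'
#' @param matches A `match_set` computed from `(a, b)` with at least 3 rows.
#' @param a,b The `feature_set` objects the matches index into.
#' @inheritParams estimate_affine_points
#' @return List with `transform` and `inliers` (row indices into `matches`).
#' @export
estimate_affine <- function(matches, a, b, inlier_tol = 3, max_iter = 2000L,
                            seed = 1L) {
  if (nrow(matches) < 3L) {
    gg_stop("at least 3 matches are required for an affine fit",
            "gg_insufficient_correspondences")
  }
  src <- as.matrix(a$keypoints[matches$idx_a, c("x", "y")])
  dst <- as.matrix(b$keypoints[matches$idx_b, c("x", "y")])
  estimate_affine_points(src, dst, inlier_tol = inlier_tol,
                         max_iter = max_iter, seed = seed)
}
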