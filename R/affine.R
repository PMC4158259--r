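#' Planar affine transforms
#'
#' An `affine_transform` is a 3x3 real matrix whose last row is `(0, 0, 1)`
#' and whose upper-left 2x2 block is invertible.  Throughout the package a
#' transform `H_ij` maps point coordinates of frame *i* into frame *j*:
#' points are column vectors `(x, y, 1)` with `x` = column and `y` = row,
#' both 0-based, pixel-center convention.  Under this convention the same
#' matrix that retargets a marker from frame *i* onto frame *j* is used
#' directly as the inverse map when warping image *j* onto frame *i*'s
#' canvas (see [warp_image()]).
#'
#' @param m A 3x3 numeric matrix; the last row must be `(0, 0, 1)` up to
#'   1e-12 and the upper-left 2x2 block must have `|det| > 1e-8`.
#' @return An object of class `affine_transform` (a validated 3x3 matrix).
#' @examples
#' affine_transform(diag(3))
#' affine_translation(5, -2)
#' @export
affine_transform <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || !all(dim(m) == c(3L, 3L))) {
    gg_stop("affine transform must be a 3x3 numeric matrix", "gg_invalid_input")
  }
  if (any(abs(m[3, ] - c(0, 0, 1)) > 1e-12)) {
    gg_stop("last row of an affine transform must be (0, 0, 1)", "gg_invalid_input")
  }
  m[3, ] <- c(0, 0, 1)
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(d) || abs(d) <= 1e-8) {
    gg_stop("affine transform is (numerically) singular", "gg_degenerate_geometry")
  }
  structure(m, class = c("affine_transform", "matrix", "array"))
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(diag(3))

#' @rdname affine_transform
#' @param dx,dy Translation in pixels along x (columns) and y (rows).
#' @export
affine_translation <- function(dx, dy) {
  m <- diag(3)
  m[1, 3] <- dx
  m[2, 3] <- dy
  affine_transform(m)
}

#' @rdname affine_transform
#' @param rotation Rotation angle in radians (counter-clockwise in the
#'   x-right / y-down image coordinate system).
#' @param scale Isotropic scale factor (length 1) or `c(sx, sy)`.
#' @param translation Length-2 translation `c(dx, dy)`.
#' @param center Length-2 point the rotation/scaling pivots about.
#' @export
make_affine <- function(rotation = 0, scale = 1, translation = c(0, 0),
                        center = c(0, 0)) {
  if (length(scale) == 1L) scale <- c(scale, scale)
  cs <- cos(rotation)
  sn <- sin(rotation)
  a <- matrix(c(scale[1] * cs, -scale[2] * sn, 0,
                scale[1] * sn,  scale[2] * cs, 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  # shift center to origin, rotate/scale, shift back, then translate
  pre <- affine_translation(-center[1], -center[2])
  post <- affine_translation(center[1] + translation[1],
                             center[2] + translation[2])
  affine_compose(list(pre, affine_transform(a), post))
}

#' Invert an affine transform
#'
#' The graph stores `H_ij` and relies on `H_ji = H_ij^{-1}`.
#'
#' @param t An [affine_transform()].
#' @return The inverse transform, with the last row re-fixed to `(0,0,1)`.
#' @export
affine_invert <- function(t) {
  t <- affine_transform(unclass(t))
  inv <- tryCatch(solve(unclass(t)), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(inv))) {
    gg_stop("affine transform is numerically singular", "gg_degenerate_geometry")
  }
  inv[3, ] <- c(0, 0, 1)
  affine_transform(inv)
}

#' Compose a chain of affine transforms
#'
#' Transforms are applied to points in the order listed: for a pathway
#' `n_1, n_2, ..., n_m` through the graph, pass
#' `list(H_{n1 n2}, H_{n2 n3}, ...)` and the result maps frame `n_1`
#' coordinates into frame `n_m`.  Since points are column vectors, the
#' matrix product accumulates on the left
#' (`H = H_{n_{m-1} n_m} %*% ... %*% H_{n1 n2}`).
#'
#' @param chain Non-empty list of [affine_transform()] objects (a single
#'   transform is also accepted).
#' @return The composed `affine_transform`.
#' @export
affine_compose <- function(chain) {
  if (inherits(chain, "affine_transform")) chain <- list(chain)
  if (!is.list(chain) || length(chain) == 0L) {
    gg_stop("compose needs a non-empty list of transforms", "gg_invalid_input")
  }
  m <- Reduce(function(acc, t) unclass(t) %*% acc, chain[-1],
              init = unclass(affine_transform(unclass(chain[[1]]))))
  affine_transform(m)
}

#' Apply an affine transform to points
#'
#' @param t An [affine_transform()].
#' @param xy An n x 2 matrix (or length-2 vector) of `(x, y)` coordinates.
#' @return An n x 2 matrix of transformed coordinates.
#' @export
apply_affine <- function(t, xy) {
  t <- affine_transform(unclass(t))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  p <- cbind(xy[, 1], xy[, 2], 1) %*% t(unclass(t))
  p[, 1:2, drop = FALSE]
}

#' Warp an image onto a target canvas
#'
#' Inverse-mapping warp with bilinear interpolation: output pixel `p`
#' (0-based `(x, y)`) takes the intensity of `src` at `t(p)`.  To warp a
#' moving image *j* onto reference frame *i*'s canvas, pass the transform
#' `H_ij` that maps frame-*i* points into frame *j*.
#'
#' @param src 2-D numeric matrix (rows = y, cols = x).
#' @param t An [affine_transform()] mapping target coordinates to source
#'   coordinates.
#' @param target_shape `c(rows, cols)` of the output canvas; defaults to
#'   `dim(src)`.
#' @return A `warp_result`: list with `image` (matrix, out-of-source pixels
#'   are 0) and `validity_mask` (logical matrix, `TRUE` where the preimage
#'   lies inside `src`).
#' @export
warp_image <- function(src, t, target_shape = dim(src)) {
  assert_image(src, "src")
  t <- affine_transform(unclass(t))
  if (length(target_shape) != 2L || any(target_shape < 1)) {
    gg_stop("target_shape must be positive (rows, cols)", "gg_invalid_input")
  }
  nr <- as.integer(target_shape[1])
  nc <- as.integer(target_shape[2])
  xs <- rep(seq_len(nc) - 1L, each = nr)   # column-major order matches matrix()
  ys <- rep(seq_len(nr) - 1L, times = nc)
  m <- unclass(t)
  sx <- m[1, 1] * xs + m[1, 2] * ys + m[1, 3]
  sy <- m[2, 1] * xs + m[2, 2] * ys + m[2, 3]

  h <- nrow(src); w <- ncol(src)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  valid <- sx >= 0 & sy >= 0 & sx <= w - 1 & sy <= h - 1
  # clamp so the corner samples stay addressable; masked out afterwards
  x0c <- pmin(pmax(x0, 0), w - 1L); x1c <- pmin(x0c + 1, w - 1L)
  y0c <- pmin(pmax(y0, 0), h - 1L); y1c <- pmin(y0c + 1, h - 1L)
  idx <- function(yy, xx) yy + 1L + xx * h   # column-major linear index
  v <- (1 - fx) * (1 - fy) * src[idx(y0c, x0c)] +
       fx       * (1 - fy) * src[idx(y0c, x1c)] +
       (1 - fx) * fy       * src[idx(y1c, x0c)] +
       fx       * fy       * src[idx(y1c, x1c)]
  v[!valid] <- 0
  structure(
    list(image = matrix(v, nr, nc),
         validity_mask = matrix(valid, nr, nc)),
    class = "warp_result"
  )
}

#' Normalized cross-correlation registration score
#'
#' Warps `moving` onto `reference`'s canvas by `t` and computes the
#' zero-normalized cross-correlation (ZNCC) over the valid-overlap pixels.
#' This is the `Dif_H` statistic used to validate that two frames really
#' are related by the estimated affine transform: values near 1 mean the
#' affine assumption holds; the graph builder accepts a pair when
#' `dif_h > 0.8` and the matcher abandons a subgraph when `dif_h < 0.2`.
#'
#' @param reference,moving 2-D numeric matrices.
#' @param t [affine_transform()] mapping reference coordinates into the
#'   moving image (`H_ij` with *i* = reference).
#' @param min_overlap Minimum valid-overlap fraction of the reference
#'   canvas; below this the score is meaningless and an
#'   `gg_insufficient_overlap` error is signalled.
#' @return A `registration_score`: list with `dif_h` (in `[-1, 1]`) and
#'   `overlap_fraction`.
#' @export
ncc_score <- function(reference, moving, t, min_overlap = 0.25) {
  assert_image(reference, "reference")
  assert_image(moving, "moving")
  w <- warp_image(moving, t, dim(reference))
  mask <- w$validity_mask
  ov <- mean(mask)
  if (ov < min_overlap) {
    gg_stop(sprintf("valid overlap %.3f below min_overlap %.3f", ov, min_overlap),
            "gg_insufficient_overlap")
  }
  a <- reference[mask]
  b <- w$image[mask]
  a <- a - mean(a)
  b <- b - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  dif_h <- if (den <= 0) 0 else sum(a * b) / den
  structure(list(dif_h = min(max(dif_h, -1), 1), overlap_fraction = ov),
            class = "registration_score")
}

#' Mean squared difference between two warps
#'
#' Edge-weight statistic for the pathway search: the mean squared
#' intensity difference over the intersection of the two validity masks.
#' The mean (rather than the raw sum) is used so that edges with different
#' overlap areas are comparable.
#'
#' @param a,b `warp_result` objects of identical shape.
#' @return Non-negative scalar.
#' @export
ssd_score <- function(a, b) {
  if (!inherits(a, "warp_result") || !inherits(b, "warp_result")) {
    gg_stop("ssd_score expects two warp_result objects", "gg_invalid_input")
  }
  if (!all(dim(a$image) == dim(b$image))) {
    gg_stop("warp results must share shape", "gg_invalid_input")
  }
  mask <- a$validity_mask & b$validity_mask
  if (!any(mask)) {
    gg_stop("validity masks do not overlap", "gg_insufficient_overlap")
  }
  d <- a$image[mask] - b$image[mask]
  mean(d * d)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(unclass(x))
  invisible(x)
}
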