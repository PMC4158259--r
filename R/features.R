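# Scale-restricted SIFT-style keypoints and simplified 32-D descriptors.
#
# Scale convention: the detector builds Gaussian levels whose absolute scale
# sigma (relative to the input image, assumed to carry sigma = 0.5 of
# acquisition blur) follows a geometric ladder with ratio 2^(1/3).  Extrema
# are only searched at difference-of-Gaussian levels whose assigned sigma
# lies in [1, 3] — the endoscopic setting has a fixed focal length and a
# narrow motion range, so image scale barely changes and keypoints outside
# that band are not worth the cost.

SIFT_SIGMA_RATIO <- 2^(1 / 3)
SIFT_SIGMAS <- 2^((-1:6) / 3)   # 0.794 .. 4.0; DoG interior scales fall in [1, 3]
SIFT_BASE_SIGMA <- 0.5
SIFT_BORDER <- 8L
SIFT_DESC_LEVEL_OFFSET <- 3L   # descriptor gradients at sigma x 2
SIFT_DOG_SMOOTH <- 0.8         # response-map stabilization blur

# shift matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

# max/min over the 8 in-plane neighbours (centre excluded)
neigh8 <- function(m, fun, fill) {
  acc <- NULL
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- shift_mat(m, dy, dx, fill)
    acc <- if (is.null(acc)) s else fun(acc, s)
  }
  acc
}

neigh9 <- function(m, fun, fill) {
  fun(neigh8(m, fun, fill), m)
}

gauss_level <- function(image, sigma) {
  s <- sqrt(max(sigma^2 - SIFT_BASE_SIGMA^2, 1e-4))
  r <- 2L * as.integer(ceiling(3 * s)) + 1L
  rmax <- min(dim(image))
  rmax <- rmax - (1L - rmax %% 2L)        # largest odd radius that fits
  as.matrix(EBImage::gblur(image, sigma = s, radius = min(r, rmax)))
}

grad_maps <- function(level) {
  nr <- nrow(level); nc <- ncol(level)
  gx <- (shift_mat(level, 0L, -1L, NA) - shift_mat(level, 0L, 1L, NA)) / 2
  gy <- (shift_mat(level, -1L, 0L, NA) - shift_mat(level, 1L, 0L, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  list(gx = gx, gy = gy)
}

# bilinear interpolation of map `m` at 0-based coords (xs, ys); 0 outside
interp_bilinear <- function(m, xs, ys) {
  h <- nrow(m); w <- ncol(m)
  valid <- xs >= 0 & ys >= 0 & xs <= w - 1 & ys <= h - 1
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  idx <- function(yy, xx) yy + 1 + xx * h
  v <- (1 - fx) * (1 - fy) * m[idx(y0c, x0c)] +
       fx * (1 - fy) * m[idx(y0c, x1c)] +
       (1 - fx) * fy * m[idx(y1c, x0c)] +
       fx * fy * m[idx(y1c, x1c)]
  v[!valid] <- 0
  v
}

#' Clamp-normalize a raw descriptor vector
#'
#' Illumination suppression rule of the simplified descriptor: every
#' element strictly greater than 0.4 is set to 1; all others are kept.
#' There is deliberately no re-normalization afterwards — the rule
#' suppresses, rather than removes, illumination effects, and later
#' similarity estimation relies on the clamped values as-is.
#'
#' @param raw Numeric vector of length 32, non-negative, conventionally
#'   unit-L2-normalized beforehand.
#' @return Numeric vector of length 32 with all elements in `[0, 1]`.
#' @examples
#' clamp_normalize(c(0.5, rep(0, 31)))
#' @export
clamp_normalize <- function(raw) {
  if (!is.numeric(raw) || length(raw) != 32L) {
    gg_stop("descriptor must be a numeric vector of length 32", "gg_invalid_input")
  }
  ifelse(raw > 0.4, 1, raw)
}

empty_feature_set <- function(frame_id = NULL) {
  structure(
    list(
      keypoints = data.frame(x = numeric(0), y = numeric(0),
                             scale = numeric(0), orientation = numeric(0),
                             response = numeric(0)),
      descriptors = matrix(numeric(0), nrow = 0, ncol = 32),
      frame_id = frame_id
    ),
    class = "feature_set"
  )
}

#' Number of keypoints in a feature set
#' @param x A `feature_set`.
#' @export
n_features <- function(x) nrow(x$keypoints)

#' Detect scale-restricted SIFT-style keypoints with simplified descriptors
#'
#' Difference-of-Gaussian extrema are detected only at image scales
#' (Gaussian sigma) between 1 and 3, and each keypoint carries a
#' 32-dimensional descriptor: a 2x2 spatial grid of 8-bin gradient
#' orientation histograms, L2-normalized and then clamp-normalized
#' (elements > 0.4 set to 1, see [clamp_normalize()]).
#'
#' @param image 2-D numeric matrix with intensities in `[0, 1]`
#'   (rows = y, cols = x); at least 16x16 pixels for a non-empty result.
#' @param max_features Keep at most this many keypoints, strongest
#'   detection response first (ties broken by ascending `(y, x)`).
#'   Default 200.
#' @param contrast_threshold Minimum absolute DoG response.
#' @param edge_ratio Principal-curvature ratio bound for rejecting
#'   edge-like responses.
#' @param frame_id Optional identifier recorded on the result.
#' @return A `feature_set`: list with `keypoints` (data.frame of `x`, `y`
#'   0-based pixel coordinates, `scale` in `[1, 3]`, `orientation` in
#'   `[0, 2*pi)`, `response`), `descriptors` (n x 32 matrix, elements in
#'   `[0, 1]`) and `frame_id`.  Constant or too-small images yield an
#'   empty feature set; the output is fully deterministic.
#' @export
extract_features <- function(image, max_features = 200L,
                             contrast_threshold = 0.008, edge_ratio = 10,
                             frame_id = NULL) {
  assert_image(image)
  if (length(max_features) != 1L || max_features < 1) {
    gg_stop("max_features must be a positive integer", "gg_invalid_parameter")
  }
  if (nrow(image) < 16L || ncol(image) < 16L) return(empty_feature_set(frame_id))
  rng <- range(image)
  if (rng[2] - rng[1] <= .Machine$double.eps) return(empty_feature_set(frame_id))

  levels <- lapply(SIFT_SIGMAS, function(s) gauss_level(image, s))
  # light smoothing of the DoG response maps stabilizes extremum selection
  # and response ranking against pixel noise without moving the scale band
  dogs <- lapply(seq_len(length(levels) - 1L), function(i) {
    as.matrix(EBImage::gblur(levels[[i + 1L]] - levels[[i]],
                             sigma = SIFT_DOG_SMOOTH))
  })

  nr <- nrow(image); nc <- ncol(image)
  cand <- list()
  for (i in 2:(length(dogs) - 1L)) {
    d <- dogs[[i]]
    up <- dogs[[i + 1L]]; dn <- dogs[[i - 1L]]
    is_max <- d > neigh8(d, pmax, -Inf) &
              d > neigh9(up, pmax, -Inf) & d > neigh9(dn, pmax, -Inf)
    is_min <- d < neigh8(d, pmin, Inf) &
              d < neigh9(up, pmin, Inf) & d < neigh9(dn, pmin, Inf)
    ext <- (is_max | is_min) & abs(d) > contrast_threshold
    # keep away from borders so orientation/descriptor windows are stable
    ext[c(seq_len(SIFT_BORDER), nr - seq_len(SIFT_BORDER) + 1L), ] <- FALSE
    ext[, c(seq_len(SIFT_BORDER), nc - seq_len(SIFT_BORDER) + 1L)] <- FALSE
    if (!any(ext)) next
    w <- which(ext)
    yy <- (w - 1L) %% nr + 1L
    xx <- (w - 1L) %/% nr + 1L
    # edge response: ratio of principal curvatures of the DoG surface
    dxx <- d[cbind(yy, xx + 1L)] + d[cbind(yy, xx - 1L)] - 2 * d[w]
    dyy <- d[cbind(yy + 1L, xx)] + d[cbind(yy - 1L, xx)] - 2 * d[w]
    dxy <- (d[cbind(yy + 1L, xx + 1L)] + d[cbind(yy - 1L, xx - 1L)] -
            d[cbind(yy + 1L, xx - 1L)] - d[cbind(yy - 1L, xx + 1L)]) / 4
    tr <- dxx + dyy
    det <- dxx * dyy - dxy * dxy
    ok <- det > 0 & tr^2 / det < (edge_ratio + 1)^2 / edge_ratio
    if (!any(ok)) next
    cand[[length(cand) + 1L]] <- data.frame(
      x = xx[ok] - 1L, y = yy[ok] - 1L,
      level = i, scale = SIFT_SIGMAS[i],
      response = abs(d[w])[ok]
    )
  }
  if (length(cand) == 0L) return(empty_feature_set(frame_id))
  kp <- do.call(rbind, cand)
  kp <- kp[order(-kp$response, kp$y, kp$x), , drop = FALSE]
  kp <- kp[seq_len(min(nrow(kp), max_features)), , drop = FALSE]

  # orientation and descriptor gradients are sampled two octave-thirds
  # coarser (sigma x2) than the detection level: detection stays in the
  # restricted scale band while the descriptor support suppresses pixel
  # noise (window sizes still scale with the detection sigma)
  kp$glevel <- pmin(kp$level + SIFT_DESC_LEVEL_OFFSET, length(levels))
  grads <- list()
  for (lv in unique(kp$glevel)) grads[[as.character(lv)]] <- grad_maps(levels[[lv]])

  kp$orientation <- vapply(seq_len(nrow(kp)), function(r) {
    keypoint_orientation(kp$x[r], kp$y[r], kp$scale[r],
                         grads[[as.character(kp$glevel[r])]])
  }, numeric(1))

  desc <- matrix(0, nrow(kp), 32L)
  for (lv in unique(kp$glevel)) {
    sel <- which(kp$glevel == lv)
    desc[sel, ] <- descriptor_block(kp[sel, , drop = FALSE],
                                    grads[[as.character(lv)]])
  }

  rownames(kp) <- NULL
  structure(
    list(keypoints = kp[, c("x", "y", "scale", "orientation", "response")],
         descriptors = desc,
         frame_id = frame_id),
    class = "feature_set"
  )
}

# dominant gradient orientation: 36-bin Gaussian-weighted histogram with
# parabolic peak interpolation; deterministic (single dominant peak,
# lowest bin index on exact ties)
keypoint_orientation <- function(x, y, scale, g) {
  r <- max(3L, as.integer(round(3 * 1.5 * scale)))
  h <- nrow(g$gx); w <- ncol(g$gx)
  xs <- max(0L, x - r):min(w - 1L, x + r)
  ys <- max(0L, y - r):min(h - 1L, y + r)
  gx <- g$gx[ys + 1L, xs + 1L, drop = FALSE]
  gy <- g$gy[ys + 1L, xs + 1L, drop = FALSE]
  dx <- matrix(rep(xs - x, each = length(ys)), length(ys))
  dy <- matrix(rep(ys - y, times = length(xs)), length(ys))
  wgt <- exp(-(dx^2 + dy^2) / (2 * (1.5 * scale)^2)) * sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * 36), 35)
  hist <- vapply(0:35, function(b) sum(wgt[bin == b]), numeric(1))
  if (all(hist == 0)) return(0)
  b <- which.max(hist) - 1L
  l <- hist[(b - 1L) %% 36L + 1L]; c0 <- hist[b + 1L]; rgt <- hist[(b + 1L) %% 36L + 1L]
  den <- l - 2 * c0 + rgt
  off <- if (abs(den) < 1e-12) 0 else 0.5 * (l - rgt) / den
  ((b + 0.5 + off) / 36 * 2 * pi) %% (2 * pi)
}

# simplified descriptors for all keypoints sharing one Gaussian level:
# 8x8 rotated sample grid -> 2x2 spatial cells x 8 orientation bins
descriptor_block <- function(kp, g) {
  n <- nrow(kp)
  grid <- seq(-3.5, 3.5, by = 1)                 # 8 samples per axis, grid units
  offs <- expand.grid(u = grid, v = grid)        # 64 samples
  ns <- nrow(offs)
  spacing <- 1.5 * kp$scale                      # px per grid unit
  cs <- cos(kp$orientation); sn <- sin(kp$orientation)
  # rotated sample positions, n x ns
  U <- outer(spacing * cs, offs$u) - outer(spacing * sn, offs$v)
  V <- outer(spacing * sn, offs$u) + outer(spacing * cs, offs$v)
  X <- kp$x + U
  Y <- kp$y + V
  gx <- interp_bilinear(g$gx, as.vector(X), as.vector(Y))
  gy <- interp_bilinear(g$gy, as.vector(X), as.vector(Y))
  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) - rep(kp$orientation, times = ns)) %% (2 * pi)
  wgt <- exp(-(rep(offs$u, each = n)^2 + rep(offs$v, each = n)^2) / (2 * 4^2))

  # spatial cell coordinate in [-0.5, 1.5): cells centred at u = -2, +2
  cu <- (rep(offs$u, each = n) + 4) / 4 - 0.5
  cv <- (rep(offs$v, each = n) + 4) / 4 - 0.5
  ob <- theta / (2 * pi) * 8
  kpi <- rep(seq_len(n), times = ns)

  desc_flat <- numeric(n * 32L)
  cu0 <- floor(cu); fu <- cu - cu0
  cv0 <- floor(cv); fv <- cv - cv0
  ob0 <- floor(ob); fo <- ob - ob0
  for (du in 0:1) for (dv in 0:1) for (do in 0:1) {
    ucell <- cu0 + du; vcell <- cv0 + dv
    obin <- (ob0 + do) %% 8
    wu <- if (du == 0) 1 - fu else fu
    wv <- if (dv == 0) 1 - fv else fv
    wo <- if (do == 0) 1 - fo else fo
    keep <- ucell >= 0 & ucell <= 1 & vcell >= 0 & vcell <= 1
    if (!any(keep)) next
    contrib <- (mag * wgt * wu * wv * wo)[keep]
    idx <- (kpi[keep] - 1L) * 32L + (vcell[keep] * 2L + ucell[keep]) * 8L +
      obin[keep] + 1L
    agg <- rowsum(contrib, group = idx)
    ii <- as.integer(rownames(agg))
    desc_flat[ii] <- desc_flat[ii] + agg[, 1]
  }
  desc <- matrix(desc_flat, nrow = n, ncol = 32L, byrow = TRUE)
  nrm <- sqrt(rowSums(desc^2))
  nrm[nrm == 0] <- 1
  desc <- desc / nrm
  t(apply(desc, 1L, clamp_normalize))
}

#' Match two feature sets
#'
#' Mutual-nearest-neighbour matching in Euclidean descriptor space with
#' Lowe's ratio test (strict inequality): a pair `(i, j)` is kept when `j`
#' is `i`'s nearest neighbour, `i` is `j`'s nearest neighbour, and the
#' nearest distance is strictly less than `ratio` times the second-nearest.
#' The result is one-to-one by construction; distance ties resolve to the
#' lower index.
#'
#' @param a,b `feature_set` objects.
#' @param ratio Ratio-test threshold in `(0, 1]`; default 0.8.
#' @return A `match_set`: data.frame with columns `idx_a`, `idx_b`
#'   (1-based indices into the two sets) and `distance`.
#' @export
match_features <- function(a, b, ratio = 0.8) {
  if (!inherits(a, "feature_set") || !inherits(b, "feature_set")) {
    gg_stop("match_features expects two feature_set objects", "gg_invalid_input")
  }
  if (length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    gg_stop("ratio must lie in (0, 1]", "gg_invalid_parameter")
  }
  empty <- data.frame(idx_a = integer(0), idx_b = integer(0),
                      distance = numeric(0))
  class(empty) <- c("match_set", "data.frame")
  na <- n_features(a); nb <- n_features(b)
  if (na == 0L || nb == 0L) return(empty)
  da <- a$descriptors; db <- b$descriptors
  d2 <- outer(rowSums(da^2), rep(1, nb)) + outer(rep(1, na), rowSums(db^2)) -
    2 * tcrossprod(da, db)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1L, which.min)
  nn_ba <- apply(d2, 2L, which.min)
  keep <- logical(na)
  dist1 <- numeric(na)
  for (i in seq_len(na)) {
    j <- nn_ab[i]
    if (nn_ba[j] != i) next
    d1 <- d2[i, j]
    # ratio test on both sides keeps the match set (and hence the
    # similarity statistic) symmetric in the two frames
    d2nd_a <- if (nb > 1L) min(d2[i, -j]) else Inf
    d2nd_b <- if (na > 1L) min(d2[-i, j]) else Inf
    if (sqrt(d1) < ratio * sqrt(d2nd_a) && sqrt(d1) < ratio * sqrt(d2nd_b)) {
      keep[i] <- TRUE
      dist1[i] <- sqrt(d1)
    }
  }
  out <- data.frame(idx_a = which(keep), idx_b = nn_ab[keep],
                    distance = dist1[keep])
  rownames(out) <- NULL
  class(out) <- c("match_set", "data.frame")
  out
}

#' Feature-based similarity between two frames
#'
#' The graph's node-similarity statistic: the number of matched points
#' divided by the larger of the two feature counts,
#' `S_ij = M_p / max(Fp_i, Fp_j)`.  It is symmetric and lies in `[0, 1]`;
#' 1 indicates highly consistent frames, 0 entirely different ones.
#'
#' @param a,b `feature_set` objects (at least one non-empty).
#' @param matches A `match_set` computed from `(a, b)`; computed on the
#'   fly when omitted.
#' @param ratio Ratio-test threshold forwarded to [match_features()].
#' @return Similarity in `[0, 1]`.
#' @export
feature_similarity <- function(a, b, matches = NULL, ratio = 0.8) {
  na <- n_features(a); nb <- n_features(b)
  if (max(na, nb) == 0L) {
    gg_stop("similarity undefined: both feature sets are empty",
            "gg_undefined_similarity")
  }
  if (is.null(matches)) matches <- match_features(a, b, ratio = ratio)
  nrow(matches) / max(na, nb)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d keypoints%s\n", n_features(x),
              if (!is.null(x$frame_id)) paste0(" [", x$frame_id, "]") else ""))
  invisible(x)
}
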