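# Forward-backward error framework, Kullback-Leibler trajectory-accuracy
# criterion, and accuracy reporting with pixel -> mm calibration.

#' Forward-backward point-tracking evaluation
#'
#' Tracks each seed point forward frame-by-frame to the last frame of the
#' sequence, then backward to the first.  A perfectly detected and matched
#' point returns to its origin; the Euclidean distance between origin and
#' return position is its forward-backward (FB) error.  Points lost in
#' either direction (tracker returns `NA`) are flagged and excluded from
#' error statistics.
#'
#' @param sequence List of 2-D numeric matrices (>= 2 frames).
#' @param tracker Deterministic `function(from_image, to_image, points)`
#'   mapping an n x 2 matrix of `(x, y)` points in `from_image` to their
#'   positions in `to_image` (`NA` rows for lost points).
#' @param seeds n x 2 matrix of starting points in the first frame.
#' @return A data.frame (class `fb_record`) with `feature_id`,
#'   `origin_x`, `origin_y`, `returned_x`, `returned_y`, `fb_error`
#'   (pixels, `NA` when lost) and `lost`.
#' @export
forward_backward <- function(sequence, tracker, seeds) {
  if (length(sequence) < 2L) {
    gg_stop("need at least 2 frames", "gg_invalid_input")
  }
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2L)
  n <- nrow(seeds)
  empty <- data.frame(feature_id = integer(0), origin_x = numeric(0),
                      origin_y = numeric(0), returned_x = numeric(0),
                      returned_y = numeric(0), fb_error = numeric(0),
                      lost = logical(0))
  class(empty) <- c("fb_record", "data.frame")
  if (n == 0L) return(empty)
  pts <- seeds
  nf <- length(sequence)
  for (f in seq_len(nf - 1L)) {
    pts <- tracker(sequence[[f]], sequence[[f + 1L]], pts)
  }
  for (f in rev(seq_len(nf - 1L))) {
    pts <- tracker(sequence[[f + 1L]], sequence[[f]], pts)
  }
  lost <- !stats::complete.cases(pts)
  err <- sqrt((pts[, 1] - seeds[, 1])^2 + (pts[, 2] - seeds[, 2])^2)
  err[lost] <- NA_real_
  out <- data.frame(feature_id = seq_len(n),
                    origin_x = seeds[, 1], origin_y = seeds[, 2],
                    returned_x = pts[, 1], returned_y = pts[, 2],
                    fb_error = err, lost = lost)
  class(out) <- c("fb_record", "data.frame")
  out
}

#' Add seeded Gaussian noise to an image
#'
#' Robustness-protocol noise model: zero-mean Gaussian noise with standard
#' deviation `sigma` added to an intensity image in `[0, 1]`, clipped back
#' to `[0, 1]`.  Deterministic per seed.
#'
#' @param image 2-D numeric matrix in `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return The noisy image.
#' @export
gaussian_noise <- function(image, sigma, seed = 1L) {
  assert_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    gg_stop("sigma must be a non-negative number", "gg_invalid_parameter")
  }
  if (sigma == 0) return(image)
  noise <- with_seed(seed, matrix(stats::rnorm(length(image), 0, sigma),
                                  nrow(image), ncol(image)))
  out <- image + noise
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Bin a point trajectory onto a spatial grid
#'
#' Builds the normalized spatial histogram of a marker's per-frame
#' positions over square cells covering the frame — the distribution the
#' KL trajectory criterion compares between forward and backward passes.
#'
#' @param positions n x 2 matrix of `(x, y)` positions in pixels.
#' @param frame_shape `c(rows, cols)` of the frame.
#' @param cell Cell size in pixels (default 8).
#' @return A `trajectory_distribution`: list with `weights` (normalized,
#'   sums to 1), `dims` (grid rows/cols), `cell`, `frame_shape`.
#' @export
trajectory_distribution <- function(positions, frame_shape, cell = 8) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  if (nrow(positions) < 1L) {
    gg_stop("need at least one position", "gg_insufficient_trajectory")
  }
  gr <- ceiling(frame_shape[1] / cell)
  gc <- ceiling(frame_shape[2] / cell)
  cx <- pmin(pmax(floor(positions[, 1] / cell), 0), gc - 1)
  cy <- pmin(pmax(floor(positions[, 2] / cell), 0), gr - 1)
  w <- matrix(0, gr, gc)
  for (i in seq_len(nrow(positions))) {
    w[cy[i] + 1, cx[i] + 1] <- w[cy[i] + 1, cx[i] + 1] + 1
  }
  structure(list(weights = w / sum(w), dims = c(gr, gc), cell = cell,
                 frame_shape = frame_shape),
            class = "trajectory_distribution")
}

#' Kullback-Leibler divergence between two trajectory distributions
#'
#' Standard discrete KL in both directions,
#' `KL(p || q) = sum p(x) log(p(x)/q(x))` (natural log), after additive
#' `epsilon` smoothing and renormalization of both histograms so that
#' disjoint supports stay finite.
#'
#' @param p,q `trajectory_distribution` objects on the same grid, or plain
#'   numeric histograms of equal length.
#' @param epsilon Additive smoothing weight (default 1e-6); 0 disables
#'   smoothing.
#' @return Named numeric vector `c(d_kl1 = KL(p||q), d_kl2 = KL(q||p))`,
#'   both non-negative.
#' @export
kl_divergence <- function(p, q, epsilon = 1e-6) {
  pw <- if (inherits(p, "trajectory_distribution")) p$weights else p
  qw <- if (inherits(q, "trajectory_distribution")) q$weights else q
  if (inherits(p, "trajectory_distribution") &&
      inherits(q, "trajectory_distribution") && !all(p$dims == q$dims)) {
    gg_stop("distributions are on different grids", "gg_invalid_input")
  }
  if (length(pw) != length(qw)) {
    gg_stop("histograms must have equal length", "gg_invalid_input")
  }
  pw <- as.numeric(pw) + epsilon
  qw <- as.numeric(qw) + epsilon
  pw <- pw / sum(pw)
  qw <- qw / sum(qw)
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  c(d_kl1 = kl(pw, qw), d_kl2 = kl(qw, pw))
}

#' Accept or reject marker trajectories by the KL criterion
#'
#' For each marker the forward and backward per-frame positions are binned
#' into spatial histograms and compared with [kl_divergence()]; a
#' trajectory is accurate only when both directed divergences fall below
#' `kl_threshold` (default 0.1).
#'
#' @param forward,backward data.frames with columns `label`, `x`, `y`
#'   covering the same frames and markers (one row per frame per marker).
#' @param frame_shape `c(rows, cols)` of the frames.
#' @param cell Histogram cell size in pixels (default 8).
#' @param kl_threshold Acceptance threshold on both divergences
#'   (default 0.1).
#' @param epsilon Smoothing weight for [kl_divergence()].
#' @return data.frame with one row per marker: `label`, `d_kl1`, `d_kl2`,
#'   `accepted`.
#' @export
trajectory_accuracy <- function(forward, backward, frame_shape, cell = 8,
                                kl_threshold = 0.1, epsilon = 1e-6) {
  labels <- sort(unique(forward$label))
  if (!setequal(labels, unique(backward$label))) {
    gg_stop("forward and backward must cover the same markers", "gg_invalid_input")
  }
  rows <- lapply(labels, function(l) {
    pf <- as.matrix(forward[forward$label == l, c("x", "y")])
    pb <- as.matrix(backward[backward$label == l, c("x", "y")])
    if (nrow(pf) < 2L || nrow(pb) < 2L) {
      gg_stop("fewer than 2 positions for a marker", "gg_insufficient_trajectory")
    }
    dp <- trajectory_distribution(pf, frame_shape, cell)
    dq <- trajectory_distribution(pb, frame_shape, cell)
    d <- kl_divergence(dp, dq, epsilon)
    data.frame(label = l, d_kl1 = d[["d_kl1"]], d_kl2 = d[["d_kl2"]],
               accepted = d[["d_kl1"]] < kl_threshold && d[["d_kl2"]] < kl_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a pixel distance to millimetres
#'
#' The biopsy forceps (8 mm diameter) visible in-frame provides the scale
#' standard: `mm = px * 8 / forceps_diameter_px`.
#'
#' @param distance_px Distance in pixels.
#' @param forceps_diameter_px Apparent forceps diameter in pixels (> 0).
#' @param forceps_diameter_mm Physical forceps diameter (default 8 mm).
#' @return Distance in millimetres.
#' @export
pixels_to_mm <- function(distance_px, forceps_diameter_px,
                         forceps_diameter_mm = 8) {
  if (!is.numeric(forceps_diameter_px) || forceps_diameter_px <= 0) {
    gg_stop("forceps_diameter_px must be positive", "gg_invalid_parameter")
  }
  distance_px * forceps_diameter_mm / forceps_diameter_px
}

#' Accuracy report over tracked markers
#'
#' Combines the KL trajectory criterion with FB-error statistics: the
#' accuracy percent is the fraction of markers accepted by
#' [trajectory_accuracy()], and the mean/spread of the per-marker FB error
#' (distance between a marker's origin and its backward-returned position)
#' are reported in millimetres over the accepted markers.  Because
#' "variance" reported in mm units is a standard deviation, both are
#' exposed under unambiguous names.
#'
#' @param forward,backward Per-frame marker positions (see
#'   [trajectory_accuracy()]); the first frame of `forward` holds the
#'   origins and the last frame of `backward` the returned positions.
#' @param frame_shape `c(rows, cols)`.
#' @param forceps_diameter_px Pixel scale calibration (> 0).
#' @param kl_threshold KL acceptance threshold (default 0.1).
#' @param cell Histogram cell size (default 8).
#' @return An `accuracy_report`: list with `per_marker` (data.frame with
#'   KL values, acceptance, fb_error_px, fb_error_mm), `accuracy_percent`,
#'   `mean_mm`, `sd_mm`, `var_mm2`, `n_markers`, `n_accepted`,
#'   `undefined_stats` (TRUE when no marker was accepted).
#' @export
accuracy_report <- function(forward, backward, frame_shape,
                            forceps_diameter_px, kl_threshold = 0.1,
                            cell = 8) {
  acc <- trajectory_accuracy(forward, backward, frame_shape, cell = cell,
                             kl_threshold = kl_threshold)
  fb <- vapply(acc$label, function(l) {
    pf <- forward[forward$label == l, c("x", "y")]
    pb <- backward[backward$label == l, c("x", "y")]
    o <- as.numeric(pf[1, ])              # origin: first forward position
    r <- as.numeric(pb[nrow(pb), ])       # return: last backward position
    sqrt(sum((o - r)^2))
  }, numeric(1))
  acc$fb_error_px <- fb
  acc$fb_error_mm <- pixels_to_mm(fb, forceps_diameter_px)
  sel <- acc$accepted
  undef <- !any(sel)
  structure(
    list(per_marker = acc,
         accuracy_percent = mean(sel),
         mean_mm = if (undef) NA_real_ else mean(acc$fb_error_mm[sel]),
         sd_mm = if (undef) NA_real_ else stats::sd(acc$fb_error_mm[sel]),
         var_mm2 = if (undef) NA_real_ else stats::var(acc$fb_error_mm[sel]),
         n_markers = nrow(acc),
         n_accepted = sum(sel),
         undefined_stats = undef),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  cat(sprintf("  markers: %d, accepted: %d\n", x$n_markers, x$n_accepted))
  cat(sprintf("  accuracy percent: %.2f\n", x$accuracy_percent))
  if (!x$undefined_stats) {
    cat(sprintf("  mean error: %.2f mm, sd: %.2f mm\n", x$mean_mm,
                if (is.na(x$sd_mm)) 0 else x$sd_mm))
  } else {
    cat("  error statistics undefined (no accepted markers)\n")
  }
  invisible(x)
}
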