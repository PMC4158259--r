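# Seeded synthetic fixtures: textured surfaces imaged through a chain of
# smooth affine motions, with ground-truth transforms and landmarks.
# These stand in for gastroscopic acquisitions at desk scale.

#' Generate a band-limited random texture
#'
#' Multi-octave ridged value noise: random coarse grids are bilinearly
#' upsampled, folded into ridges (`|2u - 1|`, mimicking the vessel- and
#' fold-like line structure of mucosal surfaces), and summed with
#' geometrically decaying amplitudes, giving broad gradient content at
#' several scales; the result is rescaled to `[0, 1]`.  Deterministic per
#' seed.
#'
#' @param size `c(rows, cols)`, at least 64 x 64.
#' @param seed RNG seed.
#' @param octaves Number of noise octaves (default 6).
#' @param persistence Amplitude decay per octave (default 0.7).
#' @return 2-D numeric matrix in `[0, 1]`.
#' @export
make_texture <- function(size = c(240L, 280L), seed = 1L, octaves = 6L,
                         persistence = 0.7) {
  if (length(size) != 2L || any(size < 64L)) {
    gg_stop("texture size must be at least 64 x 64", "gg_invalid_parameter")
  }
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  with_seed(seed, {
    out <- matrix(0, nr, nc)
    amp <- 1
    cells <- 4L
    for (o in seq_len(octaves)) {
      gr <- cells + 1L
      gcl <- cells + 1L
      grid <- matrix(stats::runif(gr * gcl), gr, gcl)
      ys <- seq(1, gr, length.out = nr)
      xs <- seq(1, gcl, length.out = nc)
      y0 <- pmin(floor(ys), gr - 1L); fy <- ys - y0
      x0 <- pmin(floor(xs), gcl - 1L); fx <- xs - x0
      a <- grid[cbind(rep(y0, nc), rep(x0, each = nr))]
      b <- grid[cbind(rep(y0, nc), rep(x0 + 1L, each = nr))]
      c2 <- grid[cbind(rep(y0 + 1L, nc), rep(x0, each = nr))]
      d <- grid[cbind(rep(y0 + 1L, nc), rep(x0 + 1L, each = nr))]
      fyv <- rep(fy, nc); fxv <- rep(fx, each = nr)
      layer <- (1 - fxv) * (1 - fyv) * a + fxv * (1 - fyv) * b +
        (1 - fxv) * fyv * c2 + fxv * fyv * d
      layer <- abs(2 * layer - 1)      # ridge fold: vessel/fold-like lines
      out <- out + amp * matrix(layer, nr, nc)
      amp <- amp * persistence
      cells <- cells * 2L
    }
    rng <- range(out)
    (out - rng[1]) / (rng[2] - rng[1])
  })
}

#' Generate a synthetic frame sequence with ground truth
#'
#' Emulates an endoscopic acquisition of a textured deformable surface:
#' a smooth random walk in affine-parameter space (per-step rotation,
#' translation and scale bounded by `motion`) is applied to a base
#' texture, each frame is rendered by warping an enlarged base so content
#' stays available at the frame borders, seeded Gaussian noise is added,
#' and landmark positions are mapped through the cumulative transforms.
#' Site labels are assigned in contiguous blocks to emulate anatomic
#' subgraphs.
#'
#' @param base Base texture (2-D matrix), strictly larger than
#'   `frame_size`; one is generated from `seed` when omitted.
#' @param n_frames Number of frames (>= 2; default 12).
#' @param motion List with `max_rotation` (radians), `max_translation`
#'   (px) and `scale_range` (`c(lo, hi)`) bounding each step.
#' @param noise_sigma Additive Gaussian noise level (default 0).
#' @param n_landmarks Ground-truth landmarks placed in the central region
#'   of frame 0 (default 10).
#' @param n_sites Number of contiguous site-label blocks (default 1).
#' @param frame_size `c(rows, cols)` of the rendered frames
#'   (default 240 x 280, half the clinical 560 x 480 resolution).
#' @param seed RNG seed.
#' @return A `synthetic_sequence`: list with `frames` (list of
#'   [image_frame()]), `true_transforms` (list of `n_frames - 1`
#'   [affine_transform()], frame k -> frame k+1 point maps), `landmarks`
#'   (list of n x 2 matrices per frame), `site_labels`, `frame_size`,
#'   `seed`.
#' @export
make_sequence <- function(base = NULL, n_frames = 12L,
                          motion = list(max_rotation = 0.05,
                                        max_translation = 4,
                                        scale_range = c(0.99, 1.01)),
                          noise_sigma = 0, n_landmarks = 10L, n_sites = 1L,
                          frame_size = c(240L, 280L), seed = 1L) {
  if (n_frames < 2L) gg_stop("n_frames must be >= 2", "gg_invalid_parameter")
  if (is.null(base)) {
    base <- make_texture(frame_size + c(120L, 120L), seed = child_seed(seed, 99L))
  }
  if (any(dim(base) < frame_size)) {
    gg_stop("base texture must be at least frame_size", "gg_invalid_parameter")
  }
  nr <- frame_size[1]; nc <- frame_size[2]
  off <- c((ncol(base) - nc) / 2, (nrow(base) - nr) / 2)  # (x, y)
  c0 <- affine_translation(off[1], off[2])                 # frame-0 -> base coords
  center <- c((nc - 1) / 2, (nr - 1) / 2)

  steps <- with_seed(child_seed(seed, 1L), {
    lapply(seq_len(n_frames - 1L), function(k) {
      make_affine(
        rotation = stats::runif(1, -motion$max_rotation, motion$max_rotation),
        scale = stats::runif(1, motion$scale_range[1], motion$scale_range[2]),
        translation = c(stats::runif(1, -motion$max_translation, motion$max_translation),
                        stats::runif(1, -motion$max_translation, motion$max_translation)),
        center = center)
    })
  })

  # cumulative map: frame-k coordinates -> frame-0 coordinates
  cum <- vector("list", n_frames)
  cum[[1]] <- affine_identity()
  for (k in seq_len(n_frames - 1L)) {
    cum[[k + 1L]] <- affine_compose(list(steps[[k]], cum[[k]]))
  }

  lm0 <- with_seed(child_seed(seed, 2L), {
    cbind(stats::runif(n_landmarks, nc * 0.25, nc * 0.75),
          stats::runif(n_landmarks, nr * 0.25, nr * 0.75))
  })

  site_labels <- paste0("site", ceiling(seq_len(n_frames) / (n_frames / n_sites)))
  frames <- vector("list", n_frames)
  landmarks <- vector("list", n_frames)
  true_transforms <- vector("list", n_frames - 1L)
  for (k in seq_len(n_frames)) {
    to_base <- affine_compose(list(cum[[k]], c0))   # frame-k -> base coords
    w <- warp_image(base, to_base, frame_size)
    if (mean(w$validity_mask) < 0.6) {
      gg_stop("motion pushed the texture out of frame", "gg_degenerate_sequence")
    }
    img <- w$image
    if (noise_sigma > 0) {
      img <- gaussian_noise(img, noise_sigma, seed = child_seed(seed, 100L + k))
    }
    frames[[k]] <- image_frame(img, sprintf("frame%03d", k - 1L), site_labels[k])
    landmarks[[k]] <- apply_affine(affine_invert(cum[[k]]), lm0)
    if (k > 1L) {
      # frame (k-1) -> frame k point map
      true_transforms[[k - 1L]] <- affine_compose(list(cum[[k - 1L]],
                                                       affine_invert(cum[[k]])))
    }
  }
  structure(
    list(frames = frames, true_transforms = true_transforms,
         landmarks = landmarks, site_labels = site_labels,
         frame_size = frame_size, seed = seed),
    class = "synthetic_sequence")
}

#' Place phantom markers on the first frame of a synthetic sequence
#'
#' Markers are seeded at a subset of the sequence's frame-0 landmarks so
#' their ground-truth positions in later frames follow directly from the
#' stored true transforms.  Placement retries until the circles are
#' pairwise non-overlapping (center distance > 2 * radius).
#'
#' @param sequence A `synthetic_sequence`.
#' @param n_markers Number of markers (>= 1).
#' @param radius Circle radius in pixels (default 6).
#' @param seed RNG seed.
#' @param max_tries Resampling budget (default 200).
#' @return A `marker_set` on frame 0, labelled `1..n_markers`.
#' @export
make_phantom_markers <- function(sequence, n_markers, radius = 6, seed = 1L,
                                 max_tries = 200L) {
  if (n_markers < 1L) gg_stop("n_markers must be >= 1", "gg_invalid_parameter")
  lm <- sequence$landmarks[[1]]
  if (n_markers > nrow(lm)) {
    gg_stop("more markers than landmarks available", "gg_invalid_parameter")
  }
  sel <- with_seed(seed, {
    found <- NULL
    for (t in seq_len(max_tries)) {
      cand <- sort(sample.int(nrow(lm), n_markers))
      p <- lm[cand, , drop = FALSE]
      if (n_markers == 1L || min(stats::dist(p)) > 2 * radius) {
        found <- cand
        break
      }
    }
    found
  })
  if (is.null(sel)) {
    gg_stop("could not place non-overlapping markers", "gg_placement_error")
  }
  out <- data.frame(label = seq_len(n_markers),
                    x = lm[sel, 1], y = lm[sel, 2], radius = radius)
  attr(out, "landmark_index") <- sel
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Ground-truth marker positions in a later frame
#'
#' @param sequence A `synthetic_sequence`.
#' @param markers A `marker_set` from [make_phantom_markers()].
#' @param frame_index 1-based frame index.
#' @return n x 2 matrix of `(x, y)` ground-truth centers.
#' @export
true_marker_positions <- function(sequence, markers, frame_index) {
  sel <- attr(markers, "landmark_index")
  if (is.null(sel)) {
    gg_stop("markers carry no landmark index (not from make_phantom_markers)",
            "gg_invalid_input")
  }
  sequence$landmarks[[frame_index]][sel, , drop = FALSE]
}
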