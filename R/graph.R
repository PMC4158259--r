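# Image-graph construction: optimal connection threshold h and the N x N
# (similarity, transform) adjacency, partitioned into anatomic subgraphs.

#' Create a frame (graph node payload)
#'
#' @param image 2-D numeric intensity matrix in `[0, 1]`.
#' @param frame_id Unique identifier (character).
#' @param site_label Anatomic-site tag (e.g. `"angularis"`, `"antrum"`,
#'   `"body"`); drives the subgraph partition used during node matching.
#' @return An `image_frame` object.
#' @export
image_frame <- function(image, frame_id, site_label = "default") {
  assert_image(image)
  if (length(frame_id) != 1L) {
    gg_stop("frame_id must be a single identifier", "gg_invalid_input")
  }
  structure(list(image = image, frame_id = as.character(frame_id),
                 site_label = as.character(site_label)),
            class = "image_frame")
}

frame_features <- function(frames, max_features = 200L) {
  lapply(frames, function(f) {
    extract_features(f$image, max_features = max_features,
                     frame_id = f$frame_id)
  })
}

#' Sample pairwise similarities across a frame set
#'
#' Draws `n_samples` unordered frame pairs (seeded, without replacement up
#' to the number of available pairs), computes the feature similarity of
#' each, and brackets the observed range: `b_low = min`, `b_high = max`.
#' This bracket seeds the connection-threshold search.
#'
#' @param frames List of [image_frame()] objects (>= 2).
#' @param n_samples Number of pairs to draw (default 200).
#' @param seed RNG seed.
#' @param max_features,ratio Feature extraction/matching parameters.
#' @param features Optional precomputed list of feature sets (parallel to
#'   `frames`), to avoid re-extraction.
#' @return List with `pairs` (m x 2 index matrix), `values` (similarities),
#'   `b_low`, `b_high`.
#' @export
sample_similarities <- function(frames, n_samples = 200L, seed = 1L,
                                max_features = 200L, ratio = 0.8,
                                features = NULL) {
  if (length(frames) < 2L) {
    gg_stop("need at least 2 frames", "gg_invalid_input")
  }
  if (n_samples < 1L) gg_stop("n_samples must be >= 1", "gg_invalid_parameter")
  n <- length(frames)
  all_pairs <- t(utils::combn(n, 2L))
  take <- min(nrow(all_pairs), n_samples)
  sel <- with_seed(seed, sample.int(nrow(all_pairs), take))
  sel <- sort(sel)
  pairs <- all_pairs[sel, , drop = FALSE]
  if (is.null(features)) features <- frame_features(frames, max_features)
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- features[[pairs[k, 1]]]; b <- features[[pairs[k, 2]]]
    if (max(n_features(a), n_features(b)) == 0L) return(NA_real_)
    feature_similarity(a, b, ratio = ratio)
  }, numeric(1))
  if (all(is.na(vals))) {
    gg_stop("no sampled pair had any features", "gg_no_features")
  }
  vals <- vals[!is.na(vals)]
  list(pairs = pairs, values = vals, b_low = min(vals), b_high = max(vals))
}

#' One step of the connection-threshold update
#'
#' `h = b_high - lam * (b_high - b_low)`, the bracket-shrinking rule of the
#' iterative threshold search (`lam = 0.1` by default).
#'
#' @param state List with `b_low`, `b_high` and optionally `lam`
#'   (a `threshold_state`); `b_low <= b_high` required.
#' @param lam Shrink factor in `(0, 1)`; overrides `state$lam`.
#' @return The updated threshold `h`.
#' @examples
#' update_threshold(list(b_low = 0.2, b_high = 0.9))  # 0.83
#' @export
update_threshold <- function(state, lam = state$lam %||% 0.1) {
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0 || lam >= 1) {
    gg_stop("lam must lie in (0, 1)", "gg_invalid_parameter")
  }
  if (state$b_low > state$b_high) {
    gg_stop("b_low must not exceed b_high", "gg_invalid_input")
  }
  state$b_high - lam * (state$b_high - state$b_low)
}

#' Core threshold-search loop over precomputed pair similarities
#'
#' Iterates the bracket update: at each step `h = b_high - lam*(b_high -
#' b_low)`; every sampled pair with similarity `> h` is validated through
#' `validate_fn`; if any validated pair scores `dif_h <= dif_accept` the
#' lower bracket is raised to `h` and the step repeats, otherwise `h` is
#' returned.  Pairs whose validation is impossible (registration failure)
#' should return `-Inf` from `validate_fn` so the search raises `h` past
#' them.
#'
#' @param similarities Numeric vector of sampled pair similarities.
#' @param validate_fn `function(pair_index)` returning that pair's `dif_h`
#'   (memoize inside if expensive).
#' @param lam Shrink factor (default 0.1).
#' @param dif_accept Validation acceptance level (default 0.8).
#' @param max_iter Iteration budget.
#' @return List with `h` and `state` (a `threshold_state`: `b_low`,
#'   `b_high`, `lam`, `h`, `iteration`, `history` of h values).
#' @export
threshold_search <- function(similarities, validate_fn, lam = 0.1,
                             dif_accept = 0.8, max_iter = 50L) {
  if (!is.numeric(lam) || lam <= 0 || lam >= 1) {
    gg_stop("lam must lie in (0, 1)", "gg_invalid_parameter")
  }
  b_low <- min(similarities)
  b_high <- max(similarities)
  history <- numeric(0)
  iter <- 0L
  repeat {
    if (iter >= max_iter) {
      st <- structure(list(b_low = b_low, b_high = b_high, lam = lam,
                           h = if (length(history)) history[length(history)] else NA_real_,
                           iteration = iter, history = history),
                      class = "threshold_state")
      cond <- structure(
        class = c("gg_nonconvergence", "gg_error", "error", "condition"),
        list(message = sprintf("threshold search did not converge in %d iterations", max_iter),
             call = sys.call(-1), state = st))
      stop(cond)
    }
    iter <- iter + 1L
    h <- b_high - lam * (b_high - b_low)
    history <- c(history, h)
    active <- which(similarities > h)
    if (length(active) == 0L) {
      gg_warn("no sampled pair exceeds h; threshold is vacuously valid",
              "gg_vacuous_threshold")
      break
    }
    difs <- vapply(active, validate_fn, numeric(1))
    if (all(difs > dif_accept)) break
    b_low <- h
  }
  st <- structure(list(b_low = b_low, b_high = b_high, lam = lam, h = h,
                       iteration = iter, history = history),
                  class = "threshold_state")
  list(h = h, state = st)
}

# memoized pairwise registration: similarity, transform, dif_h
pair_registry <- function(frames, features, inlier_tol = 3,
                          ransac_iter = 2000L, seed = 1L, ratio = 0.8,
                          min_overlap = 0.25) {
  cache <- new.env(parent = emptyenv())
  get_pair <- function(i, j) {
    key <- paste0(min(i, j), "-", max(i, j))
    if (!is.null(cache[[key]])) {
      r <- cache[[key]]
    } else {
      lo <- min(i, j); hi <- max(i, j)
      a <- features[[lo]]; b <- features[[hi]]
      r <- list(similarity = 0, transform = NULL, dif_h = -Inf)
      if (max(n_features(a), n_features(b)) > 0L) {
        m <- match_features(a, b, ratio = ratio)
        r$similarity <- nrow(m) / max(n_features(a), n_features(b))
        if (nrow(m) >= 3L) {
          fit <- tryCatch(
            estimate_affine(m, a, b, inlier_tol = inlier_tol,
                            max_iter = ransac_iter,
                            seed = child_seed(seed, lo * 1000L + hi)),
            gg_error = function(e) NULL)
          if (!is.null(fit)) {
            r$transform <- fit$transform   # maps frame lo coords -> frame hi
            sc <- tryCatch(
              ncc_score(frames[[lo]]$image, frames[[hi]]$image,
                        fit$transform, min_overlap = min_overlap),
              gg_error = function(e) NULL)
            if (!is.null(sc)) r$dif_h <- sc$dif_h
          }
        }
      }
      cache[[key]] <- r
    }
    if (i <= j) return(r)
    out <- r
    if (!is.null(r$transform)) out$transform <- affine_invert(r$transform)
    out
  }
  get_pair
}

#' Find the optimal connection threshold for a frame set
#'
#' Implements the iterative search: sample pair similarities to bracket
#' `[b_low, b_high]`; shrink with `h = b_high - lam*(b_high - b_low)`; for
#' each sampled pair above `h`, estimate the affine transform by RANSAC,
#' warp, and validate with normalized cross-correlation; accept `h` once
#' every pair above it validates at `dif_h > dif_accept`, else raise
#' `b_low` to `h` and repeat.  Pairs whose RANSAC fails count as failed
#' validation, so the search raises `h` past their similarity.
#'
#' @inheritParams sample_similarities
#' @param lam Bracket shrink factor (default 0.1).
#' @param dif_accept NCC acceptance level (default 0.8).
#' @param max_iter Iteration budget (default 50).
#' @param inlier_tol,ransac_iter RANSAC parameters.
#' @return List with `h` and `state` (see [threshold_search()]).
#' @export
find_threshold <- function(frames, lam = 0.1, dif_accept = 0.8,
                           max_iter = 50L, n_samples = 200L, seed = 1L,
                           max_features = 200L, ratio = 0.8,
                           inlier_tol = 3, ransac_iter = 2000L,
                           features = NULL) {
  if (length(frames) < 2L) gg_stop("need at least 2 frames", "gg_invalid_input")
  if (is.null(features)) features <- frame_features(frames, max_features)
  ss <- sample_similarities(frames, n_samples = n_samples, seed = seed,
                            ratio = ratio, features = features)
  reg <- pair_registry(frames, features, inlier_tol = inlier_tol,
                       ransac_iter = ransac_iter, seed = seed, ratio = ratio)
  validate_fn <- function(k) {
    reg(ss$pairs[k, 1], ss$pairs[k, 2])$dif_h
  }
  threshold_search(ss$values, validate_fn, lam = lam,
                   dif_accept = dif_accept, max_iter = max_iter)
}

#' Build the image graph
#'
#' Computes all pairwise similarities over the frame set; every pair with
#' `S_ij > h` becomes an edge carrying the RANSAC affine transform `H_ij`
#' (and its inverse `H_ji`); all other entries hold the `(0, 0)` sentinel.
#' Pairs whose RANSAC fails are left unconnected.  Frames keep their
#' anatomic `site_label`, which partitions the graph into subgraphs for
#' node matching.
#'
#' @param frames List of [image_frame()] objects with unique ids.
#' @param h Connection threshold in `[0, 1]` (see [find_threshold()]).
#' @param max_features,ratio,inlier_tol,ransac_iter,seed,min_overlap
#'   Registration parameters.
#' @param features Optional precomputed feature sets.
#' @return An `image_graph`: list with `frame_ids`, `frames`, `site_labels`,
#'   `similarity` (N x N matrix, zero where unconnected, per the `(0, 0)`
#'   sentinel), `transforms` (named list `"i->j"` of affine transforms for
#'   connected ordered pairs), `threshold`, and `features`.
#' @export
build_graph <- function(frames, h, max_features = 200L, ratio = 0.8,
                        inlier_tol = 3, ransac_iter = 2000L, seed = 1L,
                        min_overlap = 0.25, features = NULL) {
  if (h < 0 || h > 1) gg_stop("h must lie in [0, 1]", "gg_invalid_parameter")
  n <- length(frames)
  ids <- vapply(frames, function(f) f$frame_id, character(1))
  if (anyDuplicated(ids)) gg_stop("frame ids must be unique", "gg_invalid_input")
  if (is.null(features)) features <- frame_features(frames, max_features)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  transforms <- list()
  reg <- pair_registry(frames, features, inlier_tol = inlier_tol,
                       ransac_iter = ransac_iter, seed = seed, ratio = ratio,
                       min_overlap = min_overlap)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      r <- reg(i, j)
      if (r$similarity > h && !is.null(r$transform)) {
        sim[i, j] <- sim[j, i] <- r$similarity
        transforms[[paste0(ids[i], "->", ids[j])]] <- r$transform
        transforms[[paste0(ids[j], "->", ids[i])]] <- affine_invert(r$transform)
      }
    }
  }
  g <- structure(
    list(frame_ids = ids,
         frames = frames,
         site_labels = vapply(frames, function(f) f$site_label, character(1)),
         similarity = sim,
         transforms = transforms,
         threshold = h,
         features = features),
    class = "image_graph")
  g
}

graph_edges <- function(g) {
  n <- length(g$frame_ids)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  idx <- which(upper.tri(g$similarity) & g$similarity > g$threshold, arr.ind = TRUE)
  unname(idx)
}

graph_neighbors <- function(g, i) {
  which(g$similarity[i, ] > g$threshold)
}

graph_transform <- function(g, i, j) {
  g$transforms[[paste0(g$frame_ids[i], "->", g$frame_ids[j])]]
}

#' Connectivity report for an image graph
#'
#' Connected-component analysis of the edge set.  A usable graph has a
#' single component: isolated nodes cannot take part in deformation
#' estimation, so a multi-component graph is flagged.
#'
#' @param g An `image_graph`.
#' @return List with `n_components`, `membership` (integer per frame),
#'   `n_edges` and `connected` (logical).
#' @export
validate_connectivity <- function(g) {
  n <- length(g$frame_ids)
  edges <- graph_edges(g)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L) ig <- igraph::add_edges(ig, t(edges))
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    gg_warn(sprintf("graph has %d components; isolated nodes cannot be tracked",
                    comp$no), "gg_disconnected_graph")
  }
  list(n_components = comp$no,
       membership = as.integer(comp$membership),
       n_edges = nrow(edges),
       connected = comp$no <= 1L)
}

#' @export
print.image_graph <- function(x, ...) {
  e <- graph_edges(x)
  cat(sprintf("<image_graph> %d nodes, %d edges, h = %.4f, sites: %s\n",
              length(x$frame_ids), nrow(e), x$threshold,
              paste(unique(x$site_labels), collapse = ", ")))
  invisible(x)
}
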