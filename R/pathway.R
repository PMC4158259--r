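# Pathway determination: SSD edge weights, Dijkstra shortest-path search,
# transform composition along the pathway, and marker retargeting.

#' SSD edge weight for the pathway search
#'
#' For an edge from the reference's node `node_i` to a connected candidate
#' `node_k`: both the candidate's image and the moving image are warped
#' onto the reference canvas (the candidate through the stored graph
#' transform, the moving image through the direct query transform), and
#' the mean squared difference of the two warps is the edge weight.  The
#' smaller the weight, the more the candidate looks like the moving image
#' from the reference's viewpoint, hence the better the pathway candidate.
#'
#' @param g An `image_graph`.
#' @param ref_image Reference canvas (2-D matrix) the warps are compared
#'   on — the reference image itself, or `node_i`'s image when the query
#'   transform is folded in.
#' @param node_i,node_k Connected node indices.
#' @param moving_image The moving image (2-D matrix).
#' @param direct_transform [affine_transform()] mapping `ref_image`
#'   coordinates into `moving_image` (the direct reference-to-moving
#'   RANSAC estimate).
#' @param transform_ref_to_i Optional [affine_transform()] mapping
#'   `ref_image` coordinates into `node_i`'s frame (identity when
#'   `ref_image` is node i's own image).
#' @return Non-negative weight; `Inf` (with a warning) when the warps do
#'   not overlap enough to compare.
#' @export
edge_weight <- function(g, ref_image, node_i, node_k, moving_image,
                        direct_transform, transform_ref_to_i = affine_identity()) {
  t_ik <- graph_transform(g, node_i, node_k)
  if (is.null(t_ik)) {
    gg_stop("node_i and node_k are not connected", "gg_invalid_input")
  }
  t_ref_k <- affine_compose(list(transform_ref_to_i, t_ik))
  wk <- warp_image(g$frames[[node_k]]$image, t_ref_k, dim(ref_image))
  wj <- warp_image(moving_image, direct_transform, dim(ref_image))
  tryCatch(ssd_score(wk, wj), gg_insufficient_overlap = function(e) {
    gg_warn("warps do not overlap; edge treated as absent",
            "gg_insufficient_overlap")
    Inf
  })
}

#' Dijkstra shortest pathway through the image graph
#'
#' Single-source shortest path over the graph's edge set with non-negative
#' weights supplied by `weight_fn`.  Ties in total weight are broken by
#' fewer hops, then by the lexicographically smaller node-id sequence, so
#' the result is deterministic.
#'
#' @param g An `image_graph`.
#' @param src,dst Node indices.
#' @param weight_fn `function(i, k)` returning the non-negative weight of
#'   edge `(i, k)`; `Inf` removes the edge.  Defaults to uniform weights.
#' @return A `pathway_result`: list with `nodes` (index vector from `src`
#'   to `dst`), `node_ids`, and `total_weight`.  Signals `gg_no_pathway`
#'   when `dst` is unreachable.
#' @export
shortest_pathway <- function(g, src, dst, weight_fn = function(i, k) 1) {
  n <- length(g$frame_ids)
  if (src < 1L || src > n || dst < 1L || dst > n) {
    gg_stop("src/dst out of range", "gg_invalid_input")
  }
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[src] <- 0; hops[src] <- 0
  # lexicographic path keys for deterministic tie-breaks
  path_key <- vector("list", n)
  path_key[[src]] <- g$frame_ids[src]
  lex_less <- function(a, b) {
    # TRUE if path-id sequence a < b lexicographically
    la <- length(a); lb <- length(b)
    for (t in seq_len(min(la, lb))) {
      if (a[t] < b[t]) return(TRUE)
      if (a[t] > b[t]) return(FALSE)
    }
    la < lb
  }
  repeat {
    active <- which(!done & is.finite(dist))
    if (length(active) == 0L) break
    u <- active[order(dist[active], hops[active])[1]]
    # among equal (dist, hops) pick lexicographically smallest path
    cand <- active[dist[active] == dist[u] & hops[active] == hops[u]]
    if (length(cand) > 1L) {
      for (c2 in cand) if (lex_less(path_key[[c2]], path_key[[u]])) u <- c2
    }
    if (u == dst) break
    done[u] <- TRUE
    for (k in graph_neighbors(g, u)) {
      if (done[k]) next
      w <- weight_fn(u, k)
      if (!is.finite(w)) next
      if (w < 0) gg_stop("negative edge weight", "gg_invalid_input")
      nd <- dist[u] + w
      nh <- hops[u] + 1
      nk <- c(path_key[[u]], g$frame_ids[k])
      better <- nd < dist[k] ||
        (nd == dist[k] && (nh < hops[k] ||
                           (nh == hops[k] && lex_less(nk, path_key[[k]]))))
      if (better) {
        dist[k] <- nd; hops[k] <- nh; prev[k] <- u; path_key[[k]] <- nk
      }
    }
  }
  if (!is.finite(dist[dst])) {
    gg_stop("destination unreachable from source (graph not connected)",
            "gg_no_pathway")
  }
  nodes <- dst
  while (nodes[1] != src) nodes <- c(prev[nodes[1]], nodes)
  structure(list(nodes = nodes, node_ids = g$frame_ids[nodes],
                 total_weight = dist[dst]),
            class = "pathway_result")
}

#' Compose the deformation along a pathway
#'
#' Multiplies the stored edge transforms along the node sequence, yielding
#' the affine map from the first node's coordinates into the last node's
#' frame.  A single-node pathway gives the identity.
#'
#' @param g An `image_graph`.
#' @param pathway Integer node-index vector with consecutive nodes
#'   connected in `g` (e.g. `shortest_pathway()$nodes`).
#' @return The composed [affine_transform()].
#' @export
estimate_deformation <- function(g, pathway) {
  if (length(pathway) == 0L) gg_stop("empty pathway", "gg_invalid_input")
  if (length(pathway) == 1L) return(affine_identity())
  chain <- vector("list", length(pathway) - 1L)
  for (s in seq_len(length(pathway) - 1L)) {
    t <- graph_transform(g, pathway[s], pathway[s + 1L])
    if (is.null(t)) {
      gg_stop(sprintf("pathway step %d: nodes not connected", s),
              "gg_invalid_pathway")
    }
    chain[[s]] <- t
  }
  affine_compose(chain)
}

#' Create a circular marker
#'
#' @param x,y Center coordinates in pixels (0-based).
#' @param radius Circle radius in pixels (> 0).
#' @param label Integer label shown to the endoscopist.
#' @return A one-row data.frame with class `marker_set`.
#' @export
marker <- function(x, y, radius, label = 1L) {
  if (radius <= 0) gg_stop("marker radius must be positive", "gg_invalid_input")
  out <- data.frame(label = as.integer(label), x = as.numeric(x),
                    y = as.numeric(y), radius = as.numeric(radius))
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Combine markers into a marker set
#' @param ... `marker()` objects or marker-set data.frames.
#' @export
marker_set <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Retarget markers through a deformation
#'
#' Maps each marker center through the affine deformation; the radius is
#' scaled by `sqrt(|det|)` of the 2x2 linear block (a circle stays a
#' circle for display purposes; anisotropy is ignored).  Markers whose
#' mapped center falls outside the target canvas are flagged not visible —
#' the "missing marker" case when a lesion leaves the field of view.
#'
#' @param markers A `marker_set` (non-empty).
#' @param deformation [affine_transform()] mapping reference coordinates
#'   into the target frame.
#' @param target_shape `c(rows, cols)` of the target frame.
#' @return The marker set with transformed `x`, `y`, `radius` and a
#'   `visible` logical column; labels preserved.
#' @export
retarget <- function(markers, deformation, target_shape) {
  if (nrow(markers) == 0L) gg_stop("markers must be non-empty", "gg_invalid_input")
  m <- unclass(affine_transform(unclass(deformation)))
  p <- apply_affine(deformation, cbind(markers$x, markers$y))
  s <- sqrt(abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]))
  out <- data.frame(label = markers$label,
                    x = p[, 1], y = p[, 2],
                    radius = markers$radius * s,
                    visible = p[, 1] >= 0 & p[, 1] <= target_shape[2] - 1 &
                              p[, 2] >= 0 & p[, 2] <= target_shape[1] - 1)
  class(out) <- c("marker_set", "data.frame")
  out
}

# per-query weight function: Eq.-7-style SSD against the moving image for
# edges leaving the reference's node; registration residual of the edge
# itself elsewhere (see methods vignette); memoized
tracking_weight_fn <- function(g, ref_image, ref_node, ref_transform,
                               moving_image, direct_transform) {
  memo <- new.env(parent = emptyenv())
  function(i, k) {
    key <- paste0(i, "-", k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    w <- if (i == ref_node && !is.null(direct_transform)) {
      tryCatch(
        edge_weight(g, ref_image, i, k, moving_image, direct_transform,
                    transform_ref_to_i = ref_transform),
        gg_error = function(e) Inf)
    } else {
      t_ik <- graph_transform(g, i, k)
      wk <- warp_image(g$frames[[k]]$image, t_ik, dim(g$frames[[i]]$image))
      full <- structure(list(image = g$frames[[i]]$image,
                             validity_mask = matrix(TRUE, nrow(g$frames[[i]]$image),
                                                    ncol(g$frames[[i]]$image))),
                        class = "warp_result")
      tryCatch(ssd_score(wk, full), gg_insufficient_overlap = function(e) Inf)
    }
    memo[[key]] <- w
    w
  }
}

#' Track markers across a moving sequence
#'
#' End-to-end retargeting: the reference frame is matched to the graph
#' once; then for every `stride`-th moving frame the frame is matched to
#' the graph, the shortest pathway from the reference's node to the
#' moving frame's node is searched (SSD edge weights), the deformation is
#' composed as (reference -> node) o (pathway) o (node -> moving), and all
#' markers are retargeted.  Frames between strides reuse the last computed
#' positions; frames that cannot be matched keep their markers flagged
#' not visible.
#'
#' @param g An `image_graph`.
#' @param reference An [image_frame()] carrying the markers.
#' @param markers A `marker_set` on the reference frame.
#' @param moving_frames List of [image_frame()] objects to track across.
#' @param stride Compute the deformation every `stride` frames (default 3,
#'   the real-time decimation rate).
#' @param seed RNG seed for the graph matching.
#' @param reject_dif,accept_dif,max_features,ratio,inlier_tol,ransac_iter
#'   Matching parameters (see [match_query()]).
#' @return A `tracking_record` data.frame: one row per frame and marker
#'   with `frame_id`, `frame_index`, `label`, `x`, `y`, `radius`,
#'   `visible`, `computed` (whether that frame carried a fresh
#'   deformation) and `path_length`.
#' @export
track_sequence <- function(g, reference, markers, moving_frames, stride = 3L,
                           seed = 1L, reject_dif = 0.2, accept_dif = 0.8,
                           max_features = 200L, ratio = 0.8, inlier_tol = 3,
                           ransac_iter = 2000L) {
  if (stride < 1L) gg_stop("stride must be >= 1", "gg_invalid_parameter")
  if (nrow(markers) == 0L) gg_stop("markers must be non-empty", "gg_invalid_input")
  ref_match <- match_query(reference$image, g, reject_dif = reject_dif,
                           accept_dif = accept_dif, seed = seed,
                           max_features = max_features, ratio = ratio,
                           inlier_tol = inlier_tol, ransac_iter = ransac_iter)
  ref_feat <- extract_features(reference$image, max_features = max_features)

  records <- vector("list", length(moving_frames))
  last <- NULL
  for (f in seq_along(moving_frames)) {
    mv <- moving_frames[[f]]
    fresh <- (f - 1L) %% stride == 0L
    if (fresh) {
      rec <- tryCatch({
        mv_match <- match_query(mv$image, g, reject_dif = reject_dif,
                                accept_dif = accept_dif,
                                seed = child_seed(seed, f),
                                max_features = max_features, ratio = ratio,
                                inlier_tol = inlier_tol,
                                ransac_iter = ransac_iter)
        # direct reference -> moving estimate for the Eq.-7 edge weights
        mv_feat <- extract_features(mv$image, max_features = max_features)
        direct <- tryCatch({
          dm <- match_features(ref_feat, mv_feat, ratio = ratio)
          if (nrow(dm) >= 3L) {
            estimate_affine(dm, ref_feat, mv_feat, inlier_tol = inlier_tol,
                            max_iter = ransac_iter,
                            seed = child_seed(seed, 7000L + f))$transform
          } else NULL
        }, gg_error = function(e) NULL)
        wfn <- tracking_weight_fn(g, reference$image, ref_match$node,
                                  ref_match$transform, mv$image, direct)
        path <- shortest_pathway(g, ref_match$node, mv_match$node, wfn)
        deform <- affine_compose(list(ref_match$transform,
                                      estimate_deformation(g, path$nodes),
                                      affine_invert(mv_match$transform)))
        rt <- retarget(markers, deform, dim(mv$image))
        attr(rt, "path_length") <- length(path$nodes)
        rt
      }, gg_error = function(e) NULL)
      if (!is.null(rec)) {
        last <- rec
      } else if (!is.null(last)) {
        last$visible <- FALSE
      } else {
        last <- markers
        last$visible <- FALSE
        attr(last, "path_length") <- NA_integer_
      }
    }
    rec <- as.data.frame(last)
    rec$frame_id <- mv$frame_id
    rec$frame_index <- f
    rec$computed <- fresh
    rec$path_length <- attr(last, "path_length") %||% NA_integer_
    records[[f]] <- rec
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out <- out[, c("frame_id", "frame_index", "label", "x", "y", "radius",
                 "visible", "computed", "path_length")]
  class(out) <- c("tracking_record", "data.frame")
  out
}
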