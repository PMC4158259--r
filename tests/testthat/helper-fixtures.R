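# Shared fixtures, generated in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# small texture for cheap feature tests
small_texture <- function(seed = 7) {
  fixture(paste0("tex", seed), make_texture(c(96L, 112L), seed = seed))
}

# 5-frame compact sequence + graph for matching/pathway tests
tiny_sequence <- function() {
  fixture("tiny_seq", make_sequence(
    n_frames = 5L, frame_size = c(120L, 140L),
    motion = list(max_rotation = 0.04, max_translation = 3,
                  scale_range = c(0.99, 1.01)),
    n_landmarks = 8L, seed = 21L))
}

tiny_graph <- function() {
  fixture("tiny_graph", {
    sq <- tiny_sequence()
    build_graph(sq$frames, 0.3, seed = 5L)
  })
}

# the full-size study sequence (12 frames, 240 x 280) and its graph
study_sequence <- function() {
  fixture("study_seq", make_sequence(n_frames = 12L, seed = 11L))
}

study_graph <- function() {
  fixture("study_graph", {
    sq <- study_sequence()
    feats <- lapply(sq$frames, function(f) {
      extract_features(f$image, 200L, frame_id = f$frame_id)
    })
    build_graph(sq$frames, 0.3, seed = 5L, features = feats)
  })
}

# well-conditioned random affine
rand_affine <- function() {
  make_affine(rotation = stats::runif(1, -pi / 3, pi / 3),
              scale = stats::runif(2, 0.7, 1.4),
              translation = stats::runif(2, -30, 30))
}

# feature set built directly from a descriptor matrix (positions on a grid)
fake_feature_set <- function(desc, frame_id = NULL) {
  n <- nrow(desc)
  structure(
    list(keypoints = data.frame(x = as.numeric(seq_len(n)),
                                y = rep(0, n), scale = rep(1.5, n),
                                orientation = rep(0, n),
                                response = rep(1, n)),
         descriptors = desc, frame_id = frame_id),
    class = "feature_set")
}

# minimal hand-built image graph (no images needed beyond placeholders)
toy_graph <- function(n, edges, weights = NULL, sims = NULL, threshold = 0.5,
                      transforms = NULL, images = NULL, sites = NULL) {
  ids <- sprintf("n%02d", seq_len(n))
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  tf <- list()
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      s <- if (is.null(sims)) 0.9 else sims[r]
      sim[i, j] <- sim[j, i] <- s
      t <- if (is.null(transforms)) affine_identity() else transforms[[r]]
      tf[[paste0(ids[i], "->", ids[j])]] <- t
      tf[[paste0(ids[j], "->", ids[i])]] <- affine_invert(t)
    }
  }
  frames <- lapply(seq_len(n), function(i) {
    img <- if (is.null(images)) matrix(0.5, 16, 16) else images[[i]]
    structure(list(image = img, frame_id = ids[i],
                   site_label = if (is.null(sites)) "default" else sites[i]),
              class = "image_frame")
  })
  structure(
    list(frame_ids = ids, frames = frames,
         site_labels = vapply(frames, function(f) f$site_label, character(1)),
         similarity = sim, transforms = tf, threshold = threshold,
         features = lapply(seq_len(n), function(i) {
           extract_features(frames[[i]]$image, frame_id = ids[i])
         })),
    class = "image_graph")
}

# brute-force shortest path by enumerating all simple paths
brute_shortest <- function(adj, wmat, src, dst) {
  n <- nrow(adj)
  best <- list(weight = Inf, path = NULL)
  recurse <- function(path, w) {
    u <- path[length(path)]
    if (u == dst) {
      if (w < best$weight) best <<- list(weight = w, path = path)
      return(invisible())
    }
    for (v in which(adj[u, ])) {
      if (v %in% path) next
      recurse(c(path, v), w + wmat[u, v])
    }
  }
  recurse(src, 0)
  best
}

# transitive-closure reachability (component oracle)
closure_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

expect_affine_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}
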