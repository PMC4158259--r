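test_that("threshold update follows the bracket-shrinking rule", {
  expect_equal(update_threshold(list(b_low = 0.2, b_high = 0.9)), 0.83)
  expect_equal(update_threshold(list(b_low = 0.4, b_high = 0.4)), 0.4)
  expect_error(update_threshold(list(b_low = 0.2, b_high = 0.9), lam = 0),
               class = "gg_invalid_parameter")
  expect_error(update_threshold(list(b_low = 0.2, b_high = 0.9), lam = 1),
               class = "gg_invalid_parameter")
  expect_error(update_threshold(list(b_low = 0.9, b_high = 0.2)),
               class = "gg_invalid_input")
})

test_that("threshold search exits immediately when every active pair validates", {
  sims <- c(0.3, 0.5, 0.7, 0.9)
  res <- threshold_search(sims, function(k) 0.95, lam = 0.1)
  expect_equal(res$h, 0.9 - 0.1 * (0.9 - 0.3))
  expect_equal(res$state$iteration, 1L)
})

test_that("threshold search clears a planted validation cutoff", {
  set.seed(8)
  for (trial in 1:5) {
    sims <- stats::runif(60, 0.05, 0.95)
    cutoff <- stats::runif(1, 0.85, 0.93)   # above the first bracket value
    validate <- function(k) if (sims[k] > cutoff) 0.95 else 0.5
    res <- threshold_search(sims, validate, lam = 0.1, max_iter = 200L)
    # exit condition: every pair above h validates
    active <- which(sims > res$h)
    expect_true(all(vapply(active, validate, numeric(1)) > 0.8))
    # h can only rise across iterations, and it took > 1 iteration when the
    # first bracket value sat below the planted cutoff
    expect_true(all(diff(res$state$history) >= -1e-12))
    failing <- sims[sims <= cutoff]
    if (res$state$history[1] < cutoff && any(failing > res$state$history[1])) {
      expect_gt(res$state$iteration, 1L)
      # h must have risen past every failing similarity
      expect_gte(res$h, max(failing) - 1e-9)
    }
  }
})

test_that("threshold search signals nonconvergence with its final state", {
  err <- tryCatch(
    threshold_search(c(0.2, 0.8), function(k) 0.1, max_iter = 0L),
    gg_nonconvergence = function(e) e)
  expect_s3_class(err, "gg_nonconvergence")
  expect_s3_class(err$state, "threshold_state")
  err2 <- tryCatch(
    threshold_search(c(0.2, 0.8), function(k) 0.1, max_iter = 5L),
    gg_nonconvergence = function(e) e)
  expect_s3_class(err2, "gg_nonconvergence")
  expect_equal(err2$state$iteration, 5L)
})

test_that("similarity sampling brackets the range deterministically", {
  sq <- tiny_sequence()
  s1 <- sample_similarities(sq$frames, n_samples = 6, seed = 3)
  s2 <- sample_similarities(sq$frames, n_samples = 6, seed = 3)
  expect_identical(s1, s2)
  expect_equal(s1$b_low, min(s1$values))
  expect_equal(s1$b_high, max(s1$values))
  expect_true(all(s1$values >= 0 & s1$values <= 1))

  tex <- small_texture()
  twins <- list(image_frame(tex, "a"), image_frame(tex, "b"))
  st <- sample_similarities(twins, n_samples = 1, seed = 1)
  expect_equal(st$values, 1.0)
  expect_equal(st$b_low, 1.0)
  expect_equal(st$b_high, 1.0)
})

test_that("graph construction: single frame, identical frames, stored inverses", {
  tex <- small_texture()
  g1 <- build_graph(list(image_frame(tex, "only")), h = 0.5)
  expect_equal(length(g1$frame_ids), 1L)
  expect_equal(suppressWarnings(validate_connectivity(g1))$n_edges, 0L)

  triplet <- list(image_frame(tex, "a"), image_frame(tex, "b"),
                  image_frame(tex, "c"))
  g3 <- build_graph(triplet, h = 0.5, seed = 2)
  conn <- validate_connectivity(g3)
  expect_equal(conn$n_edges, 3L)       # complete graph on 3 nodes
  expect_equal(conn$n_components, 1L)
  for (nm in names(g3$transforms)) {
    expect_affine_equal(g3$transforms[[nm]], affine_identity(), tol = 0.2)
  }
  expect_error(build_graph(list(image_frame(tex, "x"), image_frame(tex, "x")),
                           h = 0.5),
               class = "gg_invalid_input")   # duplicate ids
})

test_that("stored reverse transforms are the inverses of forward ones", {
  g <- tiny_graph()
  edges <- gastrograph:::graph_edges(g)
  expect_gt(nrow(edges), 0L)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    fwd <- gastrograph:::graph_transform(g, i, j)
    rev <- gastrograph:::graph_transform(g, j, i)
    expect_affine_equal(affine_compose(list(fwd, rev)), affine_identity(),
                        tol = 1e-6)
  }
})

test_that("raising the threshold never adds edges", {
  sq <- tiny_sequence()
  feats <- lapply(sq$frames, function(f) extract_features(f$image, 200L))
  g_lo <- build_graph(sq$frames, 0.2, seed = 5, features = feats)
  g_hi <- suppressWarnings(build_graph(sq$frames, 0.5, seed = 5,
                                       features = feats))
  e_lo <- gastrograph:::graph_edges(g_lo)
  e_hi <- gastrograph:::graph_edges(g_hi)
  expect_lte(nrow(e_hi), nrow(e_lo))
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(e_hi) %in% key(e_lo)))
})

test_that("connectivity report matches a transitive-closure oracle", {
  cg <- toy_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)))
  expect_equal(validate_connectivity(cg)$n_components, 1L)
  eg <- toy_graph(5, matrix(integer(0), ncol = 2))
  expect_equal(suppressWarnings(validate_connectivity(eg))$n_components, 5L)

  set.seed(14)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- stats::runif(1) < 0.25
    }
    edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    g <- toy_graph(n, edges)
    got <- suppressWarnings(validate_connectivity(g))
    oracle <- closure_components(adj)
    expect_equal(got$n_components, length(unique(oracle)))
    # same partition up to relabeling
    expect_equal(length(unique(paste(got$membership, oracle))),
                 length(unique(oracle)))
  }
})

test_that("find_threshold returns an h that satisfies its own exit condition", {
  sq <- tiny_sequence()
  feats <- lapply(sq$frames, function(f) extract_features(f$image, 200L))
  res <- find_threshold(sq$frames, seed = 3, features = feats)
  expect_true(res$h >= res$state$b_low && res$h <= res$state$b_high)
  expect_true(all(diff(res$state$history) >= -1e-12))
})
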