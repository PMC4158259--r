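test_that("trivial pathways: src == dst, and forced two-hop arithmetic", {
  g <- toy_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  p0 <- shortest_pathway(g, 2, 2)
  expect_equal(p0$nodes, 2)
  expect_equal(p0$total_weight, 0)

  w <- matrix(Inf, 3, 3)
  w[1, 2] <- w[2, 1] <- 2; w[2, 3] <- w[3, 2] <- 2; w[1, 3] <- w[3, 1] <- 5
  p <- shortest_pathway(g, 1, 3, function(i, k) w[i, k])
  expect_equal(p$nodes, c(1, 2, 3))
  expect_equal(p$total_weight, 4)
})

test_that("unreachable destinations raise a no-pathway error", {
  g <- toy_graph(4, rbind(c(1, 2)))
  expect_error(shortest_pathway(g, 1, 4), class = "gg_no_pathway")
  expect_error(shortest_pathway(g, 1, 9), class = "gg_invalid_input")
})

test_that("ties break by fewer hops then lexicographic node ids", {
  # two equal-weight routes 1->4: direct (weight 2) vs 1->2->4 (1+1)
  g <- toy_graph(4, rbind(c(1, 2), c(2, 4), c(1, 4), c(1, 3), c(3, 4)))
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[2, 4] <- w[4, 2] <- 1
  w[1, 4] <- w[4, 1] <- 2
  w[1, 3] <- w[3, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  p <- shortest_pathway(g, 1, 4, function(i, k) w[i, k])
  expect_equal(p$total_weight, 2)
  expect_equal(p$nodes, c(1, 4))      # fewest hops wins the tie
  # equal weight, equal hops: lexicographically smaller id sequence wins
  w[1, 4] <- w[4, 1] <- 5
  p2 <- shortest_pathway(g, 1, 4, function(i, k) w[i, k])
  expect_equal(p2$nodes, c(1, 2, 4))  # "n02" < "n03"
})

test_that("pathway weights equal brute-force enumeration on random graphs", {
  set.seed(23)
  for (trial in 1:30) {
    n <- sample(4:8, 1)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE  # connected
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.3) adj[i, j] <- adj[j, i] <- TRUE
    }
    wmat <- matrix(0, n, n)
    wmat[upper.tri(wmat)] <- stats::runif(n * (n - 1) / 2, 0.1, 5)
    wmat <- wmat + t(wmat)
    edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    g <- toy_graph(n, edges)
    src <- sample(n, 1); dst <- sample(n, 1)
    got <- shortest_pathway(g, src, dst, function(i, k) wmat[i, k])
    oracle <- brute_shortest(adj, wmat, src, dst)
    expect_equal(got$total_weight, oracle$weight, tolerance = 1e-12)
    # independent cross-check with igraph
    ig <- igraph::graph_from_adjacency_matrix(adj * wmat, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(got$total_weight,
                 as.numeric(igraph::distances(ig, src, dst)),
                 tolerance = 1e-12)
  }
})

test_that("deformation composition along a pathway multiplies edge transforms", {
  tfs <- list(affine_translation(2, 0), affine_translation(0, 3))
  g <- toy_graph(3, rbind(c(1, 2), c(2, 3)), transforms = tfs)
  expect_affine_equal(estimate_deformation(g, 1L), affine_identity())
  expect_affine_equal(estimate_deformation(g, c(1L, 2L, 3L)),
                      affine_translation(2, 3))
  expect_error(estimate_deformation(g, c(1L, 3L)),
               class = "gg_invalid_pathway")

  # reversed pathway composes to the inverse deformation
  set.seed(12)
  tfs2 <- replicate(3, rand_affine(), simplify = FALSE)
  g2 <- toy_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)), transforms = tfs2)
  fwd <- estimate_deformation(g2, 1:4)
  bwd <- estimate_deformation(g2, 4:1)
  expect_affine_equal(affine_compose(list(fwd, bwd)), affine_identity(),
                      tol = 1e-6)
})

test_that("edge weights reproduce the SSD of the two warps", {
  img <- matrix(0, 20, 20)
  g <- toy_graph(2, rbind(c(1, 2)), images = list(img, img))
  w0 <- edge_weight(g, img, 1L, 2L, img, affine_identity())
  expect_equal(w0, 0)
  g2 <- toy_graph(2, rbind(c(1, 2)),
                  images = list(matrix(0, 20, 20), matrix(0, 20, 20)))
  w10 <- edge_weight(g2, matrix(0, 20, 20), 1L, 2L, matrix(10, 20, 20),
                     affine_identity())
  expect_equal(w10, 100)

  set.seed(4)
  a <- matrix(stats::runif(400), 20, 20)
  b <- matrix(stats::runif(400), 20, 20)
  ref <- matrix(stats::runif(400), 20, 20)
  g3 <- toy_graph(2, rbind(c(1, 2)), images = list(ref, a))
  got <- edge_weight(g3, ref, 1L, 2L, b, affine_identity())
  naive <- mean((a - b)^2)
  expect_equal(got, naive, tolerance = 1e-9)
  expect_gte(got, 0)
  expect_error(edge_weight(g3, ref, 2L, 2L, b, affine_identity()),
               class = "gg_invalid_input")
})

test_that("retargeting maps centers, scales radii, and flags off-frame markers", {
  mk <- marker_set(marker(10, 20, 5, 1), marker(100, 50, 4, 2))
  id <- retarget(mk, affine_identity(), c(120, 140))
  expect_equal(id$x, mk$x)
  expect_equal(id$y, mk$y)
  expect_equal(id$radius, mk$radius)
  expect_true(all(id$visible))

  sc <- retarget(mk, make_affine(scale = 2), c(400, 400))
  expect_equal(sc$x, mk$x * 2)
  expect_equal(sc$radius, mk$radius * 2)

  tr <- retarget(mk, affine_translation(60, 0), c(120, 140))
  expect_equal(tr$visible, c(TRUE, FALSE))
  expect_equal(tr$label, mk$label)
})

test_that("retargeting forward then back returns markers to their origin", {
  set.seed(3)
  mk <- marker_set(marker(40, 60, 6, 1), marker(80, 30, 6, 2))
  tfs <- replicate(3, rand_affine(), simplify = FALSE)
  g <- toy_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)), transforms = tfs)
  fwd <- estimate_deformation(g, 1:4)
  there <- retarget(mk, fwd, c(1000, 1000))
  back <- retarget(there, estimate_deformation(g, 4:1), c(1000, 1000))
  expect_lt(max(abs(back$x - mk$x)), 1e-6)
  expect_lt(max(abs(back$y - mk$y)), 1e-6)
})

test_that("tracking an identical moving frame reproduces the markers", {
  g <- tiny_graph()
  sq <- tiny_sequence()
  mk <- make_phantom_markers(sq, 3, radius = 5, seed = 4)
  rec <- track_sequence(g, sq$frames[[1]], mk, sq$frames[1], stride = 1,
                        seed = 6)
  expect_equal(nrow(rec), 3L)
  expect_lt(max(abs(rec$x - mk$x)), 1)
  expect_lt(max(abs(rec$y - mk$y)), 1)
  expect_true(all(rec$visible))
})

test_that("stride controls which frames carry a fresh deformation", {
  g <- tiny_graph()
  sq <- tiny_sequence()
  mk <- make_phantom_markers(sq, 2, radius = 5, seed = 4)
  moving <- sq$frames[c(2, 3, 4, 2, 3, 4, 2, 3, 4, 2)]
  for (k in seq_along(moving)) {
    f <- moving[[k]]
    moving[[k]] <- image_frame(f$image, sprintf("mv%02d", k), f$site_label)
  }
  rec <- track_sequence(g, sq$frames[[1]], mk, moving, stride = 3, seed = 6)
  comp <- tapply(rec$computed, rec$frame_index, unique)
  expect_equal(as.logical(comp), rep(c(TRUE, FALSE, FALSE), length.out = 10))
})
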