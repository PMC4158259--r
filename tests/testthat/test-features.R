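test_that("clamp normalization applies the strict 0.4 rule without renormalizing", {
  expect_equal(clamp_normalize(rep(0, 32)), rep(0, 32))
  v <- rep(0, 32); v[5] <- 0.5
  out <- clamp_normalize(v)
  expect_equal(out[5], 1)
  expect_equal(out[-5], rep(0, 31))
  v[5] <- 0.4
  expect_equal(clamp_normalize(v)[5], 0.4)  # strictly "bigger than 0.4"
  expect_error(clamp_normalize(rep(0.1, 16)), class = "gg_invalid_input")
})

test_that("degenerate images yield empty feature sets; bad input errors", {
  expect_equal(n_features(extract_features(matrix(0.5, 64, 64))), 0L)
  expect_equal(n_features(extract_features(matrix(0.5, 8, 8))), 0L)
  expect_error(extract_features(array(0.1, c(4, 4, 3))),
               class = "gg_invalid_input")
  expect_error(extract_features(small_texture(), max_features = 0),
               class = "gg_invalid_parameter")
})

test_that("detection respects the scale band, the budget, and response ordering", {
  tex <- small_texture()
  fs <- extract_features(tex, max_features = 50L)
  expect_lte(n_features(fs), 50L)
  expect_gt(n_features(fs), 5L)
  expect_true(all(fs$keypoints$scale >= 1 & fs$keypoints$scale <= 3))
  expect_true(all(diff(fs$keypoints$response) <= 1e-15))
  expect_true(all(fs$keypoints$x >= 0 & fs$keypoints$x < ncol(tex)))
  expect_true(all(fs$keypoints$y >= 0 & fs$keypoints$y < nrow(tex)))
  expect_equal(dim(fs$descriptors), c(n_features(fs), 32L))
  expect_true(all(fs$descriptors >= 0 & fs$descriptors <= 1))
  expect_true(all(fs$keypoints$orientation >= 0 &
                  fs$keypoints$orientation < 2 * pi))
})

test_that("feature extraction is bitwise deterministic", {
  tex <- small_texture(13)
  expect_identical(extract_features(tex, 100L), extract_features(tex, 100L))
})

test_that("a 90-degree rotation permutes keypoint coordinates", {
  tex <- make_texture(c(128L, 128L), seed = 31)
  rot_ccw <- function(m) {
    tm <- t(m)
    tm[rev(seq_len(nrow(tm))), , drop = FALSE]
  }
  f0 <- extract_features(tex, 150L)
  f1 <- extract_features(rot_ccw(tex), 150L)
  w <- ncol(tex)
  # original (x, y) appears at (y, w - 1 - x) in the rotated image
  mapped <- cbind(f0$keypoints$y, w - 1 - f0$keypoints$x)
  p1 <- as.matrix(f1$keypoints[, c("x", "y")])
  mind <- apply(mapped, 1, function(p) {
    min(sqrt((p1[, 1] - p[1])^2 + (p1[, 2] - p[2])^2))
  })
  expect_gte(mean(mind <= 1), 0.8)
})

test_that("matching is mutual-NN with a strict ratio test, one-to-one", {
  set.seed(5)
  d <- matrix(stats::runif(10 * 32), 10, 32)
  d <- d / sqrt(rowSums(d^2))
  a <- fake_feature_set(d)
  m_self <- match_features(a, a)
  expect_equal(nrow(m_self), 10L)
  expect_equal(m_self$idx_a, m_self$idx_b)

  # orthogonal sets with equal pairwise distances: ratio test rejects ties
  ea <- fake_feature_set(cbind(diag(4), matrix(0, 4, 28)))
  eb <- fake_feature_set(cbind(matrix(0, 4, 4), diag(4), matrix(0, 4, 24)))
  expect_equal(nrow(match_features(ea, eb, ratio = 1)), 0L)

  expect_equal(nrow(match_features(a, fake_feature_set(matrix(numeric(0), 0, 32)))), 0L)
})

test_that("matching agrees with an exhaustive brute-force oracle", {
  set.seed(17)
  for (trial in 1:5) {
    da <- matrix(stats::runif(10 * 32), 10, 32)
    db <- matrix(stats::runif(10 * 32), 10, 32)
    a <- fake_feature_set(da); b <- fake_feature_set(db)
    got <- match_features(a, b, ratio = 0.8)
    # oracle: all-pairs distances, mutual NN, strict ratio applied on both
    # sides (the two-sided form keeps the match set symmetric in a and b)
    d2 <- as.matrix(stats::dist(rbind(da, db)))[1:10, 11:20]
    expected <- list()
    for (i in 1:10) {
      j <- which.min(d2[i, ])
      if (which.min(d2[, j]) != i) next
      second_a <- min(d2[i, -j])
      second_b <- min(d2[-i, j])
      if (d2[i, j] < 0.8 * second_a && d2[i, j] < 0.8 * second_b) {
        expected[[length(expected) + 1L]] <- c(i, j)
      }
    }
    expected <- do.call(rbind, expected)
    expect_equal(nrow(got), NROW(expected))
    if (NROW(expected)) {
      expect_equal(as.matrix(got[, c("idx_a", "idx_b")]),
                   expected, ignore_attr = TRUE)
    }
  }
})

test_that("similarity is the matched fraction of the larger set, symmetric", {
  set.seed(3)
  mk <- function(n) {
    d <- matrix(stats::runif(n * 32), n, 32)
    fake_feature_set(d / sqrt(rowSums(d^2)))
  }
  a200 <- mk(200); b150 <- mk(150)
  fake_matches <- structure(
    data.frame(idx_a = 1:60, idx_b = 1:60, distance = 0),
    class = c("match_set", "data.frame"))
  expect_equal(feature_similarity(a200, b150, fake_matches), 0.30)

  a <- mk(12)
  expect_equal(feature_similarity(a, a), 1.0)
  empty_m <- fake_matches[0, ]
  expect_equal(feature_similarity(a200, b150, empty_m), 0)
  expect_equal(feature_similarity(a200, b150), feature_similarity(b150, a200))

  none <- fake_feature_set(matrix(numeric(0), 0, 32))
  expect_error(feature_similarity(none, none),
               class = "gg_undefined_similarity")
})
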