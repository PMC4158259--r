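test_that("forward-backward error is zero for perfect trackers", {
  frames <- replicate(4, matrix(0.5, 16, 16), simplify = FALSE)
  seeds <- cbind(c(3, 8), c(4, 9))
  perfect <- function(from, to, pts) pts
  fb <- forward_backward(frames, perfect, seeds)
  expect_equal(fb$fb_error, c(0, 0))
  expect_false(any(fb$lost))

  # planted affine forward, exact inverse backward
  A <- make_affine(rotation = 0.2, translation = c(3, -2))
  calls <- 0
  tracker <- function(from, to, pts) {
    calls <<- calls + 1
    if (calls <= 1) apply_affine(A, pts) else apply_affine(affine_invert(A), pts)
  }
  fb2 <- forward_backward(frames[1:2], tracker, seeds)
  expect_lt(max(fb2$fb_error), 1e-6)
})

test_that("a planted forward bias accumulates into the hand-computed FB error", {
  frames <- replicate(3, matrix(0.5, 16, 16), simplify = FALSE)
  # 3 frames: 2 forward hops each biased +2 px in x, backward hops exact
  n_fwd <- length(frames) - 1
  calls <- 0
  tracker <- function(from, to, pts) {
    calls <<- calls + 1
    if (calls <= n_fwd) cbind(pts[, 1] + 2, pts[, 2]) else pts
  }
  fb <- forward_backward(frames, tracker, cbind(5, 5))
  expect_equal(fb$fb_error, 4.0)
})

test_that("lost points are flagged and excluded from error statistics", {
  frames <- replicate(3, matrix(0.5, 16, 16), simplify = FALSE)
  tracker <- function(from, to, pts) {
    pts[1, ] <- NA
    pts
  }
  fb <- forward_backward(frames, tracker, cbind(c(1, 2), c(1, 2)))
  expect_true(fb$lost[1])
  expect_true(is.na(fb$fb_error[1]))
  expect_error(forward_backward(frames[1], function(a, b, p) p, cbind(1, 1)),
               class = "gg_invalid_input")
  expect_equal(nrow(forward_backward(frames, tracker,
                                     matrix(numeric(0), ncol = 2))), 0L)
})

test_that("gaussian noise is seeded, bounded, and moment-correct", {
  img <- matrix(0.5, 256, 256)
  expect_identical(gaussian_noise(img, 0), img)
  n1 <- gaussian_noise(img, 0.1, seed = 3)
  n2 <- gaussian_noise(img, 0.1, seed = 3)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_equal(stats::sd(n1 - img), 0.1, tolerance = 0.05)
  expect_error(gaussian_noise(img, -0.1), class = "gg_invalid_parameter")
})

test_that("KL divergence matches direct summation and is non-negative", {
  d <- kl_divergence(c(0.5, 0.5), c(0.25, 0.75), epsilon = 0)
  oracle <- 0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75)
  expect_equal(unname(d["d_kl1"]), oracle, tolerance = 1e-12)
  expect_equal(unname(d["d_kl1"]), 0.1438, tolerance = 1e-3)

  p <- trajectory_distribution(cbind(c(10, 20, 30), c(10, 20, 30)), c(64, 64))
  expect_equal(sum(p$weights), 1, tolerance = 1e-9)
  expect_equal(unname(kl_divergence(p, p)), c(0, 0))

  set.seed(2)
  for (k in 1:20) {
    a <- stats::runif(16); b <- stats::runif(16)
    d2 <- kl_divergence(a / sum(a), b / sum(b))
    expect_true(all(d2 >= 0))
  }
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)),
               class = "gg_invalid_input")
  q <- trajectory_distribution(cbind(1, 1), c(32, 32))
  expect_error(kl_divergence(p, q), class = "gg_invalid_input")
})

test_that("trajectory acceptance flips between identical and offset paths", {
  set.seed(8)
  fwd <- data.frame(label = rep(1:2, each = 6),
                    x = stats::runif(12, 40, 80),
                    y = stats::runif(12, 40, 80))
  same <- trajectory_accuracy(fwd, fwd, c(240, 280))
  expect_true(all(same$accepted))
  expect_equal(same$d_kl1, c(0, 0), tolerance = 1e-9)

  off <- fwd
  off$x <- off$x + 80    # 10 grid cells at the 8-px default
  mixed <- trajectory_accuracy(fwd, off, c(240, 280))
  expect_false(any(mixed$accepted))

  # jittered: the decision must equal direct computation of both KLs
  jit <- fwd
  jit$x <- jit$x + stats::rnorm(12, 0, 4)
  jit$y <- jit$y + stats::rnorm(12, 0, 4)
  got <- trajectory_accuracy(fwd, jit, c(240, 280))
  for (l in 1:2) {
    dp <- trajectory_distribution(as.matrix(fwd[fwd$label == l, c("x", "y")]),
                                  c(240, 280))
    dq <- trajectory_distribution(as.matrix(jit[jit$label == l, c("x", "y")]),
                                  c(240, 280))
    d <- kl_divergence(dp, dq)
    expect_equal(got$accepted[got$label == l],
                 d[["d_kl1"]] < 0.1 && d[["d_kl2"]] < 0.1)
  }
  expect_error(trajectory_accuracy(fwd[1, ], fwd[1, ], c(240, 280)),
               class = "gg_insufficient_trajectory")
})

test_that("pixel distances convert through the forceps calibration", {
  expect_equal(pixels_to_mm(37, 37), 8.0)
  expect_equal(pixels_to_mm(0, 50), 0)
  expect_equal(pixels_to_mm(10, 40), 2.0)
  expect_error(pixels_to_mm(10, 0), class = "gg_invalid_parameter")
})

test_that("accuracy reports aggregate acceptance and FB statistics", {
  set.seed(5)
  fwd <- data.frame(label = rep(1:4, each = 5),
                    x = rep(c(40, 80, 120, 160), each = 5) + stats::runif(20, 0, 2),
                    y = rep(50, 20) + stats::runif(20, 0, 2))
  # a backward pass traverses the frames in reverse, ending at the origin
  bwd0 <- do.call(rbind, lapply(split(fwd, fwd$label), function(d) d[nrow(d):1, ]))
  bwd <- bwd0
  bwd$x[bwd$label == 4] <- bwd$x[bwd$label == 4] + 100  # one bad marker
  rep4 <- accuracy_report(fwd, bwd, c(240, 280), forceps_diameter_px = 40)
  expect_equal(rep4$accuracy_percent, 0.75)
  expect_equal(rep4$n_accepted, 3L)

  perfect <- accuracy_report(fwd, bwd0, c(240, 280), forceps_diameter_px = 40)
  expect_equal(perfect$accuracy_percent, 1.0)
  expect_equal(perfect$mean_mm, 0)
  expect_equal(perfect$var_mm2, 0)

  # permutation invariance in marker order (within-marker order preserved)
  perm <- unlist(lapply(sample(4), function(l) which(fwd$label == l)))
  rep_perm <- accuracy_report(fwd[perm, ], bwd[perm, ], c(240, 280),
                              forceps_diameter_px = 40)
  expect_equal(rep_perm$accuracy_percent, rep4$accuracy_percent)
  expect_equal(sort(rep_perm$per_marker$fb_error_mm),
               sort(rep4$per_marker$fb_error_mm))
})
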