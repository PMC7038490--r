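test_that("backward cloud matches the direct arithmetic oracle", {
  # hand-computed for {1, 2, 3}: D = 2/3, S^2 (n-1 divisor) = 1
  d <- backward_cloud(c(1, 2, 3))
  expect_equal(d$ex, 2)
  expect_equal(d$en, sqrt(pi / 2) * 2 / 3)
  expect_equal(d$he, sqrt(1 - pi / 2 * 4 / 9))

  # constant sample collapses to a point concept
  d0 <- backward_cloud(rep(3.7, 10))
  expect_equal(unlist(d0[c("ex", "en", "he")]),
               c(ex = 3.7, en = 0, he = 0))

  # sample variance below En^2 clamps He to zero with a warning:
  # {-1,-1,1,1} has S^2 = 4/3 < En^2 = pi/2
  expect_warning(dc <- backward_cloud(c(-1, -1, 1, 1)), "clamping He")
  expect_equal(dc$he, 0)
  expect_equal(dc$en, sqrt(pi / 2))

  expect_error(backward_cloud(5), "insufficient data")
  expect_error(backward_cloud(c(1, NA)), "non-finite")
  expect_error(backward_cloud(c(1, Inf)), "non-finite")
})

test_that("2-D backward cloud works per dimension and is symmetric", {
  pts <- matrix(c(rep(2.5, 6), rep(-1.25, 6)), ncol = 2)
  d <- backward_cloud2d(pts)
  expect_equal(d$dim1$ex, 2.5)
  expect_equal(d$dim2$ex, -1.25)
  expect_equal(c(d$dim1$en, d$dim1$he, d$dim2$en, d$dim2$he), rep(0, 4))

  withr::with_seed(11, {
    p2 <- cbind(rnorm(50, 3, 2), rnorm(50, -4, 0.5))
  })
  # a pure normal sample sits at the S^2 = En^2 boundary, so the He clamp
  # may fire either way; it is not the subject here
  a <- suppressWarnings(backward_cloud2d(p2))
  b <- suppressWarnings(backward_cloud2d(p2[, 2:1]))
  expect_equal(a$dim1, b$dim2)
  expect_equal(a$dim2, b$dim1)
  expect_error(backward_cloud2d(matrix(1:9, 3)), "2 columns")
})

test_that("forward cloud handles degenerate descriptors and exposes exact certainty", {
  d0 <- desc2d(ex = c(4, -7), en = c(0, 0))
  drops <- forward_cloud2d(d0, 20, seed = 1)
  expect_true(all(drops$x1 == 4 & drops$x2 == -7 & drops$mu == 1))

  # with he = 0 the per-droplet entropy equals en, so mu is a closed form
  d1 <- desc2d(ex = c(1, -2), en = c(2, 0.5))
  dr <- forward_cloud2d(d1, 500, seed = 2)
  mu_oracle <- exp(-((dr$x1 - 1)^2 / (2 * 4) + (dr$x2 + 2)^2 / (2 * 0.25)))
  expect_equal(dr$mu, mu_oracle, tolerance = 1e-12)
  expect_true(all(dr$mu > 0 & dr$mu <= 1))

  # seeded reproducibility
  expect_identical(forward_cloud2d(d1, 100, seed = 9),
                   forward_cloud2d(d1, 100, seed = 9))
  expect_error(forward_cloud2d(d1, 0), "invalid argument")
})

test_that("droplet variance follows the law of total variance en^2 + he^2", {
  d <- liquor_descriptors()$jiang
  dr <- forward_cloud2d(d, 1e5, seed = 4)
  expect_equal(var(dr$x1), d$dim1$en^2 + d$dim1$he^2, tolerance = 0.03)
  expect_equal(var(dr$x2), d$dim2$en^2 + d$dim2$he^2, tolerance = 0.03)
})

test_that("forward-backward round trip recovers mild-hyper-entropy descriptors", {
  cases <- list(c(0, 1, 0), c(5, 2, 0.6), c(-3, 1.5, 0.7), c(41.65, 2.75, 0))
  for (cs in cases) {
    d <- desc2d(ex = c(cs[1], 0), en = c(cs[2], 1), he = c(cs[3], 0))
    dr <- forward_cloud2d(d, 1e5, seed = 21)
    est <- backward_cloud(dr$x1)
    expect_lt(abs(est$ex - cs[1]), 0.02 * cs[2])
    expect_lt(abs(est$en - cs[2]) / cs[2], 0.02)
  }
})

test_that("certainty depends only on standardized offsets: translation equivariance", {
  d <- desc2d(ex = c(0, 0), en = c(1.5, 2), he = c(0.3, 0.4))
  ds <- desc2d(ex = c(10, -20), en = c(1.5, 2), he = c(0.3, 0.4))
  a <- forward_cloud2d(d, 200, seed = 5)
  b <- forward_cloud2d(ds, 200, seed = 5)
  expect_equal(b$x1, a$x1 + 10)
  expect_equal(b$x2, a$x2 - 20)
  expect_equal(b$mu, a$mu, tolerance = 1e-12)
})

test_that("interval contribution integrates the cloud density like a normal CDF", {
  d <- cloud_descriptor(3, 1.7)
  expect_equal(contribution_interval(d, 3 - 1.7, 3 + 1.7),
               pnorm(1) - pnorm(-1), tolerance = 1e-8)
  expect_equal(contribution_interval(d, -Inf, Inf), 1, tolerance = 1e-8)
  expect_identical(contribution_interval(d, 3, 3), 0)
  # random intervals against the CDF oracle
  withr::with_seed(6, {
    for (i in 1:10) {
      ab <- sort(rnorm(2, 3, 3))
      expect_equal(contribution_interval(d, ab[1], ab[2]),
                   pnorm(ab[2], 3, 1.7) - pnorm(ab[1], 3, 1.7),
                   tolerance = 1e-8)
    }
  })
  expect_error(contribution_interval(cloud_descriptor(0, 0), -1, 1),
               "degenerate")
  expect_error(contribution_interval(d, 2, 1), "a <= b")
})

test_that("total 2-D contribution is unity and rejects degenerate descriptors", {
  expect_equal(total_contribution(liquor_descriptors()$jiang), 1,
               tolerance = 1e-6)
  expect_equal(total_contribution(desc2d(ex = c(-5, 100), en = c(0.1, 30))), 1,
               tolerance = 1e-6)
  expect_error(total_contribution(desc2d(ex = c(0, 0), en = c(0, 1))),
               "degenerate")
})
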