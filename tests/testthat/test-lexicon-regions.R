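jiang_words <- c("Fully mellow", "Elegant and delicate", "Full bodied",
                 "Long aftertaste", "Coordination")

test_that("panel frequencies sort descending with stable ties", {
  wf <- word_frequency_table("jiang", jiang_words, c(20, 10, 4, 4, 2), 40)
  sf <- sort_frequencies(wf)
  expect_equal(sf$frequency, c(50, 25, 10, 10, 5))
  expect_equal(sf$word, jiang_words)

  tied <- word_frequency_table("x", paste0("w", 1:5), rep(8, 5), 40)
  st <- sort_frequencies(tied)
  expect_equal(st$frequency, rep(20, 5))
  expect_equal(st$word, paste0("w", 1:5))   # input order preserved

  one <- word_frequency_table("x", paste0("w", 1:5), c(40, 0, 0, 0, 0), 40)
  expect_equal(sort_frequencies(one)$frequency, c(100, 0, 0, 0, 0))

  expect_error(word_frequency_table("x", paste0("w", 1:5), c(1, 1, 1, 1, 1), 40),
               "inconsistency error")
})

test_that("multipliers are standard-normal quantiles of the central mass", {
  expect_equal(central_multiplier(50), qnorm(0.75))
  expect_equal(central_multiplier(50), 0.6745, tolerance = 1e-4)
  expect_equal(central_multiplier(68.27), 1, tolerance = 1e-3)
  expect_equal(ring_multiplier(75), 1.1503, tolerance = 1e-4)
  expect_equal(ring_multiplier(95), qnorm(0.975))
  expect_equal(ring_multiplier(95), 1.9600, tolerance = 1e-4)
  expect_identical(ring_multiplier(100), 3)
  expect_identical(ring_multiplier(100, cap = 2.5), 2.5)
  expect_error(ring_multiplier(0), "invalid frequency")
  expect_error(central_multiplier(-5), "invalid frequency")
  expect_error(ring_multiplier(101), "exceeds 100")
})

test_that("frequency-derived region sets are centred, capped and monotone", {
  desc <- liquor_descriptors()$jiang
  wf <- word_frequency_table("jiang", jiang_words, c(20, 10, 4, 4, 2), 40)
  r <- build_region_set(desc, wf)
  expect_equal(r$center, c(41.6501, -23.6840))
  expect_equal(length(r$multipliers), 5L)
  expect_equal(semi_axes(r)[5, ], c(pc1 = 3 * 2.7506, pc2 = 3 * 2.3288))
  expect_equal(r$multipliers[1], qnorm(0.75))
  expect_true(all(diff(r$multipliers) > 0))
  expect_equal(r$words, jiang_words)

  # strict monotonicity for any strictly positive frequency vector
  withr::with_seed(12, {
    for (i in 1:20) {
      counts <- as.integer(rmultinom(1, 35, runif(5, 0.5, 1))) + 1L
      wfr <- word_frequency_table("x", paste0("w", 1:5), counts, sum(counts))
      rr <- build_region_set(desc, wfr)
      expect_true(all(diff(rr$multipliers) > 0))
    }
  })

  # a single word at 100% occupies the whole cap ellipse
  one <- word_frequency_table("x", paste0("w", 1:5), c(40, 0, 0, 0, 0), 40)
  r1 <- build_region_set(desc, one)
  expect_equal(r1$multipliers[1], 3)
  # zero-frequency words are retained but never selectable
  pts <- forward_cloud2d(desc, 500, seed = 1)
  expect_true(all(locate_region(r1, pts[, 1:2]) %in% c(1L, NA)))

  expect_error(build_region_set(desc2d(ex = c(0, 0), en = c(0, 1)), wf),
               "degenerate")
})

test_that("explicit multipliers reproduce the published region geometry", {
  desc <- liquor_descriptors()
  mult <- liquor_region_multipliers()
  rj <- build_region_set_explicit(desc$jiang, mult$jiang$multipliers,
                                  mult$jiang$words)
  ax <- semi_axes(rj)
  expect_equal(ax[1, ], c(pc1 = 2.8881, pc2 = 2.4452), tolerance = 1e-4)
  expect_equal(ax[2, ], c(pc1 = 4.1259, pc2 = 3.4932), tolerance = 1e-4)
  expect_equal(ax[5, ], c(pc1 = 8.2518, pc2 = 6.9864), tolerance = 1e-4)

  rf <- build_region_set_explicit(desc$feng, mult$feng$multipliers,
                                  mult$feng$words)
  expect_equal(semi_axes(rf)[1, ], c(pc1 = 2.2081, pc2 = 2.9945),
               tolerance = 1e-4)

  expect_equal(locate_region(rj, rj$center), 1L)
  expect_error(build_region_set_explicit(desc$jiang, c(1, 0.5), c("a", "b")),
               "strictly increasing")
})

test_that("locate_region assigns the innermost containing band", {
  desc <- liquor_descriptors()$jiang
  mult <- liquor_region_multipliers()$jiang
  r <- build_region_set_explicit(desc, mult$multipliers, mult$words)
  en1 <- desc$dim1$en
  expect_equal(locate_region(r, c(41.6501, -23.6840)), 1L)
  # 1.2 En offset on PC1 sits between multipliers 1.05 and 1.50
  expect_equal(locate_region(r, c(41.6501 + 1.2 * en1, -23.6840)), 2L)
  # boundary points belong to the inner region
  expect_equal(locate_region(r, c(41.6501 + 1.05 * en1, -23.6840)), 1L)
  # beyond the 3-En cap
  expect_true(is.na(locate_region(r, c(41.6501 + 5 * en1, -23.6840))))

  # consistency with a brute-force membership scan
  withr::with_seed(13, pts <- cbind(rnorm(300, 41.65, 6), rnorm(300, -23.68, 5)))
  idx <- locate_region(r, pts)
  brute <- apply(pts, 1, function(p) {
    inside <- ((p[1] - r$center[1]) / (r$multipliers * r$scales[1]))^2 +
      ((p[2] - r$center[2]) / (r$multipliers * r$scales[2]))^2 <= 1
    if (any(inside)) min(which(inside)) else NA_integer_
  })
  expect_equal(idx, as.integer(brute))
  # interior points map to exactly one band: indices partition the cap
  expect_true(all(idx[!is.na(idx)] %in% seq_along(r$multipliers)))
})

test_that("region geometry ignores the input order of tied words", {
  desc <- liquor_descriptors()$nong
  wf1 <- word_frequency_table("x", paste0("w", 1:5), c(16, 10, 6, 4, 4), 40)
  wf2 <- word_frequency_table("x", paste0("w", c(1:3, 5, 4)),
                              c(16, 10, 6, 4, 4), 40)
  r1 <- build_region_set(desc, wf1)
  r2 <- build_region_set(desc, wf2)
  expect_equal(r1$multipliers, r2$multipliers)
  expect_equal(r1$center, r2$center)
})

test_that("Monte-Carlo coverage of the k-ellipse follows the 2-D law", {
  # he = 0 droplets: ((x-ex)/en1)^2 + ((y-ex)/en2)^2 ~ chi^2_2, so the mass
  # inside the k-ellipse is 1 - exp(-k^2/2) -- the true 2-D coverage, which
  # deliberately differs from the 1-D cumulative frequency used to choose k
  desc <- desc2d(ex = c(10, -5), en = c(2, 3))
  n <- 1e5
  dr <- forward_cloud2d(desc, n, seed = 14)
  rad2 <- ((dr$x1 - 10) / 2)^2 + ((dr$x2 + 5) / 3)^2
  for (k in c(qnorm(0.75), 1.5, 2.24)) {
    p <- 1 - exp(-k^2 / 2)
    frac <- mean(rad2 <= k^2)
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  }
})
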