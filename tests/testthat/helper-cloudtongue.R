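# four well-separated gaussian clusters in `p` dimensions, `m` points each;
# separation >> spread so any reasonable RBF-SVM attains 100%
make_separated_clusters <- function(m = 10, p = 4, spread = 0.05,
                                    gap = 10, seed = 7) {
  withr::with_seed(seed, {
    centers <- diag(gap, 4, p)
    x <- do.call(rbind, lapply(1:4, function(i)
      matrix(rnorm(m * p, 0, spread), m, p) +
        matrix(centers[i, ], m, p, byrow = TRUE)))
    list(x = x, y = rep(paste0("c", 1:4), each = m))
  })
}

# mild-hyper-entropy descriptor helper
desc2d <- function(ex, en, he = c(0, 0))
  cloud_descriptor2d(ex = ex, en = en, he = he)
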