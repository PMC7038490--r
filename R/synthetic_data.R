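#' Configuration of the synthetic electronic-tongue data generator
#'
#' Describes the study design the generator emulates: each flavor is a 2-D
#' normal cloud in a latent plane (the per-flavor descriptors), embedded into
#' `n_channels` sensor channels by a seeded random orthonormal loading, with
#' isotropic residual noise of standard deviation `residual_sd` (mV) in the
#' remaining non-informative channel directions and a fixed channel mean
#' offset so values resemble steady-state potentials.
#'
#' The default `residual_sd = 1.35` mV is a one-time calibration constant
#' chosen so that pooled PCA of the default 4 x 20 dataset has a first
#' contribution rate near 0.9424 and a cumulative first-two rate near 0.9825.
#'
#' @param per_flavor_descriptors named list of `cloud2d` descriptors, one per
#'   flavor (default: the packaged published values).
#' @param loading_seed integer seed for the random orthonormal 10 x 2 loading.
#' @param residual_sd non-negative noise sd (mV) in the non-informative
#'   directions.
#' @param samples_per_flavor positive integer, replicates per flavor
#'   (default 20).
#' @param n_channels positive integer, sensor channels (default 10: 5 taste +
#'   5 aftertaste).
#' @param channel_means numeric vector of length `n_channels`; fixed offsets
#'   (mV) with no effect after centering.
#' @return an object of class `synth_config`.
#' @export
synthetic_config <- function(per_flavor_descriptors = liquor_descriptors(),
                             loading_seed = 42L,
                             residual_sd = 1.35,
                             samples_per_flavor = 20L,
                             n_channels = 10L,
                             channel_means = NULL) {
  .assert(is.list(per_flavor_descriptors) &&
            length(per_flavor_descriptors) >= 1L &&
            !is.null(names(per_flavor_descriptors)) &&
            all(nzchar(names(per_flavor_descriptors))) &&
            !anyDuplicated(names(per_flavor_descriptors)),
          "invalid config: per_flavor_descriptors must be a named list")
  .assert(all(vapply(per_flavor_descriptors, inherits, TRUE, "cloud2d")),
          "invalid config: descriptors missing a flavor or not cloud2d")
  .assert(.is_count(loading_seed), "invalid config: loading_seed not integer")
  .assert(is.numeric(residual_sd) && length(residual_sd) == 1L &&
            is.finite(residual_sd) && residual_sd >= 0,
          "invalid config: residual_sd must be >= 0")
  .assert(.is_count(samples_per_flavor) && samples_per_flavor >= 1,
          "invalid config: samples_per_flavor must be a positive integer")
  .assert(.is_count(n_channels) && n_channels >= 2,
          "invalid config: n_channels must be an integer >= 2")
  if (is.null(channel_means)) {
    # fixed arbitrary potentials-in-mV offsets, recycled to n_channels
    base <- c(-5, 22, -37, 11, 63, -14, 6, 31, -26, 48)
    channel_means <- rep_len(base, n_channels)
  }
  .assert(is.numeric(channel_means) && length(channel_means) == n_channels,
          "invalid config: channel_means length must equal n_channels")
  structure(list(per_flavor_descriptors = per_flavor_descriptors,
                 loading_seed = as.integer(loading_seed),
                 residual_sd = residual_sd,
                 samples_per_flavor = as.integer(samples_per_flavor),
                 n_channels = as.integer(n_channels),
                 channel_means = channel_means),
            class = "synth_config")
}

# seeded random orthonormal basis: first 2 columns span the latent plane,
# the rest the residual (non-informative) directions
.synthetic_basis <- function(config) {
  p <- config$n_channels
  withr::with_seed(config$loading_seed, {
    Q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
    # deterministic sign convention: largest-magnitude entry positive
    for (j in seq_len(p)) if (Q[which.max(abs(Q[, j])), j] < 0) Q[, j] <- -Q[, j]
    Q
  })
}

#' Generate a synthetic labelled electronic-tongue dataset
#'
#' Draws `samples_per_flavor` latent PC-plane points per flavor with the
#' forward cloud generator of that flavor's descriptor, embeds them into the
#' sensor channels via the fixed orthonormal loading, and adds the channel
#' mean offsets plus residual noise confined to the non-informative
#' directions. Deterministic given `(config, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return data frame with columns `sample_id`, `flavor`, `ch01`...; the true
#'   loading, residual basis, channel means and latent coordinates are
#'   attached as attributes `"loading"`, `"residual_basis"`,
#'   `"channel_means"`, `"latent"`.
#' @examples
#' d <- generate_taste_dataset(synthetic_config(), seed = 1)
#' dim(d)          # 80 x 12
#' table(d$flavor) # 20 per flavor
#' @export
generate_taste_dataset <- function(config, seed) {
  .assert(inherits(config, "synth_config"),
          "invalid config: not a synth_config")
  .assert(.is_count(seed), "invalid argument: seed must be an integer")
  flavors <- names(config$per_flavor_descriptors)
  m <- config$samples_per_flavor
  p <- config$n_channels
  Q <- .synthetic_basis(config)
  L <- Q[, 1:2, drop = FALSE]
  R <- if (p > 2) Q[, 3:p, drop = FALSE] else matrix(0, p, 0)

  withr::with_seed(as.integer(seed), {
    latent <- NULL
    noise <- NULL
    for (f in flavors) {
      drops <- .forward_cloud2d_impl(config$per_flavor_descriptors[[f]], m)
      latent <- rbind(latent, cbind(drops$x1, drops$x2))
      noise <- rbind(noise,
                     matrix(rnorm(m * ncol(R), 0, config$residual_sd),
                            m, ncol(R)))
    }
  })
  X <- latent %*% t(L)
  if (ncol(R) > 0) X <- X + noise %*% t(R)
  X <- sweep(X, 2, config$channel_means, "+")
  colnames(X) <- sprintf("ch%02d", seq_len(p))

  out <- data.frame(
    sample_id = sprintf("%s_%02d", rep(flavors, each = m),
                        rep(seq_len(m), length(flavors))),
    flavor = rep(flavors, each = m),
    X,
    stringsAsFactors = FALSE)
  attr(out, "loading") <- L
  attr(out, "residual_basis") <- R
  attr(out, "channel_means") <- config$channel_means
  attr(out, "latent") <- latent
  out
}

#' Extract the numeric feature matrix from a taste dataset
#'
#' @param data a data frame from [generate_taste_dataset()] or a CSV read
#'   with the same `sample_id, flavor, ch..` layout.
#' @return numeric matrix of the channel columns, rownames = sample ids.
#' @export
taste_features <- function(data) {
  ch <- grep("^ch[0-9]+$", names(data), value = TRUE)
  .assert(length(ch) >= 2L, "invalid data: no channel columns found")
  x <- as.matrix(data[, ch])
  rownames(x) <- data$sample_id
  x
}

#' Sensory-panel configuration for one flavor
#'
#' @param flavor flavor identifier.
#' @param words the flavor's 5 lexicon words, ordered by expected frequency.
#' @param probabilities 5 non-negative selection probabilities summing to 1.
#' @param panel_size positive integer, number of assessors (default 40).
#' @return an object of class `panel_cfg`.
#' @export
panel_config <- function(flavor, words, probabilities, panel_size = 40L) {
  .assert(is.character(words) && length(words) == 5L,
          "invalid config: exactly 5 lexicon words required")
  .assert(is.numeric(probabilities) && length(probabilities) == 5L &&
            all(probabilities >= 0),
          "invalid config: 5 non-negative probabilities required")
  .assert(abs(sum(probabilities) - 1) <= 1e-12,
          "invalid config: probabilities must sum to 1")
  .assert(.is_count(panel_size) && panel_size >= 1,
          "invalid config: panel_size must be >= 1")
  structure(list(flavor = flavor, words = words,
                 probabilities = probabilities,
                 panel_size = as.integer(panel_size)),
            class = "panel_cfg")
}

#' Simulate panel vote counts for a flavor
#'
#' Draws a multinomial sample of `panel_size` single-word votes over the
#' configured selection probabilities (each assessor picks exactly one
#' description word).
#'
#' @param config a [panel_config()].
#' @param seed integer seed.
#' @return a [word_frequency_table()] whose counts sum to the panel size.
#' @export
generate_panel_votes <- function(config, seed) {
  .assert(inherits(config, "panel_cfg"), "invalid config: not a panel_cfg")
  counts <- withr::with_seed(as.integer(seed),
    as.integer(rmultinom(1, config$panel_size, config$probabilities)))
  word_frequency_table(config$flavor, config$words, counts, config$panel_size)
}
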