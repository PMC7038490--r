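#' One-dimensional cloud descriptor
#'
#' The digital characteristics of a normal cloud concept along one axis:
#' expected value `ex` (the concept's centre), entropy `en` (its fuzziness
#' scale, the mean droplet-generating standard deviation) and hyper-entropy
#' `he` (the uncertainty of `en` itself, responsible for the cloud's fat
#' tail). Units are those of the underlying axis (here, principal-component
#' scores of steady-state potentials in mV).
#'
#' @param ex numeric scalar, expected value.
#' @param en non-negative numeric scalar, entropy.
#' @param he non-negative numeric scalar, hyper-entropy.
#' @return an object of class `cloud1d`.
#' @examples
#' cloud_descriptor(41.6501, 2.7506, 1.2743)
#' @export
cloud_descriptor <- function(ex, en, he = 0) {
  .assert(is.numeric(ex) && length(ex) == 1L && is.finite(ex),
          "invalid value: 'ex' must be a finite numeric scalar")
  .assert(is.numeric(en) && length(en) == 1L && is.finite(en) && en >= 0,
          "invalid value: 'en' must be a finite non-negative scalar")
  .assert(is.numeric(he) && length(he) == 1L && is.finite(he) && he >= 0,
          "invalid value: 'he' must be a finite non-negative scalar")
  structure(list(ex = ex, en = en, he = he), class = "cloud1d")
}

#' Two-dimensional cloud descriptor
#'
#' A per-dimension pair of [cloud_descriptor()]s describing a flavor's taste
#' information in the PC1/PC2 plane.
#'
#' @param dim1,dim2 `cloud1d` descriptors for PC1 and PC2; alternatively pass
#'   length-2 numeric vectors via `ex`, `en`, `he`.
#' @param ex,en,he optional length-2 numeric vectors used when `dim1`/`dim2`
#'   are missing.
#' @return an object of class `cloud2d`.
#' @examples
#' cloud_descriptor2d(ex = c(41.6501, -23.6840),
#'                    en = c(2.7506, 2.3288),
#'                    he = c(1.2743, 1.1007))
#' @export
cloud_descriptor2d <- function(dim1, dim2, ex = NULL, en = NULL, he = NULL) {
  if (missing(dim1) || missing(dim2)) {
    .assert(length(ex) == 2L && length(en) == 2L,
            "invalid value: supply dim1/dim2 or length-2 ex/en (+ optional he)")
    if (is.null(he)) he <- c(0, 0)
    dim1 <- cloud_descriptor(ex[1], en[1], he[1])
    dim2 <- cloud_descriptor(ex[2], en[2], he[2])
  }
  .assert(inherits(dim1, "cloud1d") && inherits(dim2, "cloud1d"),
          "invalid value: dim1 and dim2 must be cloud1d descriptors")
  structure(list(dim1 = dim1, dim2 = dim2), class = "cloud2d")
}

#' @export
print.cloud1d <- function(x, ...) {
  cat(sprintf("cloud1d: Ex = %.4f, En = %.4f, He = %.4f\n", x$ex, x$en, x$he))
  invisible(x)
}

#' @export
print.cloud2d <- function(x, ...) {
  cat(sprintf("cloud2d:\n  PC1: Ex = %.4f, En = %.4f, He = %.4f\n  PC2: Ex = %.4f, En = %.4f, He = %.4f\n",
              x$dim1$ex, x$dim1$en, x$dim1$he,
              x$dim2$ex, x$dim2$en, x$dim2$he))
  invisible(x)
}

#' Backward cloud generator (one dimension)
#'
#' Estimates the digital characteristics of a cloud concept from observed
#' quantitative values: `Ex` is the sample mean, `En = sqrt(pi/2) * D` where
#' `D` is the first-order absolute central moment (mean absolute deviation
#' from the mean), and `He = sqrt(S2 - En^2)` where `S2` is the `n - 1`
#' sample variance. When `S2 < En^2` (possible on small real samples) `He`
#' is clamped to 0 with a warning, the standard fallback that keeps the
#' pipeline total.
#'
#' @param values numeric vector of at least 2 finite observations.
#' @return a `cloud1d` descriptor.
#' @examples
#' backward_cloud(c(1, 2, 3))
#' @export
backward_cloud <- function(values) {
  .assert(is.numeric(values), "invalid value: 'values' must be numeric")
  .assert(length(values) >= 2L,
          "insufficient data: backward cloud needs at least 2 values")
  .assert(all(is.finite(values)),
          "invalid value: 'values' contains non-finite entries")
  ex <- mean(values)
  d  <- mean(abs(values - ex))
  en <- sqrt(pi / 2) * d
  s2 <- var(values)
  if (s2 < en^2) {
    if (s2 < en^2 - 1e-12)   # silent for pure round-off
      warning("sample variance below En^2; clamping He to 0", call. = FALSE)
    he <- 0
  } else {
    he <- sqrt(s2 - en^2)
  }
  cloud_descriptor(ex, en, he)
}

#' Backward cloud generator (two dimensions)
#'
#' Applies [backward_cloud()] independently to each column of a set of
#' 2-D points (e.g. PC1/PC2 projections of electronic-tongue samples).
#'
#' @param points a 2-column matrix or data frame of coordinates.
#' @return a `cloud2d` descriptor.
#' @export
backward_cloud2d <- function(points) {
  points <- as.matrix(points)
  .assert(ncol(points) == 2L,
          "invalid value: 'points' must have exactly 2 columns")
  cloud_descriptor2d(backward_cloud(points[, 1]), backward_cloud(points[, 2]))
}

# forward generator core, consuming the current RNG stream.
# Per droplet and dimension: En' ~ Normal(en, he^2) used through its
# magnitude (only En'^2 enters the droplet law), x ~ Normal(ex, En'^2),
# mu = exp(-sum((x - ex)^2 / (2 En'^2))). Degenerate en = he = 0 pins the
# coordinate at ex with zero contribution to the exponent.
.forward_cloud2d_impl <- function(desc, n) {
  dims <- list(desc$dim1, desc$dim2)
  x <- matrix(NA_real_, n, 2)
  enp <- matrix(NA_real_, n, 2)
  expo <- numeric(n)
  for (i in 1:2) {
    d <- dims[[i]]
    if (d$en == 0 && d$he == 0) {
      x[, i] <- d$ex
      enp[, i] <- 0
      next                              # contributes 0 to the exponent
    }
    e <- if (d$he > 0) abs(rnorm(n, d$en, d$he)) else rep(d$en, n)
    e[e == 0] <- .Machine$double.eps    # measure-zero guard
    xi <- rnorm(n, d$ex, e)
    x[, i] <- xi
    enp[, i] <- e
    expo <- expo + (xi - d$ex)^2 / (2 * e^2)
  }
  out <- data.frame(x1 = x[, 1], x2 = x[, 2], mu = exp(-expo))
  attr(out, "en_prime") <- enp
  out
}

#' Forward cloud generator (two dimensions)
#'
#' Samples `n` cloud droplets from a 2-D descriptor. For each droplet and
#' each dimension a per-droplet entropy `En'` is drawn from
#' `Normal(en, he^2)` (its magnitude is used; only `En'^2` enters the law),
#' then the coordinate is drawn from `Normal(ex, En'^2)`. The certainty
#' degree is `mu = exp(-sum_i (x_i - ex_i)^2 / (2 En'_i^2))`, the droplet's
#' membership in the taste concept. A dimension with `en = he = 0` collapses
#' to `ex` and contributes nothing to the exponent.
#'
#' @param desc a `cloud2d` descriptor.
#' @param n number of droplets (>= 1).
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return a data frame with columns `x1`, `x2`, `mu` (one row per droplet)
#'   and an `"en_prime"` attribute holding the sampled per-droplet entropies.
#' @examples
#' d <- cloud_descriptor2d(ex = c(0, 0), en = c(1, 1), he = c(0.1, 0.1))
#' forward_cloud2d(d, 5, seed = 1)
#' @export
forward_cloud2d <- function(desc, n, seed = NULL) {
  .assert(inherits(desc, "cloud2d"), "invalid argument: 'desc' must be cloud2d")
  .assert(.is_count(n) && n >= 1, "invalid argument: 'n' must be >= 1")
  if (is.null(seed)) return(.forward_cloud2d_impl(desc, n))
  withr::with_seed(as.integer(seed), .forward_cloud2d_impl(desc, n))
}

#' Contribution rate of an interval to a 1-D cloud concept
#'
#' Numerically integrates the cloud contribution density
#' `exp(-(x - Ex)^2 / (2 En^2)) / (sqrt(2 pi) En)` over `[a, b]`: the
#' probability mass the interval contributes to the qualitative concept.
#' Hyper-entropy does not enter the contribution density; it acts only
#' through droplet sampling.
#'
#' @param desc a `cloud1d` descriptor with `en > 0`.
#' @param a,b interval bounds, `a <= b`; infinite bounds allowed.
#' @return the contribution fraction in `[0, 1]`.
#' @examples
#' d <- cloud_descriptor(0, 1)
#' contribution_interval(d, -1, 1)  # ~0.6827
#' @export
contribution_interval <- function(desc, a, b) {
  .assert(inherits(desc, "cloud1d"), "invalid argument: 'desc' must be cloud1d")
  .assert(desc$en > 0, "degenerate descriptor: en = 0 is a point mass")
  .assert(a <= b, "invalid argument: requires a <= b")
  if (a == b) return(0)
  dens <- function(x) exp(-(x - desc$ex)^2 / (2 * desc$en^2)) /
    (sqrt(2 * pi) * desc$en)
  integrate(dens, a, b, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Total contribution rate of a 2-D cloud concept
#'
#' Numeric double integral of the 2-D cloud contribution density
#' `exp(-((x - Ex1)^2/En1^2 + (y - Ex2)^2/En2^2) / 2) / (2 pi En1 En2)`
#' over a box extending `box_k * En` beyond the centre in each dimension,
#' with a 64-node Gauss-Legendre product rule. For any valid descriptor the
#' result is 1 (the cloud droplet group carries the whole qualitative
#' concept).
#'
#' @param desc a `cloud2d` descriptor with strictly positive entropies.
#' @param box_k half-width of the integration box in units of `En`
#'   (default 8, where the omitted tail mass is ~1e-15).
#' @return the integral, ~1 within 1e-6.
#' @export
total_contribution <- function(desc, box_k = 8) {
  .assert(inherits(desc, "cloud2d"), "invalid argument: 'desc' must be cloud2d")
  ex1 <- desc$dim1$ex; en1 <- desc$dim1$en
  ex2 <- desc$dim2$ex; en2 <- desc$dim2$en
  .assert(en1 > 0 && en2 > 0, "degenerate descriptor: entropies must be > 0")
  f <- function(x, y)
    exp(-0.5 * ((x - ex1)^2 / en1^2 + (y - ex2)^2 / en2^2)) /
      (2 * pi * en1 * en2)
  pracma::quad2d(f,
                 ex1 - box_k * en1, ex1 + box_k * en1,
                 ex2 - box_k * en2, ex2 + box_k * en2,
                 n = 64)
}
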