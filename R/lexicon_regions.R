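#' Word-frequency table of a sensory panel
#'
#' A flavor's five description words with their single-vote counts from a
#' panel of `panel_size` assessors.
#'
#' @param flavor flavor identifier.
#' @param words character(5) lexicon words.
#' @param counts integer(5) non-negative vote counts summing to `panel_size`.
#' @param panel_size positive integer.
#' @return an object of class `word_freq`.
#' @examples
#' word_frequency_table("jiang",
#'   c("Fully mellow", "Elegant and delicate", "Full bodied",
#'     "Long aftertaste", "Coordination"),
#'   c(20, 10, 4, 4, 2), 40)
#' @export
word_frequency_table <- function(flavor, words, counts, panel_size) {
  .assert(is.character(words) && length(words) == 5L,
          "invalid table: exactly 5 words required")
  .assert(is.numeric(counts) && length(counts) == 5L &&
            all(counts >= 0) && all(counts == floor(counts)),
          "invalid table: counts must be 5 non-negative integers")
  .assert(.is_count(panel_size) && panel_size >= 1,
          "invalid table: panel_size must be >= 1")
  .assert(sum(counts) == panel_size,
          "inconsistency error: counts do not sum to panel_size")
  structure(list(flavor = flavor, words = words,
                 counts = as.integer(counts),
                 panel_size = as.integer(panel_size)),
            class = "word_freq")
}

#' @export
print.word_freq <- function(x, ...) {
  sf <- sort_frequencies(x)
  cat(sprintf("word_freq (%s, panel of %d):\n", x$flavor, x$panel_size))
  for (i in seq_len(nrow(sf)))
    cat(sprintf("  %-22s %5.1f%%\n", sf$word[i], sf$frequency[i]))
  invisible(x)
}

#' Sort panel word frequencies in descending order
#'
#' Converts counts to percentages of the panel size and orders them
#' descending (n1 >= n2 >= ... >= n5); ties keep the original lexicon order.
#'
#' @param table a [word_frequency_table()].
#' @return data frame with columns `word` and `frequency` (percent).
#' @export
sort_frequencies <- function(table) {
  .assert(inherits(table, "word_freq"), "invalid table: not a word_freq")
  freq <- 100 * table$counts / table$panel_size
  ord <- order(-freq)                   # stable: ties keep input order
  data.frame(word = table$words[ord], frequency = freq[ord],
             stringsAsFactors = FALSE)
}

#' Central-region multiplier from the top word frequency
#'
#' Maps the most frequent word's percentage `n1` to the multiplier `k1` of
#' the central ellipse: the word occupies the symmetric central mass `n1`%
#' of a standard normal, so `k1 = qnorm(1/2 + n1/200)`. A frequency of 100%
#' returns the outer cap.
#'
#' @param n1 frequency in percent, `0 < n1 <= 100`.
#' @param cap outer cap multiplier (default 3, the 3-En convention).
#' @return the multiplier `k1 > 0`.
#' @examples
#' central_multiplier(50)     # qnorm(0.75) ~ 0.6745
#' central_multiplier(68.27)  # ~ 1
#' @export
central_multiplier <- function(n1, cap = 3) {
  ring_multiplier(n1, cap = cap)
}

#' Ring multiplier from a cumulative word frequency
#'
#' Maps the cumulative percentage of the first `i` sorted words to the outer
#' multiplier of word `i`'s annulus: `k_i = qnorm(1/2 + cumulative/200)`.
#' A cumulative of 100% maps to the outer cap.
#'
#' @param cumulative cumulative frequency in percent, `0 < cumulative <= 100`.
#' @param cap outer cap multiplier (default 3).
#' @return the multiplier `k_i > 0`.
#' @export
ring_multiplier <- function(cumulative, cap = 3) {
  .assert(is.numeric(cumulative) && length(cumulative) == 1L &&
            is.finite(cumulative) && cumulative > 0,
          "invalid frequency: must be a positive percentage")
  .assert(cumulative <= 100, "invalid frequency: exceeds 100%")
  if (cumulative >= 100) return(cap)
  qnorm(0.5 + cumulative / 200)
}

# shared constructor/validator for region sets
.region_set <- function(center, scales, multipliers, words, strict) {
  .assert(length(center) == 2L && all(is.finite(center)),
          "invalid region set: center must be 2 finite values")
  .assert(length(scales) == 2L && all(scales > 0),
          "degenerate error: entropies (scales) must be > 0")
  .assert(length(multipliers) >= 1L && all(multipliers > 0),
          "invalid region set: multipliers must be positive")
  .assert(length(words) == length(multipliers),
          "invalid region set: one word per multiplier required")
  dk <- diff(multipliers)
  if (strict)
    .assert(all(dk > 0), "invalid region set: multipliers must be strictly increasing")
  else
    .assert(all(dk >= 0), "construction error: multipliers must be non-decreasing")
  structure(list(center = unname(center), scales = unname(scales),
                 multipliers = unname(multipliers), words = words),
            class = "region_set")
}

#' Build nested word regions from panel frequencies
#'
#' Converts a flavor's sorted word frequencies into a nested
#' ellipse/annulus partition of the PC plane centred at the cloud's
#' `(Ex1, Ex2)` and scaled by `(En1, En2)`: the i-th multiplier is
#' [ring_multiplier()] at the i-th cumulative frequency, and the last is
#' forced to the outer cap. Region 1 is the full central ellipse; region i
#' (i > 1) is the annulus between multipliers i-1 and i. A zero-frequency
#' word yields a zero-width annulus that can never be selected (the word is
#' retained in the word list).
#'
#' @param desc a `cloud2d` descriptor with positive entropies.
#' @param table a [word_frequency_table()].
#' @param cap outer cap multiplier (default 3).
#' @return an object of class `region_set`.
#' @export
build_region_set <- function(desc, table, cap = 3) {
  .assert(inherits(desc, "cloud2d"), "invalid argument: 'desc' must be cloud2d")
  sf <- sort_frequencies(table)
  .assert(sf$frequency[1] > 0, "invalid table: top frequency is zero")
  cum <- cumsum(sf$frequency)
  k <- vapply(pmin(cum, 100), ring_multiplier, numeric(1), cap = cap)
  k[length(k)] <- cap
  k <- cummax(k)                        # zero-width annuli collapse onto the
                                        # previous boundary
  .region_set(center = c(desc$dim1$ex, desc$dim2$ex),
              scales = c(desc$dim1$en, desc$dim2$en),
              multipliers = k, words = sf$word, strict = FALSE)
}

#' Build word regions from explicit multipliers
#'
#' Constructs a region set directly from a published multiplier sequence
#' (strictly increasing) and its centre-to-periphery word order; used to
#' reproduce the published region geometry exactly.
#'
#' @param desc a `cloud2d` descriptor with positive entropies.
#' @param multipliers strictly increasing positive multipliers.
#' @param words words ordered centre to periphery, one per multiplier.
#' @return an object of class `region_set`.
#' @examples
#' d <- liquor_descriptors()$jiang
#' m <- liquor_region_multipliers()$jiang
#' r <- build_region_set_explicit(d, m$multipliers, m$words)
#' semi_axes(r)[5, ]  # c(8.2518, 6.9864)
#' @export
build_region_set_explicit <- function(desc, multipliers, words) {
  .assert(inherits(desc, "cloud2d"), "invalid argument: 'desc' must be cloud2d")
  .region_set(center = c(desc$dim1$ex, desc$dim2$ex),
              scales = c(desc$dim1$en, desc$dim2$en),
              multipliers = multipliers, words = words, strict = TRUE)
}

#' Ellipse semi-axes of a region set
#'
#' @param regions a `region_set`.
#' @return matrix (regions x 2) of semi-axes `k_i * En` per dimension.
#' @export
semi_axes <- function(regions) {
  .assert(inherits(regions, "region_set"), "invalid argument: not a region_set")
  out <- outer(regions$multipliers, regions$scales)
  colnames(out) <- c("pc1", "pc2")
  out
}

#' Locate points in a region set
#'
#' Returns, for each point, the smallest region index i whose ellipse
#' `((x - Ex1)/(k_i En1))^2 + ((y - Ex2)/(k_i En2))^2 <= 1` contains it
#' (boundary points belong to the inner region), or `NA` when the point
#' falls outside the outer cap.
#'
#' @param regions a `region_set`.
#' @param points 2-column matrix/data frame of coordinates, or a length-2
#'   vector for a single point.
#' @return integer vector of region indices, `NA` = outside the cap.
#' @export
locate_region <- function(regions, points) {
  .assert(inherits(regions, "region_set"), "invalid argument: not a region_set")
  p <- if (is.null(dim(points))) matrix(points, ncol = 2)
       else as.matrix(points[, 1:2, drop = FALSE])
  # shared-multiplier ellipses reduce to an elliptical radius test
  r <- sqrt(((p[, 1] - regions$center[1]) / regions$scales[1])^2 +
            ((p[, 2] - regions$center[2]) / regions$scales[2])^2)
  idx <- vapply(r, function(ri) {
    i <- which(ri <= regions$multipliers)
    if (length(i)) min(i) else NA_integer_
  }, integer(1))
  idx
}

#' @export
print.region_set <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Format a region set as inequality strings
#'
#' Produces one inequality description per region in the published style:
#' the central ellipse as `(x-Ex1)^2/a1^2 + (y-Ex2)^2/a2^2 <= 1`, each
#' annulus as the conjunction of an outer `<=` and an inner `>` clause.
#'
#' @param x a `region_set`.
#' @param digits rounding for the printed coefficients.
#' @param ... unused.
#' @return character vector, one element per region.
#' @export
format.region_set <- function(x, digits = 4, ...) {
  ax <- semi_axes(x)
  cterm <- function(c0) {
    if (c0 >= 0) sprintf("x-%.*f", digits, c0) else sprintf("x+%.*f", digits, -c0)
  }
  yterm <- function(c0) {
    if (c0 >= 0) sprintf("y-%.*f", digits, c0) else sprintf("y+%.*f", digits, -c0)
  }
  ell <- function(i, op)
    sprintf("(%s)^2/%.*f^2 + (%s)^2/%.*f^2 %s 1",
            cterm(x$center[1]), digits, ax[i, 1],
            yterm(x$center[2]), digits, ax[i, 2], op)
  vapply(seq_along(x$multipliers), function(i) {
    s <- ell(i, "<=")
    if (i > 1) s <- paste(s, "&", ell(i - 1, ">"))
    sprintf("[%s] %s", x$words[i], s)
  }, character(1))
}
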