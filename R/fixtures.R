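#' Packaged characteristic values of the four liquor flavors
#'
#' Loads the published per-flavor 2-D cloud descriptors (Ex, En, He for PC1
#' and PC2, in PC-score units of mV) estimated from electronic-tongue data
#' of jiang-, feng-, nong- and mild-flavor Chinese liquor.
#'
#' @return named list of `cloud2d` descriptors (`jiang`, `feng`, `nong`,
#'   `mild`).
#' @examples
#' liquor_descriptors()$jiang
#' @export
liquor_descriptors <- function() {
  raw <- jsonlite::fromJSON(.extdata("liquor_descriptors.json"),
                            simplifyVector = FALSE)
  lapply(raw, function(d)
    cloud_descriptor2d(
      cloud_descriptor(d$pc1$ex, d$pc1$en, d$pc1$he),
      cloud_descriptor(d$pc2$ex, d$pc2$en, d$pc2$he)))
}

#' Standardized liquor taste description lexicons
#'
#' The five GB/T 33405-2016 sensory description words per flavor, in the
#' standard's listing order (not frequency order).
#'
#' @return named list of character(5) vectors.
#' @export
liquor_lexicons <- function() {
  jsonlite::fromJSON(.extdata("liquor_lexicons.json"))
}

#' Default sensory-panel configurations
#'
#' Per-flavor word lists ordered by panel vote frequency, the selection
#' probabilities, and the panel size (40 assessors). The jiang probabilities
#' (50/25/10/10/5 %) come with the observed vote counts (20, 10, 4, 4, 2);
#' the other flavors are anchored at their published top frequencies (feng
#' 35%, nong 40%, mild 30/30%) with documented assumptions for the
#' remaining splits.
#'
#' @return named list of [panel_config()] objects, with observed counts (when
#'   available) attached as attribute `"counts"`.
#' @export
liquor_panels <- function() {
  raw <- jsonlite::fromJSON(.extdata("liquor_panel.json"),
                            simplifyVector = FALSE)
  n <- raw$panel_size
  raw$panel_size <- NULL
  out <- lapply(names(raw), function(f) {
    p <- raw[[f]]
    cfg <- panel_config(f, unlist(p$words), unlist(p$probabilities), n)
    if (!is.null(p$counts)) attr(cfg, "counts") <- as.integer(unlist(p$counts))
    cfg
  })
  names(out) <- names(raw)
  out
}

#' Published region multipliers per flavor
#'
#' The multipliers k1 < ... < k5 of the published nested-ellipse word
#' regions (semi-axes are `k * En` per dimension), together with the words
#' ordered centre-to-periphery. The outermost multiplier is the 3-En cap.
#'
#' @return named list with elements `multipliers` (numeric(5)) and `words`
#'   (character(5)) per flavor.
#' @export
liquor_region_multipliers <- function() {
  jsonlite::fromJSON(.extdata("liquor_region_multipliers.json"),
                     simplifyVector = TRUE)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cloudtongue")
  .assert(nzchar(path), paste("packaged fixture not found:", file))
  path
}
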