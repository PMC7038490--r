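#' Fit a 2-component PCA model of electronic-tongue features
#'
#' Centers the channel table and eigen-decomposes its `n - 1` sample
#' covariance. The first two eigenvectors (sign-fixed so each column's
#' largest-magnitude entry is positive) form the loadings; variance
#' contribution rates are the eigenvalues divided by the trace. Channels are
#' centered only, not standardized: the inputs are commensurate steady-state
#' potentials in mV.
#'
#' @param data numeric matrix/data frame of features (rows = samples), or a
#'   labelled taste dataset (channel columns are extracted).
#' @return object of class `pc_model` with fields `mean`, `loadings`
#'   (p x 2, column-orthonormal), `contribution_rates` (length p,
#'   descending).
#' @examples
#' d <- generate_taste_dataset(synthetic_config(), seed = 1)
#' m <- fit_pca(d)
#' m$contribution_rates[1:2]
#' @export
fit_pca <- function(data) {
  if (is.data.frame(data) && "flavor" %in% names(data))
    data <- taste_features(data)
  x <- as.matrix(data)
  .assert(is.numeric(x), "invalid data: features must be numeric")
  .assert(nrow(x) >= 3L, "insufficient data: PCA needs at least 3 rows")
  .assert(ncol(x) >= 2L, "insufficient data: PCA needs at least 2 columns")
  .assert(!anyNA(x) && all(is.finite(x)),
          "invalid data: missing or non-finite values")
  mu <- colMeans(x)
  S <- cov(x)
  tr <- sum(diag(S))
  .assert(tr > 0, "degenerate data: zero covariance (constant columns)")
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)            # clamp numeric negatives
  load <- e$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) if (load[which.max(abs(load[, j])), j] < 0)
    load[, j] <- -load[, j]
  rownames(load) <- colnames(x)
  colnames(load) <- c("PC1", "PC2")
  structure(list(mean = mu, loadings = load,
                 contribution_rates = vals / sum(vals)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cr <- x$contribution_rates
  cat(sprintf("pc_model: %d channels; PC1 %.4f, PC2 %.4f (cumulative %.4f)\n",
              length(x$mean), cr[1], cr[2], cr[1] + cr[2]))
  invisible(x)
}

#' Project samples onto the first two principal components
#'
#' Computes `(x - mean) %*% loadings` for each sample; linear and
#' deterministic.
#'
#' @param model a `pc_model`.
#' @param samples numeric vector (one sample), matrix/data frame of samples,
#'   or a labelled taste dataset.
#' @return matrix with columns `pc1`, `pc2`, one row per sample.
#' @export
project <- function(model, samples) {
  .assert(inherits(model, "pc_model"), "invalid argument: not a pc_model")
  if (is.data.frame(samples) && "flavor" %in% names(samples))
    samples <- taste_features(samples)
  x <- if (is.null(dim(samples))) matrix(samples, nrow = 1)
       else as.matrix(samples)
  .assert(ncol(x) == length(model$mean),
          "shape error: sample dimension does not match model")
  scores <- sweep(x, 2, model$mean) %*% model$loadings
  colnames(scores) <- c("pc1", "pc2")
  scores
}

#' @rdname project
#' @param object,newdata,... standard `predict` arguments (`newdata` as in
#'   `samples`).
#' @export
predict.pc_model <- function(object, newdata, ...) project(object, newdata)

#' Serialize / deserialize a PCA model as JSON
#'
#' @param model a `pc_model`.
#' @param path file path.
#' @return `read_pc_model` returns the restored `pc_model`.
#' @export
write_pc_model <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean,
                            loadings = model$loadings,
                            contribution_rates = model$contribution_rates),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_pc_model
#' @export
read_pc_model <- function(path) {
  raw <- jsonlite::fromJSON(path)
  load <- as.matrix(raw$loadings)
  colnames(load) <- c("PC1", "PC2")
  structure(list(mean = as.numeric(raw$mean), loadings = load,
                 contribution_rates = as.numeric(raw$contribution_rates)),
            class = "pc_model")
}
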