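#' Stratified cross-validation fold assignment
#'
#' @param y class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the within-class shuffle.
#' @return integer vector of fold ids in `1..k`, one per sample, with every
#'   class spread as evenly as possible across folds.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  .assert(.is_count(k) && k >= 2, "invalid argument: k must be >= 2")
  .assert(min(table(y)) >= k,
          "stratification error: a class has fewer members than folds")
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified train/test split
#'
#' Reproduces the study's per-class "14 train / 6 test" design with a seeded
#' random draw within each class.
#'
#' @param y class labels.
#' @param train_per_class training samples per class.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_per_class = 14L, seed = 1L) {
  y <- as.factor(y)
  .assert(.is_count(train_per_class) && train_per_class >= 1,
          "invalid argument: train_per_class must be >= 1")
  .assert(min(table(y)) > train_per_class,
          "invalid argument: a class has no samples left for testing")
  train <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cl in levels(y))
      train <- c(train, sample(which(y == cl), train_per_class))
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# single RBF-SVM fit; libsvm soft-margin dual, one-vs-one multiclass.
# Features are used raw (no internal rescaling): channels are commensurate mV.
.svm_fit <- function(x, y, cost, gamma) {
  e1071::svm(x = as.matrix(x), y = as.factor(y), type = "C-classification",
             kernel = "radial", cost = cost, gamma = gamma, scale = FALSE)
}

#' Cross-validation fitness of an RBF-SVM parameter pair
#'
#' Stratified k-fold cross-validation accuracy (in percent) of a
#' C-classification SVM with radial kernel `K(x, y) = exp(-g ||x - y||^2)`,
#' penalty `cost` and width `gamma`. This is the fitness function the
#' genetic search maximizes.
#'
#' @param x feature matrix, `y` labels.
#' @param y class labels (one per row of `x`).
#' @param cost,gamma positive SVM parameters.
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @param fold_ids optional precomputed fold assignment (overrides
#'   `folds`/`seed`).
#' @return CV accuracy as a percentage in `[0, 100]`.
#' @export
cv_fitness <- function(x, y, cost, gamma, folds = 5L, seed = 1L,
                       fold_ids = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (is.null(fold_ids)) fold_ids <- stratified_folds(y, folds, seed)
  correct <- 0L
  for (k in sort(unique(fold_ids))) {
    te <- fold_ids == k
    fit <- .svm_fit(x[!te, , drop = FALSE], y[!te], cost, gamma)
    pred <- predict(fit, x[te, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  100 * correct / length(y)
}

#' Genetic-algorithm search configuration
#'
#' Defaults follow the study protocol: population 20, up to 200 generations,
#' both `c` (penalty) and `g` (kernel width) searched in `[2^-10, 2^10]`,
#' 5-fold cross-validation fitness. Genes are real-valued on the log2 scale;
#' operators are tournament selection (size 2), uniform crossover, Gaussian
#' mutation in log2 space, and 1-elitism. The search may stop early once the
#' fitness ceiling (100%) is reached.
#'
#' @param pop_size population size (>= 2).
#' @param max_generations generation cap (>= 1).
#' @param c_range,g_range positive 2-vectors, parameter search intervals.
#' @param cv_folds cross-validation folds for the fitness.
#' @param seed integer seed driving the whole search.
#' @param crossover_rate,mutation_rate,mutation_sd,elitism GA operator
#'   settings.
#' @param early_stop stop when best fitness reaches 100%.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 20L, max_generations = 200L,
                      c_range = c(2^-10, 2^10), g_range = c(2^-10, 2^10),
                      cv_folds = 5L, seed = 1L,
                      crossover_rate = 0.7, mutation_rate = 0.1,
                      mutation_sd = 0.5, elitism = 1L, early_stop = TRUE) {
  .assert(.is_count(pop_size) && pop_size >= 2,
          "invalid config: pop_size must be >= 2")
  .assert(.is_count(max_generations) && max_generations >= 1,
          "invalid config: max_generations must be >= 1")
  .assert(length(c_range) == 2L && all(c_range > 0) && c_range[1] < c_range[2],
          "invalid config: c_range must be a positive increasing interval")
  .assert(length(g_range) == 2L && all(g_range > 0) && g_range[1] < g_range[2],
          "invalid config: g_range must be a positive increasing interval")
  .assert(.is_count(cv_folds) && cv_folds >= 2,
          "invalid config: cv_folds must be >= 2")
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 c_range = c_range, g_range = g_range,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 elitism = as.integer(elitism), early_stop = early_stop),
            class = "ga_config")
}

#' Genetic-algorithm search for RBF-SVM parameters
#'
#' Evolves a population of `(c, g)` pairs under cross-validation fitness
#' (see [cv_fitness()]); the fold assignment is fixed once per search so all
#' individuals are compared on identical folds. Deterministic given the
#' config seed.
#'
#' @param x feature matrix, `y` labels.
#' @param y class labels.
#' @param config a [ga_config()].
#' @return object of class `ga_result`: `best_params` (list with `cost`,
#'   `gamma`), `best_fitness` (%), and `history` (data frame with
#'   `generation`, `mean_fitness`, `best_fitness`; best is cumulative, hence
#'   non-decreasing).
#' @export
ga_search <- function(x, y, config = ga_config()) {
  .assert(inherits(config, "ga_config"), "invalid config: not a ga_config")
  x <- as.matrix(x)
  .assert(nrow(x) >= 1L && length(y) == nrow(x),
          "invalid input: empty training table or label length mismatch")
  lo <- log2(c(config$c_range[1], config$g_range[1]))
  hi <- log2(c(config$c_range[2], config$g_range[2]))
  fold_ids <- stratified_folds(y, config$cv_folds,
                               .child_seed(config$seed, 101))
  fit_of <- function(genes)
    cv_fitness(x, y, cost = 2^genes[1], gamma = 2^genes[2],
               fold_ids = fold_ids)

  withr::with_seed(config$seed, {
    np <- config$pop_size
    pop <- cbind(runif(np, lo[1], hi[1]), runif(np, lo[2], hi[2]))
    fitness <- apply(pop, 1, fit_of)
    best_i <- which.max(fitness)
    best_genes <- pop[best_i, ]
    best_fit <- fitness[best_i]
    hist_mean <- mean(fitness)
    hist_best <- best_fit
    gen <- 1L
    while (gen < config$max_generations &&
           !(config$early_stop && best_fit >= 100)) {
      newpop <- matrix(NA_real_, np, 2)
      n_elite <- min(config$elitism, np)
      if (n_elite > 0) {
        keep <- order(fitness, decreasing = TRUE)[seq_len(n_elite)]
        newpop[seq_len(n_elite), ] <- pop[keep, , drop = FALSE]
      }
      for (i in seq_len(np - n_elite) + n_elite) {
        # tournament selection, size 2
        pick <- function() {
          cand <- sample.int(np, 2)
          cand[which.max(fitness[cand])]
        }
        child <- pop[pick(), ]
        if (runif(1) < config$crossover_rate) {
          mate <- pop[pick(), ]
          swap <- runif(2) < 0.5        # uniform crossover per gene
          child[swap] <- mate[swap]
        }
        mut <- runif(2) < config$mutation_rate
        child[mut] <- child[mut] + rnorm(sum(mut), 0, config$mutation_sd)
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- newpop
      fitness <- apply(pop, 1, fit_of)
      gen <- gen + 1L
      if (max(fitness) > best_fit) {
        best_fit <- max(fitness)
        best_genes <- pop[which.max(fitness), ]
      }
      hist_mean <- c(hist_mean, mean(fitness))
      hist_best <- c(hist_best, best_fit)
    }
  })
  structure(list(
    best_params = list(cost = 2^best_genes[1], gamma = 2^best_genes[2]),
    best_fitness = best_fit,
    history = data.frame(generation = seq_along(hist_mean),
                         mean_fitness = hist_mean,
                         best_fitness = hist_best)),
    class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: best CV fitness %.2f%% after %d generation(s); c = %.6g, g = %.6g\n",
              x$best_fitness, nrow(x$history),
              x$best_params$cost, x$best_params$gamma))
  invisible(x)
}

#' Train an RBF-SVM and predict test labels
#'
#' Fits the soft-margin dual with radial kernel on the training data
#' (one-vs-one for multiclass) and returns one predicted flavor label per
#' test row.
#'
#' @param train_x,train_y training features and labels.
#' @param test_x test features (same dimension as `train_x`).
#' @param params list with `cost` and `gamma` (e.g. `best_params` of a
#'   [ga_search()]).
#' @return character vector of predicted labels.
#' @export
train_predict <- function(train_x, train_y, test_x, params) {
  train_x <- as.matrix(train_x)
  test_x <- if (is.null(dim(test_x))) matrix(test_x, nrow = 1)
            else as.matrix(test_x)
  .assert(ncol(test_x) == ncol(train_x),
          "shape error: test feature dimension differs from training")
  fit <- .svm_fit(train_x, train_y, params$cost, params$gamma)
  as.character(predict(fit, test_x))
}

#' Fit a reusable flavor classifier
#'
#' @inheritParams train_predict
#' @return object of class `flavor_svm` usable with `predict()`.
#' @export
fit_flavor_svm <- function(train_x, train_y, params) {
  fit <- .svm_fit(as.matrix(train_x), train_y, params$cost, params$gamma)
  structure(list(fit = fit, params = params, p = ncol(as.matrix(train_x))),
            class = "flavor_svm")
}

#' @export
predict.flavor_svm <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  .assert(ncol(x) == object$p, "shape error: feature dimension mismatch")
  as.character(predict(object$fit, x))
}
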