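#' Registry of per-flavor cloud descriptors and word regions
#'
#' @param descriptors named list of `cloud2d` descriptors.
#' @param region_sets named list of `region_set`s with the same names.
#' @return an object of class `flavor_registry`.
#' @export
flavor_registry <- function(descriptors, region_sets) {
  .assert(is.list(descriptors) && is.list(region_sets) &&
            setequal(names(descriptors), names(region_sets)) &&
            length(descriptors) >= 1L,
          "registry error: descriptors and region_sets must share flavor names")
  structure(list(descriptors = descriptors, region_sets = region_sets),
            class = "flavor_registry")
}

#' Registry built from the packaged liquor fixtures
#'
#' @param method `"printed"` uses the published explicit region multipliers;
#'   `"frequency"` derives regions from the default panel frequencies via the
#'   standard-normal-quantile construction.
#' @return a [flavor_registry()] covering jiang, feng, nong and mild.
#' @export
liquor_registry <- function(method = c("printed", "frequency")) {
  method <- match.arg(method)
  desc <- liquor_descriptors()
  regions <- if (method == "printed") {
    mult <- liquor_region_multipliers()
    lapply(names(desc), function(f)
      build_region_set_explicit(desc[[f]], mult[[f]]$multipliers,
                                mult[[f]]$words))
  } else {
    panels <- liquor_panels()
    lapply(names(desc), function(f) {
      p <- panels[[f]]
      counts <- attr(p, "counts")
      if (is.null(counts)) counts <- round(p$probabilities * p$panel_size)
      build_region_set(desc[[f]],
                       word_frequency_table(f, p$words, counts, p$panel_size))
    })
  }
  names(regions) <- names(desc)
  flavor_registry(desc, regions)
}

#' Compose a fuzzy evaluation sentence
#'
#' @param words at least one word, ordered centre to periphery.
#' @return `"This liquor is "` followed by the lowercase words joined by
#'   `", "`.
#' @examples
#' compose_sentence(c("Soft and sweet", "Sweet and refreshing", "Mellow"))
#' @export
compose_sentence <- function(words) {
  .assert(is.character(words) && length(words) >= 1L && all(nzchar(words)),
          "invalid words: at least one non-empty word required")
  paste0("This liquor is ", paste(tolower(words), collapse = ", "))
}

#' Evaluate one electronic-tongue sample
#'
#' The full single-sample protocol: predict the flavor with the trained
#' classifier, fetch that flavor's cloud descriptor and word regions from
#' the registry, generate `n_droplets` cloud droplets from the descriptor
#' (droplets are anchored at the flavor concept, not at the sample's own
#' coordinates), locate each droplet's region, and compose the sentence from
#' the unique words ordered centre to periphery.
#'
#' @param features the sample's channel vector (or 1-row matrix).
#' @param classifier a fitted [fit_flavor_svm()] model.
#' @param registry a [flavor_registry()] covering every classifier label.
#' @param seed integer seed for the droplet draw.
#' @param n_droplets number of droplets (default 5).
#' @param outside `"outermost"` assigns a droplet beyond the outer cap to the
#'   outermost region; `"resample"` redraws it until it lands inside.
#' @param sample_id optional identifier carried into the result.
#' @return object of class `taste_evaluation` with fields `sample_id`,
#'   `predicted_flavor`, `droplets`, `region_indices`, `words`, `sentence`.
#' @export
evaluate_sample <- function(features, classifier, registry, seed,
                            n_droplets = 5L,
                            outside = c("outermost", "resample"),
                            sample_id = NA_character_) {
  outside <- match.arg(outside)
  .assert(inherits(registry, "flavor_registry"),
          "registry error: not a flavor_registry")
  flavor <- predict(classifier, features)[1]
  .assert(flavor %in% names(registry$descriptors),
          paste("registry error: predicted flavor has no entry:", flavor))
  desc <- registry$descriptors[[flavor]]
  regions <- registry$region_sets[[flavor]]
  droplets <- forward_cloud2d(desc, n_droplets, seed = seed)
  idx <- locate_region(regions, droplets[, c("x1", "x2")])
  if (anyNA(idx)) {
    if (outside == "resample") {
      tries <- 0L
      while (anyNA(idx) && tries < 1000L) {
        tries <- tries + 1L
        redo <- which(is.na(idx))
        redraw <- forward_cloud2d(desc, length(redo),
                                  seed = .child_seed(seed, 7e4 + tries))
        droplets[redo, ] <- redraw
        idx[redo] <- locate_region(regions, redraw[, c("x1", "x2")])
      }
    }
    idx[is.na(idx)] <- length(regions$multipliers)
  }
  uniq <- sort(unique(idx))             # centre -> periphery, de-duplicated
  words <- regions$words[uniq]
  structure(list(sample_id = sample_id,
                 predicted_flavor = flavor,
                 droplets = droplets,
                 region_indices = idx,
                 words = words,
                 sentence = compose_sentence(words)),
            class = "taste_evaluation")
}

#' @export
print.taste_evaluation <- function(x, ...) {
  cat(sprintf("%s [%s] regions {%s}: %s\n",
              ifelse(is.na(x$sample_id), "sample", x$sample_id),
              x$predicted_flavor,
              paste(x$region_indices, collapse = ","), x$sentence))
  invisible(x)
}

#' Run the end-to-end fuzzy-evaluation pipeline
#'
#' Orchestrates the full study workflow on a labelled dataset (simulated by
#' default): stratified train/test split, GA search for the SVM parameters
#' under cross-validation fitness, test-set classification, PCA fit on the
#' training split, per-flavor backward-cloud descriptors from the training
#' projections, word regions from (simulated) panel votes, and fuzzy
#' evaluation of held-out samples. Fully seeded: identical `(config, seed)`
#' give identical reports.
#'
#' @param config list of options; unknown keys raise an error naming the
#'   key. Recognised keys: `data` (labelled taste data frame; default:
#'   simulate), `synthetic` ([synthetic_config()]), `panels` (named list of
#'   [panel_config()], default [liquor_panels()]), `ga` ([ga_config()];
#'   default pop 20, at most 20 generations, 5-fold CV),
#'   `train_per_class` (default 14), `eval_per_flavor` (default 2),
#'   `cap` (outer region multiplier, default 3), `n_droplets` (default 5).
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, writes `report.json` and
#'   `evaluations.csv`.
#' @return object of class `taste_report`: `accuracy` (%), `ga`, `pca`,
#'   `descriptors`, `region_sets`, `evaluations` (data frame), `predictions`.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  known <- c("data", "synthetic", "panels", "ga", "train_per_class",
             "eval_per_flavor", "cap", "n_droplets")
  bad <- setdiff(names(config), known)
  .assert(length(bad) == 0,
          paste("config error: unknown key(s):", paste(bad, collapse = ", ")))
  get_or <- function(key, default) if (is.null(config[[key]])) default
                                   else config[[key]]
  synth <- get_or("synthetic", synthetic_config())
  data <- get_or("data", NULL)
  if (is.null(data)) data <- generate_taste_dataset(synth,
                                                    .child_seed(seed, 0))
  .assert(is.data.frame(data) && "flavor" %in% names(data),
          "config error: key 'data' must be a labelled taste data frame")
  if (is.null(data$sample_id))
    data$sample_id <- sprintf("s%03d", seq_len(nrow(data)))
  flavors <- sort(unique(data$flavor))
  .assert(length(flavors) >= 2,
          "config error: at least 2 flavor classes are required")
  x <- taste_features(data)
  y <- data$flavor
  panels <- get_or("panels", liquor_panels())
  .assert(all(flavors %in% names(panels)),
          "config error: key 'panels' missing a flavor entry")
  gacfg <- get_or("ga", ga_config(pop_size = 20L, max_generations = 20L,
                                  cv_folds = 5L,
                                  seed = .child_seed(seed, 2)))
  cap <- get_or("cap", 3)
  n_droplets <- get_or("n_droplets", 5L)

  split <- stratified_split(y, get_or("train_per_class", 14L),
                            seed = .child_seed(seed, 1))
  ga <- ga_search(x[split$train, ], y[split$train], gacfg)
  pred <- train_predict(x[split$train, ], y[split$train], x[split$test, ],
                        ga$best_params)
  accuracy <- 100 * mean(pred == y[split$test])
  classifier <- fit_flavor_svm(x[split$train, ], y[split$train],
                               ga$best_params)

  pca <- fit_pca(x[split$train, ])
  scores <- project(pca, x[split$train, ])
  descriptors <- lapply(flavors, function(f)
    backward_cloud2d(scores[y[split$train] == f, , drop = FALSE]))
  names(descriptors) <- flavors
  region_sets <- lapply(flavors, function(f) {
    votes <- generate_panel_votes(panels[[f]],
                                  seed = .child_seed(seed, 10 + match(f, flavors)))
    build_region_set(descriptors[[f]], votes, cap = cap)
  })
  names(region_sets) <- flavors
  registry <- flavor_registry(descriptors, region_sets)

  per_flavor <- get_or("eval_per_flavor", 2L)
  eval_idx <- integer(0)
  withr::with_seed(.child_seed(seed, 3), {
    for (f in flavors) {
      cand <- split$test[y[split$test] == f]
      eval_idx <- c(eval_idx, sample(cand, min(per_flavor, length(cand))))
    }
  })
  evals <- lapply(seq_along(eval_idx), function(i) {
    j <- eval_idx[i]
    evaluate_sample(x[j, ], classifier, registry,
                    seed = .child_seed(seed, 100 + i),
                    n_droplets = n_droplets,
                    sample_id = data$sample_id[j])
  })
  evaluations <- data.frame(
    sample_id = vapply(evals, `[[`, character(1), "sample_id"),
    actual_flavor = y[eval_idx],
    predicted_flavor = vapply(evals, `[[`, character(1), "predicted_flavor"),
    regions = vapply(evals, function(e)
      paste(e$region_indices, collapse = " "), character(1)),
    sentence = vapply(evals, `[[`, character(1), "sentence"),
    stringsAsFactors = FALSE)

  report <- structure(list(accuracy = accuracy, ga = ga, pca = pca,
                           descriptors = descriptors,
                           region_sets = region_sets,
                           evaluations = evaluations,
                           predictions = data.frame(
                             sample_id = data$sample_id[split$test],
                             actual = y[split$test], predicted = pred,
                             stringsAsFactors = FALSE),
                           seed = as.integer(seed)),
                      class = "taste_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.taste_report <- function(x, ...) {
  cat(sprintf("taste_report: test accuracy %.1f%% (CV fitness %.1f%%); PC1 %.4f, cumulative %.4f\n",
              x$accuracy, x$ga$best_fitness,
              x$pca$contribution_rates[1],
              sum(x$pca$contribution_rates[1:2])))
  print(x$evaluations[, c("sample_id", "predicted_flavor", "sentence")],
        row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Serializes the report as `report.json` (accuracy, GA optimum, PCA
#' contribution rates, per-flavor descriptors and region geometry, and the
#' evaluation sentences) plus `evaluations.csv`.
#'
#' @param report a `taste_report`.
#' @param out_dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  desc_json <- lapply(report$descriptors, function(d)
    list(pc1 = d$dim1[c("ex", "en", "he")], pc2 = d$dim2[c("ex", "en", "he")]))
  regions_json <- lapply(report$region_sets, function(r)
    list(center = r$center, scales = r$scales,
         multipliers = r$multipliers, words = r$words,
         inequalities = format(r)))
  payload <- list(
    seed = report$seed,
    accuracy = report$accuracy,
    ga = list(best_fitness = report$ga$best_fitness,
              cost = report$ga$best_params$cost,
              gamma = report$ga$best_params$gamma,
              generations = nrow(report$ga$history)),
    pca = list(contribution_rates = report$pca$contribution_rates),
    descriptors = desc_json,
    regions = regions_json,
    evaluations = report$evaluations)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  write.csv(report$evaluations, file.path(out_dir, "evaluations.csv"),
            row.names = FALSE)
  invisible(out_dir)
}
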