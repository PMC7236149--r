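#' Configure an end-to-end landscape classification experiment
#'
#' Bundles every choice of a full experiment: the data source (a list
#' of activity classes, compound CSV paths, or a synthetic-class
#' count), the projection method(s), the image collection, the
#' encoding, the classifiers with their search budgets, the number of
#' independent trials and the master seed. All per-stage randomness is
#' derived deterministically from the master seed, so a config plus a
#' seed reproduces the whole experiment.
#'
#' @param classes List of [activity_class()] objects, or `NULL` to use
#'   `csv_paths` or synthetic data.
#' @param csv_paths Optional compound CSV paths read with
#'   [read_compound_table()].
#' @param n_classes Number of synthetic classes generated when no
#'   classes/paths are given (default 12).
#' @param class_args Extra arguments for [synthetic_class_spec()] when
#'   generating.
#' @param collection A [collection_spec()] or a standard collection
#'   number 1-7.
#' @param encoding Image encoding variant (overrides the collection's).
#' @param classifiers Subset of `c("cnn", "svm", "rf")`.
#' @param n_trials Number of independent class-split trials (default
#'   10).
#' @param seed Master seed.
#' @param out_dir Output directory for images, manifests and reports.
#' @param render_width,render_height Raw render resolution.
#' @param resolution Surface grid nodes per axis.
#' @param ns_candidates Neuroscale candidate RBF counts (a single value
#'   skips cross-validation).
#' @param cnn_args,svm_args,rf_args Named argument lists forwarded to
#'   the trainers.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(classes = NULL, csv_paths = NULL,
                              n_classes = 12L, class_args = list(),
                              collection = 7, encoding = "grayscale",
                              classifiers = c("cnn", "svm"),
                              n_trials = 10L, seed = 1L,
                              out_dir = tempfile("altopo_run"),
                              render_width = 600L, render_height = 400L,
                              resolution = 48L, ns_candidates = 8L,
                              cnn_args = list(), svm_args = list(),
                              rf_args = list()) {
  spec <- if (inherits(collection, "collection_spec")) {
    collection
  } else {
    standard_collections(collection)
  }
  spec$encoding <- encoding
  classifiers <- match.arg(classifiers, c("cnn", "svm", "rf"),
                           several.ok = TRUE)
  stopifnot(n_trials >= 1L)
  structure(
    list(classes = classes, csv_paths = csv_paths,
         n_classes = as.integer(n_classes), class_args = class_args,
         collection = spec, classifiers = classifiers,
         n_trials = as.integer(n_trials), seed = as.integer(seed),
         out_dir = out_dir,
         render_width = as.integer(render_width),
         render_height = as.integer(render_height),
         resolution = as.integer(resolution),
         ns_candidates = ns_candidates,
         cnn_args = cnn_args, svm_args = svm_args, rf_args = rf_args),
    class = "experiment_config"
  )
}

# resolve the configured data source into a list of activity classes
resolve_classes <- function(cfg) {
  if (!is.null(cfg$classes)) return(cfg$classes)
  if (!is.null(cfg$csv_paths)) {
    return(lapply(cfg$csv_paths, read_compound_table))
  }
  do.call(generate_class_set,
          c(list(n_classes = cfg$n_classes,
                 seed = derive_seed(cfg$seed, "classes")),
            cfg$class_args))
}

#' Build the image dataset of an experiment
#'
#' Runs the data half of the pipeline: resolve the activity classes,
#' similarity-filter them, derive the smooth/rugged reference variants,
#' embed, interpolate the potency surfaces, and render the configured
#' collection into `out_dir` with a manifest. The build is resumable:
#' images already on disk with a matching checksum are not regenerated.
#'
#' @param cfg An [experiment_config()].
#' @param progress Print progress messages.
#' @return The manifest data frame (invisibly also written to
#'   `manifest.csv` in the image directory).
#' @export
build_dataset <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  classes <- resolve_classes(cfg)
  landscapes <- build_landscapes(
    classes, projections = cfg$collection$projections,
    seed = derive_seed(cfg$seed, "landscapes"),
    resolution = cfg$resolution, ns_candidates = cfg$ns_candidates,
    progress = progress
  )
  render_collection(landscapes, cfg$collection,
                    file.path(cfg$out_dir, "images"),
                    width = cfg$render_width, height = cfg$render_height)
}

# load manifest images as features (flattened) and as image list
load_manifest_images <- function(manifest, img_dir) {
  imgs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    imgs[[i]] <- read_image(
      file.path(img_dir, manifest$path[i]),
      meta = list(class = manifest$class[i], variant = manifest$variant[i],
                  projection = manifest$projection[i],
                  azimuth = manifest$azimuth[i],
                  elevation = manifest$elevation[i],
                  encoding = manifest$encoding[i])
    )
  }
  imgs
}

#' Run a multi-trial classification experiment
#'
#' For each trial: draws a disjoint half/half class split (seeded from
#' the master seed and the trial index), trains each configured
#' classifier on all images of the training classes, predicts all
#' images of the held-out classes, and evaluates. Aggregates the trial
#' reports per classifier and writes a JSON summary plus per-trial
#' reports under the experiment output directory. A classifier failure
#' marks the trial as failed for that classifier; the summary counts
#' completed trials.
#'
#' @param cfg An [experiment_config()].
#' @param manifest Optional prebuilt manifest from [build_dataset()]
#'   (it is built on demand otherwise).
#' @param progress Print progress messages.
#' @return List with per-classifier elements: `trials` (list of
#'   [evaluation_report()]s), `aggregate` (from [aggregate_trials()]),
#'   and `failed` (failed trial indices). The summary is also written
#'   to `summary.json`.
#' @export
run_experiment <- function(cfg, manifest = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(manifest)) manifest <- build_dataset(cfg, progress = progress)
  img_dir <- file.path(cfg$out_dir, "images")
  imgs <- load_manifest_images(manifest, img_dir)
  labels <- manifest$variant
  class_names <- sort(unique(manifest$class))

  needs_features <- any(cfg$classifiers %in% c("svm", "rf"))
  features <- NULL
  if (needs_features) {
    features <- t(vapply(imgs, function(im) {
      px <- im$pixels
      if (!is.matrix(px)) px <- to_grayscale(im)$pixels
      normalize_and_flatten(al_image(px), check_dims = FALSE)
    }, numeric(length(imgs[[1]]$pixels) /
                 max(1L, dim(imgs[[1]]$pixels)[3] %||% 1L))))
  }

  results <- list()
  for (clf in cfg$classifiers) results[[clf]] <- list(trials = list(),
                                                      failed = integer(0))
  for (t in seq_len(cfg$n_trials)) {
    split <- split_classes(class_names,
                           seed = derive_seed(cfg$seed, paste0("split", t)))
    tr <- manifest$class %in% split$train
    te <- !tr
    for (clf in cfg$classifiers) {
      tseed <- derive_seed(cfg$seed, paste0(clf, t))
      rep <- tryCatch({
        if (clf == "cnn") {
          model <- do.call(train_cnn,
                           c(list(images = imgs[tr], labels = labels[tr],
                                  groups = manifest$class[tr],
                                  seed = tseed), cfg$cnn_args))
          pred <- stats::predict(model, imgs[te])
        } else if (clf == "svm") {
          model <- do.call(train_svm,
                           c(list(features = features[tr, , drop = FALSE],
                                  labels = labels[tr],
                                  groups = manifest$class[tr],
                                  seed = tseed),
                             cfg$svm_args))
          pred <- stats::predict(model, features[te, , drop = FALSE])
        } else {
          model <- do.call(train_rf,
                           c(list(features = features[tr, , drop = FALSE],
                                  labels = labels[tr],
                                  groups = manifest$class[tr],
                                  seed = tseed),
                             cfg$rf_args))
          pred <- stats::predict(model, features[te, , drop = FALSE])
        }
        prob <- pred$prob
        if (!all(topology_labels() %in% colnames(prob))) {
          miss <- setdiff(topology_labels(), colnames(prob))
          add <- matrix(0, nrow(prob), length(miss),
                        dimnames = list(NULL, miss))
          prob <- cbind(prob, add)[, topology_labels(), drop = FALSE]
        }
        evaluation_report(pred$label, labels[te], prob = prob)
      }, error = function(e) e)
      if (inherits(rep, "error")) {
        warning("trial ", t, " failed for ", clf, ": ",
                conditionMessage(rep))
        results[[clf]]$failed <- c(results[[clf]]$failed, t)
      } else {
        results[[clf]]$trials[[length(results[[clf]]$trials) + 1L]] <- rep
      }
      if (progress) {
        message(sprintf("trial %d/%d %s: %s", t, cfg$n_trials, clf,
                        if (inherits(rep, "error")) "failed"
                        else sprintf("acc %.3f", rep$accuracy)))
      }
    }
  }
  for (clf in cfg$classifiers) {
    if (length(results[[clf]]$trials) >= 2L) {
      results[[clf]]$aggregate <- aggregate_trials(results[[clf]]$trials)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment_summary(results, cfg,
                           file.path(cfg$out_dir, "summary.json"))
  results
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# serialize the aggregate results (not the fitted models) as JSON
write_experiment_summary <- function(results, cfg, path) {
  out <- list(seed = cfg$seed, n_trials = cfg$n_trials,
              collection = cfg$collection$name,
              encoding = cfg$collection$encoding,
              classifiers = list())
  for (clf in names(results)) {
    r <- results[[clf]]
    entry <- list(completed_trials = length(r$trials),
                  failed_trials = r$failed)
    entry$trial_accuracy <- vapply(r$trials, `[[`, numeric(1), "accuracy")
    if (!is.null(r$aggregate)) {
      m <- r$aggregate$metrics
      entry$mean <- as.list(stats::setNames(m$mean, m$metric))
      entry$sd <- as.list(stats::setNames(m$sd, m$metric))
      entry$mean_recall <- as.list(r$aggregate$mean_recall)
      entry$mean_confusion <- r$aggregate$mean_confusion
    }
    out$classifiers[[clf]] <- entry
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
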