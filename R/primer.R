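# ---- feature extraction -----------------------------------------------------

#' @importFrom randomForest randomForest
NULL

#' Quality-score features for primer-presence detection
#'
#' Untrimmed primers at read starts leave a low-base-diversity signature in
#' the quality scores of the first sequencing cycles. From the first
#' `n_max` reads, quality values at read positions 1-5 (segment A) and 6-10
#' (segment B) are pooled across reads, and eight statistics are computed per
#' segment: count, mean, median, standard deviation (population), minimum,
#' maximum, 25th percentile and 75th percentile (the latter two standing in
#' for skewness and kurtosis) - a 16-value vector in fixed order (segment A
#' first).
#'
#' @param reads An [hvr_reads()] object with qualities (FASTA input has
#'   none and is an error). Reads shorter than 10 bases contribute only
#'   their existing positions.
#' @param n_max Use at most the first `n_max` reads (default 1000).
#' @return Named numeric vector of length 16.
#' @export
extract_features <- function(reads, n_max = 1000L) {
  stopifnot(inherits(reads, "hvr_reads"))
  if (is.null(reads$qual)) {
    stop("quality-score features unavailable for FASTA input")
  }
  if (length(reads) == 0L) stop("no reads for feature extraction")
  qual <- reads$qual[seq_len(min(length(reads), n_max))]
  seg_a <- unlist(lapply(qual, function(q) q[seq_len(min(5L, length(q)))]),
                  use.names = FALSE)
  seg_b <- unlist(lapply(qual, function(q) {
    if (length(q) >= 6L) q[6L:min(10L, length(q))] else integer(0)
  }), use.names = FALSE)
  c(segment_stats(seg_a, "s1"), segment_stats(seg_b, "s2"))
}

# the eight per-segment statistics; sd is the population standard deviation,
# quartiles use linear interpolation (stats::quantile type 7)
segment_stats <- function(q, prefix) {
  if (length(q) == 0L) {
    v <- c(0, rep(NA_real_, 7))
  } else {
    q <- as.numeric(q)
    v <- c(length(q), mean(q), stats::median(q),
           sqrt(mean((q - mean(q))^2)), min(q), max(q),
           unname(stats::quantile(q, 0.25, type = 7)),
           unname(stats::quantile(q, 0.75, type = 7)))
  }
  names(v) <- paste0(prefix, "_",
                     c("count", "mean", "median", "sd", "min", "max",
                       "q25", "q75"))
  v
}

#' Names and order of the 16 classifier features
#' @return Character vector of length 16.
#' @export
hvr_feature_names <- function() {
  paste0(rep(c("s1", "s2"), each = 8), "_",
         c("count", "mean", "median", "sd", "min", "max", "q25", "q75"))
}

# ---- training ---------------------------------------------------------------

#' Train the primer-presence random forest
#'
#' Stratified 80/20 train/test split, a 100-tree random forest fitted with a
#' fixed seed, and held-out per-class precision/recall reported as the
#' model's metrics.
#'
#' @param features Numeric matrix or data.frame, one row per sample, columns
#'   [hvr_feature_names()].
#' @param labels Character/factor vector with levels `"primer"` /
#'   `"no-primer"`.
#' @param n_trees Ensemble size (default 100).
#' @param seed Seed for the split and the forest (default 42).
#' @param train_frac Training fraction of the stratified split (default 0.8).
#' @param class_weights Optional named class weights (off by default).
#' @return An `hvr_primer_model`: list with the fitted `forest`,
#'   `feature_names`, `classes`, `seed`, `version` and held-out `metrics`
#'   (per-class precision/recall and the confusion matrix).
#' @export
train_primer_model <- function(features, labels, n_trees = 100L, seed = 42L,
                               train_frac = 0.8, class_weights = NULL) {
  features <- as.data.frame(features)
  if (!identical(names(features), hvr_feature_names())) {
    stop("feature table must have exactly the 16 columns of ",
         "hvr_feature_names(), in order")
  }
  labels <- factor(as.character(labels), levels = c("no-primer", "primer"))
  if (any(is.na(labels))) stop("labels must be 'primer' or 'no-primer'")
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training needs both classes present")
  }
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")

  set.seed(seed)
  train_idx <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sort(sample(idx, max(1L, round(train_frac * length(idx)))))
  }))
  test_idx <- setdiff(seq_along(labels), train_idx)
  if (length(test_idx) == 0L) stop("split leaves no held-out samples")

  set.seed(seed)
  forest <- randomForest::randomForest(
    x = features[train_idx, , drop = FALSE],
    y = droplevels(labels[train_idx]),
    ntree = n_trees,
    classwt = class_weights
  )
  pred <- stats::predict(forest, features[test_idx, , drop = FALSE])
  truth <- labels[test_idx]
  conf <- table(truth = truth, pred = factor(pred, levels = levels(labels)))
  metrics <- lapply(levels(labels), function(cl) {
    tp <- conf[cl, cl]
    list(precision = if (sum(conf[, cl]) == 0) NA_real_
                     else tp / sum(conf[, cl]),
         recall = tp / sum(conf[cl, ]))
  })
  names(metrics) <- levels(labels)

  structure(list(forest = forest,
                 feature_names = hvr_feature_names(),
                 classes = levels(labels),
                 n_trees = n_trees, seed = seed,
                 version = as.character(utils::packageVersion("hvrscan")),
                 metrics = list(per_class = metrics, confusion = conf,
                                n_train = length(train_idx),
                                n_test = length(test_idx))),
            class = "hvr_primer_model")
}

#' @export
print.hvr_primer_model <- function(x, ...) {
  cat("<hvr_primer_model> ", x$n_trees, " trees, seed ", x$seed,
      ", held-out n=", x$metrics$n_test, "\n", sep = "")
  for (cl in names(x$metrics$per_class)) {
    m <- x$metrics$per_class[[cl]]
    cat(sprintf("  %-9s precision %.4f recall %.4f\n", cl, m$precision,
                m$recall))
  }
  invisible(x)
}

#' Predict primer presence for one sample
#'
#' @param model An `hvr_primer_model`.
#' @param features Length-16 feature vector from [extract_features()].
#' @param threshold Probability threshold for calling presence
#'   (default 0.5). The score is always returned so users can re-threshold.
#' @return List with `presence` (logical) and `score` (probability of the
#'   `"primer"` class).
#' @export
predict_primer <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "hvr_primer_model"))
  if (length(features) != 16L) {
    stop("feature vector must have length 16, got ", length(features))
  }
  nd <- as.data.frame(as.list(stats::setNames(as.numeric(features),
                                              model$feature_names)))
  score <- unname(stats::predict(model$forest, nd, type = "prob")[, "primer"])
  list(presence = score >= threshold, score = score)
}

# ---- persistence and default model -----------------------------------------

#' Save / load a primer model
#'
#' The serialized object embeds the feature-order manifest, package version,
#' training seed and held-out metrics.
#'
#' @param model An `hvr_primer_model`.
#' @param path File path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_primer_model <- function(model, path) {
  stopifnot(inherits(model, "hvr_primer_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_primer_model
#' @export
load_primer_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hvr_primer_model")) {
    stop("not an hvr_primer_model: ", path)
  }
  if (!identical(model$feature_names, hvr_feature_names())) {
    stop("model feature manifest does not match this package version")
  }
  model
}

.hvr_model_cache <- new.env(parent = emptyenv())

#' Default primer model
#'
#' Trained deterministically from the simulated corpus (200 samples per
#' class) on first use and cached for the session.
#'
#' @param reference A `ReferenceGene` (defaults to the bundled reference).
#' @param n_per_class Simulated samples per class (default 200).
#' @param seed Seed (default 42).
#' @return An `hvr_primer_model`.
#' @export
default_primer_model <- function(reference = load_reference(),
                                 n_per_class = 200L, seed = 42L) {
  key <- paste0("m", n_per_class, "_", seed)
  if (!is.null(.hvr_model_cache[[key]])) return(.hvr_model_cache[[key]])
  corpus <- simulate_training_corpus(n_per_class = n_per_class, seed = seed,
                                     reference = reference)
  model <- train_primer_model(corpus[, hvr_feature_names()], corpus$label,
                              seed = seed)
  .hvr_model_cache[[key]] <- model
  model
}
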