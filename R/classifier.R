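#' Label candidate pairs against a ground-truth table and draw a training set
#'
#' Joins each candidate pair to the truth table (`record_id`, `entity_id`)
#' and labels it `match` when both records belong to the same entity. A
#' class-balanced sample of the requested size is then drawn (using the
#' current RNG stream) for classifier training; held-out pairs retain their
#' labels for evaluation. Half of the negative draws are hard negatives,
#' stratified over the two ways distinct persons collide in registry data:
#' name twins (high name similarity and shared birth year, common under a
#' heavy-tailed name distribution) and identifier twins (coinciding date
#' of birth with unrelated names). A maximum-margin boundary only learns
#' to demand agreement on names *and* a corroborating identifier if both
#' collision classes are present in training; the remaining negatives are
#' drawn uniformly.
#'
#' @param features Comparison-vector tibble from [compare_pairs()].
#' @param truth Tibble with `record_id`, `entity_id`.
#' @param n_train Total training pairs to sample (half per class where
#'   available).
#' @return A list: `train` (sampled feature rows plus a `label` factor),
#'   `train_idx` (row indices of `features` used for training), and
#'   `labels` (the truth label of every candidate pair, for held-out
#'   evaluation). Label levels are `non-match`, `match`.
#' @export
make_training_pairs <- function(features, truth, n_train = 5000) {
  ea <- truth$entity_id[match(features$record_id_a, truth$record_id)]
  eb <- truth$entity_id[match(features$record_id_b, truth$record_id)]
  lab <- factor(ifelse(!is.na(ea) & !is.na(eb) & ea == eb, "match", "non-match"),
                levels = c("non-match", "match"))
  idx_m <- which(lab == "match")
  idx_n <- which(lab == "non-match")
  if (length(idx_m) == 0 || length(idx_n) == 0) {
    stop("training requires at least one pair of each label", call. = FALSE)
  }
  k <- n_train %/% 2
  pick_m <- if (length(idx_m) > k) sort(sample(idx_m, k)) else idx_m
  if (length(idx_n) > k) {
    name_hard <- features$sim_first_name[idx_n] + features$sim_surname[idx_n] +
      features$age_agreement[idx_n]
    id_hard <- 3 * features$dob_exact[idx_n] + features$episode_match[idx_n] +
      features$folder_match[idx_n] + 0.5 * name_hard
    m <- k %/% 4
    hard <- idx_n[union(order(name_hard, decreasing = TRUE)[seq_len(m)],
                        order(id_hard, decreasing = TRUE)[seq_len(m)])]
    pool <- idx_n[!(idx_n %in% hard)]
    pick_n <- sort(c(hard, sample(pool, min(k - length(hard), length(pool)))))
  } else {
    pick_n <- idx_n
  }
  pick <- c(pick_m, pick_n)
  train <- features[pick, ]
  train$label <- lab[pick]
  list(train = train, train_idx = pick, labels = lab)
}

#' Fit the linear maximum-margin match classifier
#'
#' Trains a linear support vector machine on the six comparison features
#' (C-classification, no feature scaling: all features are already bounded
#' in `[0, 1]`). Non-match errors are weighted double by default: the
#' class-balanced training sample vastly overstates the match prior of the
#' blocked pair space, and a false merge propagates through transitive
#' closure while a missed pair is usually rescued by it, so the margin is
#' placed conservatively. The fitted separating hyperplane is reduced to an explicit
#' weight vector and bias, so scoring is a single matrix product and the
#' model serialises to JSON. Training is deterministic for a given training
#' table. Pairs score `>= threshold` (default 0, the margin zero-point)
#' are classified as matches.
#'
#' @param train Tibble of comparison vectors with a `label` factor
#'   (`non-match`/`match`), e.g. `make_training_pairs()$train`.
#' @param cost Soft-margin cost parameter.
#' @param class_weights Named error weights for the two classes.
#' @param threshold Decision threshold on the signed margin.
#' @return An object of class `hcm_match_model`.
#' @export
fit_match_classifier <- function(train, cost = 10,
                                 class_weights = c("non-match" = 2, match = 1),
                                 threshold = 0) {
  feats <- match_feature_names()
  stopifnot(all(feats %in% names(train)), "label" %in% names(train))
  y <- factor(train$label, levels = c("non-match", "match"))
  if (dplyr::n_distinct(y) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  x <- as.matrix(train[, feats])
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = class_weights)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the margin so that positive scores mean "match"
  dec <- drop(x %*% w) + b
  pred <- fit$fitted
  if (mean(dec[pred == "match"]) < mean(dec[pred == "non-match"])) {
    w <- -w
    b <- -b
  }
  scores <- drop(x %*% w) + b
  acc <- mean((scores >= threshold) == (y == "match"))
  structure(
    list(weights = setNames(as.numeric(w), feats), bias = b,
         threshold = threshold, feature_names = feats,
         cost = cost, n_train = nrow(train), train_accuracy = acc),
    class = "hcm_match_model"
  )
}

#' Score and classify candidate pairs
#'
#' @param object An `hcm_match_model`.
#' @param features Comparison-vector tibble from [compare_pairs()].
#' @param ... Unused.
#' @return `features`' pair identifiers with `score` (signed margin) and
#'   `label` (`match` iff `score >= threshold`).
#' @export
predict.hcm_match_model <- function(object, features, ...) {
  x <- as.matrix(features[, object$feature_names])
  score <- drop(x %*% object$weights) + object$bias
  rm(x)
  tibble::tibble(
    record_id_a = features$record_id_a,
    record_id_b = features$record_id_b,
    score = score,
    label = structure(1L + (score >= object$threshold),
                      levels = c("non-match", "match"), class = "factor")
  )
}

#' @export
print.hcm_match_model <- function(x, ...) {
  cat("<hcm_match_model> linear SVM,", x$n_train, "training pairs\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  cat(sprintf("  bias: %.3f  threshold: %.3f  training accuracy: %.4f\n",
              x$bias, x$threshold, x$train_accuracy))
  invisible(x)
}

#' @rdname fit_match_classifier
#' @param x An `hcm_match_model`.
#' @export
tidy.hcm_match_model <- function(x, ...) {
  tibble::tibble(term = c(x$feature_names, "(bias)"),
                 estimate = c(unname(x$weights), x$bias))
}

#' @rdname fit_match_classifier
#' @export
glance.hcm_match_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, cost = x$cost, threshold = x$threshold,
                 train_accuracy = x$train_accuracy)
}

#' Serialise a match model to JSON and back
#'
#' @param model An `hcm_match_model`.
#' @param path JSON file path.
#' @return `write_match_model()` returns `path` invisibly;
#'   `read_match_model()` returns the model.
#' @export
write_match_model <- function(model, path) {
  stopifnot(inherits(model, "hcm_match_model"))
  out <- unclass(model)
  out$weights <- as.list(model$weights)  # keep feature names in the JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_match_model
#' @export
read_match_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = setNames(as.numeric(unlist(raw$weights)),
                            names(raw$weights)),
         bias = raw$bias, threshold = raw$threshold,
         feature_names = raw$feature_names, cost = raw$cost,
         n_train = raw$n_train, train_accuracy = raw$train_accuracy),
    class = "hcm_match_model"
  )
}

#' Held-out pair-classification metrics
#'
#' Precision, recall and F1 of the pair decisions over the candidate pairs
#' not used for training, against the truth labels.
#'
#' @param decisions Tibble from [predict.hcm_match_model()] over all
#'   candidate pairs, in the same row order as the labels.
#' @param labels Label factor for every candidate pair
#'   (`make_training_pairs()$labels`).
#' @param train_idx Row indices that were used for training and are
#'   excluded here.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `n_holdout`.
#' @export
holdout_pair_metrics <- function(decisions, labels, train_idx) {
  stopifnot(nrow(decisions) == length(labels))
  keep <- rep(TRUE, length(labels))
  keep[train_idx] <- FALSE
  pred <- decisions$label[keep] == "match"
  truth <- labels[keep] == "match"
  tp <- sum(pred & truth)
  precision <- if (sum(pred) > 0) tp / sum(pred) else 1
  recall <- if (sum(truth) > 0) tp / sum(truth) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_holdout = sum(keep))
}
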