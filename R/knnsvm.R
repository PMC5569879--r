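#' Cosine distance between two feature vectors
#'
#' `1 - cos(angle)` between the vectors; 0 for identical directions, 1
#' for orthogonal, 2 for opposite.
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined direction: zero vector")
  1 - sum(u * v) / (nu * nv)
}

standardize_stats <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_standardize <- function(x, stats) {
  sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
}

#' Fit the hybrid KNN-SVM classifier
#'
#' Stores the (optionally standardized) training features for the
#' cosine-distance K-nearest-neighbour stage and trains one binary SVM
#' per unordered class pair on that pair's training subset
#' (one-against-one). At prediction time the KNN stage shortlists the
#' two highest-weight classes; if the neighbourhood is unanimous the
#' class is taken directly, otherwise the matching pair SVM decides.
#'
#' @param features numeric matrix, trials x feature dimensions.
#' @param labels class labels (see [class_levels()]), one per row.
#' @param k neighbour count (default 5).
#' @param kernel SVM kernel, "radial" (default) or "linear".
#' @param cost SVM regularization constant.
#' @param standardize standardize features to zero mean / unit variance
#'   (statistics from this training set) before both stages?
#' @param weight_mode per-class KNN weight: "similarity" sums the cosine
#'   similarities (clamped at zero) of the class's neighbours; "count"
#'   counts them.
#' @return Object of class `knnsvm_model`.
#' @export
knnsvm_fit <- function(features, labels, k = 5,
                       kernel = c("radial", "linear"), cost = 1,
                       standardize = TRUE,
                       weight_mode = c("similarity", "count")) {
  kernel <- match.arg(kernel)
  weight_mode <- match.arg(weight_mode)
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("one label per feature row required")
  if (k < 1 || k > nrow(features))
    stop("k must lie between 1 and the training size")
  counts <- table(factor(labels, levels = class_levels()))
  if (any(counts < 2))
    stop("incomplete training set: need >= 2 trials per class (",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  st <- if (standardize) standardize_stats(features)
        else list(center = rep(0, ncol(features)),
                  scale = rep(1, ncol(features)))
  x <- apply_standardize(features, st)
  pairs <- class_pairs()
  svms <- list()
  for (i in seq_len(nrow(pairs))) {
    keep <- labels %in% pairs[i, ]
    y <- factor(labels[keep], levels = pairs[i, ])
    svms[[paste(pairs[i, ], collapse = "|")]] <-
      e1071::svm(x[keep, , drop = FALSE], y, kernel = kernel, cost = cost,
                 scale = FALSE)
  }
  structure(list(k = as.integer(k), train_features = x,
                 train_labels = labels, pair_classifiers = svms,
                 pairs = pairs, standardize = st,
                 params = list(kernel = kernel, cost = cost,
                               standardize = standardize,
                               weight_mode = weight_mode)),
            class = "knnsvm_model")
}

#' @export
print.knnsvm_model <- function(x, ...) {
  cat("KNN-SVM model: K =", x$k, ",", nrow(x$train_features),
      "training trials,", length(x$pair_classifiers), "pairwise",
      x$params$kernel, "SVMs\n")
  invisible(x)
}

#' Rough KNN classification stage
#'
#' Finds the K training trials nearest to the query in cosine distance,
#' accumulates a per-class weight over the neighbourhood, and returns the
#' one or two top-weight classes. Ties are broken by weight, then by
#' canonical class order; neighbour-rank ties by training index.
#'
#' @param sample raw feature vector (standardized internally with the
#'   model's training statistics).
#' @param model a `knnsvm_model`.
#' @return List with `shortlist` (1 or 2 labels, weight-descending) and
#'   `weights`.
#' @export
knn_rough <- function(sample, model) {
  q <- (as.numeric(sample) - model$standardize$center) /
    model$standardize$scale
  d <- apply(model$train_features, 1, cosine_distance, v = q)
  nn <- order(d)[seq_len(model$k)]
  sim <- if (model$params$weight_mode == "similarity")
           pmax(1 - d[nn], 0) else rep(1, length(nn))
  w <- tapply(sim, factor(model$train_labels[nn], levels = class_levels()),
              sum, default = 0)
  w <- w[!is.na(w)]
  # order by weight descending, canonical order breaking ties
  ord <- order(-w, match(names(w), class_levels()))
  cls <- names(w)[ord]
  in_nbhd <- cls %in% model$train_labels[nn]
  cls <- cls[in_nbhd]
  shortlist <- cls[seq_len(min(2, length(cls)))]
  list(shortlist = shortlist, weights = w[shortlist])
}

#' Predict class labels with the hybrid classifier
#'
#' @param object a `knnsvm_model`.
#' @param newdata feature matrix (trials x dimensions) or single vector.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.knnsvm_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  apply(as.matrix(newdata), 1, function(s) {
    rough <- knn_rough(s, object)
    if (length(rough$shortlist) == 1) return(rough$shortlist)
    pair <- sort_pair(rough$shortlist)
    key <- paste(pair, collapse = "|")
    q <- (s - object$standardize$center) / object$standardize$scale
    as.character(stats::predict(object$pair_classifiers[[key]],
                                matrix(q, nrow = 1)))
  })
}

sort_pair <- function(pair) {
  pair[order(match(pair, class_levels()))]
}

#' KNN-only prediction (full four-class vote)
#'
#' Baseline using only the KNN stage: the class with the largest
#' neighbourhood weight wins.
#'
#' @inheritParams predict.knnsvm_model
#' @param model a `knnsvm_model`.
#' @param features feature matrix.
#' @return Character vector of predicted labels.
#' @export
predict_knn <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  apply(as.matrix(features), 1, function(s) knn_rough(s, model)$shortlist[1])
}

#' SVM-only prediction (one-against-one majority vote)
#'
#' Baseline using only the pairwise SVMs: each of the six binary
#' classifiers votes, the majority class wins, ties broken by canonical
#' order.
#'
#' @param model a `knnsvm_model`.
#' @param features feature matrix.
#' @return Character vector of predicted labels.
#' @export
predict_svm <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  x <- apply_standardize(as.matrix(features), model$standardize)
  votes <- matrix(0, nrow(x), length(class_levels()),
                  dimnames = list(NULL, class_levels()))
  for (key in names(model$pair_classifiers)) {
    pred <- as.character(stats::predict(model$pair_classifiers[[key]], x))
    for (cl in unique(pred))
      votes[pred == cl, cl] <- votes[pred == cl, cl] + 1
  }
  class_levels()[apply(votes, 1, which.max)]
}
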