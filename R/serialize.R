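# Text serialization of fitted objects: delimited matrices with a JSON
# header line for filter banks and feature matrices, and a JSON container
# for the classifier. The classifier file stores the standardized
# training set and hyperparameters; the pairwise SVMs are refit
# deterministically on load, so the on-disk format stays plain text and
# version-independent.

#' Write a spatial filter bank as delimited text with a JSON header
#'
#' @param bank a `spatial_filter_bank`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_bank <- function(bank, path) {
  header <- jsonlite::toJSON(
    list(type = "spatial_filter_bank",
         n_channels = bank$n_channels,
         alpha = bank$config$alpha, beta = bank$config$beta,
         gamma = bank$config$gamma,
         pair_order = names(bank$filters)),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", header), con)
  for (key in names(bank$filters)) {
    w <- bank$filters[[key]]
    for (q in seq_len(ncol(w)))
      writeLines(paste(c(key, q, format(w[, q], digits = 17)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a spatial filter bank written by [write_filter_bank()]
#'
#' @param path input path.
#' @return A `spatial_filter_bank`.
#' @export
read_filter_bank <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  body <- utils::read.table(text = lines[-1], sep = "\t",
                            stringsAsFactors = FALSE)
  filters <- list()
  for (key in header$pair_order) {
    rows <- body[body[[1]] == key, , drop = FALSE]
    rows <- rows[order(rows[[2]]), , drop = FALSE]
    filters[[key]] <- t(as.matrix(rows[, -(1:2), drop = FALSE]))
    dimnames(filters[[key]]) <- NULL
  }
  structure(list(filters = filters,
                 pairs = do.call(rbind, strsplit(header$pair_order,
                                                 "|", fixed = TRUE)),
                 config = rcsp_config(header$beta, header$gamma,
                                      header$alpha),
                 n_channels = header$n_channels),
            class = "spatial_filter_bank")
}

#' Write a feature matrix with labels as delimited text
#'
#' @param features matrix with a `labels` attribute (see
#'   [feature_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(label = attr(features, "labels"),
                   as.data.frame(unclass(features)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path input path.
#' @return Feature matrix with a `labels` attribute.
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  attr(m, "labels") <- as.character(df[[1]])
  m
}

#' Write a KNN-SVM model as a JSON container
#'
#' Stores K, the standardization statistics, the standardized training
#' features and labels, and the SVM hyperparameters. [read_knnsvm()]
#' refits the pairwise SVMs from the stored training set, which is
#' deterministic, so a written-and-reloaded model predicts identically.
#'
#' @param model a `knnsvm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_knnsvm <- function(model, path) {
  jsonlite::write_json(
    list(type = "knnsvm_model", k = model$k,
         center = model$standardize$center,
         scale = model$standardize$scale,
         train_features = model$train_features,
         train_labels = model$train_labels,
         params = model$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a KNN-SVM model written by [write_knnsvm()]
#' @param path input path.
#' @return A `knnsvm_model`.
#' @export
read_knnsvm <- function(path) {
  obj <- jsonlite::fromJSON(path)
  model <- knnsvm_fit(obj$train_features, obj$train_labels, k = obj$k,
                      kernel = obj$params$kernel, cost = obj$params$cost,
                      standardize = FALSE,
                      weight_mode = obj$params$weight_mode)
  model$standardize <- list(center = obj$center, scale = obj$scale)
  model$params$standardize <- obj$params$standardize
  model
}
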