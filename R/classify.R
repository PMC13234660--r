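#' Cosine similarity of two feature vectors
#'
#' For nonzero vectors x and y, `S_c(x, y) = (x . y) / (||x|| ||y||)`, lying
#' in \[-1, 1\]; for the nonnegative mean-RGB vectors of this domain it lies
#' in \[0, 1\]. Symmetric and invariant under positive scaling of either
#' argument. Zero vectors and length mismatches are rejected.
#'
#' @param x,y Numeric vectors of equal length, each with at least one nonzero
#'   entry.
#' @return Numeric scalar in \[-1, 1\].
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # cos 45 degrees
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)), call. = FALSE)
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("cosine similarity requires nonzero feature vectors", call. = FALSE)
  }
  sum(x * y) / (nx * ny)
}

#' Fit per-category average feature vectors
#'
#' The model for each category is simply the element-wise arithmetic mean of
#' that category's training feature vectors (its centroid). No iterative
#' training is involved; classification assigns the centroid with maximum
#' cosine similarity.
#'
#' @param training Feature tibble from [featurize_images()] with columns
#'   `label` and `feature`; every label needs at least one vector and all
#'   vectors one common length.
#' @return An object of class `voc_model`: centroid matrix (one row per
#'   category, canonically ordered), per-label training counts, and the
#'   grid/region metadata carried by the features.
#' @export
fit_centroids <- function(training) {
  stopifnot(is.data.frame(training), all(c("label", "feature") %in% names(training)))
  if (nrow(training) == 0L) stop("empty training set", call. = FALSE)
  if (any(is.na(training$label))) stop("all training images must be labeled", call. = FALSE)
  lens <- lengths(training$feature)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("inconsistent feature lengths: %s",
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  }
  labels <- order_labels(unique(training$label))
  cent <- t(vapply(labels, function(lab) {
    vecs <- training$feature[training$label == lab]
    colMeans(do.call(rbind, vecs))
  }, numeric(lens[[1L]])))
  if (any(rowSums(cent^2) == 0)) stop("a category centroid is the zero vector", call. = FALSE)
  structure(
    list(
      centroids = cent,
      counts = vapply(labels, function(lab) sum(training$label == lab), 0L),
      grid = unique(training[["grid"]] %||% NA_character_),
      region = unique(training[["region"]] %||% NA_character_)
    ),
    class = "voc_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.voc_model <- function(x, ...) {
  cat(sprintf("<voc_model> %d categories, feature length %d (region %s, grid %s)\n",
              nrow(x$centroids), ncol(x$centroids),
              paste(x$region, collapse = "+"), paste(x$grid, collapse = "+")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted category model
#'
#' @param x A `voc_model`.
#' @param ... Unused.
#' @return One row per category: `label`, `n_train`, `centroid_norm`.
#' @method tidy voc_model
#' @export
tidy.voc_model <- function(x, ...) {
  tibble::tibble(
    label = rownames(x$centroids),
    n_train = as.integer(x$counts),
    centroid_norm = sqrt(rowSums(x$centroids^2))
  )
}

#' @rdname tidy.voc_model
#' @method glance voc_model
#' @export
glance.voc_model <- function(x, ...) {
  tibble::tibble(
    n_categories = nrow(x$centroids),
    n_features = ncol(x$centroids),
    n_train = sum(x$counts),
    region = paste(x$region, collapse = "+"),
    grid = paste(x$grid, collapse = "+")
  )
}

# rows: test vectors (matrix m x n), cols: centroids; plain cosine via
# normalised cross-product
similarity_to_centroids <- function(X, model) {
  C <- model$centroids
  if (ncol(X) != ncol(C)) {
    stop(sprintf("feature length %d does not match model length %d",
                 ncol(X), ncol(C)), call. = FALSE)
  }
  nx <- sqrt(rowSums(X^2)); nc <- sqrt(rowSums(C^2))
  if (any(nx == 0)) stop("cosine similarity requires nonzero feature vectors", call. = FALSE)
  S <- (X / nx) %*% t(C / nc)
  colnames(S) <- rownames(C)
  S
}

#' Classify feature vectors by maximum cosine similarity
#'
#' Each test vector is assigned the category whose centroid yields the
#' maximum cosine similarity. Ties (measure-zero on real data) break to the
#' first category in canonical label order, deterministically.
#'
#' @param data Feature tibble (columns `source_id`, `feature`, optionally
#'   `label`) or a single numeric feature vector.
#' @param model A `voc_model` from [fit_centroids()].
#' @return For a tibble: the input plus columns `predicted` and `similarity`
#'   (list-column of named per-category similarity rows). For a single
#'   vector: a list with `label` and the named `similarity` row.
#' @export
classify <- function(data, model) {
  stopifnot(inherits(model, "voc_model"))
  if (is.numeric(data)) {
    S <- similarity_to_centroids(matrix(data, nrow = 1L), model)
    return(list(label = colnames(S)[which.max(S[1L, ])], similarity = S[1L, ]))
  }
  stopifnot(is.data.frame(data), "feature" %in% names(data))
  if (nrow(data) == 0L) stop("empty test set", call. = FALSE)
  X <- do.call(rbind, data$feature)
  S <- similarity_to_centroids(X, model)
  pred <- colnames(S)[max.col(S, ties.method = "first")]
  out <- data
  out$predicted <- pred
  out$similarity <- lapply(seq_len(nrow(S)), function(i) S[i, ])
  tibble::as_tibble(out)
}

#' Normalize a similarity matrix for display
#'
#' Rescales raw cosine similarities, which on plasma images all sit very close
#' to 1, to `S_norm = (S_c - S_min) / (1 - S_min)` where `S_min` is the
#' minimum over the entire matrix of one classification test (all test images
#' by all categories, not per row). The minimum entry maps exactly to 0, any
#' entry equal to 1 stays 1, and the map is affine so similarity rank order
#' is unchanged.
#'
#' @param S Numeric matrix of raw cosine similarities.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
normalize_similarities <- function(S) {
  if (length(S) == 0L) stop("empty similarity matrix", call. = FALSE)
  s_min <- min(S)
  if (s_min == 1) {
    stop("all similarities equal 1: normalization is degenerate", call. = FALSE)
  }
  (S - s_min) / (1 - s_min)
}

#' Evaluate a model on a labeled test set
#'
#' Classifies every test vector, reports accuracy (the fraction of test
#' images assigned their true category), the misidentified images with their
#' predicted categories, the raw and display-normalized similarity matrices,
#' and the wall time spent classifying. Test labels absent from the model are
#' still classified into the closest present category and flagged.
#'
#' @param test Feature tibble with columns `source_id`, `label`, `feature`.
#' @param model A `voc_model`.
#' @return An object of class `voc_eval`; see [tidy.voc_eval()] and
#'   [glance.voc_eval()].
#' @export
evaluate <- function(test, model) {
  stopifnot(is.data.frame(test), nrow(test) > 0L,
            all(c("source_id", "label", "feature") %in% names(test)))
  t0 <- proc.time()[["elapsed"]]
  X <- do.call(rbind, test$feature)
  S <- similarity_to_centroids(X, model)
  pred <- colnames(S)[max.col(S, ties.method = "first")]
  elapsed <- proc.time()[["elapsed"]] - t0
  rownames(S) <- test$source_id
  correct <- pred == test$label
  predictions <- tibble::tibble(
    source_id = test$source_id,
    label = test$label,
    predicted = pred,
    correct = correct,
    similarity = S[cbind(seq_along(pred), match(pred, colnames(S)))],
    label_in_model = test$label %in% rownames(model$centroids)
  )
  structure(
    list(
      predictions = predictions,
      accuracy = mean(correct),
      accuracy_pct = round(100 * mean(correct), 1L),
      misclassified = predictions[!predictions$correct, c("source_id", "label", "predicted")],
      similarity = S,
      similarity_norm = tryCatch(normalize_similarities(S), error = function(e) NULL),
      time_s = elapsed,
      model = model
    ),
    class = "voc_eval"
  )
}

#' @export
print.voc_eval <- function(x, ...) {
  cat(sprintf("<voc_eval> accuracy %.1f%% (%d/%d correct), %d categories\n",
              x$accuracy_pct, sum(x$predictions$correct), nrow(x$predictions),
              nrow(x$model$centroids)))
  if (nrow(x$misclassified) > 0L) {
    cat("misidentified:\n")
    print(as.data.frame(x$misclassified), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy / glance an evaluation
#'
#' `tidy()` returns per-image predictions; `glance()` a one-row summary with
#' the exact accuracy fraction, the one-decimal percentage, and the wall time.
#'
#' @param x A `voc_eval` from [evaluate()].
#' @param ... Unused.
#' @method tidy voc_eval
#' @export
tidy.voc_eval <- function(x, ...) x$predictions

#' @rdname tidy.voc_eval
#' @method glance voc_eval
#' @export
glance.voc_eval <- function(x, ...) {
  tibble::tibble(
    n_test = nrow(x$predictions),
    n_correct = sum(x$predictions$correct),
    accuracy = x$accuracy,
    accuracy_pct = x$accuracy_pct,
    n_misclassified = nrow(x$misclassified),
    time_s = x$time_s
  )
}

#' Per-category similarity statistics
#'
#' For each category, the cosine similarities of its images (typically the
#' pooled test and training sets) to its own centroid are summarised as mean,
#' maximum and the difference (maximum - mean). On real data the differences
#' for pure helium plasma are 1-2 orders of magnitude smaller than for VOC
#' plasma, reflecting the much tighter within-category similarity of helium
#' images.
#'
#' @param data Feature tibble with columns `label` and `feature`; every label
#'   must be present in the model.
#' @param model A `voc_model`.
#' @return Tibble with columns `label`, `n`, `mean`, `max`, `diff`.
#' @export
category_similarity_stats <- function(data, model) {
  stopifnot(is.data.frame(data), all(c("label", "feature") %in% names(data)))
  missing_labels <- setdiff(unique(data$label), rownames(model$centroids))
  if (length(missing_labels) > 0L) {
    stop(sprintf("label(s) absent from model: %s",
                 paste(missing_labels, collapse = ", ")), call. = FALSE)
  }
  sims <- vapply(seq_len(nrow(data)), function(i) {
    cosine_similarity(data$feature[[i]], model$centroids[data$label[[i]], ])
  }, 0)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(label = data$label, sim = sims), .data$label),
    n = dplyr::n(),
    mean = mean(.data$sim),
    max = max(.data$sim),
    diff = max(.data$sim) - mean(.data$sim),
    .groups = "drop"
  )
}

#' Write / read a fitted model as JSON
#'
#' @param model A `voc_model`.
#' @param path Output JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "voc_model"))
  obj <- list(
    labels = rownames(model$centroids),
    counts = as.integer(model$counts),
    grid = model$grid,
    region = model$region,
    centroids = unname(apply(model$centroids, 1L, identity, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- if (is.list(obj$centroids)) do.call(rbind, obj$centroids) else obj$centroids
  if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1L)
  rownames(cent) <- obj$labels
  structure(
    list(centroids = cent,
         counts = stats::setNames(as.integer(obj$counts), obj$labels),
         grid = obj$grid, region = obj$region),
    class = "voc_model"
  )
}
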