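# Feature-vector assembly from map cells and leave-one-session-out kNN.
#
# A feature set is a contiguous run of 1-3 map levels crossed with 1-3
# measures. The classes are the segments at the finest selected level; each
# class's feature vector stacks the normalised value of its own cell with
# the values of its ancestor cells at the coarser selected levels, for each
# selected measure. Classification is plain kNN (Euclidean, majority vote,
# ties broken toward the lowest class index) with one cross-validation fold
# per participant-session.

#' Define a feature set
#'
#' @param levels Contiguous run of 1-3 map levels out of 1..4 (finest level
#'   first or in any order; sorted internally). Levels are named by their
#'   segment length in ms in the set name, e.g. `set64_128_256`.
#' @param measures Character subset of `c("ApEn", "FuzEn", "LLE")`.
#' @param nss_ms,nemr_ms Map geometry.
#' @return An object of class `"feature_spec"`: a list with the levels,
#'   measures, the derived set `name`, feature dimension `n_features`
#'   (`|levels| * |measures|`) and class count `n_classes` (segments at the
#'   finest level).
#' @export
#' @examples
#' feature_spec(1:3, c("ApEn", "FuzEn", "LLE")) # set64_128_256_..., 9 features
feature_spec <- function(levels, measures = c("ApEn", "FuzEn", "LLE"),
                         nss_ms = 64, nemr_ms = 1024) {
  levels <- sort(unique(as.integer(levels)))
  if (length(levels) < 1L || length(levels) > 3L ||
      any(levels < 1L) || any(levels > map_levels(nemr_ms, nss_ms) - 1L) ||
      (length(levels) > 1L && any(diff(levels) != 1L))) {
    stop("`levels` must be a contiguous run of 1-3 levels out of 1..",
         map_levels(nemr_ms, nss_ms) - 1L, ".", call. = FALSE)
  }
  measures <- match.arg(measures, c("ApEn", "FuzEn", "LLE"),
                        several.ok = TRUE)
  lens <- nss_ms * 2^(levels - 1)
  name <- paste0("set", paste(lens, collapse = "_"), "_",
                 paste(measures, collapse = "_"))
  structure(list(levels = levels, measures = measures, name = name,
                 nss_ms = nss_ms, nemr_ms = nemr_ms,
                 n_features = length(levels) * length(measures),
                 n_classes = class_count(min(levels), nss_ms, nemr_ms)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec> ", x$name, "\n",
      "  levels: ", paste(x$levels, collapse = ", "),
      "  measures: ", paste(x$measures, collapse = ", "), "\n",
      "  features: ", x$n_features, "  classes: ", x$n_classes, "\n",
      sep = "")
  invisible(x)
}

#' Assemble labelled feature vectors from normalised maps
#'
#' Each series contributes one row per class (segment at the finest selected
#' level). The row's features are, for every selected measure, the
#' normalised value of the class's own cell plus the values of its ancestor
#' cells at each coarser selected level (the cell whose window contains the
#' class segment). Rows with any missing feature are dropped, with the count
#' reported in the `dropped` attribute.
#'
#' @param maps Normalised long map tibble (must carry `value_norm`; see
#'   [normalize_maps()]). Use `value_col = "value"` to assemble raw values,
#'   e.g. for fold-safe normalisation inside [knn_loso_cv()].
#' @param spec A [feature_spec()].
#' @param value_col Column to take feature values from (default
#'   `"value_norm"`).
#' @return A tibble of class `"labeled_features"`: identity columns, `group`
#'   (participant-session, the cross-validation unit), `label` (class index,
#'   1 = earliest segment), and one `<measure>_<ms>` column per feature.
#' @export
assemble_features <- function(maps, spec, value_col = "value_norm") {
  stopifnot(inherits(spec, "feature_spec"))
  if (!value_col %in% names(maps)) {
    stop("Column `", value_col, "` not found in `maps`; run normalize_maps() ",
         "first or set `value_col`.", call. = FALSE)
  }
  l_x <- min(spec$levels)
  ncl <- spec$n_classes
  wanted <- maps |>
    dplyr::filter(.data$measure %in% spec$measures,
                  .data$level %in% spec$levels)

  # ancestor of class c at level l: index ceiling(c / 2^(l - l_x))
  key <- tidyr::expand_grid(label = seq_len(ncl), level = spec$levels,
                            measure = spec$measures) |>
    dplyr::mutate(index = ceiling(.data$label / 2^(.data$level - l_x)),
                  feature = paste0(.data$measure, "_",
                                   spec$nss_ms * 2^(.data$level - 1)))

  long <- wanted |>
    dplyr::select(dplyr::all_of(series_id_cols), "measure", "level", "index",
                  value = dplyr::all_of(value_col)) |>
    dplyr::inner_join(key, by = c("measure", "level", "index"),
                      relationship = "many-to-many")

  feat_cols <- unique(key$feature)
  wide <- long |>
    dplyr::select(dplyr::all_of(series_id_cols), "label", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value") |>
    dplyr::mutate(group = paste(.data$participant, .data$session, sep = "_"),
                  .after = dplyr::all_of(series_id_cols)) |>
    dplyr::arrange(.data$participant, .data$session, .data$point, .data$label)

  complete <- stats::complete.cases(wide[, feat_cols, drop = FALSE])
  dropped <- sum(!complete)
  if (dropped > 0L) {
    message(dropped, " feature row(s) dropped due to missing map cells.")
  }
  out <- wide[complete, c(series_id_cols, "group", "label", feat_cols)]
  attr(out, "spec") <- spec
  attr(out, "dropped") <- dropped
  class(out) <- c("labeled_features", class(out))
  out
}

feature_columns <- function(data) {
  setdiff(names(data), c(series_id_cols, "group", "label"))
}

# Deterministic kNN: Euclidean distance, majority vote, ties in distance
# resolved by training-row order, ties in votes toward the lowest class.
knn_predict <- function(train_x, train_y, test_x, k, n_classes) {
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- tabulate(train_y[nn], nbins = n_classes)
    which.max(votes) # first max = lowest class index among ties
  })
}

#' Leave-one-session-out kNN cross-validation
#'
#' One fold per `group` (participant-session): all rows of the group form
#' the test set, every other row the training set. Prediction is k-nearest
#' neighbours with Euclidean distance and majority vote; tied votes go to
#' the lowest class index, so the whole procedure is deterministic.
#'
#' @param data A `labeled_features` tibble from [assemble_features()].
#' @param k Number of neighbours; must be smaller than the training size of
#'   every fold. The study grid is `c(3, 7, 15, 31, 63, 127, 255)`.
#' @param accuracy Per-class accuracy pooled over folds (`"pooled"`,
#'   default) or averaged per fold then across folds (`"per_fold"`).
#' @param normalization `"as_is"` uses the feature values as supplied
#'   (normally min-max normalised over the full dataset before splitting,
#'   matching the study pipeline); `"fold_safe"` re-fits the min-max rescale
#'   on each fold's training rows only — the leakage-free alternative
#'   (assemble the features from raw values with `value_col = "value"`).
#' @return An object of class `"knn_report"`: list with `k`, `spec`
#'   (feature-set name), `n_folds`, `confusion` (true x predicted count
#'   matrix, pooled), and `per_class` (tibble of class index, segment
#'   window, n, accuracy).
#' @export
knn_loso_cv <- function(data, k,
                        accuracy = c("pooled", "per_fold"),
                        normalization = c("as_is", "fold_safe")) {
  accuracy <- match.arg(accuracy)
  normalization <- match.arg(normalization)
  spec <- attr(data, "spec")
  if (!inherits(spec, "feature_spec")) spec <- NULL # e.g. readr col_spec
  feat <- feature_columns(data)
  groups <- unique(data$group)
  if (length(groups) < 2L) {
    stop("Cross-validation needs at least two groups (participant-sessions).",
         call. = FALSE)
  }
  k <- as.integer(k)
  n_classes <- if (!is.null(spec)) spec$n_classes else max(data$label)
  x <- as.matrix(data[, feat, drop = FALSE])
  y <- as.integer(data$label)

  confusion <- matrix(0L, n_classes, n_classes,
                      dimnames = list(true = seq_len(n_classes),
                                      predicted = seq_len(n_classes)))
  fold_acc <- matrix(NA_real_, length(groups), n_classes)
  for (gi in seq_along(groups)) {
    te <- data$group == groups[gi]
    if (k >= sum(!te)) {
      stop("k = ", k, " is not smaller than the training size (",
           sum(!te), ") of fold ", groups[gi], ".", call. = FALSE)
    }
    tr_x <- x[!te, , drop = FALSE]; te_x <- x[te, , drop = FALSE]
    if (normalization == "fold_safe") {
      for (j in seq_len(ncol(tr_x))) {
        rng <- range(tr_x[, j])
        span <- if (diff(rng) > 0) diff(rng) else 1
        te_x[, j] <- (te_x[, j] - rng[1]) / span
        tr_x[, j] <- (tr_x[, j] - rng[1]) / span
      }
    }
    pred <- knn_predict(tr_x, y[!te], te_x, k, n_classes)
    truth <- y[te]
    for (i in seq_along(pred)) {
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    }
    for (cl in unique(truth)) {
      fold_acc[gi, cl] <- mean(pred[truth == cl] == cl)
    }
  }

  n_per_class <- rowSums(confusion)
  acc <- if (accuracy == "pooled") {
    ifelse(n_per_class > 0, diag(confusion) / n_per_class, NA_real_)
  } else {
    colMeans(fold_acc, na.rm = TRUE)
  }
  l_x <- if (!is.null(spec)) min(spec$levels) else 1L
  nss <- if (!is.null(spec)) spec$nss_ms else 64
  nemr <- if (!is.null(spec)) spec$nemr_ms else 1024
  seg <- segment_bounds(rep(l_x, n_classes), seq_len(n_classes),
                        nss_ms = nss, nemr_ms = nemr)
  per_class <- tibble::tibble(
    class = seq_len(n_classes),
    segment = paste0(seg$start_ms, "-", seg$end_ms),
    n = as.integer(n_per_class),
    accuracy = as.numeric(acc)
  )
  structure(list(k = k,
                 spec = if (!is.null(spec)) spec$name else NA_character_,
                 n_folds = length(groups),
                 accuracy_mode = accuracy,
                 confusion = confusion,
                 per_class = per_class),
            class = "knn_report")
}

#' @export
print.knn_report <- function(x, ...) {
  cat("<knn_report> ", x$spec, "  k = ", x$k, "  folds = ", x$n_folds,
      "  (", x$accuracy_mode, " accuracy)\n", sep = "")
  print(x$per_class, n = nrow(x$per_class))
  invisible(x)
}

#' Tidy a kNN cross-validation report
#'
#' @param x A `knn_report` from [knn_loso_cv()].
#' @param ... Unused.
#' @return Per-class tibble: `spec`, `k`, `class`, `segment`, `n`,
#'   `accuracy`.
#' @method tidy knn_report
#' @export
tidy.knn_report <- function(x, ...) {
  dplyr::mutate(x$per_class, spec = x$spec, k = x$k,
                .before = 1L)
}

#' One-row summary of a kNN cross-validation report
#'
#' @param x A `knn_report`.
#' @param ... Unused.
#' @return Tibble with `spec`, `k`, `n_folds`, `n`, `accuracy` (overall
#'   fraction of correctly classified samples).
#' @method glance knn_report
#' @export
glance.knn_report <- function(x, ...) {
  tibble::tibble(spec = x$spec, k = x$k, n_folds = x$n_folds,
                 n = sum(x$confusion),
                 accuracy = sum(diag(x$confusion)) / sum(x$confusion))
}

#' Per-segment accuracy table across feature sets
#'
#' Mirrors the study's result tables: rows are the first
#' `first_n_segments` classes (earliest time windows), columns the feature
#' sets, cells the per-class accuracy.
#'
#' @param reports List of `knn_report` objects (one per feature set).
#' @param first_n_segments How many leading segments to keep (default 4);
#'   `Inf` keeps all.
#' @return A tibble: `segment` plus one column per report's set name.
#' @export
accuracy_table <- function(reports, first_n_segments = 4) {
  if (inherits(reports, "knn_report")) reports <- list(reports)
  rows <- purrr::map(reports, function(r) {
    dplyr::mutate(r$per_class, spec = r$spec)
  })
  long <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$class <= first_n_segments)
  tidyr::pivot_wider(long[, c("class", "segment", "spec", "accuracy")],
                     names_from = "spec", values_from = "accuracy") |>
    dplyr::arrange(.data$class) |>
    dplyr::select(-"class")
}
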