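make_features <- function(n_groups = 8, n_classes = 16, sd = 0.01,
                          seed = 1, shuffle = FALSE) {
  # one synthetic "series" per group, feature = class index + noise
  set.seed(seed)
  rows <- tidyr::expand_grid(participant = seq_len(n_groups), session = 1L,
                             point = 1L, label = seq_len(n_classes))
  rows$group <- paste(rows$participant, rows$session, sep = "_")
  rows$f1 <- rows$label / n_classes + rnorm(nrow(rows), 0, sd)
  if (shuffle) rows$label <- sample(rows$label)
  out <- rows[, c("participant", "session", "point", "group", "label", "f1")]
  class(out) <- c("labeled_features", class(out))
  out
}

test_that("feature specs carry the documented dimensions and class counts", {
  s9 <- feature_spec(1:3, c("ApEn", "FuzEn", "LLE"))
  expect_equal(s9$n_features, 9L)
  expect_equal(s9$n_classes, 16L)
  expect_equal(s9$name, "set64_128_256_ApEn_FuzEn_LLE")

  s6 <- feature_spec(2:3, c("ApEn", "FuzEn", "LLE"))
  expect_equal(s6$n_features, 6L)
  expect_equal(s6$n_classes, 8L)

  s1 <- feature_spec(1, "ApEn")
  expect_equal(s1$n_features, 1L)
  expect_equal(s1$n_classes, 16L)
  expect_equal(s1$name, "set64_ApEn")

  expect_error(feature_spec(c(1, 3)), "contiguous")
  expect_error(feature_spec(integer(0)), "contiguous")
  expect_error(feature_spec(1:4), "contiguous")
  expect_error(feature_spec(5), "contiguous")
})

test_that("assembled features stack each class's cell with its ancestors", {
  d <- tiny_dataset(seed = 17)
  maps <- normalize_maps(build_maps(d, list(apen_params(), fuzen_params())))
  spec <- feature_spec(1:3, c("ApEn", "FuzEn"))
  lf <- assemble_features(maps, spec)

  n_series <- nrow(dplyr::distinct(d, participant, session, point))
  expect_equal(nrow(lf), n_series * 16L)
  feat_cols <- setdiff(names(lf),
                       c("participant", "session", "point", "group", "label"))
  expect_equal(length(feat_cols), 6L)
  expect_true(all(as.matrix(lf[, feat_cols]) >= 0 &
                    as.matrix(lf[, feat_cols]) <= 1))

  # spot-check the ancestor lookup: class 5 at level 3 sits in cell
  # ceiling(5 / 4) = 2
  row5 <- lf[lf$participant == 1 & lf$session == 1 & lf$point == 1 &
               lf$label == 5, ]
  cell <- maps$value_norm[maps$participant == 1 & maps$session == 1 &
                            maps$point == 1 & maps$measure == "ApEn" &
                            maps$level == 3 & maps$index == 2]
  expect_equal(row5$ApEn_256, cell)

  # fully missing map contributes no rows
  maps_na <- maps
  maps_na$value_norm[maps_na$participant == 1 & maps_na$session == 1 &
                       maps_na$point == 1 & maps_na$level == 1 &
                       maps_na$index == 1 & maps_na$measure == "ApEn"] <- NA
  expect_message(lf2 <- assemble_features(maps_na, spec), "dropped")
  expect_equal(nrow(lf2), n_series * 16L - 1L)
})

test_that("leave-one-session-out kNN is deterministic, fold-exclusive and
          perfect on separable classes", {
  lf <- make_features(n_groups = 6, sd = 0.005)
  rep1 <- knn_loso_cv(lf, k = 3)
  expect_equal(rep1$n_folds, 6L)
  expect_true(all(rep1$per_class$accuracy == 1))
  expect_equal(sum(rep1$confusion), nrow(lf))
  # rows of the confusion matrix sum to per-class test counts
  expect_equal(unname(rowSums(rep1$confusion)), rep(6L, 16L))

  rep2 <- knn_loso_cv(lf, k = 3)
  expect_identical(rep1$confusion, rep2$confusion)

  expect_error(knn_loso_cv(lf, k = 200), "training size")
  one_group <- lf[lf$group == "1_1", ]
  class(one_group) <- class(lf)
  expect_error(knn_loso_cv(one_group, k = 3), "two groups")
})

test_that("label-permuted features classify at chance level", {
  n_classes <- 16
  accs <- sapply(1:50, function(s) {
    lf <- make_features(n_groups = 6, n_classes = n_classes, sd = 0.3,
                        seed = s, shuffle = TRUE)
    generics::glance(knn_loso_cv(lf, k = 7))$accuracy
  })
  # binomial 99% band around 1/16 for n = 50 * 96 pooled predictions
  n_tot <- 50 * 6 * 16
  p <- 1 / n_classes
  half <- 2.58 * sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(mean(accs) - p), half + 0.01)
})

test_that("tidy, glance and the accuracy table project the report
          faithfully", {
  lf <- make_features(n_groups = 5, sd = 0.02)
  rep1 <- knn_loso_cv(lf, k = 3)
  td <- generics::tidy(rep1)
  expect_equal(nrow(td), 16L)
  expect_named(td, c("spec", "k", "class", "segment", "n", "accuracy"))
  gl <- generics::glance(rep1)
  expect_equal(gl$accuracy,
               sum(diag(rep1$confusion)) / sum(rep1$confusion))

  tab <- accuracy_table(list(rep1), first_n_segments = 4)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab[[2]], rep1$per_class$accuracy[1:4])

  # CSV round trip at 6 decimals
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(tab,
                                 dplyr::across(-segment, ~round(.x, 6))), f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back)[[2]], round(tab[[2]], 6))
})

test_that("fold-safe normalisation rescales with training-fold ranges only", {
  d <- tiny_dataset(seed = 19)
  maps <- normalize_maps(build_maps(d, apen_params()))
  spec <- feature_spec(1, "ApEn")
  raw <- assemble_features(maps, spec, value_col = "value")
  r_pooled <- knn_loso_cv(assemble_features(maps, spec), k = 3)
  r_safe <- knn_loso_cv(raw, k = 3, normalization = "fold_safe")
  expect_s3_class(r_safe, "knn_report")
  expect_equal(dim(r_safe$confusion), dim(r_pooled$confusion))
})
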