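test_that("map geometry: level count, cell counts, segment windows", {
  expect_equal(map_levels(1024, 64), 5L)
  expect_error(map_levels(1000, 64), "power of two")

  counts <- sapply(1:5, function(l) 1024 / (64 * 2^(l - 1)))
  expect_equal(counts, c(16, 8, 4, 2, 1))

  b <- segment_bounds(1, 3)
  expect_equal(c(b$start_ms, b$end_ms), c(128, 192))
  b <- segment_bounds(2, 2)
  expect_equal(c(b$start_ms, b$end_ms, b$length_ms), c(128, 256, 128))
  b <- segment_bounds(5, 1)
  expect_equal(c(b$start_ms, b$end_ms), c(0, 1024))
  expect_error(segment_bounds(6, 1), "level")
  expect_error(segment_bounds(2, 9), "out of range")

  # parent-child coverage: each parent window is exactly its two children
  for (l in 1:4) {
    n_seg <- 1024 / (64 * 2^l)
    for (i in seq_len(n_seg)) {
      parent <- segment_bounds(l + 1, i)
      kids <- segment_bounds(l, c(2 * i - 1, 2 * i))
      expect_equal(parent$start_ms, kids$start_ms[1])
      expect_equal(parent$end_ms, kids$end_ms[2])
      expect_equal(kids$end_ms[1], kids$start_ms[2])
    }
  }
})

test_that("class counts follow N_cl = NEMr / (Nss * 2^(lX-1))", {
  expect_equal(class_count(1:4), c(16L, 8L, 4L, 2L))
})

test_that("build_maps evaluates each measure on exactly its window", {
  d <- tiny_dataset(n_participants = 1, n_sessions = 1, n_points = 1,
                    seed = 7)
  maps <- build_maps(d, list(apen_params(), fuzen_params()))
  expect_equal(nrow(maps), 2 * 31)

  u <- d$velocity
  r_a <- 0.2 * series_sd(u)
  # cell (5,1) is the whole series
  top <- maps$value[maps$measure == "ApEn" & maps$level == 5]
  expect_equal(top, approximate_entropy(u, 2, r_a), tolerance = 1e-12)
  # cell (1,3) is samples 129..192 with the whole-series tolerance
  c13 <- maps$value[maps$measure == "ApEn" & maps$level == 1 & maps$index == 3]
  expect_equal(c13, approximate_entropy(u[129:192], 2, r_a),
               tolerance = 1e-12)
  c22 <- maps$value[maps$measure == "FuzEn" & maps$level == 2 &
                      maps$index == 2]
  expect_equal(c22, fuzzy_entropy(u[129:256], 2, 2, 0.075 * series_sd(u)),
               tolerance = 1e-12)

  # determinism: same series, same params -> identical map
  maps2 <- build_maps(d, list(apen_params(), fuzen_params()))
  expect_identical(maps$value, maps2$value)

  # constant series: entropy cells are zero when given an explicit
  # segment-scope tolerance would fail, whole-series SD is zero -> all NA
  dc <- d
  dc$velocity <- 1
  expect_warning(mc <- build_maps(dc, apen_params()), "could not")
  expect_true(all(is.na(mc$value)))
})

test_that("averaging maps is cell-wise over non-missing values", {
  d <- tiny_dataset(seed = 31)  # 8 series
  maps <- build_maps(d, apen_params())
  avg <- average_maps(maps)
  expect_equal(nrow(avg), 31L)
  # averaged twice over identical copies = same map
  two <- dplyr::bind_rows(
    dplyr::mutate(maps, participant = 100),
    dplyr::mutate(maps, participant = 200))
  avg2 <- average_maps(two)
  expect_equal(dplyr::arrange(avg2, level, index)$value,
               dplyr::arrange(avg, level, index)$value, tolerance = 1e-12)
  # a cell missing in one input contributes the other value
  m1 <- maps
  one_cell <- m1$level == 1 & m1$index == 5 &
    m1$participant == m1$participant[1] & m1$session == m1$session[1] &
    m1$point == m1$point[1]
  m1$value[one_cell] <- NA
  avg3 <- average_maps(m1)
  v_others <- maps$value[maps$level == 1 & maps$index == 5 & !one_cell]
  expect_equal(avg3$value[avg3$level == 1 & avg3$index == 5],
               mean(v_others), tolerance = 1e-12)
})

test_that("min-max normalisation maps to [0,1], is invertible, and errors
          on degenerate input", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(c(0, 0.25, 1)), c(0, 0.25, 1))
  expect_error(normalize_minmax(c(3, 3, 3)), "Degenerate")

  set.seed(41)
  x <- rnorm(50)
  y <- normalize_minmax(x)
  expect_equal(y * (max(x) - min(x)) + min(x), x, tolerance = 1e-12)

  d <- tiny_dataset(seed = 43)
  maps <- build_maps(d, apen_params())
  nm <- normalize_maps(maps)
  expect_true(all(nm$value_norm >= 0 & nm$value_norm <= 1, na.rm = TRUE))
  # per (measure, level): min -> 0 and max -> 1 somewhere
  chk <- nm |>
    dplyr::group_by(measure, level) |>
    dplyr::summarise(lo = min(value_norm), hi = max(value_norm),
                     .groups = "drop")
  expect_true(all(abs(chk$lo) < 1e-12 & abs(chk$hi - 1) < 1e-12))
})

test_that("averaged synthetic maps show the saccade-window signature", {
  # batch-averaged form: entropy minima in the saccade window (level-1
  # cells 3-4, level-2 cell 2) and positive divergence in the latency cells
  d <- tiny_dataset(n_participants = 5, n_sessions = 2, n_points = 3,
                    seed = 53)
  maps <- build_maps(d)
  avg <- average_maps(maps)
  for (me in c("ApEn", "FuzEn")) {
    l1 <- dplyr::arrange(dplyr::filter(avg, measure == me, level == 1),
                         index)$value
    l2 <- dplyr::arrange(dplyr::filter(avg, measure == me, level == 2),
                         index)$value
    expect_setequal(order(l1)[1:2], c(3, 4))
    expect_equal(which.min(l2), 2L)
  }
  lle1 <- dplyr::arrange(dplyr::filter(avg, measure == "LLE", level == 1),
                         index)$value
  expect_true(all(lle1[1:2] > 0))

  # fixation cells (512-1024 ms) are more homogeneous than the
  # saccade-vs-fixation contrast
  ap <- dplyr::filter(avg, measure == "ApEn", level == 1)
  fix_vals <- ap$value[ap$index >= 9]
  sac_vals <- ap$value[ap$index %in% 3:4]
  fix_spread <- max(fix_vals) - min(fix_vals)
  contrast <- mean(fix_vals) - mean(sac_vals)
  expect_lt(fix_spread, contrast)
})
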