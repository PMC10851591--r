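test_that("threshold config validates its ranges", {
  expect_error(threshold_config(100, 50), "low threshold")
  expect_error(threshold_config(-1, 50), "\\[0, 255\\]")
  expect_error(threshold_config(0, 300), "\\[0, 255\\]")
  cfg <- threshold_config(50, 150)
  expect_identical(cfg$low, 50L)
  expect_identical(cfg$high, 150L)
})

test_that("threshold masks obey the inclusion chain H in L in T", {
  set.seed(11)
  dm <- random_dab_map(24)
  cfg <- threshold_config(60, 180)
  m <- apply_thresholds(dm, cfg)
  expect_true(all(!m$H | m$L))  # H subset of L
  expect_true(all(!m$L | m$T))  # L subset of T
  # degenerate window low == high collapses L and H
  m2 <- apply_thresholds(dm, threshold_config(90, 90))
  expect_identical(m2$L, m2$H)
  f2 <- compute_image_features(m2, dm)
  expect_identical(f2$pct_area_extra, 0)
  # uniform zero intensity gives empty masks
  dm0 <- new_dab_map(matrix(0L, 8, 8), matrix(TRUE, 8, 8))
  m0 <- apply_thresholds(dm0, threshold_config(10, 20))
  expect_false(any(m0$L) || any(m0$H))
})

test_that("hand-computed 4x4 example reproduces all 12 parameters", {
  intensity <- matrix(0L, 4, 4)
  intensity[c(1, 2, 3)] <- 100L
  intensity[4] <- 200L
  dm <- new_dab_map(intensity, matrix(TRUE, 4, 4))
  f <- compute_image_features(apply_thresholds(dm, threshold_config(50, 150)),
                              dm)
  expect_equal(f$pct_area_total, 4 / 16)
  expect_equal(f$pct_area_intra, 1 / 16)
  expect_equal(f$pct_area_extra, 3 / 16)
  expect_equal(f$intra_extra_ratio, 1 / 3)
  expect_equal(f$mean_dab_total, 125)
  expect_equal(f$median_dab_total, 100)
  expect_equal(f$mode_dab_total, 100)
  expect_equal(f$mean_intra, 200)
  expect_equal(f$mean_intensity_tissue, 500 / 16)
  expect_equal(f$mean_intensity_intra_tissue, 200 / 16)
  expect_false(f$ratio_flagged)
})

test_that("degenerate masks follow the documented conventions", {
  # saturated: everything above both thresholds -> extra empty, flagged
  dm <- new_dab_map(matrix(255L, 4, 4), matrix(TRUE, 4, 4))
  f <- compute_image_features(apply_thresholds(dm, threshold_config(1, 1)),
                              dm)
  expect_equal(f$pct_area_total, 1)
  expect_equal(f$pct_area_intra, 1)
  expect_equal(f$pct_area_extra, 0)
  expect_true(f$ratio_flagged)
  expect_equal(f$intra_extra_ratio, 16)  # |H| / max(|L|-|H|, 1)
  # blank section: empty L -> all statistics zero
  dm0 <- new_dab_map(matrix(0L, 4, 4), matrix(TRUE, 4, 4))
  f0 <- compute_image_features(apply_thresholds(dm0,
                                                threshold_config(50, 150)),
                               dm0)
  for (col in feature_names()) expect_equal(f0[[col]], 0)
  # no tissue at all is an error
  dmn <- new_dab_map(matrix(0L, 4, 4), matrix(FALSE, 4, 4))
  expect_error(compute_image_features(
    apply_thresholds(dmn, threshold_config(50, 150)), dmn), "no tissue")
})

test_that("features match the naive per-pixel oracle on random maps", {
  set.seed(21)
  for (rep in 1:25) {
    dm <- random_dab_map(16)
    lo <- sample(0:200, 1)
    hi <- lo + sample(0:55, 1)
    f <- compute_image_features(apply_thresholds(dm,
                                                 threshold_config(lo, hi)),
                                dm)
    ref <- naive_features(dm$intensity, dm$tissue, lo, hi)
    for (col in feature_names()) {
      expect_equal(f[[col]], ref[[col]], tolerance = 1e-12, label = col)
    }
  }
})

test_that("area fractions are additive and the ratio identity holds", {
  set.seed(31)
  for (rep in 1:20) {
    dm <- random_dab_map(16)
    lo <- sample(0:150, 1)
    f <- compute_image_features(
      apply_thresholds(dm, threshold_config(lo, lo + sample(0:100, 1))), dm)
    expect_equal(f$pct_area_total, f$pct_area_intra + f$pct_area_extra,
                 tolerance = 1e-12)
    if (f$pct_area_extra > 0)
      expect_equal(f$intra_extra_ratio * f$pct_area_extra, f$pct_area_intra,
                   tolerance = 1e-12)
  }
})

test_that("raising thresholds never increases the stained fractions", {
  set.seed(41)
  dm <- random_dab_map(24)
  lows <- c(0, 40, 80, 120, 160)
  tot <- sapply(lows, function(lo)
    compute_image_features(apply_thresholds(dm, threshold_config(lo, 200)),
                           dm)$pct_area_total)
  expect_true(all(diff(tot) <= 0))
  highs <- c(100, 140, 180, 220, 255)
  intra <- sapply(highs, function(hi)
    compute_image_features(apply_thresholds(dm, threshold_config(50, hi)),
                           dm)$pct_area_intra)
  expect_true(all(diff(intra) <= 0))
})

test_that("features are scale invariant: 2x2 tiling changes nothing", {
  set.seed(51)
  dm <- random_dab_map(16)
  tiled_int <- rbind(cbind(dm$intensity, dm$intensity),
                     cbind(dm$intensity, dm$intensity))
  tiled_tis <- rbind(cbind(dm$tissue, dm$tissue),
                     cbind(dm$tissue, dm$tissue))
  dm4 <- new_dab_map(tiled_int, tiled_tis)
  cfg <- threshold_config(60, 170)
  f1 <- compute_image_features(apply_thresholds(dm, cfg), dm)
  f4 <- compute_image_features(apply_thresholds(dm4, cfg), dm4)
  for (col in feature_names())
    expect_equal(f1[[col]], f4[[col]], tolerance = 1e-12, label = col)
})

test_that("patient aggregation is the fieldwise arithmetic mean", {
  set.seed(61)
  cfg <- threshold_config(60, 170)
  rows <- do.call(rbind, lapply(1:6, function(i) {
    dm <- random_dab_map(12)
    f <- compute_image_features(apply_thresholds(dm, cfg), dm)
    f$patient <- if (i <= 3) "A" else "B"
    f
  }))
  agg <- aggregate_patients(rows)
  expect_identical(sort(agg$patient), c("A", "B"))
  expect_identical(agg$n_images, c(3L, 3L))
  for (col in feature_names()) {
    manual <- tapply(rows[[col]], rows$patient, mean)
    expect_equal(agg[[col]], as.vector(manual[agg$patient]),
                 tolerance = 1e-12, label = col)
  }
  # identical inputs aggregate to themselves
  rows$patient <- "C"
  one <- rows[rep(1, 3), ]
  aggc <- aggregate_patients(one)
  expect_equal(aggc$pct_area_total, one$pct_area_total[1])
  # closed form
  df <- rows[1:3, ]
  df$pct_area_total <- c(0.1, 0.2, 0.3)
  expect_equal(aggregate_patients(df)$pct_area_total, 0.2)
  expect_error(aggregate_patients(rows[0, ]), "no image features")
})

test_that("feature tables round trip through TSV", {
  set.seed(71)
  cfg <- threshold_config(60, 170)
  dm <- random_dab_map(12)
  f <- compute_image_features(apply_thresholds(dm, cfg), dm)
  f$patient <- "P001"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(f, path)
  back <- read_feature_table(path)
  expect_equal(back$mean_dab_total, f$mean_dab_total, tolerance = 1e-9)
  expect_identical(back$patient, "P001")
})
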