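test_that("virtual feature rows carry anchors and objectives exactly", {
  cohort <- tiny_cohort(n = 3)
  p <- cohort$profiles[["1"]]
  rows <- rows_from_profile(p, cohort$pop$age[1], cohort$pop$lbm[1],
                            cohort$regimen)
  expect_equal(nrow(rows), 5)
  expect_equal(rows$target_time, c(5, 15, 30, 50, 100))
  expect_equal(unique(rows$cp_tinf), p$cp[p$times == 10])
  expect_equal(unique(rows$cp_4tinf), p$cp[p$times == 40])
  expect_equal(rows$y, p$cp[match(rows$target_time, p$times)])
  expect_equal(nrow(rows_from_profile(p, 40, 55, cohort$regimen,
                                      target_times = numeric(0))), 0)
  # a profile lacking a required time signals
  short <- simulate_profile(typical_params(cohort$model, 40, 55),
                            cohort$regimen, c(5, 10, 40))
  expect_error(rows_from_profile(short, 40, 55, cohort$regimen), "t = 15")
})

test_that("cohort feature table matches per-subject assembly and clustering anchors", {
  cohort <- tiny_cohort(n = 6)
  tab <- virtual_feature_table(cohort$pop, cohort$profiles, cohort$regimen)
  expect_equal(nrow(tab), 30)
  by_hand <- do.call(rbind, lapply(1:6, function(i) {
    rows_from_profile(cohort$profiles[[i]], cohort$pop$age[i],
                      cohort$pop$lbm[i], cohort$regimen)
  }))
  expect_equal(tab, by_hand, ignore_attr = TRUE)
  # anchors coincide with the clustering features under the shared regimen
  feats <- build_cluster_features(cohort$pop, cohort$profiles)
  expect_equal(unique(tab$cp_tinf), feats$cp10)
  expect_equal(unique(tab$cp_4tinf), feats$cp40)
})

test_that("fixed-time extraction picks exact samples when available", {
  rec <- exact_record()
  rows <- extract_fixed_times(rec)
  expect_equal(nrow(rows), 5)
  expect_equal(rows$target_time, c(5, 15, 30, 50, 100))
  expect_equal(unique(rows$cp_tinf), rec$samples$cp[rec$samples$time == 10])
  expect_equal(unique(rows$cp_4tinf), rec$samples$cp[rec$samples$time == 40])
  expect_equal(rows$time_group, c("5", "15", "30", "50", "100"))
})

test_that("nearest-sample matching prefers smaller gaps then earlier times", {
  base <- exact_record()
  # samples at 4.8 and 5.3 around grid point 5: 4.8 wins (gap 0.2 < 0.3)
  rec <- clinical_record(1, 40, 55, 227, 10,
                         times = c(4.8, 5.3, 10, 15, 30, 40, 50, 100),
                         cp = c(30, 31, base$samples$cp[base$samples$time %in%
                                                          c(10, 15, 30, 40, 50, 100)]))
  rows <- extract_fixed_times(rec)
  expect_equal(rows$target_time[rows$time_group == "5"], 4.8)
  # symmetric tie at 4.9/5.1: the earlier sample wins
  rec2 <- clinical_record(1, 40, 55, 227, 10,
                          times = c(4.9, 5.1, 10, 15, 30, 40, 50, 100),
                          cp = rec$samples$cp)
  rows2 <- extract_fixed_times(rec2)
  expect_equal(rows2$target_time[rows2$time_group == "5"], 4.9)
})

test_that("unmatched grid times are dropped and missing anchors signal", {
  base <- exact_record(times = c(5, 10, 15, 30, 40, 50))  # nothing near 100
  rows <- extract_fixed_times(base)
  expect_equal(nrow(rows), 4)                 # 50 survives, 100 dropped
  expect_false("100" %in% rows$time_group)
  no_anchor <- clinical_record(1, 40, 55, 227, 10, times = c(5, 100),
                               cp = c(30, 0.2))
  expect_error(extract_fixed_times(no_anchor), "anchor")
})

test_that("infusion-duration multiples build the scaled grid", {
  rec <- exact_record()
  # tinfcat = 10: the multiple grid coincides with the fixed grid
  expect_equal(extract_tinf_multiples(rec)$target_time, c(5, 15, 30, 50, 100))
  expect_equal(extract_tinf_multiples(rec)$time_group,
               c("0.5x", "1.5x", "3x", "5x", "10x"))
  rec20 <- exact_record(tinf = 20, times = c(10, 20, 30, 60, 80, 100, 200))
  rows <- extract_tinf_multiples(rec20)
  expect_equal(rows$target_time, c(0.5, 1.5, 3, 5, 10) * 20)
  # multiple = 1 duplicates the anchor and warns
  expect_warning(one <- extract_tinf_multiples(rec, multiples = 1), "leakage")
  expect_equal(one$y, unique(one$cp_tinf))
})

test_that("objectives never duplicate anchors outside the flagged case", {
  cohort <- tiny_cohort(n = 10, seed = 17)
  tab <- virtual_feature_table(cohort$pop, cohort$profiles, cohort$regimen)
  expect_true(all(tab$y != tab$cp_tinf))
  expect_true(all(tab$y != tab$cp_4tinf))
})

test_that("k-fold splits are subject-level, balanced and deterministic", {
  folds <- kfold_split(1:64, k = 5, seed = 8)
  sizes <- sort(vapply(folds, function(f) length(f$test), 1L))
  expect_equal(sizes, c(12, 13, 13, 13, 13))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:64)
  }
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:64)
  expect_identical(kfold_split(1:64, 5, seed = 8), folds)
  # leave-one-subject-out and degenerate k
  loo <- kfold_split(1:6, k = 6, seed = 1)
  expect_true(all(vapply(loo, function(f) length(f$test), 1L) == 1))
  expect_error(kfold_split(1:4, k = 5), "between 2")
})
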